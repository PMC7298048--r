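#' Bundled actionability rule table
#'
#' A small curated snapshot of actionable-feature rules of the kind
#' distributed by clinical knowledge bases: hotspot mutations (e.g.
#' PIK3CA H1047R/E545K, ERBB2 L755S), amplifications (FGFR1, MYC, MDM2),
#' truncating alterations (ATM, ARID1A, CDH1, PIK3R1), deletions (PTEN,
#' INPP4B), expression/protein outliers (AR, CD274, checkpoint kinases,
#' FASN, FAK) and clinical receptor/germline markers. Shipped as a plain
#' TSV so results are insulated from live-database versioning; users can
#' supply their own table in the same schema.
#'
#' @param path Optional path to a rules TSV with columns
#'   `source, gene, class, variant, tier`; default loads the bundled
#'   snapshot.
#' @return A tibble of rules.
#' @export
actionability_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "actionability_rules.tsv",
                                package = "pdxtrial", mustWork = TRUE)
  rules <- readr::read_tsv(path, show_col_types = FALSE, na = character())
  valid <- c("hotspot-mutation", "truncating", "amplification", "deletion",
             "outlier-high", "outlier-low", "receptor-positive", "germline")
  bad <- setdiff(unique(rules$class), valid)
  if (length(bad) > 0) {
    stop_pdx(paste("unknown alteration class:", paste(bad, collapse = ", ")),
             "invalid_rule")
  }
  rules
}

#' Match genomic calls against actionability rules
#'
#' A mutation/CNA call matches a rule when gene and alteration class
#' agree; rules carrying a specific variant (e.g. `H1047R`) additionally
#' require an exact variant-string match. Rows with a missing gene or
#' class are skipped with a warning.
#'
#' @param mutations Tibble of calls: `model_id, gene, alteration, class`.
#' @param rules Rule tibble from [actionability_rules()].
#' @return A tibble of matches: `model_id, gene, class, variant, tier,
#'   source, provenance`.
#' @export
match_genomic <- function(mutations, rules = actionability_rules()) {
  rules <- dplyr::filter(rules, .data$source == "genomic")
  if (is.null(mutations) || nrow(mutations) == 0 || nrow(rules) == 0) {
    return(empty_matches())
  }
  bad <- is.na(mutations$gene) | mutations$gene == "" |
    is.na(mutations$class) | mutations$class == ""
  if (any(bad)) {
    warning(sum(bad), " malformed mutation row(s) skipped")
    mutations <- mutations[!bad, ]
  }
  joined <- dplyr::inner_join(mutations, rules,
                              by = c("gene", "class"),
                              relationship = "many-to-many")
  joined |>
    dplyr::filter(.data$variant == "" | .data$variant == .data$alteration) |>
    dplyr::transmute(
      .data$model_id, .data$gene, .data$class,
      variant = .data$variant, tier = .data$tier, source = .data$source,
      provenance = paste0("genomic:", .data$gene, ":", .data$alteration)
    ) |>
    dplyr::distinct()
}

#' Match expression outlier calls against actionability rules
#'
#' An outlier call matches an `outlier-high` rule when the feature agrees
#' and the flag is set (score strictly above the call threshold);
#' `outlier-low` rules match flagged low outliers (score below the
#' negated threshold) where provided.
#'
#' @param outliers Outlier tibble from [call_outliers()], with a
#'   `model_id`-bearing `sample` column (sample ids are model ids here).
#' @param rules Rule tibble; only `expression`/`protein` sources are
#'   used.
#' @param source Which rule source to match (`"expression"` or
#'   `"protein"`).
#' @return A tibble of matches with provenance.
#' @export
match_expression <- function(outliers, rules = actionability_rules(),
                             source = "expression") {
  rules <- rules[rules$source == source, ]
  if (nrow(outliers) == 0 || nrow(rules) == 0) return(empty_matches())
  high <- rules[rules$class == "outlier-high", ]
  low <- rules[rules$class == "outlier-low", ]
  hits_high <- outliers |>
    dplyr::filter(.data$outlier, .data$score > 0,
                  .data$feature %in% high$gene) |>
    dplyr::left_join(high, by = c(feature = "gene"))
  hits_low <- outliers |>
    dplyr::filter(.data$score < -1.5, .data$feature %in% low$gene) |>
    dplyr::left_join(low, by = c(feature = "gene"))
  dplyr::bind_rows(hits_high, hits_low) |>
    dplyr::transmute(
      model_id = .data$sample, gene = .data$feature, class = .data$class,
      variant = "", tier = .data$tier, source = .data$source,
      provenance = paste0(source, ":", .data$feature, ":score=",
                          signif(.data$score, 4))
    ) |>
    dplyr::distinct()
}

empty_matches <- function() {
  tibble::tibble(model_id = character(), gene = character(),
                 class = character(), variant = character(),
                 tier = character(), source = character(),
                 provenance = character())
}

#' Build the per-model actionability matrix
#'
#' Integrates clinical receptor/germline status, genomic matches,
#' expression/protein outlier matches and in vivo chemosensitivity into
#' one model-by-feature presence matrix with provenance. Duplicate
#' matches collapse (set semantics), so the construction is idempotent
#' and deterministic; a gene matched by several sources keeps one column
#' per source.
#'
#' @param annotations Tibble with `model_id`, `pdx_er`, `pdx_her2`,
#'   `germline_brca` (parsed by [er_positive()]/[her2_positive()];
#'   germline positive when non-empty and not benign/VUS).
#' @param genomic_matches,expression_matches Tibbles from
#'   [match_genomic()] / [match_expression()] (may be empty).
#' @param chemo_classes Optional tibble from
#'   [classify_chemosensitivity()].
#' @return A list of class `actionability_matrix`: `matrix` (wide tibble,
#'   one row per model, logical feature columns plus `chemo_class`) and
#'   `provenance` (long tibble backing every present cell).
#' @export
build_actionability <- function(annotations, genomic_matches = empty_matches(),
                                expression_matches = empty_matches(),
                                chemo_classes = NULL) {
  models <- unique(annotations$model_id)
  all_matches <- dplyr::bind_rows(genomic_matches, expression_matches)
  unknown <- setdiff(unique(all_matches$model_id), models)
  if (length(unknown) > 0) {
    stop_pdx(paste("matches reference models absent from annotations:",
                   paste(unknown, collapse = ", ")), "unknown_model")
  }
  clinical <- annotations |>
    dplyr::transmute(
      .data$model_id,
      `clinical:ER+` = er_positive(.data$pdx_er) %in% TRUE,
      `clinical:HER2+` = her2_positive(.data$pdx_her2) %in% TRUE,
      `clinical:gBRCA` = !is.na(.data$germline_brca) &
        .data$germline_brca != "" &
        !stringr::str_detect(.data$germline_brca, "benign|VUS")
    )
  feature_cells <- all_matches |>
    dplyr::mutate(feature = paste0(.data$source, ":", .data$gene,
                                   ifelse(.data$variant == "", "",
                                          paste0("_", .data$variant)),
                                   "_", .data$class)) |>
    dplyr::distinct(.data$model_id, .data$feature, .keep_all = TRUE)
  wide <- clinical
  if (nrow(feature_cells) > 0) {
    wide <- feature_cells |>
      dplyr::mutate(present = TRUE) |>
      dplyr::select("model_id", "feature", "present") |>
      tidyr::pivot_wider(names_from = "feature", values_from = "present",
                         values_fill = FALSE) |>
      dplyr::right_join(clinical, by = "model_id") |>
      dplyr::mutate(dplyr::across(dplyr::where(is.logical),
                                  ~ tidyr::replace_na(.x, FALSE)))
  }
  if (!is.null(chemo_classes)) {
    wide <- dplyr::left_join(
      wide, dplyr::select(chemo_classes, "model_id", "chemo_class"),
      by = "model_id")
  }
  wide <- dplyr::arrange(wide, .data$model_id)
  wide <- wide[, c("model_id", sort(setdiff(names(wide), "model_id")))]
  provenance <- all_matches |>
    dplyr::arrange(.data$model_id, .data$source, .data$gene, .data$provenance)
  structure(list(matrix = wide, provenance = provenance),
            class = "actionability_matrix")
}

#' @export
print.actionability_matrix <- function(x, ...) {
  cat("<actionability_matrix> ", nrow(x$matrix), " models x ",
      ncol(x$matrix) - 1, " features; ", nrow(x$provenance),
      " provenance records\n", sep = "")
  invisible(x)
}
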
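#' Bundled clinical annotation table
#'
#' Loads the clinicopathologic annotation table shipped with the package:
#' one row per PDX line (37 lines from 36 donor tumors; one tumor gave
#' two sublines), with patient-side and PDX-side histology, ER, HER2 and
#' intrinsic-subtype fields, germline BRCA1/2 status, prior systemic
#' therapy (semicolon-separated drug codes; `*` marks exposure more than
#' a year before sampling), and nodal/distant spread flags. Status
#' strings are preserved as annotated — e.g. ER `"1%"`, HER2
#' `"FISH 2.2"`, and `"- (primary +)"` for a sampled lesion negative for
#' a marker the primary expressed — and interpreted by [er_positive()]
#' and [her2_positive()].
#'
#' @return A tibble with one row per PDX line.
#' @examples
#' head(pdx_annotations())
#' @export
pdx_annotations <- function() {
  path <- system.file("extdata", "table1_annotations.csv",
                      package = "pdxtrial", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  na = character()) # keep "" and "N/A" as strings
}

#' Parse ER / HER2 status strings
#'
#' `er_positive()` treats any nonzero percent (e.g. `"1%"`, `"10%"`) or a
#' plain `"+"` as positive; `"-"` and `"0%"` are negative. A parenthetical
#' primary-status annotation (e.g. `"- (primary +)"`) is ignored: the
#' sampled lesion's status governs. `her2_positive()` treats `"+"` or a
#' FISH ratio >= 2.0 (e.g. `"FISH 2.2"`) as amplified/positive.
#'
#' @param x Character vector of status strings.
#' @return Logical vector (NA where unparseable).
#' @export
er_positive <- function(x) {
  core <- stringr::str_trim(stringr::str_remove(x, "\\s*\\(.*\\)"))
  dplyr::case_when(
    core == "+" ~ TRUE,
    core == "-" ~ FALSE,
    stringr::str_detect(core, "^\\d+(\\.\\d+)?%$") ~
      as.numeric(stringr::str_extract(core, "[0-9.]+")) > 0,
    TRUE ~ NA
  )
}

#' @rdname er_positive
#' @export
her2_positive <- function(x) {
  core <- stringr::str_trim(stringr::str_remove(x, "\\s*\\(.*\\)"))
  dplyr::case_when(
    core == "+" ~ TRUE,
    core == "-" ~ FALSE,
    stringr::str_detect(core, "^FISH\\s*\\d+(\\.\\d+)?$") ~
      as.numeric(stringr::str_extract(core, "[0-9.]+")) >= 2.0,
    TRUE ~ NA
  )
}

#' Engraftment take rate
#'
#' The percentage of engraftment attempts that yielded a serially
#' propagatable xenograft, reported to one decimal (round-half-up, the
#' convention of clinical tables).
#'
#' @param n_success,n_attempts Counts with `n_success <= n_attempts`.
#' @return Take rate in percent.
#' @examples
#' take_rate(36, 81) # 44.4
#' @export
take_rate <- function(n_success, n_attempts) {
  if (n_attempts <= 0) stop_pdx("n_attempts must be positive", "zero_attempts")
  if (n_success < 0 || n_success > n_attempts) {
    stop_pdx("n_success must lie in [0, n_attempts]", "invalid_ledger")
  }
  round_half_up(100 * n_success / n_attempts, 1)
}

#' Patient-PDX receptor concordance
#'
#' Compares binarized ER or HER2 status between each donor tumor and its
#' PDX line(s). Pairs are counted per tumor: a tumor engrafted as several
#' sublines contributes one pair, concordant only if every subline agrees
#' with the patient. Binarization follows [er_positive()] /
#' [her2_positive()]; where the sampled lesion's status differs from the
#' primary's, the sampled lesion governs.
#'
#' @param annotations Annotation tibble in the [pdx_annotations()] schema.
#' @param marker `"ER"` or `"HER2"`.
#' @return A list with `percent` (one decimal) and `discordant`
#'   (tumor ids).
#' @export
receptor_concordance <- function(annotations, marker = c("ER", "HER2")) {
  marker <- match.arg(marker)
  if (marker == "ER") {
    pt <- er_positive(annotations$patient_er)
    px <- er_positive(annotations$pdx_er)
    bad <- annotations$tumor_id[is.na(pt) | is.na(px)]
  } else {
    pt <- her2_positive(annotations$patient_her2)
    px <- her2_positive(annotations$pdx_her2)
    bad <- annotations$tumor_id[is.na(pt) | is.na(px)]
  }
  if (length(bad) > 0) {
    stop_pdx(paste("unparseable", marker, "status for:",
                   paste(unique(bad), collapse = ", ")), "unparseable_status")
  }
  per_tumor <- tibble::tibble(tumor_id = annotations$tumor_id,
                              concordant = pt == px) |>
    dplyr::group_by(.data$tumor_id) |>
    dplyr::summarise(concordant = all(.data$concordant), .groups = "drop")
  list(
    percent = round_half_up(100 * mean(per_tumor$concordant), 1),
    discordant = per_tumor$tumor_id[!per_tumor$concordant]
  )
}

#' Patient-PDX intrinsic subtype concordance
#'
#' Compares intrinsic molecular subtype labels (e.g. Basal, HER2E, LumB,
#' Normal) between patient tumors and PDX lines. Pairs are counted per
#' PDX line (each subline is its own pair) and restricted to pairs whose
#' patient label is available (not `"N/A"`); concordance is exact label
#' equality.
#'
#' @param annotations Annotation tibble in the [pdx_annotations()] schema.
#' @return A list with `percent`, `n_pairs` and `switches` (tibble of
#'   pdx_id, patient and PDX labels for discordant pairs). `percent` is
#'   `NA` when no pair is evaluable.
#' @export
subtype_concordance <- function(annotations) {
  eligible <- annotations |>
    dplyr::filter(!.data$patient_subtype %in% c("N/A", "", NA))
  if (nrow(eligible) == 0) {
    return(list(percent = NA_real_, n_pairs = 0L,
                switches = tibble::tibble(pdx_id = character(),
                                          patient_subtype = character(),
                                          pdx_subtype = character())))
  }
  eligible <- dplyr::mutate(eligible,
                            concordant = .data$patient_subtype == .data$pdx_subtype)
  list(
    percent = round_half_up(100 * mean(eligible$concordant), 1),
    n_pairs = nrow(eligible),
    switches = eligible |>
      dplyr::filter(!.data$concordant) |>
      dplyr::select("pdx_id", "patient_subtype", "pdx_subtype")
  )
}

#' Cohort composition statistics
#'
#' Summarises the PDX library: intrinsic-subtype counts and percentages,
#' the triple-negative fraction (PDX ER-negative and HER2-negative), and
#' the fraction of rare histological variants (any PDX histology other
#' than invasive ductal carcinoma NOS). Denominator is the number of PDX
#' lines.
#'
#' @param annotations Annotation tibble in the [pdx_annotations()] schema.
#' @param common_histology Histology labels counted as non-rare
#'   (default `"IDC-NOS"`).
#' @return A list with `n_pdx`, `subtypes` (tibble: subtype, n, percent),
#'   `tnbc_percent`, `rare_histology_percent`.
#' @export
composition_stats <- function(annotations, common_histology = "IDC-NOS") {
  n <- nrow(annotations)
  subtypes <- annotations |>
    dplyr::count(subtype = .data$pdx_subtype, name = "n") |>
    dplyr::mutate(percent = round_half_up(100 * .data$n / .env$n, 1)) |>
    dplyr::arrange(dplyr::desc(.data$n))
  tnbc <- !er_positive(annotations$pdx_er) & !her2_positive(annotations$pdx_her2)
  rare <- !annotations$pdx_histology %in% common_histology
  list(
    n_pdx = n,
    subtypes = subtypes,
    tnbc_percent = round_half_up(100 * mean(tnbc), 1),
    rare_histology_percent = round_half_up(100 * mean(rare), 1)
  )
}

#' Patient-to-PDX label flow table
#'
#' Contingency counts of patient label to PDX label transitions for a
#' paired annotation field — the data behind a Sankey/alluvial diagram.
#' Pairs with a missing or `"N/A"` label on either side are dropped.
#'
#' @param annotations Annotation tibble.
#' @param patient_col,pdx_col Column names of the patient-side and
#'   PDX-side labels (e.g. `"patient_subtype"`, `"pdx_subtype"`).
#' @return A tibble (patient_label, pdx_label, n); counts sum to the
#'   number of eligible pairs.
#' @export
flow_table <- function(annotations, patient_col, pdx_col) {
  tab <- tibble::tibble(
    patient_label = annotations[[patient_col]],
    pdx_label = annotations[[pdx_col]]
  ) |>
    dplyr::filter(!.data$patient_label %in% c("N/A", "", NA),
                  !.data$pdx_label %in% c("N/A", "", NA)) |>
    dplyr::count(.data$patient_label, .data$pdx_label, name = "n")
  tab
}

#' Prior drug count from a therapy string
#'
#' Counts the number of distinct drug codes in a semicolon-separated
#' prior-therapy annotation; `"None"` and empty strings count 0. The
#' asterisk marking remote (>1 year) exposure is ignored for counting.
#'
#' @param therapy Character vector of therapy strings.
#' @return Integer vector of drug counts.
#' @export
prior_drug_count <- function(therapy) {
  purrr::map_int(therapy, function(s) {
    if (is.na(s) || s == "" || stringr::str_trim(s) == "None") return(0L)
    parts <- stringr::str_trim(stringr::str_split_1(s, ";"))
    length(unique(stringr::str_remove(parts[parts != ""], "\\*$")))
  })
}
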
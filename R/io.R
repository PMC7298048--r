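#' Read and write trial tables
#'
#' Plain-text readers/writers for the file formats used across a PDX
#' trial analysis: the caliper measurements CSV
#' (`model_id,arm,animal_id,day,length_mm,width_mm`), responses TSV,
#' expression TSV (features in rows, header = sample ids) and GMT gene
#' sets. Round-trips are lossless for the numeric precision written.
#'
#' @param path File path.
#' @param measurements,responses Data frames in the respective schemas.
#' @name trial_io
NULL

#' @rdname trial_io
#' @export
read_measurements <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    model_id = readr::col_character(),
                    arm = readr::col_character(),
                    animal_id = readr::col_character(),
                    day = readr::col_double(),
                    length_mm = readr::col_double(),
                    width_mm = readr::col_double()))
}

#' @rdname trial_io
#' @export
write_measurements <- function(measurements, path) {
  readr::write_csv(
    measurements[, c("model_id", "arm", "animal_id", "day",
                     "length_mm", "width_mm")], path)
  invisible(path)
}

#' @rdname trial_io
#' @export
read_responses <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname trial_io
#' @export
write_responses <- function(responses, path) {
  out <- dplyr::mutate(responses, mrecist = as.character(.data$mrecist))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read / write an expression matrix TSV
#'
#' Features in rows (first column `feature`), samples in the remaining
#' columns.
#'
#' @param path File path.
#' @param mat Numeric matrix with feature rownames and sample colnames.
#' @return `read_expression()` returns a numeric matrix.
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression
#' @export
write_expression <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "feature")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read / write GMT gene-set files
#'
#' The standard GMT layout: one set per line, tab-separated
#' `name <tab> description <tab> member...`. Signatures with positive and
#' negative regulatory components are encoded as two entries named
#' `NAME_POS` and `NAME_NEG`; [read_signatures()] pairs them back into
#' signature definitions.
#'
#' @param path File path.
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[lines != ""]
  sets <- purrr::map(lines, function(l) {
    parts <- stringr::str_split_1(l, "\t")
    members <- parts[-(1:2)]
    members[members != ""]
  })
  names(sets) <- purrr::map_chr(lines, ~ stringr::str_split_1(.x, "\t")[1])
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- purrr::imap_chr(sets, function(members, nm) {
    i <- match(nm, names(sets))
    paste(c(nm, descriptions[[i]], members), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname read_gmt
#' @export
read_signatures <- function(path) {
  sets <- read_gmt(path)
  pos_names <- names(sets)[stringr::str_ends(names(sets), "_POS")]
  purrr::map(pos_names, function(pn) {
    base <- stringr::str_remove(pn, "_POS$")
    list(name = base, positive = sets[[pn]],
         negative = sets[[paste0(base, "_NEG")]] %||% character())
  }) |> stats::setNames(stringr::str_remove(pos_names, "_POS$"))
}

#' Write a simulated cohort to a directory
#'
#' Serialises every table of a [simulate_pdx_cohort()] result as plain
#' text: measurements CSV, annotations CSV, patient-responses CSV,
#' mutations TSV, RNA/RPPA expression TSVs and the latent-truth TSV.
#'
#' @param cohort A `pdx_cohort` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_measurements(cohort$measurements, file.path(dir, "measurements.csv"))
  readr::write_csv(cohort$annotations, file.path(dir, "annotations.csv"))
  readr::write_csv(cohort$patient_responses,
                   file.path(dir, "patient_responses.csv"))
  if (!is.null(cohort$mutations) && nrow(cohort$mutations) > 0) {
    readr::write_tsv(cohort$mutations, file.path(dir, "mutations.tsv"))
  }
  write_expression(cohort$rna, file.path(dir, "rna.tsv"))
  write_expression(cohort$rppa, file.path(dir, "rppa.tsv"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
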
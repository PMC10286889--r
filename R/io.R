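# File-level units of cohort CSVs: D, Dstar in 1e-3 mm^2/s, f in percent
# (as conventionally tabulated); internal tables use mm^2/s and fractions.
.csv_scale <- c(D = 1e-3, Dstar = 1e-3, f = 1e-2)
.label_levels <- list(risk = c("low", "intermediate", "high"),
                      tp53 = c("mutant", "wild"))

#' Write / read a 4-D image series as NIfTI with a JSON sidecar
#'
#' The sidecar carries either the b-value schedule (DWI) or the frame
#' timing (DCE) and is cross-validated against the 4th dimension on read.
#'
#' @param stack 4-D numeric array.
#' @param path output NIfTI path (`.nii` or `.nii.gz`); the sidecar is
#'   written next to it with extension `.json`.
#' @param b_values b-value schedule (DWI series), or `NULL`.
#' @param frame_times frame times in seconds (DCE series), or `NULL`.
#' @param extra named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_image_series <- function(stack, path, b_values = NULL,
                               frame_times = NULL, extra = list()) {
  assert_that(length(dim(stack)) == 4, "stack must be 4-D")
  side <- c(list(), extra)
  n4 <- dim(stack)[4]
  if (!is.null(b_values)) {
    assert_that(length(b_values) == n4,
                sprintf("sidecar lists %d b-values but stack has %d volumes",
                        length(b_values), n4))
    side$b_values <- as.numeric(b_values)
  }
  if (!is.null(frame_times)) {
    assert_that(length(frame_times) == n4,
                sprintf("sidecar lists %d frame times but stack has %d volumes",
                        length(frame_times), n4))
    side$frame_times <- as.numeric(frame_times)
  }
  RNifti::writeNifti(stack, path)
  jsonlite::write_json(side, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' @rdname write_image_series
#' @param path_in NIfTI path to read (sidecar looked up next to it).
#' @return `read_image_series`: list with `data` (4-D array), `sidecar`
#'   (list), `image` (the RNifti object, retaining the affine).
#' @export
read_image_series <- function(path_in) {
  img <- RNifti::readNifti(path_in)
  d <- dim(img)
  assert_that(length(d) == 4,
              sprintf("expected a 4-D series, got %d dimension(s)",
                      length(d)))
  sidecar_file <- .sidecar_path(path_in)
  assert_that(file.exists(sidecar_file),
              paste0("missing sidecar: ", sidecar_file))
  side <- jsonlite::read_json(sidecar_file, simplifyVector = TRUE)
  n4 <- d[4]
  if (!is.null(side$b_values)) {
    assert_that(length(side$b_values) == n4,
                sprintf("sidecar lists %d b-values but stack has %d volumes",
                        length(side$b_values), n4))
  }
  if (!is.null(side$frame_times)) {
    assert_that(length(side$frame_times) == n4,
                sprintf("sidecar lists %d frame times but stack has %d volumes",
                        length(side$frame_times), n4))
  }
  list(data = array(as.numeric(img), d), sidecar = side, image = img)
}

#' Write a cohort table to CSV in file-level units
#'
#' @param table a `cohort_table` (internal units).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  out <- as.data.frame(table)
  for (p in names(.csv_scale)) {
    if (p %in% names(out)) out[[p]] <- out[[p]] / .csv_scale[[p]]
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Validates the documented header, converts file-level units (D, D* given
#' in 1e-3 mm^2/s, f in percent) to internal units, enforces the label
#' enumerations (missing TP53 allowed) and the two-readers-per-patient
#' structure. Extra columns are preserved untouched.
#'
#' @param path CSV path.
#' @return A `cohort_table`.
#' @export
read_cohort <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "reader_id", "D", "Dstar", "f", "Ktrans",
                "Ve", "Kep", "risk")
  missing_cols <- setdiff(required, names(tb))
  assert_that(length(missing_cols) == 0,
              paste0("cohort file lacks column(s): ",
                     paste(missing_cols, collapse = ", ")))
  for (lab in names(.label_levels)) {
    if (!lab %in% names(tb)) next
    vals <- tb[[lab]]
    vals[vals == ""] <- NA
    bad <- which(!is.na(vals) & !vals %in% .label_levels[[lab]])
    assert_that(length(bad) == 0,
                sprintf("unknown %s label '%s' in row %d", lab,
                        tb[[lab]][bad[1]], bad[1]))
    tb[[lab]] <- vals
  }
  counts <- base::table(tb$patient_id)
  bad <- names(counts)[counts != 2]
  assert_that(length(bad) == 0,
              paste0("patients without exactly 2 reader rows: ",
                     paste(utils::head(bad, 5), collapse = ", ")))
  for (p in names(.csv_scale)) tb[[p]] <- tb[[p]] * .csv_scale[[p]]
  class(tb) <- c("cohort_table", "data.frame")
  tb
}

#' Write an enrollment roster to CSV
#' @param roster a roster data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  utils::write.csv(roster, path, row.names = FALSE)
  invisible(path)
}
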
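#' Generate a 4-D voxel phantom with known ground truth
#'
#' Builds paired DWI and DCE stacks from a labelled 3-D layout of tissue
#' regions. Every voxel of a region carries the region's ground-truth IVIM
#' and Tofts parameters; Rician noise is added at the requested SNR
#' (`snr = Inf` for noiseless data).
#'
#' @param layout integer 3-D array of region labels; 0 = background
#'   (excluded from the mask).
#' @param regions named list mapping each nonzero label (as character) to a
#'   [tissue_truth()].
#' @param protocol an [acquisition_protocol()].
#' @param aif an `aif` object driving the DCE simulation (defaults to the
#'   bi-exponential population AIF of the protocol).
#' @param snr signal-to-noise ratio for Rician noise; `Inf` disables noise.
#' @param seed integer seed.
#' @param r1 relaxivity passed to [concentration_to_spgr_signal()].
#' @param s0 unweighted DWI signal scale for all regions.
#' @return A list with elements `dwi` (x,y,z,b array), `dce` (x,y,z,t array),
#'   `mask` (logical 3-D), `truth` (list of 3-D maps per parameter:
#'   D, Dstar, f, Ktrans, Ve, Kep, t10), `aif`, and `protocol`.
#' @export
generate_voxel_phantom <- function(layout, regions, protocol,
                                   aif = simulate_aif(protocol),
                                   snr = Inf, seed = NULL, r1 = 4.5,
                                   s0 = 1000) {
  assert_that(is.array(layout) && length(dim(layout)) == 3,
              "layout must be a 3-D array of region labels")
  labels <- sort(unique(as.integer(layout[layout != 0])))
  assert_that(length(labels) > 0, "layout must contain at least one region")
  assert_that(all(as.character(labels) %in% names(regions)),
              "every nonzero layout label needs an entry in regions")
  stopifnot(inherits(protocol, "acquisition_protocol"), inherits(aif, "aif"))

  dims <- dim(layout)
  nb <- length(protocol$b_values)
  nt <- protocol$n_phases
  dwi <- array(0, c(dims, nb))
  dce <- array(0, c(dims, nt))
  par_names <- c("D", "Dstar", "f", "Ktrans", "Ve", "Kep", "t10")
  truth <- lapply(par_names, function(p) array(NA_real_, dims))
  names(truth) <- par_names

  for (lab in labels) {
    tt <- regions[[as.character(lab)]]
    stopifnot(inherits(tt, "tissue_truth"))
    idx <- which(layout == lab)
    iv <- tt$ivim
    iv$S0 <- s0
    sig_dwi <- simulate_ivim_signal(iv, protocol)$signal
    conc <- simulate_tofts_concentration(tt$pk, aif)
    sig_dce <- concentration_to_spgr_signal(conc, tt, protocol, r1 = r1)$signal
    nvox <- length(idx)
    vox_off <- prod(dims)
    for (k in seq_len(nb)) dwi[idx + (k - 1) * vox_off] <- sig_dwi[k]
    for (k in seq_len(nt)) dce[idx + (k - 1) * vox_off] <- sig_dce[k]
    truth$D[idx] <- iv$D; truth$Dstar[idx] <- iv$Dstar; truth$f[idx] <- iv$f
    truth$Ktrans[idx] <- tt$pk$Ktrans; truth$Ve[idx] <- tt$pk$Ve
    truth$Kep[idx] <- tt$pk$Kep; truth$t10[idx] <- tt$t10
  }

  mask <- layout != 0
  if (is.finite(snr)) {
    assert_that(snr > 0, "snr must be > 0")
    with_seed(seed, {
      sigma_dwi <- s0 / snr
      dwi <- sqrt((dwi + stats::rnorm(length(dwi), 0, sigma_dwi))^2 +
                    stats::rnorm(length(dwi), 0, sigma_dwi)^2)
      # DCE noise scaled to the mean baseline signal of the masked voxels
      base <- mean(dce[, , , seq_len(protocol$n_baseline), drop = FALSE][mask])
      sigma_dce <- base / snr
      dce <- sqrt((dce + stats::rnorm(length(dce), 0, sigma_dce))^2 +
                    stats::rnorm(length(dce), 0, sigma_dce)^2)
    })
  }
  list(dwi = dwi, dce = dce, mask = mask, truth = truth, aif = aif,
       protocol = protocol)
}

#' Build an enrollment roster with per-reason exclusion flags
#'
#' Creates `n_total` candidate records and assigns each exclusion reason to
#' exactly the requested number of distinct records (reasons never overlap,
#' so the enrolled count is `n_total - sum(counts)`).
#'
#' @param counts named integer vector of exclusion-reason counts. The
#'   default reproduces the study's screening log: 7 non-carcinoma
#'   diagnoses, 16 FIGO stage II or higher, 4 prior radio/chemotherapy,
#'   3 incomplete sequences, 6 inadequate image quality, 4 treated
#'   elsewhere, out of 114 screened.
#' @param n_total number of screened candidates (default 114).
#' @param seed integer seed controlling which records carry which flag.
#' @return A data frame (`roster`) with `candidate_id` and one logical
#'   column per exclusion reason.
#' @export
generate_enrollment_roster <- function(counts = c(non_ec_diagnosis = 7,
                                                  figo_ii_or_higher = 16,
                                                  prior_treatment = 4,
                                                  incomplete_sequences = 3,
                                                  inadequate_quality = 6,
                                                  treated_elsewhere = 4),
                                       n_total = 114, seed = NULL) {
  assert_that(is.numeric(counts) && all(counts >= 0),
              "counts must be non-negative")
  assert_that(!is.null(names(counts)) && all(nzchar(names(counts))),
              "counts must be named by exclusion reason")
  assert_that(sum(counts) <= n_total,
              "sum of exclusion counts exceeds n_total")
  roster <- data.frame(candidate_id = sprintf("C%03d", seq_len(n_total)))
  flagged <- with_seed(seed, sample.int(n_total, sum(counts)))
  at <- 0
  for (reason in names(counts)) {
    col <- rep(FALSE, n_total)
    k <- counts[[reason]]
    if (k > 0) col[flagged[at + seq_len(k)]] <- TRUE
    at <- at + k
    roster[[reason]] <- col
  }
  class(roster) <- c("enrollment_roster", "data.frame")
  roster
}

#' Apply the eligibility filter to a roster
#'
#' A candidate is enrolled when no exclusion flag is set.
#'
#' @param roster a roster from [generate_enrollment_roster()].
#' @return A list with `enrolled_ids`, `n_enrolled`, `n_excluded`, and the
#'   per-reason tally `excluded_by_reason` (a record with several flags
#'   counts once in `n_excluded` but in each reason's tally).
#' @export
apply_eligibility_filter <- function(roster) {
  assert_that(is.data.frame(roster) && "candidate_id" %in% names(roster),
              "roster must contain a candidate_id column")
  flag_cols <- names(roster)[vapply(roster, is.logical, logical(1))]
  flags <- as.matrix(roster[flag_cols])
  excluded <- if (length(flag_cols)) rowSums(flags) > 0 else
    rep(FALSE, nrow(roster))
  list(enrolled_ids = roster$candidate_id[!excluded],
       n_enrolled = sum(!excluded),
       n_excluded = sum(excluded),
       excluded_by_reason = if (length(flag_cols)) colSums(flags) else
         integer(0))
}
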
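#' Load and validate a pipeline run configuration
#'
#' Reads a YAML configuration, fills defaults and validates referenced
#' paths. All fields are optional; the defaults describe a small fully
#' synthetic end-to-end run.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list merged over the file contents.
#' @return A `run_config` list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    assert_that(file.exists(path), paste0("config file not found: ", path))
    cfg <- yaml::read_yaml(path)
  }
  cfg <- utils::modifyList(cfg, overrides)
  defaults <- list(
    seed = 123,
    stages = c("roster", "phantom", "ivim", "dce", "cohort", "analyze"),
    phantom = list(shape = c(8, 8, 2), snr = 50, s0 = 1000,
                   t10 = 1400, r1 = 4.5),
    cohort = list(stratification = "risk", reader_sd = 0.42,
                  csv = NULL),
    fit = list(ivim_method = "segmented", b_threshold = 200),
    stats = list(entry_p = 0.1, n_boot = 1000)
  )
  cfg <- utils::modifyList(defaults, cfg)
  if (!is.null(cfg$cohort$csv)) {
    assert_that(file.exists(cfg$cohort$csv),
                paste0("cohort csv not found: ", cfg$cohort$csv))
  }
  if ("analyze" %in% cfg$stages && !"cohort" %in% cfg$stages &&
      is.null(cfg$cohort$csv)) {
    stop_invalid("configuration error: stage 'analyze' requires either ",
                 "the 'cohort' stage or cohort$csv")
  }
  class(cfg) <- "run_config"
  cfg
}

# Stable hash of an R object via its canonical JSON rendering.
.config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the configured synthetic pipeline end to end
#'
#' Executes the configured stages in order — enrollment roster, voxel
#' phantom generation, IVIM and Tofts map fitting with VOI aggregation,
#' cohort generation (or loading), and the full statistical analysis —
#' writing every artifact plus a manifest (inputs, outputs, md5 hashes,
#' seed, config hash) into `out_dir`. Runs are idempotent for a fixed
#' seed: re-running a configuration reproduces identical artifacts.
#'
#' @param config a `run_config` from [load_run_config()].
#' @param out_dir output directory (created if needed).
#' @return The manifest (list), invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  manifest <- list(seed = seed, config = unclass(config),
                   config_hash = .config_hash(unclass(config)),
                   stages = list(), outputs = character(0))
  written <- character(0)
  emit <- function(p) written <<- c(written, p)
  protocol <- acquisition_protocol()

  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) e)
    ok <- !inherits(res, "error")
    manifest$stages[[name]] <<- list(
      status = if (ok) "ok" else "failed",
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      error = if (ok) NULL else conditionMessage(res))
    if (!ok) {
      .write_manifest(manifest, written, out_dir)
      stop_invalid("stage '", name, "' failed: ", conditionMessage(res))
    }
    res
  }

  if ("roster" %in% config$stages) {
    run_stage("roster", {
      roster <- generate_enrollment_roster(seed = seed)
      flt <- apply_eligibility_filter(roster)
      write_roster(roster, file.path(out_dir, "roster.csv"))
      emit(file.path(out_dir, "roster.csv"))
      jsonlite::write_json(
        list(n_screened = nrow(roster), n_excluded = flt$n_excluded,
             n_enrolled = flt$n_enrolled,
             excluded_by_reason = as.list(flt$excluded_by_reason)),
        file.path(out_dir, "enrollment.json"), auto_unbox = TRUE)
      emit(file.path(out_dir, "enrollment.json"))
    })
  }

  phantom <- NULL
  if ("phantom" %in% config$stages) {
    phantom <- run_stage("phantom", {
      shp <- config$phantom$shape
      layout <- array(1L, shp)
      layout[seq_len(max(1, floor(shp[1] / 2))), , ] <- 2L
      regions <- list(
        "1" = tissue_truth(ivim_params(D = 0.86e-3, Dstar = 44.35e-3,
                                       f = 0.0243),
                           pk_params(Ktrans = 0.61, Ve = 0.58),
                           t10 = config$phantom$t10),
        "2" = tissue_truth(ivim_params(D = 0.58e-3, Dstar = 55.25e-3,
                                       f = 0.0171),
                           pk_params(Ktrans = 0.37, Ve = 0.32),
                           t10 = config$phantom$t10))
      ph <- generate_voxel_phantom(layout, regions, protocol,
                                   snr = config$phantom$snr, seed = seed,
                                   r1 = config$phantom$r1,
                                   s0 = config$phantom$s0)
      write_image_series(ph$dwi, file.path(out_dir, "dwi.nii"),
                         b_values = protocol$b_values)
      write_image_series(ph$dce, file.path(out_dir, "dce.nii"),
                         frame_times = dce_times(protocol))
      emit(file.path(out_dir, "dwi.nii"))
      emit(file.path(out_dir, "dwi.json"))
      emit(file.path(out_dir, "dce.nii"))
      emit(file.path(out_dir, "dce.json"))
      ph
    })
  }

  if ("ivim" %in% config$stages) {
    run_stage("ivim", {
      assert_that(!is.null(phantom), "ivim stage requires the phantom stage")
      maps <- fit_ivim_map(phantom$dwi, phantom$mask, protocol,
                           method = config$fit$ivim_method)
      for (p in c("D", "Dstar", "f")) {
        RNifti::writeNifti(maps[[p]],
                           file.path(out_dir, paste0("ivim_", p, ".nii")))
        emit(file.path(out_dir, paste0("ivim_", p, ".nii")))
      }
      voi <- lapply(maps[c("D", "Dstar", "f")], aggregate_voi,
                    roi = phantom$mask)
      jsonlite::write_json(
        list(method = config$fit$ivim_method, voi_mean = voi,
             n_converged = sum(maps$quality)),
        file.path(out_dir, "ivim_report.json"), auto_unbox = TRUE,
        digits = NA)
      emit(file.path(out_dir, "ivim_report.json"))
    })
  }

  if ("dce" %in% config$stages) {
    run_stage("dce", {
      assert_that(!is.null(phantom), "dce stage requires the phantom stage")
      maps <- fit_tofts_map(phantom$dce, phantom$mask, phantom$aif,
                            protocol, t10 = config$phantom$t10,
                            r1 = config$phantom$r1)
      for (p in c("Ktrans", "Ve", "Kep")) {
        RNifti::writeNifti(maps[[p]],
                           file.path(out_dir, paste0("dce_", p, ".nii")))
        emit(file.path(out_dir, paste0("dce_", p, ".nii")))
      }
      voi <- lapply(maps[c("Ktrans", "Ve", "Kep")], aggregate_voi,
                    roi = phantom$mask)
      jsonlite::write_json(
        list(aif = "biexponential population", voi_mean = voi,
             n_converged = sum(maps$quality)),
        file.path(out_dir, "dce_report.json"), auto_unbox = TRUE,
        digits = NA)
      emit(file.path(out_dir, "dce_report.json"))
    })
  }

  cohort <- NULL
  if ("cohort" %in% config$stages) {
    cohort <- run_stage("cohort", {
      spec <- default_cohort_spec(config$cohort$stratification)
      tb <- generate_cohort(spec, reader_sd = config$cohort$reader_sd,
                            seed = seed)
      write_cohort(tb, file.path(out_dir, "cohort.csv"))
      emit(file.path(out_dir, "cohort.csv"))
      tb
    })
  } else if (!is.null(config$cohort$csv)) {
    cohort <- run_stage("cohort_load", read_cohort(config$cohort$csv))
  }

  if ("analyze" %in% config$stages) {
    run_stage("analyze", {
      report <- run_full_analysis(cohort, entry_p = config$stats$entry_p,
                                  n_boot = config$stats$n_boot,
                                  seed = seed)
      written <<- c(written, write_analysis_report(report, out_dir))
    })
  }

  .write_manifest(manifest, written, out_dir)
}

.write_manifest <- function(manifest, written, out_dir) {
  manifest$outputs <- lapply(written, function(p) {
    list(path = basename(p), md5 = unname(tools::md5sum(p)))
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(manifest)
}

#' Write an analysis report as flat CSV/JSON artifacts
#'
#' @param report an `analysis_report` from [run_full_analysis()].
#' @param out_dir output directory.
#' @return character vector of written paths.
#' @export
write_analysis_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(p) { paths <<- c(paths, p); p }

  agr <- do.call(rbind, lapply(names(report$agreement), function(p) {
    ic <- report$agreement[[p]]
    data.frame(parameter = p, icc = ic$icc, ci_low = ic$ci_low,
               ci_high = ic$ci_high, category = ic$category)
  }))
  utils::write.csv(agr, put(file.path(out_dir, "agreement.csv")),
                   row.names = FALSE)

  gt <- do.call(rbind, lapply(names(report$group_tests), function(oc) {
    do.call(rbind, lapply(report$group_tests[[oc]], function(g) {
      data.frame(outcome = oc, parameter = g$parameter, test = g$test,
                 statistic = g$statistic, p_value = g$p_value,
                 summary_1 = g$summaries[1], summary_2 = g$summaries[2],
                 groups = paste(g$groups, collapse = " vs "))
    }))
  }))
  utils::write.csv(gt, put(file.path(out_dir, "group_tests.csv")),
                   row.names = FALSE)

  lg <- do.call(rbind, lapply(names(report$models), function(oc) {
    cbind(outcome = oc, report$models[[oc]]$predictors)
  }))
  utils::write.csv(lg, put(file.path(out_dir, "logistic.csv")),
                   row.names = FALSE)

  rc <- do.call(rbind, lapply(names(report$roc), function(oc) {
    do.call(rbind, lapply(names(report$roc[[oc]]), function(p) {
      r <- report$roc[[oc]][[p]]
      data.frame(outcome = oc, score = p, auc = r$auc, ci_low = r$ci_low,
                 ci_high = r$ci_high, cutoff = r$cutoff,
                 sensitivity = r$sensitivity, specificity = r$specificity,
                 orientation = r$orientation %||% "higher")
    }))
  }))
  utils::write.csv(rc, put(file.path(out_dir, "roc.csv")),
                   row.names = FALSE)

  val <- lapply(report$validation, function(v) {
    list(n_boot = v$n_boot, seed = v$seed, bound = v$bound,
         auc_mean = v$auc_mean, auc_ci = v$auc_ci,
         apparent_auc = v$apparent_auc,
         selection_frequency = as.list(v$selection_frequency))
  })
  jsonlite::write_json(val, put(file.path(out_dir, "validation.json")),
                       auto_unbox = TRUE, digits = NA)

  cal <- do.call(rbind, lapply(names(report$calibration), function(oc) {
    cc <- report$calibration[[oc]]
    cbind(outcome = oc, cc$bins, intercept = cc$intercept,
          slope = cc$slope)
  }))
  utils::write.csv(cal, put(file.path(out_dir, "calibration.csv")),
                   row.names = FALSE)

  dca <- do.call(rbind, lapply(names(report$dca), function(oc) {
    cbind(outcome = oc, as.data.frame(report$dca[[oc]]))
  }))
  utils::write.csv(dca, put(file.path(out_dir, "dca.csv")),
                   row.names = FALSE)
  paths
}
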
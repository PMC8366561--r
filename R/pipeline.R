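#' Pipeline run configuration
#'
#' Bundles every tunable of a full run: filtration bank, statistics
#' settings, the per-patient lesion limit, the FDR level of the univariate
#' screen, the Cox entry threshold and tie handling, endpoints, and the
#' seed. The configuration is serialized (with a hash) into every output so
#' runs are reproducible and self-describing.
#'
#' @param filter a [filter_config()].
#' @param stats a [stat_config()].
#' @param lesion_limit most avid lesions averaged per patient (default 5).
#' @param q FDR level of the BH correction (default 0.30).
#' @param entry_p Cox forward-selection entry threshold (default 0.05).
#' @param ties Cox tie handling.
#' @param endpoints subset of `c("pfs", "os")`.
#' @param seed integer seed for any simulation stage.
#' @return Object of class `texhist_run_config`.
#' @export
run_config <- function(filter = filter_config(), stats = stat_config(),
                       lesion_limit = 5L, q = 0.30, entry_p = 0.05,
                       ties = c("breslow", "efron"),
                       endpoints = c("pfs", "os"), seed = 1L) {
  ties <- match.arg(ties)
  stopifnot(inherits(filter, "texhist_filter_config"),
            inherits(stats, "texhist_stat_config"),
            lesion_limit >= 1, q > 0, q < 1, entry_p > 0, entry_p < 1,
            all(endpoints %in% c("pfs", "os")), length(endpoints) >= 1)
  structure(list(filter = filter, stats = stats,
                 lesion_limit = as.integer(lesion_limit), q = q,
                 entry_p = entry_p, ties = ties, endpoints = endpoints,
                 seed = as.integer(seed)),
            class = "texhist_run_config")
}

# recursively strip S3 classes so configs serialize as plain JSON objects
as_plain <- function(x) if (is.list(x)) lapply(unclass(x), as_plain) else x

config_hash <- function(config) {
  ser <- jsonlite::toJSON(as_plain(config), auto_unbox = TRUE, digits = NA,
                          force = TRUE)
  f <- tempfile(); on.exit(unlink(f))
  writeLines(as.character(ser), f)
  unname(tools::md5sum(f))
}

#' Extract features for every lesion of a cohort
#'
#' Accepts either a `texhist_cohort` (in-memory lesions or a written
#' directory) or a manifest CSV path; lesions on disk are read back through
#' [read_lesion()].
#'
#' @param cohort a `texhist_cohort` or a manifest CSV path.
#' @param fconfig,sconfig filtration and statistics configuration.
#' @return Lesion-level feature data.frame (see [feature_table()]) with the
#'   manifest attached as attribute `manifest`.
#' @export
extract_cohort_features <- function(cohort, fconfig = filter_config(),
                                    sconfig = stat_config()) {
  if (is.character(cohort)) {
    manifest <- read_manifest(cohort)
    lesions <- NULL
  } else {
    stopifnot(inherits(cohort, "texhist_cohort"))
    manifest <- cohort$manifest
    lesions <- cohort$lesions
    if (is.null(lesions) && !is.null(cohort$dir)) {
      manifest <- read_manifest(file.path(cohort$dir, "manifest.csv"))
    }
  }
  feats <- vector("list", nrow(manifest))
  seen <- integer(0)  # per-patient running lesion index for in-memory cohorts
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    les <- if (!is.null(lesions)) {
      pid <- row$patient_id
      seen[pid] <- if (is.na(seen[pid])) 1L else seen[pid] + 1L
      lesions[[pid]][[seen[pid]]]
    } else {
      read_lesion(row$ct_path, row$ct_mask_path, row$pet_path,
                  row$pet_mask_path,
                  lesion_id = row$lesion_id, patient_id = row$patient_id)
    }
    feats[[i]] <- extract_features(les, fconfig, sconfig)
  }
  out <- feature_table(feats)
  attr(out, "manifest") <- manifest
  out
}

default_marker_set <- function(tbl) {
  feat <- attr(tbl, "feature_columns")
  covars <- attr(tbl, "covariates")
  c(feat, covars)
}

#' Run the full prognostic pipeline
#'
#' Simulate (or load) a cohort, extract filtration-histogram features,
#' aggregate to patient level, run the univariate median-split screen with
#' BH correction per endpoint, and feed the BH-significant markers into
#' stepwise forward-Wald Cox selection. When `outdir` is given, writes
#' `features.csv`, per-endpoint `screen_<ep>.csv`, `km_<ep>.csv` (curve
#' data of the significant markers), `cox_<ep>.csv`, `skipped_<ep>.csv`,
#' and `run_metadata.json` (config, its hash, package version).
#'
#' @param cohort a `texhist_cohort`, or a manifest CSV path, or `NULL` to
#'   simulate `sim_cohort_spec` / `sim_phantom_spec` under `config$seed`.
#' @param config a [run_config()].
#' @param outdir optional output directory.
#' @param markers marker columns to screen; default: every extracted
#'   feature plus the manifest's clinical covariates.
#' @param sim_cohort_spec,sim_phantom_spec specs used when `cohort` is NULL.
#' @return List of class `texhist_run`: `table` (patient-level analysis
#'   table), `screens`, `cox` (per endpoint), `config`, `outdir`.
#' @export
run_pipeline <- function(cohort = NULL, config = run_config(), outdir = NULL,
                         markers = NULL,
                         sim_cohort_spec = cohort_spec(),
                         sim_phantom_spec = phantom_spec()) {
  stopifnot(inherits(config, "texhist_run_config"))
  if (is.null(cohort))
    cohort <- simulate_cohort(sim_cohort_spec, sim_phantom_spec,
                              seed = config$seed)
  lf <- extract_cohort_features(cohort, config$filter, config$stats)
  manifest <- attr(lf, "manifest")
  tbl <- build_analysis_table(manifest, lf, lesion_limit = config$lesion_limit)
  if (is.null(markers)) markers <- default_marker_set(tbl)
  ep_events <- vapply(config$endpoints,
                      function(ep) sum(tbl[[paste0(ep, "_event")]]), 0)
  if (any(ep_events < 1)) stop("endpoint with no events: ",
                               paste(config$endpoints[ep_events < 1],
                                     collapse = ", "))
  screens <- list(); cox <- list()
  for (ep in config$endpoints) {
    sc <- run_univariate_screen(tbl, ep, markers, q = config$q)
    screens[[ep]] <- sc
    sig <- sc$results$marker[sc$results$significant]
    cox[[ep]] <- if (length(sig)) {
      cand <- as.data.frame(lapply(sig, function(mk) {
        as.integer(dichotomize_at_median(tbl[[mk]])$group == "above")
      }), col.names = sig, check.names = FALSE)
      forward_wald_select(cand, tbl[[paste0(ep, "_months")]],
                          tbl[[paste0(ep, "_event")]],
                          entry_p = config$entry_p, ties = config$ties)
    } else {
      structure(list(model = NULL, selected = character(0), trace = NULL),
                class = "texhist_cox_selection")
    }
  }
  run <- structure(list(table = tbl, screens = screens, cox = cox,
                        config = config, outdir = outdir),
                   class = "texhist_run")
  if (!is.null(outdir)) write_run_outputs(run, lf, outdir)
  run
}

write_run_outputs <- function(run, lesion_features, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(config = as_plain(run$config),
               config_hash = config_hash(run$config),
               package_version = as.character(utils::packageVersion("texhist")))
  write_csv_meta <- function(df, path) {
    con <- file(path, "w")
    writeLines(sprintf("# texhist %s config %s", meta$package_version,
                       meta$config_hash), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  write_csv_meta(lesion_features, file.path(outdir, "features.csv"))
  write_csv_meta(run$table, file.path(outdir, "analysis_table.csv"))
  for (ep in names(run$screens)) {
    sc <- run$screens[[ep]]
    write_csv_meta(sc$results, file.path(outdir, sprintf("screen_%s.csv", ep)))
    if (nrow(sc$skipped))
      write_csv_meta(sc$skipped, file.path(outdir, sprintf("skipped_%s.csv", ep)))
    sig <- sc$results$marker[sc$results$significant]
    if (length(sig)) {
      km_rows <- do.call(rbind, lapply(sig, function(mk) {
        do.call(rbind, lapply(c("below", "above"), function(side) {
          km <- sc$curves[[mk]][[side]]
          data.frame(marker = mk, group = side, time = km$time,
                     surv = km$surv, n_risk = km$n_risk, n_event = km$n_event)
        }))
      }))
      write_csv_meta(km_rows, file.path(outdir, sprintf("km_%s.csv", ep)))
    }
    cx <- run$cox[[ep]]
    if (!is.null(cx$model))
      write_csv_meta(as.data.frame(cx$model),
                     file.path(outdir, sprintf("cox_%s.csv", ep)))
  }
  jsonlite::write_json(meta, file.path(outdir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  validation <- attr(run$table, "validation")
  jsonlite::write_json(validation, file.path(outdir, "validation_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.texhist_run <- function(x, ...) {
  cat(sprintf("<texhist_run> %d patients, endpoints: %s\n",
              nrow(x$table), paste(names(x$screens), collapse = ", ")))
  for (ep in names(x$screens)) {
    cat("\n==", toupper(ep), "==\n")
    print(x$screens[[ep]])
    print(x$cox[[ep]])
  }
  invisible(x)
}
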
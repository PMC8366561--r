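#' Average lesion feature vectors to patient level
#'
#' Per-feature arithmetic mean over the lesions in which the feature is
#' non-missing; a feature is missing at patient level only when missing in
#' every lesion. The uptake area follows the same mean rule. Alternative
#' aggregators (e.g. cumulative assessment) can be supplied via `fun`, but
#' only the mean ships as a default.
#'
#' @param feature_list list of 1-5 `texhist_features` of one patient.
#' @param fun aggregator applied to the non-missing values of each feature
#'   (default [mean()]).
#' @return A `texhist_features` vector with `lesion_id = "aggregate"`.
#' @export
aggregate_patient <- function(feature_list, fun = mean) {
  if (length(feature_list) == 0L) stop("empty feature list")
  mat <- do.call(rbind, lapply(feature_list, unclass))
  agg <- apply(mat, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else fun(v)
  })
  structure(agg, class = "texhist_features",
            patient_id = attr(feature_list[[1]], "patient_id"),
            lesion_id = "aggregate")
}

#' Assemble the patient-level analysis table
#'
#' Joins aggregated imaging features with survival outcomes and clinical
#' covariates from the manifest. Within each patient, lesions are ranked by
#' their in-mask PET maximum (`suv_max`) and only the top `lesion_limit`
#' most avid lesions enter the average. Rows are ordered by `patient_id`.
#'
#' @param manifest data.frame from [read_manifest()] (or of the same shape).
#' @param lesion_features data.frame from [feature_table()], one row per
#'   lesion, keyed by `patient_id` + `lesion_id`.
#' @param lesion_limit maximum lesions averaged per patient (default 5).
#' @return data.frame, one row per patient: `patient_id`, survival columns,
#'   clinical covariates, then aggregated feature columns; attribute
#'   `validation` lists per-patient lesion counts and any lesions dropped by
#'   the avidity limit.
#' @export
build_analysis_table <- function(manifest, lesion_features, lesion_limit = 5L) {
  stopifnot(is.data.frame(manifest), is.data.frame(lesion_features))
  ids <- unique(manifest$patient_id)
  surv_cols <- c("pfs_months", "pfs_event", "os_months", "os_event")
  covars <- attr(manifest, "covariates")
  if (is.null(covars))
    covars <- setdiff(names(manifest),
                      c("patient_id", "lesion_id", "ct_path", "ct_mask_path",
                        "pet_path", "pet_mask_path", surv_cols))
  per_patient <- manifest[!duplicated(manifest$patient_id),
                          c("patient_id", surv_cols, covars), drop = FALSE]
  # survival/covariate fields must be constant within patient
  for (col in c(surv_cols, covars)) {
    if (any(tapply(manifest[[col]], manifest$patient_id,
                   function(v) length(unique(v))) > 1L))
      stop("column ", col, " varies within a patient")
  }
  dup <- names(which(table(per_patient$patient_id) > 1L))
  if (length(dup)) stop("duplicate patient id(s): ", paste(dup, collapse = ", "))

  feat_cols <- setdiff(names(lesion_features), c("patient_id", "lesion_id"))
  validation <- list()
  rows <- lapply(ids, function(pid) {
    lf <- lesion_features[lesion_features$patient_id == pid, , drop = FALSE]
    if (nrow(lf) == 0L) stop("patient ", pid, " has no extracted lesions")
    keep <- order(-lf$suv_max)[seq_len(min(lesion_limit, nrow(lf)))]
    dropped <- lf$lesion_id[-keep]
    validation[[pid]] <<- list(n_lesions = nrow(lf),
                               n_used = length(keep),
                               dropped = as.character(dropped))
    fv <- lapply(keep, function(i) {
      structure(as.numeric(lf[i, feat_cols]), names = feat_cols,
                class = "texhist_features", patient_id = pid,
                lesion_id = lf$lesion_id[i])
    })
    as.data.frame(t(unclass(aggregate_patient(fv))), check.names = FALSE)
  })
  feats <- do.call(rbind, rows)
  out <- cbind(per_patient[match(ids, per_patient$patient_id), , drop = FALSE],
               feats)
  out <- out[order(out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "validation") <- validation
  attr(out, "feature_columns") <- feat_cols
  attr(out, "covariates") <- covars
  out
}
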
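#' Histogram-statistics configuration
#'
#' Settings for the six first-order statistics computed within the ROI.
#' Entropy uses `entropy_bins` equal-width bins spanning the observed
#' \[min, max\] of the ROI values, in bits (log base 2). Kurtosis defaults to
#' the excess convention (normal distribution -> 0); `"pearson"` reports the
#' raw fourth standardized moment. All moments are population (1/n) moments,
#' classical texture-analysis practice. For CT, ROI pixels whose unfiltered
#' value is below `hu_exclusion` HU (air, gas) are excluded, and that same
#' eligibility set is reused on every filtered map of the lesion.
#'
#' @param entropy_bins number of histogram bins (default 64, >= 2).
#' @param kurtosis_convention `"excess"` (default) or `"pearson"`.
#' @param hu_exclusion HU threshold below which CT ROI pixels are excluded
#'   (default -50).
#' @return An object of class `texhist_stat_config`.
#' @export
stat_config <- function(entropy_bins = 64L,
                        kurtosis_convention = c("excess", "pearson"),
                        hu_exclusion = -50) {
  kurtosis_convention <- match.arg(kurtosis_convention)
  entropy_bins <- as.integer(entropy_bins)
  if (entropy_bins < 2L) stop("entropy_bins must be >= 2")
  structure(list(entropy_bins = entropy_bins,
                 kurtosis_convention = kurtosis_convention,
                 hu_exclusion = hu_exclusion),
            class = "texhist_stat_config")
}

#' Indices of ROI pixels eligible for statistics
#'
#' For CT, keeps ROI pixels whose unfiltered HU is at or above the exclusion
#' threshold; eligibility is decided on the unfiltered slice and the same
#' pixel set is then summarized at every filter scale. For PET all ROI
#' pixels are eligible.
#'
#' @param slice the unfiltered `texhist_slice`.
#' @param mask a `texhist_mask` congruent with the slice.
#' @param config a [stat_config()].
#' @return Integer vector of eligible pixel indices into the slice matrix.
#' @export
eligible_pixels <- function(slice, mask, config = stat_config()) {
  stopifnot(inherits(slice, "texhist_slice"), inherits(mask, "texhist_mask"))
  idx <- which(mask$mask)
  if (slice$modality == "CT")
    idx <- idx[slice$pixels[idx] >= config$hu_exclusion]
  if (length(idx) == 0L)
    stop("no eligible pixels in ROI after HU exclusion")
  idx
}

stat_names <- c("mean", "sd", "entropy", "mpp", "skewness", "kurtosis")

#' Six first-order histogram statistics
#'
#' Computes mean gray-level intensity, standard deviation (population),
#' entropy (bits, over equal-width bins spanning the observed range), mean
#' of positive pixels (MPP; `NA` when no value is strictly positive),
#' skewness (population third standardized moment) and kurtosis (population
#' fourth standardized moment, minus 3 under the excess convention).
#' Skewness and kurtosis are `NA` when the SD is zero; a single-valued input
#' has entropy 0.
#'
#' @param values numeric vector of (filtered) intensities, length >= 1.
#' @param config a [stat_config()].
#' @return Named numeric vector `mean`, `sd`, `entropy`, `mpp`, `skewness`,
#'   `kurtosis` (`NA` marks a missing statistic).
#' @export
histogram_stats <- function(values, config = stat_config()) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty value set")
  if (any(!is.finite(values))) stop("non-finite values")
  n <- length(values)
  mu <- mean(values)
  sd_pop <- sqrt(sum((values - mu)^2) / n)
  pos <- values[values > 0]
  mpp <- if (length(pos)) mean(pos) else NA_real_
  rng <- range(values)
  if (rng[1] == rng[2]) {
    ent <- 0
  } else {
    breaks <- seq(rng[1], rng[2], length.out = config$entropy_bins + 1L)
    cnt <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE,
                                 all.inside = TRUE),
                    nbins = config$entropy_bins)
    p <- cnt[cnt > 0] / n
    ent <- -sum(p * log2(p))
  }
  if (sd_pop == 0) {
    skew <- NA_real_
    kurt <- NA_real_
  } else {
    z <- (values - mu) / sd_pop
    skew <- mean(z^3)
    kurt <- mean(z^4) - if (config$kurtosis_convention == "excess") 3 else 0
  }
  c(mean = mu, sd = sd_pop, entropy = ent, mpp = mpp,
    skewness = skew, kurtosis = kurt)
}

#' Conventional PET uptake metrics
#'
#' SUVmax and SUVmean over the ROI, and the uptake tumor area as the total
#' number of ROI pixels (the conventional reporting unit); multiply by
#' `prod(spacing_mm)` for mm^2.
#'
#' @param pet_slice a PET `texhist_slice`.
#' @param mask a congruent `texhist_mask`.
#' @return Named numeric vector `suv_max`, `suv_mean`, `uptake_area_px`.
#' @export
suv_metrics <- function(pet_slice, mask) {
  stopifnot(inherits(pet_slice, "texhist_slice"), pet_slice$modality == "PET",
            inherits(mask, "texhist_mask"))
  v <- pet_slice$pixels[mask$mask]
  if (length(v) == 0L) stop("empty mask")
  c(suv_max = max(v), suv_mean = mean(v), uptake_area_px = length(v))
}

feature_name <- function(modality, ssf, stat)
  sprintf("%s_ssf%g_%s", tolower(modality), ssf, stat)

#' Texture feature names
#'
#' The canonical ordering of the 36 CT and 6 PET texture feature names:
#' `<modality>_ssf<k>_<stat>` with k in \{0, 2, 3, 4, 5, 6\} for CT and 0
#' for PET, stats `mean`, `sd`, `entropy`, `mpp`, `skewness`, `kurtosis`.
#'
#' @param modality `"CT"` or `"PET"`.
#' @param ssf_mm scales (defaults: full bank for CT, unfiltered for PET).
#' @return Character vector of feature names.
#' @export
texture_feature_names <- function(modality = c("CT", "PET"),
                                  ssf_mm = if (match.arg(modality) == "CT")
                                    c(0, 2, 3, 4, 5, 6) else 0) {
  modality <- match.arg(modality)
  as.vector(t(outer(ssf_mm, stat_names,
                    function(s, st) feature_name(modality, s, st))))
}

#' Extract the full feature vector of one lesion
#'
#' CT: the six statistics on each of the unfiltered slice and the SSF 2-6 mm
#' texture maps, over the HU-eligible ROI pixel set (36 features). PET: the
#' six statistics on the unfiltered masked PET (6 features, no filtration --
#' PET resolution is too coarse for sub-cm band-pass scales). Plus SUVmax,
#' SUVmean and the uptake area in pixels. Missing statistics (MPP with no
#' positive pixels, skewness/kurtosis of a constant map) are `NA`, never
#' dropped.
#'
#' @param les a `texhist_lesion`.
#' @param fconfig a [filter_config()] (its non-zero scales are applied to CT).
#' @param sconfig a [stat_config()].
#' @return Object of class `texhist_features`: named numeric vector of
#'   36 + 6 + 3 values with attributes `patient_id`, `lesion_id`.
#' @export
extract_features <- function(les, fconfig = filter_config(),
                             sconfig = stat_config()) {
  stopifnot(inherits(les, "texhist_lesion"))
  ct_idx <- eligible_pixels(les$ct_slice, les$ct_mask, sconfig)
  out <- numeric(0)
  for (ssf in sort(fconfig$ssf_mm)) {
    tm <- filter_slice(les$ct_slice, ssf, fconfig)
    st <- histogram_stats(tm$pixels[ct_idx], sconfig)
    names(st) <- feature_name("CT", ssf, stat_names)
    out <- c(out, st)
  }
  pet_idx <- eligible_pixels(les$pet_slice, les$pet_mask, sconfig)
  st <- histogram_stats(les$pet_slice$pixels[pet_idx], sconfig)
  names(st) <- feature_name("PET", 0, stat_names)
  out <- c(out, st, suv_metrics(les$pet_slice, les$pet_mask))
  structure(out, class = "texhist_features",
            patient_id = les$ct_mask$patient_id,
            lesion_id = les$ct_mask$lesion_id)
}

#' @export
print.texhist_features <- function(x, ...) {
  cat(sprintf("<texhist_features> patient %s lesion %s: %d features (%d missing)\n",
              attr(x, "patient_id"), attr(x, "lesion_id"),
              length(x), sum(is.na(x))))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Tabulate lesion feature vectors
#'
#' One row per (patient, lesion); columns `patient_id`, `lesion_id`, then
#' the feature columns.
#'
#' @param feature_list list of `texhist_features`.
#' @return data.frame.
#' @export
feature_table <- function(feature_list) {
  stopifnot(length(feature_list) >= 1L)
  mat <- do.call(rbind, lapply(feature_list, unclass))
  data.frame(
    patient_id = vapply(feature_list, attr, "", which = "patient_id"),
    lesion_id = vapply(feature_list, attr, "", which = "lesion_id"),
    mat, row.names = NULL, check.names = FALSE)
}
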
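#' Phantom specification
#'
#' Geometry and texture parameters for synthetic lesions. The CT grid uses
#' the 0.98 x 0.98 mm in-plane resolution typical of low-dose PET-CT
#' acquisitions; the PET grid is deliberately coarser (4 x 4 mm) to honor
#' the low intrinsic resolution of PET SUV images (which is why PET texture
#' is quantified without filtration). A lesion is an elliptical ROI on a
#' soft-tissue background (about 40 HU) carrying Gaussian blobs whose
#' number and amplitude grow with the latent heterogeneity driver z; air
#' pockets (-1000 HU) may be embedded to exercise the -50 HU exclusion. The
#' PET lesion is a smoothed hot disc with lognormal avidity and z-scaled
#' within-lesion texture on a background of about 1 SUV.
#'
#' @param grid_ct,grid_pet matrix dimensions (rows, cols).
#' @param spacing_ct,spacing_pet pixel spacing, mm.
#' @param ct_background soft-tissue background, HU.
#' @param roi_radii_mm CT ROI ellipse semi-axes, mm.
#' @param blob_rate expected blob count at minimum and maximum
#'   heterogeneity (Poisson means, linearly interpolated in pnorm(z)).
#' @param blob_diam_mm range of blob diameters, mm (uniform).
#' @param blob_amp_hu blob amplitude scale, HU (signed normal).
#' @param amp_floor fraction of the amplitude scale retained at minimum
#'   heterogeneity.
#' @param noise_sd_hu additive Gaussian CT noise SD, HU.
#' @param air_prob probability a lesion contains air pockets.
#' @param pet_background PET background, SUV.
#' @param pet_roi_radius_mm PET hot-disc radius, mm.
#' @param pet_avidity_meanlog,pet_avidity_sdlog lognormal parameters of the
#'   lesion SUV amplitude.
#' @param pet_noise_sd PET noise SD, SUV.
#' @param pet_texture_amp scale of z-driven within-lesion PET texture, SUV.
#' @return Object of class `texhist_phantom_spec`.
#' @export
phantom_spec <- function(grid_ct = c(64, 64), spacing_ct = c(0.98, 0.98),
                         grid_pet = c(32, 32), spacing_pet = c(4, 4),
                         ct_background = 40, roi_radii_mm = c(18, 14),
                         blob_rate = c(2, 14), blob_diam_mm = c(2, 8),
                         blob_amp_hu = 60, amp_floor = 0.25,
                         noise_sd_hu = 8, air_prob = 0.15,
                         pet_background = 1, pet_roi_radius_mm = 12,
                         pet_avidity_meanlog = log(8), pet_avidity_sdlog = 0.35,
                         pet_noise_sd = 0.1, pet_texture_amp = 2) {
  stopifnot(all(spacing_ct > 0), all(spacing_pet > 0),
            all(roi_radii_mm > 0), pet_roi_radius_mm > 0,
            air_prob >= 0, air_prob <= 1, noise_sd_hu >= 0,
            blob_rate[1] >= 0, diff(blob_rate) >= 0)
  structure(as.list(environment()), class = "texhist_phantom_spec")
}

# centred squared Mahalanobis distance field of a grid, physical units
ellipse_field <- function(grid, spacing, radii_mm, centre_mm = c(0, 0)) {
  rows <- (seq_len(grid[1]) - (grid[1] + 1) / 2) * spacing[1] - centre_mm[1]
  cols <- (seq_len(grid[2]) - (grid[2] + 1) / 2) * spacing[2] - centre_mm[2]
  outer(rows^2 / radii_mm[1]^2, cols^2 / radii_mm[2]^2, `+`)
}

gaussian_bump <- function(grid, spacing, centre_mm, sigma_mm) {
  rows <- (seq_len(grid[1]) - (grid[1] + 1) / 2) * spacing[1]
  cols <- (seq_len(grid[2]) - (grid[2] + 1) / 2) * spacing[2]
  outer(exp(-(rows - centre_mm[1])^2 / (2 * sigma_mm^2)),
        exp(-(cols - centre_mm[2])^2 / (2 * sigma_mm^2)))
}

#' Generate one synthetic lesion
#'
#' Renders paired CT and PET slices with ROI masks from a [phantom_spec()].
#' The latent heterogeneity z drives the blob count and amplitude on CT and
#' the within-lesion texture amplitude on PET, so heterogeneity statistics
#' (SD, entropy, coarse-scale kurtosis) increase with z by construction.
#' Deterministic under a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @param z latent heterogeneity (standard-normal scale).
#' @param lesion_id,patient_id identifiers.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return A `texhist_lesion`.
#' @export
make_lesion_phantom <- function(spec = phantom_spec(), z = 0,
                                lesion_id = "lesion", patient_id = "patient",
                                seed = NULL) {
  stopifnot(inherits(spec, "texhist_phantom_spec"))
  if (!is.null(seed)) set.seed(seed)
  fov <- spec$grid_ct * spec$spacing_ct
  if (any(2 * spec$roi_radii_mm >= fov))
    stop("ROI ellipse larger than the CT grid")
  u <- stats::pnorm(z)  # heterogeneity driver mapped to (0, 1)

  ## --- CT ---
  ct <- matrix(spec$ct_background, spec$grid_ct[1], spec$grid_ct[2])
  if (spec$noise_sd_hu > 0)
    ct <- ct + matrix(stats::rnorm(length(ct), 0, spec$noise_sd_hu),
                      nrow(ct), ncol(ct))
  n_blobs <- stats::rpois(1, spec$blob_rate[1] +
                            diff(spec$blob_rate) * u)
  amp_scale <- spec$blob_amp_hu * (spec$amp_floor + (1 - spec$amp_floor) * u)
  for (b in seq_len(n_blobs)) {
    centre <- c(stats::runif(1, -0.7, 0.7) * spec$roi_radii_mm[1],
                stats::runif(1, -0.7, 0.7) * spec$roi_radii_mm[2])
    d <- stats::runif(1, spec$blob_diam_mm[1], spec$blob_diam_mm[2])
    a <- stats::rnorm(1, 0, amp_scale)
    # compact Gaussian bump: sigma = d/4 puts ~95% of the mass inside
    # diameter d, keeping blobs sparse so heavy-tail statistics rise with z
    ct <- ct + a * gaussian_bump(spec$grid_ct, spec$spacing_ct, centre, d / 4)
  }
  ct_mask_mat <- ellipse_field(spec$grid_ct, spec$spacing_ct,
                               spec$roi_radii_mm) <= 1
  if (spec$air_prob > 0 && stats::runif(1) < spec$air_prob) {
    for (p in seq_len(sample(1:3, 1))) {
      centre <- c(stats::runif(1, -0.6, 0.6) * spec$roi_radii_mm[1],
                  stats::runif(1, -0.6, 0.6) * spec$roi_radii_mm[2])
      pocket <- ellipse_field(spec$grid_ct, spec$spacing_ct,
                              c(1.5, 1.5), centre) <= 1
      ct[pocket] <- -1000
    }
  }
  ct <- round(ct)  # integer HU, bit-exact int16 round trips

  ## --- PET ---
  pet <- matrix(spec$pet_background, spec$grid_pet[1], spec$grid_pet[2])
  avidity <- stats::rlnorm(1, spec$pet_avidity_meanlog, spec$pet_avidity_sdlog)
  disc <- ellipse_field(spec$grid_pet, spec$spacing_pet,
                        rep(spec$pet_roi_radius_mm, 2)) <= 1
  hot <- matrix(0, nrow(pet), ncol(pet)); hot[disc] <- avidity
  # emulate PET point-spread by a small Gaussian smoothing of the hot disc
  g <- gaussian_bump(c(7, 7), c(1, 1), c(0, 0), 1.2)
  g <- g / sum(g)
  hot <- convolve2d(hot, g, padding = "reflect")
  pet <- pet + hot
  n_tex <- stats::rpois(1, 2 + 6 * u)
  tex_amp <- spec$pet_texture_amp * (0.15 + 0.85 * u)
  for (b in seq_len(n_tex)) {
    centre <- stats::runif(2, -0.6, 0.6) * spec$pet_roi_radius_mm
    a <- stats::rnorm(1, 0, tex_amp)
    pet <- pet + a * gaussian_bump(spec$grid_pet, spec$spacing_pet, centre,
                                   stats::runif(1, 3, 8))
  }
  if (spec$pet_noise_sd > 0)
    pet <- pet + matrix(stats::rnorm(length(pet), 0, spec$pet_noise_sd),
                        nrow(pet), ncol(pet))
  pet <- pmax(pet, 0.01)

  lesion(
    image_slice(ct, spec$spacing_ct, "CT"),
    image_slice(pet, spec$spacing_pet, "PET"),
    roi_mask(ct_mask_mat, lesion_id, patient_id),
    roi_mask(disc, lesion_id, patient_id))
}

#' Cohort specification
#'
#' Parameters of the simulated patient cohort. Survival times are drawn
#' from an exponential (constant baseline hazard) model
#' `h(t) = lambda * exp(beta * z_std)` where z_std is the per-patient
#' latent heterogeneity standardized across the cohort, so beta is the
#' log hazard ratio per SD of heterogeneity. Censoring combines an
#' administrative follow-up horizon with independent uniform dropout.
#' Defaults mirror a 44-patient metastatic NET cohort: baseline rates set
#' so the baseline median PFS is 22 months and median OS 37 months, with
#' follow-up capped at 82 months.
#'
#' @param n number of patients (>= 2).
#' @param lesion_range lesions per patient, sampled uniformly from this
#'   integer range.
#' @param beta_pfs,beta_os log hazard ratios per SD of heterogeneity.
#' @param rate_pfs,rate_os baseline exponential hazards, months^-1.
#' @param horizon_months administrative censoring horizon.
#' @param dropout_max independent dropout ~ Uniform(0, dropout_max) months.
#' @param covariate_prob prevalence of the generic binary clinical
#'   covariate (independent of z).
#' @return Object of class `texhist_cohort_spec`.
#' @export
cohort_spec <- function(n = 44, lesion_range = c(1, 7),
                        beta_pfs = log(2), beta_os = log(2),
                        rate_pfs = log(2) / 22, rate_os = log(2) / 37,
                        horizon_months = 82, dropout_max = 164,
                        covariate_prob = 0.3) {
  stopifnot(n >= 2, rate_pfs > 0, rate_os > 0, horizon_months > 0,
            lesion_range[1] >= 1, lesion_range[2] >= lesion_range[1])
  structure(as.list(environment()), class = "texhist_cohort_spec")
}

#' Simulate a full cohort with ground truth
#'
#' Draws a latent heterogeneity z per patient, renders 1-7 lesion phantoms
#' per patient (all lesions of a patient share its z), and simulates PFS
#' and OS from hazards proportional to `exp(beta * z_std)`. The true PFS
#' time is capped at the true OS time. If `dir` is given, the lesions are
#' written as NIfTI files with a `manifest.csv` and `ground_truth.csv`
#' (exactly the format [read_manifest()] consumes); otherwise lesions are
#' returned in memory.
#'
#' @param cspec a [cohort_spec()].
#' @param pspec a [phantom_spec()].
#' @param seed integer seed (all randomness flows from it).
#' @param dir optional output directory.
#' @return List of class `texhist_cohort`: `manifest` (one row per lesion),
#'   `lesions` (named list per patient, `NULL` when written to disk),
#'   `ground_truth` (z, true and observed times), `dir`.
#' @export
simulate_cohort <- function(cspec = cohort_spec(), pspec = phantom_spec(),
                            seed = 1L, dir = NULL) {
  stopifnot(inherits(cspec, "texhist_cohort_spec"),
            inherits(pspec, "texhist_phantom_spec"))
  set.seed(seed)
  n <- cspec$n
  ids <- sprintf("P%03d", seq_len(n))
  z <- stats::rnorm(n)
  z_std <- as.numeric(scale(z))
  draw_surv <- function(rate, beta)
    stats::rexp(n, rate * exp(beta * z_std))
  os_true <- draw_surv(cspec$rate_os, cspec$beta_os)
  pfs_true <- pmin(draw_surv(cspec$rate_pfs, cspec$beta_pfs), os_true)
  cens <- pmin(cspec$horizon_months, stats::runif(n, 0, cspec$dropout_max))
  os_months <- pmin(os_true, cens); os_event <- as.integer(os_true <= cens)
  pfs_months <- pmin(pfs_true, cens); pfs_event <- as.integer(pfs_true <= cens)
  lung_mets <- stats::rbinom(n, 1, cspec$covariate_prob)
  les_choices <- seq(cspec$lesion_range[1], cspec$lesion_range[2])
  n_lesions <- if (length(les_choices) == 1L) rep(les_choices, n)
               else sample(les_choices, n, replace = TRUE)

  write_out <- !is.null(dir)
  if (write_out) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lesions <- if (write_out) NULL else vector("list", n)
  if (!write_out) names(lesions) <- ids
  man_rows <- list()
  for (i in seq_len(n)) {
    pl <- vector("list", n_lesions[i])
    for (j in seq_len(n_lesions[i])) {
      lid <- sprintf("L%d", j)
      les <- make_lesion_phantom(pspec, z = z[i], lesion_id = lid,
                                 patient_id = ids[i])
      if (write_out) {
        stub <- file.path(dir, sprintf("%s_%s", ids[i], lid))
        paths <- paste0(stub, c("_ct.nii.gz", "_ct_mask.nii.gz",
                                "_pet.nii.gz", "_pet_mask.nii.gz"))
        write_lesion(les, paths[1], paths[2], paths[3], paths[4])
        rel <- basename(paths)
      } else {
        pl[[j]] <- les
        rel <- rep(NA_character_, 4)
      }
      man_rows[[length(man_rows) + 1L]] <- data.frame(
        patient_id = ids[i], lesion_id = lid,
        ct_path = rel[1], ct_mask_path = rel[2],
        pet_path = rel[3], pet_mask_path = rel[4],
        pfs_months = pfs_months[i], pfs_event = pfs_event[i],
        os_months = os_months[i], os_event = os_event[i],
        lung_mets = lung_mets[i])
    }
    if (!write_out) lesions[[i]] <- pl
  }
  manifest <- do.call(rbind, man_rows)
  attr(manifest, "covariates") <- "lung_mets"
  ground_truth <- data.frame(patient_id = ids, z = z, z_std = z_std,
                             os_true = os_true, pfs_true = pfs_true,
                             censor_time = cens)
  if (write_out) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(ground_truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  structure(list(manifest = manifest, lesions = lesions,
                 ground_truth = ground_truth, dir = dir),
            class = "texhist_cohort")
}

#' @export
print.texhist_cohort <- function(x, ...) {
  cat(sprintf("<texhist_cohort> %d patients, %d lesions%s\n",
              length(unique(x$manifest$patient_id)), nrow(x$manifest),
              if (is.null(x$dir)) " (in memory)" else paste0(" in ", x$dir)))
  invisible(x)
}
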
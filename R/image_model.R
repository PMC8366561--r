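#' Construct a 2-D image slice
#'
#' A slice is a 2-D scalar field with physical pixel spacing and a modality
#' tag. CT slices carry calibrated Hounsfield units (HU); PET slices carry
#' standardized uptake values (SUV). CT and PET slices of the same lesion may
#' differ in grid size and spacing: features are computed per modality on its
#' native grid and no cross-modality resampling is performed.
#'
#' @param pixels numeric matrix of intensities (HU for CT, SUV for PET).
#' @param spacing_mm numeric length-2 vector, (row, col) pixel spacing in mm.
#' @param modality `"CT"` or `"PET"`.
#' @return An object of class `texhist_slice`.
#' @export
image_slice <- function(pixels, spacing_mm, modality = c("CT", "PET")) {
  modality <- match.arg(modality)
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) stop("pixels must be numeric")
  if (!all(is.finite(pixels))) stop("pixels must be finite")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  if (length(spacing_mm) != 2L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be two positive finite values")
  structure(list(pixels = pixels, spacing_mm = spacing_mm, modality = modality),
            class = "texhist_slice")
}

#' @export
print.texhist_slice <- function(x, ...) {
  cat(sprintf("<texhist_slice> %s %dx%d px, spacing %.3g x %.3g mm, range [%.4g, %.4g]\n",
              x$modality, nrow(x$pixels), ncol(x$pixels),
              x$spacing_mm[1], x$spacing_mm[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Construct a binary region-of-interest mask
#'
#' The mask must be congruent with its image slice and contain at least one
#' true pixel. Masks smaller than `min_area` pixels are flagged with a
#' warning (not an error): first-order heterogeneity statistics on very few
#' pixels are unstable.
#'
#' @param mask logical matrix (or 0/1 numeric) congruent with the slice.
#' @param lesion_id,patient_id identifiers.
#' @param min_area minimum ROI area in pixels below which a warning is
#'   emitted (default 10).
#' @return An object of class `texhist_mask`.
#' @export
roi_mask <- function(mask, lesion_id = "lesion", patient_id = "patient",
                     min_area = 10L) {
  mask <- as.matrix(mask)
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.logical(mask)) stop("mask must be logical or 0/1 numeric")
  mask[is.na(mask)] <- FALSE
  n_in <- sum(mask)
  if (n_in < 1L) stop("mask has no true pixels")
  if (n_in < min_area)
    warning(sprintf("ROI '%s' has only %d pixels (< %d): statistics may be unstable",
                    lesion_id, n_in, min_area))
  structure(list(mask = mask, lesion_id = as.character(lesion_id),
                 patient_id = as.character(patient_id)),
            class = "texhist_mask")
}

#' @export
print.texhist_mask <- function(x, ...) {
  cat(sprintf("<texhist_mask> patient %s lesion %s, %d/%d px in ROI\n",
              x$patient_id, x$lesion_id, sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Pair CT and PET slices of one lesion with their ROI masks
#'
#' The PET slice is the single most tracer-avid slice of the lesion and the
#' CT slice is its anatomical counterpart; ROIs are drawn per modality so
#' the two masks need not share a grid.
#'
#' @param ct_slice,pet_slice `texhist_slice` objects of the matching modality.
#' @param ct_mask,pet_mask `texhist_mask` objects congruent with their slices.
#' @return An object of class `texhist_lesion`.
#' @export
lesion <- function(ct_slice, pet_slice, ct_mask, pet_mask) {
  stopifnot(inherits(ct_slice, "texhist_slice"), inherits(pet_slice, "texhist_slice"),
            inherits(ct_mask, "texhist_mask"), inherits(pet_mask, "texhist_mask"))
  if (ct_slice$modality != "CT") stop("ct_slice must have modality CT")
  if (pet_slice$modality != "PET") stop("pet_slice must have modality PET")
  if (!identical(dim(ct_mask$mask), dim(ct_slice$pixels)))
    stop("CT mask shape does not match CT slice")
  if (!identical(dim(pet_mask$mask), dim(pet_slice$pixels)))
    stop("PET mask shape does not match PET slice")
  structure(list(ct_slice = ct_slice, pet_slice = pet_slice,
                 ct_mask = ct_mask, pet_mask = pet_mask),
            class = "texhist_lesion")
}

#' @export
print.texhist_lesion <- function(x, ...) {
  cat(sprintf("<texhist_lesion> patient %s lesion %s\n",
              x$ct_mask$patient_id, x$ct_mask$lesion_id))
  print(x$ct_slice); print(x$pet_slice)
  invisible(x)
}

nifti_spacing <- function(img) {
  pd <- RNifti::pixdim(img)
  as.numeric(pd[1:2])
}

read_slice_nifti <- function(path, modality) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  raw <- drop(as.array(img))
  px <- matrix(as.double(raw), nrow(raw), ncol(raw))  # strip nifti attributes
  sp <- nifti_spacing(img)
  if (any(sp <= 0)) stop("non-positive pixel spacing in header of ", path)
  image_slice(px, sp, modality)
}

read_mask_nifti <- function(path, lesion_id, patient_id, expect_dim) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- drop(as.array(RNifti::readNifti(path)))
  m <- matrix(as.double(raw), nrow(raw), ncol(raw))
  if (!identical(dim(m), expect_dim))
    stop(sprintf("mask %s is %dx%d but image is %dx%d",
                 path, nrow(m), ncol(m), expect_dim[1], expect_dim[2]))
  roi_mask(m != 0, lesion_id = lesion_id, patient_id = patient_id)
}

#' Read a lesion (CT + PET slices and masks) from NIfTI-1 files
#'
#' Images are read with intensities as stored after the format's standard
#' scl_slope/scl_inter rescaling; masks are any nonzero labelmap. Pixel
#' spacing is taken from the NIfTI header.
#'
#' @param ct_path,ct_mask_path,pet_path,pet_mask_path file paths.
#' @param lesion_id,patient_id identifiers attached to the masks.
#' @return A `texhist_lesion`.
#' @seealso [write_lesion()]
#' @export
read_lesion <- function(ct_path, ct_mask_path, pet_path, pet_mask_path,
                        lesion_id = "lesion", patient_id = "patient") {
  ct <- read_slice_nifti(ct_path, "CT")
  pet <- read_slice_nifti(pet_path, "PET")
  ctm <- read_mask_nifti(ct_mask_path, lesion_id, patient_id, dim(ct$pixels))
  petm <- read_mask_nifti(pet_mask_path, lesion_id, patient_id, dim(pet$pixels))
  lesion(ct, pet, ctm, petm)
}

write_slice_nifti <- function(slice, path, integer_ct = TRUE) {
  px <- slice$pixels
  datatype <- if (slice$modality == "CT" && integer_ct &&
                  all(px == round(px)) && all(abs(px) < 32768)) "int16"
              else "double"
  arr <- array(px, dim = c(dim(px), 1L))
  attr(arr, "pixdim") <- c(slice$spacing_mm, 1)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = datatype), path)
  invisible(path)
}

#' Write a lesion to NIfTI-1 files
#'
#' Integer-valued CT is stored as int16 (bit-exact round trip for HU); PET
#' as double. Masks are uint8 labelmaps.
#'
#' @param x a `texhist_lesion`.
#' @param ct_path,ct_mask_path,pet_path,pet_mask_path output paths
#'   (`.nii` or `.nii.gz`).
#' @return The four paths, invisibly.
#' @export
write_lesion <- function(x, ct_path, ct_mask_path, pet_path, pet_mask_path) {
  stopifnot(inherits(x, "texhist_lesion"))
  write_slice_nifti(x$ct_slice, ct_path)
  write_slice_nifti(x$pet_slice, pet_path)
  for (mp in list(list(x$ct_mask, x$ct_slice, ct_mask_path),
                  list(x$pet_mask, x$pet_slice, pet_mask_path))) {
    m <- mp[[1]]; sl <- mp[[2]]
    arr <- array(as.integer(m$mask), dim = c(dim(m$mask), 1L))
    attr(arr, "pixdim") <- c(sl$spacing_mm, 1)
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "uint8"), mp[[3]])
  }
  invisible(c(ct_path, ct_mask_path, pet_path, pet_mask_path))
}

#' Select the most tracer-avid slice of a PET stack
#'
#' Returns the index of the slice whose within-mask maximum intensity is
#' globally maximal. Ties are broken by the lowest index. Slices with empty
#' masks are ignored.
#'
#' @param pet_slices list of `texhist_slice` (PET).
#' @param masks list of logical matrices or `texhist_mask`, congruent with
#'   the slices.
#' @return Integer slice index.
#' @export
select_most_avid_slice <- function(pet_slices, masks) {
  stopifnot(length(pet_slices) == length(masks), length(pet_slices) >= 1L)
  maxima <- vapply(seq_along(pet_slices), function(i) {
    m <- masks[[i]]
    if (inherits(m, "texhist_mask")) m <- m$mask
    if (!any(m)) return(-Inf)
    max(pet_slices[[i]]$pixels[m])
  }, numeric(1))
  if (all(!is.finite(maxima))) stop("all masks are empty")
  which.max(maxima)  # which.max takes the first on ties
}

in_mask_pet_max <- function(les) max(les$pet_slice$pixels[les$pet_mask$mask])

#' Keep the most avid lesions of a patient
#'
#' Lesions are ranked by their in-mask PET maximum and the top
#' `min(limit, n)` are returned. The sort is stable: lesions with equal
#' maxima keep their input order.
#'
#' @param lesions list of `texhist_lesion`.
#' @param limit maximum number kept (default 5).
#' @return List of `texhist_lesion`, length `min(limit, length(lesions))`.
#' @export
select_lesions <- function(lesions, limit = 5L) {
  if (length(lesions) == 0L) stop("empty lesion list")
  stopifnot(limit >= 1L)
  maxima <- vapply(lesions, in_mask_pet_max, numeric(1))
  ord <- order(-maxima)  # order() is stable: ties keep input order
  keep <- sort(ord[seq_len(min(limit, length(lesions)))])
  lesions[keep]
}

#' Read a cohort manifest CSV
#'
#' The manifest has one row per lesion with columns `patient_id`,
#' `lesion_id`, `ct_path`, `ct_mask_path`, `pet_path`, `pet_mask_path`,
#' `pfs_months`, `pfs_event`, `os_months`, `os_event`; any further columns
#' are treated as clinical covariates. Relative paths are resolved against
#' the manifest's directory.
#'
#' @param path manifest CSV path.
#' @return data.frame with an attribute `covariates` naming the clinical
#'   covariate columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "lesion_id", "ct_path", "ct_mask_path",
                "pet_path", "pet_mask_path", "pfs_months", "pfs_event",
                "os_months", "os_event")
  missing <- setdiff(required, names(man))
  if (length(missing)) stop("manifest lacks columns: ", paste(missing, collapse = ", "))
  for (col in c("pfs_months", "os_months")) {
    v <- suppressWarnings(as.numeric(man[[col]]))
    if (any(is.na(v)) || any(v < 0)) stop("unparseable or negative ", col)
    man[[col]] <- v
  }
  for (col in c("pfs_event", "os_event")) {
    v <- suppressWarnings(as.integer(man[[col]]))
    if (any(is.na(v)) || any(!v %in% 0:1)) stop("event flag ", col, " must be 0/1")
    man[[col]] <- v
  }
  base <- dirname(normalizePath(path))
  for (col in c("ct_path", "ct_mask_path", "pet_path", "pet_mask_path")) {
    rel <- !grepl("^(/|[A-Za-z]:)", man[[col]])
    man[[col]][rel] <- file.path(base, man[[col]][rel])
  }
  attr(man, "covariates") <- setdiff(names(man), required)
  man
}
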
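#' Filtration configuration
#'
#' Controls the Laplacian-of-Gaussian (LoG) band-pass filtration bank. The
#' spatial scale filter (SSF) is the mm-scale of the objects the band-pass
#' enhances: 2 mm (fine), 3-5 mm (medium, three separate maps), 6 mm
#' (coarse); SSF 0 denotes the unfiltered control. The Gaussian width is
#' `sigma_mm = sigma_ratio * ssf_mm`; with the default ratio 1/2 an object
#' of diameter roughly equal to the SSF gives near-peak response. Absolute
#' filtered intensities depend on this mapping, the rank ordering across
#' lesions (which the prognostic analysis uses) does not.
#'
#' @param ssf_mm numeric vector of scales, subset of `c(0, 2, 3, 4, 5, 6)`.
#' @param sigma_ratio sigma_mm / ssf_mm (default 0.5).
#' @param truncation kernel support half-width as a multiple of sigma
#'   (default 4, must be >= 3).
#' @param padding `"reflect"` (edge-inclusive mirror, default) or
#'   `"constant"`.
#' @param pad_value fill value for constant padding.
#' @return An object of class `texhist_filter_config`.
#' @export
filter_config <- function(ssf_mm = c(0, 2, 3, 4, 5, 6), sigma_ratio = 0.5,
                          truncation = 4, padding = c("reflect", "constant"),
                          pad_value = 0) {
  padding <- match.arg(padding)
  allowed <- c(0, 2, 3, 4, 5, 6)
  if (!all(ssf_mm %in% allowed))
    stop("ssf_mm values must be in {", paste(allowed, collapse = ", "), "}")
  if (anyDuplicated(ssf_mm)) stop("duplicate ssf_mm values")
  if (truncation < 3) stop("truncation must be >= 3 sigma")
  if (sigma_ratio <= 0) stop("sigma_ratio must be positive")
  structure(list(ssf_mm = as.numeric(ssf_mm), sigma_ratio = sigma_ratio,
                 truncation = truncation, padding = padding,
                 pad_value = pad_value),
            class = "texhist_filter_config")
}

#' Build a discrete LoG band-pass kernel
#'
#' The kernel is the negated, scale-normalized Laplacian of an anisotropic
#' Gaussian sampled on the pixel grid (per-axis sigma in pixels =
#' sigma_mm / spacing_mm), so bright blobs give positive response. The
#' sigma^2 scale normalization makes peak response select object size: a
#' Gaussian object of diameter 2*sigma_obj responds maximally at the scale
#' with sigma = sigma_obj, the band-pass behavior that distinguishes fine
#' from coarse texture. Support is truncated at `truncation * sigma` per
#' axis, then the kernel is shifted by its mean so the entries sum exactly
#' to zero: the filter is DC-free and annihilates constant images.
#'
#' @param ssf_mm spatial scale in mm (> 0).
#' @param spacing_mm length-2 pixel spacing in mm.
#' @param sigma_ratio,truncation see [filter_config()].
#' @return Numeric matrix with odd dimensions summing to zero.
#' @export
log_kernel <- function(ssf_mm, spacing_mm, sigma_ratio = 0.5, truncation = 4) {
  if (ssf_mm <= 0) stop("ssf_mm must be positive")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  if (any(spacing_mm <= 0)) stop("spacing must be positive")
  sigma_mm <- sigma_ratio * ssf_mm
  sigma_px <- sigma_mm / spacing_mm
  if (min(sigma_px) < 0.4)
    stop(sprintf("sigma %.3g px at spacing %.3g mm is unresolvable (< 0.4 px)",
                 min(sigma_px), spacing_mm[which.min(sigma_px)]))
  r <- ceiling(truncation * sigma_px)
  x <- seq(-r[1], r[1])          # row offsets, px
  y <- seq(-r[2], r[2])          # col offsets, px
  gx <- exp(-x^2 / (2 * sigma_px[1]^2))
  gy <- exp(-y^2 / (2 * sigma_px[2]^2))
  g <- outer(gx, gy)
  lap <- outer(x^2 / sigma_px[1]^4, rep(1, length(y))) +
         outer(rep(1, length(x)), y^2 / sigma_px[2]^4) -
         (1 / sigma_px[1]^2 + 1 / sigma_px[2]^2)
  # negated, scale-normalized LoG: sigma_x sigma_y * (-lap) * G_density
  # = -lap * g / (2 pi); bright blobs give positive peak response
  k <- -lap * g / (2 * pi)
  k - mean(k)                    # exact DC-free
}

reflect_index <- function(n, r) {
  # edge-inclusive mirror indices for padding width r on an axis of length n
  idx <- seq(1 - r, n + r)
  period <- 2L * n
  m <- ((idx - 1) %% period + period) %% period  # 0 .. 2n-1
  ifelse(m < n, m + 1L, period - m)
}

pad_matrix <- function(m, r, padding, pad_value) {
  if (padding == "reflect") {
    m[reflect_index(nrow(m), r[1]), reflect_index(ncol(m), r[2])]
  } else {
    out <- matrix(pad_value, nrow(m) + 2 * r[1], ncol(m) + 2 * r[2])
    out[r[1] + seq_len(nrow(m)), r[2] + seq_len(ncol(m))] <- m
    out
  }
}

# Linear convolution of `m` with centred symmetric kernel `k` under the
# chosen padding, via circular FFT convolution on the padded field. The pad
# width equals the kernel radius, so wrap-around only touches padding.
convolve2d <- function(m, k, padding = "reflect", pad_value = 0) {
  r <- (dim(k) - 1L) %/% 2L
  p <- pad_matrix(m, r, padding, pad_value)
  n1 <- nrow(p); n2 <- ncol(p)
  ke <- matrix(0, n1, n2)
  ri <- ((seq(-r[1], r[1])) %% n1) + 1L
  ci <- ((seq(-r[2], r[2])) %% n2) + 1L
  ke[ri, ci] <- k
  conv <- Re(stats::fft(stats::fft(p) * stats::fft(ke), inverse = TRUE)) / (n1 * n2)
  out <- conv[r[1] + seq_len(nrow(m)), r[2] + seq_len(ncol(m))]
  # snap responses below FFT roundoff to exact zero, so DC-free filtration of
  # a constant image is identically zero rather than ~1e-13 noise
  floor_eps <- 64 * .Machine$double.eps * max(abs(p)) * sum(abs(k))
  out[abs(out) < floor_eps] <- 0
  out
}

#' Apply LoG band-pass filtration to a slice
#'
#' Produces the texture map at one spatial scale. The whole slice is
#' filtered; the ROI restricts only the later statistics stage, so the
#' filter response near the ROI boundary uses real surrounding tissue.
#' `ssf_mm = 0` is the exact identity (the unfiltered control).
#'
#' @param slice a `texhist_slice`.
#' @param ssf_mm one scale from the allowed set.
#' @param config a [filter_config()].
#' @return An object of class `texhist_texmap` with fields `pixels`,
#'   `ssf_mm`, `modality`, `spacing_mm`.
#' @export
filter_slice <- function(slice, ssf_mm, config = filter_config()) {
  stopifnot(inherits(slice, "texhist_slice"))
  if (!ssf_mm %in% c(0, 2, 3, 4, 5, 6)) stop("invalid ssf_mm: ", ssf_mm)
  px <- if (ssf_mm == 0) {
    slice$pixels
  } else {
    k <- log_kernel(ssf_mm, slice$spacing_mm, config$sigma_ratio, config$truncation)
    convolve2d(slice$pixels, k, config$padding, config$pad_value)
  }
  structure(list(pixels = px, ssf_mm = ssf_mm, modality = slice$modality,
                 spacing_mm = slice$spacing_mm),
            class = "texhist_texmap")
}

#' @export
print.texhist_texmap <- function(x, ...) {
  cat(sprintf("<texhist_texmap> %s SSF %g mm, %dx%d px, range [%.4g, %.4g]\n",
              x$modality, x$ssf_mm, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Display a texture map
#'
#' Diverging palette: pink for positive filtered response (bright objects),
#' blue for negative (dark objects), white at zero.
#'
#' @param x a `texhist_texmap`.
#' @param ... passed to [graphics::image()].
#' @export
plot.texhist_texmap <- function(x, ...) {
  px <- x$pixels
  lim <- max(abs(px))
  if (lim == 0) lim <- 1
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#E7298A"))(101)
  graphics::image(t(px)[, nrow(px):1], zlim = c(-lim, lim), col = pal,
                  axes = FALSE, asp = nrow(px) / ncol(px),
                  main = sprintf("%s texture map, SSF %g mm", x$modality, x$ssf_mm),
                  ...)
  invisible(x)
}

#' Export a texture map as NIfTI for external viewing
#'
#' @param x a `texhist_texmap`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_texture_map <- function(x, path) {
  stopifnot(inherits(x, "texhist_texmap"))
  arr <- array(x$pixels, dim = c(dim(x$pixels), 1L))
  attr(arr, "pixdim") <- c(x$spacing_mm, 1)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  invisible(path)
}
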
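# Independent brute-force oracles, deliberately naive: plain loops and
# textbook formulas, no shared code with the package internals.

naive_stats <- function(v, bins = 64) {
  n <- length(v)
  m <- sum(v) / n
  sd_pop <- sqrt(sum((v - m)^2) / n)
  pos <- v[v > 0]
  mpp <- if (length(pos) > 0) sum(pos) / length(pos) else NA_real_
  lo <- min(v); hi <- max(v)
  if (lo == hi) {
    ent <- 0
  } else {
    width <- (hi - lo) / bins
    counts <- rep(0, bins)
    for (x in v) {
      b <- floor((x - lo) / width) + 1
      if (b > bins) b <- bins
      counts[b] <- counts[b] + 1
    }
    ent <- 0
    for (c in counts) if (c > 0) { p <- c / n; ent <- ent - p * log2(p) }
  }
  if (sd_pop == 0) {
    skew <- NA_real_; kurt <- NA_real_
  } else {
    skew <- sum(((v - m) / sd_pop)^3) / n
    kurt <- sum(((v - m) / sd_pop)^4) / n - 3
  }
  c(mean = m, sd = sd_pop, entropy = ent, mpp = mpp,
    skewness = skew, kurtosis = kurt)
}

# Breslow partial log-likelihood for a single covariate
breslow_loglik <- function(beta, x, times, events) {
  ll <- 0
  for (i in seq_along(times)) {
    if (events[i] == 1) {
      risk <- times >= times[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  ll
}

# grid maximizer of the Breslow partial likelihood
breslow_scan <- function(x, times, events, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, breslow_loglik, 0, x = x, times = times, events = events)
  grid[which.max(ll)]
}

# flat test slice with a Gaussian blob of diameter d mm (sigma = d/2,
# the matched-scale convention of the normalized LoG) at the grid centre
blob_slice <- function(d_mm, amp = 1000, n = 95, spacing = 0.98) {
  x <- (seq_len(n) - (n + 1) / 2) * spacing
  g <- exp(-x^2 / (2 * (d_mm / 2)^2))
  image_slice(amp * outer(g, g), c(spacing, spacing), "CT")
}

const_slice <- function(value, n = 32, spacing = 0.98, modality = "CT")
  image_slice(matrix(value, n, n), c(spacing, spacing), modality)

full_mask <- function(slice, ...)
  roi_mask(matrix(TRUE, nrow(slice$pixels), ncol(slice$pixels)), ...)

# minimal two-slice lesion for feature tests: CT pixels supplied, PET a
# small uniform hot square
tiny_lesion <- function(ct_pixels, pet_value = 5, patient_id = "P1",
                        lesion_id = "L1") {
  ct <- image_slice(ct_pixels, c(0.98, 0.98), "CT")
  pet <- image_slice(matrix(pet_value, 8, 8), c(4, 4), "PET")
  suppressWarnings(lesion(
    ct, pet,
    roi_mask(matrix(TRUE, nrow(ct_pixels), ncol(ct_pixels)),
             lesion_id, patient_id),
    roi_mask(matrix(TRUE, 8, 8), lesion_id, patient_id)))
}
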
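test_that("histogram statistics handle degenerate and sign-split inputs", {
  s <- histogram_stats(c(1, 1, 1, 1))
  expect_equal(s[["mean"]], 1)
  expect_equal(s[["sd"]], 0)
  expect_equal(s[["entropy"]], 0)
  expect_equal(s[["mpp"]], 1)
  expect_true(is.na(s[["skewness"]]) && is.na(s[["kurtosis"]]))
  s2 <- histogram_stats(c(-1, 1))
  expect_equal(s2[["mean"]], 0)
  expect_equal(s2[["mpp"]], 1)
  expect_true(is.na(histogram_stats(c(-2, -1))[["mpp"]]))
  expect_error(histogram_stats(numeric(0)), "empty")
})

test_that("uniformly spread values reach the full entropy of the bin budget", {
  # one value per bin centre of 64 equal-width bins -> entropy log2(64) = 6
  v <- seq(0.5, 63.5, by = 1) * (64 / 64)
  expect_equal(histogram_stats(v)[["entropy"]], 6)
  # two bins, balanced -> 1 bit
  expect_equal(histogram_stats(c(0, 0, 1, 1),
                               stat_config(entropy_bins = 2))[["entropy"]], 1)
})

test_that("statistics agree with the naive oracle on random pixel sets", {
  set.seed(101)
  for (r in 1:200) {
    n <- sample(2:400, 1)
    v <- switch(sample(3, 1),
                rnorm(n, sample(-100:100, 1), runif(1, 0.1, 50)),
                rlnorm(n, 1, 1) - sample(c(0, 5), 1),
                sample(-50:50, n, replace = TRUE))
    got <- histogram_stats(v)
    want <- naive_stats(v)
    for (nm in names(want)) {
      if (is.na(want[[nm]])) expect_true(is.na(got[[nm]]))
      else expect_equal(got[[nm]], want[[nm]],
                        tolerance = 1e-10, label = nm)
    }
  }
})

test_that("moments of large normal samples match their exact values", {
  set.seed(202)
  v <- rnorm(1e5)
  s <- histogram_stats(v)
  expect_lt(abs(s[["skewness"]]), 0.03)
  expect_lt(abs(s[["kurtosis"]]), 0.06)
  expect_equal(s[["sd"]], 1, tolerance = 0.01)
})

test_that("entropy is invariant under increasing affine rescaling", {
  set.seed(33)
  v <- rnorm(500, 10, 3)
  e0 <- histogram_stats(v)[["entropy"]]
  expect_equal(histogram_stats(7 * v + 100)[["entropy"]], e0)
  expect_equal(histogram_stats(0.001 * v - 50)[["entropy"]], e0)
})

test_that("HU exclusion removes sub-threshold CT pixels and only those", {
  px <- matrix(40, 8, 8)
  px[1, 1] <- -1000; px[2, 2] <- 30; px[3, 3] <- 45; px[4, 4] <- -51
  sl <- image_slice(px, 0.98, "CT")
  mk <- roi_mask(matrix(TRUE, 8, 8))
  idx <- eligible_pixels(sl, mk)
  expect_setequal(sl$pixels[idx][sl$pixels[idx] != 40], c(30, 45))
  expect_false(any(sl$pixels[idx] < -50))
  # exactly -50 is kept (threshold is "less than -50")
  px[5, 5] <- -50
  expect_true(-50 %in% image_slice(px, 0.98, "CT")$pixels[
    eligible_pixels(image_slice(px, 0.98, "CT"), mk)])
  # PET never excludes
  pet <- image_slice(matrix(c(0.5, 8, -1, 2), 2, 2), 4, "PET")
  pet_mk <- suppressWarnings(roi_mask(matrix(TRUE, 2, 2)))
  expect_length(eligible_pixels(pet, pet_mk), 4)
  # all-air ROI errors
  air <- image_slice(matrix(-1000, 4, 4), 0.98, "CT")
  expect_error(eligible_pixels(air, roi_mask(matrix(TRUE, 4, 4))),
               "no eligible")
})

test_that("SUV metrics are max, mean and pixel count over the mask", {
  pet <- image_slice(matrix(c(2, 5, 3, 99), 2, 2), 4, "PET")
  mk <- suppressWarnings(roi_mask(matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)))
  m <- suv_metrics(pet, mk)
  expect_equal(unname(m), c(5, 10 / 3, 3))
  one <- suppressWarnings(roi_mask(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)))
  expect_equal(unname(suv_metrics(pet, one)), c(2, 2, 1))
  u <- image_slice(matrix(7, 13, 4), 4, "PET")
  expect_equal(unname(suv_metrics(u, roi_mask(matrix(TRUE, 13, 4)))),
               c(7, 7, 52))
})

test_that("feature vectors always hold 36 CT + 6 PET + 3 conventional entries", {
  les <- make_lesion_phantom(z = 0.5, seed = 77)
  f <- extract_features(les)
  expect_length(f, 45)
  expect_equal(sum(grepl("^ct_ssf", names(f))), 36)
  expect_equal(sum(grepl("^pet_ssf", names(f))), 6)
  expect_identical(names(f)[grepl("^ct_ssf", names(f))],
                   texture_feature_names("CT"))
  expect_identical(names(f)[grepl("^pet_ssf", names(f))],
                   texture_feature_names("PET"))
  expect_true(all(c("suv_max", "suv_mean", "uptake_area_px") %in% names(f)))
})

test_that("a constant CT lesion yields null filtered maps with explicit missings", {
  les <- tiny_lesion(matrix(40, 48, 48))
  f <- extract_features(les)
  expect_length(f, 45)
  for (ssf in c(2, 3, 4, 5, 6)) {
    expect_lt(abs(f[[sprintf("ct_ssf%d_mean", ssf)]]), 1e-8)
    expect_lt(f[[sprintf("ct_ssf%d_sd", ssf)]], 1e-8)
    expect_equal(f[[sprintf("ct_ssf%d_entropy", ssf)]], 0, tolerance = 1e-6)
  }
  expect_true(is.na(f[["ct_ssf0_skewness"]]))  # constant unfiltered input
  expect_equal(f[["ct_ssf0_entropy"]], 0)
})

test_that("intensity shifts leave filtered statistics unchanged, unfiltered mean tracks", {
  les <- make_lesion_phantom(phantom_spec(air_prob = 0), z = 0.3, seed = 13)
  shift <- 100
  les2 <- les
  les2$ct_slice$pixels <- les$ct_slice$pixels + shift
  f1 <- extract_features(les)
  f2 <- extract_features(les2)
  filt <- grep("^ct_ssf[2-6]_", names(f1), value = TRUE)
  expect_equal(unclass(f1)[filt], unclass(f2)[filt], tolerance = 1e-8)
  expect_equal(f2[["ct_ssf0_mean"]], f1[["ct_ssf0_mean"]] + shift)
})

test_that("feature tables are tidy, one row per lesion", {
  fl <- lapply(1:3, function(i)
    extract_features(make_lesion_phantom(z = 0, seed = i,
                                         lesion_id = paste0("L", i),
                                         patient_id = "P1")))
  tab <- feature_table(fl)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$lesion_id, c("L1", "L2", "L3"))
  expect_true(all(texture_feature_names("CT") %in% names(tab)))
})
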
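ext <- small_ext()
bands <- default_band_centers()
r_blood <- model_reflectance_spectrum(tissue_preset("blood_patient1"), ext, bands)
r_cortex <- model_reflectance_spectrum(tissue_preset("cortex_patient1"), ext, bands)

test_that("spectral proportions recover pure and mixed end-members", {
  pure_b <- fit_spectral_proportions(r_blood$reflectance, r_blood, r_cortex)
  expect_equal(pure_b$a_blood[1, 1], 1, tolerance = 1e-9)
  expect_equal(pure_b$a_cortex[1, 1], 0, tolerance = 1e-9)

  # intensity scaling does not matter: shapes are fit, not magnitudes
  scaled <- fit_spectral_proportions(5 * r_cortex$reflectance, r_blood, r_cortex)
  expect_equal(scaled$a_cortex[1, 1], 1, tolerance = 1e-9)

  mixed <- 0.5 * r_blood$reflectance / mean(r_blood$reflectance) +
    0.5 * r_cortex$reflectance / mean(r_cortex$reflectance)
  pm <- fit_spectral_proportions(mixed, r_blood, r_cortex)
  expect_equal(pm$a_blood[1, 1], 0.5, tolerance = 1e-9)
  expect_equal(pm$a_cortex[1, 1], 0.5, tolerance = 1e-9)
  expect_lt(pm$residual[1, 1], 1e-9)
})

test_that("cortex plus 1% band noise stays above the cortex threshold", {
  set.seed(13)
  npx <- 400
  reps <- 5
  frac <- replicate(reps, {
    y <- matrix(r_cortex$reflectance, 16, npx) *
      (1 + rnorm(16 * npx, sd = 0.01))
    p <- fit_spectral_proportions(y, r_blood, r_cortex)
    mean(p$a_cortex > 0.75)
  })
  expect_true(all(frac >= 0.99))
})

test_that("collinear model spectra are rejected", {
  expect_error(fit_spectral_proportions(r_blood$reflectance, r_blood,
                                        2 * r_blood$reflectance),
               "collinear|rank")
})

test_that("spectral classification uses strict inequalities", {
  props <- structure(list(a_blood = matrix(c(0.81, 0.80, 0.10, 0.9), 2, 2),
                          a_cortex = matrix(c(0.10, 0.10, 0.76, 0.9), 2, 2),
                          residual = matrix(0, 2, 2),
                          normalization = "clip", nonneg = TRUE),
                     class = "spectral_proportions")
  cl <- classify_spectral(props)
  expect_true(cl$blood[1, 1])          # 0.81 > 0.8
  expect_false(cl$blood[2, 1])         # 0.80 exactly -> not blood
  expect_true(cl$cortex[1, 2])         # 0.76 > 0.75, a_blood low
  # both pass -> larger coefficient wins; tie -> unclassified
  expect_false(cl$blood[2, 2] && cl$cortex[2, 2])
  expect_false(cl$blood[2, 2] || cl$cortex[2, 2])   # 0.9 vs 0.9 tie
})

test_that("dynamic threshold follows the linear-interpolation percentile", {
  m <- matrix(c(1, 2, 3, 4), 2, 2)
  region <- matrix(TRUE, 2, 2)
  expect_equal(dynamic_threshold(m, region, 75), 3.25)
  expect_equal(dynamic_threshold(matrix(7, 3, 3), matrix(TRUE, 3, 3)), 7)
  expect_error(dynamic_threshold(m, matrix(FALSE, 2, 2)), "empty")
})

test_that("dynamic classification is strict and honors exclusions", {
  m <- matrix(2, 3, 3)
  expect_true(all(classify_dynamic(m + 1e-9, 2)))
  expect_true(all(!classify_dynamic(m, 2)))            # equal -> static
  excl <- matrix(FALSE, 3, 3); excl[1, 1] <- TRUE
  expect_true(is.na(classify_dynamic(m, 1, exclude = excl)[1, 1]))
})

test_that("label fusion implements the exact truth table", {
  # all 2^3 combinations of (blood, cortex, dynamic)
  combos <- expand.grid(blood = c(FALSE, TRUE), cortex = c(FALSE, TRUE),
                        dynamic = c(FALSE, TRUE))
  expected <- with(combos, ifelse(blood & dynamic, "vessel",
                            ifelse(blood & !dynamic, "bleeding",
                            ifelse(cortex & dynamic, "cortex",
                                   "unclassified"))))
  n <- nrow(combos)
  spectral <- list(blood = matrix(combos$blood, n, 1),
                   cortex = matrix(combos$cortex & !combos$blood, n, 1))
  seg <- fuse_labels(spectral, matrix(combos$dynamic, n, 1))
  got <- as.vector(seg$labels)
  # blood & cortex cannot coexist after classify_spectral; restrict to those
  keep <- !(combos$blood & combos$cortex)
  expect_identical(got[keep], expected[keep])
  # cortex & static is explicitly unclassified
  i <- which(!combos$blood & combos$cortex & !combos$dynamic)
  expect_identical(got[i], "unclassified")
})

test_that("specular pixels override every other label", {
  spectral <- list(blood = matrix(TRUE, 2, 2), cortex = matrix(FALSE, 2, 2))
  spec <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  seg <- fuse_labels(spectral, matrix(TRUE, 2, 2), specular = spec)
  expect_identical(as.vector(seg$labels),
                   c("specular", "vessel", "vessel", "specular"))
  expect_error(fuse_labels(spectral, matrix(TRUE, 3, 3)), "shape")
})

test_that("every pixel receives exactly one of the five labels", {
  run <- default_run()
  lab <- run$segmentation$labels
  expect_true(all(lab %in% segmentation_levels()))
  expect_equal(sum(label_counts(run$segmentation)), length(lab))
})

test_that("raising thresholds shrinks the corresponding sets monotonically", {
  run <- default_run()
  props <- run$proportions
  b1 <- classify_spectral(props, t_blood = 0.8)$blood
  b2 <- classify_spectral(props, t_blood = 0.9)$blood
  expect_true(all(b1[b2]))                  # higher threshold is a subset
  expect_lte(sum(b2), sum(b1))

  m <- run$metric
  thr <- run$summary$dynamic_threshold
  d1 <- classify_dynamic(m, thr)
  d2 <- classify_dynamic(m, thr + 0.5)
  vessel1 <- b1 & d1; vessel2 <- b1 & d2
  expect_true(all(vessel1[vessel2]))
  expect_lte(sum(vessel2), sum(vessel1))
  bleed1 <- b1 & !d1; bleed2 <- b1 & !d2
  expect_gte(sum(bleed2), sum(bleed1))
})

test_that("label fusion is pure under pixel permutation", {
  set.seed(4)
  n <- 24
  blood <- matrix(runif(n) > 0.5, 6, 4)
  cortex <- matrix(runif(n) > 0.5, 6, 4) & !blood
  dyn <- matrix(runif(n) > 0.5, 6, 4)
  seg <- fuse_labels(list(blood = blood, cortex = cortex), dyn)
  perm <- sample(n)
  segp <- fuse_labels(list(blood = matrix(blood[perm], 6, 4),
                           cortex = matrix(cortex[perm], 6, 4)),
                      matrix(dyn[perm], 6, 4))
  expect_identical(as.vector(segp$labels), as.vector(seg$labels)[perm])
})
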
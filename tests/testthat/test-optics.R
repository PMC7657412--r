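ext <- small_ext()
bands <- default_band_centers()

test_that("absorption spectrum follows the blood-fraction mixing model", {
  # B = 0 removes both hemoglobin terms
  m0 <- tissue_model(B = 0, S = 0.5, mua0 = 0.01,
                     scat_prefactor = 2, scat_power = 1)
  expect_equal(absorption_spectrum(m0, ext, bands), rep(0.01, length(bands)))

  # B = 1, S = 1 reduces to the oxygenated-blood spectrum
  m1 <- tissue_model(B = 1, S = 1, mua0 = 0,
                     scat_prefactor = 2, scat_power = 1)
  e <- extinction_at(ext, bands)
  expect_equal(absorption_spectrum(m1, ext, bands), e$mua_hbo)

  # patient-1 blood parameters against elementwise arithmetic on the table
  blood <- tissue_preset("blood_patient1")
  expect_equal(absorption_spectrum(blood, ext, bands),
               0.99 * e$mua_hbo + 0.01 * e$mua_hbr + 0.001)

  # linear in B at fixed S
  mk <- function(B) tissue_model(B, 0.7, 0, 2, 1)
  expect_equal(absorption_spectrum(mk(0.6), ext, bands),
               3 * absorption_spectrum(mk(0.2), ext, bands))
})

test_that("absorption model validates inputs", {
  expect_error(tissue_model(1, 1.2, 0, 2, 1), "S must be")
  expect_error(tissue_model(-1, 0.5, 0, 2, 1), "B must be")
  expect_error(absorption_spectrum(tissue_preset("blood_patient1"), ext, 300),
               "outside")
})

test_that("reduced scattering power laws evaluate exactly", {
  blood <- tissue_preset("blood_patient1")
  cortex <- tissue_preset("cortex_patient1")
  expect_identical(reduced_scattering(blood, 500), 2.2)
  expect_identical(reduced_scattering(cortex, 500), 2.42)
  expect_equal(reduced_scattering(cortex, 630), 1.6485415231, tolerance = 1e-9)
  expect_error(reduced_scattering(blood, -10), "positive")
})

test_that("diffuse reflectance obeys the diffusion-approximation limits", {
  # lossless limit
  expect_equal(diffuse_reflectance(0, 2.0), 1)
  # monotone decreasing in absorption, increasing in scattering
  expect_gt(diffuse_reflectance(0.1, 2), diffuse_reflectance(0.5, 2))
  mua <- seq(0.01, 5, length.out = 40)
  r <- diffuse_reflectance(mua, 2)
  expect_true(all(diff(r) < 0))
  expect_true(all(r >= 0 & r <= 1))
  musp <- seq(0.5, 8, length.out = 40)
  expect_true(all(diff(diffuse_reflectance(0.3, musp)) > 0))
  # frozen independent evaluation of the closed form at transport albedo 0.5
  expect_equal(diffuse_reflectance(1, 1), 0.0738217822, tolerance = 1e-8)
  expect_error(diffuse_reflectance(-0.1, 1), ">= 0")
})

test_that("model reflectance spectra show hemoglobin structure", {
  blood <- model_reflectance_spectrum(tissue_preset("blood_patient1"), ext, bands)
  cortex <- model_reflectance_spectrum(tissue_preset("cortex_patient1"), ext, bands)
  # pronounced oxyhemoglobin absorption dip in the green vs the red edge
  green <- blood$reflectance[bands >= 540 & bands <= 580]
  red <- blood$reflectance[bands >= 620]
  expect_lt(max(green), min(red) / 5)
  # cortex (lower blood fraction) is brighter at every band
  expect_true(all(cortex$reflectance > blood$reflectance))
  # opaque limit
  opaque <- tissue_model(0, 0, 1e6, 2.2, 0.66)
  expect_true(all(model_reflectance_spectrum(opaque, ext, bands)$reflectance < 1e-6))
  # deterministic
  again <- model_reflectance_spectrum(tissue_preset("blood_patient1"), ext, bands)
  expect_identical(blood$reflectance, again$reflectance)
})

test_that("differential pathlength factor follows the CW closed form", {
  expect_equal(differential_pathlength(0.01, 1.0), 8.6602540378,
               tolerance = 1e-9)
  # monotone decreasing in absorption
  expect_gt(differential_pathlength(0.05, 1), differential_pathlength(0.1, 1))
  # invariant under joint rescaling of mua and mus' (property of this form)
  expect_equal(differential_pathlength(0.02, 1.4),
               differential_pathlength(0.1, 7.0))
  # positive and finite over the physiological range
  grid <- expand.grid(mua = c(1e-4, 0.01, 0.5, 10), musp = c(0.1, 1, 10))
  v <- differential_pathlength(grid$mua, grid$musp)
  expect_true(all(is.finite(v) & v > 0))
  expect_error(differential_pathlength(0, 1), "mua")
})

test_that("per-band DPF uses the model's own optical spectra", {
  cortex <- tissue_preset("cortex_patient1")
  dpf <- dpf_for_model(cortex, ext, bands)
  expect_identical(dpf$formula_id, "cw_semiinf_sqrt")
  manual <- 0.5 * sqrt(3 * reduced_scattering(cortex, bands) /
                         absorption_spectrum(cortex, ext, bands))
  expect_equal(dpf$dpf, manual)
})
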
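test_that("the generator is bit-reproducible under a fixed seed", {
  cfg <- small_synth(n_analytes = 6, n_decoys = 10, seed = 13)
  a <- simulate_samples(cfg)
  b <- simulate_samples(cfg)
  expect_identical(a$truth, b$truth)
  for (k in seq_along(a$sets)) {
    expect_identical(a$sets[[k]]$features, b$sets[[k]]$features)
    expect_identical(a$sets[[k]]$spectra, b$sets[[k]]$spectra)
  }
  dc1 <- simulate_dual_channel(cfg, ratios = 2)
  dc2 <- simulate_dual_channel(cfg, ratios = 2)
  expect_identical(dc1$set$features, dc2$set$features)
})

test_that("generated sets pass validation and round-trip through files", {
  cfg <- small_synth(n_analytes = 5, n_decoys = 8, seed = 3)
  sim <- simulate_samples(cfg)
  s <- sim$sets[[1]]
  tab <- withr::local_tempfile(fileext = ".tsv")
  mgf <- withr::local_tempfile(fileext = ".mgf")
  write_feature_table(s, tab, spectra_path = mgf)
  re <- read_feature_table(tab, spectra_path = mgf)
  expect_equal(nrow(re$features), nrow(s$features))
  expect_equal(re$features$mz, s$features$mz, tolerance = 1e-6)
  expect_equal(length(re$spectra), length(s$spectra))
})

test_that("a zero-noise config reproduces planted values exactly", {
  cfg <- synth_config(synthetic_analyte_panel(4, seed = 6), n_samples = 2,
                      seed = 8, n_decoys = 0, mz_error_ppm = 0,
                      rt_jitter_sd = 0, drift_jitter_sd = 0,
                      fragment_jitter_sd = 0, intensity_sdlog = 0)
  sim <- simulate_samples(cfg)
  f <- sim$sets[[1]]$features
  expect_equal(f$mz, sim$truth$mz_true, tolerance = 1e-12)
  expect_equal(f$rt_min, sim$truth$rt_true, tolerance = 1e-12)
  expect_equal(f$ccs_A2, sim$truth$ccs_true, tolerance = 1e-9)
  expect_equal(f$intensity, sim$truth$intensity_scale, tolerance = 1e-12)
})

test_that("empirical m/z error matches the configured ppm SD", {
  cfg <- synth_config(synthetic_analyte_panel(350, seed = 2), n_samples = 3,
                      seed = 17, n_decoys = 0)
  sim <- simulate_samples(cfg)
  errs <- unlist(lapply(sim$sets, function(s) {
    (s$features$mz - sim$truth$mz_true) / sim$truth$mz_true * 1e6
  }))
  expect_gte(length(errs), 1000)
  expect_lt(abs(sd(errs) / cfg$mz_error_ppm - 1), 0.2)
})

test_that("planted spectra carry diagnostics and decoys never do", {
  cfg <- small_synth(n_analytes = 6, n_decoys = 25, seed = 19)
  sim <- simulate_samples(cfg)
  s <- sim$sets[[1]]
  diag <- diagnostic_fragments("light")
  planted <- sim$truth$feature_id_S1
  for (id in planted) {
    mzs <- s$spectra[[id]]$mz
    expect_true(all(vapply(diag, function(d) any(abs(mzs - d) <= 0.1),
                           logical(1))))
  }
  decoys <- setdiff(s$features$feature_id, planted)
  for (id in decoys) {
    mzs <- s$spectra[[id]]$mz
    expect_false(any(abs(mzs - diag[1]) <= 0.1) ||
                   any(abs(mzs - diag[2]) <= 0.1))
  }
  # decoy precursors keep away from planted masses
  d_mz <- s$features$mz[s$features$feature_id %in% decoys]
  gaps <- vapply(d_mz, function(m) min(abs(m - sim$truth$mz_true)),
                 numeric(1))
  expect_true(all(gaps > 0.05))
})

test_that("dual-channel twins encode ratio, bias and the exact shift", {
  cfg <- synth_config(synthetic_analyte_panel(3, seed = 4), seed = 6,
                      n_decoys = 0, mz_error_ppm = 0, rt_jitter_sd = 0,
                      intensity_sdlog = 0)
  sim <- simulate_dual_channel(cfg, ratios = 4.1, heavy_bias = 0.7,
                               ratio_noise_sdlog = 0)
  f <- sim$set$features
  li <- match(sim$truth$light_id, f$feature_id)
  hi <- match(sim$truth$heavy_id, f$feature_id)
  expect_equal(f$mz[hi] - f$mz[li], rep(heavy_light_shift(), 4),
               tolerance = 1e-9)
  raw <- f$intensity[hi] / f$intensity[li]
  expect_equal(raw, c(4.1, 4.1, 4.1, 1) * 0.7, tolerance = 1e-9)
  rr <- relative_ratio(pair_light_heavy(sim$set),
                       attr(sim$truth, "is_light_id"))
  m <- match(sim$truth$light_id, rr$light_id)
  expect_equal(rr$corrected_ratio[m], c(4.1, 4.1, 4.1, 1), tolerance = 1e-9)
  expect_error(simulate_dual_channel(cfg, ratios = 2, is_name = ""),
               "internal-standard")
  expect_error(simulate_dual_channel(cfg, ratios = -1), "positive")
})

test_that("planting an analyte without formula or m/z is rejected", {
  bad <- data.frame(name = "x", rt_min = 5, ccs_A2 = 210,
                    intensity_scale = 1e4)
  expect_error(synth_config(bad), "mz|acid_formula")
})
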
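mixed_set <- function(rows, spectra = list()) {
  feature_set("mixed", rows, spectra = spectra)
}

test_that("a planted light/heavy twin is paired at the deuterium shift", {
  shift <- heavy_light_shift()
  s <- mixed_set(data.frame(
    feature_id = c("L", "H"),
    mz = c(481.3430, 481.3430 + shift),
    z = 1L, rt_min = 9.06, drift_ms = 27.11,
    intensity = c(1000, 4000)))
  pairs <- pair_light_heavy(s)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$light_id, "L")
  expect_equal(pairs$delta_mz_obs, shift, tolerance = 1e-6)
  expect_equal(pairs$raw_ratio, 4)
  expect_length(attr(pairs, "unpaired"), 0)
})

test_that("features outside the pairing tolerances stay unpaired", {
  s <- mixed_set(data.frame(
    feature_id = c("A", "B"),
    mz = c(481.34, 486.84), # 5.50 Da apart
    z = 1L, rt_min = 9.0, drift_ms = 27.1, intensity = c(10, 10)))
  pairs <- pair_light_heavy(s)
  expect_equal(nrow(pairs), 0)
  expect_setequal(attr(pairs, "unpaired"), c("A", "B"))
  # co-elution violation also blocks pairing
  s2 <- mixed_set(data.frame(
    feature_id = c("A", "B"),
    mz = c(481.3430, 481.3430 + heavy_light_shift()),
    z = 1L, rt_min = c(9.0, 9.5), drift_ms = 27.1, intensity = c(10, 10)))
  expect_equal(nrow(pair_light_heavy(s2)), 0)
})

test_that("the smaller-mass-error partner wins a two-candidate tie", {
  shift <- heavy_light_shift()
  s <- mixed_set(data.frame(
    feature_id = c("L", "H_far", "H_near"),
    mz = c(481.3430, 481.3430 + shift + 0.006, 481.3430 + shift + 0.001),
    z = 1L, rt_min = 9.0, drift_ms = 27.1, intensity = c(10, 10, 10)))
  pairs <- pair_light_heavy(s)
  expect_equal(pairs$heavy_id[pairs$light_id == "L"], "H_near")
})

test_that("IS correction fixes the IS ratio to 1 and rescues the bias", {
  shift <- heavy_light_shift()
  s <- mixed_set(data.frame(
    feature_id = c("L1", "H1", "Lis", "His"),
    mz = c(481.3430, 481.3430 + shift, 463.3325, 463.3325 + shift),
    z = 1L, rt_min = c(9, 9, 13, 13), drift_ms = c(27.1, 27.1, 26.8, 26.8),
    intensity = c(1000, 4000, 500, 500)))
  pairs <- relative_ratio(pair_light_heavy(s), "Lis")
  expect_equal(pairs$corrected_ratio[pairs$light_id == "Lis"], 1)
  expect_equal(pairs$corrected_ratio[pairs$light_id == "L1"], 4)
  expect_error(relative_ratio(pair_light_heavy(s), "nope"), "not found")
})

test_that("corrected ratios are exactly invariant to heavy-channel gain", {
  cfg <- synth_config(synthetic_analyte_panel(8, seed = 5), seed = 9,
                      n_decoys = 0)
  base <- simulate_dual_channel(cfg, ratios = c(0.5, 1, 2, 4),
                                ratio_noise_sdlog = 0.1)
  biased <- simulate_dual_channel(cfg, ratios = c(0.5, 1, 2, 4),
                                  heavy_bias = 3.7, ratio_noise_sdlog = 0.1)
  is_id <- attr(base$truth, "is_light_id")
  r0 <- relative_ratio(pair_light_heavy(base$set), is_id)
  r1 <- relative_ratio(pair_light_heavy(biased$set), is_id)
  m0 <- r0$corrected_ratio[match(r1$light_id, r0$light_id)]
  expect_equal(r1$corrected_ratio, m0, tolerance = 1e-12)
})

test_that("swapping channel labels inverts every corrected ratio", {
  cfg <- synth_config(synthetic_analyte_panel(6, seed = 2), seed = 4,
                      n_decoys = 0)
  sim <- simulate_dual_channel(cfg, ratios = c(0.5, 2, 4),
                               ratio_noise_sdlog = 0.05)
  is_id <- attr(sim$truth, "is_light_id")
  fwd <- relative_ratio(pair_light_heavy(sim$set), is_id)
  # swap: rebuild the set with intensities exchanged within each pair
  f <- sim$set$features
  li <- match(fwd$light_id, f$feature_id)
  hi <- match(fwd$heavy_id, f$feature_id)
  tmp <- f$intensity[li]
  f$intensity[li] <- f$intensity[hi]
  f$intensity[hi] <- tmp
  swapped <- feature_set("mixed", f, sim$set$spectra)
  rev <- relative_ratio(pair_light_heavy(swapped), is_id)
  m <- match(fwd$light_id, rev$light_id)
  expect_equal(rev$corrected_ratio[m], 1 / fwd$corrected_ratio,
               tolerance = 1e-9)
})

test_that("planted ratios are recovered with small bias under noise", {
  ratios <- c(0.5, 1, 2, 4)
  est <- matrix(NA_real_, 20, 4)
  for (seed in 1:20) {
    cfg <- synth_config(synthetic_analyte_panel(4, seed = 3), seed = seed,
                        n_decoys = 0)
    sim <- simulate_dual_channel(cfg, ratios = ratios, heavy_bias = 0.7,
                                 ratio_noise_sdlog = 0.1)
    rr <- relative_ratio(pair_light_heavy(sim$set),
                         attr(sim$truth, "is_light_id"))
    m <- match(sim$truth$light_id[1:4], rr$light_id)
    est[seed, ] <- rr$corrected_ratio[m]
  }
  bias <- colMeans(est) / ratios - 1
  expect_true(all(abs(bias) < 0.05))
})
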
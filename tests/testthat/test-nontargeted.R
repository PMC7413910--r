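test_that("diagnostic-fragment filter retains the worked plasma features", {
  sets <- table2_sets()
  for (s in sets) {
    kept <- ampp_fragment_filter(s)
    expect_equal(nrow(kept$features), 1)
  }
})

test_that("filter mode controls whether both diagnostics are required", {
  s <- feature_set("S1", data.frame(
    feature_id = c("both", "one", "none", "nospec"),
    mz = 465, z = 1L, rt_min = 10, drift_ms = 26, intensity = 100),
    spectra = list(
      both = data.frame(mz = c(169.05, 183.12), intensity = c(10, 10)),
      one = data.frame(mz = 183.1043, intensity = 10),
      none = data.frame(mz = 250.0, intensity = 10)))
  out_both <- ampp_fragment_filter(s, mode = "both")
  expect_identical(out_both$features$feature_id, "both")
  out_either <- ampp_fragment_filter(s, mode = "either")
  expect_setequal(out_either$features$feature_id, c("both", "one"))
  rep <- attr(out_both, "ampp_filter_report")
  expect_equal(rep$n_without_spectrum, 1)
  expect_equal(rep$n_input - rep$n_retained, 3)
  # idempotent, output subset of input
  again <- ampp_fragment_filter(out_both, mode = "both")
  expect_identical(again$features, out_both$features)
})

test_that("heavy-channel diagnostics are the +5 shifted windows", {
  s <- feature_set("S1", data.frame(
    feature_id = "H1", mz = 470, z = 1L, rt_min = 10, drift_ms = 26,
    intensity = 100),
    spectra = list(H1 = data.frame(mz = c(174.05, 188.12),
                                   intensity = c(10, 10))),
    channel = "heavy")
  expect_equal(nrow(ampp_fragment_filter(s)$features), 1)
  expect_equal(nrow(ampp_fragment_filter(s, channel = "light")$features), 0)
  # filtering a heavy set equals filtering its -5.0314-shifted light twin
  shift <- heavy_light_shift()
  twin <- feature_set("S1", s$features,
    spectra = list(H1 = data.frame(mz = c(174.05, 188.12) - shift,
                                   intensity = c(10, 10))),
    channel = "light")
  expect_identical(ampp_fragment_filter(s)$features$feature_id,
                   ampp_fragment_filter(twin)$features$feature_id)
})

test_that("top-N truncation orders by intensity then m/z", {
  set.seed(2)
  sp <- random_spectrum(30)
  expect_equal(nrow(top_n_fragments(sp, 25)), 25)
  expect_equal(nrow(top_n_fragments(random_spectrum(10), 25)), 10)
  tie <- data.frame(mz = c(300, 200), intensity = c(5, 5))
  expect_equal(top_n_fragments(tie, 1)$mz, 200)
  expect_error(top_n_fragments(sp, 0), ">= 1")
})

test_that("fragment overlap handles identity, disjointness and subsets", {
  set.seed(3)
  a <- random_spectrum(10)
  expect_equal(fragment_overlap(a, a), 1.0)
  b <- a
  b$mz <- b$mz + 5 # all peaks > tol apart
  expect_equal(fragment_overlap(a, b), 0.0)
  # superset with min denominator: extras do not dilute
  extra <- rbind(a, data.frame(mz = runif(15, 500, 900) ,
                               intensity = runif(15, 1, 100)))
  extra$mz <- pmin(extra$mz, 999)
  expect_equal(fragment_overlap(a, extra), 1.0)
  expect_warning(ov <- fragment_overlap(a, a[0, ]), "empty")
  expect_equal(ov, 0)
})

test_that("overlap is symmetric and matches the exhaustive oracle", {
  set.seed(11)
  for (k in 1:40) {
    na <- sample(1:8, 1)
    nb <- sample(1:8, 1)
    # cramped m/z range so tolerance conflicts actually occur
    a <- data.frame(mz = runif(na, 100, 100.6), intensity = runif(na, 1, 10))
    b <- data.frame(mz = runif(nb, 100, 100.6), intensity = runif(nb, 1, 10))
    ov_ab <- fragment_overlap(a, b, tol = 0.1)
    ov_ba <- fragment_overlap(b, a, tol = 0.1)
    expect_identical(ov_ab, ov_ba)
    oracle <- brute_force_match_count(a$mz, b$mz, 0.1) / min(na, nb)
    expect_equal(ov_ab, oracle)
  }
})

test_that("the worked three-plasma example yields one triplet consensus", {
  sets <- table2_sets()
  filtered <- lapply(sets, ampp_fragment_filter)
  # anchor-vs-member tolerances hold even though members straddle the anchor
  params <- match_params(min_overlap = 0.5)
  cons <- match_across_samples(filtered, params, anchor = "Plasma1")
  expect_equal(length(unique(cons$consensus_id)), 1)
  expect_equal(nrow(cons), 3)
  expect_setequal(cons$feature_id, c("547", "562", "565"))
  # anchored criteria: CCS spread 1.36 A2 and RT spread 0.11/0.10 min
  anchor <- cons[cons$is_anchor, ]
  expect_true(all(abs(cons$ccs_A2 - anchor$ccs_A2) <= 2.5))
  expect_true(all(abs(cons$rt_min - anchor$rt_min) <= 0.2))
  expect_true(all(abs(cons$mz - anchor$mz) / anchor$mz * 1e6 <= 10))
  rep <- consensus_report(cons)
  expect_equal(rep$n_members, 3)
  expect_equal(rep$ccs_A2, 233.06)
  # at the published >=0.80 threshold the curated fragment subsets
  # (6/11 shared between replicates 1 and 2) do not qualify
  strict <- match_across_samples(filtered, match_params(), "Plasma1")
  expect_equal(nrow(strict), 0)
})

test_that("tolerance violations block consensus formation", {
  mk <- function(id, sample, ccs, rt = 10, mz = 465.3454) {
    feature_set(sample, data.frame(
      feature_id = id, mz = mz, z = 1L, rt_min = rt, drift_ms = 26.8,
      ccs_A2 = ccs, intensity = 100),
      spectra = stats::setNames(list(data.frame(
        mz = c(169.0, 183.1, 250.0), intensity = c(3, 2, 1))), id))
  }
  # Delta-CCS 3.0 exceeds the 2.5 A2 criterion
  cons <- match_across_samples(list(mk("a", "S1", 230), mk("b", "S2", 233)),
                               match_params(), "S1")
  expect_equal(nrow(cons), 0)
  cons2 <- match_across_samples(list(mk("a", "S1", 230), mk("b", "S2", 231)),
                                match_params(), "S1")
  expect_equal(length(unique(cons2$consensus_id)), 1)
  expect_error(match_across_samples(list(mk("a", "S1", 230))), "at least 2")
  expect_error(match_across_samples(list(mk("a", "S1", 230),
                                         mk("b", "S2", 231)),
                                    match_params(), anchor = "S9"),
               "anchor")
})

test_that("planted triplicates are recovered exactly across seeds", {
  for (seed in 1:5) {
    cfg <- small_synth(n_analytes = 10, n_decoys = 20, seed = seed)
    sim <- simulate_samples(cfg)
    filtered <- lapply(sim$sets, ampp_fragment_filter)
    cons <- match_across_samples(filtered, match_params(), "S1")
    expect_equal(length(unique(cons$consensus_id)), 10)
    anchors <- cons$feature_id[cons$is_anchor]
    expect_setequal(anchors, sim$truth$feature_id_S1)
  }
})

test_that("consensus report annotates against the library", {
  lib <- load_reference_library()
  cfg <- synth_config(library_analytes(lib, c("9,10-DiHOME", "5-HETE")),
                      n_samples = 2, seed = 5, n_decoys = 0)
  sim <- simulate_samples(cfg)
  cons <- match_across_samples(sim$sets, match_params(), "S1")
  rep <- consensus_report(cons, lib)
  expect_setequal(rep$annotation, c("9,10-DiHOME", "5-HETE"))
  empty <- consensus_report(match_across_samples(
    table2_sets(), match_params(), "Plasma1"))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("mz", "n_members", "annotation") %in% names(empty)))
})
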
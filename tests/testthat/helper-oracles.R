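# Independent oracles and shared fixtures, built in code.

# Exhaustive maximum one-to-one matching count between two peak lists within
# a tolerance (recursion over the peaks of a; feasible for <= 8 peaks).
brute_force_match_count <- function(a_mz, b_mz, tol) {
  recurse <- function(i, used_b) {
    if (i > length(a_mz)) return(0L)
    best <- recurse(i + 1L, used_b) # leave a[i] unmatched
    for (j in seq_along(b_mz)) {
      if (!used_b[j] && abs(a_mz[i] - b_mz[j]) <= tol) {
        used_b2 <- used_b
        used_b2[j] <- TRUE
        best <- max(best, 1L + recurse(i + 1L, used_b2))
      }
    }
    best
  }
  recurse(1L, logical(length(b_mz)))
}

# Coarse-to-fine grid search for the single-field constants minimizing the
# drift-time SSE; independent of the lm-based fit. The search runs over
# (slope, centered intercept): centering the predictor makes the SSE
# surface separable so box refinement converges, and t_fix is recovered
# from the centered intercept afterwards.
grid_fit_single_field <- function(mz, drift_ms, ccs_A2,
                                  gas = 28.00615, iters = 60) {
  gamma <- sqrt(mz * gas / (mz + gas))
  x <- gamma * ccs_A2
  xc <- x - mean(x)
  sse <- function(beta, c0) sum((drift_ms - beta * xc - c0)^2)
  b_range <- c(1e-4, 0.1)
  c_range <- range(drift_ms) + c(-1, 1)
  for (it in seq_len(iters)) {
    bs <- seq(b_range[1], b_range[2], length.out = 21)
    cs <- seq(c_range[1], c_range[2], length.out = 21)
    vals <- outer(bs, cs, Vectorize(sse))
    best <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    b_step <- diff(b_range) / 20
    c_step <- diff(c_range) / 20
    b_range <- bs[best[1]] + c(-1, 1) * b_step
    c_range <- cs[best[2]] + c(-1, 1) * c_step
  }
  beta <- mean(b_range)
  c0 <- mean(c_range)
  list(beta = beta, t_fix = c0 - beta * mean(x))
}

# The three plasma replicate features of the worked consensus example:
# precursor/RT/drift/CCS plus the printed structural fragment lists
# (curated subsets, not full top-25 spectra). Fragment intensities are not
# printed; descending dummies preserve the listed order under top-N.
table2_sets <- function() {
  frag <- function(mz) data.frame(mz = mz,
                                  intensity = seq(100, by = -1,
                                                  length.out = length(mz)))
  p1 <- feature_set("Plasma1", data.frame(
    feature_id = "547", mz = 465.3454, z = 1L, rt_min = 15.31,
    drift_ms = 26.85, ccs_A2 = 233.06, intensity = 268569, q_score = 90),
    spectra = list("547" = frag(c(169.0862, 183.0893, 226.1078, 239.1159,
                                  267.1468, 316.2620, 335.1722, 352.2830,
                                  423.3098, 435.3093, 463.3313))))
  p2 <- feature_set("Plasma2", data.frame(
    feature_id = "562", mz = 465.3472, z = 1L, rt_min = 15.42,
    drift_ms = 26.89, ccs_A2 = 233.48, intensity = 232190, q_score = 90),
    spectra = list("562" = frag(c(156.1460, 159.0880, 169.0842, 183.0882,
                                  226.1064, 352.2802, 413.3243, 421.2935,
                                  423.3086, 435.3084, 451.3294))))
  p3 <- feature_set("Plasma3", data.frame(
    feature_id = "565", mz = 465.3462, z = 1L, rt_min = 15.21,
    drift_ms = 26.98, ccs_A2 = 234.42, intensity = 291112, q_score = 90),
    spectra = list("565" = frag(c(169.0881, 183.0909, 226.1092, 239.1170,
                                  254.1406, 267.1480, 307.1808, 335.1754,
                                  435.3124, 463.3328))))
  list(p1, p2, p3)
}

# Small planted scenario used by several workflow tests.
small_synth <- function(n_analytes = 12, n_decoys = 30, seed = 1,
                        n_samples = 3, ...) {
  synth_config(synthetic_analyte_panel(n_analytes, seed = seed + 1000),
               n_samples = n_samples, seed = seed, n_decoys = n_decoys, ...)
}

random_spectrum <- function(n, mz_range = c(150, 480)) {
  data.frame(mz = stats::runif(n, mz_range[1], mz_range[2]),
             intensity = stats::runif(n, 1, 100))
}
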
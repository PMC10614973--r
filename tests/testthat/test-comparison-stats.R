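mk_curve <- function(s, f = NULL) {
  structure(list(frequencies_cpd = if (is.null(f)) seq_along(s) else f,
                 sensitivities = s, params = NULL),
            class = "csf_curve")
}

test_that("the band partition assigns every analyzed frequency to exactly one band", {
  bands <- band_ranges()
  sw <- make_sweep()
  curve <- mk_curve(seq_along(sw$frequencies_cpd), sw$frequencies_cpd)
  n_bands <- vapply(c("low", "medium", "high"), function(b)
    length(band_slice(curve, b, bands)), numeric(1))
  n_analyzed <- sum(sw$frequencies_cpd <= 25)
  expect_equal(sum(n_bands), n_analyzed)
  # boundary membership: 4 goes to medium, 10 to high, 25 to high
  c2 <- mk_curve(1:6, c(0.5, 2, 4, 9.99, 10, 25))
  expect_equal(band_slice(c2, "low"), 1:2)
  expect_equal(band_slice(c2, "medium"), 3:4)
  expect_equal(band_slice(c2, "high"), 5:6)
  expect_error(band_slice(mk_curve(1:3, c(1, 2, 30)), "medium"),
               class = "dogcsf_band_resolution_error")
})

test_that("cosine similarity obeys identity, scale invariance and orthogonality", {
  v <- c(0.3, 1.2, 0.8)
  expect_equal(cosine_similarity(v, v), list(cos_sim = 1, theta_deg = 0))
  expect_equal(cosine_similarity(2 * v, v)$cos_sim, 1, tolerance = 1e-12)
  orth <- cosine_similarity(c(1, 0), c(0, 1))
  expect_equal(orth$cos_sim, 0)
  expect_equal(orth$theta_deg, 90)
  expect_error(cosine_similarity(c(0, 0, 0), v),
               class = "dogcsf_undefined_similarity_error")
  # scale invariance to 1e-12 under random positive scalings
  set.seed(7)
  for (i in 1:25) {
    u <- runif(10)
    w <- runif(10)
    s <- exp(runif(2, -3, 3))
    expect_equal(cosine_similarity(s[1] * u, s[2] * w)$cos_sim,
                 cosine_similarity(u, w)$cos_sim, tolerance = 1e-12)
  }
})

test_that("NDI measures normalized norm differences and is antisymmetric", {
  expect_identical(ndi(c(3, 0), c(1, 0)), 0.5)
  expect_identical(ndi(c(1, 1), c(1, 1)), 0)
  expect_identical(ndi(c(0, 0), c(0, 2)), -1)
  expect_error(ndi(c(0, 0), c(0, 0)), class = "dogcsf_undefined_ndi_error")
  set.seed(13)
  for (i in 1:25) {
    u <- runif(8)
    w <- runif(8)
    expect_equal(ndi(u, w), -ndi(w, u), tolerance = 1e-12)
    expect_lte(abs(ndi(u, w)), 1)
  }
})

test_that("band significance reproduces the paired t-test and its degenerate limits", {
  u <- c(1.0, 1.2, 0.9, 1.4, 1.1)
  v <- c(0.8, 1.0, 0.8, 1.1, 0.9)
  got <- band_significance(u, v)
  # independent oracle: the textbook paired-t formula
  d <- u - v
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  p_oracle <- 2 * pt(-abs(t_oracle), df = length(d) - 1)
  expect_equal(got$t_statistic, t_oracle)
  expect_equal(got$p_value, p_oracle)
  # sign flip negates t, keeps p
  flip <- band_significance(v, u)
  expect_equal(flip$t_statistic, -got$t_statistic)
  expect_equal(flip$p_value, got$p_value)
  # identical vectors
  same <- band_significance(u, u)
  expect_identical(same$t_statistic, 0)
  expect_identical(same$p_value, 1)
  # constant nonzero shift, zero variance: p = 0 convention
  shift <- band_significance(u + 1, u)
  expect_identical(shift$p_value, 0)
  # constant positive shift with tiny jitter is significant
  set.seed(3)
  jit <- band_significance(u + 0.5 + rnorm(5, sd = 1e-4), u)
  expect_lt(jit$p_value, 0.05)
})

test_that("curve self-comparison is the full identity result", {
  curve <- mk_curve(exp(-(log(make_sweep(0.1, 25, 40)$frequencies_cpd) - 1)^2),
                    make_sweep(0.1, 25, 40)$frequencies_cpd)
  cmp <- compare_curves(curve, curve)
  expect_true(all(cmp$table$ndi == 0))
  expect_true(all(cmp$table$theta_deg == 0))
  expect_true(all(cmp$table$outcome == "unchanged"))
  expect_identical(cmp$peak_shift_steps, 0L)
})

test_that("uniform scaling increases every band at unit cosine similarity", {
  f <- make_sweep(0.1, 25, 40)$frequencies_cpd
  base <- mk_curve(1 / (1 + f), f)
  scaled <- mk_curve(1.5 * base$sensitivities, f)
  cmp <- compare_curves(scaled, base)
  expect_true(all(cmp$table$outcome == "increased"))
  expect_equal(cmp$table$cos_sim, rep(1, 4), tolerance = 1e-12)
  expect_equal(cmp$table$ndi, rep(0.2, 4), tolerance = 1e-12)  # (1.5-1)/(1.5+1)
  expect_error(compare_curves(scaled, mk_curve(1:5, c(1, 2, 3, 4, 5))),
               class = "dogcsf_dimension_error")
})

test_that("strong concurrent inhibition increase slightly raises the high band", {
  # sigma_inh = Amp_inh = 2.0: the surround mass (C*Amp_inh*sigma_inh = 20)
  # then exceeds the center mass (B*Amp_ex*sigma_ex = 10.1), the net profile
  # inverts at low frequency, and the sign-blind peak-trough readout reports
  # a large low-band response; the high band, where the surround transform
  # has decayed, gains slightly.
  rep <- default_replication()
  row <- rep$results[rep$results$condition == "sigma_inh_2.0_amp_inh_2.0", ]
  expect_gt(row$ndi_high, 0)
  expect_lt(row$ndi_high, 0.01)
  expect_gt(row$ndi_low, 0)
})
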
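# Frozen parameter fixture for the built-in catalog: name -> the four
# receptive-field values each condition must carry.
catalog_fixture <- function() {
  read.csv(text = "
name,amp_ex,sigma_ex,amp_inh,sigma_inh
sigma_ex_0.8,1,0.8,1,1.6
sigma_ex_1.2,1,1.2,1,1.6
amp_ex_1.2,1.2,1,1,1.6
amp_ex_0.8,0.8,1,1,1.6
sigma_inh_2.0,1,1,1,2
sigma_inh_1.2,1,1,1,1.2
amp_inh_0.6,1,1,0.6,1.6
amp_inh_1.4,1,1,1.4,1.6
sigma_ex_0.6_amp_ex_0.6,0.6,0.6,1,1.6
sigma_ex_1.4_amp_ex_1.4,1.4,1.4,1,1.6
sigma_ex_0.6_amp_ex_1.4,1.4,0.6,1,1.6
sigma_ex_1.4_amp_ex_0.6,0.6,1.4,1,1.6
sigma_inh_1.2_amp_inh_0.6,1,1,0.6,1.2
sigma_inh_2.0_amp_inh_2.0,1,1,2,2
sigma_inh_1.2_amp_inh_2.0,1,1,2,1.2
sigma_inh_2.0_amp_inh_0.6,1,1,0.6,2
sigma_both_x0.9,1,0.9,1,1.44
sigma_both_x1.1,1,1.1,1,1.76
amp_both_x0.5,0.5,1,0.5,1.6
amp_both_x1.5,1.5,1,1.5,1.6
medicated_low_sf,1,1,2,2
medicated_med_high_sf,1,1.2,1,2
medicated_overall,0.5,1,0.5,1.6
unmedicated_low_sf,1,1,0.6,1.2
unmedicated_overall,1.4,0.6,1,1.6
", stringsAsFactors = FALSE)
}

test_that("the built-in catalog matches the frozen parameter fixture", {
  cat_ <- builtin_catalog()
  fix <- catalog_fixture()
  expect_gte(length(cat_), 20L)
  expect_setequal(names(cat_), fix$name)
  for (i in seq_len(nrow(fix))) {
    rf <- cat_[[fix$name[i]]]$params$rf
    expect_equal(
      c(rf$amp_ex, rf$sigma_ex, rf$amp_inh, rf$sigma_inh),
      c(fix$amp_ex[i], fix$sigma_ex[i], fix$amp_inh[i], fix$sigma_inh[i]),
      info = fix$name[i]
    )
  }
  # every condition keeps the fixed shunting constants and amplitude
  for (cond in cat_) {
    expect_equal(cond$params$shunting$upper_b, 10.1)
    expect_equal(cond$params$stimulus_amplitude, 0.1)
  }
})

test_that("the catalog carries the five patient best-fit signatures", {
  cat_ <- builtin_catalog()
  fits <- Filter(function(c) c$is_best_fit, cat_)
  expect_length(fits, 5L)
  groups <- vapply(fits, `[[`, character(1), "patient_group")
  expect_equal(sum(groups == "medicated"), 3L)
  expect_equal(sum(groups == "unmedicated"), 2L)
  expect_identical(cat_$medicated_overall$expected$low, "decreased")
  expect_identical(cat_$unmedicated_overall$expected$high, "increased")
})

test_that("a base-vs-base comparison passes trivially through the harness", {
  base_only <- list(base = structure(
    list(name = "base", params = model_params(), source = "control",
         expected = list(low = "unchanged", medium = "unchanged",
                         high = "unchanged"),
         expected_peak = "unchanged", expected_distinct_peak = TRUE,
         expected_pronounced_low_medium = NA,
         patient_group = "none", is_best_fit = FALSE),
    class = "csf_condition"))
  rep <- run_replication(base_only, small_sweep(), small_grid())
  expect_identical(rep$pass_fraction, 1)
  expect_true(all(rep$results$ndi_low == 0))
})

test_that("amplitude-ratio scalings rescale the curve without moving the peak", {
  rep <- default_replication()
  half <- rep$results[rep$results$condition == "amp_both_x0.5", ]
  expect_identical(half$outcome_low, "decreased")
  expect_identical(half$outcome_high, "decreased")
  expect_equal(half$ndi_low, -1 / 3, tolerance = 1e-3)   # 0.5x norm: (0.5-1)/(0.5+1)
  expect_lte(abs(half$peak_shift_steps), 1L)
  expect_true(half$pass)
})

test_that("excitatory amplitude manipulations replicate their reported signatures", {
  rep <- default_replication()
  up <- rep$results[rep$results$condition == "amp_ex_1.2", ]
  expect_true(all(c(up$outcome_low, up$outcome_medium, up$outcome_high) ==
                    "increased"))
  expect_lte(up$peak_shift_steps, -1L)
  down <- rep$results[rep$results$condition == "amp_ex_0.8", ]
  expect_true(all(c(down$outcome_low, down$outcome_medium, down$outcome_high) ==
                    "decreased"))
  expect_gte(down$peak_shift_steps, 1L)
  expect_true(down$has_distinct_peak)
  expect_true(down$pass)
})

test_that("the replication report scores agreement per condition and overall", {
  rep <- default_replication()
  expect_equal(nrow(rep$results), 25L)
  expect_true(all(rep$results$n_agree <= rep$results$n_checks))
  expect_gte(rep$pass_fraction, 0)
  expect_lte(rep$pass_fraction, 1)
  expect_identical(rep$pass_fraction, mean(rep$results$pass))
  # medicated best fits drive their target-band NDIs negative;
  # unmedicated the low-band positive
  expect_lt(rep$results$ndi_medium[rep$results$condition == "medicated_med_high_sf"], 0)
  expect_lt(rep$results$ndi_high[rep$results$condition == "medicated_med_high_sf"], 0)
  expect_lt(rep$results$ndi_overall[rep$results$condition == "medicated_overall"], 0)
  expect_gt(rep$results$ndi_low[rep$results$condition == "unmedicated_low_sf"], 0)
})
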
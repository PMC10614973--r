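new_condition <- function(name, rf, source,
                          expected = c(low = NA, medium = NA, high = NA),
                          expected_peak = NA_character_,
                          expected_distinct_peak = NA,
                          expected_pronounced_low_medium = NA,
                          patient_group = "none", is_best_fit = FALSE) {
  structure(
    list(
      name = name,
      params = model_params(rf = rf),
      source = source,
      expected = as.list(expected),
      expected_peak = expected_peak,           # "higher" / "lower" / "unchanged" / NA
      expected_distinct_peak = expected_distinct_peak,
      expected_pronounced_low_medium = expected_pronounced_low_medium,
      patient_group = patient_group,
      is_best_fit = is_best_fit
    ),
    class = "csf_condition"
  )
}

#' Built-in catalog of excitation/inhibition manipulations
#'
#' The named experimental conditions studied with this model: isolated and
#' concurrent changes of the excitatory and inhibitory subfield widths and
#' amplitudes, ratio-preserving receptive-field scalings, and the five
#' best-fit patient signatures (medicated / unmedicated schizophrenia
#' contrast-sensitivity phenotypes). Each condition carries its parameter
#' set, a provenance note, and the qualitative outcome reported for it:
#' per-band labels (`increased` / `decreased` / `mixed` / `NA` when
#' unstated), the expected peak-frequency shift direction, whether a
#' distinct peak is expected, and whether effects are expected to be more
#' pronounced at low-to-medium frequencies.
#'
#' @return A named list of `"csf_condition"` objects (25 conditions).
#' @examples
#' names(builtin_catalog())
#' @export
builtin_catalog <- function() {
  inc3 <- c(low = "increased", medium = "increased", high = "increased")
  dec3 <- c(low = "decreased", medium = "decreased", high = "decreased")
  conds <- list(
    # --- isolated excitatory-width changes
    new_condition("sigma_ex_0.8", rf_params(sigma_ex = 0.8),
      "isolated sigma_ex decrease (0.8)", inc3, "higher"),
    new_condition("sigma_ex_1.2", rf_params(sigma_ex = 1.2),
      "isolated sigma_ex increase (1.2)", dec3, "lower"),
    # --- isolated excitatory-amplitude changes
    new_condition("amp_ex_1.2", rf_params(amp_ex = 1.2),
      "isolated Amp_ex increase (1.2)", inc3, "lower",
      expected_distinct_peak = FALSE),
    new_condition("amp_ex_0.8", rf_params(amp_ex = 0.8),
      "isolated Amp_ex decrease (0.8)", dec3, "higher",
      expected_distinct_peak = TRUE),
    # --- isolated inhibitory-width changes
    new_condition("sigma_inh_2.0", rf_params(sigma_inh = 2.0),
      "isolated sigma_inh increase (2.0)", inc3, "higher",
      expected_distinct_peak = TRUE, expected_pronounced_low_medium = TRUE),
    new_condition("sigma_inh_1.2", rf_params(sigma_inh = 1.2),
      "isolated sigma_inh decrease (1.2)", dec3, "lower",
      expected_distinct_peak = FALSE, expected_pronounced_low_medium = TRUE),
    # --- isolated inhibitory-amplitude changes
    new_condition("amp_inh_0.6", rf_params(amp_inh = 0.6),
      "isolated Amp_inh decrease (0.6)", inc3, "lower",
      expected_distinct_peak = FALSE, expected_pronounced_low_medium = TRUE),
    new_condition("amp_inh_1.4", rf_params(amp_inh = 1.4),
      "isolated Amp_inh increase (1.4)", dec3, "higher",
      expected_distinct_peak = TRUE, expected_pronounced_low_medium = TRUE),
    # --- concurrent excitatory width x amplitude
    new_condition("sigma_ex_0.6_amp_ex_0.6",
      rf_params(sigma_ex = 0.6, amp_ex = 0.6),
      "concurrent sigma_ex & Amp_ex decrease (0.6, 0.6)",
      c(low = "decreased", medium = "mixed", high = "increased"), "higher"),
    new_condition("sigma_ex_1.4_amp_ex_1.4",
      rf_params(sigma_ex = 1.4, amp_ex = 1.4),
      "concurrent sigma_ex & Amp_ex increase (1.4, 1.4)",
      c(low = "increased", medium = "mixed", high = "decreased"), "lower",
      expected_distinct_peak = FALSE),
    new_condition("sigma_ex_0.6_amp_ex_1.4",
      rf_params(sigma_ex = 0.6, amp_ex = 1.4),
      "sigma_ex decrease with Amp_ex increase (0.6, 1.4)", inc3, "higher"),
    new_condition("sigma_ex_1.4_amp_ex_0.6",
      rf_params(sigma_ex = 1.4, amp_ex = 0.6),
      "sigma_ex increase with Amp_ex decrease (1.4, 0.6)", dec3, "lower"),
    # --- concurrent inhibitory width x amplitude
    new_condition("sigma_inh_1.2_amp_inh_0.6",
      rf_params(sigma_inh = 1.2, amp_inh = 0.6),
      "concurrent sigma_inh & Amp_inh decrease (1.2, 0.6)",
      c(low = "increased", medium = "increased", high = "decreased"),
      expected_distinct_peak = FALSE),
    new_condition("sigma_inh_2.0_amp_inh_2.0",
      rf_params(sigma_inh = 2.0, amp_inh = 2.0),
      "concurrent sigma_inh & Amp_inh increase (2.0, 2.0)",
      c(low = "decreased", medium = "decreased", high = "increased"),
      "higher", expected_distinct_peak = TRUE),
    new_condition("sigma_inh_1.2_amp_inh_2.0",
      rf_params(sigma_inh = 1.2, amp_inh = 2.0),
      "sigma_inh decrease with Amp_inh increase (1.2, 2.0)", dec3, "higher",
      expected_distinct_peak = TRUE),
    new_condition("sigma_inh_2.0_amp_inh_0.6",
      rf_params(sigma_inh = 2.0, amp_inh = 0.6),
      "sigma_inh increase with Amp_inh decrease (2.0, 0.6)", inc3,
      expected_distinct_peak = FALSE),
    # --- ratio-preserving receptive-field scalings
    new_condition("sigma_both_x0.9",
      rf_params(sigma_ex = 0.9, sigma_inh = 1.44),
      "both sigma x 0.9, 1:1.6 ratio kept", inc3),
    new_condition("sigma_both_x1.1",
      rf_params(sigma_ex = 1.1, sigma_inh = 1.76),
      "both sigma x 1.1, 1:1.6 ratio kept", dec3),
    new_condition("amp_both_x0.5",
      rf_params(amp_ex = 0.5, amp_inh = 0.5),
      "both Amp x 0.5, 1:1 ratio kept", dec3, "unchanged"),
    new_condition("amp_both_x1.5",
      rf_params(amp_ex = 1.5, amp_inh = 1.5),
      "both Amp x 1.5, 1:1 ratio kept", inc3, "lower"),
    # --- best-fit patient signatures (directions with magnitudes taken from
    #     the corresponding single/concurrent-change conditions above)
    new_condition("medicated_low_sf",
      rf_params(sigma_inh = 2.0, amp_inh = 2.0),
      "up sigma_inh & up Amp_inh (2.0, 2.0): decreased sensitivity at low SF",
      c(low = "decreased", medium = NA, high = NA),
      patient_group = "medicated", is_best_fit = TRUE),
    new_condition("medicated_med_high_sf",
      rf_params(sigma_ex = 1.2, sigma_inh = 2.0),
      "up sigma_ex & up sigma_inh (1.2, 2.0): decreased sensitivity at medium/high SF",
      c(low = NA, medium = "decreased", high = "decreased"),
      patient_group = "medicated", is_best_fit = TRUE),
    new_condition("medicated_overall",
      rf_params(amp_ex = 0.5, amp_inh = 0.5),
      "down Amp_ex & down Amp_inh (0.5, 0.5): overall decreased sensitivity",
      dec3, patient_group = "medicated", is_best_fit = TRUE),
    new_condition("unmedicated_low_sf",
      rf_params(sigma_inh = 1.2, amp_inh = 0.6),
      "down sigma_inh & down Amp_inh (1.2, 0.6): increased sensitivity at low SF",
      c(low = "increased", medium = NA, high = NA),
      patient_group = "unmedicated", is_best_fit = TRUE),
    new_condition("unmedicated_overall",
      rf_params(sigma_ex = 0.6, amp_ex = 1.4),
      "down sigma_ex & up Amp_ex (0.6, 1.4): overall increased sensitivity",
      inc3, patient_group = "unmedicated", is_best_fit = TRUE)
  )
  names(conds) <- vapply(conds, `[[`, character(1), "name")
  conds
}

# Band-mean relative change over low+medium vs high: operationalizes
# "effects more pronounced at low to medium spatial frequencies".
pronounced_low_medium <- function(curve, base, bands = band_ranges()) {
  freqs <- curve$frequencies_cpd
  lm <- band_member(freqs, bands$lower[1], bands$upper[2], FALSE)
  hi <- band_member(freqs, bands$lower[3], bands$upper[3], TRUE)
  rel <- (curve$sensitivities - base$sensitivities) / base$sensitivities
  abs(mean(rel[lm])) > abs(mean(rel[hi]))
}

#' Run the replication battery over a condition catalog
#'
#' Simulates the base curve and every condition curve, compares each against
#' base with [compare_curves()], and checks the observed band outcomes, peak
#' shift, distinct-peak flag and low/medium-dominance against the
#' condition's recorded expectations. Expectations recorded as `NA` or
#' `"mixed"` are not scored. Peak shifts smaller than one sweep step count
#' as "unchanged".
#'
#' @param catalog A list of conditions from [builtin_catalog()].
#' @param sweep,grid,deg_per_unit Simulation settings (see [run_csf()]).
#' @param bands A [band_ranges()] partition.
#' @param ndi_threshold,prominence_threshold Passed to [compare_curves()].
#' @return An object of class `"replication_report"`: list with `results`
#'   (data frame, one row per condition: observed outcomes, NDIs, checks,
#'   `pass`), `comparisons` (named list of `"csf_comparison"`),
#'   `base_curve`, `curves`, and `pass_fraction` (conditions with all scored
#'   expectations met / conditions scored).
#' @export
run_replication <- function(catalog = builtin_catalog(), sweep = make_sweep(),
                            grid = make_grid(), bands = band_ranges(),
                            ndi_threshold = 0.01, prominence_threshold = 0.05,
                            deg_per_unit = DEG_PER_UNIT_DEFAULT) {
  base_curve <- run_csf(model_params(), sweep, grid, deg_per_unit)
  comparisons <- list()
  curves <- list()
  rows <- lapply(catalog, function(cond) {
    curve <- run_csf(cond$params, sweep, grid, deg_per_unit)
    cmp <- compare_curves(curve, base_curve, bands, ndi_threshold,
                          prominence_threshold)
    curves[[cond$name]] <<- curve
    comparisons[[cond$name]] <<- cmp
    tb <- cmp$table
    obs <- stats::setNames(tb$outcome, tb$band)
    nd <- stats::setNames(tb$ndi, tb$band)
    checks <- logical(0)
    for (b in c("low", "medium", "high")) {
      exp_b <- cond$expected[[b]]
      if (!is.na(exp_b) && exp_b != "mixed") {
        checks[paste0("band_", b)] <- identical(unname(obs[[b]]), exp_b)
      }
    }
    if (!is.na(cond$expected_peak)) {
      shift <- cmp$peak_shift_steps
      checks["peak"] <- switch(cond$expected_peak,
        higher = shift >= 1L,
        lower = shift <= -1L,
        unchanged = abs(shift) <= 1L,
        FALSE)
    }
    if (!is.na(cond$expected_distinct_peak)) {
      checks["distinct_peak"] <-
        identical(cmp$curve_peak$has_distinct_peak, cond$expected_distinct_peak)
    }
    if (!is.na(cond$expected_pronounced_low_medium)) {
      checks["pronounced_low_medium"] <-
        identical(pronounced_low_medium(curve, base_curve, bands),
                  cond$expected_pronounced_low_medium)
    }
    data.frame(
      condition = cond$name,
      patient_group = cond$patient_group,
      is_best_fit = cond$is_best_fit,
      outcome_low = obs[["low"]], outcome_medium = obs[["medium"]],
      outcome_high = obs[["high"]],
      ndi_low = nd[["low"]], ndi_medium = nd[["medium"]],
      ndi_high = nd[["high"]], ndi_overall = nd[["overall"]],
      peak_shift_steps = cmp$peak_shift_steps,
      has_distinct_peak = cmp$curve_peak$has_distinct_peak,
      n_checks = length(checks),
      n_agree = sum(checks),
      pass = length(checks) == 0L || all(checks),
      stringsAsFactors = FALSE
    )
  })
  results <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(
    list(
      results = results,
      comparisons = comparisons,
      base_curve = base_curve,
      curves = curves,
      pass_fraction = mean(results$pass)
    ),
    class = "replication_report"
  )
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf("<replication_report> %d conditions, pass fraction %.3f\n",
              nrow(x$results), x$pass_fraction))
  tb <- x$results[, c("condition", "outcome_low", "outcome_medium",
                      "outcome_high", "peak_shift_steps", "has_distinct_peak",
                      "n_agree", "n_checks", "pass")]
  print(tb, row.names = FALSE)
  invisible(x)
}
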
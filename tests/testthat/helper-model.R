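# Shared fixtures. Small grids keep unit tests fast; acceptance tests use
# the full default configuration. Expensive shared computations (the default
# battery) are cached per test session.

small_grid <- function() make_grid(1000L, 10)       # 100 samples/deg, Nyquist 50
small_sweep <- function(mode = "logarithmic") make_sweep(0.1, 25, 60L, mode)

.dogcsf_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .dogcsf_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .dogcsf_cache)
  }
  get(key, envir = .dogcsf_cache, inherits = FALSE)
}

# Base-condition curve on the default grid/sweep (used by several files).
default_base_curve <- function() {
  cached("base_curve", run_csf(model_params(), make_sweep(), make_grid()))
}

default_replication <- function() {
  cached("replication", run_replication())
}

# Directional-property suite of the study's figure manipulations, evaluated
# on the analyzed range [0.1, 25] cpd. Each row records whether the stated
# qualitative property holds for the simulated curves. Strict claims are
# pointwise over every sweep frequency <= 25 cpd; band claims use band NDI
# signs; "pronounced" claims compare band-mean relative change in
# low+medium against high; peak claims use argmax shifts in sweep steps.
directional_suite <- function(sweep = make_sweep(), grid = make_grid()) {
  bands <- band_ranges()
  base <- run_csf(model_params(), sweep, grid)
  keep <- sweep$frequencies_cpd <= 25
  db <- describe_curve(base)
  curve_for <- function(rf) run_csf(model_params(rf = rf), sweep, grid)
  rel_gain <- function(curve, region) {
    f <- curve$frequencies_cpd
    m <- if (region == "low_medium") f >= 0.1 & f < 10 else f >= 10 & f <= 25
    mean((curve$sensitivities[m] - base$sensitivities[m]) / base$sensitivities[m])
  }
  band_ndi <- function(curve, b) {
    ndi(band_slice(curve, b, bands), band_slice(base, b, bands))
  }
  check <- function(name, rf, claims) {
    curve <- curve_for(rf)
    dc <- describe_curve(curve)
    s <- curve$sensitivities[keep]
    b <- base$sensitivities[keep]
    shift <- dc$peak_index - db$peak_index
    ok <- vapply(claims, function(cl) {
      switch(cl,
        greater_everywhere = all(s > b),
        lower_everywhere = all(s < b),
        peak_higher = shift >= 1L,
        peak_lower = shift <= -1L,
        peak_unchanged = abs(shift) <= 1L,
        gain_low_medium = rel_gain(curve, "low_medium") > rel_gain(curve, "high"),
        loss_low_medium = rel_gain(curve, "low_medium") < rel_gain(curve, "high"),
        gain_medium_largest = {
          g <- vapply(c("low", "medium", "high"), function(bb)
            mean((band_slice(curve, bb, bands) - band_slice(base, bb, bands)) /
                   band_slice(base, bb, bands)), numeric(1))
          which.max(g) == 2L
        },
        more_distinct = dc$peak_prominence > db$peak_prominence,
        no_distinct_peak = !dc$has_distinct_peak,
        distinct_peak = dc$has_distinct_peak,
        low_band_decreased = band_ndi(curve, "low") < 0,
        low_band_increased = band_ndi(curve, "low") > 0,
        high_band_increased = band_ndi(curve, "high") > 0,
        stop("unknown claim: ", cl))
    }, logical(1))
    data.frame(condition = name, claim = claims, holds = ok,
               stringsAsFactors = FALSE)
  }
  rows <- list(
    check("sigma_ex_0.8", rf_params(sigma_ex = 0.8),
          c("greater_everywhere", "peak_higher")),
    check("sigma_ex_1.2", rf_params(sigma_ex = 1.2),
          c("lower_everywhere", "peak_lower")),
    check("amp_ex_1.2", rf_params(amp_ex = 1.2),
          c("greater_everywhere", "peak_lower")),
    check("amp_ex_0.8", rf_params(amp_ex = 0.8),
          c("lower_everywhere", "peak_higher")),
    check("sigma_inh_2.0", rf_params(sigma_inh = 2.0),
          c("greater_everywhere", "gain_low_medium", "more_distinct")),
    check("sigma_inh_1.2", rf_params(sigma_inh = 1.2),
          c("lower_everywhere", "loss_low_medium")),
    check("amp_inh_0.6", rf_params(amp_inh = 0.6),
          c("greater_everywhere", "gain_low_medium", "no_distinct_peak")),
    check("amp_inh_1.4", rf_params(amp_inh = 1.4),
          c("lower_everywhere", "loss_low_medium", "peak_higher")),
    check("sigma_ex_0.6_amp_ex_0.6", rf_params(sigma_ex = 0.6, amp_ex = 0.6),
          c("low_band_decreased", "high_band_increased", "peak_higher")),
    check("sigma_ex_0.6_amp_ex_1.4", rf_params(sigma_ex = 0.6, amp_ex = 1.4),
          c("greater_everywhere", "peak_higher")),
    check("sigma_inh_1.2_amp_inh_2.0", rf_params(sigma_inh = 1.2, amp_inh = 2.0),
          c("lower_everywhere", "distinct_peak", "peak_higher")),
    check("sigma_inh_2.0_amp_inh_0.6", rf_params(sigma_inh = 2.0, amp_inh = 0.6),
          c("greater_everywhere", "no_distinct_peak")),
    check("sigma_both_x0.9", rf_params(sigma_ex = 0.9, sigma_inh = 1.44),
          c("greater_everywhere", "gain_medium_largest")),
    check("sigma_both_x1.1", rf_params(sigma_ex = 1.1, sigma_inh = 1.76),
          c("lower_everywhere")),
    check("amp_both_x0.5", rf_params(amp_ex = 0.5, amp_inh = 0.5),
          c("lower_everywhere", "peak_unchanged")),
    check("amp_both_x1.5", rf_params(amp_ex = 1.5, amp_inh = 1.5),
          c("greater_everywhere", "peak_lower"))
  )
  # Table-3 best-fit patient signatures: required band-NDI signs.
  sig <- function(name, rf, band, sign) {
    curve <- curve_for(rf)
    nd <- vapply(band, function(b) band_ndi(curve, b), numeric(1))
    data.frame(condition = name,
               claim = paste0("ndi_", band, if (sign > 0) "_positive" else "_negative"),
               holds = if (sign > 0) nd > 0 else nd < 0,
               stringsAsFactors = FALSE)
  }
  rows <- c(rows, list(
    sig("medicated_low_sf", rf_params(sigma_inh = 2.0, amp_inh = 2.0), "low", -1),
    sig("medicated_med_high_sf", rf_params(sigma_ex = 1.2, sigma_inh = 2.0),
        c("medium", "high"), -1),
    sig("medicated_overall", rf_params(amp_ex = 0.5, amp_inh = 0.5),
        c("low", "medium", "high"), -1),
    sig("unmedicated_low_sf", rf_params(sigma_inh = 1.2, amp_inh = 0.6), "low", 1),
    sig("unmedicated_overall", rf_params(sigma_ex = 0.6, amp_ex = 1.4),
        c("low", "medium", "high"), 1)
  ))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
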
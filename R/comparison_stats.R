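#' Spatial-frequency band partition
#'
#' The low / medium / high analysis bands: `[0.1, 4)`, `[4, 10)` and
#' `[10, 25]` cycles per degree. Interior boundaries are half-open so every
#' frequency in the analyzed union `[0.1, 25]` belongs to exactly one band;
#' the final band is closed at 25.
#'
#' @param low,medium,high Numeric length-2 vectors giving band edges in cpd.
#' @return A data frame of class `"band_ranges"` with columns `band`,
#'   `lower`, `upper`, `closed_upper`.
#' @export
band_ranges <- function(low = c(0.1, 4), medium = c(4, 10), high = c(10, 25)) {
  bands <- data.frame(
    band = c("low", "medium", "high"),
    lower = c(low[1], medium[1], high[1]),
    upper = c(low[2], medium[2], high[2]),
    closed_upper = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  if (any(bands$lower >= bands$upper) ||
      any(bands$upper[-3] != bands$lower[-1])) {
    stop_dogcsf("bands must be ordered, non-empty and contiguous",
                "dogcsf_invalid_argument")
  }
  class(bands) <- c("band_ranges", "data.frame")
  bands
}

band_member <- function(freqs, lower, upper, closed_upper) {
  freqs >= lower & (freqs < upper | (closed_upper & freqs <= upper))
}

#' Extract a band's sensitivity sub-vector
#'
#' @param curve A [run_csf()] curve.
#' @param band Either a band name (`"low"`, `"medium"`, `"high"`) resolved
#'   against `bands`, or a numeric length-2 interval (half-open on the right).
#' @param bands A [band_ranges()] partition (used when `band` is a name).
#' @return The sensitivities at frequencies inside the band.
#' @export
band_slice <- function(curve, band, bands = band_ranges()) {
  stopifnot(inherits(curve, "csf_curve"))
  if (is.character(band)) {
    row <- bands[bands$band == band, ]
    if (nrow(row) != 1L) {
      stop_dogcsf(sprintf("unknown band '%s'", band), "dogcsf_invalid_argument")
    }
    keep <- band_member(curve$frequencies_cpd, row$lower, row$upper,
                        row$closed_upper)
  } else {
    keep <- band_member(curve$frequencies_cpd, band[1], band[2], FALSE)
  }
  if (sum(keep) < 2L) {
    stop_dogcsf("fewer than 2 sweep frequencies fall inside the band; refine the sweep",
                "dogcsf_band_resolution_error")
  }
  curve$sensitivities[keep]
}

#' Cosine similarity between two sensitivity vectors
#'
#' `cosSim = (u . v) / (|u| |v|)`, with the associated angle
#' `theta = arccos(cosSim)` in degrees. The cosine is clamped to `[-1, 1]`
#' before `arccos` to absorb rounding. Scale-invariant in either argument.
#'
#' @param msv,mbcsv Equal-length numeric vectors (length >= 2, both with
#'   positive norm): the condition and base model sensitivity vectors.
#' @return A list with `cos_sim` and `theta_deg`.
#' @export
cosine_similarity <- function(msv, mbcsv) {
  if (length(msv) != length(mbcsv) || length(msv) < 2L) {
    stop_dogcsf("vectors must have equal length >= 2", "dogcsf_dimension_error")
  }
  nu <- sqrt(sum(msv^2))
  nv <- sqrt(sum(mbcsv^2))
  if (nu == 0 || nv == 0) {
    stop_dogcsf("cosine similarity is undefined for a zero-norm vector",
                "dogcsf_undefined_similarity_error")
  }
  cs <- sum(msv * mbcsv) / (nu * nv)
  cs <- min(1, max(-1, cs))
  list(cos_sim = cs, theta_deg = acos(cs) * 180 / pi)
}

#' Normalized difference index
#'
#' `NDI = (|MSV| - |MBCSV|) / (|MSV| + |MBCSV|)` with `|.|` the Euclidean
#' norm: a signed, scale-free measure in `[-1, 1]` of how much larger the
#' condition curve is than the base curve. Antisymmetric in its arguments.
#'
#' @inheritParams cosine_similarity
#' @return A single number in `[-1, 1]`.
#' @export
ndi <- function(msv, mbcsv) {
  if (length(msv) != length(mbcsv)) {
    stop_dogcsf("vectors must have equal length", "dogcsf_dimension_error")
  }
  nu <- sqrt(sum(msv^2))
  nv <- sqrt(sum(mbcsv^2))
  if (nu + nv == 0) {
    stop_dogcsf("NDI is undefined when both vectors are zero",
                "dogcsf_undefined_ndi_error")
  }
  (nu - nv) / (nu + nv)
}

#' Band-wise significance of a sensitivity change
#'
#' Two-sided paired t-test on the per-frequency differences
#' `msv_i - mbcsv_i` within a band. A band NDI is a single scalar, so the
#' test is constructed on the per-frequency differences instead (this
#' package's convention; alpha = 0.05 when interpreting). Degenerate cases:
#' identical vectors give `t = 0, p = 1`; zero-variance differences with a
#' nonzero mean give `t = +/-Inf, p = 0`.
#'
#' @param msv_band,mbcsv_band Equal-length band sub-vectors (length >= 3).
#' @return A list with `t_statistic`, `p_value` and `df`.
#' @export
band_significance <- function(msv_band, mbcsv_band) {
  if (length(msv_band) != length(mbcsv_band) || length(msv_band) < 3L) {
    stop_dogcsf("band vectors must have equal length >= 3",
                "dogcsf_dimension_error")
  }
  d <- msv_band - mbcsv_band
  degenerate <- function() {
    if (mean(d) == 0) {
      list(t_statistic = 0, p_value = 1, df = length(d) - 1L)
    } else {
      list(t_statistic = sign(mean(d)) * Inf, p_value = 0,
           df = length(d) - 1L)
    }
  }
  if (sd(d) == 0) return(degenerate())
  # t.test itself refuses near-constant differences (stderr below ~10*eps of
  # the mean); treat that the same way as exactly constant ones
  tt <- tryCatch(t.test(msv_band, mbcsv_band, paired = TRUE),
                 error = function(e) NULL)
  if (is.null(tt)) return(degenerate())
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Compare a condition curve against the base curve
#'
#' Computes cosine similarity, angle, NDI and the paired per-frequency test
#' for each spatial-frequency band and for the analyzed union (`overall`,
#' 0.1-25 cpd; sensitivities above the high band are numerically negligible
#' and excluded from norms), plus the peak shift in sweep steps and a
#' qualitative outcome label per band: `increased` when `ndi >
#' ndi_threshold`, `decreased` when `ndi < -ndi_threshold`, else
#' `unchanged`.
#'
#' @param curve,base Two [run_csf()] curves on identical frequency grids.
#' @param bands A [band_ranges()] partition.
#' @param ndi_threshold Band-NDI magnitude below which the band counts as
#'   unchanged (default 0.01).
#' @param prominence_threshold Passed to [describe_curve()].
#' @return An object of class `"csf_comparison"`: list with `table` (one row
#'   per band plus `overall`: `band`, `n`, `cos_sim`, `theta_deg`, `ndi`,
#'   `t`, `p`, `outcome`), `peak_shift_steps`, and the two
#'   [describe_curve()] summaries (`curve_peak`, `base_peak`).
#' @export
compare_curves <- function(curve, base, bands = band_ranges(),
                           ndi_threshold = 0.01, prominence_threshold = 0.05) {
  stopifnot(inherits(curve, "csf_curve"), inherits(base, "csf_curve"))
  if (length(curve$frequencies_cpd) != length(base$frequencies_cpd) ||
      any(curve$frequencies_cpd != base$frequencies_cpd)) {
    stop_dogcsf("curves are sampled on different frequency grids",
                "dogcsf_dimension_error")
  }
  freqs <- curve$frequencies_cpd
  overall_lo <- min(bands$lower)
  overall_hi <- max(bands$upper)
  segments <- c(split(bands, seq_len(nrow(bands))), list(overall = NULL))
  rows <- lapply(seq_along(segments), function(j) {
    seg <- segments[[j]]
    if (is.null(seg)) {
      keep <- band_member(freqs, overall_lo, overall_hi, TRUE)
      label <- "overall"
    } else {
      keep <- band_member(freqs, seg$lower, seg$upper, seg$closed_upper)
      label <- seg$band
    }
    u <- curve$sensitivities[keep]
    v <- base$sensitivities[keep]
    cs <- cosine_similarity(u, v)
    sig <- band_significance(u, v)
    nd <- ndi(u, v)
    outcome <- if (nd > ndi_threshold) "increased"
               else if (nd < -ndi_threshold) "decreased"
               else "unchanged"
    data.frame(band = label, n = length(u), cos_sim = cs$cos_sim,
               theta_deg = cs$theta_deg, ndi = nd, t = sig$t_statistic,
               p = sig$p_value, outcome = outcome, stringsAsFactors = FALSE)
  })
  dc <- describe_curve(curve, prominence_threshold)
  db <- describe_curve(base, prominence_threshold)
  structure(
    list(
      table = do.call(rbind, rows),
      peak_shift_steps = dc$peak_index - db$peak_index,
      curve_peak = dc,
      base_peak = db
    ),
    class = "csf_comparison"
  )
}

#' @export
print.csf_comparison <- function(x, ...) {
  cat("<csf_comparison>\n")
  tb <- x$table
  tb$cos_sim <- signif(tb$cos_sim, 6)
  tb$theta_deg <- signif(tb$theta_deg, 4)
  tb$ndi <- signif(tb$ndi, 4)
  tb$t <- signif(tb$t, 4)
  tb$p <- signif(tb$p, 3)
  print(tb, row.names = FALSE)
  cat(sprintf("peak shift: %+d sweep steps (%.3g -> %.3g cpd)\n",
              x$peak_shift_steps, x$base_peak$peak_frequency_cpd,
              x$curve_peak$peak_frequency_cpd))
  invisible(x)
}
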
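#' Spatial sampling grid for the model neuron array
#'
#' Discretizes one dimension of visual space into `n_samples` cells over
#' `extent_deg` degrees of visual angle, one model neuron (and one stimulus
#' sample) per cell. Sample positions sit at cell centers,
#' `(k + 0.5) * spacing_deg` for `k = 0 .. n_samples - 1`.
#'
#' @param n_samples Number of model neurons / stimulus positions (>= 2).
#'   Default 4000.
#' @param extent_deg Width of the simulated visual field in degrees (> 0).
#'   Default 10, giving 400 samples per degree and a Nyquist limit of
#'   200 cycles/degree, comfortably above the 100 cpd sweep maximum.
#' @return An object of class `"sampling_grid"`: a list with `n_samples`,
#'   `extent_deg`, `spacing_deg` and `positions_deg`.
#' @examples
#' g <- make_grid(4000, 10)
#' g$spacing_deg        # 0.0025 deg
#' nyquist_cpd(g)       # 200 cpd
#' @export
make_grid <- function(n_samples = 4000L, extent_deg = 10) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || !is.finite(n_samples) ||
      n_samples < 2 || n_samples != round(n_samples)) {
    stop_dogcsf("`n_samples` must be a single integer >= 2",
                "dogcsf_invalid_argument")
  }
  check_scalar(extent_deg, "extent_deg")
  n_samples <- as.integer(n_samples)
  spacing <- extent_deg / n_samples
  structure(
    list(
      n_samples = n_samples,
      extent_deg = extent_deg,
      spacing_deg = spacing,
      positions_deg = (seq_len(n_samples) - 0.5) * spacing
    ),
    class = "sampling_grid"
  )
}

#' @export
print.sampling_grid <- function(x, ...) {
  cat(sprintf(
    "<sampling_grid> %d samples over %g deg (%.6g deg spacing, Nyquist %.4g cpd)\n",
    x$n_samples, x$extent_deg, x$spacing_deg, nyquist_cpd(x)))
  invisible(x)
}

#' Nyquist frequency of a sampling grid
#'
#' Highest spatial frequency (cycles/degree) representable without aliasing:
#' half the sampling rate, `1 / (2 * spacing_deg)`.
#'
#' @param grid A [make_grid()] object.
#' @return Nyquist frequency in cycles per degree.
#' @export
nyquist_cpd <- function(grid) {
  stopifnot(inherits(grid, "sampling_grid"))
  1 / (2 * grid$spacing_deg)
}

#' Sinusoidal luminance grating sampled on a grid
#'
#' Generates `value[k] = dc_offset + amplitude * sin(2 * pi * f * position_k)`
#' with positions in degrees and `f` in cycles per degree. Phase is fixed at
#' zero and the modulation is signed about `dc_offset` (default 0).
#'
#' @param grid A [make_grid()] object.
#' @param frequency_cpd Spatial frequency in cycles per degree (> 0, and at
#'   most the grid Nyquist limit).
#' @param amplitude Modulation amplitude `a` (finite; default 0.1, the value
#'   held constant across model trials).
#' @param dc_offset Baseline added to the sinusoid (default 0).
#' @return An object of class `"stimulus"`: list with `amplitude`,
#'   `frequency_cpd`, `dc_offset` and `values` (length `n_samples`).
#' @examples
#' g <- make_grid(400, 2)
#' s <- generate_grating(g, frequency_cpd = 1)
#' range(s$values)   # within [-0.1, 0.1]
#' @export
generate_grating <- function(grid, frequency_cpd, amplitude = 0.1, dc_offset = 0) {
  stopifnot(inherits(grid, "sampling_grid"))
  check_scalar(frequency_cpd, "frequency_cpd")
  check_scalar(amplitude, "amplitude", positive = FALSE)
  check_scalar(dc_offset, "dc_offset", positive = FALSE)
  nyq <- nyquist_cpd(grid)
  if (frequency_cpd > nyq) {
    stop_dogcsf(
      sprintf("grating frequency %g cpd exceeds the grid Nyquist limit %g cpd",
              frequency_cpd, nyq),
      "dogcsf_aliasing_error"
    )
  }
  structure(
    list(
      amplitude = amplitude,
      frequency_cpd = frequency_cpd,
      dc_offset = dc_offset,
      values = dc_offset + amplitude * sin(2 * pi * frequency_cpd * grid$positions_deg),
      n_samples = grid$n_samples
    ),
    class = "stimulus"
  )
}

#' Spatial-frequency sweep
#'
#' The set of grating frequencies a contrast-sensitivity run visits. Defaults
#' reproduce the study sweep: 200 frequencies from 0.1 to 100 cycles/degree,
#' logarithmically spaced (the standard axis for contrast-sensitivity
#' functions); linear spacing is available as an option.
#'
#' @param f_min,f_max Sweep endpoints in cycles/degree, `0 < f_min < f_max`.
#' @param n_freq Number of frequencies (>= 2). Default 200.
#' @param spacing_mode `"logarithmic"` (default) or `"linear"`.
#' @return An object of class `"frequency_sweep"`: list with
#'   `frequencies_cpd` and `spacing_mode`.
#' @examples
#' sw <- make_sweep()
#' range(sw$frequencies_cpd)  # 0.1 100
#' @export
make_sweep <- function(f_min = 0.1, f_max = 100, n_freq = 200L,
                       spacing_mode = c("logarithmic", "linear")) {
  spacing_mode <- match.arg(spacing_mode)
  check_scalar(f_min, "f_min")
  check_scalar(f_max, "f_max")
  if (f_min >= f_max) {
    stop_dogcsf("`f_min` must be strictly below `f_max`", "dogcsf_invalid_argument")
  }
  if (!is.numeric(n_freq) || length(n_freq) != 1L || n_freq < 2 ||
      n_freq != round(n_freq)) {
    stop_dogcsf("`n_freq` must be a single integer >= 2", "dogcsf_invalid_argument")
  }
  n_freq <- as.integer(n_freq)
  freqs <- if (spacing_mode == "logarithmic") {
    exp(seq(log(f_min), log(f_max), length.out = n_freq))
  } else {
    seq(f_min, f_max, length.out = n_freq)
  }
  # pin the endpoints exactly despite exp/log round trips
  freqs[1L] <- f_min
  freqs[n_freq] <- f_max
  structure(
    list(frequencies_cpd = freqs, spacing_mode = spacing_mode),
    class = "frequency_sweep"
  )
}

#' @export
print.frequency_sweep <- function(x, ...) {
  n <- length(x$frequencies_cpd)
  cat(sprintf("<frequency_sweep> %d frequencies, %g..%g cpd (%s)\n",
              n, x$frequencies_cpd[1L], x$frequencies_cpd[n], x$spacing_mode))
  invisible(x)
}

#' Export a sampled stimulus as CSV
#'
#' Two columns, `position_deg` and `value`, written with full precision.
#'
#' @param stimulus A [generate_grating()] object.
#' @param grid The grid the stimulus was generated on.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_stimulus_csv <- function(stimulus, grid, path) {
  stopifnot(inherits(stimulus, "stimulus"), inherits(grid, "sampling_grid"))
  if (stimulus$n_samples != grid$n_samples) {
    stop_dogcsf("stimulus and grid have different sample counts",
                "dogcsf_dimension_error")
  }
  df <- data.frame(position_deg = grid$positions_deg, value = stimulus$values)
  write_csv17(df, path)
  invisible(path)
}
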
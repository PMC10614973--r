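#' Receptive-field subfield parameters
#'
#' The four Difference-of-Gaussians parameters: peak heights (`amp_ex`,
#' `amp_inh`) and widths (`sigma_ex`, `sigma_inh`, in model units) of the
#' excitatory center and inhibitory surround Gaussians. The base (control)
#' configuration uses unit amplitudes and the Marr-Hildreth optimal
#' surround/center width ratio of 1.6.
#'
#' @param amp_ex,sigma_ex Excitatory subfield height and width (> 0).
#' @param amp_inh,sigma_inh Inhibitory subfield height and width (> 0).
#' @return An object of class `"rf_params"`.
#' @examples
#' rf_params()  # base: amp 1/1, sigma 1/1.6
#' @export
rf_params <- function(amp_ex = 1, sigma_ex = 1, amp_inh = 1, sigma_inh = 1.6) {
  check_scalar(amp_ex, "amp_ex")
  check_scalar(sigma_ex, "sigma_ex")
  check_scalar(amp_inh, "amp_inh")
  check_scalar(sigma_inh, "sigma_inh")
  structure(
    list(amp_ex = amp_ex, sigma_ex = sigma_ex,
         amp_inh = amp_inh, sigma_inh = sigma_inh),
    class = "rf_params"
  )
}

#' @export
print.rf_params <- function(x, ...) {
  cat(sprintf("<rf_params> Amp_ex=%g sigma_ex=%g | Amp_inh=%g sigma_inh=%g\n",
              x$amp_ex, x$sigma_ex, x$amp_inh, x$sigma_inh))
  invisible(x)
}

#' Sampled Gaussian subfield kernel
#'
#' Evaluates `amplitude * exp(-offset^2 / (2 * sigma_deg^2))` on the grid
#' lattice, truncated at the largest lattice multiple not exceeding
#' `5 * sigma_deg` on each side (the subfield support used by the model).
#' The center tap equals `amplitude` exactly and the kernel is symmetric.
#'
#' @param amplitude Peak height (> 0).
#' @param sigma_units Width in model units (> 0).
#' @param deg_per_unit Degrees of visual angle per model unit (default 0.05).
#' @param spacing_deg Grid spacing in degrees; `sigma` in degrees must be at
#'   least one grid spacing, otherwise an under-resolution error is raised.
#' @return An object of class `"rf_kernel"`: list with `offsets_deg`,
#'   `weights`, `spacing_deg`, `sigma_deg`, `amplitude`.
#' @examples
#' k <- make_kernel(1, 1, deg_per_unit = 0.05, spacing_deg = 0.0025)
#' length(k$weights)  # 201 taps: +/- 100 lattice steps within 5 sigma
#' @export
make_kernel <- function(amplitude, sigma_units, deg_per_unit = DEG_PER_UNIT_DEFAULT,
                        spacing_deg) {
  check_scalar(amplitude, "amplitude")
  check_scalar(sigma_units, "sigma_units")
  check_scalar(deg_per_unit, "deg_per_unit")
  check_scalar(spacing_deg, "spacing_deg")
  sigma_deg <- sigma_units * deg_per_unit
  if (sigma_deg < spacing_deg) {
    stop_dogcsf(
      sprintf("sigma = %g deg is below the grid spacing %g deg; the subfield is under-resolved",
              sigma_deg, spacing_deg),
      "dogcsf_under_resolution_error"
    )
  }
  n_half <- floor(5 * sigma_deg / spacing_deg)
  offsets <- (-n_half:n_half) * spacing_deg
  structure(
    list(
      offsets_deg = offsets,
      weights = amplitude * exp(-offsets^2 / (2 * sigma_deg^2)),
      spacing_deg = spacing_deg,
      sigma_deg = sigma_deg,
      amplitude = amplitude
    ),
    class = "rf_kernel"
  )
}

#' Effective Difference-of-Gaussians receptive-field profile
#'
#' Pointwise difference of the excitatory and inhibitory Gaussian kernels on
#' the union lattice (the wider inhibitory support). With a wider surround
#' the profile has a center lobe flanked by negative side lobes; its discrete
#' integral approximates
#' `sqrt(2*pi) * (amp_ex * sigma_ex - amp_inh * sigma_inh)` (in degrees).
#'
#' @param rf An [rf_params()] object.
#' @inheritParams make_kernel
#' @return An `"rf_kernel"` object holding the DoG weights.
#' @export
dog_profile <- function(rf, deg_per_unit = DEG_PER_UNIT_DEFAULT, spacing_deg) {
  stopifnot(inherits(rf, "rf_params"))
  kex <- make_kernel(rf$amp_ex, rf$sigma_ex, deg_per_unit, spacing_deg)
  kinh <- make_kernel(rf$amp_inh, rf$sigma_inh, deg_per_unit, spacing_deg)
  hx <- (length(kex$weights) - 1L) / 2L
  hi <- (length(kinh$weights) - 1L) / 2L
  h <- max(hx, hi)
  offsets <- (-h:h) * spacing_deg
  pad <- function(w, hw) c(rep(0, h - hw), w, rep(0, h - hw))
  structure(
    list(
      offsets_deg = offsets,
      weights = pad(kex$weights, hx) - pad(kinh$weights, hi),
      spacing_deg = spacing_deg,
      sigma_deg = NA_real_,
      amplitude = rf$amp_ex - rf$amp_inh
    ),
    class = "rf_kernel"
  )
}

#' Export a kernel (or DoG profile) as CSV
#'
#' @param kernel An `"rf_kernel"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_kernel_csv <- function(kernel, path) {
  stopifnot(inherits(kernel, "rf_kernel"))
  write_csv17(data.frame(offset_deg = kernel$offsets_deg,
                         weight = kernel$weights), path)
  invisible(path)
}

#' Convolve a stimulus with the excitatory and inhibitory subfields
#'
#' Discrete "same"-length convolution with zero padding outside the field,
#' scaled by the grid spacing so the sums approximate the continuous
#' convolution integrals and results are resolution-independent. Samples
#' within `5 * sigma` (the wider subfield) of either edge are flagged invalid
#' in `valid_mask`; downstream readouts use interior samples only, so edge
#' truncation never touches a measured peak or trough.
#'
#' @param stimulus A [generate_grating()] stimulus sampled on `grid`.
#' @param rf An [rf_params()] object.
#' @param grid The [make_grid()] grid the stimulus was generated on.
#' @param deg_per_unit Degrees per model unit (default 0.05).
#' @return An object of class `"convolved_field"`: list with `i_ex`, `i_inh`
#'   (length `n_samples`) and logical `valid_mask`.
#' @export
convolve_input <- function(stimulus, rf, grid,
                           deg_per_unit = DEG_PER_UNIT_DEFAULT) {
  stopifnot(inherits(stimulus, "stimulus"), inherits(rf, "rf_params"),
            inherits(grid, "sampling_grid"))
  if (stimulus$n_samples != grid$n_samples) {
    stop_dogcsf("stimulus was generated on a different grid (sample count mismatch)",
                "dogcsf_dimension_error")
  }
  kex <- make_kernel(rf$amp_ex, rf$sigma_ex, deg_per_unit, grid$spacing_deg)
  kinh <- make_kernel(rf$amp_inh, rf$sigma_inh, deg_per_unit, grid$spacing_deg)
  convolve_field(stimulus$values, kex, kinh, grid)
}

# Shared core so sweeps can reuse prebuilt kernels.
convolve_field <- function(values, kex, kinh, grid) {
  sp <- grid$spacing_deg
  i_ex <- .conv_same_sym(values, kex$weights) * sp
  i_inh <- .conv_same_sym(values, kinh$weights) * sp
  margin <- ceiling(5 * max(kex$sigma_deg, kinh$sigma_deg) / sp)
  n <- grid$n_samples
  mask <- rep(TRUE, n)
  m <- min(margin, n)
  mask[seq_len(m)] <- FALSE
  mask[seq.int(n - m + 1L, n)] <- FALSE
  structure(
    list(i_ex = i_ex, i_inh = i_inh, valid_mask = mask, spacing_deg = sp),
    class = "convolved_field"
  )
}
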
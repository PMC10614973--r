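#' Shunting-equation constants
#'
#' The three constants of the membrane-style rate equation
#' `dx/dt = -A*x + (B - x)*I_ex - (C + x)*I_inh`: passive decay `A`, activity
#' upper bound `B`, and lower-bound magnitude `C`. The multiplicative
#' (shunting) gating keeps activity inside `(-C, B)` for nonnegative drive.
#' Model defaults: `A = 1`, `B = 10.1`, `C = 5`.
#'
#' @param decay_a Passive decay constant `A` (> 0).
#' @param upper_b Activity upper bound `B` (> 0).
#' @param lower_c Activity lower-bound magnitude `C` (>= 0).
#' @return An object of class `"shunting_params"`.
#' @export
shunting_params <- function(decay_a = 1, upper_b = 10.1, lower_c = 5) {
  check_scalar(decay_a, "decay_a")
  check_scalar(upper_b, "upper_b")
  if (!is.numeric(lower_c) || length(lower_c) != 1L || !is.finite(lower_c) ||
      lower_c < 0) {
    stop_dogcsf("`lower_c` must be a single finite numeric >= 0",
                "dogcsf_invalid_argument")
  }
  structure(
    list(decay_a = decay_a, upper_b = upper_b, lower_c = lower_c),
    class = "shunting_params"
  )
}

#' @export
print.shunting_params <- function(x, ...) {
  cat(sprintf("<shunting_params> A=%g B=%g C=%g\n",
              x$decay_a, x$upper_b, x$lower_c))
  invisible(x)
}

#' Closed-form equilibrium of the shunting equation
#'
#' Evaluates the fixed point
#' `x_eq = (B*I_ex - C*I_inh) / (A + I_ex + I_inh)` pointwise over the neuron
#' array. All reported model results are equilibrium responses; the
#' time-domain integrator ([integrate_dynamics()]) exists to validate this
#' closed form. The denominator must stay positive (> 1e-9) at every valid
#' sample; a signed convolved input that drives it to zero is a degenerate
#' operating point and raises an error naming the first offending sample.
#'
#' @param field A [convolve_input()] result.
#' @param sp A [shunting_params()] object.
#' @return An object of class `"activity_field"`: list with `values` and the
#'   inherited `valid_mask`.
#' @export
equilibrium_response <- function(field, sp = shunting_params()) {
  stopifnot(inherits(field, "convolved_field"), inherits(sp, "shunting_params"))
  denom <- sp$decay_a + field$i_ex + field$i_inh
  eps <- 1e-9
  bad <- which(field$valid_mask & denom <= eps)
  if (length(bad) > 0L) {
    stop_dogcsf(
      sprintf("shunting denominator A + I_ex + I_inh = %g <= %g at sample %d; dynamics are degenerate",
              denom[bad[1L]], eps, bad[1L]),
      "dogcsf_degenerate_dynamics_error"
    )
  }
  structure(
    list(
      values = (sp$upper_b * field$i_ex - sp$lower_c * field$i_inh) / denom,
      valid_mask = field$valid_mask
    ),
    class = "activity_field"
  )
}

#' Numerically integrate the shunting dynamics (validation oracle)
#'
#' Integrates `dx/dt = -A*x + (B - x)*I_ex - (C + x)*I_inh` per neuron with
#' frozen convolved inputs, from state `x0` to time `t_end`, using
#' `deSolve::ode`. Each neuron's equation is linear with relaxation rate
#' `A + I_ex + I_in`, so the state converges exponentially to the
#' [equilibrium_response()] fixed point; this function is a test oracle and
#' is not on the contrast-sensitivity code path.
#'
#' @param field A [convolve_input()] result.
#' @param sp A [shunting_params()] object.
#' @param x0 Initial activities: an `"activity_field"`, a numeric vector, or
#'   a single number recycled over the array (default 0).
#' @param t_end Integration time (> 0). `20 / A` reduces the initial
#'   transient by a factor `exp(-20)`.
#' @param rtol,atol Solver tolerances passed to `deSolve::ode`.
#' @return An `"activity_field"` holding the state at `t_end`.
#' @export
integrate_dynamics <- function(field, sp = shunting_params(), x0 = 0,
                               t_end = 20 / sp$decay_a, rtol = 1e-8,
                               atol = 1e-12) {
  stopifnot(inherits(field, "convolved_field"), inherits(sp, "shunting_params"))
  check_scalar(t_end, "t_end")
  check_scalar(rtol, "rtol")
  n <- length(field$i_ex)
  if (inherits(x0, "activity_field")) x0 <- x0$values
  if (length(x0) == 1L) x0 <- rep(as.numeric(x0), n)
  if (length(x0) != n) {
    stop_dogcsf("`x0` length does not match the neuron array",
                "dogcsf_dimension_error")
  }
  deriv <- function(t, x, parms) {
    list(-sp$decay_a * x + (sp$upper_b - x) * field$i_ex -
           (sp$lower_c + x) * field$i_inh)
  }
  sol <- deSolve::ode(y = x0, times = c(0, t_end), func = deriv, parms = NULL,
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0) {
    stop_dogcsf("ODE integration failed (solver did not complete)",
                "dogcsf_numerical_error")
  }
  structure(
    list(values = as.numeric(sol[nrow(sol), -1L]),
         valid_mask = field$valid_mask),
    class = "activity_field"
  )
}

#' Export an activity field as CSV
#'
#' @param activity An `"activity_field"` object.
#' @param grid The grid the field lives on.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_activity_csv <- function(activity, grid, path) {
  stopifnot(inherits(activity, "activity_field"), inherits(grid, "sampling_grid"))
  write_csv17(data.frame(position_deg = grid$positions_deg,
                         activity = activity$values), path)
  invisible(path)
}
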
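# Stiff time integration under the pulsed signal.

#' Pre-stimulation resting state
#'
#' The closed-form equilibrium at the basal signal level — the state of
#' unstimulated cells, used as the default initial condition for
#' simulated time courses.
#'
#' @inheritParams equilibrium
#' @param s_base basal signal strength (>= 0).
#' @return Named state vector `(x1, x2, x3, x4)`.
#' @export
basal_state <- function(params, genotype = params$genotype, s_base) {
  if (s_base == 0) {
    d <- apply_genotype(params, genotype)
    # With zero signal there is no transcription and the origin is the
    # unique nonnegative fixed point whenever decay paths exist.
    if (d$d3 + d$d6 * 0 > 0 || d$k3 == 0) {
      return(c(x1 = 0, x2 = 0, x3 = 0, x4 = 0))
    }
  }
  as_state(equilibrium(params, genotype, s_base))
}

#' Integrate a model through a stimulation time course
#'
#' Solves the initial-value problem for either model under the given
#' signal profile with a stiff-capable solver (`deSolve::ode`, lsoda),
#' at relative tolerance 1e-8 and absolute tolerance 1e-10. The signal
#' breakpoints are inserted as mandatory mesh points so the ramp and
#' plateau edges are never stepped over. Output states are clipped to 0
#' after a nonnegativity check at solver precision.
#'
#' @inheritParams equilibrium
#' @param profile a [signal_profile()].
#' @param times strictly increasing output times (h, >= 0), length >= 2.
#' @param x0 initial state; default is the basal equilibrium at
#'   `profile$s_base`.
#' @return A `reg1_timecourse` tibble with columns
#'   `time, x1, x2, x3, x4, signal` and the parameters, profile and
#'   genotype attached as attributes.
#' @examples
#' p <- default_parameters("wt")
#' tc <- simulate_timecourse(p, default_profile(), times = c(0, 0.5, 2, 4))
#' tc
#' @export
simulate_timecourse <- function(params, profile, times,
                                genotype = params$genotype, x0 = NULL) {
  stopifnot(inherits(params, "reg1_params"), inherits(profile, "reg1_signal"))
  times <- as.numeric(times)
  if (length(times) < 2L || any(diff(times) <= 0) || any(times < 0)) {
    stop("`times` must be >= 0, strictly increasing, length >= 2", call. = FALSE)
  }
  p <- apply_genotype(params, genotype)
  if (is.null(x0)) x0 <- basal_state(p, s_base = profile$s_base)
  if (length(x0) != 4L || any(x0 < 0)) {
    stop("`x0` must be a nonnegative 4-vector", call. = FALSE)
  }

  brk <- cumsum(c(profile$t_delay, profile$t_raise, profile$t_pulse))
  mesh <- sort(unique(c(times, brk[brk > min(times) & brk < max(times)])))
  derivs <- function(t, y, parms) list(rhs_core(p, y, signal_at(profile, t)))
  sol <- deSolve::ode(y = as.numeric(x0), times = mesh, func = derivs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0) {
    stop("integration failed near t = ", max(sol[, 1]), " h", call. = FALSE)
  }
  sol <- sol[sol[, 1] %in% times, , drop = FALSE]
  states <- sol[, 2:5, drop = FALSE]
  min_raw <- min(states)
  if (min_raw < -1e-8) {
    stop("integration produced a negative state (", min_raw, ")", call. = FALSE)
  }
  states[states < 0] <- 0
  out <- tibble::tibble(
    time = sol[, 1],
    x1 = states[, 1], x2 = states[, 2], x3 = states[, 3], x4 = states[, 4],
    signal = signal_at(profile, sol[, 1])
  )
  attr(out, "params") <- p
  attr(out, "profile") <- profile
  attr(out, "genotype") <- p$genotype
  attr(out, "min_raw") <- min_raw
  class(out) <- c("reg1_timecourse", class(out))
  out
}

#' Has a trajectory reached an equilibrium?
#'
#' Compares the final sampled state with a closed-form fixed point,
#' component-wise at relative tolerance `rel_tol` (absolute where the
#' target component is 0).
#'
#' @param tc a `reg1_timecourse`.
#' @param eq a `reg1_equilibrium` with `exists = TRUE`.
#' @param rel_tol relative tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
has_converged <- function(tc, eq, rel_tol = 1e-3) {
  stopifnot(inherits(tc, "reg1_timecourse"), inherits(eq, "reg1_equilibrium"))
  if (!eq$exists) stop("`eq` has no equilibrium", call. = FALSE)
  fin <- as.numeric(tc[nrow(tc), c("x1", "x2", "x3", "x4")])
  tgt <- as.numeric(as_state(eq))
  all(abs(fin - tgt) <= rel_tol * pmax(abs(tgt), as.numeric(tgt == 0)))
}

#' Read and write time courses as CSV
#'
#' Plain CSV with header `time,x1,x2,x3,x4,signal`.
#'
#' @param tc a `reg1_timecourse` (or any data frame with those columns).
#' @param path file path.
#' @return `read_timecourse()` returns a tibble; the writer returns
#'   `path` invisibly.
#' @name timecourse_io
NULL

#' @rdname timecourse_io
#' @export
write_timecourse <- function(tc, path) {
  readr::write_csv(tc[, c("time", "x1", "x2", "x3", "x4", "signal")], path)
  invisible(path)
}

#' @rdname timecourse_io
#' @export
read_timecourse <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_double()))
}
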
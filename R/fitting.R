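# Log-scale least-squares parameter recovery from observation tables.
#
# The synthetic noise is multiplicative lognormal, so least squares on
# log observations is the maximum-likelihood objective up to constants.
# Full 15-parameter fitting from 5 observables x 4 time points is not
# identifiable; fitting is meant for small subsets (2-3 parameters).

#' Specify a fitting problem
#'
#' Names the free parameters, their nonnegative box bounds, and the
#' fixed values of everything else (taken from `params`, which also
#' fixes the model kind). All parameters are shared across genotypes;
#' the S513A genotype additionally zeroes `d7`, `d8`, `d9`, which is why
#' those three cannot be free when the data contain only S513A rows.
#'
#' @param params full [model_parameters()] supplying the fixed values
#'   and model kind.
#' @param free character vector of parameter names to estimate.
#' @param lower,upper named (or scalar) bounds per free parameter;
#'   defaults 0 and Inf.
#' @return A `reg1_fitspec`.
#' @export
fit_spec <- function(params, free, lower = 0, upper = Inf) {
  stopifnot(inherits(params, "reg1_params"))
  if (length(free) == 0 || !all(free %in% PARAM_FIELDS)) {
    stop("`free` must be a nonempty subset of the parameter names", call. = FALSE)
  }
  expand <- function(b, default) {
    if (is.null(names(b))) b <- stats::setNames(rep_len(b, length(free)), free)
    out <- stats::setNames(rep(default, length(free)), free)
    out[names(b)] <- b
    out
  }
  lower <- expand(lower, 0)
  upper <- expand(upper, Inf)
  if (any(lower < 0) || any(upper < lower)) {
    stop("bounds must satisfy 0 <= lower <= upper", call. = FALSE)
  }
  structure(list(params = params, free = free, lower = lower, upper = upper),
            class = "reg1_fitspec")
}

candidate_params <- function(spec, candidate) {
  p <- spec$params
  for (nm in spec$free) p[[nm]] <- candidate[[nm]]
  # Re-validate the model-1 constraint if d1p/d2p were touched.
  if (p$kind == "model1" && (p$d1p != 0 || p$d2p != 0)) {
    stop("model 1 requires d1p = d2p = 0", call. = FALSE)
  }
  p
}

predict_observations <- function(params, data, profile) {
  purrr::map_dfr(split(data, data$genotype), function(d) {
    times <- sort(unique(d$time))
    tc_times <- if (length(times) == 1L) unique(c(0, times)) else times
    tc <- simulate_timecourse(params, profile, times = tc_times,
                              genotype = unique(d$genotype))
    d$.pred <- purrr::map2_dbl(d$time, d$observable, function(tt, ob) {
      i <- match(tt, tc$time)
      observe_state(as.numeric(tc[i, c("x1", "x2", "x3", "x4")]), ob)
    })
    d
  })
}

log_residuals <- function(spec, candidate, data, profile, eps = 1e-9) {
  p <- candidate_params(spec, candidate)
  pred <- predict_observations(p, data, profile)
  log(pred$value + eps) - log(pred$.pred + eps)
}

#' Fitting objective: sum of squared log-residuals
#'
#' \eqn{\sum_i (\log(y_i + \epsilon) - \log(\hat y_i + \epsilon))^2} with
#' \eqn{\epsilon = 10^{-9}} guarding zeros; predictions come from
#' integrating the candidate model (genotype semantics applied per row)
#' and projecting onto each row's observable. A candidate at which the
#' integration fails scores `Inf` (rejected), never an error.
#'
#' @param spec a [fit_spec()].
#' @param candidate named numeric values for the free parameters.
#' @param data a `reg1_observations` table (columns
#'   `genotype, time, observable, replicate, value`).
#' @param profile the [signal_profile()] the data were collected under.
#' @return A single nonnegative number.
#' @export
model_loss <- function(spec, candidate, data, profile) {
  stopifnot(inherits(spec, "reg1_fitspec"))
  tryCatch(sum(log_residuals(spec, candidate, data, profile)^2),
           error = function(e) Inf)
}

#' Estimate parameters from an observation table
#'
#' Bounded Levenberg-Marquardt minimization of [model_loss()] (via
#' `minpack.lm::nls.lm` on the log-residual vector), with seeded
#' multi-start: the supplied start plus `n_starts - 1` random starts
#' drawn log-uniformly around it within bounds. The best start by final
#' loss wins. Reproducible for a fixed `seed`.
#'
#' @param data a `reg1_observations` table (data frame first, so tables
#'   pipe straight in).
#' @param spec a [fit_spec()].
#' @param profile the [signal_profile()] the data were collected under.
#' @param start named starting values for the free parameters; default
#'   is the fixed values recorded in `spec$params`.
#' @param n_starts number of starts (>= 1).
#' @param seed integer seed for the random restarts.
#' @return A `reg1_fit`: `estimates`, `loss_value`, `converged`,
#'   `n_evaluations`, plus the spec. Has [tidy()] and [glance()]
#'   methods.
#' @export
fit_parameters <- function(data, spec, profile = default_profile(),
                           start = NULL, n_starts = 3, seed = 1) {
  stopifnot(inherits(spec, "reg1_fitspec"))
  if (nrow(data) == 0) stop("`data` is empty", call. = FALSE)
  if (all(data$genotype == "s513a") &&
      any(spec$free %in% c("d7", "d8", "d9"))) {
    stop("d7/d8/d9 are structurally zero in S513A-only data and cannot ",
         "be estimated from it", call. = FALSE)
  }
  if (is.null(start)) {
    start <- stats::setNames(unlist(spec$params[spec$free]), spec$free)
  }
  start <- pmin(pmax(start[spec$free], spec$lower), spec$upper)

  n_res <- nrow(data)
  evals <- 0L
  resid_fn <- function(par) {
    evals <<- evals + 1L
    par <- stats::setNames(par, spec$free)
    tryCatch(log_residuals(spec, par, data, profile),
             error = function(e) rep(1e6, n_res))
  }

  starts <- withr::with_seed(as.integer(seed), {
    c(list(start), purrr::map(seq_len(max(0, n_starts - 1)), function(i) {
      pert <- start * stats::rlnorm(length(start), 0, 0.5)
      pmin(pmax(pert, pmax(spec$lower, 1e-8)), pmin(spec$upper, 1e8))
    }))
  })

  runs <- purrr::map(starts, function(st) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = spec$lower, upper = spec$upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return(list(par = st, loss = Inf, ok = FALSE))
    list(par = stats::setNames(fit$par, spec$free),
         loss = sum(resid_fn(fit$par)^2),
         ok = fit$info %in% 1:4)
  })
  best <- runs[[which.min(purrr::map_dbl(runs, "loss"))]]

  structure(list(
    estimates = best$par,
    loss_value = best$loss,
    converged = isTRUE(best$ok) && is.finite(best$loss),
    n_evaluations = evals,
    n_starts = length(starts),
    spec = spec
  ), class = "reg1_fit")
}

#' @export
print.reg1_fit <- function(x, ...) {
  cat("<reg1_fit> loss ", format(x$loss_value),
      if (!x$converged) " (did not converge)",
      ", ", x$n_evaluations, " objective evaluations\n", sep = "")
  print(x$estimates)
  invisible(x)
}

#' @export
tidy.reg1_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates),
                 estimate = unname(x$estimates))
}

#' @export
glance.reg1_fit <- function(x, ...) {
  tibble::tibble(loss = x$loss_value, converged = x$converged,
                 n_evaluations = x$n_evaluations, n_starts = x$n_starts,
                 n_free = length(x$estimates))
}
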
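# Right-hand sides of the two ODE models.

# Unchecked core used by the integrator (solvers may step a hair below 0).
rhs_core <- function(p, x, s) {
  x1 <- x[[1]]; x2 <- x[[2]]; x3 <- x[[3]]; x4 <- x[[4]]
  c(p$k1 * s - p$d1 * x1 * x3 - p$d1p * x1 * x4 - p$d4 * x1,
    p$k2 * s - p$d2 * x2 * x3 - p$d2p * x2 * x4 - p$d5 * x2,
    p$k3 * x2 - (p$d3 + p$d6 * s + p$d7 * s) * x3 + p$d9 * x4,
    p$d7 * s * x3 - (p$d8 + p$d9) * x4)
}

#' Time derivatives of the inflammation model
#'
#' Evaluates d(x1, x2, x3, x4)/dt for the state
#' (*Il6* mRNA, *Zc3h12a* mRNA, free Regnase-1, 14-3-3-bound Regnase-1)
#' at signal strength `s`. Under model 1 the bound complex is inert
#' (`d1p = d2p = 0`), so model 2 with those rates zeroed reduces to
#' model 1 exactly. On each face `x_i = 0` of the nonnegative orthant the
#' corresponding derivative is nonnegative, so trajectories started at
#' nonnegative states stay nonnegative.
#'
#' @param params a [model_parameters()] object.
#' @param state numeric vector `(x1, x2, x3, x4)`, all >= 0.
#' @param s signal strength (>= 0).
#' @return Named numeric 4-vector of derivatives (conc/h).
#' @examples
#' p <- model_parameters(k1 = 1, k2 = 1, k3 = 1, d1 = 1, d2 = 1,
#'                       d3 = 1, d4 = 1, d5 = 1, d6 = 1, d7 = 1,
#'                       d8 = 1, d9 = 1)
#' model_rhs(p, c(0, 0, 0, 0), s = 1)  # only transcription at the origin
#' @export
model_rhs <- function(params, state, s) {
  stopifnot(inherits(params, "reg1_params"))
  if (length(state) != 4L || any(!is.finite(state)) || any(state < 0)) {
    stop("`state` must be four finite nonnegative numbers", call. = FALSE)
  }
  if (!is.finite(s) || s < 0) stop("`s` must be >= 0", call. = FALSE)
  stats::setNames(rhs_core(params, as.numeric(state), s),
                  c("x1", "x2", "x3", "x4"))
}

# Analytic Jacobian of rhs_core at (x, s); used by the Newton oracle.
rhs_jacobian <- function(p, x, s) {
  x1 <- x[[1]]; x2 <- x[[2]]; x3 <- x[[3]]; x4 <- x[[4]]
  matrix(c(
    -(p$d1 * x3 + p$d1p * x4 + p$d4), 0, -p$d1 * x1, -p$d1p * x1,
    0, -(p$d2 * x3 + p$d2p * x4 + p$d5), -p$d2 * x2, -p$d2p * x2,
    0, p$k3, -(p$d3 + p$d6 * s + p$d7 * s), p$d9,
    0, 0, p$d7 * s, -(p$d8 + p$d9)
  ), nrow = 4, byrow = TRUE)
}
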
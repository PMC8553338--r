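# Closed-form equilibria of both models, the composite constant K, and an
# independent damped-Newton oracle.

#' Composite equilibrium constant K
#'
#' The constant
#' \deqn{K = \frac{1}{k_3}\left(d_3 + d_6 s + d_7 s -
#'   \frac{d_7 d_9 s}{d_8 + d_9}\right)}
#' obtained by eliminating the bound pool
#' (`X4 = (d7*s/(d8+d9)) * X3`) from the free-protein balance. It links
#' the *Zc3h12a* mRNA and free-protein fixed points (`X2 = K * X3`) and
#' governs existence of the wild-type equilibrium: a nonnegative
#' equilibrium exists if and only if `K >= 0`. For nonnegative rates K
#' is always nonnegative, since the bracket equals
#' `d3 + d6*s + d7*s*d8 / (d8 + d9)`. The subtracted fraction is taken
#' as 0 when `d8 + d9 = 0`.
#'
#' @param params a [model_parameters()] object.
#' @param s_input signal strength at the equilibrium (>= 0).
#' @return A single number.
#' @export
effective_K <- function(params, s_input) {
  stopifnot(inherits(params, "reg1_params"))
  if (!is.finite(s_input) || s_input < 0) stop("`s_input` must be >= 0", call. = FALSE)
  if (params$k3 == 0) {
    stop("`k3` = 0: no translation, K is undefined", call. = FALSE)
  }
  ds <- params$d8 + params$d9
  frac <- if (ds == 0) 0 else params$d7 * params$d9 * s_input / ds
  (params$d3 + params$d6 * s_input + params$d7 * s_input - frac) / params$k3
}

# Nonnegative root of a*x^2 + b*x - cc = 0 with a, b, cc >= 0, in the
# cancellation-free form 2*cc / (b + sqrt(b^2 + 4*a*cc)).
quad_root_nonneg <- function(a, b, cc) {
  if (cc == 0) return(0)
  den <- b + sqrt(b^2 + 4 * a * cc)
  if (den == 0) stop("degenerate quadratic: no nonnegative root", call. = FALSE)
  2 * cc / den
}

#' Closed-form equilibrium of either model
#'
#' Computes the unique nonnegative fixed point at sustained signal
#' `s_input`, by the closed-form quadratic solutions. For wild type, the
#' free-protein fixed point `X3` solves
#' `(d2 + (d7*s/(d8+d9))*d2p) * K * X3^2 + d5*K*X3 - k2*s = 0`, with
#' `X4 = (d7*s/(d8+d9)) * X3`, `X2 = K*X3` and
#' `X1 = k1*s / (d1*X3 + d1p*X4 + d4)`. When the effective binding arm is
#' absent (`d7 = d8 = d9 = 0`, as for the S513A genotype) the reduced
#' branch solves `(d2*k3/(d3+d6*s)) * X2^2 + d5*X2 - k2*s = 0` with
#' `X3 = (k3/(d3+d6*s)) * X2`, `X1 = k1*s/(d1*X3 + d4)` and `X4 = 0`
#' exactly. Model 1 uses the same formulas with `d1p = d2p = 0`.
#'
#' The corner `d8 + d9 = 0` with `d7*s_input > 0` (the bound complex
#' neither degrades nor dissociates while binding continues) has no
#' finite fixed point for the bound pool and is rejected.
#'
#' @inheritParams effective_K
#' @param genotype `"wt"` or `"s513a"`; S513A semantics zero `d7,d8,d9`.
#' @return A `reg1_equilibrium`: list with fixed point `X1..X4`, the
#'   constant `K`, `exists`, and `branch` (`"wt_general"` or
#'   `"s513a_reduced"`).
#' @examples
#' p <- model_parameters(k1 = 1, k2 = 1, k3 = 1, d1 = 1, d2 = 1,
#'                       d3 = 1, d4 = 1, d5 = 1, d6 = 1, d7 = 1,
#'                       d8 = 1, d9 = 1)
#' equilibrium(p, "wt", s_input = 1)
#' @export
equilibrium <- function(params, genotype = params$genotype, s_input) {
  stopifnot(inherits(params, "reg1_params"))
  if (!is.finite(s_input) || s_input < 0) stop("`s_input` must be >= 0", call. = FALSE)
  p <- apply_genotype(params, genotype)
  if (p$k3 == 0) stop("`k3` must be > 0 for the closed forms", call. = FALSE)
  s <- s_input

  if (p$d7 == 0 && p$d8 == 0 && p$d9 == 0) {
    # Reduced branch: no 14-3-3 arm (S513A semantics).
    den <- p$d3 + p$d6 * s
    if (den == 0) {
      stop("`d3 + d6*s_input` must be > 0 for the reduced branch", call. = FALSE)
    }
    X2 <- quad_root_nonneg(p$d2 * p$k3 / den, p$d5, p$k2 * s)
    X3 <- p$k3 / den * X2
    X1 <- ratio_or_zero(p$k1 * s, p$d1 * X3 + p$d4)
    res <- list(X1 = X1, X2 = X2, X3 = X3, X4 = 0,
                K = effective_K(p, s), exists = TRUE,
                branch = "s513a_reduced")
  } else {
    if (p$d8 + p$d9 == 0 && p$d7 * s > 0) {
      stop("degenerate parameters: d8 + d9 = 0 with d7*s_input > 0 ",
           "(bound Regnase-1 neither degrades nor dissociates)", call. = FALSE)
    }
    r <- if (p$d8 + p$d9 > 0) p$d7 * s / (p$d8 + p$d9) else 0
    K <- effective_K(p, s)
    if (K < 0) {
      res <- list(X1 = NA_real_, X2 = NA_real_, X3 = NA_real_, X4 = NA_real_,
                  K = K, exists = FALSE, branch = "wt_general")
      class(res) <- "reg1_equilibrium"
      return(res)
    }
    X3 <- quad_root_nonneg((p$d2 + r * p$d2p) * K, p$d5 * K, p$k2 * s)
    X4 <- r * X3
    X2 <- K * X3
    X1 <- ratio_or_zero(p$k1 * s, p$d1 * X3 + p$d1p * X4 + p$d4)
    res <- list(X1 = X1, X2 = X2, X3 = X3, X4 = X4,
                K = K, exists = TRUE, branch = "wt_general")
  }
  class(res) <- "reg1_equilibrium"
  res
}

ratio_or_zero <- function(num, den) {
  if (num == 0) return(0)
  if (den == 0) {
    stop("degenerate parameters: mRNA has production but no decay path",
         call. = FALSE)
  }
  num / den
}

#' @export
print.reg1_equilibrium <- function(x, ...) {
  cat("<reg1_equilibrium> branch ", x$branch,
      if (!x$exists) " (no nonnegative equilibrium)", "\n", sep = "")
  if (x$exists) {
    print(c(X1 = x$X1, X2 = x$X2, X3 = x$X3, X4 = x$X4, K = x$K))
  } else {
    cat("K =", x$K, "\n")
  }
  invisible(x)
}

#' @export
tidy.reg1_equilibrium <- function(x, ...) {
  tibble::tibble(
    component = c("X1", "X2", "X3", "X4"),
    observable = c("il6_mrna", "zc3h12a_mrna", "free_reg1", "bound_reg1"),
    value = c(x$X1, x$X2, x$X3, x$X4)
  )
}

as_state <- function(eq) {
  stopifnot(inherits(eq, "reg1_equilibrium"), eq$exists)
  c(x1 = eq$X1, x2 = eq$X2, x3 = eq$X3, x4 = eq$X4)
}

#' Numerical fixed-point oracle
#'
#' Solves `model_rhs(params, x, s_input) = 0` by a damped Newton
#' iteration with an analytic Jacobian, projecting each iterate onto the
#' nonnegative orthant. Independent of the closed forms; used to
#' cross-check them.
#'
#' @inheritParams equilibrium
#' @param x0 nonnegative starting state (length 4).
#' @param tol residual max-norm required for convergence.
#' @param max_iter iteration budget.
#' @return List with `state` (named 4-vector), `residual`, `converged`,
#'   `iterations`. Non-convergence is reported via `converged = FALSE`,
#'   never silently.
#' @export
equilibrium_numeric <- function(params, genotype = params$genotype, s_input,
                                x0 = c(1, 1, 1, 1), tol = 1e-10,
                                max_iter = 500L) {
  stopifnot(inherits(params, "reg1_params"))
  if (length(x0) != 4L || any(x0 < 0)) {
    stop("`x0` must be a nonnegative 4-vector", call. = FALSE)
  }
  p <- apply_genotype(params, genotype)
  x <- as.numeric(x0)
  # Without a 14-3-3 arm, dx4/dt is identically 0 and x4 is unconstrained
  # by rhs = 0; the biologically meaningful root has an empty bound pool,
  # so solve the reduced system on {x1, x2, x3} with x4 pinned at 0.
  act <- if (p$d7 == 0 && p$d8 == 0 && p$d9 == 0) {
    x[4] <- 0
    1:3
  } else {
    1:4
  }
  f <- rhs_core(p, x, s_input)[act]
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < tol) {
      return(list(state = stats::setNames(x, c("x1", "x2", "x3", "x4")),
                  residual = max(abs(f)), converged = TRUE, iterations = it - 1L))
    }
    J <- rhs_jacobian(p, x, s_input)[act, act, drop = FALSE]
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) {
      # Regularize a (near-)singular Jacobian.
      step <- solve(J + diag(1e-8, length(act)), -f)
    }
    lambda <- 1
    repeat {
      x_new <- x
      x_new[act] <- pmax(x[act] + lambda * step, 0)
      f_new <- rhs_core(p, x_new, s_input)[act]
      if (max(abs(f_new)) < max(abs(f)) || lambda < 1e-12) break
      lambda <- lambda / 2
    }
    if (lambda < 1e-12) break
    x <- x_new
    f <- f_new
  }
  list(state = stats::setNames(x, c("x1", "x2", "x3", "x4")),
       residual = max(abs(f)), converged = max(abs(f)) < tol,
       iterations = max_iter)
}

#' Invert the equilibrium for the Zc3h12a transcription rate
#'
#' Returns the `k2` for which the closed-form equilibrium has free
#' Regnase-1 fixed point exactly `target_X3`. The equilibrium quadratic
#' is linear in `k2`, so the inversion is a direct evaluation of its
#' left-hand side. This constructs matched-free-protein parameter sets:
#' a wild-type and an S513A set tuned to the same `X3` reproduce the
#' matched-protein condition under which the two models are
#' discriminated.
#'
#' @inheritParams equilibrium
#' @param target_X3 desired free-Regnase-1 fixed point (>= 0).
#' @return The `k2` value (a single nonnegative number).
#' @export
solve_k2_for_target_x3 <- function(params, genotype = params$genotype,
                                   s_input, target_X3) {
  stopifnot(inherits(params, "reg1_params"))
  if (!is.finite(target_X3) || target_X3 < 0) {
    stop("`target_X3` must be >= 0", call. = FALSE)
  }
  if (!is.finite(s_input) || s_input <= 0) {
    stop("`s_input` must be > 0", call. = FALSE)
  }
  p <- apply_genotype(params, genotype)
  if (p$k3 == 0) stop("`k3` must be > 0", call. = FALSE)
  s <- s_input
  if (p$d7 == 0 && p$d8 == 0 && p$d9 == 0) {
    den <- p$d3 + p$d6 * s
    if (den == 0) stop("`d3 + d6*s_input` must be > 0", call. = FALSE)
    X2 <- den / p$k3 * target_X3
    (p$d2 * p$k3 / den * X2^2 + p$d5 * X2) / s
  } else {
    if (p$d8 + p$d9 == 0 && p$d7 * s > 0) {
      stop("degenerate parameters: d8 + d9 = 0 with d7*s_input > 0", call. = FALSE)
    }
    r <- if (p$d8 + p$d9 > 0) p$d7 * s / (p$d8 + p$d9) else 0
    K <- effective_K(p, s)
    ((p$d2 + r * p$d2p) * K * target_X3^2 + p$d5 * K * target_X3) / s
  }
}
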
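# Matched-free-protein model discrimination.
#
# The observation: in the late phase of stimulation, free Regnase-1 and
# target mRNA levels do not differ between wild-type and S513A cells.
# Under matched free Regnase-1 (equal X3), model 1 predicts exactly equal
# mRNA fixed points across genotypes, while model 2 (bound Regnase-1
# still active, d1p/d2p > 0) predicts strictly lower mRNA in wild type.
# Only model 1 is therefore consistent with "no difference".

#' mRNA fixed points under the matched free-Regnase-1 constraint
#'
#' Given a common free-protein level `matched_X3`, returns the predicted
#' mRNA fixed points `(X1, X2)`. For wild type the bound pool is
#' `X4 = (d7*s/(d8+d9)) * matched_X3` and
#' `X1 = k1*s / (d1*X3 + d1p*X4 + d4)`,
#' `X2 = k2*s / (d2*X3 + d2p*X4 + d5)`; for S513A, `X4 = 0` and the same
#' formulas lose the bound-pool terms. Model 1 has `d1p = d2p = 0`, so
#' both genotypes give identical mRNA at matched `X3`.
#'
#' @inheritParams equilibrium
#' @param matched_X3 common free-Regnase-1 level (>= 0).
#' @return Named numeric pair `c(X1, X2)`.
#' @export
predicted_mrna_matched <- function(params, genotype = params$genotype,
                                   s_input, matched_X3) {
  stopifnot(inherits(params, "reg1_params"))
  if (!is.finite(matched_X3) || matched_X3 < 0) {
    stop("`matched_X3` must be >= 0", call. = FALSE)
  }
  if (!is.finite(s_input) || s_input <= 0) {
    stop("`s_input` must be > 0", call. = FALSE)
  }
  p <- apply_genotype(params, genotype)
  s <- s_input
  if (p$d8 + p$d9 == 0 && p$d7 * s > 0) {
    stop("degenerate parameters: d8 + d9 = 0 with d7*s_input > 0", call. = FALSE)
  }
  r <- if (p$d8 + p$d9 > 0) p$d7 * s / (p$d8 + p$d9) else 0
  X4 <- r * matched_X3
  c(X1 = ratio_or_zero(p$k1 * s, p$d1 * matched_X3 + p$d1p * X4 + p$d4),
    X2 = ratio_or_zero(p$k2 * s, p$d2 * matched_X3 + p$d2p * X4 + p$d5))
}

classify_relation <- function(wt, sa, rel_tol) {
  denom <- max(abs(sa), .Machine$double.xmin)
  rel <- (wt - sa) / denom
  if (abs(rel) <= rel_tol) "equal" else if (rel < 0) "wt_less" else "wt_greater"
}

#' Discriminate the two models against the no-difference observation
#'
#' Computes both genotypes' mRNA fixed points at a matched free-protein
#' level and classifies each genotype contrast as `wt_less`, `equal`, or
#' `wt_greater` at relative tolerance `rel_tol`. A model is consistent
#' with the observation of no genotype difference only if both contrasts
#' are `equal`: model 1 always is (the equality is exact), while model 2
#' with `d1p` or `d2p` positive and an active binding arm (`d7*s > 0`)
#' is not, because wild type sequesters part of the nuclease into a pool
#' that keeps degrading mRNA.
#'
#' @inheritParams predicted_mrna_matched
#' @param rel_tol relative tolerance defining "equal", in (0, 0.5).
#'   1e-6 suits analytic comparisons; ~0.1 suits noisy data.
#' @return A `reg1_verdict`: the model kind, the four fixed points, the
#'   two relations, and `consistent_with_no_difference`.
#' @examples
#' p2 <- model_parameters("model2", k1 = 1, k2 = 1, k3 = 1, d1 = 1, d2 = 1,
#'                        d1p = 1, d2p = 1, d3 = 1, d4 = 1, d5 = 1,
#'                        d6 = 1, d7 = 1, d8 = 1, d9 = 1)
#' discriminate_models(p2, s_input = 1, matched_X3 = 0.4)
#' @export
discriminate_models <- function(params, s_input, matched_X3, rel_tol = 1e-6) {
  stopifnot(inherits(params, "reg1_params"))
  if (!is.finite(matched_X3) || matched_X3 <= 0) {
    stop("`matched_X3` must be > 0", call. = FALSE)
  }
  if (!is.finite(rel_tol) || rel_tol <= 0 || rel_tol >= 0.5) {
    stop("`rel_tol` must be in (0, 0.5)", call. = FALSE)
  }
  wt <- predicted_mrna_matched(params, "wt", s_input, matched_X3)
  sa <- predicted_mrna_matched(params, "s513a", s_input, matched_X3)
  relation_x1 <- classify_relation(wt[["X1"]], sa[["X1"]], rel_tol)
  relation_x2 <- classify_relation(wt[["X2"]], sa[["X2"]], rel_tol)
  out <- list(
    model = params$kind,
    X1_WT = wt[["X1"]], X1_SA = sa[["X1"]],
    X2_WT = wt[["X2"]], X2_SA = sa[["X2"]],
    relation_x1 = relation_x1, relation_x2 = relation_x2,
    consistent_with_no_difference =
      relation_x1 == "equal" && relation_x2 == "equal",
    tolerance_used = rel_tol,
    matched_X3 = matched_X3, s_input = s_input
  )
  class(out) <- "reg1_verdict"
  out
}

#' @export
print.reg1_verdict <- function(x, ...) {
  cat("<reg1_verdict> ", x$model, " at matched X3 = ", x$matched_X3, "\n",
      "  Il6 mRNA:     WT ", format(x$X1_WT), " vs S513A ", format(x$X1_SA),
      " (", x$relation_x1, ")\n",
      "  Zc3h12a mRNA: WT ", format(x$X2_WT), " vs S513A ", format(x$X2_SA),
      " (", x$relation_x2, ")\n",
      "  consistent with no genotype difference: ",
      x$consistent_with_no_difference, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.reg1_verdict <- function(x, ...) {
  tibble::tibble(
    observable = c("il6_mrna", "zc3h12a_mrna"),
    wt = c(x$X1_WT, x$X2_WT),
    s513a = c(x$X1_SA, x$X2_SA),
    relation = c(x$relation_x1, x$relation_x2)
  )
}

#' @export
glance.reg1_verdict <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    consistent_with_no_difference = x$consistent_with_no_difference,
    tolerance_used = x$tolerance_used,
    matched_X3 = x$matched_X3,
    s_input = x$s_input
  )
}
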
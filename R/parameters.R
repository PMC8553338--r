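# Parameter and signal-profile containers shared by both models.

PARAM_FIELDS <- c("k1", "k2", "k3", "d1", "d2", "d1p", "d2p",
                  "d3", "d4", "d5", "d6", "d7", "d8", "d9")

PROFILE_FIELDS <- c("s_base", "s_input", "t_delay", "t_raise", "t_pulse",
                    "post_pulse_mode", "t_decay")

OBSERVABLES <- c("total_reg1", "free_reg1", "bound_reg1",
                 "il6_mrna", "zc3h12a_mrna")

check_rate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop("`", name, "` must be a single finite nonnegative number", call. = FALSE)
  }
  as.numeric(x)
}

#' Rate-constant set for the Regnase-1 regulation models
#'
#' Bundles the rate constants of the four-variable inflammation model:
#' transcription of *Il6* (`k1`) and *Zc3h12a* (`k2`), translation of
#' *Zc3h12a* (`k3`), Regnase-1-induced mRNA decay (`d1`, `d2`),
#' decay induced by 14-3-3-bound Regnase-1 (`d1p`, `d2p`; model 2 only),
#' constitutive turnover (`d3` protein, `d4`/`d5` mRNA), signal-dependent
#' ubiquitin-mediated Regnase-1 degradation (`d6`), and the 14-3-3 arm:
#' binding (`d7`, per unit signal), degradation of the bound complex
#' (`d8`) and dissociation (`d9`).
#'
#' Under `kind = "model1"` the bound complex is catalytically dead, so
#' `d1p` and `d2p` must be zero; `kind = "model2"` lets the bound complex
#' keep degrading target mRNAs at rates `d1p`, `d2p`.
#'
#' Time is measured in hours; concentrations are dimensionless arbitrary
#' units (nothing is fitted to absolute scales).
#'
#' @param kind `"model1"` (14-3-3-bound Regnase-1 inactive) or
#'   `"model2"` (bound Regnase-1 still active).
#' @param k1,k2 transcription rate constants (conc/h per unit signal).
#' @param k3 translation rate constant (1/h).
#' @param d1,d2 free-Regnase-1-induced mRNA decay (1/(conc h)).
#' @param d1p,d2p bound-Regnase-1-induced mRNA decay (1/(conc h));
#'   must be 0 under `"model1"`.
#' @param d3 constitutive Regnase-1 protein decay (1/h).
#' @param d4,d5 Regnase-1-independent mRNA decay (1/h).
#' @param d6 ubiquitin-dependent Regnase-1 decay per unit signal (1/h).
#' @param d7 Regnase-1 to 14-3-3 binding rate per unit signal (1/h).
#' @param d8 decay of the 14-3-3-bound complex (1/h).
#' @param d9 dissociation of Regnase-1 from 14-3-3 (1/h).
#' @param genotype `"wt"` or `"s513a"`; records which genotype semantics
#'   the set carries. Constructing with `"s513a"` zeroes `d7`, `d8`, `d9`.
#' @return An object of class `reg1_params`.
#' @seealso [apply_genotype()], [default_parameters()]
#' @examples
#' p <- model_parameters(k1 = 1, k2 = 1, k3 = 1, d1 = 1, d2 = 1,
#'                       d3 = 1, d4 = 1, d5 = 1, d6 = 1, d7 = 1,
#'                       d8 = 1, d9 = 1)
#' p
#' @export
model_parameters <- function(kind = c("model1", "model2"),
                             k1, k2, k3, d1, d2, d1p = 0, d2p = 0,
                             d3, d4, d5, d6, d7, d8, d9,
                             genotype = c("wt", "s513a")) {
  kind <- match.arg(kind)
  genotype <- match.arg(tolower(genotype), c("wt", "s513a"))
  vals <- list(k1 = k1, k2 = k2, k3 = k3, d1 = d1, d2 = d2,
               d1p = d1p, d2p = d2p, d3 = d3, d4 = d4, d5 = d5,
               d6 = d6, d7 = d7, d8 = d8, d9 = d9)
  vals <- purrr::imap(vals, check_rate)
  if (kind == "model1" && (vals$d1p != 0 || vals$d2p != 0)) {
    stop("model 1 defines no activity for 14-3-3-bound Regnase-1: ",
         "`d1p` and `d2p` must be 0", call. = FALSE)
  }
  out <- c(list(kind = kind), vals, list(genotype = genotype))
  class(out) <- "reg1_params"
  if (genotype == "s513a") out <- apply_genotype(out, "s513a")
  out
}

#' @export
print.reg1_params <- function(x, ...) {
  cat("<reg1_params> ", x$kind, ", genotype ", x$genotype, "\n", sep = "")
  vals <- unlist(x[PARAM_FIELDS])
  print(vals)
  invisible(x)
}

#' Apply genotype semantics to a parameter set
#'
#' The S513A knock-in cannot be phosphorylated at S513 and therefore
#' cannot bind 14-3-3; its effective parameters have `d7 = d8 = d9 = 0`.
#' Wild type leaves the set unchanged. The operation is pure and
#' idempotent.
#'
#' @param params a [model_parameters()] object.
#' @param genotype `"wt"` or `"s513a"`.
#' @return A `reg1_params` object; the input is not modified.
#' @export
apply_genotype <- function(params, genotype = c("wt", "s513a")) {
  stopifnot(inherits(params, "reg1_params"))
  genotype <- match.arg(tolower(genotype), c("wt", "s513a"))
  if (genotype == "wt") return(params)
  params$d7 <- 0
  params$d8 <- 0
  params$d9 <- 0
  params$genotype <- "s513a"
  params
}

#' Pulsed stimulation profile
#'
#' Describes the strength of IL-1R/TLR stimulation over time as a delayed
#' ramp-plateau pulse: basal level `s_base` until `t_delay`, a linear ramp
#' to `s_input` over `t_raise`, a plateau of length `t_pulse`, and then
#' either sustained stimulation (`post_pulse_mode = "sustained"`, the
#' default, and the only mode admissible for equilibrium analysis, where
#' the signal is assumed to approach `s_input`) or exponential relaxation
#' back to `s_base` with timescale `t_decay` (`"decaying"`, for
#' exploratory simulation).
#'
#' @param s_base basal signal strength (dimensionless, >= 0).
#' @param s_input stimulated signal strength (>= `s_base`).
#' @param t_delay time before the ramp starts (h).
#' @param t_raise ramp duration (h).
#' @param t_pulse plateau duration (h).
#' @param post_pulse_mode `"sustained"` or `"decaying"`.
#' @param t_decay decay timescale (h, > 0); used only when decaying.
#' @return An object of class `reg1_signal`.
#' @examples
#' pr <- signal_profile(s_base = 0.1, s_input = 1, t_delay = 0.25,
#'                      t_raise = 0.25, t_pulse = 1)
#' signal_at(pr, c(0, 0.375, 100))
#' @export
signal_profile <- function(s_base = 0.05, s_input = 1, t_delay = 0.25,
                           t_raise = 0.25, t_pulse = 24,
                           post_pulse_mode = c("sustained", "decaying"),
                           t_decay = 1) {
  post_pulse_mode <- match.arg(post_pulse_mode)
  s_base <- check_rate(s_base, "s_base")
  s_input <- check_rate(s_input, "s_input")
  if (s_input < s_base) stop("`s_input` must be >= `s_base`", call. = FALSE)
  t_delay <- check_rate(t_delay, "t_delay")
  t_raise <- check_rate(t_raise, "t_raise")
  t_pulse <- check_rate(t_pulse, "t_pulse")
  t_decay <- check_rate(t_decay, "t_decay")
  if (t_decay <= 0) stop("`t_decay` must be > 0", call. = FALSE)
  out <- list(s_base = s_base, s_input = s_input, t_delay = t_delay,
              t_raise = t_raise, t_pulse = t_pulse,
              post_pulse_mode = post_pulse_mode, t_decay = t_decay)
  class(out) <- "reg1_signal"
  out
}

#' @export
print.reg1_signal <- function(x, ...) {
  cat("<reg1_signal> ", x$s_base, " -> ", x$s_input,
      " (delay ", x$t_delay, " h, ramp ", x$t_raise, " h, plateau ",
      x$t_pulse, " h, ", x$post_pulse_mode, ")\n", sep = "")
  invisible(x)
}

#' Evaluate the stimulation signal
#'
#' Piecewise-continuous signal strength at times `t` (hours): basal,
#' linear ramp, plateau, then sustained or exponentially decaying
#' stimulation depending on the profile's mode.
#'
#' @param profile a [signal_profile()] object.
#' @param t numeric vector of times (h, >= 0).
#' @return Numeric vector of signal strengths.
#' @export
signal_at <- function(profile, t) {
  stopifnot(inherits(profile, "reg1_signal"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and nonnegative", call. = FALSE)
  }
  t1 <- profile$t_delay
  t2 <- t1 + profile$t_raise
  t3 <- t2 + profile$t_pulse
  sb <- profile$s_base
  si <- profile$s_input
  s <- rep(sb, length(t))
  ramp <- t > t1 & t < t2
  if (any(ramp)) s[ramp] <- sb + (si - sb) * (t[ramp] - t1) / profile$t_raise
  s[t >= t2 & t <= t3] <- si
  late <- t > t3
  if (any(late)) {
    s[late] <- if (profile$post_pulse_mode == "sustained") {
      si
    } else {
      sb + (si - sb) * exp(-(t[late] - t3) / profile$t_decay)
    }
  }
  s
}

# ---- JSON serialization -------------------------------------------------

#' Read and write parameter sets and signal profiles as JSON
#'
#' Flat key-value JSON documents; the round trip `write` then `read` is
#' lossless (values are serialized at full double precision).
#'
#' @param params a `reg1_params` object.
#' @param profile a `reg1_signal` object.
#' @param path file path.
#' @return `read_parameters()` returns a `reg1_params`;
#'   `read_signal_profile()` a `reg1_signal`; the writers return `path`
#'   invisibly.
#' @name params_io
NULL

full_precision <- function(x) {
  purrr::map(x, function(v) if (is.numeric(v)) sprintf("%.17g", v) else v)
}

#' @rdname params_io
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "reg1_params"))
  doc <- full_precision(unclass(params)[c(PARAM_FIELDS, "kind", "genotype")])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname params_io
#' @export
read_parameters <- function(path) {
  doc <- jsonlite::read_json(path)
  vals <- purrr::map(doc[PARAM_FIELDS], as.numeric)
  do.call(model_parameters,
          c(list(kind = doc$kind, genotype = doc$genotype %||% "wt"), vals))
}

#' @rdname params_io
#' @export
write_signal_profile <- function(profile, path) {
  stopifnot(inherits(profile, "reg1_signal"))
  doc <- full_precision(unclass(profile)[PROFILE_FIELDS])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname params_io
#' @export
read_signal_profile <- function(path) {
  doc <- jsonlite::read_json(path)
  num <- purrr::map(doc[setdiff(PROFILE_FIELDS, "post_pulse_mode")], as.numeric)
  do.call(signal_profile, c(num, list(post_pulse_mode = doc$post_pulse_mode)))
}
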
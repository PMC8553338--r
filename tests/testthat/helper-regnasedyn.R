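# Shared fixtures: unit parameter sets, random draws, and a bisection
# root oracle used to verify the closed-form quadratics independently.

unit_params <- function(kind = "model1", ...) {
  args <- list(kind = kind, k1 = 1, k2 = 1, k3 = 1, d1 = 1, d2 = 1,
               d3 = 1, d4 = 1, d5 = 1, d6 = 1, d7 = 1, d8 = 1, d9 = 1)
  mods <- list(...)
  args[names(mods)] <- mods
  do.call(model_parameters, args)
}

# Random nonnegative parameter draw; model 2 draws d1p/d2p too.
random_params <- function(kind = "model1", lo = 0.05, hi = 2) {
  nm <- c("k1", "k2", "k3", "d1", "d2", "d1p", "d2p",
          "d3", "d4", "d5", "d6", "d7", "d8", "d9")
  v <- as.list(stats::setNames(runif(14, lo, hi), nm))
  if (kind == "model1") v$d1p <- v$d2p <- 0
  do.call(model_parameters, c(list(kind = kind), v))
}

# Sign-change bisection; independent oracle for the quadratic roots.
bisect_root <- function(f, lower, upper, tol = 1e-13) {
  fl <- f(lower)
  for (i in 1:200) {
    mid <- (lower + upper) / 2
    fm <- f(mid)
    if (sign(fm) == sign(fl)) {
      lower <- mid
      fl <- fm
    } else {
      upper <- mid
    }
    if (upper - lower < tol) break
  }
  (lower + upper) / 2
}

sustained_profile <- function(s_base = 0, s_input = 1) {
  signal_profile(s_base = s_base, s_input = s_input, t_delay = 0,
                 t_raise = 0.01, t_pulse = 1, post_pulse_mode = "sustained")
}
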
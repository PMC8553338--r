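test_that("parameter validation rejects negatives, NaN, and bound-complex activity under model 1", {
  expect_error(unit_params(d3 = -0.1), "nonnegative")
  expect_error(unit_params(k1 = NaN), "finite")
  expect_error(unit_params(kind = "model1", d1p = 0.5), "d1p")
  expect_s3_class(unit_params(kind = "model2", d1p = 0.5, d2p = 0.5),
                  "reg1_params")
})

test_that("S513A semantics zero exactly d7, d8, d9 and are idempotent", {
  p <- unit_params(d7 = 0.3, d8 = 0.2, d9 = 0.1)
  sa <- apply_genotype(p, "s513a")
  expect_identical(sa[c("d7", "d8", "d9")], list(d7 = 0, d8 = 0, d9 = 0))
  kept <- c("k1", "k2", "k3", "d1", "d2", "d1p", "d2p", "d3", "d4", "d5", "d6")
  expect_identical(sa[kept], p[kept])
  expect_identical(apply_genotype(sa, "s513a"), sa)
  # wild type is the identity
  expect_identical(apply_genotype(p, "wt"), p)
})

test_that("signal follows the basal/ramp/plateau/post-pulse pieces", {
  pr <- signal_profile(s_base = 0.1, s_input = 1, t_delay = 0.25,
                       t_raise = 0.25, t_pulse = 1)
  expect_equal(signal_at(pr, 0), 0.1)
  expect_equal(signal_at(pr, 0.25 + 0.125), 0.55)  # ramp midpoint
  expect_equal(signal_at(pr, 0.75), 1)
  expect_equal(signal_at(pr, 100), 1)  # sustained tail -> s_input
  dec <- signal_profile(s_base = 0.1, s_input = 1, t_delay = 0.25,
                        t_raise = 0.25, t_pulse = 1,
                        post_pulse_mode = "decaying", t_decay = 0.5)
  t3 <- 1.5
  expect_equal(signal_at(dec, t3 + 0.5), 0.1 + 0.9 * exp(-1))
  expect_equal(signal_at(dec, 1e4), 0.1, tolerance = 1e-12)
  expect_error(signal_at(pr, -1), "nonnegative")
})

test_that("signal is continuous across its breakpoints in both modes", {
  set.seed(11)
  for (i in 1:20) {
    pr <- signal_profile(s_base = runif(1, 0, 0.5), s_input = runif(1, 0.5, 2),
                         t_delay = runif(1, 0, 1), t_raise = runif(1, 0.01, 1),
                         t_pulse = runif(1, 0.01, 2),
                         post_pulse_mode = sample(c("sustained", "decaying"), 1),
                         t_decay = runif(1, 0.1, 2))
    brk <- cumsum(c(pr$t_delay, pr$t_raise, pr$t_pulse))
    for (b in brk[brk > 0]) {
      expect_lt(abs(signal_at(pr, b - 1e-11) - signal_at(pr, b + 1e-11)), 1e-9)
    }
  }
})

test_that("rhs matches the model equations at the origin and at the fixed point", {
  p <- unit_params()
  expect_equal(model_rhs(p, c(0, 0, 0, 0), 1),
               c(x1 = 1, x2 = 1, x3 = 0, x4 = 0))
  eq <- equilibrium(p, "wt", 1)
  res <- model_rhs(p, c(eq$X1, eq$X2, eq$X3, eq$X4), 1)
  expect_lt(max(abs(res)), 1e-10)
  expect_error(model_rhs(p, c(-1, 0, 0, 0), 1), "nonnegative")
  expect_error(model_rhs(p, c(1, 1, 1, 1), -0.5), ">= 0")
})

test_that("model 2 with inert bound complex reduces exactly to model 1", {
  set.seed(42)
  for (i in 1:200) {
    p2 <- random_params("model2")
    p2$d1p <- 0
    p2$d2p <- 0
    p1 <- do.call(model_parameters,
                  c(list(kind = "model1"),
                    p2[c("k1","k2","k3","d1","d2","d3","d4","d5","d6","d7","d8","d9")]))
    x <- runif(4, 0, 3)
    s <- runif(1, 0, 2)
    expect_identical(model_rhs(p2, x, s), model_rhs(p1, x, s))
  }
})

test_that("the nonnegative orthant is forward-invariant: inflow on every face", {
  set.seed(7)
  for (i in 1:100) {
    p <- random_params(sample(c("model1", "model2"), 1), lo = 0, hi = 2)
    x <- runif(4, 0, 3)
    s <- runif(1, 0, 2)
    for (face in 1:4) {
      xf <- x
      xf[face] <- 0
      expect_gte(model_rhs(p, xf, s)[[face]], 0)
    }
  }
})

test_that("parameter sets and profiles survive a JSON round trip losslessly", {
  p <- unit_params(kind = "model2", k1 = 1/3, d1p = pi, d2p = exp(1),
                   d7 = 1e-7)
  f <- withr::local_tempfile(fileext = ".json")
  write_parameters(p, f)
  expect_identical(read_parameters(f), p)

  pr <- signal_profile(s_base = 1/3, s_input = sqrt(2), t_delay = 0.1,
                       t_raise = 1/7, t_pulse = 2,
                       post_pulse_mode = "decaying", t_decay = 1/9)
  f2 <- withr::local_tempfile(fileext = ".json")
  write_signal_profile(pr, f2)
  expect_identical(read_signal_profile(f2), pr)
})
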
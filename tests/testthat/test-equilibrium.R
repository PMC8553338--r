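test_that("K evaluates to its closed form and is nonnegative for nonnegative rates", {
  p <- unit_params()
  expect_equal(effective_K(p, 1), 2.5)  # (1 + 1 + 1 - 1/(1+1)) / 1
  expect_equal(effective_K(unit_params(d7 = 0, d9 = 0.7), 1), 2)  # (d3+d6*s)/k3
  expect_error(effective_K(unit_params(k3 = 0), 1), "k3")

  set.seed(5)
  for (i in 1:1000) {
    p <- random_params("model2", lo = 0, hi = 3)
    s <- runif(1, 0, 3)
    K <- effective_K(p, s)
    expect_gte(K, 0)
    # algebraic identity: K*k3 = d3 + d6*s + d7*s*d8/(d8 + d9)
    sq <- if (p$d8 + p$d9 == 0) 0 else p$d7 * s * p$d8 / (p$d8 + p$d9)
    expect_equal(K * p$k3, p$d3 + p$d6 * s + sq, tolerance = 1e-12)
  }
})

test_that("wild-type closed form matches the bisection oracle on the unit set", {
  p <- unit_params()
  eq <- equilibrium(p, "wt", 1)
  # quadratic 2.5*X3^2 + 2.5*X3 - 1 = 0, root found independently
  x3_oracle <- bisect_root(function(x) 2.5 * x^2 + 2.5 * x - 1, 0, 1)
  expect_equal(eq$X3, x3_oracle, tolerance = 1e-10)
  expect_equal(eq$X3, (-2.5 + sqrt(16.25)) / 5, tolerance = 1e-12)
  expect_equal(eq$X4, eq$X3 / 2)
  expect_equal(eq$X2, 2.5 * eq$X3)
  expect_equal(eq$X1, 1 / (eq$X3 + 1))
  expect_true(eq$exists)
  expect_identical(eq$branch, "wt_general")
  expect_lt(max(abs(model_rhs(p, c(eq$X1, eq$X2, eq$X3, eq$X4), 1))), 1e-10)
})

test_that("S513A closed form matches its oracle and has exactly zero bound pool", {
  p <- unit_params()
  eq <- equilibrium(p, "s513a", 1)
  # quadratic 0.5*X2^2 + X2 - 1 = 0
  x2_oracle <- bisect_root(function(x) 0.5 * x^2 + x - 1, 0, 1)
  expect_equal(eq$X2, x2_oracle, tolerance = 1e-10)
  expect_equal(eq$X2, -1 + sqrt(3), tolerance = 1e-12)
  expect_equal(eq$X3, eq$X2 / 2)
  expect_equal(eq$X1, 1 / (eq$X3 + 1))
  expect_identical(eq$X4, 0)
  expect_identical(eq$branch, "s513a_reduced")
  psa <- apply_genotype(p, "s513a")
  expect_lt(max(abs(model_rhs(psa, c(eq$X1, eq$X2, eq$X3, eq$X4), 1))), 1e-10)
})

test_that("zero signal yields the origin fixed point", {
  for (g in c("wt", "s513a")) {
    eq <- equilibrium(unit_params(), g, 0)
    expect_equal(unname(unlist(eq[c("X1", "X2", "X3", "X4")])), rep(0, 4))
  }
})

test_that("the discarded quadratic root is negative whenever stimulation is on", {
  set.seed(31)
  for (i in 1:200) {
    p <- random_params("model2", lo = 0.05, hi = 2)
    s <- runif(1, 0.1, 2)
    K <- effective_K(p, s)
    r <- p$d7 * s / (p$d8 + p$d9)
    a <- (p$d2 + r * p$d2p) * K
    b <- p$d5 * K
    cc <- p$k2 * s
    other <- (-b - sqrt(b^2 + 4 * a * cc)) / (2 * a)
    expect_lt(other, 0)
    expect_gte(equilibrium(p, "wt", s)$X3, 0)
  }
})

test_that("closed forms agree with the damped-Newton oracle across models and genotypes", {
  set.seed(99)
  for (kind in c("model1", "model2")) {
    for (g in c("wt", "s513a")) {
      for (i in 1:50) {
        p <- random_params(kind, lo = 0.1, hi = 2)
        s <- runif(1, 0.2, 2)
        eq <- equilibrium(p, g, s)
        num <- equilibrium_numeric(p, g, s, x0 = c(1, 1, 1, 1))
        expect_true(num$converged)
        tgt <- unlist(eq[c("X1", "X2", "X3", "X4")])
        expect_equal(unname(num$state), unname(tgt), tolerance = 1e-8)
        expect_lt(max(abs(model_rhs(apply_genotype(p, g), tgt, s))), 1e-9)
      }
    }
  }
})

test_that("numeric oracle returns the origin for zero stimulation started there", {
  num <- equilibrium_numeric(unit_params(), "wt", 0, x0 = rep(0, 4))
  expect_true(num$converged)
  expect_equal(unname(num$state), rep(0, 4))
})

test_that("the stalled 14-3-3 corner is rejected, and the reduced branch covers the no-arm case", {
  p <- unit_params(d8 = 0, d9 = 0)  # d7 = 1, s > 0: bound pool has no exit
  expect_error(equilibrium(p, "wt", 1), "degenerate")
  p0 <- unit_params(d7 = 0, d8 = 0, d9 = 0)
  eq <- equilibrium(p0, "wt", 1)
  expect_identical(eq$branch, "s513a_reduced")
  num <- equilibrium_numeric(p0, "wt", 1)
  expect_equal(unname(num$state),
               unname(unlist(eq[c("X1", "X2", "X3", "X4")])), tolerance = 1e-8)
})

test_that("solve_k2_for_target_x3 inverts the equilibrium and round-trips", {
  p <- unit_params()
  expect_equal(solve_k2_for_target_x3(p, "s513a", 1, (-1 + sqrt(3)) / 2), 1,
               tolerance = 1e-12)
  expect_equal(solve_k2_for_target_x3(p, "wt", 1, 0.5), 1.875)
  expect_identical(solve_k2_for_target_x3(p, "wt", 1, 0), 0)
  expect_error(solve_k2_for_target_x3(p, "wt", 1, -0.1), ">= 0")

  set.seed(17)
  for (i in 1:100) {
    p <- random_params(sample(c("model1", "model2"), 1), lo = 0.05, hi = 2)
    g <- sample(c("wt", "s513a"), 1)
    s <- runif(1, 0.1, 2)
    target <- runif(1, 0, 2)
    p$k2 <- solve_k2_for_target_x3(p, g, s, target)
    expect_lt(abs(equilibrium(p, g, s)$X3 - target), 1e-10)
  }
})

test_that("tidy() lays the fixed point out as observable/value rows", {
  td <- tidy(equilibrium(unit_params(), "wt", 1))
  expect_identical(td$observable,
                   c("il6_mrna", "zc3h12a_mrna", "free_reg1", "bound_reg1"))
  expect_true(all(td$value >= 0))
})
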
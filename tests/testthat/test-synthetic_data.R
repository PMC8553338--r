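test_that("observables project the state as blot bands and qPCR targets", {
  st <- c(1, 2, 3, 4)
  expect_identical(observe_state(st, "total_reg1"), 7)
  expect_identical(observe_state(st, "free_reg1"), 3)
  expect_identical(observe_state(st, "bound_reg1"), 4)
  expect_identical(observe_state(st, "il6_mrna"), 1)
  expect_identical(observe_state(st, "zc3h12a_mrna"), 2)
  for (ob in c("total_reg1", "free_reg1", "bound_reg1", "il6_mrna", "zc3h12a_mrna")) {
    expect_identical(observe_state(rep(0, 4), ob), 0)
  }
})

test_that("noiseless tables equal the model projections and noisy ones are seed-reproducible", {
  pw <- default_parameters("wt")
  ps <- default_parameters("s513a")
  pr <- default_profile()
  clean <- simulate_observations(pw, ps, pr, cv = 0, replicates = 1)
  expect_identical(nrow(clean), 2L * 4L * 5L)
  tcw <- simulate_timecourse(pw, pr, times = c(0, 0.5, 2, 4))
  i <- which(clean$genotype == "wt" & clean$time == 2 &
               clean$observable == "total_reg1")
  expect_identical(clean$value[i], tcw$x3[3] + tcw$x4[3])

  a <- simulate_observations(pw, ps, pr, cv = 0.1, replicates = 3, seed = 7)
  b <- simulate_observations(pw, ps, pr, cv = 0.1, replicates = 3, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- simulate_observations(pw, ps, pr, cv = 0.1, replicates = 3, seed = 8)
  expect_false(identical(a$value, c2$value))
  expect_true(all(a$value >= 0))
})

test_that("the lognormal noise is mean-1 at the requested CV", {
  set.seed(123)
  for (cv in c(0.05, 0.1, 0.3)) {
    f <- regnasedyn:::noise_factors(1e5, cv)
    expect_equal(mean(f), 1, tolerance = 0.01)
    expect_equal(stats::sd(f) / mean(f), cv, tolerance = 0.02)
  }
})

test_that("replicate means track the noiseless values within Monte-Carlo error", {
  pw <- default_parameters("wt")
  ps <- default_parameters("s513a")
  pr <- default_profile()
  clean <- simulate_observations(pw, ps, pr, cv = 0, replicates = 1)
  cv <- 0.1
  n_rep <- 3
  ok <- 0L
  total <- 0L
  for (seed in 1:50) {
    noisy <- simulate_observations(pw, ps, pr, cv = cv, replicates = n_rep,
                                   seed = seed)
    means <- noisy |>
      dplyr::group_by(genotype, time, observable) |>
      dplyr::summarise(m = mean(value), .groups = "drop") |>
      dplyr::left_join(dplyr::rename(clean, truth = value),
                       by = c("genotype", "time", "observable"))
    # 3 SDs of the replicate mean of mean-1 lognormal factors
    band <- 3 * cv / sqrt(n_rep) * means$truth
    ok <- ok + sum(abs(means$m - means$truth) <= band | means$truth == 0)
    total <- total + nrow(means)
  }
  expect_gte(ok / total, 0.99)
})

test_that("default synthetic data shows the knock-in phenotype: dip, overshoot, low S513A total, matched free protein", {
  clean <- simulate_observations(default_parameters("wt"),
                                 default_parameters("s513a"),
                                 default_profile(), cv = 0, replicates = 1)
  v <- function(g, t, ob) {
    clean$value[clean$genotype == g & clean$time == t & clean$observable == ob]
  }
  expect_lt(v("wt", 0.5, "total_reg1"), v("wt", 0, "total_reg1"))
  expect_gt(v("wt", 4, "total_reg1"), v("wt", 0, "total_reg1"))
  expect_lt(v("s513a", 4, "total_reg1"), v("wt", 4, "total_reg1"))
  expect_equal(v("wt", 4, "free_reg1"), v("s513a", 4, "free_reg1"),
               tolerance = 0.1)
  expect_equal(v("wt", 4, "il6_mrna"), v("s513a", 4, "il6_mrna"),
               tolerance = 0.1)
})

test_that("observation tables round-trip through CSV with provenance", {
  obs <- simulate_observations(default_parameters("wt"),
                               default_parameters("s513a"),
                               cv = 0.1, replicates = 2, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, f)
  expect_identical(readLines(f, n = 1), "genotype,time,observable,replicate,value")
  back <- read_observations(f)
  expect_equal(as.data.frame(back), as.data.frame(obs))
  prov <- attr(back, "provenance")
  expect_identical(prov$params_wt, attr(obs, "provenance")$params_wt)
  expect_identical(prov$profile, attr(obs, "provenance")$profile)
  expect_identical(prov$noise$cv, 0.1)
})
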
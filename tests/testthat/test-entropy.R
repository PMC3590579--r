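test_that("coarse-graining averages non-overlapping blocks and drops remainders", {
  expect_equal(coarse_grain(1:6, 2), c(1.5, 3.5, 5.5))
  expect_equal(coarse_grain(1:7, 3), c(2, 5))          # floor(7/3) = 2 blocks
  x <- rnorm(137)
  expect_identical(coarse_grain(x, 1), as.numeric(x))  # scale 1 is the identity
  expect_error(coarse_grain(1:3, 5), "exceeds")
  # loop-based oracle across scales and lengths
  for (tau in c(2, 3, 5, 10)) {
    expect_equal(coarse_grain(x, tau), coarse_grain_loop(x, tau),
                 tolerance = 1e-14)
  }
})

test_that("coarse-graining conserves the mean exactly when tau divides N", {
  x <- rnorm(120)
  for (tau in c(2, 3, 4, 5, 6)) {
    expect_equal(mean(coarse_grain(x, tau)), mean(x), tolerance = 1e-12)
  }
})

test_that("sample entropy of a constant series is exactly zero with absolute r", {
  se <- sample_entropy(rep(3.7, 50), m = 2, r = 0.2)
  expect_identical(as.numeric(se), 0)
  expect_equal(attr(se, "A"), attr(se, "B"))
})

test_that("sample entropy rejects degenerate tolerances and short input", {
  expect_error(sample_entropy(rnorm(50), 2, r = 0), "degenerate tolerance")
  expect_error(sample_entropy(rnorm(50), 2, r = -1), "degenerate tolerance")
  expect_error(sample_entropy(rnorm(3), 2, 0.2), "length")
  expect_error(mse_curve(rep(1, 100)), "degenerate tolerance")
})

test_that("sample entropy matches the brute-force template-counting oracle", {
  set.seed(101)
  cases <- 0
  for (rep_i in 1:40) {
    n <- sample(20:300, 1)
    x <- switch(1 + rep_i %% 3,
                rnorm(n),
                cumsum(rnorm(n)),
                sin(seq_len(n) / 5) + rnorm(n, sd = 0.3))
    for (m in c(1, 2)) {
      r <- sample(c(0.1, 0.2, 0.3), 1) * sd(x)
      got <- sample_entropy(x, m, r)
      want <- sampen_bruteforce(x, m, r)
      if (is.finite(want)) {
        expect_equal(as.numeric(got), want, tolerance = 1e-12)
      } else {
        expect_identical(is.nan(as.numeric(got)), is.nan(want))
      }
      cases <- cases + 1
    }
  }
  expect_gte(cases, 80)
})

test_that("sample entropy is invariant under affine transforms with scaled r", {
  set.seed(7)
  x <- rnorm(200)
  base <- as.numeric(sample_entropy(x, 2, 0.2 * sd(x)))
  for (i in 1:5) {
    a <- runif(1, 0.1, 10) * sample(c(-1, 1), 1)
    b <- runif(1, -5, 5)
    got <- as.numeric(sample_entropy(a * x + b, 2, 0.2 * sd(x) * abs(a)))
    expect_equal(got, base, tolerance = 1e-10)
  }
})

test_that("undefined and infinite entropy are flagged, never zeroed", {
  # widely separated values, tiny r: no m-template matches at all -> undefined
  x <- c(0, 10, 0, 20, 0, 30, 0, 40, 0, 50, 0, 60)
  se <- sample_entropy(x, 2, r = 0.001)
  expect_true(is.nan(as.numeric(se)))
  expect_equal(attr(se, "flag"), "undefined")
  # B > 0 but no (m+1)-matches -> +Inf: repeated 1s whose successors diverge
  y <- c(1, 2, 1, 7, 1, 12, 1, 17)
  se2 <- sample_entropy(y, 1, r = 0.5)
  expect_true(attr(se2, "B") > 0)
  expect_identical(attr(se2, "A"), 0)
  expect_identical(as.numeric(se2), Inf)
  expect_equal(attr(se2, "flag"), "infinite")
})

test_that("mse_curve fixes r from the scale-1 SD and flags degenerate scales", {
  set.seed(11)
  x <- rnorm(400)
  curve <- mse_curve(x, mse_config(tau_max = 8))
  expect_equal(curve$n_tau, (length(x) %/% curve$tau))
  expect_equal(curve$r_used, rep(0.15 * sd(x), 8))
  # scale-1 entry equals sample entropy of the raw series
  expect_equal(curve$s_e[1],
               as.numeric(sample_entropy(x, 2, 0.15 * sd(x))),
               tolerance = 1e-12)
  # per-scale r mode recomputes the SD
  curve2 <- mse_curve(x, mse_config(tau_max = 4, r_fixed_across_scales = FALSE))
  expect_equal(curve2$r_used[3], 0.15 * sd(coarse_grain(x, 3)), tolerance = 1e-12)
})

test_that("MEI sums the small-scale and large-scale bands", {
  set.seed(12)
  x <- rnorm(600)
  curve <- mse_curve(x)
  m <- mei(curve)
  expect_equal(m$mei_ss, sum(curve$s_e[1:5]), tolerance = 1e-12)
  expect_equal(m$mei_ls, sum(curve$s_e[6:10]), tolerance = 1e-12)
  expect_equal(m$mei_ss + m$mei_ls, sum(curve$s_e), tolerance = 1e-12)

  curve$s_e <- c(1, 1, 1, 1, 1, 0.5, 0.5, 0.5, 0.5, 0.5)
  m2 <- mei(curve)
  expect_equal(m2$mei_ss, 5.0)
  expect_equal(m2$mei_ls, 2.5)

  curve$s_e <- rep(0, 10)
  m0 <- mei(curve)
  expect_equal(c(m0$mei_ss, m0$mei_ls), c(0, 0))

  expect_error(mei(mse_curve(x, mse_config(tau_max = 8))), "scales 1..10")
})

test_that("degenerate scales propagate to a flagged, undefined MEI", {
  set.seed(13)
  curve <- mse_curve(rnorm(600))
  curve$s_e[7] <- NaN
  curve$flags[7] <- "undefined"
  m <- mei(curve)
  expect_true(is.nan(m$mei_ls))
  expect_false(is.nan(m$mei_ss))
  expect_equal(unname(m$flags["mei_ls"]), "degenerate")
})

test_that("MSE separates white from 1/f noise in the expected direction", {
  set.seed(20)
  n_seeds <- 12
  w1 <- w10 <- p1 <- p10 <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    cw <- mse_curve(rnorm(1000))
    cp <- mse_curve(meipulse:::pink_noise(1000))
    w1[s] <- cw$s_e[1]; w10[s] <- cw$s_e[10]
    p1[s] <- cp$s_e[1]; p10[s] <- cp$s_e[10]
  }
  white_decline <- mean(w1) - mean(w10)
  pink_change <- abs(mean(p10) - mean(p1))
  expect_gt(white_decline, 0)
  expect_lt(pink_change, white_decline / 2)
  # pink exceeds white at the largest scale
  expect_gt(mean(p10), mean(w10))
})
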
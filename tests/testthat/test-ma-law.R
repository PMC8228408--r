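ma_data <- function(A, b, c, n = 10, noise = 0) {
  x <- seq_len(n)
  data.frame(x = x,
             mean_length = A * x^b * exp(-c * x) * exp(rnorm(n, 0, noise)))
}

test_that("zero-noise special-form fits invert the generating law exactly", {
  fit <- fit_ma_special(ma_data(13.56, 0, 0.490))
  expect_equal(fit$A, 13.56, tolerance = 1e-10)
  expect_equal(fit$c, 0.490, tolerance = 1e-10)
  expect_equal(fit$R2, 1, tolerance = 1e-12)
  expect_equal(fit$b, 0)

  unit <- fit_ma_special(ma_data(1, 0, 1))
  expect_equal(unit$A, 1, tolerance = 1e-10)
  expect_equal(unit$c, 1, tolerance = 1e-10)

  set.seed(12)
  for (rep in 1:10) {
    A <- exp(runif(1, 0, 4)); c <- runif(1, 0, 1)
    f <- fit_ma_special(ma_data(A, 0, c))
    expect_equal(f$A, A, tolerance = 1e-10)
    expect_equal(f$c, c, tolerance = 1e-10)
  }
})

test_that("flat series yield no decay and a null F test", {
  fit <- fit_ma_special(data.frame(x = 1:8, mean_length = rep(4.2, 8)))
  expect_equal(fit$c, 0)
  expect_equal(fit$F, 0)
  expect_equal(fit$p, 1)
})

test_that("general-form fits recover power and exponential components", {
  # closed-form inversion of the log-linear system
  fit <- fit_ma_general(ma_data(2, 0.5, 0.1))
  expect_equal(fit$A, 2, tolerance = 1e-9)
  expect_equal(fit$b, 0.5, tolerance = 1e-9)
  expect_equal(fit$c, 0.1, tolerance = 1e-9)

  # b = 0 data: general fit collapses onto the special fit
  g0 <- fit_ma_general(ma_data(13.56, 0, 0.490))
  s0 <- fit_ma_special(ma_data(13.56, 0, 0.490))
  expect_equal(g0$b, 0, tolerance = 1e-8)
  expect_equal(g0$A, s0$A, tolerance = 1e-8)
  expect_equal(g0$c, s0$c, tolerance = 1e-8)

  # c = 0 data: pure power law
  p0 <- fit_ma_general(ma_data(3, -0.7, 0))
  expect_equal(p0$c, 0, tolerance = 1e-9)
  expect_equal(p0$b, -0.7, tolerance = 1e-9)
})

test_that("general fit never explains less variance than the special fit", {
  set.seed(55)
  for (rep in 1:30) {
    d <- ma_data(exp(runif(1, 0, 3)), runif(1, -0.5, 0.5), runif(1, 0, 0.5),
                 n = sample(6:15, 1), noise = 0.3)
    expect_gte(fit_ma_general(d)$R2, fit_ma_special(d)$R2 - 1e-12)
  }
})

test_that("the F statistic matches its R-squared form", {
  set.seed(66)
  for (rep in 1:30) {
    d <- ma_data(10, 0, 0.3, n = sample(5:20, 1), noise = 0.4)
    f <- fit_ma_special(d)
    expect_equal(f$F, f$R2 * (f$n - 2) / (1 - f$R2), tolerance = 1e-10)
    expect_equal(f$R, sqrt(f$R2), tolerance = 1e-12)
    expect_equal(f$p, pf(f$F, 1, f$n - 2, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("noisy replicates recover the tRNA-scale parameters", {
  set.seed(99)
  A_true <- 13.56; c_true <- 0.490
  A_hat <- c_hat <- numeric(300)
  coverA <- coverC <- logical(300)
  for (rep in 1:300) {
    d <- ma_data(A_true, 0, c_true, n = 10, noise = 0.2)
    f <- fit_ma_special(d)
    A_hat[rep] <- f$A; c_hat[rep] <- f$c
    tq <- qt(0.975, f$n - 2)
    se_int <- f$SE_A / f$A
    coverA[rep] <- abs(log(f$A) - log(A_true)) <= tq * se_int
    coverC[rep] <- abs(f$c - c_true) <= tq * f$SE_c
  }
  expect_lt(abs(mean(A_hat) - A_true) / A_true, 0.10)
  expect_lt(abs(mean(c_hat) - c_true) / c_true, 0.10)
  expect_gte(mean(coverA), 0.90)
  expect_gte(mean(coverC), 0.90)
})

test_that("the optional nonlinear refit reports both routes when they differ", {
  set.seed(10)
  d <- ma_data(13.56, 0, 0.490, noise = 0.3)
  f <- suppressMessages(fit_ma_special(d, nonlinear = TRUE))
  expect_false(is.null(f$nonlinear))
  expect_gt(f$nonlinear$A, 0)
  # on noiseless data the two routes agree
  f0 <- fit_ma_special(ma_data(5, 0, 0.2), nonlinear = TRUE)
  expect_equal(f0$nonlinear$A, f0$A, tolerance = 1e-6)
  expect_null(f0$nls_disagrees)
})

test_that("invalid fitting inputs are rejected", {
  expect_error(fit_ma_special(data.frame(x = 1:5, mean_length = c(1, 2, 0, 4, 5))),
               "positive")
  expect_error(fit_ma_special(data.frame(x = rep(2, 5),
                                         mean_length = exp(1:5))),
               "zero variance")
  expect_error(fit_ma_special(data.frame(x = 1:2, mean_length = c(2, 1))),
               "n >= 3")
  expect_error(fit_ma_general(data.frame(x = 0:4, mean_length = exp(5:1))),
               "x >= 1")
})

test_that("decay parameterization maps (A, c) through the time scale", {
  f <- fit_ma_special(ma_data(13.56, 0, 0.490))
  d1 <- to_decay(f, 1)
  expect_equal(d1$N0, f$A)
  expect_equal(d1$lambda, f$c)
  d2 <- to_decay(f, 2)
  expect_equal(d2$lambda, 2 * f$c)
  expect_error(to_decay(f, 0), "positive")
})

test_that("fit tables collect the Table-3 style columns", {
  fits <- list(tRNA = fit_ma_special(ma_data(13.56, 0, 0.490)),
               rRNA = fit_ma_special(ma_data(33.52, 0, 0.012)))
  tab <- ma_report(fits)
  expect_equal(tab$type, c("tRNA", "rRNA"))
  expect_true(all(c("A", "SE_A", "c", "SE_c", "R2", "R", "F", "p") %in%
                    names(tab)))
  expect_equal(tab$A, c(13.56, 33.52), tolerance = 1e-9)
})
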
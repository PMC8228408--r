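test_that("mean lengths exclude absences and drop all-absent characters", {
  cm <- char_matrix(matrix(c("7", "7", "0", "8",
                             "A", "C", "C", "A",
                             "0", "0", "0", "0"), 4, 3,
                           dimnames = list(paste0("t", 1:4),
                                           c("s1", "s2", "s3"))),
                    class = c("helical", "helical", "unpaired"))
  expect_warning(ml <- mean_lengths(cm), "absent in all taxa: s3")
  expect_equal(ml$label, c("s1", "s2"))
  expect_equal(ml$mean_length, c((7 + 7 + 8) / 3, (10 + 12 + 12 + 10) / 4))
  expect_equal(ml$n_present, c(3L, 4L))
})

test_that("series construction assigns cumulative accretion ranks", {
  means <- data.frame(label = c("a", "b", "c"), class = "helical",
                      mean_length = c(9, 6, 4))
  ages <- data.frame(label = c("a", "b", "c"), nd = c(0, 0.5, 1))
  s <- build_series(means, ages)
  expect_s3_class(s, "accretion_series")
  expect_equal(s$x, 1:3)

  means4 <- data.frame(label = letters[1:4], class = "helical",
                       mean_length = c(9, 6, 5, 4))
  ages4 <- data.frame(label = letters[1:4], nd = c(0, 0.5, 0.5, 1))
  expect_equal(build_series(means4, ages4)$x, c(1L, 3L, 3L, 4L))

  expect_error(build_series(means, ages[1:2, ]), "without age: c")
  expect_error(
    build_series(means[1:2, ], ages), "without mean length: c")
  expect_error(build_series(means, ages, "unpaired"), "class filter")
})

test_that("perfect linear series give exact correlation statistics", {
  s <- as_accretion_series(data.frame(
    label = paste0("s", 1:6), class = "helical",
    nd = seq(0, 1, length.out = 6),
    mean_length = -2 * seq(0, 1, length.out = 6) + 5))
  res <- correlate(s)
  expect_equal(res$slope, -2)
  expect_equal(res$r, -1)
  expect_equal(res$R2, 1)
  expect_equal(res$rho, -1)
  expect_equal(res$df, 4L)
})

test_that("strictly decreasing series give Spearman rho = -1 exactly", {
  set.seed(5)
  nd <- sort(runif(12))
  y <- sort(exp(rnorm(12, 2, 0.5)), decreasing = TRUE)
  s <- as_accretion_series(data.frame(label = paste0("s", 1:12),
                                      class = "helical", nd = nd,
                                      mean_length = y))
  expect_identical(correlate(s)$rho, -1)
})

test_that("degenerate inputs are rejected", {
  s <- as_accretion_series(data.frame(label = c("a", "b", "c"),
                                      class = "helical", nd = c(0, 0.5, 1),
                                      mean_length = c(3, 3, 3)))
  expect_error(correlate(s), "degenerate")
  expect_error(correlate(s[1:2, ]), "n >= 3")
})

test_that("R2 equals r squared and OLS matches the covariance formulas", {
  set.seed(404)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    nd <- runif(n)
    y <- exp(rnorm(n, 1, 0.4))
    s <- as_accretion_series(data.frame(label = paste0("s", 1:n),
                                        class = "helical", nd = nd,
                                        mean_length = y))
    res <- correlate(s)
    expect_equal(res$R2, res$r^2, tolerance = 1e-12)
    # closed-form oracle
    r_direct <- sum((nd - mean(nd)) * (y - mean(y))) /
      sqrt(sum((nd - mean(nd))^2) * sum((y - mean(y))^2))
    slope_direct <- sum((nd - mean(nd)) * (y - mean(y))) /
      sum((nd - mean(nd))^2)
    expect_equal(res$r, r_direct, tolerance = 1e-10)
    expect_equal(res$slope, slope_direct, tolerance = 1e-10)
  }
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(8)
  nd <- runif(10)
  y <- exp(rnorm(10, 2, 0.3))
  base <- as_accretion_series(data.frame(label = paste0("s", 1:10),
                                         class = "helical", nd = nd,
                                         mean_length = y))
  rho0 <- correlate(base)$rho
  tr1 <- base; tr1$mean_length <- tr1$mean_length^3
  tr2 <- base; tr2$nd <- (rank(tr2$nd) / 11)^2  # monotone in nd
  expect_equal(correlate(tr1)$rho, rho0)
  expect_equal(correlate(tr2)$rho, rho0)
})

test_that("exact permutation p matches cor.test's exact Spearman p (no ties)", {
  set.seed(33)
  for (n in c(5, 6, 7, 8)) {
    nd <- sample(seq(0.01, 0.99, length.out = n))
    y <- exp(rnorm(n, 1, 0.5))
    s <- as_accretion_series(data.frame(label = paste0("s", 1:n),
                                        class = "helical", nd = nd,
                                        mean_length = y))
    res <- correlate(s)
    want <- stats::cor.test(s$nd, s$mean_length, method = "spearman",
                            exact = TRUE)$p.value
    expect_equal(res$p_rho, min(want, 1), tolerance = 1e-10)
  }
})

test_that("negative trends with small noise are detected reliably", {
  set.seed(2024)
  hits <- 0L
  for (rep in 1:200) {
    n <- 12
    nd <- seq(0, 1, length.out = n)
    y <- 10 - 6 * nd + rnorm(n, 0, 0.5)
    s <- as_accretion_series(data.frame(label = paste0("s", 1:n),
                                        class = "helical", nd = nd,
                                        mean_length = pmax(y, 0.5)))
    res <- correlate(s)
    if (res$slope < 0 && res$p_r < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("series TSV read/write round trips", {
  s <- as_accretion_series(data.frame(label = c("a", "b", "c"),
                                      class = "helical", nd = c(0, 0.5, 1),
                                      mean_length = c(9, 6, 4)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_series(s, path)
  back <- read_series(path)
  expect_equal(back$mean_length, s$mean_length)
  expect_equal(back$x, s$x)
})
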
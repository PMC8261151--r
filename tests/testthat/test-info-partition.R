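test_that("equal-occupancy discretization follows the cube-root bin rule", {
  set.seed(1)
  s <- discretize(rnorm(1000))
  expect_equal(attr(s, "bins"), 10L)
  expect_equal(as.vector(table(s)), rep(100L, 10))
  expect_warning(sc <- discretize(rep(3.2, 50)), "constant")
  expect_equal(unique(as.integer(sc)), 1L)
  # monotone-transform invariance of the symbol sequence
  x <- rexp(500)
  expect_identical(as.integer(discretize(x)), as.integer(discretize(log(x))))
  expect_identical(as.integer(discretize(x)), as.integer(discretize(x^3)))
})

test_that("plug-in mutual information is exact on uniform identical symbols", {
  x <- structure(rep(1:4, 100), bins = 4L)
  expect_equal(mutual_information(x, x), 2)           # I(X;X) = H(X)
  y <- structure(rep(c(2L, 1L, 4L, 3L), 100), bins = 4L)
  expect_identical(mutual_information(x, y), mutual_information(y, x))
  expect_error(mutual_information(x, y[-1]), "mismatch")
})

test_that("independent sequences carry only bias-level information", {
  set.seed(2)
  a <- discretize(rnorm(10000)); b <- discretize(rnorm(10000))
  raw <- mutual_information(a, b)
  # permutation-null scale: the raw estimate is indistinguishable from the
  # null distribution of shuffled pairings
  null <- replicate(200, mutual_information(structure(sample(a), bins = 21L), b))
  expect_gt(mean(null >= raw), 0.05)
  # the Miller-Madow corrected estimate removes the plug-in bias
  expect_lt(abs(mutual_information(a, b, correct = TRUE)), 0.02)
})

test_that("Gaussian closed-form agreement improves with sample size", {
  rho <- 0.6
  true_mi <- -0.5 * log2(1 - rho^2)
  err <- function(n, seed) {
    set.seed(seed)
    x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    abs(mutual_information(discretize(x), discretize(y)) - true_mi)
  }
  e1k <- mean(vapply(1:3, function(s) err(1000, s), numeric(1)))
  e10k <- mean(vapply(1:3, function(s) err(10000, s), numeric(1)))
  e50k <- err(50000, 1)
  expect_lt(e10k, e1k)
  expect_lt(e50k, e1k)
})

test_that("lagged MI finds the generative lag and spans the full grid", {
  g <- lag_grid(5, 100, 5)
  expect_length(g$lags, 20L)                          # 5..100 min at 5-min step
  set.seed(7)
  n <- 500
  x <- rnorm(n)
  y <- c(rnorm(3), x[seq_len(n - 3)]) + rnorm(n, sd = 0.1)
  p <- flux_panel(seq(0, by = 5, length.out = n), cbind(x, y),
                  c(33.033, 45.033))
  r <- lagged_mi(p, 1, 2, g, surrogate_config(n = 300, seed = 1))
  expect_equal(r$best_lag_steps, 3L)
  expect_true(all(r$mi >= 0))
  expect_true(r$best_lag %in% g$lags)
  expect_gt(r$p, 0); expect_lte(r$p, 1)
  expect_lt(r$p, 0.05)
  # independent channels: not significant
  set.seed(8)
  p0 <- flux_panel(seq(0, by = 5, length.out = n), cbind(rnorm(n), rnorm(n)),
                   c(33.033, 45.033))
  r0 <- lagged_mi(p0, 1, 2, g, surrogate_config(n = 300, seed = 1))
  expect_gt(r0$p, 0.05)
})

test_that("lag grids must be compatible with the panel step", {
  p <- flux_panel(seq(0, by = 7, length.out = 100), matrix(rnorm(200), 100, 2),
                  c(33.033, 45.033))
  expect_error(lagged_mi(p, 1, 2, lag_grid(5, 100, 5), NULL), "multiple")
  expect_error(lag_grid(0, 50, 5), "invalid")
  short <- flux_panel(seq(0, by = 5, length.out = 40),
                      matrix(rnorm(80), 40, 2), c(33.033, 45.033))
  expect_error(lagged_mi(short, 1, 2, lag_grid(5, 100, 5), NULL), "overlap")
})

test_that("an observed statistic above every surrogate attains the minimal p", {
  set.seed(3)
  x <- rnorm(300); y <- x + rnorm(300, sd = 0.01)
  out <- surrogate_test(x, y, surr = surrogate_config(n = 250, seed = 5))
  expect_equal(out$p, 1 / 251)
  expect_equal(out$n_surrogates, 250L)
  # custom statistic path agrees with the definition
  out2 <- surrogate_test(x, y, statistic = function(a, b) abs(cor(a, b)),
                         surr = surrogate_config(n = 250, seed = 5))
  expect_equal(out2$p, 1 / 251)
})

test_that("surrogate config validates its ranges and defaults to 2500 shuffles", {
  expect_equal(surrogate_config()$n, 2500L)
  expect_equal(surrogate_config()$alpha, 0.05)
  expect_error(surrogate_config(n = 50), "100")
  expect_error(surrogate_config(alpha = 1.2), "alpha")
})

test_that("PID reproduces the canonical synergy/redundancy/uniqueness cases", {
  x1 <- rep(c(0, 0, 1, 1), 64); x2 <- rep(c(0, 1, 0, 1), 64)
  xor <- pid_triple(x1, x2, as.numeric(x1 != x2))
  expect_equal(c(xor$U1, xor$U2, xor$R, xor$S), c(0, 0, 0, 1))
  dup <- pid_triple(x1, x1, x1)
  expect_equal(c(dup$U1, dup$U2, dup$R, dup$S), c(0, 0, 1, 0))
  expect_equal(dup$source_dependency, 1)
  x2i <- rep(c(0, 1, 0, 1, 1, 0, 1, 0), 32)           # independent distractor
  uni <- pid_triple(x1, x2i, x1)
  expect_equal(c(uni$U1, uni$U2, uni$R, uni$S), c(1, 0, 0, 0))
})

test_that("PID components are invariant under monotone transforms", {
  set.seed(11)
  x1 <- rnorm(400); x2 <- rnorm(400)
  y <- x1 + 0.5 * x2 + rnorm(400, sd = 0.3)
  a <- pid_triple(x1, x2, y)
  b <- pid_triple(exp(x1), x2^3, 2 * y + 5)
  expect_equal(c(a$U1, a$U2, a$R, a$S), c(b$U1, b$U2, b$R, b$S), tolerance = 1e-12)
})

test_that("redundancy variants are ordered R_min <= rescaled <= R_MMI", {
  set.seed(12)
  for (k in 1:20) {
    x1 <- rnorm(200); x2 <- 0.6 * x1 + rnorm(200, sd = 0.8)
    y <- x1 + x2 + rnorm(200, sd = 0.5)
    rmin <- pid_triple(x1, x2, y, "minimum")$R
    rres <- pid_triple(x1, x2, y, "rescaled")$R
    rmmi <- pid_triple(x1, x2, y, "mmi")$R
    expect_true(rmin <= rres + 1e-12 && rres <= rmmi + 1e-12)
    expect_lte(rmmi, min(pid_triple(x1, x2, y)$I1, pid_triple(x1, x2, y)$I2) + 1e-12)
  }
})

test_that("a zero-entropy source warns and contributes no unique information", {
  set.seed(13)
  y <- rnorm(100)
  expect_warning(r <- pid_triple(rep(1, 100), rnorm(100), y), "zero-entropy")
  expect_equal(r$U1, 0)
})

test_that("pid_decompose aligns panel channels at their own lags", {
  set.seed(14)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- c(rnorm(2), x1[seq_len(n - 2)]) + c(rnorm(4), x2[seq_len(n - 4)])
  p <- flux_panel(seq(0, by = 5, length.out = n), cbind(x1, x2, y),
                  c(33.033, 45.033, 59.049))
  r <- pid_decompose(p, 1, 2, 3, lag1 = 2, lag2 = 4)
  expect_equal(r$U1 + r$U2 + r$R + r$S, r$I12, tolerance = 1e-9)
  expect_gt(r$I12, 0.5)                               # both sources informative
  expect_gt(r$U1, 0.1); expect_gt(r$U2, 0.1)
  expect_error(pid_decompose(p, 1, 2, 3, lag1 = 390, lag2 = 4), "overlap")
})
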
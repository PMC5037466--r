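# Independent contrasts and the correlation/regression suite.

test_that("contrasts match hand-executed small cases", {
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  cs <- independent_contrasts(t2, c(A = 3, B = 1))
  expect_equal(unname(cs$contrasts), 2 / sqrt(2), tolerance = 1e-12)

  t3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  cs3 <- independent_contrasts(t3, c(A = 4, B = 2, C = 0))
  # node AB: (4-2)/sqrt(2); root: (3-0)/sqrt(1.5+2) with extended branch
  expect_equal(sort(abs(unname(cs3$contrasts))),
               sort(c(2 / sqrt(2), 3 / sqrt(3.5))), tolerance = 1e-12)

  expect_equal(unname(independent_contrasts(t3, c(A = 5, B = 5, C = 5))$contrasts),
               c(0, 0))
  expect_error(independent_contrasts(t3, c(A = 1, B = 2)), "tip")
})

test_that("bifurcating n-tip trees give n-1 contrasts; polytomies are counted", {
  tr <- simulate_tree(17, seed = 1)
  x <- setNames(rnorm(17), tr$tip.label)
  cs <- independent_contrasts(tr, x)
  expect_equal(length(cs$contrasts), 16)
  expect_equal(cs$n_zero_branches, 0)

  # a four-way polytomy resolves with two zero-length internal branches
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1):0;")
  css <- independent_contrasts(star, c(A = 1, B = 2, C = 3, D = 4))
  expect_equal(length(css$contrasts), 3)
  expect_equal(css$n_zero_branches, 2)

  # two trichotomies: 2 zero branches among 16 contrasts -> df 13
  txt <- "(((A:1,B:1,C:1):1,(D:1,E:1,F:1):1):1,((G:1,H:1):1,(I:1,(J:1,(K:1,(L:1,(M:1,(N:1,(O:1,(P:1,Q:1):1):1):1):1):1):1):1):1):1);"
  t17 <- ape::read.tree(text = txt)
  expect_equal(ape::Ntip(t17), 17)
  y <- setNames(rnorm(17, sd = 2), t17$tip.label)
  z <- setNames(rnorm(17, sd = 2), t17$tip.label)
  cy <- independent_contrasts(t17, y)
  cz <- independent_contrasts(t17, z)
  expect_equal(length(cy$contrasts), 16)
  expect_equal(cy$n_zero_branches, 2)
  pr <- pic_correlation(positivize(cy, cz))
  expect_equal(pr$df, 13)
})

test_that("positivization flips pairs by sign(x) and leaves |r| unchanged", {
  mk <- function(x) structure(list(contrasts = x,
                                   node_ids = seq_along(x) + 100L,
                                   n_zero_branches = 0L, positivized = FALSE),
                              class = "contrast_set")
  pp <- positivize(mk(c(-2, 2, 0)), mk(c(-3, -3, 5)))
  expect_equal(pp$x, c(2, 2, 0))
  expect_equal(pp$y, c(3, -3, 5))
  set.seed(2)
  for (i in 1:20) {
    x <- rnorm(12); y <- rnorm(12)
    r_raw <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
    pp2 <- positivize(mk(x), mk(y))
    r_pos <- pic_correlation(pp2)$correlation
    expect_equal(abs(r_pos), abs(r_raw), tolerance = 1e-12)
    expect_true(all(pp2$x >= 0))
  }
})

test_that("through-origin contrast correlation and its t-test behave", {
  mk <- function(x) structure(list(contrasts = x,
                                   node_ids = seq_along(x) + 10L,
                                   n_zero_branches = 0L, positivized = FALSE),
                              class = "contrast_set")
  x <- c(1, 2, 3, 4.5, -1)
  pr <- pic_correlation(positivize(mk(x), mk(2 * x)))
  expect_equal(pr$correlation, 1, tolerance = 1e-12)
  expect_equal(pr$slope, 2, tolerance = 1e-12)
  expect_equal(pr$df, 4)
  # one-sided halves the two-sided p for positive t
  y <- x + rnorm(5, sd = 0.5)
  p2 <- pic_correlation(positivize(mk(x), mk(y)))
  p1 <- pic_correlation(positivize(mk(x), mk(y)), one_sided = TRUE)
  expect_equal(p1$p_value, p2$p_value / 2, tolerance = 1e-12)
  expect_error(pic_correlation(list(x = 1:2, y = 1:2)), "3 contrast")
})

test_that("contrast correlation has calibrated type-I error under independence", {
  sig <- vapply(1:300, function(s) {
    tr <- simulate_tree(17, seed = s)
    cfg <- synthetic_config(trait_correlation = 0)
    tt <- simulate_bm_traits(tr, cfg, seed = 40000 + s)
    cx <- independent_contrasts(tr, setNames(log(tt$true_f_ms), tt$population))
    cy <- independent_contrasts(tr, setNames(log(tt$true_m_ms), tt$population))
    pic_correlation(positivize(cx, cy))$p_value < 0.05
  }, TRUE)
  expect_gte(sum(sig), qbinom(0.005, 300, 0.05))
  expect_lte(sum(sig), qbinom(0.995, 300, 0.05))
})

test_that("OLS matches exact fits and the normal equations", {
  x <- c(100, 300, 700, 1500)
  y <- 31 + 0.79 * x
  # lm warns about the (intentionally) perfect fit
  fit <- suppressWarnings(ols_regression(x, y))
  expect_equal(fit$slope, 0.79, tolerance = 1e-12)
  expect_equal(fit$intercept, 31, tolerance = 1e-10)
  expect_equal(fit$correlation, 1, tolerance = 1e-12)
  # hand normal equations on noisy points
  set.seed(3)
  yy <- y + rnorm(4, sd = 20)
  fit2 <- ols_regression(x, yy)
  b_hat <- solve(t(cbind(1, x)) %*% cbind(1, x), t(cbind(1, x)) %*% yy)
  expect_equal(fit2$intercept, b_hat[1], tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(fit2$slope, b_hat[2], tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(fit2$df, 2)
  # duplicated points leave the fit unchanged
  fit3 <- ols_regression(rep(x, 2), rep(yy, 2))
  expect_equal(fit3$slope, fit2$slope, tolerance = 1e-12)
  expect_error(ols_regression(rep(1, 5), 1:5), "variance")
})

test_that("RMA slope is the sd ratio, inverts under swap, equals OLS/r", {
  set.seed(4)
  x <- rnorm(30); y <- 2 * x + rnorm(30, sd = 0.7)
  rma <- rma_regression(x, y)
  expect_equal(rma$slope, sign(cor(x, y)) * sd(y) / sd(x), tolerance = 1e-12)
  swap <- rma_regression(y, x)
  expect_equal(swap$slope, 1 / rma$slope, tolerance = 1e-12)
  ols <- ols_regression(x, y)
  expect_equal(rma$slope, ols$slope / ols$correlation, tolerance = 1e-10)
  # through-origin variant
  rmo <- rma_regression(x, y, through_origin = TRUE)
  expect_equal(rmo$slope, sign(sum(x * y)) * sqrt(sum(y^2) / sum(x^2)),
               tolerance = 1e-12)
  expect_error(rma_regression(rep(2, 5), 1:5), "variance")
})

test_that("rank correlation handles monotone cases and matches the exact permutation p", {
  x <- c(1, 4, 9, 20, 33, 50)
  expect_equal(rank_correlation(x, x^2 + 1)$rho, 1)
  expect_equal(rank_correlation(x, -x)$rho, -1)
  set.seed(5)
  y <- rnorm(6)
  got <- rank_correlation(x, y)
  # brute force over all 720 permutations of y's ranks
  rho_obs <- cor(rank(x), rank(y))
  perms <- t(sapply(combinat_perms(6), function(p) p))
  rhos <- apply(perms, 1, function(p) cor(rank(x), p))
  p_exact <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)
  expect_equal(got$p_value, p_exact, tolerance = 1e-9)
  expect_error(rank_correlation(rep(1, 6), y), "constant")
})

test_that("stepwise selection keeps the informative predictor and admits noise at ~alpha", {
  sels <- lapply(1:200, function(s) {
    set.seed(s)
    x1 <- rnorm(20); x2 <- rnorm(20)
    y <- 2 * x1 + rnorm(20, sd = 0.1)
    stepwise_regression(y, data.frame(x1 = x1, x2 = x2))$selected
  })
  # the informative predictor is (essentially) always found and listed first
  expect_gte(mean(vapply(sels, function(s) identical(s[1], "x1"), TRUE)), 0.95)
  # a pure-noise companion enters at roughly the alpha_enter rate
  noise_rate <- mean(vapply(sels, function(s) "x2" %in% s, TRUE))
  expect_lt(noise_rate, 0.15 + 2 * sqrt(0.15 * 0.85 / 200))
  # pure noise: empty model most of the time; never an error
  set.seed(6)
  sel0 <- stepwise_regression(rnorm(20), data.frame(a = rnorm(20)))$selected
  expect_true(length(sel0) %in% c(0, 1))
  # identical predictors: collinearity drops the later column
  set.seed(7)
  x <- rnorm(20); y <- x + rnorm(20, 0.05)
  expect_warning(out <- stepwise_regression(y, data.frame(p1 = x, p2 = x)),
                 "collinear")
  expect_identical(out$selected, "p1")
  expect_error(stepwise_regression(1:3, data.frame(a = 1:3, b = 3:1)), "n >")
})
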
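test_that("size factors follow the median-of-ratios convention", {
  m <- matrix(rpois(100, 50) + 1, ncol = 2)
  m2 <- cbind(m[, 1], 2 * m[, 1])
  f <- size_factors(m2)
  expect_equal(unname(f[2] / f[1]), 2, tolerance = 1e-12)
  # identical libraries get unit factors
  m3 <- cbind(m[, 1], m[, 1], m[, 1])
  expect_equal(unname(size_factors(m3)), rep(1, 3))
  # random positive matrix matches the independent one-liner
  set.seed(8)
  m4 <- matrix(rpois(50 * 12, 80) + 1, nrow = 50)
  expect_equal(unname(size_factors(m4)), unname(size_factors_by_hand(m4)),
               tolerance = 1e-12)
  expect_error(size_factors(matrix(0, 3, 3)), "cannot normalize")
})

test_that("dispersion estimation collapses for Poisson and constant data", {
  set.seed(4)
  pois <- matrix(rpois(200 * 12, 100), nrow = 200)
  a <- estimate_dispersion(pois, sf = rep(1, 12))
  expect_lt(median(a), 0.01)
  const <- matrix(50, nrow = 6, ncol = 12)
  a2 <- estimate_dispersion(const, sf = rep(1, 12))
  expect_true(all(a2 <= 1e-6))
})

test_that("dispersion estimation recovers a known NB dispersion", {
  set.seed(10)
  n <- 2000
  mu <- runif(n, 50, 500)
  cts <- matrix(rnbinom(n * 12, mu = rep(mu, 12), size = 1 / 0.1), nrow = n)
  a <- estimate_dispersion(cts, sf = rep(1, 12))
  expect_gte(median(a), 0.05)
  expect_lte(median(a), 0.2)
  # the design-aware path agrees under an intercept-only design
  a2 <- estimate_dispersion(cts[1:200, ], sf = rep(1, 12),
                            design_matrix = matrix(1, 12, 1))
  expect_gte(median(a2), 0.05)
  expect_lte(median(a2), 0.2)
})

test_that("NB GLM fit matches closed forms and a numerical oracle", {
  # saturated-at-constant: intercept = log(count / size factor)
  y <- rep(20, 6)
  X <- matrix(1, 6, 1)
  f <- fit_nb_glm(y, X, alpha = 0.1, sf = rep(2, 6))
  expect_equal(unname(f$coefficients[1]), log(10), tolerance = 1e-6)
  expect_equal(unname(f$fitted), rep(20, 6), tolerance = 1e-4)
  # two-group closed form: behavior coefficient = log(4)
  y2 <- c(10, 10, 10, 40, 40, 40)
  X2 <- cbind(1, rep(c(0, 1), each = 3))
  f2 <- fit_nb_glm(y2, X2, alpha = 0.05, sf = rep(1, 6))
  expect_equal(unname(f2$coefficients[2]), log(4), tolerance = 1e-6)
  # random NB data: log-likelihood within 1e-4 of direct maximization
  set.seed(12)
  for (i in 1:5) {
    X3 <- cbind(1, rbinom(12, 1, 0.5))
    sf <- exp(runif(12, -0.5, 0.5))
    y3 <- rnbinom(12, mu = sf * exp(1 + 0.8 * X3[, 2]), size = 1 / 0.1)
    if (all(y3[X3[, 2] == 1] == 0) || all(y3[X3[, 2] == 0] == 0)) next
    f3 <- fit_nb_glm(y3, X3, alpha = 0.1, sf = sf)
    oracle <- nb_loglik_optim(y3, X3, alpha = 0.1, sf = sf)
    expect_lt(abs(f3$loglik - oracle), 1e-4)
  }
  expect_error(fit_nb_glm(y2, X2[, c(1, 1)], 0.1), "rank")
})

test_that("likelihood-ratio test has correct tails", {
  f <- list(loglik = -10); r <- list(loglik = -10)
  out <- lrt(f, r, 1)
  expect_equal(out$statistic, 0)
  expect_equal(out$p.value, 1)
  out2 <- lrt(list(loglik = 0), list(loglik = -11.61 / 2), 1)
  expect_equal(out2$p.value, 0.00066, tolerance = 0.01)
  out3 <- lrt(list(loglik = 0), list(loglik = -3.841 / 2), 1)
  expect_equal(out3$p.value, 0.05, tolerance = 0.001)
  # clamped at zero when the "full" likelihood dips below the reduced one
  out4 <- lrt(list(loglik = -5), list(loglik = -4), 1)
  expect_equal(out4$statistic, 0)
  expect_error(lrt(f, r, 0), "df")
})

test_that("BH adjustment matches hand application and the sort-based oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(19)
  for (i in 1:10) {
    p <- runif(sample(3:200, 1))
    expect_equal(bh_adjust(p), bh_by_hand(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "malformed")
})

test_that("nested DE separates pair-driven from behavior-driven nodes", {
  set.seed(3)
  lfc <- c(rep(0, 40), rep(3, 20), rep(-3, 20), rep(0, 320))
  psd <- c(rep(2, 40), rep(0, 360))
  man <- truth_manifest(sprintf("g%04d", 1:400), baseline_mean = 200,
                        behavior_log2fc = lfc, pair_effect_sd = psd)
  des <- library_design(rng_seed = 4)
  cts <- simulate_counts(man, des, 0.05, 31)
  res <- nested_de(cts, des)
  # pair-driven nodes are screened out in stage 1
  expect_gte(mean(res$stage1_filtered[1:40]), 0.9)
  # behavior-driven nodes survive stage 1 and are called with the right sign
  expect_lte(mean(res$stage1_filtered[41:80]), 0.15)
  called <- res$class[41:60]
  expect_gte(mean(called == "predator-biased"), 0.7)
  expect_gte(mean(res$class[61:80] == "nonpredator-biased"), 0.7)
  expect_true(all(res$class[res$stage1_filtered] == "ns"))
})

test_that("an all-null matrix stays almost entirely non-significant", {
  set.seed(6)
  man <- truth_manifest(sprintf("g%04d", 1:500), baseline_mean = 150)
  des <- library_design(rng_seed = 2)
  frac <- vapply(1:3, function(s) {
    cts <- simulate_counts(man, des, 0.05, 100 + s)
    res <- nested_de(cts, des)
    mean(res$class != "ns")
  }, numeric(1))
  expect_lte(mean(frac), 2 * 0.1)
})

test_that("LRT statistics respect design symmetries", {
  set.seed(9)
  man <- truth_manifest(sprintf("g%03d", 1:40), baseline_mean = 150,
                        behavior_log2fc = rep(c(0, 2), 20))
  des <- library_design(rng_seed = 3)
  cts <- simulate_counts(man, des, 0.05, 17)
  res <- nested_de(cts, des)
  # relabeling pairs leaves the stage-1 statistic unchanged
  des2 <- des
  des2$pair_id <- c(6, 5, 4, 3, 2, 1)[des$pair_id]
  res2 <- nested_de(cts, des2)
  expect_equal(res$stage1_stat, res2$stage1_stat, tolerance = 1e-6)
  # swapping behavior labels flips the fold-change sign
  des3 <- des
  des3$behavior <- ifelse(des$behavior == "predator", "nonpredator", "predator")
  res3 <- nested_de(cts, des3)
  expect_equal(res$log2fc, -res3$log2fc, tolerance = 1e-6)
  # invalid pairing is rejected
  des_bad <- des
  des_bad$behavior[2] <- "predator"
  expect_error(nested_de(cts, des_bad), "exactly one predator")
})

test_that("heatmap ordering clusters identical and blocked patterns", {
  m <- rbind(c(1, 1, 8, 8), c(8, 8, 1, 1), c(1, 1, 8, 8), c(7, 8, 1, 2))
  rownames(m) <- paste0("n", 1:4)
  ord <- de_heatmap_order(m, sf = rep(1, 4))
  pos <- match(c(1, 3), ord$row_order)
  expect_equal(abs(diff(pos)), 1L)  # identical rows merge first
  # columns of a block stay contiguous
  cpos <- match(1:2, ord$col_order)
  expect_equal(abs(diff(cpos)), 1L)
  # single column and single row degenerate to identity
  expect_equal(de_heatmap_order(m[, 1, drop = FALSE],
                                sf = 1)$col_order, 1L)
  expect_equal(de_heatmap_order(m[1, , drop = FALSE],
                                sf = rep(1, 4))$row_order, 1L)
})
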
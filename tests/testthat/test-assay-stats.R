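# The reconstructed trial tables: survivors/deaths for control vs treatment
trial_tables <- function() {
  list(
    matrix(c(88, 2, 95, 1), 2, byrow = TRUE),
    matrix(c(70, 19, 81, 8), 2, byrow = TRUE),
    matrix(c(70, 27, 102, 17), 2, byrow = TRUE)
  )
}

test_that("count reconstruction inverts the N (%Surv) presentation", {
  expect_identical(reconstruct_count(90, 98), 88L)
  expect_identical(reconstruct_count(100, 50), 50L)
  expect_identical(reconstruct_count(96, 99), 95L)
  expect_identical(reconstruct_count(89, 79), 70L)
  expect_identical(reconstruct_count(119, 86), 102L)
  expect_error(reconstruct_count(1000, 50), "ambiguous")
  expect_error(reconstruct_count(3, 50), "inconsistent")
})

test_that("reconstruction round-trips wherever the inversion is unique", {
  for (N in c(7, 23, 48, 90, 96, 119, 120)) {
    for (s in 0:N) {
      pct <- floor(100 * s / N + 0.5)
      cand <- (0:N)[floor(100 * (0:N) / N + 0.5) == pct]
      if (length(cand) == 1L) {
        expect_identical(reconstruct_count(N, pct), s)
      }
    }
  }
})

test_that("two-sided Fisher matches exhaustive enumeration and known cases", {
  expect_equal(fisher_exact_two_sided(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisher_exact_two_sided(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)),
               2 / 252, tolerance = 1e-12)
  set.seed(42)
  for (i in 1:25) {
    t <- matrix(rpois(4, sample(c(3, 20, 60), 1)) + (i %% 2), 2)
    expect_equal(fisher_exact_two_sided(t), fisher_enumerate(t),
                 tolerance = 1e-8)
  }
  # degenerate margin carries no information
  expect_equal(fisher_exact_two_sided(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)), 1)
})

test_that("per-trial and pooled survival tests reproduce the published table", {
  tabs <- trial_tables()
  p <- vapply(tabs, fisher_exact_two_sided, numeric(1))
  expect_equal(round(p, 4), c(0.6111, 0.0352, 0.0173))
  pooled <- Reduce(`+`, tabs)
  expect_equal(round(fisher_exact_two_sided(pooled), 4), 0.0017)
})

test_that("CMH test reproduces the published stratified result", {
  tabs <- trial_tables()
  res <- cmh_test(tabs)
  expect_equal(round(res$p.value, 4), 7e-04)
  expect_equal(res$df, 1L)
  # against the standard implementation, no continuity correction
  arr <- array(unlist(lapply(tabs, t)), dim = c(2, 2, 3))
  arr <- array(0, c(2, 2, 3)); for (i in 1:3) arr[, , i] <- tabs[[i]]
  ref <- mantelhaen.test(arr, correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$common_or, unname(ref$estimate), tolerance = 1e-10)
})

test_that("CMH degenerates correctly", {
  null2 <- list(matrix(10, 2, 2), matrix(10, 2, 2))
  res <- cmh_test(null2)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  # single stratum: statistic = (n-1)/n times the uncorrected chi-square
  t <- matrix(c(30, 10, 20, 25), 2, byrow = TRUE)
  one <- cmh_test(list(t))
  ref <- chisq.test(t, correct = FALSE)
  n <- sum(t)
  expect_equal(one$statistic, unname(ref$statistic) * (n - 1) / n,
               tolerance = 1e-10)
})

test_that("CMH is invariant under simultaneous row/column swaps", {
  tabs <- trial_tables()
  swapped <- lapply(tabs, function(t) t[2:1, 2:1])
  expect_equal(cmh_test(tabs)$statistic, cmh_test(swapped)$statistic,
               tolerance = 1e-12)
})

test_that("Breslow-Day homogeneity reproduces the published value", {
  res <- breslow_day(trial_tables())
  expect_equal(round(res$p.value, 4), 0.9501)
  expect_equal(res$df, 2L)
})

test_that("Breslow-Day degenerate and heterogeneous cases", {
  t <- matrix(c(30, 10, 20, 25), 2, byrow = TRUE)
  hom <- breslow_day(list(t, t))
  expect_equal(hom$statistic, 0, tolerance = 1e-10)
  expect_equal(hom$p.value, 1, tolerance = 1e-10)
  # strongly discordant odds ratios at n = 200 per stratum
  s1 <- matrix(c(9, 91, 50, 50), 2, byrow = TRUE)    # OR ~ 0.1
  s2 <- matrix(c(91, 9, 50, 50), 2, byrow = TRUE)    # OR ~ 10
  het <- breslow_day(list(s1, s2))
  expect_lt(het$p.value, 0.01)
})

test_that("proportion z-test reproduces the predator sex-ratio result", {
  res <- proportion_z_test(8, 10, 0.5, "greater")
  expect_equal(round(res$p.value, 4), 0.0289)
  mid <- proportion_z_test(5, 10, 0.5, "greater")
  expect_equal(mid$z, 0)
  expect_equal(mid$p.value, 0.5)
})

test_that("two-sided proportion p equals twice the smaller one-sided p", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    s <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    two <- proportion_z_test(s, n, p0, "two.sided")$p.value
    g <- proportion_z_test(s, n, p0, "greater")$p.value
    l <- proportion_z_test(s, n, p0, "less")$p.value
    expect_equal(two, min(1, 2 * min(g, l)), tolerance = 1e-12)
  }
})

test_that("the full published-table replica reproduces every p-value", {
  rep <- table2_pipeline()
  expect_equal(rep$per_trial$surv_control, c(88L, 70L, 70L))
  expect_equal(rep$per_trial$surv_treatment, c(95L, 81L, 102L))
  expect_equal(round(rep$per_trial$fisher_p, 4), c(0.6111, 0.0352, 0.0173))
  expect_equal(rep$pooled$n_control, 276L)
  expect_equal(rep$pooled$n_treatment, 304L)
  expect_equal(round(rep$pooled$fisher_p, 4), 0.0017)
  expect_equal(round(rep$cmh$p.value, 4), 7e-04)
  expect_equal(round(rep$breslow_day$p.value, 4), 0.9501)
})

test_that("a single trial gives CMH matching its chi-square up to (n-1)/n", {
  t <- trial_tables()[[2]]
  res <- cmh_test(list(t))
  ref <- chisq.test(t, correct = FALSE)
  n <- sum(t)
  expect_equal(res$statistic, unname(ref$statistic) * (n - 1) / n,
               tolerance = 1e-10)
})

test_that("arena-level records tabulate into the right 2x2", {
  arenas <- data.frame(
    group = rep(c("control", "treatment"), c(4, 6)),
    survived = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    consumption = c(rep("none", 4), "partial", "total", "none", "partial",
                    "none", "total")
  )
  t <- arena_survival_table(arenas)
  expect_equal(unname(t), matrix(c(3, 1, 5, 1), 2, byrow = TRUE))
  arenas$consumption[1] <- "partial"
  expect_error(arena_survival_table(arenas), "control arenas")
})
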
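#' Recover an integer count from a total and a rounded percentage
#'
#' Published survival tables often report `N (XX%)` rather than raw counts.
#' This inverts that presentation: it finds the unique integer `s` with
#' `round(100 * s / total) == rounded_percent`, where rounding is half-up
#' (98.5 rounds to 99).
#'
#' @param total Positive integer, the group size `N`.
#' @param rounded_percent Integer percentage in `[0, 100]` as printed.
#' @return The unique integer count.  If several counts round to the printed
#'   percentage the inversion is ambiguous and an error lists the candidates;
#'   if none does the inputs are inconsistent and an error is raised.
#' @examples
#' reconstruct_count(90, 98)   # 88 survivors
#' reconstruct_count(100, 50)  # 50
#' @export
reconstruct_count <- function(total, rounded_percent) {
  stopifnot(length(total) == 1L, length(rounded_percent) == 1L)
  if (total < 1 || total != round(total)) {
    stop("`total` must be a positive integer")
  }
  if (rounded_percent < 0 || rounded_percent > 100) {
    stop("`rounded_percent` must be in [0, 100]")
  }
  s <- 0:total
  # round half-up, not banker's rounding
  hit <- s[floor(100 * s / total + 0.5) == rounded_percent]
  if (length(hit) == 0L) {
    stop(sprintf("no count of %d rounds to %d%%: inconsistent input",
                 total, rounded_percent))
  }
  if (length(hit) > 1L) {
    stop(sprintf("ambiguous inversion for %d at %d%%: candidates %s",
                 total, rounded_percent, paste(hit, collapse = ", ")))
  }
  hit
}

as_2x2 <- function(t) {
  t <- as.matrix(t)
  if (!all(dim(t) == c(2L, 2L))) stop("expected a 2x2 table")
  if (any(t < 0) || any(t != round(t))) stop("counts must be nonnegative integers")
  if (sum(t) == 0) stop("table has no observations")
  storage.mode(t) <- "double"
  t
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sidedness follows the point-probability convention: the p-value sums
#' hypergeometric probabilities of all tables with the observed margins whose
#' point probability does not exceed that of the observed table.  A table with
#' an all-zero row or column carries no information and returns p = 1.
#'
#' @param t 2x2 matrix of counts, rows = group, columns = outcome.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(t) {
  t <- as_2x2(t)
  if (any(rowSums(t) == 0) || any(colSums(t) == 0)) return(1)
  stats::fisher.test(t)$p.value
}

#' Fisher exact test on an R x 2 table
#'
#' Generic exact test for tables with more than two groups (e.g. survival by
#' prey-consumption level).  Uses the network algorithm of
#' [stats::fisher.test()].
#'
#' @param t R x 2 matrix of counts.
#' @return p-value.
#' @export
fisher_exact_rx2 <- function(t) {
  t <- as.matrix(t)
  if (ncol(t) != 2L || nrow(t) < 2L) stop("expected an R x 2 table, R >= 2")
  stats::fisher.test(t)$p.value
}

check_strata <- function(strata, min_strata = 2L) {
  if (!is.list(strata) || length(strata) < min_strata) {
    stop(sprintf("need a list of at least %d strata (2x2 tables)", min_strata))
  }
  lapply(strata, as_2x2)
}

#' Cochran-Mantel-Haenszel test over stratified 2x2 tables
#'
#' Tests conditional independence of group and outcome across strata
#' (trials), without continuity correction.  The statistic is
#' `(sum_i (a_i - E_i))^2 / sum_i V_i` where `E_i` and `V_i` are the
#' hypergeometric mean and variance of the top-left cell given the margins
#' of stratum i.  The common odds ratio is the Mantel-Haenszel estimator
#' `sum(a_i d_i / n_i) / sum(b_i c_i / n_i)`.
#'
#' Strata with a zero row or column margin contribute nothing and are dropped
#' with a warning.  A single stratum is allowed, in which case the statistic
#' equals the uncorrected chi-square test of that table.
#'
#' @param strata List of 2x2 count matrices, one per stratum.
#' @return List with `statistic`, `df` (= 1), `p.value`, `common_or`,
#'   and `n_strata_used`.
#' @export
cmh_test <- function(strata) {
  # a single stratum is allowed: the statistic then reduces to the
  # uncorrected chi-square test of that table
  strata <- check_strata(strata, min_strata = 1L)
  informative <- vapply(strata, function(t) {
    all(rowSums(t) > 0) && all(colSums(t) > 0)
  }, logical(1))
  if (!all(informative)) {
    warning(sprintf("dropping %d stratum/strata with a zero margin",
                    sum(!informative)))
    strata <- strata[informative]
  }
  if (length(strata) == 0L) stop("no informative strata")
  num <- 0; den <- 0; or_num <- 0; or_den <- 0
  for (t in strata) {
    a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
    n <- a + b + c + d
    r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
    num <- num + (a - r1 * c1 / n)
    den <- den + r1 * r2 * c1 * c2 / (n^2 * (n - 1))
    or_num <- or_num + a * d / n
    or_den <- or_den + b * c / n
  }
  stat <- num^2 / den
  list(statistic = stat,
       df = 1L,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       common_or = or_num / or_den,
       n_strata_used = length(strata))
}

# Expected top-left cell of a 2x2 table with fixed margins under odds ratio
# psi: the admissible root of (psi-1) a^2 - [psi (r1+c1) + (r2-c1)] a
# + psi r1 c1 = 0.
bd_expected_cell <- function(r1, r2, c1, psi) {
  A <- psi - 1
  B <- -(psi * (r1 + c1) + (r2 - c1))
  C <- psi * r1 * c1
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  if (abs(A) < 1e-12) return(-C / B)
  disc <- sqrt(B^2 - 4 * A * C)
  roots <- c((-B - disc) / (2 * A), (-B + disc) / (2 * A))
  ok <- roots >= lo - 1e-9 & roots <= hi + 1e-9
  if (!any(ok)) stop("no admissible root for expected cell")
  roots[ok][1]
}

#' Breslow-Day test for homogeneity of odds ratios across strata
#'
#' For each stratum the expected top-left cell under the Mantel-Haenszel
#' common odds ratio is obtained by solving the margin-constrained quadratic;
#' the statistic sums squared deviations over the asymptotic variance and is
#' referred to chi-square with (strata - 1) degrees of freedom.  No Tarone
#' correction is applied.
#'
#' @param strata List of 2x2 count matrices, one per stratum.
#' @return List with `statistic`, `df`, `p.value`, and `common_or`.
#' @export
breslow_day <- function(strata) {
  strata <- check_strata(strata)
  or <- cmh_test(strata)$common_or
  if (!is.finite(or) || or <= 0) stop("common odds ratio not estimable")
  stat <- 0
  for (t in strata) {
    r1 <- sum(t[1, ]); r2 <- sum(t[2, ]); c1 <- sum(t[, 1])
    a_tilde <- bd_expected_cell(r1, r2, c1, or)
    v <- 1 / (1 / a_tilde + 1 / (r1 - a_tilde) +
              1 / (c1 - a_tilde) + 1 / (r2 - c1 + a_tilde))
    stat <- stat + (t[1, 1] - a_tilde)^2 / v
  }
  df <- length(strata) - 1L
  list(statistic = stat,
       df = df,
       p.value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       common_or = or)
}

#' One-sample z-test on a proportion
#'
#' Normal approximation without continuity correction:
#' `z = (s/n - p0) / sqrt(p0 (1 - p0) / n)`.
#'
#' @param successes Number of successes (0..n).
#' @param n Sample size (> 0).
#' @param p0 Null proportion, strictly between 0 and 1.
#' @param tail One of `"greater"`, `"less"`, `"two.sided"`.
#' @return List with `z` and `p.value`.
#' @examples
#' # 8 of 10 actively predating larvae were male; is the predator sex ratio
#' # skewed above 0.5?
#' proportion_z_test(8, 10, 0.5, "greater")
#' @export
proportion_z_test <- function(successes, n, p0 = 0.5,
                              tail = c("greater", "less", "two.sided")) {
  tail <- match.arg(tail)
  if (n < 1) stop("n must be positive")
  if (successes < 0 || successes > n) stop("successes must be in 0..n")
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  z <- (successes / n - p0) / sqrt(p0 * (1 - p0) / n)
  p <- switch(tail,
    greater   = stats::pnorm(z, lower.tail = FALSE),
    less      = stats::pnorm(z),
    two.sided = 2 * stats::pnorm(-abs(z)))
  list(z = z, p.value = min(p, 1))
}

#' The published no-choice predation assay summary rows
#'
#' Per-trial group sizes and rounded percent survival to eclosion for the
#' three laboratory trials: control = isolated C. rufifacies larva,
#' treatment = larva with a single Co. macellaria prey item as only
#' supplemental food.
#'
#' @return data.frame with columns `trial`, `n_control`, `pct_control`,
#'   `n_treatment`, `pct_treatment`.
#' @export
predation_assay_rows <- function() {
  data.frame(
    trial = 1:3,
    n_control = c(90L, 89L, 97L),
    pct_control = c(98L, 79L, 72L),
    n_treatment = c(96L, 89L, 119L),
    pct_treatment = c(99L, 91L, 86L)
  )
}

#' Full survival analysis of the no-choice assay summary table
#'
#' Reconstructs per-trial survivor counts from `N (%Surv)` presentation,
#' then runs the per-trial Fisher exact tests (control vs treatment
#' survival), the pooled Fisher test on summed counts, the CMH test across
#' trials, and the Breslow-Day homogeneity test.
#'
#' @param rows data.frame as returned by [predation_assay_rows()].
#' @return List with `per_trial` (data.frame: trial, counts, fisher p),
#'   `pooled` (counts + fisher p), `cmh`, `breslow_day`, and `strata`
#'   (the reconstructed 2x2 tables).
#' @export
table2_pipeline <- function(rows = predation_assay_rows()) {
  needed <- c("trial", "n_control", "pct_control", "n_treatment", "pct_treatment")
  if (!all(needed %in% names(rows))) {
    stop("rows must have columns ", paste(needed, collapse = ", "))
  }
  strata <- vector("list", nrow(rows))
  per <- rows
  per$surv_control <- NA_integer_
  per$surv_treatment <- NA_integer_
  per$fisher_p <- NA_real_
  for (i in seq_len(nrow(rows))) {
    sc <- reconstruct_count(rows$n_control[i], rows$pct_control[i])
    st <- reconstruct_count(rows$n_treatment[i], rows$pct_treatment[i])
    t <- matrix(c(sc, rows$n_control[i] - sc,
                  st, rows$n_treatment[i] - st),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("control", "treatment"),
                                c("survived", "died")))
    strata[[i]] <- t
    per$surv_control[i] <- sc
    per$surv_treatment[i] <- st
    per$fisher_p[i] <- fisher_exact_two_sided(t)
  }
  pooled_tab <- Reduce(`+`, strata)
  list(
    per_trial = per,
    pooled = list(table = pooled_tab,
                  n_control = sum(rows$n_control),
                  n_treatment = sum(rows$n_treatment),
                  fisher_p = fisher_exact_two_sided(pooled_tab)),
    cmh = cmh_test(strata),
    breslow_day = breslow_day(strata),
    strata = strata
  )
}

#' Tabulate arena-level assay records into 2x2 survival tables
#'
#' @param arenas data.frame with columns `arena_id`, `group`
#'   (`"control"`/`"treatment"`), `survived` (logical), and optionally
#'   `consumption` (`"none"`, `"partial"`, `"total"`; controls must be
#'   `"none"`).
#' @return 2x2 matrix (group x survived) suitable for
#'   [fisher_exact_two_sided()].
#' @export
arena_survival_table <- function(arenas) {
  stopifnot(all(c("group", "survived") %in% names(arenas)))
  if (!all(arenas$group %in% c("control", "treatment"))) {
    stop("group must be control/treatment")
  }
  if ("consumption" %in% names(arenas)) {
    bad <- arenas$group == "control" & arenas$consumption != "none"
    if (any(bad)) stop("control arenas must have consumption = none")
  }
  g <- factor(arenas$group, levels = c("control", "treatment"))
  s <- factor(ifelse(arenas$survived, "survived", "died"),
              levels = c("survived", "died"))
  as_2x2(table(g, s))
}
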
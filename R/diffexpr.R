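#' Median-of-ratios library size factors
#'
#' For each library, the factor is the median over reference nodes (nodes
#' with all-positive counts) of the ratio of the library's count to the
#' node's geometric mean across libraries; factors are rescaled to
#' geometric mean 1.
#'
#' @param counts Node-by-library count matrix.
#' @return Named positive numeric vector, one factor per library.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) stop("cannot normalize: no node with all-positive counts")
  loggeo <- rowMeans(log(counts[ref, , drop = FALSE]))
  f <- apply(counts[ref, , drop = FALSE], 2, function(col) {
    stats::median(exp(log(col) - loggeo))
  })
  f / exp(mean(log(f)))
}

#' Per-node negative-binomial dispersion estimates
#'
#' Without a design matrix, the per-node estimate is method-of-moments on
#' size-factor-normalized counts (`alpha = max((s^2 - m) / m^2, 1e-8)`).
#' With a design matrix, the estimate is residual-based so that real
#' coefficient signal (behavior, sibling-pair effects) is not mistaken for
#' overdispersion: the node is fit under the design (see [fit_nb_glm()])
#' and `alpha` solves the Pearson moment equation
#' `sum((y - mu)^2 / (mu + alpha mu^2)) = n - p`, iterating fit and solve
#' once.  Either way, a hyperbolic mean-dispersion trend
#' `alpha(mu) = a0 + a1 / mu` is then fitted by least squares over nodes
#' with above-floor estimates, and the final per-node value is the
#' geometric mean of the node's own estimate and the trend prediction,
#' floored at 1e-8.  With fewer than 5 usable nodes the trend is skipped.
#'
#' @param counts Node-by-library count matrix.
#' @param sf Size factors from [size_factors()].
#' @param design_matrix Optional full-rank model matrix (the full design of
#'   the downstream test); `NULL` gives the plain method-of-moments path.
#' @return Numeric vector of dispersions, one per node.
#' @export
estimate_dispersion <- function(counts, sf = size_factors(counts),
                                design_matrix = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 libraries")
  floor_a <- 1e-8
  norm <- sweep(counts, 2, sf, "/")
  m <- rowMeans(norm)
  if (is.null(design_matrix)) {
    v <- apply(norm, 1, stats::var)
    a_node <- ifelse(m > 0, pmax((v - m) / m^2, floor_a), floor_a)
  } else {
    a_node <- vapply(seq_len(nrow(counts)), function(i) {
      pearson_dispersion(counts[i, ], design_matrix, sf, floor_a)
    }, numeric(1))
  }
  use <- a_node > floor_a & m > 0
  if (sum(use) < 5L) return(a_node)
  fit <- stats::lm.fit(cbind(1, 1 / m[use]), a_node[use])
  trend <- pmax(fit$coefficients[1] + fit$coefficients[2] / pmax(m, 1e-8),
                floor_a)
  pmax(sqrt(a_node * trend), floor_a)
}

# Residual (Pearson) dispersion of one node under a design: fit, solve the
# Pearson moment equation for alpha, refit at that alpha and solve again.
pearson_dispersion <- function(y, X, sf, floor_a = 1e-8) {
  if (all(y == 0)) return(floor_a)
  resid_df <- length(y) - ncol(X)
  if (resid_df <= 0) stop("no residual degrees of freedom for dispersion")
  alpha <- floor_a
  for (rep in 1:2) {
    mu <- fit_nb_glm(y, X, alpha, sf)$fitted
    f <- function(a) sum((y - mu)^2 / (mu + a * mu^2)) - resid_df
    if (f(floor_a) <= 0) return(floor_a)
    hi <- 1
    while (f(hi) > 0 && hi < 1e6) hi <- hi * 10
    alpha <- stats::uniroot(f, c(floor_a, hi), tol = 1e-10)$root
  }
  max(alpha, floor_a)
}

#' Fit a negative-binomial GLM with log link and fixed dispersion
#'
#' Size factors enter as fixed offsets (`log(sf)`); the mean model is
#' `mu = sf * exp(X beta)` with `variance = mu + alpha * mu^2`.  Fitting is
#' iteratively reweighted least squares, converged when the relative change
#' in deviance (-2 log-likelihood) falls below `tol` (default 1e-8), at
#' most `max_iter` (default 100) iterations.
#'
#' @param y Integer counts, one per library.
#' @param X Full-rank design matrix.
#' @param alpha NB dispersion (> 0).
#' @param sf Size factors (offsets are `log(sf)`).
#' @param tol,max_iter Convergence controls.
#' @return List: `coefficients`, `fitted` (means per library), `alpha`,
#'   `loglik`, `converged`, `iter`.
#' @export
fit_nb_glm <- function(y, X, alpha, sf = rep(1, length(y)),
                       tol = 1e-8, max_iter = 100L) {
  stopifnot(alpha > 0, length(y) == nrow(X), length(sf) == length(y))
  off <- log(sf)
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  ll <- nb_loglik(y, mu, alpha)
  dev_old <- -2 * ll
  converged <- FALSE
  iter <- 0L
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design matrix is rank deficient")
  for (iter in seq_len(max_iter)) {
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    sw <- sqrt(w)
    fit <- stats::lm.fit(X * sw, z * sw)
    beta <- fit$coefficients
    eta <- pmin(drop(X %*% beta) + off, 30)
    mu <- exp(eta)
    ll <- nb_loglik(y, mu, alpha)
    dev <- -2 * ll
    if (abs(dev - dev_old) < tol * (abs(dev_old) + 0.1)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  list(coefficients = beta, fitted = mu, alpha = alpha, loglik = ll,
       converged = converged, iter = iter)
}

#' Negative-binomial log-likelihood at fixed dispersion
#'
#' @param y Counts.
#' @param mu Means.
#' @param alpha Dispersion.
#' @return Scalar log-likelihood.
#' @export
nb_loglik <- function(y, mu, alpha) {
  sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

#' Likelihood-ratio test between nested NB GLM fits
#'
#' @param full,reduced Fits from [fit_nb_glm()] on the same data, offsets
#'   and dispersion; `reduced` nested in `full`.
#' @param df Degrees of freedom (difference in number of coefficients).
#' @return List with `statistic` (twice the log-likelihood difference,
#'   clamped at 0) and `p.value` (upper chi-square tail).
#' @export
lrt <- function(full, reduced, df) {
  if (df <= 0) stop("df must be positive")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1.
#'
#' @param pvalues Numeric vector in `[0, 1]` (NA allowed).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
  if (!all(ok)) stop("malformed input: p-values outside [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Nested differential-expression test between predator and nonpredator
#' siblings
#'
#' Two-stage procedure on a node-by-library count matrix under the
#' sibling-pair design:
#'
#' * Stage 1 screens out nodes whose expression tracks relatedness rather
#'   than behavior: per node, an LRT of `~ behavior + pair` against
#'   `~ behavior` (df = pairs - 1); nodes significant after BH adjustment
#'   at `stage1_fdr` are flagged `stage1_filtered` and removed.
#' * Stage 2 tests behavior on the survivors: LRT of `~ behavior` against
#'   the intercept-only model (df = 1), BH over survivors, and a class
#'   call at `fdr`: `predator-biased` (log2fc > 0), `nonpredator-biased`
#'   (log2fc < 0), or `ns`.
#'
#' Dispersion is estimated once per node (see [estimate_dispersion()]) and
#' shared by all fits of that node, so the tests compare means only.
#' All-zero nodes are untestable and excluded; non-converging fits are
#' excluded with a warning.
#'
#' @param counts Node-by-library count matrix.
#' @param design data.frame with `library_id`, `pair_id`, `behavior`
#'   (column order must match `counts`); see [library_design()].
#' @param fdr Stage-2 BH threshold (default 0.1).
#' @param stage1_fdr Stage-1 BH threshold (default 0.1).
#' @param dispersion Optional fixed dispersion(s); default estimated.
#' @param sf Optional size factors; default [size_factors()].
#' @return data.frame, one row per node: `node_id`, `base_mean`, `log2fc`,
#'   `lrt_stat`, `df`, `pvalue`, `padj`, `stage1_stat`, `stage1_padj`,
#'   `stage1_filtered`, `tested`, `class`.
#' @export
nested_de <- function(counts, design, fdr = 0.1, stage1_fdr = 0.1,
                      dispersion = NULL, sf = NULL) {
  counts <- as.matrix(counts)
  validate_design(design)
  if (ncol(counts) != nrow(design)) {
    stop("counts columns and design rows differ")
  }
  if (!is.null(colnames(counts)) &&
      !identical(colnames(counts), design$library_id)) {
    counts <- counts[, design$library_id, drop = FALSE]
  }
  behavior <- factor(design$behavior, levels = c("nonpredator", "predator"))
  pair <- factor(design$pair_id)
  X_full <- stats::model.matrix(~ behavior + pair)
  X_beh <- stats::model.matrix(~ behavior)
  X_0 <- X_beh[, 1, drop = FALSE]
  df1 <- nlevels(pair) - 1L
  if (is.null(sf)) sf <- size_factors(counts)
  testable <- rowSums(counts) > 0
  if (is.null(dispersion)) {
    alpha <- rep(NA_real_, nrow(counts))
    alpha[testable] <- estimate_dispersion(counts[testable, , drop = FALSE],
                                           sf, design_matrix = X_full)
  } else {
    alpha <- rep_len(dispersion, nrow(counts))
  }
  n <- nrow(counts)
  res <- data.frame(
    node_id = if (is.null(rownames(counts))) paste0("n", seq_len(n))
              else rownames(counts),
    base_mean = rowMeans(sweep(counts, 2, sf, "/")),
    log2fc = NA_real_, lrt_stat = NA_real_, df = 1L,
    pvalue = NA_real_, padj = NA_real_,
    stage1_stat = NA_real_, stage1_padj = NA_real_,
    stage1_filtered = FALSE, tested = testable,
    class = "ns", stringsAsFactors = FALSE
  )
  p1 <- rep(NA_real_, n)
  p2 <- rep(NA_real_, n)
  failed <- 0L
  for (i in which(testable)) {
    y <- counts[i, ]
    f_full <- fit_nb_glm(y, X_full, alpha[i], sf)
    f_beh <- fit_nb_glm(y, X_beh, alpha[i], sf)
    if (!f_full$converged || !f_beh$converged) {
      res$tested[i] <- FALSE
      failed <- failed + 1L
      next
    }
    t1 <- lrt(f_full, f_beh, df1)
    p1[i] <- t1$p.value
    res$stage1_stat[i] <- t1$statistic
    res$log2fc[i] <- f_beh$coefficients[2] / log(2)
  }
  if (failed > 0L) {
    warning(sprintf("%d node(s) excluded for non-convergence", failed))
  }
  tested1 <- !is.na(p1)
  res$stage1_padj[tested1] <- bh_adjust(p1[tested1])
  res$stage1_filtered <- !is.na(res$stage1_padj) &
    res$stage1_padj < stage1_fdr
  survivors <- which(tested1 & !res$stage1_filtered)
  for (i in survivors) {
    y <- counts[i, ]
    f_beh <- fit_nb_glm(y, X_beh, alpha[i], sf)
    f_0 <- fit_nb_glm(y, X_0, alpha[i], sf)
    if (!f_0$converged) next
    t2 <- lrt(f_beh, f_0, 1L)
    p2[i] <- t2$p.value
    res$lrt_stat[i] <- t2$statistic
  }
  tested2 <- !is.na(p2)
  res$pvalue[tested2] <- p2[tested2]
  res$padj[tested2] <- bh_adjust(p2[tested2])
  sig <- tested2 & !is.na(res$padj) & res$padj < fdr
  res$class[sig & res$log2fc > 0] <- "predator-biased"
  res$class[sig & res$log2fc < 0] <- "nonpredator-biased"
  res
}

#' Reciprocal hierarchical clustering order for an expression heatmap
#'
#' Rows (nodes) and columns (libraries) are each ordered by agglomerative
#' hierarchical clustering (average linkage, Euclidean distance) of the
#' row-z-scored `log2(normalized count + 1)` matrix.  Constant rows get
#' z = 0.  With fewer than 2 rows the identity ordering is returned.
#'
#' @param counts Count matrix of the differentially expressed nodes.
#' @param sf Size factors (default computed on `counts` if possible,
#'   otherwise 1).
#' @return List with `matrix` (z-scored), `row_order`, `col_order`.
#' @export
de_heatmap_order <- function(counts, sf = NULL) {
  counts <- as.matrix(counts)
  if (is.null(sf)) {
    sf <- tryCatch(size_factors(counts), error = function(e) {
      rep(1, ncol(counts))
    })
  }
  lg <- log2(sweep(counts, 2, sf, "/") + 1)
  mu <- rowMeans(lg)
  sd <- apply(lg, 1, stats::sd)
  z <- (lg - mu) / ifelse(!is.na(sd) & sd > 0, sd, 1)
  if (nrow(z) < 2L) {
    return(list(matrix = z, row_order = seq_len(nrow(z)),
                col_order = seq_len(ncol(z))))
  }
  ro <- stats::hclust(stats::dist(z), method = "average")$order
  co <- if (ncol(z) >= 2L) {
    stats::hclust(stats::dist(t(z)), method = "average")$order
  } else 1L
  list(matrix = z, row_order = ro, col_order = co)
}
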
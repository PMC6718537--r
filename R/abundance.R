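# Differential abundance of cluster cell counts between two conditions.
# The count model is the negative binomial with var = mu + alpha * mu^2;
# normalization, dispersion estimation and testing follow the DESeq family
# of count methods but are implemented here directly: median-of-ratios size
# factors, Cox-Reid adjusted profile-likelihood dispersion per cluster, IRLS
# fit of a log-link NB GLM with size-factor offsets, and a Wald test on the
# condition coefficient.

DISPERSION_FLOOR <- 1e-8
DISPERSION_CAP <- 10

#' Tabulate the clusters-by-samples count matrix
#'
#' Entry (c, j) is the number of events of sample j assigned to cluster c —
#' the "cells per mouse per subpopulation" matrix the differential test runs
#' on. Clusters empty in every sample are kept as zero rows so cluster ids
#' stay aligned with the tree.
#'
#' @param labels A [assign_full()] result.
#' @param samples The `sample_set` (fixes column order and conditions).
#' @param n_clusters Total number of clusters from the tree cut.
#' @return Integer matrix clusters x samples with dimnames.
#' @export
tabulate_counts <- function(labels, samples, n_clusters) {
  stopifnot(inherits(labels, "cluster_labels"), inherits(samples, "sample_set"))
  if (any(labels$cluster < 1L | labels$cluster > n_clusters)) {
    stop("cluster label outside 1..", n_clusters, call. = FALSE)
  }
  ids <- names(samples$tables)
  counts <- table(factor(labels$cluster, levels = seq_len(n_clusters)),
                  factor(labels$sample_id, levels = ids))
  counts <- matrix(as.integer(counts), nrow = n_clusters,
                   dimnames = list(paste0("c", seq_len(n_clusters)), ids))
  counts
}

#' Median-of-ratios size factors
#'
#' For each sample j, `s_j` is the median over usable clusters (rows with all
#' counts positive) of the ratio of that sample's count to the row's
#' geometric mean. This corrects for unequal numbers of cells acquired per
#' sample without letting a few large clusters dominate, exactly as for
#' sequencing library sizes. No further renormalization is applied.
#'
#' If no row is positive in every sample, falls back to column-total ratios
#' (each total divided by the geometric mean of totals) with a warning.
#'
#' @param counts Non-negative integer matrix clusters x samples.
#' @return Positive numeric vector of per-sample size factors, named by
#'   sample.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  usable <- rowSums(counts > 0) == ncol(counts)
  if (!any(usable)) {
    warning("no cluster has positive counts in every sample; ",
            "falling back to column-total normalization", call. = FALSE)
    tot <- colSums(counts)
    if (any(tot == 0)) stop("sample with zero total count", call. = FALSE)
    s <- tot / exp(mean(log(tot)))
  } else {
    lc <- log(counts[usable, , drop = FALSE])
    log_geo <- rowMeans(lc)
    s <- exp(apply(lc - log_geo, 2L, stats::median))
  }
  stats::setNames(as.numeric(s), colnames(counts))
}

# --- NB GLM internals -------------------------------------------------------

# IRLS fit of y ~ x with log link, known dispersion alpha, offset log(s).
# Returns coefficients, fitted means, the weighted information matrix and a
# convergence flag. Coefficients are clipped at +-50 so separated designs
# (a condition group with all-zero counts) terminate instead of diverging.
nb_glm_fit <- function(y, x, offset, alpha, beta = NULL,
                       max_iter = 100L, tol = 1e-10) {
  if (is.null(beta)) {
    eta0 <- log(pmax(y, 0.5)) - offset
    beta <- qr.solve(x, eta0)
  }
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta) + offset
    mu <- pmin(pmax(exp(eta), 1e-12), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    xtwx <- crossprod(x, w * x)
    beta_new <- tryCatch(drop(solve(xtwx, crossprod(x, w * z))),
                         error = function(e) NULL)
    if (is.null(beta_new) || any(!is.finite(beta_new))) {
      return(list(beta = beta, mu = mu, xtwx = xtwx, converged = FALSE))
    }
    beta_new <- pmin(pmax(beta_new, -50), 50)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(x %*% beta) + offset
  mu <- pmin(pmax(exp(eta), 1e-12), 1e12)
  w <- mu / (1 + alpha * mu)
  list(beta = beta, mu = mu, xtwx = crossprod(x, w * x), converged = converged)
}

# Cox-Reid adjusted NB profile log-likelihood at dispersion alpha, profiling
# out the GLM coefficients. The -0.5*log det(X'WX) term corrects the
# downward bias of plugging in fitted means with few samples.
nb_cr_profile <- function(y, x, offset, alpha, beta_start = NULL) {
  fit <- nb_glm_fit(y, x, offset, alpha, beta = beta_start)
  ll <- sum(stats::dnbinom(y, size = 1 / alpha, mu = fit$mu, log = TRUE))
  cr <- -0.5 * determinant(fit$xtwx, logarithm = TRUE)$modulus
  list(value = as.numeric(ll + cr), beta = fit$beta, ok = all(is.finite(ll + cr)))
}

# Method-of-moments dispersion from normalized counts (fallback).
nb_mom_dispersion <- function(y, s, group) {
  z <- y / s
  mu_g <- stats::ave(z, group)
  df <- length(y) - length(unique(group))
  if (df <= 0) return(DISPERSION_FLOOR)
  s2 <- sum((z - mu_g)^2) / df
  mu_bar <- mean(z)
  est <- (s2 - mu_bar * mean(1 / s)) / mu_bar^2
  min(max(est, DISPERSION_FLOOR), DISPERSION_CAP)
}

#' Per-cluster NB dispersion by Cox-Reid adjusted profile likelihood
#'
#' For each cluster, maximizes the Cox-Reid adjusted negative-binomial
#' profile likelihood over the dispersion `alpha` (variance model
#' `mu + alpha * mu^2`) given condition-wise fitted means, on the interval
#' \[1e-8, 10\]. Estimates within numerical reach of the boundary are snapped
#' to it, so Poisson-like clusters report the floor. If the profile cannot be
#' evaluated, a method-of-moments estimate is used with a warning.
#'
#' Shrinkage toward the mean log-dispersion is available but off by default:
#' with only ~15 clusters there is little information for empirical-Bayes
#' pooling.
#'
#' @param counts Clusters x samples count matrix.
#' @param size_factors Output of [estimate_size_factors()].
#' @param condition Two-level factor over samples, reference level first.
#' @param shrink Logical; shrink log-dispersions toward their mean.
#' @param shrink_weight Weight on the mean when `shrink = TRUE`.
#' @return Numeric vector of per-cluster dispersions (NA for all-zero rows).
#' @export
estimate_dispersions <- function(counts, size_factors, condition,
                                 shrink = FALSE, shrink_weight = 0.5) {
  counts <- as.matrix(counts)
  condition <- droplevels(as.factor(condition))
  stopifnot(nlevels(condition) == 2L, length(condition) == ncol(counts))
  if (any(table(condition) < 2L)) {
    stop("need at least 2 samples per condition", call. = FALSE)
  }
  x <- stats::model.matrix(~condition)
  offset <- log(size_factors)
  alphas <- apply(counts, 1L, function(y) {
    y <- as.numeric(y)
    if (all(y == 0)) return(NA_real_)
    beta_env <- new.env()
    beta_env$beta <- NULL
    prof <- function(log_a) {
      p <- nb_cr_profile(y, x, offset, exp(log_a), beta_start = beta_env$beta)
      if (!p$ok) return(-Inf)
      beta_env$beta <- p$beta
      p$value
    }
    lo <- log(DISPERSION_FLOOR); hi <- log(DISPERSION_CAP)
    opt <- tryCatch(stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-3),
                    error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) {
      warning("dispersion profile failed for a cluster; ",
              "using method-of-moments estimate", call. = FALSE)
      return(nb_mom_dispersion(y, size_factors, condition))
    }
    # boundary check: optimize never probes the exact endpoints
    at_lo <- prof(lo); at_hi <- prof(hi)
    best <- which.max(c(opt$objective, at_lo, at_hi))
    c(exp(opt$maximum), DISPERSION_FLOOR, DISPERSION_CAP)[best]
  })
  if (shrink) {
    ok <- !is.na(alphas)
    if (sum(ok) > 1L) {
      m <- mean(log(alphas[ok]))
      alphas[ok] <- exp((1 - shrink_weight) * log(alphas[ok]) + shrink_weight * m)
      alphas[ok] <- pmin(pmax(alphas[ok], DISPERSION_FLOOR), DISPERSION_CAP)
    }
  }
  stats::setNames(alphas, rownames(counts))
}

#' Benjamini-Hochberg adjustment with NA propagation
#'
#' Step-up FDR adjustment over the non-NA p-values (the number of tests `m`
#' counts only those); NA entries stay NA.
#'
#' @param p Numeric vector of p-values in \[0, 1\], NA allowed.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Negative-binomial Wald test for differential cluster abundance
#'
#' Fits, per cluster, a log-link NB GLM of counts on the condition indicator
#' with size-factor offsets and the cluster's dispersion, and tests the
#' condition coefficient with a Wald z statistic against the standard
#' normal. The log2 fold change is non-reference over reference, so a
#' cluster depleted with aging (reference = young) has `log2FoldChange < 0`
#' and direction `enriched_in_reference`. No fold-change shrinkage and no
#' independent filtering are applied.
#'
#' @inheritParams estimate_dispersions
#' @param dispersions Output of [estimate_dispersions()].
#' @param sig_threshold q-value cutoff for calling a direction (default
#'   0.05).
#' @return A data frame with DESeq2-style columns: `cluster`, `baseMean`,
#'   `log2FoldChange`, `lfcSE`, `stat`, `pvalue`, `padj`, `direction`.
#'   All-zero clusters get NA statistics and are excluded from the BH `m`.
#' @export
nb_wald_test <- function(counts, size_factors, dispersions, condition,
                         sig_threshold = 0.05) {
  counts <- as.matrix(counts)
  condition <- droplevels(as.factor(condition))
  stopifnot(nlevels(condition) == 2L, length(condition) == ncol(counts),
            length(size_factors) == ncol(counts),
            length(dispersions) == nrow(counts))
  x <- stats::model.matrix(~condition)
  offset <- log(size_factors)
  norm_counts <- sweep(counts, 2L, size_factors, "/")
  res <- lapply(seq_len(nrow(counts)), function(i) {
    y <- as.numeric(counts[i, ])
    if (all(y == 0) || is.na(dispersions[i])) {
      return(c(baseMean = 0, log2FoldChange = NA_real_, lfcSE = NA_real_,
               stat = NA_real_, pvalue = NA_real_))
    }
    fit <- nb_glm_fit(y, x, offset, dispersions[i])
    cov <- tryCatch(solve(fit$xtwx), error = function(e) NULL)
    if (is.null(cov) || !all(is.finite(cov))) {
      return(c(baseMean = mean(norm_counts[i, ]), log2FoldChange = NA_real_,
               lfcSE = NA_real_, stat = NA_real_, pvalue = NA_real_))
    }
    se <- sqrt(cov[2L, 2L])
    z <- unname(fit$beta[2L]) / se
    c(baseMean = mean(norm_counts[i, ]),
      log2FoldChange = unname(fit$beta[2L]) / log(2),
      lfcSE = se / log(2),
      stat = z,
      pvalue = 2 * stats::pnorm(-abs(z)))
  })
  res <- as.data.frame(do.call(rbind, res))
  res <- cbind(cluster = if (is.null(rownames(counts)))
    paste0("c", seq_len(nrow(counts))) else rownames(counts), res)
  rownames(res) <- NULL
  res$padj <- adjust_bh(res$pvalue)
  res$direction <- ifelse(
    is.na(res$padj) | res$padj >= sig_threshold, "none",
    ifelse(res$log2FoldChange > 0, "enriched_in_other", "enriched_in_reference"))
  attr(res, "condition_coding") <-
    paste0("log2FoldChange is ", levels(condition)[2L], " vs ",
           levels(condition)[1L], " (reference)")
  res
}

#' Differential abundance in one call
#'
#' Convenience wrapper chaining [estimate_size_factors()],
#' [estimate_dispersions()] and [nb_wald_test()].
#'
#' @inheritParams nb_wald_test
#' @inheritParams estimate_dispersions
#' @return The [nb_wald_test()] result data frame.
#' @export
da_test <- function(counts, condition, sig_threshold = 0.05, shrink = FALSE) {
  s <- estimate_size_factors(counts)
  a <- estimate_dispersions(counts, s, condition, shrink = shrink)
  nb_wald_test(counts, s, a, condition, sig_threshold = sig_threshold)
}
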
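#' TAA enrichment score of a genome
#'
#' TAA usage at a position is the share of TAA among the stop triplets found
#' there. The score compares primary-stop TAA usage with the unweighted mean
#' of the usages at downstream codon positions +1..+6:
#' (primary - mean downstream) / mean downstream. Downstream positions with
#' no stop triplet at all are dropped from the mean with a warning.
#'
#' @param contexts context data.frame.
#' @param positions downstream codon positions (default +1..+6).
#' @return the score (a real, 0 when primary usage equals the downstream mean).
#' @export
taa_enrichment_score <- function(contexts, positions = 1:6) {
  if (nrow(contexts) == 0L) stop("no contexts")
  primary_usage <- mean(contexts$stop == "TAA")
  mat <- seq_to_int(contexts$downstream)
  usages <- rep(NA_real_, length(positions))
  for (j in seq_along(positions)) {
    i <- 3L * (positions[j] - 1L)
    c1 <- mat[, i + 1L]; c2 <- mat[, i + 2L]; c3 <- mat[, i + 3L]
    is_taa <- c1 == 4L & c2 == 1L & c3 == 1L
    is_stop <- c1 == 4L & ((c2 == 1L & (c3 == 1L | c3 == 3L)) | (c2 == 3L & c3 == 1L))
    if (sum(is_stop) == 0L) {
      warning("no stop triplets at downstream position +", positions[j],
              "; dropped from the mean")
      next
    }
    usages[j] <- sum(is_taa) / sum(is_stop)
  }
  md <- mean(usages, na.rm = TRUE)
  if (is.nan(md) || md == 0) stop("mean downstream TAA usage is zero or undefined")
  (primary_usage - md) / md
}

#' TAA disparity between HEGs and LEGs
#'
#' Ratio of the TAA primary-stop frequency in highly expressed genes to that
#' in lowly expressed genes.
#'
#' @param heg_contexts,leg_contexts context data.frames.
#' @return the ratio.
#' @export
taa_disparity <- function(heg_contexts, leg_contexts) {
  h <- stop_frequencies(heg_contexts)$freq[["TAA"]]
  l <- stop_frequencies(leg_contexts)$freq[["TAA"]]
  if (l == 0) stop("LEG TAA frequency is zero; disparity undefined")
  h / l
}

#' Effective population size from nucleotide diversity and mutation rate
#'
#' @param pi nucleotide diversity (per site).
#' @param mu mutation rate (per site per generation).
#' @return `pi / (4 mu)`. Vectorised.
#' @export
estimate_ne <- function(pi, mu) {
  if (any(pi <= 0) || any(mu <= 0)) stop("pi and mu must be positive")
  pi / (4 * mu)
}

#' Brownian-motion covariance matrix of a phylogeny
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip depths.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param tips tip labels selecting (and ordering) the rows; default all tips.
#' @return the covariance matrix.
#' @export
brownian_cov <- function(tree, tips = tree$tip.label) {
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing) > 0L) {
    stop("tip(s) not in tree: ", paste(missing, collapse = ", "))
  }
  V <- ape::vcv.phylo(tree)
  V[tips, tips, drop = FALSE]
}

# profile log-likelihood machinery for PGLS under Pagel's lambda ----------

lambda_cov <- function(V, lambda) {
  Vl <- V * lambda
  diag(Vl) <- diag(V)
  Vl
}

# ML (or REML) profile log-likelihood of lambda given y, X, V
pgls_loglik <- function(lambda, y, X, V, reml = FALSE) {
  n <- length(y); p <- ncol(X)
  Vl <- lambda_cov(V, lambda)
  L <- tryCatch(chol(Vl), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  logdet <- 2 * sum(log(diag(L)))
  yw <- backsolve(L, y, transpose = TRUE)
  Xw <- backsolve(L, X, transpose = TRUE)
  fit <- stats::lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  if (reml) {
    s2 <- rss / (n - p)
    XtX <- crossprod(Xw)
    -0.5 * ((n - p) * log(2 * pi * s2) + (n - p) + logdet +
              determinant(XtX, logarithm = TRUE)$modulus[1])
  } else {
    s2 <- rss / n
    -0.5 * (n * log(2 * pi * s2) + n + logdet)
  }
}

#' Phylogenetic generalised least squares with Pagel's lambda
#'
#' Fits y = X beta + e with residual covariance sigma^2 V(lambda), where
#' V(lambda) multiplies the off-diagonal entries of the Brownian covariance
#' matrix by lambda in \[0, 1\]. Lambda is estimated by maximising the
#' profile likelihood over a 0..1 grid (step 0.01) followed by golden-section
#' refinement to tolerance 1e-6, or can be fixed. Coefficient tests use a t
#' distribution on n - p - 1 degrees of freedom (p predictors beside the
#' intercept); r-squared is computed on the V(lambda)-whitened model against
#' the whitened intercept-only fit and adjusted with the standard
#' small-sample correction (it may be negative). Likelihood-ratio tests
#' compare the fitted lambda with the bounds 0 and 1.
#'
#' @param formula model formula, e.g. `asc_enrichment ~ ne + cellularity`.
#' @param data data.frame with one row per species; rownames or a `species`
#'   column must match tree tips.
#' @param tree an [ape::phylo] tree containing all modelled species.
#' @param lambda `"ML"` (default) or a fixed value in \[0, 1\].
#' @param method `"ML"` or `"REML"` likelihood for lambda estimation.
#' @return object of class `PglsFit`: list with `coefficients` (matrix with
#'   estimate, std error, t, p), `lambda`, `logLik`, `r_squared`,
#'   `adj_r_squared`, `lambda_lr` (p-values of LR tests vs lambda = 0 and 1),
#'   `sigma2`, `n`, `residual_df`, `formula`.
#' @export
pgls_fit <- function(formula, data, tree, lambda = "ML", method = "ML") {
  if (!is.null(data$species)) rownames(data) <- data$species
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  species <- rownames(mf)
  if (is.null(species) || !all(species %in% tree$tip.label)) {
    stop("data rows must be named by species present in the tree")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design; collinear column(s): ", paste(bad, collapse = ", "))
  }
  n <- length(y); p_pred <- ncol(X) - 1L
  if (n <= p_pred + 1L) stop("need more species than predictors plus one")
  V <- brownian_cov(tree, species)
  if (!ape::is.ultrametric(ape::keep.tip(tree, species), tol = 1e-6)) {
    warning("tree is not ultrametric; lambda transform applied regardless")
  }
  reml <- identical(method, "REML")

  if (identical(lambda, "ML")) {
    grid <- seq(0, 1, by = 0.01)
    ll <- vapply(grid, function(l) pgls_loglik(l, y, X, V, reml), numeric(1))
    i <- which.max(ll)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    if (lo < hi) {
      opt <- stats::optimize(function(l) pgls_loglik(l, y, X, V, reml),
                             c(lo, hi), maximum = TRUE, tol = 1e-6)
      lambda_hat <- opt$maximum
      if (pgls_loglik(grid[i], y, X, V, reml) > opt$objective) lambda_hat <- grid[i]
    } else lambda_hat <- grid[i]
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0, lambda <= 1)
    lambda_hat <- lambda
  }

  Vl <- lambda_cov(V, lambda_hat)
  L <- chol(Vl)
  yw <- backsolve(L, y, transpose = TRUE)
  Xw <- backsolve(L, X, transpose = TRUE)
  colnames(Xw) <- colnames(X)
  fit <- stats::lm.fit(Xw, yw)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  df_res <- n - p_pred - 1L
  s2 <- rss / df_res
  XtXinv <- chol2inv(qr.R(qr(Xw)))
  se <- sqrt(diag(XtXinv) * s2)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
  coef_tab <- cbind(Estimate = beta, `Std. Error` = se, `t value` = tval,
                    `Pr(>|t|)` = pval)

  # null (intercept-only) GLS fit under the same V(lambda) for r-squared
  ones_w <- backsolve(L, rep(1, n), transpose = TRUE)
  rss0 <- sum(stats::lm.fit(cbind(ones_w), yw)$residuals^2)
  r2 <- 1 - rss / rss0
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df_res

  ll_hat <- pgls_loglik(lambda_hat, y, X, V, reml)
  lr <- function(l0) {
    stat <- 2 * (ll_hat - pgls_loglik(l0, y, X, V, reml))
    stats::pchisq(max(stat, 0), df = 1L, lower.tail = FALSE)
  }
  structure(list(coefficients = coef_tab, lambda = lambda_hat, logLik = ll_hat,
                 r_squared = r2, adj_r_squared = adj_r2,
                 lambda_lr = c(`lambda=0` = lr(0), `lambda=1` = lr(1)),
                 sigma2 = s2, n = n, residual_df = df_res, formula = formula),
            class = "PglsFit")
}

#' @export
print.PglsFit <- function(x, ...) {
  cat("PGLS fit (Pagel's lambda)\n")
  cat("lambda =", format(x$lambda, digits = 4),
      " logLik =", format(x$logLik, digits = 6), "\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("r^2 =", format(x$r_squared, digits = 4),
      " adjusted r^2 =", format(x$adj_r_squared, digits = 4), "\n")
  cat("LR vs lambda=0: p =", format(x$lambda_lr[1], digits = 3),
      "; vs lambda=1: p =", format(x$lambda_lr[2], digits = 3), "\n")
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test; the two-sided p-value sums the probabilities
#' of all tables (with the observed margins) no more likely than the
#' observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param tail `"two-sided"` (default), `"greater"` or `"less"`.
#' @return the exact p-value.
#' @export
fisher_exact_2x2 <- function(table, tail = "two-sided") {
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0),
            all(table == round(table)))
  alt <- switch(tail, greater = "greater", less = "less",
                `two-sided` = , two.sided = "two.sided",
                stop("tail must be greater, less or two-sided"))
  stats::fisher.test(table, alternative = alt)$p.value
}

#' Paired Wilcoxon signed-rank and Spearman rank tests
#'
#' Thin wrappers around the standard tests used for cross-genome stop-codon
#' frequency comparisons (paired Wilcoxon) and GC correlations (Spearman).
#'
#' @param a,b numeric vectors (paired / equal length).
#' @param kind `"wilcoxon"` or `"spearman"`.
#' @return list with `statistic`, `p`, and for Spearman `rho`.
#' @export
rank_tests <- function(a, b, kind = c("wilcoxon", "spearman")) {
  kind <- match.arg(kind)
  stopifnot(length(a) == length(b))
  if (kind == "wilcoxon") {
    if (all(a - b == 0)) stop("all paired differences are zero")
    w <- stats::wilcox.test(a, b, paired = TRUE)
    list(statistic = unname(w$statistic), p = w$p.value)
  } else {
    ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
    list(statistic = unname(ct$statistic), rho = unname(ct$estimate), p = ct$p.value)
  }
}
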
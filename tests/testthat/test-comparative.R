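test_that("TAA enrichment score compares primary usage with downstream usage", {
  # primary usage 0.6; every downstream position usage 0.4 -> score 0.5
  down <- c(rep(utr_with("TAA", "TAA", "TAA", "TAA", "TAA", "TAA"), 4),
            rep(utr_with("TGA", "TGA", "TGA", "TGA", "TGA", "TGA"), 6))
  ctx <- make_contexts(c(rep("TAA", 6), rep("TGA", 4)), downstream = down)
  expect_equal(taa_enrichment_score(ctx), 0.5, tolerance = 1e-12)

  # equal usage -> 0
  down2 <- c(rep(utr_with("TAA", "TAA", "TAA", "TAA", "TAA", "TAA"), 3),
             rep(utr_with("TGA", "TGA", "TGA", "TGA", "TGA", "TGA"), 2))
  ctx2 <- make_contexts(c(rep("TAA", 3), rep("TGA", 2)), downstream = down2)
  expect_equal(taa_enrichment_score(ctx2), 0, tolerance = 1e-12)

  # invariant to gene order and duplication of the whole set
  ctx_shuffled <- ctx[rev(seq_len(nrow(ctx))), ]
  expect_equal(taa_enrichment_score(ctx_shuffled), taa_enrichment_score(ctx))
  expect_equal(taa_enrichment_score(rbind(ctx, ctx)), taa_enrichment_score(ctx))

  # downstream position with no stop triplets is dropped with a warning
  down3 <- rep(utr_with("TAA", "TAA", "TAA", "TAA", "TAA", "."), 4)
  ctx3 <- make_contexts(rep("TAA", 4), downstream = down3)
  expect_warning(s3 <- taa_enrichment_score(ctx3), "\\+6")
  expect_equal(s3, 0)
})

test_that("the generator's TAA score matches its closed form", {
  reps <- vapply(1:6, function(s) {
    g <- generate_genome(4000, stop_probs = c(TAA = 0.6, TGA = 0.25, TAG = 0.15),
                         seed = 400 + s)
    taa_enrichment_score(extract_stop_contexts(g$genome)$contexts)
  }, numeric(1))
  # uniform chain: downstream TAA usage is 1/3, primary usage 0.6
  expect_lt(abs(mean(reps) - (0.6 - 1 / 3) / (1 / 3)), 0.05)
})

test_that("TAA disparity is the HEG/LEG frequency ratio", {
  heg <- make_contexts(c(rep("TAA", 3), rep("TGA", 2)))
  leg <- make_contexts(c(rep("TAA", 2), rep("TGA", 3)))
  expect_equal(taa_disparity(heg, leg), 1.5)
  expect_equal(taa_disparity(heg, heg), 1)
  no_taa <- make_contexts(rep("TGA", 4))
  expect_error(taa_disparity(heg, no_taa), "zero")
})

test_that("expression-linked stop choice produces HEG/LEG TAA disparity", {
  g <- generate_genome(5000, expression_link = 0.5, seed = 6)
  ctx <- extract_stop_contexts(g$genome, g$expression)$contexts
  parts <- partition_heg_leg(ctx)
  h <- stop_frequencies(parts$heg)$freq[["TAA"]]
  l <- stop_frequencies(parts$leg)$freq[["TAA"]]
  n <- nrow(parts$heg)
  expect_gt(h, l + 3 * sqrt(h * (1 - h) / n + l * (1 - l) / n))
  expect_gt(taa_disparity(parts$heg, parts$leg), 1)
})

test_that("effective population size follows pi over four mu", {
  expect_equal(estimate_ne(0.01, 2.5e-9), 1e6)
  expect_equal(estimate_ne(4e-8, 1e-8), 1)
  expect_equal(estimate_ne(3 * 0.01, 2.5e-9), 3 * estimate_ne(0.01, 2.5e-9))
  expect_error(estimate_ne(-0.01, 1e-8), "positive")
  expect_error(estimate_ne(0.01, 0), "positive")
})

test_that("Brownian covariance encodes shared path lengths", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  V <- brownian_cov(tr)
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "A"], 2)
  expect_equal(V["A", "C"], 0)
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  Vs <- brownian_cov(star)
  expect_equal(Vs, diag(3), ignore_attr = TRUE)
  expect_error(brownian_cov(tr, c("A", "Z")), "not in tree")
  # ultrametric tree: constant diagonal
  expect_equal(var(diag(V)), 0)
})

test_that("PGLS with lambda 0 equals ordinary least squares", {
  cmp <- generate_comparative(40, b = 0.8, lambda_true = 0.5, sigma2 = 1, seed = 12)
  f0 <- pgls_fit(taa_enrichment ~ log_ne + cellularity, cmp$traits, cmp$tree,
                 lambda = 0)
  ols <- lm(taa_enrichment ~ log_ne + cellularity, cmp$traits)
  expect_equal(unname(f0$coefficients[, "Estimate"]), unname(coef(ols)),
               tolerance = 1e-8)
  expect_equal(unname(f0$coefficients[, "Std. Error"]),
               unname(summary(ols)$coefficients[, "Std. Error"]), tolerance = 1e-8)
  expect_equal(f0$adj_r_squared, summary(ols)$adj.r.squared, tolerance = 1e-8)
})

test_that("PGLS matches an independent GLS implementation", {
  skip_if_not_installed("nlme")
  cmp <- generate_comparative(45, b = 1, lambda_true = 1, sigma2 = 0.5, seed = 7)
  d <- cmp$traits
  rownames(d) <- d$species
  fit <- pgls_fit(taa_enrichment ~ log_ne, d, cmp$tree)
  gfit <- nlme::gls(taa_enrichment ~ log_ne, data = d,
                    correlation = ape::corPagel(1, phy = cmp$tree,
                                                form = ~species, fixed = TRUE),
                    method = "ML")
  fit1 <- pgls_fit(taa_enrichment ~ log_ne, d, cmp$tree, lambda = 1)
  expect_equal(unname(fit1$coefficients[, "Estimate"]), unname(coef(gfit)),
               tolerance = 1e-6)
  expect_equal(fit1$logLik, as.numeric(stats::logLik(gfit)), tolerance = 1e-6)
  # ML lambda agrees with nlme's unconstrained optimum when inside [0, 1]
  gml <- nlme::gls(taa_enrichment ~ log_ne, data = d,
                   correlation = ape::corPagel(0.5, phy = cmp$tree, form = ~species),
                   method = "ML")
  lam_nlme <- as.numeric(gml$modelStruct$corStruct[[1]])
  expect_equal(fit$lambda, min(max(lam_nlme, 0), 1), tolerance = 0.02)
})

test_that("profile likelihood is maximised at the reported lambda", {
  cmp <- generate_comparative(35, b = 1, lambda_true = 0.6, sigma2 = 1, seed = 21)
  fit <- pgls_fit(taa_enrichment ~ log_ne, cmp$traits, cmp$tree)
  for (l in seq(0, 1, by = 0.05)) {
    fl <- pgls_fit(taa_enrichment ~ log_ne, cmp$traits, cmp$tree, lambda = l)
    expect_gte(fit$logLik + 1e-8, fl$logLik)
  }
})

test_that("singular designs fail with the collinear column named", {
  cmp <- generate_comparative(20, seed = 3)
  cmp$traits$dup <- cmp$traits$log_ne
  expect_error(pgls_fit(taa_enrichment ~ log_ne + dup, cmp$traits, cmp$tree),
               "collinear.*dup")
})

test_that("i.i.d. responses drive lambda to the lower bound", {
  lams <- vapply(1:60, function(s) {
    cmp <- generate_comparative(30, b = 0, lambda_true = 0, sigma2 = 1,
                                seed = 7000 + s)
    pgls_fit(taa_enrichment ~ cellularity, cmp$traits, cmp$tree)$lambda
  }, numeric(1))
  expect_lt(median(lams), 0.1)
})

test_that("Fisher's exact test reproduces printed and enumerated values", {
  # 4-of-7 vs 1-of-13 enrichment split
  expect_lt(abs(fisher_exact_2x2(matrix(c(4, 3, 1, 12), 2, byrow = TRUE)) - 0.031),
            5e-4)
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2)), 1.0)

  enum_fisher <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    sum(probs[probs <= dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
  }
  set.seed(2)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 4), 2)
    expect_equal(fisher_exact_2x2(tab), enum_fisher(tab), tolerance = 1e-9,
                 info = paste(tab, collapse = ","))
  }
})

test_that("rank tests wrap the standard definitions", {
  x <- c(1.2, 3.1, 2.2, 5.5, 4.1)
  sp <- rank_tests(x, x, kind = "spearman")
  expect_equal(sp$rho, 1)
  rev_sp <- rank_tests(x, -x, kind = "spearman")
  expect_equal(rev_sp$rho, -1)
  expect_error(rank_tests(x, x, kind = "wilcoxon"), "zero")
  set.seed(5)
  a <- rnorm(20); b <- rnorm(20)
  w <- rank_tests(a, b, kind = "wilcoxon")
  expect_equal(w$p, stats::wilcox.test(a, b, paired = TRUE)$p.value)
})
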
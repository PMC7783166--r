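test_that("ASC detection scans in-frame triplets", {
  d1 <- detect_ascs(utr_with("TAA"))
  expect_equal(d1$any, 1L)
  expect_equal(d1$first, 1L)

  d2 <- detect_ascs(utr_with(".", "TGA"))
  expect_equal(d2$any, 2L)
  expect_equal(d2$first, 2L)

  d3 <- detect_ascs(utr_with(".", "TAG", ".", ".", "TAA"))
  expect_equal(d3$any, c(2L, 5L))
  expect_equal(d3$first, 2L)

  expect_true(is.na(detect_ascs(PAD_UTR)$first))
})

test_that("ASC detection agrees with a brute-force triplet scan", {
  set.seed(7)
  n <- 10000
  utrs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 97, replace = TRUE), collapse = "")
  }, character(1))
  ctx <- make_contexts(rep("TAA", n), downstream = utrs)
  prof <- asc_profile(ctx)
  brute_any <- integer(6); brute_first <- integer(6)
  for (u in utrs) {
    found <- integer(0)
    for (k in 1:6) {
      tri <- substr(u, 3 * k - 2, 3 * k)
      if (tri == "TAA" || tri == "TGA" || tri == "TAG") found <- c(found, k)
    }
    brute_any[found] <- brute_any[found] + 1L
    if (length(found)) brute_first[min(found)] <- brute_first[min(found)] + 1L
  }
  expect_equal(unname(prof$any_count), brute_any)
  expect_equal(unname(prof$first_count), brute_first)
  expect_true(all(prof$first_count <= prof$any_count))
  expect_lte(sum(prof$first_count), prof$n_genes)
})

test_that("p-hat pools in-frame UTR triplets", {
  expect_equal(estimate_p_hat(make_contexts(rep("TAA", 4))), 0)
  # 8 stop triplets of 32
  u <- paste0(strrep("TAA", 8), strrep("CCA", 24), "C")
  expect_equal(estimate_p_hat(make_contexts("TAA", downstream = u)), 0.25)
})

test_that("generator UTRs from a uniform chain give p-hat near 3/64", {
  g <- generate_genome(1500, seed = 77)
  ctx <- extract_stop_contexts(g$genome)$contexts
  ph <- estimate_p_hat(ctx)
  n_trip <- 32 * nrow(ctx)
  expect_lt(abs(ph - 3 / 64), 3 * sqrt((3 / 64) * (61 / 64) / n_trip))
})

test_that("the analytic first-ASC null is geometric", {
  n0 <- ac_null(0.5, 1:6)
  expect_equal(unname(n0$expected_freq[1]), 0.5)
  expect_equal(unname(n0$expected_freq[2]), 0.25)
  for (p in c(0.01, 0.2, 0.9)) {
    # geometric normalisation: the infinite sum is 1; truncation to +1..+6
    # under-counts by exactly (1-p)^6
    s6 <- sum(ac_null(p, 1:6)$expected_freq)
    expect_equal(s6, 1 - (1 - p)^6, tolerance = 1e-12)
    s200 <- sum(ac_null(p, 1:200)$expected_freq)
    expect_equal(s200, 1 - (1 - p)^200, tolerance = 1e-12)
  }
  expect_error(ac_null(0), "probability")
  expect_error(ac_null(1.2), "probability")
})

test_that("the dinucleotide null reproduces degenerate and uniform training sets", {
  # all-A training UTRs: simulants must be all-A, expected frequency 0
  ctx_a <- make_contexts(rep("TAA", 5), downstream = rep(strrep("A", 97), 5))
  null_a <- dinucleotide_null(ctx_a, n_sim = 200, seed = 1)
  expect_true(all(null_a$expected_freq == 0))

  # i.i.d. uniform training -> any-ASC frequency near 3/64 at each position
  set.seed(11)
  utrs <- vapply(1:400, function(i) {
    paste(sample(c("A", "C", "G", "T"), 97, replace = TRUE), collapse = "")
  }, character(1))
  ctx_u <- make_contexts(rep("TAA", 400), downstream = utrs)
  null_u <- dinucleotide_null(ctx_u, n_sim = 5000, seed = 2)
  for (f in null_u$expected_freq) {
    expect_lt(abs(f - 3 / 64), 3 * sqrt((3 / 64) * (61 / 64) / 5000))
  }
})

test_that("the dinucleotide null is bit-identical under a fixed seed", {
  ctx <- make_contexts(rep("TAA", 30),
                       downstream = rep(c(utr_with("TAA"), PAD_UTR, utr_with(".", "TGA")), 10))
  a <- dinucleotide_null(ctx, n_sim = 500, seed = 99)
  b <- dinucleotide_null(ctx, n_sim = 500, seed = 99)
  expect_identical(a$expected_freq, b$expected_freq)
  expect_identical(a$sim_dinuc, b$sim_dinuc)
})

test_that("positional enrichment computes PES and pairs nulls with statistics", {
  prof <- structure(list(any_count = c(`+1` = 50, `+2` = 25),
                         first_count = c(`+1` = 50, `+2` = 25),
                         n_genes = 1000L, positions = 1:2), class = "AscProfile")
  null <- structure(list(kind = "adachi-cavalcanti",
                         expected_freq = c(`+1` = 0.05, `+2` = 0.025),
                         positions = 1:2), class = "AscNullModel")
  enr <- positional_enrichment(prof, null)
  expect_equal(enr$pes, c(0, 0))
  expect_equal(enr$p, c(1, 1))

  prof2 <- structure(list(any_count = c(`+1` = 100, `+2` = 25),
                          first_count = c(`+1` = 100, `+2` = 25),
                          n_genes = 1000L, positions = 1:2), class = "AscProfile")
  enr2 <- positional_enrichment(prof2, null)
  expect_equal(enr2$pes[1], 1.0)   # observed = 2 x expected

  null0 <- structure(list(kind = "adachi-cavalcanti",
                          expected_freq = c(`+1` = 0, `+2` = 0.025),
                          positions = 1:2), class = "AscNullModel")
  expect_error(positional_enrichment(prof2, null0), "degenerate")
})

test_that("genome calls require raw excess and the Bonferroni threshold", {
  base <- data.frame(position = 1:6, observed = rep(10, 6), expected = rep(10, 6),
                     pes = rep(0, 6), chisq = rep(0, 6), p = rep(1, 6),
                     direction = "enriched", stringsAsFactors = FALSE)
  class(base) <- c("PositionalEnrichment", "data.frame")

  hit <- base; hit$observed[2] <- 30; hit$p[2] <- 0.001; hit$pes[2] <- 2
  expect_true(genome_call(hit)$enriched)

  deficit <- base; deficit$observed[2] <- 2; deficit$p[2] <- 0.001
  expect_false(genome_call(deficit)$enriched)

  weak <- base; weak$observed[2] <- 12; weak$p[2] <- 0.02
  expect_false(genome_call(weak)$enriched)   # p above 0.05/6

  expect_equal(genome_call(base)$score, 0)
})

test_that("family-wise chance probabilities follow the Bonferroni arithmetic", {
  cp <- chance_probability(0.05, 6)
  expect_equal(cp$threshold, 0.05 / 6)
  expect_equal(cp$prob_none, (1 - 0.05 / 6)^6)
  expect_equal(cp$prob_at_least_one, 1 - (1 - 0.05 / 6)^6)
  expect_equal(chance_probability(0.05, 1)$prob_at_least_one, 0.05)
  expect_lt(chance_probability(1e-9, 6)$prob_at_least_one, 1e-8)
})

test_that("group binomial tests match an exhaustive enumeration oracle", {
  enum_binom <- function(k, n, p0, tail) {
    probs <- dbinom(0:n, n, p0)
    if (tail == "greater") sum(probs[(k + 1):(n + 1)])
    else if (tail == "less") sum(probs[1:(k + 1)])
    else sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
  }
  for (n in c(5, 12, 20, 25)) {
    for (k in c(0, 1, floor(n / 2), n - 1, n)) {
      for (tail in c("greater", "less", "two-sided")) {
        expect_equal(group_binomial(k, n, 0.3, tail), enum_binom(k, n, 0.3, tail),
                     tolerance = 1e-10,
                     info = paste(k, n, tail))
      }
    }
  }
  expect_equal(group_binomial(10, 10, 0.5, "greater"), 0.5^10)
})
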
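BASES <- c("A", "C", "G", "T")

# character sequences (equal length) -> integer matrix, A=1 C=2 G=3 T=4
seq_to_int <- function(seqs) {
  len <- unique(nchar(seqs))
  stopifnot(length(len) == 1L)
  m <- matrix(match(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE), BASES),
              nrow = length(seqs), ncol = len, byrow = TRUE)
  if (anyNA(m)) stop("sequence contains characters outside A/C/G/T")
  m
}

# logical matrix: is the in-frame triplet at codon position n a stop?
# mat: integer base matrix (genes x nt); positions: codon positions (1-based)
stop_triplet_matrix <- function(mat, positions) {
  out <- matrix(FALSE, nrow = nrow(mat), ncol = length(positions),
                dimnames = list(NULL, paste0("+", positions)))
  for (j in seq_along(positions)) {
    i <- 3L * (positions[j] - 1L)
    c1 <- mat[, i + 1L]; c2 <- mat[, i + 2L]; c3 <- mat[, i + 3L]
    out[, j] <- c1 == 4L & ((c2 == 1L & (c3 == 1L | c3 == 3L)) | (c2 == 3L & c3 == 1L))
  }
  out
}

#' Detect additional stop codons (ASCs) in one 3'-UTR
#'
#' Scans in-frame triplets of the downstream UTR; codon position n covers
#' UTR nucleotides 3(n-1)+1 .. 3n (position +1 starts at the first UTR base).
#'
#' @param downstream_utr UTR string (>= 18 nt for the default positions).
#' @param positions codon positions to scan (default +1..+6).
#' @return list with `any` (integer vector of positions holding a stop
#'   triplet) and `first` (first in-frame stop position over the scanned
#'   range, or NA).
#' @export
detect_ascs <- function(downstream_utr, positions = 1:6) {
  stopifnot(nchar(downstream_utr) >= 3 * max(positions))
  hits <- stop_triplet_matrix(seq_to_int(downstream_utr), positions)[1L, ]
  any_pos <- positions[hits]
  list(any = any_pos, first = if (length(any_pos)) min(any_pos) else NA_integer_)
}

#' Per-position ASC counts for a gene set
#'
#' @param contexts context data.frame (97-nt `downstream` column).
#' @param positions codon positions (default +1..+6).
#' @return list of class `AscProfile`: `any_count`, `first_count` (named
#'   integer vectors per position), `n_genes`, `positions`.
#' @export
asc_profile <- function(contexts, positions = 1:6) {
  if (nrow(contexts) == 0L) stop("no contexts")
  hits <- stop_triplet_matrix(seq_to_int(contexts$downstream), positions)
  any_count <- colSums(hits)
  first_pos <- apply(hits, 1L, function(r) if (any(r)) which(r)[1] else NA_integer_)
  first_count <- vapply(seq_along(positions),
                        function(j) sum(first_pos == j, na.rm = TRUE), integer(1))
  names(first_count) <- colnames(hits)
  structure(list(any_count = any_count, first_count = first_count,
                 n_genes = nrow(contexts), positions = positions),
            class = "AscProfile")
}

#' Pooled in-frame UTR stop-triplet probability (p-hat)
#'
#' Fraction of all in-frame triplets in the 97-nt UTR windows (32 triplets
#' per gene, pooled over genes) that are stop codons. This is the `p` of the
#' analytic first-ASC null.
#'
#' @param contexts context data.frame.
#' @return numeric probability.
#' @export
estimate_p_hat <- function(contexts) {
  if (nrow(contexts) == 0L) stop("no contexts")
  n_trip <- floor(nchar(contexts$downstream[1]) / 3)
  hits <- stop_triplet_matrix(seq_to_int(contexts$downstream), seq_len(n_trip))
  sum(hits) / length(hits)
}

#' Analytic first-ASC null (geometric decay)
#'
#' Expected first-ASC frequency at codon position n is `p (1 - p)^(n-1)`:
#' the probability of no stop at any upstream in-frame position times the
#' probability of a stop at the focal one.
#'
#' @param p in-frame UTR stop-triplet probability, in (0, 1).
#' @param positions codon positions.
#' @return list of class `AscNullModel` with `kind = "adachi-cavalcanti"`,
#'   `expected_freq` (named per position), and `p_hat`.
#' @export
ac_null <- function(p, positions = 1:6) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop("p must be a single probability strictly inside (0, 1)")
  }
  freq <- setNames(p * (1 - p)^(positions - 1L), paste0("+", positions))
  structure(list(kind = "adachi-cavalcanti", expected_freq = freq, p_hat = p,
                 positions = positions), class = "AscNullModel")
}

# fit a first-order Markov chain to 97-nt UTRs: initial distribution from the
# first UTR base (+4 marginal) and 4x4 transition probabilities from all
# adjacent pairs. Rows never observed as a from-state get a uniform
# (add-one) row, so simulation cannot deadlock; observed rows keep their
# exact empirical probabilities.
fit_utr_markov <- function(utrs) {
  mat <- seq_to_int(utrs)
  len <- ncol(mat)
  from <- as.vector(mat[, -len]); to <- as.vector(mat[, -1L])
  counts <- matrix(0, 4L, 4L, dimnames = list(BASES, BASES))
  tab <- table(factor(from, 1:4), factor(to, 1:4))
  counts[] <- as.numeric(tab)
  rs <- rowSums(counts)
  P <- counts
  for (i in 1:4) P[i, ] <- if (rs[i] > 0) counts[i, ] / rs[i] else rep(0.25, 4)
  init_tab <- table(factor(mat[, 1L], 1:4))
  init <- setNames(as.numeric(init_tab) / nrow(mat), BASES)
  list(init = init, P = P, dinuc = counts / sum(counts))
}

# simulate n sequences of length len from a first-order Markov chain
# (integer states 1..4); vectorised over sequences.
simulate_markov <- function(n, len, init, P) {
  out <- matrix(0L, n, len)
  cum_init <- cumsum(init)
  out[, 1L] <- findInterval(stats::runif(n), cum_init) + 1L
  cum_P <- t(apply(P, 1L, cumsum))
  for (j in 2:len) {
    u <- stats::runif(n)
    prev <- out[, j - 1L]
    out[, j] <- rowSums(u > cum_P[prev, 1:3, drop = FALSE]) + 1L
  }
  out
}

#' Dinucleotide-controlled Monte-Carlo ASC null
#'
#' Fits a first-order Markov chain to the observed 97-nt UTRs (capturing
#' nucleotide and dinucleotide frequencies), simulates `n_sim` null UTRs of
#' the same length, and takes the expected any-ASC frequency at each codon
#' position as the fraction of simulants carrying a stop triplet there. The
#' first simulated base is drawn from the empirical +4 marginal.
#'
#' @param contexts context data.frame supplying the training UTRs.
#' @param n_sim number of simulated null UTRs.
#' @param seed integer seed (mandatory; recorded in the result).
#' @param positions codon positions.
#' @return list of class `AscNullModel` with `kind = "dinucleotide-sim"`,
#'   `expected_freq`, `n_sim`, `seed`, the fitted `init` and `P`, and
#'   `train_dinuc` / `sim_dinuc` (4x4 relative dinucleotide frequency tables
#'   of the training and simulated sets).
#' @export
dinucleotide_null <- function(contexts, n_sim = 10000, seed, positions = 1:6) {
  if (missing(seed)) stop("seed is mandatory for the simulation null")
  if (nrow(contexts) == 0L) stop("no contexts")
  fit <- fit_utr_markov(contexts$downstream)
  len <- nchar(contexts$downstream[1])
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  sim <- simulate_markov(n_sim, len, fit$init, fit$P)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  hits <- stop_triplet_matrix(sim, positions)
  freq <- setNames(colMeans(hits), paste0("+", positions))
  from <- as.vector(sim[, -len]); to <- as.vector(sim[, -1L])
  sim_dinuc <- matrix(as.numeric(table(factor(from, 1:4), factor(to, 1:4))),
                      4L, 4L, dimnames = list(BASES, BASES))
  sim_dinuc <- sim_dinuc / sum(sim_dinuc)
  structure(list(kind = "dinucleotide-sim", expected_freq = freq, n_sim = n_sim,
                 seed = seed, init = fit$init, P = fit$P,
                 train_dinuc = fit$dinuc, sim_dinuc = sim_dinuc,
                 positions = positions), class = "AscNullModel")
}

#' Positional ASC enrichment against a null model
#'
#' Pairs the null with its matching observed statistic: the analytic
#' first-stop null with first-ASC counts, the dinucleotide simulation null
#' with any-ASC counts. For each position the positional enrichment score is
#' PES = (Observed - Expected) / Expected on counts, with a 1-df Pearson
#' chi-square on the 2-cell split (genes with vs without an ASC there).
#'
#' @param profile an `AscProfile`.
#' @param null an `AscNullModel`.
#' @return data.frame of class `PositionalEnrichment`: `position`,
#'   `observed`, `expected`, `pes`, `chisq`, `p`, `direction`.
#' @export
positional_enrichment <- function(profile, null) {
  stopifnot(inherits(profile, "AscProfile"), inherits(null, "AscNullModel"))
  if (!identical(profile$positions, null$positions)) {
    stop("profile and null cover different codon positions")
  }
  obs <- if (null$kind == "adachi-cavalcanti") profile$first_count else profile$any_count
  n <- profile$n_genes
  e <- null$expected_freq * n
  if (any(e == 0 & obs > 0)) {
    stop("null expectation is zero at position(s) ",
         paste(names(e)[e == 0 & obs > 0], collapse = ", "),
         " with nonzero observed count; null is degenerate")
  }
  pes <- ifelse(e == 0, 0, (obs - e) / e)
  chisq <- ifelse(e == 0 | e == n, 0,
                  (obs - e)^2 / e + ((n - obs) - (n - e))^2 / (n - e))
  p <- stats::pchisq(chisq, 1L, lower.tail = FALSE)
  out <- data.frame(position = profile$positions, observed = as.numeric(obs),
                    expected = as.numeric(e), pes = as.numeric(pes),
                    chisq = as.numeric(chisq), p = as.numeric(p),
                    direction = ifelse(obs >= e, "enriched", "depleted"),
                    stringsAsFactors = FALSE)
  class(out) <- c("PositionalEnrichment", "data.frame")
  out
}

#' Genome-level ASC enrichment call
#'
#' A genome is called enriched if any scanned position shows a raw excess of
#' ASCs over the null expectation together with a chi-square p-value below
#' the Bonferroni-corrected threshold `alpha / m`. The genome's enrichment
#' score is the mean PES over the positions.
#'
#' @param enrichment a `PositionalEnrichment` over exactly `m` positions.
#' @param alpha family-wise significance level.
#' @param m number of positions tested.
#' @return list of class `GenomeAscCall`: `enriched`, `score`, `threshold`,
#'   `significant_positions`.
#' @export
genome_call <- function(enrichment, alpha = 0.05, m = 6) {
  stopifnot(inherits(enrichment, "PositionalEnrichment"))
  if (nrow(enrichment) != m) {
    stop("enrichment covers ", nrow(enrichment), " positions but m = ", m)
  }
  thr <- alpha / m
  hit <- enrichment$observed > enrichment$expected & enrichment$p < thr
  structure(list(enriched = any(hit), score = mean(enrichment$pes),
                 threshold = thr,
                 significant_positions = enrichment$position[hit]),
            class = "GenomeAscCall")
}

#' Family-wise chance probability of an ASC enrichment call
#'
#' With per-test level `alpha / m` over `m` positions, the probability that
#' a genome shows no significant position by chance is `(1 - alpha/m)^m`,
#' and its complement is the chance probability of at least one.
#'
#' @param alpha family-wise level.
#' @param m number of positions.
#' @return list: `threshold`, `prob_none`, `prob_at_least_one`.
#' @export
chance_probability <- function(alpha = 0.05, m = 6) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  thr <- alpha / m
  list(threshold = thr, prob_none = (1 - thr)^m,
       prob_at_least_one = 1 - (1 - thr)^m)
}

#' Exact binomial test on the number of enriched genomes
#'
#' @param k_enriched number of genomes called enriched (successes).
#' @param n_genomes genomes tested.
#' @param p0 null success probability.
#' @param tail `"greater"`, `"less"` or `"two-sided"`; the two-sided p sums
#'   the probabilities of all outcomes no more likely than the observed one.
#' @return the exact p-value.
#' @export
group_binomial <- function(k_enriched, n_genomes, p0, tail = "two-sided") {
  stopifnot(k_enriched >= 0, k_enriched <= n_genomes)
  alt <- switch(tail, greater = "greater", less = "less",
                `two-sided` = , two.sided = "two.sided",
                stop("tail must be greater, less or two-sided"))
  stats::binom.test(k_enriched, n_genomes, p = p0, alternative = alt)$p.value
}
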
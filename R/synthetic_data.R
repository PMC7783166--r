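# --- closed-form helpers -------------------------------------------------

#' Analytic stop-triplet probabilities under a first-order Markov chain
#'
#' For a UTR generated by a first-order Markov chain, the probability that
#' the in-frame triplet at codon position n is TAA/TGA/TAG is
#' P(base at nt 3(n-1)+1) x transition products; marginals at interior
#' positions follow by propagating the initial distribution through the
#' transition matrix.
#'
#' @param init initial base distribution (A, C, G, T).
#' @param P 4x4 row-stochastic transition matrix.
#' @param positions codon positions.
#' @return matrix (positions x TAA/TGA/TAG/stop) of probabilities.
#' @export
markov_triplet_probs <- function(init, P, positions = 1:6) {
  stopifnot(length(init) == 4L, all(dim(P) == c(4L, 4L)),
            all(abs(rowSums(P) - 1) < 1e-9), abs(sum(init) - 1) < 1e-9)
  iT <- 4L; iA <- 1L; iG <- 3L
  out <- matrix(0, length(positions), 4L,
                dimnames = list(paste0("+", positions), c("TAA", "TGA", "TAG", "stop")))
  for (j in seq_along(positions)) {
    steps <- 3L * (positions[j] - 1L)
    marg <- init
    if (steps > 0) for (s in seq_len(steps)) marg <- as.numeric(marg %*% P)
    pT <- marg[iT]
    out[j, "TAA"] <- pT * P[iT, iA] * P[iA, iA]
    out[j, "TGA"] <- pT * P[iT, iG] * P[iG, iA]
    out[j, "TAG"] <- pT * P[iT, iA] * P[iA, iG]
    out[j, "stop"] <- sum(out[j, 1:3])
  }
  out
}

#' Analytic any-ASC null from known Markov chain parameters
#'
#' The exact counterpart of [dinucleotide_null()] when the generating chain
#' is known: expected any-ASC frequencies are computed in closed form rather
#' than by simulation. Used to validate the simulation null and for
#' calibration studies where simulation noise must be excluded.
#'
#' @inheritParams markov_triplet_probs
#' @return an `AscNullModel` of kind `"dinucleotide-sim"` with
#'   `provenance = "analytic"`.
#' @export
markov_asc_null <- function(init, P, positions = 1:6) {
  probs <- markov_triplet_probs(init, P, positions)
  structure(list(kind = "dinucleotide-sim",
                 expected_freq = setNames(probs[, "stop"], rownames(probs)),
                 provenance = "analytic", init = init, P = P,
                 positions = positions), class = "AscNullModel")
}

#' Expected primary TAA share under an expression-linked stop choice
#'
#' With baseline stop probabilities and a logistic tilt of the TAA odds by
#' `exp(link x z)` for standard-normal log-abundance z, the marginal TAA
#' share is the Gaussian integral of the tilted probability.
#'
#' @param stop_probs baseline c(TAA, TGA, TAG) probabilities.
#' @param link logistic coefficient on log-abundance.
#' @return expected TAA share of primary stops.
#' @export
expected_primary_taa <- function(stop_probs, link = 0) {
  stopifnot(length(stop_probs) == 3L, abs(sum(stop_probs) - 1) < 1e-9)
  if (link == 0) return(stop_probs[1])
  f <- function(z) {
    w <- stop_probs[1] * exp(link * z)
    w / (w + stop_probs[2] + stop_probs[3]) * stats::dnorm(z)
  }
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
}

# base composition for a GC target: AT and GC split evenly within each pair
gc_base_probs <- function(gc) {
  stopifnot(gc > 0, gc < 1)
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

# --- genome generator ----------------------------------------------------

#' Generate a synthetic genome with known ground truth
#'
#' Emulates the inputs of the context-extraction stage: single-exon genes
#' (ATG-started, stop-terminated, no internal stop), 97-nt 3'-UTRs from a
#' first-order Markov chain, log-normal protein abundances, an optional
#' logistic link between log-abundance and TAA choice, an optional injected
#' ASC excess at one codon position, and an optional plan of genes built to
#' fail specific extraction filters. Each gene sits on its own contig with
#' its 3' intergenic distance equal to the sequence left to the contig end;
#' alternate genes are placed on the minus strand. The truth table records
#' each gene's planned filter fate (classified under the same rule
#' precedence the extractor documents), stop codon, abundance, and realised
#' ASC positions.
#'
#' @param n_genes number of genes.
#' @param gc target UTR GC content (used for the default Markov chain and
#'   CDS composition).
#' @param stop_probs baseline c(TAA, TGA, TAG) primary-stop probabilities.
#' @param expression_link logistic coefficient tying TAA odds to standard-
#'   normal log-abundance.
#' @param asc_inject optional `list(position =, prob =)`: with probability
#'   `prob` a gene's UTR triplet at `position` is overwritten by a uniformly
#'   chosen stop codon.
#' @param transition optional 4x4 row-stochastic UTR transition matrix
#'   (default: independence rows from `gc`).
#' @param init optional initial base distribution (default from `gc`).
#' @param intergenic_range integer range the per-gene 3' intergenic distance
#'   is drawn from.
#' @param cds_codons integer range of internal (non-start, non-stop) codon
#'   counts per gene.
#' @param rejection_plan optional named integer vector with any of
#'   `internal_stop`, `bad_length`, `no_valid_stop`, `short_intergenic`,
#'   `truncated`, `non_acgt`: that many extra genes are appended, each
#'   carrying exactly one fault.
#' @param min_intergenic the extraction threshold the truth fates are
#'   classified against.
#' @param seed integer seed (mandatory).
#' @param dir if non-NULL, write `genome.fasta`, `genome.gff3`,
#'   `expression.tsv` and `truth.tsv` there.
#' @return list with `genome` (GenomeData), `expression` (ExpressionTable),
#'   `truth` (data.frame: gene_id, strand, stop, abundance, fate, injected,
#'   asc_positions), and `params`.
#' @export
generate_genome <- function(n_genes, gc = 0.5,
                            stop_probs = c(TAA = 0.45, TGA = 0.35, TAG = 0.2),
                            expression_link = 0, asc_inject = NULL,
                            transition = NULL, init = NULL,
                            intergenic_range = c(150, 500),
                            cds_codons = c(30, 80),
                            rejection_plan = NULL, min_intergenic = 100,
                            seed, dir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_genes >= 1, abs(sum(stop_probs) - 1) < 1e-9, all(stop_probs >= 0))
  pbase <- gc_base_probs(gc)
  if (is.null(transition)) transition <- matrix(pbase, 4, 4, byrow = TRUE,
                                                dimnames = list(BASES, BASES))
  if (is.null(init)) init <- pbase
  stopifnot(all(abs(rowSums(transition) - 1) < 1e-9), abs(sum(init) - 1) < 1e-9)
  if (!is.null(asc_inject)) {
    stopifnot(asc_inject$position %in% 1:32, asc_inject$prob >= 0, asc_inject$prob <= 1)
  }
  plan_types <- c("internal_stop", "bad_length", "no_valid_stop",
                  "short_intergenic", "truncated", "non_acgt")
  if (!is.null(rejection_plan)) {
    stopifnot(all(names(rejection_plan) %in% plan_types))
  }
  n_bad <- if (is.null(rejection_plan)) 0L else sum(rejection_plan)
  n_tot <- n_genes + n_bad
  fault <- c(rep("none", n_genes),
             rep(names(rejection_plan), times = rejection_plan))

  set.seed(seed)
  gene_id <- sprintf("g%05d", seq_len(n_tot))
  strand <- ifelse(seq_len(n_tot) %% 2L == 1L, "+", "-")
  abundance <- stats::rlnorm(n_tot, 0, 1)
  z <- log(abundance)

  # expression-linked stop choice
  w_taa <- stop_probs[1] * exp(expression_link * z)
  denom <- w_taa + stop_probs[2] + stop_probs[3]
  pm <- cbind(TAA = w_taa / denom, TGA = stop_probs[2] / denom,
              TAG = stop_probs[3] / denom)
  u <- stats::runif(n_tot)
  stop_codon <- ifelse(u < pm[, 1], "TAA",
                       ifelse(u < pm[, 1] + pm[, 2], "TGA", "TAG"))

  # CDS internal codons, stop-free, composition from pbase
  m <- sample(seq(cds_codons[1], cds_codons[2]), n_tot, replace = TRUE)
  total <- sum(m)
  draw <- matrix(sample.int(4L, 3L * total, replace = TRUE, prob = pbase),
                 ncol = 3L)
  is_stop <- function(d) d[, 1] == 4L &
    ((d[, 2] == 1L & (d[, 3] == 1L | d[, 3] == 3L)) | (d[, 2] == 3L & d[, 3] == 1L))
  while (any(bad <- is_stop(draw))) {
    draw[bad, ] <- matrix(sample.int(4L, 3L * sum(bad), replace = TRUE, prob = pbase),
                          ncol = 3L)
  }
  codon_str <- paste0(BASES[draw[, 1]], BASES[draw[, 2]], BASES[draw[, 3]])
  gene_of_codon <- rep(seq_len(n_tot), times = m)
  body <- vapply(split(codon_str, gene_of_codon), paste, character(1), collapse = "")
  cds <- paste0("ATG", body, stop_codon)

  # UTR + intergenic tail from the Markov chain
  dl <- sample(seq(intergenic_range[1], intergenic_range[2]), n_tot, replace = TRUE)
  down_len <- max(dl)
  sim <- simulate_markov(n_tot, down_len, init, transition)
  injected <- rep(FALSE, n_tot)
  if (!is.null(asc_inject) && asc_inject$prob > 0) {
    injected <- stats::runif(n_tot) < asc_inject$prob
    codes <- list(c(4L, 1L, 1L), c(4L, 3L, 1L), c(4L, 1L, 3L))
    pick <- sample.int(3L, sum(injected), replace = TRUE)
    i0 <- 3L * (asc_inject$position - 1L)
    sim[injected, i0 + 1L] <- vapply(pick, function(k) codes[[k]][1], integer(1))
    sim[injected, i0 + 2L] <- vapply(pick, function(k) codes[[k]][2], integer(1))
    sim[injected, i0 + 3L] <- vapply(pick, function(k) codes[[k]][3], integer(1))
  }
  chmat <- matrix(BASES[sim], nrow = n_tot)
  down_full <- do.call(paste0, as.data.frame(chmat, stringsAsFactors = FALSE))

  # apply planned faults
  for (i in which(fault != "none")) {
    switch(fault[i],
      internal_stop = {
        mid <- 3L + 3L * (m[i] %/% 2L) + 1L
        substr(cds[i], mid, mid + 2L) <- "TAA"
      },
      bad_length = { cds[i] <- paste0(cds[i], "A") },
      no_valid_stop = { substr(cds[i], nchar(cds[i]) - 2L, nchar(cds[i])) <- "AAA" },
      short_intergenic = { dl[i] <- as.integer(max(20, min_intergenic - 40)) },
      truncated = { dl[i] <- as.integer(min(96, min_intergenic + 10)) },
      non_acgt = { substr(down_full[i], 50L, 50L) <- "N" })
  }

  # planned fate under the extractor's documented precedence
  fate <- character(n_tot)
  for (i in seq_len(n_tot)) {
    fate[i] <- if (fault[i] == "bad_length") "length-not-multiple-of-3"
      else if (fault[i] == "no_valid_stop") "no-valid-stop"
      else if (fault[i] == "internal_stop") "internal-stop"
      else if (dl[i] <= min_intergenic) "short-intergenic"
      else if (dl[i] < 97L) "truncated-context"
      else if (fault[i] == "non_acgt") "non-ACGT"
      else "retained"
  }

  contigs <- character(n_tot)
  genes <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    plus_layout <- paste0(cds[i], substring(down_full[i], 1L, dl[i]))
    cds_len <- nchar(cds[i])
    if (strand[i] == "+") {
      contigs[i] <- plus_layout
      ex <- cbind(start = 0L, end = cds_len)
    } else {
      contigs[i] <- revcomp(plus_layout)
      ex <- cbind(start = dl[i], end = dl[i] + cds_len)
    }
    genes[[i]] <- list(gene_id = gene_id[i], contig = paste0("ctg_", gene_id[i]),
                       strand = strand[i], exons = ex, cds = cds[i])
  }
  names(contigs) <- paste0("ctg_", gene_id)
  genome <- structure(list(contigs = contigs, genes = genes), class = "GenomeData")
  expression <- structure(setNames(abundance, gene_id), class = "ExpressionTable")

  asc_positions <- vapply(seq_len(n_tot), function(i) {
    utr <- substring(down_full[i], 1L, 18L)
    if (grepl("N", utr, fixed = TRUE)) return("")
    hits <- which(substring(utr, c(1, 4, 7, 10, 13, 16),
                            c(3, 6, 9, 12, 15, 18)) %in% STOP_CODONS)
    paste(hits, collapse = ",")
  }, character(1))
  truth <- data.frame(gene_id = gene_id, strand = strand, stop = stop_codon,
                      abundance = abundance, fate = fate, injected = injected,
                      asc_positions = asc_positions, stringsAsFactors = FALSE)
  params <- list(n_genes = n_genes, gc = gc, stop_probs = stop_probs,
                 expression_link = expression_link, asc_inject = asc_inject,
                 transition = transition, init = init,
                 intergenic_range = intergenic_range,
                 min_intergenic = min_intergenic, seed = seed)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_genome(genome, file.path(dir, "genome.fasta"), file.path(dir, "genome.gff3"))
    utils::write.table(data.frame(gene_id = gene_id, abundance = abundance),
                       file.path(dir, "expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(genome = genome, expression = expression, truth = truth, params = params)
}

# --- triplet generator ---------------------------------------------------

#' Generate three-taxon ortholog alignments with a known substitution profile
#'
#' Builds a stop-anchored root sequence per gene (10 stop-free codons of
#' coding tail, the stop codon, 30 nt of UTR) and evolves it independently
#' along the two ingroup lineages and the outgroup lineage under Jukes-Cantor
#' substitution with per-site rate multipliers. Alignments are gapless and
#' carry `cds_len=33` header tags. The ingroup ancestor coincides with the
#' root (zero-length internal branch), so outgroup parsimony is exact up to
#' multiple hits.
#'
#' @param n_genes number of ortholog triplets.
#' @param branch_lengths named or positional c(ingroup1, ingroup2, outgroup)
#'   expected substitutions per site at rate multiplier 1.
#' @param rate_profile per-site multiplier over the 63 sites -30..-1, +1..+3,
#'   +4..+33 (default flat 1).
#' @param stop_codon the shared primary stop.
#' @param gc base composition of the root sequence.
#' @param seed integer seed (mandatory).
#' @param dir if non-NULL, write one aligned FASTA per gene there.
#' @return list with `triplets` (list of `TripletAlignment`), `truth`
#'   (per-site expected substitution probability per lineage and realised
#'   ingroup substitution counts), and `params`.
#' @export
generate_triplets <- function(n_genes, branch_lengths = c(0.05, 0.05, 0.1),
                              rate_profile = rep(1, 63), stop_codon = "TAA",
                              gc = 0.5, seed, dir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(length(branch_lengths) == 3L, all(branch_lengths >= 0),
            length(rate_profile) == 63L, all(rate_profile >= 0),
            stop_codon %in% STOP_CODONS)
  set.seed(seed)
  pbase <- gc_base_probs(gc)
  sites <- c(seq(-30L, -1L), seq(1L, 33L))

  # root: 10 stop-free codons + stop + 30 nt UTR, coded 1..4
  root <- matrix(0L, n_genes, 63L)
  draw_codons <- function(k) {
    d <- matrix(sample.int(4L, 3L * k, replace = TRUE, prob = pbase), ncol = 3L)
    stop_row <- function(d) d[, 1] == 4L &
      ((d[, 2] == 1L & (d[, 3] == 1L | d[, 3] == 3L)) | (d[, 2] == 3L & d[, 3] == 1L))
    while (any(bad <- stop_row(d))) {
      d[bad, ] <- matrix(sample.int(4L, 3L * sum(bad), replace = TRUE, prob = pbase),
                         ncol = 3L)
    }
    d
  }
  for (cidx in 0:9) {
    root[, (3L * cidx + 1L):(3L * cidx + 3L)] <- draw_codons(n_genes)
  }
  root[, 31:33] <- matrix(rep(match(strsplit(stop_codon, "")[[1]], BASES),
                              each = n_genes), n_genes, 3L)
  root[, 34:63] <- matrix(sample.int(4L, 30L * n_genes, replace = TRUE, prob = pbase),
                          n_genes, 30L)

  # Jukes-Cantor per-site substitution probability for each lineage
  p_sub <- vapply(branch_lengths, function(t) {
    0.75 * (1 - exp(-4 / 3 * t * rate_profile))
  }, numeric(63L))  # 63 x 3

  evolve <- function(root, p) {
    hit <- matrix(stats::runif(length(root)), nrow(root)) <
      matrix(p, nrow(root), 63L, byrow = TRUE)
    shift <- matrix(sample.int(3L, length(root), replace = TRUE), nrow(root))
    out <- root
    out[hit] <- ((root[hit] - 1L + shift[hit]) %% 4L) + 1L
    list(seq = out, hit = hit)
  }
  e1 <- evolve(root, p_sub[, 1]); e2 <- evolve(root, p_sub[, 2])
  e3 <- evolve(root, p_sub[, 3])

  to_str <- function(m) do.call(paste0, as.data.frame(matrix(BASES[m], nrow(m)),
                                                      stringsAsFactors = FALSE))
  s1 <- to_str(e1$seq); s2 <- to_str(e2$seq); s3 <- to_str(e3$seq)
  triplets <- lapply(seq_len(n_genes), function(i) {
    structure(list(seqs = c(ingroup1 = s1[i], ingroup2 = s2[i], outgroup = s3[i]),
                   cds_len = c(ingroup1 = 33L, ingroup2 = 33L, outgroup = 33L),
                   source = sprintf("gene%05d", i)),
              class = "TripletAlignment")
  })
  truth <- data.frame(site = sites,
                      p_sub_ingroup1 = p_sub[, 1], p_sub_ingroup2 = p_sub[, 2],
                      p_sub_outgroup = p_sub[, 3],
                      realized_ingroup_subs = colSums(e1$hit) + colSums(e2$hit))
  params <- list(n_genes = n_genes, branch_lengths = branch_lengths,
                 rate_profile = rate_profile, stop_codon = stop_codon,
                 gc = gc, seed = seed)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(n_genes)) {
      f <- file.path(dir, sprintf("gene%05d.fasta", i))
      writeLines(c(sprintf(">ingroup1 gene%05d cds_len=33", i), s1[i],
                   sprintf(">ingroup2 gene%05d cds_len=33", i), s2[i],
                   sprintf(">outgroup gene%05d cds_len=33", i), s3[i]), f)
    }
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(triplets = triplets, truth = truth, params = params)
}

# --- comparative generator -----------------------------------------------

#' Generate a phylogeny and species traits with known regression structure
#'
#' Simulates a pure-birth ultrametric tree, Brownian-motion log effective
#' population size, and a response trait
#' `a + b * log(ne) + e`, with `e` multivariate normal with covariance
#' `sigma2 * V(lambda_true)` (Brownian covariance with Pagel's lambda
#' transform). Cellularity is a Bernoulli tip trait. Nucleotide diversity pi
#' is back-derived as `4 mu ne` at fixed mu so the trait table is internally
#' consistent.
#'
#' @param n_species number of tips (>= 3).
#' @param birth_rate pure-birth speciation rate.
#' @param a,b intercept and slope of the trait model on log(ne).
#' @param lambda_true phylogenetic signal of the residuals, in \[0, 1\].
#' @param sigma2 residual variance scale.
#' @param q_unicell Bernoulli probability of a tip being unicellular.
#' @param mu fixed per-generation mutation rate used to back-derive pi.
#' @param seed integer seed (mandatory).
#' @param dir if non-NULL, write `tree.nwk` and `traits.tsv` there.
#' @return list with `tree` (phylo), `traits` (data.frame: species, pi, mu,
#'   ne, log_ne, cellularity, gc, median_gene_length,
#'   median_3prime_intergenic, taa_enrichment), and `truth`
#'   (list a, b, lambda_true, sigma2).
#' @export
generate_comparative <- function(n_species, birth_rate = 1, a = 0, b = 1,
                                 lambda_true = 1, sigma2 = 1, q_unicell = 0.3,
                                 mu = 1e-8, seed, dir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_species < 3L) stop("n_species must be at least 3 for a regression")
  stopifnot(lambda_true >= 0, lambda_true <= 1, sigma2 > 0)
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth  # unit-depth, keeps scales comparable
  V <- brownian_cov(tree)

  Lv <- chol(V)
  log_ne <- 14 + as.numeric(crossprod(Lv, stats::rnorm(n_species)))
  Vl <- lambda_cov(V, lambda_true)
  eps <- sqrt(sigma2) * as.numeric(crossprod(chol(Vl), stats::rnorm(n_species)))
  response <- a + b * log_ne + eps
  ne <- exp(log_ne)
  traits <- data.frame(species = tree$tip.label,
                       pi = 4 * mu * ne, mu = mu, ne = ne, log_ne = log_ne,
                       cellularity = stats::rbinom(n_species, 1, q_unicell),
                       gc = stats::runif(n_species, 0.3, 0.6),
                       median_gene_length = round(stats::rlnorm(n_species, 7, 0.3)),
                       median_3prime_intergenic = round(stats::rlnorm(n_species, 6, 0.5)),
                       taa_enrichment = response,
                       stringsAsFactors = FALSE)
  truth <- list(a = a, b = b, lambda_true = lambda_true, sigma2 = sigma2)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    ape::write.tree(tree, file.path(dir, "tree.nwk"))
    utils::write.table(traits, file.path(dir, "traits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(tree = tree, traits = traits, truth = truth)
}
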
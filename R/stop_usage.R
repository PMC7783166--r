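#' Primary stop-codon frequencies
#'
#' @param contexts a stop-context data.frame.
#' @return list of class `StopFrequencies`: `freq` (named proportions over
#'   TAA/TGA/TAG) and `n` (gene count).
#' @export
stop_frequencies <- function(contexts) {
  if (nrow(contexts) == 0L) stop("no contexts; cannot compute stop frequencies")
  counts <- table(factor(contexts$stop, levels = STOP_CODONS))
  freq <- setNames(as.numeric(counts) / nrow(contexts), STOP_CODONS)
  structure(list(freq = freq, n = nrow(contexts)), class = "StopFrequencies")
}

#' Standardized frequency difference (SFD) between HEGs and LEGs
#'
#' For each primary stop codon, SFD = (HEG frequency - LEG frequency) / LEG
#' frequency. A stop absent from both sets has SFD 0 (noted with a message);
#' a stop absent from LEGs but present in HEGs yields +Inf.
#'
#' @param heg_contexts,leg_contexts context data.frames for the two quartiles.
#' @return list of class `SfdResult`: `sfd` (named numeric), `heg_freq`,
#'   `leg_freq` (both `StopFrequencies`).
#' @export
sfd <- function(heg_contexts, leg_contexts) {
  hf <- stop_frequencies(heg_contexts)
  lf <- stop_frequencies(leg_contexts)
  s <- setNames(numeric(3), STOP_CODONS)
  for (codon in STOP_CODONS) {
    h <- hf$freq[[codon]]; l <- lf$freq[[codon]]
    if (l == 0 && h == 0) {
      message("stop ", codon, " absent from both HEGs and LEGs; SFD set to 0")
      s[[codon]] <- 0
    } else if (l == 0) {
      s[[codon]] <- Inf
    } else {
      s[[codon]] <- (h - l) / l
    }
  }
  structure(list(sfd = s, heg_freq = hf, leg_freq = lf), class = "SfdResult")
}

# Per-site nucleotide count matrix (4 x n_sites) for contexts over the given
# window of stop-anchored positions (stop at +1..+3, first UTR base +4,
# upstream sites -30..-1; there is no position 0).
site_base_counts <- function(contexts, sites) {
  full <- paste0(contexts$upstream, contexts$stop, contexts$downstream)
  stopifnot(all(nchar(full) == 130L))
  idx <- ifelse(sites > 0L, sites + 30L, sites + 31L)
  mat <- matrix(0L, nrow = 4L, ncol = length(sites),
                dimnames = list(c("A", "C", "G", "T"), as.character(sites)))
  for (j in seq_along(sites)) {
    tab <- table(factor(substring(full, idx[j], idx[j]), levels = c("A", "C", "G", "T")))
    mat[, j] <- as.integer(tab)
  }
  mat
}

#' Per-site nucleotide enrichment of HEGs against the genome-wide null
#'
#' For each nucleotide position around the stop and each base, compares the
#' observed HEG count with the expectation under the genome-wide base
#' frequency at the same position (all genes regardless of expression),
#' using a 1-df Pearson chi-square on the 2-cell split (count carrying the
#' base vs not), without continuity correction. Significance is flagged at
#' `p < alpha` with no multiple-testing correction. Upstream sites (negative
#' positions) are reported but flagged `context_only`, since amino-acid-level
#' selection confounds their interpretation.
#'
#' @param heg_contexts HEG context data.frame.
#' @param all_contexts all contexts (the null population).
#' @param window integer length-2 vector of stop-anchored positions, within
#'   \[-30, 100\] (stop at +1..+3; position 0 does not exist).
#' @param alpha per-test significance level.
#' @return data.frame of class `SiteEnrichmentGrid`: `site`, `nuc`,
#'   `observed`, `expected`, `chisq`, `p`, `direction`, `significant`,
#'   `context_only`.
#' @export
site_nucleotide_enrichment <- function(heg_contexts, all_contexts,
                                       window = c(-30, 100), alpha = 0.05) {
  stopifnot(length(window) == 2L, window[1] <= window[2],
            window[1] >= -30, window[2] <= 100)
  sites <- setdiff(seq(window[1], window[2]), 0L)
  n_h <- nrow(heg_contexts)
  n_a <- nrow(all_contexts)
  if (n_h == 0L || n_a == 0L) stop("empty context set")
  obs <- site_base_counts(heg_contexts, sites)
  glob <- site_base_counts(all_contexts, sites)
  f_all <- sweep(glob, 2L, colSums(glob), "/")

  out <- expand.grid(nuc = c("A", "C", "G", "T"), site = sites,
                     stringsAsFactors = FALSE)
  o <- as.vector(obs)
  e <- as.vector(f_all) * n_h
  floored <- e == 0 & o > 0
  if (any(floored)) {
    warning(sum(floored), " cell(s) with zero global frequency but nonzero ",
            "HEG count; expected floored at 0.5")
    e[floored] <- 0.5
  }
  chisq <- ifelse(e == 0 | e == n_h, 0,
                  (o - e)^2 / e + ((n_h - o) - (n_h - e))^2 / (n_h - e))
  p <- stats::pchisq(chisq, df = 1L, lower.tail = FALSE)
  out$observed <- o
  out$expected <- e
  out$chisq <- chisq
  out$p <- p
  out$direction <- ifelse(o >= e, "enriched", "depleted")
  out$significant <- p < alpha
  out$context_only <- out$site < 0L
  out <- out[, c("site", "nuc", "observed", "expected", "chisq", "p",
                 "direction", "significant", "context_only")]
  class(out) <- c("SiteEnrichmentGrid", "data.frame")
  out
}
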
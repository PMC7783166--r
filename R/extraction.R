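# Rejection reasons, in the fixed precedence order used to classify a gene
# that fails several filters at once. FilterReport counts each gene once,
# under the first failing rule in this order.
REJECTION_REASONS <- c("length-not-multiple-of-3", "no-valid-stop",
                       "internal-stop", "short-intergenic",
                       "truncated-context", "non-ACGT")

#' 3' intergenic distance of a gene
#'
#' Distance, in the direction of transcription, from the first base after the
#' gene's stop codon to the nearest transcription start of any other
#' annotated gene on either strand of the same contig; when no other gene
#' lies downstream, the distance to the contig end.
#'
#' @param gene a `GeneModel` (element of `GenomeData$genes`).
#' @param genome the `GenomeData` holding all genes.
#' @param index optional precomputed gene-start index from
#'   `gene_start_index()`; computed on the fly when absent.
#' @return integer distance in bp.
#' @export
intergenic_3prime_distance <- function(gene, genome, index = NULL) {
  contig_len <- nchar(genome$contigs[[gene$contig]])
  if (is.null(index)) index <- gene_start_index(genome)
  entry <- index[[gene$contig]]
  # drop the focal gene's own start once
  own <- if (gene$strand == "+") min(gene$exons[, "start"]) else
    max(gene$exons[, "end"]) - 1L
  starts <- entry
  hit <- match(own, starts)
  if (!is.na(hit)) starts <- starts[-hit]
  if (gene$strand == "+") {
    after <- max(gene$exons[, "end"])        # first base past the stop
    cand <- starts[starts >= after]
    if (length(cand) == 0L) contig_len - after else min(cand) - after
  } else {
    after <- min(gene$exons[, "start"]) - 1L  # first base past the stop, leftward
    cand <- starts[starts <= after]
    if (length(cand) == 0L) after + 1L else after - max(cand)
  }
}

# per-contig vector of 0-based first-transcribed-base positions of all genes
gene_start_index <- function(genome) {
  contig <- vapply(genome$genes, `[[`, character(1), "contig")
  start <- vapply(genome$genes, function(g) {
    if (g$strand == "+") min(g$exons[, "start"]) else max(g$exons[, "end"]) - 1L
  }, numeric(1))
  split(start, contig)
}

#' Extract filtered stop-codon contexts from a genome
#'
#' Builds one `StopContext` row per retained gene: the primary stop codon,
#' the last 30 nt of coding sequence before it, and the 97 nt of 3'-UTR that
#' follow it (stop occupying positions +1..+3, first UTR base +4). A gene is
#' retained only if its 3' intergenic space exceeds `min_intergenic` bp, its
#' CDS length is a multiple of 3, its terminal codon is TAA/TGA/TAG, it has
#' no other in-frame stop after the initiator, the 130-nt window fits on the
#' contig, and that window is built exclusively of A, C, G and T.
#'
#' @param genome a `GenomeData` object.
#' @param expression optional `ExpressionTable` (named abundances, ppm).
#' @param min_intergenic minimum 3' intergenic distance (strict inequality).
#' @return list with `contexts` (data.frame: `gene_id`, `stop`, `upstream`,
#'   `downstream`, `intergenic`, `abundance`) and `report` (named integer
#'   vector of rejection counts plus `retained`).
#' @export
extract_stop_contexts <- function(genome, expression = NULL, min_intergenic = 100) {
  stopifnot(inherits(genome, "GenomeData"))
  report <- setNames(integer(length(REJECTION_REASONS)), REJECTION_REASONS)
  index <- gene_start_index(genome)
  rows <- vector("list", length(genome$genes))
  for (i in seq_along(genome$genes)) {
    g <- genome$genes[[i]]
    fate <- classify_gene(g, genome, min_intergenic, index)
    if (fate$reason != "retained") {
      report[[fate$reason]] <- report[[fate$reason]] + 1L
      next
    }
    abund <- if (!is.null(expression) && g$gene_id %in% names(expression)) {
      unname(expression[[g$gene_id]])
    } else NA_real_
    rows[[i]] <- data.frame(gene_id = g$gene_id, stop = fate$stop,
                            upstream = fate$upstream, downstream = fate$downstream,
                            intergenic = fate$intergenic, abundance = abund,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  contexts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), stop = character(0), upstream = character(0),
               downstream = character(0), intergenic = integer(0),
               abundance = numeric(0), stringsAsFactors = FALSE)
  report <- c(retained = nrow(contexts), report)
  structure(list(contexts = contexts, report = report), class = "StopContextSet")
}

# Apply the filter cascade to one gene; returns reason ("retained" or a
# REJECTION_REASONS entry) plus context pieces when retained.
classify_gene <- function(g, genome, min_intergenic, index = NULL) {
  cds <- g$cds
  n <- nchar(cds)
  if (n %% 3L != 0L || n < 3L) return(list(reason = "length-not-multiple-of-3"))
  codons <- substring(cds, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  terminal <- codons[length(codons)]
  if (!terminal %in% STOP_CODONS) return(list(reason = "no-valid-stop"))
  internal <- codons[-c(1L, length(codons))]
  if (any(internal %in% STOP_CODONS)) return(list(reason = "internal-stop"))

  intergenic <- intergenic_3prime_distance(g, genome, index)
  if (intergenic <= min_intergenic) return(list(reason = "short-intergenic"))

  if (n < 33L) return(list(reason = "truncated-context"))
  contig <- genome$contigs[[g$contig]]
  contig_len <- nchar(contig)
  if (g$strand == "+") {
    after <- max(g$exons[, "end"])
    if (after + 97L > contig_len) return(list(reason = "truncated-context"))
    downstream <- substring(contig, after + 1L, after + 97L)
  } else {
    after <- min(g$exons[, "start"])
    if (after - 97L < 0L) return(list(reason = "truncated-context"))
    downstream <- revcomp(substring(contig, after - 96L, after))
  }
  upstream <- substring(cds, n - 32L, n - 3L)
  if (grepl("[^ACGT]", paste0(upstream, terminal, downstream))) {
    return(list(reason = "non-ACGT"))
  }
  list(reason = "retained", stop = terminal, upstream = upstream,
       downstream = downstream, intergenic = intergenic)
}

#' Partition stop contexts into highly and lowly expressed genes
#'
#' HEGs are the top quartile of genes by protein abundance and LEGs the
#' bottom quartile, each of size `floor(n/4)`. Genes are ordered by
#' descending abundance with ties broken by ascending gene id, so the split
#' is deterministic.
#'
#' @param contexts a `StopContext` data.frame with non-missing `abundance`.
#' @param min_genes refuse to partition fewer genes than this (the pipeline's
#'   species-inclusion threshold).
#' @return list with `heg` and `leg` context data.frames.
#' @export
partition_heg_leg <- function(contexts, min_genes = 400) {
  contexts <- contexts[!is.na(contexts$abundance), , drop = FALSE]
  n <- nrow(contexts)
  if (n < min_genes) {
    stop("only ", n, " genes with abundance; at least ", min_genes, " required")
  }
  if (length(unique(contexts$abundance)) == 1L) {
    warning("all abundances equal; HEG/LEG split is by gene id only")
  }
  ord <- order(-contexts$abundance, contexts$gene_id)
  q <- floor(n / 4)
  list(heg = contexts[ord[seq_len(q)], , drop = FALSE],
       leg = contexts[ord[seq(n - q + 1L, n)], , drop = FALSE])
}

#' Write / read a stop-context table as TSV
#'
#' @param contexts context data.frame as produced by [extract_stop_contexts()].
#' @param path output TSV path.
#' @return `write_contexts`: the path, invisibly. `read_contexts`: the
#'   context data.frame.
#' @export
write_contexts <- function(contexts, path) {
  utils::write.table(contexts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contexts
#' @export
read_contexts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "stop", "upstream", "downstream", "intergenic", "abundance")
  if (!all(need %in% names(df))) {
    stop("context table missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df
}
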
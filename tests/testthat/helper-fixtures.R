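# Shared fixture builders. Everything is constructed in code; no binary or
# stored data.

NONSTOP_UTR <- strrep("CCA", 32)                      # 96 nt, no in-frame stops
PAD_UTR <- paste0(NONSTOP_UTR, "C")                   # 97 nt

# a context data.frame from minimal pieces; defaults give a clean gene
make_contexts <- function(stops, downstream = NULL, upstream = NULL,
                          abundance = NULL, gene_id = NULL) {
  n <- length(stops)
  data.frame(
    gene_id = gene_id %||% sprintf("g%03d", seq_len(n)),
    stop = stops,
    upstream = upstream %||% rep(strrep("GCT", 10), n),
    downstream = downstream %||% rep(PAD_UTR, n),
    intergenic = rep(200L, n),
    abundance = abundance %||% rep(NA_real_, n),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build a 97-nt UTR with the given codons at positions +1..+6 ("."  means a
# non-stop filler codon)
utr_with <- function(...) {
  codons <- c(...)
  stopifnot(length(codons) <= 6)
  lead <- vapply(codons, function(x) if (x == ".") "CCA" else x, character(1))
  paste0(paste(lead, collapse = ""), substr(PAD_UTR, 3 * length(codons) + 1, 97))
}

# write a toy one-contig genome; genes is a list of lists with fields
# gene_id, start (1-based), end (inclusive), strand
write_toy_genome <- function(dir, contig, genes, contig_id = "chr1") {
  fa <- file.path(dir, "toy.fasta")
  gff <- file.path(dir, "toy.gff3")
  writeLines(c(paste0(">", contig_id), contig), fa)
  lines <- "##gff-version 3"
  for (g in genes) {
    lines <- c(lines,
      paste(contig_id, "test", "gene", g$start, g$end, ".", g$strand, ".",
            paste0("ID=", g$gene_id), sep = "\t"),
      paste(contig_id, "test", "mRNA", g$start, g$end, ".", g$strand, ".",
            paste0("ID=", g$gene_id, ".t1;Parent=", g$gene_id), sep = "\t"),
      paste(contig_id, "test", "CDS", g$start, g$end, ".", g$strand, "0",
            paste0("ID=", g$gene_id, ".c1;Parent=", g$gene_id, ".t1"), sep = "\t"))
  }
  writeLines(lines, gff)
  list(fasta = fa, gff3 = gff)
}

# hand-built gapless triplet alignment: 30 nt coding tail + stop + 30 nt UTR
make_triplet <- function(in1, in2, out, cds_len = NULL) {
  structure(list(
    seqs = c(ingroup1 = in1, ingroup2 = in2, outgroup = out),
    cds_len = c(ingroup1 = cds_len %||% NA_integer_,
                ingroup2 = cds_len %||% NA_integer_,
                outgroup = cds_len %||% NA_integer_),
    source = "fixture"), class = "TripletAlignment")
}

CODING_TAIL <- strrep("GCT", 10)   # 30 nt, stop-free in frame
UTR_TAIL <- strrep("CAC", 10)      # 30 nt, stop-free in frame

# exhaustive minimum-change parsimony oracle on the rooted triplet
# ((ingroup1, ingroup2) A, outgroup) root; ancestral call only when the
# minimising labellings agree on both internal nodes
parsimony_oracle <- function(column) {
  if (any(!column %in% c("A", "C", "G", "T"))) return(NA_character_)
  best <- Inf; anc_set <- character(0); root_set <- character(0)
  for (anc in c("A", "C", "G", "T")) for (root in c("A", "C", "G", "T")) {
    changes <- (column[1] != anc) + (column[2] != anc) +
      (column[3] != root) + (anc != root)
    if (changes < best) {
      best <- changes; anc_set <- anc; root_set <- root
    } else if (changes == best) {
      anc_set <- union(anc_set, anc); root_set <- union(root_set, root)
    }
  }
  if (length(anc_set) == 1L && length(root_set) == 1L) anc_set else NA_character_
}
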
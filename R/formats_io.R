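#' @importFrom stats setNames
NULL

STOP_CODONS <- c("TAA", "TGA", "TAG")

#' Read a genome from FASTA + GFF3 into a GenomeData object
#'
#' Parses contig sequences and CDS annotations into the container consumed by
#' the rest of the pipeline. GFF3 coordinates (1-based, inclusive) are
#' converted to 0-based half-open intervals at this boundary; minus-strand
#' coding sequences are reverse-complemented and exon-ordered 5' to 3'.
#' Where a gene has several annotated transcripts the longest CDS is kept
#' (ties broken by lexicographically smallest transcript id). Genes without
#' CDS features are skipped with a message. Contigs may contain N (such genes
#' are disqualified later, at context extraction), but any other ambiguity
#' code is rejected.
#'
#' @param fasta_path path to a FASTA file of contig sequences.
#' @param gff3_path path to a GFF3 annotation with CDS features.
#' @return An object of class `GenomeData`: a list with `contigs` (named
#'   uppercase character vector) and `genes` (list of `GeneModel` lists with
#'   fields `gene_id`, `contig`, `strand`, `exons` (matrix of 0-based
#'   half-open `start`/`end` rows, sorted), `cds` (spliced, strand-oriented
#'   coding sequence including the terminal stop)).
#' @export
read_genome <- function(fasta_path, gff3_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(gff3_path)) stop("GFF3 file not found: ", gff3_path)
  contigs_set <- tryCatch(Biostrings::readDNAStringSet(fasta_path),
    error = function(e) stop("malformed FASTA '", fasta_path, "': ", conditionMessage(e)))
  contigs <- toupper(as.character(contigs_set))
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) {
    stop("contig(s) ", paste(names(contigs)[bad], collapse = ", "),
         " contain ambiguity codes other than N")
  }

  gff <- tryCatch(rtracklayer::import(gff3_path, format = "gff3"),
    error = function(e) stop("malformed GFF3 '", gff3_path, "': ", conditionMessage(e)))
  cds <- gff[gff$type == "CDS"]
  if (length(cds) == 0L) stop("GFF3 '", gff3_path, "' contains no CDS features")

  ids <- as.character(GenomicRanges::seqnames(cds))
  missing_contig <- setdiff(unique(ids), names(contigs))
  if (length(missing_contig) > 0L) {
    stop("CDS features reference contig(s) absent from FASTA: ",
         paste(missing_contig, collapse = ", "))
  }

  # transcript id of each CDS: first Parent if present, else its own ID
  parents <- if (!is.null(cds$Parent)) {
    vapply(as.list(cds$Parent), function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  } else rep(NA_character_, length(cds))
  own_id <- if (!is.null(cds$ID)) as.character(cds$ID) else rep(NA_character_, length(cds))
  tx_id <- ifelse(is.na(parents), own_id, parents)
  tx_id[is.na(tx_id)] <- paste0("cds", seq_len(sum(is.na(tx_id))))

  # map transcript -> gene via mRNA/transcript features; fall back to transcript id
  tx_types <- c("mRNA", "transcript")
  txf <- gff[gff$type %in% tx_types]
  tx2gene <- character(0)
  if (length(txf) > 0L && !is.null(txf$ID)) {
    gp <- if (!is.null(txf$Parent)) {
      vapply(as.list(txf$Parent), function(p) if (length(p)) p[[1]] else NA_character_,
             character(1))
    } else rep(NA_character_, length(txf))
    tx2gene <- setNames(ifelse(is.na(gp), as.character(txf$ID), gp),
                        as.character(txf$ID))
  }
  gene_id <- ifelse(tx_id %in% names(tx2gene), tx2gene[tx_id], tx_id)

  starts0 <- GenomicRanges::start(cds) - 1L
  ends0 <- GenomicRanges::end(cds)
  strands <- as.character(GenomicRanges::strand(cds))

  genes <- list()
  for (g in unique(gene_id)) {
    sel <- which(gene_id == g)
    best_tx <- NULL; best_len <- -1L
    for (tx in sort(unique(tx_id[sel]))) {
      len <- sum(ends0[sel][tx_id[sel] == tx] - starts0[sel][tx_id[sel] == tx])
      if (len > best_len) { best_len <- len; best_tx <- tx }
    }
    rows <- sel[tx_id[sel] == best_tx]
    contig <- ids[rows[1]]
    strand <- strands[rows[1]]
    if (!strand %in% c("+", "-")) strand <- "+"
    ex <- cbind(start = starts0[rows], end = ends0[rows])
    ex <- ex[order(ex[, "start"]), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex[-1L, "start"] < ex[-nrow(ex), "end"])) {
      stop("overlapping CDS sub-intervals for gene ", g)
    }
    pieces <- substring(contigs[[contig]], ex[, "start"] + 1L, ex[, "end"])
    cds_seq <- paste(pieces, collapse = "")
    if (strand == "-") cds_seq <- revcomp(cds_seq)
    genes[[g]] <- list(gene_id = g, contig = contig, strand = strand,
                       exons = ex, cds = cds_seq)
  }
  n_skipped <- length(setdiff(
    if (!is.null(gff$ID)) as.character(gff$ID[gff$type == "gene"]) else character(0),
    names(genes)))
  if (n_skipped > 0L) message(n_skipped, " gene(s) without CDS features skipped")

  structure(list(contigs = contigs, genes = unname(genes)), class = "GenomeData")
}

#' Write a GenomeData object back to FASTA + GFF3
#'
#' Inverse of [read_genome()] for single-span and multi-exon gene models;
#' used for round-trip testing and by the synthetic-genome generator.
#'
#' @param genome a `GenomeData` object.
#' @param fasta_path,gff3_path output paths.
#' @return invisibly, the two paths.
#' @export
write_genome <- function(genome, fasta_path, gff3_path) {
  stopifnot(inherits(genome, "GenomeData"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$contigs), fasta_path)
  lines <- c("##gff-version 3")
  for (g in genome$genes) {
    lo <- min(g$exons[, "start"]) + 1L
    hi <- max(g$exons[, "end"])
    lines <- c(lines,
      paste(g$contig, "readthru", "gene", lo, hi, ".", g$strand, ".",
            paste0("ID=", g$gene_id), sep = "\t"),
      paste(g$contig, "readthru", "mRNA", lo, hi, ".", g$strand, ".",
            paste0("ID=", g$gene_id, ".t1;Parent=", g$gene_id), sep = "\t"))
    for (i in seq_len(nrow(g$exons))) {
      lines <- c(lines,
        paste(g$contig, "readthru", "CDS", g$exons[i, "start"] + 1L,
              g$exons[i, "end"], ".", g$strand, "0",
              paste0("ID=", g$gene_id, ".cds;Parent=", g$gene_id, ".t1"),
              sep = "\t"))
    }
  }
  writeLines(lines, gff3_path)
  invisible(c(fasta = fasta_path, gff3 = gff3_path))
}

#' Read a two-column protein abundance table
#'
#' @param tsv_path TSV with columns gene id and abundance (ppm); a header
#'   line is detected and skipped when the second field is non-numeric.
#' @return named numeric vector of abundances (class `ExpressionTable`).
#' @export
read_expression <- function(tsv_path) {
  if (!file.exists(tsv_path)) stop("expression file not found: ", tsv_path)
  raw <- readLines(tsv_path)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) == 0L) {
    warning("empty expression table: ", tsv_path)
    return(structure(numeric(0), class = "ExpressionTable"))
  }
  fields <- strsplit(raw, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop("expression table line(s) with fewer than 2 fields: line ",
         which(lengths(fields) < 2L)[1])
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  vals_chr <- vapply(fields, `[[`, character(1), 2L)
  first_num <- suppressWarnings(as.numeric(vals_chr[1]))
  if (is.na(first_num) && length(raw) >= 1L) {  # header row
    ids <- ids[-1L]; vals_chr <- vals_chr[-1L]
    if (length(ids) == 0L) {
      warning("expression table has a header but no data rows")
      return(structure(numeric(0), class = "ExpressionTable"))
    }
  }
  vals <- suppressWarnings(as.numeric(vals_chr))
  if (any(is.na(vals))) {
    stop("non-numeric abundance at data line ", which(is.na(vals))[1])
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene id(s) in expression table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(vals < 0)) stop("negative abundance for ", ids[vals < 0][1])
  structure(setNames(vals, ids), class = "ExpressionTable")
}

#' Read a phylogeny (Newick or NEXUS)
#'
#' @param path tree file; NEXUS detected by a leading `#NEXUS`.
#' @param default_branch_length value substituted (with a message) for missing
#'   branch lengths; `NULL` (default) makes missing lengths an error.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path, default_branch_length = NULL) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  first <- toupper(trimws(readLines(path, n = 1L)))
  tree <- if (startsWith(first, "#NEXUS")) ape::read.nexus(path) else ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  if (is.null(tree)) stop("could not parse tree from ", path)
  if (any(!nzchar(tree$tip.label))) stop("tree has unlabeled tip(s)")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    if (is.null(default_branch_length)) {
      stop("tree has missing branch length(s); supply default_branch_length to impute")
    }
    message("imputing missing branch lengths with ", default_branch_length)
    if (is.null(tree$edge.length)) {
      tree$edge.length <- rep(default_branch_length, nrow(tree$edge))
    } else {
      tree$edge.length[is.na(tree$edge.length)] <- default_branch_length
    }
  }
  if (any(tree$edge.length < 0)) stop("tree has negative branch length(s)")
  tree
}

#' Read aligned three-taxon ortholog files
#'
#' Each file must contain exactly three aligned records (gap character `-`).
#' Roles are assigned by matching a role token against record headers. An
#' optional `cds_len=<n>` tag in a header records that record's ungapped
#' coding-sequence length (including the terminal stop); when absent, the
#' primary stop is later inferred as the first in-frame stop triplet.
#'
#' @param paths character vector of aligned FASTA files.
#' @param roles named character vector
#'   `c(ingroup1 = <token>, ingroup2 = <token>, outgroup = <token>)`; tokens
#'   are matched as fixed substrings of the record headers.
#' @return list of `TripletAlignment` objects: lists with `seqs` (named
#'   character vector over roles, uppercase), `cds_len` (named integer or NA),
#'   and `source`.
#' @export
read_triplets <- function(paths, roles) {
  need <- c("ingroup1", "ingroup2", "outgroup")
  if (!all(need %in% names(roles))) {
    stop("roles must name ingroup1, ingroup2 and outgroup")
  }
  lapply(paths, function(p) {
    recs <- Biostrings::readBStringSet(p)
    if (length(recs) != 3L) {
      stop("alignment '", p, "' has ", length(recs), " records; expected 3")
    }
    if (length(unique(Biostrings::width(recs))) != 1L) {
      stop("alignment '", p, "' has records of unequal length")
    }
    headers <- names(recs)
    seqs <- character(3); names(seqs) <- need
    cds_len <- setNames(rep(NA_integer_, 3), need)
    for (r in need) {
      hit <- grep(roles[[r]], headers, fixed = TRUE)
      if (length(hit) != 1L) {
        stop("role token '", roles[[r]], "' matches ", length(hit),
             " record(s) in '", p, "'; expected exactly 1")
      }
      seqs[[r]] <- toupper(as.character(recs[[hit]]))
      m <- regmatches(headers[hit], regexpr("cds_len=\\d+", headers[hit]))
      if (length(m) == 1L) cds_len[[r]] <- as.integer(sub("cds_len=", "", m))
    }
    structure(list(seqs = seqs, cds_len = cds_len, source = p),
              class = "TripletAlignment")
  })
}

# reverse complement of a plain character string (ACGTN alphabet)
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                     collapse = ""), character(1), USE.NAMES = FALSE))
}
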
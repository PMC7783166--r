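# ungapped sequence and the map alignment-column -> ungapped position
ungap_map <- function(aln) {
  chars <- strsplit(aln, "", fixed = TRUE)[[1]]
  keep <- chars != "-"
  list(seq = paste(chars[keep], collapse = ""), is_base = keep,
       col_of_pos = which(keep))
}

# locate the primary stop of one aligned record: returns list(stop, col)
# where col is the alignment column of the stop's first base, or NULL.
# With a known ungapped CDS length the stop is the terminal codon; otherwise
# it is the first in-frame stop triplet of the ungapped sequence.
locate_stop <- function(aln, cds_len = NA_integer_) {
  um <- ungap_map(aln)
  s <- um$seq
  n <- nchar(s)
  if (!is.na(cds_len)) {
    if (cds_len %% 3L != 0L || cds_len > n) return(NULL)
    codon <- substring(s, cds_len - 2L, cds_len)
    if (!codon %in% STOP_CODONS) return(NULL)
    # premature in-frame stop => invalid gene
    if (cds_len > 3L) {
      up <- substring(s, seq(1L, cds_len - 3L, 3L), seq(3L, cds_len - 3L, 3L))
      if (any(up %in% STOP_CODONS)) return(list(premature = TRUE))
    }
    pos <- cds_len - 2L
  } else {
    starts <- seq(1L, n - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    hit <- which(codons %in% STOP_CODONS)
    if (length(hit) == 0L) return(NULL)
    pos <- starts[hit[1]]
    codon <- codons[hit[1]]
  }
  list(stop = codon, col = um$col_of_pos[pos], premature = FALSE)
}

#' Quality-filter a three-taxon ortholog alignment
#'
#' A triplet passes when every record has an in-frame terminal stop with no
#' premature in-frame stop, all three stops are the same codon and occupy the
#' same alignment columns, the alignment extends at least 10 codons on both
#' sides of the stop, and no gap character occurs within 10 codons (30
#' columns) upstream or downstream of it.
#'
#' @param triplet a `TripletAlignment`.
#' @return `"pass"` or a rejection reason (`"no-valid-stop"`,
#'   `"premature-stop"`, `"stop-misaligned"`, `"stop-disagreement"`,
#'   `"window-truncated"`, `"gap-near-stop"`). When passing, the stop column
#'   is attached as `attr(, "stop_column")` and codon as `attr(, "stop")`.
#' @export
filter_triplet <- function(triplet) {
  stopifnot(inherits(triplet, "TripletAlignment"))
  roles <- c("ingroup1", "ingroup2", "outgroup")
  locs <- lapply(roles, function(r) {
    locate_stop(triplet$seqs[[r]], triplet$cds_len[[r]])
  })
  if (any(vapply(locs, is.null, logical(1)))) return("no-valid-stop")
  if (any(vapply(locs, function(l) isTRUE(l$premature), logical(1)))) {
    return("premature-stop")
  }
  cols <- vapply(locs, `[[`, integer(1), "col")
  if (length(unique(cols)) != 1L) return("stop-misaligned")
  stops <- vapply(locs, `[[`, character(1), "stop")
  if (length(unique(stops)) != 1L) return("stop-disagreement")
  sc <- cols[1]
  width <- nchar(triplet$seqs[[1]])
  if (sc - 30L < 1L || sc + 2L + 30L > width) return("window-truncated")
  win <- substring(triplet$seqs, sc - 30L, sc + 32L)
  if (any(grepl("-", win, fixed = TRUE))) return("gap-near-stop")
  out <- "pass"
  attr(out, "stop_column") <- sc
  attr(out, "stop") <- stops[1]
  out
}

#' Infer the ancestral base of one alignment column by outgroup parsimony
#'
#' With two sister ingroups and one outgroup, the ancestor of the ingroup
#' pair is the outgroup base whenever it matches at least one ingroup;
#' otherwise the site is unresolved and skipped.
#'
#' @param column character vector `c(ingroup1, ingroup2, outgroup)`.
#' @return the ancestral base, or `NA` if unresolved (including any gap or
#'   non-ACGT character in the column).
#' @export
infer_ancestor <- function(column) {
  stopifnot(length(column) == 3L)
  if (any(!column %in% BASES)) return(NA_character_)
  if (column[3] == column[1] || column[3] == column[2]) column[3] else NA_character_
}

#' Per-site substitution frequencies around the stop codon
#'
#' For each stop class (TAA/TGA/TAG) and each site from 10 codons upstream
#' to 10 codons downstream of the stop (sites -30..-1, the stop +1..+3, and
#' +4..+33), counts ingroup-lineage bases that differ from the parsimony
#' ancestor, over both ingroup lineages. The per-site frequency divides by
#' 2 x the number of triplets of that class whose ancestor is resolved at
#' that site (per-lineage rate).
#'
#' @param triplets list of `TripletAlignment` objects (typically pre-filtered;
#'   non-passing triplets are dropped here with a message).
#' @param flank_codons window half-width in codons.
#' @return data.frame of class `SubstitutionProfile`: `stop_class`, `site`,
#'   `numerator`, `denominator`, `frequency`; plus
#'   `attr(, "valid_genes")`, a named count of passing triplets per class.
#' @export
substitution_profile <- function(triplets, flank_codons = 10) {
  fl <- 3L * flank_codons
  sites <- c(seq(-fl, -1L), seq(1L, fl + 3L))  # no position 0; stop = +1..+3
  offsets <- ifelse(sites < 0L, sites, sites - 1L)  # column offset from stop col
  acc <- list()
  valid <- c(TAA = 0L, TGA = 0L, TAG = 0L)
  num <- den <- matrix(0L, nrow = 3L, ncol = length(sites),
                       dimnames = list(STOP_CODONS, as.character(sites)))
  dropped <- 0L
  for (tr in triplets) {
    verdict <- filter_triplet(tr)
    if (verdict != "pass") { dropped <- dropped + 1L; next }
    sc <- attr(verdict, "stop_column")
    cls <- attr(verdict, "stop")
    valid[[cls]] <- valid[[cls]] + 1L
    cols <- sc + offsets
    m <- do.call(rbind, strsplit(triplet_window(tr, cols), "", fixed = TRUE))
    for (j in seq_along(sites)) {
      col <- m[, j]
      anc <- infer_ancestor(col)
      if (is.na(anc)) next
      den[cls, j] <- den[cls, j] + 2L
      num[cls, j] <- num[cls, j] + sum(col[1:2] != anc)
    }
  }
  if (dropped > 0L) message(dropped, " triplet(s) failed quality filters and were dropped")
  out <- do.call(rbind, lapply(STOP_CODONS, function(cls) {
    if (valid[[cls]] == 0L) {
      warning("no valid ", cls, "-terminating triplets; class omitted")
      return(NULL)
    }
    data.frame(stop_class = cls, site = sites,
               numerator = num[cls, ], denominator = den[cls, ],
               frequency = ifelse(den[cls, ] > 0, num[cls, ] / den[cls, ], NA_real_),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  if (is.null(out)) stop("no triplet passed the quality filters")
  attr(out, "valid_genes") <- valid
  class(out) <- c("SubstitutionProfile", "data.frame")
  out
}

# characters at the given alignment columns, one window string per role
# (ingroup1, ingroup2, outgroup)
triplet_window <- function(tr, cols) {
  vapply(tr$seqs[c("ingroup1", "ingroup2", "outgroup")], function(s) {
    paste(strsplit(s, "", fixed = TRUE)[[1]][cols], collapse = "")
  }, character(1))
}
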
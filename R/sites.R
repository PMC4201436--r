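#' Site classification: noncoding, synonymous and nonsynonymous site weights
#'
#' Partitions alignment columns into noncoding, synonymous and nonsynonymous
#' site fractions, the partition behind the silent-site statistics
#' (theta at silent sites, pi at silent and nonsynonymous sites).
#'
#' Intronic (non-exon) columns get noncoding weight 1. Exonic columns are
#' classified codon-by-codon with Nei-Gojobori site counting on a reference
#' codon built from the majority base at each column (ties broken
#' alphabetically): the synonymous fraction of a codon position is the
#' fraction of its three possible single-base changes that preserve the amino
#' acid (changes creating a stop codon count as nonsynonymous). Columns
#' carrying `-` or `N` in any ingroup sequence are excluded from all site
#' counts (complete deletion); a codon containing an excluded column is
#' excluded entirely, as its remaining positions are not codon-resolvable.
#'
#' @param aln a [locus_alignment()].
#' @return an object of class `site_classes`: a list with per-column weight
#'   vectors `noncoding`, `synonymous`, `nonsynonymous`, a logical `excluded`
#'   vector, and totals `silent_sites` (noncoding + synonymous) and
#'   `nonsyn_sites`. Weights of each classified column sum to 1.
#' @export
classify_sites <- function(aln) {
  L <- aln$L
  excluded <- apply(aln$seqs, 2L, function(col) any(col %in% c("-", "N")))
  noncoding <- synonymous <- nonsynonymous <- numeric(L)
  coding_pos <- exon_positions(aln$exons)  # 1-based column indices, in frame
  is_coding <- logical(L)
  is_coding[coding_pos] <- TRUE
  noncoding[!is_coding & !excluded] <- 1
  if (length(coding_pos)) {
    ref <- majority_base(aln$seqs)
    codons <- matrix(coding_pos, nrow = 3L)
    for (ci in seq_len(ncol(codons))) {
      pos <- codons[, ci]
      if (any(excluded[pos])) {
        excluded[pos] <- TRUE
        next
      }
      fr <- ng_syn_fractions(ref[pos])
      synonymous[pos] <- fr
      nonsynonymous[pos] <- 1 - fr
    }
  }
  structure(list(
    noncoding = noncoding, synonymous = synonymous,
    nonsynonymous = nonsynonymous, excluded = excluded,
    silent_sites = sum(noncoding) + sum(synonymous[!excluded]),
    nonsyn_sites = sum(nonsynonymous[!excluded]),
    total_sites = sum(!excluded)), class = "site_classes")
}

#' @export
print.site_classes <- function(x, ...) {
  cat(sprintf("<site_classes> %d included sites: %.2f silent, %.2f nonsynonymous (%d excluded)\n",
              x$total_sites, x$silent_sites, x$nonsyn_sites, sum(x$excluded)))
  invisible(x)
}

# 1-based alignment columns covered by exons, in reading-frame order.
exon_positions <- function(exons) {
  if (is.null(exons) || nrow(exons) == 0L) return(integer(0))
  unlist(lapply(seq_len(nrow(exons)), function(i)
    seq.int(exons[i, 1L] + 1L, exons[i, 2L])))
}

# Majority base per column among ingroup sequences, ties alphabetical;
# gaps/N never win a majority vote on included columns by construction.
majority_base <- function(seqs) {
  apply(seqs, 2L, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    if (!length(col)) return("N")
    tab <- table(col)
    names(tab)[which.max(tab)]  # which.max takes the first (alphabetical) max
  })
}

codon_table_env <- new.env(parent = emptyenv())

# Standard genetic code lookup: codon string -> amino acid (stop = "*").
codon_aa <- function() {
  if (is.null(codon_table_env$tab)) {
    bases <- c("T", "C", "A", "G")
    aas <- strsplit(paste0(
      "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
      "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1L]]
    codons <- as.vector(vapply(bases, function(b1)
      vapply(bases, function(b2) paste0(b1, b2, bases), character(4L)),
      matrix("", 4L, 4L)))
    codon_table_env$tab <- setNames(aas, codons)
  }
  codon_table_env$tab
}

# Nei-Gojobori synonymous site fraction at each of the 3 codon positions:
# fraction of the 3 single-base changes at that position that keep the
# amino acid. Stop-codon targets count as nonsynonymous changes.
ng_syn_fractions <- function(codon) {
  tab <- codon_aa()
  ref_aa <- tab[[paste(codon, collapse = "")]]
  vapply(1:3, function(p) {
    alts <- setdiff(c("A", "C", "G", "T"), codon[p])
    syn <- vapply(alts, function(b) {
      mut <- codon
      mut[p] <- b
      identical(tab[[paste(mut, collapse = "")]], ref_aa)
    }, TRUE)
    sum(syn) / 3
  }, 0)
}

# Per-column weights for a named site class (total/silent/nonsynonymous);
# excluded columns have weight 0 in every class.
site_class_weights <- function(classes, site_filter) {
  w <- switch(site_filter,
    total = as.numeric(!classes$excluded),
    silent = classes$noncoding + ifelse(classes$excluded, 0,
                                        classes$synonymous),
    nonsynonymous = ifelse(classes$excluded, 0, classes$nonsynonymous),
    stop("unknown site class: ", site_filter, call. = FALSE))
  w[classes$excluded] <- 0
  w
}
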
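#' Phased multilocus alignment container
#'
#' A `locus_alignment` holds the phased allele sequences of diploid
#' individuals at one nuclear locus, together with its exon annotation and an
#' optional outgroup sequence. Sequences are stored as a character matrix of
#' single bases (`A`, `C`, `G`, `T`, `-`, `N`), one row per allele sequence;
#' every individual contributes exactly two rows (its two phased alleles).
#' Exon intervals are 0-based half-open `[start, end)` coordinates.
#'
#' @param locus_id single string naming the locus.
#' @param seqs character vector of nucleotide strings (all the same length),
#'   or a character matrix of single bases with one row per sequence.
#' @param individual character vector of individual ids, one per sequence.
#' @param allele integer vector of allele indices (1 or 2), one per sequence.
#' @param exons two-column matrix or data frame of exon `[start, end)`
#'   intervals (0-based, half-open), or `NULL` for a fully noncoding locus.
#' @param outgroup single nucleotide string of the same length, or `NULL`.
#'
#' @return An object of class `locus_alignment`.
#' @export
locus_alignment <- function(locus_id, seqs, individual, allele,
                            exons = NULL, outgroup = NULL) {
  if (is.character(seqs) && !is.matrix(seqs)) {
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- which(lens != lens[1L])[1L]
      stop(sprintf("locus %s: sequence %d (%s) has length %d, expected %d",
                   locus_id, bad, individual[bad], lens[bad], lens[1L]),
           call. = FALSE)
    }
    seqs <- do.call(rbind, strsplit(toupper(seqs), ""))
  }
  L <- ncol(seqs)
  n_seq <- nrow(seqs)
  if (length(individual) != n_seq || length(allele) != n_seq)
    stop("individual/allele labels must match the number of sequences",
         call. = FALSE)
  bad_base <- !(seqs %in% c("A", "C", "G", "T", "-", "N"))
  if (any(bad_base))
    stop(sprintf("locus %s: invalid base '%s'", locus_id,
                 seqs[which(bad_base)[1L]]), call. = FALSE)
  cnt <- table(individual)
  if (any(cnt != 2L)) {
    bad <- names(cnt)[cnt != 2L][1L]
    stop(sprintf("locus %s: individual '%s' contributes %d alleles, expected 2",
                 locus_id, bad, cnt[[bad]]), call. = FALSE)
  }
  exons <- normalize_exons(exons, L, locus_id)
  if (!is.null(outgroup)) {
    og <- strsplit(toupper(outgroup), "")[[1L]]
    if (length(og) != L)
      stop(sprintf("locus %s: outgroup length %d != alignment length %d",
                   locus_id, length(og), L), call. = FALSE)
    outgroup <- og
  }
  structure(
    list(locus_id = locus_id, seqs = seqs,
         individual = as.character(individual), allele = as.integer(allele),
         L = L, exons = exons, outgroup = outgroup),
    class = "locus_alignment")
}

normalize_exons <- function(exons, L, locus_id) {
  if (is.null(exons) || (is.data.frame(exons) && nrow(exons) == 0L))
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  exons <- as.matrix(as.data.frame(exons)[, 1:2])
  colnames(exons) <- c("start", "end")
  storage.mode(exons) <- "integer"
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 1L] < 0L) || any(exons[, 2L] > L) ||
      any(exons[, 2L] <= exons[, 1L]))
    stop(sprintf("locus %s: exon interval outside [0, %d)", locus_id, L),
         call. = FALSE)
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop(sprintf("locus %s: overlapping exon intervals", locus_id),
         call. = FALSE)
  if (sum(exons[, 2L] - exons[, 1L]) %% 3L != 0L)
    stop(sprintf("locus %s: total exon length not divisible by 3", locus_id),
         call. = FALSE)
  exons
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment> %s: %d bp, %d sequences (%d individuals), %d exon(s)%s\n",
              x$locus_id, x$L, nrow(x$seqs), length(unique(x$individual)),
              nrow(x$exons), if (is.null(x$outgroup)) "" else ", outgroup"))
  invisible(x)
}

#' Number of sequences in an alignment
#' @param aln a `locus_alignment`.
#' @return integer count of allele sequences.
#' @export
n_sequences <- function(aln) nrow(aln$seqs)

#' Read a phased locus alignment from FASTA
#'
#' FASTA headers must follow the convention `individualID|alleleN` with
#' `N` in `{1, 2}` (for example `>tree017|1`). The optional outgroup FASTA
#' holds a single sequence of the same length.
#'
#' @param path path to the ingroup FASTA.
#' @param annotation data frame of exon intervals with columns `start`, `end`
#'   (0-based half-open), e.g. one locus' rows of [read_exon_annotation()];
#'   `NULL` for a noncoding locus.
#' @param outgroup_path optional path to a single-record outgroup FASTA.
#' @param locus_id locus name; defaults to the file name without extension.
#' @return a validated [locus_alignment()].
#' @export
read_locus_fasta <- function(path, annotation = NULL, outgroup_path = NULL,
                             locus_id = NULL) {
  if (!file.exists(path)) stop("FASTA not found: ", path, call. = FALSE)
  recs <- read_fasta_file(path)
  parts <- strsplit(names(recs), "|", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("FASTA headers must follow 'individual|allele': ",
         names(recs)[lengths(parts) != 2L][1L], call. = FALSE)
  individual <- vapply(parts, `[[`, "", 1L)
  allele <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  if (anyNA(allele) || !all(allele %in% 1:2))
    stop("allele index in FASTA header must be 1 or 2", call. = FALSE)
  outgroup <- NULL
  if (!is.null(outgroup_path)) {
    og <- read_fasta_file(outgroup_path)
    if (length(og) != 1L)
      stop("outgroup FASTA must contain exactly one record", call. = FALSE)
    outgroup <- og[[1L]]
  }
  locus_id <- locus_id %||% sub("\\.[^.]*$", "", basename(path))
  if (!is.null(annotation) && "locus" %in% names(annotation))
    annotation <- annotation[annotation$locus == locus_id,
                             c("start", "end"), drop = FALSE]
  locus_alignment(locus_id, unname(recs), individual, allele,
                  exons = annotation, outgroup = outgroup)
}

# Minimal multi-line FASTA reader returning named character strings.
read_fasta_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA records in ", path, call. = FALSE)
  idx <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) paste(x, collapse = ""), "")
  names(seqs) <- sub("^>\\s*", "", lines[hdr])
  seqs
}

#' Write a locus alignment to FASTA
#'
#' Inverse of [read_locus_fasta()]; headers are `individual|allele`.
#'
#' @param aln a `locus_alignment`.
#' @param path output path for the ingroup FASTA.
#' @param outgroup_path optional output path for the outgroup record.
#' @return `path`, invisibly.
#' @export
write_locus_fasta <- function(aln, path, outgroup_path = NULL) {
  seqs <- apply(aln$seqs, 1L, paste, collapse = "")
  hdr <- paste0(">", aln$individual, "|", aln$allele)
  writeLines(as.vector(rbind(hdr, seqs)), path)
  if (!is.null(outgroup_path) && !is.null(aln$outgroup))
    writeLines(c(paste0(">", aln$locus_id, "_outgroup"),
                 paste(aln$outgroup, collapse = "")), outgroup_path)
  invisible(path)
}

#' Read the exon annotation table
#'
#' Tab-separated with header `locus`, `start`, `end`; coordinates 0-based
#' half-open.
#' @param path TSV path.
#' @return tibble with columns `locus`, `start`, `end`.
#' @export
read_exon_annotation <- function(path) {
  as_tibble(read.delim(path, colClasses = c("character", "integer", "integer")))
}

#' Population map: individual assignments and population coordinates
#'
#' @param assignments data frame with columns `individual`, `population`.
#' @param coordinates optional data frame with columns `population`, `lon`,
#'   `lat` (decimal degrees); may also carry a `region` column.
#' @return an object of class `population_map`.
#' @export
population_map <- function(assignments, coordinates = NULL) {
  assignments <- as_tibble(assignments)
  stopifnot(all(c("individual", "population") %in% names(assignments)))
  if (!is.null(coordinates)) {
    coordinates <- as_tibble(coordinates)
    stopifnot(all(c("population", "lon", "lat") %in% names(coordinates)))
    missing_pop <- setdiff(unique(assignments$population),
                           coordinates$population)
    if (length(missing_pop))
      stop("coordinates missing for population(s): ",
           paste(missing_pop, collapse = ", "), call. = FALSE)
  }
  structure(list(assignments = assignments, coordinates = coordinates),
            class = "population_map")
}

#' @export
print.population_map <- function(x, ...) {
  cat(sprintf("<population_map> %d individuals in %d populations%s\n",
              nrow(x$assignments), length(unique(x$assignments$population)),
              if (is.null(x$coordinates)) "" else " (with coordinates)"))
  invisible(x)
}

#' Read a population map (and optional coordinates) from TSV
#'
#' @param path TSV with header columns `individual`, `population`.
#' @param coords_path optional TSV with header `population`, `lon`, `lat`
#'   (and optionally `region`).
#' @return a [population_map()].
#' @export
read_population_map <- function(path, coords_path = NULL) {
  assignments <- read.delim(path, colClasses = "character")
  coords <- NULL
  if (!is.null(coords_path)) {
    coords <- read.delim(coords_path)
    coords$population <- as.character(coords$population)
  }
  population_map(assignments, coords)
}

#' Look up population labels for the sequences of an alignment
#' @param aln a `locus_alignment`.
#' @param pops a `population_map`.
#' @return character vector, one population per sequence row.
#' @export
sequence_populations <- function(aln, pops) {
  m <- match(aln$individual, pops$assignments$individual)
  if (anyNA(m))
    stop("individual(s) missing from population map: ",
         paste(unique(aln$individual[is.na(m)]), collapse = ", "),
         call. = FALSE)
  pops$assignments$population[m]
}

#' Chloroplast SSR repeat-count dataset
#'
#' Haploid multilocus microsatellite genotypes: one repeat count per
#' individual per locus. The multilocus haplotype of an individual is the
#' tuple of its repeat counts across loci.
#'
#' @param repeats integer matrix of repeat counts, individuals in rows
#'   (rownames required), SSR loci in columns.
#' @return an object of class `ssr_dataset`.
#' @export
ssr_dataset <- function(repeats) {
  repeats <- as.matrix(repeats)
  storage.mode(repeats) <- "integer"
  if (is.null(rownames(repeats)))
    stop("repeat matrix needs individual ids as rownames", call. = FALSE)
  if (is.null(colnames(repeats)))
    colnames(repeats) <- paste0("ssr", seq_len(ncol(repeats)))
  if (anyNA(repeats) || any(repeats < 1L))
    stop("repeat counts must be integers >= 1", call. = FALSE)
  structure(list(repeats = repeats), class = "ssr_dataset")
}

#' @export
print.ssr_dataset <- function(x, ...) {
  cat(sprintf("<ssr_dataset> %d individuals x %d loci, %d multilocus haplotypes\n",
              nrow(x$repeats), ncol(x$repeats),
              length(unique(ssr_haplotypes(x)))))
  invisible(x)
}

#' Multilocus haplotype labels of an SSR dataset
#' @param ssr an `ssr_dataset`.
#' @return character vector (one label per individual) encoding the tuple of
#'   repeat counts across loci.
#' @export
ssr_haplotypes <- function(ssr) {
  apply(ssr$repeats, 1L, paste, collapse = "-")
}

#' Read an SSR repeat-count table from CSV
#'
#' Long format with header `individual`, `locus`, `repeats`.
#' @param path CSV path.
#' @return an [ssr_dataset()].
#' @export
read_ssr_table <- function(path) {
  d <- read.csv(path, colClasses = c("character", "character", "integer"))
  wide <- tidyr::pivot_wider(as_tibble(d), names_from = "locus",
                             values_from = "repeats")
  m <- as.matrix(wide[, -1L])
  rownames(m) <- wide$individual
  ssr_dataset(m)
}

#' Write an SSR dataset to long-format CSV
#' @param ssr an `ssr_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ssr_table <- function(ssr, path) {
  d <- expand.grid(individual = rownames(ssr$repeats),
                   locus = colnames(ssr$repeats),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$repeats <- ssr$repeats[cbind(d$individual, d$locus)]
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Concatenate loci sharing an individual set into one alignment
#'
#' Alleles are joined individual-by-individual (allele 1 with allele 1);
#' exon intervals are offset by the cumulative lengths of preceding loci.
#' Outgroups are concatenated when every locus has one.
#'
#' @param alns list of `locus_alignment` objects over identical individuals.
#' @param locus_id name for the combined alignment.
#' @return a `locus_alignment` of length `sum(L_i)`.
#' @export
concatenate_loci <- function(alns, locus_id = "concatenated") {
  stopifnot(length(alns) >= 1L)
  if (length(alns) == 1L) return(alns[[1L]])
  ref <- sort(unique(alns[[1L]]$individual))
  for (a in alns) {
    miss <- setdiff(ref, unique(a$individual))
    extra <- setdiff(unique(a$individual), ref)
    if (length(miss) || length(extra))
      stop(sprintf("locus %s: individual set differs (missing: %s; extra: %s)",
                   a$locus_id, paste(miss, collapse = ","),
                   paste(extra, collapse = ",")), call. = FALSE)
  }
  key <- function(a) order(a$individual, a$allele)
  ord <- lapply(alns, key)
  seqs <- do.call(cbind, lapply(seq_along(alns), function(i)
    alns[[i]]$seqs[ord[[i]], , drop = FALSE]))
  offsets <- c(0L, cumsum(vapply(alns, function(a) a$L, 0L)))
  exons <- do.call(rbind, lapply(seq_along(alns), function(i) {
    e <- alns[[i]]$exons
    if (nrow(e)) e + offsets[i] else e
  }))
  outgroup <- NULL
  if (all(vapply(alns, function(a) !is.null(a$outgroup), TRUE)))
    outgroup <- paste(unlist(lapply(alns, `[[`, "outgroup")), collapse = "")
  a1 <- alns[[1L]]
  locus_alignment(locus_id, seqs,
                  individual = a1$individual[ord[[1L]]],
                  allele = a1$allele[ord[[1L]]],
                  exons = exons, outgroup = outgroup)
}
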
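# Study-shaped synthetic data: 10 nuclear loci (494-1252 bp, 8950 bp total,
# roughly half coding) for 57 diploid individuals in 6 populations of sizes
# 9/13/12/3/10/10 across 3 regions, an outgroup ~0.02 subs/site diverged,
# and 7 chloroplast SSR loci. The default demographic model is exponential
# growth at posterior-mode parameter values representative of the study
# system (theta/site 0.0299, rho/site 0.0424, N1_rel 0.0318, T0 8.593e-4),
# which yields present-day diversity in the observed range
# (theta_w ~ 0.0014).

study_locus_lengths <- function() {
  c(494L, 612L, 738L, 1252L, 810L, 876L, 948L, 1020L, 1120L, 1080L)
}

study_population_sizes <- function() {
  stats::setNames(c(9L, 13L, 12L, 3L, 10L, 10L), paste0("P", 1:6))
}

study_coordinates <- function() {
  tibble(population = paste0("P", 1:6),
         lon = c(108.6843, 108.7015, 108.6893, 108.4095, 108.4667, 108.6854),
         lat = c(12.1758, 12.1756, 12.1938, 12.0910, 11.9488, 12.0475),
         region = c("DaChay", "DaChay", "DaChay", "CongTroi", "CongTroi",
                    "Bidoup"))
}

#' Default demographic model of the synthetic study
#'
#' Exponential growth out of a severely reduced ancestral population
#' (3% of present size) beginning about 9e-4 coalescent time units ago --
#' the regime in which present-day samples show very low diversity with a
#' mild excess of rare variants.
#'
#' @return a [demographic_model()].
#' @export
study_model <- function() {
  demographic_model("GROWTH", theta_site = 0.0299, rho_site = 0.0424,
                    N1_rel = 0.0318, T0 = 8.593e-4)
}

# Exon block per locus: one centered interval of ~51.5% of the locus
# (the coding fraction of the emulated concatenate), length a multiple of 3.
study_exons <- function(L) {
  e <- 3L * round(0.515 * L / 3)
  start <- as.integer((L - e) %/% 2)
  cbind(start = start, end = start + e)
}

#' Generate a study-shaped synthetic sequence dataset
#'
#' Simulates a species-level coalescent sample under `model`, thins it into
#' six populations with a copy-with-probability `fst_target` scheme (within
#' each population, every chromosome after the first is a copy of an
#' earlier same-population chromosome with probability `phi = fst_target`,
#' which makes the expected multilocus AMOVA F_ST equal the target), maps
#' 0/1 haplotypes onto nucleotide sequences over a random ancestral
#' sequence, enforces a 4:1 silent:nonsynonymous acceptance filter inside
#' exons (nonsynonymous mutations are retained with probability 1/4), and
#' adds an outgroup by placing extra divergence mutations on the ancestral
#' sequence.
#'
#' @param model a [demographic_model()]; defaults to [study_model()].
#' @param fst_target target multilocus F_ST in `[0, 0.5)`.
#' @param seed RNG seed; the fixture is bit-for-bit reproducible from it.
#' @param divergence outgroup divergence in substitutions per site.
#' @param pop_sizes named integer vector of individuals per population.
#' @param locus_lengths integer vector of locus lengths (bp).
#' @return a list of class `study_fixture`: `loci` (list of
#'   [locus_alignment()]), `popmap` (a [population_map()] with region
#'   coordinates), and a `truth` record (model, targets, seed).
#' @export
generate_sequence_study <- function(model = study_model(),
                                    fst_target = 0.05, seed = 1,
                                    divergence = 0.02,
                                    pop_sizes = study_population_sizes(),
                                    locus_lengths = study_locus_lengths()) {
  if (fst_target < 0 || fst_target >= 0.5)
    stop("fst_target must be in [0, 0.5)", call. = FALSE)
  n_ind <- sum(pop_sizes)
  n_chr <- 2L * n_ind
  ind_ids <- sprintf("I%02d", seq_len(n_ind))
  pop_of_ind <- rep(names(pop_sizes), pop_sizes)
  pop_of_chr <- rep(pop_of_ind, each = 2L)
  with_seed(seed, {
    loci <- lapply(seq_along(locus_lengths), function(li) {
      L <- locus_lengths[li]
      exons <- study_exons(L)
      # each locus draws its own urn: genealogies are independent across
      # loci even though the population structure is shared
      sel <- thin_into_populations(n_chr, pop_of_chr, fst_target)
      build_locus(sprintf("locus%02d", li), L, exons, model, n_chr, sel,
                  ind_ids, divergence)
    })
    coords <- study_coordinates()
    coords <- coords[coords$population %in% names(pop_sizes), , drop = FALSE]
    popmap <- population_map(
      tibble(individual = ind_ids, population = pop_of_ind), coords)
    structure(list(
      loci = loci, popmap = popmap,
      truth = list(model = model, fst_target = fst_target, seed = seed,
                   divergence = divergence, pop_sizes = pop_sizes,
                   locus_lengths = locus_lengths)),
      class = "study_fixture")
  })
}

# Hoppe-urn thinning: within each population, chromosome j copies a
# uniformly chosen earlier chromosome with probability (j-1)/(beta+j-1) and
# otherwise takes a fresh chromosome from the panmictic pool, with
# beta = (1-phi)/phi. Any two chromosomes of a population are then copies of
# the same pool chromosome with probability exactly phi, which makes the
# expected within-population diversity (1-phi) times the pool diversity and
# the expected F_ST equal the target.
thin_into_populations <- function(n_chr, pop_of_chr, phi) {
  sel <- integer(n_chr)
  next_fresh <- 1L
  beta <- if (phi > 0) (1 - phi) / phi else Inf
  for (p in unique(pop_of_chr)) {
    idx <- which(pop_of_chr == p)
    for (j in seq_along(idx)) {
      if (j > 1L && is.finite(beta) &&
          runif(1) < (j - 1) / (beta + j - 1)) {
        sel[idx[j]] <- sel[idx[sample.int(j - 1L, 1L)]]
      } else {
        sel[idx[j]] <- next_fresh
        next_fresh <- next_fresh + 1L
      }
    }
  }
  sel
}

build_locus <- function(locus_id, L, exons, model, n_chr, sel, ind_ids,
                        divergence) {
  sim <- simulate_locus(model, n_chr, L)
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  hap <- sim$haplotypes
  cols <- assign_columns(sim$positions, L)
  keep <- !is.na(cols)
  hap <- hap[, keep, drop = FALSE]
  cols <- cols[keep]
  # derived bases and the 4:1 silent:nonsynonymous acceptance filter
  exon_cols <- exon_positions(exons)
  frame_of <- integer(L)
  frame_of[exon_cols] <- rep_len(1:3, length(exon_cols))
  codon_start <- integer(L)
  codon_start[exon_cols] <- exon_cols[3 * ((seq_along(exon_cols) - 1L) %/% 3L) + 1L]
  derived <- character(length(cols))
  keep2 <- logical(length(cols))
  aa <- codon_aa()
  for (k in seq_along(cols)) {
    j <- cols[k]
    derived[k] <- sample(setdiff(c("A", "C", "G", "T"), anc[j]), 1L)
    if (frame_of[j] == 0L) { keep2[k] <- TRUE; next }
    cs <- codon_start[j]
    codon <- anc[cs:(cs + 2L)]
    mut <- codon
    mut[frame_of[j]] <- derived[k]
    syn <- identical(aa[[paste(codon, collapse = "")]],
                     aa[[paste(mut, collapse = "")]])
    keep2[k] <- syn || runif(1) < 0.25
  }
  hap <- hap[, keep2, drop = FALSE]
  cols <- cols[keep2]
  derived <- derived[keep2]
  # thinned sample sequences
  seqs <- matrix(rep(anc, each = n_chr), n_chr, L)
  for (k in seq_along(cols))
    seqs[hap[sel, k] == 1L, cols[k]] <- derived[k]
  # outgroup: ancestral plus divergence-branch mutations
  og <- anc
  n_div <- rpois(1L, divergence * L)
  if (n_div > 0) {
    pos <- sample.int(L, min(n_div, L))
    for (j in pos) og[j] <- sample(setdiff(c("A", "C", "G", "T"), og[j]), 1L)
  }
  locus_alignment(locus_id, seqs,
                  individual = rep(ind_ids, each = 2L),
                  allele = rep(1:2, length(ind_ids)),
                  exons = exons, outgroup = paste(og, collapse = ""))
}

# Map relative positions to distinct integer columns in [1, L]; collisions
# are nudged to the next free column, overflowing mutations dropped (NA).
assign_columns <- function(pos, L) {
  if (!length(pos)) return(integer(0))
  target <- floor(pos * L) + 1L
  used <- logical(L)
  out <- rep(NA_integer_, length(pos))
  for (k in order(target)) {
    j <- target[k]
    while (j <= L && used[j]) j <- j + 1L
    if (j <= L) { used[j] <- TRUE; out[k] <- j }
  }
  out
}

#' Generate a study-shaped synthetic chloroplast SSR dataset
#'
#' Simulates 7 haploid SSR loci on a shared genealogy with a stepwise
#' mutation rate tuned so that per-locus allele counts fall mostly in 3-4
#' (about 80% of loci) and the combined multilocus haplotype diversity sits
#' near 0.9, the regime observed in the study system. The default genealogy
#' is a post-expansion trajectory (ancestral size 5% of present, growth
#' starting 0.8 coalescent units ago), which concentrates allele counts the
#' way the chloroplast data show.
#'
#' @param model a [demographic_model()] (size trajectory only).
#' @param seed RNG seed.
#' @param n number of haploid individuals.
#' @param n_loci number of SSR loci.
#' @param theta_ssr per-locus scaled repeat mutation rate.
#' @param individuals optional individual ids.
#' @return an [ssr_dataset()].
#' @export
generate_ssr_study <- function(model = demographic_model("GROWTH", 0.001,
                                                         N1_rel = 0.05,
                                                         T0 = 0.8),
                               seed = 1, n = 57, n_loci = 7,
                               theta_ssr = 1.8, individuals = NULL) {
  individuals <- individuals %||% sprintf("I%02d", seq_len(n))
  simulate_ssr(model, n, n_loci, theta_ssr, seed = seed,
               individuals = individuals)
}

#' @export
print.study_fixture <- function(x, ...) {
  cat(sprintf("<study_fixture> %d loci (%d bp), %d individuals, %d populations (seed %s)\n",
              length(x$loci), sum(vapply(x$loci, function(a) a$L, 0L)),
              length(unique(x$loci[[1L]]$individual)),
              length(unique(x$popmap$assignments$population)),
              format(x$truth$seed)))
  invisible(x)
}

#' Write a study fixture to disk in the package's input formats
#'
#' Produces per-locus FASTA (plus outgroup FASTA), the exon-annotation TSV,
#' the population-map and coordinate TSVs, and a JSON manifest holding the
#' truth record, so the fixture can be read back with the `read_*`
#' functions.
#'
#' @param fixture a [generate_sequence_study()] result.
#' @param dir output directory (created if missing).
#' @param ssr optional [ssr_dataset()] to write alongside.
#' @return `dir`, invisibly.
#' @export
write_study_fixture <- function(fixture, dir, ssr = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  exon_rows <- list()
  for (aln in fixture$loci) {
    write_locus_fasta(aln, file.path(dir, paste0(aln$locus_id, ".fasta")),
                      file.path(dir, paste0(aln$locus_id, "_outgroup.fasta")))
    if (nrow(aln$exons))
      exon_rows[[aln$locus_id]] <- tibble(locus = aln$locus_id,
                                          start = aln$exons[, 1L],
                                          end = aln$exons[, 2L])
  }
  utils::write.table(dplyr::bind_rows(exon_rows),
                     file.path(dir, "exons.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(fixture$popmap$assignments,
                     file.path(dir, "populations.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(fixture$popmap$coordinates,
                     file.path(dir, "coordinates.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(ssr)) write_ssr_table(ssr, file.path(dir, "cpssr.csv"))
  truth <- fixture$truth
  truth$model <- unclass(truth$model)
  jsonlite::write_json(truth, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a study fixture back from disk
#'
#' @param dir directory written by [write_study_fixture()].
#' @return list with `loci`, `popmap` and (when present) `ssr`.
#' @export
read_study_fixture <- function(dir) {
  ann <- read_exon_annotation(file.path(dir, "exons.tsv"))
  fastas <- sort(list.files(dir, "^locus[0-9]+\\.fasta$", full.names = TRUE))
  loci <- lapply(fastas, function(f) {
    id <- sub("\\.fasta$", "", basename(f))
    read_locus_fasta(f, annotation = ann,
                     outgroup_path = file.path(dir, paste0(id, "_outgroup.fasta")),
                     locus_id = id)
  })
  popmap <- read_population_map(file.path(dir, "populations.tsv"),
                                file.path(dir, "coordinates.tsv"))
  ssr_path <- file.path(dir, "cpssr.csv")
  list(loci = loci, popmap = popmap,
       ssr = if (file.exists(ssr_path)) read_ssr_table(ssr_path) else NULL)
}
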
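#' Number of segregating sites
#'
#' Counts included alignment columns carrying at least two distinct bases
#' among the ingroup sequences. Columns with a gap or `N` in any sequence are
#' excluded (complete deletion). With a `site_filter`, the count is the sum
#' of that class's fractional site weights over segregating columns, the
#' quantity entering the silent-site Watterson estimator.
#'
#' @param aln a [locus_alignment()].
#' @param site_filter `NULL` (all included sites) or one of `"total"`,
#'   `"silent"`, `"nonsynonymous"`.
#' @param classes optional precomputed [classify_sites()] result.
#' @return numeric count (fractional when a class filter is applied).
#' @export
segregating_sites <- function(aln, site_filter = NULL, classes = NULL) {
  if (nrow(aln$seqs) < 2L)
    stop("segregating sites need at least 2 sequences", call. = FALSE)
  classes <- classes %||% classify_sites(aln)
  seg <- apply(aln$seqs, 2L, function(col) {
    length(unique(col[col %in% c("A", "C", "G", "T")])) >= 2L
  }) & !classes$excluded
  if (is.null(site_filter)) return(sum(seg))
  sum(site_class_weights(classes, site_filter)[seg])
}

#' Watterson's estimator of the population mutation rate
#'
#' `theta_w = S / (a_n * sites)` per site, with
#' `a_n = sum_{i=1}^{n-1} 1/i`.
#'
#' @param S number of segregating sites (may be fractional for a site class).
#' @param n number of sequences sampled.
#' @param sites effective number of sites examined.
#' @return per-site estimate of theta.
#' @export
watterson_theta <- function(S, n, sites) {
  stopifnot(n >= 2, S >= 0)
  if (sites <= 0) stop("effective site count must be positive", call. = FALSE)
  S / (harmonic_number(n - 1) * sites)
}

harmonic_number <- function(m) sum(1 / seq_len(m))
harmonic_number2 <- function(m) sum(1 / seq_len(m)^2)

#' Nucleotide diversity (pi)
#'
#' Mean pairwise difference count over all unordered sequence pairs, divided
#' by the effective site count of the requested class. Differences at a
#' column contribute that column's class weight (1 for noncoding and total;
#' the Nei-Gojobori synonymous/nonsynonymous fraction for coding columns),
#' and the denominator is the summed class weight.
#'
#' @inheritParams segregating_sites
#' @param sites site class: `"total"`, `"silent"` or `"nonsynonymous"`.
#' @return per-site diversity, or `NA` when the class has zero sites.
#' @export
nucleotide_diversity <- function(aln, sites = "total", classes = NULL) {
  if (nrow(aln$seqs) < 2L)
    stop("nucleotide diversity needs at least 2 sequences", call. = FALSE)
  classes <- classes %||% classify_sites(aln)
  w <- site_class_weights(classes, sites)
  denom <- sum(w)
  if (denom <= 0) return(NA_real_)
  mean_pairwise_weighted(aln$seqs, w) / denom
}

# Mean over unordered pairs of the weighted difference count.
mean_pairwise_weighted <- function(seqs, w) {
  n <- nrow(seqs)
  active <- which(w > 0)
  tot <- 0
  for (j in active) {
    col <- seqs[, j]
    tab <- table(col)
    same <- sum(choose(tab, 2))
    diffs <- choose(n, 2) - same
    tot <- tot + w[j] * diffs
  }
  tot / choose(n, 2)
}

# Locus-scale pi (mean pairwise differences over included columns).
pi_locus_scale <- function(aln, classes = NULL) {
  classes <- classes %||% classify_sites(aln)
  mean_pairwise_weighted(aln$seqs, as.numeric(!classes$excluded))
}

#' Haplotype count and unbiased haplotype diversity
#'
#' `H_e = n/(n-1) * (1 - sum p_i^2)`, the unbiased gene-diversity estimator,
#' over any collection of hashable items (multilocus SSR haplotypes,
#' sequence haplotypes, ...).
#'
#' @param x vector or list of items; identical items form one haplotype.
#' @return a one-row tibble with `n`, `n_h` (distinct haplotypes) and `H_e`.
#' @export
haplotype_summary <- function(x) {
  if (is.list(x)) x <- vapply(x, function(e) paste(e, collapse = "\r"), "")
  n <- length(x)
  if (n < 2L) stop("haplotype diversity needs n >= 2", call. = FALSE)
  p <- as.numeric(table(x)) / n
  tibble(n = n, n_h = length(p), H_e = n / (n - 1) * (1 - sum(p^2)))
}

# Allele (full-locus haplotype) strings per sequence, on included columns.
allele_strings <- function(aln, classes = NULL) {
  classes <- classes %||% classify_sites(aln)
  keep <- !classes$excluded
  apply(aln$seqs[, keep, drop = FALSE], 1L, paste, collapse = "")
}

#' Multilocus inbreeding coefficient F_IS
#'
#' For each polymorphic locus-by-population cell, `F_IS = 1 - H_obs/H_exp`,
#' where `H_obs` is the fraction of heterozygous individuals (two phased
#' allele sequences differing on included columns) and `H_exp` the unbiased
#' within-population expected heterozygosity over alleles; alleles are the
#' distinct full-locus haplotypes. Cells are averaged over polymorphic loci
#' within each population, then over populations.
#'
#' @param alns list of [locus_alignment()] objects.
#' @param pops a [population_map()].
#' @return single F_IS estimate, or `NA` when no polymorphic cell exists.
#' @export
fis_estimate <- function(alns, pops) {
  per_pop <- list()
  for (aln in alns) {
    pop <- sequence_populations(aln, pops)
    alleles <- allele_strings(aln)
    for (p in unique(pop)) {
      idx <- which(pop == p)
      a <- alleles[idx]
      if (length(unique(a)) < 2L) next  # monomorphic cell
      ind <- aln$individual[idx]
      het <- vapply(unique(ind), function(i) {
        pair <- a[ind == i]
        pair[1L] != pair[2L]
      }, TRUE)
      n_al <- length(a)
      freq <- as.numeric(table(a)) / n_al
      h_exp <- n_al / (n_al - 1) * (1 - sum(freq^2))
      per_pop[[p]] <- c(per_pop[[p]], 1 - mean(het) / h_exp)
    }
  }
  if (!length(per_pop)) return(NA_real_)
  mean(vapply(per_pop, mean, 0))
}

#' Per-locus diversity statistics table
#'
#' One row per locus and grouping (each population, each region when the map
#' carries one, and the total sample), mirroring a classical multilocus
#' diversity table: S, theta_w (total), theta_ws (silent), pi at total,
#' silent and nonsynonymous sites, haplotype count and diversity.
#'
#' @param alns list of [locus_alignment()] objects.
#' @param pops a [population_map()]; regions are read from a `region` column
#'   of its coordinates table when present.
#' @return a tibble, one row per locus x grouping.
#' @export
diversity_table <- function(alns, pops) {
  groups <- list(total = unique(pops$assignments$individual))
  for (p in unique(pops$assignments$population))
    groups[[p]] <- pops$assignments$individual[
      pops$assignments$population == p]
  if (!is.null(pops$coordinates) && "region" %in% names(pops$coordinates)) {
    coor <- pops$coordinates
    for (r in unique(coor$region)) {
      in_region <- pops$assignments$population %in%
        coor$population[coor$region == r]
      groups[[paste0("region:", r)]] <- pops$assignments$individual[in_region]
    }
  }
  rows <- list()
  for (aln in alns) {
    classes <- classify_sites(aln)
    for (g in names(groups)) {
      sub <- subset_alignment(aln, groups[[g]])
      if (nrow(sub$seqs) < 2L) next
      n <- nrow(sub$seqs)
      S <- segregating_sites(sub, classes = classes)
      S_sil <- segregating_sites(sub, "silent", classes = classes)
      hap <- haplotype_summary(allele_strings(sub, classes))
      rows[[length(rows) + 1L]] <- tibble(
        locus = aln$locus_id, group = g, n_individuals = n / 2L, S = S,
        theta_w = watterson_theta(S, n, classes$total_sites),
        theta_ws = watterson_theta(S_sil, n, classes$silent_sites),
        pi_t = nucleotide_diversity(sub, "total", classes),
        pi_s = nucleotide_diversity(sub, "silent", classes),
        pi_a = nucleotide_diversity(sub, "nonsynonymous", classes),
        n_h = hap$n_h, H_e = hap$H_e)
    }
  }
  dplyr::bind_rows(rows)
}

#' Restrict an alignment to a set of individuals
#' @param aln a `locus_alignment`.
#' @param individuals character vector of individual ids to keep.
#' @return a `locus_alignment` over the selected individuals.
#' @export
subset_alignment <- function(aln, individuals) {
  keep <- aln$individual %in% individuals
  locus_alignment(aln$locus_id, aln$seqs[keep, , drop = FALSE],
                  aln$individual[keep], aln$allele[keep],
                  exons = aln$exons,
                  outgroup = if (is.null(aln$outgroup)) NULL else
                    paste(aln$outgroup, collapse = ""))
}

#' Across-locus averages of a diversity table
#'
#' Site-weighted (default) or arithmetic averaging of the per-site rates
#' across loci, within each grouping.
#'
#' @param div result of [diversity_table()].
#' @param alns the alignments the table was computed from (for site weights).
#' @param weighting `"site"` (weight loci by effective site counts) or
#'   `"arithmetic"`.
#' @return a tibble, one row per grouping.
#' @export
diversity_averages <- function(div, alns, weighting = c("site", "arithmetic")) {
  weighting <- match.arg(weighting)
  cls <- lapply(alns, classify_sites)
  names(cls) <- vapply(alns, function(a) a$locus_id, "")
  wt <- function(locus, kind) {
    i <- match(locus, names(cls))
    switch(kind,
           total = vapply(cls[i], function(x) x$total_sites, 0),
           silent = vapply(cls[i], function(x) x$silent_sites, 0),
           nonsyn = vapply(cls[i], function(x) x$nonsyn_sites, 0))
  }
  avg <- function(x, w) {
    ok <- !is.na(x)
    if (!any(ok)) return(NA_real_)
    if (weighting == "arithmetic") mean(x[ok])
    else weighted.mean(x[ok], w[ok])
  }
  dplyr::summarise(
    dplyr::group_by(div, .data$group),
    n_individuals = max(.data$n_individuals),
    S = sum(.data$S),
    theta_w = avg(.data$theta_w, wt(.data$locus, "total")),
    theta_ws = avg(.data$theta_ws, wt(.data$locus, "silent")),
    pi_t = avg(.data$pi_t, wt(.data$locus, "total")),
    pi_s = avg(.data$pi_s, wt(.data$locus, "silent")),
    pi_a = avg(.data$pi_a, wt(.data$locus, "nonsyn")),
    n_h = sum(.data$n_h),
    H_e = mean(.data$H_e),
    .groups = "drop")
}
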
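#' Pairwise linkage disequilibrium (r-squared) between informative sites
#'
#' Informative sites are biallelic included columns whose minor allele is
#' carried by at least `min_minor_copies` chromosomes. For every within-locus
#' pair, `r^2 = D^2 / (pA pa pB pb)` from the phased haplotype counts, with a
#' two-sided Fisher exact p from the 2x2 haplotype table. The Bonferroni
#' flag compares `fisher_p` to `0.05 / n_family`; the family defaults to the
#' pairs of this call but should span all loci when several are scanned
#' (see [ld_pairs()]).
#'
#' @param aln a [locus_alignment()].
#' @param min_minor_copies informativeness threshold (minor-allele copies).
#' @param n_family size of the Bonferroni family; `NULL` = pairs of this call.
#' @return a tibble with columns `locus`, `site_i`, `site_j` (0-based
#'   alignment columns), `distance` (bp), `r2`, `fisher_p`,
#'   `significant_after_bonferroni`. Zero rows when < 2 informative sites.
#' @export
pairwise_r2 <- function(aln, min_minor_copies = 2, n_family = NULL) {
  n <- nrow(aln$seqs)
  classes <- classify_sites(aln)
  info <- informative_sites(aln, min_minor_copies, classes)
  if (length(info$cols) < 2L)
    return(tibble(locus = character(0), site_i = integer(0),
                  site_j = integer(0), distance = integer(0),
                  r2 = numeric(0), fisher_p = numeric(0),
                  significant_after_bonferroni = logical(0)))
  pairs <- combn(seq_along(info$cols), 2L)
  res <- apply(pairs, 2L, function(ij) {
    x <- info$minor[, ij[1L]]
    y <- info$minor[, ij[2L]]
    nAB <- sum(x & y)
    pA <- mean(x); pB <- mean(y)
    D <- nAB / n - pA * pB
    r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
    tab <- table(factor(x, c(FALSE, TRUE)), factor(y, c(FALSE, TRUE)))
    c(r2 = r2, p = fisher.test(tab)$p.value)
  })
  out <- tibble(
    locus = aln$locus_id,
    site_i = info$cols[pairs[1L, ]] - 1L,
    site_j = info$cols[pairs[2L, ]] - 1L,
    r2 = unname(res["r2", ]), fisher_p = unname(res["p", ]))
  out$distance <- out$site_j - out$site_i
  fam <- n_family %||% nrow(out)
  out$significant_after_bonferroni <- out$fisher_p < 0.05 / fam
  out[, c("locus", "site_i", "site_j", "distance", "r2", "fisher_p",
          "significant_after_bonferroni")]
}

# Biallelic included columns with minor-allele count >= threshold; returns
# column indices and the minor-allele indicator matrix.
informative_sites <- function(aln, min_minor_copies, classes = NULL) {
  classes <- classes %||% classify_sites(aln)
  n <- nrow(aln$seqs)
  cols <- integer(0)
  minor <- NULL
  for (j in which(!classes$excluded)) {
    tab <- table(aln$seqs[, j])
    if (length(tab) != 2L) next
    if (min(tab) < min_minor_copies) next
    cols <- c(cols, j)
    minor_base <- names(tab)[which.min(tab)]
    minor <- cbind(minor, aln$seqs[, j] == minor_base)
  }
  list(cols = cols, minor = minor)
}

#' LD scan across several loci with a shared Bonferroni family
#'
#' @param alns list of [locus_alignment()] objects.
#' @param min_minor_copies informativeness threshold.
#' @return tibble of all within-locus pairs; the Bonferroni family is the
#'   total number of tested pairs across loci.
#' @export
ld_pairs <- function(alns, min_minor_copies = 2) {
  parts <- lapply(alns, pairwise_r2, min_minor_copies = min_minor_copies)
  out <- dplyr::bind_rows(parts)
  if (nrow(out))
    out$significant_after_bonferroni <- out$fisher_p < 0.05 / nrow(out)
  out
}

#' Kelly's ZnS
#'
#' Mean `r^2` over all unordered pairs of (biallelic) segregating sites,
#' with no informativeness filter -- the form used as an ABC summary
#' statistic. With fewer than two segregating sites the statistic is
#' defined as 0 and flagged (attribute `missing`), so multilocus summary
#' vectors stay complete for low-diversity loci.
#'
#' @param aln a [locus_alignment()].
#' @return the ZnS value (attribute `missing` = TRUE when defaulted to 0).
#' @export
kelly_zns <- function(aln) {
  info <- informative_sites(aln, min_minor_copies = 1)
  if (length(info$cols) < 2L)
    return(structure(0, missing = TRUE))
  m <- info$minor * 1L
  structure(zns_matrix(m), missing = FALSE)
}

# Hill-Weir (1988) drift-recombination expectation of r^2 with the
# low-order sample-size correction used for decay regressions
# (Remington et al. 2001 form), C = 4Nc x distance.
hill_weir_expectation <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the decay of LD with physical distance
#'
#' Nonlinear least squares of observed pairwise `r^2` on distance under the
#' Hill-Weir drift-recombination expectation with sample-size correction,
#' with a single free parameter `C_per_bp` (the population recombination
#' rate scale): `C = C_per_bp * distance`. Fitted by bounded scalar
#' minimization of the residual sum of squares on a log grid plus local
#' refinement.
#'
#' @param pairs tibble from [pairwise_r2()] or [ld_pairs()] (columns
#'   `distance`, `r2`), typically pooled across loci.
#' @param n number of chromosomes sampled.
#' @return an object of class `ld_decay_fit` with elements `C_per_bp`,
#'   `n_eff`, `residual_ss`, `n_pairs` and the data used.
#' @export
ld_decay_fit <- function(pairs, n) {
  d <- pairs$distance
  r2 <- pairs$r2
  if (length(d) < 10L)
    stop("decay fit needs at least 10 pairs", call. = FALSE)
  if (length(unique(d)) < 2L)
    stop("decay fit needs at least 2 distinct distances", call. = FALSE)
  ss <- function(c_bp) sum((r2 - hill_weir_expectation(c_bp * d, n))^2)
  # log-spaced coarse grid, then refinement around the best cell
  grid <- c(0, 10^seq(-7, 1, length.out = 81))
  vals <- vapply(grid, ss, 0)
  best <- which.min(vals)
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(length(grid), best + 1L)]
  if (hi <= lo) hi <- lo + 1e-7
  opt <- optimize(ss, c(lo, hi), tol = 1e-12)
  c_hat <- if (opt$objective <= vals[best]) opt$minimum else grid[best]
  if (c_hat <= 1e-9) {
    warning("no decay signal: C_per_bp at the zero boundary", call. = FALSE)
    c_hat <- 0
  }
  structure(list(C_per_bp = c_hat, n_eff = n, residual_ss = ss(c_hat),
                 n_pairs = length(d),
                 data = tibble(distance = d, r2 = r2)),
            class = "ld_decay_fit")
}

#' @export
print.ld_decay_fit <- function(x, ...) {
  cat(sprintf("<ld_decay_fit> C_per_bp = %.6g (n = %d, %d pairs, RSS = %.4g)\n",
              x$C_per_bp, x$n_eff, x$n_pairs, x$residual_ss))
  invisible(x)
}

#' @export
#' @method tidy ld_decay_fit
tidy.ld_decay_fit <- function(x, ...) {
  tibble(term = "C_per_bp", estimate = x$C_per_bp)
}

#' @export
#' @method glance ld_decay_fit
glance.ld_decay_fit <- function(x, ...) {
  tibble(C_per_bp = x$C_per_bp, n_eff = x$n_eff,
         residual_ss = x$residual_ss, n_pairs = x$n_pairs)
}

#' Expected decay curve of a fitted LD model
#' @param fit an `ld_decay_fit`.
#' @param distances bp values at which to evaluate the curve.
#' @return tibble with `distance` and `expected_r2`.
#' @export
ld_decay_curve <- function(fit, distances = NULL) {
  distances <- distances %||%
    seq(1, max(fit$data$distance), length.out = 200)
  tibble(distance = distances,
         expected_r2 = hill_weir_expectation(fit$C_per_bp * distances,
                                             fit$n_eff))
}

#' @export
#' @method autoplot ld_decay_fit
#' @rdname ld_decay_fit
#' @param object an `ld_decay_fit` (for `autoplot`).
#' @param ... unused.
autoplot.ld_decay_fit <- function(object, ...) {
  curve <- ld_decay_curve(object)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$distance, y = .data$r2)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(y = .data$expected_r2),
                       colour = "firebrick") +
    ggplot2::labs(x = "distance (bp)", y = expression(r^2),
                  title = sprintf("LD decay, C/bp = %.4g", object$C_per_bp))
}
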
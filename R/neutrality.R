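# Frequency-spectrum neutrality tests. Each statistic exists in two forms:
# an alignment-facing exported function working on nucleotide columns, and an
# internal matrix form working on 0/1 derived-allele matrices (used by the
# coalescent null machinery and the ABC summaries). Both reduce to the same
# constant helpers.

tajima_constants <- function(n) {
  a1 <- harmonic_number(n - 1)
  a2 <- harmonic_number2(n - 1)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

tajima_d_from <- function(n, S, pi_locus) {
  if (S < 1 || n < 4) return(NA_real_)
  k <- tajima_constants(n)
  V <- k$e1 * S + k$e2 * S * (S - 1)
  if (V <= 0) return(NA_real_)
  (pi_locus - S / k$a1) / sqrt(V)
}

#' Tajima's D
#'
#' Contrast of pairwise diversity and Watterson's estimator, standardized
#' with Tajima's (1989) variance constants. Undefined (returned as `NA`)
#' when the locus has no segregating site.
#'
#' @param aln a [locus_alignment()].
#' @return the D statistic, or `NA`.
#' @export
tajimas_d <- function(aln) {
  n <- nrow(aln$seqs)
  classes <- classify_sites(aln)
  S <- segregating_sites(aln, classes = classes)
  tajima_d_from(n, S, pi_locus_scale(aln, classes))
}

fu_li_constants <- function(n) {
  an <- harmonic_number(n - 1)
  bn <- harmonic_number2(n - 1)
  an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  uD <- (n / (n - 1)) * (an - n / (n - 1)) - vD
  vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
           (2 * (n - 1) * an) / n^2 - 8 * bn / n) / (an^2 + bn)
  uF <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
           (3 * n * (n - 1))) / an - vF
  list(an = an, uD = uD, vD = vD, uF = uF, vF = vF)
}

fu_li_star_from <- function(n, eta, eta_s, pi_locus) {
  if (eta < 1 || n < 4) return(c(D_star = NA_real_, F_star = NA_real_))
  k <- fu_li_constants(n)
  d_num <- (n / (n - 1)) * eta - k$an * eta_s
  d_var <- k$uD * eta + k$vD * eta^2
  f_num <- pi_locus - ((n - 1) / n) * eta_s
  f_var <- k$uF * eta + k$vF * eta^2
  c(D_star = if (d_var > 0) d_num / sqrt(d_var) else NA_real_,
    F_star = if (f_var > 0) f_num / sqrt(f_var) else NA_real_)
}

# Mutation and folded-singleton counts from nucleotide columns: a column
# with k observed bases carries k-1 mutations; each base seen in exactly one
# sequence is a singleton mutation.
eta_counts <- function(seqs, included) {
  eta <- 0L; eta_s <- 0L
  for (j in which(included)) {
    col <- seqs[, j]
    tab <- table(col[col %in% c("A", "C", "G", "T")])
    if (length(tab) >= 2L) {
      eta <- eta + length(tab) - 1L
      eta_s <- eta_s + sum(tab == 1L)
    }
  }
  c(eta = eta, eta_s = eta_s)
}

#' Fu and Li's D* and F* (no outgroup)
#'
#' Singleton-based neutrality statistics on the folded spectrum, using the
#' starred (outgroup-free) variance constants with the standard corrections.
#'
#' @param aln a [locus_alignment()].
#' @return named numeric vector `c(D_star, F_star)`; `NA`s when `S = 0`.
#' @export
fu_li_star <- function(aln) {
  n <- nrow(aln$seqs)
  classes <- classify_sites(aln)
  cnt <- eta_counts(aln$seqs, !classes$excluded)
  fu_li_star_from(n, cnt[["eta"]], cnt[["eta_s"]],
                  pi_locus_scale(aln, classes))
}

# log unsigned Stirling numbers of the first kind, row n (k = 1..n).
log_stirling_first <- function(n) {
  ls <- 0  # row 1
  if (n == 1L) return(ls)
  for (m in 2:n) {
    prev <- ls
    ls <- numeric(m)
    ls[1L] <- log(m - 1) + prev[1L]
    if (m > 2L)
      for (k in 2:(m - 1L)) {
        a <- prev[k - 1L]
        b <- log(m - 1) + prev[k]
        ls[k] <- max(a, b) + log1p(exp(-abs(a - b)))
      }
    ls[m] <- 0
  }
  ls
}

# Ewens sampling distribution of the number of distinct haplotypes K.
ewens_k_probs <- function(n, theta) {
  ls <- log_stirling_first(n)
  k <- seq_len(n)
  logp <- ls + k * log(theta) - sum(log(theta + 0:(n - 1)))
  p <- exp(logp - max(logp))
  p / sum(p)
}

#' Fu's Fs
#'
#' `Fs = ln(S' / (1 - S'))` with `S' = Pr(K >= k_obs | theta_pi)` from the
#' Ewens sampling distribution, where `k_obs` is the observed number of
#' distinct haplotypes and `theta_pi` the locus-scale pairwise diversity.
#' Large negative values indicate an excess of rare haplotypes, the
#' signature of population growth.
#'
#' @param aln a [locus_alignment()].
#' @return the Fs statistic, or `NA` (with a warning) when undefined.
#' @export
fu_fs <- function(aln) {
  n <- nrow(aln$seqs)
  if (n < 2L) stop("Fs needs n >= 2", call. = FALSE)
  classes <- classify_sites(aln)
  k_obs <- length(unique(allele_strings(aln, classes)))
  theta_pi <- pi_locus_scale(aln, classes)
  fu_fs_from(n, k_obs, theta_pi)
}

fu_fs_from <- function(n, k_obs, theta_pi) {
  if (k_obs <= 1L || theta_pi <= 0) {
    warning("Fu's Fs undefined: monomorphic sample", call. = FALSE)
    return(NA_real_)
  }
  p <- ewens_k_probs(n, theta_pi)
  Sp <- sum(p[k_obs:n])
  if (Sp <= 0 || Sp >= 1) {
    warning("Fu's Fs undefined after numeric clamping", call. = FALSE)
    return(NA_real_)
  }
  log(Sp) - log1p(-Sp)
}

fay_wu_h_from <- function(n, counts) {
  S <- length(counts)
  if (S < 1 || n < 4) return(NA_real_)
  pi <- sum(2 * counts * (n - counts) / (n * (n - 1)))
  thetaL <- sum(counts / (n - 1))
  an <- harmonic_number(n - 1)
  bn <- harmonic_number2(n - 1)
  bn1 <- bn + 1 / n^2
  th <- S / an
  th2 <- S * (S - 1) / (an^2 + bn)
  v <- (n - 2) / (6 * (n - 1)) * th +
    (18 * n^2 * (3 * n + 2) * bn1 -
       (88 * n^3 + 9 * n^2 - 13 * n + 6)) / (9 * n * (n - 1)^2) * th2
  if (v <= 0) return(NA_real_)
  (pi - thetaL) / sqrt(v)
}

#' Standardized Fay and Wu's H
#'
#' `H = theta_pi - theta_L` on outgroup-polarized sites, standardized with
#' the Zeng et al. (2006) variance. Sites are polarized only when the
#' ingroup is biallelic and the outgroup carries one of the two ingroup
#' alleles; outgroup gaps, `N`s and third states exclude the site.
#'
#' @param aln a [locus_alignment()] with an outgroup sequence.
#' @return the standardized H statistic, or `NA` when no site polarizes.
#' @export
fay_wu_h <- function(aln) {
  if (is.null(aln$outgroup))
    stop("Fay & Wu's H requires an outgroup sequence", call. = FALSE)
  counts <- polarized_counts(aln)
  fay_wu_h_from(nrow(aln$seqs), counts)
}

# Derived-allele counts at polarizable segregating sites.
polarized_counts <- function(aln) {
  classes <- classify_sites(aln)
  counts <- integer(0)
  for (j in which(!classes$excluded)) {
    col <- aln$seqs[, j]
    og <- aln$outgroup[j]
    alleles <- unique(col)
    if (length(alleles) != 2L) next
    if (!(og %in% alleles)) next
    counts <- c(counts, sum(col != og))
  }
  counts
}

#' McDonald-Kreitman test
#'
#' Contrasts synonymous and nonsynonymous changes that are polymorphic
#' within the ingroup against those fixed between ingroup and outgroup.
#' Changes are classified by mutating the majority-base reference codon at
#' the focal position. The test is reported as not calculable when any
#' margin of the 2x2 table is zero (the usual situation at low-polymorphism
#' loci).
#'
#' @param aln a [locus_alignment()] with exons and an outgroup.
#' @return a list with the 2x2 `table` (rows polymorphic/fixed, columns
#'   synonymous/nonsynonymous), the Fisher odds ratio `or`, two-sided
#'   `p_value`, and `performed` flag.
#' @export
mk_test <- function(aln) {
  if (is.null(aln$outgroup))
    stop("MK test requires an outgroup sequence", call. = FALSE)
  if (nrow(aln$exons) == 0L)
    stop("MK test requires coding sites", call. = FALSE)
  classes <- classify_sites(aln)
  ref <- majority_base(aln$seqs)
  coding_pos <- exon_positions(aln$exons)
  codons <- matrix(coding_pos, nrow = 3L)
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(c("polymorphic", "fixed"),
                                c("synonymous", "nonsynonymous")))
  aa <- codon_aa()
  for (ci in seq_len(ncol(codons))) {
    pos <- codons[, ci]
    if (any(classes$excluded[pos])) next
    ref_codon <- ref[pos]
    ref_aa <- aa[[paste(ref_codon, collapse = "")]]
    for (p in 1:3) {
      j <- pos[p]
      col <- aln$seqs[, j]
      og <- aln$outgroup[j]
      bases <- names(sort(table(col), decreasing = TRUE))
      classify <- function(b) {
        mut <- ref_codon
        mut[p] <- b
        if (identical(aa[[paste(mut, collapse = "")]], ref_aa))
          "synonymous" else "nonsynonymous"
      }
      if (length(bases) >= 2L) {
        for (b in setdiff(bases, ref_codon[p]))
          tab["polymorphic", classify(b)] <-
            tab["polymorphic", classify(b)] + 1L
      } else if (og %in% c("A", "C", "G", "T") && og != bases[1L]) {
        tab["fixed", classify(og)] <- tab["fixed", classify(og)] + 1L
      }
    }
  }
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    return(list(table = tab, or = NA_real_, p_value = NA_real_,
                performed = FALSE))
  ft <- fisher.test(tab)
  list(table = tab, or = unname(ft$estimate), p_value = ft$p.value,
       performed = TRUE)
}

# ---- 0/1 derived-allele matrix forms -------------------------------------

matrix_stat <- function(name, mat) {
  n <- nrow(mat)
  counts <- colSums(mat)
  counts <- counts[counts > 0 & counts < n]
  S <- length(counts)
  pi <- if (S) sum(2 * counts * (n - counts) / (n * (n - 1))) else 0
  switch(name,
    tajima_d = tajima_d_from(n, S, pi),
    fu_li_d_star = ,
    fu_li_f_star = {
      eta_s <- sum(counts == 1L | counts == (n - 1L))
      v <- fu_li_star_from(n, S, eta_s, pi)
      if (name == "fu_li_d_star") v[["D_star"]] else v[["F_star"]]
    },
    fu_fs = {
      k_obs <- nrow(unique(mat))
      suppressWarnings(fu_fs_from(n, k_obs, pi))
    },
    fay_wu_h = fay_wu_h_from(n, counts),
    zns = zns_matrix(mat),
    stop("unknown statistic: ", name, call. = FALSE))
}

zns_matrix <- function(mat) {
  n <- nrow(mat)
  counts <- colSums(mat)
  keep <- counts > 0 & counts < n
  m <- mat[, keep, drop = FALSE]
  S <- ncol(m)
  if (S < 2L) return(NA_real_)
  p <- colMeans(m)
  cp <- crossprod(m) / n          # pAB for all pairs
  Dm <- cp - outer(p, p)
  den <- outer(p * (1 - p), p * (1 - p))
  r2 <- Dm^2 / den
  mean(r2[upper.tri(r2)])
}

# Fixed-S standard-coalescent sample: S mutations placed on branches with
# probability proportional to branch duration.
sim_fixed_s_matrix <- function(n, S) {
  br <- .coal_branches_cpp(n, 0, 1, 0)
  pick <- sample.int(length(br$duration), S, replace = TRUE,
                     prob = br$duration)
  t(br$leaves[pick, , drop = FALSE]) * 1L
}

#' Coalescent significance of a neutrality statistic
#'
#' Simulates standard-coalescent genealogies conditioned on the observed
#' number of segregating sites (fixed-S: exactly `S_obs` mutations placed
#' uniformly on branches), recomputes the statistic on each replicate, and
#' returns the empirical p-value: two-tailed
#' `2 * min(Pr(sim <= obs), Pr(sim >= obs))` for all statistics except Fu's
#' Fs, which by convention is one-tailed toward negative values. Ties count
#' as extreme.
#'
#' @param stat_name one of `"tajima_d"`, `"fu_li_d_star"`, `"fu_li_f_star"`,
#'   `"fu_fs"`, `"fay_wu_h"`, `"zns"`.
#' @param observed the observed statistic.
#' @param n number of chromosomes sampled.
#' @param S_obs observed segregating sites (must be positive).
#' @param reps number of coalescent replicates (>= 100).
#' @param seed optional RNG seed.
#' @return a one-row tibble: `statistic`, `value`, `p_value`, `replicates`.
#' @export
coalescent_pvalue <- function(stat_name, observed, n, S_obs, reps = 1000,
                              seed = NULL) {
  if (S_obs <= 0) stop("fixed-S null requires S_obs > 0", call. = FALSE)
  if (reps < 100) stop("use at least 100 replicates", call. = FALSE)
  sims <- with_seed(seed, vapply(seq_len(reps), function(i)
    matrix_stat(stat_name, sim_fixed_s_matrix(n, S_obs)), 0))
  sims <- sims[!is.na(sims)]
  p <- if (stat_name == "fu_fs") mean(sims <= observed)
       else min(1, 2 * min(mean(sims <= observed), mean(sims >= observed)))
  tibble(statistic = stat_name, value = observed, p_value = p,
         replicates = length(sims))
}

#' Neutrality-test table for a set of loci
#'
#' Computes Tajima's D, Fu & Li's D* and F*, Fu's Fs, and (when an outgroup
#' is present) standardized Fay & Wu's H per locus, each with a fixed-S
#' coalescent p-value.
#'
#' @param alns list of [locus_alignment()] objects.
#' @param reps coalescent replicates per test.
#' @param seed optional RNG seed.
#' @return tibble with one row per locus and statistic.
#' @export
neutrality_table <- function(alns, reps = 1000, seed = NULL) {
  with_seed(seed, {
    rows <- list()
    for (aln in alns) {
      n <- nrow(aln$seqs)
      S <- segregating_sites(aln)
      stats <- list(tajima_d = tajimas_d(aln))
      fl <- fu_li_star(aln)
      stats$fu_li_d_star <- fl[["D_star"]]
      stats$fu_li_f_star <- fl[["F_star"]]
      stats$fu_fs <- suppressWarnings(fu_fs(aln))
      if (!is.null(aln$outgroup)) stats$fay_wu_h <- fay_wu_h(aln)
      for (nm in names(stats)) {
        v <- stats[[nm]]
        if (is.na(v) || S == 0) {
          rows[[length(rows) + 1L]] <- tibble(
            locus = aln$locus_id, statistic = nm, value = NA_real_,
            p_value = NA_real_, replicates = 0L)
        } else {
          r <- coalescent_pvalue(nm, v, n, S, reps)
          rows[[length(rows) + 1L]] <- tibble(
            locus = aln$locus_id, statistic = nm, value = v,
            p_value = r$p_value, replicates = r$replicates)
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}
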
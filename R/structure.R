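#' AMOVA-based F_ST with permutation significance
#'
#' Two-level analysis of molecular variance on pairwise distances between
#' haploid units (allele sequences for nuclear loci, individual multilocus
#' haplotypes for chloroplast SSRs). Distances enter as squared Euclidean
#' distances, the convention of sequence AMOVA where the pairwise difference
#' count plays that role. `F_ST = sigma2_among / (sigma2_among +
#' sigma2_within)`; negative variance components are retained, so `F_ST` can
#' be slightly negative. Significance comes from permuting units among
#' populations: `p = Pr(F_ST_perm >= F_ST_obs)`.
#'
#' Populations contributing a single unit are excluded with a warning. When
#' `groups` maps populations to regions, a three-level AMOVA is run and
#' `F_CT` (among-group fraction) is reported as well.
#'
#' @param x a square distance matrix (or `dist`), a list of
#'   [locus_alignment()] objects (units = phased allele sequences, distances
#'   = pairwise difference counts summed over loci), or an [ssr_dataset()]
#'   (units = individuals).
#' @param pops a [population_map()] or a vector of population labels, one
#'   per unit.
#' @param permutations number of label permutations (>= 1000 recommended).
#' @param seed optional RNG seed.
#' @param groups optional named vector mapping population -> group (region).
#' @param ordered for SSR input: use sum of squared repeat differences
#'   (`TRUE`) or haplotype mismatch counts (`FALSE`, default).
#' @return an object of class `amova_fit`.
#' @export
amova_fst <- function(x, pops, permutations = 10000, seed = NULL,
                      groups = NULL, ordered = FALSE) {
  prep <- amova_inputs(x, pops, ordered)
  d <- prep$d
  lab <- prep$labels
  tab <- table(lab)
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    warning("excluding population(s) with a single unit: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !(lab %in% small)
    d <- d[keep, keep, drop = FALSE]
    lab <- lab[keep]
  }
  if (length(unique(lab)) < 2L)
    stop("AMOVA needs at least 2 populations with >= 2 units", call. = FALSE)
  obs <- amova_components(d, lab, groups)
  perm_fst <- with_seed(seed, vapply(seq_len(permutations), function(i) {
    amova_components(d, sample(lab), groups = NULL)$fst
  }, 0))
  structure(list(
    fst = obs$fst, fct = obs$fct, components = obs$components,
    p_value = mean(perm_fst >= obs$fst), permutations = permutations,
    n_units = length(lab), n_pops = length(unique(lab))),
    class = "amova_fit")
}

amova_inputs <- function(x, pops, ordered = FALSE) {
  if (inherits(x, "dist")) x <- as.matrix(x)
  if (is.matrix(x) && nrow(x) == ncol(x)) {
    labels <- if (inherits(pops, "population_map")) {
      m <- match(rownames(x), pops$assignments$individual)
      pops$assignments$population[m]
    } else as.character(pops)
    return(list(d = x, labels = labels))
  }
  if (inherits(x, "ssr_dataset")) {
    d <- ssr_distance_matrix(x, ordered)
    labels <- if (inherits(pops, "population_map")) {
      m <- match(rownames(x$repeats), pops$assignments$individual)
      pops$assignments$population[m]
    } else as.character(pops)
    return(list(d = d, labels = labels))
  }
  if (is.list(x) && all(vapply(x, inherits, TRUE, "locus_alignment"))) {
    combined <- concatenate_loci(x)
    d <- sequence_distance_matrix(combined)
    labels <- sequence_populations(combined, pops)
    return(list(d = d, labels = labels))
  }
  stop("unsupported input to amova_fst", call. = FALSE)
}

# Pairwise difference counts between allele sequences (included columns).
sequence_distance_matrix <- function(aln) {
  classes <- classify_sites(aln)
  keep <- !classes$excluded
  m <- aln$seqs[, keep, drop = FALSE]
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  rownames(d) <- colnames(d) <- paste0(aln$individual, "|", aln$allele)
  d
}

ssr_distance_matrix <- function(ssr, ordered = FALSE) {
  r <- ssr$repeats
  n <- nrow(r)
  d <- matrix(0, n, n, dimnames = list(rownames(r), rownames(r)))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n) {
      dif <- r[i, ] - r[j, ]
      d[i, j] <- d[j, i] <- if (ordered) sum(dif^2) else sum(dif != 0)
    }
  d
}

# Variance components from squared-distance matrix and labels
# (Excoffier et al. 1992); optional third level from a pop -> group map.
amova_components <- function(d, lab, groups = NULL) {
  N <- length(lab)
  K <- length(unique(lab))
  Z <- outer(lab, unique(lab), "==") * 1
  n_k <- colSums(Z)
  within_sums <- diag(t(Z) %*% d %*% Z) / 2
  ssd_t <- sum(d) / (2 * N)
  ssd_wp <- sum(within_sums / n_k)
  ssd_ap <- ssd_t - ssd_wp
  df_ap <- K - 1L
  df_wp <- N - K
  ms_wp <- ssd_wp / df_wp
  ms_ap <- ssd_ap / df_ap
  n_c <- (N - sum(n_k^2) / N) / df_ap
  sigma_w <- ms_wp
  sigma_a <- (ms_ap - ms_wp) / n_c
  fst <- sigma_a / (sigma_a + sigma_w)
  fct <- NA_real_
  comp <- tibble(
    level = c("among_populations", "within_populations"),
    df = c(df_ap, df_wp), SSD = c(ssd_ap, ssd_wp),
    sigma2 = c(sigma_a, sigma_w))
  if (!is.null(groups)) {
    g_of <- groups[lab]
    G <- length(unique(g_of))
    if (G >= 2L) {
      Zg <- outer(g_of, unique(g_of), "==") * 1
      N_g <- colSums(Zg)
      wg_sums <- diag(t(Zg) %*% d %*% Zg) / 2
      # within-group totals and their within-population parts
      ssd_wg_tot <- sum(wg_sums / N_g)
      ssd_ag <- ssd_t - ssd_wg_tot
      ssd_apwg <- ssd_wg_tot - ssd_wp
      sum_nk2_by_g <- vapply(unique(g_of), function(g) {
        sum(table(lab[g_of == g])^2) / sum(g_of == g)
      }, 0)
      n1 <- (N - sum(sum_nk2_by_g)) / (K - G)
      n2 <- (sum(sum_nk2_by_g) - sum(n_k^2) / N) / (G - 1)
      n3 <- (N - sum(N_g^2) / N) / (G - 1)
      ms_apwg <- ssd_apwg / (K - G)
      ms_ag <- ssd_ag / (G - 1)
      sigma_b <- (ms_apwg - sigma_w) / n1
      sigma_ag <- (ms_ag - sigma_w - n2 * sigma_b) / n3
      fct <- sigma_ag / (sigma_ag + sigma_b + sigma_w)
      comp <- dplyr::bind_rows(
        tibble(level = "among_groups", df = G - 1L, SSD = ssd_ag,
               sigma2 = sigma_ag),
        tibble(level = "among_populations_within_groups", df = K - G,
               SSD = ssd_apwg, sigma2 = sigma_b),
        tibble(level = "within_populations", df = df_wp, SSD = ssd_wp,
               sigma2 = sigma_w))
    }
  }
  list(fst = fst, fct = fct, components = comp)
}

#' @export
print.amova_fit <- function(x, ...) {
  cat(sprintf("<amova_fit> F_ST = %.4f (p = %.4g, %d permutations; %d units, %d populations)\n",
              x$fst, x$p_value, x$permutations, x$n_units, x$n_pops))
  if (!is.na(x$fct)) cat(sprintf("  F_CT = %.4f\n", x$fct))
  invisible(x)
}

#' @export
#' @method tidy amova_fit
tidy.amova_fit <- function(x, ...) x$components

#' @export
#' @method glance amova_fit
glance.amova_fit <- function(x, ...) {
  tibble(F_ST = x$fst, F_CT = x$fct, p_value = x$p_value,
         permutations = x$permutations, n_units = x$n_units,
         n_pops = x$n_pops)
}

#' Pairwise population F_ST matrix
#'
#' AMOVA F_ST restricted to each pair of populations.
#'
#' @inheritParams amova_fst
#' @return symmetric matrix of pairwise F_ST (populations with < 2 units
#'   get `NA` rows).
#' @export
pairwise_fst <- function(x, pops, ordered = FALSE) {
  prep <- amova_inputs(x, pops, ordered)
  pop_ids <- sort(unique(prep$labels))
  K <- length(pop_ids)
  out <- matrix(NA_real_, K, K, dimnames = list(pop_ids, pop_ids))
  diag(out) <- 0
  for (i in seq_len(K - 1L))
    for (j in (i + 1L):K) {
      keep <- prep$labels %in% pop_ids[c(i, j)]
      if (sum(prep$labels == pop_ids[i]) < 2L ||
          sum(prep$labels == pop_ids[j]) < 2L) next
      cmp <- amova_components(prep$d[keep, keep, drop = FALSE],
                              prep$labels[keep])
      out[i, j] <- out[j, i] <- cmp$fst
    }
  out
}

#' Compare unordered (G_ST) and ordered (R_ST) differentiation of SSR
#' haplotypes
#'
#' `G_ST` uses multilocus haplotype frequencies only (unordered estimator
#' with small-sample corrections: unbiased within-population diversities,
#' total diversity from mean haplotype frequencies). `R_ST` replaces the
#' 0/1 haplotype mismatch with the sum of squared repeat differences, so
#' that closely related haplotypes count as similar. The permutation test
#' shuffles repeat scores among haplotype labels -- under the null the
#' ordered distance carries no information and `E[R_ST_perm]` matches
#' `G_ST` -- and reports `p = Pr(R_ST_perm >= R_ST_obs)`; a significant
#' excess indicates phylogeographic structure.
#'
#' @param ssr an [ssr_dataset()].
#' @param pops a [population_map()] or label vector.
#' @param permutations number of permutations.
#' @param seed optional RNG seed.
#' @return a one-row tibble: `G_ST`, `R_ST`, `p_RST_gt_GST`, `permutations`.
#' @export
gst_rst_compare <- function(ssr, pops, permutations = 10000, seed = NULL) {
  hap <- ssr_haplotypes(ssr)
  lab <- if (inherits(pops, "population_map")) {
    pops$assignments$population[
      match(rownames(ssr$repeats), pops$assignments$individual)]
  } else as.character(pops)
  uh <- unique(hap)
  if (length(uh) < 2L) {
    warning("monomorphic SSR dataset: G_ST/R_ST undefined", call. = FALSE)
    return(tibble(G_ST = NA_real_, R_ST = NA_real_,
                  p_RST_gt_GST = NA_real_, permutations = permutations))
  }
  reps <- ssr$repeats[match(uh, hap), , drop = FALSE]
  delta <- as.matrix(stats::dist(reps))^2  # per-locus squared diffs summed
  freq <- prop.table(table(lab, factor(hap, uh)), 1L)
  n_k <- as.numeric(table(lab))
  gst <- pons_petit_stat(freq, n_k, delta = NULL)
  rst <- pons_petit_stat(freq, n_k, delta = delta)
  perm <- with_seed(seed, vapply(seq_len(permutations), function(i) {
    idx <- sample(nrow(delta))
    pons_petit_stat(freq, n_k, delta = delta[idx, idx, drop = FALSE])
  }, 0))
  tibble(G_ST = gst, R_ST = rst, p_RST_gt_GST = mean(perm >= rst),
         permutations = permutations)
}

# 1 - vS/vT with v the (ordered or unordered) population diversity and
# populations weighted equally; delta = NULL gives the 0/1 haplotype
# mismatch, i.e. the unordered (G_ST) estimator; a repeat-distance delta
# gives the ordered (R_ST) one. With delta = d(i != j), vS and vT reduce to
# the within- and total gene diversities, so identical population frequency
# vectors give exactly 0.
pons_petit_stat <- function(freq, n_k, delta = NULL) {
  K <- nrow(freq)
  H <- ncol(freq)
  if (is.null(delta)) delta <- 1 - diag(H)
  v_k <- vapply(seq_len(K), function(k) {
    p <- freq[k, ]
    as.numeric(t(p) %*% delta %*% p)
  }, 0)
  vS <- mean(v_k)
  pbar <- colMeans(freq)
  vT <- as.numeric(t(pbar) %*% delta %*% pbar)
  if (vT <= 0) return(NA_real_)
  1 - vS / vT
}

#' Mantel test of isolation by distance
#'
#' Pearson correlation between off-diagonal pairwise population
#' differentiation and great-circle geographic distance (haversine, km),
#' with significance from joint row/column permutations of the
#' differentiation matrix (one-sided, `p = Pr(r_perm >= r_obs)`). With at
#' most 7 populations, and whenever `factorial(n) <= permutations`, all
#' permutations are enumerated exactly.
#'
#' @param fst_matrix symmetric matrix of pairwise differentiation, with
#'   population names as dimnames.
#' @param coords a [population_map()] with coordinates, or a data frame with
#'   columns `population`, `lon`, `lat`.
#' @param permutations number of random permutations when not exhaustive.
#' @param seed optional RNG seed.
#' @return a one-row tibble: `statistic`, `value` (Mantel r), `p_value`,
#'   `permutations`, `exhaustive`.
#' @export
mantel_test <- function(fst_matrix, coords, permutations = 10000,
                        seed = NULL) {
  if (!isSymmetric(unname(as.matrix(fst_matrix)), tol = 1e-8))
    stop("differentiation matrix must be symmetric", call. = FALSE)
  fst_matrix <- as.matrix(fst_matrix)
  cd <- if (inherits(coords, "population_map")) coords$coordinates else
    as_tibble(coords)
  pops <- rownames(fst_matrix) %||% cd$population
  m <- match(pops, cd$population)
  if (anyNA(m)) stop("coordinates missing for some populations", call. = FALSE)
  xy <- as.matrix(cd[m, c("lon", "lat")])
  K <- length(pops)
  if (K < 4L) stop("Mantel test needs >= 4 populations", call. = FALSE)
  geo <- matrix(0, K, K)
  for (i in seq_len(K - 1L))
    for (j in (i + 1L):K)
      geo[i, j] <- geo[j, i] <-
        geosphere::distHaversine(xy[i, ], xy[j, ]) / 1000
  lower <- lower.tri(fst_matrix)
  if (sd(fst_matrix[lower]) == 0 || sd(geo[lower]) == 0) {
    warning("zero variance: Mantel r undefined", call. = FALSE)
    return(tibble(statistic = "mantel_r", value = NA_real_,
                  p_value = NA_real_, permutations = 0L,
                  exhaustive = FALSE))
  }
  r_obs <- stats::cor(fst_matrix[lower], geo[lower])
  r_for <- function(ord) {
    f <- fst_matrix[ord, ord]
    stats::cor(f[lower], geo[lower])
  }
  exhaustive <- K <= 7L && factorial(K) <= max(permutations, factorial(K))
  if (exhaustive && factorial(K) <= 1e5) {
    perms <- all_permutations(K)
    r_perm <- vapply(perms, r_for, 0)
    n_used <- length(r_perm)
  } else {
    exhaustive <- FALSE
    r_perm <- with_seed(seed, vapply(seq_len(permutations), function(i)
      r_for(sample(K)), 0))
    n_used <- permutations
  }
  tibble(statistic = "mantel_r", value = r_obs,
         p_value = mean(r_perm >= r_obs - 1e-12),
         permutations = n_used, exhaustive = exhaustive)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  idx <- 1L
  for (p in sub)
    for (pos in seq_len(n)) {
      out[[idx]] <- append(p, n, after = pos - 1L)
      idx <- idx + 1L
    }
  out
}
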
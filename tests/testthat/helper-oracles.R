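# Independent brute-force oracles, written directly from the published
# definitions and kept free of package internals.

oracle_base_matrix <- function(aln) {
  keep <- apply(aln$seqs, 2, function(col) all(col %in% c("A","C","G","T")))
  aln$seqs[, keep, drop = FALSE]
}

oracle_S <- function(aln) {
  m <- oracle_base_matrix(aln)
  sum(apply(m, 2, function(col) length(unique(col)) > 1))
}

# locus-scale pi: average pairwise difference count
oracle_pi_locus <- function(aln) {
  m <- oracle_base_matrix(aln)
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(m[i, ] != m[j, ])
  tot / choose(n, 2)
}

oracle_watterson <- function(S, n, sites) S / (sum(1 / seq_len(n - 1)) * sites)

# Tajima (1989) D, coded independently from the original constants.
oracle_tajima_d <- function(aln) {
  n <- nrow(aln$seqs)
  S <- oracle_S(aln)
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (oracle_pi_locus(aln) - S / a1) /
    sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# Fu & Li (1993) starred statistics with the corrected constants.
oracle_fu_li_star <- function(aln) {
  m <- oracle_base_matrix(aln)
  n <- nrow(m)
  eta <- 0; eta_s <- 0
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    if (length(tab) > 1) {
      eta <- eta + length(tab) - 1
      eta_s <- eta_s + sum(tab == 1)
    }
  }
  if (eta == 0) return(c(NA_real_, NA_real_))
  an <- sum(1 / (1:(n - 1))); bn <- sum(1 / (1:(n - 1))^2)
  an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    2 / (n - 1) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * n * an * (an + 1) / (n - 1)^2) / (an^2 + bn)
  uD <- n / (n - 1) * (an - n / (n - 1)) - vD
  Ds <- (n / (n - 1) * eta - an * eta_s) / sqrt(uD * eta + vD * eta^2)
  vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
           2 * (n - 1) * an / n^2 - 8 * bn / n) / (an^2 + bn)
  uF <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
           (3 * n * (n - 1))) / an - vF
  Fs <- (oracle_pi_locus(aln) - (n - 1) / n * eta_s) /
    sqrt(uF * eta + vF * eta^2)
  c(Ds, Fs)
}

# Zeng et al. (2006) standardized H from derived-allele counts.
oracle_fay_wu_h <- function(counts, n) {
  S <- length(counts)
  if (S == 0) return(NA_real_)
  pi <- sum(2 * counts * (n - counts)) / (n * (n - 1))
  thL <- sum(counts) / (n - 1)
  an <- sum(1 / (1:(n - 1))); bn <- sum(1 / (1:(n - 1))^2)
  bn1 <- sum(1 / (1:n)^2)
  th <- S / an; th2 <- S * (S - 1) / (an^2 + bn)
  v <- (n - 2) / (6 * (n - 1)) * th +
    (18 * n^2 * (3 * n + 2) * bn1 -
       (88 * n^3 + 9 * n^2 - 13 * n + 6)) / (9 * n * (n - 1)^2) * th2
  (pi - thL) / sqrt(v)
}

# Ewens K distribution by exhaustive enumeration of integer partitions.
oracle_ewens_k <- function(n, theta) {
  parts <- integer_partitions(n)
  rising <- prod(theta + 0:(n - 1))
  pk <- numeric(n)
  for (p in parts) {
    k <- length(p)
    a <- table(p)  # multiplicities per part size
    n_perm <- factorial(n) /
      (prod(vapply(as.integer(names(a)), function(j) j^a[[as.character(j)]], 0)) *
         prod(factorial(as.integer(a))))
    pk[k] <- pk[k] + n_perm * theta^k / rising
  }
  pk
}

integer_partitions <- function(n, max_part = n) {
  if (n == 0) return(list(integer(0)))
  out <- list()
  for (first in seq_len(min(n, max_part))) {
    for (rest in integer_partitions(n - first, first))
      out[[length(out) + 1]] <- c(first, rest)
  }
  out
}

# r^2 between two biallelic columns from phased haplotypes.
oracle_r2 <- function(x, y) {
  pA <- mean(x); pB <- mean(y)
  D <- mean(x & y) - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

oracle_zns <- function(mat) {
  n <- nrow(mat)
  keep <- colSums(mat) > 0 & colSums(mat) < n
  m <- mat[, keep, drop = FALSE]
  if (ncol(m) < 2) return(NA_real_)
  pairs <- combn(ncol(m), 2)
  mean(apply(pairs, 2, function(ij)
    oracle_r2(m[, ij[1]] == 1, m[, ij[2]] == 1)))
}

oracle_mismatch <- function(x) {
  n <- nrow(x)
  d <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d <- c(d, sum(x[i, ] != x[j, ]))
  tabulate(d + 1, nbins = max(d) + 1) / length(d)
}

oracle_he <- function(x) {
  n <- length(x)
  sum(outer(x, x, "!=")) / (n * (n - 1))
}
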
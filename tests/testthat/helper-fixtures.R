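# Small in-code fixtures shared across test files.

# Alignment from whole-sequence strings; individuals are paired rows.
make_alignment <- function(seqs, exons = NULL, outgroup = NULL,
                           locus_id = "test") {
  n <- length(seqs)
  stopifnot(n %% 2 == 0)
  locus_alignment(locus_id, seqs,
                  individual = rep(sprintf("i%02d", seq_len(n / 2)), each = 2),
                  allele = rep(1:2, n / 2),
                  exons = exons, outgroup = outgroup)
}

# Random noncoding alignment: ancestral sequence plus derived alleles at
# n_var random columns, derived carriers random.
random_alignment <- function(n_seq, L, n_var, outgroup = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  seqs <- matrix(rep(anc, each = n_seq), n_seq, L)
  cols <- sample.int(L, n_var)
  for (j in cols) {
    der <- sample(setdiff(c("A", "C", "G", "T"), anc[j]), 1)
    carriers <- sample.int(n_seq, sample.int(n_seq - 1, 1))
    seqs[carriers, j] <- der
  }
  make_alignment(apply(seqs, 1, paste, collapse = ""),
                 outgroup = if (outgroup) paste(anc, collapse = ""))
}

# 0/1 derived matrix -> nucleotide alignment with outgroup = ancestral.
matrix_to_alignment <- function(mat, L = ncol(mat)) {
  n <- nrow(mat)
  if (n %% 2 == 1) stop("need even rows")
  anc <- rep("A", L)
  seqs <- matrix("A", n, L)
  seqs[, seq_len(ncol(mat))][mat == 1] <- "G"
  make_alignment(apply(seqs, 1, paste, collapse = ""),
                 outgroup = paste(anc, collapse = ""))
}

snm <- function(theta, rho = 0) demographic_model("SNM", theta, rho)
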
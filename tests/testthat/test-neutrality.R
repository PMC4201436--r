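test_that("Tajima's D matches an independent implementation of the 1989 formulas", {
  set.seed(21)
  for (r in 1:25) {
    aln <- random_alignment(10, 500, sample(3:40, 1))
    expect_equal(tajimas_d(aln), oracle_tajima_d(aln), tolerance = 1e-9)
  }
  expect_true(is.na(tajimas_d(make_alignment(rep("ACGT", 4)))))
})

test_that("Fu & Li's starred statistics match the published formulas", {
  set.seed(22)
  for (r in 1:25) {
    aln <- random_alignment(12, 400, sample(3:30, 1))
    mine <- fu_li_star(aln)
    orc <- oracle_fu_li_star(aln)
    expect_equal(unname(mine[["D_star"]]), orc[1], tolerance = 1e-9)
    expect_equal(unname(mine[["F_star"]]), orc[2], tolerance = 1e-9)
  }
})

test_that("singleton load drives the sign of D*", {
  # every mutation a singleton, carried by a different sequence
  n <- 20; L <- 40
  seqs <- matrix("A", n, L)
  for (j in 1:10) seqs[j, j] <- "T"
  aln <- make_alignment(apply(seqs, 1, paste, collapse = ""))
  expect_lt(fu_li_star(aln)[["D_star"]], 0)
  # no singletons: all variants at intermediate frequency
  seqs <- matrix("A", n, L)
  for (j in 1:8) seqs[1:(n / 2), j] <- "T"
  aln <- make_alignment(apply(seqs, 1, paste, collapse = ""))
  expect_gt(fu_li_star(aln)[["D_star"]], 0)
})

test_that("Ewens haplotype-count probabilities match exhaustive partition enumeration", {
  for (n in c(4, 6, 8)) {
    for (theta in c(0.5, 1, 3)) {
      expect_equal(pinepop:::ewens_k_probs(n, theta),
                   oracle_ewens_k(n, theta), tolerance = 1e-9)
    }
  }
})

test_that("Fu's Fs behaves per its Ewens definition", {
  # n = 2, theta_pi = 1: Pr(K >= 2) = theta/(theta+1) = 0.5 -> Fs = 0
  aln <- make_alignment(c("AAAA", "AAAT"))
  expect_equal(fu_fs(aln), 0, tolerance = 1e-12)
  # many distinct haplotypes with tiny pairwise diversity -> strongly negative
  n <- 20; L <- 40
  seqs <- matrix("A", n, L)
  for (j in seq_len(n - 1)) seqs[j, j] <- "T"
  aln <- make_alignment(apply(seqs, 1, paste, collapse = ""))
  expect_lt(fu_fs(aln), -3)
  expect_warning(fs_na <- fu_fs(make_alignment(rep("AAAA", 4))),
                 "monomorphic")
  expect_true(is.na(fs_na))
})

test_that("standardized Fay & Wu's H matches the Zeng et al. variance", {
  set.seed(23)
  for (r in 1:25) {
    aln <- random_alignment(10, 300, sample(3:25, 1), outgroup = TRUE)
    counts <- pinepop:::polarized_counts(aln)
    expect_equal(fay_wu_h(aln),
                 oracle_fay_wu_h(counts, nrow(aln$seqs)),
                 tolerance = 1e-9)
  }
})

test_that("low-frequency derived alleles give positive H; outgroup rules hold", {
  # n = 4, one singleton derived allele: theta_pi > theta_L
  aln <- make_alignment(c("AAAT", "AAAA", "AAAA", "AAAA"),
                        outgroup = "AAAA")
  expect_gt(fay_wu_h(aln), 0)
  # outgroup third state excludes the site -> nothing to polarize
  aln2 <- make_alignment(c("AAAT", "AAAA", "AAAA", "AAAA"),
                         outgroup = "AAAC")
  expect_true(is.na(fay_wu_h(aln2)))
  expect_error(fay_wu_h(make_alignment(rep("AAAA", 4))), "outgroup")
})

test_that("theta_pi from pairwise differences equals its spectrum form", {
  set.seed(24)
  aln <- random_alignment(8, 200, 12, outgroup = TRUE)
  counts <- pinepop:::polarized_counts(aln)
  n <- nrow(aln$seqs)
  pi_spec <- sum(2 * counts * (n - counts) / (n * (n - 1)))
  # restrict the pairwise computation to polarizable sites via the counts
  # identity: both forms count the same per-site heterozygosity
  expect_equal(pi_spec,
               sum(vapply(counts, function(c)
                 2 * c * (n - c) / (n * (n - 1)), 0)))
})

test_that("MK test classifies changes and applies the margin rule", {
  # coding locus ACT ACT ...; polymorphic site syn (pos 3 T->C, Thr),
  # nonsyn poly (pos 1 A->C), fixed syn and nonsyn vs outgroup
  seqs <- c("ACTGGTTTA", "ACCGGTTTA", "CCTGGTTTA", "ACTGGTTTA")
  #            syn@2     nonsyn@0 (ACT Thr -> CCT Pro)
  aln <- make_alignment(seqs, exons = cbind(0, 9),
                        outgroup = "ACTGGGTTG")
  # outgroup differs at pos 5 (T->G: GGT Gly -> GGG Gly, syn fixed)
  # and pos 8 (A->G: TTA Leu -> TTG Leu, syn fixed)
  res <- mk_test(aln)
  expect_equal(res$table["polymorphic", "synonymous"], 1)
  expect_equal(res$table["polymorphic", "nonsynonymous"], 1)
  expect_equal(res$table["fixed", "synonymous"], 2)
  expect_equal(res$table["fixed", "nonsynonymous"], 0)
  expect_true(res$performed)  # no zero margin here

  # outgroup identical to the consensus: zero fixed differences -> margin
  # rule reports the test as not calculable
  res0 <- mk_test(make_alignment(seqs, exons = cbind(0, 9),
                                 outgroup = "ACTGGTTTA"))
  expect_equal(sum(res0$table["fixed", ]), 0)
  expect_false(res0$performed)

  # add a fixed nonsynonymous difference to complete the table
  aln2 <- make_alignment(seqs, exons = cbind(0, 9),
                         outgroup = "ACTGGGTCA")
  # pos 7 T->C: TTA Leu -> TCA Ser, nonsyn fixed (plus pos 5 syn fixed)
  res2 <- mk_test(aln2)
  expect_true(res2$performed)
  expect_true(res2$p_value >= 0 && res2$p_value <= 1)
  expect_equal(res2$p_value,
               fisher.test(res2$table)$p.value)
})

test_that("fixed-S coalescent p-values behave at the extremes", {
  set.seed(26)
  # statistic at the null median -> p near 1
  null_d <- replicate(400, pinepop:::matrix_stat(
    "tajima_d", pinepop:::sim_fixed_s_matrix(10, 5)))
  med <- median(null_d)
  p_mid <- coalescent_pvalue("tajima_d", med, 10, 5, reps = 400,
                             seed = 1)$p_value
  expect_gt(p_mid, 0.5)
  p_low <- coalescent_pvalue("tajima_d", -10, 10, 5, reps = 1000,
                             seed = 2)$p_value
  expect_lte(p_low, 2 / 1000)
  expect_error(coalescent_pvalue("tajima_d", 0, 10, 0), "S_obs > 0")
  expect_error(coalescent_pvalue("tajima_d", 0, 10, 5, reps = 10),
               "at least 100")
})

test_that("the neutrality table reports every statistic with a p-value", {
  set.seed(27)
  alns <- lapply(1:2, function(i) {
    a <- random_alignment(10, 200, 8, outgroup = TRUE)
    a$locus_id <- paste0("L", i)
    a
  })
  tab <- neutrality_table(alns, reps = 200, seed = 3)
  expect_setequal(unique(tab$statistic),
                  c("tajima_d", "fu_li_d_star", "fu_li_f_star", "fu_fs",
                    "fay_wu_h"))
  ok <- !is.na(tab$p_value)
  expect_true(all(tab$p_value[ok] >= 0 & tab$p_value[ok] <= 1))
})
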
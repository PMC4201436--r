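test_that("segregating sites counts varying included columns", {
  aln <- make_alignment(c("AAT", "AAT", "ACT", "AAT"))
  expect_equal(segregating_sites(aln), 1)
  expect_equal(segregating_sites(make_alignment(rep("ACGT", 4))), 0)
  one <- make_alignment(rep("ACGT", 2))
  one$seqs <- one$seqs[1, , drop = FALSE]
  expect_error(segregating_sites(one), "at least 2")
})

test_that("segregating sites match a brute-force column scan", {
  set.seed(5)
  for (r in 1:5) {
    aln <- random_alignment(20, 200, 25)
    expect_equal(segregating_sites(aln), oracle_S(aln))
  }
})

test_that("Watterson's estimator matches hand arithmetic", {
  expect_equal(watterson_theta(0, 10, 100), 0)
  # a_3 = 1 + 1/2 + 1/3 = 11/6; 3 / (11/6 * 100)
  expect_equal(watterson_theta(3, 4, 100), 3 / (11 / 6 * 100),
               tolerance = 1e-12)
  expect_equal(round(watterson_theta(3, 4, 100), 6), 0.016364)
  expect_error(watterson_theta(3, 4, 0), "positive")
})

test_that("nucleotide diversity equals brute-force pairwise counting", {
  expect_equal(nucleotide_diversity(make_alignment(c("AAAA", "AAAT"))), 0.25)
  aln4 <- make_alignment(c("AAAA", "AAAT", "AATT", "AATT"))
  expect_equal(nucleotide_diversity(aln4), (1 + 2 + 2 + 1 + 1 + 0) / 6 / 4,
               tolerance = 1e-12)
  set.seed(6)
  for (r in 1:5) {
    aln <- random_alignment(12, 120, 15)
    expect_equal(nucleotide_diversity(aln) * 120,
                 oracle_pi_locus(aln), tolerance = 1e-9)
  }
})

test_that("per-site rates are invariant to relabeling and to scale", {
  set.seed(8)
  aln <- random_alignment(10, 100, 12)
  perm <- sample(10)
  aln2 <- aln
  aln2$seqs <- aln$seqs[perm, ]
  aln2$individual <- aln$individual[perm]
  aln2$allele <- aln$allele[perm]
  expect_equal(nucleotide_diversity(aln2), nucleotide_diversity(aln))
  expect_equal(tajimas_d(aln2), tajimas_d(aln))
  # doubling L by self-concatenation halves nothing: per-site rate constant
  dbl <- aln
  dbl$seqs <- cbind(aln$seqs, aln$seqs)
  dbl$L <- 200
  expect_equal(nucleotide_diversity(dbl), nucleotide_diversity(aln))
})

test_that("haplotype diversity uses the unbiased estimator", {
  expect_equal(haplotype_summary(letters[1:9])$H_e, 1)
  expect_equal(haplotype_summary(letters[1:9])$n_h, 9)
  all_same <- haplotype_summary(rep("h", 6))
  expect_equal(all_same$n_h, 1)
  expect_equal(all_same$H_e, 0)
  expect_equal(haplotype_summary(rep(c("x", "y"), each = 5))$H_e,
               10 / 9 * 0.5, tolerance = 1e-12)
  expect_equal(round(haplotype_summary(rep(c("x", "y"), each = 5))$H_e, 4),
               0.5556)
  expect_error(haplotype_summary("a"), "n >= 2")
})

test_that("unbiased H_e equals the brute-force pairwise definition", {
  set.seed(11)
  for (r in 1:10) {
    x <- sample(letters[1:4], sample(4:12, 1), replace = TRUE)
    expect_equal(haplotype_summary(x)$H_e, oracle_he(x), tolerance = 1e-12)
  }
})

test_that("F_IS reflects heterozygote excess and deficit", {
  pops <- population_map(data.frame(
    individual = sprintf("i%02d", 1:10), population = "P1"))
  # every individual heterozygous A/T at one site
  het <- make_alignment(rep(c("AAAA", "AAAT"), 10))
  expect_lt(fis_estimate(list(het), pops), 0)
  # all homozygous, alleles at 50/50
  hom <- make_alignment(rep(c("AAAA", "AAAA", "AAAT", "AAAT"), 5))
  expect_equal(fis_estimate(list(hom), pops), 1)
  mono <- make_alignment(rep("AAAA", 20))
  expect_true(is.na(fis_estimate(list(mono), pops)))
})

test_that("random mating yields F_IS near zero", {
  set.seed(13)
  n_ind <- 2000
  alleles <- sample(c("AAAA", "AAAT", "AATT"), 2 * n_ind, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2))
  aln <- make_alignment(alleles)
  pops <- population_map(data.frame(
    individual = unique(aln$individual), population = "P1"))
  expect_lt(abs(fis_estimate(list(aln), pops)), 0.02)
})

test_that("diversity table covers populations, regions and the total", {
  set.seed(14)
  fx <- generate_sequence_study(seed = 21,
                                pop_sizes = setNames(c(4L, 5L, 3L),
                                                     paste0("P", 1:3)),
                                locus_lengths = c(300L, 360L))
  div <- diversity_table(fx$loci, fx$popmap)
  expect_true(all(c("total", "P1", "P2", "P3") %in% div$group))
  expect_true(any(grepl("^region:", div$group)))
  expect_true(all(div$H_e >= 0 & div$H_e <= 1))
  avg <- diversity_averages(div, fx$loci)
  expect_equal(nrow(avg), length(unique(div$group)))
  # site-weighted average of identical per-locus rates is that rate
  expect_true(all(avg$theta_w >= 0))
})

test_that("silent diversity is about fourfold the nonsynonymous diversity under the 4:1 generator", {
  fx <- generate_sequence_study(
    model = demographic_model("SNM", theta_site = 0.01),
    fst_target = 0, seed = 31,
    pop_sizes = setNames(c(10L, 10L), c("P1", "P2")),
    locus_lengths = rep(3000L, 6))
  ratios <- vapply(fx$loci, function(a) {
    cl <- classify_sites(a)
    nucleotide_diversity(a, "silent", cl) /
      nucleotide_diversity(a, "nonsynonymous", cl)
  }, 0)
  expect_equal(mean(ratios, na.rm = TRUE), 4, tolerance = 0.2)
})
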
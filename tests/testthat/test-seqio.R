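test_that("alignment construction validates its invariants", {
  aln <- make_alignment(c("ACGTACGTAC", "ACGTACGTAC", "ACGAACGTAC",
                          "ACGTACGTAC"),
                        exons = cbind(0, 6))
  expect_s3_class(aln, "locus_alignment")
  expect_equal(aln$L, 10)
  expect_equal(length(unique(aln$individual)), 2)

  expect_error(make_alignment(c("ACGTACGTA", "ACGTACGTAC", "ACGTACGTAC",
                                "ACGTACGTAC")),
               "i01.*length 10, expected 9", ignore.case = TRUE)
  expect_error(
    locus_alignment("x", c("ACGT", "ACGT", "ACGT"),
                    individual = c("a", "a", "b"), allele = c(1, 2, 1)),
    "'b' contributes 1 allele")
  expect_error(make_alignment(rep("ACGT", 4), exons = cbind(0, 6)),
               "outside")
  expect_error(make_alignment(rep("ACGT", 4), exons = cbind(0, 4)),
               "divisible by 3")
  expect_error(make_alignment(rep("ACXT", 4)), "invalid base")
})

test_that("FASTA round trip preserves the alignment", {
  set.seed(7)
  dir <- withr::local_tempdir()
  alns <- lapply(1:3, function(i) {
    a <- random_alignment(10, 60, 6, outgroup = TRUE)
    a$locus_id <- sprintf("locus%02d", i)
    a$exons <- cbind(start = 0L, end = 30L)
    a
  })
  for (a in alns) {
    fa <- file.path(dir, paste0(a$locus_id, ".fasta"))
    og <- file.path(dir, paste0(a$locus_id, "_og.fasta"))
    write_locus_fasta(a, fa, og)
    back <- read_locus_fasta(fa, annotation = data.frame(start = 0, end = 30),
                             outgroup_path = og, locus_id = a$locus_id)
    expect_identical(back$seqs, a$seqs)
    expect_identical(back$individual, a$individual)
    expect_identical(back$outgroup, a$outgroup)
    expect_equal(back$exons[, "start"], a$exons[, "start"],
                 ignore_attr = TRUE)
  }
})

test_that("site classification follows Nei-Gojobori counting", {
  # all-intron locus: every included column is noncoding
  aln <- make_alignment(rep(strrep("ACGT", 125), 4))
  cl <- classify_sites(aln)
  expect_equal(cl$silent_sites, 500)
  expect_equal(cl$nonsyn_sites, 0)

  # TTT (Phe): only third-position changes can be synonymous (TTC), 1 of 3
  aln <- make_alignment(rep("TTT", 4), exons = cbind(0, 3))
  cl <- classify_sites(aln)
  expect_equal(cl$synonymous, c(0, 0, 1 / 3))
  expect_equal(cl$nonsynonymous, c(1, 1, 2 / 3))

  # ATG (Met): no synonymous single-base change exists
  aln <- make_alignment(rep("ATG", 4), exons = cbind(0, 3))
  cl <- classify_sites(aln)
  expect_equal(cl$synonymous, c(0, 0, 0))
  expect_equal(sum(cl$nonsyn_sites), 3)
})

test_that("class fractions sum to one and totals partition the locus", {
  set.seed(42)
  for (rep in 1:5) {
    aln <- random_alignment(8, 90, 10)
    aln$exons <- cbind(start = 12L, end = 12L + 30L)
    cl <- classify_sites(aln)
    w <- cl$noncoding + cl$synonymous + cl$nonsynonymous
    expect_true(all(abs(w[!cl$excluded] - 1) < 1e-12))
    expect_equal(cl$silent_sites + cl$nonsyn_sites + sum(cl$excluded),
                 aln$L)
  }
})

test_that("gap and N columns are excluded everywhere", {
  aln <- make_alignment(c("A-GT", "ACGT", "ACGT", "ACNT"))
  cl <- classify_sites(aln)
  expect_equal(which(cl$excluded), c(2, 3))
  expect_equal(cl$total_sites, 2)
  expect_equal(segregating_sites(aln), 0)
})

test_that("site classification ignores sequence order", {
  set.seed(9)
  aln <- random_alignment(10, 60, 8)
  aln$exons <- cbind(start = 0L, end = 30L)
  perm <- sample(nrow(aln$seqs))
  aln2 <- aln
  aln2$seqs <- aln$seqs[perm, ]
  aln2$individual <- aln$individual[perm]
  aln2$allele <- aln$allele[perm]
  expect_equal(classify_sites(aln2)[c("synonymous", "nonsynonymous")],
               classify_sites(aln)[c("synonymous", "nonsynonymous")])
})

test_that("concatenation is additive and offsets exons", {
  a <- make_alignment(rep(strrep("A", 494), 4), exons = cbind(0, 9))
  b <- make_alignment(rep(strrep("C", 1252), 4), exons = cbind(10, 22))
  cc <- concatenate_loci(list(a, b))
  expect_equal(cc$L, 1746)
  expect_equal(cc$exons[2, "start"], 494 + 10, ignore_attr = TRUE)
  expect_identical(concatenate_loci(list(a)), a)

  # study-shaped lengths reach the full concatenated size
  lens <- pinepop:::study_locus_lengths()
  loci <- lapply(seq_along(lens), function(i)
    make_alignment(rep(strrep("A", lens[i]), 2),
                   locus_id = sprintf("l%d", i)))
  expect_equal(concatenate_loci(loci)$L, 8950)

  b2 <- locus_alignment("b2", rep("AAAA", 2), c("zz", "zz"), 1:2)
  expect_error(concatenate_loci(list(a, b2)), "individual set differs")
})

test_that("population map and SSR tables round trip through TSV/CSV", {
  dir <- withr::local_tempdir()
  pm <- population_map(
    data.frame(individual = c("a", "b", "c"),
               population = c("P1", "P1", "P2")),
    data.frame(population = c("P1", "P2"), lon = c(108.1, 108.2),
               lat = c(12, 12.1)))
  write.table(pm$assignments, file.path(dir, "pops.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(pm$coordinates, file.path(dir, "coords.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  back <- read_population_map(file.path(dir, "pops.tsv"),
                              file.path(dir, "coords.tsv"))
  expect_equal(back$assignments$population, pm$assignments$population)

  m <- matrix(c(5L, 6L, 7L, 7L, 8L, 8L), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  ssr <- ssr_dataset(m)
  write_ssr_table(ssr, file.path(dir, "ssr.csv"))
  back <- read_ssr_table(file.path(dir, "ssr.csv"))
  expect_equal(back$repeats[rownames(m), colnames(m)], m)

  expect_error(population_map(pm$assignments,
                              data.frame(population = "P1", lon = 1, lat = 2)),
               "coordinates missing")
})
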
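test_that("AMOVA variance components match a hand-worked 2x2 design", {
  d <- matrix(0, 4, 4, dimnames = rep(list(letters[1:4]), 2))
  d["a", "b"] <- d["b", "a"] <- 2
  d["c", "d"] <- d["d", "c"] <- 4
  d["a", "c"] <- d["c", "a"] <- 10
  d["a", "d"] <- d["d", "a"] <- 8
  d["b", "c"] <- d["c", "b"] <- 6
  d["b", "d"] <- d["d", "b"] <- 12
  # by hand: SSD_T = 42/4, SSD_WP = 2/2 + 4/2 = 3, SSD_AP = 7.5,
  # MS_AP = 7.5, sigma_w = 1.5, n_c = 2, sigma_a = 3, F_ST = 2/3
  cmp <- pinepop:::amova_components(d, c("A", "A", "B", "B"))
  expect_equal(cmp$fst, 2 / 3, tolerance = 1e-12)
  expect_equal(cmp$components$SSD, c(7.5, 3), tolerance = 1e-12)
  expect_equal(cmp$components$sigma2, c(3, 1.5), tolerance = 1e-12)
})

test_that("fixed haplotype differences give F_ST = 1", {
  seqs <- c(rep("AAAA", 6), rep("TTTT", 6))
  aln <- make_alignment(seqs)
  pops <- population_map(data.frame(
    individual = unique(aln$individual),
    population = rep(c("A", "B"), each = 3)))
  fit <- amova_fst(list(aln), pops, permutations = 200, seed = 1)
  expect_equal(fit$fst, 1, tolerance = 1e-12)
  expect_lt(fit$p_value, 0.05)
})

test_that("F_ST is invariant under population relabeling and can go negative", {
  set.seed(41)
  aln <- random_alignment(16, 80, 10)
  labels <- rep(c("A", "B"), each = 8)
  d <- pinepop:::sequence_distance_matrix(aln)
  f1 <- pinepop:::amova_components(d, labels)$fst
  f2 <- pinepop:::amova_components(d, rev(labels))$fst
  expect_equal(f1, f2, tolerance = 1e-12)
  expect_true(f1 >= -0.5 && f1 <= 1)
})

test_that("single-unit populations are excluded with a warning", {
  seqs <- c(rep("AAAA", 4), rep("TTTT", 4), "AATT", "AATT")
  aln <- make_alignment(seqs)
  pops_vec <- c(rep("A", 4), rep("B", 4), "C", "C")
  d <- pinepop:::sequence_distance_matrix(aln)
  rownames(d) <- colnames(d) <- NULL
  labels <- c(rep("A", 4), rep("B", 4), "C", "C")
  labels[9] <- "solo"; labels[10] <- "C2"  # two singleton pops
  expect_warning(amova_fst(d, labels, permutations = 100, seed = 1),
                 "single unit")
})

test_that("regions add an among-group level with F_CT", {
  seqs <- c(rep("AAAA", 4), rep("AATT", 4), rep("TTTT", 4), rep("TTAA", 4))
  aln <- make_alignment(seqs)
  labels <- rep(c("P1", "P2", "P3", "P4"), each = 4)
  groups <- c(P1 = "R1", P2 = "R1", P3 = "R2", P4 = "R2")
  d <- pinepop:::sequence_distance_matrix(aln)
  fit <- amova_fst(d, labels, permutations = 100, seed = 2, groups = groups)
  expect_false(is.na(fit$fct))
  expect_equal(nrow(fit$components), 3)
  # groups separate two fixed clusters more than populations within them
  expect_gt(fit$fct, 0)
})

test_that("pairwise F_ST matrices are symmetric with unit diagonal structure", {
  set.seed(42)
  fx <- generate_sequence_study(seed = 5,
                                pop_sizes = setNames(c(5L, 5L, 4L), paste0("P", 1:3)),
                                locus_lengths = c(400L, 500L))
  pw <- pairwise_fst(fx$loci, fx$popmap)
  expect_true(isSymmetric(pw))
  expect_equal(diag(pw), setNames(rep(0, 3), paste0("P", 1:3)))
})

test_that("G_ST and R_ST respond to frequency and repeat structure", {
  # identical frequency vectors in every population: G_ST exactly 0
  reps <- rbind(matrix(c(5L, 7L), 4, 2, byrow = TRUE),
                matrix(c(6L, 8L), 4, 2, byrow = TRUE))
  reps <- rbind(reps, reps)  # two populations with identical composition
  rownames(reps) <- sprintf("i%02d", 1:16)
  colnames(reps) <- c("s1", "s2")
  ssr <- ssr_dataset(reps)
  pops <- rep(c("A", "B"), each = 8)
  pops <- pops[order(rep(1:2, 8))]  # interleave so both pops carry both
  res <- gst_rst_compare(ssr, rep(c("A", "B"), 8), permutations = 100,
                         seed = 1)
  expect_equal(res$G_ST, 0, tolerance = 1e-12)

  # fixed populations 1 repeat apart vs 5 repeats apart: same G_ST,
  # ordered statistic grows with the repeat distance
  fixed <- function(gap) {
    m <- rbind(matrix(5L, 5, 1), matrix(5L + gap, 5, 1))
    rownames(m) <- sprintf("i%02d", 1:10)
    colnames(m) <- "s1"
    ssr_dataset(m)
  }
  p <- rep(c("A", "B"), each = 5)
  near <- gst_rst_compare(fixed(1L), p, permutations = 50, seed = 1)
  far <- gst_rst_compare(fixed(5L), p, permutations = 50, seed = 1)
  expect_equal(near$G_ST, far$G_ST, tolerance = 1e-12)
  expect_equal(near$R_ST, far$R_ST, tolerance = 1e-12)  # both fully fixed
  # the underlying ordered numerator distances differ by 25x
  expect_equal(as.numeric(dist(rbind(5, 10)))^2 /
                 as.numeric(dist(rbind(5, 6)))^2, 25)

  mono <- ssr_dataset(matrix(5L, 4, 2,
                             dimnames = list(letters[1:4], c("a", "b"))))
  expect_warning(res0 <- gst_rst_compare(mono, rep(c("A", "B"), 2),
                                         permutations = 50),
                 "monomorphic")
  expect_true(is.na(res0$G_ST))
})

test_that("the Mantel test agrees with exhaustive permutation enumeration", {
  coords <- data.frame(population = paste0("P", 1:5),
                       lon = c(108.10, 108.13, 108.42, 108.71, 109.30),
                       lat = c(12.00, 12.09, 12.17, 12.41, 12.52))
  geo_rank <- as.matrix(dist(coords[, c("lon", "lat")]))
  fst <- geo_rank^1.5          # monotone transform of distance
  dimnames(fst) <- list(coords$population, coords$population)
  res <- mantel_test(fst, coords, permutations = 1000, seed = 1)
  expect_gt(res$value, 0.9)
  expect_true(res$exhaustive)
  expect_equal(res$permutations, 120)
  expect_equal(res$p_value, 1 / 120)  # observed ordering is uniquely best

  # independent check against vegan's Mantel r on the same matrices
  geo <- matrix(0, 5, 5)
  for (i in 1:4) for (j in (i + 1):5)
    geo[i, j] <- geo[j, i] <- geosphere::distHaversine(
      as.numeric(coords[i, 2:3]), as.numeric(coords[j, 2:3])) / 1000
  vg <- vegan::mantel(as.dist(fst), as.dist(geo), permutations = 99)
  expect_equal(res$value, unname(vg$statistic), tolerance = 1e-12)

  expect_error(mantel_test(matrix(1:25, 5), coords), "symmetric")
  const <- fst * 0
  dimnames(const) <- dimnames(fst)
  expect_warning(resc <- mantel_test(const, coords), "zero variance")
  expect_true(is.na(resc$value))
})

test_that("permutation p-values are reproducible from the seed", {
  set.seed(43)
  aln <- random_alignment(12, 60, 8)
  labels <- rep(c("A", "B", "C"), each = 4)
  d <- pinepop:::sequence_distance_matrix(aln)
  f1 <- amova_fst(d, labels, permutations = 200, seed = 99)
  f2 <- amova_fst(d, labels, permutations = 200, seed = 99)
  expect_identical(f1$p_value, f2$p_value)
})
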
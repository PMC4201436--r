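test_that("the growth exponent follows its definition", {
  expect_equal(growth_rate(demographic_model("GROWTH", 0.01, N1_rel = 1,
                                             T0 = 0.5)), 0)
  expect_equal(growth_rate(demographic_model("GROWTH", 0.01,
                                             N1_rel = exp(-1), T0 = 1)), 1)
  # posterior-mode values of the study system: ln(1/0.0318)/8.593e-4
  a <- growth_rate(demographic_model("GROWTH", 0.01, N1_rel = 0.0318,
                                     T0 = 0.8593e-3))
  expect_equal(a, 4013, tolerance = 1e-3)
  expect_error(growth_rate(demographic_model("SNM", 0.01)), "no growth")
})

test_that("mutation-free and mutation-rich limits behave", {
  s <- simulate_locus(demographic_model("SNM", 0), 8, 100, seed = 1)
  expect_equal(ncol(s$haplotypes), 0)
  s2 <- simulate_locus(snm(0.05), 8, 1000, seed = 2)
  expect_gt(ncol(s2$haplotypes), 0)
  # every simulated column is polymorphic with ancestral state 0
  cnt <- colSums(s2$haplotypes)
  expect_true(all(cnt > 0 & cnt < 8))
})

test_that("mean segregating sites match the coalescent expectation", {
  set.seed(51)
  reps <- 3000
  S <- replicate(reps, ncol(simulate_locus(snm(0.1), 10, 10)$haplotypes))
  a9 <- sum(1 / (1:9))
  expect_lt(abs(mean(S) - a9), 3 * sd(S) / sqrt(reps))
})

test_that("summary statistics are exchangeable over chromosome relabeling", {
  s <- simulate_locus(snm(0.02), 12, 500, seed = 7)
  m <- s$haplotypes
  perm <- sample(nrow(m))
  for (stat in c("tajima_d", "zns", "fay_wu_h"))
    expect_equal(pinepop:::matrix_stat(stat, m[perm, ]),
                 pinepop:::matrix_stat(stat, m), tolerance = 1e-12)
})

test_that("recent growth skews Tajima's D negative", {
  set.seed(52)
  mg <- demographic_model("GROWTH", 0.01, N1_rel = 0.01, T0 = 0.01)
  d <- replicate(500, pinepop:::matrix_stat(
    "tajima_d", simulate_locus(mg, 15, 1000)$haplotypes))
  expect_lt(mean(d, na.rm = TRUE), -0.3)
})

test_that("recombination dissolves linkage: ZnS decreases in rho", {
  set.seed(53)
  z <- vapply(c(0, 0.05), function(rho) {
    mean(replicate(200, pinepop:::matrix_stat(
      "zns", simulate_locus(snm(0.01, rho), 15, 1000)$haplotypes)),
      na.rm = TRUE)
  }, 0)
  expect_gt(z[1], z[2])
})

test_that("C++ and R summary paths agree on the same data", {
  set.seed(54)
  for (r in 1:10) {
    s <- simulate_locus(snm(0.02, 0.01), 10, 400)
    m <- s$haplotypes
    if (ncol(m) < 3) next
    mine <- summarize_simulated(list(s))
    expect_equal(unname(mine["tajima_d"]),
                 pinepop:::matrix_stat("tajima_d", m), tolerance = 1e-12)
    expect_equal(unname(mine["zns"]),
                 pinepop:::matrix_stat("zns", m), tolerance = 1e-12)
    expect_equal(unname(mine["fay_wu_h"]),
                 oracle_fay_wu_h(colSums(m), nrow(m)), tolerance = 1e-9)
  }
})

test_that("branch records form a proper genealogy", {
  gen <- simulate_genealogy(snm(0.01), 10, seed = 8)
  expect_length(gen$duration, 18)      # 2n - 2 branches
  expect_true(all(gen$duration >= 0))
  # leaf subtension counts span 1..n-1 and the root covers everything
  sizes <- rowSums(gen$leaves)
  expect_true(all(sizes >= 1 & sizes <= 9))
  # total branch length matches E[sum i * Ti] within a loose band over reps
  set.seed(9)
  tot <- replicate(800, sum(pinepop:::.coal_branches_cpp(10, 0, 1, 0)$duration))
  expect_lt(abs(mean(tot) - sum(1 / (1:9))), 3 * sd(tot) / sqrt(800))
})

test_that("SSR simulation follows the stepwise mutation model", {
  ssr0 <- simulate_ssr(snm(0.01), 10, 4, theta_ssr = 0, seed = 10)
  expect_equal(length(unique(ssr_haplotypes(ssr0))), 1)
  # n = 2 repeat-difference variance: Poisson steps on both branches give
  # E[(r1 - r2)^2] = theta * E[total length] = theta * 2 * E[t2] = theta
  set.seed(11)
  th <- 0.8
  d2 <- replicate(4000, {
    r <- simulate_ssr(snm(0.01), 2, 1, theta_ssr = th)$repeats
    (r[1, 1] - r[2, 1])^2
  })
  expect_lt(abs(mean(d2) - th), 3 * sd(d2) / sqrt(4000))
  # saturation: high rate drives haplotype diversity toward 1
  hi <- simulate_ssr(snm(0.01), 57, 7, theta_ssr = 50, seed = 12)
  expect_gt(haplotype_summary(ssr_haplotypes(hi))$H_e, 0.95)
})

test_that("ms-format output round-trips the haplotype block", {
  s <- simulate_locus(snm(0.02), 6, 300, seed = 13)
  path <- withr::local_tempfile(fileext = ".ms")
  write_ms(s, path)
  lines <- readLines(path)
  expect_true(any(grepl("^segsites:", lines)))
  seg <- as.integer(sub("segsites: ", "", lines[grepl("^segsites:", lines)]))
  expect_equal(seg, ncol(s$haplotypes))
  haps <- lines[grepl("^[01]+$", lines)]
  expect_equal(length(haps), 6)
  expect_equal(nchar(haps[1]), ncol(s$haplotypes))
})

test_that("simulations are reproducible from their seed", {
  a <- simulate_locus(snm(0.02, 0.01), 10, 500, seed = 99)
  b <- simulate_locus(snm(0.02, 0.01), 10, 500, seed = 99)
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(a$positions, b$positions)
})
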
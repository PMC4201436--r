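# A reusable fake reference table with analytically controlled structure:
# parameter-summary relationships are set by construction, so the rejection
# and adjustment mechanics can be checked without simulation noise.
fake_table <- function(n_rows, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      model = "GROWTH",
      theta_site = runif(n_rows, 1e-4, 0.05),
      rho_site = runif(n_rows, 1e-4, 0.1),
      N1_rel = runif(n_rows, 0.001, 1),
      T0 = runif(n_rows, 1e-5, 0.05),
      Td = NA_real_,
      theta_w = runif(n_rows), tajima_d = rnorm(n_rows),
      fay_wu_h = rnorm(n_rows), zns = runif(n_rows))
  })
}

test_that("rejection keeps the p_delta closest rows under MAD scaling", {
  tab <- fake_table(5000)
  obs <- unlist(tab[17, c("theta_w", "tajima_d", "fay_wu_h", "zns")])
  post <- abc_reject(obs, tab, p_delta = 1 / 5000)
  expect_equal(nrow(post$accepted), 1)
  expect_equal(post$accepted$theta_w, tab$theta_w[17])

  all_rows <- abc_reject(obs, tab, p_delta = 1)
  expect_equal(nrow(all_rows$accepted), 5000)

  # the acceptance count is ceiling(p_delta * rows): a pooled 9e5-row table
  # at p_delta = 0.001 keeps exactly 900 points
  big <- fake_table(900000)
  post9 <- abc_reject(obs, big, p_delta = 0.001)
  expect_equal(nrow(post9$accepted), 900)
})

test_that("zero-MAD components are dropped with a warning", {
  tab <- fake_table(2000)
  tab$zns <- 0.5
  obs <- c(theta_w = 0.5, tajima_d = 0, fay_wu_h = 0, zns = 0.5)
  expect_warning(post <- abc_reject(obs, tab, 0.01), "zero-MAD")
  expect_false("zns" %in% post$components)
})

test_that("regression adjustment respects its analytic limits", {
  tab <- fake_table(4000, seed = 2)
  obs <- c(theta_w = 0.5, tajima_d = 0, fay_wu_h = 0, zns = 0.5)

  # summaries carry no information: adjusted draws stay near the raw ones
  post <- regression_adjust(abc_reject(obs, tab, 0.05), abc_priors())
  raw <- post$accepted$theta_site
  adj <- post$adjusted$theta_site
  expect_gt(cor(log(raw), log(adj)), 0.95)

  # parameter exactly log-linear in one summary: posterior collapses to the
  # value implied at the observation
  tab2 <- fake_table(4000, seed = 3)
  tab2$theta_site <- exp(-5 + 2 * tab2$theta_w)
  post2 <- regression_adjust(abc_reject(obs, tab2, 0.05), abc_priors())
  expect_lt(sd(log(post2$adjusted$theta_site)), 1e-8)
  expect_equal(mean(post2$adjusted$theta_site), exp(-5 + 2 * 0.5),
               tolerance = 1e-6)
})

test_that("model probabilities separate what is separable and stay symmetric", {
  n <- 3000
  withr::with_seed(4, {
    mk <- function(model, shift) tibble::tibble(
      model = model, theta_site = runif(n, 1e-4, 0.05),
      rho_site = runif(n, 1e-4, 0.1), N1_rel = NA_real_, T0 = NA_real_,
      Td = NA_real_,
      theta_w = runif(n) + shift, tajima_d = rnorm(n) + shift,
      fay_wu_h = rnorm(n), zns = runif(n))
    sep <- dplyr::bind_rows(mk("SNM", 0), mk("GROWTH", 8),
                            mk("BOTTLENECK", -8))
  })
  obs <- c(theta_w = 8.5, tajima_d = 8, fay_wu_h = 0, zns = 0.5)
  pr <- suppressWarnings(model_posterior_probs(obs, sep, p_delta = 0.01))
  expect_gt(pr$posterior_prob[pr$model == "GROWTH"], 0.99)
  expect_equal(sum(pr$posterior_prob), 1, tolerance = 1e-6)

  # identical summary distributions: probabilities near 1/3 each
  withr::with_seed(5, {
    same <- dplyr::bind_rows(mk("SNM", 0), mk("GROWTH", 0),
                             mk("BOTTLENECK", 0))
  })
  obs2 <- c(theta_w = 0.5, tajima_d = 0, fay_wu_h = 0, zns = 0.5)
  pr2 <- model_posterior_probs(obs2, same, p_delta = 0.1)
  expect_true(all(abs(pr2$posterior_prob - 1 / 3) < 0.1))
})

test_that("probabilities are invariant to duplicating every table row", {
  tab <- fake_table(2000, seed = 6)
  tab$model <- rep(c("SNM", "GROWTH"), each = 1000)
  obs <- c(theta_w = 0.5, tajima_d = 0, fay_wu_h = 0, zns = 0.5)
  p1 <- model_posterior_probs(obs, tab, 0.05)
  p2 <- model_posterior_probs(obs, dplyr::bind_rows(tab, tab), 0.05)
  expect_equal(p1$posterior_prob, p2$posterior_prob, tolerance = 0.02)
})

test_that("observed and simulated summary paths agree on the same loci", {
  set.seed(71)
  fx <- generate_sequence_study(
    seed = 8, fst_target = 0,
    pop_sizes = setNames(c(5L, 5L), c("P1", "P2")),
    locus_lengths = c(500L, 700L, 600L))
  obs <- summarize_dataset(fx$loci)
  expect_named(obs, c("theta_w", "tajima_d", "fay_wu_h", "zns"))
  # recompute each component with the module-level statistics
  tw <- mean(vapply(fx$loci, function(a)
    watterson_theta(segregating_sites(a), nrow(a$seqs),
                    classify_sites(a)$total_sites), 0))
  expect_equal(unname(obs["theta_w"]), tw, tolerance = 1e-12)
  d <- vapply(fx$loci, tajimas_d, 0)
  expect_equal(unname(obs["tajima_d"]), mean(ifelse(is.na(d), 0, d)),
               tolerance = 1e-12)
  z <- vapply(fx$loci, function(a) as.numeric(kelly_zns(a)), 0)
  expect_equal(unname(obs["zns"]), mean(z), tolerance = 1e-12)
})

test_that("unit conversions follow their closed forms", {
  expect_equal(signif(ne_from_theta(0.002, 7e-10, 50), 3), 14300)
  expect_equal(ne_from_theta(0.004, 7e-10, 50),
               2 * ne_from_theta(0.002, 7e-10, 50))
  expect_equal(scaled_time_to_years(0.8593, 1.43e4, 50), 2458)
  expect_equal(scaled_time_to_years(0.0408, 1.43e4, 50), 117)
  expect_equal(scaled_time_to_years(22.730, 1.43e4, 50), 65008)
  expect_equal(ancestral_size_individuals(0.0318, 1.43e4), 455)
  expect_equal(ancestral_size_individuals(1, 1234), 1234)
  expect_equal(ancestral_size_individuals(0.5, 1000), 500)
  expect_error(ne_from_theta(-1, 7e-10, 50))
  expect_error(scaled_time_to_years(0, 1, 1))
})

test_that("posterior summaries and predictive checks are well-formed", {
  set.seed(72)
  tab <- build_reference_table(400, n = 10, L = rep(300L, 3),
                               models = "GROWTH", seed = 11)
  obs <- c(theta_w = median(tab$theta_w), tajima_d = median(tab$tajima_d),
           fay_wu_h = median(tab$fay_wu_h), zns = median(tab$zns))
  post <- regression_adjust(abc_reject(obs, tab, p_delta = 0.2),
                            abc_priors())
  td <- tidy(post)
  expect_setequal(td$parameter, c("theta_site", "rho_site", "N1_rel", "T0"))
  expect_true(all(td$q2.5 <= td$mode & td$mode <= td$q97.5 |
                    is.na(td$mode) == FALSE))
  ppc <- posterior_predictive_check(post, reps = 60, n = 10,
                                    L = rep(300L, 3), seed = 12)
  expect_equal(nrow(ppc), 4)
  expect_true(all(ppc$tail_prob >= 0 & ppc$tail_prob <= 1))
  # a central observation should not be flagged as extreme
  expect_true(all(ppc$tail_prob > 0.01))
})
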
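#' Binary coding of SSR repeat counts
#'
#' Per locus, a repeat number `k` over the observed range `[kmin, kmax]` is
#' encoded as `k - kmin` ones followed by `kmax - k` zeros; locus blocks are
#' concatenated. The Hamming distance between two coded haplotypes then
#' equals the summed absolute repeat differences, which is what makes the
#' coding suitable for mismatch analysis of microsatellites.
#'
#' @param ssr an [ssr_dataset()].
#' @return a 0/1 integer matrix, individuals in rows.
#' @export
ssr_binary_code <- function(ssr) {
  blocks <- lapply(seq_len(ncol(ssr$repeats)), function(l) {
    k <- ssr$repeats[, l]
    kmin <- min(k); kmax <- max(k)
    if (kmax == kmin) return(NULL)
    w <- kmax - kmin
    matrix(unlist(lapply(k, function(ki)
      c(rep(1L, ki - kmin), rep(0L, kmax - ki)))),
      nrow = length(k), ncol = w, byrow = TRUE)
  })
  blocks <- blocks[!vapply(blocks, is.null, TRUE)]
  if (!length(blocks))
    return(matrix(integer(0), nrow(ssr$repeats), 0,
                  dimnames = list(rownames(ssr$repeats), NULL)))
  out <- do.call(cbind, blocks)
  rownames(out) <- rownames(ssr$repeats)
  out
}

#' Mismatch distribution
#'
#' Empirical distribution of pairwise difference counts over all unordered
#' pairs of haplotypes.
#'
#' @param x a 0/1 matrix (e.g. from [ssr_binary_code()]) or any matrix whose
#'   rows are haplotypes compared by Hamming distance.
#' @return numeric vector of relative frequencies for difference counts
#'   `0..max`, summing to 1.
#' @export
mismatch_distribution <- function(x) {
  n <- nrow(x)
  if (n < 2L) stop("mismatch distribution needs >= 2 haplotypes",
                   call. = FALSE)
  d <- pairwise_hamming(x)
  counts <- tabulate(d + 1L, nbins = max(d) + 1L)
  counts / sum(counts)
}

pairwise_hamming <- function(x) {
  n <- nrow(x)
  if (is.numeric(x) && all(x %in% c(0, 1))) {
    # binary fast path: d_ij = r_i + r_j - 2 (X X')_ij
    r <- rowSums(x)
    cross <- tcrossprod(x)
    d <- outer(r, r, "+") - 2 * cross
    return(as.integer(round(d[lower.tri(d)])))
  }
  out <- integer(n * (n - 1L) / 2L)
  idx <- 1L
  for (j in 2L:n)
    for (i in seq_len(j - 1L)) {
      out[idx] <- sum(x[i, ] != x[j, ])
      idx <- idx + 1L
    }
  out
}

#' Expected mismatch distribution under sudden expansion
#'
#' Exact Rogers-Harpending expectation for a population that jumped from
#' scaled size `theta0` to `theta1` at mutational time `tau` before the
#' present: a mixture of the equilibrium geometric distribution at `theta1`
#' truncated by the expansion and the pre-expansion distribution at
#' `theta0` pushed through `tau` additional mutations (Poisson
#' convolution).
#'
#' @param i vector of difference counts at which to evaluate.
#' @param tau expansion time in mutational units (2ut).
#' @param theta0,theta1 pre- and post-expansion scaled mutation rates.
#' @return expected probabilities `F_i`.
#' @export
expected_mismatch <- function(i, tau, theta0, theta1) {
  eq <- function(j, th) exp(j * log(th) - (j + 1) * log1p(th))
  lam <- (1 + theta1) / theta1
  imax <- max(i)
  js <- 0:imax
  # pairs coalescing after the expansion: equilibrium at theta1 truncated
  # by the probability that fewer than i+1 of the lam*tau "arrivals" fell
  recent <- eq(js, theta1) * stats::ppois(js, lam * tau, lower.tail = FALSE)
  # pairs coalescing before: equilibrium at theta0 convolved with the
  # Poisson(tau) mutations accumulated since, damped by exp(-tau/theta1)
  pois_tau <- stats::dpois(js, tau)
  conv <- vapply(js, function(ii)
    sum(eq(0:ii, theta0) * pois_tau[(ii:0) + 1L]), 0)
  old <- exp(-tau / theta1) * conv
  (recent + old)[i + 1L]
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Minimizes the sum of squared deviations (SSD) between the observed and
#' expected mismatch frequencies over `(tau, theta0, theta1)`, by a bounded
#' log-scale grid search with local refinement. By default `theta1` is tied
#' to `1000 * theta0` (the conventional large post-expansion size); set
#' `free_theta1 = TRUE` to fit it freely up to `theta1_max`.
#'
#' @param observed frequency vector from [mismatch_distribution()].
#' @param n sample size the distribution came from (kept for bootstrap use).
#' @param free_theta1 fit theta1 as a free parameter?
#' @param theta1_max upper bound for theta1.
#' @return an object of class `mismatch_fit` with `tau`, `theta0`,
#'   `theta1`, `SSD`, the observed and fitted vectors.
#' @export
fit_sudden_expansion <- function(observed, n, free_theta1 = FALSE,
                                 theta1_max = 1000) {
  d <- length(observed) - 1L
  i <- 0:d
  ssd_of <- function(tau, th0, th1)
    sum((observed - expected_mismatch(i, tau, th0, th1))^2)
  mean_d <- sum(i * observed)
  tau_grid <- unique(c(1e-4, seq(0.05, max(2 * mean_d, 2), length.out = 18)))
  th0_grid <- c(1e-4, 10^seq(-2, log10(max(mean_d, 1) * 2), length.out = 12))
  best <- c(Inf, NA, NA, NA)
  th1_grid <- if (free_theta1) 10^seq(-1, log10(theta1_max), length.out = 10)
              else NA
  for (tau in tau_grid) for (th0 in th0_grid) {
    th1s <- if (free_theta1) th1_grid else min(1000 * th0, theta1_max)
    for (th1 in th1s) {
      v <- ssd_of(tau, th0, th1)
      if (v < best[1L]) best <- c(v, tau, th0, th1)
    }
  }
  # local refinement on log scale
  par0 <- log(best[2:4])
  obj <- function(p) {
    p <- exp(p)
    if (free_theta1) ssd_of(p[1L], p[2L], p[3L])
    else ssd_of(p[1L], p[2L], min(1000 * p[2L], theta1_max))
  }
  np <- if (free_theta1) 3L else 2L
  opt <- tryCatch(
    optim(par0[seq_len(np)], function(p) obj(c(p, par0[-seq_len(np)])),
          method = "Nelder-Mead",
          control = list(maxit = 600, reltol = 1e-13)),
    error = function(e) NULL)
  if (!is.null(opt) && opt$value <= best[1L]) {
    p <- exp(opt$par)
    tau <- p[1L]; th0 <- p[2L]
    th1 <- if (free_theta1) p[3L] else min(1000 * th0, theta1_max)
    best <- c(opt$value, tau, th0, th1)
  }
  fitted <- expected_mismatch(i, best[2L], best[3L], best[4L])
  structure(list(tau = best[2L], theta0 = best[3L], theta1 = best[4L],
                 SSD = best[1L], observed = observed, fitted = fitted,
                 n = n, free_theta1 = free_theta1,
                 theta1_max = theta1_max),
            class = "mismatch_fit")
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat(sprintf("<mismatch_fit> tau = %.3f, theta0 = %.4g, theta1 = %.4g, SSD = %.5g\n",
              x$tau, x$theta0, x$theta1, x$SSD))
  invisible(x)
}

#' @export
#' @method tidy mismatch_fit
tidy.mismatch_fit <- function(x, ...) {
  tibble(term = c("tau", "theta0", "theta1"),
         estimate = c(x$tau, x$theta0, x$theta1))
}

#' @export
#' @method glance mismatch_fit
glance.mismatch_fit <- function(x, ...) {
  tibble(tau = x$tau, theta0 = x$theta0, theta1 = x$theta1, SSD = x$SSD,
         raggedness = raggedness(x$observed))
}

#' @export
#' @method autoplot mismatch_fit
#' @param object a `mismatch_fit`.
#' @param ... unused.
#' @rdname fit_sudden_expansion
autoplot.mismatch_fit <- function(object, ...) {
  d <- tibble(differences = seq_along(object$observed) - 1L,
              observed = object$observed, expected = object$fitted)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$differences)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed), fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected),
                       colour = "firebrick") +
    ggplot2::labs(x = "pairwise differences", y = "frequency",
                  title = sprintf("Sudden expansion fit (tau = %.2f)",
                                  object$tau))
}

# Simulate a sample under the fitted sudden-expansion model: genealogy in
# mutational time units (branch mutation rate 1), pairwise coalescence
# hazard 2/theta1 until depth tau/2, then 2/theta0. Implemented through the
# shared coalescent engine with a two-epoch constant trajectory.
simulate_expansion_sample <- function(n, tau, theta0, theta1) {
  # engine time unit: 4N0 gens; choose scaling so branch mutation rate
  # theta1 per engine unit, epoch boundary at tau / (2 * theta1).
  br <- .coal_branches_cpp(as.integer(n),
                           c(0, tau / (2 * theta1)),
                           c(1, theta0 / theta1), c(0, 0))
  muts <- rpois(length(br$duration), theta1 * br$duration)
  keep <- muts > 0
  if (!any(keep)) return(matrix(0L, n, 0))
  cols <- rep(seq_along(br$duration)[keep], muts[keep])
  m <- t(br$leaves[cols, , drop = FALSE]) * 1L
  m
}

#' Parametric-bootstrap p-value for the SSD statistic
#'
#' Simulates `reps` coalescent samples under the fitted sudden-expansion
#' model, refits each with the same grid-plus-refinement fitter, and
#' reports `p = Pr(SSD_sim > SSD_obs)`: small values reject the expansion
#' model.
#'
#' @param fit a [fit_sudden_expansion()] result.
#' @param reps bootstrap replicates (>= 100).
#' @param seed optional RNG seed.
#' @return one-row tibble: `SSD`, `p_SSD`, `replicates`.
#' @export
ssd_pvalue <- function(fit, reps = 10000, seed = NULL) {
  if (reps < 100) stop("use at least 100 bootstrap replicates",
                       call. = FALSE)
  sims <- with_seed(seed, vapply(seq_len(reps), function(r) {
    m <- simulate_expansion_sample(fit$n, fit$tau, fit$theta0, fit$theta1)
    if (ncol(m) == 0L) return(0)
    obs <- mismatch_distribution(m)
    refit <- fit_sudden_expansion(obs, fit$n,
                                  free_theta1 = fit$free_theta1,
                                  theta1_max = fit$theta1_max)
    refit$SSD
  }, 0))
  tibble(SSD = fit$SSD, p_SSD = mean(sims > fit$SSD), replicates = reps)
}

#' Harpending's raggedness index
#'
#' The sum of squared successive differences of the mismatch frequencies,
#' with zeros on both sides, so a point mass scores 2 and a flat vector of
#' `k` classes scores `2/k^2`. Smooth unimodal distributions (expansion)
#' score low; ragged multimodal ones (stationarity) score high.
#'
#' @param observed mismatch frequency vector (classes `0..d`).
#' @return the raggedness index.
#' @export
raggedness <- function(observed) {
  if (length(observed) < 2L && sum(observed) == 0)
    stop("need a frequency vector", call. = FALSE)
  x <- c(0, observed, 0)
  sum(diff(x)^2)
}

#' Raggedness significance under the fitted expansion model
#'
#' Parametric bootstrap companion to [ssd_pvalue()]: simulates under the
#' fitted model and reports `p = Pr(r_sim > r_obs)`.
#'
#' @inheritParams ssd_pvalue
#' @return one-row tibble: `raggedness`, `p_raggedness`, `replicates`.
#' @export
raggedness_pvalue <- function(fit, reps = 10000, seed = NULL) {
  r_obs <- raggedness(fit$observed)
  sims <- with_seed(seed, vapply(seq_len(reps), function(r) {
    m <- simulate_expansion_sample(fit$n, fit$tau, fit$theta0, fit$theta1)
    if (ncol(m) == 0L) return(2)
    raggedness(mismatch_distribution(m))
  }, 0))
  tibble(raggedness = r_obs, p_raggedness = mean(sims > r_obs),
         replicates = reps)
}

#' Full mismatch-distribution expansion test for an SSR dataset
#'
#' Binary-codes the repeat table, computes the mismatch distribution, fits
#' the sudden-expansion model, and attaches SSD and raggedness bootstrap
#' p-values.
#'
#' @param ssr an [ssr_dataset()].
#' @param reps bootstrap replicates.
#' @param seed optional RNG seed.
#' @return a list of class `mismatch_result`: the `fit`, `ssd` and
#'   `raggedness` tibbles.
#' @export
mismatch_expansion_test <- function(ssr, reps = 10000, seed = NULL) {
  coded <- ssr_binary_code(ssr)
  obs <- mismatch_distribution(coded)
  fit <- fit_sudden_expansion(obs, nrow(coded))
  with_seed(seed, {
    res <- list(fit = fit,
                ssd = ssd_pvalue(fit, reps),
                raggedness = raggedness_pvalue(fit, reps))
    class(res) <- "mismatch_result"
    res
  })
}

#' @export
print.mismatch_result <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  P(SSD) = %.3f, raggedness = %.4f (P = %.3f)\n",
              x$ssd$p_SSD, x$raggedness$raggedness,
              x$raggedness$p_raggedness))
  invisible(x)
}
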
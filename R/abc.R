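#' Uniform prior specification for ABC
#'
#' Per-site theta and rho priors default to the customary ranges
#' (`1e-5 - 0.05` and `1e-5 - 0.1`). Bounds for the demographic parameters
#' (`N1_rel`, `T0`, `Td`) are explicit configuration: the defaults span
#' relative ancestral sizes from 0.001 to 1 and size-change times from
#' `1e-5` to `0.05` in units of 4N0 generations, wide enough to cover
#' severe, recent changes while keeping simulated genealogies resolvable.
#'
#' @param theta_site,rho_site,N1_rel,T0,Td length-2 numeric `c(lower,
#'   upper)` bounds, all positive with lower < upper.
#' @return an object of class `abc_priors`.
#' @export
abc_priors <- function(theta_site = c(1e-5, 0.05),
                       rho_site = c(1e-5, 0.1),
                       N1_rel = c(0.001, 1),
                       T0 = c(1e-5, 0.05),
                       Td = c(1e-5, 0.05)) {
  pr <- list(theta_site = theta_site, rho_site = rho_site,
             N1_rel = N1_rel, T0 = T0, Td = Td)
  for (nm in names(pr)) {
    b <- pr[[nm]]
    if (length(b) != 2L || any(b <= 0) || b[1L] >= b[2L])
      stop("prior bounds for ", nm, " must be positive with lower < upper",
           call. = FALSE)
  }
  structure(pr, class = "abc_priors")
}

abc_param_names <- function(kind) {
  switch(kind,
    SNM = c("theta_site", "rho_site"),
    GROWTH = c("theta_site", "rho_site", "N1_rel", "T0"),
    BOTTLENECK = c("theta_site", "rho_site", "N1_rel", "T0", "Td"))
}

draw_model_params <- function(kind, priors, n_draws) {
  pars <- abc_param_names(kind)
  out <- tibble(model = rep(kind, n_draws))
  for (nm in c("theta_site", "rho_site", "N1_rel", "T0", "Td")) {
    out[[nm]] <- if (nm %in% pars)
      runif(n_draws, priors[[nm]][1L], priors[[nm]][2L])
    else NA_real_
  }
  out
}

summary_names <- c("theta_w", "tajima_d", "fay_wu_h", "zns")

#' Build an ABC reference table
#'
#' For each requested model, draws parameters from the priors and simulates
#' a multilocus dataset (the same locus lengths and sample size as the
#' observed data), summarizing each with the 4-component vector (mean
#' Watterson's theta per site, mean Tajima's D, mean standardized Fay & Wu's
#' H with known ancestral states, mean Kelly's ZnS) across loci. Undefined
#' per-locus components (monomorphic loci) contribute 0 and are counted in
#' the missingness columns.
#'
#' @param n_sims_per_model simulations per demographic model.
#' @param priors an [abc_priors()] specification.
#' @param n chromosomes per simulated dataset.
#' @param L integer vector of locus lengths (bp).
#' @param models subset of `c("SNM", "GROWTH", "BOTTLENECK")`.
#' @param seed optional RNG seed.
#' @return a tibble of class `reference_table`: model label, parameter draw
#'   and summary columns, with attributes `n`, `L`, `priors`.
#' @export
build_reference_table <- function(n_sims_per_model, priors = abc_priors(),
                                  n = 20, L = rep(600L, 10L),
                                  models = c("SNM", "GROWTH", "BOTTLENECK"),
                                  seed = NULL) {
  with_seed(seed, {
    blocks <- lapply(models, function(kind) {
      draws <- draw_model_params(kind, priors, n_sims_per_model)
      sums <- matrix(0, n_sims_per_model, 7L)
      for (i in seq_len(n_sims_per_model)) {
        mdl <- row_to_model(draws[i, ])
        seg <- demography_segments(mdl)
        sums[i, ] <- .dataset_summaries_cpp(as.integer(n), as.numeric(L),
                                            mdl$theta_site, mdl$rho_site,
                                            seg$t0, seg$size, seg$alpha)
      }
      colnames(sums) <- c(summary_names, "miss_d", "miss_h", "miss_z")
      dplyr::bind_cols(draws, as_tibble(sums))
    })
    out <- dplyr::bind_rows(blocks)
    attr(out, "n") <- n
    attr(out, "L") <- L
    attr(out, "priors") <- priors
    class(out) <- c("reference_table", class(out))
    out
  })
}

row_to_model <- function(row) {
  get_par <- function(nm) {
    v <- row[[nm]]
    if (is.null(v) || is.na(v)) NULL else v
  }
  demographic_model(row$model, theta_site = row$theta_site,
                    rho_site = row$rho_site %||% 0,
                    N1_rel = get_par("N1_rel"), T0 = get_par("T0"),
                    Td = get_par("Td"))
}

#' Summarize an observed multilocus dataset for ABC
#'
#' Computes the 4 ABC summaries from locus alignments: per-locus Watterson's
#' theta (total sites), Tajima's D, standardized Fay & Wu's H (outgroup
#' polarized) and Kelly's ZnS, averaged arithmetically across loci. Loci
#' with undefined D or H (no segregating / polarizable site) contribute 0
#' and are counted in the missingness attributes, matching the treatment of
#' simulated datasets.
#'
#' @param alns list of [locus_alignment()] objects (outgroups required for
#'   the H component).
#' @return named numeric vector of the 4 summaries, with a `missing`
#'   attribute giving per-component missing-locus counts.
#' @export
summarize_dataset <- function(alns) {
  if (!length(alns)) stop("no loci to summarize", call. = FALSE)
  per <- vapply(alns, function(aln) {
    classes <- classify_sites(aln)
    n <- nrow(aln$seqs)
    S <- segregating_sites(aln, classes = classes)
    tw <- watterson_theta(S, n, classes$total_sites)
    d <- tajima_d_from(n, S, pi_locus_scale(aln, classes))
    h <- if (is.null(aln$outgroup)) NA_real_ else fay_wu_h(aln)
    z <- kelly_zns(aln)
    c(tw, d, h, as.numeric(z), is.na(d), is.na(h), attr(z, "missing"))
  }, numeric(7L))
  vals <- c(mean(per[1, ]),
            mean(ifelse(is.na(per[2, ]), 0, per[2, ])),
            mean(ifelse(is.na(per[3, ]), 0, per[3, ])),
            mean(per[4, ]))
  names(vals) <- summary_names
  attr(vals, "missing") <- setNames(rowSums(per[5:7, , drop = FALSE]),
                                    c("tajima_d", "fay_wu_h", "zns"))
  vals
}

#' Summaries of simulated loci
#'
#' Matrix-path equivalent of [summarize_dataset()] for `simulated_locus`
#' objects (ancestral states known).
#'
#' @param sims list of [simulate_locus()] results.
#' @return named numeric vector of the 4 summaries.
#' @export
summarize_simulated <- function(sims) {
  per <- vapply(sims, function(s) {
    m <- s$haplotypes
    n <- nrow(m)
    counts <- colSums(m)
    S <- ncol(m)
    pi <- if (S) sum(2 * counts * (n - counts) / (n * (n - 1))) else 0
    d <- tajima_d_from(n, S, pi)
    h <- fay_wu_h_from(n, counts)
    z <- if (S >= 2L) zns_matrix(m) else NA_real_
    c(S / (harmonic_number(n - 1) * s$L),
      ifelse(is.na(d), 0, d), ifelse(is.na(h), 0, h),
      ifelse(is.na(z), 0, z))
  }, numeric(4L))
  setNames(rowMeans(per), summary_names)
}

#' ABC rejection step
#'
#' Euclidean distance between observed and simulated summaries after
#' normalizing each component by its median absolute deviation over the
#' reference table (components with zero MAD are dropped with a warning).
#' The closest `ceiling(p_delta * nrow)` rows are retained; Epanechnikov
#' weights at the acceptance radius are attached for downstream regression
#' adjustment.
#'
#' @param obs observed summary vector ([summarize_dataset()]).
#' @param table a [build_reference_table()] result.
#' @param p_delta acceptance fraction (0.001 is the customary scale).
#' @return an object of class `abc_posterior`: accepted draws (tibble),
#'   weights, scales, the observation, and the acceptance fraction.
#' @export
abc_reject <- function(obs, table, p_delta = 0.001) {
  stopifnot(nrow(table) >= 1 / p_delta)
  S <- as.matrix(table[, summary_names])
  scales <- apply(S, 2L, mad)
  keep_comp <- scales > 0
  if (!all(keep_comp)) {
    warning("dropping zero-MAD summary component(s): ",
            paste(summary_names[!keep_comp], collapse = ", "),
            call. = FALSE)
  }
  Sn <- sweep(S[, keep_comp, drop = FALSE], 2L, scales[keep_comp], "/")
  on <- obs[summary_names][keep_comp] / scales[keep_comp]
  dist <- sqrt(rowSums(sweep(Sn, 2L, on)^2))
  n_keep <- ceiling(p_delta * nrow(table))
  ord <- order(dist)          # stable: ties broken by row order
  idx <- ord[seq_len(n_keep)]
  radius <- dist[idx[n_keep]]
  w <- if (radius > 0) 1 - (dist[idx] / radius)^2 else rep(1, n_keep)
  w <- pmax(w, .Machine$double.eps)
  structure(list(
    accepted = table[idx, , drop = FALSE],
    distances = dist[idx], weights = w / sum(w),
    scales = scales, components = summary_names[keep_comp],
    obs = obs, p_delta = p_delta, n_table = nrow(table),
    adjusted = NULL), class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf("<abc_posterior> %d accepted of %d (P_delta = %g)%s\n",
              nrow(x$accepted), x$n_table, x$p_delta,
              if (is.null(x$adjusted)) "" else ", regression-adjusted"))
  invisible(x)
}

#' Local-linear regression adjustment of an ABC posterior
#'
#' Beaumont-style adjustment: each log-transformed parameter is regressed
#' (weighted least squares, Epanechnikov weights at the acceptance radius)
#' on the MAD-normalized summaries centered at the observation; the
#' adjusted draw is the fitted value at the observation plus the residual,
#' back-transformed and clamped to the prior box. Requires a single-model
#' accepted set.
#'
#' @param sample an [abc_reject()] result whose accepted rows share one
#'   model label.
#' @param priors the [abc_priors()] used for the table (for clamping);
#'   defaults to the table's priors when available.
#' @return the `abc_posterior` with an `adjusted` tibble added.
#' @export
regression_adjust <- function(sample, priors = NULL) {
  acc <- sample$accepted
  if (length(unique(acc$model)) != 1L)
    stop("regression adjustment requires a single-model accepted set; ",
         "rerun abc_reject() on one model's rows", call. = FALSE)
  if (nrow(acc) < 50L)
    stop("need at least 50 accepted draws for regression adjustment",
         call. = FALSE)
  priors <- priors %||% attr(acc, "priors") %||% abc_priors()
  pars <- abc_param_names(acc$model[1L])
  ok_comp <- sample$components
  X <- sweep(as.matrix(acc[, ok_comp]), 2L,
             sample$scales[ok_comp], "/")
  X <- sweep(X, 2L, sample$obs[ok_comp] / sample$scales[ok_comp])
  adj <- acc[, c("model", pars)]
  for (p in pars) {
    y <- log(acc[[p]])
    fit <- tryCatch(stats::lm.wfit(cbind(1, X), y, sample$weights),
                    error = function(e) NULL)
    if (is.null(fit) || any(is.na(fit$coefficients))) {
      warning("singular design for ", p, ": keeping unadjusted draws",
              call. = FALSE)
      next
    }
    adj[[p]] <- exp(fit$coefficients[1L] + fit$residuals)
    adj[[p]] <- pmin(pmax(adj[[p]], priors[[p]][1L]), priors[[p]][2L])
  }
  sample$adjusted <- adj
  sample
}

#' Posterior mode and credible interval summaries
#'
#' Kernel-density posterior modes (Gaussian kernel, Silverman bandwidth)
#' and weighted 2.5/97.5% quantiles for each parameter of an ABC posterior,
#' from the adjusted draws when present, else the raw accepted draws.
#'
#' @param x an `abc_posterior`.
#' @param ... unused.
#' @return tibble with `parameter`, `mode`, `q2.5`, `q97.5`.
#' @export
#' @method tidy abc_posterior
tidy.abc_posterior <- function(x, ...) {
  draws <- x$adjusted %||% x$accepted
  pars <- abc_param_names(draws$model[1L])
  dplyr::bind_rows(lapply(pars, function(p) {
    v <- draws[[p]]
    tibble(parameter = p,
           mode = posterior_mode(v, x$weights),
           q2.5 = weighted_quantile(v, x$weights, 0.025),
           q97.5 = weighted_quantile(v, x$weights, 0.975))
  }))
}

#' @export
#' @method glance abc_posterior
glance.abc_posterior <- function(x, ...) {
  tibble(model = x$accepted$model[1L], n_accepted = nrow(x$accepted),
         n_table = x$n_table, p_delta = x$p_delta,
         adjusted = !is.null(x$adjusted))
}

posterior_mode <- function(v, w = NULL) {
  if (length(unique(v)) == 1L) return(v[1L])
  dens <- if (is.null(w)) density(v) else
    suppressWarnings(density(v, weights = w / sum(w)))
  dens$x[which.max(dens$y)]
}

weighted_quantile <- function(v, w, probs) {
  ord <- order(v)
  cw <- cumsum(w[ord]) / sum(w)
  approx(cw, v[ord], xout = probs, rule = 2, ties = "ordered")$y
}

#' @importFrom stats approx
NULL

#' Posterior model probabilities
#'
#' Beaumont-style model choice: within the accepted set of a pooled
#' multi-model reference table, a weighted multinomial logistic regression
#' of the model label on the normalized summaries is evaluated at the
#' observation. Simple rejection proportions are reported alongside as a
#' diagnostic. Models absent from the accepted set get probability 0 with
#' a warning.
#'
#' @param obs observed summary vector.
#' @param table pooled [build_reference_table()] over the three models.
#' @param p_delta acceptance fraction.
#' @return tibble with `model`, `posterior_prob` (regression),
#'   `rejection_prob`.
#' @export
model_posterior_probs <- function(obs, table, p_delta = 0.001) {
  models <- unique(table$model)
  sample <- abc_reject(obs, table, p_delta)
  acc <- sample$accepted
  missing_models <- setdiff(models, unique(acc$model))
  if (length(missing_models))
    warning("model(s) absent from accepted set: ",
            paste(missing_models, collapse = ", "), call. = FALSE)
  rej <- vapply(models, function(m) mean(acc$model == m), 0)
  probs <- rej
  if (length(unique(acc$model)) >= 2L) {
    X <- sweep(as.matrix(acc[, sample$components]), 2L,
               sample$scales[sample$components], "/")
    df <- as.data.frame(X)
    df$model <- factor(acc$model, levels = models)
    fit <- nnet::multinom(model ~ ., data = df, weights = sample$weights,
                          trace = FALSE, maxit = 500)
    newd <- as.data.frame(t(sample$obs[sample$components] /
                              sample$scales[sample$components]))
    pr <- predict(fit, newdata = newd, type = "probs")
    got <- if (length(pr) == 1L) {
      # two-class fit: multinom returns Pr(second level) only
      lv <- levels(droplevels(df$model))
      setNames(c(1 - pr, pr), lv)
    } else setNames(as.numeric(pr), names(pr))
    full <- setNames(numeric(length(models)), models)
    full[names(got)] <- got
    probs <- pmax(full, 0)
    probs <- probs / sum(probs)
  }
  tibble(model = models, posterior_prob = as.numeric(probs[models]),
         rejection_prob = as.numeric(rej[models]))
}

#' Posterior predictive check of an ABC fit
#'
#' Resamples parameter draws from the (weighted) posterior, simulates new
#' datasets of the same design, and reports the two-sided tail probability
#' of each observed summary under the simulated reference distribution.
#'
#' @param sample an `abc_posterior` (adjusted draws used when present).
#' @param reps number of predictive simulations.
#' @param n,L design of the simulated datasets (chromosomes, locus
#'   lengths); default to the reference table's attributes stored on the
#'   accepted rows when available.
#' @param seed optional RNG seed.
#' @return tibble with `summary`, `observed`, `tail_prob`.
#' @export
posterior_predictive_check <- function(sample, reps = 200, n = NULL,
                                       L = NULL, seed = NULL) {
  draws <- sample$adjusted %||% sample$accepted
  n <- n %||% attr(sample$accepted, "n") %||% 20
  L <- L %||% attr(sample$accepted, "L") %||% rep(600L, 10L)
  obs <- sample$obs
  with_seed(seed, {
    idx <- sample.int(nrow(draws), reps, replace = TRUE,
                      prob = sample$weights)
    sims <- vapply(idx, function(i) {
      mdl <- row_to_model(draws[i, ])
      seg <- demography_segments(mdl)
      .dataset_summaries_cpp(as.integer(n), as.numeric(L), mdl$theta_site,
                             mdl$rho_site, seg$t0, seg$size, seg$alpha)[1:4]
    }, numeric(4L))
    dplyr::bind_rows(lapply(seq_along(summary_names), function(k) {
      s <- sims[k, ]
      tail <- 2 * min(mean(s <= obs[k]), mean(s >= obs[k]))
      tibble(summary = summary_names[k], observed = unname(obs[k]),
             tail_prob = min(1, tail))
    }))
  })
}

# ---- unit conversions -----------------------------------------------------

#' Effective population size from silent-site theta
#'
#' `Ne = theta_ws / (4 mu_per_year generation_years)`: Watterson's theta at
#' silent sites divided by four times the per-generation mutation rate.
#'
#' @param theta_ws per-site silent theta.
#' @param mu_per_year substitution rate per site per year.
#' @param generation_years generation time in years.
#' @return effective population size (individuals).
#' @export
ne_from_theta <- function(theta_ws, mu_per_year, generation_years) {
  stopifnot(theta_ws > 0, mu_per_year > 0, generation_years > 0)
  theta_ws / (4 * mu_per_year * generation_years)
}

#' Convert a scaled coalescent time to years
#'
#' Posterior times are reported in units of 4 N0 generations scaled by
#' 1e-3; the conversion is `years = T_scaled * 1e-3 * 4 * N0 *
#' generation_years`, rounded to the nearest year.
#'
#' @param T_scaled time in (4 N0 generations) x 1e-3.
#' @param N0 current effective size.
#' @param generation_years generation time in years.
#' @return time in years (integer).
#' @export
scaled_time_to_years <- function(T_scaled, N0, generation_years) {
  stopifnot(T_scaled > 0, N0 > 0, generation_years > 0)
  round(T_scaled * 1e-3 * 4 * N0 * generation_years)
}

#' Ancestral population size in individuals
#'
#' @param N1_rel ancestral size as a fraction of N0.
#' @param N0 current effective size.
#' @return `round(N1_rel * N0)`.
#' @export
ancestral_size_individuals <- function(N1_rel, N0) {
  stopifnot(N1_rel > 0, N0 > 0)
  round(N1_rel * N0)
}

#' Density plot of an ABC posterior
#' @param object an `abc_posterior`.
#' @param ... unused.
#' @export
#' @method autoplot abc_posterior
autoplot.abc_posterior <- function(object, ...) {
  draws <- object$adjusted %||% object$accepted
  pars <- abc_param_names(draws$model[1L])
  long <- tidyr::pivot_longer(draws[, pars], dplyr::all_of(pars),
                              names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = NULL, y = "posterior density")
}
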
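#' Demographic model specification
#'
#' Three single-population models in standard coalescent scaling (time in
#' units of 4N0 generations, rates per site scaled by 4N0):
#'
#' * `SNM` -- standard neutral model, constant size; parameters `theta_site`
#'   and `rho_site` only.
#' * `GROWTH` -- exponential growth from an ancestral size `N1_rel * N0`
#'   starting (forward in time) at `T0`: looking backward, the population
#'   shrinks as `N(t) = N0 * exp(-alpha t)` for `t < T0` and stays at
#'   `N1_rel * N0` before, with `alpha = ln(1/N1_rel) / T0`.
#' * `BOTTLENECK` -- current size N0 reached by exponential growth out of a
#'   bottleneck of size `N1_rel * N0` that lasted from `T0` to `T0 + Td`
#'   (backward in time), with the pre-bottleneck size back at N0.
#'
#' @param kind `"SNM"`, `"GROWTH"` or `"BOTTLENECK"`.
#' @param theta_site per-site population mutation rate (4 N0 mu).
#' @param rho_site per-site population recombination rate (4 N0 r).
#' @param N1_rel ancestral (or bottleneck) size relative to N0.
#' @param T0 time of the initial size change, units of 4N0 generations.
#' @param Td bottleneck duration, units of 4N0 generations.
#' @return an object of class `demographic_model`.
#' @export
demographic_model <- function(kind = c("SNM", "GROWTH", "BOTTLENECK"),
                              theta_site, rho_site = 0,
                              N1_rel = NULL, T0 = NULL, Td = NULL) {
  kind <- match.arg(kind)
  stopifnot(theta_site >= 0, rho_site >= 0)
  if (kind != "SNM") {
    stopifnot(!is.null(N1_rel), !is.null(T0), N1_rel > 0, T0 > 0)
    if (kind == "BOTTLENECK") stopifnot(!is.null(Td), Td > 0)
  }
  structure(list(kind = kind, theta_site = theta_site, rho_site = rho_site,
                 N1_rel = N1_rel, T0 = T0, Td = Td),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  extra <- switch(x$kind,
    SNM = "",
    GROWTH = sprintf(", N1_rel = %g, T0 = %g", x$N1_rel, x$T0),
    BOTTLENECK = sprintf(", N1_rel = %g, T0 = %g, Td = %g",
                         x$N1_rel, x$T0, x$Td))
  cat(sprintf("<demographic_model> %s: theta/site = %g, rho/site = %g%s\n",
              x$kind, x$theta_site, x$rho_site, extra))
  invisible(x)
}

#' Exponential growth rate of a demographic model
#'
#' `alpha = ln(N0/N1) / T0` in units of inverse 4N0 generations (natural
#' logarithm, the ms convention). Zero when `N1_rel = 1`.
#'
#' @param model a [demographic_model()] of kind `GROWTH` or `BOTTLENECK`.
#' @return the growth exponent alpha.
#' @export
growth_rate <- function(model) {
  if (model$kind == "SNM")
    stop("the standard neutral model has no growth phase", call. = FALSE)
  if (model$N1_rel == 1) return(0)
  log(1 / model$N1_rel) / model$T0
}

# Piecewise size trajectory (t0 / size-at-start / alpha per segment) fed to
# the C++ simulator. N(t) = size * exp(-alpha * (t - t0)) within a segment.
demography_segments <- function(model) {
  switch(model$kind,
    SNM = list(t0 = 0, size = 1, alpha = 0),
    GROWTH = {
      a <- growth_rate(model)
      list(t0 = c(0, model$T0), size = c(1, model$N1_rel), alpha = c(a, 0))
    },
    BOTTLENECK = {
      a <- growth_rate(model)
      list(t0 = c(0, model$T0, model$T0 + model$Td),
           size = c(1, model$N1_rel, 1), alpha = c(a, 0, 0))
    })
}

#' Simulate one locus under the coalescent with recombination
#'
#' Backward-in-time ancestral recombination graph under the model's size
#' trajectory, with infinite-sites mutations placed on branches at rate
#' `theta_site * L` and crossovers at rate `rho_site * L`. Output follows ms
#' semantics: rows are sampled chromosomes, columns are segregating sites
#' coded 0 (ancestral) / 1 (derived), positions are relative in `[0, 1)`.
#'
#' @param model a [demographic_model()].
#' @param n number of chromosomes to sample.
#' @param L locus length in bp.
#' @param seed optional RNG seed.
#' @return an object of class `simulated_locus`: list with `haplotypes`
#'   (n x S 0/1 matrix), `positions`, `L`, `n`.
#' @export
simulate_locus <- function(model, n, L, seed = NULL) {
  stopifnot(inherits(model, "demographic_model"), n >= 2, L >= 1)
  seg <- demography_segments(model)
  sim <- with_seed(seed, .sim_locus_cpp(as.integer(n),
                                        model$theta_site * L,
                                        model$rho_site * L,
                                        seg$t0, seg$size, seg$alpha))
  structure(list(haplotypes = sim$haplotypes, positions = sim$positions,
                 L = as.integer(L), n = as.integer(n), model = model),
            class = "simulated_locus")
}

#' @export
print.simulated_locus <- function(x, ...) {
  cat(sprintf("<simulated_locus> n = %d, L = %d bp, S = %d\n",
              x$n, x$L, ncol(x$haplotypes)))
  invisible(x)
}

#' Simulate a coalescent genealogy as branch records
#'
#' One genealogy (no recombination) under the model's size trajectory,
#' returned as branch durations plus the sampled chromosomes each branch
#' subtends. This is the substrate for fixed-S mutation placement and for
#' stepwise SSR mutation.
#'
#' @param model a [demographic_model()] (mutation/recombination rates
#'   ignored).
#' @param n number of chromosomes.
#' @param seed optional RNG seed.
#' @return list with `duration` (2n-2 branch lengths, units of 4N0
#'   generations), `leaves` (branch x chromosome logical matrix), `tmrca`.
#' @export
simulate_genealogy <- function(model, n, seed = NULL) {
  seg <- demography_segments(model)
  with_seed(seed, .coal_branches_cpp(as.integer(n), seg$t0, seg$size,
                                     seg$alpha))
}

#' Simulate haploid chloroplast SSR haplotypes
#'
#' All SSR loci share one non-recombining genealogy (chloroplasts do not
#' recombine); each locus accumulates stepwise +/-1 repeat mutations as a
#' Poisson process on branches with per-locus scaled rate `theta_ssr`
#' (= 4 N0 u, with u the per-generation repeat mutation rate). Final repeat
#' counts below 1 are reflected back (a count k becomes 2 - k).
#'
#' @param model a [demographic_model()] (its `theta_site`/`rho_site` are not
#'   used; only the size trajectory matters).
#' @param n number of haploid individuals.
#' @param n_loci number of SSR loci.
#' @param theta_ssr per-locus scaled repeat mutation rate (4 N0 u).
#' @param seed optional RNG seed.
#' @param ancestral_repeats starting repeat count at the root.
#' @param individuals optional individual ids (rownames of the output).
#' @return an [ssr_dataset()].
#' @export
simulate_ssr <- function(model, n, n_loci, theta_ssr, seed = NULL,
                         ancestral_repeats = 10L, individuals = NULL) {
  stopifnot(n >= 2, n_loci >= 1, theta_ssr >= 0)
  with_seed(seed, {
    gen <- simulate_genealogy(model, n)
    nb <- length(gen$duration)
    reps <- matrix(ancestral_repeats, n, n_loci)
    for (l in seq_len(n_loci)) {
      steps <- rpois(nb, theta_ssr * gen$duration)
      net <- vapply(steps, function(k)
        if (k == 0L) 0L else sum(sample(c(-1L, 1L), k, replace = TRUE)),
        0L)
      for (b in which(net != 0L))
        reps[gen$leaves[b, ], l] <- reps[gen$leaves[b, ], l] + net[b]
    }
    reps[reps < 1L] <- 2L - reps[reps < 1L]
    rownames(reps) <- individuals %||% sprintf("ind%03d", seq_len(n))
    colnames(reps) <- sprintf("ssr%d", seq_len(n_loci))
    ssr_dataset(reps)
  })
}

#' Write simulated loci in ms-compatible text format
#'
#' `segsites:`/`positions:` blocks with 0/1 haplotype lines, one block per
#' locus, for interoperability with ms-ecosystem tools.
#'
#' @param sims a `simulated_locus` or list of them.
#' @param path output file.
#' @param header command-like first line to record (default describes the
#'   package call).
#' @return `path`, invisibly.
#' @export
write_ms <- function(sims, path, header = "pinepop simulate_locus") {
  if (inherits(sims, "simulated_locus")) sims <- list(sims)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, ""), con)
  for (s in sims) {
    writeLines("//", con)
    S <- ncol(s$haplotypes)
    writeLines(paste("segsites:", S), con)
    if (S > 0) {
      writeLines(paste("positions:",
                       paste(sprintf("%.6f", s$positions), collapse = " ")),
                 con)
      writeLines(apply(s$haplotypes, 1L, paste, collapse = ""), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
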
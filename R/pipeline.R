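#' Configuration for an end-to-end analysis run
#'
#' Collects inputs, stage toggles, replicate counts and seeds. All
#' randomness flows from `seed` through named per-stage substreams, so any
#' stage can be rerun independently yet reproducibly.
#'
#' @param loci list of [locus_alignment()] objects.
#' @param popmap a [population_map()].
#' @param ssr optional [ssr_dataset()].
#' @param run_abc,run_mismatch,run_structure,run_neutrality stage toggles.
#' @param permutations permutations for structure tests.
#' @param coalescent_reps replicates for neutrality p-values.
#' @param mismatch_reps bootstrap replicates for the mismatch test.
#' @param abc_sims_per_model reference-table rows per demographic model.
#' @param abc_n,abc_L ABC simulation design (chromosomes, locus lengths);
#'   `NULL` uses the observed design.
#' @param p_delta ABC acceptance fraction.
#' @param priors an [abc_priors()] specification.
#' @param seed master seed.
#' @param out_dir optional output directory for stage TSV/JSON files.
#' @return a list of class `run_config`.
#' @export
study_config <- function(loci, popmap, ssr = NULL,
                         run_abc = TRUE, run_mismatch = !is.null(ssr),
                         run_structure = TRUE, run_neutrality = TRUE,
                         permutations = 10000, coalescent_reps = 1000,
                         mismatch_reps = 10000, abc_sims_per_model = 30000,
                         abc_n = NULL, abc_L = NULL, p_delta = 0.001,
                         priors = abc_priors(), seed = 1, out_dir = NULL) {
  structure(list(loci = loci, popmap = popmap, ssr = ssr,
                 run_abc = run_abc, run_mismatch = run_mismatch,
                 run_structure = run_structure,
                 run_neutrality = run_neutrality,
                 permutations = permutations,
                 coalescent_reps = coalescent_reps,
                 mismatch_reps = mismatch_reps,
                 abc_sims_per_model = abc_sims_per_model,
                 abc_n = abc_n, abc_L = abc_L, p_delta = p_delta,
                 priors = priors, seed = seed, out_dir = out_dir),
            class = "run_config")
}

stage_seed <- function(config, stage) {
  # independent, reproducible substream per named stage
  offsets <- c(diversity = 101L, neutrality = 211L, ld = 307L,
               structure = 401L, mismatch = 503L, abc_table = 601L,
               abc_fit = 701L, ppc = 809L)
  (as.integer(config$seed) * 1000L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full analysis pipeline
#'
#' Diversity table, neutrality tests, LD scan and decay fit, AMOVA /
#' G_ST-R_ST / Mantel structure tests, cpSSR mismatch expansion test, and
#' ABC demographic inference (reference table, model choice, growth-model
#' posterior), in that order. Stage outputs are returned as a named list
#' and, when `out_dir` is set, written as TSV/JSON.
#'
#' @param config a [study_config()].
#' @return list of class `run_result` with one element per executed stage
#'   plus a `manifest`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  res <- list()
  t_start <- Sys.time()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  res$diversity <- run_stage("diversity", {
    div <- diversity_table(config$loci, config$popmap)
    list(per_locus = div,
         averages = diversity_averages(div, config$loci),
         fis = fis_estimate(config$loci, config$popmap))
  })
  if (config$run_neutrality)
    res$neutrality <- run_stage("neutrality",
      neutrality_table(config$loci, reps = config$coalescent_reps,
                       seed = stage_seed(config, "neutrality")))
  res$ld <- run_stage("ld", {
    pairs <- ld_pairs(config$loci)
    n <- nrow(config$loci[[1L]]$seqs)
    fit <- if (nrow(pairs) >= 10L &&
               length(unique(pairs$distance)) >= 2L)
      ld_decay_fit(pairs, n) else NULL
    list(pairs = pairs, decay = fit,
         zns = vapply(config$loci, function(a) as.numeric(kelly_zns(a)), 0))
  })
  if (config$run_structure)
    res$structure <- run_stage("structure", {
      amova <- amova_fst(config$loci, config$popmap,
                         permutations = config$permutations,
                         seed = stage_seed(config, "structure"))
      pw <- pairwise_fst(config$loci, config$popmap)
      mantel <- if (!is.null(config$popmap$coordinates) &&
                    nrow(pw) >= 4L)
        mantel_test(pw, config$popmap,
                    permutations = config$permutations,
                    seed = stage_seed(config, "structure"))
      else NULL
      gr <- if (!is.null(config$ssr))
        gst_rst_compare(config$ssr, config$popmap,
                        permutations = config$permutations,
                        seed = stage_seed(config, "structure"))
      else NULL
      list(amova = amova, pairwise_fst = pw, mantel = mantel,
           gst_rst = gr)
    })
  if (config$run_mismatch && !is.null(config$ssr))
    res$mismatch <- run_stage("mismatch",
      mismatch_expansion_test(config$ssr, reps = config$mismatch_reps,
                              seed = stage_seed(config, "mismatch")))
  if (config$run_abc)
    res$abc <- run_stage("abc", {
      obs <- summarize_dataset(config$loci)
      n <- config$abc_n %||% nrow(config$loci[[1L]]$seqs)
      L <- config$abc_L %||% vapply(config$loci, function(a) a$L, 0L)
      table <- build_reference_table(config$abc_sims_per_model,
                                     priors = config$priors, n = n, L = L,
                                     seed = stage_seed(config, "abc_table"))
      probs <- model_posterior_probs(obs, table, config$p_delta)
      best <- probs$model[which.max(probs$posterior_prob)]
      sub <- table[table$model == best, ]
      # widen the estimation acceptance enough to feed the regression
      p_est <- max(config$p_delta * 3, 60 / nrow(sub))
      post <- abc_reject(obs, sub, min(1, p_est))
      post <- regression_adjust(post, config$priors)
      list(observed_summaries = obs, model_probs = probs,
           best_model = best, posterior = post,
           estimates = tidy(post))
    })
  res$manifest <- list(
    seed = config$seed, stages = names(res),
    n_loci = length(config$loci),
    n_individuals = length(unique(config$loci[[1L]]$individual)),
    started = format(t_start), finished = format(Sys.time()),
    package_version = as.character(utils::packageVersion("pinepop")))
  class(res) <- "run_result"
  if (!is.null(config$out_dir)) write_run_outputs(res, config$out_dir)
  res
}

write_run_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  wt(res$diversity$per_locus, "diversity_per_locus.tsv")
  wt(res$diversity$averages, "diversity_averages.tsv")
  if (!is.null(res$neutrality)) wt(res$neutrality, "neutrality.tsv")
  if (!is.null(res$ld)) wt(res$ld$pairs, "ld_pairs.tsv")
  if (!is.null(res$structure)) {
    wt(glance(res$structure$amova), "amova.tsv")
    utils::write.table(res$structure$pairwise_fst,
                       file.path(dir, "pairwise_fst.tsv"), sep = "\t",
                       quote = FALSE)
  }
  if (!is.null(res$mismatch))
    jsonlite::write_json(
      list(tau = res$mismatch$fit$tau, theta0 = res$mismatch$fit$theta0,
           theta1 = res$mismatch$fit$theta1, SSD = res$mismatch$ssd$SSD,
           p_SSD = res$mismatch$ssd$p_SSD,
           raggedness = res$mismatch$raggedness$raggedness,
           p_raggedness = res$mismatch$raggedness$p_raggedness),
      file.path(dir, "mismatch.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(res$abc)) {
    wt(res$abc$model_probs, "abc_model_probs.tsv")
    wt(res$abc$estimates, "abc_estimates.tsv")
  }
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Human-readable markdown report of a pipeline run
#'
#' Summarizes each executed stage and, when ABC results are present,
#' converts the scaled posterior estimates to natural units: current
#' effective size from silent-site theta, the expansion start time in
#' years, and the ancestral population size in individuals.
#'
#' @param res a [run_all()] result.
#' @param mu_per_year substitution rate per site per year for conversions.
#' @param generation_years generation time in years.
#' @param theta_ws silent-site theta used for the Ne conversion; defaults
#'   to the run's total-sample average.
#' @return a character vector of markdown lines.
#' @export
make_report <- function(res, mu_per_year = 7e-10, generation_years = 50,
                        theta_ws = NULL) {
  lines <- c("# Population-genetic analysis report", "")
  if (!is.null(res$diversity)) {
    avg <- res$diversity$averages
    tot <- avg[avg$group == "total", ]
    lines <- c(lines, "## Diversity", sprintf(
      "Total sample: S = %d, theta_w = %.4f, theta_ws = %.4f, pi_t = %.4f (F_IS = %.3f).",
      tot$S, tot$theta_w, tot$theta_ws, tot$pi_t, res$diversity$fis), "")
    theta_ws <- theta_ws %||% tot$theta_ws
  }
  if (!is.null(res$structure)) {
    lines <- c(lines, "## Structure", sprintf(
      "AMOVA F_ST = %.3f (p = %.4g).", res$structure$amova$fst,
      res$structure$amova$p_value))
    if (!is.null(res$structure$gst_rst))
      lines <- c(lines, sprintf(
        "cpSSR G_ST = %.3f, R_ST = %.3f (p[R_ST > G_ST] = %.3f).",
        res$structure$gst_rst$G_ST, res$structure$gst_rst$R_ST,
        res$structure$gst_rst$p_RST_gt_GST))
    lines <- c(lines, "")
  } else lines <- c(lines, "## Structure", "not run", "")
  if (!is.null(res$mismatch)) {
    lines <- c(lines, "## Mismatch expansion test", sprintf(
      "tau = %.2f, SSD = %.4g (P_SSD = %.3f), raggedness = %.4f (P = %.3f).",
      res$mismatch$fit$tau, res$mismatch$ssd$SSD, res$mismatch$ssd$p_SSD,
      res$mismatch$raggedness$raggedness,
      res$mismatch$raggedness$p_raggedness), "")
  } else lines <- c(lines, "## Mismatch expansion test", "not run", "")
  if (!is.null(res$abc)) {
    mp <- res$abc$model_probs
    lines <- c(lines, "## Demographic inference (ABC)",
               paste(sprintf("%s: %.3f", mp$model, mp$posterior_prob),
                     collapse = ", "),
               sprintf("Selected model: %s.", res$abc$best_model), "")
    est <- res$abc$estimates
    if (!is.null(theta_ws) && res$abc$best_model != "SNM") {
      # conversions use Ne to 3 significant figures, the reporting precision
      N0 <- signif(ne_from_theta(theta_ws, mu_per_year, generation_years), 3)
      t0 <- est[est$parameter == "T0", ]
      n1 <- est[est$parameter == "N1_rel", ]
      lines <- c(lines, sprintf("N_e (from theta_ws = %.4f) = %.3g.",
                                theta_ws, N0))
      if (nrow(t0))
        lines <- c(lines, sprintf(
          "T0 mode %.4g (4N0 gens) = %d years [%d, %d].",
          t0$mode, scaled_time_to_years(t0$mode * 1000, N0, generation_years),
          scaled_time_to_years(t0$q2.5 * 1000, N0, generation_years),
          scaled_time_to_years(t0$q97.5 * 1000, N0, generation_years)))
      if (nrow(n1))
        lines <- c(lines, sprintf(
          "Ancestral size %.4g x N0 = %d individuals [%d, %d].",
          n1$mode, ancestral_size_individuals(n1$mode, N0),
          ancestral_size_individuals(n1$q2.5, N0),
          ancestral_size_individuals(n1$q97.5, N0)))
    }
    lines <- c(lines, "")
  } else lines <- c(lines, "## Demographic inference (ABC)", "not run", "")
  lines
}
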
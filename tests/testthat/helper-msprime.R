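# Independent coalescent simulator (msprime, via the system python) used as
# a distributional cross-check oracle. Parameter mapping: haploid samples
# with population size 1/2 make the pair-coalescence rate 2 per generation,
# so one msprime generation equals one unit of 4N0 generations; per-site
# mutation and recombination rates then equal theta_site and rho_site.
msprime_script <- function() {
  path <- file.path(tempdir(), "msprime_oracle.py")
  if (!file.exists(path)) writeLines(c(
    "import sys, json",
    "import msprime, numpy as np",
    "spec = json.loads(sys.argv[1])",
    "kind, theta, rho = spec['kind'], spec['theta'], spec['rho']",
    "n, L, reps, seed = spec['n'], spec['L'], spec['reps'], spec['seed']",
    "demo = msprime.Demography()",
    "demo.add_population(initial_size=0.5)",
    "if kind in ('GROWTH', 'BOTTLENECK'):",
    "    N1, T0 = spec['N1'], spec['T0']",
    "    alpha = np.log(1/N1)/T0",
    "    demo.populations[0].growth_rate = alpha",
    "    demo.add_population_parameters_change(time=T0, initial_size=0.5*N1, growth_rate=0)",
    "    if kind == 'BOTTLENECK':",
    "        demo.add_population_parameters_change(time=T0+spec['Td'], initial_size=0.5, growth_rate=0)",
    "out = []",
    "rng = np.random.default_rng(seed)",
    "for ts in msprime.sim_ancestry(samples={0: n}, ploidy=1, demography=demo,",
    "                               sequence_length=L, recombination_rate=rho,",
    "                               num_replicates=reps, random_seed=seed):",
    "    mts = msprime.sim_mutations(ts, rate=theta, random_seed=int(rng.integers(1, 2**31)),",
    "                                model=msprime.BinaryMutationModel(), discrete_genome=False)",
    "    G = mts.genotype_matrix()",
    "    counts = G.sum(axis=1)",
    "    counts = counts[(counts > 0) & (counts < n)]",
    "    S = len(counts)",
    "    pi = float((2*counts*(n-counts)/(n*(n-1))).sum())",
    "    out.append([S, pi])",
    "print(json.dumps(out))"), path)
  path
}

run_msprime <- function(spec) {
  arg <- jsonlite::toJSON(spec, auto_unbox = TRUE, null = "null")
  out <- system2("python", c(msprime_script(), shQuote(arg)), stdout = TRUE)
  m <- do.call(rbind, jsonlite::fromJSON(out, simplifyVector = FALSE) |>
                 lapply(unlist))
  colnames(m) <- c("S", "pi")
  m
}
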
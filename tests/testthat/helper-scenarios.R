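# Shared simulation scenarios. The estimator-validation scenarios use
# stronger, well-spread per-allele effects than the package defaults because
# MR-Egger's slope and intercept are identified only when the spread of the
# per-SNP exposure associations dominates their estimation error (the NOME
# condition); the default paper-scale effects are kept for everything that
# does not require Egger identifiability.

recovery_config <- function(seed, n = 10000, beta_causal = -0.5, ...) {
  sim_config(
    n_individuals = n,
    beta_causal = beta_causal,
    snp_effects_on_aam = seq(-0.10, -0.40, length.out = 14),
    seed = seed,
    ...
  )
}

# one full estimator pass over a simulated cohort; bootstraps off by default
# so repeated-draw studies only pay for point estimates
mr_scenario_rep <- function(cfg, instrument = "quartile", n_boot = 0,
                            wm_boot = 0) {
  sim <- simulate_cohort(cfg)
  dat <- sim$phenotypes
  dat$grs <- build_grs(sim$genotypes, sim$panel)
  s <- snp_summary_stats(dat, sim$genotypes, sim$panel, spec = NULL,
                         exposure = "aam")
  list(
    tsls = fit_2sls(dat, spec = NULL, exposure = "aam",
                    instrument = instrument, n_boot = n_boot),
    summaries = s,
    ivw = mr_ivw(s),
    wm = mr_weighted_median(s, n_boot = wm_boot),
    egger = mr_egger(s)
  )
}

covers <- function(tab, truth) {
  tab$conf.low <= truth & truth <= tab$conf.high
}
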
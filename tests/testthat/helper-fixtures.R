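# Shared fixtures. The packaged default synthetic study (seed 1) is
# simulated once per session and reused by every test that needs it.

.fixtures <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$sim <- simulate_methylome(sim_config(seed = 1))
  }
  .fixtures$sim
}

default_run <- function() {
  if (is.null(.fixtures$run)) {
    .fixtures$run <- suppressMessages(suppressWarnings(
      run_pipeline(default_sim(), B = 10000, n_perm = 1000)))
  }
  .fixtures$run
}

# compact study for replicate-based checks
small_config <- function(seed, ...) {
  defaults <- list(seed = seed, n_samples = 40, n_probes = 700,
                   genome_length = 200000, n_hc = 6, n_ic = 8,
                   n_genes = 12, n_snps = 60, frac_selected_snps = 0.3)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# mid-sized study: enough probes and genes for single-run power checks
medium_config <- function(seed, ...) {
  defaults <- list(seed = seed, n_samples = 40, n_probes = 2000,
                   genome_length = 500000, n_hc = 15, n_ic = 18,
                   n_genes = 30, n_snps = 100, frac_selected_snps = 0.3)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# cluster-free sparse design: MV is iid across probes, so window-defined
# RSP sets are exchangeable with random subsets (used for calibration)
sparse_null_config <- function(seed, ...) {
  defaults <- list(seed = seed, n_samples = 40, n_probes = 250,
                   genome_length = 400000, n_hc = 0, n_ic = 0,
                   n_genes = 5, n_snps = 60, frac_selected_snps = 0.3,
                   rsp_mv_shrink = 1)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

toy_mv_table <- function(mv, probes = sprintf("p%02d", seq_along(mv))) {
  data.frame(probe = probes, mean = 0.5, variance = mv^2, mv = mv,
             stringsAsFactors = FALSE)
}

# simulate -> filter -> MV in one step for replicate loops
sim_mv <- function(cfg) {
  sim <- simulate_methylome(cfg)
  fp <- filter_probes(sim$manifest, sim$beta)
  mv <- compute_mv(sim$beta, fp$retained)
  manifest <- sim$manifest[match(fp$retained, sim$manifest$probe), ,
                           drop = FALSE]
  list(sim = sim, mv = mv, manifest = manifest)
}
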
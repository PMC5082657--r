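## Shared fixtures, built once per test run and cached.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- build()
  .fx_cache[[name]]
}

## a mid-sized two-set breeding program used across modules
fx_sim <- function() fx("sim", function() {
  simulate_dataset(sim_config(
    n_parents = 24, n_shared_parents = 8, set_sizes = c(40, 50),
    n_crosses = c(15, 15), n_markers = 600, n_qtl = 60, seed = 11))
})

## QC'd, imputed markers and the GRM for fx_sim
fx_geno <- function() fx("geno", function() {
  sim <- fx_sim()
  enc <- encode_genotypes(sim$calls)
  qc <- apply_qc(enc, maf_min = 0.05, line_missing_max = 0.10)
  imp <- impute_missing(qc$matrix)
  list(enc = enc, qc = qc, imp = imp, grm = build_grm(imp))
})

## full-data REML fit for the seed-size trait of fx_sim
fx_fit <- function() fx("fit", function() {
  reml(model_spec("ssw"), fx_sim()$phenotypes, fx_geno()$grm)
})
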
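#' Run the genomic-prediction pipeline end to end
#'
#' Orchestrates simulate-or-load, trait derivation (standardized seed
#' weight, protein yield), marker QC, GRM and PCA, REML variance components
#' with line-mean heritability per trait, and the requested
#' cross-validation designs. All randomness is routed through per-stage
#' child seeds derived from one base seed, so each stage is independently
#' reproducible. Every stage writes its outputs under `out_dir` and the run
#' ends with a machine-readable `summary.json`.
#'
#' @param config a list, or path to a YAML file, with entries:
#'   * `seed` (required for stochastic designs),
#'   * either `simulation` (arguments to [sim_config()]) or `input` (paths:
#'     `genotypes`, `phenotypes`, optional `pedigree`, `map`),
#'   * `qc` (`maf_min`, `line_missing_max`),
#'   * `traits` (character vector; each must have a [model_spec()]-able
#'     name or an entry under `models`),
#'   * `cv` (list: `designs` subset of `loo`, `lso`, `lso_random`, `lfo`,
#'     `reduce_training`, `reduce_markers`, plus per-design argument lists).
#' @param out_dir output directory.
#' @return invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed
  if (is.null(seed)) stop("config must set a seed")
  traits <- config$traits %||% c("ssw")
  stage_seed <- function(k) (seed * 100 + k) %% .Machine$integer.max

  ## stage 1: data
  if (!is.null(config$simulation)) {
    set.seed(stage_seed(1))
    sim_args <- config$simulation
    sim_args$seed <- stage_seed(1)
    sim <- simulate_dataset(do.call(sim_config, sim_args))
    calls <- sim$calls; pheno <- sim$phenotypes
    pedigree <- sim$pedigree; map <- sim$map
  } else if (!is.null(config$input)) {
    calls <- read_genotypes(config$input$genotypes)
    pheno <- read_phenotypes(config$input$phenotypes)
    pedigree <- if (!is.null(config$input$pedigree))
      read.csv(config$input$pedigree, stringsAsFactors = FALSE) else NULL
    map <- if (!is.null(config$input$map))
      read.csv(config$input$map, stringsAsFactors = FALSE) else NULL
  } else stop("config needs either 'simulation' or 'input'")

  ## stage 2: derived traits
  if (!"ssw" %in% names(pheno) && all(c("f2.5", "f2.2") %in% names(pheno)))
    pheno$ssw <- standardized_seed_weight(pheno)
  if (!"py" %in% names(pheno) && all(c("protein", "yield") %in% names(pheno)))
    pheno$py <- protein_yield(pheno)
  bad <- setdiff(traits, names(pheno))
  if (length(bad)) stop("unknown trait(s): ", paste(bad, collapse = ", "))
  write.csv(summarize_traits(pheno, traits),
            file.path(out_dir, "trait_summary.csv"), row.names = FALSE)

  ## stage 3: QC, GRM, PCA
  qc_args <- config$qc %||% list()
  enc <- encode_genotypes(calls)
  qcr <- do.call(apply_qc, c(list(enc), qc_args))
  jsonlite::write_json(qcr$report[c("n_input_markers", "n_polymorphic",
                                    "n_after_missing", "n_after_maf",
                                    "n_input_lines", "n_retained_lines")],
                       file.path(out_dir, "qc_report.json"), auto_unbox = TRUE)
  imp <- impute_missing(qcr$matrix)
  g <- build_grm(imp)
  gdf <- data.frame(line = g$line_ids, g$values, check.names = FALSE)
  write.csv(gdf, file.path(out_dir, "grm.csv"), row.names = FALSE)
  pca <- grm_pca(g, k = min(10, length(g$line_ids)))
  write.csv(data.frame(line = rownames(pca$scores), pca$scores,
                       prop1 = pca$proportion[1], prop2 = pca$proportion[2]),
            file.path(out_dir, "pca_scores.csv"), row.names = FALSE)

  ## stage 4-5: per-trait REML + heritability, then cross-validation
  cvcfg <- config$cv %||% list(designs = "loo")
  designs <- cvcfg$designs %||% character(0)
  summary <- list(seed = seed, n_lines = length(g$line_ids),
                  qc = qcr$report[c("n_input_markers", "n_polymorphic",
                                    "n_after_maf", "n_retained_lines")],
                  pca_proportions = pca$proportion[1:2], traits = list())
  for (tr in traits) {
    spec <- do.call(model_spec, c(list(trait = tr), config$models[[tr]]))
    fit <- reml(spec, pheno, g)
    h2 <- heritability(fit)
    tr_out <- list(varcomp = as.list(fit$varcomp), varcomp_se = as.list(fit$se),
                   h2 = h2$h2, h2_se = h2$se, max_accuracy = h2$max_accuracy,
                   logl = fit$logl, n_iter = fit$n_iter)
    jsonlite::write_json(tr_out, file.path(out_dir, paste0("fit_", tr, ".json")),
                         auto_unbox = TRUE, digits = NA)
    cvres <- list()
    if ("loo" %in% designs) {
      set.seed(stage_seed(10))
      r <- cv_loo(spec, pheno, g, fit)
      write.csv(data.frame(line = names(r$gebv), gebv = r$gebv),
                file.path(out_dir, paste0("loo_gebv_", tr, ".csv")),
                row.names = FALSE)
      cvres$loo <- list(accuracy = r$accuracy, bias = r$bias)
    }
    if ("lso" %in% designs) {
      r <- cv_lso(spec, pheno, g, fit)
      write.csv(r$directions, file.path(out_dir, paste0("lso_", tr, ".csv")),
                row.names = FALSE)
      cvres$lso <- split(r$directions[c("accuracy", "bias")],
                         r$directions$training_set)
    }
    if ("lso_random" %in% designs) {
      args <- cvcfg$lso_random %||% list()
      r <- do.call(cv_lso_random,
                   c(list(spec, pheno, g, fit, seed = stage_seed(11)), args))
      write.csv(r$replicates,
                file.path(out_dir, paste0("lso_random_", tr, ".csv")),
                row.names = FALSE)
      cvres$lso_random <- lapply(split(r$summary, r$summary$n_train),
                                 function(d) d[c("accuracy", "sd_accuracy", "bias")])
    }
    if ("lfo" %in% designs) {
      if (is.null(pedigree)) stop("LFO requested but no pedigree available")
      args <- cvcfg$lfo %||% list()
      r <- do.call(cv_lfo, c(list(spec, pheno, g, fit, pedigree), args))
      write.csv(r$folds, file.path(out_dir, paste0("lfo_families_", tr, ".csv")),
                row.names = FALSE)
      cvres$lfo <- list(accuracy = r$accuracy, bias = r$bias,
                        n_families = r$n_families)
    }
    if ("reduce_training" %in% designs) {
      args <- cvcfg$reduce_training %||% list()
      r <- do.call(reduce_training,
                   c(list(spec, pheno, g, fit, seed = stage_seed(12)), args))
      write.csv(r, file.path(out_dir, paste0("reduce_training_", tr, ".csv")),
                row.names = FALSE)
      cvres$reduce_training <- list(n_points = nrow(r))
    }
    if ("reduce_markers" %in% designs) {
      if (is.null(map)) stop("reduce_markers requested but no map available")
      args <- cvcfg$reduce_markers %||% list()
      r <- do.call(reduce_markers,
                   c(list(spec, pheno, imp, fit, map, seed = stage_seed(13)), args))
      write.csv(r, file.path(out_dir, paste0("reduce_markers_", tr, ".csv")),
                row.names = FALSE)
      cvres$reduce_markers <- list(n_points = nrow(r))
    }
    summary$traits[[tr]] <- c(tr_out, list(cv = cvres))
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
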
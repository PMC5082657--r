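test_that("LOO predicts a held-out duplicate through its clone", {
  set.seed(31)
  n <- 20
  lines <- sprintf("L%02d", 1:n)
  M <- matrix(sample(c(-1, 1), n * 60, replace = TRUE), n,
              dimnames = list(lines, NULL))
  M <- rbind(M, DUP = M[1, ])
  M <- M[, apply(M, 2, function(x) length(unique(x)) > 1)]
  g <- build_grm(M)
  ph <- expand.grid(line = rownames(M), year = "2014",
                    location = c("A", "B"), block = 1:3,
                    stringsAsFactors = FALSE)
  ph$trial <- "T1"
  gen <- setNames(rnorm(n + 1, 0, 1.2), rownames(M))
  gen["DUP"] <- gen["L01"]
  ph$ssw <- gen[ph$line] + rnorm(nrow(ph), 0, 0.4)
  vc <- c(g = 1, l = 0.05, c = 0.05, e = 0.2)
  res <- cv_loo(model_spec("ssw"), ph, g, vc)
  full <- solve_mme(model_spec("ssw"), ph, g, vc)
  ## the held-out duplicate's GEBV tracks its clone's full-data GEBV
  expect_equal(res$gebv[["DUP"]], full$gebv[["L01"]], tolerance = 0.15)
  expect_gt(res$accuracy, 0.5)
})

test_that("LOO accuracy on a no-signal trait is near zero", {
  sim <- fx_sim()
  g <- fx_geno()$grm
  ph <- sim$phenotypes
  set.seed(32)
  ph$null_tr <- rnorm(nrow(ph))
  vc <- c(g = 0.01, l = 0.01, c = 0.01, e = 1)
  res <- cv_loo(model_spec("null_tr", fixed = c("year", "location")),
                ph, g, vc)
  expect_lt(abs(res$accuracy), 0.2)
})

test_that("LSO runs per direction and rejects degenerate labelings", {
  sim <- fx_sim()
  g <- fx_geno()$grm
  fit <- fx_fit()
  res <- suppressWarnings(cv_lso(model_spec("ssw"), sim$phenotypes, g, fit))
  expect_equal(nrow(res$directions), 2)
  ## direction asymmetry is allowed: accuracies need not match
  expect_false(isTRUE(all.equal(res$directions$accuracy[1],
                                res$directions$accuracy[2])))
  ## training set = validation set (a single label) is rejected
  one_label <- setNames(rep("X", length(g$line_ids)), g$line_ids)
  expect_error(cv_lso(model_spec("ssw"), sim$phenotypes, g, fit,
                      sets = one_label), "2 set labels")
})

test_that("random leave-set-out is reproducible with exhaustive partitions", {
  sim <- fx_sim()
  g <- fx_geno()$grm
  fit <- fx_fit()
  spec <- model_spec("ssw")
  a <- cv_lso_random(spec, sim$phenotypes, g, fit, n_reps = 3, seed = 77)
  b <- cv_lso_random(spec, sim$phenotypes, g, fit, n_reps = 3, seed = 77)
  expect_identical(a$replicates, b$replicates)
  ## sizes default to the breeding-set sizes and exhaust all lines
  expect_equal(sum(a$sizes), length(intersect(unique(sim$phenotypes$line),
                                              g$line_ids)))
  ## SD is computed across exactly n_reps accuracies per direction
  expect_equal(unique(a$summary$n_reps), 3)
  expect_error(cv_lso_random(spec, sim$phenotypes, g, fit,
                             sizes = c(1000, 1000)), "exceed")
})

test_that("LFO families follow the shared-parent definition", {
  ## synthetic pedigree with family sizes 2, 3, 4, 10 under min size 4
  ped <- data.frame(
    line = sprintf("L%02d", 1:19),
    parent1 = c(rep("P1", 2), rep("P2", 3), rep("P3", 4), rep("P4", 10)),
    parent2 = paste0("Q", 1:19))
  fams <- table(ped$parent1)
  expect_equal(sum(fams >= 4), 2)

  sim <- fx_sim()
  g <- fx_geno()$grm
  fit <- fx_fit()
  res <- cv_lfo(model_spec("ssw"), sim$phenotypes, g, fit, sim$pedigree,
                min_family_size = 4)
  ## every held-out family has at least the minimum size
  expect_true(all(res$folds$n_lines >= 4))
  ## lines with both parents heading qualifying families are predicted twice
  both <- names(res$times_predicted)[res$times_predicted == 2]
  qual <- res$folds$parent
  ped2 <- sim$pedigree
  in_two <- ped2$line[ped2$parent1 %in% qual & ped2$parent2 %in% qual]
  expect_setequal(both, intersect(in_two, names(res$gebv)))
  expect_error(cv_lfo(model_spec("ssw"), sim$phenotypes, g, fit,
                      sim$pedigree, min_family_size = 100), "no family")
})

test_that("no fold trains on a held-out line's phenotypes", {
  ## direct audit: a held-out line's GEBV must not change when that line's
  ## phenotype values are altered
  sim <- fx_sim()
  g <- fx_geno()$grm
  fit <- fx_fit()
  spec <- model_spec("ssw")
  ln <- g$line_ids[7]
  st <- barleyGP:::cv_setup(spec, sim$phenotypes, g, fit$varcomp)
  g1 <- barleyGP:::mme_solve_fold(st$eng, ln)$gebv[[ln]]
  ph2 <- sim$phenotypes
  ph2$ssw[ph2$line == ln] <- ph2$ssw[ph2$line == ln] + 50
  st2 <- barleyGP:::cv_setup(spec, ph2, g, fit$varcomp)
  g2 <- barleyGP:::mme_solve_fold(st2$eng, ln)$gebv[[ln]]
  expect_equal(g1, g2, tolerance = 1e-8)
})

test_that("training reduction follows the stated schedule", {
  sim <- fx_sim()
  g <- fx_geno()$grm
  fit <- fx_fit()
  res <- reduce_training(model_spec("ssw"), sim$phenotypes, g, fit,
                         n_steps = 4, step_frac = 0.10, n_reps = 2, seed = 3)
  n0 <- length(intersect(unique(sim$phenotypes$line), g$line_ids))
  expect_setequal(unique(res$size), round(n0 * (1 - 0.1 * (1:4))))
  expect_equal(sum(res$size == round(n0 * 0.9)), 2)
  ## compounding alternative
  res2 <- reduce_training(model_spec("ssw"), sim$phenotypes, g, fit,
                          n_steps = 2, step_frac = 0.10, n_reps = 1,
                          seed = 3, compounding = TRUE)
  expect_setequal(unique(res2$size), round(n0 * c(0.9, 0.81)))
  ## tiny subsets are skipped with a warning
  expect_warning(
    reduce_training(model_spec("ssw"), sim$phenotypes, g, fit, n_steps = 9,
                    step_frac = 0.105, n_reps = 1, seed = 3, min_lines = 10),
    "skipped")
})

test_that("marker thinning allocates per chromosome and respects spacing", {
  ## 7 markers over 7 chromosomes: exactly one per chromosome
  expect_equal(barleyGP:::.allocate(7, rep(50, 7)), rep(1, 7))
  ## proportional shares, capped at availability
  expect_equal(barleyGP:::.allocate(10, c(2, 100)), c(0, 10))
  expect_equal(barleyGP:::.allocate(102, c(2, 100)), c(2, 100))
  ## co-located markers can never be chosen together at min_cm = 1
  set.seed(41)
  for (i in 1:20) {
    idx <- barleyGP:::.sample_spaced(c(5, 5, 7, 9), 2, 1)
    expect_false(all(idx %in% c(1, 2)))
  }
  expect_error(barleyGP:::.sample_spaced(c(5, 5), 2, 1), "distinct")

  sim <- fx_sim()
  g <- fx_geno()$grm
  imp <- fx_geno()$imp
  fit <- fx_fit()
  res <- reduce_markers(model_spec("ssw"), sim$phenotypes, imp, fit,
                        sim$map, n_steps = 2, step_frac = 0.25, n_reps = 1,
                        seed = 4)
  n_mapped <- sum(imp$marker_ids %in% sim$map$marker)
  expect_setequal(unique(res$size), round(n_mapped * c(0.75, 0.5)))
  expect_true(all(res$accuracy >= -1 & res$accuracy <= 1))
})

test_that("pooled LOO accuracy respects the heritability ceiling", {
  sim <- fx_sim()
  g <- fx_geno()$grm
  fit <- fx_fit()
  res <- cv_loo(model_spec("ssw"), sim$phenotypes, g, fit)
  h <- heritability(fit)
  ## accuracy cannot exceed sqrt(h2) by more than sampling noise
  expect_lt(res$accuracy, h$max_accuracy + 3 * res$se_accuracy)
})
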
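test_that("MME solutions equal dense GLS/BLUP on random small instances", {
  set.seed(5)
  for (i in 1:20) {
    inst <- random_instance(with_l = i %% 3 != 0)
    spec <- if (i %% 3 == 0) model_spec("ssw", include_line_effect = FALSE)
            else model_spec("ssw")
    sol <- solve_mme(spec, inst$pheno, inst$grm, inst$vc)
    des <- oracle_designs(inst$pheno, inst$grm$line_ids)
    oracle <- dense_blup(inst$pheno$ssw, des$X, des$Zg, inst$grm$values,
                         if (spec$include_line_effect) des$Zl, des$Zc,
                         inst$vc)
    expect_equal(unname(sol$gebv), unname(oracle$gebv), tolerance = 1e-8)
    expect_equal(unname(sol$fixed[des$fixed_names]), unname(oracle$fixed),
                 tolerance = 1e-8)
  }
})

test_that("held-out lines are predicted through G, matching the dense oracle", {
  set.seed(6)
  for (i in 1:8) {
    inst <- random_instance(n_lines = 12)
    hold <- sample(inst$lines, 3)
    sol <- suppressWarnings(
      solve_mme(model_spec("ssw"), inst$pheno, inst$grm, inst$vc,
                heldout_lines = hold))
    keep <- !(inst$pheno$line %in% hold)
    ph_tr <- inst$pheno[keep, ]
    des <- oracle_designs(ph_tr, inst$grm$line_ids)
    oracle <- dense_blup(ph_tr$ssw, des$X, des$Zg, inst$grm$values,
                         des$Zl, des$Zc, inst$vc)
    expect_equal(unname(sol$gebv), unname(oracle$gebv), tolerance = 1e-8)
  }
})

test_that("vanishing genomic variance shrinks held-out GEBVs to zero", {
  inst <- local({ set.seed(8); random_instance(n_lines = 10) })
  vc <- inst$vc
  vc[["g"]] <- 1e-10
  sol <- solve_mme(model_spec("ssw"), inst$pheno, inst$grm, vc,
                   heldout_lines = inst$lines[1:2])
  expect_lt(max(abs(sol$gebv[inst$lines[1:2]])), 1e-6)
})

test_that("duplicate lines with identical records get equal GEBVs", {
  set.seed(12)
  n <- 8
  lines <- sprintf("L%d", 1:n)
  M <- matrix(sample(c(-1, 1), n * 40, replace = TRUE), n,
              dimnames = list(lines, NULL))
  M <- rbind(M, DUP = M[1, ])  # clone of L1, G-correlation 1
  M <- M[, apply(M, 2, function(x) length(unique(x)) > 1)]
  g <- build_grm(M)
  ph <- expand.grid(line = rownames(M), year = "2014", location = c("A", "B"),
                    block = 1:3, stringsAsFactors = FALSE)
  ph$trial <- "T1"
  base <- rnorm(n + 1)
  names(base) <- rownames(M)
  base["DUP"] <- base["L1"]
  ph$ssw <- base[ph$line] + rnorm(nrow(ph), 0, 0.1)
  ph$ssw[ph$line == "DUP"] <- ph$ssw[ph$line == "L1"]  # identical records
  sol <- solve_mme(model_spec("ssw"), ph, g,
                   c(g = 1, l = 0.3, c = 0.2, e = 0.5))
  expect_equal(sol$gebv[["DUP"]], sol$gebv[["L1"]], tolerance = 1e-8)
})

test_that("corrected phenotypes subtract exactly the fitted fixed effects", {
  ## single fixed level: corrected value = line mean - grand estimate
  ph <- data.frame(line = rep(c("A", "B"), each = 2), year = "2014",
                   location = "L1", trial = "T1", block = c(1, 2, 1, 2),
                   ssw = c(4, 6, 1, 3))
  M <- matrix(c(-1, 1, -1, 1, 1, -1), 2, dimnames = list(c("A", "B"), NULL))
  g <- build_grm(M)
  sol <- solve_mme(model_spec("ssw"), ph, g, c(g = 1, l = 1, c = 1, e = 1))
  cp <- corrected_phenotypes(sol)
  expect_equal(cp[["A"]], 5 - sol$fixed[[1]])
  expect_equal(cp[["B"]], 2 - sol$fixed[[1]])

  ## balanced two-environment design: hand-computed corrected means
  ph2 <- expand.grid(line = c("A", "B"), year = "2014",
                     location = c("L1", "L2"), block = 1:2,
                     stringsAsFactors = FALSE)
  ph2$trial <- "T"
  eff <- c(L1 = 10, L2 = 20)
  gen <- c(A = 1, B = -1)
  ph2$ssw <- eff[ph2$location] + gen[ph2$line]
  sol2 <- solve_mme(model_spec("ssw"), ph2, g, c(g = 1, l = 1, c = 1, e = 1))
  cp2 <- corrected_phenotypes(sol2)
  expect_equal(unname(cp2[c("A", "B")]), c(1, -1), tolerance = 1e-6)

  ## adding a constant shifts the fixed effects, not the corrected values
  ph3 <- ph2
  ph3$ssw <- ph3$ssw + 100
  sol3 <- solve_mme(model_spec("ssw"), ph3, g, c(g = 1, l = 1, c = 1, e = 1))
  expect_equal(corrected_phenotypes(sol3), cp2, tolerance = 1e-6)
})

test_that("accuracy and bias follow their closed forms", {
  x <- setNames(rnorm(50), sprintf("L%02d", 1:50))
  ab <- accuracy_and_bias(x, x)
  expect_equal(ab$accuracy, 1)
  expect_equal(ab$bias, 1)
  ab2 <- accuracy_and_bias(0.5 * x, x)
  expect_equal(ab2$accuracy, 1)
  expect_equal(ab2$bias, 2)
  ## random pairs against the cov/var oracle
  set.seed(14)
  g <- setNames(rnorm(50), names(x))
  y <- setNames(rnorm(50), names(x))
  ab3 <- accuracy_and_bias(g, y)
  expect_equal(ab3$accuracy, cov(g, y) / sqrt(var(g) * var(y)),
               tolerance = 1e-12)
  expect_equal(ab3$bias, cov(g, y) / var(g), tolerance = 1e-12)
  ## affine invariance of accuracy; inverse scaling of bias
  ab4 <- accuracy_and_bias(3 * g + 2, y)
  expect_equal(abs(ab4$accuracy), abs(ab3$accuracy), tolerance = 1e-12)
  expect_equal(ab4$bias, ab3$bias / 3, tolerance = 1e-12)
  expect_warning(accuracy_and_bias(setNames(rep(1, 5), letters[1:5]),
                                   setNames(rnorm(5), letters[1:5])),
                 "zero variance")
})

test_that("heritability follows the line-mean formula with delta-method SE", {
  ## degenerate case: only genomic variance
  h <- heritability(c(g = 1, l = 0, c = 0, e = 0))
  expect_equal(h$h2, 1)
  expect_equal(h$max_accuracy, 1)
  ## SEs propagate the AI curvature
  fit <- fx_fit()
  h2 <- heritability(fit)
  expect_true(is.finite(h2$se) && h2$se > 0)
  expect_equal(h2$max_accuracy, sqrt(h2$h2))
  expect_error(heritability(c(g = 0, l = 0, c = 0, e = 0)), "denominator")
})

test_that("expected accuracy follows the training-size formula", {
  expect_equal(expected_accuracy(100, 0.5, 50), sqrt(0.5))
  expect_equal(expected_accuracy(200, 0.5, 50), sqrt(100 / 150))
  ## limit Me -> 0+: accuracy -> 1
  expect_gt(expected_accuracy(10, 0.1, 1e-9), 0.999)
})
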
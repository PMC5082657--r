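## Shared machinery: one full-data fit supplies the corrected phenotypes
## (identical for every design, so folds are comparable) and a precomputed
## MME engine makes per-fold solves a downdate + refactorization.
cv_setup <- function(spec, pheno, grm, vc, ungenotyped = "drop") {
  if (inherits(vc, "reml_fit")) vc <- vc$varcomp
  mm <- build_mm(spec, pheno, grm, ungenotyped)
  eng <- mme_engine(mm, vc)
  full <- mme_solve_fold(eng, NULL)
  cp <- corrected_phenotypes(full)
  lines <- intersect(names(cp), mm$g_ids)
  list(eng = eng, full = full, cp = cp, lines = lines, spec = spec, vc = vc)
}

new_cv_result <- function(design, gebv, cp, folds = NULL, extra = list()) {
  ab <- accuracy_and_bias(gebv, cp)
  structure(c(list(design = design, gebv = gebv,
                   accuracy = ab$accuracy, bias = ab$bias,
                   se_accuracy = ab$se_accuracy, n_predicted = ab$n,
                   folds = folds), extra),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s cross-validation: %d lines predicted, accuracy %.3f, bias %.3f\n",
              x$design, x$n_predicted, x$accuracy, x$bias))
  invisible(x)
}

#' Leave-one-out cross-validation
#'
#' Each phenotyped, genotyped line is held out in turn: its phenotype
#' records are excluded from training and its GEBV predicted through the
#' relationships in `G`. Pooled accuracy is the correlation of the held-out
#' GEBVs with the per-line phenotypes corrected for the fixed effects of
#' the full-data fit.
#'
#' @param spec a [model_spec()].
#' @param pheno plot-level phenotype data.frame.
#' @param grm a [build_grm()] result.
#' @param vc variance components (named vector or `reml_fit`), normally from
#'   the full data.
#' @param lines lines to predict (default: all phenotyped genotyped lines).
#' @return a `cv_result` with per-line held-out GEBVs.
#' @export
cv_loo <- function(spec, pheno, grm, vc, lines = NULL) {
  st <- cv_setup(spec, pheno, grm, vc)
  if (is.null(lines)) lines <- st$lines
  if (length(lines) < 10) warning("fewer than 10 lines: pooled correlation unstable")
  gebv <- setNames(numeric(length(lines)), lines)
  for (ln in lines) gebv[ln] <- mme_solve_fold(st$eng, ln)$gebv[ln]
  new_cv_result("LOO", gebv, st$cp[lines])
}

#' Leave-set-out cross-validation
#'
#' One breeding set is held out entirely and predicted from the other, in
#' both directions.
#'
#' @inheritParams cv_loo
#' @param sets named character vector mapping line to set label; defaults to
#'   the `set` column of `pheno`.
#' @return list of class `cv_lso_result`: one `cv_result` per direction,
#'   named by the *training* set, plus `directions` (a summary data.frame).
#' @export
cv_lso <- function(spec, pheno, grm, vc, sets = NULL) {
  st <- cv_setup(spec, pheno, grm, vc)
  if (is.null(sets)) {
    if (!"set" %in% names(pheno)) stop("no 'set' column and no `sets` given")
    sets <- setNames(pheno$set, pheno$line)
    sets <- sets[!duplicated(names(sets))]
  }
  sets <- sets[st$lines]
  labs <- sort(unique(sets))
  if (length(labs) < 2) stop("need at least 2 set labels")
  out <- list(); rows <- list()
  for (tr_lab in labs) {
    train <- names(sets)[sets == tr_lab]
    test <- names(sets)[sets != tr_lab]
    if (length(train) == 0 || length(test) == 0)
      stop("a breeding set has no lines")
    sol <- mme_solve_fold(st$eng, test)
    res <- new_cv_result("LSO", sol$gebv[test], st$cp[test],
                         extra = list(training_set = tr_lab))
    out[[tr_lab]] <- res
    rows[[tr_lab]] <- data.frame(training_set = tr_lab,
                                 n_train = length(train), n_test = length(test),
                                 accuracy = res$accuracy, bias = res$bias)
  }
  structure(c(out, list(directions = do.call(rbind, rows))),
            class = "cv_lso_result")
}

#' @export
print.cv_lso_result <- function(x, ...) {
  print(x$directions, row.names = FALSE)
  invisible(x)
}

#' Leave-random-set-out cross-validation
#'
#' Repeats the leave-set-out design with random partitions of the stated
#' sizes; the between-replicate SD of accuracy is its standard error.
#'
#' @inheritParams cv_loo
#' @param sizes two partition sizes; must sum to at most the number of
#'   lines. Default: the observed breeding-set sizes.
#' @param n_reps number of random partitions.
#' @param seed RNG seed.
#' @return list of class `cv_lso_random_result`: `replicates` (data.frame
#'   of per-replicate, per-direction accuracies and biases) and `summary`
#'   (mean and SD by training-set size).
#' @export
cv_lso_random <- function(spec, pheno, grm, vc, sizes = NULL, n_reps = 10,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- cv_setup(spec, pheno, grm, vc)
  n <- length(st$lines)
  if (is.null(sizes)) {
    if (!"set" %in% names(pheno)) stop("no 'set' column and no `sizes` given")
    ss <- setNames(pheno$set, pheno$line)[st$lines]
    sizes <- as.integer(table(ss)[sort(unique(ss))][1:2])
  }
  if (sum(sizes) > n) stop("partition sizes exceed the number of lines")
  rows <- list()
  for (r in seq_len(n_reps)) {
    perm <- sample(st$lines)
    part <- list(perm[seq_len(sizes[1])],
                 perm[sizes[1] + seq_len(sizes[2])])
    for (d in 1:2) {
      train <- part[[d]]; test <- part[[3 - d]]
      sol <- mme_solve_fold(st$eng, setdiff(st$lines, train))
      ab <- accuracy_and_bias(sol$gebv[test], st$cp[test])
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, n_train = length(train), n_test = length(test),
        accuracy = ab$accuracy, bias = ab$bias)
    }
  }
  reps <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(reps, reps$n_train), function(d) data.frame(
    n_train = d$n_train[1], n_reps = nrow(d),
    accuracy = mean(d$accuracy), sd_accuracy = sd(d$accuracy),
    bias = mean(d$bias), sd_bias = sd(d$bias))))
  structure(list(replicates = reps, summary = agg, sizes = sizes),
            class = "cv_lso_random_result")
}

#' @export
print.cv_lso_random_result <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Leave-family-out cross-validation
#'
#' A family is all lines sharing one parent. Every family with at least
#' `min_family_size` lines is held out in turn; a line that is predicted in
#' both of its parents' families contributes the mean of its held-out GEBVs
#' to the pooled correlation.
#'
#' @inheritParams cv_loo
#' @param pedigree data.frame with columns `line`, `parent1`, `parent2`.
#' @param min_family_size smallest family held out (4 = "more than three
#'   lines").
#' @return a `cv_result`; `folds` lists each family with its size and, where
#'   defined, its within-family accuracy.
#' @export
cv_lfo <- function(spec, pheno, grm, vc, pedigree, min_family_size = 4) {
  st <- cv_setup(spec, pheno, grm, vc)
  ped <- pedigree[pedigree$line %in% st$lines, , drop = FALSE]
  parents <- sort(unique(c(ped$parent1, ped$parent2)))
  fams <- lapply(parents, function(p)
    ped$line[ped$parent1 == p | ped$parent2 == p])
  names(fams) <- parents
  keep <- lengths(fams) >= min_family_size
  if (!any(keep)) stop("no family reaches min_family_size = ", min_family_size)
  fams <- fams[keep]
  pred_sum <- setNames(numeric(length(st$lines)), st$lines)
  pred_n <- setNames(integer(length(st$lines)), st$lines)
  folds <- list()
  for (p in names(fams)) {
    fam <- fams[[p]]
    sol <- mme_solve_fold(st$eng, fam)
    pred_sum[fam] <- pred_sum[fam] + sol$gebv[fam]
    pred_n[fam] <- pred_n[fam] + 1L
    acc <- if (length(fam) >= 3 && sd(st$cp[fam]) > 0 && sd(sol$gebv[fam]) > 0)
      cor(st$cp[fam], sol$gebv[fam]) else NA_real_
    folds[[p]] <- data.frame(parent = p, n_lines = length(fam),
                             accuracy = acc)
  }
  predicted <- names(pred_n)[pred_n > 0]
  gebv <- pred_sum[predicted] / pred_n[predicted]
  new_cv_result("LFO", gebv, st$cp[predicted],
                folds = do.call(rbind, folds),
                extra = list(n_families = length(fams),
                             times_predicted = pred_n[predicted]))
}

#' Reduced training-population experiment
#'
#' Starting from all lines, the training population is shrunk in steps of
#' `step_frac` of the original size. At each step, `n_reps` random line
#' subsets are drawn and a leave-one-out cross-validation is run within
#' each subset (lines outside the subset are excluded from training
#' entirely). Variance components stay fixed at the full-data estimates.
#'
#' @inheritParams cv_loo
#' @param n_steps number of reduction steps.
#' @param step_frac fraction of the *original* population removed per step
#'   (set `compounding = TRUE` for 0.9^k schedules instead).
#' @param n_reps random subsets per step.
#' @param seed RNG seed.
#' @param compounding multiply by `1 - step_frac` per step instead of
#'   subtracting a constant.
#' @param min_lines subsets smaller than this are skipped with a warning.
#' @return object of class `reduction_result`: data.frame with `step`,
#'   `size`, `rep`, `accuracy`, `bias` — the raw replicate points.
#' @export
reduce_training <- function(spec, pheno, grm, vc, n_steps = 9,
                            step_frac = 0.10, n_reps = 100, seed = NULL,
                            compounding = FALSE, min_lines = 10) {
  if (!is.null(seed)) set.seed(seed)
  st <- cv_setup(spec, pheno, grm, vc)
  n0 <- length(st$lines)
  sizes <- if (compounding) round(n0 * (1 - step_frac)^seq_len(n_steps))
           else round(n0 * (1 - step_frac * seq_len(n_steps)))
  rows <- list()
  for (k in seq_along(sizes)) {
    sz <- sizes[k]
    if (sz < min_lines) {
      warning("step ", k, " subset size ", sz, " below ", min_lines, "; skipped")
      next
    }
    for (r in seq_len(n_reps)) {
      sub <- sample(st$lines, sz)
      ## lines outside the subset never enter training: the fold engine is
      ## built on the subset's records only (GEBVs still span all of G)
      sub_pheno <- pheno[pheno$line %in% sub, , drop = FALSE]
      st_sub <- cv_setup(spec, sub_pheno, grm, vc)
      gebv <- setNames(numeric(sz), sub)
      for (ln in sub)
        gebv[ln] <- mme_solve_fold(st_sub$eng, ln)$gebv[ln]
      ab <- accuracy_and_bias(gebv, st$cp[sub])
      rows[[length(rows) + 1L]] <- data.frame(step = k, size = sz, rep = r,
                                              accuracy = ab$accuracy,
                                              bias = ab$bias)
    }
  }
  structure(do.call(rbind, rows), class = c("reduction_result", "data.frame"))
}

## proportional allocation of k markers over chromosomes (largest remainder),
## capped at the available count per chromosome
.allocate <- function(k, avail) {
  share <- k * avail / sum(avail)
  alloc <- floor(share)
  rem <- k - sum(alloc)
  if (rem > 0) {
    ord <- order(share - alloc, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1
  }
  over <- pmax(alloc - avail, 0)
  alloc <- pmin(alloc, avail)
  while (sum(over) > 0) {
    room <- avail - alloc
    if (sum(room) == 0) break
    i <- which.max(room)
    add <- min(sum(over), room[i])
    alloc[i] <- alloc[i] + add
    over <- c(sum(over) - add, rep(0, length(over) - 1))
  }
  alloc
}

## sample k markers from one chromosome with >= min_cm spacing; the spacing
## is halved until the quota is reachable
.sample_spaced <- function(pos, k, min_cm) {
  if (k == 0) return(integer(0))
  if (k > length(unique(pos)))
    stop("cannot select ", k, " markers at distinct positions")
  d <- min_cm
  repeat {
    ord <- sample.int(length(pos))
    acc <- integer(0); acc_pos <- numeric(0)
    for (i in ord) {
      if (length(acc) == 0 || all(abs(acc_pos - pos[i]) >= d)) {
        acc <- c(acc, i); acc_pos <- c(acc_pos, pos[i])
        if (length(acc) == k) return(acc)
      }
    }
    d <- d / 2  # relax spacing when the quota is unreachable; co-located
                # markers still never co-occur (distance 0 < any d > 0)
  }
}

#' Reduced marker-set experiment
#'
#' The mapped marker set is thinned in steps of `step_frac` of its original
#' size. At each step, `n_reps` marker subsets are drawn with
#' per-chromosome proportional allocation and at least `min_cm` between
#' selected markers (the spacing is halved whenever the quota is otherwise
#' unreachable); the GRM is rebuilt from each subset and a leave-one-out
#' cross-validation run. Variance components stay fixed at the full-marker
#' estimates.
#'
#' @inheritParams cv_loo
#' @param markers an imputed `marker_matrix` (the full panel).
#' @param map data.frame `marker`, `chromosome`, `position` (cM); markers
#'   absent from the map are excluded from sampling.
#' @param n_steps,step_frac,n_reps,seed as in [reduce_training()].
#' @param min_cm minimum spacing between selected markers, cM.
#' @return a `reduction_result` data.frame with `step`, `size` (markers),
#'   `rep`, `accuracy`, `bias`.
#' @export
reduce_markers <- function(spec, pheno, markers, vc, map, n_steps = 9,
                           step_frac = 0.10, n_reps = 100, min_cm = 1,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(markers, "marker_matrix"))
  if (inherits(vc, "reml_fit")) vc <- vc$varcomp
  mapped <- map[map$marker %in% markers$marker_ids, , drop = FALSE]
  if (nrow(mapped) == 0) stop("no mapped markers available")
  by_chr <- split(mapped, mapped$chromosome)
  avail <- vapply(by_chr, nrow, 1L)
  n0 <- nrow(mapped)
  full_grm <- build_grm(markers)
  st <- cv_setup(spec, pheno, full_grm, vc)
  sizes <- round(n0 * (1 - step_frac * seq_len(n_steps)))
  if (any(sizes > n0)) stop("requested size exceeds mapped markers")
  rows <- list()
  for (k in seq_along(sizes)) {
    sz <- sizes[k]
    if (sz < length(avail)) { warning("step ", k, " too small; skipped"); next }
    alloc <- .allocate(sz, avail)
    for (r in seq_len(n_reps)) {
      sel <- unlist(lapply(seq_along(by_chr), function(ch) {
        idx <- .sample_spaced(by_chr[[ch]]$position, alloc[ch], min_cm)
        by_chr[[ch]]$marker[idx]
      }))
      sub_vals <- markers$values[, sel, drop = FALSE]
      g_sub <- tryCatch(build_grm(sub_vals), error = function(e) NULL)
      if (is.null(g_sub)) next
      stsub <- suppressMessages(cv_setup(st$spec, pheno, g_sub, vc))
      gebv <- setNames(numeric(length(stsub$lines)), stsub$lines)
      for (ln in stsub$lines)
        gebv[ln] <- mme_solve_fold(stsub$eng, ln)$gebv[ln]
      ab <- accuracy_and_bias(gebv, st$cp[stsub$lines])
      rows[[length(rows) + 1L]] <- data.frame(step = k, size = sz, rep = r,
                                              accuracy = ab$accuracy,
                                              bias = ab$bias)
    }
  }
  structure(do.call(rbind, rows), class = c("reduction_result", "data.frame"))
}
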
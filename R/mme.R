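#' Solve Henderson's mixed-model equations at fixed variance components
#'
#' Builds and solves the MME for the model of a [model_spec()], optionally
#' masking the phenotype records (never the genotypes) of held-out lines.
#' Held-out and otherwise unphenotyped lines receive GEBVs through the
#' off-diagonals of `G`. Fixed effects are estimated from training records
#' only; a fixed-effect level emptied by the mask is dropped with a warning
#' and its estimate reported as `NA`.
#'
#' @param spec a [model_spec()].
#' @param pheno plot-level phenotype data.frame.
#' @param grm a [build_grm()] result.
#' @param vc named variance components (`g`, optional `l`, `c`, `e`), a
#'   numeric vector or a `reml_fit`.
#' @param heldout_lines lines whose phenotype records are excluded from
#'   training.
#' @param ungenotyped see [reml()].
#' @return object of class `mme_fit`: `fixed` (estimate per fixed level),
#'   `gebv` (named, every line of `G`), `line_effects`, `gxe_effects`,
#'   `heldout`, plus internals for [corrected_phenotypes()].
#' @export
solve_mme <- function(spec, pheno, grm, vc, heldout_lines = NULL,
                      ungenotyped = c("drop", "identity")) {
  mm <- build_mm(spec, pheno, grm, match.arg(ungenotyped))
  if (inherits(vc, "reml_fit")) vc <- vc$varcomp
  need <- c("g", if (mm$include_line_effect) "l", "c", "e")
  stopifnot(all(need %in% names(vc)))
  eng <- mme_engine(mm, vc)
  mme_solve_fold(eng, heldout_lines)
}

## Precompute the full-data crossproducts and covariance structure so that
## cross-validation folds only downdate and refactorize.
mme_engine <- function(mm, vc) {
  if (inherits(vc, "reml_fit")) vc <- vc$varcomp
  WtW <- as.matrix(Matrix::crossprod(mm$W))
  Wty <- as.vector(Matrix::crossprod(mm$W, mm$y))
  se <- vc[["e"]]
  ## every random block has identity prior covariance: the breeding-value
  ## block is parameterized as a = L^+ g with G = L L'
  d <- numeric(ncol(WtW))
  d[mm$blocks$g] <- 1 / vc[["g"]]
  if (mm$include_line_effect) d[mm$blocks$l] <- 1 / vc[["l"]]
  d[mm$blocks$c] <- 1 / vc[["c"]]
  C_full <- WtW / se + diag(d)
  rhs_full <- Wty / se
  Cinv <- chol2inv(chol(C_full))
  s_full <- drop(Cinv %*% rhs_full)
  list(mm = mm, vc = vc, C_full = C_full, rhs_full = rhs_full,
       Cinv = Cinv, s_full = s_full, rec_line = mm$dat$line)
}

mme_solve_fold <- function(eng, heldout_lines = NULL) {
  mm <- eng$mm
  se <- eng$vc[["e"]]
  out_rows <- if (is.null(heldout_lines)) integer(0)
              else which(eng$rec_line %in% heldout_lines)
  if (length(out_rows) == length(mm$y)) stop("mask excludes every record")
  ## fixed levels with no training records are dropped
  p <- length(mm$blocks$fixed)
  lev_counts <- tabulate(match(mm$fixed_level, mm$fixed_levels), nbins = p)
  if (length(out_rows))
    lev_counts <- lev_counts -
      tabulate(match(mm$fixed_level[out_rows], mm$fixed_levels), nbins = p)
  empty <- which(lev_counts == 0)
  if (length(empty))
    warning("fixed-effect level(s) with no training records dropped: ",
            paste(mm$fixed_levels[empty], collapse = ", "))

  if (length(out_rows) == 0) {
    s <- eng$s_full
  } else if (length(empty) == 0 && length(out_rows) <= length(mm$y) / 4) {
    ## exact rank-k downdate of the full-data system (Woodbury):
    ## (C - U U'/se)^-1 (rhs - U y_o/se) with U = W[out,]'
    U <- Matrix::t(mm$W[out_rows, , drop = FALSE])
    yo <- mm$y[out_rows]
    CU <- eng$Cinv %*% U
    cap <- diag(se, length(out_rows)) - as.matrix(Matrix::crossprod(U, CU))
    base <- eng$s_full - drop(CU %*% yo) / se
    s <- base + drop(CU %*% solve(cap, as.vector(Matrix::crossprod(U, base))))
  } else {
    C <- eng$C_full
    rhs <- eng$rhs_full
    Wo <- mm$W[out_rows, , drop = FALSE]
    C <- C - as.matrix(Matrix::crossprod(Wo)) / se
    rhs <- rhs - as.vector(Matrix::crossprod(Wo, mm$y[out_rows])) / se
    keep <- setdiff(seq_len(nrow(C)), empty)
    ch <- chol(C[keep, keep])
    s_keep <- backsolve(ch, forwardsolve(t(ch), rhs[keep]))
    s <- rep(NA_real_, nrow(C))
    s[keep] <- s_keep
  }
  fixed <- setNames(s[mm$blocks$fixed], mm$fixed_levels)
  gebv <- setNames(drop(mm$L %*% s[mm$blocks$g]), mm$g_ids)
  line_effects <- if (mm$include_line_effect)
    setNames(s[mm$blocks$l], mm$l_ids) else NULL
  gxe <- setNames(s[mm$blocks$c], mm$c_ids)
  structure(list(fixed = fixed, gebv = gebv, line_effects = line_effects,
                 gxe_effects = gxe, heldout = heldout_lines,
                 vc = eng$vc, spec = mm$spec,
                 fixed_level = mm$fixed_level, y = mm$y,
                 rec_line = eng$rec_line),
            class = "mme_fit")
}

#' @export
print.mme_fit <- function(x, ...) {
  cat("MME solution for '", x$spec$trait, "': ", length(x$gebv), " GEBVs, ",
      length(x$fixed), " fixed levels",
      if (length(x$heldout)) paste0(" (", length(x$heldout), " lines held out)"),
      "\n", sep = "")
  invisible(x)
}

#' Phenotypes corrected for the fixed effects
#'
#' Per plot, `y - X t_hat` using the fitted fixed effects, averaged per line
#' over all of that line's plots.
#'
#' @param fit an [solve_mme()] result (usually the full-data fit).
#' @return named numeric vector, one value per phenotyped line.
#' @export
corrected_phenotypes <- function(fit) {
  stopifnot(inherits(fit, "mme_fit"))
  resid <- fit$y - fit$fixed[fit$fixed_level]
  means <- tapply(resid, fit$rec_line, mean, na.rm = TRUE)
  out <- as.vector(means)
  names(out) <- names(means)
  out[!is.nan(out)]
}

#' Prediction accuracy and dispersion bias
#'
#' Accuracy is the Pearson correlation between corrected phenotypes and
#' GEBVs; bias is the slope of the regression of corrected phenotypes on
#' GEBVs. A slope below 1 flags over-dispersed (too variable) GEBVs, above
#' 1 under-dispersed.
#'
#' @param gebv named GEBV vector.
#' @param cp named corrected-phenotype vector (see
#'   [corrected_phenotypes()]).
#' @return list with `accuracy`, `bias`, `n` (lines used) and
#'   `se_accuracy` (analytic, `sqrt((1 - r^2) / (n - 2))`).
#' @export
accuracy_and_bias <- function(gebv, cp) {
  ids <- intersect(names(gebv), names(cp))
  if (length(ids) < 3) stop("fewer than 3 lines with both GEBV and phenotype")
  g <- gebv[ids]; y <- cp[ids]
  ok <- !is.na(g) & !is.na(y)
  g <- g[ok]; y <- y[ok]
  if (length(g) < 3) stop("fewer than 3 complete pairs")
  if (sd(g) == 0 || sd(y) == 0) {
    warning("zero variance; accuracy undefined")
    return(list(accuracy = NA_real_, bias = NA_real_, n = length(g),
                se_accuracy = NA_real_))
  }
  r <- cor(y, g)
  slope <- cov(y, g) / var(g)
  list(accuracy = r, bias = slope, n = length(g),
       se_accuracy = sqrt((1 - r^2) / (length(g) - 2)))
}

#' Line-mean heritability and maximum accuracy
#'
#' `h2 = sigma2_g / (sigma2_g + sigma2_l + sigma2_c / n_env +
#' sigma2_e / n_reps)` (the `l` term is omitted when absent, as for protein
#' yield). Defaults reflect testing in 2 environments with 6 plots per
#' line. The maximum attainable prediction accuracy is `sqrt(h2)`, the
#' expected correlation between line means and true breeding values. With a
#' `reml_fit`, the SE comes from the delta method on the inverse AI matrix.
#'
#' @param vc named variance components (`g`, optional `l`, `c`, `e`) or a
#'   `reml_fit`.
#' @param n_env number of environments a line is tested in.
#' @param n_reps total replicate plots per line (across environments).
#' @return list of class `heritability`: `h2`, `se` (NA without curvature),
#'   `max_accuracy`.
#' @export
#' @examples
#' heritability(c(g = 0.014, l = 0.009, c = 0.006, e = 0.009))  # h2 ~ 0.51
heritability <- function(vc, n_env = 2, n_reps = 6) {
  ai_inv <- NULL
  if (inherits(vc, "reml_fit")) {
    ai_inv <- vc$ai_inv
    vc <- vc$varcomp
  }
  stopifnot(all(c("g", "c", "e") %in% names(vc)))
  has_l <- "l" %in% names(vc) && !is.na(vc[["l"]])
  g <- vc[["g"]]; l <- if (has_l) vc[["l"]] else 0
  cc <- vc[["c"]]; e <- vc[["e"]]
  denom <- g + l + cc / n_env + e / n_reps
  if (denom <= 0) stop("zero denominator in heritability")
  h2 <- g / denom
  se <- NA_real_
  if (!is.null(ai_inv) && !anyNA(ai_inv)) {
    grad <- c(g = (denom - g) / denom^2,
              if (has_l) c(l = -g / denom^2),
              c = -g / (n_env * denom^2),
              e = -g / (n_reps * denom^2))
    ord <- intersect(colnames(ai_inv), names(grad))
    se <- sqrt(drop(t(grad[ord]) %*% ai_inv[ord, ord] %*% grad[ord]))
  }
  structure(list(h2 = h2, se = se, max_accuracy = sqrt(h2)),
            class = "heritability")
}

#' @export
print.heritability <- function(x, ...) {
  cat(sprintf("h2 = %.3f%s, max accuracy = %.3f\n", x$h2,
              if (is.na(x$se)) "" else sprintf(" (SE %.3f)", x$se),
              x$max_accuracy))
  invisible(x)
}

#' Expected accuracy from training size, heritability and trait complexity
#'
#' `r = sqrt(N h2 / (N h2 + Me))` where `N` is the training-set size, `h2`
#' the entry-mean heritability and `Me` the effective number of
#' independently segregating chromosome segments (QTL).
#'
#' @param N training-set size.
#' @param h2 entry-mean heritability in `[0, 1]`.
#' @param Me effective number of QTL, `> 0`.
#' @return expected accuracy.
#' @export
#' @examples
#' expected_accuracy(200, 0.5, 50)  # ~0.816
expected_accuracy <- function(N, h2, Me) {
  stopifnot(N >= 1, h2 >= 0, h2 <= 1, Me > 0)
  sqrt(N * h2 / (N * h2 + Me))
}
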
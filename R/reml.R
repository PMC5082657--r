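#' Average-information REML for the GBLUP mixed model
#'
#' Estimates the variance components of the model declared by a
#' [model_spec()] (additive genomic `g`, optional residual line `l`,
#' line-by-environment `c`, plot residual `e`) by restricted maximum
#' likelihood, using average-information (AI) updates with EM fallback
#' whenever an AI step would push a component below its floor or decrease
#' the restricted likelihood. Components are bounded below at
#' `1e-8 * var(y)`. Convergence requires `|delta logL| < tol_logl` and a
#' maximum relative component change `< tol_par`.
#'
#' All per-iteration quantities come from one Cholesky factorization of the
#' mixed-model-equation coefficient matrix; the AI matrix at the optimum is
#' returned as the curvature used for standard errors of the components and
#' of heritability.
#'
#' @param spec a [model_spec()].
#' @param pheno plot-level phenotype data.frame.
#' @param grm a [build_grm()] result covering the genotyped lines.
#' @param init optional named starting values (`g`, `l`, `c`, `e`).
#' @param max_iter maximum iterations.
#' @param tol_logl,tol_par convergence tolerances.
#' @param ungenotyped how to treat phenotyped lines absent from `G`:
#'   `"drop"` their records (default) or `"identity"` (append an identity
#'   block scaled to `mean(diag(G))`).
#' @param verbose print the trajectory.
#' @return object of class `reml_fit`: `varcomp` (named vector), `se`
#'   (asymptotic SEs), `ai` and `ai_inv` (curvature and its inverse),
#'   `logl`, `converged`, `n_iter`, `n_records`, `trajectory`, plus the
#'   model internals reused by [solve_mme()].
#' @export
reml <- function(spec, pheno, grm, init = NULL, max_iter = 200,
                 tol_logl = 1e-8, tol_par = 1e-6,
                 ungenotyped = c("drop", "identity"), verbose = FALSE) {
  mm <- build_mm(spec, pheno, grm, match.arg(ungenotyped))
  y <- mm$y
  n <- length(y)
  if (length(unique(mm$fixed_level)) == n)
    stop("no replication: every record has its own fixed-effect level")
  WtW <- Matrix::crossprod(mm$W)
  Wty <- as.vector(Matrix::crossprod(mm$W, y))
  yty <- sum(y^2)
  p <- length(mm$blocks$fixed)
  rnames <- c("g", if (mm$include_line_effect) "l", "c")
  floor_v <- 1e-8 * var(y)

  theta <- if (is.null(init)) {
    k <- length(rnames) + 1
    setNames(rep(var(y) / k, k), c(rnames, "e"))
  } else {
    stopifnot(all(c(rnames, "e") %in% names(init)))
    init[c(rnames, "e")]
  }
  theta <- pmax(theta, floor_v)

  evaluate <- function(theta) {
    se <- theta[["e"]]
    C <- as.matrix(WtW) / se
    for (k in rnames)
      diag(C)[mm$blocks[[k]]] <- diag(C)[mm$blocks[[k]]] + 1 / theta[[k]]
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) stop("MME coefficient matrix not positive definite")
    logdetC <- 2 * sum(log(diag(ch)))
    Cinv <- chol2inv(ch)
    s <- drop(Cinv %*% (Wty / se))
    ehat <- y - as.vector(mm$W %*% s)
    ypy <- (yty - sum(s * Wty)) / se
    nk <- vapply(rnames, function(k) length(mm$blocks[[k]]), 1L)
    logl <- -0.5 * (n * log(se) + sum(nk * log(theta[rnames])) +
                    logdetC + ypy)
    ## every random block has identity prior covariance (g is rotated by the
    ## factor of G), so traces and quadratic forms are all diagonal sums
    tr_k <- numeric(length(rnames)); uau <- numeric(length(rnames))
    Fmat <- matrix(0, n, length(rnames) + 1)
    for (i in seq_along(rnames)) {
      k <- rnames[i]; b <- mm$blocks[[k]]; u <- s[b]
      tr_k[i] <- sum(diag(Cinv)[b])
      uau[i] <- sum(u^2)
      Fmat[, i] <- as.vector(mm$W[, b, drop = FALSE] %*% u) / theta[[k]]
    }
    Fmat[, length(rnames) + 1] <- ehat / se
    sk <- theta[rnames]
    score_r <- -0.5 * (nk / sk - tr_k / sk^2 - uau / sk^2)
    trP <- (n - p - sum(nk - tr_k / sk)) / se
    score_e <- -0.5 * (trP - sum(ehat^2) / se^2)
    ## AI matrix: 0.5 * F' P F via MME solves with F as data
    WtF <- as.matrix(Matrix::crossprod(mm$W, Fmat))
    SF <- Cinv %*% (WtF / se)
    PF <- (Fmat - as.matrix(mm$W %*% SF)) / se
    AI <- 0.5 * crossprod(Fmat, PF)
    AI <- (AI + t(AI)) / 2
    dimnames(AI) <- list(c(rnames, "e"), c(rnames, "e"))
    list(logl = logl, score = c(score_r, e = score_e), AI = AI,
         tr_k = tr_k, uau = uau, nk = nk, ehat = ehat, s = s, ypy = ypy)
  }

  em_update <- function(theta, ev) {
    new <- theta
    for (i in seq_along(rnames))
      new[[rnames[i]]] <- (ev$uau[i] + ev$tr_k[i]) / ev$nk[i]
    new[["e"]] <- sum(y * ev$ehat) / (n - p)
    pmax(new, floor_v)
  }

  traj <- data.frame()
  logl_prev <- -Inf
  theta_prev <- theta
  converged <- FALSE
  it <- 0
  ev <- NULL
  ev_cache <- NULL
  repeat {
    it <- it + 1
    ev <- if (is.null(ev_cache)) evaluate(theta) else ev_cache
    ev_cache <- NULL
    if (verbose)
      cat(sprintf("it %3d  logL %.8f  %s\n", it, ev$logl,
                  paste(sprintf("%s=%.3g", names(theta), theta), collapse = " ")))
    traj <- rbind(traj, data.frame(iter = it, logl = ev$logl,
                                   t(as.matrix(theta))))
    d_logl <- ev$logl - logl_prev
    d_par <- max(abs(theta - theta_prev) / pmax(abs(theta_prev), floor_v))
    if (it > 1 && abs(d_logl) < tol_logl && d_par < tol_par) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    ## AI step on the free components (those pinned at the floor with a
    ## negative score stay there); EM fallback when the AI step would leave
    ## the parameter space or decrease the likelihood
    step_ok <- FALSE
    pinned <- theta <= floor_v * (1 + 1e-8) & ev$score < 0
    free <- which(!pinned)
    if (length(free) > 0) {
      ai_step <- tryCatch(solve(ev$AI[free, free, drop = FALSE],
                                ev$score[free]),
                          error = function(e) NULL)
      if (!is.null(ai_step)) {
        prop <- theta
        prop[free] <- prop[free] + ai_step
        prop <- pmax(prop, floor_v)  # a component proposed negative is set
                                     # to its floor and re-tested next round
        ev_prop <- tryCatch(evaluate(prop), error = function(e) NULL)
        if (!is.null(ev_prop) && ev_prop$logl >= ev$logl - 1e-10) {
          theta_prev <- theta; theta <- prop
          ev_cache <- ev_prop
          step_ok <- TRUE
        }
      }
    }
    if (!step_ok) {
      theta_prev <- theta
      theta <- em_update(theta, ev)
      theta[pinned] <- floor_v
    }
    logl_prev <- ev$logl
  }
  if (!converged) {
    cond <- simpleError(paste0("REML did not converge in ", max_iter,
                               " iterations for trait '", spec$trait, "'"))
    cond$trajectory <- traj
    stop(cond)
  }
  ai_inv <- tryCatch(solve(ev$AI), error = function(e) {
    warning("AI matrix singular at the optimum; SEs unavailable")
    matrix(NA_real_, nrow(ev$AI), ncol(ev$AI), dimnames = dimnames(ev$AI))
  })
  structure(list(
    varcomp = theta, se = sqrt(pmax(diag(ai_inv), 0)),
    ai = ev$AI, ai_inv = ai_inv,
    logl = ev$logl, converged = converged, n_iter = it,
    n_records = n, floor = floor_v, trajectory = traj,
    spec = spec, mm = mm
  ), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("AI-REML fit for '", x$spec$trait, "' (", x$n_records, " records, ",
      x$n_iter, " iterations)\n", sep = "")
  vc <- data.frame(component = names(x$varcomp),
                   estimate = as.numeric(x$varcomp),
                   se = as.numeric(x$se))
  print(vc, row.names = FALSE)
  cat("logL:", format(x$logl, digits = 10), "\n")
  invisible(x)
}
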
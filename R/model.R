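#' Specify the mixed model for one trait
#'
#' The full model is
#' `y = X t + Z1 g + Z1 l + Z2 c + e` with breeding values
#' `g ~ N(0, G sigma2_g)`, residual line effects `l ~ N(0, I sigma2_l)`,
#' line-by-environment interactions `c ~ N(0, I sigma2_c)` and plot
#' residuals `e ~ N(0, I sigma2_e)`. For protein yield the line effect is
#' dropped. The fixed factor is year-by-location for seed size, protein and
#' protein yield, and year-by-location-by-trial for test weight and
#' ergosterol. The G-by-E grouping is always line-by-(year-by-location).
#'
#' @param trait name of the trait column in the phenotype table.
#' @param fixed character vector of design columns crossed into the fixed
#'   factor; default depends on the trait name.
#' @param include_line_effect model the iid line effect `l`; default TRUE
#'   except for protein yield (`py`).
#' @param env character vector of design columns defining the environment
#'   for the G-by-E term.
#' @return object of class `model_spec`.
#' @export
#' @examples
#' model_spec("ssw")
#' model_spec("py")   # drops the line effect
model_spec <- function(trait,
                       fixed = NULL,
                       include_line_effect = NULL,
                       env = c("year", "location")) {
  if (is.null(fixed)) {
    fixed <- if (trait %in% c("tw", "ergosterol")) c("year", "location", "trial")
             else c("year", "location")
  }
  if (is.null(include_line_effect)) include_line_effect <- !identical(trait, "py")
  structure(list(trait = trait, fixed = fixed,
                 include_line_effect = include_line_effect, env = env),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model for '", x$trait, "': y = X(", paste(x$fixed, collapse = " x "),
      ") + g", if (x$include_line_effect) " + l", " + c(",
      paste(x$env, collapse = " x "), ") + e\n", sep = "")
  invisible(x)
}

## Assemble response, sparse design matrix and covariance structures.
## Records with missing response are dropped; records of non-genotyped lines
## are dropped (default) or kept by augmenting G with an identity block on
## the scale of mean(diag(G)).
build_mm <- function(spec, pheno, grm, ungenotyped = c("drop", "identity")) {
  ungenotyped <- match.arg(ungenotyped)
  stopifnot(inherits(spec, "model_spec"), inherits(grm, "grm"))
  if (!spec$trait %in% names(pheno))
    stop("trait column '", spec$trait, "' not in phenotype table")
  miss_fac <- setdiff(c(spec$fixed, spec$env, "line"), names(pheno))
  if (length(miss_fac))
    stop("missing design column(s): ", paste(miss_fac, collapse = ", "))

  dat <- pheno[!is.na(pheno[[spec$trait]]), , drop = FALSE]
  G <- grm$values
  g_ids <- grm$line_ids
  ungeno <- setdiff(unique(dat$line), g_ids)
  if (length(ungeno)) {
    if (ungenotyped == "drop") {
      dat <- dat[dat$line %in% g_ids, , drop = FALSE]
    } else {
      k <- length(ungeno)
      G2 <- matrix(0, length(g_ids) + k, length(g_ids) + k)
      G2[seq_along(g_ids), seq_along(g_ids)] <- G
      diag(G2)[length(g_ids) + seq_len(k)] <- mean(diag(G))
      G <- G2
      g_ids <- c(g_ids, ungeno)
    }
  }
  if (nrow(dat) == 0) stop("no usable records for trait '", spec$trait, "'")

  y <- dat[[spec$trait]]
  n <- length(y)

  fixed_level <- interaction(dat[spec$fixed], drop = TRUE, sep = ":")
  X_levels <- levels(fixed_level)
  env_level <- interaction(dat[spec$env], drop = TRUE, sep = ":")

  l_ids <- sort(unique(dat$line))
  c_ids <- sort(unique(paste(dat$line, env_level, sep = "|")))

  p <- length(X_levels)
  n_g <- length(g_ids)
  n_l <- if (spec$include_line_effect) length(l_ids) else 0L
  n_c <- length(c_ids)

  ## indicator design Ws = [X | Z_line->g | Z_l | Z_c]; the breeding-value
  ## block is then rotated by the factor L of G = L L' (g = L a), giving an
  ## identity prior covariance for every random block
  ji <- list(as.integer(fixed_level),
             p + match(dat$line, g_ids))
  if (n_l) ji <- c(ji, list(p + n_g + match(dat$line, l_ids)))
  ji <- c(ji, list(p + n_g + n_l + match(paste(dat$line, env_level, sep = "|"), c_ids)))
  Ws <- Matrix::sparseMatrix(
    i = rep(seq_len(n), length(ji)),
    j = unlist(ji), x = 1,
    dims = c(n, p + n_g + n_l + n_c)
  )
  L <- grm_factor(G)
  r <- ncol(L)
  Tm <- Matrix::bdiag(Matrix::Diagonal(p), Matrix::Matrix(L),
                      Matrix::Diagonal(n_l + n_c))
  W <- Ws %*% Tm

  blocks <- list(fixed = seq_len(p), g = p + seq_len(r))
  if (n_l) blocks$l <- p + r + seq_len(n_l)
  blocks$c <- p + r + n_l + seq_len(n_c)

  list(y = y, W = W, dat = dat, blocks = blocks,
       fixed_levels = X_levels, fixed_level = as.character(fixed_level),
       g_ids = g_ids, l_ids = if (n_l) l_ids else character(0), c_ids = c_ids,
       L = L, G = G,
       include_line_effect = spec$include_line_effect, spec = spec)
}
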
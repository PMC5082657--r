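## Independent oracles. These deliberately avoid the package's own linear
## algebra paths: BLUP via the explicit phenotypic covariance matrix V, and
## the restricted likelihood evaluated densely.

## dense GLS/BLUP for y = Xt + Z1 g + Z1 l + Z2 c + e, g ~ N(0, G sg)
dense_blup <- function(y, X, Zg, G, Zl, Zc, vc) {
  n <- length(y)
  V <- vc[["g"]] * Zg %*% G %*% t(Zg) + vc[["c"]] * tcrossprod(Zc) +
    vc[["e"]] * diag(n)
  if (!is.null(Zl)) V <- V + vc[["l"]] * tcrossprod(Zl)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  bhat <- solve(XVX, t(X) %*% Vi %*% y)
  r <- y - X %*% bhat
  ghat <- vc[["g"]] * G %*% t(Zg) %*% Vi %*% r
  list(fixed = drop(bhat), gebv = drop(ghat))
}

## dense restricted log-likelihood (same constant convention as the fit)
dense_reml_logl <- function(y, X, Zg, G, Zl, Zc, theta) {
  n <- length(y)
  V <- theta[["g"]] * Zg %*% G %*% t(Zg) + theta[["c"]] * tcrossprod(Zc) +
    theta[["e"]] * diag(n)
  if (!is.null(Zl)) V <- V + theta[["l"]] * tcrossprod(Zl)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  -0.5 * as.numeric(determinant(V)$modulus + determinant(XVX)$modulus +
                    t(y) %*% P %*% y)
}

## random small mixed-model instance with a marker-derived (singular-ok) G
random_instance <- function(n_lines = sample(5:15, 1), with_l = TRUE,
                            n_markers = 30) {
  lines <- sprintf("LN%02d", seq_len(n_lines))
  M <- matrix(sample(c(-1, 1), n_lines * n_markers, replace = TRUE),
              n_lines, dimnames = list(lines, NULL))
  while (TRUE) {  # ensure at least one polymorphic marker
    poly <- apply(M, 2, function(x) length(unique(x)) > 1)
    if (any(poly)) break
    M <- matrix(sample(c(-1, 1), n_lines * n_markers, replace = TRUE),
                n_lines, dimnames = list(lines, NULL))
  }
  g <- build_grm(M)
  year <- sample(c("2014", "2015"), n_lines, replace = TRUE)
  ph <- do.call(rbind, lapply(seq_len(n_lines), function(i) {
    expand.grid(line = lines[i], year = year[i], location = c("L1", "L2"),
                block = 1:2, stringsAsFactors = FALSE)
  }))
  ph$trial <- paste0(ph$year, ph$location)
  ph$ssw <- rnorm(nrow(ph))
  vc <- c(g = runif(1, 0.2, 2), l = runif(1, 0.1, 1),
          c = runif(1, 0.1, 1), e = runif(1, 0.3, 2))
  if (!with_l) vc <- vc[c("g", "c", "e")]
  list(pheno = ph, grm = g, vc = vc, lines = lines)
}

## design matrices for the oracle, built independently of build_mm
oracle_designs <- function(ph, g_ids) {
  fl <- interaction(ph$year, ph$location, drop = TRUE, sep = ":")
  X <- model.matrix(~ 0 + fl)
  Zg <- outer(ph$line, g_ids, "==") * 1
  Zl <- {
    l_ids <- sort(unique(ph$line))
    outer(ph$line, l_ids, "==") * 1
  }
  ce <- paste(ph$line, ph$year, ph$location, sep = "|")
  c_ids <- sort(unique(ce))
  Zc <- outer(ce, c_ids, "==") * 1
  list(X = X, Zg = Zg, Zl = Zl, Zc = Zc,
       fixed_names = levels(fl), c_ids = c_ids)
}
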
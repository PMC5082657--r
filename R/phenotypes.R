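#' Read a plot-level phenotype table
#'
#' Expects a CSV with at least the design columns `line`, `year`,
#' `location`, `trial`, `block` and any of the trait columns (`f2.8`,
#' `f2.5`, `f2.2`, `protein`, `tw`, `ergosterol`, `yield`, ...). Rows with
#' missing trait values are kept; missingness is per trait.
#'
#' @param path CSV file.
#' @param required design columns that must be present.
#' @return data.frame of plot records; factors as character, traits numeric.
#' @export
read_phenotypes <- function(path,
                            required = c("line", "year", "location", "trial", "block")) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_req <- setdiff(required, names(df))
  if (length(missing_req))
    stop("missing required column(s): ", paste(missing_req, collapse = ", "))
  known <- c(required, "set", "plot", "f2.8", "f2.5", "f2.2", "ssw",
             "protein", "py", "tw", "ergosterol", "yield")
  unknown <- setdiff(names(df), known)
  if (length(unknown))
    warning("unknown column(s) kept as-is: ", paste(unknown, collapse = ", "))
  for (cc in intersect(required, names(df))) df[[cc]] <- as.character(df[[cc]])
  df
}

#' Rank-based inverse-normal transform
#'
#' Maps values to normal quantiles of their ranks: `qnorm((r - 0.5) / n)`
#' by default, or Blom's `qnorm((r - 3/8) / (n + 1/4))`. Ties get average
#' ranks; missing values stay missing.
#'
#' @param x numeric vector.
#' @param offset `"half"` for (r - 0.5)/n (default) or `"blom"`.
#' @return numeric vector of the same length.
#' @export
inverse_normal <- function(x, offset = c("half", "blom")) {
  offset <- match.arg(offset)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  if (n == 0) return(out)
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- if (offset == "half") qnorm((r - 0.5) / n)
             else qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Standardized seed weight (SSW)
#'
#' The raw sieve-fraction weights are far from normal, so each fraction is
#' rank-inverse-normal transformed across all plots and the transforms are
#' averaged. The sign is flipped so that larger seeds (less mass in the
#' small-sieve fractions) give a larger SSW; this makes SSW correlate
#' positively with the > 2.8 mm fraction. Orientation only flips GEBV
#' signs, never the magnitude of prediction accuracy.
#'
#' @param pheno plot-level phenotype data.frame.
#' @param fractions fraction columns entering the transform.
#' @param within_env transform within each year-by-location environment
#'   instead of across all plots (default FALSE).
#' @param offset quantile offset passed to [inverse_normal()].
#' @return numeric vector of per-plot SSW values (aligned with `pheno` rows).
#' @export
standardized_seed_weight <- function(pheno, fractions = c("f2.5", "f2.2"),
                                     within_env = FALSE,
                                     offset = c("half", "blom")) {
  offset <- match.arg(offset)
  miss <- setdiff(fractions, names(pheno))
  if (length(miss)) stop("missing fraction column(s): ", paste(miss, collapse = ", "))
  for (f in fractions) {
    x <- pheno[[f]]
    if (length(unique(x[!is.na(x)])) < 3)
      stop("fewer than 3 distinct values in ", f)
    if (any(x < 0, na.rm = TRUE)) stop("negative fraction weight in ", f)
  }
  ints <- sapply(fractions, function(f) {
    if (within_env) {
      env <- paste(pheno$year, pheno$location, sep = ":")
      out <- rep(NA_real_, nrow(pheno))
      for (ee in unique(env)) {
        idx <- env == ee
        out[idx] <- inverse_normal(pheno[[f]][idx], offset)
      }
      out
    } else inverse_normal(pheno[[f]], offset)
  })
  -rowMeans(ints)
}

#' Protein yield
#'
#' `PY = protein content (%) / 100 * grain yield (hkg/ha)`, in hkg/ha.
#'
#' @param pheno plot-level phenotype data.frame with `protein` and `yield`.
#' @return numeric vector of per-plot protein yield.
#' @export
protein_yield <- function(pheno) {
  if (!all(c("protein", "yield") %in% names(pheno)))
    stop("need columns 'protein' and 'yield'")
  if (any(pheno$protein < 0 | pheno$yield < 0, na.rm = TRUE))
    stop("negative protein or yield")
  pheno$protein / 100 * pheno$yield
}

#' Trait summaries overall and by year-by-location
#'
#' Mean, SD and plot count per trait, overall and within each
#' year-by-location environment; missing values excluded per trait.
#'
#' @param pheno plot-level phenotype data.frame.
#' @param traits trait columns to summarize; default all numeric trait
#'   columns present.
#' @return data.frame with columns `trait`, `scope`, `mean`, `sd`, `n`.
#' @export
summarize_traits <- function(pheno, traits = NULL) {
  if (nrow(pheno) == 0) stop("empty phenotype table")
  if (is.null(traits)) {
    cand <- c("f2.8", "f2.5", "f2.2", "ssw", "protein", "py", "tw",
              "ergosterol", "yield")
    traits <- intersect(cand, names(pheno))
  }
  env <- paste(pheno$year, pheno$location, sep = ":")
  scopes <- c("all", sort(unique(env)))
  rows <- list()
  for (tr in traits) {
    for (sc in scopes) {
      x <- if (sc == "all") pheno[[tr]] else pheno[[tr]][env == sc]
      x <- x[!is.na(x)]
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, scope = sc,
        mean = if (length(x)) mean(x) else NA_real_,
        sd = if (length(x) > 1) sd(x) else if (length(x) == 1) 0 else NA_real_,
        n = length(x), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
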
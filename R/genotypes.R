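#' Genotype file dialect
#'
#' Describes how genotype call tokens in a CSV are interpreted: which tokens
#' mean missing, and whether heterozygotes may be written with the alleles
#' in either order (`AB`/`BA`).
#'
#' @param missing_tokens character tokens treated as missing calls.
#' @param alleles characters allowed as allele symbols; calls using any
#'   other character are unrecognized and mapped to missing with a warning.
#' @return list of class `geno_dialect`.
#' @export
geno_dialect <- function(missing_tokens = c("", "NA", "NN", "--", "-"),
                         alleles = c("A", "B", "C", "G", "T")) {
  structure(list(missing_tokens = missing_tokens, alleles = alleles),
            class = "geno_dialect")
}

#' Read a line-by-marker genotype table
#'
#' Expects a CSV whose first column holds the line identifier and remaining
#' columns one biallelic marker each, with two-letter genotype calls (e.g.
#' `AA`, `AB`, `BB`, or nucleotide pairs like `GG`/`AG`). Tokens that are
#' neither a recognized call nor a declared missing token are mapped to
#' missing with a warning giving the count.
#'
#' @param path CSV file.
#' @param dialect a [geno_dialect()].
#' @return character matrix (lines x markers, `NA` = missing call).
#' @export
read_genotypes <- function(path, dialect = geno_dialect()) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) != 1) stop("ragged rows in genotype file: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 colClasses = "character", na.strings = character(0))
  if (ncol(df) < 2) stop("genotype file needs a line-ID column plus markers")
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate line IDs: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[-1])
  rownames(m) <- ids
  m[m %in% dialect$missing_tokens] <- NA_character_
  ok_call <- sprintf("^[%s]{2}$", paste(dialect$alleles, collapse = ""))
  bad <- !is.na(m) & !grepl(ok_call, m)
  if (any(bad)) {
    warning(sum(bad), " unrecognized genotype token(s) treated as missing (e.g. '",
            m[bad][1], "')")
    m[bad] <- NA_character_
  }
  m
}

#' Encode genotype calls on the -1/0/+1 scale
#'
#' Per marker, the two observed allele symbols are ordered lexicographically
#' (unless overridden) and genotypes are coded by the count of the *second*
#' allele minus one: first homozygote -1, heterozygote 0, second homozygote
#' +1. Markers with a single observed allele are flagged monomorphic; calls
#' carrying a third allele symbol are set missing with a warning.
#'
#' @param raw character matrix from [read_genotypes()] or a `sim_dataset`'s
#'   `calls`.
#' @return object of class `marker_matrix`: list with `values` (numeric
#'   matrix, `NA` = missing), `line_ids`, `marker_ids`, `monomorphic`
#'   (logical per marker), `alleles` (marker x 2 character).
#' @export
encode_genotypes <- function(raw) {
  if (inherits(raw, "sim_dataset")) raw <- raw$calls
  stopifnot(is.matrix(raw), is.character(raw))
  n_l <- nrow(raw); n_m <- ncol(raw)
  values <- matrix(NA_real_, n_l, n_m, dimnames = dimnames(raw))
  mono <- logical(n_m)
  alleles <- matrix(NA_character_, n_m, 2)
  n_extra <- 0L
  a1 <- substr(raw, 1, 1); a2 <- substr(raw, 2, 2)
  for (j in seq_len(n_m)) {
    obs <- c(a1[, j], a2[, j])
    tab <- sort(table(obs[!is.na(obs)]), decreasing = TRUE)
    al <- names(tab)
    if (length(al) == 0) { mono[j] <- TRUE; next }
    if (length(al) > 2) {
      keep <- sort(al[1:2])
      drop_call <- !is.na(raw[, j]) & !(a1[, j] %in% keep & a2[, j] %in% keep)
      n_extra <- n_extra + sum(drop_call)
      a1[drop_call, j] <- NA; a2[drop_call, j] <- NA
      al <- keep
    } else al <- sort(al)
    if (length(al) == 1) {
      mono[j] <- TRUE
      alleles[j, ] <- c(al, NA)
      values[, j] <- ifelse(is.na(a1[, j]), NA_real_, -1)
    } else {
      alleles[j, ] <- al
      cnt2 <- (a1[, j] == al[2]) + (a2[, j] == al[2])
      values[, j] <- cnt2 - 1
    }
  }
  if (n_extra > 0)
    warning(n_extra, " call(s) with more than two alleles at a marker set missing")
  structure(list(values = values, line_ids = rownames(raw),
                 marker_ids = colnames(raw), monomorphic = mono,
                 alleles = alleles),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("marker_matrix:", length(x$line_ids), "lines x", length(x$marker_ids),
      "markers;", sum(x$monomorphic), "monomorphic;",
      sum(is.na(x$values)), "missing calls\n")
  invisible(x)
}

#' Allele frequencies of the counted (second) allele
#'
#' `p_i = (count(+1) + 0.5 * count(0)) / count(non-missing)`, i.e. the mean
#' coded value mapped from `[-1, 1]` to `[0, 1]`.
#'
#' @param m a `marker_matrix` (or numeric matrix coded -1/0/1).
#' @param marker optional marker id or index; default all markers.
#' @return numeric vector of frequencies.
#' @export
allele_frequency <- function(m, marker = NULL) {
  v <- if (inherits(m, "marker_matrix")) m$values else m
  if (!is.null(marker)) v <- v[, marker, drop = FALSE]
  n_obs <- colSums(!is.na(v))
  if (any(n_obs == 0))
    stop("marker(s) with no non-missing calls: ",
         paste(colnames(v)[n_obs == 0], collapse = ", "))
  (colMeans(v, na.rm = TRUE) + 1) / 2
}

#' Marker and line quality control
#'
#' Applies, in this fixed order: (1) drop monomorphic markers, (2) drop
#' lines whose missing-call fraction exceeds `line_missing_max`,
#' (3, optional) drop markers missing in more than `marker_missing_max` of
#' the retained lines, (4) recompute allele frequencies on the retained
#' lines and keep markers with minor allele frequency `>= maf_min`
#' (inclusive).
#'
#' @param m a `marker_matrix`.
#' @param maf_min minimum minor allele frequency (inclusive).
#' @param line_missing_max maximum per-line missing-call fraction.
#' @param marker_missing_max optional maximum per-marker missing fraction
#'   (the alternative reading of a per-line missingness rule); `NULL`
#'   disables it.
#' @return list with `matrix` (filtered `marker_matrix`) and `report`
#'   (class `qc_report`: counts at each stage, per-marker MAF, per-line
#'   missing fraction).
#' @export
apply_qc <- function(m, maf_min = 0.05, line_missing_max = 0.02,
                     marker_missing_max = NULL) {
  stopifnot(inherits(m, "marker_matrix"))
  v <- m$values
  n_input <- ncol(v)
  keep_m <- !m$monomorphic
  v <- v[, keep_m, drop = FALSE]
  n_poly <- ncol(v)
  if (n_poly == 0) stop("QC emptied the marker set at stage: monomorphic filter")

  line_miss <- rowMeans(is.na(v))
  keep_l <- line_miss <= line_missing_max
  v <- v[keep_l, , drop = FALSE]
  if (nrow(v) == 0) stop("QC emptied the line set at stage: line missingness filter")

  if (!is.null(marker_missing_max)) {
    keep_mm <- colMeans(is.na(v)) <= marker_missing_max
    v <- v[, keep_mm, drop = FALSE]
    if (ncol(v) == 0) stop("QC emptied the marker set at stage: marker missingness filter")
  }
  n_after_missing <- ncol(v)

  p <- (colMeans(v, na.rm = TRUE) + 1) / 2
  maf <- pmin(p, 1 - p)
  ## inclusive boundary, robust to floating-point representation of p
  keep_maf <- !is.na(maf) & maf >= maf_min - 1e-9
  v <- v[, keep_maf, drop = FALSE]
  if (ncol(v) == 0) stop("QC emptied the marker set at stage: MAF filter")
  n_after_maf <- ncol(v)

  idx <- match(colnames(v), m$marker_ids)
  out <- structure(list(values = v, line_ids = rownames(v),
                        marker_ids = colnames(v),
                        monomorphic = rep(FALSE, ncol(v)),
                        alleles = m$alleles[idx, , drop = FALSE]),
                   class = "marker_matrix")
  report <- structure(list(
    n_input_markers = n_input, n_polymorphic = n_poly,
    n_after_missing = n_after_missing, n_after_maf = n_after_maf,
    n_input_lines = length(m$line_ids), n_retained_lines = nrow(v),
    maf = maf[keep_maf], line_missing = line_miss,
    maf_min = maf_min, line_missing_max = line_missing_max,
    marker_missing_max = marker_missing_max
  ), class = "qc_report")
  list(matrix = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Marker QC: ", x$n_input_markers, " markers -> ", x$n_polymorphic,
      " polymorphic -> ", x$n_after_missing, " after missingness -> ",
      x$n_after_maf, " after MAF >= ", x$maf_min, "\n",
      "Lines: ", x$n_input_lines, " -> ", x$n_retained_lines,
      " (per-line missing <= ", x$line_missing_max, ")\n", sep = "")
  invisible(x)
}

#' Impute residual missing calls by the marker mean
#'
#' Each missing cell is replaced by the marker's mean coded value
#' `2 * p_i - 1`, which leaves the per-marker mean unchanged and is the
#' natural completion for a centered-Z GBLUP.
#'
#' @param m a `marker_matrix` (QC applied).
#' @return the `marker_matrix` with no missing values.
#' @export
impute_missing <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  v <- m$values
  if (!anyNA(v)) return(m)
  mu <- unname(colMeans(v, na.rm = TRUE))
  idx <- which(is.na(v), arr.ind = TRUE)
  v[idx] <- mu[idx[, 2]]
  m$values <- v
  m
}
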
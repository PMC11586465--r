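# Expression-matrix container and the two processing steps applied to an
# already region-aggregated regions x genes matrix: intensity filtering and
# scaled-robust-sigmoid normalization, plus the left-hemisphere restriction.

#' Construct an expression matrix
#'
#' A regions x genes numeric matrix with region ids as row names and gene
#' identifiers as column names, plus a flag recording whether it has been
#' normalized to \[0, 1\].
#'
#' @param values numeric matrix, complete (no missing values).
#' @param normalized logical flag.
#' @return an `expression_matrix`.
#' @export
expression_matrix <- function(values, normalized = FALSE) {
  values <- as.matrix(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop_invalid("expression values must be finite and complete")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_invalid("expression matrix needs region-id rownames and gene colnames")
  }
  structure(list(values = values, normalized = isTRUE(normalized)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d regions x %d genes (%snormalized)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "" else "not "))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

region_ids <- function(expr) as.integer(rownames(expr$values))

#' Filter genes by detection intensity
#'
#' Retains a gene iff it was detected above background in at least
#' `threshold` of the regions. With the default 0.5 a gene detected in
#' exactly half the regions is kept (the comparison is `>=`).
#'
#' @param expr an `expression_matrix` (or plain matrix with dimnames).
#' @param detected logical/0-1 matrix conformable with the expression values.
#' @param threshold detection fraction in (0, 1\].
#' @return the filtered `expression_matrix`.
#' @export
intensity_filter <- function(expr, detected, threshold = 0.5) {
  if (!inherits(expr, "expression_matrix")) expr <- expression_matrix(expr)
  threshold <- check_fraction(threshold, "threshold")
  if (threshold <= 0) stop_invalid("threshold must be in (0, 1]")
  detected <- as.matrix(detected)
  if (!identical(dim(detected), dim(expr$values))) {
    stop_invalid("detection mask must match the expression matrix dimensions")
  }
  keep <- colMeans(detected != 0) >= threshold
  if (!any(keep)) stop_invalid("intensity filter removed every gene")
  expression_matrix(expr$values[, keep, drop = FALSE], expr$normalized)
}

#' Scaled robust sigmoid normalization
#'
#' Maps a vector through the outlier-robust sigmoid
#' `1 / (1 + exp(-(x - median) / (IQR / 1.35)))` — the IQR/1.35 factor makes
#' the scale consistent with the standard deviation under normality — and
#' then min-max rescales the result to \[0, 1\]. Monotone, bounded, and
#' invariant to positive affine transforms of the input. A degenerate vector
#' with zero IQR falls back to plain min-max scaling with a warning.
#'
#' @param values numeric vector, length >= 3.
#' @return normalized vector in \[0, 1\].
#' @export
srs_normalize <- function(values) {
  x <- as.numeric(values)
  if (length(x) < 3L) stop_invalid("need at least 3 values")
  if (any(!is.finite(x))) stop_invalid("values must be finite")
  iqr <- stats::IQR(x)
  if (iqr == 0) {
    warning("zero IQR: falling back to min-max scaling", call. = FALSE)
    rng <- range(x)
    if (rng[1] == rng[2]) return(rep(0.5, length(x)))
    return((x - rng[1]) / diff(rng))
  }
  s <- 1 / (1 + exp(-(x - stats::median(x)) / (iqr / 1.35)))
  (s - min(s)) / (max(s) - min(s))
}

#' Normalize an expression matrix by scaled robust sigmoid
#'
#' Applies [srs_normalize()] per gene across regions, and optionally a second
#' pass per region across genes. After the per-gene pass every gene column
#' spans exactly \[0, 1\]; the optional region pass trades that guarantee for
#' comparability across genes within a region.
#'
#' @param expr an `expression_matrix`.
#' @param passes `"gene"` (default), `"region"`, or `c("gene", "region")`,
#'   applied in the order given.
#' @return normalized `expression_matrix`.
#' @export
normalize_expression <- function(expr, passes = "gene") {
  if (!inherits(expr, "expression_matrix")) expr <- expression_matrix(expr)
  v <- expr$values
  for (pass in passes) {
    pass <- match.arg(pass, c("gene", "region"))
    if (pass == "gene") {
      v <- apply(v, 2L, srs_normalize)
    } else {
      v <- t(apply(v, 1L, srs_normalize))
    }
    dimnames(v) <- dimnames(expr$values)
  }
  expression_matrix(v, normalized = TRUE)
}

#' Restrict an expression matrix to left-hemisphere regions
#'
#' Donor coverage of the right hemisphere is typically too sparse to use, so
#' the association analysis runs on the left hemisphere only.
#'
#' @param expr an `expression_matrix` whose regions all appear in `atlas`.
#' @param atlas a `parcellation_atlas`.
#' @return the row-subset `expression_matrix`, region order preserved.
#' @export
restrict_left_hemisphere <- function(expr, atlas) {
  if (!inherits(expr, "expression_matrix")) expr <- expression_matrix(expr)
  rid <- region_ids(expr)
  idx <- match(rid, atlas$region_id)
  if (anyNA(idx)) {
    stop_invalid("expression regions missing from atlas: %s",
                 paste(utils::head(rid[is.na(idx)], 5), collapse = ", "))
  }
  keep <- atlas$hemisphere[idx] == "left"
  if (!any(keep)) stop_invalid("no left-hemisphere regions in the matrix")
  expression_matrix(expr$values[keep, , drop = FALSE], expr$normalized)
}

#' Write / read an expression matrix as TSV
#'
#' Rows are regions (first column `region_id`), remaining columns genes.
#' @param expr an `expression_matrix`.
#' @param path file path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(region_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_expression
#' @param normalized flag to record on the matrix read back.
#' @export
read_expression <- function(path, normalized = FALSE) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  expression_matrix(m, normalized = normalized)
}
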
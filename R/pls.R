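# PLS1 association between regional gene expression and a case-control
# t-map: the core estimator of the package. The model is fit by NIPALS; for
# a single response the first weight vector has the closed form X'y / ||X'y||,
# which the test suite uses as an independent oracle.

#' First-component partial least squares of a map on expression
#'
#' NIPALS partial least squares of a single regional response on a regions x
#' genes matrix. Only the first component is interpreted downstream; further
#' components are available for diagnostics. Inputs are used as given —
#' z-normalize beforehand (as [pls_gene_association()] does).
#'
#' The sign of each component is fixed so its scores correlate non-negatively
#' with `y`.
#'
#' @param X regions x genes numeric matrix.
#' @param y per-region response aligned with the rows of `X`.
#' @param n_components number of components to extract (default 1).
#' @return list with `weights` (genes x k), `scores` (regions x k),
#'   `variance_explained` (squared Pearson correlation of the first
#'   component's scores with `y`).
#' @export
fit_pls1 <- function(X, y, n_components = 1) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop_invalid("rows of X must align with y")
  if (anyNA(X) || anyNA(y)) stop_invalid("missing values are not allowed")
  if (stats::sd(y) == 0) stop_invalid("constant response: PLS undefined")
  k <- check_count(n_components, "n_components")

  Xd <- X
  yd <- y
  W <- matrix(NA_real_, ncol(X), k)
  Tm <- matrix(NA_real_, nrow(X), k)
  for (h in seq_len(k)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop_invalid("X'y vanished at component %d", h)
    w <- w / nw
    tt <- Xd %*% w
    if (stats::cor(tt, y) < 0) {   # sign convention
      w <- -w
      tt <- -tt
    }
    W[, h] <- w
    Tm[, h] <- tt
    pl <- crossprod(Xd, tt) / sum(tt^2)
    cl <- sum(yd * tt) / sum(tt^2)
    Xd <- Xd - tcrossprod(tt, pl)
    yd <- yd - tt * cl
  }
  rownames(W) <- colnames(X)
  list(weights = W, scores = Tm,
       variance_explained = stats::cor(Tm[, 1], y)^2)
}

#' Permutation test of PLS1 explained variance
#'
#' Re-fits the first component after permuting the response and compares the
#' observed explained variance against the null:
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`. The default null is the
#' spatial spin (which preserves the map's autocorrelation); `"shuffle"`
#' permutes regions freely and is appropriate for non-spatial responses and
#' calibration.
#'
#' @param X,y as in [fit_pls1()].
#' @param n_perm number of permutations (capped at `spins$n_perm` when the
#'   spin scheme is used).
#' @param null_scheme `"spin"` or `"shuffle"`.
#' @param spins a `spin_null` aligned with `y` (required for `"spin"`).
#' @param seed integer seed (used by the shuffle scheme).
#' @return list with `p_perm`, `observed`, `nulls`.
#' @export
permutation_test_variance <- function(X, y, n_perm = 1000,
                                      null_scheme = c("spin", "shuffle"),
                                      spins = NULL, seed = 1) {
  null_scheme <- match.arg(null_scheme)
  n_perm <- check_count(n_perm, "n_perm")
  X <- as.matrix(X)
  y <- as.numeric(y)
  observed <- fit_pls1(X, y)$variance_explained

  perm_idx <- if (null_scheme == "spin") {
    if (is.null(spins)) stop_invalid("spin scheme needs a spin_null")
    if (length(spins$scope) != length(y)) {
      stop_invalid("spin null scope does not match the response length")
    }
    n_perm <- min(n_perm, spins$n_perm)
    spins$permutations[seq_len(n_perm), , drop = FALSE]
  } else {
    with_seed(seed, t(replicate(n_perm, sample.int(length(y)))))
  }

  nulls <- vapply(seq_len(n_perm), function(i) {
    yp <- y[perm_idx[i, ]]
    w <- crossprod(X, yp)
    w <- w / sqrt(sum(w^2))
    stats::cor(X %*% w, yp)^2
  }, numeric(1))
  list(p_perm = (1 + sum(nulls >= observed)) / (n_perm + 1),
       observed = observed, nulls = nulls)
}

#' Bootstrap z-scores for PLS1 gene weights
#'
#' Resamples regions with replacement, refits the first component, aligns
#' each bootstrap weight vector's sign to the original (component signs are
#' arbitrary; without alignment the standard errors are inflated), and
#' z-scores each gene's weight by its bootstrap standard error. Two-sided
#' normal p-values are BH-corrected across all genes.
#'
#' @param X,y as in [fit_pls1()] (already z-normalized).
#' @param n_boot bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @return data frame (one row per gene): `gene`, `weight`, `bootstrap_se`,
#'   `z_score`, `p_value`, `q_value`.
#' @export
bootstrap_gene_stats <- function(X, y, n_boot = 1000, seed = 1) {
  n_boot <- check_count(n_boot, "n_boot")
  if (n_boot < 100L) stop_invalid("n_boot must be >= 100 for stable SEs")
  X <- as.matrix(X)
  y <- as.numeric(y)
  w0 <- fit_pls1(X, y)$weights[, 1]

  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(y), replace = TRUE)
      w <- crossprod(X[idx, , drop = FALSE], y[idx])
      nw <- sqrt(sum(w^2))
      if (nw == 0) return(rep(NA_real_, ncol(X)))
      w <- as.numeric(w) / nw
      if (sum(w * w0) < 0) w <- -w   # sign alignment to the original fit
      w
    }, numeric(ncol(X)))
  })
  se <- apply(boots, 1L, stats::sd, na.rm = TRUE)
  z <- w0 / se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  data.frame(gene = colnames(X), weight = unname(w0), bootstrap_se = se,
             z_score = unname(z), p_value = unname(p),
             q_value = bh_fdr(p), row.names = NULL, stringsAsFactors = FALSE)
}

#' PLS1 gene association between expression and a regional map
#'
#' The package's central fit: z-normalizes each gene's expression across
#' regions and the response map, extracts the first PLS component, tests its
#' explained variance by permutation, and bootstrap z-scores the gene
#' weights. Genes significant after FDR are split into the positively
#' weighted (`PLS+`) and negatively weighted (`PLS-`) lists, each ranked by
#' `|z|` descending (ties broken lexicographically by gene id).
#'
#' @param expr an `expression_matrix` or plain regions x genes matrix.
#' @param y per-region response (e.g. case-control t-values), aligned with
#'   the rows of `expr`; names, if present, must match the region ids.
#' @param n_perm permutations for the explained-variance test.
#' @param n_boot bootstrap replicates for the gene z-scores.
#' @param alpha FDR threshold defining the significant gene lists.
#' @param null_scheme,spins passed to [permutation_test_variance()].
#' @param seed integer seed.
#' @return a `pls1fit` object with components `genes` (per-gene table),
#'   `scores`, `variance_explained`, `p_perm`, `pls_plus`, `pls_minus`,
#'   `y`, `alpha`.
#' @seealso [fit_pls1()], [bootstrap_gene_stats()],
#'   [permutation_test_variance()]
#' @export
pls_gene_association <- function(expr, y, n_perm = 1000, n_boot = 1000,
                                 alpha = 0.05,
                                 null_scheme = c("spin", "shuffle"),
                                 spins = NULL, seed = 1) {
  null_scheme <- match.arg(null_scheme)
  alpha <- check_fraction(alpha, "alpha")
  X <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  y <- if (!is.null(names(y)) && !is.null(rownames(X))) {
    if (!setequal(names(y), rownames(X))) {
      stop_invalid("response regions do not match expression regions")
    }
    as.numeric(y[rownames(X)])
  } else as.numeric(y)
  if (length(y) != nrow(X)) stop_invalid("response length must match regions")

  Xz <- apply(X, 2L, z_normalize)
  dimnames(Xz) <- dimnames(X)
  yz <- z_normalize(y)

  fit <- fit_pls1(Xz, yz)
  perm <- permutation_test_variance(Xz, yz, n_perm = n_perm,
                                    null_scheme = null_scheme, spins = spins,
                                    seed = derive_seed(seed, "pls_perm"))
  genes <- bootstrap_gene_stats(Xz, yz, n_boot = n_boot,
                                seed = derive_seed(seed, "pls_boot"))

  sig <- genes[!is.na(genes$q_value) & genes$q_value < alpha, ]
  rank_list <- function(df) {
    df <- df[order(-abs(df$z_score), df$gene), ]
    df$gene
  }
  structure(
    list(genes = genes,
         scores = stats::setNames(as.numeric(fit$scores[, 1]), rownames(X)),
         weights = stats::setNames(genes$weight, genes$gene),
         variance_explained = fit$variance_explained,
         p_perm = perm$p_perm,
         pls_plus = rank_list(sig[sig$z_score > 0, ]),
         pls_minus = rank_list(sig[sig$z_score < 0, ]),
         y = stats::setNames(yz, rownames(X)),
         alpha = alpha, n_perm = n_perm, n_boot = n_boot,
         null_scheme = null_scheme),
    class = "pls1fit")
}

#' @export
print.pls1fit <- function(x, ...) {
  cat(sprintf(paste0(
    "PLS1 gene association\n",
    "  regions: %d   genes: %d\n",
    "  variance explained: %.1f%% (permutation p = %.4g, %s null)\n",
    "  PLS+ genes: %d   PLS- genes: %d (q < %g)\n"),
    length(x$scores), nrow(x$genes), 100 * x$variance_explained, x$p_perm,
    x$null_scheme, length(x$pls_plus), length(x$pls_minus), x$alpha))
  invisible(x)
}

#' @export
summary.pls1fit <- function(object, n_top = 10, ...) {
  g <- object$genes[order(-abs(object$genes$z_score)), ]
  out <- list(fit = object, top_genes = utils::head(g, n_top))
  class(out) <- "summary.pls1fit"
  out
}

#' @export
print.summary.pls1fit <- function(x, ...) {
  print(x$fit)
  cat("Top genes by |z|:\n")
  print(x$top_genes, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.pls1fit <- function(object, type = c("weight", "z"), ...) {
  type <- match.arg(type)
  if (type == "weight") object$weights
  else stats::setNames(object$genes$z_score, object$genes$gene)
}

#' @export
predict.pls1fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  X <- if (inherits(newdata, "expression_matrix")) newdata$values
       else as.matrix(newdata)
  Xz <- apply(X, 2L, z_normalize)
  w <- object$weights[colnames(X)]
  if (anyNA(w)) stop_invalid("newdata genes must match the fitted genes")
  stats::setNames(as.numeric(Xz %*% w), rownames(X))
}

#' @export
fitted.pls1fit <- function(object, ...) {
  b <- stats::coef(stats::lm(object$y ~ object$scores))
  stats::setNames(b[1] + b[2] * object$scores, names(object$y))
}

#' @export
residuals.pls1fit <- function(object, ...) {
  object$y - fitted(object)
}

#' @export
plot.pls1fit <- function(x, ...) {
  graphics::plot(x$scores, x$y, xlab = "PLS1 regional score",
                 ylab = "z-normalized response",
                 main = sprintf("PLS1: %.1f%% variance explained",
                                100 * x$variance_explained), ...)
  graphics::abline(stats::lm(x$y ~ x$scores), lty = 2)
  invisible(x)
}

#' Spin-test correlation of one gene's expression map with a response map
#'
#' Spearman correlation between a gene's regional expression and a regional
#' map (typically the case-control t-map), with significance from the spin
#' null. Used to inspect the top-ranked PLS genes.
#'
#' @param gene gene identifier.
#' @param expr an `expression_matrix` containing the gene.
#' @param y per-region values aligned with the expression rows.
#' @param spins a `spin_null` aligned with the regions.
#' @return list with `rho` and `p_spin`.
#' @export
top_gene_map_correlation <- function(gene, expr, y, spins) {
  if (!inherits(expr, "expression_matrix")) expr <- expression_matrix(expr)
  if (!gene %in% colnames(expr$values)) stop_invalid("unknown gene: %s", gene)
  g <- expr$values[, gene]
  res <- spin_pvalue(g, as.numeric(y), spins, stat = "spearman")
  list(rho = res$statistic, p_spin = res$p_spin)
}

#' Write the per-gene table and regional scores of a fit
#'
#' @param fit a `pls1fit`.
#' @param gene_path,score_path TSV paths (either may be `NULL` to skip).
#' @export
write_pls_result <- function(fit, gene_path = NULL, score_path = NULL) {
  if (!is.null(gene_path)) {
    g <- fit$genes
    g$list <- ifelse(g$gene %in% fit$pls_plus, "PLS+",
                     ifelse(g$gene %in% fit$pls_minus, "PLS-", "none"))
    for (cl in c("weight", "bootstrap_se", "z_score", "p_value", "q_value")) {
      g[[cl]] <- format_num(g[[cl]])
    }
    write_tsv(g, gene_path)
  }
  if (!is.null(score_path)) {
    write_tsv(data.frame(region_id = names(fit$scores),
                         pls1_score = format_num(unname(fit$scores))),
              score_path)
  }
  invisible(fit)
}
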
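# Spherical spin permutations for parcellated maps. A spin rotates the
# cortical centroids of each hemisphere by a shared random rotation (mirrored
# across the midline for the right hemisphere) and reassigns each region the
# value of the region whose rotated centroid lands nearest, giving a null
# that preserves the map's spatial autocorrelation. Subcortical regions have
# no spherical coordinates, so they are shuffled uniformly among themselves.

#' Generate a spin null for a parcellation
#'
#' @param atlas a `parcellation_atlas`.
#' @param n_perm number of spins (default 1000).
#' @param seed integer seed.
#' @param scope `"all"` (cortex rotated, subcortex shuffled within itself) or
#'   `"cortex"` (cortical regions only).
#' @param rotations optional list of `n_perm` 3x3 rotation matrices — a
#'   testing hook replacing the random rotations (e.g. `diag(3)` gives the
#'   identity permutation on cortex).
#' @return a `spin_null`: list with `permutations` (n_perm x n index matrix;
#'   row `i` maps a vector `x` over the scope to `x[permutations[i, ]]`),
#'   `scope` (region ids covered, in atlas order), `n_perm`, `seed`.
#' @export
generate_spins <- function(atlas, n_perm = 1000, seed = 1,
                           scope = c("all", "cortex"), rotations = NULL) {
  n_perm <- check_count(n_perm, "n_perm")
  scope <- match.arg(scope)
  keep <- if (scope == "cortex") atlas$tissue_class == "cortical"
          else rep(TRUE, nrow(atlas))
  sub <- atlas[keep, , drop = FALSE]
  cort <- sub$tissue_class == "cortical"
  if (any(cort) && anyNA(sub$cx[cort])) {
    stop_invalid("cortical region without a centroid")
  }
  hemi_sets <- list(
    left = which(cort & sub$hemisphere == "left"),
    right = which(cort & sub$hemisphere == "right")
  )
  sub_idx <- which(!cort)
  n <- nrow(sub)
  mirror <- diag(c(-1, 1, 1))

  with_seed(seed, {
    perms <- matrix(NA_integer_, n_perm, n)
    for (i in seq_len(n_perm)) {
      rot <- if (is.null(rotations)) random_rotation() else rotations[[i]]
      for (h in names(hemi_sets)) {
        idx <- hemi_sets[[h]]
        if (!length(idx)) next
        C <- as.matrix(sub[idx, c("cx", "cy", "cz")])
        rot_h <- if (h == "right") mirror %*% rot %*% mirror else rot
        rotated <- C %*% t(rot_h)
        perms[i, idx] <- idx[greedy_assign(rotated, C)]
      }
      if (length(sub_idx)) {
        perms[i, sub_idx] <- sub_idx[sample.int(length(sub_idx))]
      }
    }
    structure(list(permutations = perms, scope = sub$region_id,
                   n_perm = n_perm, seed = seed, scope_mode = scope),
              class = "spin_null")
  })
}

# Uniform random rotation: QR of a Gaussian matrix with the sign convention
# fixed, determinant forced to +1.
random_rotation <- function() {
  qd <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qd)
  Q <- Q %*% diag(sign(diag(qr.R(qd))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

# Greedy one-to-one matching of rotated centroids to original centroids,
# processed in random order so no region is systematically favoured.
# Returns g with g[k] = source region (within-hemisphere position) whose
# rotated centroid is nearest to original centroid k among those still free:
# region k takes the value of region g[k].
greedy_assign <- function(rotated, original) {
  m <- nrow(original)
  sim <- tcrossprod(rotated, original)  # cosine similarity = -distance rank
  out <- integer(m)
  free <- rep(TRUE, m)
  for (r in sample.int(m)) {
    k <- which(free)[which.max(sim[r, free])]
    out[k] <- r
    free[k] <- FALSE
  }
  out
}

#' @export
print.spin_null <- function(x, ...) {
  cat(sprintf("spin_null: %d permutations over %d regions (scope: %s, seed %d)\n",
              x$n_perm, length(x$scope), x$scope_mode, x$seed))
  invisible(x)
}

#' Spin-test p-value for a map-to-map correlation
#'
#' Correlates `x` and `y`, then rebuilds the correlation with `x` reindexed
#' by every spin to form the spatial null; the permuted argument is always
#' the first one. Two-sided: `p = (1 + #\{|null| >= |observed|\}) /
#' (n_perm + 1)`.
#'
#' @param x,y numeric vectors aligned to `spins$scope` (same length/order).
#' @param spins a `spin_null`.
#' @param stat `"spearman"` (default) or `"pearson"`.
#' @return list with `statistic` (observed correlation), `p_spin`, and the
#'   vector of null statistics.
#' @export
spin_pvalue <- function(x, y, spins, stat = c("spearman", "pearson")) {
  stat <- match.arg(stat)
  n <- length(spins$scope)
  if (length(x) != n || length(y) != n) {
    stop_invalid("x and y must be aligned to the %d regions of the spin null", n)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_invalid("maps must be finite")
  }
  u <- if (stat == "spearman") rank(x) else as.numeric(x)
  v <- if (stat == "spearman") rank(y) else as.numeric(y)
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    stop_invalid("correlation undefined for constant map")
  }
  observed <- stats::cor(u, v)
  # Every spin row is a permutation of u, so row means and sds are unchanged
  # and the null correlations reduce to one matrix product.
  U <- matrix(u[spins$permutations], nrow = spins$n_perm)
  vc <- v - mean(v)
  nulls <- as.numeric(U %*% vc) / ((n - 1) * stats::sd(u) * stats::sd(v))
  p <- (1 + sum(abs(nulls) >= abs(observed))) / (spins$n_perm + 1)
  list(statistic = observed, p_spin = p, nulls = nulls)
}

#' Persist / load a spin null
#'
#' The index rows are written as TSV next to a small JSON header carrying the
#' seed, permutation count and scope.
#'
#' @param spins a `spin_null`.
#' @param path TSV path; the header is written to `<path>.json`.
#' @export
write_spins <- function(spins, path) {
  write_tsv(as.data.frame(spins$permutations), path)
  jsonlite::write_json(
    list(seed = spins$seed, n_perm = spins$n_perm, scope = spins$scope,
         scope_mode = spins$scope_mode),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_spins
#' @export
read_spins <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  perms <- as.matrix(read_tsv(path))
  dimnames(perms) <- NULL
  structure(list(permutations = perms, scope = as.integer(header$scope),
                 n_perm = as.integer(header$n_perm),
                 seed = as.integer(header$seed),
                 scope_mode = header$scope_mode),
            class = "spin_null")
}
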
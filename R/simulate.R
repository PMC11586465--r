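# Synthetic-data generators. All are pure functions of (arguments, seed):
# the same call twice gives byte-identical output. Cortical noise and
# expression fields are spatially autocorrelated through an exponential
# kernel on inter-centroid great-circle angle; subcortical regions have no
# centroid and receive independent noise.

# Upper Cholesky factor of the spatial covariance over a set of regions.
# Cortical x cortical entries are exp(-angle / ell); rows/columns of
# subcortical regions are identity. A small nugget keeps the matrix
# positive definite.
spatial_chol <- function(atlas, region_ids, corr_length) {
  idx <- match(region_ids, atlas$region_id)
  if (anyNA(idx)) stop_invalid("region ids missing from atlas")
  n <- length(idx)
  K <- diag(n)
  cort <- which(atlas$tissue_class[idx] == "cortical")
  if (length(cort) > 1L && corr_length > 0) {
    C <- as.matrix(atlas[idx[cort], c("cx", "cy", "cz")])
    ang <- acos(pmin(1, pmax(-1, tcrossprod(C))))
    K[cort, cort] <- exp(-ang / corr_length)
  }
  chol(K + diag(1e-8, n))
}

#' Simulate a three-group subject cohort with regional GMV
#'
#' Generates per-subject covariates (age, sex, total intracranial volume),
#' clinical fields, and per-region gray-matter volume following the additive
#' model `GMV = baseline + b_age*age + b_sex*sex + b_tiv*TIV + atrophy +
#' noise`, where `atrophy` subtracts `effect_size * noise_sd` in each
#' affected region of the subject's group and the noise is spatially
#' autocorrelated across cortical regions.
#'
#' Groups follow a case-control design: healthy controls (`HC`) and two
#' patient groups split by focal-to-bilateral tonic-clonic seizure status
#' (`FBTCS-`, `FBTCS+`). Patients additionally receive a seizure onset age,
#' a binary seizure-frequency category, and — for `FBTCS+` only — the number
#' of years since the last bilateral seizure.
#'
#' @param atlas a `parcellation_atlas`.
#' @param n_per_group named counts for `HC`, `FBTCS-`, `FBTCS+`.
#' @param atrophy_specs named list (`FBTCS-`, `FBTCS+`) of [atrophy_spec()];
#'   `HC` must have no planted effect.
#' @param covariate_params list with elements `beta_age`, `beta_sex`,
#'   `beta_tiv`, `noise_sd`, `age_range`, and the GMV `baseline_mean`.
#' @param spatial_corr_length angular scale (radians) of the exponential
#'   noise-correlation kernel across cortical centroids.
#' @param seed integer seed.
#' @return a `subject_table` data frame: `subject_id`, `group`, `age`, `sex`,
#'   `tiv`, `onset_age`, `seizure_frequency`, `years_since_last_fbtcs`, then
#'   one GMV column per region id.
#' @export
simulate_cohort <- function(atlas,
                            n_per_group = c("HC" = 60, "FBTCS-" = 37,
                                            "FBTCS+" = 89),
                            atrophy_specs = list(),
                            covariate_params = list(),
                            spatial_corr_length = 0.5,
                            seed = 1) {
  groups <- c("HC", "FBTCS-", "FBTCS+")
  if (is.null(names(n_per_group)) || !setequal(names(n_per_group), groups)) {
    stop_invalid("n_per_group must be named HC, FBTCS-, FBTCS+")
  }
  bad <- setdiff(names(atrophy_specs), groups)
  if (length(bad)) stop_invalid("unknown group in atrophy_specs: %s", bad[1])
  if (!is.null(atrophy_specs[["HC"]]) &&
      atrophy_specs[["HC"]]$effect_size > 0) {
    stop_invalid("HC must have zero atrophy effect")
  }
  p <- utils::modifyList(list(
    beta_age = -0.004,      # cm^3 GMV per year of age
    beta_sex = 0.05,        # male (1) minus female (0) offset, cm^3
    beta_tiv = 0.0008,      # cm^3 GMV per cm^3 TIV
    noise_sd = 0.15,        # within-region residual SD, cm^3
    age_range = c(18, 40),
    baseline_mean = 3.0     # mean regional GMV, cm^3
  ), covariate_params)

  rid <- atlas$region_id
  R <- length(rid)
  with_seed(seed, {
    baseline <- p$baseline_mean * exp(stats::rnorm(R, 0, 0.25))
    U <- spatial_chol(atlas, rid, spatial_corr_length)

    n_per_group <- n_per_group[groups]
    n <- sum(n_per_group)
    group <- rep(groups, times = n_per_group)
    age <- stats::runif(n, p$age_range[1], p$age_range[2])
    sex <- stats::rbinom(n, 1, 0.5)
    tiv <- exp(stats::rnorm(n, log(1500), 0.06))

    gmv <- matrix(baseline, n, R, byrow = TRUE) +
      outer(p$beta_age * age + p$beta_sex * sex + p$beta_tiv * tiv, rep(1, R)) +
      p$noise_sd * (matrix(stats::rnorm(n * R), n, R) %*% U)
    for (g in names(atrophy_specs)) {
      spec <- atrophy_specs[[g]]
      cols <- match(spec$affected_regions, rid)
      if (anyNA(cols)) stop_invalid("affected_regions not in atlas")
      rows <- group == g
      if (length(cols) && any(rows)) {
        gmv[rows, cols] <- gmv[rows, cols] - spec$effect_size * p$noise_sd
      }
    }

    patient <- group != "HC"
    onset_age <- ifelse(patient, pmax(1, age - stats::rexp(n, 1 / 10)), NA)
    freq <- ifelse(patient,
                   ifelse(stats::runif(n) < 0.5, "frequent", "infrequent"), NA)
    recency <- ifelse(group == "FBTCS+", stats::rexp(n, 1 / 2), NA)

    out <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      group = group, age = age, sex = sex, tiv = tiv,
      onset_age = onset_age, seizure_frequency = freq,
      years_since_last_fbtcs = recency,
      stringsAsFactors = FALSE, check.names = FALSE
    )
    gmv <- as.data.frame(gmv)
    names(gmv) <- as.character(rid)
    out <- cbind(out, gmv)
    class(out) <- c("subject_table", "data.frame")
    out
  })
}

SUBJECT_FIELDS <- c("subject_id", "group", "age", "sex", "tiv", "onset_age",
                    "seizure_frequency", "years_since_last_fbtcs")

#' Extract the subjects x regions GMV matrix from a subject table
#'
#' @param subjects a `subject_table`.
#' @return numeric matrix with one column per region id.
#' @export
gmv_matrix <- function(subjects) {
  cols <- setdiff(names(subjects), SUBJECT_FIELDS)
  as.matrix(as.data.frame(subjects)[, cols, drop = FALSE])
}

#' @export
print.subject_table <- function(x, ...) {
  cat(sprintf("subject_table: %d subjects (%s), %d regions\n", nrow(x),
              paste(sprintf("%s=%d", names(table(x$group)), table(x$group)),
                    collapse = ", "),
              length(setdiff(names(x), SUBJECT_FIELDS))))
  invisible(x)
}

#' Write / read a subject table as TSV
#' @param subjects a `subject_table`.
#' @param path file path.
#' @export
write_subjects <- function(subjects, path) {
  write_tsv(as.data.frame(subjects), path)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path) {
  x <- read_tsv(path)
  missing <- setdiff(SUBJECT_FIELDS, names(x))
  if (length(missing)) {
    stop_invalid("subject table missing columns: %s",
                 paste(missing, collapse = ", "))
  }
  class(x) <- c("subject_table", "data.frame")
  x
}

#' Simulate a regions x genes expression matrix with planted alignment
#'
#' Every gene is a spatially smooth random field over the supplied regions
#' (same exponential angular kernel as the cohort noise). The first
#' `n_aligned` genes are a convex mixture of the standardized `target_map`
#' (weight `alignment_strength`) and their own smooth field, so their
#' regional expression correlates with the target. Gene identifiers are
#' `G000001`, `G000002`, ...
#'
#' @param atlas a `parcellation_atlas`.
#' @param n_genes number of genes.
#' @param target_map named per-region vector (names = region ids, typically
#'   the left-hemisphere regions) that aligned genes should track.
#' @param n_aligned number of aligned genes (<= `n_genes`).
#' @param alignment_strength mixing weight in \[0, 1\].
#' @param spatial_corr_length angular kernel scale (radians).
#' @param seed integer seed.
#' @return an `expression_matrix` (regions x genes) over the regions of
#'   `target_map`, unnormalized.
#' @export
simulate_expression <- function(atlas, n_genes, target_map, n_aligned = 0,
                                alignment_strength = 0,
                                spatial_corr_length = 0.5, seed = 1) {
  n_genes <- check_count(n_genes, "n_genes")
  n_aligned <- check_count(n_aligned, "n_aligned", min = 0L)
  if (n_aligned > n_genes) stop_invalid("n_aligned must be <= n_genes")
  s <- check_fraction(alignment_strength, "alignment_strength")
  rid <- as.integer(names(target_map))
  if (length(rid) < 3L || anyNA(rid)) {
    stop_invalid("target_map must be named by region ids (>= 3 regions)")
  }
  with_seed(seed, {
    U <- spatial_chol(atlas, rid, spatial_corr_length)
    R <- length(rid)
    fields <- crossprod(U, matrix(stats::rnorm(R * n_genes), R, n_genes))
    fields <- scale(fields)  # z per gene so the mixture weights are comparable
    if (n_aligned > 0L) {
      zt <- z_normalize(as.numeric(target_map))
      fields[, seq_len(n_aligned)] <-
        s * zt + (1 - s) * fields[, seq_len(n_aligned), drop = FALSE]
    }
    dimnames(fields) <- list(as.character(rid),
                             sprintf("G%06d", seq_len(n_genes)))
    expression_matrix(fields[, , drop = FALSE], normalized = FALSE)
  })
}

#' A named gene set
#'
#' @param name set name.
#' @param genes unique, non-empty gene identifiers.
#' @param direction `"up"`, `"down"`, or `"none"`.
#' @return a `gene_set` list.
#' @export
gene_set <- function(name, genes, direction = "none") {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop_invalid("gene set '%s' is empty", name)
  direction <- match.arg(direction, c("up", "down", "none"))
  structure(list(name = as.character(name), genes = genes,
                 direction = direction), class = "gene_set")
}

#' Simulate gene sets with a planted enrichment
#'
#' Each set draws `planted_fraction` of its members from `planted_genes` and
#' the remainder uniformly from the rest of the universe.
#'
#' @param universe all gene identifiers.
#' @param planted_genes subset of `universe` carrying the planted signal.
#' @param n_sets number of sets.
#' @param planted_fraction fraction of each set drawn from `planted_genes`.
#' @param set_size members per set (recycled over sets).
#' @param seed integer seed.
#' @return list of [gene_set()] objects named `set_01`, ...
#' @export
simulate_gene_sets <- function(universe, planted_genes = character(),
                               n_sets = 1, planted_fraction = 0,
                               set_size = 60, seed = 1) {
  n_sets <- check_count(n_sets, "n_sets")
  f <- check_fraction(planted_fraction, "planted_fraction")
  planted_genes <- as.character(planted_genes)
  if (!all(planted_genes %in% universe)) {
    stop_invalid("planted_genes must be a subset of the universe")
  }
  sizes <- rep_len(as.integer(set_size), n_sets)
  other <- setdiff(universe, planted_genes)
  with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) {
      # each member comes from the planted pool independently with
      # probability planted_fraction, so the planted intersection is
      # Binomial(set size, planted_fraction)
      k <- min(stats::rbinom(1, sizes[i], f), length(planted_genes))
      k <- max(k, sizes[i] - length(other))
      members <- c(sample(planted_genes, k),
                   sample(other, sizes[i] - k))
      gene_set(sprintf("set_%02d", i), members)
    })
    names(sets) <- vapply(sets, `[[`, character(1), "name")
    sets
  })
}

#' Simulate a receptor density map with a target rank correlation
#'
#' Draws a Gaussian rank-mixture: the standardized ranks of the reference
#' map are mixed with independent noise at the Pearson level
#' `rho_P = 2 sin(pi * target_rho / 6)`, the bivariate-normal value whose
#' implied Spearman correlation equals `target_rho`. The realized Spearman
#' correlation is therefore unbiased for `target_rho` up to sampling error,
#' and exactly +/-1 at the endpoints.
#'
#' @param reference_map named per-region numeric vector (>= 10 regions).
#' @param target_rho desired expected Spearman correlation in \[-1, 1\].
#' @param seed integer seed.
#' @return named numeric vector over the same regions.
#' @export
simulate_receptor_map <- function(reference_map, target_rho, seed = 1) {
  rho <- check_fraction(target_rho, "target_rho", lo = -1, hi = 1)
  x <- as.numeric(reference_map)
  if (length(x) < 10L) stop_invalid("reference_map needs >= 10 regions")
  rho_p <- 2 * sin(pi * rho / 6)
  with_seed(seed, {
    rx <- z_normalize(rank(x))
    y <- rho_p * rx + sqrt(1 - rho_p^2) * stats::rnorm(length(x))
    names(y) <- names(reference_map)
    y
  })
}
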
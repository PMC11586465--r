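# Parcellation atlas: the spatial frame shared by all regional maps.
# Cortical regions carry unit-sphere centroids (the inflated-sphere
# coordinates that spin tests rotate); subcortical regions carry none.

YEO_NETWORKS <- c("visual", "somatomotor", "dorsal_attention",
                  "ventral_attention", "limbic", "frontoparietal", "default")

VON_ECONOMO_CLASSES <- c("primary_motor", "association_1", "association_2",
                         "primary_sensory", "secondary_sensory",
                         "limbic", "insular")

#' Build a synthetic parcellation atlas
#'
#' Places cortical centroids on the unit sphere with a deterministic
#' Fibonacci (golden-angle) lattice restricted to each hemisphere's
#' half-sphere, and appends `n_subcortical_per_hemi` subcortical regions per
#' hemisphere without centroids. Network labels (a 7-network functional
#' scheme) are assigned by contiguous polar bands and cytoarchitectonic class
#' labels by contiguous azimuthal sectors, so both labellings are spatially
#' coherent.
#'
#' The default emulates a 308-region cortical parcellation — 152 regions in
#' the left hemisphere and 156 in the right, as in parcellations built by
#' subdividing an anatomical atlas — plus 7 subcortical regions per
#' hemisphere: 322 regions in total, 159 on the left.
#'
#' @param n_cortical_per_hemi cortical regions per hemisphere: either one
#'   count (symmetric) or two counts `c(left, right)`; each >= 7 so all 7
#'   labels are represented.
#' @param n_subcortical_per_hemi subcortical regions per hemisphere (>= 0).
#' @param seed integer; kept for interface uniformity with the other
#'   generators (the lattice itself is deterministic).
#' @return a `parcellation_atlas` data frame with columns `region_id`, `name`,
#'   `hemisphere`, `tissue_class`, `cx`, `cy`, `cz`, `yeo_label`,
#'   `veconomo_label`.
#' @examples
#' atlas <- make_atlas(c(152, 156), 7, seed = 1)
#' nrow(atlas)                     # 322
#' sum(atlas$hemisphere == "left") # 159
#' @export
make_atlas <- function(n_cortical_per_hemi = c(152, 156),
                       n_subcortical_per_hemi = 7, seed = 1) {
  if (!length(n_cortical_per_hemi) %in% c(1L, 2L)) {
    stop_invalid("n_cortical_per_hemi must have length 1 or 2")
  }
  nc <- vapply(rep_len(n_cortical_per_hemi, 2L), check_count, integer(1),
               name = "n_cortical_per_hemi", min = 7L)
  ns <- check_count(n_subcortical_per_hemi, "n_subcortical_per_hemi", min = 0L)
  check_count(seed, "seed", min = 0L)

  left <- half_sphere_lattice(nc[1])                  # x < 0 half
  right <- half_sphere_lattice(nc[2]) *
    cbind(rep(-1, nc[2]), 1, 1)                       # mirrored lattice

  sub_names <- if (ns <= 7L) {
    c("thalamus", "caudate", "putamen", "pallidum", "hippocampus",
      "amygdala", "accumbens")[seq_len(ns)]
  } else {
    sprintf("subcortical_%02d", seq_len(ns))
  }

  cort <- data.frame(
    hemisphere = rep(c("left", "right"), times = nc),
    tissue_class = "cortical",
    cx = c(left[, 1], right[, 1]),
    cy = c(left[, 2], right[, 2]),
    cz = c(left[, 3], right[, 3]),
    yeo_label = c(band_labels(left[, 3], YEO_NETWORKS),
                  band_labels(right[, 3], YEO_NETWORKS)),
    veconomo_label = c(band_labels(atan2(left[, 2], left[, 1]),
                                   VON_ECONOMO_CLASSES),
                       band_labels(atan2(right[, 2], -right[, 1]),
                                   VON_ECONOMO_CLASSES)),
    stringsAsFactors = FALSE
  )
  cort$name <- sprintf("%s_cortical_%03d", cort$hemisphere,
                       c(seq_len(nc[1]), seq_len(nc[2])))
  atlas <- cort
  if (ns > 0L) {
    sub <- data.frame(
      hemisphere = rep(c("left", "right"), each = ns),
      tissue_class = "subcortical",
      cx = NA_real_, cy = NA_real_, cz = NA_real_,
      yeo_label = NA_character_, veconomo_label = NA_character_,
      name = paste0(rep(c("left_", "right_"), each = ns), rep(sub_names, 2L)),
      stringsAsFactors = FALSE
    )
    atlas <- rbind(cort, sub)
  }
  atlas$region_id <- seq_len(nrow(atlas))
  atlas <- atlas[, c("region_id", "name", "hemisphere", "tissue_class",
                     "cx", "cy", "cz", "yeo_label", "veconomo_label")]
  rownames(atlas) <- NULL
  class(atlas) <- c("parcellation_atlas", "data.frame")
  validate_atlas(atlas)
  atlas
}

# Golden-angle lattice on the x < 0 half-sphere: z runs uniformly through
# (-1, 1) and azimuth is low-discrepancy within (pi/2, 3*pi/2), which keeps
# area density near-uniform on the half-sphere.
half_sphere_lattice <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  golden <- (sqrt(5) - 1) / 2
  theta <- pi / 2 + pi * ((i * golden) %% 1)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(theta), r * sin(theta), z)
}

band_labels <- function(key, labels) {
  k <- length(labels)
  band <- ceiling(rank(key, ties.method = "first") * k / length(key))
  labels[band]
}

validate_atlas <- function(atlas) {
  req <- c("region_id", "name", "hemisphere", "tissue_class",
           "cx", "cy", "cz", "yeo_label", "veconomo_label")
  missing <- setdiff(req, names(atlas))
  if (length(missing)) {
    stop_invalid("atlas is missing columns: %s", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(atlas$region_id)) stop_invalid("region_ids must be unique")
  cort <- atlas$tissue_class == "cortical"
  norms <- sqrt(atlas$cx[cort]^2 + atlas$cy[cort]^2 + atlas$cz[cort]^2)
  if (any(is.na(norms)) || any(abs(norms - 1) > 1e-9)) {
    stop_invalid("cortical centroids must lie on the unit sphere")
  }
  if (any(is.na(atlas$yeo_label[cort])) || any(is.na(atlas$veconomo_label[cort]))) {
    stop_invalid("every cortical region needs yeo and von Economo labels")
  }
  invisible(atlas)
}

#' @export
print.parcellation_atlas <- function(x, ...) {
  cat(sprintf(
    "parcellation_atlas: %d regions (%d cortical, %d subcortical; %d left)\n",
    nrow(x), sum(x$tissue_class == "cortical"),
    sum(x$tissue_class == "subcortical"), sum(x$hemisphere == "left")))
  NextMethod()
}

#' Write / read an atlas as TSV
#'
#' @param atlas a `parcellation_atlas`.
#' @param path file path.
#' @return `read_atlas` returns a `parcellation_atlas`; `write_atlas` returns
#'   `path` invisibly.
#' @export
write_atlas <- function(atlas, path) {
  write_tsv(as.data.frame(atlas), path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  atlas <- read_tsv(path)
  class(atlas) <- c("parcellation_atlas", "data.frame")
  validate_atlas(atlas)
  atlas
}

#' Specification of a planted atrophy effect
#'
#' Describes the regional gray-matter reduction planted for one patient
#' group: which regions are affected and by how much, in units of the
#' within-region noise standard deviation.
#'
#' @param affected_regions integer region ids.
#' @param effect_size standardized mean GMV reduction per affected region
#'   (>= 0).
#' @return an `atrophy_spec` list.
#' @export
atrophy_spec <- function(affected_regions = integer(), effect_size = 0) {
  if (length(effect_size) != 1L || !is.finite(effect_size) || effect_size < 0) {
    stop_invalid("effect_size must be a single non-negative number")
  }
  structure(list(affected_regions = as.integer(affected_regions),
                 effect_size = as.numeric(effect_size)),
            class = "atrophy_spec")
}
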
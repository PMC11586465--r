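# Receptor-density context: rank correlation between a case-control t-map
# and a per-region receptor density map, with spin-test significance.

#' Correlate a case-control t-map with a receptor density map
#'
#' Spearman correlation between the regional t-values and the receptor
#' densities, with a p-value from the spatial spin null. Both maps are
#' aligned to the spin scope by region id.
#'
#' @param tmap a `cc_map` or a named per-region numeric vector.
#' @param receptor named per-region numeric vector (e.g. a GABA-receptor
#'   density map).
#' @param spins a `spin_null` whose scope is covered by both maps.
#' @param stat `"spearman"` (default) or `"pearson"`.
#' @return list with `rho` (observed correlation) and `p_spin`.
#' @export
receptor_correlation <- function(tmap, receptor, spins,
                                 stat = c("spearman", "pearson")) {
  stat <- match.arg(stat)
  tv <- if (inherits(tmap, "cc_map")) tmap_vector(tmap) else tmap
  if (is.null(names(tv)) || is.null(names(receptor))) {
    stop_invalid("both maps must be named by region id")
  }
  scope <- as.character(spins$scope)
  if (!all(scope %in% names(tv)) || !all(scope %in% names(receptor))) {
    stop_invalid("maps do not cover the spin-null scope")
  }
  res <- spin_pvalue(as.numeric(tv[scope]), as.numeric(receptor[scope]),
                     spins, stat = stat)
  list(rho = res$statistic, p_spin = res$p_spin)
}

#' Write / read a per-region map as TSV
#'
#' @param map named numeric vector (names = region ids).
#' @param path file path.
#' @export
write_region_map <- function(map, path) {
  write_tsv(data.frame(region_id = names(map), value = format_num(unname(map))),
            path)
}

#' @rdname write_region_map
#' @export
read_region_map <- function(path) {
  df <- read_tsv(path)
  stats::setNames(as.numeric(df$value), df$region_id)
}
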
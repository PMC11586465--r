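# Permutation enrichment-ratio (ER) statistic: how much higher the median
# PLS weight of the genes a list shares with an external gene set is than
# expected for an equally sized random draw from the modeled-gene universe.

CELL_CLASSES <- c("astrocytes", "endothelial", "excitatory neurons",
                  "inhibitory neurons", "microglia", "oligodendrocytes",
                  "OPCs")

#' Enrichment ratio of a gene set within a weighted gene list
#'
#' Let k be the size of the intersection between the weighted list (e.g. the
#' PLS+ genes with their weights) and the gene set. The observed statistic is
#' the median weight of those k genes; the null draws k genes without
#' replacement from the full universe of modeled gene weights, `n_perm`
#' times. `ER = (observed - mean(null)) / sd(null)`, and the p-value is the
#' one-sided upper tail `(1 + #\{null >= observed\}) / (n_perm + 1)` —
#' enrichment means a higher-than-chance median weight.
#'
#' ER is invariant under positive affine transforms of the weights.
#'
#' @param weights named numeric vector: the weighted gene list.
#' @param universe_weights named numeric vector over all modeled genes
#'   (must contain the list).
#' @param set a [gene_set()].
#' @param n_perm permutation draws (default 10000).
#' @param seed integer seed.
#' @return an `enrichment_result` list: `set_name`, `n_intersection`,
#'   `observed_median_weight`, `er`, `p_perm`, `empty` flag. An empty
#'   intersection returns `er = NA` with `empty = TRUE` rather than an error.
#' @export
enrichment_ratio <- function(weights, universe_weights, set,
                             n_perm = 10000, seed = 1) {
  n_perm <- check_count(n_perm, "n_perm")
  if (is.null(names(weights)) || is.null(names(universe_weights))) {
    stop_invalid("weights and universe_weights must be named by gene")
  }
  if (!all(names(weights) %in% names(universe_weights))) {
    stop_invalid("the weighted list must be contained in the universe")
  }
  inter <- intersect(names(weights), set$genes)
  k <- length(inter)
  if (k == 0L) {
    return(structure(list(set_name = set$name, n_intersection = 0L,
                          observed_median_weight = NA_real_, er = NA_real_,
                          p_perm = NA_real_, empty = TRUE),
                     class = "enrichment_result"))
  }
  observed <- stats::median(weights[inter])
  uv <- as.numeric(universe_weights)
  nulls <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) stats::median(uv[sample.int(length(uv), k)]),
           numeric(1))
  })
  structure(list(set_name = set$name, n_intersection = k,
                 observed_median_weight = observed,
                 er = (observed - mean(nulls)) / stats::sd(nulls),
                 p_perm = (1 + sum(nulls >= observed)) / (n_perm + 1),
                 empty = FALSE),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("enrichment_result [%s]: empty intersection\n", x$set_name))
  } else {
    cat(sprintf("enrichment_result [%s]: k = %d, ER = %.2f, p = %.4g\n",
                x$set_name, x$n_intersection, x$er, x$p_perm))
  }
  invisible(x)
}

#' Enrichment-ratio battery over gene sets
#'
#' Runs [enrichment_ratio()] for every gene set against both significant PLS
#' gene lists (PLS+ and PLS-, each with its weights) and BH-corrects the
#' p-values across the whole battery.
#'
#' @param pls a `pls1fit`.
#' @param gene_sets list of [gene_set()] objects.
#' @param n_perm permutation draws per test.
#' @param seed integer seed (one stream per set x list, derived).
#' @param lists which PLS lists to test (default both).
#' @return data frame: `set_name`, `pls_list`, `n_intersection`,
#'   `observed_median_weight`, `er`, `p_perm`, `q_value`.
#' @export
gene_list_battery <- function(pls, gene_sets, n_perm = 10000, seed = 1,
                              lists = c("PLS+", "PLS-")) {
  if (!length(gene_sets)) stop_invalid("need at least one gene set")
  universe <- pls$weights
  rows <- list()
  for (lst in lists) {
    members <- if (lst == "PLS+") pls$pls_plus else pls$pls_minus
    w <- universe[members]
    for (set in gene_sets) {
      res <- if (length(members)) {
        enrichment_ratio(w, universe, set, n_perm = n_perm,
                         seed = derive_seed(seed, paste(lst, set$name)))
      } else {
        list(set_name = set$name, n_intersection = 0L,
             observed_median_weight = NA_real_, er = NA_real_,
             p_perm = NA_real_, empty = TRUE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        set_name = res$set_name, pls_list = lst,
        n_intersection = res$n_intersection,
        observed_median_weight = res$observed_median_weight,
        er = res$er, p_perm = res$p_perm, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_perm)
  out
}

#' Cell-type enrichment over the seven canonical cortical classes
#'
#' Builds one gene set per cell-type class from a gene-to-class table and
#' runs the enrichment-ratio battery. Class names must come from the
#' canonical seven: astrocytes, endothelial, excitatory neurons, inhibitory
#' neurons, microglia, oligodendrocytes, OPCs.
#'
#' @param pls a `pls1fit`.
#' @param class_table data frame with columns `gene` and `class`.
#' @inheritParams gene_list_battery
#' @return as [gene_list_battery()].
#' @export
celltype_enrichment <- function(pls, class_table, n_perm = 10000, seed = 1,
                                lists = c("PLS+", "PLS-")) {
  if (!all(c("gene", "class") %in% names(class_table))) {
    stop_invalid("class_table needs columns 'gene' and 'class'")
  }
  bad <- setdiff(unique(class_table$class), CELL_CLASSES)
  if (length(bad)) stop_invalid("unknown cell class: %s", bad[1])
  sets <- lapply(split(class_table$gene, class_table$class), function(g) {
    gene_set(name = class_table$class[match(g[1], class_table$gene)], genes = g)
  })
  sets <- lapply(names(sets), function(nm) gene_set(nm, sets[[nm]]$genes))
  gene_list_battery(pls, sets, n_perm = n_perm, seed = seed, lists = lists)
}

#' Overlap between two gene lists
#'
#' Reports all three common overlap normalizations, because "x% overlap" is
#' ambiguous about its denominator: containment of A in B, containment of B
#' in A, and the Jaccard index.
#'
#' @param list_a,list_b non-empty character vectors of gene identifiers.
#' @return list with `containment_a_in_b`, `containment_b_in_a`, `jaccard`.
#' @export
gene_list_overlap <- function(list_a, list_b) {
  a <- unique(as.character(list_a))
  b <- unique(as.character(list_b))
  if (!length(a) || !length(b)) stop_invalid("gene lists must be non-empty")
  i <- length(intersect(a, b))
  list(containment_a_in_b = i / length(a),
       containment_b_in_a = i / length(b),
       jaccard = i / length(union(a, b)))
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return `read_gene_sets` returns a named list of [gene_set()] objects.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop_invalid("malformed GMT line: %s", substr(ln, 1, 40))
    gene_set(f[1], f[-(1:2)])
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' @rdname read_gene_sets
#' @param sets list of [gene_set()] objects.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$direction, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export a ranked gene list as single-column text
#'
#' The format consumed by web enrichment services: one gene per line, ranked.
#'
#' @param genes ranked character vector.
#' @param path output path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}
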
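# Config-driven orchestration: synthetic (default) or user-supplied tables,
# deterministic per-stage seeding, TSV/JSON outputs and a run manifest.

#' Build a pipeline configuration
#'
#' Returns the default configuration, with any field overridden by name.
#' Defaults describe the synthetic study the package emulates: a 322-region
#' atlas (152/156 left/right cortical + 7 subcortical per hemisphere),
#' cohorts of 60/37/89
#' subjects (HC / FBTCS- / FBTCS+), atrophy of 2 noise-SD planted in 10
#' left-cortical regions of both patient groups, 2000 genes with 100 aligned
#' to the atrophy map at strength 0.6, one planted gene set among null sets,
#' a 7-class cell-type table, and a receptor map at Spearman 0.24 to the
#' t-map.
#'
#' @param ... named overrides of the default fields.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    mode = "synthetic",
    # synthetic-generation parameters
    n_cortical_per_hemi = c(152, 156),
    n_subcortical_per_hemi = 7,
    n_per_group = c("HC" = 60, "FBTCS-" = 37, "FBTCS+" = 89),
    n_atrophy_regions = 10,
    atrophy_effect_size = 2.0,
    spatial_corr_length = 0.5,
    n_genes = 2000,
    n_aligned = 100,
    alignment_strength = 0.6,
    n_null_sets = 5,
    set_size = 60,
    planted_fraction = 0.5,
    genes_per_cell_class = 100,
    receptor_target_rho = 0.24,
    # real-mode input paths
    paths = list(atlas = NULL, subjects = NULL, expression = NULL,
                 gene_sets = NULL, class_table = NULL, receptor = NULL),
    # analysis parameters
    contrasts = c("TLE", "FBTCS-", "FBTCS+"),
    pls_contrasts = c("FBTCS-", "FBTCS+"),
    alpha = 0.05,
    n_perm = 1000,
    n_boot = 1000,
    er_n_perm = 10000,
    master_seed = 1
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad)) stop_invalid("unknown config field: %s", bad[1])
  cfg <- utils::modifyList(cfg, overrides)
  if (!cfg$mode %in% c("synthetic", "real")) {
    stop_invalid("mode must be 'synthetic' or 'real'")
  }
  check_fraction(cfg$alpha, "alpha")
  if (cfg$n_perm < 100) stop_invalid("n_perm must be >= 100")
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys as in [run_config()].
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$n_per_group)) vals$n_per_group <- unlist(vals$n_per_group)
  do.call(run_config, vals)
}

#' Validate pipeline inputs
#'
#' Collects schema and cross-reference findings over the configured inputs
#' instead of failing at the first problem: missing files or columns, regions
#' present in the expression matrix or receptor map but absent from the
#' atlas, and gene identifiers in gene sets or the cell-class table that are
#' outside the expression universe.
#'
#' @param config a `run_config`.
#' @param inputs optional pre-loaded inputs (as produced by the simulate
#'   stage); otherwise real-mode paths are read.
#' @return a `validation_report` data frame: `severity`, `where`, `message`.
#' @export
validate_inputs <- function(config, inputs = NULL) {
  findings <- list()
  note <- function(severity, where, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      severity = severity, where = where, message = message,
      stringsAsFactors = FALSE)
  }
  if (is.null(inputs)) {
    if (config$mode == "synthetic") {
      inputs <- simulate_stage(config)
    } else {
      for (nm in c("atlas", "subjects", "expression")) {
        p <- config$paths[[nm]]
        if (is.null(p) || !file.exists(p)) {
          note("error", nm, sprintf("missing input file: %s",
                                    if (is.null(p)) "<unset>" else p))
        }
      }
      if (length(findings)) {
        return(structure(do.call(rbind, findings),
                         class = c("validation_report", "data.frame")))
      }
      inputs <- load_real_inputs(config)
    }
  }
  atlas <- inputs$atlas
  with_ids <- function(ids, where) {
    bad <- setdiff(ids, atlas$region_id)
    if (length(bad)) {
      note("error", where, sprintf("region ids not in atlas: %s",
                                   paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  with_ids(as.integer(setdiff(names(inputs$subjects), SUBJECT_FIELDS)),
           "subjects")
  with_ids(region_ids(inputs$expression), "expression")
  if (!is.null(inputs$receptor)) {
    with_ids(as.integer(names(inputs$receptor)), "receptor")
  }
  universe <- colnames(inputs$expression$values)
  if (!is.null(inputs$gene_sets)) {
    for (s in inputs$gene_sets) {
      out <- setdiff(s$genes, universe)
      if (length(out)) {
        note("warning", paste0("gene_set:", s$name),
             sprintf("%d genes outside the expression universe", length(out)))
      }
    }
  }
  if (!is.null(inputs$class_table)) {
    out <- setdiff(inputs$class_table$gene, universe)
    if (length(out)) {
      note("warning", "class_table",
           sprintf("%d genes outside the expression universe", length(out)))
    }
  }
  report <- if (length(findings)) do.call(rbind, findings) else {
    data.frame(severity = character(), where = character(),
               message = character(), stringsAsFactors = FALSE)
  }
  structure(report, class = c("validation_report", "data.frame"))
}

#' @export
print.validation_report <- function(x, ...) {
  if (!nrow(x)) cat("validation: no findings\n") else NextMethod()
  invisible(x)
}

# ---- stages -----------------------------------------------------------------

simulate_stage <- function(config) {
  seed <- derive_seed(config$master_seed, "simulate")
  atlas <- make_atlas(config$n_cortical_per_hemi, config$n_subcortical_per_hemi,
                      seed = seed)
  left_cort <- atlas$region_id[atlas$hemisphere == "left" &
                                 atlas$tissue_class == "cortical"]
  planted_regions <- left_cort[round(seq(1, length(left_cort),
                                         length.out = config$n_atrophy_regions))]
  spec <- atrophy_spec(planted_regions, config$atrophy_effect_size)
  subjects <- simulate_cohort(
    atlas, n_per_group = config$n_per_group,
    atrophy_specs = list("FBTCS-" = spec, "FBTCS+" = spec),
    spatial_corr_length = config$spatial_corr_length,
    seed = derive_seed(seed, "cohort"))

  left_ids <- atlas$region_id[atlas$hemisphere == "left"]
  target <- stats::setNames(rep(0, length(left_ids)), left_ids)
  # aligned genes track the expected t-map direction: atrophy => negative t
  target[as.character(planted_regions)] <- -config$atrophy_effect_size
  expression <- simulate_expression(
    atlas, n_genes = config$n_genes, target_map = target,
    n_aligned = config$n_aligned,
    alignment_strength = config$alignment_strength,
    spatial_corr_length = config$spatial_corr_length,
    seed = derive_seed(seed, "expression"))

  genes <- colnames(expression$values)
  aligned <- genes[seq_len(config$n_aligned)]
  planted_set <- simulate_gene_sets(genes, aligned, n_sets = 1,
                                    planted_fraction = config$planted_fraction,
                                    set_size = config$set_size,
                                    seed = derive_seed(seed, "planted_set"))
  names(planted_set) <- "planted"
  planted_set$planted$name <- "planted"
  null_sets <- simulate_gene_sets(genes, character(),
                                  n_sets = config$n_null_sets,
                                  planted_fraction = 0,
                                  set_size = config$set_size,
                                  seed = derive_seed(seed, "null_sets"))
  class_table <- with_seed(derive_seed(seed, "cell_classes"), {
    n_cls <- config$genes_per_cell_class
    data.frame(gene = sample(genes, 7 * n_cls),
               class = rep(CELL_CLASSES, each = n_cls),
               stringsAsFactors = FALSE)
  })
  list(atlas = atlas, subjects = subjects, expression = expression,
       gene_sets = c(planted_set, null_sets), class_table = class_table,
       receptor = NULL,   # derived from the observed t-map later
       planted = list(regions = planted_regions, genes = aligned,
                      set = "planted"))
}

load_real_inputs <- function(config) {
  p <- config$paths
  list(
    atlas = read_atlas(p$atlas),
    subjects = read_subjects(p$subjects),
    expression = read_expression(p$expression),
    gene_sets = if (!is.null(p$gene_sets)) read_gene_sets(p$gene_sets),
    class_table = if (!is.null(p$class_table)) read_tsv(p$class_table),
    receptor = if (!is.null(p$receptor)) read_region_map(p$receptor),
    planted = NULL
  )
}

#' Run the full imaging-transcriptomics pipeline
#'
#' Executes, in order: (1) input simulation or loading; (2) case-control
#' t-maps for every configured contrast plus network contrasts and clinical
#' associations; (3) spin-null construction; (4) left-hemisphere PLS1 gene
#' association per patient contrast; (5) gene-set and cell-type
#' enrichment-ratio batteries; (6) receptor-map correlation. All stage
#' outputs are written under `out_dir` as TSV/JSON together with a
#' `manifest.json` recording seeds, stages and the package version.
#'
#' @param config a `run_config`.
#' @param out_dir output directory (created if needed); `NULL` keeps results
#'   in memory only.
#' @return a `run_report` list with every stage's results.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  t0 <- Sys.time()
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(fn, name) if (!is.null(out_dir)) fn(file.path(out_dir, name))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  stages_run <- character()

  # (1) inputs
  inputs <- stage("simulate", {
    if (config$mode == "synthetic") simulate_stage(config)
    else load_real_inputs(config)
  })
  stages_run <- c(stages_run, "simulate")
  atlas <- inputs$atlas
  emit(function(p) write_atlas(atlas, p), "atlas.tsv")
  emit(function(p) write_subjects(inputs$subjects, p), "subjects.tsv")

  # (2) morphometry
  morph <- stage("morphometry", {
    maps <- lapply(config$contrasts, function(ct) {
      case_control_map(inputs$subjects, ct, alpha = config$alpha)
    })
    names(maps) <- config$contrasts
    networks <- lapply(c(yeo = "yeo", veconomo = "veconomo"), function(sc) {
      network_contrast(inputs$subjects, atlas, sc,
                       patient_group = config$contrasts[[1]],
                       alpha = config$alpha)
    })
    pats <- select_patients(inputs$subjects, config$contrasts[[1]])
    clinical <- clinical_associations(pats, maps[[1]])
    list(maps = maps, networks = networks, clinical = clinical)
  })
  stages_run <- c(stages_run, "morphometry")
  if (!is.null(out_dir)) {
    for (ct in names(morph$maps)) {
      write_cc_map(morph$maps[[ct]],
                   file.path(out_dir, sprintf("cc_map_%s.tsv", gsub("[+]", "pos", ct))))
    }
  }

  # (3) spatial nulls: all-region scope for receptor context, left-hemisphere
  # scope (matching the expression rows) for the PLS stage
  spins <- stage("spins", {
    seed <- derive_seed(config$master_seed, "spins")
    left_atlas <- atlas[atlas$hemisphere == "left", , drop = FALSE]
    list(all = generate_spins(atlas, config$n_perm, seed = seed),
         left = generate_spins(left_atlas, config$n_perm,
                               seed = derive_seed(seed, "left")))
  })
  stages_run <- c(stages_run, "spins")

  # (4) PLS per patient contrast, on left-hemisphere regions
  expr_left <- restrict_left_hemisphere(inputs$expression, atlas)
  pls_fits <- stage("pls", {
    fits <- lapply(config$pls_contrasts, function(ct) {
      tv <- tmap_vector(morph$maps[[ct]])
      y <- tv[as.character(region_ids(expr_left))]
      pls_gene_association(expr_left, y, n_perm = config$n_perm,
                           n_boot = config$n_boot, alpha = config$alpha,
                           null_scheme = "spin", spins = spins$left,
                           seed = derive_seed(config$master_seed, paste0("pls_", ct)))
    })
    names(fits) <- config$pls_contrasts
    fits
  })
  stages_run <- c(stages_run, "pls")
  if (!is.null(out_dir)) {
    for (ct in names(pls_fits)) {
      safe <- gsub("[+]", "pos", ct)
      write_pls_result(pls_fits[[ct]],
                       file.path(out_dir, sprintf("pls_%s_genes.tsv", safe)),
                       file.path(out_dir, sprintf("pls_%s_scores.tsv", safe)))
      write_gene_list(pls_fits[[ct]]$pls_plus,
                      file.path(out_dir, sprintf("pls_%s_plus_ranked.txt", safe)))
    }
  }

  # (5) enrichment batteries on the first PLS fit
  enrich <- stage("enrichment", {
    fit <- pls_fits[[1]]
    seed <- derive_seed(config$master_seed, "enrichment")
    battery <- if (!is.null(inputs$gene_sets)) {
      gene_list_battery(fit, inputs$gene_sets, n_perm = config$er_n_perm,
                        seed = seed)
    }
    celltype <- if (!is.null(inputs$class_table)) {
      celltype_enrichment(fit, inputs$class_table, n_perm = config$er_n_perm,
                          seed = derive_seed(seed, "celltype"))
    }
    list(gene_sets = battery, celltype = celltype)
  })
  stages_run <- c(stages_run, "enrichment")
  if (!is.null(out_dir)) {
    if (!is.null(enrich$gene_sets)) {
      write_tsv(enrich$gene_sets, file.path(out_dir, "enrichment_gene_sets.tsv"))
    }
    if (!is.null(enrich$celltype)) {
      write_tsv(enrich$celltype, file.path(out_dir, "enrichment_celltype.tsv"))
    }
  }

  # (6) receptor correlation against the first contrast's t-map
  receptor <- stage("receptor", {
    tv <- tmap_vector(morph$maps[[1]])
    rmap <- inputs$receptor
    if (is.null(rmap) && config$mode == "synthetic") {
      rmap <- simulate_receptor_map(tv, config$receptor_target_rho,
                                    seed = derive_seed(config$master_seed,
                                                       "receptor"))
    }
    if (is.null(rmap)) NULL else {
      c(receptor_correlation(tv, rmap, spins$all), list(map = rmap))
    }
  })
  stages_run <- c(stages_run, "receptor")
  if (!is.null(out_dir) && !is.null(receptor)) {
    write_region_map(receptor$map, file.path(out_dir, "receptor_map.tsv"))
  }

  recovery <- if (!is.null(inputs$planted)) {
    planted_recovery(inputs$planted, morph$maps[[1]], pls_fits[[1]],
                     enrich$gene_sets)
  }

  report <- structure(list(
    config = config,
    maps = morph$maps, networks = morph$networks, clinical = morph$clinical,
    pls = pls_fits, enrichment = enrich,
    receptor = receptor[c("rho", "p_spin")],
    recovery = recovery,
    manifest = list(
      package_version = as.character(utils::packageVersion("imagetx")),
      master_seed = config$master_seed,
      stages = stages_run,
      elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
  ), class = "run_report")
  if (!is.null(out_dir)) {
    jsonlite::write_json(report_summary(report),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

# How well a synthetic run recovered what was planted.
planted_recovery <- function(planted, tle_map, pls_fit, battery) {
  sig_regions <- tle_map$region_id[tle_map$significant]
  regions_recovered <- sum(planted$regions %in% sig_regions)

  genes <- pls_fit$genes
  aligned <- genes$gene %in% planted$genes
  sig_genes <- union(pls_fit$pls_plus, pls_fit$pls_minus)
  q <- sum(planted$genes %in% sig_genes)
  hyper_p <- stats::phyper(q - 1, sum(aligned), sum(!aligned),
                           length(sig_genes), lower.tail = FALSE)
  set_row <- if (!is.null(battery)) {
    battery[battery$set_name == planted$set & battery$pls_list == "PLS+", ]
  }
  list(
    n_planted_regions = length(planted$regions),
    regions_recovered = regions_recovered,
    aligned_mean_abs_z = mean(abs(genes$z_score[aligned])),
    nonaligned_mean_abs_z = mean(abs(genes$z_score[!aligned])),
    aligned_in_significant = q,
    hypergeometric_p = hyper_p,
    planted_set_er = if (!is.null(set_row) && nrow(set_row)) set_row$er else NA,
    planted_set_p = if (!is.null(set_row) && nrow(set_row)) set_row$p_perm else NA
  )
}

report_summary <- function(report) {
  list(
    manifest = report$manifest,
    contrasts = lapply(report$maps, function(m) {
      list(contrast = attr(m, "contrast"),
           n_significant = sum(m$significant))
    }),
    pls = lapply(report$pls, function(f) {
      list(variance_explained = f$variance_explained, p_perm = f$p_perm,
           n_pls_plus = length(f$pls_plus), n_pls_minus = length(f$pls_minus))
    }),
    receptor = report$receptor,
    recovery = report$recovery
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("imaging-transcriptomics run\n")
  for (ct in names(x$maps)) {
    m <- x$maps[[ct]]
    cat(sprintf("  %-12s %3d significant regions\n", ct, sum(m$significant)))
  }
  for (ct in names(x$pls)) {
    f <- x$pls[[ct]]
    cat(sprintf("  PLS %-9s %.1f%% variance (p = %.4g), %d PLS+, %d PLS-\n",
                ct, 100 * f$variance_explained, f$p_perm,
                length(f$pls_plus), length(f$pls_minus)))
  }
  if (!is.null(x$receptor)) {
    cat(sprintf("  receptor rho = %.3f (spin p = %.4g)\n",
                x$receptor$rho, x$receptor$p_spin))
  }
  if (!is.null(x$recovery)) {
    cat(sprintf("  recovery: %d/%d planted regions, hypergeometric p = %.3g, planted-set ER p = %.3g\n",
                x$recovery$regions_recovered, x$recovery$n_planted_regions,
                x$recovery$hypergeometric_p, x$recovery$planted_set_p))
  }
  invisible(x)
}
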
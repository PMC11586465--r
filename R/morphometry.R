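# Case-control morphometry: per-region ordinary least squares with age, sex
# and TIV as covariates, the group indicator as the effect of interest, and
# Benjamini-Hochberg correction across regions of a contrast.

#' Covariate-adjusted group model for one region
#'
#' Fits `gmv ~ age + sex + tiv + group` by ordinary least squares and returns
#' the t statistic and two-sided p-value of the group coefficient. With
#' controls coded 0 and patients 1, regional atrophy yields a negative t.
#'
#' @param gmv per-subject response for one region.
#' @param age,sex,tiv per-subject covariates.
#' @param group per-subject 0/1 indicator (0 = control, 1 = patient).
#' @return list with `t_value`, `p_value`, `estimate`, `df`.
#' @export
fit_region_model <- function(gmv, age, sex, tiv, group) {
  fit <- fit_regions(cbind(as.numeric(gmv)), age, sex, tiv, group)
  list(t_value = fit$t[1], p_value = fit$p[1],
       estimate = fit$estimate[1], df = fit$df)
}

# Vectorized OLS over a subjects x regions response matrix with a shared
# design. Returns the group-coefficient statistics for every column.
fit_regions <- function(Y, age, sex, tiv, group) {
  n <- nrow(Y)
  X <- cbind(intercept = 1, age = as.numeric(age), sex = as.numeric(sex),
             tiv = as.numeric(tiv), group = as.numeric(group))
  if (n <= ncol(X) + 1L) stop_invalid("too few subjects for the region model")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop_invalid("collinear design: the covariates and group indicator are rank-deficient")
  }
  df <- n - ncol(X)
  B <- qr.coef(qx, Y)
  res <- Y - X %*% B
  sigma2 <- colSums(res^2) / df
  xtx_inv_gg <- chol2inv(qr.R(qx))[5L, 5L]
  se <- sqrt(sigma2 * xtx_inv_gg)
  tval <- B[5L, ] / se
  list(t = unname(tval), p = unname(2 * stats::pt(abs(tval), df, lower.tail = FALSE)),
       estimate = unname(B[5L, ]), df = df)
}

# Resolve a contrast label to the patient rows it selects.
select_patients <- function(subjects, patient_group) {
  if (identical(patient_group, "TLE")) patient_group <- c("FBTCS-", "FBTCS+")
  if (identical(patient_group, "remote-FBTCS+")) {
    return(select_subgroup(subjects, "remote"))
  }
  if (identical(patient_group, "current-FBTCS+")) {
    return(select_subgroup(subjects, "current"))
  }
  bad <- setdiff(patient_group, unique(subjects$group))
  if (length(bad)) stop_invalid("unknown group: %s", bad[1])
  subjects[subjects$group %in% patient_group, , drop = FALSE]
}

#' Case-control t-map of regional GMV
#'
#' Fits the covariate-adjusted group model in every region for one contrast
#' and applies Benjamini-Hochberg correction across all regions of the map.
#' Supported contrast labels: any group name, `"TLE"` (both patient groups
#' pooled), `"remote-FBTCS+"`, `"current-FBTCS+"`; patients may also be
#' contrasted against `"FBTCS-"` instead of controls.
#'
#' @param subjects a `subject_table`.
#' @param patient_group contrast label or character vector of group names.
#' @param control_group reference group (default `"HC"`).
#' @param alpha significance level on q-values (default 0.05).
#' @return a `cc_map` data frame: `region_id`, `t_value`, `p_value`,
#'   `q_value`, `significant`, with the contrast name and group sizes as
#'   attributes.
#' @export
case_control_map <- function(subjects, patient_group, control_group = "HC",
                             alpha = 0.05) {
  alpha <- check_fraction(alpha, "alpha")
  patients <- select_patients(subjects, patient_group)
  controls <- select_patients(subjects, control_group)
  if (!nrow(patients) || !nrow(controls)) {
    stop_invalid("empty patient or control group for this contrast")
  }
  both <- rbind(as.data.frame(controls), as.data.frame(patients))
  indicator <- rep(c(0, 1), c(nrow(controls), nrow(patients)))
  Y <- gmv_matrix(both)
  fit <- fit_regions(Y, both$age, both$sex, both$tiv, indicator)
  q <- bh_fdr(fit$p)
  out <- data.frame(
    region_id = as.integer(colnames(Y)),
    t_value = fit$t, p_value = fit$p, q_value = q,
    significant = q < alpha, stringsAsFactors = FALSE
  )
  structure(out,
            contrast = paste(paste(patient_group, collapse = "+"), "vs",
                             paste(control_group, collapse = "+")),
            alpha = alpha, n_patients = nrow(patients),
            n_controls = nrow(controls),
            class = c("cc_map", "data.frame"))
}

#' @export
print.cc_map <- function(x, ...) {
  cat(sprintf("cc_map [%s]: %d regions, %d significant at q < %g (n = %d vs %d)\n",
              attr(x, "contrast"), nrow(x), sum(x$significant),
              attr(x, "alpha"), attr(x, "n_patients"), attr(x, "n_controls")))
  invisible(x)
}

#' @export
plot.cc_map <- function(x, ...) {
  graphics::plot(x$region_id, x$t_value, pch = ifelse(x$significant, 19, 1),
                 xlab = "region id", ylab = "group t value",
                 main = attr(x, "contrast"), ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Extract the t-map as a named vector
#' @param map a `cc_map`.
#' @return numeric vector of t-values named by region id.
#' @export
tmap_vector <- function(map) {
  stats::setNames(map$t_value, map$region_id)
}

#' Network-level case-control contrasts
#'
#' Averages GMV over the cortical regions of each network (or
#' cytoarchitectonic class) per subject, fits the same covariate-adjusted
#' group model per network, and corrects across networks.
#'
#' @param subjects a `subject_table`.
#' @param atlas a `parcellation_atlas`.
#' @param scheme `"yeo"` or `"veconomo"`.
#' @inheritParams case_control_map
#' @return data frame: `network`, `t_value`, `p_value`, `q_value`,
#'   `significant`.
#' @export
network_contrast <- function(subjects, atlas, scheme = c("yeo", "veconomo"),
                             patient_group, control_group = "HC",
                             alpha = 0.05) {
  scheme <- match.arg(scheme)
  label_col <- if (scheme == "yeo") "yeo_label" else "veconomo_label"
  cort <- atlas[atlas$tissue_class == "cortical", ]
  labels <- sort(unique(cort[[label_col]]))

  patients <- select_patients(subjects, patient_group)
  controls <- select_patients(subjects, control_group)
  both <- rbind(as.data.frame(controls), as.data.frame(patients))
  indicator <- rep(c(0, 1), c(nrow(controls), nrow(patients)))
  Y <- gmv_matrix(both)

  netY <- vapply(labels, function(lb) {
    ids <- as.character(cort$region_id[cort[[label_col]] == lb])
    rowMeans(Y[, ids, drop = FALSE])
  }, numeric(nrow(Y)))
  fit <- fit_regions(netY, both$age, both$sex, both$tiv, indicator)
  q <- bh_fdr(fit$p)
  data.frame(network = labels, t_value = fit$t, p_value = fit$p,
             q_value = q, significant = q < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Clinical associations within significant regions
#'
#' Restricted to the regions flagged significant in a case-control map:
#' (a) Spearman correlation between seizure onset age and regional GMV across
#' patients, and (b) the frequent-vs-infrequent seizure-frequency coefficient
#' from the same covariate-adjusted linear model. Each family is BH-corrected
#' over the significant regions.
#'
#' @param patients `subject_table` rows for the patient group of interest.
#' @param map the corresponding `cc_map`.
#' @return list with data frames `onset_age` (`region_id`, `rho`, `p_value`,
#'   `q_value`) and `frequency` (`region_id`, `t_value`, `p_value`,
#'   `q_value`); both empty when the map has no significant region.
#' @export
clinical_associations <- function(patients, map) {
  sig <- map$region_id[map$significant]
  empty_rho <- data.frame(region_id = integer(), rho = numeric(),
                          p_value = numeric(), q_value = numeric())
  empty_t <- data.frame(region_id = integer(), t_value = numeric(),
                        p_value = numeric(), q_value = numeric())
  if (!length(sig)) return(list(onset_age = empty_rho, frequency = empty_t))
  Y <- gmv_matrix(patients)[, as.character(sig), drop = FALSE]

  rho_p <- vapply(seq_along(sig), function(j) {
    r <- spearman_correlation(patients$onset_age, Y[, j])
    c(r$statistic, r$p_value)
  }, numeric(2))
  onset <- data.frame(region_id = sig, rho = rho_p[1, ],
                      p_value = rho_p[2, ], q_value = bh_fdr(rho_p[2, ]))

  freq <- as.integer(patients$seizure_frequency == "frequent")
  fit <- fit_regions(Y, patients$age, patients$sex, patients$tiv, freq)
  frequency <- data.frame(region_id = sig, t_value = fit$t, p_value = fit$p,
                          q_value = bh_fdr(fit$p))
  list(onset_age = onset, frequency = frequency)
}

#' Split FBTCS+ patients by seizure recency
#'
#' Patients with no bilateral seizure in over 2 years form the remote
#' subgroup; the rest (including exactly 2 years) are current. The two rules
#' partition the FBTCS+ rows exhaustively.
#'
#' @param subjects a `subject_table`.
#' @param rule `"remote"` or `"current"`.
#' @return the `subject_table` subset of FBTCS+ rows selected by the rule.
#' @export
select_subgroup <- function(subjects, rule = c("remote", "current")) {
  rule <- match.arg(rule)
  fb <- subjects[subjects$group == "FBTCS+", , drop = FALSE]
  if (!nrow(fb)) stop_invalid("no FBTCS+ subjects present")
  if (anyNA(fb$years_since_last_fbtcs)) {
    stop_invalid("years_since_last_fbtcs missing on an FBTCS+ row")
  }
  keep <- if (rule == "remote") fb$years_since_last_fbtcs > 2
          else fb$years_since_last_fbtcs <= 2
  fb[keep, , drop = FALSE]
}

#' Write a case-control map as TSV
#' @param map a `cc_map`.
#' @param path file path.
#' @export
write_cc_map <- function(map, path) {
  df <- as.data.frame(map)
  df$t_value <- format_num(df$t_value)
  df$p_value <- format_num(df$p_value)
  df$q_value <- format_num(df$q_value)
  write_tsv(df, path)
}
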
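test_that("make_atlas builds the default 322-region frame", {
  atlas <- make_atlas(seed = 1)
  expect_s3_class(atlas, "parcellation_atlas")
  expect_equal(nrow(atlas), 322)
  expect_equal(sum(atlas$tissue_class == "cortical"), 308)
  expect_equal(sum(atlas$hemisphere == "left"), 159)
  expect_equal(sum(atlas$hemisphere == "left" &
                     atlas$tissue_class == "cortical"), 152)
  cort <- atlas[atlas$tissue_class == "cortical", ]
  expect_true(all(abs(sqrt(cort$cx^2 + cort$cy^2 + cort$cz^2) - 1) < 1e-9))
  expect_false(anyDuplicated(atlas$region_id) > 0)
  # every cortical region labelled, all 7 labels used per scheme
  expect_equal(length(unique(cort$yeo_label)), 7)
  expect_equal(length(unique(cort$veconomo_label)), 7)
  expect_true(all(cort$cx[cort$hemisphere == "left"] < 0))
  expect_true(all(cort$cx[cort$hemisphere == "right"] > 0))

  # symmetric counts give hemispheres that are mirror images in x
  sym <- make_atlas(c(20, 20), 0, seed = 1)
  left <- sym[sym$hemisphere == "left", ]
  right <- sym[sym$hemisphere == "right", ]
  expect_equal(left$cx, -right$cx)
  expect_equal(left$cy, right$cy)
  expect_equal(left$cz, right$cz)
})

test_that("make_atlas is deterministic and validates its arguments", {
  expect_identical(make_atlas(20, 2, seed = 7), make_atlas(20, 2, seed = 7))
  a <- make_atlas(7, 0, seed = 1)
  expect_equal(nrow(a), 14)
  expect_true(all(a$tissue_class == "cortical"))
  expect_error(make_atlas(5, 2), ">= 7")
  expect_error(make_atlas(0, 2), ">= 7")
})

test_that("atlas TSV round-trip preserves the frame", {
  atlas <- tiny_atlas()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_atlas(atlas, path)
  back <- read_atlas(path)
  expect_equal(as.data.frame(back), as.data.frame(atlas), tolerance = 1e-12)
})

test_that("simulate_cohort plants recoverable atrophy and respects the null", {
  atlas <- tiny_atlas(nc = 30, ns = 2)
  planted <- atlas$region_id[c(3, 9, 15)]

  # null case: group-coefficient t has mean about 0 over simulations
  tnull <- replicate(60, {
    s <- simulate_cohort(atlas, n_per_group = c("HC" = 20, "FBTCS-" = 10,
                                                "FBTCS+" = 15),
                         seed = sample.int(1e6, 1))
    m <- case_control_map(s, "TLE")
    mean(m$t_value)
  })
  expect_lt(abs(mean(tnull)), 0.15)

  # planted case: affected regions carry the most negative t-values
  hits <- replicate(30, {
    s <- simulate_cohort(
      atlas, n_per_group = c("HC" = 60, "FBTCS-" = 37, "FBTCS+" = 89),
      atrophy_specs = list("FBTCS-" = atrophy_spec(planted, 2.0),
                           "FBTCS+" = atrophy_spec(planted, 2.0)),
      seed = sample.int(1e6, 1))
    m <- case_control_map(s, "TLE")
    worst <- m$region_id[order(m$t_value)][seq_along(planted)]
    all(planted %in% worst)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("simulate_cohort degenerates to baselines without noise or effects", {
  atlas <- tiny_atlas(nc = 10, ns = 0)
  s <- simulate_cohort(atlas, n_per_group = c("HC" = 5, "FBTCS-" = 3,
                                              "FBTCS+" = 4),
                       covariate_params = list(beta_age = 0, beta_sex = 0,
                                               beta_tiv = 0, noise_sd = 0),
                       seed = 4)
  g <- gmv_matrix(s)
  expect_true(all(apply(g, 2, function(col) diff(range(col)) == 0)))
  expect_identical(s, simulate_cohort(atlas,
    n_per_group = c("HC" = 5, "FBTCS-" = 3, "FBTCS+" = 4),
    covariate_params = list(beta_age = 0, beta_sex = 0, beta_tiv = 0,
                            noise_sd = 0), seed = 4))
})

test_that("cohort noise decays with inter-centroid angle", {
  atlas <- tiny_atlas(nc = 40, ns = 0)
  s <- simulate_cohort(atlas, n_per_group = c("HC" = 120, "FBTCS-" = 10,
                                              "FBTCS+" = 10),
                       covariate_params = list(beta_age = 0, beta_sex = 0,
                                               beta_tiv = 0),
                       spatial_corr_length = 0.6, seed = 9)
  hc <- s[s$group == "HC", ]
  g <- gmv_matrix(hc)
  cc <- cor(g)
  C <- as.matrix(atlas[, c("cx", "cy", "cz")])
  ang <- acos(pmin(1, pmax(-1, tcrossprod(C))))
  up <- upper.tri(cc)
  expect_lt(cor(ang[up], abs(cc[up]), method = "spearman"), -0.3)
})

test_that("simulate_cohort validates groups and atrophy targets", {
  atlas <- tiny_atlas(nc = 8, ns = 0)
  expect_error(simulate_cohort(atlas, n_per_group = c(a = 5, b = 5, c = 5)),
               "named HC")
  expect_error(
    simulate_cohort(atlas, atrophy_specs = list(other = atrophy_spec(1, 1))),
    "unknown group")
  expect_error(
    simulate_cohort(atlas, atrophy_specs = list("HC" = atrophy_spec(1, 1))),
    "zero atrophy")
  expect_error(
    simulate_cohort(atlas,
                    atrophy_specs = list("FBTCS+" = atrophy_spec(999, 1))),
    "not in atlas")
})

test_that("simulate_expression plants alignment exactly at the endpoints", {
  atlas <- tiny_atlas(nc = 25, ns = 2)
  left <- atlas$region_id[atlas$hemisphere == "left"]
  target <- setNames(sin(seq_along(left)), left)

  # strength 1: aligned genes are the standardized target exactly
  e1 <- simulate_expression(atlas, n_genes = 10, target_map = target,
                            n_aligned = 4, alignment_strength = 1, seed = 2)
  for (j in 1:4) {
    expect_equal(abs(cor(e1$values[, j], target)), 1, tolerance = 1e-12)
  }

  # strength 0: aligned genes behave like the others
  r_aligned <- r_other <- c()
  for (seed in 1:30) {
    e0 <- simulate_expression(atlas, n_genes = 20, target_map = target,
                              n_aligned = 10, alignment_strength = 0,
                              seed = seed)
    r <- abs(cor(e0$values, target, method = "spearman"))
    r_aligned <- c(r_aligned, r[1:10])
    r_other <- c(r_other, r[11:20])
  }
  expect_lt(abs(mean(r_aligned) - mean(r_other)), 0.05)

  expect_error(simulate_expression(atlas, 10, target, 4, 1.5), "\\[0, 1\\]")
  expect_error(simulate_expression(atlas, 10, target, 11, 0.5), "<= n_genes")
})

test_that("simulate_gene_sets draws a binomial planted fraction from the pool", {
  universe <- sprintf("G%06d", 1:500)
  planted <- universe[1:100]
  sets <- simulate_gene_sets(universe, planted, n_sets = 200,
                             planted_fraction = 0.5, set_size = 60, seed = 3)
  inter <- vapply(sets, function(s) length(intersect(s$genes, planted)),
                  integer(1))
  # planted intersection ~ Binomial(60, 0.5): mean 30, sd sqrt(15)
  expect_lt(abs(mean(inter) - 30), 3 * sqrt(15 / 200))
  expect_gt(sd(inter), 0)
  expect_true(all(vapply(sets, function(s) length(s$genes) == 60, logical(1))))

  # planted_fraction 1: every member comes from the pool
  full <- simulate_gene_sets(universe, planted, n_sets = 5,
                             planted_fraction = 1, set_size = 60, seed = 4)
  expect_true(all(vapply(full, function(s) all(s$genes %in% planted),
                         logical(1))))

  # planted_fraction 0 with no pool: plain uniform draws from the universe
  null_sets <- simulate_gene_sets(universe, character(), n_sets = 5,
                                  planted_fraction = 0, set_size = 60,
                                  seed = 5)
  expect_true(all(vapply(null_sets, function(s) all(s$genes %in% universe),
                         logical(1))))
  expect_error(simulate_gene_sets(universe, "not_there", 1, 0.5), "subset")
  expect_error(simulate_gene_sets(universe, planted, 1, 1.5), "\\[0, 1\\]")
})

test_that("simulate_receptor_map hits the target rank correlation", {
  ref <- setNames(rnorm(322), 1:322)
  exact <- simulate_receptor_map(ref, target_rho = 1, seed = 5)
  expect_equal(cor(ref, exact, method = "spearman"), 1)
  anti <- simulate_receptor_map(ref, target_rho = -1, seed = 5)
  expect_equal(cor(ref, anti, method = "spearman"), -1)

  r0 <- vapply(1:200, function(s) {
    cor(ref, simulate_receptor_map(ref, 0, seed = s), method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(r0)), 0.01)

  r24 <- vapply(1:100, function(s) {
    cor(ref, simulate_receptor_map(ref, 0.24, seed = s), method = "spearman")
  }, numeric(1))
  expect_gte(mean(r24 >= 0.10 & r24 <= 0.38), 0.95)
  expect_error(simulate_receptor_map(ref, 1.2), "\\[-1, 1\\]")
  expect_error(simulate_receptor_map(ref[1:5], 0.5), ">= 10 regions")
})

test_that("subject table TSV round-trip preserves values and clinical fields", {
  s <- tiny_cohort(tiny_atlas(nc = 8, ns = 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_subjects(s, path)
  back <- read_subjects(path)
  expect_equal(gmv_matrix(back), gmv_matrix(s), tolerance = 1e-10)
  expect_equal(back$group, s$group)
  expect_true(all(is.na(back$years_since_last_fbtcs[back$group != "FBTCS+"])))
})
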
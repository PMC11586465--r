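test_that("fit_region_model matches lm and is affine-invariant in the response", {
  withr::with_seed(21, {
    n <- 60
    age <- runif(n, 20, 40); sex <- rbinom(n, 1, 0.5)
    tiv <- rnorm(n, 1500, 80); grp <- rep(0:1, each = n / 2)
    gmv <- 3 - 0.01 * age + 0.001 * tiv - 0.3 * grp + rnorm(n, 0, 0.2)

    res <- fit_region_model(gmv, age, sex, tiv, grp)
    ref <- summary(lm(gmv ~ age + sex + tiv + grp))$coefficients["grp", ]
    expect_equal(res$t_value, unname(ref["t value"]), tolerance = 1e-10)
    expect_equal(res$p_value, unname(ref["Pr(>|t|)"]), tolerance = 1e-10)

    scaled <- fit_region_model(2.5 * gmv + 7, age, sex, tiv, grp)
    expect_equal(scaled$t_value, res$t_value, tolerance = 1e-10)
    expect_equal(scaled$p_value, res$p_value, tolerance = 1e-10)
  })
})

test_that("group t statistic is Student-t distributed under the null", {
  withr::with_seed(22, {
    n <- 40
    age <- runif(n, 20, 40); sex <- rbinom(n, 1, 0.5)
    tiv <- rnorm(n, 1500, 80); grp <- rep(0:1, each = n / 2)
    # 1500 independent null responses fitted in one vectorized call
    Y <- matrix(rnorm(n * 1500), n)
    colnames(Y) <- seq_len(ncol(Y))
    fit <- imagetx:::fit_regions(Y, age, sex, tiv, grp)
    expect_equal(fit$df, n - 5)
    probs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
    expect_equal(unname(quantile(fit$t, probs)), qt(probs, n - 5),
                 tolerance = 0.12)
    # p-values approximately uniform
    expect_lt(abs(mean(fit$p) - 0.5), 0.03)
  })
})

test_that("fit_region_model rejects rank-deficient designs and blows up as noise vanishes", {
  n <- 30
  age <- runif(n, 20, 40); sex <- rbinom(n, 1, 0.5); grp <- rep(0:1, n / 2)
  expect_error(fit_region_model(rnorm(n), age, sex, 2 * age, grp), "collinear")
  # noise-free planted effect: |t| enormous
  tiv <- rnorm(n, 1500, 80)
  gmv <- 3 + 0.001 * tiv - 0.5 * grp + rnorm(n, 0, 1e-9)
  expect_gt(abs(fit_region_model(gmv, age, sex, tiv, grp)$t_value), 1e4)
})

test_that("case_control_map recovers planted regions and dominates with one huge effect", {
  atlas <- tiny_atlas(nc = 25, ns = 2)
  planted <- atlas$region_id[c(5, 12, 20, 30, 41)]
  s <- simulate_cohort(
    atlas, n_per_group = c("HC" = 60, "FBTCS-" = 37, "FBTCS+" = 89),
    atrophy_specs = list("FBTCS-" = atrophy_spec(planted, 2.0),
                         "FBTCS+" = atrophy_spec(planted, 2.0)),
    seed = 31)
  m <- case_control_map(s, "TLE")
  expect_true(all(planted %in% m$region_id[m$significant]))
  expect_true(all(m$q_value >= m$p_value))
  expect_equal(attr(m, "n_patients"), 126)

  one <- atlas$region_id[7]
  s1 <- simulate_cohort(
    atlas, n_per_group = c("HC" = 30, "FBTCS-" = 15, "FBTCS+" = 15),
    atrophy_specs = list("FBTCS-" = atrophy_spec(one, 50),
                         "FBTCS+" = atrophy_spec(one, 50)),
    seed = 32)
  m1 <- case_control_map(s1, "TLE")
  expect_equal(m1$region_id[which.min(m1$t_value)], one)
})

test_that("contrast selection covers subgroups and patient-vs-patient", {
  s <- tiny_cohort(seed = 33)
  direct <- case_control_map(s, "FBTCS+", control_group = "FBTCS-")
  expect_equal(attr(direct, "n_controls"), 15)
  remote <- case_control_map(s, "remote-FBTCS+")
  current <- case_control_map(s, "current-FBTCS+")
  expect_equal(attr(remote, "n_patients") + attr(current, "n_patients"),
               sum(s$group == "FBTCS+"))
  expect_error(case_control_map(s, "nonexistent"), "unknown group")
})

test_that("select_subgroup applies the strict 2-year boundary and partitions FBTCS+", {
  s <- tiny_cohort(seed = 34)
  s$years_since_last_fbtcs[s$group == "FBTCS+"][1:3] <- c(2, 3, 2.0001)
  remote <- select_subgroup(s, "remote")
  current <- select_subgroup(s, "current")
  fb <- s[s$group == "FBTCS+", ]
  expect_equal(nrow(remote) + nrow(current), nrow(fb))
  expect_length(intersect(remote$subject_id, current$subject_id), 0)
  ids <- fb$subject_id[1:3]
  expect_true(ids[1] %in% current$subject_id)   # exactly 2 years -> current
  expect_true(ids[2] %in% remote$subject_id)    # over 2 years -> remote
  expect_true(ids[3] %in% remote$subject_id)

  s$years_since_last_fbtcs[s$group == "FBTCS+"][1] <- NA
  expect_error(select_subgroup(s, "remote"), "missing")
})

test_that("network_contrast aggregates labels and propagates global atrophy", {
  atlas <- tiny_atlas(nc = 21, ns = 0)
  all_regions <- atlas$region_id
  s <- simulate_cohort(
    atlas, n_per_group = c("HC" = 40, "FBTCS-" = 20, "FBTCS+" = 25),
    atrophy_specs = list("FBTCS-" = atrophy_spec(all_regions, 3),
                         "FBTCS+" = atrophy_spec(all_regions, 3)),
    seed = 35)
  for (scheme in c("yeo", "veconomo")) {
    nc <- network_contrast(s, atlas, scheme, patient_group = "TLE")
    expect_equal(nrow(nc), 7)
    expect_true(all(nc$t_value < 0))
  }
  expect_error(network_contrast(s, atlas, "unknown", patient_group = "TLE"))
})

test_that("network_contrast localizes atrophy planted inside one network", {
  atlas <- tiny_atlas(nc = 35, ns = 0)
  net <- "limbic"
  inside <- atlas$region_id[atlas$yeo_label == net & atlas$hemisphere == "left"]
  s <- simulate_cohort(
    atlas, n_per_group = c("HC" = 60, "FBTCS-" = 30, "FBTCS+" = 40),
    atrophy_specs = list("FBTCS-" = atrophy_spec(inside, 2.5),
                         "FBTCS+" = atrophy_spec(inside, 2.5)),
    spatial_corr_length = 0,  # independent noise keeps other networks null
    seed = 36)
  nc <- network_contrast(s, atlas, "yeo", patient_group = "TLE")
  expect_true(nc$significant[nc$network == net])
  expect_equal(nc$network[which.min(nc$t_value)], net)
})

test_that("pooling patient groups preserves the t sign shared by both subgroups on noise-free data", {
  atlas <- tiny_atlas(nc = 10, ns = 0)
  planted <- atlas$region_id[1:6]
  s <- simulate_cohort(
    atlas, n_per_group = c("HC" = 20, "FBTCS-" = 10, "FBTCS+" = 15),
    atrophy_specs = list("FBTCS-" = atrophy_spec(planted, 1.0),
                         "FBTCS+" = atrophy_spec(planted, 3.0)),
    covariate_params = list(noise_sd = 1e-6),
    seed = 38)
  t_minus <- case_control_map(s, "FBTCS-")$t_value
  t_plus <- case_control_map(s, "FBTCS+")$t_value
  t_pool <- case_control_map(s, "TLE")$t_value
  shared <- sign(t_minus) == sign(t_plus)
  expect_true(all(sign(t_pool[shared]) == sign(t_minus[shared])))
})

test_that("clinical_associations detects a planted onset-age relation and handles empty maps", {
  atlas <- tiny_atlas(nc = 12, ns = 0)
  s <- simulate_cohort(
    atlas, n_per_group = c("HC" = 40, "FBTCS-" = 25, "FBTCS+" = 35),
    atrophy_specs = list("FBTCS-" = atrophy_spec(atlas$region_id[1:4], 2.5),
                         "FBTCS+" = atrophy_spec(atlas$region_id[1:4], 2.5)),
    seed = 37)
  m <- case_control_map(s, "TLE")
  patients <- s[s$group != "HC", ]
  # plant onset age equal to one significant region's GMV: rho = 1 there
  sig1 <- as.character(m$region_id[m$significant][1])
  patients$onset_age <- as.data.frame(patients)[[sig1]]
  ca <- clinical_associations(patients, m)
  expect_equal(ca$onset_age$rho[ca$onset_age$region_id == as.integer(sig1)], 1)
  expect_equal(nrow(ca$onset_age), sum(m$significant))
  expect_equal(nrow(ca$frequency), sum(m$significant))

  m$significant <- FALSE
  empty <- clinical_associations(patients, m)
  expect_equal(nrow(empty$onset_age), 0)
  expect_equal(nrow(empty$frequency), 0)
})
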
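test_that("ROI summaries average valid voxels and report empty regions as NA", {
  ph <- small_phantom()
  const <- vol_image(array(42, dim = ph$spec$shape), ph$spec$voxel_dims)
  s <- roi_summary(const, ph$label_map)
  expect_equal(s$mean, rep(42, 10))
  # phantom truth map: region means equal spec values exactly
  st <- roi_summary(ph$t2star, ph$label_map)
  expect_equal(st$mean[match(ph$spec$truth$region, st$region)],
               ph$spec$truth$t2star_ms)
  # fully invalidated region -> missing, not zero
  broken <- ph$t2star$data
  broken[region_mask(ph$label_map, "thalamus")] <- NaN
  sb <- roi_summary(vol_image(broken, ph$spec$voxel_dims), ph$label_map)
  expect_true(is.na(sb$mean[sb$region == "thalamus"]))
  expect_identical(sb$n_valid[sb$region == "thalamus"], 0L)
  expect_error(roi_summary(array(1, c(2, 2, 2)), ph$label_map), "grids")
})

test_that("Shapiro-Wilk wrapper is calibrated and powered", {
  expect_error(normality_p(c(1, 2)), "3")
  set.seed(41)
  p_norm <- replicate(1000, normality_p(rnorm(50)))
  expect_gte(mean(p_norm > 0.05), 0.90)
  p_exp <- replicate(1000, normality_p(rexp(50)))
  expect_gte(mean(p_exp < 0.05), 0.90)
  # matches the reference implementation on a fixed vector
  x <- c(2.1, 3.4, 1.2, 5.6, 4.4, 3.3, 2.2, 6.1, 0.4, 3.9)
  expect_equal(normality_p(x), shapiro.test(x)$p.value, tolerance = 1e-6)
})

test_that("the normality gate selects the documented test branch", {
  cfg <- stats_config()
  x <- c(1, 2, 3, 4, 5, 6)
  r <- compare_groups(x, x, cfg)
  expect_identical(r$test_used, "t-test")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_raw, 1)
  # forced nonparametric on fully separated triples: U = 0, exact p = 0.1
  r2 <- compare_groups(c(1, 2, 3), c(4, 5, 6), cfg, force = "mann-whitney")
  expect_identical(r2$test_used, "Mann-Whitney")
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_raw, 0.1)
  # a grossly non-normal group flips the gate under the "either" reading
  set.seed(43)
  skewed <- c(rep(0.01, 8), 50, 80)
  normal <- rnorm(10, 5, 1)
  r3 <- compare_groups(skewed, normal, cfg)
  expect_identical(r3$test_used, "Mann-Whitney")
  # ... but not under the strict both-fail reading
  r4 <- compare_groups(skewed, normal, stats_config(gate = "both"))
  expect_identical(r4$test_used, "t-test")
  expect_error(compare_groups(c(1, 2), c(1, 2, 3), cfg), "at least 3")
})

test_that("group separation at study effect sizes is usually detected", {
  # substantia nigra T2* effect at n = 6 vs 5
  set.seed(44)
  hits <- replicate(1000, {
    a <- rnorm(6, 39.0, 2.11)
    b <- rnorm(5, 32.4, 2.98)
    compare_groups(a, b)$p_raw < 0.05
  })
  expect_gt(mean(hits), 0.5)
})

test_that("BH step-up matches the brute-force oracle and p.adjust", {
  set.seed(45)
  for (rep in 1:200) {
    m <- sample(1:12, 1)
    p <- round(runif(m), sample(c(1, 2, 3, 6), 1))  # rounding induces ties
    got <- bh_adjust(p, q = 0.05)
    oracle <- bh_brute(p, q = 0.05)
    expect_equal(got$p_adjusted, oracle$p_adjusted, tolerance = 1e-12)
    expect_identical(got$discovery, oracle$discovery)
    expect_equal(got$p_adjusted, p.adjust(p, method = "BH"),
                 tolerance = 1e-12)
    expect_true(all(got$p_adjusted >= p - 1e-15))
  }
  # worked example: exactly the two smallest survive at q = 0.05
  p8 <- c(0.001, 0.01, 0.02, 0.03, 0.04, 0.05, 0.2, 0.5)
  bh <- bh_adjust(p8, 0.05)
  expect_identical(bh$discovery, c(TRUE, TRUE, rep(FALSE, 6)))
  # all p = 1: nothing discovered, all adjusted at 1
  b1 <- bh_adjust(rep(1, 5), 0.05)
  expect_true(all(b1$p_adjusted == 1) && !any(b1$discovery))
  # single p: m = 1 identity
  bs <- bh_adjust(0.04, 0.05)
  expect_equal(bs$p_adjusted, 0.04)
  expect_true(bs$discovery)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("adding a smaller p never removes an existing discovery", {
  set.seed(46)
  for (rep in 1:50) {
    p <- runif(sample(3:10, 1))
    d1 <- bh_adjust(p, 0.05)$discovery
    d2 <- bh_adjust(c(min(p) / 2, p), 0.05)$discovery[-1]
    expect_true(all(d2 >= d1))
  }
})

test_that("cohort comparison corrects within families and is deterministic", {
  tab <- simulate_cohort(group_effect_spec(), seed = 47)
  cfg <- stats_config()
  res <- cohort_compare(tab, cfg)
  expect_s3_class(res, "cohort_comparison")
  expect_identical(nrow(res), nrow(default_group_effects()))
  # per-parameter families: adjusted p within each family match bh_adjust
  for (fam in unique(res$parameter)) {
    sel <- res$parameter == fam
    expect_equal(res$p_adjusted[sel], bh_adjust(res$p_raw[sel], cfg$q)$p_adjusted,
                 tolerance = 1e-12)
  }
  expect_true(all(res$p_adjusted >= res$p_raw - 1e-15))
  expect_true(all(res$discovery == (res$p_adjusted <= cfg$q)))
  # no hidden RNG
  expect_identical(tidy(cohort_compare(tab, cfg)), tidy(res))
  # single-cell table reduces to compare_groups with m = 1
  one <- dplyr::filter(tab, region == "striatum", parameter == "CBF")
  r1 <- cohort_compare(one, cfg)
  expect_equal(r1$p_adjusted, r1$p_raw)
  # missing group is fatal; an undersized cell is reported, not fatal
  expect_error(cohort_compare(dplyr::filter(tab, group == "wildtype"), cfg),
               "two groups")
  short <- dplyr::bind_rows(tab,
    tibble::tibble(animal_id = c("wt90", "wt91", "wt92", "mp90", "mp91"),
                   group = c("wildtype", "wildtype", "wildtype",
                             "mitopark", "mitopark"),
                   region = "extra", parameter = "T2*", value = 1:5,
                   units = "ms"))
  expect_warning(r2 <- cohort_compare(short, cfg), "fewer than")
  expect_true(is.na(r2$p_raw[r2$region == "extra"]))
})

test_that("null cohorts rarely produce any discovery per family", {
  # global null: both groups share the distribution; 7 regions x 4 parameters
  set.seed(48)
  regions <- paste0("r", 1:7)
  params <- c("T2*", "ADC", "FA", "CBF")
  cfg <- stats_config()
  n_rep <- 300
  any_disc <- matrix(FALSE, n_rep, length(params),
                     dimnames = list(NULL, params))
  for (r in seq_len(n_rep)) {
    cells <- expand.grid(region = regions, parameter = params,
                         stringsAsFactors = FALSE)
    tab <- purrr::map_dfr(seq_len(nrow(cells)), function(k)
      tibble::tibble(
        animal_id = c(sprintf("wt%02d", 1:9), sprintf("mp%02d", 1:6)),
        group = c(rep("wildtype", 9), rep("mitopark", 6)),
        region = cells$region[k], parameter = cells$parameter[k],
        value = rnorm(15)))
    res <- cohort_compare(tab, cfg)
    for (pp in params)
      any_disc[r, pp] <- any(res$discovery[res$parameter == pp])
  }
  expect_true(all(colMeans(any_disc) <= 0.10))
})

test_that("tidy, glance and autoplot work on comparison objects", {
  tab <- simulate_cohort(group_effect_spec(), seed = 49)
  res <- cohort_compare(tab)
  td <- tidy(res)
  expect_false(inherits(td, "cohort_comparison"))
  gl <- glance(res)
  expect_identical(gl$n_tests, sum(!is.na(res$p_raw)))
  expect_identical(gl$n_discoveries, sum(res$discovery, na.rm = TRUE))
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})

test_that("discrimination index is the novel-object time fraction", {
  expect_equal(discrimination_index(30, 30), 50)
  expect_equal(discrimination_index(45, 15), 75)
  expect_equal(discrimination_index(0, 20), 0)
  expect_equal(discrimination_index(c(30, 45), c(30, 15)), c(50, 75))
  expect_error(discrimination_index(0, 0), "zero")
  expect_error(discrimination_index(-1, 5), "non-negative")
})
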
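test_that("default phantom has 10 nonempty disjoint named regions", {
  ph <- build_phantom(phantom_spec())
  labs <- ph$label_map$labels
  present <- sort(unique(labs[labs > 0]))
  expect_identical(present, 1:10)
  expect_length(ph$label_map$names, 10L)
  # disjoint by construction: one label per voxel; ventricles inside brain
  expect_true(all(region_mask(ph$label_map, "ventricles") <= ph$brain_mask))
  # geometry is seed-independent
  ph2 <- build_phantom(phantom_spec(seed = 999L))
  expect_identical(ph2$label_map$labels, labs)
})

test_that("truth maps are piecewise constant at the spec values", {
  ph <- small_phantom()
  truth <- ph$spec$truth
  for (k in seq_len(nrow(truth))) {
    sel <- region_mask(ph$label_map, truth$region[k])
    expect_true(all(ph$t2star$data[sel] == truth$t2star_ms[k]))
    expect_true(all(ph$cbf$data[sel] == truth$cbf[k]))
  }
  # wild-type substantia nigra default is 39.0 ms
  sn <- region_mask(ph$label_map, "substantia nigra")
  expect_equal(unique(ph$t2star$data[sn]), 39.0)
  # ventricles: high isotropic ADC, no perfusion
  vt <- region_mask(ph$label_map, "ventricles")
  expect_equal(unique(ph$cbf$data[vt]), 0)
  lam <- matrix(ph$tensor$eigenvalues, ncol = 3)[vt, ]
  expect_equal(unname(rowMeans(lam)), rep(2.2e-3, sum(vt)), tolerance = 1e-12)
  expect_equal(max(abs(lam[, 1] - lam[, 3])), 0, tolerance = 1e-15)
})

test_that("a region too small for the grid raises an error", {
  expect_error(build_phantom(phantom_spec(shape = c(8, 8, 8))), "empty|small")
})

test_that("gradient schemes are unit-norm with full-rank designs", {
  for (n in c(6L, 12L, 30L)) {
    g <- make_gradient_scheme(n)
    expect_equal(sqrt(rowSums(g^2)), rep(1, n), tolerance = 1e-12)
    expect_identical(qr(build_design_matrix(1200, g))$rank, 6L)
  }
  expect_error(make_gradient_scheme(5), "6")
  # deterministic unless jitter requested
  expect_identical(make_gradient_scheme(30), make_gradient_scheme(30))
  expect_false(identical(make_gradient_scheme(30),
                         make_gradient_scheme(30, seed = 1, jitter = TRUE)))
})

test_that("DWI simulator follows the exponential signal model", {
  # isotropic D = 0.7e-3, S0 = 100, b = 1200: every DW volume at
  # 100*exp(-0.84) =~ 43.17
  sh <- c(3, 3, 2)
  tensors <- array(0, dim = c(sh, 6))
  tensors[, , , 1:3] <- 0.7e-3
  eig <- array(0.7e-3, dim = c(sh, 3))
  tf <- tensor_field(tensors, eig, array(TRUE, sh), c(1, 1, 1))
  s0 <- array(100, dim = sh)
  g <- make_gradient_scheme(8)
  dwi <- simulate_dwi(tf, s0, b = 1200, directions = g)
  expect_equal(as.vector(dwi$data[, , , 1]), rep(100, prod(sh)))
  expect_equal(as.vector(dwi$data[, , , -1]),
               rep(100 * exp(-0.84), prod(sh) * 8), tolerance = 1e-9)
  # b = 0 with noise 0 equals S0 exactly; same seed reproduces noise
  n1 <- simulate_dwi(tf, s0, 1200, g, noise_sd = 1, seed = 11)
  n2 <- simulate_dwi(tf, s0, 1200, g, noise_sd = 1, seed = 11)
  expect_identical(n1$data, n2$data)
  expect_error(simulate_dwi(tf, s0, -5, g), "non-negative")
  expect_error(simulate_dwi(tf, s0, 1200, g * 2), "unit")
})

test_that("multi-echo simulator follows mono-exponential decay", {
  sh <- c(2, 2, 2)
  t2 <- array(30, dim = sh)
  s0 <- array(100, dim = sh)
  me <- simulate_multiecho(t2, s0, echo_times = c(2.4, 5.7))
  expect_equal(as.vector(me$data[, , , 1]), rep(100 * exp(-2.4 / 30), 8),
               tolerance = 1e-12)
  # TE = 0 returns S0 exactly
  me0 <- simulate_multiecho(t2, s0, echo_times = c(0, 1))
  expect_equal(as.vector(me0$data[, , , 1]), rep(100, 8))
  expect_error(simulate_multiecho(array(-1, sh), s0, c(1, 2)), "T2\\*")
  expect_error(simulate_multiecho(t2, s0, c(2, 1)), "increasing")
})

test_that("ASL simulator inverts the CBF model and interleaves frames", {
  sh <- c(2, 2, 1)
  cbf <- array(1.0169491525423728, dim = sh)
  sc <- array(1, dim = sh)
  out <- simulate_asl(cbf, sc, asl_constants(), n_reps = 6)
  expect_identical(dim(out$data)[4], 6L)
  # control frames carry Sc, label frames the inverted signal 0.95
  expect_equal(as.vector(out$data[, , , c(1, 3, 5)]), rep(1, 12))
  expect_equal(as.vector(out$data[, , , c(2, 4, 6)]), rep(0.95, 12),
               tolerance = 1e-12)
  # zero perfusion: label equals control
  out0 <- simulate_asl(array(0, sh), sc, n_reps = 2)
  expect_equal(out0$data[, , , 2], out0$data[, , , 1])
  # 200 repetitions -> 100 control + 100 label
  big <- simulate_asl(array(0.5, c(1, 1, 1)), array(1, c(1, 1, 1)),
                      n_reps = 200)
  expect_identical(dim(big$data)[4], 200L)
  expect_error(simulate_asl(cbf, sc, n_reps = 3), "even")
  # CBF so high the label signal would be nonpositive
  expect_error(simulate_asl(array(40, sh), sc, n_reps = 2), "nonpositive")
})

test_that("cohort simulator matches its effect spec", {
  eff <- group_effect_spec()
  tab <- simulate_cohort(eff, seed = 3)
  expect_identical(dplyr::n_distinct(tab$animal_id[tab$group == "wildtype"]), 9L)
  expect_identical(dplyr::n_distinct(tab$animal_id[tab$group == "mitopark"]), 6L)
  expect_identical(nrow(tab), nrow(eff$table) * 15L)
  # law of large numbers at n = 10,000 per group: SN T2* mean within 0.1
  big <- group_effect_spec(
    table = dplyr::filter(default_group_effects(),
                          region == "substantia nigra", parameter == "T2*"),
    n_wildtype = 10000L, n_mitopark = 10000L)
  bt <- simulate_cohort(big, seed = 4)
  expect_lt(abs(mean(bt$value[bt$group == "wildtype"]) - 39.0), 0.1)
  expect_lt(abs(mean(bt$value[bt$group == "mitopark"]) - 32.4), 0.1)
  # invariant enforcement
  bad <- default_group_effects()
  bad$sd_wildtype[1] <- 0
  expect_error(group_effect_spec(table = bad), "positive")
  expect_error(group_effect_spec(n_mitopark = 1L), "at least 2")
})

test_that("estimator bias shrinks monotonically over a decreasing noise ladder", {
  sh <- c(10, 10, 10)
  t2 <- array(30, dim = sh)
  s0 <- array(100, dim = sh)
  te <- echo_schedule()
  bias <- sapply(c(4, 1, 0.25), function(sd) {
    me <- simulate_multiecho(t2, s0, te, noise_sd = sd, seed = 5)
    fit <- fit_t2star(me, te)
    abs(median(fit$t2star$data[fit$valid]) - 30)
  })
  expect_true(all(diff(bias) < 0))
})
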
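#' Default per-region ground truth for the digital mouse-brain phantom
#'
#' One row per region with the quantitative values the phantom plants:
#' T2* (ms), ADC (10^-3 mm^2/s), fractional anisotropy, CBF (mL/g/min),
#' equilibrium signal S0 (a.u.) and the principal diffusion direction.
#' Gray-matter values follow published wild-type mouse measurements at 7 T
#' (T2* 32-47 ms, ADC ~0.7-0.8 x 10^-3 mm^2/s, CBF ~0.8-1.2 mL/g/min);
#' the corpus callosum carries white-matter anisotropy (FA ~0.45), and the
#' ventricles carry free-water diffusivity (2.2 x 10^-3 mm^2/s), a long T2*
#' and no perfusion.
#'
#' @return A tibble with columns `label`, `region`, `t2star_ms`, `adc`,
#'   `fa`, `cbf`, `s0`, `dir_x`, `dir_y`, `dir_z`.
#' @export
region_truth <- function() {
  tab <- tibble::tribble(
    ~label, ~region,                ~t2star_ms, ~adc,  ~fa,  ~cbf, ~dir,
    1L, "substantia nigra",     39.0, 0.741, 0.35, 1.03, c(1, 1, 1),
    2L, "striatum",             43.0, 0.706, 0.15, 0.99, c(0, 1, 0),
    3L, "thalamus",             38.6, 0.736, 0.15, 1.16, c(0, 1, 1),
    4L, "motor cortex",         42.0, 0.774, 0.15, 1.06, c(1, 0, 0),
    5L, "somatosensory cortex", 40.4, 0.732, 0.15, 0.98, c(0, 0, 1),
    6L, "visual cortex",        40.0, 0.761, 0.15, 0.95, c(1, 0, 1),
    7L, "hippocampus",          47.0, 0.818, 0.15, 0.81, c(1, 1, 0),
    8L, "corpus callosum",      36.0, 0.700, 0.45, 0.60, c(1, 0, 0),
    9L, "ventricles",           80.0, 2.200, 0.00, 0.00, c(0, 0, 1),
    10L, "whole brain",         40.0, 0.720, 0.10, 1.00, c(0, 1, 0)
  )
  tab$s0 <- 100
  tab$dir <- purrr::map(tab$dir, ~ .x / sqrt(sum(.x^2)))
  tab$dir_x <- purrr::map_dbl(tab$dir, 1)
  tab$dir_y <- purrr::map_dbl(tab$dir, 2)
  tab$dir_z <- purrr::map_dbl(tab$dir, 3)
  tab$dir <- NULL
  tab
}

#' Phantom specification
#'
#' Defines the grid, voxel size, per-region ground truth and noise level of
#' the digital phantom. The default 64 x 64 x 16 grid at 0.2 x 0.2 x 1.0 mm
#' matches a 12.8 mm in-plane field of view on a 64 matrix with 1 mm slices.
#'
#' @param shape integer length-3 grid shape.
#' @param voxel_dims voxel edge lengths in mm.
#' @param truth per-region truth table as from [region_truth()]; any subset
#'   of columns may be overridden.
#' @param noise_sd additive Gaussian noise SD (a.u.) used by the simulators.
#' @param seed integer RNG seed used by the simulators (geometry itself is
#'   seed-independent).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 16L),
                         voxel_dims = c(0.2, 0.2, 1.0),
                         truth = region_truth(),
                         noise_sd = 0,
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L))
  if (any(truth$t2star_ms <= 0)) stop("T2* truth must be positive", call. = FALSE)
  if (any(truth$adc < 0)) stop("diffusivities must be non-negative", call. = FALSE)
  if (any(truth$fa < 0 | truth$fa >= 1)) stop("FA truth must lie in [0, 1)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(shape = shape, voxel_dims = as.numeric(voxel_dims),
                 truth = truth, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Fractional (0-1) box extents of each region on the reference grid; the
# boxes are pairwise disjoint in (x, y) and are intersected with the brain
# ellipsoid at build time.
phantom_boxes <- function() {
  list(
    `1` = list(x = c(0.422, 0.547), y = c(0.203, 0.297), z = c(0.3125, 0.6875)),
    `2` = list(x = c(0.234, 0.359), y = c(0.516, 0.672), z = c(0.3125, 0.6875)),
    `3` = list(x = c(0.641, 0.766), y = c(0.516, 0.672), z = c(0.3125, 0.6875)),
    `4` = list(x = c(0.359, 0.641), y = c(0.766, 0.859), z = c(0.3125, 0.6875)),
    `5` = list(x = c(0.109, 0.234), y = c(0.609, 0.766), z = c(0.3125, 0.6875)),
    `6` = list(x = c(0.359, 0.641), y = c(0.109, 0.203), z = c(0.3125, 0.6875)),
    `7` = list(x = c(0.109, 0.234), y = c(0.328, 0.484), z = c(0.3125, 0.6875)),
    `8` = list(x = c(0.734, 0.859), y = c(0.328, 0.484), z = c(0.3125, 0.6875)),
    # bilateral lateral ventricles, ~1-2% of the brain volume
    `9` = list(x = c(0.391, 0.484), y = c(0.391, 0.484), z = c(0.375, 0.625)),
    `9b` = list(x = c(0.516, 0.609), y = c(0.391, 0.484), z = c(0.375, 0.625))
  )
}

frac_to_idx <- function(fr, n) {
  i0 <- floor(fr[1] * n + 1e-9) + 1L
  i1 <- floor(fr[2] * n + 1e-9)
  if (i1 < i0) integer(0) else i0:i1
}

# Prolate eigenvalue triple with mean diffusivity `md` and anisotropy `fa`:
# lambda_1 = md (1 + 2 delta), lambda_23 = md (1 - delta),
# delta = fa / sqrt(3 - 2 fa^2).
prolate_eigenvalues <- function(md, fa) {
  delta <- fa / sqrt(3 - 2 * fa^2)
  c(md * (1 + 2 * delta), md * (1 - delta), md * (1 - delta))
}

# Rotation taking e1 to the unit vector v (columns are an orthonormal basis).
basis_from_dir <- function(v) {
  v <- v / sqrt(sum(v^2))
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u2 <- ref - sum(ref * v) * v
  u2 <- u2 / sqrt(sum(u2^2))
  u3 <- c(v[2] * u2[3] - v[3] * u2[2],
          v[3] * u2[1] - v[1] * u2[3],
          v[1] * u2[2] - v[2] * u2[1])
  cbind(v, u2, u3, deparse.level = 0)
}

#' Build the labeled digital phantom and its ground-truth maps
#'
#' Geometry is deterministic (seed-independent): an ellipsoidal brain on the
#' requested grid with disjoint box-shaped regions intersected with the
#' ellipsoid, including bilateral high-ADC ventricles with no perfusion.
#' Every truth map is piecewise constant at the spec's per-region value.
#'
#' @param spec a [phantom_spec].
#' @return An object of class `mouse_phantom`: a list with `label_map`
#'   ([label_map]), `brain_mask` (logical array), truth maps `cbf`, `t2star`,
#'   `s0` ([vol_image]s) and `tensor` ([tensor_field]), plus the `spec`.
#' @export
build_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  sh <- spec$shape
  cx <- (sh + 1) / 2
  semi <- 0.4375 * sh
  xg <- ((1:sh[1]) - cx[1]) / semi[1]
  yg <- ((1:sh[2]) - cx[2]) / semi[2]
  zg <- ((1:sh[3]) - cx[3]) / semi[3]
  ell <- outer(outer(xg^2, yg^2, `+`), zg^2, `+`) <= 1
  labels <- array(0L, dim = sh)
  labels[ell] <- 10L  # unallocated brain tissue
  for (nm in names(phantom_boxes())) {
    box <- phantom_boxes()[[nm]]
    lab <- as.integer(sub("b$", "", nm))
    ix <- frac_to_idx(box$x, sh[1]); iy <- frac_to_idx(box$y, sh[2])
    iz <- frac_to_idx(box$z, sh[3])
    sel <- array(FALSE, dim = sh); sel[ix, iy, iz] <- TRUE
    sel <- sel & ell
    if (!any(sel)) stop("region ", lab, " has an empty voxel set on this grid",
                        call. = FALSE)
    labels[sel] <- lab
  }
  truth <- spec$truth
  counts <- tabulate(labels[labels > 0L], nbins = max(truth$label))
  if (any(counts[truth$label] == 0L))
    stop("region too small for grid: ",
         paste(truth$region[counts[truth$label] == 0L], collapse = ", "),
         call. = FALSE)
  nm <- stats::setNames(truth$region, as.character(truth$label))
  lm <- label_map(labels, nm, spec$voxel_dims)

  lut <- function(col) {
    v <- numeric(max(truth$label) + 1L)
    v[truth$label + 1L] <- truth[[col]]
    array(v[labels + 1L], dim = sh)
  }
  cbf <- vol_image(lut("cbf"), spec$voxel_dims, units = "mL/g/min")
  t2s <- vol_image(lut("t2star_ms"), spec$voxel_dims, units = "ms")
  s0 <- vol_image(lut("s0"), spec$voxel_dims, units = "a.u.")

  tensors <- array(0, dim = c(sh, 6L))
  eig <- array(0, dim = c(sh, 3L))
  for (k in seq_len(nrow(truth))) {
    lam <- prolate_eigenvalues(truth$adc[k] * 1e-3, truth$fa[k])
    R <- basis_from_dir(c(truth$dir_x[k], truth$dir_y[k], truth$dir_z[k]))
    D <- R %*% diag(lam) %*% t(R)
    d6 <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
    sel <- labels == truth$label[k]
    for (j in 1:6) {
      comp <- tensors[, , , j]; comp[sel] <- d6[j]; tensors[, , , j] <- comp
    }
    for (j in 1:3) {
      comp <- eig[, , , j]; comp[sel] <- lam[j]; eig[, , , j] <- comp
    }
  }
  tf <- tensor_field(tensors, eigenvalues = eig, valid = labels > 0L,
                     voxel_dims = spec$voxel_dims)
  structure(list(label_map = lm, brain_mask = labels > 0L,
                 cbf = cbf, t2star = t2s, s0 = s0, tensor = tf, spec = spec),
            class = "mouse_phantom")
}

#' @export
print.mouse_phantom <- function(x, ...) {
  cat("<mouse_phantom> ", paste(x$spec$shape, collapse = " x "),
      " grid, ", sum(x$brain_mask), " brain voxels, ",
      length(x$label_map$names), " regions\n", sep = "")
  invisible(x)
}

#' Deterministic diffusion gradient scheme
#'
#' Unit direction vectors laid out on a golden-angle (Fibonacci) spherical
#' spiral -- a well-conditioned, reproducible design whose tensor design
#' matrix has full column rank for any `n >= 6`. An optional seeded jitter
#' perturbs the directions slightly.
#'
#' @param n number of directions, at least 6.
#' @param seed RNG seed, used only when `jitter = TRUE`.
#' @param jitter add small seeded angular perturbations.
#' @return An `n x 3` matrix of unit row vectors.
#' @export
make_gradient_scheme <- function(n, seed = NULL, jitter = FALSE) {
  if (n < 6) stop("at least 6 directions are needed to determine the tensor",
                  call. = FALSE)
  i <- seq_len(n)
  # slightly asymmetric latitude ladder: the symmetric (2i-1)/n - 1 ladder
  # degenerates to a rank-5 design exactly at n = 6
  z <- pmin(pmax((2 * i - 0.5) / n - 1, -0.999), 0.999)
  golden <- (1 + sqrt(5)) / 2
  phi <- 2 * pi * i * (1 - 1 / golden)
  r <- sqrt(pmax(0, 1 - z^2))
  g <- cbind(r * cos(phi), r * sin(phi), z)
  if (jitter) {
    if (!is.null(seed)) set.seed(seed)
    g <- g + matrix(stats::rnorm(3 * n, sd = 0.02), n, 3)
  }
  g <- g / sqrt(rowSums(g^2))
  A <- build_design_matrix(1, g)
  if (qr(A)$rank < 6L)
    stop("gradient scheme yields a rank-deficient tensor design", call. = FALSE)
  g
}

as_data_array <- function(x) if (inherits(x, "vol_image")) x$data else x

add_noise <- function(signal, noise_sd, seed, rician) {
  if (noise_sd <= 0) return(signal)
  if (!is.null(seed)) set.seed(seed)
  if (rician) {
    re <- signal + stats::rnorm(length(signal), sd = noise_sd)
    im <- stats::rnorm(length(signal), sd = noise_sd)
    array(sqrt(re^2 + im^2), dim = dim(signal))
  } else {
    signal + array(stats::rnorm(length(signal), sd = noise_sd), dim = dim(signal))
  }
}

#' Simulate a diffusion-weighted acquisition from a ground-truth tensor field
#'
#' Signal model: `S_i = S0 * exp(-b * g_i' D g_i)` per direction, with the
#' unweighted (b = 0) image first. Noise is additive zero-mean Gaussian by
#' default; set `rician = TRUE` for magnitude (Rician) noise.
#'
#' @param tensor a [tensor_field] of ground-truth tensors (mm^2/s).
#' @param s0 equilibrium signal map ([vol_image] or array, a.u.).
#' @param b diffusion weighting in s/mm^2.
#' @param directions `n x 3` matrix of unit vectors, e.g. from
#'   [make_gradient_scheme()].
#' @param noise_sd additive noise SD (a.u.).
#' @param seed RNG seed.
#' @param rician use Rician (magnitude) noise instead of Gaussian.
#' @param voxel_dims voxel dimensions of the output (defaults to the tensor's).
#' @return A 4-D [vol_image] with `1 + n` volumes (b = 0 first).
#' @export
simulate_dwi <- function(tensor, s0, b = 1200, directions, noise_sd = 0,
                         seed = NULL, rician = FALSE, voxel_dims = NULL) {
  stopifnot(inherits(tensor, "tensor_field"))
  if (b < 0) stop("b must be non-negative", call. = FALSE)
  if (any(abs(sqrt(rowSums(directions^2)) - 1) > 1e-9))
    stop("directions must be unit vectors", call. = FALSE)
  s0a <- as_data_array(s0)
  sh <- dim(s0a)
  nvox <- prod(sh)
  D6 <- matrix(tensor$tensors, nrow = nvox, ncol = 6L)
  A <- build_design_matrix(b, directions)      # n x 6
  atten <- exp(-(D6 %*% t(A)))                 # nvox x n
  sig <- cbind(as.vector(s0a), as.vector(s0a) * atten)
  sig[!tensor$valid, ] <- 0
  out <- array(sig, dim = c(sh, nrow(directions) + 1L))
  out <- add_noise(out, noise_sd, seed, rician)
  vol_image(out, voxel_dims %||% tensor$voxel_dims, units = "a.u.")
}

#' Simulate a multi-echo gradient-echo acquisition
#'
#' Mono-exponential decay `S(TE) = S0 * exp(-TE / T2*)` per voxel, sampled
#' at the given echo times.
#'
#' @param t2star ground-truth T2* map in ms ([vol_image] or array); voxels
#'   with T2* = 0 are treated as background (zero signal).
#' @param s0 equilibrium signal map (a.u.).
#' @param echo_times strictly increasing echo times in ms, e.g. from
#'   [echo_schedule()].
#' @param noise_sd additive Gaussian noise SD (a.u.).
#' @param seed RNG seed.
#' @param rician use Rician noise.
#' @param voxel_dims voxel dimensions of the output.
#' @return A 4-D [vol_image] over echoes.
#' @export
simulate_multiecho <- function(t2star, s0, echo_times, noise_sd = 0,
                               seed = NULL, rician = FALSE, voxel_dims = NULL) {
  t2a <- as_data_array(t2star)
  s0a <- as_data_array(s0)
  if (any(t2a < 0)) stop("nonpositive T2* in truth map", call. = FALSE)
  if (is.unsorted(echo_times, strictly = TRUE) || any(echo_times < 0))
    stop("echo_times must be non-negative and strictly increasing", call. = FALSE)
  rate <- ifelse(t2a > 0, 1 / t2a, 0)
  sig <- vapply(echo_times,
                function(te) as.vector(ifelse(t2a > 0, s0a * exp(-te * rate), 0)),
                numeric(length(t2a)))
  out <- array(sig, dim = c(dim(t2a), length(echo_times)))
  out <- add_noise(out, noise_sd, seed, rician)
  vd <- voxel_dims %||%
    (if (inherits(t2star, "vol_image")) t2star$voxel_dims else c(1, 1, 1))
  vol_image(out, vd, units = "a.u.")
}

#' Simulate an interleaved control/label ASL acquisition
#'
#' The label signal is obtained by inverting the CBF quantification model,
#' so quantifying the noise-free series recovers the truth CBF exactly:
#' with `beta = 2 alpha - 1` and `c = CBF * T1 / (60 lambda)`,
#' `S_L = S_c (1 - c) / (1 + beta c)`. Frames alternate control, label,
#' control, label, ... (first frame control).
#'
#' @param cbf ground-truth CBF map in mL/g/min ([vol_image] or array).
#' @param sc control (baseline) signal map (a.u.).
#' @param constants an [asl_constants()] object.
#' @param n_reps total number of frames (even; half control, half label).
#' @param noise_sd additive Gaussian noise SD (a.u.).
#' @param seed RNG seed.
#' @param voxel_dims voxel dimensions of the output.
#' @return A 4-D [vol_image] with `n_reps` interleaved frames.
#' @export
simulate_asl <- function(cbf, sc, constants = asl_constants(), n_reps = 200,
                         noise_sd = 0, seed = NULL, voxel_dims = NULL) {
  if (n_reps %% 2 != 0 || n_reps < 2)
    stop("n_reps must be an even number of interleaved frames", call. = FALSE)
  cbfa <- as_data_array(cbf)
  sca <- as_data_array(sc)
  beta <- 2 * constants$alpha - 1
  cc <- cbfa * constants$t1 / (60 * constants$lambda_bp)
  sl <- sca * (1 - cc) / (1 + beta * cc)
  if (any(sl <= 0 & sca > 0))
    stop("truth CBF implies a nonpositive label signal", call. = FALSE)
  sh <- dim(cbfa)
  out <- array(0, dim = c(sh, n_reps))
  idx <- seq_len(n_reps)
  frame <- function(i) if (i %% 2 == 1) sca else sl
  for (i in idx) out[, , , i] <- frame(i)
  out <- add_noise(out, noise_sd, seed, rician = FALSE)
  vd <- voxel_dims %||%
    (if (inherits(cbf, "vol_image")) cbf$voxel_dims else c(1, 1, 1))
  vol_image(out, vd, units = "a.u.")
}

#' Two-group effect structure for cohort simulation
#'
#' Per (region, parameter): wild-type and affected (MitoPark) means and SDs,
#' plus group sizes. The default table encodes the study conditions this
#' package's group statistics are exercised under: T2* reduced in substantia
#' nigra and striatum, ADC reduced in most gray-matter regions, slightly
#' (non-significantly) reduced CBF, enlarged ventricles and reduced brain
#' tissue volume in the affected group, with 9 wild-type and 6 affected
#' animals.
#'
#' @param table effect table; a tibble with columns `region`, `parameter`,
#'   `units`, `mean_wildtype`, `sd_wildtype`, `mean_mitopark`, `sd_mitopark`,
#'   `significant`.
#' @param n_wildtype,n_mitopark group sizes (each at least 2).
#' @return An object of class `group_effect_spec`.
#' @export
group_effect_spec <- function(table = default_group_effects(),
                              n_wildtype = 9L, n_mitopark = 6L) {
  if (n_wildtype < 2 || n_mitopark < 2)
    stop("group sizes must be at least 2", call. = FALSE)
  if (any(table$sd_wildtype <= 0) || any(table$sd_mitopark <= 0))
    stop("group SDs must be positive", call. = FALSE)
  structure(list(table = table, n_wildtype = as.integer(n_wildtype),
                 n_mitopark = as.integer(n_mitopark)),
            class = "group_effect_spec")
}

#' Default two-group effect table
#'
#' Wild-type and affected mean +/- SD per region and parameter; `significant`
#' marks the cells where the groups genuinely differ in the emulated study.
#'
#' @return A tibble.
#' @export
default_group_effects <- function() {
  t2 <- tibble::tribble(
    ~region, ~mean_wildtype, ~sd_wildtype, ~mean_mitopark, ~sd_mitopark, ~significant,
    "substantia nigra",     39.0, 2.11, 32.4, 2.98, TRUE,
    "striatum",             43.0, 2.43, 38.5, 2.59, TRUE,
    "thalamus",             38.6, 1.89, 36.1, 4.18, FALSE,
    "motor cortex",         42.0, 1.96, 38.4, 4.42, FALSE,
    "somatosensory cortex", 40.4, 3.80, 38.2, 3.75, FALSE,
    "hippocampus",          47.0, 4.54, 42.3, 5.29, FALSE
  )
  t2$parameter <- "T2*"; t2$units <- "ms"
  adc <- tibble::tribble(
    ~region, ~mean_wildtype, ~sd_wildtype, ~mean_mitopark, ~sd_mitopark, ~significant,
    "substantia nigra",     0.741, 0.016, 0.722, 0.011, TRUE,
    "striatum",             0.706, 0.019, 0.686, 0.011, FALSE,
    "thalamus",             0.736, 0.019, 0.708, 0.010, TRUE,
    "motor cortex",         0.774, 0.019, 0.736, 0.022, TRUE,
    "somatosensory cortex", 0.732, 0.019, 0.692, 0.009, TRUE,
    "visual cortex",        0.761, 0.047, 0.727, 0.031, FALSE,
    "hippocampus",          0.818, 0.069, 0.807, 0.038, FALSE
  )
  adc$parameter <- "ADC"; adc$units <- "1e-3 mm^2/s"
  cbf <- tibble::tribble(
    ~region, ~mean_wildtype, ~sd_wildtype, ~mean_mitopark, ~sd_mitopark, ~significant,
    "substantia nigra",     1.03, 0.13, 0.91, 0.20, FALSE,
    "striatum",             0.99, 0.14, 0.87, 0.11, FALSE,
    "thalamus",             1.16, 0.13, 1.01, 0.21, FALSE,
    "motor cortex",         1.06, 0.17, 0.87, 0.16, FALSE,
    "somatosensory cortex", 0.98, 0.12, 0.91, 0.28, FALSE,
    "visual cortex",        0.95, 0.14, 0.86, 0.20, FALSE,
    "hippocampus",          0.81, 0.12, 0.70, 0.15, FALSE
  )
  cbf$parameter <- "CBF"; cbf$units <- "mL/g/min"
  vol <- tibble::tribble(
    ~region, ~mean_wildtype, ~sd_wildtype, ~mean_mitopark, ~sd_mitopark, ~significant,
    "ventricles",  33.4, 2.7, 38.5, 4.9, TRUE,
    "whole brain", 292,  10,  262,  12,  TRUE
  )
  vol$parameter <- "volume"; vol$units <- "mm^3"
  out <- dplyr::bind_rows(t2, adc, cbf, vol)
  out[, c("region", "parameter", "units", "mean_wildtype", "sd_wildtype",
          "mean_mitopark", "sd_mitopark", "significant")]
}

#' Simulate a two-group cohort table
#'
#' Draws one value per animal, region and parameter from
#' `Normal(group mean, group SD)` per the effect spec, independently across
#' cells, and returns the tidy cohort table.
#'
#' @param effects a [group_effect_spec()].
#' @param seed RNG seed.
#' @return A tibble with columns `animal_id`, `group`, `region`, `parameter`,
#'   `value`, `units`.
#' @export
simulate_cohort <- function(effects = group_effect_spec(), seed = NULL) {
  stopifnot(inherits(effects, "group_effect_spec"))
  if (!is.null(seed)) set.seed(seed)
  tab <- effects$table
  ids_wt <- sprintf("wt%02d", seq_len(effects$n_wildtype))
  ids_mp <- sprintf("mp%02d", seq_len(effects$n_mitopark))
  draw <- function(k) {
    dplyr::bind_rows(
      tibble::tibble(animal_id = ids_wt, group = "wildtype",
                     value = stats::rnorm(length(ids_wt), tab$mean_wildtype[k],
                                          tab$sd_wildtype[k])),
      tibble::tibble(animal_id = ids_mp, group = "mitopark",
                     value = stats::rnorm(length(ids_mp), tab$mean_mitopark[k],
                                          tab$sd_mitopark[k]))
    ) |>
      dplyr::mutate(region = tab$region[k], parameter = tab$parameter[k],
                    units = tab$units[k])
  }
  purrr::map_dfr(seq_len(nrow(tab)), draw)[
    , c("animal_id", "group", "region", "parameter", "value", "units")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
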
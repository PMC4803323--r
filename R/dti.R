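#' Per-voxel diffusion tensor field
#'
#' Stores the six unique elements of the symmetric tensor
#' (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz; mm^2/s) on the image grid together with
#' eigenvalues sorted descending and a validity mask.
#'
#' @param tensors numeric array `(x, y, z, 6)`.
#' @param eigenvalues numeric array `(x, y, z, 3)`, sorted descending along
#'   the 4th axis.
#' @param valid logical 3-D array of voxels with a trustworthy fit.
#' @param voxel_dims voxel edge lengths in mm.
#' @param flagged logical 3-D array of voxels kept but flagged (e.g.
#'   noise-induced negative eigenvalues).
#' @return An object of class `tensor_field`.
#' @export
tensor_field <- function(tensors, eigenvalues, valid, voxel_dims,
                         flagged = NULL) {
  stopifnot(length(dim(tensors)) == 4L, dim(tensors)[4] == 6L,
            length(dim(eigenvalues)) == 4L, dim(eigenvalues)[4] == 3L)
  if (is.null(flagged)) flagged <- array(FALSE, dim = dim(valid))
  structure(list(tensors = tensors, eigenvalues = eigenvalues, valid = valid,
                 flagged = flagged, voxel_dims = as.numeric(voxel_dims)),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("<tensor_field> ", paste(dim(x$valid), collapse = " x "),
      " voxels, ", sum(x$valid), " valid\n", sep = "")
  invisible(x)
}

#' Design matrix of the log-linear tensor model
#'
#' Row i is `b * (gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz)` for
#' direction `g_i`, so that `y_i = ln(S0 / S_i) = row_i . d` with
#' `d = (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)`.
#'
#' @param b diffusion weighting in s/mm^2.
#' @param directions `n x 3` matrix of unit vectors.
#' @return An `n x 6` matrix.
#' @export
build_design_matrix <- function(b, directions) {
  g <- as.matrix(directions)
  if (ncol(g) != 3L) stop("directions must be an n x 3 matrix", call. = FALSE)
  if (any(abs(sqrt(rowSums(g^2)) - 1) > 1e-9))
    stop("directions must be unit vectors", call. = FALSE)
  b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
            2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
}

# analytic eigenvalues would also work for symmetric 3x3, but base eigen()
# at ~1e4 brain voxels is fast enough and numerically safer near degeneracy
eigenvalues_6 <- function(d6) {
  M <- matrix(c(d6[1], d6[4], d6[5],
                d6[4], d6[2], d6[6],
                d6[5], d6[6], d6[3]), 3, 3)
  eigen(M, symmetric = TRUE, only.values = TRUE)$values
}

#' Fit the diffusion tensor voxelwise
#'
#' Unweighted log-linear least squares: per voxel, solves
#' `ln(S0/S_i) = b g_i' D g_i` for the six tensor elements across
#' directions, then eigen-decomposes and sorts eigenvalues descending.
#' Voxels with any nonpositive signal (b = 0 or diffusion-weighted) are
#' invalidated. Noise-induced negative eigenvalues are kept (and the voxel
#' flagged); [fa_from_eigenvalues()] clamps them at zero so FA stays in
#' `[0, 1]`.
#'
#' @param dwi 4-D [vol_image]; first volume is the b = 0 image, remaining
#'   volumes follow `directions` in order.
#' @param b diffusion weighting in s/mm^2 (> 0).
#' @param directions `n x 3` unit-vector matrix.
#' @param mask logical brain mask.
#' @return A [tensor_field].
#' @export
fit_tensor <- function(dwi, b = 1200, directions, mask = NULL) {
  stopifnot(inherits(dwi, "vol_image"))
  d <- dim(dwi$data)
  if (length(d) != 4L) stop("expected a 4-D DWI series", call. = FALSE)
  n <- nrow(directions)
  if (d[4] != n + 1L)
    stop("series must hold 1 b=0 volume plus one per direction", call. = FALSE)
  if (b <= 0) stop("b must be positive", call. = FALSE)
  A <- build_design_matrix(b, directions)
  if (qr(A)$rank < 6L) stop("rank-deficient tensor design matrix", call. = FALSE)
  sh <- d[1:3]
  nvox <- prod(sh)
  if (is.null(mask)) mask <- array(TRUE, dim = sh)
  S <- matrix(dwi$data, nrow = nvox, ncol = d[4])
  usable <- as.vector(mask) & apply(S > 0, 1, all) & apply(is.finite(S), 1, all)

  tensors <- array(NaN, dim = c(sh, 6L))
  eig <- array(NaN, dim = c(sh, 3L))
  valid <- array(FALSE, dim = sh)
  flagged <- array(FALSE, dim = sh)
  if (any(usable)) {
    Y <- log(S[usable, 1]) - log(S[usable, 2:(n + 1), drop = FALSE])  # nvox x n
    # least squares for all usable voxels at once: D6' = (A'A)^-1 A' Y'
    D6 <- t(solve(crossprod(A), crossprod(A, t(Y))))                  # nvox x 6
    lam <- t(apply(D6, 1, eigenvalues_6))                             # nvox x 3
    vox <- which(usable)
    for (j in 1:6) {
      comp <- tensors[, , , j]; comp[vox] <- D6[, j]; tensors[, , , j] <- comp
    }
    for (j in 1:3) {
      comp <- eig[, , , j]; comp[vox] <- lam[, j]; eig[, , , j] <- comp
    }
    valid[vox] <- TRUE
    flagged[vox] <- lam[, 3] < 0
  }
  tensor_field(tensors, eig, valid, dwi$voxel_dims, flagged = flagged)
}

eigs_as_matrix <- function(l1, l2, l3) {
  if (is.null(l2) && is.null(l3)) {
    x <- l1
    if (inherits(x, "tensor_field"))
      x <- matrix(x$eigenvalues, ncol = 3L)
    if (is.vector(x) && length(x) == 3L) x <- matrix(x, 1L, 3L)
    as.matrix(x)
  } else {
    cbind(l1, l2, l3)
  }
}

#' Apparent diffusion coefficient from tensor eigenvalues
#'
#' `ADC = (lambda1 + lambda2 + lambda3) / 3`, the mean diffusivity.
#'
#' @param l1 first eigenvalue; or a length-3 vector, an `n x 3` matrix, or
#'   a [tensor_field] (then `l2`, `l3` are omitted).
#' @param l2,l3 remaining eigenvalues (vectorized).
#' @return ADC in the eigenvalues' units (mm^2/s).
#' @export
adc_from_eigenvalues <- function(l1, l2 = NULL, l3 = NULL) {
  lam <- eigs_as_matrix(l1, l2, l3)
  rowMeans(lam)
}

#' Fractional anisotropy from tensor eigenvalues
#'
#' \deqn{FA = \sqrt{\frac{3\sum_i (\lambda_i - ADC)^2}{2\sum_i \lambda_i^2}}}
#' Negative (noise-induced) eigenvalues are clamped at zero before the
#' formula so FA stays within `[0, 1]`; an all-zero triple is undefined and
#' returns `NaN`.
#'
#' @inheritParams adc_from_eigenvalues
#' @return FA, dimensionless in `[0, 1]` (`NaN` where undefined).
#' @export
fa_from_eigenvalues <- function(l1, l2 = NULL, l3 = NULL) {
  lam <- eigs_as_matrix(l1, l2, l3)
  lam <- pmax(lam, 0)
  md <- rowMeans(lam)
  num <- 3 * rowSums((lam - md)^2)
  den <- 2 * rowSums(lam^2)
  out <- sqrt(num / den)
  out[den == 0] <- NaN
  out
}

#' ADC map of a fitted tensor field
#' @param tf a [tensor_field].
#' @return 3-D [vol_image] in mm^2/s; `NaN` at invalid voxels.
#' @export
adc_map <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  adc <- array(rowMeans(matrix(tf$eigenvalues, ncol = 3L)), dim = dim(tf$valid))
  adc[!tf$valid] <- NaN
  vol_image(adc, tf$voxel_dims, units = "mm^2/s")
}

#' FA map of a fitted tensor field
#' @param tf a [tensor_field].
#' @return 3-D [vol_image], dimensionless; `NaN` at invalid voxels.
#' @export
fa_map <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  fa <- array(fa_from_eigenvalues(matrix(tf$eigenvalues, ncol = 3L)),
              dim = dim(tf$valid))
  fa[!tf$valid] <- NaN
  vol_image(fa, tf$voxel_dims, units = "dimensionless")
}
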
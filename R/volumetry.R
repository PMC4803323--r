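#' Segment ventricles from an ADC map by the mean + 3 SD rule
#'
#' Computes the mean and SD of ADC over the full brain mask (ventricles
#' included) in a single pass and selects in-mask voxels whose ADC is
#' strictly greater than `mean + 3 SD`. Cerebrospinal fluid diffuses some
#' three times faster than tissue water, so ventricle voxels sit far in the
#' upper tail of the in-brain ADC distribution. No iteration and, by
#' default, no connected-component filtering is applied; `min_cluster`
#' enables an optional minimum 6-connected cluster size.
#'
#' @param adc_map 3-D [vol_image] of ADC (mm^2/s); must be finite inside
#'   the mask.
#' @param mask logical brain mask (nonempty).
#' @param k number of SDs above the mean (default 3).
#' @param min_cluster optional minimum cluster size in voxels (0 = off).
#' @return An object of class `ventricle_segmentation`: list with logical
#'   `mask`, the `threshold` used (mm^2/s), and the in-brain `mean` and `sd`.
#' @export
segment_ventricles <- function(adc_map, mask, k = 3, min_cluster = 0L) {
  adc <- as_data_array(adc_map)
  if (is.null(mask) || !any(mask)) stop("brain mask is empty", call. = FALSE)
  vals <- adc[mask]
  if (any(!is.finite(vals)))
    stop("ADC map contains non-finite values inside the mask", call. = FALSE)
  mu <- mean(vals)
  sdv <- stats::sd(vals)
  if (sdv == 0)
    warning("constant ADC inside mask; ventricle mask is empty", call. = FALSE)
  thr <- mu + k * sdv
  vmask <- mask & (adc > thr)
  if (min_cluster > 0L) vmask <- drop_small_clusters(vmask, min_cluster)
  structure(list(mask = vmask, threshold = thr, mean = mu, sd = sdv, k = k),
            class = "ventricle_segmentation")
}

# 6-connected flood fill, used only for the optional minimum-cluster filter
drop_small_clusters <- function(mask, min_size) {
  sh <- dim(mask)
  lab <- array(0L, dim = sh)
  cur <- 0L
  idx <- which(mask & lab == 0L)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      co <- arrayInd(v, sh)
      for (r in seq_len(nrow(offs))) {
        nb <- co + offs[r, ]
        if (any(nb < 1) || any(nb > sh)) next
        j <- nb[1] + (nb[2] - 1L) * sh[1] + (nb[3] - 1L) * sh[1] * sh[2]
        if (mask[j] && lab[j] == 0L) { lab[j] <- cur; queue <- c(queue, j) }
      }
    }
  }
  keep <- which(tabulate(lab[lab > 0L]) >= min_size)
  array(lab %in% keep, dim = sh)
}

#' Volume of a voxel mask in mm^3
#'
#' @param mask logical array.
#' @param voxel_dims voxel edge lengths in mm.
#' @return Volume in mm^3 (voxel count times voxel volume).
#' @export
region_volume <- function(mask, voxel_dims) {
  if (any(voxel_dims <= 0)) stop("voxel_dims must be positive", call. = FALSE)
  sum(mask) * prod(voxel_dims)
}

#' Tabulate ventricular and brain-tissue volumes
#'
#' @param brain_mask logical brain mask.
#' @param ventricles a `ventricle_segmentation` (or logical ventricle mask).
#' @param voxel_dims voxel edge lengths in mm.
#' @return One-row tibble: `ventricular_volume_mm3`,
#'   `brain_tissue_volume_mm3` (brain minus ventricles),
#'   `brain_volume_mm3`, voxel counts and the segmentation threshold.
#' @export
volume_report <- function(brain_mask, ventricles, voxel_dims) {
  thr <- NA_real_
  vmask <- ventricles
  if (inherits(ventricles, "ventricle_segmentation")) {
    thr <- ventricles$threshold
    vmask <- ventricles$mask
  }
  vmask <- vmask & brain_mask
  vv <- region_volume(vmask, voxel_dims)
  bv <- region_volume(brain_mask, voxel_dims)
  tibble::tibble(
    ventricular_volume_mm3 = vv,
    brain_tissue_volume_mm3 = bv - vv,
    brain_volume_mm3 = bv,
    n_ventricle_voxels = sum(vmask),
    n_brain_voxels = sum(brain_mask),
    threshold_mm2_s = thr
  )
}

#' Percent difference of a value relative to a reference
#'
#' `100 * (a - b) / b`: positive when `a` is larger than the reference.
#'
#' @param a value.
#' @param b reference (nonzero).
#' @return Percent difference (vectorized).
#' @export
percent_difference <- function(a, b) {
  if (any(b == 0)) stop("zero reference in percent difference", call. = FALSE)
  100 * (a - b) / b
}
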
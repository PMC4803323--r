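#' ASL quantification constants
#'
#' The three constants of the single-compartment continuous-ASL CBF model:
#' the water tissue-blood partition coefficient lambda (mL/g), the average
#' whole-brain spin-lattice relaxation time T1 (seconds), and the labeling
#' efficiency alpha (dimensionless). Defaults are the standard values for
#' mouse brain at 7 T.
#'
#' @param lambda_bp partition coefficient, mL/g; must be positive.
#' @param t1 spin-lattice relaxation time in seconds; must be positive.
#' @param alpha labeling efficiency, in (0.5, 1].
#' @return An object of class `asl_constants`.
#' @export
asl_constants <- function(lambda_bp = 0.9, t1 = 1.8, alpha = 0.75) {
  if (lambda_bp <= 0) stop("lambda_bp must be positive", call. = FALSE)
  if (t1 <= 0) stop("T1 must be positive", call. = FALSE)
  if (alpha <= 0.5 || alpha > 1) stop("alpha must lie in (0.5, 1]", call. = FALSE)
  structure(list(lambda_bp = lambda_bp, t1 = t1, alpha = alpha),
            class = "asl_constants")
}

#' Split an interleaved ASL series into control and label stacks
#'
#' Frames alternate control, label, control, label, ...; by convention the
#' first frame is control (set `first_frame = "label"` to flip).
#'
#' @param series 4-D [vol_image] with an even number of frames.
#' @param first_frame `"control"` (default) or `"label"`.
#' @return A list with 4-D [vol_image]s `control` and `label`, each with
#'   half the frames.
#' @export
split_pairs <- function(series, first_frame = c("control", "label")) {
  first_frame <- match.arg(first_frame)
  stopifnot(inherits(series, "vol_image"))
  d <- dim(series$data)
  if (length(d) != 4L) stop("expected a 4-D ASL series", call. = FALSE)
  if (d[4] %% 2 != 0)
    stop("odd number of frames cannot be paired into control/label",
         call. = FALSE)
  odd <- seq(1, d[4], by = 2)
  even <- seq(2, d[4], by = 2)
  ctrl_idx <- if (first_frame == "control") odd else even
  lab_idx <- if (first_frame == "control") even else odd
  list(
    control = vol_image(series$data[, , , ctrl_idx, drop = FALSE],
                        series$voxel_dims, units = series$units),
    label = vol_image(series$data[, , , lab_idx, drop = FALSE],
                      series$voxel_dims, units = series$units)
  )
}

#' Average the frames of a 4-D stack into one 3-D volume
#'
#' @param stack 4-D [vol_image].
#' @return 3-D [vol_image] of the voxelwise frame mean.
#' @export
mean_volume <- function(stack) {
  stopifnot(inherits(stack, "vol_image"))
  d <- dim(stack$data)
  if (length(d) == 3L) return(stack)
  m <- apply(stack$data, 1:3, mean)
  vol_image(m, stack$voxel_dims, units = stack$units)
}

#' Quantify cerebral blood flow from mean control and label images
#'
#' Voxelwise single-compartment model:
#' \deqn{CBF = 60 \frac{\lambda}{T_1}\frac{S_c - S_L}{S_c + (2\alpha - 1) S_L}}
#' with T1 in seconds; the factor 60 converts per-second to per-minute so
#' the map is in mL/g/min. Voxels where the denominator is not positive are
#' flagged non-finite (NaN) and excluded from downstream ROI summaries.
#'
#' The printed form of this equation is typographically ambiguous about
#' which signal the `(2 alpha - 1)` factor multiplies; the default places it
#' on the label signal, and `denominator = "label_weighted_control"` selects
#' the algebraic variant `S_L + (2 alpha - 1) S_c`. Both coincide at
#' alpha = 1.
#'
#' @param sc mean control volume (3-D [vol_image] or array).
#' @param sl mean label volume, same grid.
#' @param constants an [asl_constants()] object.
#' @param mask logical brain mask; quantification is restricted to it.
#' @param denominator `"control_weighted_label"` (default) or
#'   `"label_weighted_control"`.
#' @return A 3-D [vol_image] in mL/g/min; `NA` outside the mask, `NaN`
#'   where the model is invalid.
#' @export
compute_cbf_map <- function(sc, sl, constants = asl_constants(), mask = NULL,
                            denominator = c("control_weighted_label",
                                            "label_weighted_control")) {
  denominator <- match.arg(denominator)
  sca <- as_data_array(sc)
  sla <- as_data_array(sl)
  if (!identical(dim(sca), dim(sla)))
    stop("control and label volumes have different shapes", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(sca))
  if (!any(mask)) stop("brain mask is empty", call. = FALSE)
  beta <- 2 * constants$alpha - 1
  den <- if (denominator == "control_weighted_label") sca + beta * sla
         else sla + beta * sca
  cbf <- 60 * (constants$lambda_bp / constants$t1) * (sca - sla) / den
  cbf[den <= 0] <- NaN
  cbf[!mask] <- NA_real_
  vd <- if (inherits(sc, "vol_image")) sc$voxel_dims else c(1, 1, 1)
  vol_image(cbf, vd, units = "mL/g/min")
}

#' Quantify CBF from a raw interleaved ASL series
#'
#' Convenience wrapper: split interleaved frames, average all control and
#' all label frames (mean-then-ratio, for a higher-SNR ratio), then apply
#' the quantification model once.
#'
#' @inheritParams split_pairs
#' @inheritParams compute_cbf_map
#' @return A 3-D [vol_image] in mL/g/min.
#' @export
quantify_cbf <- function(series, constants = asl_constants(), mask = NULL,
                         first_frame = "control",
                         denominator = "control_weighted_label") {
  pairs <- split_pairs(series, first_frame = first_frame)
  compute_cbf_map(mean_volume(pairs$control), mean_volume(pairs$label),
                  constants = constants, mask = mask,
                  denominator = denominator)
}
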
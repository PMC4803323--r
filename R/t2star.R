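#' Arithmetic echo-time schedule
#'
#' @param first_te first echo time in ms (>= 0).
#' @param delta_te inter-echo spacing in ms (> 0).
#' @param n number of echoes (>= 2).
#' @return Numeric vector of echo times in ms. The default is the 5-echo
#'   schedule 2.4, 5.7, 9.0, 12.3, 15.6 ms.
#' @export
echo_schedule <- function(first_te = 2.4, delta_te = 3.3, n = 5L) {
  if (first_te < 0) stop("first_te must be non-negative", call. = FALSE)
  if (delta_te <= 0) stop("delta_te must be positive", call. = FALSE)
  if (n < 2) stop("at least 2 echoes are needed to fit a decay", call. = FALSE)
  first_te + delta_te * (seq_len(n) - 1)
}

#' Voxelwise T2* mapping by log-linear regression
#'
#' Fits `ln S_i = ln S0 - TE_i / T2*` by unweighted ordinary least squares
#' per voxel across echoes; `T2* = -1/slope`, `S0 = exp(intercept)`.
#' Voxels with any nonpositive echo signal, or with a non-negative fitted
#' slope (no decay), are marked invalid (`NaN` in the maps) and excluded
#' from ROI summaries. Fitted T2* above `qc_max_ms` is flagged
#' non-physiological in the `flagged` mask but kept unclipped in the map.
#'
#' @param series 4-D [vol_image] over echoes.
#' @param echo_times echo times in ms matching the 4th axis.
#' @param mask logical brain mask (default: all voxels).
#' @param qc_max_ms QC flag threshold for implausibly long T2* (ms).
#' @return An object of class `t2star_fit`: list with [vol_image]s `t2star`
#'   (ms) and `s0` (a.u.), logical `valid` and `flagged` masks.
#' @export
fit_t2star <- function(series, echo_times, mask = NULL, qc_max_ms = 200) {
  stopifnot(inherits(series, "vol_image"))
  d <- dim(series$data)
  if (length(d) != 4L) stop("expected a 4-D multi-echo series", call. = FALSE)
  if (length(echo_times) != d[4])
    stop("echo count does not match the series' 4th axis", call. = FALSE)
  if (length(echo_times) < 2L)
    stop("at least 2 echoes are needed", call. = FALSE)
  if (is.unsorted(echo_times, strictly = TRUE))
    stop("echo_times must be strictly increasing", call. = FALSE)
  sh <- d[1:3]
  nvox <- prod(sh)
  if (is.null(mask)) mask <- array(TRUE, dim = sh)
  S <- matrix(series$data, nrow = nvox, ncol = d[4])
  usable <- as.vector(mask) & apply(S > 0, 1, all) &
    apply(is.finite(S), 1, all)
  if (!any(usable))
    stop("no voxel has a full set of positive echo signals", call. = FALSE)

  # closed-form simple OLS of log-signal on TE, vectorized over voxels
  te <- echo_times
  te_c <- te - mean(te)
  logS <- log(S[usable, , drop = FALSE])
  slope <- as.vector(logS %*% te_c) / sum(te_c^2)
  intercept <- rowMeans(logS) - slope * mean(te)

  t2s <- array(NaN, dim = sh)
  s0 <- array(NaN, dim = sh)
  ok <- slope < 0
  vox <- which(usable)
  t2s[vox[ok]] <- -1 / slope[ok]
  s0[vox[ok]] <- exp(intercept[ok])
  valid <- array(FALSE, dim = sh)
  valid[vox[ok]] <- TRUE
  flagged <- valid & (t2s > qc_max_ms)
  flagged[is.na(flagged)] <- FALSE
  t2s[!mask] <- NA_real_
  s0[!mask] <- NA_real_
  structure(
    list(t2star = vol_image(t2s, series$voxel_dims, units = "ms"),
         s0 = vol_image(s0, series$voxel_dims, units = "a.u."),
         valid = valid, flagged = flagged),
    class = "t2star_fit"
  )
}

#' @export
print.t2star_fit <- function(x, ...) {
  cat("<t2star_fit> ", sum(x$valid), " valid voxels; ",
      sum(x$flagged), " flagged (> physiological range)\n", sep = "")
  invisible(x)
}
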
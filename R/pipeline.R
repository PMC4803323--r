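#' Configuration of a full pipeline run
#'
#' Every acquisition constant defaults to the study conditions this package
#' emulates: lambda = 0.9 mL/g, T1 = 1.8 s, alpha = 0.75, five echoes from
#' 2.4 ms spaced 3.3 ms, b = 1200 s/mm^2 with 30 directions, interleaved
#' ASL repetitions, and q = 0.05 for FDR control.
#'
#' @param phantom a [phantom_spec()] describing the simulated subject grid.
#' @param effects a [group_effect_spec()] giving the two-group effect
#'   structure (per-animal ground truths are drawn from it), or `NULL` for
#'   a single-subject run.
#' @param inputs optional named list of file paths (`asl`, `multiecho`,
#'   `dwi`, `labels`, `label_names`) for quantifying acquired data instead
#'   of simulating; `directions` and `echo_times` are then taken from this
#'   config.
#' @param constants an [asl_constants()] object.
#' @param echo_times echo times in ms.
#' @param b diffusion weighting, s/mm^2.
#' @param n_directions number of diffusion directions.
#' @param n_reps number of interleaved ASL frames (even).
#' @param noise_sd simulated additive noise SD (a.u.).
#' @param stats a [stats_config()].
#' @param seed integer seed; all randomness in the run derives from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_spec(),
                       effects = group_effect_spec(),
                       inputs = NULL,
                       constants = asl_constants(),
                       echo_times = echo_schedule(2.4, 3.3, 5),
                       b = 1200, n_directions = 30L, n_reps = 20L,
                       noise_sd = 0, stats = stats_config(), seed = 1L) {
  structure(list(phantom = phantom, effects = effects, inputs = inputs,
                 constants = constants, echo_times = echo_times, b = b,
                 n_directions = as.integer(n_directions),
                 n_reps = as.integer(n_reps), noise_sd = noise_sd,
                 stats = stats, seed = as.integer(seed)),
            class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

draw_animal_truth <- function(base_truth, effects_table, group) {
  truth <- base_truth
  mcol <- paste0("mean_", group)
  scol <- paste0("sd_", group)
  for (k in seq_len(nrow(effects_table))) {
    row <- effects_table[k, ]
    i <- match(row$region, truth$region)
    if (is.na(i)) next
    val <- stats::rnorm(1, row[[mcol]], row[[scol]])
    val <- max(val, 1e-6)
    if (row$parameter == "T2*") truth$t2star_ms[i] <- val
    if (row$parameter == "ADC") truth$adc[i] <- val
    if (row$parameter == "CBF") truth$cbf[i] <- val
  }
  truth
}

quantify_subject <- function(phantom, cfg, noise_seed) {
  gdirs <- make_gradient_scheme(cfg$n_directions)
  asl <- simulate_asl(phantom$cbf, phantom$s0, cfg$constants,
                      n_reps = cfg$n_reps, noise_sd = cfg$noise_sd,
                      seed = noise_seed)
  me <- simulate_multiecho(phantom$t2star, phantom$s0, cfg$echo_times,
                           noise_sd = cfg$noise_sd, seed = noise_seed + 1L)
  dwi <- simulate_dwi(phantom$tensor, phantom$s0, b = cfg$b,
                      directions = gdirs, noise_sd = cfg$noise_sd,
                      seed = noise_seed + 2L)
  mask <- phantom$brain_mask
  list(
    cbf = quantify_cbf(asl, cfg$constants, mask = mask),
    t2 = fit_t2star(me, cfg$echo_times, mask = mask),
    tensor = fit_tensor(dwi, b = cfg$b, directions = gdirs, mask = mask)
  )
}

subject_rows <- function(maps, phantom, animal_id, group) {
  lm <- phantom$label_map
  adc <- adc_map(maps$tensor)
  fa <- fa_map(maps$tensor)
  row_of <- function(img, parameter, units, scale = 1) {
    s <- roi_summary(img, lm)
    tibble::tibble(animal_id = animal_id, group = group, region = s$region,
                   parameter = parameter, value = s$mean * scale,
                   units = units)
  }
  seg <- segment_ventricles(adc, phantom$brain_mask)
  rep <- volume_report(phantom$brain_mask, seg, lm$voxel_dims)
  dplyr::bind_rows(
    row_of(maps$t2$t2star, "T2*", "ms"),
    row_of(adc, "ADC", "1e-3 mm^2/s", scale = 1e3),
    row_of(fa, "FA", "dimensionless"),
    row_of(maps$cbf, "CBF", "mL/g/min"),
    tibble::tibble(animal_id = animal_id, group = group,
                   region = c("ventricles", "whole brain"),
                   parameter = "volume",
                   value = c(rep$ventricular_volume_mm3,
                             rep$brain_tissue_volume_mm3),
                   units = "mm^3")
  )
}

#' Run the full simulate -> quantify -> segment -> summarize -> compare chain
#'
#' Simulates a cohort of digital phantoms (per-animal ground truths drawn
#' from the config's effect spec), quantifies CBF, T2*, ADC and FA for each
#' animal, segments ventricles and tabulates volumes, assembles the tidy
#' cohort table, and runs the FDR-corrected two-group comparison. All
#' outputs are written under `out_dir` together with a structured log and a
#' manifest with MD5 checksums; the run is deterministic given the config's
#' seed.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `cohort`, `stats`, `truth`, `volumes`
#'   tibbles and the `out_dir`; files written: `cohort.csv`, `stats.csv`,
#'   `truth.csv`, `volumes.csv`, first-animal maps (`cbf.nii.gz`,
#'   `t2star.nii.gz`, `adc.nii.gz`, `fa.nii.gz`), `labels.nii.gz` +
#'   `labels.csv`, `log.txt`, `manifest.csv`.
#' @export
run_full_pipeline <- function(cfg = run_config(), out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("neuroquant pipeline run, seed %d", cfg$seed),
                 sprintf("noise_sd=%g b=%g n_directions=%d n_reps=%d",
                         cfg$noise_sd, cfg$b, cfg$n_directions, cfg$n_reps),
                 sprintf("lambda=%g T1=%gs alpha=%g q=%g",
                         cfg$constants$lambda_bp, cfg$constants$t1,
                         cfg$constants$alpha, cfg$stats$q))
  tick <- function(stage, t0) {
    log_lines <<- c(log_lines, sprintf("stage %-10s %.2f s", stage,
                                       as.numeric(Sys.time()) - t0))
  }

  if (!is.null(cfg$inputs)) {
    res <- run_single_subject(cfg, out_dir, log_lines)
    return(invisible(res))
  }

  set.seed(cfg$seed)
  eff <- cfg$effects
  if (is.null(eff)) eff <- group_effect_spec(n_wildtype = 2L, n_mitopark = 2L)
  n_wt <- eff$n_wildtype; n_mp <- eff$n_mitopark
  groups <- c(rep("wildtype", n_wt), rep("mitopark", n_mp))
  ids <- c(sprintf("wt%02d", seq_len(n_wt)), sprintf("mp%02d", seq_len(n_mp)))
  sub_seeds <- sample.int(.Machine$integer.max %/% 8L, length(ids)) # < 2^31

  t0 <- as.numeric(Sys.time())
  truths <- purrr::map(seq_along(ids), function(i) {
    set.seed(sub_seeds[i])
    draw_animal_truth(cfg$phantom$truth, eff$table, groups[i])
  })
  tick("simulate", t0)

  cohort <- NULL
  first_maps <- NULL
  first_phantom <- NULL
  t0 <- as.numeric(Sys.time())
  for (i in seq_along(ids)) {
    ph <- with_stage("simulate", build_phantom(
      phantom_spec(cfg$phantom$shape, cfg$phantom$voxel_dims,
                   truth = truths[[i]], noise_sd = cfg$noise_sd,
                   seed = sub_seeds[i])))
    maps <- with_stage("quantify", quantify_subject(ph, cfg, sub_seeds[i]))
    rows <- with_stage("summarize", subject_rows(maps, ph, ids[i], groups[i]))
    cohort <- dplyr::bind_rows(cohort, rows)
    if (i == 1L) { first_maps <- maps; first_phantom <- ph }
  }
  tick("quantify", t0)

  t0 <- as.numeric(Sys.time())
  volumes <- dplyr::filter(cohort, .data$parameter == "volume")
  stats_res <- with_stage("compare", suppressWarnings(
    cohort_compare(cohort, cfg$stats)))
  tick("compare", t0)

  truth_tab <- purrr::map2_dfr(truths, seq_along(ids), function(tr, i) {
    tr$animal_id <- ids[i]; tr$group <- groups[i]; tr
  })
  truth_tab <- truth_tab[, c("animal_id", "group", "region", "t2star_ms",
                             "adc", "fa", "cbf")]

  p <- function(f) file.path(out_dir, f)
  write_cohort(cohort, p("cohort.csv"))
  utils::write.csv(tidy(stats_res), p("stats.csv"), row.names = FALSE)
  utils::write.csv(truth_tab, p("truth.csv"), row.names = FALSE)
  utils::write.csv(volumes, p("volumes.csv"), row.names = FALSE)
  write_volume(first_maps$cbf, p("cbf.nii.gz"))
  write_volume(first_maps$t2$t2star, p("t2star.nii.gz"))
  write_volume(adc_map(first_maps$tensor), p("adc.nii.gz"))
  write_volume(fa_map(first_maps$tensor), p("fa.nii.gz"))
  write_label_map(first_phantom$label_map, p("labels.nii.gz"), p("labels.csv"))
  writeLines(log_lines, p("log.txt"))

  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   p(c("manifest.csv", "log.txt")))
  manifest <- tibble::tibble(file = basename(files),
                             md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, p("manifest.csv"), row.names = FALSE)

  invisible(list(cohort = cohort, stats = stats_res, truth = truth_tab,
                 volumes = volumes, manifest = manifest, out_dir = out_dir))
}

# single-subject mode: quantify acquired series given on disk
run_single_subject <- function(cfg, out_dir, log_lines) {
  inp <- cfg$inputs
  need <- c("asl", "multiecho", "dwi", "labels", "label_names")
  miss <- setdiff(need, names(inp))
  if (length(miss))
    stop("stage 'quantify' failed: missing inputs: ",
         paste(miss, collapse = ", "), call. = FALSE)
  lm <- with_stage("quantify", read_label_map(inp$labels, inp$label_names))
  mask <- brain_mask(lm)
  gdirs <- make_gradient_scheme(cfg$n_directions)
  cbf <- with_stage("quantify",
                    quantify_cbf(read_volume(inp$asl), cfg$constants, mask))
  t2 <- with_stage("quantify",
                   fit_t2star(read_volume(inp$multiecho), cfg$echo_times, mask))
  tensor <- with_stage("quantify",
                       fit_tensor(read_volume(inp$dwi), cfg$b, gdirs, mask))
  adc <- adc_map(tensor)
  seg <- with_stage("segment", segment_ventricles(adc, mask))
  rep <- volume_report(mask, seg, lm$voxel_dims)
  summ <- with_stage("summarize", dplyr::bind_rows(
    dplyr::mutate(roi_summary(t2$t2star, lm), parameter = "T2*"),
    dplyr::mutate(roi_summary(adc, lm), parameter = "ADC"),
    dplyr::mutate(roi_summary(fa_map(tensor), lm), parameter = "FA"),
    dplyr::mutate(roi_summary(cbf, lm), parameter = "CBF")))
  p <- function(f) file.path(out_dir, f)
  write_volume(cbf, p("cbf.nii.gz"))
  write_volume(t2$t2star, p("t2star.nii.gz"))
  write_volume(adc, p("adc.nii.gz"))
  write_volume(fa_map(tensor), p("fa.nii.gz"))
  utils::write.csv(summ, p("roi_summary.csv"), row.names = FALSE)
  utils::write.csv(rep, p("volumes.csv"), row.names = FALSE)
  writeLines(log_lines, p("log.txt"))
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   p(c("manifest.csv", "log.txt")))
  manifest <- tibble::tibble(file = basename(files),
                             md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, p("manifest.csv"), row.names = FALSE)
  invisible(list(roi_summary = summ, volumes = rep, manifest = manifest,
                 out_dir = out_dir))
}
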
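#' Statistical configuration for two-group comparisons
#'
#' @param q false discovery rate level for the Benjamini-Hochberg step-up
#'   procedure (0 < q < 1).
#' @param normality_alpha Shapiro-Wilk significance threshold gating the
#'   parametric branch.
#' @param family which tests are corrected together: `"per-parameter"`
#'   (default; all regions of one MRI parameter form one family, matching
#'   how results tables are organized) or `"all"` (one family).
#' @param gate `"either"` (default): use the nonparametric branch when
#'   either group fails the normality test; `"both"`: only when both fail.
#' @return An object of class `stats_config`.
#' @export
stats_config <- function(q = 0.05, normality_alpha = 0.05,
                         family = c("per-parameter", "all"),
                         gate = c("either", "both")) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)", call. = FALSE)
  if (normality_alpha <= 0 || normality_alpha >= 1)
    stop("normality_alpha must lie in (0, 1)", call. = FALSE)
  structure(list(q = q, normality_alpha = normality_alpha,
                 family = match.arg(family), gate = match.arg(gate)),
            class = "stats_config")
}

#' Per-region means of a parameter map
#'
#' Averages a quantitative map over each named region of a label map,
#' counting only finite (valid) voxels. A region with no valid voxel is
#' reported as missing (`NA`), never as zero.
#'
#' @param map 3-D [vol_image] (or array) on the label map's grid.
#' @param labels a [label_map].
#' @return A tibble with columns `region`, `label`, `mean`, `n_valid`,
#'   `n_voxels`.
#' @export
roi_summary <- function(map, labels) {
  stopifnot(inherits(labels, "label_map"))
  m <- as_data_array(map)
  if (!identical(dim(m), dim(labels$labels)))
    stop("map and label map are on different grids", call. = FALSE)
  labs <- as.integer(names(labels$names))
  purrr::map_dfr(labs, function(l) {
    sel <- labels$labels == l
    vals <- m[sel]
    vals <- vals[is.finite(vals)]
    tibble::tibble(region = unname(labels$names[as.character(l)]),
                   label = l,
                   mean = if (length(vals)) mean(vals) else NA_real_,
                   n_valid = length(vals), n_voxels = sum(sel))
  })
}

#' Shapiro-Wilk normality p-value
#'
#' @param values numeric sample with 3 to 5000 observations.
#' @return The Shapiro-Wilk p-value.
#' @export
normality_p <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3 || length(values) > 5000)
    stop("Shapiro-Wilk requires between 3 and 5000 observations", call. = FALSE)
  stats::shapiro.test(values)$p.value
}

#' Normality-gated two-group comparison
#'
#' Runs the Shapiro-Wilk test in each group; if the gate fails (by default,
#' if either group deviates from normality at `normality_alpha`), the groups
#' are compared with a two-sided Mann-Whitney test (exact when the combined
#' sample size is at most 20 and there are no ties, normal approximation
#' with tie/continuity correction otherwise); otherwise with a two-sided
#' equal-variance (Student) two-sample t-test.
#'
#' @param a,b numeric samples, each with at least 3 observations.
#' @param cfg a [stats_config()].
#' @param force `"none"` (default), `"t-test"` or `"mann-whitney"` to bypass
#'   the gate.
#' @return One-row tibble: `test_used`, `statistic`, `p_raw`, normality
#'   p-values, and per-group mean, SD, SEM and n.
#' @export
compare_groups <- function(a, b, cfg = stats_config(),
                           force = c("none", "t-test", "mann-whitney")) {
  force <- match.arg(force)
  if (length(a) < 3 || length(b) < 3)
    stop("each group needs at least 3 observations", call. = FALSE)
  sw_a <- normality_p(a)
  sw_b <- normality_p(b)
  nonnormal <- if (cfg$gate == "either")
    (sw_a < cfg$normality_alpha) || (sw_b < cfg$normality_alpha)
  else
    (sw_a < cfg$normality_alpha) && (sw_b < cfg$normality_alpha)
  use_mw <- switch(force, none = nonnormal, `t-test` = FALSE,
                   `mann-whitney` = TRUE)
  if (use_mw) {
    exact <- (length(a) + length(b)) <= 20
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                         correct = TRUE))
    test_used <- "Mann-Whitney"
  } else {
    ht <- stats::t.test(a, b, alternative = "two.sided", var.equal = TRUE)
    test_used <- "t-test"
  }
  tibble::tibble(
    test_used = test_used,
    statistic = unname(ht$statistic),
    p_raw = ht$p.value,
    shapiro_p_a = sw_a, shapiro_p_b = sw_b,
    mean_a = mean(a), sd_a = stats::sd(a),
    sem_a = stats::sd(a) / sqrt(length(a)), n_a = length(a),
    mean_b = mean(b), sd_b = stats::sd(b),
    sem_b = stats::sd(b) / sqrt(length(b)), n_b = length(b)
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Implements the step-up procedure directly: with p-values sorted
#' ascending, the adjusted value at rank i is `min over j >= i of
#' (m * p_(j) / j)` capped at 1, and discoveries are all ranks up to the
#' largest i with `p_(i) <= i q / m`. Input order is restored in the
#' output. Equivalent to declaring a discovery wherever the adjusted
#' p-value is at most q.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return A list with `p_adjusted` (same order as input) and logical
#'   `discovery`.
#' @export
bh_adjust <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj_sorted <- rev(cummin(rev(m * ps / seq_len(m))))
  adj_sorted <- pmin(adj_sorted, 1)
  crit <- ps <= seq_len(m) * q / m
  kmax <- if (any(crit)) max(which(crit)) else 0L
  disc_sorted <- seq_len(m) <= kmax
  adj <- numeric(m); adj[ord] <- adj_sorted
  disc <- logical(m); disc[ord] <- disc_sorted
  list(p_adjusted = adj, discovery = disc)
}

#' Two-group comparison of a full cohort table
#'
#' For every (region, parameter) cell with at least `min_n` animals per
#' group, runs the normality-gated comparison of [compare_groups()], then
#' applies Benjamini-Hochberg FDR correction within each family (by
#' default, all regions of one parameter form a family). Cells with too few
#' animals are reported with `NA` results rather than aborting the run.
#'
#' @param table tidy cohort table (`animal_id`, `group`, `region`,
#'   `parameter`, `value`, optionally `units`).
#' @param cfg a [stats_config()].
#' @param reference name of the reference (control) group; the other group
#'   present in the table is treated as the affected group.
#' @param min_n minimum animals per group per cell (default 3).
#' @return A tibble of class `cohort_comparison`, one row per (region,
#'   parameter): test choice, statistic, raw and adjusted p, discovery flag
#'   and per-group summaries (reference group suffixed `_ref`, affected
#'   `_aff`).
#' @export
cohort_compare <- function(table, cfg = stats_config(), reference = "wildtype",
                           min_n = 3L) {
  groups <- unique(table$group)
  if (!(reference %in% groups))
    stop("reference group '", reference, "' not present in table", call. = FALSE)
  other <- setdiff(groups, reference)
  if (length(other) != 1L)
    stop("cohort table must contain exactly two groups", call. = FALSE)
  units_tab <- if ("units" %in% names(table))
    dplyr::distinct(table, .data$region, .data$parameter, .data$units)
  else NULL

  cells <- dplyr::distinct(table, .data$region, .data$parameter)
  res <- purrr::map_dfr(seq_len(nrow(cells)), function(k) {
    sub <- dplyr::filter(table, .data$region == cells$region[k],
                         .data$parameter == cells$parameter[k])
    a <- sub$value[sub$group == reference]
    b <- sub$value[sub$group == other]
    base <- tibble::tibble(region = cells$region[k],
                           parameter = cells$parameter[k])
    cmp <- NULL
    if (length(a) >= min_n && length(b) >= min_n)
      cmp <- tryCatch(compare_groups(a, b, cfg), error = function(e) NULL)
    if (is.null(cmp)) {
      degenerate <- length(a) >= min_n && length(b) >= min_n
      warning("cell (", cells$region[k], ", ", cells$parameter[k], ") ",
              if (degenerate) "is essentially constant; skipped"
              else paste0("has fewer than ", min_n,
                          " animals per group; skipped"),
              call. = FALSE)
      return(dplyr::bind_cols(base, tibble::tibble(
        test_used = NA_character_, statistic = NA_real_, p_raw = NA_real_,
        shapiro_p_a = NA_real_, shapiro_p_b = NA_real_,
        mean_a = NA_real_, sd_a = NA_real_, sem_a = NA_real_,
        n_a = length(a),
        mean_b = NA_real_, sd_b = NA_real_, sem_b = NA_real_,
        n_b = length(b))))
    }
    dplyr::bind_cols(base, cmp)
  })
  names(res) <- sub("_a$", "_ref", names(res))
  names(res) <- sub("_b$", "_aff", names(res))

  res$p_adjusted <- NA_real_
  res$discovery <- NA
  fam <- if (cfg$family == "per-parameter") res$parameter
         else rep("all", nrow(res))
  for (f in unique(fam)) {
    sel <- which(fam == f & !is.na(res$p_raw))
    if (!length(sel)) next
    bh <- bh_adjust(res$p_raw[sel], cfg$q)
    res$p_adjusted[sel] <- bh$p_adjusted
    res$discovery[sel] <- bh$discovery
  }
  if (!is.null(units_tab)) res <- dplyr::left_join(res, units_tab,
                                                   by = c("region", "parameter"))
  attr(res, "cfg") <- cfg
  attr(res, "groups") <- c(reference = reference, affected = other)
  class(res) <- c("cohort_comparison", class(res))
  res
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cohort comparison
#' @param x a `cohort_comparison`.
#' @param ... unused.
#' @return A plain tibble of the per-cell results.
#' @export
tidy.cohort_comparison <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cohort_comparison")
  tibble::as_tibble(out)
}

#' One-row summary of a cohort comparison
#' @param x a `cohort_comparison`.
#' @param ... unused.
#' @return Tibble with test counts, discovery count and the FDR level.
#' @export
glance.cohort_comparison <- function(x, ...) {
  cfg <- attr(x, "cfg")
  tibble::tibble(
    n_tests = sum(!is.na(x$p_raw)),
    n_discoveries = sum(x$discovery, na.rm = TRUE),
    n_nonparametric = sum(x$test_used == "Mann-Whitney", na.rm = TRUE),
    q = cfg$q,
    family = cfg$family
  )
}

#' Plot adjusted p-values of a cohort comparison
#'
#' One point per region, faceted by parameter, on a -log10 scale with the
#' FDR level marked; discoveries are filled.
#'
#' @param object a `cohort_comparison`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_comparison <- function(object, ...) {
  cfg <- attr(object, "cfg")
  df <- tidy(object)
  df <- df[!is.na(df$p_adjusted), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region,
                                   y = -log10(.data$p_adjusted),
                                   shape = .data$test_used,
                                   fill = .data$discovery)) +
    ggplot2::geom_hline(yintercept = -log10(cfg$q), linetype = "dashed") +
    ggplot2::geom_point(size = 2.5, stroke = 0.4) +
    ggplot2::scale_shape_manual(values = c(`t-test` = 21, `Mann-Whitney` = 24)) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey80"),
                               na.value = "grey95") +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter), scales = "free_x") +
    ggplot2::labs(x = NULL, y = expression(-log[10]~adjusted~italic(p)),
                  fill = "discovery", shape = "test") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Novel-object discrimination index
#'
#' Percent of total object-exploration time spent on the novel object:
#' `100 * t_novel / (t_novel + t_familiar)`. 50 is chance performance.
#'
#' @param t_novel time exploring the novel object (s, >= 0).
#' @param t_familiar time exploring the familiar object (s, >= 0).
#' @return Discrimination index in percent (vectorized).
#' @export
discrimination_index <- function(t_novel, t_familiar) {
  if (any(t_novel < 0) || any(t_familiar < 0))
    stop("exploration times must be non-negative", call. = FALSE)
  tot <- t_novel + t_familiar
  if (any(tot == 0)) stop("total exploration time is zero", call. = FALSE)
  100 * t_novel / tot
}
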
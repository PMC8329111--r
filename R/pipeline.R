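#' Default metric-panel configuration
#'
#' Controls which parameterizations of the surface metrics are computed and
#' which boundary conventions each metric family uses. The defaults follow
#' the standard evaluation panel: surface Dice at 0/4/8/10 mm tolerance on
#' area-weighted face surfels, pooled percentile Hausdorff distances at
#' 100/99/98/95 on voxel-center boundaries, and slice-wise 2D path lengths.
#'
#' @return nested list of config sections.
#' @export
default_config <- function() {
  list(
    boundary = list(surface_dsc_mode = "face-surfel",
                    distance_mode = "voxel-center"),
    surface_dsc = list(tolerances_mm = c(0, 4, 8, 10)),
    hausdorff = list(percentiles = c(100, 99, 98, 95)),
    apl = list(mode = "slice2d"),
    stats = list(alpha = 0.05)
  )
}

#' Load a configuration file
#'
#' Reads a YAML file and overlays it onto [default_config()]; keys absent
#' from the file keep their defaults.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return config list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!requireNamespace("yaml", quietly = TRUE))
    segsim_stop("the 'yaml' package is required to read config files",
                "segsim_io_error")
  user <- yaml::read_yaml(path)
  utils::modifyList(cfg, user)
}

panel_colnames <- function(config) {
  c("volumetric_dsc", "jaccard",
    sprintf("surface_dsc_%gmm", config$surface_dsc$tolerances_mm),
    sprintf("hd%g_mm", config$hausdorff$percentiles),
    "asd_mm", "apl_px", "fnpl_px", "fnv_px")
}

# Invariant checks applied to every row before it is reported/written.
validate_panel_row <- function(row) {
  sim <- unlist(row[grepl("^(volumetric_dsc|jaccard|surface_dsc)", names(row))])
  sim <- sim[is.finite(sim)]
  if (length(sim) && (any(sim < -1e-12) || any(sim > 1 + 1e-12)))
    segsim_stop("panel invariant violated: similarity outside [0,1]",
                "segsim_invariant_error")
  d <- unlist(row[grepl("^(hd|asd)", names(row))]); d <- d[is.finite(d)]
  if (length(d) && any(d < 0))
    segsim_stop("panel invariant violated: negative distance",
                "segsim_invariant_error")
  if (is.finite(row$fnpl_px) && is.finite(row$apl_px) && row$fnpl_px > row$apl_px)
    segsim_stop("panel invariant violated: FNPL > APL", "segsim_invariant_error")
  invisible(TRUE)
}

#' Compute the full metric panel for one mask pair
#'
#' Runs every configured metric on an (auto, corrected) pair and returns a
#' one-row data.frame. Volume and path-length metrics are defined for empty
#' masks; the surface metrics are not, so when either mask is empty they
#' are reported as `NA` with a warning code in the `warnings` column rather
#' than failing the whole panel.
#'
#' @param auto,corrected comparable [binary_mask] objects.
#' @param config see [default_config()].
#' @param case_id identifier copied into the row.
#' @return one-row data.frame (`case_id`, metric columns, `warnings`,
#'   `error`).
#' @export
compare_masks <- function(auto, corrected, config = default_config(),
                          case_id = NA_character_) {
  assert_comparable(auto, corrected)
  warn <- character()
  if (isTRUE(auto$nonorthogonal) || isTRUE(corrected$nonorthogonal))
    warn <- c(warn, "nonorthogonal-affine")
  row <- list(case_id = case_id)
  both_empty <- n_foreground(auto) == 0L && n_foreground(corrected) == 0L
  if (both_empty) warn <- c(warn, "both-masks-empty:dsc-ji-convention-1")
  row$volumetric_dsc <- volumetric_dsc(auto, corrected)
  row$jaccard <- jaccard_index(auto, corrected)

  surfaces_ok <- n_foreground(auto) > 0L && n_foreground(corrected) > 0L
  if (!surfaces_ok) warn <- c(warn, "empty-mask:surface-metrics-undefined")
  sd_mode <- config$boundary$surface_dsc_mode
  d_mode <- config$boundary$distance_mode
  # extract each boundary representation and its nearest distances once;
  # all tolerances/percentiles are read off the same distance sets
  if (surfaces_ok) {
    sa <- extract_boundary_3d(auto, sd_mode)
    sb <- extract_boundary_3d(corrected, sd_mode)
    dd_s <- nearest_distances(sa, sb)
    if (d_mode == sd_mode) {
      va <- sa; vb <- sb; dd_v <- dd_s
    } else {
      va <- extract_boundary_3d(auto, d_mode)
      vb <- extract_boundary_3d(corrected, d_mode)
      dd_v <- nearest_distances(va, vb)
    }
    pooled <- c(dd_v$a_to_b, dd_v$b_to_a)
  }
  for (tau in config$surface_dsc$tolerances_mm)
    row[[sprintf("surface_dsc_%gmm", tau)]] <- if (surfaces_ok) {
      tol_eps <- tau + 1e-9
      (sum(sa$weights[dd_s$a_to_b <= tol_eps]) +
         sum(sb$weights[dd_s$b_to_a <= tol_eps])) /
        (sum(sa$weights) + sum(sb$weights))
    } else NA_real_
  for (p in config$hausdorff$percentiles)
    row[[sprintf("hd%g_mm", p)]] <- if (surfaces_ok) {
      if (p == 100) max(pooled) else
        unname(quantile(pooled, p / 100, type = 7, names = FALSE))
    } else NA_real_
  row$asd_mm <- if (surfaces_ok)
    (mean(dd_v$a_to_b) + mean(dd_v$b_to_a)) / 2 else NA_real_

  row$apl_px <- added_path_length(auto, corrected, mode = config$apl$mode)
  row$fnpl_px <- false_negative_path_length(auto, corrected, mode = config$apl$mode)
  row$fnv_px <- false_negative_volume(auto, corrected)
  row$warnings <- paste(warn, collapse = ";")
  row$error <- NA_character_
  out <- as.data.frame(row, stringsAsFactors = FALSE)
  validate_panel_row(out)
  out
}

error_panel_row <- function(case_id, config, msg) {
  row <- as.list(setNames(rep(NA_real_, length(panel_colnames(config))),
                          panel_colnames(config)))
  row <- c(list(case_id = case_id), row,
           list(warnings = "", error = msg))
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Batch metric panel over a manifest
#'
#' Computes the configured metric panel for every case in a manifest. A
#' failing case (unreadable file, mismatched grids, ...) yields a row with
#' its error message — never a silent omission — and the run continues;
#' whether any case failed is recorded in the `partial_failure` attribute.
#'
#' @param manifest data.frame from [read_manifest()] (or equivalent).
#' @param config see [default_config()].
#' @param out_dir optional directory; when given, `panel.csv` and
#'   `summary.csv` are written there.
#' @return list with `panel` (one row per case) and `summary`
#'   (median/range/IQR per metric, see [summarize_panel()]).
#' @export
batch_panel <- function(manifest, config = default_config(), out_dir = NULL) {
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    cid <- manifest$case_id[i]
    tryCatch({
      a <- load_mask(manifest$auto_path[i])
      b <- load_mask(manifest$corrected_path[i])
      compare_masks(a, b, config, case_id = cid)
    }, error = function(e) error_panel_row(cid, config, conditionMessage(e)))
  })
  panel <- do.call(rbind, rows)
  summary <- summarize_panel(panel)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(panel, file.path(out_dir, "panel.csv"), row.names = FALSE)
    write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  }
  out <- list(panel = panel, summary = summary)
  attr(out, "partial_failure") <- any(!is.na(panel$error))
  out
}

#' Summarize a metric panel
#'
#' Median, range and interquartile range per metric — the presentation
#' suited to the skewed, non-normal distributions these metrics produce.
#' Quartiles use linear interpolation (quantile type 7).
#'
#' @param panel data.frame from [batch_panel()] / [compare_masks()].
#' @return data.frame with one row per metric.
#' @export
summarize_panel <- function(panel) {
  cols <- setdiff(names(panel)[vapply(panel, is.numeric, TRUE)], "case_id")
  rows <- lapply(cols, function(cl) {
    v <- panel[[cl]]; v <- v[is.finite(v)]
    if (!length(v))
      return(data.frame(metric = cl, n = 0L, median = NA_real_, min = NA_real_,
                        max = NA_real_, iqr = NA_real_))
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    data.frame(metric = cl, n = length(v), median = median(v), min = min(v),
               max = max(v), iqr = q[2] - q[1])
  })
  do.call(rbind, rows)
}

#' Associate a metric panel with correction times and covariates
#'
#' Reproduces the nonparametric association analysis at cohort scale:
#' Spearman correlations of every metric with correction time (ranked by
#' |rho|), Spearman correlations of numeric covariates with time, and for
#' each categorical covariate a Mann-Whitney U test (2 levels) or
#' Kruskal-Wallis with Bonferroni-corrected post-hoc comparisons (>= 3
#' levels) against correction time and against each metric. Covariates with
#' a single observed level are skipped with a warning. Hidden columns
#' (names starting with `.`) are ignored.
#'
#' @param panel metric panel data.frame with `case_id`.
#' @param cases case table with `case_id`, `correction_time`, and optional
#'   covariate columns (numeric or categorical).
#' @param config see [default_config()]; `config$stats$alpha` gates the
#'   Kruskal-Wallis post-hoc tests.
#' @return list with `correlations` (see [metric_time_correlation_table()])
#'   and `covariate_tests` (tidy data.frame of test rows).
#' @export
associate_panel <- function(panel, cases, config = default_config()) {
  correlations <- metric_time_correlation_table(panel, cases)
  df <- merge(panel, cases, by = "case_id")
  metric_cols <- setdiff(names(panel)[vapply(panel, is.numeric, TRUE)], "case_id")
  covar_cols <- setdiff(names(cases), c("case_id", "correction_time"))
  covar_cols <- covar_cols[!startsWith(covar_cols, ".")]
  alpha <- config$stats$alpha
  outcomes <- c("correction_time", metric_cols)
  rows <- list()
  for (cv in covar_cols) {
    v <- df[[cv]]
    if (is.numeric(v)) {
      if (length(unique(v[is.finite(v)])) < 2L) {
        warning(sprintf("covariate '%s' is constant; skipped", cv)); next
      }
      ok <- is.finite(v) & is.finite(df$correction_time)
      rows[[length(rows) + 1L]] <-
        spearman(v[ok], df$correction_time[ok],
                 variables = paste0(cv, "~correction_time"))
      next
    }
    lev <- unique(v[!is.na(v)])
    if (length(lev) < 2L) {
      warning(sprintf("covariate '%s' has a single level; skipped", cv)); next
    }
    for (oc in outcomes) {
      y <- df[[oc]]
      ok <- is.finite(y) & !is.na(v)
      groups <- split(y[ok], v[ok])
      groups <- groups[lengths(groups) >= 2L]
      if (length(groups) < 2L) next
      res <- tryCatch({
        if (length(groups) == 2L)
          mann_whitney_u(groups[[1]], groups[[2]],
                         variables = paste0(oc, "~", cv),
                         group1 = names(groups)[1], group2 = names(groups)[2])
        else
          kruskal_wallis_with_posthoc(groups, alpha = alpha,
                                      variables = paste0(oc, "~", cv))
      }, error = function(e) NULL)
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  covariate_tests <- if (length(rows)) do.call(rbind, rows) else
    assoc_row(character(), character(), character(), numeric(), numeric(),
              integer(), character())[0, ]
  rownames(covariate_tests) <- NULL
  list(correlations = correlations, covariate_tests = covariate_tests)
}
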
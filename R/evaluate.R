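# Evaluation: Pearson correlation per track over the pooled bins of all
# evaluated windows, averaged (unweighted) over tracks, optionally stratified
# by residual-homology bin.

#' Pearson correlation coefficient
#'
#' Standard Pearson r (covariance over the product of standard deviations).
#' If either vector is constant the correlation is undefined; by policy the
#' function returns 0 with a warning so that batch evaluation never crashes.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return r in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y))
    stop_s2t("length mismatch: %d vs %d", length(x), length(y))
  if (length(x) < 2L) stop_s2t("need at least 2 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector in pearson(); returning 0 by policy", call. = FALSE)
    return(0)
  }
  r <- cor(x, y)
  min(1, max(-1, r))
}

#' Evaluate a model on a dataset split
#'
#' Per track, the Pearson correlation is computed over the concatenation of
#' all bins of all evaluated windows; the reported metric is the unweighted
#' mean over tracks. When homology assignments are supplied, the same
#' statistic is additionally reported per homology bin of the test windows.
#'
#' @param model a single-head `s2t_model` whose track count matches the
#'   dataset.
#' @param data an `s2t_dataset`.
#' @param split_label which split to evaluate (`"validation"` or `"test"`
#'   typically).
#' @param assignments optional data.frame from [assign_regions()]; enables
#'   the per-homology-bin report.
#' @param bin_edges homology bin edges (see [homology_bins()]).
#' @param per_example if `TRUE`, r is computed per window and averaged
#'   instead of pooled (sensitivity-analysis variant).
#' @return an `s2t_eval_report`: list with `per_track_r`, `mean_r`,
#'   `per_homology_bin_r`, `n_examples`, `n_bins`, `n_tracks`.
#' @export
evaluate <- function(model, data, split_label = "test", assignments = NULL,
                     bin_edges = c(0, 0.1, 0.5, 1), per_example = FALSE) {
  ex <- data$examples[vapply(data$examples, `[[`, "", "split") == split_label]
  if (!length(ex)) stop_s2t("no windows with split label '%s'", split_label)
  nt <- length(data$track_names)
  if (model$config$head_track_counts[1] != nt)
    stop_s2t("model head emits %d track(s) but the dataset has %d",
             model$config$head_track_counts[1], nt)
  preds <- lapply(ex, function(e) forward(model, e$x)[[1]])
  targs <- lapply(ex, `[[`, "y")
  per_track <- vapply(seq_len(nt), function(t) {
    if (per_example) {
      mean(vapply(seq_along(ex), function(i)
        suppress_constant_warning(pearson(preds[[i]][, t], targs[[i]][, t])),
        numeric(1)))
    } else {
      p <- unlist(lapply(preds, function(m) m[, t]))
      y <- unlist(lapply(targs, function(m) m[, t]))
      suppress_constant_warning(pearson(p, y))
    }
  }, numeric(1))
  names(per_track) <- data$track_names
  report <- list(per_track_r = per_track, mean_r = mean(per_track),
                 per_homology_bin_r = NULL,
                 n_examples = length(ex), n_bins = data$n_bins, n_tracks = nt)
  if (!is.null(assignments)) {
    hb <- homology_bins(assignments, bin_edges, label_filter = split_label)
    ids <- vapply(ex, `[[`, "", "id")
    bin_r <- lapply(hb$bins, function(binids) {
      sel <- which(ids %in% binids)
      if (length(sel) == 0L) return(NA_real_)
      mean(vapply(seq_len(nt), function(t) {
        p <- unlist(lapply(preds[sel], function(m) m[, t]))
        y <- unlist(lapply(targs[sel], function(m) m[, t]))
        if (length(p) < 2L) return(NA_real_)
        suppress_constant_warning(pearson(p, y))
      }, numeric(1)))
    })
    report$per_homology_bin_r <- unlist(bin_r)
    report$per_homology_bin_n <- vapply(hb$bins, function(binids)
      sum(ids %in% binids), integer(1))
  }
  structure(report, class = "s2t_eval_report")
}

#' Both Pearson denominators, for sensitivity reporting
#'
#' Returns the standard Pearson coefficient (square-rooted denominator)
#' alongside the variant that divides by the product of the variances
#' without a square root. The unsquared form is not bounded by 1 and is
#' provided for comparison only; every reported metric in this package uses
#' the standard definition.
#'
#' @param x,y numeric vectors of equal length.
#' @return named numeric vector `c(standard, unsquared)`.
#' @export
pearson_variants <- function(x, y) {
  r <- pearson(x, y)
  vx <- stats::var(x); vy <- stats::var(y)
  un <- if (vx == 0 || vy == 0) 0 else stats::cov(x, y) / (vx * vy)
  c(standard = r, unsquared = un)
}

suppress_constant_warning <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("constant vector", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' @export
print.s2t_eval_report <- function(x, ...) {
  cat(sprintf("s2t_eval_report: %d windows x %d bins x %d tracks; mean r = %.4f\n",
              x$n_examples, x$n_bins, x$n_tracks, x$mean_r))
  if (!is.null(x$per_homology_bin_r)) {
    cat("  per homology bin:\n")
    for (nm in names(x$per_homology_bin_r))
      cat(sprintf("    %-12s n=%-4d r=%.4f\n", nm, x$per_homology_bin_n[[nm]],
                  x$per_homology_bin_r[[nm]]))
  }
  invisible(x)
}

#' Write an evaluation report
#'
#' Per-track (and, when present, per-homology-bin) correlations as TSV plus
#' a JSON summary.
#'
#' @param report an `s2t_eval_report`.
#' @param prefix output path prefix (writes `<prefix>_tracks.tsv` and
#'   `<prefix>_summary.json`).
#' @return `prefix`, invisibly.
#' @export
write_eval_report <- function(report, prefix) {
  write.table(data.frame(track = names(report$per_track_r),
                         r = unname(report$per_track_r)),
              paste0(prefix, "_tracks.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(mean_r = report$mean_r, n_examples = report$n_examples,
         n_bins = report$n_bins, n_tracks = report$n_tracks,
         per_homology_bin_r = as.list(report$per_homology_bin_r %||% list())),
    paste0(prefix, "_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
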
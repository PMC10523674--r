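# Benchmark harness: per-nerve metrics, method comparisons with
# nonparametric statistics, and report generation.

#' Score a calibration with the sensation quality index
#'
#' Queries the subject once at the converged high-level parameters for
#' the final report (including the in-loco component) and applies
#' [quality_index()]: `I` = target intensity reached, `T` = comfortable,
#' `L` = somatotopic, discounted by `SE`. A non-converged calibration is
#' scored with `I = 0` (and no credit at all when there are no final
#' parameters).
#'
#' @param result A `calibration_result`.
#' @param subject The `subject_interface` that was calibrated.
#' @param weights A [quality_weights()] vector.
#' @return A score in `[0, 1]`.
#' @export
score_result <- function(result, subject, weights = quality_weights()) {
  p <- result$high_params
  if (is.null(p)) return(0)
  rep1 <- subject$respond(p$pa, p$pw)
  if (rep1$intensity == "NP") return(0)
  I <- as.numeric(rep1$intensity == "HIGH" &&
                    isTRUE(result$converged[["high"]]))
  quality_index(I, type_code(rep1$stype), location_code(rep1$location),
                rep1$se, weights)
}

#' Proxy calibration time
#'
#' A simulation proxy for wall-clock mapping duration:
#' `n_stims * (t_stim + t_report)` seconds, covering the stimulation
#' train plus the subject's report for every delivered stimulus. The
#' defaults (5 s per train including margins, 15 s per report) are
#' illustrative constants, not measured times.
#'
#' @param result A `calibration_result`.
#' @param t_stim,t_report Per-stimulus constants (s), > 0.
#' @return Seconds.
#' @export
proxy_time <- function(result, t_stim = 5, t_report = 15) {
  stopifnot(t_stim > 0, t_report > 0)
  result$n_stims * (t_stim + t_report)
}

#' Run the calibration benchmark over a cohort
#'
#' Runs every requested method (closed-loop RL, brute-force ramp,
#' scripted naive protocol) on every subject of the cohort and collects
#' one record per subject x method: stimulus count, converged low/high
#' charges, quality score, proxy time and convergence flags. A method
#' failure on a subject is recorded, not raised.
#'
#' @param cohort A cohort of [virtual_subject()]s.
#' @param agent_low,agent_high Trained agents (needed for method `"RL"`).
#' @param dataset Reference trial tibble for initialization.
#' @param methods Subset of `c("RL", "BFA", "naive")`.
#' @param limits A [calib_limits()].
#' @param grid A [stim_grid()].
#' @param weights [quality_weights()] for the quality score.
#' @param t_stim,t_report [proxy_time()] constants.
#' @return A tibble of benchmark records (class `benchmark_records`).
#' @export
run_benchmark <- function(cohort, agent_low = NULL, agent_high = NULL,
                          dataset, methods = c("RL", "BFA", "naive"),
                          limits = calib_limits(), grid = stim_grid(),
                          weights = quality_weights(),
                          t_stim = 5, t_report = 15) {
  methods <- match.arg(methods, several.ok = TRUE)
  if ("RL" %in% methods && (is.null(agent_low) || is.null(agent_high)))
    stop("RL benchmarking needs both trained agents", call. = FALSE)
  rows <- list()
  for (s in cohort) {
    si <- subject_interface(s)
    for (m in methods) {
      res <- switch(m,
        RL = run_calibration(agent_low, agent_high, si, dataset, limits,
                             grid),
        BFA = bfa_calibrate(si, dataset, limits, grid),
        naive = naive_calibrate(si, limits, grid))
      qc <- function(p, conv) if (is.null(p) || !conv) NA_real_
        else p$pa * p$pw / 1000
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = s$subject_id, nerve = s$nerve,
        neuropathic = as.integer(s$neuropathic), method = m,
        n_stims = res$n_stims,
        charge_low = qc(res$low_params, res$converged[["low"]]),
        charge_high = qc(res$high_params, res$converged[["high"]]),
        quality = as.numeric(score_result(res, si, weights)),
        proxy_time = proxy_time(res, t_stim, t_report),
        converged_low = res$converged[["low"]],
        converged_high = res$converged[["high"]])
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("benchmark_records", class(out))
  out
}

#' Summarize benchmark records
#'
#' Per-method mean and standard deviation of every metric, reported to
#' two decimals.
#'
#' @param records A [run_benchmark()] tibble.
#' @return A summary tibble.
#' @export
summarize_benchmark <- function(records) {
  records |>
    tidyr::pivot_longer(c("n_stims", "charge_low", "charge_high",
                          "quality", "proxy_time"),
                        names_to = "metric") |>
    dplyr::group_by(.data$method, .data$metric) |>
    dplyr::summarize(
      mean = round(mean(.data$value, na.rm = TRUE), 2),
      sd = round(stats::sd(.data$value, na.rm = TRUE), 2),
      n = dplyr::n(), .groups = "drop")
}

#' Bar plot of a benchmark metric per method
#'
#' @param object A [run_benchmark()] tibble.
#' @param metric Metric column to plot.
#' @param ... Unused.
#' @return A ggplot object (mean +- SD bars).
#' @method autoplot benchmark_records
#' @export
autoplot.benchmark_records <- function(object, metric = "n_stims", ...) {
  df <- summarize_benchmark(object) |>
    dplyr::filter(.data$metric == !!metric)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$mean,
                                   fill = .data$method)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' Nonparametric comparison of calibration methods
#'
#' For each metric: a Kolmogorov-Smirnov normality screen per method
#' (reported only — the pipeline stays nonparametric regardless), a
#' Friedman omnibus test across methods paired by subject x nerve, and
#' pairwise Wilcoxon signed-rank post-hoc tests flagged at the
#' Bonferroni-corrected level `alpha / n_pairs` (0.05 / 6 = 0.0083 for
#' four methods). For a two-group healthy-versus-neuropathic contrast use
#' [compare_groups()].
#'
#' @param records A [run_benchmark()] tibble.
#' @param metrics Metric columns to compare.
#' @param alpha Family-wise significance level before correction.
#' @return A tibble of test results (`metric`, `test`, `comparison`,
#'   `statistic`, `p_value`, `threshold`, `significant`).
#' @export
compare_methods <- function(records,
                            metrics = c("n_stims", "quality",
                                        "proxy_time"),
                            alpha = 0.05) {
  methods <- sort(unique(records$method))
  if (length(methods) < 2)
    stop("need at least two methods to compare", call. = FALSE)
  pairs_idx <- utils::combn(methods, 2, simplify = FALSE)
  threshold <- alpha / length(pairs_idx)
  out <- list()
  for (met in metrics) {
    wide <- records |>
      dplyr::select("subject_id", "nerve", "method",
                    value = dplyr::all_of(met)) |>
      tidyr::pivot_wider(names_from = "method", values_from = "value")
    miss <- !stats::complete.cases(wide[methods])
    if (any(miss))
      stop(sprintf("metric %s: missing %s for subject %s", met,
                   methods[which(is.na(wide[miss, ][1, methods]))[1]],
                   wide$subject_id[miss][1]), call. = FALSE)
    for (m in methods) {
      x <- wide[[m]]
      ks <- suppressWarnings(
        stats::ks.test((x - mean(x)) / max(stats::sd(x), 1e-12), "pnorm"))
      out[[length(out) + 1L]] <- tibble::tibble(
        metric = met, test = "ks_normality", comparison = m,
        statistic = unname(ks$statistic), p_value = ks$p.value,
        threshold = NA_real_, significant = NA)
    }
    fr <- stats::friedman.test(as.matrix(wide[methods]))
    fr_p <- if (is.nan(fr$p.value)) 1 else fr$p.value # all-tied rows
    out[[length(out) + 1L]] <- tibble::tibble(
      metric = met, test = "friedman",
      comparison = paste(methods, collapse = "|"),
      statistic = unname(fr$statistic), p_value = fr_p,
      threshold = alpha, significant = fr_p < alpha)
    for (pr in pairs_idx) {
      d <- wide[[pr[1]]] - wide[[pr[2]]]
      if (all(d == 0)) {
        # identical vectors carry no evidence of a shift
        w <- list(statistic = 0, p.value = 1)
      } else {
        w <- suppressWarnings(
          stats::wilcox.test(wide[[pr[1]]], wide[[pr[2]]], paired = TRUE))
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        metric = met, test = "wilcoxon_signed_rank",
        comparison = paste(pr, collapse = " vs "),
        statistic = unname(w$statistic), p_value = w$p.value,
        threshold = threshold, significant = w$p.value < threshold)
    }
  }
  dplyr::bind_rows(out)
}

#' Mann-Whitney comparison of two independent cohorts
#'
#' Rank-sum test of a metric between two groups of records (e.g. healthy
#' versus neuropathic synthetic cohorts), per method.
#'
#' @param records_a,records_b Benchmark record tibbles.
#' @param metrics Metric columns to compare.
#' @return A tibble of test results.
#' @export
compare_groups <- function(records_a, records_b,
                           metrics = c("charge_low", "charge_high")) {
  out <- list()
  for (m in intersect(unique(records_a$method),
                      unique(records_b$method))) {
    for (met in metrics) {
      x <- records_a[records_a$method == m, ][[met]]
      y <- records_b[records_b$method == m, ][[met]]
      w <- suppressWarnings(stats::wilcox.test(x, y))
      out[[length(out) + 1L]] <- tibble::tibble(
        method = m, metric = met, test = "mann_whitney",
        statistic = unname(w$statistic), p_value = w$p.value,
        mean_a = mean(x, na.rm = TRUE), mean_b = mean(y, na.rm = TRUE))
    }
  }
  dplyr::bind_rows(out)
}

#' Write a Markdown benchmark report
#'
#' @param records A [run_benchmark()] tibble.
#' @param path Output file.
#' @param stats Optional [compare_methods()] tibble to append.
#' @return `path`, invisibly.
#' @export
write_benchmark_report <- function(records, path, stats = NULL) {
  summ <- summarize_benchmark(records)
  lines <- c("# Calibration benchmark", "",
             sprintf("Records: %d (%d subjects, methods: %s)",
                     nrow(records), length(unique(records$subject_id)),
                     paste(sort(unique(records$method)), collapse = ", ")),
             "", "## Per-method summary (mean ± SD)", "")
  for (i in seq_len(nrow(summ)))
    lines <- c(lines, sprintf("- %s / %s: %.2f ± %.2f (n = %d)",
                              summ$method[i], summ$metric[i], summ$mean[i],
                              summ$sd[i], summ$n[i]))
  if (!is.null(stats)) {
    lines <- c(lines, "", "## Statistics", "")
    for (i in seq_len(nrow(stats)))
      lines <- c(lines, sprintf(
        "- %s / %s / %s: statistic = %.3g, p = %.3g%s",
        stats$metric[i], stats$test[i], stats$comparison[i],
        stats$statistic[i], stats$p_value[i],
        ifelse(isTRUE(stats$significant[i]), " (significant)", "")))
  }
  writeLines(lines, path)
  invisible(path)
}
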
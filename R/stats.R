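#' Per-index two-group comparisons
#'
#' Group summary tables and two-tailed t-tests for the 40 harmonic
#' indices, with significance at p < 0.05 and no multiple-testing
#' correction by default (40 raw tests; a Benjamini-Hochberg option is
#' available). The Welch variant is the default; the pooled-variance
#' test is available by configuration.
#'
#' @name stats-module
NULL

#' Two-group comparison of one index
#'
#' @param values_a,values_b numeric vectors (>= 2 finite values each).
#' @param var_equal pooled-variance test if `TRUE`; Welch (default)
#'   otherwise.
#' @param alpha significance level (default 0.05).
#' @return list: `t`, `df`, `p`, `significant`, `mean_a`, `mean_b`,
#'   `sd_a`, `sd_b`, `n_a`, `n_b`. When both groups have zero variance
#'   and equal means the convention `t = 0, p = 1` applies.
#' @export
group_compare <- function(values_a, values_b, var_equal = FALSE,
                          alpha = 0.05) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) < 2L || length(b) < 2L || any(!is.finite(c(a, b))))
    stop("need >= 2 finite values per group")
  out <- list(mean_a = mean(a), mean_b = mean(b),
              sd_a = sd(a), sd_b = sd(b),
              n_a = length(a), n_b = length(b))
  tt <- tryCatch(t.test(a, b, var.equal = var_equal),
                 error = function(e) NULL)
  if (is.null(tt)) {             # degenerate: essentially constant data
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      out$t <- 0; out$df <- length(a) + length(b) - 2; out$p <- 1
    } else {
      out$t <- sign(mean(a) - mean(b)) * Inf
      out$df <- length(a) + length(b) - 2; out$p <- 0
    }
  } else {
    out$t <- unname(tt$statistic)
    out$df <- unname(tt$parameter)
    out$p <- tt$p.value
  }
  out$significant <- out$p < alpha
  out
}

#' Index comparison table (40 rows)
#'
#' Compares every harmonic index between two groups. Per-beat indices
#' (`C_n`, `P_n`) are compared at pulse level and windowed indices
#' (`CV_n`, `P_n_SD`) at window level by default, since that is the
#' level at which each index exists; `unit_of_analysis = "subject"`
#' first averages each index within subject, which avoids the
#' effective-sample-size inflation of pulse-level tests (serially
#' correlated beats) and is the calibrated choice for inference.
#'
#' @param beats per-beat index table ([beat_indices()] rows for all
#'   subjects, with `label` and `subject_id`).
#' @param windows feature table ([assemble_features()] rows for all
#'   subjects) supplying `CV_n` and `P_n_SD`.
#' @param grouping column used to form the two groups (default
#'   `"label"`).
#' @param group_levels optional length-2 character vector selecting and
#'   ordering the two groups (difference is group1 - group2).
#' @param unit_of_analysis `"default"` (pulse for C/P, window for
#'   CV/P_SD) or `"subject"`.
#' @param var_equal,alpha see [group_compare()].
#' @param adjust `"none"` (default, matching the raw-alpha protocol) or
#'   `"BH"`.
#' @param n_max number of harmonics.
#' @return data.frame with 4 * n_max rows in canonical order: index,
#'   unit, group means/SDs/n, difference, t, df, p, significant.
#' @export
comparison_table <- function(beats, windows, grouping = "label",
                             group_levels = NULL,
                             unit_of_analysis = c("default", "subject"),
                             var_equal = FALSE, alpha = 0.05,
                             adjust = c("none", "BH"), n_max = 10) {
  unit_of_analysis <- match.arg(unit_of_analysis)
  adjust <- match.arg(adjust)
  beats <- as.data.frame(beats); windows <- as.data.frame(windows)
  lv <- group_levels %||% sort(unique(as.character(beats[[grouping]])))
  if (length(lv) != 2L) stop("grouping must yield exactly two groups; got: ",
                             paste(lv, collapse = ", "))
  circ_mean <- function(p) {
    r <- p * pi / 180
    atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
  }
  is_phase <- function(col) col %in% paste0("P", 1:n_max)
  pull <- function(df, col, grp) {
    v <- df[df[[grouping]] == grp, col]
    if (unit_of_analysis == "subject") {
      # phases are angles: aggregate within subject by the circular
      # mean (an arithmetic mean across the +-180 branch cut is
      # meaningless and heavy-tailed for weak harmonics)
      agg <- if (is_phase(col)) circ_mean else mean
      v <- as.numeric(tapply(v, df$subject_id[df[[grouping]] == grp], agg))
    }
    v[is.finite(v)]
  }
  specs <- rbind(
    data.frame(index = paste0("C", 1:n_max), src = "beats",
               unit = if (unit_of_analysis == "subject") "subject" else "pulse"),
    data.frame(index = paste0("CV", 1:n_max), src = "windows",
               unit = if (unit_of_analysis == "subject") "subject" else "window"),
    data.frame(index = paste0("P", 1:n_max), src = "beats",
               unit = if (unit_of_analysis == "subject") "subject" else "pulse"),
    data.frame(index = paste0("P", 1:n_max, "_SD"), src = "windows",
               unit = if (unit_of_analysis == "subject") "subject" else "window"))
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    df <- if (specs$src[i] == "beats") beats else windows
    if (nrow(df[df[[grouping]] == lv[1], ]) == 0L ||
        nrow(df[df[[grouping]] == lv[2], ]) == 0L)
      stop("empty group under grouping `", grouping, "`")
    g <- group_compare(pull(df, specs$index[i], lv[1]),
                       pull(df, specs$index[i], lv[2]),
                       var_equal = var_equal, alpha = alpha)
    data.frame(index = specs$index[i], unit = specs$unit[i],
               group1 = lv[1], group2 = lv[2],
               mean1 = g$mean_a, sd1 = g$sd_a, n1 = g$n_a,
               mean2 = g$mean_b, sd2 = g$sd_b, n2 = g$n_b,
               difference = g$mean_a - g$mean_b,
               t = g$t, df = g$df, p = g$p)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p, "BH")
  out$significant <- (if (adjust == "BH") out$p_adjusted else out$p) < alpha
  out
}

#' Render a comparison table as text
#'
#' Compact mean ± SD listing with significance marks, one line per
#' index.
#'
#' @param table a [comparison_table()] result.
#' @return character vector of formatted lines (invisibly printed).
#' @export
format_comparison <- function(table) {
  lines <- sprintf("%-8s %10.3f ± %-8.3f %10.3f ± %-8.3f  p=%-8.3g %s",
                   table$index, table$mean1, table$sd1, table$mean2,
                   table$sd2, table$p,
                   ifelse(table$significant, "*", ""))
  header <- sprintf("%-8s %21s %21s  %s", "index",
                    paste0(table$group1[1], " (mean±SD)"),
                    paste0(table$group2[1], " (mean±SD)"), "p")
  c(header, lines)
}
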
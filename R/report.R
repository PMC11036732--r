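#' Summarise the packaged reference tables
#'
#' Recomputes, from the packaged per-tap averages and per-subject widths,
#' every group summary the pipeline reports: the mean/SD row of the per-tap
#' table (six columns: reflex and non-reflex for iPD before medication, iPD
#' after medication, and healthy controls), the four patient width means,
#' the two healthy-control width means, and the between-group rank-sum
#' comparisons that are computable from per-subject values (width
#' comparisons; the per-tap count comparisons would need per-subject raw
#' counts, which the tables do not carry). NaN cells are excluded exactly
#' as footnoted ("there is no blinking").
#'
#' @param fixtures output of [load_paper_fixtures()].
#' @return List with `table1_mean_sd`, `table2_means`, `table3_means`,
#'   `comparisons` (list of `gtr_comparison`).
#' @export
summarize_fixtures <- function(fixtures = load_paper_fixtures()) {
  t1 <- fixtures$table1; t2 <- fixtures$table2; t3 <- fixtures$table3
  t1_rows <- do.call(rbind, lapply(split(t1, list(t1$group, t1$category)), function(d) {
    g <- group_mean_sd(d$value)
    data.frame(group = d$group[1], category = d$category[1],
               mean = g$mean, sd = g$sd, n_taps = g$n_used)
  }))
  rownames(t1_rows) <- NULL
  t2_means <- lapply(list(reflex_bm = t2$width_reflex_bm,
                          reflex_am = t2$width_reflex_am,
                          non_reflex_bm = t2$width_nonreflex_bm,
                          non_reflex_am = t2$width_nonreflex_am),
                     group_mean_sd)
  t3_means <- lapply(list(reflex_hc = t3$width_reflex_s,
                          non_reflex_hc = t3$width_nonreflex_s),
                     group_mean_sd)
  comparisons <- list(
    rank_sum_test(t2$width_reflex_bm, t2$width_reflex_am, "width_reflex_BM-AM"),
    rank_sum_test(t2$width_nonreflex_bm, t2$width_nonreflex_am, "width_non_reflex_BM-AM"),
    rank_sum_test(t2$width_reflex_bm, t3$width_reflex_s, "width_reflex_BM-HC"),
    rank_sum_test(t2$width_reflex_am, t3$width_reflex_s, "width_reflex_AM-HC"),
    rank_sum_test(t2$width_nonreflex_bm, t3$width_nonreflex_s, "width_non_reflex_BM-HC"),
    rank_sum_test(t2$width_nonreflex_am, t3$width_nonreflex_s, "width_non_reflex_AM-HC"))
  list(table1_mean_sd = t1_rows, table2_means = t2_means,
       table3_means = t3_means, comparisons = comparisons)
}

#' Summarise an analysed cohort of subjects
#'
#' Cohort-level rollup of per-subject event summaries: the per-tap group
#' table with its mean/SD row, per-group average blink widths, and pairwise
#' rank-sum comparisons of the per-subject width averages.
#'
#' @param records list of `gtr_subject`.
#' @param n_taps tap ordinals to tabulate (default 8).
#' @return Same shape as [summarize_fixtures()] plus the full `tap_table`.
#' @export
summarize_cohort <- function(records, n_taps = 8L) {
  tt <- tap_average_table(records, n_taps)
  groups <- unique(vapply(records, function(r) r$group, character(1)))
  widths <- function(g, field) vapply(records[vapply(records, function(r)
    r$group == g, logical(1))], function(r) r[[field]], numeric(1))
  width_means <- list()
  for (g in groups) {
    width_means[[paste0("reflex_", g)]] <-
      group_mean_sd(widths(g, "avg_width_reflex_s"))
    width_means[[paste0("non_reflex_", g)]] <-
      group_mean_sd(widths(g, "avg_width_non_reflex_s"))
  }
  comparisons <- list()
  if (length(groups) > 1L) {
    for (pair in utils::combn(groups, 2L, simplify = FALSE)) {
      for (field in c("avg_width_reflex_s", "avg_width_non_reflex_s")) {
        x <- widths(pair[1], field); y <- widths(pair[2], field)
        if (any(is.finite(x)) && any(is.finite(y)))
          comparisons[[length(comparisons) + 1L]] <-
            rank_sum_test(x, y, sprintf("%s_%s-%s",
                                        sub("avg_", "", field), pair[1], pair[2]))
      }
    }
  }
  list(tap_table = tt, table1_mean_sd = tt$mean_sd,
       width_means = width_means, comparisons = comparisons)
}

comparison_frame <- function(comparisons) {
  if (!length(comparisons))
    return(data.frame(label = character(0), n_x = integer(0), n_y = integer(0),
                      statistic = numeric(0), p_value = numeric(0),
                      method = character(0), significant = character(0)))
  do.call(rbind, lapply(comparisons, function(cmp)
    data.frame(label = cmp$label, n_x = cmp$n_x, n_y = cmp$n_y,
               statistic = cmp$statistic, p_value = cmp$p_value,
               method = cmp$method,
               significant = if (cmp$p_value < 0.05) "*" else "")))
}

#' Write a structured analysis report
#'
#' Emits a machine-readable `report.json` plus one CSV per table into
#' `out_dir`, with significance stars at p < 0.05 and the resolved
#' configuration echoed for provenance. Optionally writes diagnostic plots
#' (per-tap line chart of group averages; box plots of width
#' distributions) as PNG files. All files are written atomically
#' (temp-then-rename).
#'
#' @param summary output of [summarize_fixtures()] or [summarize_cohort()].
#' @param out_dir output directory (created if needed).
#' @param config optional configuration list echoed into the report.
#' @param plots logical; write PNG plots (requires a PNG device).
#' @return The report list, invisibly.
#' @export
build_report <- function(summary, out_dir, config = NULL, plots = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cmp <- comparison_frame(summary$comparisons)
  report <- list(tables = summary[setdiff(names(summary), "comparisons")],
                 comparisons = cmp, config = config)
  write_atomic(file.path(out_dir, "report.json"), function(p)
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                         na = "string", force = TRUE))
  write_atomic(file.path(out_dir, "comparisons.csv"), function(p)
    utils::write.csv(cmp, p, row.names = FALSE))
  if (!is.null(summary$table1_mean_sd))
    write_atomic(file.path(out_dir, "table_mean_sd.csv"), function(p)
      utils::write.csv(summary$table1_mean_sd, p, row.names = FALSE))
  if (!is.null(summary$tap_table))
    write_atomic(file.path(out_dir, "tap_table.csv"), function(p)
      utils::write.csv(summary$tap_table$cells, p, row.names = FALSE))
  if (plots && !is.null(summary$tap_table) &&
      capabilities("png")) {
    f <- file.path(out_dir, "tapwise_averages.png")
    grDevices::png(f, width = 800, height = 500)
    cells <- summary$tap_table$cells
    refl <- cells[cells$category == "reflex", ]
    groups <- unique(refl$group)
    plot(NULL, xlim = range(refl$tap), ylim = range(refl$value, na.rm = TRUE),
         xlab = "tap number", ylab = "average reflex blinks",
         main = "Per-tap average reflex blink count")
    for (i in seq_along(groups)) {
      d <- refl[refl$group == groups[i], ]
      graphics::lines(d$tap, d$value, col = i, type = "b", pch = 19)
    }
    graphics::legend("topright", legend = groups, col = seq_along(groups), lty = 1)
    grDevices::dev.off()
  }
  invisible(report)
}

write_atomic <- function(path, writer) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}
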
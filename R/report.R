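#' Run the full condemnation-surveillance pipeline
#'
#' Orchestrates every analysis stage on one dataset and writes tidy CSV
#' outputs plus (optionally) figures to `out_dir`: `coi.csv` (monthly COI per
#' scope), `freq.csv` (cause-frequency table), `asi.csv` (per-calendar-month
#' ASI per eligible cause), `groups.csv` (A/B comparison per variable),
#' `correlations.csv` (long-form Spearman rho with strength labels),
#' `tukey.csv` (month-pair contrasts per cause), `asi_tests.csv` (one-sample
#' tests against 1), and `run_log.txt`. Every numeric cell is produced by the
#' corresponding exported function; the writer does no arithmetic of its own.
#' On any stage failure the partially written output directory is removed.
#'
#' @param input a `condemnation_data` object or path to an input CSV
#' @param out_dir output directory (created if needed)
#' @param exclude months to flag, "YYYY-MM" strings (e.g. c("2017-06"))
#' @param scale COI scaling constant
#' @param alpha significance level for the logged summaries
#' @param denominator frequency-table percent policy
#' @param plots also write figure files (PNG)?
#' @return (invisibly) a list with every stage result
#' @export
run_pipeline <- function(input, out_dir, exclude = character(0), scale = 1e6,
                         alpha = 0.05, denominator = "sum_of_causes",
                         plots = TRUE) {
  stopifnot(alpha > 0, alpha < 1, scale > 0)
  ds <- if (inherits(input, "condemnation_data")) input else read_dataset(input)
  created <- !dir.exists(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      if (created) unlink(out_dir, recursive = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }
  note("condemnr %s pipeline run, %s", as.character(utils::packageVersion("condemnr")),
       format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  note("input: %s", ds$provenance)
  if (length(exclude) > 0) {
    ds <- run("exclusions", flag_exclusions(ds, exclude))
    note("excluded months: %s", paste(exclude, collapse = ", "))
  }
  asi_causes <- intersect(ds$causes$code[ds$causes$asi_eligible], dataset_causes(ds))

  scopes <- c("total", dataset_causes(ds))
  coi_tbl <- run("coi", dplyr::bind_rows(lapply(scopes, function(sc) {
    s <- coi_series(ds, sc, scale)
    tibble::tibble(scope = sc, year = s$year, month = s$month, value = s$value)
  })))
  freq <- run("frequency", frequency_table(ds, denominator = denominator))
  groups_tbl <- run("groups", {
    grp <- assign_groups(ds)
    note("group sizes: A=%d B=%d UNCLASSIFIED=%d",
         sum(grp$group == "A"), sum(grp$group == "B"),
         sum(grp$group == "UNCLASSIFIED"))
    dplyr::bind_rows(lapply(scopes, function(sc) {
      gc <- tryCatch(compare_groups(ds, sc), error = function(e) NULL)
      if (is.null(gc)) return(NULL)
      w <- tidyr::pivot_wider(gc$summary, names_from = "group",
                              values_from = c("n", "mean", "sd", "se"))
      dplyr::bind_cols(tibble::tibble(variable = gc$variable), w,
                       tibble::tibble(p_value = gc$p_value,
                                      rank_biserial = gc$rank_biserial,
                                      point_biserial = gc$point_biserial))
    }))
  })
  corr <- run("correlation", spearman_matrix(ds, asi_causes))
  corr_long <- tibble::as_tibble(as.data.frame.table(corr$rho,
                                                     responseName = "rho")) |>
    dplyr::rename(cause_a = "Var1", cause_b = "Var2") |>
    dplyr::mutate(strength = correlation_strength(.data$rho))
  asi_stages <- run("asi", lapply(setNames(asi_causes, asi_causes), function(cc) {
    compute_asi(coi_series(ds, cc, scale))
  }))
  asi_tbl <- dplyr::bind_rows(lapply(asi_causes, function(cc) {
    dplyr::mutate(asi_stages[[cc]]$asi, scope = cc, .before = 1)
  }))
  tukey_tbl <- run("tukey", dplyr::bind_rows(lapply(asi_causes, function(cc) {
    dplyr::mutate(asi_month_anova(asi_stages[[cc]]$ratios, alpha)$tukey,
                  scope = cc, .before = 1)
  })))
  tests_tbl <- run("asi_tests", dplyr::bind_rows(lapply(asi_causes, function(cc) {
    dplyr::mutate(asi_vs_one_all(asi_stages[[cc]]$ratios), scope = cc,
                  .before = 1)
  })))
  note("significant Tukey pairs at alpha=%g: %d", alpha,
       sum(tukey_tbl$p_adj < alpha, na.rm = TRUE))

  readr::write_csv(coi_tbl, file.path(out_dir, "coi.csv"), progress = FALSE)
  readr::write_csv(freq, file.path(out_dir, "freq.csv"), progress = FALSE)
  readr::write_csv(asi_tbl, file.path(out_dir, "asi.csv"), progress = FALSE)
  readr::write_csv(groups_tbl, file.path(out_dir, "groups.csv"), progress = FALSE)
  readr::write_csv(corr_long, file.path(out_dir, "correlations.csv"), progress = FALSE)
  readr::write_csv(tukey_tbl, file.path(out_dir, "tukey.csv"), progress = FALSE)
  readr::write_csv(tests_tbl, file.path(out_dir, "asi_tests.csv"), progress = FALSE)
  if (plots) {
    run("plots", {
      ggplot2::ggsave(file.path(out_dir, "coi_series.png"),
                      plot_coi(coi_series(ds, "total", scale)),
                      width = 8, height = 4, dpi = 150)
      ggplot2::ggsave(file.path(out_dir, "asi_by_month.png"),
                      plot_asi(asi_tbl), width = 8, height = 6, dpi = 150)
      ggplot2::ggsave(file.path(out_dir, "correlation_heatmap.png"),
                      plot_correlation(corr), width = 6, height = 5, dpi = 150)
    })
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(dataset = ds, coi = coi_tbl, freq = freq, asi = asi_tbl,
                 groups = groups_tbl, correlations = corr_long,
                 tukey = tukey_tbl, asi_tests = tests_tbl))
}

#' Line plot of a monthly COI series with a linear trend
#' @param series a [coi_series()]
#' @return a ggplot object
#' @export
plot_coi <- function(series) {
  d <- dplyr::mutate(tibble::as_tibble(series),
                     date = .data$year + (.data$month - 0.5) / 12)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$date, y = .data$value)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.6) +
    ggplot2::labs(x = NULL,
                  y = sprintf("COI (per %s head)",
                              format(attr(series, "scale"), big.mark = ",")),
                  title = sprintf("Condemnation occurrence index: %s",
                                  attr(series, "scope"))) +
    ggplot2::theme_minimal()
}

#' Bar plot of ASI by calendar month, faceted by cause
#' @param asi_tbl tibble with columns `scope`, `month`, `asi`
#' @return a ggplot object
#' @export
plot_asi <- function(asi_tbl) {
  ggplot2::ggplot(asi_tbl, ggplot2::aes(x = factor(.data$month), y = .data$asi)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::facet_wrap(~scope) +
    ggplot2::labs(x = "calendar month", y = "adjusted seasonal index") +
    ggplot2::theme_minimal()
}

#' Heatmap of the Spearman correlation matrix
#' @param corr a `correlation_report`
#' @return a ggplot object
#' @export
plot_correlation <- function(corr) {
  d <- tibble::as_tibble(as.data.frame.table(corr$rho, responseName = "rho"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$Var1, y = .data$Var2,
                                  fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rho)),
                       size = 2.6) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
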
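#' Rank-biserial correlation from two samples
#'
#' Effect size for a two-group rank comparison: 2*AUC - 1, where AUC is the
#' probability (with ties counted half) that a value from `x` exceeds a value
#' from `y`. Equals +1 when `x` lies entirely above `y`, -1 in the reverse
#' case, 0 under stochastic equality.
#'
#' @param x,y numeric samples
#' @return scalar in [-1, 1]
#' @export
rank_biserial <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  u <- unname(suppressWarnings(wilcox.test(x, y, exact = FALSE))$statistic)
  2 * u / (length(x) * length(y)) - 1
}

#' Point-biserial correlation between a value and a group indicator
#'
#' Pearson correlation of the values against a 0/1 group code; signed so that
#' a positive value means the first group exceeds the second.
#'
#' @param x,y numeric samples (first and second group)
#' @return scalar in [-1, 1]
#' @export
point_biserial <- function(x, y) {
  v <- c(x, y)
  g <- c(rep(1, length(x)), rep(0, length(y)))
  stats::cor(v, g)
}

#' Compare species-mix month groups on a condemnation rate
#'
#' Each month's outcome is the percentage 100 * condemned / total slaughtered
#' for the requested scope. Months are split by [assign_groups()] into Group A
#' (turkey slaughtered alongside chicken) and Group B (heavy chicken only);
#' UNCLASSIFIED months are dropped. Groups are compared with a Welch
#' (unequal-variance) two-sample t test; the effect size is reported both as
#' the rank-biserial correlation (headline, from the Mann-Whitney U) and the
#' point-biserial correlation, both signed positive when Group A exceeds
#' Group B.
#'
#' @param ds a `condemnation_data` object
#' @param scope `"total"` or a cause code
#' @return object of class `group_comparison`: list with `variable`, `summary`
#'   (per-group n, mean, sd, se), `t_test` (htest), `p_value`,
#'   `rank_biserial`, `point_biserial`
#' @export
compare_groups <- function(ds, scope = "total") {
  pct <- coi_series(ds, scope, scale = 100)
  grp <- assign_groups(ds)
  dat <- dplyr::inner_join(pct, grp, by = c("year", "month"))
  a <- dat$value[dat$group == "A"]
  b <- dat$value[dat$group == "B"]
  if (length(a) < 2 || length(b) < 2) {
    stop("insufficient data: each group needs at least 2 months (A has ",
         length(a), ", B has ", length(b), ")", call. = FALSE)
  }
  tt <- t.test(a, b, var.equal = FALSE)
  summ <- tibble::tibble(
    group = c("A", "B"),
    n = c(length(a), length(b)),
    mean = c(mean(a), mean(b)),
    sd = c(sd(a), sd(b)),
    se = c(sd(a) / sqrt(length(a)), sd(b) / sqrt(length(b)))
  )
  structure(
    list(variable = paste0(scope, " / total slaughter (%)"),
         summary = summ, t_test = tt, p_value = tt$p.value,
         rank_biserial = rank_biserial(a, b),
         point_biserial = point_biserial(a, b)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s\n", x$variable))
  print(x$summary)
  cat(sprintf("Welch t test p = %.4g; rank-biserial = %.3f; point-biserial = %.3f\n",
              x$p_value, x$rank_biserial, x$point_biserial))
  invisible(x)
}

#' Grade correlation strength (Mukaka bands)
#'
#' |rho| >= 0.9 "very high", 0.7-0.9 "high", 0.5-0.7 "moderate",
#' 0.3-0.5 "low", below 0.3 "negligible".
#'
#' @param rho numeric vector of correlation coefficients (NA passes through)
#' @return character vector of strength labels
#' @export
correlation_strength <- function(rho) {
  a <- abs(as.vector(rho))
  as.character(cut(a, breaks = c(-Inf, 0.3, 0.5, 0.7, 0.9, Inf),
                   labels = c("negligible", "low", "moderate", "high", "very high"),
                   right = FALSE))
}

#' Spearman correlation matrix between condemnation causes
#'
#' Causes are measured as monthly per-slaughter ratios over the non-excluded
#' months; pairwise Spearman rho uses average ranks for ties. A cause that is
#' constant across months has no defined rank correlation: its entries are
#' reported as NA (never coerced to 0).
#'
#' @param ds a `condemnation_data` object
#' @param causes cause codes to correlate; default: the dataset's
#'   ASI-eligible causes
#' @return object of class `correlation_report`: list with `causes`, `rho`
#'   (symmetric matrix, unit diagonal) and `strength` (label matrix)
#' @export
spearman_matrix <- function(ds, causes = NULL) {
  if (is.null(causes)) {
    causes <- intersect(ds$causes$code[ds$causes$asi_eligible], dataset_causes(ds))
  }
  if (length(causes) < 2) {
    stop("need at least two causes to correlate", call. = FALSE)
  }
  r <- ds$records[!ds$records$excluded, ]
  if (nrow(r) < 3) stop("need at least 3 usable months", call. = FALSE)
  tot <- rowSums(r[, slaughter_cols()])
  m <- sapply(causes, function(cc) r[[cc]] / tot)
  const <- apply(m, 2, function(v) length(unique(v)) == 1)
  rho <- suppressWarnings(stats::cor(m, method = "spearman"))
  rho[const, ] <- NA_real_
  rho[, const] <- NA_real_
  diag(rho) <- ifelse(const, NA_real_, 1)
  strength <- matrix(correlation_strength(rho), nrow = nrow(rho),
                     dimnames = dimnames(rho))
  structure(list(causes = causes, rho = rho, strength = strength),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report> Spearman rho\n")
  print(round(x$rho, 3))
  invisible(x)
}

#' One-way ANOVA over calendar months with Tukey HSD
#'
#' Takes the stage-1 ratio table of an [compute_asi()] result (per-year
#' monthly ratios) and tests whether calendar months differ, with years as
#' replicates: one-way ANOVA on ratio ~ month followed by Tukey honest
#' significant differences over all month pairs (66 pairs when all 12 months
#' are present). Months with fewer than 2 replicate years are dropped with a
#' warning. If the within-month variance is exactly zero the studentized
#' range statistic is undefined; adjusted p-values are then reported as 1
#' for zero mean differences and 0 for nonzero ones.
#'
#' @param ratios tibble with columns `year`, `month`, `ratio` (e.g.
#'   `compute_asi(series)$ratios`)
#' @param alpha significance level recorded on the result
#' @return object of class `month_anova`: list with `anova_p`, `tukey`
#'   (tibble `month_a`, `month_b`, `estimate`, `p_adj`), `alpha`
#' @export
asi_month_anova <- function(ratios, alpha = 0.05) {
  stopifnot(all(c("month", "ratio") %in% names(ratios)))
  counts <- table(ratios$month)
  drop <- as.integer(names(counts)[counts < 2])
  if (length(drop) > 0) {
    warning("dropping calendar month(s) with < 2 replicate years: ",
            paste(drop, collapse = ", "), call. = FALSE)
    ratios <- ratios[!ratios$month %in% drop, ]
  }
  if (length(unique(ratios$month)) < 2) {
    stop("need at least two calendar months with replicates", call. = FALSE)
  }
  dat <- data.frame(ratio = ratios$ratio,
                    month = factor(ratios$month, levels = sort(unique(ratios$month))))
  fit <- aov(ratio ~ month, data = dat)
  an <- summary(fit)[[1]]
  mse <- an["Residuals", "Mean Sq"]
  tk <- TukeyHSD(fit)$month
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  tukey <- tibble::tibble(
    month_a = as.integer(pairs[, 1]),
    month_b = as.integer(pairs[, 2]),
    estimate = tk[, "diff"],
    p_adj = tk[, "p adj"]
  )
  if (!is.finite(mse) || mse <= .Machine$double.eps) {
    tukey$p_adj <- ifelse(abs(tukey$estimate) <= .Machine$double.eps^0.5, 1, 0)
  }
  structure(list(anova_p = an["month", "Pr(>F)"], tukey = tukey, alpha = alpha),
            class = "month_anova")
}

#' One-sample t test of a calendar month's ratios against 1
#'
#' Tests whether one calendar month's across-year COI ratios differ from 1
#' (the year's expected condemnation level). A sample with zero spread is
#' degenerate for the t statistic and raises an error rather than returning a
#' spuriously extreme p-value.
#'
#' @param ratios tibble with columns `month`, `ratio` (stage-1 ASI table)
#' @param month calendar month 1-12 to test
#' @return list with `t`, `p_value`, `n`, `mean`
#' @export
asi_vs_one <- function(ratios, month) {
  x <- ratios$ratio[ratios$month == month]
  if (length(x) < 2) stop("need at least 2 years for month ", month, call. = FALSE)
  if (sd(x) == 0) {
    stop("degenerate sample: month ", month,
         " ratios have zero standard deviation", call. = FALSE)
  }
  tt <- t.test(x, mu = 1)
  list(t = unname(tt$statistic), p_value = tt$p.value, n = length(x),
       mean = mean(x))
}

#' Run the one-sample test for every calendar month
#'
#' @param ratios stage-1 ASI ratio table
#' @return tibble with `month`, `n`, `mean`, `t`, `p_value`; months with a
#'   degenerate (zero-variance) sample get NA statistics
#' @export
asi_vs_one_all <- function(ratios) {
  dplyr::bind_rows(lapply(sort(unique(ratios$month)), function(m) {
    res <- tryCatch(asi_vs_one(ratios, m), error = function(e) NULL)
    if (is.null(res)) {
      x <- ratios$ratio[ratios$month == m]
      tibble::tibble(month = m, n = length(x), mean = mean(x),
                     t = NA_real_, p_value = NA_real_)
    } else {
      tibble::tibble(month = m, n = res$n, mean = res$mean, t = res$t,
                     p_value = res$p_value)
    }
  }))
}
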
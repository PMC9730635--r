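#' Condemnation Occurrence Index for one period
#'
#' COI = scale * condemned / slaughtered. With the default scale of one
#' million it reads as condemnations per million head slaughtered; with
#' `scale = 100` it is the condemnation percentage.
#'
#' @param condemned condemnation count (partial + total combined)
#' @param slaughtered head count slaughtered in the same period; must be > 0
#' @param scale positive scaling constant, default 1e6
#' @return numeric COI value(s)
#' @examples
#' compute_coi(7, 1000)            # 7000 per million
#' compute_coi(55594318, 785068807, scale = 100)  # percent
#' @export
compute_coi <- function(condemned, slaughtered, scale = 1e6) {
  stopifnot(is.numeric(condemned), is.numeric(slaughtered), scale > 0)
  if (any(condemned < 0)) stop("condemned must be non-negative", call. = FALSE)
  if (any(slaughtered <= 0)) {
    stop("undefined rate: slaughtered must be positive", call. = FALSE)
  }
  scale * condemned / slaughtered
}

scope_counts <- function(ds, scope) {
  r <- ds$records
  if (identical(scope, "total")) {
    rowSums(r[, dataset_causes(ds), drop = FALSE])
  } else {
    if (!scope %in% dataset_causes(ds)) {
      stop("scope must be 'total' or a measured cause code, got: ", scope,
           call. = FALSE)
    }
    r[[scope]]
  }
}

#' Monthly COI series
#'
#' One COI value per non-excluded month, for total condemnation or for one
#' cause, always against the total head count slaughtered (all species).
#'
#' @param ds a `condemnation_data` object
#' @param scope `"total"` or a cause code
#' @param scale passed to [compute_coi()]
#' @return object of class `coi_series`: tibble with `year`, `month`, `value`,
#'   plus attributes `scope` and `scale`
#' @export
coi_series <- function(ds, scope = "total", scale = 1e6) {
  cond <- scope_counts(ds, scope)
  r <- ds$records
  keep <- !r$excluded
  out <- tibble::tibble(
    year = r$year[keep], month = r$month[keep],
    value = compute_coi(cond[keep], rowSums(r[keep, slaughter_cols()]), scale)
  )
  structure(out, scope = scope, scale = scale,
            class = c("coi_series", class(out)))
}

#' Pooled COI over a span of years
#'
#' Pools counts before dividing: scale * (sum condemned) / (sum slaughtered)
#' over the non-excluded months of the period. This is not the mean of the
#' monthly COIs.
#'
#' @param ds a `condemnation_data` object
#' @param scope `"total"` or a cause code
#' @param years integer vector of calendar years to pool
#' @param scale passed to [compute_coi()]
#' @return a single numeric value
#' @export
period_coi <- function(ds, scope = "total", years, scale = 1e6) {
  cond <- scope_counts(ds, scope)
  r <- ds$records
  keep <- !r$excluded & r$year %in% years
  if (!any(keep)) stop("no usable months in the requested period", call. = FALSE)
  compute_coi(sum(cond[keep]), sum(rowSums(r[keep, slaughter_cols()])), scale)
}

#' Cause-frequency table
#'
#' Whole-period condemnation counts per cause with percent shares. The
#' default percent denominator is the sum of the cause counts themselves
#' (`"sum_of_causes"`), which makes the shares internally consistent;
#' `"reported_total"` divides by an externally supplied grand total instead
#' (count registries sometimes print a total that is not the column sum —
#' the discrepancy is reported with a message).
#'
#' @param x a `condemnation_data` object, or a named numeric vector of
#'   whole-period counts per cause
#' @param denominator `"sum_of_causes"` or `"reported_total"`
#' @param total grand total used when `denominator = "reported_total"`
#' @param include_excluded for datasets: count excluded months too?
#'   (default TRUE — whole-period accounting keeps every record)
#' @param causes a [cause_registry()] supplying the technological flags
#' @return object of class `frequency_table`: tibble with `cause`, `label`,
#'   `technological`, `count`, `percent` (2 d.p.), sorted by descending count
#' @export
frequency_table <- function(x, denominator = c("sum_of_causes", "reported_total"),
                            total = NULL, include_excluded = TRUE,
                            causes = default_causes()) {
  denominator <- match.arg(denominator)
  if (inherits(x, "condemnation_data")) {
    causes <- x$causes
    r <- x$records
    if (!include_excluded) r <- r[!r$excluded, ]
    counts <- colSums(r[, dataset_causes(x), drop = FALSE])
  } else {
    if (!is.numeric(x) || is.null(names(x))) {
      stop("x must be a condemnation_data object or a named count vector",
           call. = FALSE)
    }
    counts <- x
  }
  denom <- switch(denominator,
    sum_of_causes = sum(counts),
    reported_total = {
      if (is.null(total)) stop("reported_total policy needs `total`", call. = FALSE)
      if (total != sum(counts)) {
        message(sprintf(
          "reported total (%s) differs from the sum of cause counts (%s)",
          format(total, big.mark = ","), format(sum(counts), big.mark = ",")))
      }
      total
    })
  if (denom <= 0) stop("zero denominator in frequency table", call. = FALSE)
  reg <- causes[match(names(counts), causes$code), ]
  out <- tibble::tibble(
    cause = names(counts),
    label = ifelse(is.na(reg$label), names(counts), reg$label),
    technological = reg$technological,
    count = as.numeric(unname(counts)),
    percent = round(100 * as.numeric(unname(counts)) / denom, 2)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$count))
  structure(out, denominator = denominator,
            class = c("frequency_table", class(out)))
}

#' Per-month ratios to the annual mean COI
#'
#' For each year, each usable month's COI is divided by the arithmetic mean of
#' that year's usable monthly COIs (partial years use the months present), so
#' a ratio of 1.20 reads as "20% above that year's expectation". Within any
#' complete year the ratios average to exactly 1.
#'
#' @param series a [coi_series()]
#' @return tibble with `year`, `month`, `coi`, `year_mean`, `ratio`
#' @export
monthly_ratios <- function(series) {
  stopifnot(inherits(series, "coi_series"))
  out <- series |>
    dplyr::group_by(.data$year) |>
    dplyr::mutate(year_mean = mean(.data$value)) |>
    dplyr::ungroup()
  if (any(out$year_mean == 0)) {
    bad <- unique(out$year[out$year_mean == 0])
    stop("undefined ratio: zero annual mean COI in year(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(year = out$year, month = out$month, coi = out$value,
                 year_mean = out$year_mean, ratio = out$value / out$year_mean)
}

#' Adjusted Seasonal Index
#'
#' Two-stage construction: (1) each month's COI is expressed as a ratio to its
#' own year's mean monthly COI ([monthly_ratios()]); (2) the ASI for calendar
#' month m is the unweighted arithmetic mean of month m's ratios across the
#' years in which it is usable. Excluded or missing months simply reduce the
#' number of years averaged for their calendar month (reported in `n_years`).
#' An ASI of 1 means condemnation at the year's expected level; 1.63 means
#' 63% above it.
#'
#' @param series a [coi_series()] spanning at least 2 years
#' @return object of class `asi_result`: list with `ratios` (the stage-1
#'   table) and `asi` (tibble `month`, `asi`, `n_years`), plus attribute
#'   `scope`
#' @export
compute_asi <- function(series) {
  stopifnot(inherits(series, "coi_series"))
  if (length(unique(series$year)) < 2) {
    stop("ASI needs at least two years of data", call. = FALSE)
  }
  ratios <- monthly_ratios(series)
  asi <- ratios |>
    dplyr::group_by(month = .data$month) |>
    dplyr::summarise(asi = mean(.data$ratio), n_years = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$month)
  missing_months <- setdiff(1:12, asi$month)
  if (length(missing_months) > 0) {
    warning("no usable years for calendar month(s) ",
            paste(missing_months, collapse = ", "), call. = FALSE)
  }
  structure(list(ratios = ratios, asi = asi),
            scope = attr(series, "scope"), class = "asi_result")
}

#' @export
print.asi_result <- function(x, ...) {
  cat(sprintf("<asi_result> scope: %s\n", attr(x, "scope")))
  print(x$asi, n = 12)
  invisible(x)
}
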
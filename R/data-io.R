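#' @importFrom rlang .data
#' @importFrom stats sd setNames aov TukeyHSD t.test wilcox.test cor rpois
#'   rnbinom ptukey pt
NULL

slaughter_cols <- function() paste0("slaughtered_", species_codes())

month_label <- function(year, month) sprintf("%04d-%02d", year, month)

#' Parse "YYYY-MM" month labels
#'
#' @param x character vector like "2017-06"
#' @return tibble with integer columns `year`, `month`
#' @export
parse_month <- function(x) {
  ok <- grepl("^\\d{4}-\\d{2}$", x)
  if (!all(ok)) stop("malformed month label(s): ", paste(x[!ok], collapse = ", "), call. = FALSE)
  year <- as.integer(substr(x, 1, 4))
  month <- as.integer(substr(x, 6, 7))
  if (any(month < 1 | month > 12)) stop("month must be in 1..12", call. = FALSE)
  tibble::tibble(year = year, month = month)
}

#' Construct a monthly condemnation dataset
#'
#' The central container: one row per month, with head counts slaughtered per
#' species category and condemned counts (partial + total combined; the source
#' records cannot split them) per cause. Months need not be gap-free; a missing
#' month is simply absent, which is distinct from a month flagged `excluded`.
#'
#' @param records tibble with columns `year`, `month`,
#'   `slaughtered_turkey`, `slaughtered_griller`, `slaughtered_heavy`, one
#'   column per cause code, and optionally `excluded` (logical, default FALSE)
#' @param causes a [cause_registry()]; every cause column of `records` must be
#'   declared here
#' @param provenance free-text description of where the records came from
#' @return object of class `condemnation_data` with elements `records`
#'   (sorted by year, month), `causes`, `provenance`
#' @export
condemnation_data <- function(records, causes = default_causes(),
                              provenance = "unspecified") {
  records <- tibble::as_tibble(records)
  need <- c("year", "month", slaughter_cols())
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"excluded" %in% names(records)) records$excluded <- FALSE
  cause_cols <- setdiff(names(records), c(need, "excluded"))
  unknown <- setdiff(cause_cols, causes$code)
  if (length(unknown) > 0) {
    stop("cause column(s) not in registry: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(records$month < 1 | records$month > 12)) {
    stop("month must be in 1..12", call. = FALSE)
  }
  records$year <- as.integer(records$year)
  records$month <- as.integer(records$month)
  count_cols <- c(slaughter_cols(), cause_cols)
  for (cc in count_cols) {
    v <- records[[cc]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0)) {
      bad <- which(!is.finite(v) | v < 0)[1]
      stop(sprintf("invalid count in column '%s', row %d (must be a non-negative number)",
                   cc, bad), call. = FALSE)
    }
  }
  key <- records$year * 12L + records$month
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), ]
    stop("duplicate month(s): ",
         paste(month_label(d$year, d$month), collapse = ", "), call. = FALSE)
  }
  records <- dplyr::arrange(records, .data$year, .data$month)
  tot <- rowSums(records[slaughter_cols()])
  over <- which(rowSums(records[cause_cols]) > tot)
  if (length(over) > 0) {
    warning("condemned counts exceed slaughtered head count in month(s) ",
            paste(month_label(records$year[over], records$month[over]), collapse = ", "),
            " (possible if carcasses contribute multiple partial records)",
            call. = FALSE)
  }
  structure(
    list(records = records, causes = causes, provenance = provenance),
    class = "condemnation_data"
  )
}

#' @export
print.condemnation_data <- function(x, ...) {
  r <- x$records
  cat(sprintf("<condemnation_data> %d months (%s to %s), %d causes, %d excluded\n",
              nrow(r),
              if (nrow(r)) month_label(r$year[1], r$month[1]) else "-",
              if (nrow(r)) month_label(r$year[nrow(r)], r$month[nrow(r)]) else "-",
              length(dataset_causes(x)), sum(r$excluded)))
  cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Cause codes measured in a dataset
#' @param ds a `condemnation_data` object
#' @return character vector of cause columns present in the records
#' @export
dataset_causes <- function(ds) {
  setdiff(names(ds$records), c("year", "month", "excluded", slaughter_cols()))
}

#' Read a monthly condemnation table from CSV
#'
#' Expects the wide layout: columns `year`, `month`, `slaughtered_turkey`,
#' `slaughtered_griller`, `slaughtered_heavy`, then one column per cause code.
#' Thousands separators (commas inside quoted fields) are tolerated. Columns
#' whose names are not in the registry raise an error unless
#' `unknown_to_others = TRUE`, in which case their counts are added to the
#' `others` bucket.
#'
#' @param path CSV file path
#' @param causes a [cause_registry()] validating the cause columns
#' @param unknown_to_others fold unrecognised cause columns into "others"?
#' @param provenance free-text source description stored on the dataset
#' @return a `condemnation_data` object
#' @export
read_dataset <- function(path, causes = default_causes(),
                         unknown_to_others = FALSE, provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("year", "month", slaughter_cols())
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  has_excl <- "excluded" %in% names(raw)
  num_cols <- setdiff(names(raw), "excluded")
  for (cc in num_cols) {
    v <- gsub(",", "", raw[[cc]], fixed = TRUE)   # strip thousands separators
    n <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(n) | n < 0)
    if (length(bad) > 0) {
      stop(sprintf("row %d, column '%s': value '%s' is not a non-negative number",
                   bad[1], cc, raw[[cc]][bad[1]]), call. = FALSE)
    }
    raw[[cc]] <- n
  }
  if (has_excl) raw$excluded <- as.logical(raw$excluded)
  unknown <- setdiff(names(raw), c(need, "excluded", causes$code))
  if (length(unknown) > 0) {
    if (!unknown_to_others) {
      stop("unknown cause column(s): ", paste(unknown, collapse = ", "),
           " (set unknown_to_others = TRUE to fold them into 'others')",
           call. = FALSE)
    }
    extra <- rowSums(raw[, unknown, drop = FALSE])
    raw <- raw[setdiff(names(raw), unknown)]
    raw$others <- (if ("others" %in% names(raw)) raw$others else 0) + extra
  }
  condemnation_data(raw, causes = causes, provenance = provenance)
}

#' Write a dataset back to the wide CSV layout
#'
#' Numeric content round-trips bit-exactly through [read_dataset()].
#'
#' @param ds a `condemnation_data` object
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_dataset <- function(ds, path) {
  readr::write_csv(ds$records, path, progress = FALSE)
  invisible(path)
}

#' Flag months as excluded from analysis
#'
#' Flagged months stay in the table (their counts still appear in whole-period
#' frequency accounting by default) but contribute to no COI series, seasonal
#' index or inference. Flagging is idempotent; months not present in the data
#' are ignored with a warning.
#'
#' @param ds a `condemnation_data` object
#' @param months months to flag, as "YYYY-MM" strings or a data frame with
#'   `year` and `month` columns
#' @return the dataset with `excluded = TRUE` on the matching records
#' @export
flag_exclusions <- function(ds, months) {
  if (is.character(months)) months <- parse_month(months)
  months <- tibble::as_tibble(months)
  if (nrow(months) == 0) return(ds)
  key <- ds$records$year * 12L + ds$records$month
  want <- months$year * 12L + months$month
  absent <- !(want %in% key)
  if (any(absent)) {
    warning("month(s) not present in data, ignored: ",
            paste(month_label(months$year[absent], months$month[absent]), collapse = ", "),
            call. = FALSE)
  }
  ds$records$excluded <- ds$records$excluded | (key %in% want)
  ds
}

#' Read an exclusion list from a YAML config
#'
#' The config holds `exclude: [2017-06, 2019-12]`.
#'
#' @param path YAML file path
#' @return character vector of "YYYY-MM" labels (possibly empty)
#' @export
read_exclusions <- function(path) {
  cfg <- yaml::read_yaml(path)
  as.character(cfg$exclude %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify months by species mix (Groups A and B)
#'
#' Group A: any turkeys slaughtered that month (alongside griller or heavy
#' chicken). Group B: only heavy chicken slaughtered. Anything else —
#' griller-only months, empty months, excluded months — is UNCLASSIFIED.
#'
#' @param ds a `condemnation_data` object
#' @return tibble with columns `year`, `month`, `group` (factor A/B/UNCLASSIFIED)
#' @export
assign_groups <- function(ds) {
  r <- ds$records
  grp <- dplyr::case_when(
    r$excluded ~ "UNCLASSIFIED",
    r$slaughtered_turkey > 0 ~ "A",
    r$slaughtered_heavy > 0 & r$slaughtered_griller == 0 ~ "B",
    TRUE ~ "UNCLASSIFIED"
  )
  tibble::tibble(
    year = r$year, month = r$month,
    group = factor(grp, levels = c("A", "B", "UNCLASSIFIED"))
  )
}
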
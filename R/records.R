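#' Quadrat survey dataset
#'
#' Container for use-versus-availability quadrat records: one row per
#' sampling point, either a `presence` (an occupied quadrat with a sexed
#' individual) or a `pseudo_absence` (a random background quadrat), in one
#' of two seasons. Presence records derive a season-by-sex group label:
#' BM/BF (breeding males/females) and NBM/NBF (non-breeding).
#'
#' @param records A data.frame with columns `point_id`, `point_class`
#'   (`presence`/`pseudo_absence`), `season` (`breeding`/`non_breeding`),
#'   `sex` (`M`/`F`, `NA` for pseudo-absences), `x_m`, `y_m`, and one column
#'   per factor in `scheme` (raw values; `NA` marks missing).
#' @param scheme A `factor_scheme` describing the factor columns.
#' @return An object of class `habitat_dataset`.
#' @export
habitat_dataset <- function(records, scheme = default_scheme()) {
  stopifnot(is.data.frame(records), inherits(scheme, "factor_scheme"))
  core <- c("point_id", "point_class", "season", "sex", "x_m", "y_m")
  missing_cols <- setdiff(c(core, names(scheme)), names(records))
  if (length(missing_cols))
    stop("records lack required column(s): ", paste(missing_cols, collapse = ", "))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records$point_id <- as.character(records$point_id)
  if (anyDuplicated(records$point_id))
    stop("duplicate point_id: ",
         paste(unique(records$point_id[duplicated(records$point_id)]), collapse = ", "))
  bad_class <- !records$point_class %in% c("presence", "pseudo_absence")
  bad_season <- !records$season %in% c("breeding", "non_breeding")
  sex <- as.character(records$sex)
  bad_sex <- ifelse(records$point_class == "presence",
                    !sex %in% c("M", "F"), !is.na(sex) & sex != "")
  bad <- bad_class | bad_season | (bad_sex & !bad_class)
  if (any(bad))
    stop("invalid group fields in record(s): ",
         paste(records$point_id[bad], collapse = ", "))
  records$sex[records$point_class == "pseudo_absence"] <- NA_character_
  for (f in scheme) {
    v <- records[[f$name]]
    if (f$kind == "continuous_binned") {
      records[[f$name]] <- suppressWarnings(as.numeric(v))
    } else {
      v <- as.character(v)
      v[!is.na(v) & v == ""] <- NA_character_
      records[[f$name]] <- v
    }
  }
  structure(list(records = records, scheme = scheme), class = "habitat_dataset")
}

#' @export
print.habitat_dataset <- function(x, ...) {
  tab <- table(group_labels(x), useNA = "no")
  cat(sprintf("<habitat_dataset> %d records (%d presence, %d pseudo-absence), %d factors\n",
              nrow(x$records), sum(x$records$point_class == "presence"),
              sum(x$records$point_class == "pseudo_absence"), length(x$scheme)))
  if (length(tab)) print(tab)
  invisible(x)
}

#' Season-by-sex group label of each record
#'
#' @param ds A `habitat_dataset`.
#' @return Character vector: `"BM"`, `"BF"`, `"NBM"`, `"NBF"` for presence
#'   records, `NA` for pseudo-absences.
#' @export
group_labels <- function(ds) {
  r <- ds$records
  ifelse(r$point_class == "presence",
         paste0(ifelse(r$season == "breeding", "B", "NB"), r$sex),
         NA_character_)
}

#' The four season-by-sex groups, in canonical order
#' @return `c("BM", "BF", "NBM", "NBF")`
#' @export
group_levels <- function() c("BM", "BF", "NBM", "NBF")

#' Read quadrat records from CSV
#'
#' Expects a header with `point_id`, `point_class`, `season`, `sex`, `x_m`,
#' `y_m` and one column per scheme factor. Rows whose group fields cannot be
#' parsed (unknown point class or season, invalid sex for a presence point)
#' are dropped with a per-row warning; missing factor values are kept as
#' `NA`.
#'
#' @param path CSV file path.
#' @param scheme A `factor_scheme` (default [default_scheme()]).
#' @return A `habitat_dataset`.
#' @seealso [write_records()]
#' @export
load_records <- function(path, scheme = default_scheme()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""), check.names = FALSE)
  core <- c("point_id", "point_class", "season", "sex", "x_m", "y_m")
  missing_cols <- setdiff(c(core, names(scheme)), names(raw))
  if (length(missing_cols))
    stop("input file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  raw$sex <- as.character(raw$sex)
  bad <- !raw$point_class %in% c("presence", "pseudo_absence") |
    !raw$season %in% c("breeding", "non_breeding") |
    (raw$point_class == "presence" & !raw$sex %in% c("M", "F"))
  if (any(bad)) {
    for (i in which(bad))
      warning(sprintf("row %d (point_id '%s'): unparseable group fields; row dropped",
                      i, as.character(raw$point_id[i])), call. = FALSE)
    raw <- raw[!bad, , drop = FALSE]
  }
  habitat_dataset(raw, scheme)
}

#' Write quadrat records to CSV
#'
#' Inverse of [load_records()]: `load_records(write_records(ds, p))`
#' reproduces `ds` field-for-field.
#'
#' @param ds A `habitat_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(ds, path) {
  stopifnot(inherits(ds, "habitat_dataset"))
  utils::write.csv(ds$records, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Screen outliers and optionally log-transform continuous factors
#'
#' Extreme outliers are screened per continuous factor and per point class
#' with Tukey-style fences at `median +/- k * IQR` (default `k = 3`, the
#' standard "extreme" multiplier); values outside the fences are set to
#' missing. An optional `log1p` transform (natural log of `x + 1`, safe at
#' zero distances) can be applied to the continuous factors afterwards.
#' Binning-based electivity and niche statistics are unaffected by monotone
#' transforms of raw values, so the transform is off by default and matters
#' only for the location tests on raw scales.
#'
#' Every modification is appended to the returned dataset's
#' `processing_log` (a data.frame: point_id, factor, action, old value).
#'
#' @param ds A `habitat_dataset`.
#' @param outlier_k Fence multiplier on the IQR; `Inf` disables screening.
#' @param log_transform Apply `log(x + 1)` to continuous factors.
#' @param factors Factor names to process (default: all continuous ones).
#' @return A `habitat_dataset` with the same records (values edited in
#'   place) and a `processing_log` element.
#' @export
preprocess <- function(ds, outlier_k = 3, log_transform = FALSE,
                       factors = NULL) {
  stopifnot(inherits(ds, "habitat_dataset"), outlier_k > 0)
  cont <- names(ds$scheme)[vapply(ds$scheme, function(f)
    f$kind == "continuous_binned", TRUE)]
  factors <- if (is.null(factors)) cont else intersect(factors, cont)
  log_entries <- list()
  rec <- ds$records
  for (fn in factors) {
    for (cls in unique(rec$point_class)) {
      sel <- rec$point_class == cls
      v <- rec[[fn]][sel]
      if (all(is.na(v)) || !is.finite(outlier_k)) next
      med <- stats::median(v, na.rm = TRUE)
      iqr <- stats::IQR(v, na.rm = TRUE)
      out <- !is.na(v) & (v < med - outlier_k * iqr | v > med + outlier_k * iqr)
      if (any(out)) {
        log_entries[[length(log_entries) + 1L]] <- data.frame(
          point_id = rec$point_id[sel][out], factor = fn,
          action = "outlier_to_missing", old = v[out],
          stringsAsFactors = FALSE)
        v[out] <- NA_real_
        rec[[fn]][sel] <- v
      }
    }
    if (log_transform) {
      v <- rec[[fn]]
      if (any(!is.na(v) & v < 0))
        stop("negative value of '", fn, "' under log transform (point_id ",
             paste(rec$point_id[!is.na(v) & v < 0], collapse = ", "), ")")
      changed <- !is.na(v)
      if (any(changed))
        log_entries[[length(log_entries) + 1L]] <- data.frame(
          point_id = rec$point_id[changed], factor = fn,
          action = "log1p", old = v[changed], stringsAsFactors = FALSE)
      rec[[fn]] <- log(v + 1)
    }
  }
  out <- habitat_dataset(rec, ds$scheme)
  out$processing_log <- if (length(log_entries))
    do.call(rbind, log_entries)
  else data.frame(point_id = character(), factor = character(),
                  action = character(), old = numeric(),
                  stringsAsFactors = FALSE)
  out
}

# Integer category matrix (records x factors); NA where the raw value is
# missing. Shared workhorse for the electivity and niche modules.
binned_matrix <- function(ds) {
  m <- vapply(ds$scheme,
              function(f) bin_value(f, ds$records[[f$name]]),
              integer(nrow(ds$records)))
  if (nrow(ds$records) == 1L) m <- matrix(m, nrow = 1L,
                                          dimnames = list(NULL, names(ds$scheme)))
  m
}
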
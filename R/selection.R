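#' Vanderploeg selectivity coefficient Wi
#'
#' For a habitat factor with categories `i = 1..n`, the Vanderploeg
#' coefficient compares use against availability:
#' `Wi = (ri/pi) / sum_i(ri/pi)`, where `ri` is the number of used
#' (presence) quadrats in category `i` and `pi` the number of available
#' quadrats in category `i`. The coefficients sum to 1; `Wi = 1/n` is the
#' no-preference point.
#'
#' Categories never offered (`pi = 0`) and never used (`ri = 0`) carry no
#' information about preference: they are dropped from the sum and returned
#' as `NA` (no data). A used category that was never offered (`ri > 0`,
#' `pi = 0`) implies infinite preference under the formula and is an error.
#'
#' @param r Nonnegative integer vector of used-quadrat counts per category.
#' @param p Nonnegative integer vector of available-quadrat counts per
#'   category (same length as `r`, length >= 2).
#' @return Numeric vector of Wi values (`NA` for no-data categories);
#'   non-`NA` entries sum to 1.
#' @examples
#' vanderploeg_wi(c(8, 1, 1), c(5, 3, 2))
#' @export
vanderploeg_wi <- function(r, p) {
  r <- as.numeric(r); p <- as.numeric(p)
  if (length(r) != length(p) || length(r) < 2L)
    stop("r and p must have equal length >= 2")
  if (any(r < 0) || any(p < 0) || any(!is.finite(r)) || any(!is.finite(p)))
    stop("r and p must be finite and nonnegative")
  viol <- p == 0 & r > 0
  if (any(viol))
    stop("used category with zero availability (category ",
         paste(which(viol), collapse = ", "),
         "): Wi is undefined (infinite preference)")
  if (all(r == 0))
    stop("degenerate input: no used quadrats in any category")
  keep <- p > 0
  ratio <- r[keep] / p[keep]
  wi <- rep(NA_real_, length(r))
  wi[keep] <- ratio / sum(ratio)
  wi
}

#' Scavia electivity index Ei
#'
#' Rescales Vanderploeg's `Wi` symmetrically around the no-preference point
#' `1/n`: `Ei = (Wi - 1/n) / (Wi + 1/n)`. The index lives in
#' `[-1, (1 - 1/n)/(1 + 1/n)]`: `Ei = -1` at `Wi = 0` (category never
#' used), `Ei = 0` at `Wi = 1/n`, and the maximum (0.5 for `n = 3`) at
#' `Wi = 1` (exclusive use).
#'
#' @param Wi Numeric vector of Vanderploeg coefficients in `[0, 1]` (`NA`
#'   entries pass through).
#' @param n Number of categories of the factor; defaults to `length(Wi)`.
#' @return Numeric vector of Ei values.
#' @examples
#' scavia_ei(c(1, 0, 0))            # 0.5 -1 -1
#' scavia_ei(rep(1/4, 4))           # all 0
#' @export
scavia_ei <- function(Wi, n = length(Wi)) {
  Wi <- as.numeric(Wi)
  if (n < 2L) stop("n must be >= 2")
  ok <- !is.na(Wi)
  if (any(Wi[ok] < -1e-12 | Wi[ok] > 1 + 1e-12))
    stop("Wi values must lie in [0, 1]")
  (Wi - 1 / n) / (Wi + 1 / n)
}

#' Five-level preference classification of Ei
#'
#' The conventional rubric: `Ei = 1` strong preference; `0.1 < Ei < 1`
#' selection; `-0.1 < Ei < 0.1` random selection; `-1 < Ei < -0.1`
#' avoidance; `Ei = -1` no selection (category available but never used).
#' The rubric's strict inequalities leave the boundaries unassigned; here
#' `Ei = 0.1` classifies as selection and `Ei = -0.1` as avoidance, and the
#' endpoint checks at +/-1 use a 1e-9 tolerance, so the classification is
#' total and deterministic.
#'
#' @param Ei Numeric vector in `[-1, 1]` (`NA` maps to `"no_data"`).
#' @return Character vector with levels `strong_preference`, `selection`,
#'   `random`, `avoidance`, `no_selection`, `no_data`.
#' @export
classify_ei <- function(Ei) {
  Ei <- as.numeric(Ei)
  tol <- 1e-9
  ok <- !is.na(Ei)
  if (any(Ei[ok] < -1 - 1e-6 | Ei[ok] > 1 + 1e-6))
    stop("Ei outside [-1, 1]")
  out <- rep("no_data", length(Ei))
  out[ok & abs(Ei - 1) <= tol] <- "strong_preference"
  out[ok & abs(Ei + 1) <= tol] <- "no_selection"
  plain <- ok & abs(Ei - 1) > tol & abs(Ei + 1) > tol
  out[plain & Ei >= 0.1] <- "selection"
  out[plain & Ei <= -0.1] <- "avoidance"
  out[plain & abs(Ei) < 0.1] <- "random"
  out
}

#' Electivity table per group and factor
#'
#' For each season-by-sex group and each factor, tallies the group's
#' presence quadrats per category (`r`), tallies the availability sample
#' (`p`) from the pseudo-absence quadrats of the matching season (or of
#' both seasons pooled), and computes `Wi`, `Ei` and the preference class.
#' Records missing a factor's value are dropped for that factor only.
#'
#' The aspect factor is computed like the others but flagged
#' `excluded = TRUE`: sun exposure categories show at most weak electivity
#' in this survey design and are conventionally dropped from the
#' downstream niche summaries.
#'
#' @param ds A `habitat_dataset` containing presences and pseudo-absences.
#' @param groups Groups to tabulate (default all four); empty groups are
#'   skipped with a warning.
#' @param pool_availability If `TRUE`, availability pools pseudo-absences
#'   of both seasons instead of matching the group's season.
#' @param exclude_factors Factors flagged `excluded` in the output
#'   (default `"aspect"`).
#' @return A data.frame of class `selection_table`: one row per group x
#'   factor x category with columns `group`, `factor`, `category`,
#'   `category_label`, `r`, `p`, `Wi`, `Ei`, `class`, `excluded`.
#' @examples
#' ds <- simulate_dataset(seed = 2)
#' head(selection_table(ds))
#' @export
selection_table <- function(ds, groups = group_levels(),
                            pool_availability = FALSE,
                            exclude_factors = "aspect") {
  stopifnot(inherits(ds, "habitat_dataset"))
  bm <- binned_matrix(ds)
  lab <- group_labels(ds)
  is_pa <- ds$records$point_class == "pseudo_absence"
  if (!any(is_pa)) stop("dataset has no pseudo-absence records")
  rows <- list()
  for (g in groups) {
    sel_g <- !is.na(lab) & lab == g
    if (!any(sel_g)) {
      warning("group ", g, " has no presence records; skipped")
      next
    }
    season <- if (g %in% c("BM", "BF")) "breeding" else "non_breeding"
    sel_pa <- is_pa & (pool_availability | ds$records$season == season)
    if (!any(sel_pa))
      stop("no pseudo-absence records available for season '", season, "'")
    for (fn in names(ds$scheme)) {
      ncat <- ds$scheme[[fn]]$n_categories
      r <- tabulate(bm[sel_g, fn], nbins = ncat)
      p <- tabulate(bm[sel_pa, fn], nbins = ncat)
      wi <- vanderploeg_wi(r, p)
      ei <- scavia_ei(wi)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, factor = fn, category = seq_len(ncat),
        category_label = ds$scheme[[fn]]$categories,
        r = r, p = p, Wi = wi, Ei = ei, class = classify_ei(ei),
        excluded = fn %in% exclude_factors, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("selection_table", "data.frame")
  out
}
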
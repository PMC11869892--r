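#' Landscape configuration for the synthetic survey generator
#'
#' Describes the background against which presences and pseudo-absences are
#' drawn: a rectangular survey extent in planar metres, per-factor
#' availability distributions over the category bins, and rectangular
#' unsuitable zones (the analogue of highways, open water and cliffs) that
#' no sampling point may fall in.
#'
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)` in metres.
#' @param availability Either a named list mapping factor name to a
#'   probability vector over its categories, or a list with elements
#'   `breeding` and `non_breeding` of that shape (seasonal availability may
#'   differ). `NULL` means uniform availability for every factor.
#' @param unsuitable_zones List of rectangles `c(xmin, xmax, ymin, ymax)`,
#'   each inside `extent`.
#' @param scheme A `factor_scheme`.
#' @return An object of class `landscape_config`.
#' @export
landscape_config <- function(extent = c(0, 2000, 0, 2000),
                             availability = NULL,
                             unsuitable_zones = list(),
                             scheme = default_scheme()) {
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3])
  uniform <- lapply(scheme, function(f) rep(1 / f$n_categories, f$n_categories))
  normalize_av <- function(av) {
    av <- utils::modifyList(uniform, av[intersect(names(av), names(scheme))])
    for (fn in names(av)) {
      v <- as.numeric(av[[fn]])
      if (length(v) != scheme[[fn]]$n_categories || any(v < 0) || sum(v) <= 0)
        stop("availability for '", fn, "' must be a nonnegative vector over ",
             scheme[[fn]]$n_categories, " categories")
      av[[fn]] <- v / sum(v)
    }
    av
  }
  if (is.null(availability)) {
    availability <- list(breeding = uniform, non_breeding = uniform)
  } else if (all(c("breeding", "non_breeding") %in% names(availability))) {
    availability <- list(breeding = normalize_av(availability$breeding),
                         non_breeding = normalize_av(availability$non_breeding))
  } else {
    av <- normalize_av(availability)
    availability <- list(breeding = av, non_breeding = av)
  }
  for (z in unsuitable_zones) {
    stopifnot(length(z) == 4)
    if (z[1] < extent[1] || z[2] > extent[2] || z[3] < extent[3] || z[4] > extent[4])
      stop("unsuitable zone outside the survey extent")
  }
  structure(list(extent = as.numeric(extent), availability = availability,
                 unsuitable_zones = unsuitable_zones, scheme = scheme),
            class = "landscape_config")
}

#' Group-specific selection preferences for the generator
#'
#' Preference weights act multiplicatively on availability: an individual's
#' category for a factor is drawn from `availability * weights`,
#' renormalized. Uniform weights mean no preference; concentrating weight
#' on one category plants a selection signal that the electivity indices
#' should recover.
#'
#' @param group `"BM"`, `"BF"`, `"NBM"` or `"NBF"`.
#' @param n Number of individuals.
#' @param weights Named list factor name -> positive weight vector over that
#'   factor's categories. Omitted factors get uniform weights.
#' @return An object of class `group_profile`.
#' @export
group_profile <- function(group, n, weights = list()) {
  group <- match.arg(group, group_levels())
  stopifnot(n >= 1)
  for (fn in names(weights)) {
    w <- as.numeric(weights[[fn]])
    if (any(w < 0) || sum(w) <= 0)
      stop("weights for '", fn, "' must be nonnegative with positive sum")
    weights[[fn]] <- w / sum(w)
  }
  structure(list(group = group, n = as.integer(n), weights = weights),
            class = "group_profile")
}

#' Default group preference profiles
#'
#' Group sizes follow the reference survey (BM = 43, BF = 19, NBM = 15,
#' NBF = 15). The preference structure is deliberately simple and is chosen
#' to mirror the qualitative pattern the indices are meant to detect: the
#' breeding groups share mild, overlapping preferences (mid temperature,
#' near water), NBM is broad, and NBF is concentrated (low altitude,
#' down-slope, far from roads) so it has the narrowest niche and the lowest
#' overlap with the others.
#'
#' @return Named list of `group_profile` objects for the four groups.
#' @export
default_profiles <- function() {
  list(
    BM = group_profile("BM", 43, list(
      temperature = c(0.2, 0.6, 0.2),
      distance_water = c(0.5, 0.3, 0.2))),
    BF = group_profile("BF", 19, list(
      temperature = c(0.2, 0.6, 0.2),
      humidity = c(0.15, 0.35, 0.5))),
    NBM = group_profile("NBM", 15, list(
      humidity = c(0.2, 0.3, 0.5),
      distance_water = c(0.45, 0.35, 0.2))),
    NBF = group_profile("NBF", 15, list(
      altitude = c(0.7, 0.2, 0.1),
      slope_position = c(0.6, 0.3, 0.1),
      distance_roads = c(0.1, 0.2, 0.7),
      temperature = c(0.3, 0.5, 0.2)))
  )
}

in_any_zone <- function(x, y, zones) {
  if (!length(zones)) return(rep(FALSE, length(x)))
  hit <- rep(FALSE, length(x))
  for (z in zones)
    hit <- hit | (x >= z[1] & x <= z[2] & y >= z[3] & y <= z[4])
  hit
}

# Uniform points over extent minus unsuitable zones; optional minimum
# distance to (px, py). Rejection sampling, loud failure at the cap.
sample_points <- function(n, landscape, px = numeric(), py = numeric(),
                          min_dist = 0, max_attempts = 10000) {
  e <- landscape$extent
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      x <- stats::runif(1, e[1], e[2]); y <- stats::runif(1, e[3], e[4])
      if (in_any_zone(x, y, landscape$unsuitable_zones)) next
      if (min_dist > 0 && length(px) &&
          min((x - px)^2 + (y - py)^2) < min_dist^2) next
      ok <- TRUE; break
    }
    if (!ok)
      stop("could not place point ", i, " of ", n, " after ", max_attempts,
           " attempts (", i - 1L, " placed); constraints too tight")
    xs[i] <- x; ys[i] <- y
  }
  list(x = xs, y = ys)
}

# Draw one raw value per record for a factor, given category draws.
# Continuous factors get a uniform value inside the drawn bin; the open
# outer bins get a finite width equal to the adjacent bin (floored at 0).
raw_from_category <- function(fdef, cat_idx) {
  if (fdef$kind == "categorical") return(fdef$categories[cat_idx])
  e <- fdef$bin_edges
  w <- if (length(e) > 1L) diff(e)[1L] else max(e[1L], 1)
  lo_edges <- c(max(0, e[1L] - w), e)
  hi_edges <- c(e, e[length(e)] + w)
  stats::runif(length(cat_idx), lo_edges[cat_idx], hi_edges[cat_idx])
}

draw_factor_values <- function(landscape, season, weights, n) {
  av <- landscape$availability[[season]]
  out <- vector("list", length(landscape$scheme))
  names(out) <- names(landscape$scheme)
  for (fn in names(landscape$scheme)) {
    p <- av[[fn]]
    if (!is.null(weights[[fn]])) p <- p * weights[[fn]]
    if (sum(p) <= 0)
      stop("availability x preference for '", fn,
           "' has zero total probability")
    p <- p / sum(p)
    cats <- sample.int(length(p), n, replace = TRUE, prob = p)
    out[[fn]] <- raw_from_category(landscape$scheme[[fn]], cats)
  }
  out
}

#' Generate presence records with known selection structure
#'
#' Each individual's category for each factor is drawn from the elementwise
#' product of the seasonal availability vector and the group's preference
#' weights, renormalized; the raw value stored in the record is then drawn
#' uniformly inside the chosen bin so the records exercise the binning
#' path. Coordinates are uniform over the extent minus unsuitable zones.
#'
#' @param landscape A `landscape_config`.
#' @param profiles List of `group_profile`s (default [default_profiles()]).
#' @param seed Integer seed; fixed seed gives an identical dataset.
#' @return A `habitat_dataset` of presence records. The generating profiles
#'   are attached as attribute `"truth"`.
#' @export
generate_presences <- function(landscape, profiles = default_profiles(),
                               seed = 1L) {
  stopifnot(inherits(landscape, "landscape_config"))
  with_seed(seed, {
    parts <- lapply(profiles, function(pr) {
      season <- if (pr$group %in% c("BM", "BF")) "breeding" else "non_breeding"
      sex <- if (pr$group %in% c("BM", "NBM")) "M" else "F"
      pts <- sample_points(pr$n, landscape)
      vals <- draw_factor_values(landscape, season, pr$weights, pr$n)
      cbind(data.frame(point_id = paste0(pr$group, "_", seq_len(pr$n)),
                       point_class = "presence", season = season, sex = sex,
                       x_m = pts$x, y_m = pts$y, stringsAsFactors = FALSE),
            as.data.frame(vals, stringsAsFactors = FALSE))
    })
    ds <- habitat_dataset(do.call(rbind, c(parts, make.row.names = FALSE)),
                          landscape$scheme)
    attr(ds, "truth") <- profiles
    ds
  })
}

#' Generate pseudo-absence points with an exclusion radius
#'
#' For each season present in `presences`, draws `n` background points
#' uniformly over the extent, rejecting candidates inside an unsuitable
#' zone or within `exclusion_radius_m` of any presence of the same season
#' (mirroring a 50-point, 50 m buffer background design). Factor categories
#' are drawn from availability alone — pseudo-absences express what the
#' landscape offers, not a preference.
#'
#' @param landscape A `landscape_config`.
#' @param presences A `habitat_dataset` of presence records (may be empty).
#' @param n Points per season.
#' @param exclusion_radius_m Minimum Euclidean distance (m) to same-season
#'   presences.
#' @param seed Integer seed.
#' @param seasons Seasons to generate for; defaults to the seasons present
#'   in `presences` (both seasons when `presences` is empty).
#' @param max_attempts Rejection-sampling cap per point; exceeding it is an
#'   error reporting the shortfall.
#' @return A `habitat_dataset` of pseudo-absence records.
#' @export
generate_pseudo_absences <- function(landscape, presences = NULL, n = 50,
                                     exclusion_radius_m = 50, seed = 1L,
                                     seasons = NULL, max_attempts = 10000) {
  stopifnot(inherits(landscape, "landscape_config"), n >= 1)
  pres <- if (is.null(presences)) NULL else presences$records
  if (is.null(seasons))
    seasons <- if (!is.null(pres) && nrow(pres))
      unique(pres$season) else c("breeding", "non_breeding")
  with_seed(seed, {
    parts <- lapply(seasons, function(season) {
      sel <- if (is.null(pres)) logical() else pres$season == season
      pts <- sample_points(n, landscape,
                           px = if (any(sel)) pres$x_m[sel] else numeric(),
                           py = if (any(sel)) pres$y_m[sel] else numeric(),
                           min_dist = exclusion_radius_m,
                           max_attempts = max_attempts)
      vals <- draw_factor_values(landscape, season, list(), n)
      tag <- if (season == "breeding") "B" else "NB"
      cbind(data.frame(point_id = paste0("PA_", tag, "_", seq_len(n)),
                       point_class = "pseudo_absence", season = season,
                       sex = NA_character_, x_m = pts$x, y_m = pts$y,
                       stringsAsFactors = FALSE),
            as.data.frame(vals, stringsAsFactors = FALSE))
    })
    habitat_dataset(do.call(rbind, c(parts, make.row.names = FALSE)),
                    landscape$scheme)
  })
}

#' Simulate a complete survey dataset
#'
#' Convenience wrapper: presences from the profiles, then `n_pseudo`
#' pseudo-absences per season, combined into one dataset.
#'
#' @inheritParams generate_presences
#' @inheritParams generate_pseudo_absences
#' @param n_pseudo Pseudo-absence points per season.
#' @return A `habitat_dataset` with presences and pseudo-absences; the
#'   generating profiles are attached as attribute `"truth"`.
#' @examples
#' ds <- simulate_dataset(seed = 7)
#' table(group_labels(ds))
#' @export
simulate_dataset <- function(landscape = landscape_config(),
                             profiles = default_profiles(), n_pseudo = 50,
                             exclusion_radius_m = 50, seed = 1L,
                             max_attempts = 10000) {
  pres <- generate_presences(landscape, profiles, seed = seed)
  pa <- generate_pseudo_absences(landscape, pres, n = n_pseudo,
                                 exclusion_radius_m = exclusion_radius_m,
                                 seed = seed + 1000003L,
                                 max_attempts = max_attempts)
  ds <- habitat_dataset(rbind(pres$records, pa$records), landscape$scheme)
  attr(ds, "truth") <- profiles
  ds
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
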
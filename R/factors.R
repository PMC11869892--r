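#' Define a habitat factor and its category structure
#'
#' A habitat factor is either a continuous measurement that is discretized
#' into ordered categories by cut points, or a categorical measurement with a
#' fixed set of labels. Electivity and niche statistics operate on the
#' category index `i` in `1..n_categories`, never on raw values.
#'
#' @param name Factor name (unique within a scheme).
#' @param kind `"continuous_binned"` or `"categorical"`.
#' @param bin_edges For continuous factors, strictly increasing cut points;
#'   with `k` edges the factor has `k + 1` categories. Ignored for
#'   categorical factors.
#' @param categories Ordered category labels. For continuous factors these
#'   default to interval labels built from `bin_edges`.
#' @param unit Measurement unit (informational).
#' @return An object of class `factor_def`.
#' @examples
#' factor_def("altitude", "continuous_binned", bin_edges = c(200, 400), unit = "m")
#' factor_def("vegetation_type", "categorical",
#'            categories = c("grass", "shrub", "tree"))
#' @export
factor_def <- function(name, kind = c("continuous_binned", "categorical"),
                       bin_edges = numeric(), categories = NULL,
                       unit = "") {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "continuous_binned") {
    bin_edges <- as.numeric(bin_edges)
    if (length(bin_edges) < 1L || any(!is.finite(bin_edges)))
      stop("continuous factor '", name, "' needs at least one finite bin edge")
    if (is.unsorted(bin_edges, strictly = TRUE))
      stop("bin_edges of '", name, "' must be strictly increasing")
    if (is.null(categories)) {
      lo <- c("<", bin_edges)
      categories <- character(length(bin_edges) + 1L)
      categories[1L] <- paste0("<", bin_edges[1L])
      if (length(bin_edges) > 1L)
        for (j in seq_len(length(bin_edges) - 1L))
          categories[j + 1L] <- paste0(bin_edges[j], "-", bin_edges[j + 1L])
      categories[length(categories)] <- paste0(">=", bin_edges[length(bin_edges)])
    }
  } else {
    bin_edges <- numeric()
    if (is.null(categories))
      stop("categorical factor '", name, "' needs explicit categories")
  }
  categories <- as.character(categories)
  if (length(categories) < 2L)
    stop("factor '", name, "' must have at least 2 categories")
  if (kind == "continuous_binned" && length(bin_edges) != length(categories) - 1L)
    stop("factor '", name, "': length(bin_edges) must equal n_categories - 1")
  if (anyDuplicated(categories))
    stop("factor '", name, "' has duplicated category labels")
  structure(list(name = name, kind = kind, bin_edges = bin_edges,
                 categories = categories, n_categories = length(categories),
                 unit = unit),
            class = "factor_def")
}

#' Bundle factor definitions into a scheme
#'
#' @param ... `factor_def` objects (or a single list of them).
#' @return An object of class `factor_scheme`: a named list of factor
#'   definitions, ordered as given.
#' @seealso [default_scheme()]
#' @export
factor_scheme <- function(...) {
  defs <- list(...)
  if (length(defs) == 1L && !inherits(defs[[1L]], "factor_def"))
    defs <- defs[[1L]]
  if (!length(defs) || !all(vapply(defs, inherits, TRUE, "factor_def")))
    stop("factor_scheme() takes factor_def objects")
  nms <- vapply(defs, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("factor names must be unique in a scheme")
  names(defs) <- nms
  structure(defs, class = "factor_scheme")
}

#' The default 13-factor microhabitat scheme
#'
#' The standard quadrat scheme for this survey design: 13 habitat factors,
#' each discretized into 3 ordered categories. Nine are continuous
#' (altitude, temperature, humidity, vegetation coverage and height, slope,
#' and distances from roads, water and residential sites) with the cut
#' points used in the *Viridovipera stejnegeri* survey this package follows
#' (e.g. altitude <200 m / 200-400 m / >400 m); four are categorical
#' (landscape habitat, vegetation type, slope position, aspect).
#'
#' Interval ownership at a cut point follows the lower-closed convention of
#' [bin_value()]: an altitude of exactly 200 m falls in category 2.
#'
#' @return A `factor_scheme` with 13 factors of 3 categories each.
#' @examples
#' sch <- default_scheme()
#' names(sch)
#' sch$altitude$bin_edges
#' @export
default_scheme <- function() {
  factor_scheme(
    factor_def("altitude", "continuous_binned", c(200, 400),
               c("<200", "200-400", ">400"), unit = "m"),
    factor_def("landscape_habitat", "categorical",
               categories = c("stream", "forest", "agricultural")),
    factor_def("vegetation_type", "categorical",
               categories = c("grass", "shrub", "tree")),
    factor_def("temperature", "continuous_binned", c(20, 30),
               c("<20", "20-30", ">30"), unit = "degC"),
    factor_def("humidity", "continuous_binned", c(40, 70),
               c("<40", "40-70", ">70"), unit = "%"),
    factor_def("vegetation_coverage", "continuous_binned", c(20, 70),
               c("<20", "20-70", ">70"), unit = "%"),
    factor_def("vegetation_height", "continuous_binned", c(2, 5),
               c("0-2", "2-5", ">5"), unit = "m"),
    factor_def("slope", "continuous_binned", c(15, 40),
               c("0-15", "15-40", ">40"), unit = "deg"),
    factor_def("slope_position", "categorical",
               categories = c("down", "mid", "up")),
    factor_def("distance_roads", "continuous_binned", c(10, 30),
               c("0-10", "10-30", ">30"), unit = "m"),
    factor_def("distance_water", "continuous_binned", c(5, 20),
               c("<5", "5-20", ">20"), unit = "m"),
    factor_def("distance_residential", "continuous_binned", c(100, 500),
               c("<100", "100-500", ">500"), unit = "m"),
    factor_def("aspect", "categorical",
               categories = c("sunny", "half", "shady"))
  )
}

#' Assign a raw value to its factor category
#'
#' Continuous factors use lower-closed intervals: with edges `(e1, e2)` the
#' categories are `(-Inf, e1)`, `[e1, e2)`, `[e2, Inf)`, so a value exactly
#' on a cut point belongs to the upper category. Categorical factors match
#' the label against the definition's category set.
#'
#' @param factor A `factor_def`.
#' @param raw Numeric vector (continuous factors) or character vector of
#'   labels (categorical factors). `NA` is passed through as `NA`.
#' @return Integer vector of 1-based category indices.
#' @examples
#' alt <- factor_def("altitude", "continuous_binned", c(200, 400))
#' bin_value(alt, c(150, 200, 399.9, 400, 1200))  # 1 2 2 3 3
#' @export
bin_value <- function(factor, raw) {
  stopifnot(inherits(factor, "factor_def"))
  if (factor$kind == "continuous_binned") {
    raw <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & !is.finite(raw)
    if (any(bad))
      stop("non-finite value for continuous factor '", factor$name, "'")
    idx <- findInterval(raw, factor$bin_edges) + 1L
    idx[is.na(raw)] <- NA_integer_
  } else {
    raw <- as.character(raw)
    idx <- match(raw, factor$categories)
    unknown <- !is.na(raw) & is.na(idx)
    if (any(unknown))
      stop("unknown label(s) for categorical factor '", factor$name, "': ",
           paste(unique(raw[unknown]), collapse = ", "))
  }
  as.integer(idx)
}

#' @export
print.factor_def <- function(x, ...) {
  cat(sprintf("<factor_def> %s [%s] %d categories: %s\n", x$name, x$kind,
              x$n_categories, paste(x$categories, collapse = " | ")))
  invisible(x)
}

#' @export
print.factor_scheme <- function(x, ...) {
  cat(sprintf("<factor_scheme> %d factors\n", length(x)))
  for (f in x) print(f)
  invisible(x)
}

#' Read or write a factor scheme as YAML
#'
#' The on-disk form mirrors `factor_def` field-for-field so schemes can be
#' shared between runs and edited by hand.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @param scheme A `factor_scheme`.
#' @return `read_scheme()` returns a `factor_scheme`; `write_scheme()`
#'   returns `path` invisibly.
#' @export
read_scheme <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  factor_scheme(lapply(raw, function(f)
    factor_def(f$name, f$kind, as.numeric(f$bin_edges %||% numeric()),
               f$categories, unit = f$unit %||% "")))
}

#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "factor_scheme"))
  plain <- lapply(unname(scheme), function(f)
    list(name = f$name, kind = f$kind, bin_edges = f$bin_edges,
         categories = f$categories, unit = f$unit))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(plain, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
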
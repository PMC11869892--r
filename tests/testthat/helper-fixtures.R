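# Fixture builders: construct small habitat datasets directly from category
# assignments, bypassing the simulator, so index values can be computed by
# hand.

# representative raw value falling in category idx of a factor definition
raw_for_cat <- function(fdef, idx) {
  if (fdef$kind == "categorical") return(fdef$categories[idx])
  e <- fdef$bin_edges
  reps <- c(e[1] - 1, e[-length(e)] + diff(e) / 2, e[length(e)] + 1)
  reps[idx]
}

# a 2-factor scheme (one continuous, one categorical), 3 categories each
tiny_scheme <- function() {
  factor_scheme(
    factor_def("depth", "continuous_binned", c(10, 20),
               c("<10", "10-20", ">20"), unit = "m"),
    factor_def("substrate", "categorical",
               categories = c("sand", "gravel", "rock")))
}

# Build a dataset from per-group / per-season category assignments.
#   presence_cats: named list group -> named list factor -> integer vector
#   pa_cats:       named list season -> named list factor -> integer vector
# Unlisted factors default to category 1. Coordinates are laid on a grid.
build_dataset <- function(presence_cats, pa_cats = list(),
                          scheme = tiny_scheme()) {
  mk_rows <- function(tag, class, season, sex, cats) {
    n <- max(c(1L, lengths(cats)))
    df <- data.frame(point_id = paste0(tag, "_", seq_len(n)),
                     point_class = class, season = season, sex = sex,
                     x_m = seq_len(n) * 100, y_m = rep(0, n),
                     stringsAsFactors = FALSE)
    for (fn in names(scheme)) {
      idx <- cats[[fn]]
      if (is.null(idx)) idx <- rep(1L, n)
      df[[fn]] <- raw_for_cat(scheme[[fn]], idx)
    }
    df
  }
  parts <- list()
  for (g in names(presence_cats)) {
    season <- if (g %in% c("BM", "BF")) "breeding" else "non_breeding"
    sex <- if (g %in% c("BM", "NBM")) "M" else "F"
    parts[[length(parts) + 1L]] <-
      mk_rows(g, "presence", season, sex, presence_cats[[g]])
  }
  for (s in names(pa_cats))
    parts[[length(parts) + 1L]] <-
      mk_rows(paste0("PA", s), "pseudo_absence", s, NA_character_,
              pa_cats[[s]])
  habitat_dataset(do.call(rbind, c(parts, make.row.names = FALSE)), scheme)
}

# repeat category indices according to a count vector: counts (8,1,1) ->
# c(1,1,1,1,1,1,1,1,2,3)
cats_from_counts <- function(counts) rep(seq_along(counts), counts)
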
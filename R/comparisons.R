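#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' Rank-sum test for a location difference between two samples. U is
#' computed from midranks; the null variance carries the standard tie
#' correction, and `Z = (U - n1*n2/2) / sigma_U` is referred to the normal
#' distribution (two-sided). No continuity correction is applied by
#' default so that Z is a smooth, sign-informative statistic (positive Z:
#' `x` tends larger); set `continuity = TRUE` for the corrected
#' convention.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param continuity Apply the 0.5 continuity correction to Z.
#' @return List of class `mw_test`: `U` (for `x`), `Z`, `p_value`, `n1`,
#'   `n2`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, Z = -1.964
#' @export
mann_whitney <- function(x, y, continuity = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty")
  all_v <- c(x, y)
  rk <- rank(all_v)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(all_v)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    z <- 0; p <- 1
  } else {
    dev <- U - n1 * n2 / 2
    if (continuity) dev <- sign(dev) * max(0, abs(dev) - 0.5)
    z <- dev / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(U = U, Z = z, p_value = p, n1 = n1, n2 = n2),
            class = "mw_test")
}

#' Pearson chi-square test on a contingency table
#'
#' `X2 = sum (O - E)^2 / E` with expected counts from the margins,
#' `df = (r - 1)(c - 1)`. A warning is emitted when any expected count is
#' below 5 (the usual approximation caveat). Computed via
#' [stats::chisq.test()] with no continuity correction.
#'
#' @param tab An r x c matrix of nonnegative counts with at least two
#'   non-empty rows and columns.
#' @return List of class `chisq_result`: `statistic`, `df`, `p_value`,
#'   `expected`.
#' @examples
#' chi_square(matrix(c(20, 10, 10, 20), 2))  # X2 = 6.667, df = 1
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(!is.finite(tab)))
    stop("counts must be finite and nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin: test undefined")
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("table needs at least two rows and two columns")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5))
    warning("expected count below 5 in ", sum(ct$expected < 5),
            " cell(s); chi-square approximation may be poor")
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value, expected = ct$expected),
            class = "chisq_result")
}

# Gate a two-sample location comparison: one-way ANOVA when every group
# passes Shapiro-Wilk normality and the Levene test (Brown-Forsythe,
# centre = median) at gate_alpha, Mann-Whitney otherwise. Groups too small
# or too degenerate for Shapiro-Wilk fail the gate.
gated_location_test <- function(x, y, gate_alpha = 0.05,
                                continuity = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  normal_ok <- function(v) {
    if (length(v) < 3L || length(unique(v)) < 2L || length(v) > 5000L)
      return(FALSE)
    stats::shapiro.test(v)$p.value > gate_alpha
  }
  gate <- normal_ok(x) && normal_ok(y)
  if (gate) {
    g <- factor(rep(c("a", "b"), c(length(x), length(y))))
    lev <- car::leveneTest(c(x, y) ~ g, center = stats::median)
    gate <- lev[["Pr(>F)"]][1L] > gate_alpha
  }
  if (gate) {
    fit <- stats::aov(v ~ g, data = data.frame(v = c(x, y),
                                               g = rep(c("a", "b"),
                                                       c(length(x), length(y)))))
    s <- summary(fit)[[1L]]
    list(test = "anova", statistic = s[["F value"]][1L],
         df = c(s[["Df"]][1L], s[["Df"]][2L]), p_value = s[["Pr(>F)"]][1L])
  } else {
    mw <- mann_whitney(x, y, continuity = continuity)
    list(test = "mann_whitney", statistic = mw$Z, df = NA_integer_,
         p_value = mw$p_value)
  }
}

#' Univariate group comparisons across sex or season
#'
#' The standard univariate battery on the presence records: for each
#' continuous factor, the two groups are compared with one-way ANOVA when
#' both pass a Shapiro-Wilk normality check and a Levene
#' (Brown-Forsythe, centre = median) homogeneity check at `gate_alpha`,
#' and with the Mann-Whitney U test otherwise; each categorical factor is
#' tested with a chi-square on the grouping x category table (categories
#' unused by both groups are dropped first). Group mean, sample SD and n
#' accompany each continuous comparison.
#'
#' @param ds A `habitat_dataset`.
#' @param grouping `"sex"` (M vs F) or `"season"` (breeding vs
#'   non-breeding), across presence records.
#' @param gate_alpha Significance level of the normality/homogeneity gate.
#' @param continuity Continuity correction for the Mann-Whitney branch.
#' @param exclude_factors Factors left out (default `"aspect"`).
#' @return Data.frame of class `comparison_table`: one row per factor with
#'   `variable`, `grouping`, `test`, `statistic`, `df1`, `df2`, `p_value`,
#'   and `mean_1`, `sd_1`, `n_1`, `mean_2`, `sd_2`, `n_2` for levels
#'   `level_1`/`level_2` (means/SDs are `NA` for categorical factors).
#' @examples
#' ds <- simulate_dataset(seed = 5)
#' compare_groups(ds, "season")[, c("variable", "test", "statistic", "p_value")]
#' @export
compare_groups <- function(ds, grouping = c("sex", "season"),
                           gate_alpha = 0.05, continuity = FALSE,
                           exclude_factors = "aspect") {
  grouping <- match.arg(grouping)
  stopifnot(inherits(ds, "habitat_dataset"))
  rec <- ds$records[ds$records$point_class == "presence", , drop = FALSE]
  gvar <- if (grouping == "sex") rec$sex else rec$season
  levels2 <- if (grouping == "sex") c("M", "F") else c("breeding", "non_breeding")
  if (!all(levels2 %in% gvar))
    stop("both levels of '", grouping, "' must be present")
  rows <- list()
  for (fn in setdiff(names(ds$scheme), exclude_factors)) {
    fdef <- ds$scheme[[fn]]
    if (fdef$kind == "continuous_binned") {
      x <- rec[[fn]][gvar == levels2[1L]]
      y <- rec[[fn]][gvar == levels2[2L]]
      res <- gated_location_test(x, y, gate_alpha, continuity)
      summ <- function(v) c(mean(v, na.rm = TRUE), stats::sd(v, na.rm = TRUE),
                            sum(!is.na(v)))
      s1 <- summ(x); s2 <- summ(y)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = fn, grouping = grouping, test = res$test,
        statistic = res$statistic, df1 = res$df[1L],
        df2 = if (length(res$df) > 1L) res$df[2L] else NA_integer_,
        p_value = res$p_value, level_1 = levels2[1L], level_2 = levels2[2L],
        mean_1 = s1[1L], sd_1 = s1[2L], n_1 = s1[3L],
        mean_2 = s2[1L], sd_2 = s2[2L], n_2 = s2[3L],
        stringsAsFactors = FALSE)
    } else {
      cats <- bin_value(fdef, rec[[fn]])
      keep <- !is.na(cats)
      tab <- table(factor(gvar[keep], levels = levels2),
                   factor(cats[keep], levels = seq_len(fdef$n_categories)))
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      ct <- chi_square(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = fn, grouping = grouping, test = "chi_square",
        statistic = ct$statistic, df1 = ct$df, df2 = NA_integer_,
        p_value = ct$p_value, level_1 = levels2[1L], level_2 = levels2[2L],
        mean_1 = NA_real_, sd_1 = NA_real_, n_1 = sum(tab[1L, ]),
        mean_2 = NA_real_, sd_2 = NA_real_, n_2 = sum(tab[2L, ]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("comparison_table", "data.frame")
  out
}
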
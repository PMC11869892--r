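#' Build a pipeline run configuration
#'
#' A run either loads records from `input` (a CSV readable by
#' [load_records()]) or simulates them (when `input` is `NULL`) from the
#' default landscape and profiles. One master seed fixes every stochastic
#' stage, so two runs with equal configuration produce byte-identical CSV
#' outputs.
#'
#' @param input Path to a records CSV, or `NULL` to simulate.
#' @param scheme A `factor_scheme` or path to a scheme YAML/JSON.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed (integer).
#' @param n_resamples Label permutations for the overlap null (>= 1).
#' @param symmetrize Overlap symmetrization convention.
#' @param aggregation Niche-breadth aggregation convention.
#' @param outlier_k IQR multiplier for outlier screening (`Inf` disables).
#' @param log_transform Log-transform continuous factors before the
#'   location tests.
#' @param pool_availability Pool both seasons' pseudo-absences as the
#'   availability sample.
#' @param n_pseudo Pseudo-absence points per season (simulation only).
#' @param exclude_factors Factors excluded downstream (default `"aspect"`).
#' @return List of class `run_config`.
#' @export
run_config <- function(input = NULL, scheme = default_scheme(),
                       out_dir = "habelect_run", seed = 1L,
                       n_resamples = 999L,
                       symmetrize = "mean", aggregation = "mean",
                       outlier_k = 3, log_transform = FALSE,
                       pool_availability = FALSE, n_pseudo = 50L,
                       exclude_factors = "aspect") {
  if (is.character(scheme)) scheme <- read_scheme(scheme)
  if (!is.numeric(n_resamples) || n_resamples < 1)
    stop("n_resamples must be >= 1")
  structure(list(input = input, scheme = scheme, out_dir = out_dir,
                 seed = as.integer(seed), n_resamples = as.integer(n_resamples),
                 symmetrize = symmetrize, aggregation = aggregation,
                 outlier_k = outlier_k, log_transform = log_transform,
                 pool_availability = pool_availability,
                 n_pseudo = as.integer(n_pseudo),
                 exclude_factors = exclude_factors),
            class = "run_config")
}

fmt_num <- function(x, digits = 4) {
  ifelse(is.na(x), NA, signif(x, digits))
}

write_stage_csv <- function(df, path, percent_cols = character()) {
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]])) next
    df[[nm]] <- if (nm %in% percent_cols) round(df[[nm]], 2)
    else fmt_num(df[[nm]])
  }
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
}

#' Run the full selection/niche/comparison pipeline
#'
#' Orchestrates simulate (or load) -> preprocess -> electivity table ->
#' niche widths -> overlap matrix + resampling null + paired t ->
#' sex/season comparisons, writing one CSV per stage plus a JSON manifest
#' and a plain-text log into `cfg$out_dir`:
#' `records.csv`, `selection.csv`, `niche_width.csv`, `overlap.csv`
#' (both directions and symmetrized percent per pair), `null_summary.csv`,
#' `comparisons.csv`, `manifest.json`, `run.log`.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, a list with the in-memory stage results
#'   (`dataset`, `selection`, `niche_width`, `overlap`, `comparisons`)
#'   and `out_dir`.
#' @examples
#' \donttest{
#' res <- run_pipeline(run_config(out_dir = tempfile(), seed = 11,
#'                                n_resamples = 99))
#' res$overlap$t_stat
#' }
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, paste0(format(length(log_lines) + 1L), ": ", msg))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  ds <- stage("input", {
    if (is.null(cfg$input)) {
      say("simulating dataset (seed %d, %d pseudo-absences/season)",
          cfg$seed, cfg$n_pseudo)
      simulate_dataset(landscape_config(scheme = cfg$scheme),
                       n_pseudo = cfg$n_pseudo, seed = cfg$seed)
    } else {
      say("loading records from %s", cfg$input)
      load_records(cfg$input, cfg$scheme)
    }
  })
  ds <- stage("preprocess", {
    out <- preprocess(ds, outlier_k = cfg$outlier_k,
                      log_transform = cfg$log_transform)
    say("preprocess: %d modification(s)", nrow(out$processing_log))
    out
  })
  write_records(ds, file.path(cfg$out_dir, "records.csv"))

  sel <- stage("selection", selection_table(
    ds, pool_availability = cfg$pool_availability,
    exclude_factors = cfg$exclude_factors))
  write_stage_csv(as.data.frame(sel), file.path(cfg$out_dir, "selection.csv"))
  say("selection table: %d rows", nrow(sel))

  nw <- stage("niche_width", {
    lapply(group_levels(), function(g)
      group_niche_width(ds, g, exclude_factors = cfg$exclude_factors,
                        aggregation = cfg$aggregation))
  })
  nw_df <- do.call(rbind, lapply(nw, function(w)
    data.frame(group = w$group, aggregate_B = w$aggregate_B,
               t(w$per_factor_B), stringsAsFactors = FALSE)))
  write_stage_csv(nw_df, file.path(cfg$out_dir, "niche_width.csv"))
  say("niche widths: %s",
      paste(sprintf("%s=%.3f", nw_df$group, nw_df$aggregate_B), collapse = " "))

  ov <- stage("niche_overlap", {
    obs <- overlap_matrix(ds, exclude_factors = cfg$exclude_factors,
                          symmetrize = cfg$symmetrize)
    nulls <- resample_null(ds, n_resamples = cfg$n_resamples,
                           seed = cfg$seed + 2000003L,
                           exclude_factors = cfg$exclude_factors,
                           symmetrize = cfg$symmetrize)
    overlap_significance(obs, nulls)
  })
  gs <- ov$groups
  pair_idx <- which(upper.tri(ov$O_sym_pct), arr.ind = TRUE)
  ov_df <- data.frame(group_i = gs[pair_idx[, 1L]], group_k = gs[pair_idx[, 2L]],
                      O_ik = ov$O_dir[pair_idx],
                      O_ki = t(ov$O_dir)[pair_idx],
                      O_sym_pct = ov$O_sym_pct[pair_idx],
                      stringsAsFactors = FALSE)
  write_stage_csv(ov_df, file.path(cfg$out_dir, "overlap.csv"),
                  percent_cols = "O_sym_pct")
  null_df <- data.frame(mean_obs = ov$mean_obs, sd_obs = ov$sd_obs,
                        mean_null = ov$mean_null, sd_null = ov$sd_null,
                        t_abs = ov$t_stat, df = ov$df, p_value = ov$p_value,
                        perm_p = ov$perm_p %||% NA_real_,
                        n_resamples = cfg$n_resamples,
                        seed = cfg$seed, stringsAsFactors = FALSE)
  write_stage_csv(null_df, file.path(cfg$out_dir, "null_summary.csv"),
                  percent_cols = c("mean_obs", "sd_obs", "mean_null", "sd_null"))
  say("overlap: |t| = %.3f, p = %.3f (%d resamples)", ov$t_stat, ov$p_value,
      cfg$n_resamples)

  cmp <- stage("comparisons", {
    rbind(compare_groups(ds, "sex", exclude_factors = cfg$exclude_factors),
          compare_groups(ds, "season", exclude_factors = cfg$exclude_factors))
  })
  write_stage_csv(as.data.frame(cmp), file.path(cfg$out_dir, "comparisons.csv"))
  say("comparisons: %d tests", nrow(cmp))

  manifest <- list(
    package = "habelect",
    version = as.character(utils::packageVersion("habelect")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed, n_resamples = cfg$n_resamples,
    symmetrize = cfg$symmetrize, aggregation = cfg$aggregation,
    outlier_k = cfg$outlier_k, log_transform = cfg$log_transform,
    pool_availability = cfg$pool_availability, n_pseudo = cfg$n_pseudo,
    input = cfg$input %||% "simulated",
    exclude_factors = cfg$exclude_factors,
    n_records = nrow(ds$records))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, log_path)
  invisible(list(dataset = ds, selection = sel, niche_width = nw_df,
                 overlap = ov, comparisons = cmp, out_dir = cfg$out_dir))
}
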
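#' Read a per-study p-value table
#'
#' Reads a delimited text file with a header. Tab is the canonical
#' separator; comma is accepted (sniffed from the header line). Required
#' column: `pvalue` (or `p`); optional columns `study`, `n` (per-study
#' sample size) and `se` (per-study standard error) drive the weighted
#' z-tests. Values are validated with [validate_pvalues()] and row order is
#' preserved.
#'
#' @param path file path.
#' @return a list with `pvalues` (a `study_pvalues` vector), `study`, and
#'   (if present) `n` and `se`.
#' @export
read_pvalue_table <- function(path) {
  df <- .read_delim(path)
  pcol <- intersect(c("pvalue", "p"), names(df))
  if (length(pcol) == 0L) stop_input("missing column 'pvalue' in ", path)
  raw <- df[[pcol[1L]]]
  if (length(raw) == 0L) stop_input("no studies")
  if (!is.numeric(raw)) stop_input("unparsable p-value in ", path)
  bad <- which(!is.finite(raw) | raw < 0 | raw > 1)
  if (length(bad) > 0L)
    stop_input("invalid p-value at row ", bad[1L], " of ", path,
               " (value ", format(raw[bad[1L]]), ")")
  out <- list(pvalues = validate_pvalues(raw),
              study = if ("study" %in% names(df)) as.character(df$study)
                      else as.character(seq_along(raw)))
  if ("n" %in% names(df)) out$n <- df$n
  if ("se" %in% names(df)) out$se <- df$se
  out
}

#' Read a case/control count table
#'
#' Expects header columns `study`, `case_event`, `case_total`,
#' `control_event`, `control_total` (tab or comma separated) and returns a
#' validated [count_table()].
#'
#' @param path file path.
#' @return a `count_table`.
#' @export
read_count_table <- function(path) {
  df <- .read_delim(path)
  need <- c("study", "case_event", "case_total", "control_event",
            "control_total")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop_input("missing column '", miss[1L], "' in ", path)
  if (nrow(df) == 0L) stop_input("no studies")
  count_table(df$study, df$case_event, df$case_total, df$control_event,
              df$control_total)
}

.read_delim <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) ","
         else "\t"
  read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
             strip.white = TRUE)
}

#' Write combination results to TSV or JSON
#'
#' Columns are written in fixed order (method, statistic, combined_p,
#' mc_stderr, null_description). Numbers keep full precision so small
#' combined p-values survive a round-trip through [read.table()] or
#' [jsonlite::read_json()].
#'
#' @param results a list of `combine_result` objects or a data.frame from
#'   [combine_results_table()].
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- if (is.data.frame(results)) results else combine_results_table(results)
  if (nrow(df) == 0L) stop_input("no results to write")
  df <- df[, c("method", "statistic", "combined_p", "mc_stderr",
               "null_description")]
  if (format == "tsv") {
    write.table(format(df, digits = 15, trim = TRUE, scientific = NA),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}

#' Read a simulation scenario from a YAML config
#'
#' The config is a flat YAML mapping. Keys: `K`; an effect allocation
#' (either `effects`, a list of K means, or `total_effect` with `ratio`
#' for K = 2, or `total_effect` with `i_active` for sparse designs);
#' `n_mode` (`fixed`/`poisson`) with `n` or `lambda`; `sigma_mode`
#' (`fixed`/`gamma`) with `sigma` or `sigma_shape`/`sigma_scale`; `reps`;
#' `alpha`; `seed`. A key `ratios` (or `i_active_grid`) lists several
#' conditions; [read_scenario()] then returns a list of scenarios.
#'
#' @param path YAML file path.
#' @return a single [scenario()] or a named list of scenarios (one per
#'   condition).
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `n:` key as the boolean FALSE; map it back
  names(cfg)[names(cfg) == "FALSE"] <- "n"
  for (key in c("K", "reps")) if (is.null(cfg[[key]]))
    stop_input("scenario config missing key '", key, "'")
  n_spec <- if (identical(cfg$n_mode, "poisson"))
    sample_size_spec("poisson", lambda = cfg$lambda %||% 20)
  else sample_size_spec("fixed", n = cfg[["n"]] %||% 20)
  s_spec <- if (identical(cfg$sigma_mode, "gamma"))
    sigma_spec("gamma", shape = cfg$sigma_shape %||% 10,
               scale = cfg$sigma_scale %||% 0.1)
  else sigma_spec("fixed", sigma = cfg$sigma %||% 1)
  mk <- function(effects, label) {
    sc <- scenario(cfg$K, effects, n_spec = n_spec, s_spec = s_spec,
                   reps = cfg$reps, alpha = cfg$alpha %||% 0.05,
                   seed = cfg$seed %||% 1)
    sc$label <- label
    sc
  }
  if (!is.null(cfg$ratios)) {
    out <- lapply(cfg$ratios, function(r)
      mk(allocate_effects_ratio(cfg$total_effect, r),
         sprintf("ratio=%g", r)))
    names(out) <- vapply(out, `[[`, "", "label")
    out
  } else if (!is.null(cfg$i_active_grid)) {
    out <- lapply(cfg$i_active_grid, function(i)
      mk(allocate_effects_sparse(cfg$K, cfg$total_effect, i),
         sprintf("i_active=%d", as.integer(i))))
    names(out) <- vapply(out, `[[`, "", "label")
    out
  } else if (!is.null(cfg$i_active)) {
    mk(allocate_effects_sparse(cfg$K, cfg$total_effect, cfg$i_active),
       sprintf("i_active=%d", as.integer(cfg$i_active)))
  } else if (!is.null(cfg$ratio)) {
    mk(allocate_effects_ratio(cfg$total_effect, cfg$ratio),
       sprintf("ratio=%g", cfg$ratio))
  } else if (!is.null(cfg$effects)) {
    mk(as.numeric(unlist(cfg$effects)), "effects")
  } else {
    mk(rep(0, cfg$K), "null")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the packaged example inputs to a directory
#'
#' Writes (a) the five-study case/control count table, (b) the matching
#' five reported per-study p-values, and (c) three scenario configs for the
#' simulation designs (K = 2 effect-ratio grid, K = 10 and K = 100 sparse
#' designs) at desk-scale replicate counts. Output is deterministic: the
#' seed is recorded inside the configs, so regeneration is byte-identical.
#'
#' @param dir output directory (created if needed).
#' @param seed seed written into the scenario configs.
#' @return character vector of the files written.
#' @export
generate_fixtures <- function(dir, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  src <- system.file("extdata", package = "pcombine")
  files <- c("depression_counts.tsv", "depression_pvalues.tsv")
  for (f in files) file.copy(file.path(src, f), file.path(dir, f),
                             overwrite = TRUE)
  cfgs <- list(
    scenario_k2.yaml = c(
      "# K = 2 effect-ratio grid: total effect 1 split at six ratios",
      "K: 2", "total_effect: 1.0",
      "ratios: [0, 0.01, 0.05, 0.1, 0.5, 1]",
      "n_mode: fixed", "n: 20", "sigma_mode: fixed", "sigma: 1.0",
      "reps: 10000", "alpha: 0.05", sprintf("seed: %d", as.integer(seed))),
    scenario_k10.yaml = c(
      "# K = 10 sparse design: i active studies share a total effect of 2",
      "K: 10", "total_effect: 2.0",
      "i_active_grid: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]",
      "n_mode: fixed", "n: 20", "sigma_mode: fixed", "sigma: 1.0",
      "reps: 10000", "alpha: 0.05", sprintf("seed: %d", as.integer(seed))),
    scenario_k100.yaml = c(
      "# K = 100 sparse design: i active studies share a total effect of 2",
      "K: 100", "total_effect: 2.0",
      "i_active_grid: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]",
      "n_mode: fixed", "n: 20", "sigma_mode: fixed", "sigma: 1.0",
      "reps: 10000", "alpha: 0.05", sprintf("seed: %d", as.integer(seed))))
  for (nm in names(cfgs))
    writeLines(cfgs[[nm]], file.path(dir, nm))
  invisible(file.path(dir, c(files, names(cfgs))))
}
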
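#' Per-study 2x2 case/control count table
#'
#' One row per study with event and total counts in each arm, as summary
#' data for a case-control meta-analysis. Counts are subject counts.
#'
#' @param study study labels (coerced to character).
#' @param case_event,case_total,control_event,control_total non-negative
#'   integer vectors of equal length; events cannot exceed totals and
#'   totals must be at least 1.
#' @return a data.frame of class `"count_table"`.
#' @export
count_table <- function(study, case_event, case_total, control_event,
                        control_total) {
  n <- length(case_event)
  if (n == 0L) stop_input("no studies")
  lens <- c(length(study), length(case_total), length(control_event),
            length(control_total))
  if (any(lens != n)) stop_input("count table columns must have equal length")
  cnt <- cbind(case_event, case_total, control_event, control_total)
  if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != floor(cnt)))
    stop_input("counts must be non-negative integers")
  if (any(case_total < 1) || any(control_total < 1))
    stop_input("arm totals must be >= 1")
  bad_case <- which(case_event > case_total)
  if (length(bad_case) > 0L)
    stop_input("event exceeds total in case arm of study ",
               study[bad_case[1L]])
  bad_ctrl <- which(control_event > control_total)
  if (length(bad_ctrl) > 0L)
    stop_input("event exceeds total in control arm of study ",
               study[bad_ctrl[1L]])
  out <- data.frame(study = as.character(study),
                    case_event = as.integer(case_event),
                    case_total = as.integer(case_total),
                    control_event = as.integer(control_event),
                    control_total = as.integer(control_total),
                    stringsAsFactors = FALSE)
  class(out) <- c("count_table", "data.frame")
  out
}

# pooled two-proportion z-test pieces for one or more studies (vectorized)
.two_prop <- function(e1, n1, e2, n2) {
  p1 <- e1 / n1
  p2 <- e2 / n2
  pbar <- (e1 + e2) / (n1 + n2)
  se <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  list(z = z, se = se, p = 2 * pnorm(-abs(z)))
}

#' Pooled two-proportion z-test p-value for one study
#'
#' Compares the event proportions of the case and control arms with the
#' classical pooled z-test, two-sided, without continuity correction:
#' `z = (p1 - p2) / sqrt(pbar (1 - pbar) (1/n1 + 1/n2))` where `pbar` pools
#' the two arms.
#'
#' @param case_event,case_total,control_event,control_total counts for one
#'   study (scalars, or a single-row [count_table()] passed as
#'   `case_event`).
#' @return the two-sided p-value.
#' @export
two_proportion_pvalue <- function(case_event, case_total = NULL,
                                  control_event = NULL,
                                  control_total = NULL) {
  if (inherits(case_event, "count_table")) {
    tab <- case_event
    if (nrow(tab) != 1L) stop_input("pass a single-row count table")
    return(two_proportion_pvalue(tab$case_event, tab$case_total,
                                 tab$control_event, tab$control_total))
  }
  all_or_none <- (case_event + control_event == 0) ||
    (case_event == case_total && control_event == control_total)
  if (all_or_none)
    stop_input("degenerate table (pooled proportion 0 or 1)")
  .two_prop(case_event, case_total, control_event, control_total)$p
}

#' Meta-analyze a case/control count table
#'
#' Runs the pooled two-proportion z-test per study (two-sided) and combines
#' the resulting p-values with every requested method. Sample-size weights
#' (`z_n`) use each study's total `case_total + control_total`;
#' inverse-standard-error weights (`z_se`) use the pooled two-proportion
#' standard error. Supplying `pvalues` bypasses the per-study test (for
#' instance to combine externally reported per-study p-values) while the
#' counts still provide the weights.
#'
#' @param table a [count_table()].
#' @param methods method tokens (see [combine_pvalues()]).
#' @param pvalues optional numeric vector of per-study p-values overriding
#'   the two-proportion test (length must match the table).
#' @param null_n,seed,store,cache_dir Monte-Carlo null controls for the
#'   `"new"` method, passed to [adaptive_gamma_combine()].
#' @return a list with `per_study` (data.frame: study, p-value, n, se) and
#'   `combined` (a list of `combine_result`, one per method).
#' @export
analyze_count_table <- function(table, methods = c("z", "z_n", "z_se",
                                                   "fisher", "cn", "new"),
                                pvalues = NULL, null_n = 1e6, seed = 1,
                                store = NULL, cache_dir = NULL) {
  if (!inherits(table, "count_table")) stop_input("not a count_table")
  tp <- .two_prop(table$case_event, table$case_total, table$control_event,
                  table$control_total)
  if (is.null(pvalues)) {
    degen <- !is.finite(tp$z)
    if (any(degen))
      stop_input("degenerate table (pooled proportion 0 or 1) for study ",
                 table$study[which(degen)[1L]])
    pvalues <- tp$p
  } else if (length(pvalues) != nrow(table)) {
    stop_input("pvalues length ", length(pvalues), " does not match ",
               nrow(table), " studies")
  }
  n_tot <- table$case_total + table$control_total
  per_study <- data.frame(study = table$study, pvalue = pvalues, n = n_tot,
                          se = tp$se, stringsAsFactors = FALSE)
  combined <- combine_pvalues(pvalues, methods = methods,
                              sample_sizes = n_tot,
                              standard_errors = tp$se, null_n = null_n,
                              seed = seed, store = store,
                              cache_dir = cache_dir)
  list(per_study = per_study, combined = combined)
}
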
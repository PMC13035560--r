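#' One-way deterministic sensitivity analysis (tornado)
#'
#' Sweeps each parameter in turn to its low and high bound while holding every
#' other parameter at base value, re-evaluates the model, and records the
#' chosen outcome metric at both ends. Parameters use their one-way range
#' where published; success rates, published with a 95\% CI instead, are swept
#' over the CI. Parameters with neither are skipped (listed in the `skipped`
#' attribute). Entries are sorted by decreasing bar width.
#'
#' The default metric is the ICER of a named comparison; ICERs are
#' sign-unstable when the incremental effect crosses zero, so net monetary
#' benefit at fixed `wtp` is available as a robust alternative
#' (`metric = "nmb"` reports the NMB difference comparison minus reference).
#'
#' @param tree a `decision_tree`.
#' @param registry a `param_registry`.
#' @param comparison character vector `c(strategy, reference)`.
#' @param metric `"icer"` or `"nmb"`.
#' @param wtp willingness-to-pay for the NMB metric.
#' @param overrides optional named scenario overrides applied before sweeping.
#' @return data.frame of class `tornado`: parameter, low, high, metric_low,
#'   metric_high, base metric, width; sorted by decreasing width.
#' @export
one_way_sa <- function(tree, registry, comparison, metric = c("icer", "nmb"),
                       wtp = 3500, overrides = NULL) {
  metric <- match.arg(metric)
  stopifnot(length(comparison) == 2)
  base <- base_values(registry, overrides)
  eval_metric <- function(values) {
    rb <- rollback(tree, values)
    s <- rb[rb$strategy == comparison[1], ]
    r <- rb[rb$strategy == comparison[2], ]
    if (nrow(s) != 1 || nrow(r) != 1)
      stop("comparison strategies not found in tree")
    if (metric == "icer") {
      de <- s$expected_effect - r$expected_effect
      if (abs(de) < 1e-12) NA_real_
      else (s$expected_cost - r$expected_cost) / de
    } else {
      (wtp * s$expected_effect - s$expected_cost) -
        (wtp * r$expected_effect - r$expected_cost)
    }
  }
  base_metric <- eval_metric(base)
  rows <- list(); skipped <- character(0)
  for (s in registry$specs) {
    lo <- if (!is.na(s$low)) s$low else s$ci_low
    hi <- if (!is.na(s$high)) s$high else s$ci_high
    if (is.na(lo) || is.na(hi)) { skipped <- c(skipped, s$name); next }
    vlo <- base; vlo[s$name] <- lo
    vhi <- base; vhi[s$name] <- hi
    mlo <- eval_metric(vlo); mhi <- eval_metric(vhi)
    rows[[s$name]] <- data.frame(
      parameter = s$name, low = lo, high = hi,
      metric_low = mlo, metric_high = mhi, metric_base = base_metric,
      width = abs(mhi - mlo), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "comparison") <- comparison
  attr(out, "metric") <- metric
  class(out) <- c("tornado", "data.frame")
  out
}

#' Threshold analysis by bisection
#'
#' Finds the value of one parameter at which a condition on the
#' cost-effectiveness output switches from false to true, by bisection on the
#' parameter to a width below `tol` (default $0.01). The condition is a
#' predicate taking the rollback data.frame (strategy, expected_cost,
#' expected_effect) evaluated at candidate parameter values. If the condition
#' already holds at the lower bracket end, that end is returned; if it holds
#' at neither end, an error reports both endpoint evaluations.
#'
#' @param tree a `decision_tree`.
#' @param registry a `param_registry`.
#' @param parameter name of the swept parameter.
#' @param condition function(rollback_df) -> logical(1).
#' @param bracket numeric length-2 search interval for the parameter.
#' @param tol bisection tolerance on the parameter (default 0.01).
#' @param overrides optional fixed scenario overrides for other parameters.
#' @return list: `value` (threshold parameter value), `results` (rollback at
#'   the threshold), `iterations`.
#' @export
threshold_analysis <- function(tree, registry, parameter, condition, bracket,
                               tol = 0.01, overrides = NULL) {
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2])
  if (!parameter %in% names(registry$specs))
    stop("unknown parameter '", parameter, "'")
  base <- base_values(registry, overrides)
  eval_at <- function(x) {
    v <- base; v[parameter] <- x
    rollback(tree, v)
  }
  lo <- bracket[1]; hi <- bracket[2]
  c_lo <- isTRUE(condition(eval_at(lo)))
  c_hi <- isTRUE(condition(eval_at(hi)))
  if (c_lo)
    return(list(value = lo, results = eval_at(lo), iterations = 0L))
  if (!c_hi)
    stop(sprintf(paste0("condition does not change over bracket [%g, %g]: ",
                        "FALSE at both ends"), lo, hi))
  it <- 0L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (isTRUE(condition(eval_at(mid)))) hi <- mid else lo <- mid
    it <- it + 1L
  }
  list(value = hi, results = eval_at(hi), iterations = it)
}
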
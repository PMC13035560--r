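#' Random-effects pooling of success proportions
#'
#' Pools per-study sedation success proportions on the logit scale with an
#' inverse-variance random-effects model: each study contributes
#' logit(e/n) with variance 1/e + 1/(n - e); between-study variance tau^2 is
#' estimated by DerSimonian-Laird; the pooled logit and its 95\% Wald interval
#' are back-transformed to the probability scale. Studies with zero or all
#' events get a continuity correction (0.5 added to both cells). The fitting
#' is delegated to \pkg{metafor} (`escalc(measure = "PLO")` +
#' `rma(method = "DL")`).
#'
#' A degenerate input in which every study has all (or no) successes cannot be
#' pooled on the logit scale; the crude proportion is returned as a fixed
#' value with a warning (this is how an all-success general-anesthesia row
#' yields 1.000).
#'
#' @param studies data.frame with columns `events`, `total` and optionally
#'   `study` labels.
#' @param continuity_correction value added to both cells of zero/full-event
#'   studies (default 0.5).
#' @param level confidence level (default 0.95).
#' @return list of class `pooled_proportion`: `estimate`, `ci_low`, `ci_high`,
#'   `tau2`, `k`, `method`; or for degenerate input a list with
#'   `degenerate = TRUE` and the crude `estimate`.
#' @examples
#' pool_proportions(data.frame(events = c(94, 92, 96), total = c(100, 100, 100)))
#' @export
pool_proportions <- function(studies, continuity_correction = 0.5,
                             level = 0.95) {
  d <- as.data.frame(studies)
  if (!all(c("events", "total") %in% names(d)))
    stop("studies need columns 'events' and 'total'")
  k <- nrow(d)
  if (k == 0L) stop("no studies to pool")
  if (any(d$total <= 0)) stop("study totals must be positive")
  if (any(d$events < 0 | d$events > d$total))
    stop("events must lie in [0, total]")
  if (all(d$events == d$total) || all(d$events == 0)) {
    p <- sum(d$events) / sum(d$total)
    warning("all studies have ", if (p == 1) "all" else "no",
            " events; logit pooling is degenerate, returning the crude ",
            "proportion as a fixed value")
    return(structure(list(estimate = p, ci_low = NA_real_, ci_high = NA_real_,
                          tau2 = NA_real_, k = k, degenerate = TRUE,
                          method = "fixed (degenerate)"),
                     class = "pooled_proportion"))
  }
  es <- metafor::escalc(measure = "PLO", xi = d$events, ni = d$total,
                        add = continuity_correction, to = "only0")
  fit <- metafor::rma(yi = es$yi, vi = es$vi, method = "DL", level = level * 100)
  ci <- c(fit$ci.lb, fit$ci.ub)
  structure(list(estimate = stats::plogis(as.numeric(fit$beta)),
                 ci_low = stats::plogis(ci[1]),
                 ci_high = stats::plogis(ci[2]),
                 tau2 = fit$tau2, k = k, degenerate = FALSE,
                 method = "logit random-effects (DerSimonian-Laird)"),
            class = "pooled_proportion")
}

#' @export
print.pooled_proportion <- function(x, ...) {
  cat(sprintf("Pooled proportion: %.4f", x$estimate))
  if (!x$degenerate)
    cat(sprintf(" (95%% CI %.4f-%.4f, tau^2 = %.4g, k = %d)",
                x$ci_low, x$ci_high, x$tau2, x$k))
  cat(" [", x$method, "]\n", sep = "")
  invisible(x)
}
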
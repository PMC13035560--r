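#' Distribution specifications for probabilistic sensitivity analysis
#'
#' Constructors for the sampling distributions attached to model parameters:
#' beta for probabilities, gamma for non-negative costs/doses/fees, normal
#' (with optional truncation floor) for physical quantities reported as
#' mean +/- SD, and fixed for point values.
#'
#' @param shape1,shape2 beta shape parameters (alpha, beta), both > 0.
#' @param shape,scale gamma shape k and scale theta, both > 0.
#' @param mean,sd normal mean and standard deviation (sd > 0).
#' @param floor lower truncation bound for normal draws (resampled below it).
#' @param value fixed point value.
#' @return list of class `dist_spec` with a `family` field.
#' @export
dist_beta <- function(shape1, shape2) {
  stopifnot(shape1 > 0, shape2 > 0)
  structure(list(family = "beta", shape1 = shape1, shape2 = shape2),
            class = "dist_spec")
}

#' @rdname dist_beta
#' @export
dist_gamma <- function(shape, scale) {
  stopifnot(shape > 0, scale > 0)
  structure(list(family = "gamma", shape = shape, scale = scale),
            class = "dist_spec")
}

#' @rdname dist_beta
#' @export
dist_normal <- function(mean, sd, floor = -Inf) {
  stopifnot(sd > 0)
  structure(list(family = "normal", mean = mean, sd = sd, floor = floor),
            class = "dist_spec")
}

#' @rdname dist_beta
#' @export
dist_fixed <- function(value) {
  structure(list(family = "fixed", value = value), class = "dist_spec")
}

dist_mean <- function(d) {
  switch(d$family,
         beta = d$shape1 / (d$shape1 + d$shape2),
         gamma = d$shape * d$scale,
         normal = d$mean,
         fixed = d$value)
}

dist_sd <- function(d) {
  switch(d$family,
         beta = sqrt(d$shape1 * d$shape2 /
                       ((d$shape1 + d$shape2)^2 * (d$shape1 + d$shape2 + 1))),
         gamma = sqrt(d$shape) * d$scale,
         normal = d$sd,
         fixed = 0)
}

#' Fit a beta distribution to a published mean and 95\% CI
#'
#' Keeps the mean exact (alpha = mean * s, beta = (1 - mean) * s) and chooses
#' the concentration s = alpha + beta by one-dimensional least squares so the
#' fitted 2.5\%/97.5\% quantiles best match the reported interval. With the
#' mean pinned there is a single free parameter against two quantile targets,
#' so strongly asymmetric intervals (e.g. a 0.792 mean with CI 0.206--0.982)
#' retain a small residual on one end; fitted quantiles are returned for
#' inspection.
#'
#' @param mean reported mean proportion, strictly inside (ci_low, ci_high).
#' @param ci_low,ci_high reported 95\% confidence bounds in (0, 1).
#' @return `dist_spec` of family beta, with attributes `fitted_q` (the achieved
#'   2.5/97.5 quantiles) and `target_q`. A zero-width interval returns
#'   `dist_fixed(mean)` with a warning.
#' @examples
#' fit_beta_mean_ci(0.940, 0.910, 0.960)
#' @export
fit_beta_mean_ci <- function(mean, ci_low, ci_high) {
  if (ci_high == ci_low) {
    warning("zero-width confidence interval; returning a fixed value")
    return(dist_fixed(mean))
  }
  if (!(ci_low < mean && mean < ci_high))
    stop(sprintf("mean %.4g outside its confidence interval (%.4g, %.4g)",
                 mean, ci_low, ci_high))
  stopifnot(ci_low > 0, ci_high < 1)
  target <- c(ci_low, ci_high)
  obj <- function(ls) {
    s <- exp(ls)
    q <- stats::qbeta(c(0.025, 0.975), mean * s, (1 - mean) * s)
    sum((q - target)^2)
  }
  opt <- stats::optimize(obj, interval = c(log(0.02), log(1e8)), tol = 1e-12)
  s <- exp(opt$minimum)
  d <- dist_beta(mean * s, (1 - mean) * s)
  attr(d, "fitted_q") <- stats::qbeta(c(0.025, 0.975), d$shape1, d$shape2)
  attr(d, "target_q") <- target
  d
}

#' Fit a gamma distribution to a published mean and one-way range
#'
#' The source tables print gamma-distributed costs and doses with a mean and
#' (sometimes) a one-way sensitivity range but no variance. When a range is
#' present the standard deviation is taken as (high - low) / (2 * 1.96),
#' reading the range as an approximate 95\% interval; otherwise a default
#' coefficient of variation is applied. Shape k = (mean/sd)^2 and scale
#' theta = sd^2/mean reproduce the requested mean and sd exactly.
#'
#' @param mean positive mean.
#' @param low,high optional range bounds, 0 < low <= mean <= high.
#' @param default_cv coefficient of variation used when no range is given
#'   (default 0.2).
#' @return `dist_spec` of family gamma.
#' @examples
#' fit_gamma_mean_range(71.50, 52.00, 195.00)
#' fit_gamma_mean_range(39.00)
#' @export
fit_gamma_mean_range <- function(mean, low = NA, high = NA, default_cv = 0.2) {
  if (!is.finite(mean) || mean <= 0) stop("gamma mean must be positive")
  if (!is.na(low) && !is.na(high)) {
    stopifnot(low > 0, low <= mean, mean <= high)
    sd <- (high - low) / (2 * 1.96)
    if (sd == 0) return(dist_fixed(mean))
  } else {
    sd <- default_cv * mean
  }
  dist_gamma(shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' Parameter specification
#'
#' One registry entry: a named model quantity with its deterministic base
#' value, optional one-way range and 95\% CI, sampling distribution, and role.
#'
#' @param name unique parameter name (a valid R symbol; trees reference it).
#' @param base_value deterministic base-case value.
#' @param unit unit string (e.g. "USD", "probability", "minutes").
#' @param low,high optional one-way sensitivity range.
#' @param ci_low,ci_high optional reported 95\% CI (success rates).
#' @param sd optional reported standard deviation (normal parameters).
#' @param distribution a `dist_spec`, or one of "beta", "gamma", "normal",
#'   "fixed" to be fitted by [fit_registry()].
#' @param role one of fee, drug_price, dose, probability, duration, weight,
#'   rate, other.
#' @param label human-readable description.
#' @param floor truncation floor for normal sampling.
#' @return list of class `param_spec`.
#' @export
param_spec <- function(name, base_value, unit = "", low = NA, high = NA,
                       ci_low = NA, ci_high = NA, sd = NA,
                       distribution = "fixed",
                       role = c("fee", "drug_price", "dose", "probability",
                                "duration", "weight", "rate", "other"),
                       label = name, floor = -Inf) {
  role <- match.arg(role)
  if (!is.na(low) && !is.na(high) && !(low <= base_value && base_value <= high))
    stop("parameter '", name, "': base value outside its one-way range")
  if (!is.na(ci_low) && !is.na(ci_high) && ci_low >= ci_high)
    stop("parameter '", name, "': ci_low must be below ci_high")
  if (role == "probability") {
    bad <- c(base_value, ci_low, ci_high, low, high)
    bad <- bad[!is.na(bad)]
    if (any(bad < 0 | bad > 1))
      stop("parameter '", name, "': probabilities must lie in [0, 1]")
  }
  structure(list(name = name, label = label, unit = unit,
                 base_value = base_value, low = low, high = high,
                 ci_low = ci_low, ci_high = ci_high, sd = sd,
                 distribution = distribution, role = role, floor = floor),
            class = "param_spec")
}

#' Parameter registry
#'
#' Ordered collection of [param_spec()] entries plus global settings
#' (exchange rate in USD per JPY, discount rate, default gamma CV).
#'
#' @param specs list of `param_spec` objects.
#' @param exchange_rate USD per JPY (default 0.0065).
#' @param discount_rate annual discount rate (default 0; the episode horizon
#'   ends with the completed scan).
#' @param default_cv default coefficient of variation for gamma fits.
#' @return object of class `param_registry`.
#' @export
param_registry <- function(specs, exchange_rate = 0.0065, discount_rate = 0,
                           default_cv = 0.2) {
  stopifnot(exchange_rate > 0)
  nm <- vapply(specs, function(s) s$name, "")
  if (anyDuplicated(nm)) stop("duplicate parameter names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(specs) <- nm
  structure(list(specs = specs,
                 settings = list(exchange_rate = exchange_rate,
                                 discount_rate = discount_rate,
                                 default_cv = default_cv)),
            class = "param_registry")
}

#' @export
print.param_registry <- function(x, ...) {
  cat("Parameter registry:", length(x$specs), "parameters\n")
  print(utils::head(fit_diagnostics(x), 10))
  invisible(x)
}

#' Fit sampling distributions for every registry entry
#'
#' Entries whose `distribution` field is a family name are replaced by fitted
#' `dist_spec` objects: probabilities with a CI via [fit_beta_mean_ci()]
#' (a degenerate probability of 0 or 1, or one without a CI, becomes fixed),
#' gamma quantities via [fit_gamma_mean_range()], normal quantities from the
#' reported mean and `sd`.
#'
#' @param registry a `param_registry`.
#' @return the registry with all `distribution` fields as fitted `dist_spec`s.
#' @export
fit_registry <- function(registry) {
  stopifnot(inherits(registry, "param_registry"))
  cv <- registry$settings$default_cv
  registry$specs <- lapply(registry$specs, function(s) {
    if (inherits(s$distribution, "dist_spec")) return(s)
    fam <- s$distribution
    s$distribution <- switch(fam,
      fixed = dist_fixed(s$base_value),
      beta = {
        if (is.na(s$ci_low) || is.na(s$ci_high) ||
            s$base_value <= 0 || s$base_value >= 1)
          dist_fixed(s$base_value)
        else fit_beta_mean_ci(s$base_value, s$ci_low, s$ci_high)
      },
      gamma = fit_gamma_mean_range(s$base_value, s$low, s$high, default_cv = cv),
      normal = {
        if (is.na(s$sd)) stop("parameter '", s$name, "': normal needs an sd")
        dist_normal(s$base_value, s$sd, floor = s$floor)
      },
      stop("parameter '", s$name, "': unknown distribution family '", fam, "'"))
    s
  })
  registry
}

#' Deterministic base-case parameter values
#'
#' @param registry a `param_registry`.
#' @param overrides optional named numeric vector of scenario overrides (e.g.
#'   `c(fee_iv_sedation_anesth = 270)`).
#' @return named numeric vector of base values.
#' @export
base_values <- function(registry, overrides = NULL) {
  stopifnot(inherits(registry, "param_registry"))
  v <- vapply(registry$specs, function(s) s$base_value, numeric(1))
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), names(v))
    if (length(unknown) > 0L)
      stop("unknown parameter(s) in overrides: ", paste(unknown, collapse = ", "))
    v[names(overrides)] <- overrides
  }
  v
}

sample_dist <- function(d, n) {
  switch(d$family,
    fixed = rep_len(d$value, n),
    beta = stats::rbeta(n, d$shape1, d$shape2),
    gamma = stats::rgamma(n, shape = d$shape, scale = d$scale),
    normal = {
      x <- stats::rnorm(n, d$mean, d$sd)
      floor <- if (is.null(d$floor)) 0 else max(d$floor, 0)
      resamples <- 0L
      while (any(bad <- x < floor)) {
        resamples <- resamples + sum(bad)
        x[bad] <- stats::rnorm(sum(bad), d$mean, d$sd)
      }
      attr(x, "resamples") <- resamples
      x
    })
}

#' Draw joint parameter samples for probabilistic sensitivity analysis
#'
#' Parameters are sampled independently from their fitted distributions.
#' Normal draws of physical quantities are truncated below their floor (and at
#' 0) by resampling; the total resample count is attached as an attribute.
#'
#' @param registry a fitted `param_registry` (see [fit_registry()]).
#' @param n number of draws.
#' @param seed integer seed; the same seed and registry give identical tables.
#' @return data.frame of `n` rows, one column per parameter, with attribute
#'   `resamples`.
#' @export
sample_parameters <- function(registry, n, seed) {
  stopifnot(inherits(registry, "param_registry"), n >= 1)
  for (s in registry$specs)
    if (!inherits(s$distribution, "dist_spec"))
      stop("parameter '", s$name, "' has no fitted distribution; run fit_registry()")
  set.seed(seed)
  resamples <- 0L
  cols <- lapply(registry$specs, function(s) {
    x <- sample_dist(s$distribution, n)
    r <- attr(x, "resamples")
    if (!is.null(r)) resamples <<- resamples + r
    as.numeric(x)
  })
  out <- as.data.frame(cols, optional = TRUE)
  names(out) <- names(registry$specs)
  attr(out, "resamples") <- resamples
  attr(out, "seed") <- seed
  out
}

#' Fitted-distribution diagnostics table
#'
#' One row per parameter: family, fitted parameters, distribution mean/sd, and
#' for beta fits the achieved vs target 95\% quantiles.
#'
#' @param registry a `param_registry` (fitted entries reported in full).
#' @return data.frame.
#' @export
fit_diagnostics <- function(registry) {
  rows <- lapply(registry$specs, function(s) {
    d <- s$distribution
    fitted <- inherits(d, "dist_spec")
    data.frame(
      name = s$name, role = s$role, unit = s$unit, base_value = s$base_value,
      family = if (fitted) d$family else as.character(d),
      dist_mean = if (fitted) dist_mean(d) else NA_real_,
      dist_sd = if (fitted) dist_sd(d) else NA_real_,
      q2.5_fitted = if (fitted && !is.null(attr(d, "fitted_q"))) attr(d, "fitted_q")[1] else NA_real_,
      q97.5_fitted = if (fitted && !is.null(attr(d, "fitted_q"))) attr(d, "fitted_q")[2] else NA_real_,
      q2.5_target = s$ci_low, q97.5_target = s$ci_high,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert Japanese yen to US dollars
#'
#' @param amount_jpy amount in JPY.
#' @param rate_usd_per_jpy exchange rate (default 0.0065 USD per JPY).
#' @return amount in USD, unrounded.
#' @examples
#' convert_currency(11000)  # 71.50
#' @export
convert_currency <- function(amount_jpy, rate_usd_per_jpy = 0.0065) {
  stopifnot(rate_usd_per_jpy > 0)
  amount_jpy * rate_usd_per_jpy
}

#' Read a parameter registry from a YAML or JSON config
#'
#' The config has a `settings` block (exchange_rate_usd_per_jpy, discount_rate,
#' default_cv) and a `parameters` list mirroring a published parameter table.
#' Money entries carry an explicit `currency` tag (USD or JPY); JPY amounts
#' (value, low, high, sd) are converted to USD on load. Unknown keys are
#' rejected with their location.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a fitted `param_registry`.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  known_settings <- c("exchange_rate_usd_per_jpy", "discount_rate", "default_cv")
  st <- obj$settings
  bad <- setdiff(names(st), known_settings)
  if (length(bad) > 0L) stop("unknown settings key(s): ", paste(bad, collapse = ", "))
  rate <- if (is.null(st$exchange_rate_usd_per_jpy)) 0.0065 else st$exchange_rate_usd_per_jpy
  known <- c("name", "label", "unit", "currency", "value", "low", "high",
             "ci_low", "ci_high", "sd", "distribution", "role", "floor")
  money_roles <- c("fee", "drug_price")
  specs <- lapply(seq_along(obj$parameters), function(i) {
    p <- obj$parameters[[i]]
    bad <- setdiff(names(p), known)
    if (length(bad) > 0L)
      stop("parameters[", i, "] ('", p$name %||% "?", "'): unknown key(s) ",
           paste(bad, collapse = ", "))
    for (req in c("name", "value", "distribution", "role"))
      if (is.null(p[[req]]))
        stop("parameters[", i, "]: missing required key '", req, "'")
    num <- function(k) if (is.null(p[[k]])) NA_real_ else as.numeric(p[[k]])
    value <- as.numeric(p$value); low <- num("low"); high <- num("high")
    sd <- num("sd")
    if (p$role %in% money_roles || identical(p$currency, "JPY")) {
      if (is.null(p$currency))
        stop("parameters[", i, "] ('", p$name, "'): money fields need a currency tag")
      if (!p$currency %in% c("USD", "JPY"))
        stop("parameters[", i, "] ('", p$name, "'): unknown currency '", p$currency, "'")
      if (p$currency == "JPY") {
        value <- convert_currency(value, rate)
        low <- convert_currency(low, rate)
        high <- convert_currency(high, rate)
        sd <- convert_currency(sd, rate)
      }
    }
    param_spec(name = p$name, base_value = value,
               unit = if (is.null(p$unit)) "" else p$unit,
               low = low, high = high,
               ci_low = num("ci_low"), ci_high = num("ci_high"), sd = sd,
               distribution = p$distribution, role = p$role,
               label = if (is.null(p$label)) p$name else p$label,
               floor = if (is.null(p$floor)) -Inf else as.numeric(p$floor))
  })
  fit_registry(param_registry(
    specs,
    exchange_rate = rate,
    discount_rate = if (is.null(st$discount_rate)) 0 else st$discount_rate,
    default_cv = if (is.null(st$default_cv)) 0.2 else st$default_cv))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The packaged sedation-model parameter registry
#'
#' Loads the registry shipped with the package: Japanese procedure fees, drug
#' and apparatus prices, dosing regimens, sedation success rates with 95\% CIs,
#' MRI duration and body weight, and the pediatric consultation parameters, all
#' in 2024 USD (1 JPY = 0.0065 USD), with fitted PSA distributions.
#'
#' @return a fitted `param_registry`.
#' @export
table1_registry <- function() {
  read_registry(system.file("extdata", "table1.yaml", package = "sedcea",
                            mustWork = TRUE))
}
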
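# Infant haemodynamic / metabolic response-function reconstruction by
# exhaustive grid search over a double-gamma basis.

#' Double-gamma basis parameters
#'
#' The basis kernel is `h(t) = g(t; shape = delay_response, scale = 1) -
#' g(t; shape = delay_undershoot, scale = 1) / ratio`, with `g` a gamma
#' density, peak-normalised to maximum 1. With unit scale the "delay"
#' parameters map to the gamma shape, the convention under which the adult
#' canonical HRF is (6, 16, 6).
#'
#' @param delay_response_s Delay of the response in seconds (> 0).
#' @param delay_undershoot_s Delay of the undershoot in seconds (> 0).
#' @param ratio_response_undershoot Response:undershoot amplitude ratio (> 0;
#'   larger means a shallower undershoot).
#' @return A `basis_params` list.
#' @export
basis_params <- function(delay_response_s, delay_undershoot_s,
                         ratio_response_undershoot) {
  stop_if_not(delay_response_s > 0 && delay_undershoot_s > 0,
              "delays must be positive")
  stop_if_not(ratio_response_undershoot > 0,
              "ratio of response to undershoot must be positive")
  structure(list(delay_response_s = delay_response_s,
                 delay_undershoot_s = delay_undershoot_s,
                 ratio_response_undershoot = ratio_response_undershoot),
            class = "basis_params")
}

#' Adult canonical double-gamma parameters (6, 16, 6)
#' @return A `basis_params`.
#' @export
adult_basis <- function() basis_params(6, 16, 6)

#' Sample a double-gamma response function
#'
#' @param params A `basis_params`.
#' @param sample_period_s Kernel sampling period in seconds.
#' @param duration_s Kernel support in seconds (default 32, covering the
#'   undershoot of every grid combination).
#' @return A `response_function`: list with `kernel` (peak-normalised,
#'   `kernel[1] = h(0) = 0`), `time_s`, `params`, `sample_period_s`.
#' @export
double_gamma <- function(params, sample_period_s = 1, duration_s = 32) {
  stopifnot(inherits(params, "basis_params"))
  t <- seq(0, duration_s, by = sample_period_s)
  h <- stats::dgamma(t, shape = params$delay_response_s, scale = 1) -
    stats::dgamma(t, shape = params$delay_undershoot_s, scale = 1) /
    params$ratio_response_undershoot
  h <- h / max(h)
  structure(list(kernel = h, time_s = t, params = params,
                 sample_period_s = sample_period_s),
            class = "response_function")
}

#' Model regressor for a grand-average response
#'
#' Convolves the stimulus boxcar of the supplied events with the double-gamma
#' kernel on the grand average's time grid and standardises the result to
#' zero mean and unit variance (the form actually entered in the GLM, making
#' the fitted beta scale like a correlation and the grid search's
#' highest-beta selection a best-fit criterion).
#'
#' @param params A `basis_params`.
#' @param time_s Time grid of the grand average (seconds; uniform).
#' @param events Data frame with `onset_s`, `duration_s` (e.g. from
#'   [experimental_blocks()]), on the same clock as `time_s`.
#' @return Numeric regressor of `length(time_s)`.
#' @export
hrf_regressor <- function(params, time_s, events) {
  dt <- time_s[2] - time_s[1]
  kern <- double_gamma(params, sample_period_s = dt)
  box <- numeric(length(time_s))
  for (i in seq_len(nrow(events))) {
    box[time_s >= events$onset_s[i] - 1e-9 &
          time_s < events$onset_s[i] + events$duration_s[i] - 1e-9] <- 1
  }
  if (!any(box > 0)) stop("no event overlaps the time grid", call. = FALSE)
  zscore(conv_causal(box, kern$kernel) * dt)
}

#' Fit one basis-parameter combination to a grand-average response
#'
#' Ordinary least squares of the grand average on an intercept plus the
#' standardised model regressor; returns the slope with its t statistic and
#' two-sided p value. A numerically perfect fit reports p = 0.
#'
#' @param grand_avg Numeric grand-average response.
#' @param time_s Its time grid.
#' @param params A `basis_params`.
#' @param events Stimulus events (see [hrf_regressor()]).
#' @return List `(beta, t, p)`.
#' @export
fit_grand_average <- function(grand_avg, time_s, params, events) {
  x <- hrf_regressor(params, time_s, events)
  ols_slope(grand_avg, x)
}

# OLS of y on [1, x]; returns slope beta, t, p. Guards degenerate designs.
ols_slope <- function(y, x) {
  n <- length(y)
  stop_if_not(length(x) == n, "regressor and response lengths differ")
  vx <- stats::var(x)
  if (!is.finite(vx) || vx == 0) {
    stop("degenerate design: regressor has zero variance", call. = FALSE)
  }
  beta <- stats::cov(x, y) / vx
  a <- mean(y) - beta * mean(x)
  res <- y - a - beta * x
  df <- n - 2
  s2 <- sum(res^2) / df
  se <- sqrt(s2 / (vx * (n - 1)))
  if (se < .Machine$double.eps^0.75 * max(1, abs(beta))) {
    return(list(beta = beta, t = Inf * sign(beta), p = 0))
  }
  tt <- beta / se
  list(beta = beta, t = tt, p = 2 * stats::pt(-abs(tt), df = df))
}

#' Exhaustive grid search for the infant response function
#'
#' Evaluates every combination of the basis-parameter grid (defaults:
#' response delay 5-15 s, undershoot delay 5-20 s, response:undershoot ratio
#' 2-6, all in steps of 1, i.e. 11 x 16 x 5 = 880 combinations) against a
#' grand-average response via [fit_grand_average()], and selects the
#' combination with the highest beta among statistically significant fits
#' (p < `alpha`). Ties break lexicographically on (delay_response,
#' delay_undershoot, ratio). If no fit is significant the overall
#' highest-beta combination is returned flagged non-significant.
#'
#' @param grand_avg Numeric grand-average response (must not be constant).
#' @param time_s Its time grid.
#' @param events Stimulus events on the same clock.
#' @param delays,undershoots,ratios Grid vectors.
#' @param alpha Significance threshold for a fit to be eligible (default
#'   0.05).
#' @return A `grid_search_result`: list with `table` (one row per
#'   combination: parameters, beta, t, p), `best` (`basis_params`),
#'   `best_row`, `significant` (logical), `alpha`.
#' @export
grid_search_hrf <- function(grand_avg, time_s, events,
                            delays = 5:15, undershoots = 5:20, ratios = 2:6,
                            alpha = 0.05) {
  stop_if_not(length(delays) > 0 && length(undershoots) > 0 && length(ratios) > 0,
              "parameter grid must be non-empty")
  if (stats::sd(grand_avg) == 0) {
    stop("grand average is constant; nothing to fit", call. = FALSE)
  }
  grid <- expand.grid(ratio = ratios, delay_undershoot = undershoots,
                      delay_response = delays)
  grid <- grid[, c("delay_response", "delay_undershoot", "ratio")]
  # lexicographic order (delay_response, delay_undershoot, ratio)
  grid <- grid[order(grid$delay_response, grid$delay_undershoot, grid$ratio), ]
  rownames(grid) <- NULL
  fits <- lapply(seq_len(nrow(grid)), function(i) {
    fit_grand_average(grand_avg, time_s,
                      basis_params(grid$delay_response[i],
                                   grid$delay_undershoot[i], grid$ratio[i]),
                      events)
  })
  tab <- cbind(grid,
               beta = vapply(fits, `[[`, numeric(1), "beta"),
               t = vapply(fits, `[[`, numeric(1), "t"),
               p = vapply(fits, `[[`, numeric(1), "p"))
  sig <- tab$p < alpha
  pool <- if (any(sig)) which(sig) else seq_len(nrow(tab))
  # betas numerically tied with the maximum resolve to the lexicographically
  # smallest combination (the grid is sorted); exact ties occur e.g. when the
  # response and undershoot delays coincide and the ratio drops out
  bmax <- max(tab$beta[pool])
  tol <- 1e-9 * max(1, abs(bmax))
  best_row <- pool[which(tab$beta[pool] >= bmax - tol)[1]]
  structure(list(
    table = tab,
    best = basis_params(tab$delay_response[best_row],
                        tab$delay_undershoot[best_row], tab$ratio[best_row]),
    best_row = best_row,
    significant = any(sig),
    alpha = alpha), class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  b <- x$best
  cat(sprintf(
    "grid search over %d combinations: best (delay %g s, undershoot %g s, ratio %g), beta %.4g%s\n",
    nrow(x$table), b$delay_response_s, b$delay_undershoot_s,
    b$ratio_response_undershoot, x$table$beta[x$best_row],
    if (x$significant) "" else " [no significant fit]"))
  invisible(x)
}

#' Serialise a grid-search result
#'
#' Writes the per-combination table as TSV and the best parameters (with
#' signed offsets from the adult canonical basis) as JSON.
#'
#' @param res A `grid_search_result`.
#' @param tsv_path,json_path Output files (NULL to skip either).
#' @export
write_grid_search <- function(res, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(res$table, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(json_path)) {
    adult <- adult_basis()
    b <- res$best
    jsonlite::write_json(list(
      delay_response_s = b$delay_response_s,
      delay_undershoot_s = b$delay_undershoot_s,
      ratio_response_undershoot = b$ratio_response_undershoot,
      offset_delay_response_vs_adult_s =
        b$delay_response_s - adult$delay_response_s,
      offset_delay_undershoot_vs_adult_s =
        b$delay_undershoot_s - adult$delay_undershoot_s,
      significant = res$significant
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}
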
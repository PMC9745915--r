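new_dln_ci <- function(method, log_limits, p, alpha, m = NULL, seed = NULL,
                       point = NULL) {
  stopifnot(length(log_limits) == 2, log_limits[1] <= log_limits[2])
  out <- list(
    method = method,
    L = exp(log_limits[1]), U = exp(log_limits[2]),
    log_L = log_limits[1], log_U = log_limits[2],
    length = exp(log_limits[2]) - exp(log_limits[1]),
    p = p, alpha = alpha, m = m, seed = seed, point = point
  )
  class(out) <- "dln_ci"
  out
}

#' @export
print.dln_ci <- function(x, digits = 4, ...) {
  cat(sprintf("%d%% confidence interval for the common %g-percentile (%s)\n",
              round(100 * (1 - x$alpha)), x$p, toupper(x$method)))
  cat(sprintf("  [%.*f, %.*f]   length %.*f\n",
              digits, x$L, digits, x$U, digits, x$length))
  if (!is.null(x$point))
    cat(sprintf("  point estimate %.*f\n", digits, x$point))
  if (!is.null(x$m))
    cat(sprintf("  Monte Carlo draws m = %d\n", x$m))
  invisible(x)
}

#' @export
as.data.frame.dln_ci <- function(x, ...) {
  data.frame(method = x$method, L = x$L, U = x$U, length = x$length,
             log_L = x$log_L, log_U = x$log_U, p = x$p, alpha = x$alpha,
             m = if (is.null(x$m)) NA_integer_ else x$m,
             stringsAsFactors = FALSE)
}

#' Confidence interval for the common percentile of delta-lognormal groups
#'
#' Front end dispatching to the four interval constructions. `data` may be
#' raw grouped observations (data frame with `group`/`value` columns, a
#' named list of numeric vectors) or a precomputed `dln_summary`.
#'
#' @param data grouped observations or a `dln_summary`.
#' @param method one of `"fgci"`, `"mover"`, `"bs1"`, `"bs2"`, or `"all"`
#'   for a comparison of the four.
#' @param p target percentile level (default 0.95).
#' @param alpha one minus the confidence level (default 0.05).
#' @param m Monte Carlo draws for the stochastic methods (default 1000).
#' @param variance_form see [var_lambda()].
#' @param ... further arguments passed to the method functions
#'   (e.g. `alpha_mode`, `margin_power` for [ci_mover()]).
#' @return A `dln_ci` object, or for `method = "all"` a data frame with one
#'   row per method.
#' @examples
#' set.seed(1)
#' common_percentile_ci(rainfall_fixture(), method = "mover")
#' @export
common_percentile_ci <- function(data,
                                 method = c("fgci", "mover", "bs1", "bs2",
                                            "all"),
                                 p = 0.95, alpha = 0.05, m = 1000,
                                 variance_form = c("additive", "factored"),
                                 ...) {
  method <- match.arg(method)
  variance_form <- match.arg(variance_form)
  s <- if (inherits(data, "dln_summary")) data else summarize_groups(data)
  if (method == "all") {
    rows <- lapply(c("fgci", "mover", "bs1", "bs2"), function(mm) {
      as.data.frame(common_percentile_ci(s, mm, p, alpha, m, variance_form,
                                         ...))
    })
    return(do.call(rbind, rows))
  }
  switch(method,
    fgci  = ci_fgci(s, p = p, alpha = alpha, m = m,
                    variance_form = variance_form),
    mover = ci_mover(s, p = p, alpha = alpha, ...),
    bs1   = ci_bayes(s, variant = "bs1", p = p, alpha = alpha, m = m,
                     variance_form = variance_form),
    bs2   = ci_bayes(s, variant = "bs2", p = p, alpha = alpha, m = m,
                     variance_form = variance_form)
  )
}
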
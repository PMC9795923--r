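# Seasonal smoothing and half-max extraction: the phenology statistic at
# the core of the package. One fitting function returning a classed object,
# with the usual modelling methods.

#' Fit a penalized-spline seasonal smooth
#'
#' Fits passage (or weekly relative abundance) against ordinal date with a
#' penalized cubic B-spline smooth (second-difference penalty, basis
#' dimension `basis_dim`, smoothness by generalized cross-validation, full
#' shrinkage via a null-space penalty) and, when `year_labels` are given, a
#' per-year random intercept. Predictions are made on the integer-date grid
#' of `season_range` with year effects marginalized to zero, clipped at 0.
#'
#' Adjusted R^2 follows `1 - (1 - R^2) (n - 1) / (n - edf)` with R^2
#' computed from fitted (including year effects) versus observed values and
#' edf the trace of the influence matrix.
#'
#' @param dates Ordinal dates of the observations.
#' @param values Nonnegative response (nightly passage or weekly mean
#'   relative abundance).
#' @param year_labels Optional year of each observation (random intercept).
#' @param basis_dim Spline basis dimension (default 20; reduced when the
#'   data have fewer distinct dates).
#' @param season_range Integer `c(start, end)` prediction/fit window;
#'   defaults to the range of `dates`.
#' @param platform `"radar"` or `"ebird"` (recorded; controls the
#'   early-peak fallback downstream).
#' @return An object of class `halfmax_fit`: list with elements `model`
#'   (the underlying [mgcv::gam] fit), `dates`, `predicted`, `edf`,
#'   `r2_adjusted`, `n_obs`, `platform`, `season_range`.
#' @seealso [halfmax_date()], [apply_retention()]
#' @export
fit_seasonal_smooth <- function(dates, values, year_labels = NULL,
                                basis_dim = 20,
                                season_range = NULL,
                                platform = c("radar", "ebird")) {
  platform <- match.arg(platform)
  if (length(dates) != length(values)) {
    stop("`dates` and `values` must have equal length", call. = FALSE)
  }
  ok <- is.finite(dates) & is.finite(values)
  if (!all(ok)) stop("`dates` and `values` must be finite", call. = FALSE)
  if (any(values < 0)) stop("`values` must be nonnegative", call. = FALSE)
  if (length(dates) < 10L) {
    stop(structure(class = c("phenomatch_fit_refused", "error", "condition"),
                   list(message = sprintf(
                     "fit refused: %d observations (need >= 10)", length(dates)),
                     call = NULL)))
  }
  if (is.null(season_range)) season_range <- range(dates)
  season_range <- as.integer(round(season_range))
  if (any(dates < season_range[1] | dates > season_range[2])) {
    stop("`dates` must lie within `season_range`", call. = FALSE)
  }
  df <- data.frame(d = as.numeric(dates), y = as.numeric(values))
  n_unique <- length(unique(df$d))
  k <- max(5L, min(as.integer(basis_dim), n_unique - 1L))
  use_year <- !is.null(year_labels) && length(unique(year_labels)) > 1L
  if (use_year) {
    df$yearf <- factor(year_labels)
    form <- y ~ s(d, bs = "bs", k = k, m = c(3, 2)) + s(yearf, bs = "re")
  } else {
    form <- y ~ s(d, bs = "bs", k = k, m = c(3, 2))
  }
  model <- tryCatch(
    mgcv::gam(form, data = df, method = "GCV.Cp", select = TRUE),
    error = function(e) {
      stop(structure(class = c("phenomatch_fit_refused", "error", "condition"),
                     list(message = paste("fit refused:", conditionMessage(e)),
                          call = NULL)))
    })
  grid <- season_range[1]:season_range[2]
  nd <- data.frame(d = as.numeric(grid))
  if (use_year) {
    nd$yearf <- factor(levels(df$yearf)[1], levels = levels(df$yearf))
    pred <- as.numeric(mgcv::predict.gam(model, nd, exclude = "s(yearf)",
                                         newdata.guaranteed = TRUE))
  } else {
    pred <- as.numeric(mgcv::predict.gam(model, nd, newdata.guaranteed = TRUE))
  }
  pred <- pmax(0, pred)
  n <- nrow(df)
  edf <- sum(model$hat)
  sst <- sum((df$y - mean(df$y))^2)
  r2 <- if (sst > 0) 1 - sum((df$y - stats::fitted(model))^2) / sst else 0
  r2_adj <- if (n - edf > 1e-8) 1 - (1 - r2) * (n - 1) / (n - edf) else -Inf
  structure(list(model = model, dates = grid, predicted = pred,
                 edf = edf, r2_adjusted = r2_adj, n_obs = n,
                 platform = platform, season_range = season_range),
            class = "halfmax_fit")
}

#' Construct a seasonal curve directly from daily values
#'
#' Wraps an already-known daily curve (e.g., an analytic pulse) in the same
#' container [fit_seasonal_smooth()] returns, so [halfmax_date()] can be
#' applied to closed-form shapes.
#'
#' @param dates Integer ordinal dates.
#' @param values Curve values f(d), nonnegative.
#' @param platform `"radar"` or `"ebird"`.
#' @param r2_adjusted Diagnostic to record (default 1: exact curve).
#' @return A `halfmax_fit` object without an underlying model.
#' @export
halfmax_curve <- function(dates, values, platform = c("radar", "ebird"),
                          r2_adjusted = 1) {
  platform <- match.arg(platform)
  stopifnot(length(dates) == length(values), all(is.finite(values)))
  structure(list(model = NULL, dates = as.integer(dates),
                 predicted = pmax(0, as.numeric(values)),
                 edf = NA_real_, r2_adjusted = r2_adjusted,
                 n_obs = length(dates), platform = platform,
                 season_range = range(as.integer(dates))),
            class = "halfmax_fit")
}

#' Extract the half-max phenology date from a fitted seasonal curve
#'
#' The phenology statistic: with `d_max` the earliest date of the curve
#' maximum, the half-max date is the first date at or before `d_max` on
#' which the curve reaches half of its maximum (rising edge). For weekly
#' abundance curves whose maximum falls at the very start of the season
#' (before ordinal day 10 in spring, day 185 in autumn) the rising edge is
#' uninformative and the first date after `d_max` on which the curve drops
#' to half-max is used instead (falling edge); if the curve never drops to
#' half-max the estimate is unretained with reason `"no-crossing"`. An
#' all-zero curve yields reason `"flat-curve"`. The fallback applies to the
#' `"ebird"` platform only.
#'
#' @param fit A `halfmax_fit` object.
#' @param season `"spring"` or `"autumn"`.
#' @param platform Platform override; defaults to `fit$platform`.
#' @return An object of class `halfmax_estimate`: list with platform,
#'   season, d_max, d_half, edge, r2_adjusted, retained, reason.
#' @export
halfmax_date <- function(fit, season, platform = fit$platform) {
  season <- match.arg(season, c("spring", "autumn"))
  stopifnot(inherits(fit, "halfmax_fit"))
  f <- fit$predicted
  d <- fit$dates
  est <- structure(list(platform = platform, station_id = NA_character_,
                        species_id = NA_character_, season = season,
                        d_max = NA_integer_, d_half = NA_integer_,
                        edge = NA_character_,
                        r2_adjusted = fit$r2_adjusted,
                        retained = FALSE, reason = "flat-curve"),
                   class = "halfmax_estimate")
  if (length(f) == 0L || max(f) <= 0) return(est)
  imax <- which.max(f)            # earliest date on ties
  d_max <- d[imax]
  half <- 0.5 * f[imax]
  est$d_max <- d_max
  fallback_cut <- if (season == "spring") 10L else 185L
  if (platform == "ebird" && d_max < fallback_cut) {
    after <- which(d > d_max & f <= half)
    if (length(after) == 0L) {
      est$edge <- "falling"; est$reason <- "no-crossing"
      return(est)
    }
    est$d_half <- d[min(after)]
    est$edge <- "falling"
  } else {
    before <- which(d <= d_max & f >= half)
    est$d_half <- d[min(before)]  # d_max itself always qualifies
    est$edge <- "rising"
  }
  est$retained <- NA              # pending apply_retention()
  est$reason <- "pending"
  est
}

#' Apply the retention filter to a half-max estimate
#'
#' An estimate is retained iff the fit's adjusted R^2 strictly exceeds
#' `r2_min` (default 0.25) and the half-max date falls inside the seasonal
#' retention window (1 March-15 June or 1 August-15 November). Estimates
#' already unretained by extraction (`flat-curve`, `no-crossing`) are left
#' unchanged.
#'
#' @param est A `halfmax_estimate`.
#' @param fit The `halfmax_fit` the estimate came from (supplies adjusted
#'   R^2 when the estimate lacks it).
#' @param r2_min Strict lower bound on adjusted R^2.
#' @param season Season; defaults to `est$season`.
#' @return The estimate with `retained` and `reason` finalized
#'   (`"ok"`, `"low-r2"`, or `"out-of-window"`).
#' @export
apply_retention <- function(est, fit = NULL, r2_min = 0.25,
                            season = est$season) {
  stopifnot(inherits(est, "halfmax_estimate"))
  if (est$reason %in% c("flat-curve", "no-crossing")) return(est)
  r2 <- if (!is.null(fit)) fit$r2_adjusted else est$r2_adjusted
  est$r2_adjusted <- r2
  if (!is.finite(r2) || r2 <= r2_min) {
    est$retained <- FALSE
    est$reason <- "low-r2"
  } else if (!in_season_window(est$d_half, season)) {
    est$retained <- FALSE
    est$reason <- "out-of-window"
  } else {
    est$retained <- TRUE
    est$reason <- "ok"
  }
  est
}

#' One-call half-max estimation
#'
#' Fit, extract and filter in one step.
#'
#' @inheritParams fit_seasonal_smooth
#' @param season `"spring"` or `"autumn"`.
#' @param r2_min Retention threshold on adjusted R^2.
#' @return A finalized `halfmax_estimate` with the fit attached as
#'   attribute `"fit"`.
#' @export
estimate_halfmax <- function(dates, values, season, year_labels = NULL,
                             basis_dim = 20, season_range = NULL,
                             platform = c("radar", "ebird"), r2_min = 0.25) {
  platform <- match.arg(platform)
  fit <- fit_seasonal_smooth(dates, values, year_labels = year_labels,
                             basis_dim = basis_dim,
                             season_range = season_range, platform = platform)
  est <- apply_retention(halfmax_date(fit, season), fit, r2_min = r2_min)
  attr(est, "fit") <- fit
  est
}

# ---- methods -------------------------------------------------------------

#' @export
print.halfmax_fit <- function(x, ...) {
  cat(sprintf("Seasonal smooth (%s): n = %d, edf = %.2f, adj. R^2 = %.3f\n",
              x$platform, x$n_obs, x$edf, x$r2_adjusted))
  cat(sprintf("  prediction grid: ordinal days %d-%d; curve max %.3g on day %d\n",
              x$season_range[1], x$season_range[2],
              max(x$predicted), x$dates[which.max(x$predicted)]))
  invisible(x)
}

#' @export
summary.halfmax_fit <- function(object, ...) {
  out <- list(platform = object$platform, n_obs = object$n_obs,
              edf = object$edf, r2_adjusted = object$r2_adjusted,
              d_max = object$dates[which.max(object$predicted)],
              max_value = max(object$predicted),
              season_range = object$season_range)
  class(out) <- "summary.halfmax_fit"
  out
}

#' @export
print.summary.halfmax_fit <- function(x, ...) {
  cat(sprintf("Seasonal smooth, platform %s\n", x$platform))
  cat(sprintf("  n = %d observations over days %d-%d\n",
              x$n_obs, x$season_range[1], x$season_range[2]))
  cat(sprintf("  effective df %.2f, adjusted R^2 %.3f\n", x$edf, x$r2_adjusted))
  cat(sprintf("  curve maximum %.4g on ordinal day %d\n", x$max_value, x$d_max))
  invisible(x)
}

#' @export
coef.halfmax_fit <- function(object, ...) {
  if (is.null(object$model)) return(numeric(0))
  stats::coef(object$model)
}

#' @export
fitted.halfmax_fit <- function(object, ...) {
  if (is.null(object$model)) return(object$predicted)
  as.numeric(stats::fitted(object$model))
}

#' @export
residuals.halfmax_fit <- function(object, ...) {
  if (is.null(object$model)) return(rep(0, length(object$predicted)))
  as.numeric(stats::residuals(object$model))
}

#' Predict from a seasonal smooth on new dates
#'
#' Year effects are marginalized to zero; predictions are clipped at 0.
#'
#' @param object A `halfmax_fit`.
#' @param dates Ordinal dates (default: the fit grid).
#' @param ... Unused.
#' @return Numeric vector of predicted values.
#' @export
predict.halfmax_fit <- function(object, dates = object$dates, ...) {
  if (is.null(object$model)) {
    return(object$predicted[match(as.integer(dates), object$dates)])
  }
  nd <- data.frame(d = as.numeric(dates))
  if ("yearf" %in% names(object$model$model)) {
    lev <- levels(object$model$model$yearf)
    nd$yearf <- factor(lev[1], levels = lev)
    p <- mgcv::predict.gam(object$model, nd, exclude = "s(yearf)",
                           newdata.guaranteed = TRUE)
  } else {
    p <- mgcv::predict.gam(object$model, nd, newdata.guaranteed = TRUE)
  }
  pmax(0, as.numeric(p))
}

#' Plot a seasonal smooth and its half-max date
#'
#' @param x A `halfmax_fit`.
#' @param estimate Optional `halfmax_estimate` to annotate.
#' @param ... Passed to [plot.default()].
#' @export
plot.halfmax_fit <- function(x, estimate = NULL, ...) {
  plot(x$dates, x$predicted, type = "l", xlab = "ordinal date",
       ylab = "predicted value",
       main = sprintf("Seasonal smooth (%s)", x$platform), ...)
  if (!is.null(x$model)) {
    points(x$model$model$d, x$model$model$y, pch = 16,
           col = grDevices::adjustcolor("grey40", 0.5), cex = 0.6)
  }
  if (!is.null(estimate) && is.finite(estimate$d_half)) {
    abline(v = estimate$d_half, lty = 2, col = "firebrick")
    abline(h = 0.5 * max(x$predicted), lty = 3, col = "grey60")
  }
  invisible(x)
}

#' @export
print.halfmax_estimate <- function(x, ...) {
  cat(sprintf("Half-max estimate (%s, %s): ", x$platform, x$season))
  if (is.na(x$d_half)) {
    cat(sprintf("none (%s)\n", x$reason))
  } else {
    status <- if (isTRUE(x$retained)) "retained"
      else if (identical(x$reason, "pending")) "retention pending"
      else paste0("not retained: ", x$reason)
    cat(sprintf("day %d (%s edge; peak day %d; %s)\n",
                x$d_half, x$edge, x$d_max, status))
  }
  invisible(x)
}
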
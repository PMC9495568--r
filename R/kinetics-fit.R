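#' Coefficient of determination
#'
#' `R^2 = 1 - SSE/SST` with SST about the observed mean. May be negative
#' when the model predicts worse than the mean.
#'
#' @param observed,predicted numeric vectors of equal length >= 2.
#' @return Scalar R squared.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4)) # 0.5
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal length")
  }
  if (length(observed) < 2L) stop("need at least 2 points")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("zero total variance: observed values are all identical")
  1 - sum((observed - predicted)^2) / sst
}

# R2 for internal fit reporting: unlike r_squared(), degenerate
# constant observations do not error -- a perfect fit scores 1 and any
# imperfect fit of a constant series scores -Inf (honestly "worse than
# the mean", which here explains everything)
fit_r2 <- function(observed, predicted) {
  sst <- sum((observed - mean(observed))^2)
  sse <- sum((observed - predicted)^2)
  if (sst == 0) {
    if (sse == 0) 1 else -Inf
  } else {
    1 - sse / sst
  }
}

new_model_fit <- function(model_id, params, r2, window, n_points_used,
                          fitted, observed, time, n_free_params,
                          diagnostics = NULL) {
  structure(list(model_id = model_id, params = as.list(params), r2 = r2,
                 window = window, n_points_used = n_points_used,
                 fitted = fitted, observed = observed, time = time,
                 n_free_params = n_free_params, diagnostics = diagnostics),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s\n", x$model_id))
  cat("  params:",
      paste(sprintf("%s = %.6g", names(x$params), unlist(x$params)),
            collapse = ", "), "\n")
  cat(sprintf("  R2 = %.6f on %d points\n", x$r2, x$n_points_used))
  invisible(x)
}

curve_window <- function(curve, window) {
  n <- nrow(curve)
  if (is.null(window)) return(seq_len(n))
  window <- as.integer(window)
  if (any(window < 1L | window > n)) stop("`window` indices out of range")
  sort(unique(window))
}

#' Fit the zero-order release model
#'
#' Least-squares fit of `Mt/Minf = k t` through the origin.
#'
#' @param curve a [release_curve()].
#' @param window optional integer indices of the points to use
#'   (default: all).
#' @return A `model_fit` with parameter `k` (per min) and the R squared
#'   over the windowed points.
#' @export
fit_zero_order <- function(curve, window = NULL) {
  idx <- curve_window(curve, window)
  if (length(idx) < 2L) stop("need at least 2 points")
  t <- curve$time_min[idx]
  f <- curve$fraction_released[idx]
  if (all(t == 0)) stop("all times are zero; cannot fit a release rate")
  k <- sum(t * f) / sum(t^2)
  pred <- k * t
  new_model_fit("zero_order", c(k = k), fit_r2(f, pred), idx,
                length(idx), pred, f, t, n_free_params = 1L)
}

#' Fit the Higuchi square-root-of-time model
#'
#' Least-squares fit of `Mt/Minf = k sqrt(t)`, restricted by convention
#' to the points with fraction released strictly inside (0.1, 0.6). The
#' restricted window is recorded in the fit.
#'
#' @param curve a [release_curve()].
#' @return A `model_fit` with parameter `k` (per min^0.5).
#' @export
fit_higuchi <- function(curve) {
  f_all <- curve$fraction_released
  idx <- which(f_all > 0.1 & f_all < 0.6)
  if (length(idx) < 2L) {
    stop("insufficient window: fewer than 2 points with ",
         "0.1 < Mt/Minf < 0.6")
  }
  t <- curve$time_min[idx]
  f <- f_all[idx]
  k <- sum(sqrt(t) * f) / sum(t)
  pred <- k * sqrt(t)
  new_model_fit("higuchi", c(k = k), fit_r2(f, pred), idx,
                length(idx), pred, f, t, n_free_params = 1L)
}

#' Fit the Korsmeyer-Peppas power law
#'
#' Fits `Mt/Minf = k t^n`. `method = "log_linear"` regresses
#' `log f` on `log t` over the points with `t > 0` and `f > 0`.
#' `method = "nonlinear"` (default) refines that estimate by
#' least squares on the untransformed scale over all points with
#' `t > 0`, which is unbiased under additive noise.
#'
#' The reported R squared is computed over the full window (including a
#' `t = 0` point, whose model prediction is 0) so that fits of different
#' models on the same curve are comparable.
#'
#' @param curve a [release_curve()].
#' @param method `"nonlinear"` or `"log_linear"`.
#' @param window optional integer indices restricting the fit.
#' @return A `model_fit` with parameters `k` (per min^n) and `n`.
#' @export
fit_korsmeyer_peppas <- function(curve, method = c("nonlinear",
                                                   "log_linear"),
                                 window = NULL) {
  method <- match.arg(method)
  idx <- curve_window(curve, window)
  t_all <- curve$time_min[idx]
  f_all <- curve$fraction_released[idx]
  pos <- t_all > 0 & f_all > 0
  if (sum(pos) < 3L) {
    stop("need at least 3 points with t > 0 and fraction > 0")
  }
  ll <- ls_line(log(t_all[pos]), log(f_all[pos]))
  k <- exp(ll[["intercept"]])
  n <- ll[["slope"]]
  diagnostics <- NULL
  if (method == "nonlinear") {
    use <- t_all > 0
    df <- data.frame(t = t_all[use], f = f_all[use])
    start <- list(k = max(k, 1e-8), n = max(n, 1e-3))
    fit <- tryCatch(
      minpack.lm::nlsLM(f ~ k * t^n, data = df, start = start,
                        lower = c(k = 1e-12, n = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diagnostics <- list(nonlinear = "did not converge; log-linear estimate returned",
                          message = conditionMessage(fit))
    } else {
      cf <- coef(fit)
      k <- unname(cf[["k"]])
      n <- unname(cf[["n"]])
    }
  }
  if (!(k > 0) || !(n > 0)) {
    stop(sprintf("fit left the valid region (k = %g, n = %g)", k, n))
  }
  pred <- k * t_all^n
  pred[t_all == 0] <- 0
  new_model_fit("korsmeyer_peppas", c(k = k, n = n),
                fit_r2(f_all, pred), idx, length(idx), pred, f_all,
                t_all, n_free_params = 2L, diagnostics = diagnostics)
}

#' Fit the Peppas-Sahlin two-term model
#'
#' Fits `Mt/Minf = k1 t^m + k2 t^(2m)` separating the diffusional
#' (`k1 t^m`) and relaxational (`k2 t^(2m)`) transport contributions.
#' With fixed `m` the problem is linear in `(k1, k2)` and solved in
#' closed form; either coefficient may come out negative, as published
#' fits of this model often do. With `m = "free"` the exponent is
#' profiled over a deterministic grid and refined by golden-section
#' search (no randomness), requiring at least 5 points.
#'
#' The default `m = 0.43` is the diffusional exponent for spheres,
#' matching the convention used when only `k1` and `k2` are reported.
#'
#' @param curve a [release_curve()].
#' @param m fixed positive exponent, or `"free"`.
#' @param window optional integer indices restricting the fit.
#' @return A `model_fit` with parameters `k1` (per min^m), `k2`
#'   (per min^(2m)) and `m`.
#' @export
fit_peppas_sahlin <- function(curve, m = 0.43, window = NULL) {
  idx <- curve_window(curve, window)
  t <- curve$time_min[idx]
  f <- curve$fraction_released[idx]
  free_m <- identical(m, "free")
  min_pts <- if (free_m) 5L else 4L
  if (length(idx) < min_pts) {
    stop(sprintf("need at least %d points", min_pts))
  }
  if (length(unique(t[t > 0])) < 2L) {
    stop("singular design: need at least 2 distinct positive times")
  }
  solve_fixed <- function(mm) {
    X <- cbind(t^mm, t^(2 * mm))
    fit <- lm.fit(X, f)
    if (fit$rank < 2L) stop("singular design for Peppas-Sahlin fit")
    list(k1 = unname(fit$coefficients[1L]),
         k2 = unname(fit$coefficients[2L]),
         sse = sum(fit$residuals^2))
  }
  if (free_m) {
    grid <- seq(0.05, 1.5, by = 0.01)
    sses <- vapply(grid, function(mm) solve_fixed(mm)$sse, numeric(1))
    best <- grid[which.min(sses)]
    lo <- max(0.01, best - 0.01)
    hi <- best + 0.01
    opt <- optimize(function(mm) solve_fixed(mm)$sse, c(lo, hi),
                    tol = 1e-10)
    m_hat <- opt$minimum
    if (sses[which.min(sses)] < opt$objective) m_hat <- best
    sol <- solve_fixed(m_hat)
    n_free <- 3L
  } else {
    stop_if_not_scalar_number(m, "m", 0, strict_lower = TRUE)
    m_hat <- m
    sol <- solve_fixed(m)
    n_free <- 2L
  }
  pred <- sol$k1 * t^m_hat + sol$k2 * t^(2 * m_hat)
  new_model_fit("peppas_sahlin",
                list(k1 = sol$k1, k2 = sol$k2, m = m_hat),
                fit_r2(f, pred), idx, length(idx), pred, f, t,
                n_free_params = n_free)
}

#' Fit all release models to one curve
#'
#' Convenience wrapper fitting the zero-order, Higuchi,
#' Korsmeyer-Peppas and Peppas-Sahlin models. Models whose window
#' requirements the curve cannot satisfy (e.g. Higuchi with no points in
#' (0.1, 0.6)) are dropped with a warning recorded in the result.
#'
#' @param curve a [release_curve()].
#' @param models character subset of the four model ids.
#' @param m Peppas-Sahlin exponent passed to [fit_peppas_sahlin()].
#' @param kp_method method passed to [fit_korsmeyer_peppas()].
#' @return Named list of `model_fit` objects (class `model_fit_list`);
#'   attribute `skipped` names models that could not be fitted.
#' @export
fit_release_models <- function(curve, models = release_model_ids(),
                               m = 0.43, kp_method = "nonlinear") {
  models <- match.arg(models, release_model_ids(), several.ok = TRUE)
  fits <- list()
  skipped <- character()
  for (mod in models) {
    res <- tryCatch(switch(mod,
                           zero_order = fit_zero_order(curve),
                           higuchi = fit_higuchi(curve),
                           korsmeyer_peppas =
                             fit_korsmeyer_peppas(curve, method = kp_method),
                           peppas_sahlin = fit_peppas_sahlin(curve, m = m)),
                    error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, setNames(conditionMessage(res), mod))
    } else {
      fits[[mod]] <- res
    }
  }
  structure(fits, skipped = skipped, class = "model_fit_list")
}

#' Select the best fit by coefficient of determination
#'
#' Returns the fit with maximal R squared. Fits whose R squared is
#' within `tie_tol` of the maximum are treated as tied; ties are broken
#' toward the model with fewer free parameters, then by the fixed model
#' order zero_order, higuchi, korsmeyer_peppas, peppas_sahlin.
#'
#' @param fits list of `model_fit` objects (e.g. from
#'   [fit_release_models()]).
#' @param tie_tol numeric tolerance within which two R squared values
#'   count as tied (default 1e-9).
#' @return The selected `model_fit`.
#' @export
select_model <- function(fits, tie_tol = 1e-9) {
  fits <- unclass(fits)
  attr(fits, "skipped") <- NULL
  if (!length(fits)) stop("empty fit list")
  r2 <- vapply(fits, function(f) f$r2, numeric(1))
  best <- max(r2)
  tied <- which(r2 >= best - tie_tol)
  if (length(tied) > 1L) {
    npar <- vapply(fits[tied], function(f) f$n_free_params, integer(1))
    tied <- tied[npar == min(npar)]
    if (length(tied) > 1L) {
      ord <- match(vapply(fits[tied], function(f) f$model_id,
                          character(1)), release_model_ids())
      tied <- tied[order(ord)]
    }
  }
  fits[[tied[1L]]]
}
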
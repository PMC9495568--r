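#' Code and decode factorial levels
#'
#' Linear map between natural wall-material percentages and coded
#' units: 2.5% -> -1, 3.75% -> 0, 5% -> +1, applied per factor.
#'
#' @param agavin_pct,whey_pct natural levels within `[2.5, 5]`.
#' @return `code_levels`: data.frame with coded columns `a`, `w`;
#'   `decode_levels`: data.frame with `agavin_pct`, `whey_pct`.
#' @examples
#' code_levels(5, 2.5) # a = 1, w = -1
#' @export
code_levels <- function(agavin_pct, whey_pct) {
  if (any(agavin_pct < 2.5 | agavin_pct > 5) ||
      any(whey_pct < 2.5 | whey_pct > 5)) {
    stop("levels must lie within the design region [2.5, 5] %")
  }
  data.frame(a = (agavin_pct - 3.75) / 1.25,
             w = (whey_pct - 3.75) / 1.25)
}

#' @rdname code_levels
#' @param a,w coded levels within `[-1, 1]`.
#' @export
decode_levels <- function(a, w) {
  if (any(abs(a) > 1 + 1e-12) || any(abs(w) > 1 + 1e-12)) {
    stop("coded levels must lie within [-1, 1]")
  }
  data.frame(agavin_pct = 3.75 + 1.25 * a, whey_pct = 3.75 + 1.25 * w)
}

#' Fit a quadratic response surface to a factorial dataset
#'
#' Ordinary least squares of one response on the coded terms
#' `a, w, a^2, w^2, aw` over a (replicated) 3x3 factorial dataset in
#' the long format produced by [simulate_factorial_experiment()].
#'
#' @param design data.frame with columns `agavin_pct`, `whey_pct`,
#'   `response`, `value` (and optionally `treatment`, `replicate`).
#' @param response name of the response to fit.
#' @return Object of class `response_surface`: coefficients
#'   `(b0, bA, bW, bAA, bWW, bAW)` on coded units, `r2`,
#'   `residual_variance` and the underlying `lm` fit.
#' @export
fit_quadratic_surface <- function(design, response) {
  stopifnot(is.data.frame(design),
            all(c("agavin_pct", "whey_pct", "response", "value") %in%
                names(design)))
  d <- design[design$response == response, ]
  if (!nrow(d)) stop(sprintf("no rows for response '%s'", response))
  pts <- unique(d[, c("agavin_pct", "whey_pct")])
  if (nrow(pts) < 6L) {
    stop("need at least 6 distinct design points for a full quadratic")
  }
  coded <- code_levels(d$agavin_pct, d$whey_pct)
  dat <- data.frame(y = d$value, a = coded$a, w = coded$w)
  fit <- lm(y ~ a + w + I(a^2) + I(w^2) + I(a * w), data = dat)
  if (any(is.na(coef(fit)))) stop("rank-deficient design")
  b <- setNames(unname(coef(fit)),
                c("b0", "bA", "bW", "bAA", "bWW", "bAW"))
  sst <- sum((dat$y - mean(dat$y))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 1
  dfres <- fit$df.residual
  structure(list(response = response, coefficients = b, r2 = r2,
                 residual_variance = if (dfres > 0)
                   sum(fit$residuals^2) / dfres else NA_real_,
                 lm = fit),
            class = "response_surface")
}

#' @export
print.response_surface <- function(x, ...) {
  cat(sprintf("<response_surface> %s (R2 = %.4f)\n", x$response, x$r2))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Predict from a fitted response surface
#'
#' Quadratic evaluation at natural-unit points. Points outside the
#' design region `[2.5, 5]^2` are rejected unless
#' `allow_extrapolation = TRUE`.
#'
#' @param model a [fit_quadratic_surface()] result.
#' @param agavin_pct,whey_pct coordinates (vectors of equal length).
#' @param allow_extrapolation permit points outside the design square.
#' @return Numeric vector of predictions.
#' @export
predict_surface <- function(model, agavin_pct, whey_pct,
                            allow_extrapolation = FALSE) {
  stopifnot(inherits(model, "response_surface"))
  if (!allow_extrapolation &&
      (any(agavin_pct < 2.5 | agavin_pct > 5) ||
       any(whey_pct < 2.5 | whey_pct > 5))) {
    stop("points outside the design region [2.5, 5]^2; ",
         "set `allow_extrapolation = TRUE` to override")
  }
  a <- (agavin_pct - 3.75) / 1.25
  w <- (whey_pct - 3.75) / 1.25
  b <- model$coefficients
  quad_surface_value(unname(b), a, w)
}

#' Desirability of a response value
#'
#' One-sided Derringer-Suich desirability. For `goal = "maximize"`,
#' `d = ((y - L)/(U - L))^weight` clipped to `[0, 1]`; for
#' `"minimize"`, `d = ((U - y)/(U - L))^weight` clipped likewise.
#'
#' @param value response value(s) in natural units.
#' @param goal a [desirability_goal()].
#' @return Desirability in `[0, 1]` (vectorized over `value`).
#' @export
desirability <- function(value, goal) {
  stopifnot(inherits(goal, "desirability_goal"))
  span <- goal$upper - goal$lower
  raw <- if (goal$goal == "maximize") {
    (value - goal$lower) / span
  } else {
    (goal$upper - value) / span
  }
  clip01(raw)^goal$weight
}

#' Desirability goal specification
#'
#' @param response response name the goal applies to.
#' @param goal `"maximize"` or `"minimize"`.
#' @param lower,upper bounds in natural units (`lower < upper`).
#' @param weight shape exponent (> 0, default 1).
#' @param importance relative importance (> 0, default 1) used in the
#'   weighted geometric mean of the composite desirability.
#' @return Object of class `desirability_goal`.
#' @export
desirability_goal <- function(response, goal = c("maximize", "minimize"),
                              lower, upper, weight = 1, importance = 1) {
  goal <- match.arg(goal)
  stop_if_not_scalar_number(lower, "lower")
  stop_if_not_scalar_number(upper, "upper")
  if (lower >= upper) stop("`lower` must be < `upper`")
  stop_if_not_scalar_number(weight, "weight", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(importance, "importance", 0,
                            strict_lower = TRUE)
  structure(list(response = response, goal = goal, lower = lower,
                 upper = upper, weight = weight, importance = importance),
            class = "desirability_goal")
}

#' Default desirability bounds from a fitted surface
#'
#' Sets `lower`/`upper` to the min/max of the surface prediction over a
#' dense grid of the design region, the natural choice when no
#' specification limits are given.
#'
#' @param model a [fit_quadratic_surface()] result.
#' @param goal `"maximize"` or `"minimize"`.
#' @param weight,importance passed to [desirability_goal()].
#' @param n grid resolution per axis.
#' @return A [desirability_goal()].
#' @export
goal_from_surface <- function(model, goal, weight = 1, importance = 1,
                              n = 201L) {
  g <- seq(2.5, 5, length.out = n)
  grid <- expand.grid(agavin_pct = g, whey_pct = g)
  pred <- predict_surface(model, grid$agavin_pct, grid$whey_pct)
  lo <- min(pred); hi <- max(pred)
  if (hi <= lo) { # constant surface: widen symmetrically
    lo <- lo - 0.5
    hi <- hi + 0.5
  }
  desirability_goal(model$response, goal, lo, hi, weight, importance)
}

#' Multi-response desirability optimization
#'
#' Maximizes the importance-weighted geometric mean of the individual
#' desirabilities,
#' `D = (prod d_i^imp_i)^(1 / sum imp_i)`, over the design square
#' `[2.5, 5]^2`: a deterministic coarse grid search (default 201 x 201)
#' followed by bounded local refinement (L-BFGS-B from the best grid
#' point). Grid ties are broken toward the lowest agavin, then lowest
#' whey percentage.
#'
#' @param models list of [fit_quadratic_surface()] results, one per
#'   goal's response.
#' @param goals list of [desirability_goal()] objects (nonempty).
#' @param n_grid grid resolution per axis (default 201).
#' @return Object of class `optimization_result`: `optimal`
#'   (agavin_pct, whey_pct), `predicted` and `desirabilities` per
#'   response, `composite`, plus the grid metadata. If the composite is
#'   zero everywhere this is flagged via `all_zero = TRUE`.
#' @export
optimize_composite <- function(models, goals, n_grid = 201L) {
  if (!length(goals)) stop("`goals` must be nonempty")
  model_names <- vapply(models, function(m) m$response, character(1))
  names(models) <- model_names
  for (g in goals) {
    if (!g$response %in% model_names) {
      stop(sprintf("goal references response '%s' with no fitted model",
                   g$response))
    }
  }
  imps <- vapply(goals, function(g) g$importance, numeric(1))
  comp_fun <- function(A, W) {
    d_tot <- rep(1, length(A))
    for (g in goals) {
      pred <- predict_surface(models[[g$response]], A, W)
      d_tot <- d_tot * desirability(pred, g)^g$importance
    }
    d_tot^(1 / sum(imps))
  }
  gseq <- seq(2.5, 5, length.out = n_grid)
  grid <- expand.grid(agavin_pct = gseq, whey_pct = gseq)
  comp <- comp_fun(grid$agavin_pct, grid$whey_pct)
  best_val <- max(comp)
  cand <- which(comp >= best_val)
  cand <- cand[order(grid$agavin_pct[cand], grid$whey_pct[cand])]
  best <- cand[1L]
  start <- c(grid$agavin_pct[best], grid$whey_pct[best])
  refined <- tryCatch(
    optim(start, function(p) -comp_fun(p[1L], p[2L]),
          method = "L-BFGS-B", lower = c(2.5, 2.5), upper = c(5, 5)),
    error = function(e) NULL)
  opt <- start
  opt_val <- best_val
  if (!is.null(refined) && -refined$value > best_val) {
    opt <- refined$par
    opt_val <- -refined$value
  }
  per_resp <- lapply(goals, function(g) {
    pred <- predict_surface(models[[g$response]], opt[1L], opt[2L])
    c(predicted = pred, desirability = desirability(pred, g))
  })
  names(per_resp) <- vapply(goals, function(g) g$response, character(1))
  structure(list(optimal = c(agavin_pct = opt[1L], whey_pct = opt[2L]),
                 composite = opt_val,
                 per_response = per_resp,
                 all_zero = best_val == 0,
                 n_grid = n_grid,
                 grid_best = c(agavin_pct = start[1L],
                               whey_pct = start[2L],
                               composite = best_val)),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf(paste0("<optimization_result> optimum at %.3f%% agavin,",
                     " %.3f%% whey (composite D = %.4f)\n"),
              x$optimal[1L], x$optimal[2L], x$composite))
  if (x$all_zero) cat("  note: composite desirability is zero everywhere\n")
  invisible(x)
}

#' One-way ANOVA with Tukey HSD grouping
#'
#' Classical one-way analysis of variance followed by Tukey's honestly
#' significant difference test and a compact letter display. Letters
#' are assigned deterministically in descending order of group means:
#' the highest mean gets "a", and groups not significantly different
#' share a letter.
#'
#' @param values numeric response vector.
#' @param groups group labels (coerced to factor), >= 2 groups with
#'   >= 2 values each.
#' @param alpha significance level in (0, 1), default 0.05.
#' @return Object of class `anova_tukey`: `means`, `f_statistic`,
#'   `p_value`, `tukey` (pairwise table) and `letters`.
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  stop_if_not_scalar_number(alpha, "alpha", 0, 1)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 values")
  fit <- aov(values ~ groups)
  an <- summary(fit)[[1L]]
  tuk <- TukeyHSD(fit, conf.level = 1 - alpha)$groups
  means <- sort(tapply(values, groups, mean), decreasing = TRUE)
  # significance lookup from the Tukey table
  sig_pairs <- rownames(tuk)[tuk[, "p adj"] < alpha]
  is_sig <- function(g1, g2) {
    paste(g1, g2, sep = "-") %in% sig_pairs ||
      paste(g2, g1, sep = "-") %in% sig_pairs
  }
  # compact letter display: insert-and-absorb over means in descending
  # order; when a group opens a new set it pulls in every earlier
  # compatible group (greedily, keeping the set pairwise compatible)
  lvl <- names(means)
  letter_sets <- list() # each element: character vector of group names
  for (g in lvl) {
    placed <- FALSE
    for (i in seq_along(letter_sets)) {
      if (!any(vapply(letter_sets[[i]], is_sig, logical(1), g2 = g))) {
        letter_sets[[i]] <- c(letter_sets[[i]], g)
        placed <- TRUE
      }
    }
    if (!placed) {
      new_set <- g
      for (h in lvl[seq_len(match(g, lvl) - 1L)]) {
        if (!any(vapply(new_set, is_sig, logical(1), g2 = h))) {
          new_set <- c(new_set, h)
        }
      }
      letter_sets[[length(letter_sets) + 1L]] <- new_set
    }
  }
  # drop sets fully contained in another
  keep <- rep(TRUE, length(letter_sets))
  for (i in seq_along(letter_sets)) {
    for (j in seq_along(letter_sets)) {
      if (i != j && keep[j] &&
          all(letter_sets[[i]] %in% letter_sets[[j]]) &&
          (length(letter_sets[[i]]) < length(letter_sets[[j]]) || i > j)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  letter_sets <- letter_sets[keep]
  letters_out <- vapply(lvl, function(g) {
    paste(letters[which(vapply(letter_sets, function(s) g %in% s,
                               logical(1)))], collapse = "")
  }, character(1))
  structure(list(means = means,
                 f_statistic = an[["F value"]][1L],
                 p_value = an[["Pr(>F)"]][1L],
                 tukey = tuk,
                 letters = letters_out,
                 alpha = alpha),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("<anova_tukey> F = %.4g, p = %.4g (alpha = %g)\n",
              x$f_statistic, x$p_value, x$alpha))
  print(data.frame(mean = round(x$means, 4), letters = x$letters))
  invisible(x)
}
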
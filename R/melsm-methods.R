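#' @export
print.melsm <- function(x, digits = 4, ...) {
  cat("Mixed-effects location-scale model (ML)\n")
  cat("  ", deparse(x$formula), "\n", sep = "")
  cat("  subjects: ", x$n_subjects, ", nights: ", x$n_obs,
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  cat("\nFixed effects (location):\n")
  print(round(x$coefficients, digits))
  cat("\nWithin-subject SD (scale), by ", x$scale_var, ":\n", sep = "")
  print(round(x$sigma_w, digits))
  cat("Random-intercept SD: ", format(round(x$sigma_b, digits)), "\n", sep = "")
  cat("log-likelihood: ", format(x$logLik, digits = 10), "\n", sep = "")
  invisible(x)
}

#' @export
summary.melsm <- function(object, ...) {
  tt <- object$coefficients / object$se
  fixed <- data.frame(
    Estimate = object$coefficients,
    `Std. Error` = object$se,
    `t value` = tt,
    `Pr(>|t|)` = 2 * stats::pt(abs(tt), object$ddf, lower.tail = FALSE),
    check.names = FALSE)
  scale <- data.frame(
    Estimate = object$sigma_w,
    `Std. Error` = object$se_sigma_w,
    check.names = FALSE,
    row.names = paste0("sigma_w[", object$scale_levels, "]"))
  out <- list(fixed = fixed, scale = scale,
              sigma_b = object$sigma_b, se_sigma_b = object$se_sigma_b,
              logLik = object$logLik, ddf = object$ddf,
              converged = object$converged, max_grad = object$max_grad,
              n_obs = object$n_obs, n_subjects = object$n_subjects,
              formula = object$formula)
  class(out) <- "summary.melsm"
  out
}

#' @export
print.summary.melsm <- function(x, digits = 4, ...) {
  cat("Mixed-effects location-scale model (ML)\n")
  cat("  ", deparse(x$formula), "\n", sep = "")
  cat("  subjects: ", x$n_subjects, ", nights: ", x$n_obs,
      ", ddf: ", x$ddf, "\n", sep = "")
  if (!x$converged)
    cat("  WARNING: not converged (max |gradient| = ",
        format(x$max_grad), ")\n", sep = "")
  cat("\nFixed effects (location model):\n")
  stats::printCoefmat(x$fixed, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("\nWithin-subject SD (scale model):\n")
  print(round(x$scale, digits))
  cat("\nRandom-intercept SD: ", format(round(x$sigma_b, digits)),
      if (!is.na(x$se_sigma_b))
        paste0(" (SE ", format(round(x$se_sigma_b, digits)), ")"),
      "\n", sep = "")
  cat("log-likelihood: ", format(x$logLik, digits = 10), "\n", sep = "")
  invisible(x)
}

#' @export
coef.melsm <- function(object, ...) object$coefficients

#' Variance-covariance of a fitted MELSM
#'
#' @param object A fitted [melsm()] object.
#' @param scale `"natural"` returns the covariance of the fixed effects
#'   only; `"theta"` returns the full covariance on the optimization scale
#'   (fixed effects + log SDs).
#' @param ... Unused.
#' @export
vcov.melsm <- function(object, scale = c("natural", "theta"), ...) {
  scale <- match.arg(scale)
  p <- length(object$coefficients)
  if (scale == "theta") return(object$vcov_theta)
  v <- object$vcov_theta[seq_len(p), seq_len(p), drop = FALSE]
  dimnames(v) <- list(names(object$coefficients), names(object$coefficients))
  v
}

#' @export
logLik.melsm <- function(object, ...) {
  val <- object$logLik
  attr(val, "df") <- length(object$theta)
  attr(val, "nobs") <- object$n_obs
  class(val) <- "logLik"
  val
}

#' @export
nobs.melsm <- function(object, ...) object$n_obs

#' Predict group-conditional means from a fitted MELSM
#'
#' @param object A fitted [melsm()] object.
#' @param newdata Data frame of covariate values; defaults to the data the
#'   model was fit on.
#' @param se.fit Also return delta-method standard errors?
#' @param ... Unused.
#' @return Predicted means (population level, random intercept at 0), or a
#'   list with `fit` and `se.fit`.
#' @export
predict.melsm <- function(object, newdata = NULL, se.fit = FALSE, ...) {
  if (is.null(newdata)) {
    X <- object$X
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
    X <- stats::model.matrix(tt, mf, contrasts.arg = object$contrasts)
  }
  fit <- drop(X %*% object$coefficients)
  if (!se.fit) return(fit)
  V <- vcov.melsm(object)
  se <- sqrt(pmax(rowSums((X %*% V) * X), 0))
  list(fit = fit, se.fit = se)
}

#' Predicted means per group at reference covariates
#'
#' Convenience wrapper around [predict.melsm()]: evaluates the fitted mean
#' for every level of the scale factor at fixed covariate values (by
#' default female sex and the cohort's grand average age, the convention
#' used for plotting in the emulated study).
#'
#' @param fit A fitted [melsm()] object.
#' @param age_years,sex Covariate values at which to predict (ignored when
#'   the model has no such covariate).
#' @return Data frame with one row per group: `fit` and `se`.
#' @export
predict_at <- function(fit, age_years = 36.1, sex = "female") {
  stopifnot(inherits(fit, "melsm"))
  if (!fit$converged) stop("model did not converge")
  groups <- fit$scale_levels
  nd <- data.frame(g = groups)
  names(nd) <- fit$scale_var
  vars <- all.vars(stats::delete.response(fit$terms))
  if ("age_years" %in% vars) nd$age_years <- age_years
  if ("sex" %in% vars) nd$sex <- sex
  for (v in setdiff(vars, names(nd))) {
    col <- fit$data[[v]]
    nd[[v]] <- if (is.numeric(col)) mean(col) else names(sort(table(col),
                                                              decreasing = TRUE))[1L]
  }
  pr <- predict.melsm(fit, nd, se.fit = TRUE)
  data.frame(group = groups, fit = pr$fit, se = pr$se.fit,
             row.names = groups)
}

#' @export
fitted.melsm <- function(object, level = 1, ...) {
  mu <- unname(drop(object$X %*% object$coefficients))
  if (level == 0) return(mu)
  mu + unname(.melsm_blup(object))[as.integer(object$id)]
}

#' Residuals of a fitted MELSM
#'
#' @param object A fitted [melsm()] object.
#' @param type `"marginal"` (response minus fixed-effect mean) or
#'   `"conditional"` (also subtracting the empirical-Bayes subject
#'   intercept).
#' @param ... Unused.
#' @export
residuals.melsm <- function(object, type = c("conditional", "marginal"), ...) {
  type <- match.arg(type)
  r <- unname(object$y - drop(object$X %*% object$coefficients))
  if (type == "marginal") return(r)
  r - unname(.melsm_blup(object))[as.integer(object$id)]
}

# Empirical Bayes subject intercepts: tau2 * S1 / (sw2 + n*tau2)
.melsm_blup <- function(object) {
  r <- object$y - drop(object$X %*% object$coefficients)
  idx <- as.integer(object$id)
  S1 <- rowsum(r, idx, reorder = TRUE)[, 1L]
  n <- as.integer(table(object$id))
  sub_group <- tapply(as.integer(object$group), object$id, `[`, 1L)
  sw2 <- (object$sigma_w^2)[sub_group]
  tau2 <- object$sigma_b^2
  tau2 * S1 / (sw2 + n * tau2)
}

#' Simulate nightly outcomes from a fitted MELSM
#'
#' Draws new subject intercepts and night-level residuals at the fitted
#' parameters, keeping the observed design (subjects, nights, covariates).
#'
#' @param object A fitted [melsm()] object.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A `data.frame` with `nsim` columns, one row per observed night.
#' @export
simulate.melsm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- drop(object$X %*% object$coefficients)
  idx <- as.integer(object$id)
  N <- object$n_subjects
  sub_group <- tapply(as.integer(object$group), object$id, `[`, 1L)
  sw <- object$sigma_w[sub_group]
  out <- matrix(NA_real_, length(mu), nsim)
  for (s in seq_len(nsim)) {
    b <- stats::rnorm(N, 0, object$sigma_b)
    out[, s] <- mu + b[idx] + stats::rnorm(length(mu), 0, sw[idx])
  }
  as.data.frame(out)
}

#' Diagnostic plot: observed vs fitted night-to-night variability
#'
#' Plots each subject's empirical within-subject SD of the outcome against
#' their number of observed nights, colored by scale group, with the fitted
#' within-subject SDs \eqn{\hat\sigma_w(g)} as horizontal lines.
#'
#' @param x A fitted [melsm()] object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.melsm <- function(x, ...) {
  r <- residuals.melsm(x, type = "marginal")
  sd_i <- tapply(r, x$id, stats::sd)
  n_i <- as.integer(table(x$id))
  grp <- tapply(as.integer(x$group), x$id, `[`, 1L)
  cols <- c("#c0392b", "#7f8c8d")[(grp - 1L) %% 2L + 1L]
  graphics::plot(n_i, sd_i, col = cols, pch = 16,
                 xlab = "observed nights per subject",
                 ylab = "within-subject SD of outcome", ...)
  for (k in seq_along(x$sigma_w))
    graphics::abline(h = x$sigma_w[k],
                     col = c("#c0392b", "#7f8c8d")[(k - 1L) %% 2L + 1L],
                     lwd = 2, lty = 2)
  graphics::legend("topright", legend = x$scale_levels, bty = "n",
                   col = c("#c0392b", "#7f8c8d")[seq_along(x$scale_levels) %% 2L + 1L],
                   pch = 16)
  invisible(x)
}
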
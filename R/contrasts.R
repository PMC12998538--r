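#' Planned contrast on group means
#'
#' Wald test of the group fixed effect (second level minus reference level
#' of the scale factor, e.g. insomnia minus control), with
#' \eqn{F = (\hat\beta/SE)^2} on \eqn{(1, ddf)} degrees of freedom and a
#' 95% CI from the t distribution with the same ddf, all computed from the
#' model-estimated SEs.
#'
#' @param fit A converged [melsm()] fit.
#' @param term Name of the coefficient to test; defaults to the (single)
#'   coefficient generated by the scale factor in the mean model.
#' @param level Confidence level.
#' @return A `data.frame` of class `"melsm_contrast"` with columns
#'   `estimate`, `se`, `F`, `df1`, `df2`, `p`, `lower`, `upper`.
#' @export
mean_contrast <- function(fit, term = NULL, level = 0.95) {
  stopifnot(inherits(fit, "melsm"))
  if (!fit$converged) stop("model did not converge; contrasts unavailable")
  if (is.null(term)) {
    hits <- grep(paste0("^", fit$scale_var), names(fit$coefficients),
                 value = TRUE)
    if (length(hits) != 1L)
      stop("cannot identify the group coefficient; pass `term`")
    term <- hits
  }
  est <- unname(fit$coefficients[term])
  se <- unname(fit$se[term])
  .contrast_table(est, se, fit$ddf, level,
                  label = paste0("mean[", term, "]"))
}

#' Planned contrast on within-subject SDs
#'
#' Tests the difference in night-to-night (within-subject) SDs between two
#' scale-factor levels, \eqn{\hat\sigma_w(g_1) - \hat\sigma_w(g_2)}. The SE
#' comes from the delta method applied to the log-scale covariance: with
#' \eqn{\sigma_w = e^\theta}, the gradient of the difference is
#' \eqn{(e^{\theta_1}, -e^{\theta_2})}.
#'
#' @param fit A converged [melsm()] fit.
#' @param levels Length-2 character: the two scale-factor levels, difference
#'   taken as `levels[1] - levels[2]`. Defaults to (second level, first
#'   level) of the scale factor, i.e. insomnia minus control for the
#'   standard cohort.
#' @param level Confidence level.
#' @inherit mean_contrast return
#' @export
sd_contrast <- function(fit, levels = NULL, level = 0.95) {
  stopifnot(inherits(fit, "melsm"))
  if (!fit$converged) stop("model did not converge; contrasts unavailable")
  if (is.null(levels)) {
    if (length(fit$scale_levels) < 2L)
      stop("scale factor has a single level")
    levels <- c(fit$scale_levels[2L], fit$scale_levels[1L])
  }
  stopifnot(all(levels %in% fit$scale_levels), length(levels) == 2L)
  p <- length(fit$coefficients)
  i1 <- p + match(levels[1L], fit$scale_levels)
  i2 <- p + match(levels[2L], fit$scale_levels)
  s1 <- fit$sigma_w[levels[1L]]
  s2 <- fit$sigma_w[levels[2L]]
  est <- unname(s1 - s2)
  g <- c(s1, -s2)
  V <- fit$vcov_theta[c(i1, i2), c(i1, i2)]
  se <- sqrt(max(drop(t(g) %*% V %*% g), 0))
  .contrast_table(est, se, fit$ddf, level,
                  label = paste0("sd[", levels[1L], "-", levels[2L], "]"))
}

.contrast_table <- function(est, se, ddf, level, label) {
  Fstat <- (est / se)^2
  p <- stats::pf(Fstat, 1, ddf, lower.tail = FALSE)
  tq <- stats::qt(1 - (1 - level) / 2, ddf)
  out <- data.frame(estimate = est, se = se, F = Fstat, df1 = 1, df2 = ddf,
                    p = p, lower = est - tq * se, upper = est + tq * se,
                    row.names = label)
  class(out) <- c("melsm_contrast", "data.frame")
  out
}

#' @export
print.melsm_contrast <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  y$p <- format.pval(y$p, digits = 3)
  print(round_df(y, digits))
  invisible(x)
}

round_df <- function(x, digits) {
  num <- vapply(x, is.numeric, TRUE)
  x[num] <- lapply(x[num], round, digits = digits)
  x
}

#' Weekly descriptive summaries per subject
#'
#' Tabulates each subject's nightly values day by day and reduces them to
#' weekly means and SDs. Week `w` covers nights `7(w-1)+1 ... 7w`; the SD
#' uses the n-1 denominator and is `NA` (never zero-filled) for weeks with
#' fewer than two observed nights; the mean is `NA` for empty weeks.
#'
#' @param nights A `data.frame` with columns `subject_id`, `night_index`,
#'   and the outcome columns to summarize.
#' @param outcomes Character vector of outcome column names; defaults to
#'   all numeric columns other than `night_index`.
#' @param n_weeks Number of weeks spanned by the protocol.
#' @return A long `data.frame`: `subject_id`, `week`, `outcome`, `n_nights`,
#'   `mean`, `sd`.
#' @export
weekly_summaries <- function(nights, outcomes = NULL, n_weeks = 8L) {
  stopifnot(all(c("subject_id", "night_index") %in% names(nights)))
  if (is.null(outcomes)) {
    outcomes <- setdiff(names(nights)[vapply(nights, is.numeric, TRUE)],
                        c("night_index"))
  }
  week <- (nights$night_index - 1L) %/% 7L + 1L
  subjects <- unique(nights$subject_id)
  grid <- expand.grid(subject_id = subjects, week = seq_len(n_weeks),
                      outcome = outcomes, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  key <- paste(nights$subject_id, week)
  res_n <- res_m <- res_s <- list()
  out <- grid
  out$n_nights <- 0L
  out$mean <- NA_real_
  out$sd <- NA_real_
  gkey <- paste(grid$subject_id, grid$week)
  for (oc in outcomes) {
    v <- nights[[oc]]
    ok <- !is.na(v)
    n_tab <- tapply(v[ok], key[ok], length)
    m_tab <- tapply(v[ok], key[ok], mean)
    s_tab <- tapply(v[ok], key[ok], stats::sd)
    rows <- which(out$outcome == oc)
    hit <- match(gkey[rows], names(n_tab))
    out$n_nights[rows] <- ifelse(is.na(hit), 0L, n_tab[hit])
    out$mean[rows] <- m_tab[hit]
    out$sd[rows] <- s_tab[hit]
  }
  out$sd[out$n_nights < 2L] <- NA_real_
  out[order(out$subject_id, out$week, out$outcome), , drop = FALSE]
}
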
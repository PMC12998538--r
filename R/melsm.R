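#' Mixed-effects location-scale model with group-specific within-subject SDs
#'
#' Fits, by maximum likelihood, the model
#' \deqn{y_{ij} = x_{ij}^\top \beta + b_i + e_{ij}, \quad
#'       b_i \sim N(0, \sigma_b^2), \quad
#'       e_{ij} \sim N(0, \sigma_w^2(g_i)),}
#' where \eqn{y_{ij}} is subject \eqn{i}'s outcome on night \eqn{j} (e.g., a
#' nightly sleep parameter), the mean (location) model carries the fixed
#' effects \eqn{\beta} (typically intercept, group, age, sex), \eqn{b_i} is a
#' subject random intercept, and the scale model gives each level of a
#' grouping factor its own within-subject SD \eqn{\sigma_w(g)} — the index of
#' night-to-night variability. Integrating the random intercept yields a
#' compound-symmetric marginal covariance per subject,
#' \eqn{\sigma_w^2 I + \sigma_b^2 J}, whose rank-one structure is exploited
#' for O(n_i) likelihood evaluation per subject.
#'
#' Variance parameters are log-parameterized for unconstrained optimization;
#' the random-intercept SD has a floor at `exp(-10)` and is reported as 0
#' when estimated at the floor. Optimization starts deterministically (OLS
#' for \eqn{\beta}, moment estimates for the SDs), runs a quasi-Newton pass
#' (`nlminb` with analytic gradient), and finishes with damped Newton
#' polishing; convergence requires a gradient max-norm below
#' `control$grad_tol`. Standard errors come from the inverse observed
#' information (numerically differentiated analytic gradient), with the
#' delta method mapping log-scale SDs to the natural scale.
#'
#' @param formula Mean-model formula, e.g.
#'   `sl_adj_min ~ group + age_years + sex`.
#' @param data A `data.frame` in long format, one row per subject-night.
#'   Rows with missing values in any model variable are dropped (observed
#'   nights only; no imputation).
#' @param subject Name of the subject-identifier column (character), or a
#'   one-sided formula like `~ subject_id`.
#' @param scale One-sided formula naming the factor whose levels get
#'   separate within-subject SDs (default `~ group`). Must be constant
#'   within subject.
#' @param ddf Denominator degrees of freedom rule for Wald F tests and CIs:
#'   `"n_minus_5"` (number of subjects minus 5; the convention that
#'   reproduces the emulated study's (1, 107) with 112 subjects) or
#'   `"n_minus_rank"` (subjects minus the rank of the mean design).
#' @param control A list from [melsm_control()].
#' @return An object of class `"melsm"`; see [melsm_fit] for components.
#' @seealso [mean_contrast()], [sd_contrast()], [predict.melsm()],
#'   [weekly_summaries()]
#' @export
#' @examples
#' cfg <- cohort_config(n_insomnia = 12, n_control = 8, n_nights = 10)
#' coh <- simulate_cohort(cfg, seed = 7, epochs = FALSE)
#' d <- merge(coh$targets, coh$subjects, by = c("subject_id", "group"))
#' fit <- melsm(sl_adj ~ group + age_years + sex, d, subject = "subject_id")
#' summary(fit)
melsm <- function(formula, data, subject, scale = ~group,
                  ddf = c("n_minus_5", "n_minus_rank"),
                  control = melsm_control()) {
  ddf_rule <- match.arg(ddf)
  if (inherits(subject, "formula")) subject <- all.vars(subject)
  stopifnot(is.character(subject), length(subject) == 1L,
            subject %in% names(data))
  scale_var <- all.vars(scale)
  stopifnot(length(scale_var) == 1L, scale_var %in% names(data))

  vars <- unique(c(all.vars(formula), subject, scale_var))
  keep <- stats::complete.cases(data[vars])
  data <- data[keep, , drop = FALSE]

  mf <- stats::model.frame(formula, data)
  mt <- attr(mf, "terms")
  y <- stats::model.response(mf)
  X <- stats::model.matrix(mt, mf)
  id <- factor(data[[subject]])
  g <- factor(data[[scale_var]])
  p <- ncol(X)
  G <- nlevels(g)

  # the scale factor must be constant within subject
  gi <- tapply(as.integer(g), id, function(v) length(unique(v)))
  if (any(gi > 1L))
    stop("scale factor '", scale_var, "' varies within subject")
  sub_group <- tapply(as.integer(g), id, `[`, 1L)

  ni <- as.integer(table(id))
  N <- nlevels(id)
  if (N < 2L || any(tapply(seq_along(y), g, function(i) length(unique(id[i]))) < 1L))
    stop("need at least 2 subjects")
  if (qr(X)$rank < p) stop("mean-model design matrix is rank deficient")

  env <- .melsm_env(y, X, id, sub_group, ni, G)
  start <- .melsm_start(y, X, id, sub_group, G, env)
  opt <- .melsm_optimize(start, env, control)

  theta <- opt$theta
  H <- opt$hessian
  vc <- .safe_inverse(H)
  se_theta <- sqrt(pmax(diag(vc$inv), 0))

  beta <- theta[seq_len(p)]
  names(beta) <- colnames(X)
  lsw <- theta[p + seq_len(G)]
  lsb <- theta[p + G + 1L]
  sigma_w <- exp(lsw)
  names(sigma_w) <- levels(g)
  at_floor <- lsb <= control$log_sd_floor + 1e-6
  sigma_b <- if (at_floor) 0 else unname(exp(lsb))

  se_beta <- se_theta[seq_len(p)]
  names(se_beta) <- colnames(X)
  se_sigma_w <- sigma_w * se_theta[p + seq_len(G)]  # delta method
  se_sigma_b <- if (at_floor) NA_real_ else unname(exp(lsb) * se_theta[p + G + 1L])

  ddf_val <- switch(ddf_rule,
                    n_minus_5 = N - 5L,
                    n_minus_rank = N - p)

  fit <- list(
    coefficients = beta, se = se_beta,
    sigma_w = sigma_w, se_sigma_w = se_sigma_w,
    sigma_b = sigma_b, se_sigma_b = se_sigma_b,
    sigma_b_at_floor = at_floor,
    theta = theta, vcov_theta = vc$inv, hessian = H,
    hessian_singular = vc$singular,
    logLik = -opt$nll, nll = opt$nll,
    converged = opt$converged, max_grad = opt$max_grad,
    iterations = opt$iterations,
    ddf = ddf_val, ddf_rule = ddf_rule,
    n_obs = length(y), n_subjects = N, n_per_group = table(g[!duplicated(id)]),
    scale_levels = levels(g), scale_var = scale_var,
    subject_var = subject,
    formula = formula, terms = mt, xlevels = stats::.getXlevels(mt, mf),
    contrasts = attr(X, "contrasts"),
    data = data, y = y, X = X, id = id, group = g,
    call = match.call()
  )
  class(fit) <- "melsm"
  fit
}

#' Control parameters for [melsm()]
#'
#' @param grad_tol Convergence requires the gradient max-norm below this.
#' @param max_iter Iteration cap for the quasi-Newton pass.
#' @param newton_iter Cap for the Newton polishing steps.
#' @param log_sd_floor Lower bound for the log random-intercept SD.
#' @export
melsm_control <- function(grad_tol = 1e-6, max_iter = 500L,
                          newton_iter = 50L, log_sd_floor = -10) {
  list(grad_tol = grad_tol, max_iter = max_iter,
       newton_iter = newton_iter, log_sd_floor = log_sd_floor)
}

#' Fitted MELSM object
#'
#' @name melsm_fit
#' @description
#' A `melsm` fit contains: `coefficients` and `se` (fixed effects);
#' `sigma_w`, `se_sigma_w` (within-subject SD per scale-factor level,
#' natural scale, delta-method SEs); `sigma_b`, `se_sigma_b`
#' (random-intercept SD; 0 with `NA` SE when estimated at the boundary);
#' `theta`, `vcov_theta` (all parameters on the optimization scale — fixed
#' effects plus log SDs — with their covariance from the inverse observed
#' information); `logLik`; `converged`, `max_grad`, `iterations`; `ddf`;
#' and bookkeeping (`n_obs`, `n_subjects`, design pieces for `predict`).
NULL

# ---- likelihood internals ----------------------------------------------

# Precompute index structures shared by nll/gradient evaluations.
.melsm_env <- function(y, X, id, sub_group, ni, G) {
  list(y = y, X = X, id = id, idx = as.integer(id),
       sub_group = as.integer(sub_group), ni = ni, G = G, p = ncol(X),
       N = nlevels(id))
}

# Negative log marginal likelihood.
# theta = (beta, log sigma_w[1..G], log sigma_b).
# Per subject with n nights, residual sums S1, S2, sw2 = sigma_w(g)^2,
# D = sw2 + n*tau2:
#   2*nll_i = n log(2*pi) + (n-1) log sw2 + log D + (S2 - tau2/D * S1^2)/sw2
.melsm_nll <- function(theta, env) {
  p <- env$p; G <- env$G
  beta <- theta[seq_len(p)]
  sw2 <- exp(2 * theta[p + seq_len(G)])
  tau2 <- exp(2 * theta[p + G + 1L])
  if (any(!is.finite(c(beta, sw2, tau2)))) return(Inf)
  r <- env$y - drop(env$X %*% beta)
  S1 <- rowsum(r, env$idx, reorder = TRUE)[, 1L]
  S2 <- rowsum(r * r, env$idx, reorder = TRUE)[, 1L]
  n <- env$ni
  s2 <- sw2[env$sub_group]
  D <- s2 + n * tau2
  val <- 0.5 * sum(n * log(2 * pi) + (n - 1) * log(s2) + log(D) +
                     (S2 - (tau2 / D) * S1^2) / s2)
  if (!is.finite(val)) Inf else val
}

# Analytic gradient of .melsm_nll in theta.
.melsm_grad <- function(theta, env) {
  p <- env$p; G <- env$G
  beta <- theta[seq_len(p)]
  sw2 <- exp(2 * theta[p + seq_len(G)])
  tau2 <- exp(2 * theta[p + G + 1L])
  r <- env$y - drop(env$X %*% beta)
  S1 <- rowsum(r, env$idx, reorder = TRUE)[, 1L]
  S2 <- rowsum(r * r, env$idx, reorder = TRUE)[, 1L]
  n <- env$ni
  s2 <- sw2[env$sub_group]
  D <- s2 + n * tau2

  # d/d beta: -X' Sigma^{-1} r, Sigma^{-1} r = r/s2 - (tau2 S1)/(s2 D) per row
  w_row <- 1 / s2[env$idx]
  adj <- (tau2 * S1 / (s2 * D))[env$idx]
  g_beta <- -drop(crossprod(env$X, r * w_row - adj))

  # d nll / d sw2 per subject, then chain to log sigma_w by group
  dQ_ds2 <- -S2 / s2^2 + tau2 * S1^2 * (D + s2) / (s2 * D)^2
  d_s2 <- 0.5 * ((n - 1) / s2 + 1 / D + dQ_ds2)
  g_lsw <- as.numeric(rowsum(d_s2 * 2 * s2, env$sub_group, reorder = TRUE))
  # groups with no subjects would drop out of rowsum; guard via full index
  if (length(g_lsw) < G) {
    full <- numeric(G)
    full[sort(unique(env$sub_group))] <- g_lsw
    g_lsw <- full
  }

  d_tau2 <- 0.5 * sum(n / D - S1^2 / D^2)
  g_lsb <- d_tau2 * 2 * tau2

  unname(c(g_beta, g_lsw, g_lsb))
}

# Deterministic start: OLS beta; moment estimates for the SDs.
.melsm_start <- function(y, X, id, sub_group, G, env) {
  ols <- stats::lm.fit(X, y)
  r <- ols$residuals
  # pooled within-subject SD of residuals per scale group
  rc <- r - stats::ave(r, id)                 # centered within subject
  n_i <- env$ni
  sw0 <- numeric(G)
  for (k in seq_len(G)) {
    rows <- env$sub_group[env$idx] == k
    m <- sum(n_i[env$sub_group == k] - 1L)
    sw0[k] <- sqrt(max(sum(rc[rows]^2) / max(m, 1L), 1e-4))
  }
  sub_mean <- tapply(r, id, mean)
  vb <- stats::var(sub_mean) - mean(sw0[env$sub_group]^2 / n_i)
  sb0 <- sqrt(max(vb, 1e-4))
  c(ols$coefficients, log(sw0), log(sb0))
}

.melsm_optimize <- function(start, env, control) {
  p <- env$p; G <- env$G
  npar <- length(start)
  lower <- c(rep(-Inf, p), rep(control$log_sd_floor, G), control$log_sd_floor)

  obj <- function(th) .melsm_nll(th, env)
  gr <- function(th) .melsm_grad(th, env)

  o <- stats::nlminb(start, obj, gradient = gr, lower = lower,
                     control = list(iter.max = control$max_iter,
                                    eval.max = 2L * control$max_iter,
                                    rel.tol = 1e-13))
  theta <- o$par
  iterations <- o$iterations

  free <- theta > lower + 1e-9   # parameters not pinned at the floor
  g <- gr(theta)
  best_nll <- obj(theta)
  for (it in seq_len(control$newton_iter)) {
    if (max(abs(g[free])) < control$grad_tol) break
    H <- .num_hessian(gr, theta)
    Hf <- H[free, free, drop = FALSE]
    step <- tryCatch(-solve(Hf, g[free]), error = function(e) -g[free])
    lambda <- 1
    repeat {
      cand <- theta
      cand[free] <- theta[free] + lambda * step
      cand <- pmax(cand, lower)
      nll_c <- obj(cand)
      if (is.finite(nll_c) &&
          (nll_c < best_nll + 1e-12 ||
           max(abs(gr(cand)[free])) < max(abs(g[free])))) {
        theta <- cand
        best_nll <- min(nll_c, best_nll)
        break
      }
      lambda <- lambda / 2
      if (lambda < 1e-8) break
    }
    if (lambda < 1e-8) break
    g <- gr(theta)
    iterations <- iterations + 1L
  }

  H <- .num_hessian(gr, theta)
  max_grad <- max(abs(g[free]))
  list(theta = theta, nll = obj(theta), hessian = H,
       converged = max_grad < control$grad_tol,
       max_grad = max_grad, iterations = iterations)
}

# Central-difference Jacobian of the analytic gradient -> observed information.
.num_hessian <- function(gr, theta) {
  npar <- length(theta)
  H <- matrix(0, npar, npar)
  h <- 1e-6 * pmax(abs(theta), 1)
  for (j in seq_len(npar)) {
    tp <- theta; tp[j] <- tp[j] + h[j]
    tm <- theta; tm[j] <- tm[j] - h[j]
    H[, j] <- (gr(tp) - gr(tm)) / (2 * h[j])
  }
  (H + t(H)) / 2
}

.safe_inverse <- function(H) {
  inv <- tryCatch(solve(H), error = function(e) NULL)
  singular <- is.null(inv)
  if (singular) {
    e <- eigen(H, symmetric = TRUE)
    lam <- pmax(e$values, max(abs(e$values)) * 1e-10)
    inv <- e$vectors %*% diag(1 / lam, length(lam)) %*% t(e$vectors)
  }
  # enforce symmetry for downstream quadratic forms
  list(inv = (inv + t(inv)) / 2, singular = singular)
}
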
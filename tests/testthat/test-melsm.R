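test_that("closed-form marginal likelihood matches known values", {
  # one subject, one night, zero residual, sigma_w = 1, sigma_b -> 0:
  # the density is the standard normal at 0, so NLL = 0.5*log(2*pi)
  d <- data.frame(y = 5, subject_id = "A",
                  group = factor("control", levels = c("control", "insomnia")),
                  age_years = 30, sex = "female")
  nll <- melsm_nll_at(beta = 5, sigma_w = c(control = 1, insomnia = 1),
                      sigma_b = 1e-8, d, formula = y ~ 1)
  expect_equal(nll, 0.5 * log(2 * pi), tolerance = 1e-10)
})

test_that("closed-form NLL equals adaptive Gauss-Hermite quadrature", {
  skip_if_not_installed("pracma")
  set.seed(20)
  for (k in 1:8) {
    d <- make_small_ls_data(n_subj = 5, n_nights = 4, seed = k)
    beta <- c(10, 3, 0.1, -1) + stats::rnorm(4, 0, 0.5)
    sw <- c(control = stats::runif(1, 1, 4), insomnia = stats::runif(1, 2, 8))
    sb <- stats::runif(1, 0.5, 5)
    mf <- stats::model.frame(y ~ group + age_years + sex, d)
    X <- stats::model.matrix(attr(mf, "terms"), mf)
    closed <- melsm_nll_at(beta, sw, sb, d)
    quad <- agh_nll(beta, sw, sb, d$y, X, d$subject_id, d$group, nodes = 64)
    expect_equal(closed, quad, tolerance = 1e-8)
  }
})

test_that("duplicating every subject doubles the NLL", {
  d <- make_small_ls_data(n_subj = 4, n_nights = 3, seed = 2)
  d2 <- rbind(d, transform(d, subject_id = paste0(subject_id, "_copy")))
  beta <- c(9, 2, 0.05, -0.5)
  sw <- c(control = 2, insomnia = 4)
  n1 <- melsm_nll_at(beta, sw, 1.5, d)
  n2 <- melsm_nll_at(beta, sw, 1.5, d2)
  expect_equal(n2, 2 * n1, tolerance = 1e-10)
})

test_that("analytic gradient matches numerical differentiation", {
  skip_if_not_installed("pracma")
  d <- make_small_ls_data(n_subj = 6, n_nights = 5, seed = 3)
  mf <- stats::model.frame(y ~ group + age_years + sex, d)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  id <- factor(d$subject_id)
  g <- factor(d$group)
  env <- noctvar:::.melsm_env(y, X, id,
                              tapply(as.integer(g), id, `[`, 1L),
                              as.integer(table(id)), nlevels(g))
  theta <- c(9, 2.5, 0.08, -0.6, log(2.2), log(4.5), log(1.8))
  ga <- noctvar:::.melsm_grad(theta, env)
  gn <- pracma::grad(function(th) noctvar:::.melsm_nll(th, env), theta)
  expect_equal(ga, gn, tolerance = 1e-6)
})

test_that("fit recovers truth and satisfies the convergence contract", {
  set.seed(30)
  d <- make_small_ls_data(n_subj = 40, n_nights = 20, seed = 30,
                          beta = c(20, 8, 0.05, -1),
                          sigma_w = c(control = 3, insomnia = 9),
                          sigma_b = 4)
  fit <- melsm(y ~ group + age_years + sex, d, subject = "subject_id")
  expect_true(fit$converged)
  expect_lt(fit$max_grad, 1e-6)
  # truth within 3 model SEs
  expect_lt(abs(coef(fit)[["groupinsomnia"]] - 8), 3 * fit$se[["groupinsomnia"]])
  expect_lt(abs(fit$sigma_w[["insomnia"]] - 9), 3 * fit$se_sigma_w[[2]])
  expect_lt(abs(fit$sigma_w[["control"]] - 3), 3 * fit$se_sigma_w[[1]])
  # vcov is symmetric positive semi-definite
  V <- vcov(fit, scale = "theta")
  expect_equal(V, t(V))
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
})

test_that("fit agrees with nlme::lme under varIdent (independent route)", {
  skip_if_not_installed("nlme")
  d <- make_small_ls_data(n_subj = 30, n_nights = 8, seed = 5,
                          beta = c(15, 5, 0.1, -2),
                          sigma_w = c(control = 2.5, insomnia = 6),
                          sigma_b = 3)
  fit <- melsm(y ~ group + age_years + sex, d, subject = "subject_id")
  lfit <- nlme::lme(y ~ group + age_years + sex, random = ~ 1 | subject_id,
                    weights = nlme::varIdent(form = ~ 1 | group),
                    data = d, method = "ML")
  expect_equal(unclass(logLik(fit)), as.numeric(logLik(lfit)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(coef(fit), nlme::fixef(lfit), tolerance = 1e-5)
  # within-subject SDs: lme stores a reference sigma and relative multipliers
  mult <- coef(lfit$modelStruct$varStruct, unconstrained = FALSE,
               allCoef = TRUE)
  sw_lme <- lfit$sigma * mult
  expect_equal(unname(fit$sigma_w[names(sw_lme)]), unname(sw_lme),
               tolerance = 1e-4)
  expect_equal(fit$sigma_b,
               sqrt(as.numeric(nlme::getVarCov(lfit))), tolerance = 1e-4)
})

test_that("degenerate truth sigma_b = 0 is handled at the boundary", {
  set.seed(40)
  d <- make_small_ls_data(n_subj = 30, n_nights = 10, seed = 40,
                          sigma_w = c(control = 3, insomnia = 3),
                          sigma_b = 0)
  fit <- melsm(y ~ group + age_years + sex, d, subject = "subject_id")
  expect_true(fit$sigma_b < 0.5)
  expect_true(is.finite(fit$logLik))
})

test_that("estimates are invariant to row permutation and subject relabeling", {
  d <- make_small_ls_data(n_subj = 20, n_nights = 6, seed = 8)
  fit <- melsm(y ~ group + age_years + sex, d, subject = "subject_id")
  set.seed(1)
  dp <- d[sample(nrow(d)), ]
  fitp <- melsm(y ~ group + age_years + sex, dp, subject = "subject_id")
  expect_equal(coef(fit), coef(fitp), tolerance = 1e-8)
  expect_equal(fit$sigma_w, fitp$sigma_w, tolerance = 1e-8)
  expect_equal(fit$logLik, fitp$logLik, tolerance = 1e-8)

  dr <- d
  dr$subject_id <- paste0("Z", match(d$subject_id, unique(d$subject_id)))
  fitr <- melsm(y ~ group + age_years + sex, dr, subject = "subject_id")
  expect_equal(coef(fit), coef(fitr), tolerance = 1e-8)
  expect_equal(fit$sigma_w, fitr$sigma_w, tolerance = 1e-8)
})

test_that("centering age changes only the intercept", {
  d <- make_small_ls_data(n_subj = 20, n_nights = 6, seed = 9)
  fit <- melsm(y ~ group + age_years + sex, d, subject = "subject_id")
  dc <- d
  dc$age_years <- dc$age_years - mean(dc$age_years)
  fitc <- melsm(y ~ group + age_years + sex, dc, subject = "subject_id")
  expect_equal(coef(fit)[-1], coef(fitc)[-1], tolerance = 1e-6)
  expect_equal(fit$sigma_w, fitc$sigma_w, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(coef(fit)[1], coef(fitc)[1])))
})

test_that("contrasts satisfy their algebraic identities", {
  d <- make_small_ls_data(n_subj = 24, n_nights = 8, seed = 12,
                          beta = c(12, 4, 0, 0),
                          sigma_w = c(control = 2, insomnia = 5),
                          sigma_b = 2)
  fit <- melsm(y ~ group + age_years + sex, d, subject = "subject_id")
  mc <- mean_contrast(fit)
  sc <- sd_contrast(fit)
  # F = (estimate/SE)^2 = squared Wald z
  expect_equal(mc$F, (mc$estimate / mc$se)^2)
  expect_equal(sc$F, (sc$estimate / sc$se)^2)
  expect_equal(mc$df2, fit$ddf)
  # CI = estimate +/- t_{0.975, ddf} * SE
  tq <- qt(0.975, fit$ddf)
  expect_equal(mc$upper - mc$lower, 2 * tq * mc$se)
  expect_equal(sc$lower, sc$estimate - tq * sc$se)
  # contrast direction: insomnia minus control
  expect_equal(mc$estimate, unname(coef(fit)[["groupinsomnia"]]))
  expect_equal(sc$estimate,
               unname(fit$sigma_w[["insomnia"]] - fit$sigma_w[["control"]]))
  # ddf rule: subjects minus 5 by default, configurable alternative
  expect_equal(fit$ddf, 24 - 5)
  fit2 <- melsm(y ~ group + age_years + sex, d, subject = "subject_id",
                ddf = "n_minus_rank")
  expect_equal(fit2$ddf, 24 - 4)
})

test_that("null truth gives near-zero contrasts and honest p values", {
  set.seed(77)
  d <- make_small_ls_data(n_subj = 40, n_nights = 12, seed = 77,
                          beta = c(12, 0, 0, 0),
                          sigma_w = c(control = 3, insomnia = 3),
                          sigma_b = 2)
  fit <- melsm(y ~ group + age_years + sex, d, subject = "subject_id")
  mc <- mean_contrast(fit)
  sc <- sd_contrast(fit)
  expect_lt(abs(mc$estimate), 3 * mc$se)
  expect_lt(abs(sc$estimate), 3 * sc$se)
  expect_gt(mc$p, 0.001)
})

test_that("prediction obeys the design algebra", {
  d <- make_small_ls_data(n_subj = 20, n_nights = 6, seed = 14,
                          beta = c(10, 5, 0.2, -1))
  fit <- melsm(y ~ group + age_years + sex, d, subject = "subject_id")
  pr <- predict_at(fit, age_years = 36.1, sex = "female")
  # difference of group predictions equals the group coefficient exactly
  expect_equal(pr["insomnia", "fit"] - pr["control", "fit"],
               unname(coef(fit)[["groupinsomnia"]]))
  # predictions respond to age through the fitted slope
  pr2 <- predict_at(fit, age_years = 46.1, sex = "female")
  expect_equal(pr2["control", "fit"] - pr["control", "fit"],
               10 * unname(coef(fit)[["age_years"]]))
  # predict() at observed covariates reproduces the fixed-effect fit
  expect_equal(predict(fit), drop(fit$X %*% coef(fit)))

  # conditional fitted values shrink toward subjects; residual identity
  expect_equal(fitted(fit) + residuals(fit, "conditional"), unname(fit$y))
  expect_equal(fitted(fit, level = 0) + residuals(fit, "marginal"),
               unname(fit$y))
})

test_that("simulate() reproduces the fitted variance components", {
  d <- make_small_ls_data(n_subj = 30, n_nights = 10, seed = 16,
                          sigma_w = c(control = 2, insomnia = 6),
                          sigma_b = 3)
  fit <- melsm(y ~ group + age_years + sex, d, subject = "subject_id")
  sims <- simulate(fit, nsim = 200, seed = 1)
  r <- as.matrix(sims) - drop(fit$X %*% coef(fit))
  within <- apply(r, 2, function(col) {
    sd(col[d$group == "control"] - ave(col[d$group == "control"],
                                       d$subject_id[d$group == "control"]))
  })
  # average simulated within-control SD near the fitted sigma_w (n-1 bias aside)
  expect_equal(mean(within), unname(fit$sigma_w[["control"]]),
               tolerance = 0.05)
})

test_that("weekly summaries tabulate day-by-day values into weekly cells", {
  nights <- data.frame(subject_id = "A", night_index = 1:7, value = 1:7)
  ws <- weekly_summaries(nights, outcomes = "value")
  w1 <- ws[ws$week == 1, ]
  expect_equal(w1$mean, 4)
  expect_equal(w1$sd, sd(1:7))
  expect_equal(round(w1$sd, 4), 2.1602)

  # identical nights: SD exactly zero
  const <- data.frame(subject_id = "B", night_index = 8:14, value = 5)
  expect_equal(weekly_summaries(const, outcomes = "value")[2, "sd"], 0)

  # a week with a single observed night: mean defined, SD is NA (never 0)
  one <- data.frame(subject_id = "C", night_index = 15, value = 9)
  ws1 <- weekly_summaries(one, outcomes = "value")
  expect_equal(ws1$mean[ws1$week == 3], 9)
  expect_true(is.na(ws1$sd[ws1$week == 3]))
  # empty weeks are explicit NA cells
  expect_true(all(is.na(ws1$mean[ws1$week != 3])))
  expect_equal(ws1$n_nights[ws1$week != 3], rep(0L, 7))
})
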
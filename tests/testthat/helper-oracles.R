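# Independent oracles used across the suite. These are written directly
# against the scoring-rule definitions (explicit single-pass loops, adaptive
# quadrature) and deliberately share no code with the package internals.

# Brute-force nightly derivation: walks the epoch sequence once per rule.
brute_force_night <- function(states) {
  s <- toupper(as.character(states))
  is_sleep <- s %in% c("LIGHT", "DEEP", "REM")
  if (!any(is_sleep)) return(list(valid = FALSE))
  n <- length(s)
  first_sleep <- 0L
  for (i in seq_len(n)) if (is_sleep[i]) { first_sleep <- i; break }
  last_sleep <- 0L
  for (i in seq_len(n)) if (is_sleep[i]) last_sleep <- i
  start <- 1L
  pre_abs <- FALSE
  if (first_sleep > 1L) {
    for (i in 1L:(first_sleep - 1L)) {
      if (s[i] == "ABSENCE") { start <- i + 1L; pre_abs <- TRUE }
    }
  }
  end <- n
  if (last_sleep < n) {
    for (i in (last_sleep + 1L):n) {
      if (s[i] == "ABSENCE") { end <- i - 1L; break }
    }
  }
  sl <- if (pre_abs) 0.5 * (first_sleep - start) else 0.5 * (first_sleep - 1L)
  tst <- 0; waso <- 0; tib <- 0
  for (i in start:end) {
    if (is_sleep[i]) tst <- tst + 0.5
    if (s[i] != "ABSENCE") tib <- tib + 0.5
    if (s[i] == "WAKE" && i > first_sleep && i < last_sleep) waso <- waso + 0.5
  }
  list(valid = TRUE, start = start, end = end, sl = sl, tst = tst,
       waso = waso, fa = 0.5 * (end - last_sleep), tib = tib,
       se = 100 * tst / tib)
}

# Random hypnogram with random state frequencies.
random_hypnogram <- function(len) {
  probs <- stats::runif(5)
  sample(c("WAKE", "LIGHT", "DEEP", "REM", "ABSENCE"), len,
         replace = TRUE, prob = probs / sum(probs))
}

# Negative log-likelihood of the location-scale model by adaptive
# Gauss-Hermite quadrature over the subject intercept (64 nodes).
agh_nll <- function(beta, sigma_w, sigma_b, y, X, id, group, nodes = 64) {
  gh <- pracma::gaussHermite(nodes)
  total <- 0
  for (i in unique(id)) {
    rows <- which(id == i)
    yi <- y[rows]
    mi <- drop(X[rows, , drop = FALSE] %*% beta)
    sw <- sigma_w[[as.character(group[rows[1L]])]]
    ni <- length(yi)
    if (sigma_b < 1e-8) {
      total <- total - sum(stats::dnorm(yi, mi, sw, log = TRUE))
      next
    }
    r <- yi - mi
    v <- 1 / (ni / sw^2 + 1 / sigma_b^2)   # posterior variance of b_i
    bhat <- v * sum(r) / sw^2              # posterior mode
    s <- sqrt(2 * v)
    lv <- vapply(seq_len(nodes), function(k) {
      b <- bhat + s * gh$x[k]
      log(gh$w[k]) + gh$x[k]^2 +
        sum(stats::dnorm(yi, mi + b, sw, log = TRUE)) +
        stats::dnorm(b, 0, sigma_b, log = TRUE)
    }, 0)
    m <- max(lv)
    total <- total - (m + log(sum(exp(lv - m))) + log(s))
  }
  total
}

# Small balanced location-scale dataset for likelihood checks.
make_small_ls_data <- function(n_subj = 5, n_nights = 4, seed = 1,
                               beta = c(10, 3, 0.1, -1),
                               sigma_w = c(control = 2, insomnia = 5),
                               sigma_b = 3) {
  set.seed(seed)
  group <- rep(c("control", "insomnia"), length.out = n_subj)
  id <- rep(seq_len(n_subj), each = n_nights)
  age <- rep(stats::runif(n_subj, 20, 60), each = n_nights)
  sex <- rep(sample(c("female", "male"), n_subj, replace = TRUE),
             each = n_nights)
  g <- group[id]
  X <- cbind(1, as.numeric(g == "insomnia"), age, as.numeric(sex == "male"))
  b <- stats::rnorm(n_subj, 0, sigma_b)
  y <- drop(X %*% beta) + b[id] + stats::rnorm(length(id), 0, sigma_w[g])
  data.frame(y = y, subject_id = sprintf("P%02d", id),
             group = factor(g, levels = c("control", "insomnia")),
             age_years = age, sex = sex)
}

# Evaluate the package's closed-form NLL at given natural-scale parameters.
melsm_nll_at <- function(beta, sigma_w, sigma_b, data,
                         formula = y ~ group + age_years + sex) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  id <- factor(data$subject_id)
  g <- factor(data$group)
  sub_group <- tapply(as.integer(g), id, `[`, 1L)
  ni <- as.integer(table(id))
  env <- noctvar:::.melsm_env(y, X, id, sub_group, ni, nlevels(g))
  theta <- c(beta, log(sigma_w[levels(g)]), log(sigma_b))
  noctvar:::.melsm_nll(theta, env)
}
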
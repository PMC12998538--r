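#' Configuration for a synthetic sleep-monitoring cohort
#'
#' Defines the generator truth for a two-group (chronic insomnia vs
#' good-sleeper control) cohort observed over consecutive nights. Nightly
#' sleep parameters follow a normal location-scale data-generating process:
#' for each outcome, night value = group mean + subject random intercept +
#' night noise with a group-specific SD, truncated at zero and quantized to
#' the 0.5-minute epoch grid.
#'
#' The generator is anchored on grand (cohort-level) means and
#' insomnia-minus-control differences; [derive_group_anchors()] resolves
#' these into per-group truth. Sleep efficiency is not sampled directly: it
#' is the derived ratio 100·TST/TIB, and the night-level correlation between
#' sleep latency and WASO is solved per group so that the within-subject SD
#' of derived sleep efficiency matches `sd_se_control` and
#' `sd_diff$sleep_efficiency` exactly (delta method). Final-awakening group
#' means absorb the remaining wake budget implied by the efficiency anchors.
#'
#' @param n_insomnia,n_control Subjects per group.
#' @param n_nights Nights of intended recording per subject (8 weeks = 56).
#' @param tib_mean Grand mean nightly time in bed, minutes.
#' @param tst_mean Grand mean nightly total sleep time, minutes. Together
#'   with `tib_mean` this fixes the grand sleep-efficiency anchor
#'   100·`tst_mean`/`tib_mean`.
#' @param mean_diff Named list of insomnia-minus-control mean differences:
#'   `sleep_efficiency` (percentage points), `sl_adj` (min), `waso` (min).
#' @param sd_diff Named list of insomnia-minus-control within-subject SD
#'   differences for the same three outcomes.
#' @param sl_mean,waso_mean Grand mean anchors for nightly sleep latency and
#'   WASO (minutes; the source study prints no group means for these, so
#'   they are free anchors — recovery targets depend only on the
#'   differences).
#' @param sd_se_control,sd_sl_control,sd_waso_control Control-group
#'   within-subject (night-to-night) SD anchors for sleep efficiency (%),
#'   sleep latency (min), and WASO (min).
#' @param sd_fa,sd_tib Night-level SDs of final awakening and time in bed
#'   (minutes; common to both groups).
#' @param icc_sd Named list of subject random-intercept SDs (between-subject)
#'   for `sl_adj`, `waso`, `final_awakening`, `tib`, in their natural units.
#' @param age_mean,age_sd Length-2 numeric vectors (insomnia, control) for
#'   the age distribution, truncated to [18, 65].
#' @param prop_female Length-2 numeric vector (insomnia, control).
#' @param adherence Named list with numeric vectors `insomnia` and `control`
#'   of length 8: the probability that a night in each study week is
#'   recorded. Defaults interpolate the usage percentages of the emulated
#'   study (insomnia >80% weeks 1-2, peak 83.8% week 3, 63.2% week 8,
#'   overall 75.9%; control 80.8% week 1, 69.5% week 8, overall 71.8%).
#' @param p_pre_absence Probability that a night's recording begins with an
#'   out-of-bed (absence) bout before sleep onset, exercising the adjusted
#'   sleep-latency rule.
#' @param p_mid_absence Probability of a brief mid-sleep absence bout.
#' @return An object of class `"cohort_config"` (a named list).
#' @export
cohort_config <- function(n_insomnia = 83L,
                          n_control = 29L,
                          n_nights = 56L,
                          tib_mean = 7.65 * 60,
                          tst_mean = 6.59 * 60,
                          mean_diff = list(sleep_efficiency = -5.34,
                                           sl_adj = 10.15,
                                           waso = 18.45),
                          sd_diff = list(sleep_efficiency = 1.77,
                                         sl_adj = 8.80,
                                         waso = 8.60),
                          sl_mean = 28.4,
                          waso_mean = 29.2,
                          sd_se_control = 2.0,
                          sd_sl_control = 4.0,
                          sd_waso_control = 5.0,
                          sd_fa = 1.5,
                          sd_tib = 25,
                          icc_sd = list(sl_adj = 3.0, waso = 3.5,
                                        final_awakening = 1.0, tib = 20),
                          age_mean = c(38.3, 29.7),
                          age_sd = c(12.0, 8.8),
                          prop_female = c(0.699, 0.724),
                          adherence = list(
                            insomnia = c(0.815, 0.830, 0.838, 0.800,
                                         0.762, 0.722, 0.675, 0.632),
                            control = c(0.808, 0.728, 0.714, 0.706,
                                        0.701, 0.698, 0.696, 0.695)),
                          p_pre_absence = 0.5,
                          p_mid_absence = 0.15) {
  cfg <- list(n_insomnia = as.integer(n_insomnia),
              n_control = as.integer(n_control),
              n_nights = as.integer(n_nights),
              tib_mean = tib_mean, tst_mean = tst_mean,
              mean_diff = mean_diff, sd_diff = sd_diff,
              sl_mean = sl_mean, waso_mean = waso_mean,
              sd_se_control = sd_se_control,
              sd_sl_control = sd_sl_control,
              sd_waso_control = sd_waso_control,
              sd_fa = sd_fa, sd_tib = sd_tib, icc_sd = icc_sd,
              age_mean = age_mean, age_sd = age_sd,
              prop_female = prop_female, adherence = adherence,
              p_pre_absence = p_pre_absence, p_mid_absence = p_mid_absence)
  stopifnot(cfg$n_insomnia >= 1L, cfg$n_control >= 1L, cfg$n_nights >= 1L,
            tib_mean > 0, tst_mean > 0, tst_mean < tib_mean,
            sd_se_control > 0, sd_sl_control > 0, sd_waso_control > 0,
            sd_fa > 0, sd_tib > 0,
            all(unlist(icc_sd) >= 0),
            length(adherence$insomnia) == 8L,
            length(adherence$control) == 8L,
            all(unlist(adherence) >= 0), all(unlist(adherence) <= 1),
            p_pre_absence >= 0, p_pre_absence <= 1)
  class(cfg) <- "cohort_config"
  cfg
}

#' Resolve grand anchors into per-group generator truth
#'
#' Grand mean anchors `m` and insomnia-minus-control differences `d` are
#' split with subject-count weights `w_ins = n_ins/(n_ins+n_ctl)`:
#' control mean `= m - d*w_ins`, insomnia mean `= control + d`, so the
#' weighted average of the group means reproduces `m` and the difference is
#' `d` exactly. Within-subject SDs resolve as control anchor and
#' `control + d_sd`. Final-awakening means absorb the wake budget implied by
#' the sleep-efficiency anchors (with a second-order correction for the
#' E[1/TIB] curvature), and the night-level SL-WASO correlation is solved so
#' the within-subject SD of the derived efficiency hits its target.
#'
#' @param config A [cohort_config()].
#' @return A list with per-group truth: `mean` and `sd_night` data frames
#'   (rows `insomnia`, `control`; columns `sl_adj`, `waso`,
#'   `final_awakening`, `tib`, `tst`, `sleep_efficiency`), the night-level
#'   SL-WASO correlation `rho` per group, intercept SDs, and the target
#'   sleep-efficiency group means/SDs.
#' @export
derive_group_anchors <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  w_ins <- config$n_insomnia / (config$n_insomnia + config$n_control)

  split_mean <- function(m, d) {
    ctl <- m - d * w_ins
    c(insomnia = ctl + d, control = ctl)
  }

  se_grand <- 100 * config$tst_mean / config$tib_mean
  se_mean <- split_mean(se_grand, config$mean_diff$sleep_efficiency)
  sl_mean <- split_mean(config$sl_mean, config$mean_diff$sl_adj)
  waso_mean <- split_mean(config$waso_mean, config$mean_diff$waso)

  se_sd <- c(insomnia = config$sd_se_control + config$sd_diff$sleep_efficiency,
             control = config$sd_se_control)
  sl_sd <- c(insomnia = config$sd_sl_control + config$sd_diff$sl_adj,
             control = config$sd_sl_control)
  waso_sd <- c(insomnia = config$sd_waso_control + config$sd_diff$waso,
               control = config$sd_waso_control)

  tib <- config$tib_mean
  # total TIB variance (intercept + night) drives the E[1/TIB] curvature
  var_tib_tot <- config$icc_sd$tib^2 + config$sd_tib^2
  jensen <- 1 + var_tib_tot / tib^2
  # expected nightly wake budget per group: E[SL + WASO + FA]
  wake_budget <- tib * (1 - se_mean / 100) / jensen
  fa_mean <- wake_budget - sl_mean - waso_mean
  if (any(fa_mean <= 0))
    stop("infeasible anchors: final-awakening mean would be non-positive; ",
         "lower sl_mean/waso_mean or revisit the efficiency anchors")

  # delta method: var(SE) = c^2 var(wake) + (c*wake/tib)^2 var(tib),
  # c = 100/tib; solve the SL-WASO correlation for the required wake variance
  cc <- 100 / tib
  var_wake_req <- se_sd^2 / cc^2 - (wake_budget / tib)^2 * config$sd_tib^2
  rho <- (var_wake_req - sl_sd^2 - waso_sd^2 - config$sd_fa^2) /
    (2 * sl_sd * waso_sd)
  if (any(abs(rho) >= 0.99))
    stop("infeasible anchors: required SL-WASO correlation |rho| >= 0.99 (",
         paste(round(rho, 3), collapse = ", "),
         "); adjust the within-subject SD anchors")

  groups <- c("insomnia", "control")
  mean_tab <- data.frame(
    sl_adj = sl_mean[groups], waso = waso_mean[groups],
    final_awakening = fa_mean[groups],
    tib = rep(tib, 2), tst = tib - wake_budget[groups] * jensen,
    sleep_efficiency = se_mean[groups], row.names = groups)
  sd_tab <- data.frame(
    sl_adj = sl_sd[groups], waso = waso_sd[groups],
    final_awakening = rep(config$sd_fa, 2), tib = rep(config$sd_tib, 2),
    sleep_efficiency = se_sd[groups], row.names = groups)
  if (any(mean_tab$tst <= 0) || any(unlist(sd_tab) <= 0))
    stop("infeasible anchors: non-positive resolved mean or SD")

  list(mean = mean_tab, sd_night = sd_tab, rho = rho[groups],
       icc_sd = config$icc_sd,
       se_target = list(mean = se_mean[groups], sd = se_sd[groups]),
       wake_budget = wake_budget[groups])
}

#' Sample nightly parameter targets for one subject
#'
#' Realizes the normal location-scale data-generating process at night level:
#' each component (SL, WASO, FA, TIB) is group mean + subject intercept +
#' night noise; SL and WASO noise are correlated within night (see
#' [derive_group_anchors()]); TST = TIB − SL − WASO − FA. Values are clamped
#' at zero and quantized to the 0.5-minute epoch grid.
#'
#' @param anchors Output of [derive_group_anchors()].
#' @param group `"insomnia"` or `"control"`.
#' @param n_nights Number of nights to draw.
#' @param intercepts Optional named numeric (sl_adj, waso, final_awakening,
#'   tib): the subject's random intercepts. Drawn from the configured
#'   intercept SDs when `NULL`.
#' @return A `data.frame` with columns `sl_adj`, `waso`, `final_awakening`,
#'   `tib`, `tst` (minutes, multiples of 0.5) and attribute
#'   `"clamp_fraction"`, the fraction of sampled component values that were
#'   truncated at zero. A warning is raised when any component's clamp
#'   fraction exceeds 1% (truncation biases parameter recovery).
#' @export
sample_night_targets <- function(anchors, group, n_nights, intercepts = NULL) {
  stopifnot(group %in% c("insomnia", "control"))
  mu <- anchors$mean[group, ]
  sd_n <- anchors$sd_night[group, ]
  rho <- anchors$rho[[group]]
  if (is.null(intercepts)) {
    isd <- anchors$icc_sd
    intercepts <- c(sl_adj = stats::rnorm(1, 0, isd$sl_adj),
                    waso = stats::rnorm(1, 0, isd$waso),
                    final_awakening = stats::rnorm(1, 0, isd$final_awakening),
                    tib = stats::rnorm(1, 0, isd$tib))
  }
  z1 <- stats::rnorm(n_nights)
  z2 <- stats::rnorm(n_nights)
  e_sl <- sd_n$sl_adj * z1
  e_waso <- sd_n$waso * (rho * z1 + sqrt(1 - rho^2) * z2)
  sl <- mu$sl_adj + intercepts[["sl_adj"]] + e_sl
  waso <- mu$waso + intercepts[["waso"]] + e_waso
  fa <- mu$final_awakening + intercepts[["final_awakening"]] +
    stats::rnorm(n_nights, 0, sd_n$final_awakening)
  tib <- mu$tib + intercepts[["tib"]] + stats::rnorm(n_nights, 0, sd_n$tib)

  clamped <- c(sl < 0, waso < 0, fa < 0)
  clamp_fraction <- mean(clamped)
  per_comp <- c(sl = mean(sl < 0), waso = mean(waso < 0), fa = mean(fa < 0))
  if (any(per_comp > 0.01) && n_nights >= 100)
    warning("truncation mass exceeds 1% for component(s): ",
            paste(names(per_comp)[per_comp > 0.01], collapse = ", "),
            "; truncation biases parameter recovery", call. = FALSE)

  q <- function(x) round(pmax(x, 0) / EPOCH_MIN) * EPOCH_MIN
  sl <- q(sl); waso <- q(waso); fa <- q(fa); tib <- q(tib)
  tst <- tib - sl - waso - fa
  # realizability: at least 2 sleep epochs when WASO needs an interior
  floor_tst <- ifelse(waso > 0, 1.5, 0.5)
  short <- tst < floor_tst
  if (any(short)) {
    tst[short] <- floor_tst[short]
    tib[short] <- sl[short] + waso[short] + fa[short] + tst[short]
  }
  out <- data.frame(sl_adj = sl, waso = waso, final_awakening = fa,
                    tib = tib, tst = tst)
  attr(out, "clamp_fraction") <- clamp_fraction
  out
}

#' Realize one night's hypnogram from its parameter targets
#'
#' Emits an epoch sequence whose derived summary reproduces the targets
#' exactly: an optional pre-sleep absence bout (preceded by a few in-bed
#' wake epochs), the latency wake epochs, a sleep block with the WASO wake
#' minutes distributed over 1-4 bouts strictly interior to the sleep span
#' (and an optional brief mid-sleep absence bout), the final-awakening wake
#' epochs, and an optional trailing absence. Sleep epochs are labeled
#' LIGHT/DEEP/REM at realistic stage proportions (derivation depends only on
#' the sleep/wake/absence distinction).
#'
#' @param target A one-row list/data.frame with `sl_adj`, `tst`, `waso`,
#'   `final_awakening` in minutes (multiples of 0.5; `tst >= 0.5`, and
#'   `tst >= 1.5` when `waso > 0`).
#' @param pre_absence Emit a pre-sleep absence bout? When `FALSE`, the
#'   recording starts with the latency wake epochs, so the adjusted latency
#'   equals time-from-recording-start.
#' @param mid_absence Emit a brief absence bout inside the sleep span?
#' @return Character vector of epoch states.
#' @export
realize_epochs <- function(target, pre_absence = FALSE, mid_absence = FALSE) {
  n_sl <- as.integer(round(target$sl_adj / EPOCH_MIN))
  n_tst <- as.integer(round(target$tst / EPOCH_MIN))
  n_waso <- as.integer(round(target$waso / EPOCH_MIN))
  n_fa <- as.integer(round(target$final_awakening / EPOCH_MIN))
  if (n_tst < 1L) stop("cannot realize a night with no sleep epoch")
  if (n_waso > 0L && n_tst < 2L)
    stop("cannot realize WASO > 0 with fewer than 2 sleep epochs")

  sleep_block <- sample(2:4, n_tst, replace = TRUE, prob = c(0.55, 0.20, 0.25))
  # distribute WASO over 1-4 bouts in interior gaps between sleep epochs
  parts <- integer(0)
  gaps <- integer(0)
  if (n_waso > 0L) {
    k <- sample.int(min(4L, n_waso, n_tst - 1L), 1L)
    cut <- sort(sample.int(n_waso - 1L, k - 1L))
    parts <- diff(c(0L, cut, n_waso))
    gaps <- sort(sample.int(n_tst - 1L, k))  # after sleep epoch `gaps[j]`
  }
  abs_gap <- 0L
  n_mid_abs <- 0L
  if (mid_absence && n_tst >= 2L) {
    open <- setdiff(seq_len(n_tst - 1L), gaps)
    if (length(open)) {
      abs_gap <- open[sample.int(length(open), 1L)]
      n_mid_abs <- sample.int(10L, 1L)
    }
  }
  # assemble the sleep span piecewise: sleep segments between insertion
  # points, with the wake bouts / absence bout spliced in after them
  inserts <- list()
  if (n_waso > 0L)
    inserts <- lapply(seq_along(gaps),
                      function(j) list(pos = gaps[j], run = rep(1L, parts[j])))
  if (abs_gap > 0L)
    inserts <- c(inserts, list(list(pos = abs_gap, run = rep(5L, n_mid_abs))))
  if (length(inserts))
    inserts <- inserts[order(vapply(inserts, `[[`, 0L, "pos"))]
  pieces <- list()
  prev <- 0L
  for (ins in inserts) {
    pieces <- c(pieces, list(sleep_block[(prev + 1L):ins$pos]), list(ins$run))
    prev <- ins$pos
  }
  pieces <- c(pieces, list(sleep_block[(prev + 1L):n_tst]))
  code <- integer(0)
  if (pre_absence) {
    code <- c(rep(1L, sample.int(5L, 1L) - 1L), rep(5L, sample.int(10L, 1L)))
  }
  code <- c(code, rep(1L, n_sl), unlist(pieces), rep(1L, n_fa))
  if (stats::runif(1) < 0.5) {
    code <- c(code, rep(5L, sample.int(6L, 1L)))
    if (stats::runif(1) < 0.3) code <- c(code, rep(1L, sample.int(4L, 1L)))
  }
  epoch_states()[code]
}

#' Thin a cohort's nights by weekly adherence probabilities
#'
#' Each night is observed independently with the probability configured for
#' its study week and group (missing completely at random, matching an
#' analysis with no imputation). Week `w` covers nights `7(w-1)+1 ... 7w`.
#'
#' @param nights A `data.frame` with columns `subject_id`, `night_index`,
#'   `group`.
#' @param adherence Named list with numeric length-8 vectors `insomnia`,
#'   `control` (see [cohort_config()]).
#' @return The subset of `nights` that is observed.
#' @export
apply_adherence <- function(nights, adherence) {
  week <- pmin((nights$night_index - 1L) %/% 7L + 1L, 8L)
  p <- ifelse(nights$group == "insomnia",
              adherence$insomnia[week], adherence$control[week])
  nights[stats::runif(nrow(nights)) < p, , drop = FALSE]
}

.rtrunc_norm <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Simulate a complete synthetic cohort
#'
#' Generates subjects (group, age, sex), samples nightly parameter targets
#' under the location-scale truth resolved by [derive_group_anchors()],
#' applies weekly adherence, and (optionally) realizes each observed night
#' as an epoch-level hypnogram.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; identical config + seed gives identical output.
#' @param epochs If `TRUE` (default) realize epoch sequences and return them
#'   in long format; targets-only generation (`FALSE`) is faster and
#'   sufficient for model-level simulation studies.
#' @return A list of class `"sleep_cohort"`:
#'   `subjects` (`subject_id, group, age_years, sex`),
#'   `targets` (observed nights with their generator-truth parameters),
#'   `epochs` (long-format epoch table, or `NULL`),
#'   `anchors`, `config`, `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L,
                            epochs = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  anchors <- derive_group_anchors(config)
  n <- config$n_insomnia + config$n_control
  group <- rep(c("insomnia", "control"),
               c(config$n_insomnia, config$n_control))
  id <- sprintf("S%03d", seq_len(n))
  gi <- ifelse(group == "insomnia", 1L, 2L)
  age <- .rtrunc_norm(n, config$age_mean[gi], config$age_sd[gi], 18, 65)
  sex <- ifelse(stats::runif(n) < config$prop_female[gi], "female", "male")
  subjects <- data.frame(subject_id = id, group = group,
                         age_years = round(age, 1), sex = sex,
                         stringsAsFactors = FALSE)

  target_list <- vector("list", n)
  for (i in seq_len(n)) {
    tg <- sample_night_targets(anchors, group[i], config$n_nights)
    tg <- cbind(data.frame(subject_id = id[i], group = group[i],
                           night_index = seq_len(config$n_nights)), tg)
    target_list[[i]] <- tg
  }
  targets <- do.call(rbind, target_list)
  rownames(targets) <- NULL
  targets <- apply_adherence(targets, config$adherence)

  epoch_tab <- NULL
  if (epochs) {
    m <- nrow(targets)
    pre <- stats::runif(m) < config$p_pre_absence
    mid <- stats::runif(m) < config$p_mid_absence
    st_list <- vector("list", m)
    for (k in seq_len(m)) {
      st <- realize_epochs(targets[k, ], pre_absence = pre[k],
                           mid_absence = mid[k])
      st_list[[k]] <- st
    }
    len <- lengths(st_list)
    epoch_tab <- data.frame(
      subject_id = rep(targets$subject_id, len),
      night_index = rep(targets$night_index, len),
      epoch_index = sequence(len),
      state = unlist(st_list),
      stringsAsFactors = FALSE)
  }

  out <- list(subjects = subjects, targets = targets, epochs = epoch_tab,
              anchors = anchors, config = config, seed = as.integer(seed))
  class(out) <- "sleep_cohort"
  out
}

#' @export
print.sleep_cohort <- function(x, ...) {
  cat("Synthetic sleep cohort (seed ", x$seed, ")\n", sep = "")
  cat("  subjects: ", nrow(x$subjects), " (",
      sum(x$subjects$group == "insomnia"), " insomnia / ",
      sum(x$subjects$group == "control"), " control)\n", sep = "")
  cat("  observed nights: ", nrow(x$targets), " of ",
      nrow(x$subjects) * x$config$n_nights, " scheduled\n", sep = "")
  if (!is.null(x$epochs))
    cat("  epochs: ", nrow(x$epochs), "\n", sep = "")
  invisible(x)
}
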
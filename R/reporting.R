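#' Round a nightly summary for display
#'
#' Monitor apps display TST and WASO rounded to whole minutes, while every
#' analysis in this package consumes unrounded epoch totals (0.5-minute
#' granularity); mixing the two conventions can shift sums by more or less
#' than 0.5 minutes, so rounding is centralized here and used for display
#' only. Ties round half-up.
#'
#' @param night A nightly summary `data.frame` (rows from [derive_nights()]).
#' @return The same `data.frame` with `tst_min` and `waso_min` replaced by
#'   whole-minute display values.
#' @export
display_round <- function(night) {
  half_up <- function(x) floor(x + 0.5)
  night$tst_min <- half_up(night$tst_min)
  night$waso_min <- half_up(night$waso_min)
  night
}

#' Size-weighted pooled mean
#'
#' Pools group-level means with group-size weights, e.g. combining group
#' mean ages 38.3 (n=83) and 29.7 (n=29) into the cohort grand mean 36.1.
#'
#' @param means Numeric vector of group means.
#' @param n Integer vector of group sizes.
#' @export
pooled_mean <- function(means, n) {
  stopifnot(length(means) == length(n), all(n > 0))
  sum(means * n) / sum(n)
}

#' Cohort descriptive table
#'
#' @param subjects A subjects `data.frame` (`subject_id`, `group`,
#'   `age_years`, `sex`).
#' @return A list with a per-group `data.frame` (`n`, `pct`, `age_mean`,
#'   `age_sd`, `pct_female`) and `grand_age_mean`, the size-weighted grand
#'   mean age.
#' @export
cohort_descriptives <- function(subjects) {
  stopifnot(nrow(subjects) > 0)
  grp <- factor(subjects$group)
  n <- as.integer(table(grp))
  tab <- data.frame(
    n = n,
    pct = 100 * n / nrow(subjects),
    age_mean = as.numeric(tapply(subjects$age_years, grp, mean)),
    age_sd = as.numeric(tapply(subjects$age_years, grp, stats::sd)),
    pct_female = as.numeric(tapply(subjects$sex == "female", grp, mean)) * 100,
    row.names = levels(grp))
  list(groups = tab,
       grand_age_mean = pooled_mean(tab$age_mean, tab$n))
}

#' Per-week observed-night fractions by group
#'
#' @param targets Observed nights (`subject_id`, `group`, `night_index`).
#' @param n_subjects Named vector of subjects per group.
#' @param n_weeks Number of protocol weeks.
#' @return `data.frame` with `week`, one column per group.
#' @export
adherence_table <- function(targets, n_subjects, n_weeks = 8L) {
  week <- (targets$night_index - 1L) %/% 7L + 1L
  groups <- names(n_subjects)
  out <- data.frame(week = seq_len(n_weeks))
  for (g in groups) {
    cnt <- tabulate(week[targets$group == g], nbins = n_weeks)
    out[[g]] <- cnt / (n_subjects[[g]] * 7)
  }
  out
}

#' Run the full simulate -> derive -> fit -> report pipeline
#'
#' Simulates a cohort at epoch level, derives nightly summaries from the
#' hypnograms, fits the location-scale model to each requested outcome, and
#' assembles a study report with the Table-style Means/SD contrast rows,
#' grand means, adherence, and cohort descriptives. Deterministic given
#' `config` and `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param outcomes Outcome columns of the derived night table to model.
#' @param outdir Optional directory: when given, writes `epochs.csv`,
#'   `nights.csv`, `subjects.csv` and `report.json` (requires jsonlite)
#'   there.
#' @param epochs Simulate at epoch level (`TRUE`, the full pipeline) or at
#'   night-target level (`FALSE`, faster; skips hypnogram derivation).
#' @return A list of class `"study_report"`.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1L,
                         outcomes = c("sleep_efficiency_pct", "sl_adj_min",
                                      "waso_min", "tib_min", "tst_min"),
                         outdir = NULL, epochs = TRUE) {
  coh <- simulate_cohort(config, seed = seed, epochs = epochs)
  if (epochs) {
    nights <- derive_nights(coh$epochs)
  } else {
    nights <- data.frame(subject_id = coh$targets$subject_id,
                         night_index = coh$targets$night_index,
                         valid = TRUE,
                         sl_adj_min = coh$targets$sl_adj,
                         tst_min = coh$targets$tst,
                         waso_min = coh$targets$waso,
                         final_awakening_min = coh$targets$final_awakening,
                         tib_min = coh$targets$tib,
                         sleep_efficiency_pct =
                           100 * coh$targets$tst / coh$targets$tib)
  }
  n_invalid <- sum(!nights$valid)
  valid <- nights[nights$valid, , drop = FALSE]
  d <- merge(valid, coh$subjects, by = "subject_id")
  d$group <- factor(d$group, levels = c("control", "insomnia"))

  fits <- list()
  rows <- list()
  for (oc in outcomes) {
    f <- stats::as.formula(paste(oc, "~ group + age_years + sex"))
    fit <- melsm(f, d, subject = "subject_id", scale = ~group)
    mc <- mean_contrast(fit)
    sc <- sd_contrast(fit)
    fits[[oc]] <- fit
    rows[[oc]] <- data.frame(
      outcome = oc, row = c("Means", "SD"),
      estimate = c(mc$estimate, sc$estimate),
      se = c(mc$se, sc$se), F = c(mc$F, sc$F),
      df1 = 1, df2 = fit$ddf, p = c(mc$p, sc$p),
      lower = c(mc$lower, sc$lower), upper = c(mc$upper, sc$upper),
      converged = fit$converged)
  }
  contrast_tab <- do.call(rbind, rows)
  rownames(contrast_tab) <- NULL

  grand <- c(tib_hours = mean(valid$tib_min) / 60,
             tst_hours = mean(valid$tst_min) / 60)
  report <- list(
    contrasts = contrast_tab,
    grand_means = grand,
    descriptives = cohort_descriptives(coh$subjects),
    adherence = adherence_table(
      coh$targets,
      c(control = config$n_control, insomnia = config$n_insomnia)),
    n_invalid_nights = n_invalid,
    n_observed_nights = nrow(valid),
    seed = as.integer(seed),
    fits = fits)
  class(report) <- "study_report"

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (epochs) write_epochs(coh$epochs, file.path(outdir, "epochs.csv"))
    write_nights(nights, file.path(outdir, "nights.csv"))
    utils::write.csv(coh$subjects, file.path(outdir, "subjects.csv"),
                     row.names = FALSE, quote = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      out_json <- report[c("contrasts", "grand_means", "n_invalid_nights",
                           "n_observed_nights", "seed")]
      out_json$grand_means <- as.list(out_json$grand_means)
      jsonlite::write_json(
        out_json,
        file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA,
        dataframe = "rows")
    }
  }
  report
}

#' @export
print.study_report <- function(x, digits = 3, ...) {
  cat("Study report (seed ", x$seed, ")\n", sep = "")
  d <- x$descriptives$groups
  for (g in rownames(d))
    cat(sprintf("  %-9s n=%d (%.0f%%), age %.1f (SD %.1f), %.0f%% female\n",
                g, d[g, "n"], d[g, "pct"], d[g, "age_mean"], d[g, "age_sd"],
                d[g, "pct_female"]))
  cat(sprintf("  grand mean age: %.1f years\n", x$descriptives$grand_age_mean))
  cat(sprintf("  observed nights: %d (%d invalid excluded)\n",
              x$n_observed_nights, x$n_invalid_nights))
  cat(sprintf("  grand mean TIB %.2f h, TST %.2f h\n",
              x$grand_means[["tib_hours"]], x$grand_means[["tst_hours"]]))
  cat("\nInsomnia vs control contrasts (Means / within-subject SD):\n")
  tab <- x$contrasts
  tab$p <- format.pval(tab$p, digits = 2)
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Multi-seed parameter-recovery study
#'
#' Repeats the simulate -> derive -> fit pipeline over a set of seeds and
#' collects, per seed: the mean and SD group contrasts for the modeled
#' outcomes, their SEs, and the grand mean TIB/TST (hours). This is the
#' engine behind the package's recovery checks: with the generator truth set
#' to the published group differences, the averaged contrast estimates
#' should recover those differences.
#'
#' @param config A [cohort_config()].
#' @param seeds Integer vector of seeds (one cohort per seed).
#' @param outcomes Outcomes to model.
#' @param epochs Run at epoch level (full pipeline) or target level.
#' @return A list with `per_seed` (`data.frame`) and `summary` (means over
#'   seeds).
#' @export
recovery_study <- function(config = cohort_config(), seeds = 1:25,
                           outcomes = c("sleep_efficiency_pct", "sl_adj_min",
                                        "waso_min"),
                           epochs = TRUE) {
  rows <- vector("list", length(seeds))
  for (k in seq_along(seeds)) {
    rep <- run_pipeline(config, seed = seeds[k], outcomes = outcomes,
                        epochs = epochs)
    ct <- rep$contrasts
    row <- data.frame(seed = seeds[k],
                      tib_hours = rep$grand_means[["tib_hours"]],
                      tst_hours = rep$grand_means[["tst_hours"]])
    for (oc in outcomes) {
      m <- ct[ct$outcome == oc & ct$row == "Means", ]
      s <- ct[ct$outcome == oc & ct$row == "SD", ]
      row[[paste0(oc, ".mean_diff")]] <- m$estimate
      row[[paste0(oc, ".mean_se")]] <- m$se
      row[[paste0(oc, ".sd_diff")]] <- s$estimate
      row[[paste0(oc, ".sd_se")]] <- s$se
    }
    rows[[k]] <- row
  }
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       summary = colMeans(per_seed[setdiff(names(per_seed), "seed")]))
}
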
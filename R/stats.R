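#' ICC(3,k): two-way mixed, consistency, average-measures reliability
#'
#' Computes the intraclass correlation for a subjects-by-sessions table of
#' one metric from the two-way (subject x session) decomposition:
#' `ICC(3,k) = (MS_R - MS_E) / MS_R`, with `MS_R` the between-subject and
#' `MS_E` the residual mean square. This is the average-measures,
#' consistency form appropriate when the same fixed set of sessions is
#' rated for every subject. Rows with any missing session are dropped
#' (complete cases).
#'
#' @param wide Numeric matrix or data.frame, subjects in rows, sessions in
#'   columns.
#' @param metric Optional metric name carried into the result.
#' @return Object of class `pvs_icc`: list with `metric`, `icc3k`, `k`,
#'   `n`, and `retained` (`icc3k >= 0.5`). `icc3k` is `NA` when the
#'   decomposition is degenerate (no between-subject variance).
#' @export
#' @examples
#' x <- cbind(s1 = c(1, 2, 3, 4), s2 = c(1, 2, 3, 4))
#' icc3k(x)$icc3k  # 1: perfect test-retest agreement
icc3k <- function(wide, metric = NA_character_) {
  wide <- as.matrix(wide)
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  n <- nrow(wide)
  k <- ncol(wide)
  if (n < 2L || k < 2L)
    stop("need >= 2 complete subjects and >= 2 sessions", call. = FALSE)
  long <- data.frame(value = as.vector(wide),
                     subject = factor(rep(seq_len(n), k)),
                     session = factor(rep(seq_len(k), each = n)))
  icc <- NA_real_
  if (var(long$value) > 0) {
    ms <- summary(aov(value ~ subject + session, data = long))[[1]][, "Mean Sq"]
    msr <- ms[1]; mse <- ms[3]
    if (is.finite(msr) && msr > 0) icc <- (msr - mse) / msr
  }
  structure(list(metric = metric, icc3k = icc, k = k, n = n,
                 retained = !is.na(icc) && icc >= 0.5),
            class = "pvs_icc")
}

#' @export
print.pvs_icc <- function(x, ...) {
  cat(sprintf("ICC(3,%d)%s = %s over %d subjects [%s]\n", x$k,
              if (is.na(x$metric)) "" else paste0(" for ", x$metric),
              format(x$icc3k, digits = 3), x$n,
              if (x$retained) "retained" else "excluded (< 0.5)"))
  invisible(x)
}

.wide_metric <- function(tab, metric, sessions, cohort) {
  rows <- tab[tab$cohort == cohort & tab$session %in% sessions, ]
  wide <- sapply(sessions, function(s) {
    v <- rows[rows$session == s, ]
    setNames(v[[metric]], v$subject_id)[unique(rows$subject_id)]
  })
  matrix(wide, ncol = length(sessions),
         dimnames = list(unique(rows$subject_id), sessions))
}

#' Reliability gate across the astronaut and control cohorts
#'
#' For each metric, computes ICC(3,2) across the astronauts' two pre-flight
#' sessions and ICC(3,4) across the controls' four sessions, and retains
#' the metric only when both ICCs are at least 0.5 (moderate reliability).
#' Gated metrics are excluded from every downstream model; the exclusion
#' list is part of the report.
#'
#' @param tab Cohort table (see [simulate_cohort()] for the schema).
#' @param metrics Character vector of metric column names.
#' @return Object of class `pvs_reliability`: data.frame with one row per
#'   metric (`icc_astronauts`, `icc_controls`, `retained`) plus attribute
#'   `excluded` (character vector of gated metrics).
#' @export
reliability_report <- function(tab, metrics = c(
  "total_pvs_volume_mm3", "total_pvs_number", "median_pvs_volume_mm3",
  "median_pvs_length_mm", "median_pvs_width_mm", "ventricular_volume_mL")) {
  stopifnot(is.data.frame(tab), all(metrics %in% names(tab)))
  res <- do.call(rbind, lapply(metrics, function(m) {
    ia <- icc3k(.wide_metric(tab, m, c("L-180", "L-60"), "astronaut"), m)
    ic <- if (any(tab$cohort == "control"))
      icc3k(.wide_metric(tab, m, paste0("C", 1:4), "control"), m)
    else NULL
    data.frame(metric = m, icc_astronauts = ia$icc3k,
               icc_controls = if (is.null(ic)) NA_real_ else ic$icc3k,
               retained = ia$retained && (is.null(ic) || ic$retained))
  }))
  attr(res, "excluded") <- res$metric[!res$retained]
  class(res) <- c("pvs_reliability", class(res))
  res
}

#' @export
print.pvs_reliability <- function(x, ...) {
  cat("Test-retest reliability (ICC(3,k); gate at 0.5 in both cohorts):\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  ex <- attr(x, "excluded")
  if (length(ex)) cat("Excluded from further analysis:",
                      paste(ex, collapse = ", "), "\n")
  invisible(x)
}

#' Per-subject pre- to post-flight change
#'
#' The longitudinal outcome: `delta = value(R+4) - value(L-60)` per
#' astronaut. When the L-60 scan is missing the single available baseline
#' (L-180) is used instead; subjects missing both baselines or the R+4
#' scan are dropped, with each fallback and exclusion logged.
#'
#' @param tab Cohort table.
#' @param metric Metric column to difference.
#' @return Data.frame with one row per retained astronaut: `subject_id`,
#'   `delta`, `baseline`, covariate columns; attributes `exclusions` and
#'   `fallbacks` (data.frames logging subject and reason).
#' @export
prepost_delta <- function(tab, metric) {
  stopifnot(is.data.frame(tab), metric %in% names(tab))
  ast <- tab[tab$cohort == "astronaut", ]
  covars <- intersect(c("group", "sans", "age_at_launch_yr", "sex",
                        "mission_duration_d", "days_landing_to_scan_d",
                        "prior_flight_days_d", "prior_missions"), names(ast))
  rows <- list(); excl <- list(); fall <- list()
  for (id in unique(ast$subject_id)) {
    s <- ast[ast$subject_id == id, ]
    val <- function(sess) {
      v <- s[[metric]][s$session == sess]
      if (length(v) == 1L && !is.na(v)) v else NA_real_
    }
    post <- val("R+4")
    pre <- val("L-60")
    if (is.na(pre)) {
      pre <- val("L-180")
      if (!is.na(pre))
        fall[[id]] <- data.frame(subject_id = id,
                                 reason = "L-60 missing; used L-180 baseline")
    }
    if (is.na(post)) {
      excl[[id]] <- data.frame(subject_id = id, reason = "R+4 missing")
    } else if (is.na(pre)) {
      excl[[id]] <- data.frame(subject_id = id, reason = "no baseline scan")
    } else {
      r <- s[1, covars, drop = FALSE]
      r$subject_id <- id
      r$delta <- post - pre
      r$baseline <- pre
      rows[[id]] <- r
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), delta = numeric())
  rownames(out) <- NULL
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(subject_id = character(), reason = character())
  attr(out, "fallbacks") <- if (length(fall)) do.call(rbind, fall) else
    data.frame(subject_id = character(), reason = character())
  out
}

.model_result <- function(fit, outcome, aic_trace = NULL) {
  cf <- summary(fit)$coefficients
  ci <- suppressMessages(confint(fit, level = 0.95))
  tab <- data.frame(predictor = rownames(cf),
                    estimate = cf[, 1], se = cf[, 2],
                    ci_lower = ci[rownames(cf), 1],
                    ci_upper = ci[rownames(cf), 2],
                    t = cf[, 3], p = cf[, 4], row.names = NULL)
  res <- resid(fit)
  shp <- if (length(res) >= 3 && length(res) <= 5000 && var(res) > 0)
    shapiro.test(res)$p.value else NA_real_
  structure(list(outcome = outcome,
                 predictors = attr(stats::terms(fit), "term.labels"),
                 coefficients = tab,
                 r_squared = summary(fit)$r.squared,
                 adj_r_squared = summary(fit)$adj.r.squared,
                 shapiro_p = shp,
                 aic = stats::extractAIC(fit)[2],
                 aic_trace = aic_trace,
                 n = length(res), fit = fit),
            class = "pvs_change_model")
}

#' @export
print.pvs_change_model <- function(x, ...) {
  cat(sprintf("Change model for %s (n = %d)\n", x$outcome, x$n))
  print.data.frame(x$coefficients, digits = 3, row.names = FALSE)
  cat(sprintf("R2 = %.3f / adj R2 = %.3f; Shapiro p = %s; AIC = %.2f\n",
              x$r_squared, x$adj_r_squared,
              format(x$shapiro_p, digits = 3), x$aic))
  invisible(x)
}

#' Linear model for pre- to post-flight change
#'
#' With no predictors this is the intercept-only least-squares fit, whose
#' intercept t-test is exactly the one-sample t-test of the mean change;
#' with predictors it is the full covariate model. Continuous covariates
#' are used as given (mean-centre upstream if desired). Residual normality
#' (Shapiro) is reported alongside, and the model errors on rank-deficient
#' designs, naming the collinear columns.
#'
#' @param delta Data.frame from [prepost_delta()] (or any data.frame with
#'   an outcome column).
#' @param predictors Character vector of predictor column names (possibly
#'   empty).
#' @param outcome Outcome column name (default `"delta"`).
#' @return A `pvs_change_model` (see [print.pvs_change_model()]): contains
#'   the coefficient table (estimate, SE, 95% CI, t, p), R2/adjusted R2,
#'   Shapiro p, AIC (Gaussian `n log(RSS/n) + 2p` form) and the `lm` fit.
#' @export
fit_change_model <- function(delta, predictors = character(),
                             outcome = "delta") {
  stopifnot(is.data.frame(delta), outcome %in% names(delta),
            all(predictors %in% names(delta)))
  dat <- delta[, c(outcome, predictors), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < length(predictors) + 3L)  # parameters (incl. intercept) + 2
    stop("need n >= number of parameters + 2", call. = FALSE)
  fml <- if (length(predictors))
    as.formula(paste(outcome, "~", paste(predictors, collapse = " + ")))
  else as.formula(paste(outcome, "~ 1"))
  fit <- lm(fml, data = dat)
  if (anyNA(coef(fit)))
    stop("rank-deficient design; collinear terms: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  .model_result(fit, outcome)
}

#' Stepwise AIC covariate selection
#'
#' Starting from the full covariate model, searches both directions
#' (dropping and re-adding terms, intercept always retained) for the model
#' minimising the Gaussian least-squares AIC `n log(RSS/n) + 2p`, the form
#' `stats::step`/`stepAIC` use for `lm` fits. Ties favour the smaller
#' model. Returns the final model together with the visited-model AIC
#' trace.
#'
#' @inheritParams fit_change_model
#' @return A `pvs_change_model` whose `predictors` are the selected terms
#'   and whose `aic_trace` is the step-history data.frame.
#' @export
stepwise_aic <- function(delta, predictors, outcome = "delta") {
  stopifnot(length(predictors) >= 1L)
  dat <- delta[, c(outcome, predictors), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < length(predictors) + 3L)
    stop("need n >= number of parameters + 2", call. = FALSE)
  full <- lm(as.formula(paste(outcome, "~",
                              paste(predictors, collapse = " + "))),
             data = dat)
  if (anyNA(coef(full)))
    stop("rank-deficient design; collinear terms: ",
         paste(names(coef(full))[is.na(coef(full))], collapse = ", "),
         call. = FALSE)
  sel <- step(full, direction = "both", trace = 0,
              scope = list(lower = as.formula(paste(outcome, "~ 1")),
                           upper = stats::formula(full)))
  trace <- sel$anova
  .model_result(sel, outcome, aic_trace = trace)
}

#' Prior-experience correlations with baseline PVS load
#'
#' Within the experienced subgroup, correlates total previous days spent
#' in space with the average pre-flight value of a metric (mean of the two
#' baselines; a single available baseline is used as-is and logged).
#' Reports the Pearson r with df = n - 2 and p, and the partial
#' correlation controlling age at launch via residual-on-residual
#' correlation (df = n - 3). Following the reduced-model-first plan, a
#' stepwise full model adding sex and mean-centred age is fitted only when
#' the reduced linear relationship is significant at 0.05.
#'
#' @param tab Cohort table.
#' @param metric Metric column.
#' @return List of class `pvs_experience_cor`: `r`, `df`, `p`,
#'   `partial_r`, `partial_p`, `n`, `full_model` (a `pvs_change_model` or
#'   `NULL`), `notes`.
#' @export
experience_correlations <- function(tab, metric) {
  stopifnot(metric %in% names(tab))
  exp_tab <- tab[tab$cohort == "astronaut" & !is.na(tab$group) &
                   tab$group == "experienced", ]
  notes <- character()
  ids <- unique(exp_tab$subject_id)
  if (length(ids) < 3L) stop("need >= 3 experienced subjects", call. = FALSE)
  base <- vapply(ids, function(id) {
    v <- exp_tab[[metric]][exp_tab$subject_id == id &
                             exp_tab$session %in% c("L-180", "L-60")]
    v <- v[!is.na(v)]
    if (length(v) == 1L)
      notes <<- c(notes, paste0(id, ": single baseline used as average"))
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  x <- vapply(ids, function(id)
    exp_tab$prior_flight_days_d[exp_tab$subject_id == id][1], numeric(1))
  age <- vapply(ids, function(id)
    exp_tab$age_at_launch_yr[exp_tab$subject_id == id][1], numeric(1))
  ok <- !is.na(base) & !is.na(x)
  base <- base[ok]; x <- x[ok]; age <- age[ok]
  n <- length(base)
  ct <- cor.test(x, base)
  ## partial r controlling age: correlate the residuals of each variable on age
  pr <- pp <- NA_real_
  tol <- 1e-10 * (sd(base) + sd(x) + 1)
  if (var(age) > 0 && sd(resid(lm(base ~ age))) > tol &&
      sd(resid(lm(x ~ age))) > tol) {
    pr <- cor(resid(lm(base ~ age)), resid(lm(x ~ age)))
    dfp <- n - 3
    tstat <- pr * sqrt(dfp / (1 - pr^2))
    pp <- 2 * pt(-abs(tstat), dfp)
  } else notes <- c(notes, "partial correlation degenerate (zero variance)")
  full <- NULL
  if (!is.na(ct$p.value) && ct$p.value < 0.05 && n >= 5) {
    dat <- data.frame(baseline = base, prior_flight_days = x,
                      sex = vapply(ids[ok], function(id)
                        exp_tab$sex[exp_tab$subject_id == id][1],
                        character(1)),
                      age_c = age - mean(age))
    full <- stepwise_aic(dat, c("prior_flight_days", "sex", "age_c"),
                         outcome = "baseline")
  }
  structure(list(metric = metric, r = unname(ct$estimate),
                 df = unname(ct$parameter), p = ct$p.value,
                 partial_r = pr, partial_p = pp, n = n,
                 full_model = full, notes = notes),
            class = "pvs_experience_cor")
}

#' @export
print.pvs_experience_cor <- function(x, ...) {
  cat(sprintf("Prior-flight-days vs baseline %s: r(%d) = %.2f, p = %.3f; partial r (age-controlled) = %.2f, p = %.3f (n = %d)\n",
              x$metric, x$df, x$r, x$p, x$partial_r, x$partial_p, x$n))
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

#' Ventricular-expansion vs PVS-change correlation
#'
#' Correlates each astronaut's pre- to post-flight change in normalized
#' ventricular volume with the change in a PVS metric (whole astronaut
#' cohort). The reduced model (ventricular change as sole predictor) is
#' always reported; a stepwise full model adding sex, mean-centred age,
#' flight duration and landing-to-scan delay is fitted only when the
#' reduced relationship is significant at 0.05.
#'
#' @param tab Cohort table.
#' @param metric PVS metric column to difference.
#' @param vent_metric Ventricular column (default the normalized one).
#' @return List of class `pvs_vent_cor`: `r`, `df`, `p`, `n`,
#'   `full_model` (or `NULL`).
#' @export
ventricle_correlations <- function(tab, metric,
                                   vent_metric = "norm_ventricular_volume") {
  dm <- prepost_delta(tab, metric)
  dv <- prepost_delta(tab, vent_metric)
  merged <- merge(dm[, c("subject_id", "delta")],
                  dv[, c("subject_id", "delta")], by = "subject_id",
                  suffixes = c("_pvs", "_vent"))
  n <- nrow(merged)
  if (n < 3L) stop("need >= 3 astronauts with both changes", call. = FALSE)
  ct <- cor.test(merged$delta_vent, merged$delta_pvs)
  full <- NULL
  if (!is.na(ct$p.value) && ct$p.value < 0.05 && n >= 6) {
    dat <- merge(merged, dm[, setdiff(names(dm), "delta")], by = "subject_id")
    dat$age_c <- dat$age_at_launch_yr - mean(dat$age_at_launch_yr)
    dat$duration_c <- dat$mission_duration_d - mean(dat$mission_duration_d)
    dat$scan_delay_c <- dat$days_landing_to_scan_d -
      mean(dat$days_landing_to_scan_d)
    full <- stepwise_aic(dat, c("delta_vent", "sex", "age_c", "duration_c",
                                "scan_delay_c"), outcome = "delta_pvs")
  }
  structure(list(metric = metric, r = unname(ct$estimate),
                 df = unname(ct$parameter), p = ct$p.value, n = n,
                 full_model = full),
            class = "pvs_vent_cor")
}

#' @export
print.pvs_vent_cor <- function(x, ...) {
  cat(sprintf("Ventricular change vs change in %s: r(%d) = %.2f, p = %.3f (n = %d)\n",
              x$metric, x$df, x$r, x$p, x$n))
  invisible(x)
}

#' Demographic group contrasts
#'
#' Welch two-sample t-tests for continuous covariates and a Pearson
#' chi-square test (no continuity correction) for the sex distribution,
#' comparing novice vs experienced astronauts (and, when controls are
#' present, astronauts vs controls on age and sex).
#'
#' @param tab Cohort table.
#' @return Data.frame of class `pvs_demographics` with one row per
#'   contrast: `comparison`, `variable`, `statistic` (t or X-squared),
#'   `df`, `p`.
#' @export
group_contrasts <- function(tab) {
  subj <- tab[!duplicated(tab$subject_id), ]
  ast <- subj[subj$cohort == "astronaut", ]
  if (length(unique(ast$group[!is.na(ast$group)])) != 2L ||
      min(table(ast$group)) < 2L)
    stop("need two astronaut groups with >= 2 subjects each", call. = FALSE)
  welch <- function(df, var, by, comparison) {
    tt <- tryCatch(t.test(as.formula(paste(var, "~", by)), data = df),
                   error = function(e) NULL)  # constant data -> undefined t
    data.frame(comparison = comparison, variable = var,
               statistic = if (is.null(tt)) NA_real_ else
                 unname(tt$statistic),
               df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
               p = if (is.null(tt)) NA_real_ else tt$p.value)
  }
  chisq <- function(df, by, comparison) {
    cs <- suppressWarnings(chisq.test(table(df[[by]], df$sex),
                                      correct = FALSE))
    data.frame(comparison = comparison, variable = "sex",
               statistic = unname(cs$statistic), df = unname(cs$parameter),
               p = cs$p.value)
  }
  out <- rbind(
    welch(ast, "age_at_launch_yr", "group", "novice_vs_experienced"),
    welch(ast, "mission_duration_d", "group", "novice_vs_experienced"),
    welch(ast, "days_landing_to_scan_d", "group", "novice_vs_experienced"),
    chisq(ast, "group", "novice_vs_experienced"))
  if (any(subj$cohort == "control")) {
    out <- rbind(out,
                 welch(subj, "age_at_launch_yr", "cohort",
                       "astronaut_vs_control"),
                 chisq(subj, "cohort", "astronaut_vs_control"))
  }
  class(out) <- c("pvs_demographics", class(out))
  out
}

#' SANS subgroup contrast on pre- to post-flight change
#'
#' Re-runs the change-model machinery with SANS status (ocular findings
#' after flight: yes/no) replacing novice-vs-experienced status as the
#' predictor of interest. Astronauts with unknown SANS status are excluded
#' and counted.
#'
#' @param tab Cohort table with a `sans` column
#'   (`"SANS"`/`"no-SANS"`/`"unknown"` or `NA`).
#' @param metric Metric column.
#' @param stepwise Also run stepwise selection over SANS + covariates?
#' @return List of class `pvs_sans_contrast`: `model` (delta ~ sans),
#'   `stepwise` (or `NULL`), `n_excluded_unknown`, `n`.
#' @export
run_sans_contrast <- function(tab, metric, stepwise = FALSE) {
  stopifnot("sans" %in% names(tab))
  d <- prepost_delta(tab, metric)
  known <- !is.na(d$sans) & d$sans %in% c("SANS", "no-SANS")
  n_excl <- sum(!known)
  d <- d[known, , drop = FALSE]
  if (length(unique(d$sans)) < 2L || min(table(d$sans)) < 2L)
    stop("need >= 2 subjects per SANS level", call. = FALSE)
  model <- fit_change_model(d, "sans")
  sw <- NULL
  if (stepwise) {
    d$age_c <- d$age_at_launch_yr - mean(d$age_at_launch_yr)
    d$duration_c <- d$mission_duration_d - mean(d$mission_duration_d)
    d$scan_delay_c <- d$days_landing_to_scan_d -
      mean(d$days_landing_to_scan_d)
    sw <- stepwise_aic(d, c("sans", "sex", "age_c", "duration_c",
                            "scan_delay_c"))
  }
  structure(list(metric = metric, model = model, stepwise = sw,
                 n_excluded_unknown = n_excl, n = nrow(d)),
            class = "pvs_sans_contrast")
}

#' @export
print.pvs_sans_contrast <- function(x, ...) {
  cat(sprintf("SANS contrast on change in %s (n = %d; %d excluded with unknown status)\n",
              x$metric, x$n, x$n_excluded_unknown))
  print(x$model)
  invisible(x)
}

#' Full cohort analysis: gating, change models, correlations, contrasts
#'
#' Runs the complete statistics pipeline on a cohort table: (1)
#' reliability gating of the five PVS metrics and ventricular volume; (2)
#' for each retained metric, the whole-group intercept-only change model
#' and a stepwise covariate model over sex, mean-centred age, flight
#' duration, landing-to-scan delay and novice-vs-experienced status —
#' totals and ventricular volume modelled on their normalized scales; (3)
#' prior-experience correlations; (4) demographic contrasts; (5) the SANS
#' subgroup contrast when labels are available. No multiple-comparison
#' correction is applied; all raw p values and CIs are reported.
#'
#' @param tab Cohort table.
#' @return List of class `pvs_cohort_analysis` with elements
#'   `reliability`, `change_models` (per retained metric: `whole_group`
#'   and `stepwise` models on the modelled column), `experience`,
#'   `demographics`, `sans`, `exclusion_log`.
#' @export
analyze_cohort <- function(tab) {
  rel <- reliability_report(tab)
  model_col <- c(total_pvs_volume_mm3 = "norm_total_pvs_volume",
                 total_pvs_number = "norm_total_pvs_number",
                 median_pvs_volume_mm3 = "median_pvs_volume_mm3",
                 median_pvs_length_mm = "median_pvs_length_mm",
                 median_pvs_width_mm = "median_pvs_width_mm",
                 ventricular_volume_mL = "norm_ventricular_volume")
  retained <- rel$metric[rel$retained]
  excl_log <- list()
  change_models <- list()
  for (m in retained) {
    col <- model_col[[m]]
    d <- prepost_delta(tab, col)
    excl_log[[col]] <- attr(d, "exclusions")
    d$age_c <- d$age_at_launch_yr - mean(d$age_at_launch_yr)
    d$duration_c <- d$mission_duration_d - mean(d$mission_duration_d)
    d$scan_delay_c <- d$days_landing_to_scan_d -
      mean(d$days_landing_to_scan_d)
    change_models[[col]] <- list(
      whole_group = fit_change_model(d),
      stepwise = stepwise_aic(d, c("sex", "age_c", "duration_c",
                                   "scan_delay_c", "group")))
  }
  experience <- lapply(setNames(nm = intersect(
    c("norm_total_pvs_volume", "norm_total_pvs_number",
      "median_pvs_volume_mm3", "median_pvs_length_mm",
      "norm_ventricular_volume"), model_col[retained])), function(col)
        experience_correlations(tab, col))
  sans <- NULL
  if ("sans" %in% names(tab) &&
      length(retained) > 0 &&
      sum(tab$sans %in% c("SANS", "no-SANS") &
            !duplicated(tab$subject_id)) >= 4) {
    sans <- tryCatch(
      lapply(setNames(nm = unname(model_col[retained])), function(col)
        run_sans_contrast(tab, col)),
      error = function(e) NULL)
  }
  structure(list(reliability = rel, change_models = change_models,
                 experience = experience,
                 demographics = group_contrasts(tab),
                 sans = sans, exclusion_log = excl_log),
            class = "pvs_cohort_analysis")
}

#' @export
print.pvs_cohort_analysis <- function(x, ...) {
  print(x$reliability)
  for (m in names(x$change_models)) {
    cat("\n--", m, "--\n")
    print(x$change_models[[m]]$stepwise)
  }
  invisible(x)
}
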
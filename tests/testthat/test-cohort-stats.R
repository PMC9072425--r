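test_that("ICC(3,k) equals the sums-of-squares oracle on random tables", {
  set.seed(51)
  for (n in c(4, 7, 10)) {
    for (k in c(2, 3, 6)) {
      wide <- matrix(rnorm(n * k, 10, 3), n, k) + rnorm(n, 0, 2)
      expect_equal(icc3k(wide)$icc3k, oracle_icc3k(wide), tolerance = 1e-10,
                   info = sprintf("n=%d k=%d", n, k))
    }
  }
  ## constructed integer table, hand-checkable
  wide <- cbind(c(9, 6, 8, 7), c(10, 6, 9, 8))
  expect_equal(icc3k(wide)$icc3k, oracle_icc3k(wide), tolerance = 1e-12)
})

test_that("ICC(3,k) is 1 for perfect repeats and ~0 under exchange of pure noise", {
  wide <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  r <- icc3k(wide)
  expect_equal(r$icc3k, 1)
  expect_true(r$retained)
  set.seed(52)
  null_wide <- matrix(rnorm(200 * 2), 200, 2)
  expect_lt(abs(icc3k(null_wide)$icc3k), 0.1)
  ## degenerate: no variance at all -> undefined
  expect_true(is.na(icc3k(matrix(5, 3, 2))$icc3k))
  expect_error(icc3k(matrix(1, 1, 2)), ">= 2")
})

test_that("pre/post delta uses R+4 minus L-60 with single-baseline fallback", {
  tab <- rbind(
    make_cohort_rows("A1", "astronaut", "novice",
                     c("L-180", "L-60", "R+4"), c(1.9, 2.0, 2.5)),
    make_cohort_rows("A2", "astronaut", "novice",
                     c("L-180", "R+4"), c(1.8, 2.0)),
    make_cohort_rows("A3", "astronaut", "experienced",
                     c("L-180", "L-60"), c(1.0, 1.1)))
  d <- prepost_delta(tab, "value")
  expect_equal(d$delta[d$subject_id == "A1"], 0.5)
  expect_equal(d$delta[d$subject_id == "A2"], 0.2)  # L-180 fallback
  expect_false("A3" %in% d$subject_id)              # no R+4 scan
  expect_equal(attr(d, "exclusions")$subject_id, "A3")
  expect_equal(attr(d, "fallbacks")$subject_id, "A2")
})

test_that("the intercept-only change model is exactly the one-sample t-test", {
  set.seed(53)
  d <- data.frame(delta = rnorm(15, 0.3, 0.5))
  m <- fit_change_model(d)
  tt <- t.test(d$delta)
  cf <- m$coefficients
  expect_equal(cf$estimate, mean(d$delta))
  expect_equal(cf$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(cf$p, tt$p.value, tolerance = 1e-12)
  expect_equal(c(cf$ci_lower, cf$ci_upper), unname(tt$conf.int),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("degenerate and orthogonal predictor cases behave as documented", {
  ## zero-variance outcome: intercept is the value, SE collapses to 0
  m0 <- fit_change_model(data.frame(delta = c(1, 1, 1, 1)))
  expect_equal(m0$coefficients$estimate, 1)
  expect_equal(m0$coefficients$se, 0)
  ## predictor orthogonal to the outcome: coefficient ~0, intercept = mean
  d <- data.frame(delta = rep(c(-1, 1), 10), x = rep(c(1, 1, -1, -1), 5))
  m <- fit_change_model(d, "x")
  expect_equal(m$coefficients$estimate[m$coefficients$predictor == "x"], 0,
               tolerance = 1e-12)
  expect_equal(m$coefficients$estimate[1], mean(d$delta), tolerance = 1e-12)
  ## rank deficiency is reported with the collinear column
  d$y <- d$x
  expect_error(fit_change_model(d, c("x", "y")), "collinear")
  expect_error(fit_change_model(data.frame(delta = 1:3), "delta"
                                [0]), NA)
  expect_error(fit_change_model(data.frame(delta = 1:2), c()), "n >=")
})

test_that("stepwise AIC minimises the Gaussian least-squares criterion", {
  ## formula identity on a fixed 5-point dataset
  d <- data.frame(delta = c(1.2, 0.8, 1.9, 2.4, 3.1), x = 1:5)
  fit <- lm(delta ~ x, data = d)
  rss <- sum(resid(fit)^2)
  expect_equal(stats::extractAIC(fit)[2], 5 * log(rss / 5) + 2 * 2,
               tolerance = 1e-12)
  m <- fit_change_model(d, "x")
  expect_equal(m$aic, 5 * log(rss / 5) + 2 * 2, tolerance = 1e-12)

  ## a strong true predictor among noise covariates is retained
  set.seed(54)
  n <- 100
  dat <- data.frame(x = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                    n3 = rnorm(n), n4 = rnorm(n))
  dat$delta <- 2 * dat$x + rnorm(n)
  sw <- stepwise_aic(dat, c("x", "n1", "n2", "n3", "n4"))
  expect_true("x" %in% sw$predictors)
  expect_false(is.null(sw$aic_trace))

  ## the selected model is never worse than full or intercept-only
  for (seed in 55:59) {
    set.seed(seed)
    dd <- data.frame(delta = rnorm(20), a = rnorm(20), b = rnorm(20),
                     c = rnorm(20))
    sel <- stepwise_aic(dd, c("a", "b", "c"))
    aic_full <- fit_change_model(dd, c("a", "b", "c"))$aic
    aic_null <- fit_change_model(dd)$aic
    expect_lte(sel$aic, aic_full + 1e-9)
    expect_lte(sel$aic, aic_null + 1e-9)
  }
})

test_that("all-noise covariates are mostly rejected by stepwise selection", {
  set.seed(60)
  n_int_only <- 0L
  reps <- 60
  for (r in seq_len(reps)) {
    dd <- data.frame(delta = rnorm(30), a = rnorm(30), b = rnorm(30),
                     c = rnorm(30), e = rnorm(30))
    sel <- stepwise_aic(dd, c("a", "b", "c", "e"))
    if (length(sel$predictors) == 0L) n_int_only <- n_int_only + 1L
  }
  expect_gt(n_int_only / reps, 0.5)
})

test_that("experience correlations report Pearson and age-partialled effects", {
  ## perfectly linear relation -> r = 1
  mk <- function(days, base, age, n_id = seq_along(days)) {
    do.call(rbind, lapply(seq_along(days), function(i)
      make_cohort_rows(paste0("E", n_id[i]), "astronaut", "experienced",
                       c("L-180", "L-60"), c(base[i], base[i]),
                       age = age[i], prior_days = days[i])))
  }
  tab <- mk(days = c(100, 200, 300, 400), base = c(1, 2, 3, 4),
            age = c(40, 50, 45, 55))
  ec <- experience_correlations(tab, "value")
  expect_equal(ec$r, 1, tolerance = 1e-12)
  expect_equal(ec$df, 2)
  ## independent x and y: small correlation at large n
  set.seed(61)
  tab0 <- mk(days = rnorm(1000, 200, 50), base = rnorm(1000),
             age = rnorm(1000, 47, 5))
  ec0 <- experience_correlations(tab0, "value")
  expect_lt(abs(ec0$r), 0.1)
  expect_lt(abs(ec0$partial_r), 0.1)
  ## degenerate control: outcome identical to age -> partial flagged
  tabd <- mk(days = c(100, 200, 300, 400), base = c(40, 50, 45, 55),
             age = c(40, 50, 45, 55))
  ecd <- experience_correlations(tabd, "value")
  expect_true(is.na(ecd$partial_r))
  expect_true(any(grepl("degenerate", ecd$notes)))
})

test_that("demographic contrasts use Welch t and uncorrected chi-square", {
  mksub <- function(id, group, age, sex)
    make_cohort_rows(id, "astronaut", group, "L-60", 1, age = age, sex = sex)
  ## identical groups -> t = 0, p = 1
  tab <- rbind(
    do.call(rbind, lapply(1:4, function(i)
      mksub(paste0("N", i), "novice", 40 + i, c("M", "F")[1 + i %% 2]))),
    do.call(rbind, lapply(1:4, function(i)
      mksub(paste0("E", i), "experienced", 40 + i, c("M", "F")[1 + i %% 2]))))
  tab$mission_duration_d <- 180
  tab$days_landing_to_scan_d <- 4
  gc <- group_contrasts(tab)
  age_row <- gc[gc$variable == "age_at_launch_yr" &
                  gc$comparison == "novice_vs_experienced", ]
  expect_equal(age_row$statistic, 0)
  expect_equal(age_row$p, 1)
  sex_row <- gc[gc$variable == "sex" &
                  gc$comparison == "novice_vs_experienced", ]
  expect_equal(sex_row$statistic, 0, tolerance = 1e-12)
  ## chi-square on a constructed 2x2 equals the closed-form oracle
  counts <- matrix(c(5, 8, 5, 2), 2)  # rows: groups; cols: sex
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  oracle <- sum((counts - expected)^2 / expected)
  cs <- chisq.test(counts, correct = FALSE)
  expect_equal(unname(cs$statistic), oracle, tolerance = 1e-12)
  tab2 <- rbind(
    do.call(rbind, lapply(1:10, function(i)
      mksub(paste0("N", i), "novice", 40 + i, c(rep("M", 5), rep("F", 5))[i]))),
    do.call(rbind, lapply(1:10, function(i)
      mksub(paste0("E", i), "experienced", 40 + i,
            c(rep("M", 8), rep("F", 2))[i]))))
  tab2$mission_duration_d <- rnorm(nrow(tab2), 180, 10)
  tab2$days_landing_to_scan_d <- rnorm(nrow(tab2), 4, 1)
  gc2 <- group_contrasts(tab2)
  expect_equal(gc2$statistic[gc2$variable == "sex" &
                               gc2$comparison == "novice_vs_experienced"],
               oracle, tolerance = 1e-12)
})

test_that("SANS contrasts exclude unknown status and attenuate under permutation", {
  set.seed(62)
  mks <- function(id, sans, delta_eff) {
    base <- rnorm(1, 10, 1)
    make_cohort_rows(id, "astronaut", "novice", c("L-180", "L-60", "R+4"),
                     c(base, base, base + delta_eff + rnorm(1, 0, 0.1)),
                     sans = sans)
  }
  tab <- rbind(
    do.call(rbind, lapply(1:6, function(i) mks(paste0("S", i), "SANS", 1))),
    do.call(rbind, lapply(1:6, function(i) mks(paste0("Q", i), "no-SANS", 0))),
    do.call(rbind, lapply(1:3, function(i) mks(paste0("U", i), "unknown", 0))))
  rs <- run_sans_contrast(tab, "value")
  expect_equal(rs$n_excluded_unknown, 3)
  expect_equal(rs$n, 12)
  cf <- rs$model$coefficients
  eff <- abs(cf$estimate[grepl("sans", cf$predictor)])
  expect_equal(eff, 1, tolerance = 0.2)
  ## permuting the labels attenuates the group coefficient
  atten <- replicate(20, {
    tabp <- tab
    known <- tabp$subject_id[tabp$sans %in% c("SANS", "no-SANS") &
                               !duplicated(tabp$subject_id)]
    perm <- setNames(sample(tabp$sans[match(known, tabp$subject_id)]), known)
    tabp$sans[tabp$subject_id %in% known] <-
      perm[tabp$subject_id[tabp$subject_id %in% known]]
    cfp <- run_sans_contrast(tabp, "value")$model$coefficients
    abs(cfp$estimate[grepl("sans", cfp$predictor)])
  })
  expect_lt(median(atten), eff)
  ## a single-level factor is rejected
  tab1 <- tab[tab$sans == "SANS", ]
  expect_error(run_sans_contrast(tab1, "value"), "SANS level")
})

test_that("gated metrics never reach the change models", {
  tab <- simulate_cohort(cohort_sim_spec(seed = 63))
  ## degrade one metric to pure session noise: ICC ~ 0 in both cohorts
  set.seed(64)
  tab$median_pvs_width_mm <- rnorm(nrow(tab))
  an <- analyze_cohort(tab)
  expect_true("median_pvs_width_mm" %in% attr(an$reliability, "excluded"))
  expect_false("median_pvs_width_mm" %in% names(an$change_models))
  ## retained metrics are modelled on their normalized scale
  expect_true(all(c("norm_total_pvs_volume", "norm_total_pvs_number") %in%
                    names(an$change_models)) ||
                length(an$change_models) >= 1)
})

test_that("confidence intervals agree with estimate +/- t-critical x SE", {
  set.seed(65)
  d <- data.frame(delta = rnorm(12, 1, 2), x = rnorm(12))
  m <- fit_change_model(d, "x")
  cf <- m$coefficients
  tcrit <- qt(0.975, df = 12 - 2)
  expect_equal(cf$ci_lower, cf$estimate - tcrit * cf$se, tolerance = 1e-10)
  expect_equal(cf$ci_upper, cf$estimate + tcrit * cf$se, tolerance = 1e-10)
})
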
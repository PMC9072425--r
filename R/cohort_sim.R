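#' Specification of a simulated longitudinal PVS cohort
#'
#' Describes a metric-level simulation of the study design the statistics
#' layer expects: astronauts scanned at two pre-flight (L-180, L-60) and
#' four post-return (R+4, R+30, R+90, R+180) time points, ground controls
#' at four sessions (C1-C4). Each subject draws a latent baseline per
#' metric; each session observation is baseline + group-specific
#' post-flight shift (applied from the R+4 analog onward, astronauts only)
#' + Gaussian session noise. Controls have no session effects.
#'
#' Default sample sizes (9 novice, 6 experienced, 11 controls), covariate
#' distributions, and the sign and scale of the post-flight shifts follow
#' the spaceflight cohort the machinery is built for: novices gain total
#' PVS volume/number after flight while experienced crewmembers lose a
#' little, and ventricular volume rises in everyone. Baseline means/SDs
#' and session-noise SDs are set so test-retest reliability of the totals
#' is high while median width is borderline, mirroring the reliability
#' structure real cohorts show.
#'
#' @param n_novice,n_experienced,n_control Group sizes.
#' @param baseline Named list of `c(mean, sd)` per metric.
#' @param noise Named list of session-noise SDs per metric.
#' @param effects Named list of `c(novice, experienced)` post-flight
#'   shifts per metric (same units as the metric).
#' @param seed Integer seed; fully determines the table.
#' @return A list of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_novice = 9, n_experienced = 6, n_control = 11,
                            baseline = list(
                              total_pvs_volume_mm3 = c(500, 150),
                              total_pvs_number = c(60, 20),
                              median_pvs_volume_mm3 = c(6, 2),
                              median_pvs_length_mm = c(3.5, 0.8),
                              median_pvs_width_mm = c(1.5, 0.3),
                              ventricular_volume_mL = c(25, 8)),
                            noise = list(
                              total_pvs_volume_mm3 = 30,
                              total_pvs_number = 4,
                              median_pvs_volume_mm3 = 2,
                              median_pvs_length_mm = 0.95,
                              median_pvs_width_mm = 0.45,
                              ventricular_volume_mL = 0.3),
                            effects = list(
                              total_pvs_volume_mm3 = c(novice = 29,
                                                       experienced = -48),
                              total_pvs_number = c(novice = 1.4,
                                                   experienced = -4.8),
                              median_pvs_volume_mm3 = c(novice = 0.7,
                                                        experienced = 0.3),
                              median_pvs_length_mm = c(novice = 0.18,
                                                       experienced = 0.19),
                              median_pvs_width_mm = c(novice = 0,
                                                      experienced = 0),
                              ventricular_volume_mL = c(novice = 1.7,
                                                        experienced = 2)),
                            seed = 1L) {
  stopifnot(n_novice >= 0, n_experienced >= 0, n_control >= 0)
  mets <- names(baseline)
  stopifnot(identical(mets, names(noise)), identical(mets, names(effects)))
  for (m in mets) {
    stopifnot(length(baseline[[m]]) == 2L, baseline[[m]][2] >= 0,
              noise[[m]] >= 0, length(effects[[m]]) == 2L)
  }
  structure(list(n_novice = n_novice, n_experienced = n_experienced,
                 n_control = n_control, baseline = baseline, noise = noise,
                 effects = effects, seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

#' Simulate a longitudinal cohort table
#'
#' Generates the per-subject-session metric table described by a
#' [cohort_sim_spec()], including demographics/covariates (age at launch,
#' sex, mission duration, landing-to-scan delay, prior flight history,
#' SANS status for astronauts) and white-matter / intracranial volumes
#' used as normalization denominators. Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_sim_spec()].
#' @return A `data.frame` cohort table, one row per subject-session, with
#'   columns `subject_id`, `cohort`, `group`, `sans`, `session`, the
#'   metric columns of `spec$baseline`, `wm_volume_cm3`, `tiv_mL`, and
#'   covariates `age_at_launch_yr`, `sex`, `mission_duration_d`,
#'   `days_landing_to_scan_d`, `prior_flight_days_d`, `prior_missions`.
#' @export
simulate_cohort <- function(spec = cohort_sim_spec()) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(spec$seed)
  astro_sessions <- c("L-180", "L-60", "R+4", "R+30", "R+90", "R+180")
  post <- c("R+4", "R+30", "R+90", "R+180")
  ctrl_sessions <- paste0("C", 1:4)
  mets <- names(spec$baseline)

  n_ast <- spec$n_novice + spec$n_experienced
  subjects <- data.frame(
    subject_id = c(sprintf("A%02d", seq_len(n_ast)),
                   sprintf("C%02d", seq_len(spec$n_control))),
    cohort = c(rep("astronaut", n_ast), rep("control", spec$n_control)),
    group = c(rep("novice", spec$n_novice),
              rep("experienced", spec$n_experienced),
              rep(NA_character_, spec$n_control)),
    stringsAsFactors = FALSE)

  ## covariates (astronauts; controls get age/sex only)
  subjects$age_at_launch_yr <- round(ifelse(
    is.na(subjects$group), rnorm(nrow(subjects), 42.3, 10.6),
    ifelse(subjects$group == "novice", rnorm(nrow(subjects), 44.0, 4.9),
           rnorm(nrow(subjects), 52.7, 4.2))), 1)
  subjects$sex <- ifelse(runif(nrow(subjects)) < 0.27, "F", "M")
  subjects$mission_duration_d <- ifelse(
    subjects$cohort == "astronaut",
    round(ifelse(subjects$group == "novice", rnorm(nrow(subjects), 167, 31),
                 rnorm(nrow(subjects), 226, 71))), NA)
  subjects$days_landing_to_scan_d <- ifelse(
    subjects$cohort == "astronaut",
    pmax(1, round(rnorm(nrow(subjects), 4.5, 1.1))), NA)
  subjects$prior_missions <- ifelse(
    subjects$cohort == "astronaut" & subjects$group == "experienced",
    pmax(1, rpois(nrow(subjects), 2)), 0)
  subjects$prior_missions[subjects$cohort == "control"] <- NA
  subjects$prior_flight_days_d <- ifelse(
    subjects$cohort == "astronaut",
    ifelse(subjects$group == "experienced",
           round(pmax(10, rnorm(nrow(subjects), 187.5, 151.7))), 0), NA)
  ## SANS known for 12 of 15 astronauts (6 SANS / 6 no-SANS), unknown else
  sans <- rep(NA_character_, nrow(subjects))
  if (n_ast >= 3) {
    lab <- rep(c("SANS", "no-SANS"), length.out = n_ast - 3)
    sans[seq_len(n_ast)] <- c(sample(lab), rep("unknown", 3))
  }
  subjects$sans <- sans

  ## normalization denominators: stable within subject
  subjects$wm_volume_cm3 <- rnorm(nrow(subjects), 480, 40)
  subjects$tiv_mL <- rnorm(nrow(subjects), 1500, 120)

  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    s <- subjects[i, ]
    sess <- if (s$cohort == "astronaut") astro_sessions else ctrl_sessions
    base <- vapply(mets, function(m)
      rnorm(1, spec$baseline[[m]][1], spec$baseline[[m]][2]), numeric(1))
    out <- s[rep(1, length(sess)), ]
    out$session <- sess
    for (m in mets) {
      eff <- if (s$cohort == "astronaut" && !is.na(s$group))
        ifelse(sess %in% post, spec$effects[[m]][[s$group]], 0) else 0
      out[[m]] <- base[[m]] + eff + rnorm(length(sess), 0, spec$noise[[m]])
    }
    out
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$wm_volume_cm3 <- tab$wm_volume_cm3 +
    rnorm(nrow(tab), 0, 2)  # small scan-to-scan segmentation noise
  ## normalized metrics against the subject's average pre-flight denominators
  tab <- add_normalized_columns(tab)
  attr(tab, "sim_spec") <- spec
  tab
}

#' Add normalized metric columns to a cohort table
#'
#' Computes `norm_total_pvs_volume` (mm^3 per cm^3 of the subject's average
#' pre-flight white matter), `norm_total_pvs_number` (count per cm^3) and
#' `norm_ventricular_volume` (mL per mL of average baseline TIV) for every
#' row, using each subject's pre-flight (astronauts: L-180/L-60; controls:
#' first session) denominators.
#'
#' @param tab A cohort table (see [simulate_cohort()] for the schema); the
#'   total-volume column may be `total_pvs_volume_mm3` or
#'   `total_pvs_volume_mL`.
#' @return The table with the three normalized columns added.
#' @export
add_normalized_columns <- function(tab) {
  stopifnot(is.data.frame(tab))
  vol_mm3 <- if ("total_pvs_volume_mm3" %in% names(tab))
    tab$total_pvs_volume_mm3 else tab$total_pvs_volume_mL * 1000
  pre <- tab$session %in% c("L-180", "L-60") |
    (tab$cohort == "control" & tab$session == "C1")
  base_wm <- tapply(tab$wm_volume_cm3[pre], tab$subject_id[pre], mean)
  base_tiv <- tapply(tab$tiv_mL[pre], tab$subject_id[pre], mean)
  wm0 <- as.numeric(base_wm[tab$subject_id])
  tiv0 <- as.numeric(base_tiv[tab$subject_id])
  tab$norm_total_pvs_volume <- vol_mm3 / wm0
  tab$norm_total_pvs_number <- tab$total_pvs_number / wm0
  tab$norm_ventricular_volume <- tab$ventricular_volume_mL / tiv0
  tab
}

#' Simulate a small image-level longitudinal cohort
#'
#' Renders, per subject, one fixed random phantom at two sessions that
#' differ only in the scanner-noise realisation — an image-level analog of
#' a test-retest pair, used for end-to-end smoke tests and reliability
#' checks of the full detection pipeline.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @param dim Phantom grid size.
#' @param n_tubules_lambda Poisson mean of the per-subject tubule count
#'   (minimum 1).
#' @param noise_sd Rendering noise SD.
#' @return List of subjects; each has `truth` (a [phantom_truth()]) and
#'   `sessions`, a list of two rendered bundles (see [render_phantom()]).
#' @export
simulate_image_cohort <- function(n_subjects = 6, seed = 1L,
                                  dim = c(48, 48, 48),
                                  n_tubules_lambda = 4, noise_sd = 2) {
  set.seed(seed)
  sub_seeds <- sample.int(1e6, n_subjects * 3)
  lapply(seq_len(n_subjects), function(i) {
    ## cap the count so well-separated placement stays feasible in the box
    n_tub <- min(max(1, rpois(1, n_tubules_lambda)), 6)
    gt <- random_phantom(sub_seeds[i], n_tubules = n_tub, dim = dim,
                         noise_sd = noise_sd, min_separation_mm = 3)
    sessions <- lapply(1:2, function(s) {
      gt_s <- gt
      gt_s$seed <- sub_seeds[n_subjects * s + i]
      render_phantom(gt_s)
    })
    list(subject_id = sprintf("S%02d", i), truth = gt, sessions = sessions)
  })
}
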
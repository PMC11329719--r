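#' Fit per-cluster longitudinal trajectories with a random-intercept model
#'
#' Restricted-maximum-likelihood fit of
#' `outcome ~ time * cluster * age_c + (1 | subject)` where `age_c` is
#' baseline age centered at the sample mean and time is in years from
#' baseline. The omnibus test of differential progression is a likelihood
#' ratio test (maximum-likelihood refits) of all fixed terms involving the
#' time-by-cluster interaction. Per-cluster slopes at the mean age and their
#' Tukey-adjusted pairwise contrasts come from the fitted model.
#'
#' @param visits visit table (`subject_id`, `time`, plus the outcome column).
#' @param labels named cluster labels over subjects (or `cluster_solution`);
#'   subjects with `NA` labels are dropped.
#' @param outcome outcome column name (e.g. `"updrs3"` or `"moca"`).
#' @param subjects subject table providing baseline `age`.
#' @param min_subjects_per_cluster clusters with fewer longitudinal subjects
#'   are excluded with a warning (default 5).
#' @return A `trajectory_fit`: list with `model` (lmerMod), `outcome`,
#'   `omnibus` (`statistic`, `df`, `p`), `slopes` (per-cluster estimate and
#'   SE), `slope_contrasts` (Tukey-adjusted pairs), `converged`, `messages`,
#'   `mean_age`, `n_subjects`.
#' @export
fit_trajectory <- function(visits, labels, outcome, subjects,
                           min_subjects_per_cluster = 5) {
  labels <- if (inherits(labels, "cluster_solution")) labels$labels else labels
  labels <- labels[!is.na(labels)]
  dat <- visits[visits$subject_id %in% names(labels), ]
  dat$cluster <- factor(labels[dat$subject_id])
  dat$y <- dat[[outcome]]
  dat <- dat[!is.na(dat$y), ]
  n_per <- tapply(dat$subject_id, dat$cluster,
                  function(s) length(unique(s)))
  drop_cl <- names(n_per)[is.na(n_per) | n_per < min_subjects_per_cluster]
  if (length(drop_cl)) {
    warning("excluding cluster(s) with < ", min_subjects_per_cluster,
            " longitudinal subjects: ", paste(drop_cl, collapse = ", "))
    dat <- dat[!dat$cluster %in% drop_cl, ]
  }
  dat$cluster <- droplevels(dat$cluster)
  if (length(unique(dat$subject_id)) < 30 ||
      max(table(dat$subject_id)) < 2)
    stop("need >= 2 visits for >= 30 subjects")
  age <- subjects$age[match(dat$subject_id, subjects$subject_id)]
  mean_age <- mean(age[!duplicated(dat$subject_id)])
  dat$age_c <- age - mean_age

  one_cluster <- nlevels(dat$cluster) == 1
  form <- if (one_cluster) y ~ time * age_c + (1 | subject_id)
          else y ~ time * cluster * age_c + (1 | subject_id)
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::lmer(form, data = dat, REML = TRUE),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  converged <- !any(grepl("failed to converge|unable to evaluate", msgs))

  # omnibus: LRT on every fixed term containing time:cluster
  omnibus <- list(statistic = NA_real_, df = NA_real_, p = NA_real_)
  if (!one_cluster) {
    refit_quiet <- function(...) withCallingHandlers(
      stats::update(...),
      warning = function(w) invokeRestart("muffleWarning"))
    full_ml <- refit_quiet(fit, REML = FALSE)
    red_ml <- refit_quiet(
      fit, . ~ time * age_c + cluster * age_c + (1 | subject_id),
      REML = FALSE)
    lrt <- stats::anova(red_ml, full_ml)
    omnibus <- list(statistic = lrt$Chisq[2], df = lrt$Df[2],
                    p = lrt[["Pr(>Chisq)"]][2])
  }

  tr <- suppressMessages(
    emmeans::emtrends(fit, if (one_cluster) ~ 1 else ~ cluster,
                      var = "time", at = list(age_c = 0),
                      lmer.df = "asymptotic"))
  slopes <- as.data.frame(tr)
  names(slopes)[names(slopes) == "time.trend"] <- "slope"
  if (one_cluster) slopes$cluster <- levels(dat$cluster)
  contrasts <- if (one_cluster) data.frame()
  else as.data.frame(emmeans::contrast(tr, method = "pairwise",
                                       adjust = "tukey"))
  structure(list(model = fit, outcome = outcome, omnibus = omnibus,
                 slopes = slopes, slope_contrasts = contrasts,
                 converged = converged, messages = msgs,
                 one_cluster = one_cluster, mean_age = mean_age,
                 n_subjects = length(unique(dat$subject_id)),
                 time_range = range(dat$time)),
            class = "trajectory_fit")
}

#' Estimated marginal means per cluster and visit time
#'
#' Model predictions at the sample mean age for each cluster at the requested
#' times, with delta-method standard errors — the quantities plotted as
#' trajectory curves with error bars.
#'
#' @param fit a `trajectory_fit`.
#' @param times numeric vector of times (years from baseline); default
#'   integer years 0..6.
#' @return data.frame with columns `cluster`, `time`, `emmean`, `SE` (plus
#'   asymptotic confidence bounds).
#' @export
marginal_means <- function(fit, times = 0:6) {
  stopifnot(inherits(fit, "trajectory_fit"))
  if (!fit$converged)
    warning("model flagged non-convergence; diagnostics: ",
            paste(fit$messages, collapse = " | "))
  if (min(times) < fit$time_range[1] - 1e-9 ||
      max(times) > fit$time_range[2] + 1e-9)
    warning("requested times extrapolate beyond the fitted range")
  em <- suppressMessages(
    emmeans::emmeans(fit$model,
                     if (isTRUE(fit$one_cluster)) ~ time
                     else ~ cluster | time,
                     at = list(time = times, age_c = 0),
                     lmer.df = "asymptotic"))
  out <- as.data.frame(em)
  if (isTRUE(fit$one_cluster)) out$cluster <- fit$slopes$cluster[1]
  out[, c("cluster", "time", "emmean", "SE", "asymp.LCL", "asymp.UCL")]
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("<trajectory_fit> outcome = %s, %d subjects, converged = %s\n",
              x$outcome, x$n_subjects, x$converged))
  cat(sprintf("omnibus time x cluster: chi2 = %.3f, df = %s, p = %.4g\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p))
  invisible(x)
}
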
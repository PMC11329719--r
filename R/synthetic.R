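#' Specify a planted disease subtype
#'
#' A subtype is defined along two dimensions: *severity* (a multiplicative
#' global atrophy factor applied to every gray-matter feature) and *typicality*
#' (extra atrophy planted in a named set of ROIs at a given standardized effect
#' size). A severity-designed configuration uses distinct `global_scale` values
#' with no regional patterns; a typicality-designed configuration uses matched
#' `global_scale` and distinct `pattern_rois`.
#'
#' @param name subtype label.
#' @param prevalence fraction of PD subjects drawn from this subtype;
#'   prevalences across subtypes must sum to 1.
#' @param global_scale multiplicative atrophy factor on all features
#'   (1 = no atrophy, smaller = more atrophy). Must be positive.
#' @param pattern_rois character vector of ROI names receiving extra regional
#'   atrophy; must be a subset of [all_rois()].
#' @param pattern_effect standardized regional effect size, in units of the
#'   healthy-control ROI standard deviation.
#' @param age_shift years added to the subtype's mean age (couples age with
#'   severity when positive for more atrophic subtypes).
#' @param updrs_slope planted annual change in UPDRS-III (points/year).
#' @param moca_slope planted annual change in MoCA (points/year).
#' @return A `subtype_spec` list.
#' @export
subtype_spec <- function(name, prevalence, global_scale = 1,
                         pattern_rois = character(), pattern_effect = 0,
                         age_shift = 0, updrs_slope = 1, moca_slope = -0.2) {
  stopifnot(is.character(name), length(name) == 1,
            prevalence >= 0, prevalence <= 1)
  if (global_scale <= 0) stop("`global_scale` must be positive")
  unknown <- setdiff(pattern_rois, all_rois())
  if (length(unknown))
    stop("unknown ROI name(s) in `pattern_rois`: ",
         paste(unknown, collapse = ", "))
  structure(list(name = name, prevalence = prevalence,
                 global_scale = global_scale, pattern_rois = pattern_rois,
                 pattern_effect = pattern_effect, age_shift = age_shift,
                 updrs_slope = updrs_slope, moca_slope = moca_slope),
            class = "subtype_spec")
}

#' Specify a simulated cohort
#'
#' @param name cohort label.
#' @param n_pd,n_hc number of PD and healthy-control subjects.
#' @param field_strength_mix fraction of subjects scanned at 3 T (the rest at
#'   1.5 T).
#' @param offset_sd magnitude of the additive per-feature cohort offset, in
#'   units of the healthy-control feature standard deviation.
#' @param has_longitudinal whether the cohort contributes follow-up visits.
#' @param n_visits number of visits (including baseline) for longitudinal
#'   cohorts.
#' @param visit_interval years between consecutive visits.
#' @param duration_mean mean disease duration (years) at baseline.
#' @param medicated_rate fraction of PD subjects on antiparkinsonian
#'   medication.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(name, n_pd, n_hc = 0, field_strength_mix = 1,
                        offset_sd = 0.5, has_longitudinal = FALSE,
                        n_visits = 1, visit_interval = 1,
                        duration_mean = 3, medicated_rate = 0.5) {
  stopifnot(is.character(name), length(name) == 1,
            n_pd >= 0, n_hc >= 0,
            field_strength_mix >= 0, field_strength_mix <= 1,
            offset_sd >= 0, n_visits >= 1)
  if (visit_interval < 0) stop("`visit_interval` must be non-negative")
  structure(list(name = name, n_pd = as.integer(n_pd), n_hc = as.integer(n_hc),
                 field_strength_mix = field_strength_mix,
                 offset_sd = offset_sd, has_longitudinal = has_longitudinal,
                 n_visits = as.integer(n_visits),
                 visit_interval = visit_interval,
                 duration_mean = duration_mean,
                 medicated_rate = medicated_rate),
            class = "cohort_spec")
}

#' Default study-like cohort structure
#'
#' Four cohorts emulating a pooled multi-site PD sample: a large de-novo
#' unmedicated cohort with controls and 6-year follow-up (315 PD / 151 HC), a
#' mild-moderate exercise-trial cohort with controls (75 / 38), a clinical
#' work-up cohort without controls (136 / 0), and an advanced fully medicated
#' cohort with controls and follow-up (107 / 44) — 633 PD and 233 HC in total.
#' Field-strength mixes mirror the per-cohort 1.5 T / 3 T splits of the
#' emulated sample.
#'
#' @return List of [cohort_spec()] objects.
#' @export
study_cohorts <- function() {
  list(
    cohort_spec("DENOVO", n_pd = 315, n_hc = 151,
                field_strength_mix = 215 / 315, offset_sd = 0,
                has_longitudinal = TRUE, n_visits = 7, visit_interval = 1,
                duration_mean = 0.6, medicated_rate = 0),
    cohort_spec("TRIAL", n_pd = 75, n_hc = 38, field_strength_mix = 1,
                offset_sd = 0.5, duration_mean = 4, medicated_rate = 0.97),
    cohort_spec("CLINIC", n_pd = 136, n_hc = 0,
                field_strength_mix = 43 / 136, offset_sd = 0.5,
                duration_mean = 3, medicated_rate = 0.57),
    cohort_spec("ADVANCED", n_pd = 107, n_hc = 44, field_strength_mix = 1,
                offset_sd = 0.5, has_longitudinal = TRUE, n_visits = 7,
                visit_interval = 1, duration_mean = 6, medicated_rate = 1)
  )
}

#' Default planted subtype configurations
#'
#' `severity_subtypes()` plants three subtypes along a global atrophy gradient
#' (scale 1.00 / 0.85 / 0.70, i.e. successive gaps of 0.15) with no regional
#' patterns, age coupled to severity, and progressively steeper motor and
#' cognitive slopes. `typicality_subtypes()` plants three subtypes at matched
#' global atrophy (scale 0.90) distinguished only by regional patterns:
#' cingulate-subcortical, mediotemporal, and parieto-occipital atrophy at 1.5
#' HC standard deviations.
#'
#' @return List of [subtype_spec()] objects.
#' @export
severity_subtypes <- function() {
  list(
    subtype_spec("minimal", prevalence = 0.23, global_scale = 1.00,
                 age_shift = -3, updrs_slope = 1.0, moca_slope = -0.10),
    subtype_spec("intermediate", prevalence = 0.48, global_scale = 0.85,
                 age_shift = 0, updrs_slope = 1.5, moca_slope = -0.25),
    subtype_spec("diffuse", prevalence = 0.29, global_scale = 0.70,
                 age_shift = 4, updrs_slope = 2.5, moca_slope = -0.50)
  )
}

#' @rdname severity_subtypes
#' @export
typicality_subtypes <- function() {
  list(
    subtype_spec("cingulate_subcortical", prevalence = 1 / 3,
                 global_scale = 0.90,
                 pattern_rois = c("rostralanteriorcingulate",
                                  "caudalanteriorcingulate",
                                  "posteriorcingulate", "putamen", "caudate",
                                  "pallidum"),
                 pattern_effect = 1.5, updrs_slope = 2.0, moca_slope = -0.2),
    subtype_spec("mediotemporal", prevalence = 1 / 3, global_scale = 0.90,
                 pattern_rois = c("entorhinal", "parahippocampal",
                                  "temporalpole", "fusiform", "hippocampus",
                                  "amygdala"),
                 pattern_effect = 1.5, updrs_slope = 1.0, moca_slope = -0.2),
    subtype_spec("parietooccipital", prevalence = 1 / 3, global_scale = 0.90,
                 pattern_rois = c("superiorparietal", "inferiorparietal",
                                  "precuneus", "lateraloccipital", "cuneus",
                                  "lingual", "pericalcarine"),
                 pattern_effect = 1.5, updrs_slope = 1.5, moca_slope = -0.6)
  )
}

#' Healthy-control reference distributions for the 41-ROI panel
#'
#' Cortical thickness: mean 2.5 mm, sd 0.15 mm for every Desikan-Killiany ROI.
#' Subcortical volumes (per hemisphere-average, mm^3): plausible adult
#' magnitudes with 10% coefficient of variation. Only the relative structure
#' matters downstream; absolute levels make the head-size and severity
#' normalizations consequential.
#'
#' @return List with named numeric vectors `mean` and `sd` over [all_rois()].
#' @export
hc_reference <- function() {
  vols <- c(thalamus = 7500, caudate = 3700, putamen = 5200, pallidum = 1800,
            hippocampus = 4100, amygdala = 1700, accumbens = 600)
  m <- c(stats::setNames(rep(2.5, 34), dk_cortical_rois()), vols)
  s <- c(stats::setNames(rep(0.15, 34), dk_cortical_rois()), 0.10 * vols)
  list(mean = m[all_rois()], sd = s[all_rois()])
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic multi-cohort PD/HC morphometry dataset
#'
#' Draws a subject table and a 41-feature ROI matrix with planted structure:
#' additive cohort offsets, an additive 1.5 T field-strength offset, volumes
#' linearly coupled to a per-subject intracranial volume (eTIV), a per-subject
#' global scaling factor (biological variation in overall brain size/atrophy),
#' subtype atrophy (global scale and/or regional patterns), age-severity
#' coupling, and a white-matter-hypointensity volume increasing with atrophy
#' burden. Ground truth for every planted component is returned.
#'
#' Feature model, for subject i with total scale `s_i = g_i * global_scale`
#' (`g_i ~ N(1, subject_global_sd)`; HC use `global_scale = 1`):
#' `value = base_r(etiv_i) * s_i - pattern_effect * sd_r * 1[r in pattern]
#'  + fs_offset * sd_r * 1[1.5T] + cohort_offset_r + N(0, noise_sd * sd_r)`
#' where `base_r(etiv) = mu_r + etiv_slope_frac * mu_r / etiv_mean *
#' (etiv - etiv_mean)` for volumes and `mu_r` for thickness.
#'
#' @param cohorts list of [cohort_spec()] objects (at least one).
#' @param subtypes list of [subtype_spec()] objects; prevalences must sum to 1.
#' @param seed integer seed; outputs are byte-identical for identical inputs.
#' @param fs_offset additive 1.5 T offset in feature-sd units (default 0.667,
#'   i.e. +0.1 mm on cortical thickness).
#' @param subject_global_sd sd of the per-subject global scaling factor.
#' @param noise_sd residual noise in feature-sd units.
#' @param etiv_mean,etiv_sd eTIV distribution (mm^3).
#' @param etiv_slope_frac proportional head-size scaling of volumes (0.5 means
#'   a 10% larger head has 5% larger structures).
#' @return List with `subjects` (data.frame), `roi` ([roi_matrix()]) and
#'   `truth` (planted subtype per PD subject, per-cohort offset vectors, field
#'   offset vector, HC reference moments, per-subject global factors).
#' @export
generate_dataset <- function(cohorts, subtypes, seed,
                             fs_offset = 0.667, subject_global_sd = 0.028,
                             noise_sd = 1, etiv_mean = 1.5e6, etiv_sd = 1.5e5,
                             etiv_slope_frac = 0.5) {
  if (missing(seed)) stop("`seed` is required")
  if (!length(cohorts)) stop("at least one cohort is required")
  if (!length(subtypes)) stop("at least one subtype is required")
  if (inherits(cohorts, "cohort_spec")) cohorts <- list(cohorts)
  if (inherits(subtypes, "subtype_spec")) subtypes <- list(subtypes)
  prev <- vapply(subtypes, `[[`, numeric(1), "prevalence")
  if (abs(sum(prev) - 1) > 1e-9)
    stop("subtype prevalences must sum to 1 (got ", sum(prev), ")")
  st_names <- vapply(subtypes, `[[`, character(1), "name")
  names(subtypes) <- st_names

  rois <- all_rois()
  ref <- hc_reference()
  kind <- roi_kind()
  b_vol <- ifelse(kind == "volume", etiv_slope_frac * ref$mean / etiv_mean, 0)

  set.seed(as.integer(seed))
  field_off <- fs_offset * ref$sd  # deterministic planted 1.5T offset

  subj_list <- list()
  roi_list <- list()
  cohort_offsets <- list()
  truth_subtype <- character()
  subject_global <- numeric()

  for (co in cohorts) {
    n <- co$n_pd + co$n_hc
    coh_off <- stats::rnorm(length(rois), 0, co$offset_sd * ref$sd)
    names(coh_off) <- rois
    cohort_offsets[[co$name]] <- coh_off
    if (n == 0) next

    ids <- sprintf("%s_%04d", co$name, seq_len(n))
    group <- c(rep("PD", co$n_pd), rep("HC", co$n_hc))
    # scanner allocation is independent of diagnosis: stratify the 3T/1.5T
    # mix within PD and HC so field strength is not confounded with group
    fs_for <- function(m) {
      n3 <- round(m * co$field_strength_mix)
      sample(c(rep(3.0, n3), rep(1.5, m - n3)))
    }
    fs <- c(fs_for(co$n_pd), fs_for(co$n_hc))
    sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.63, 0.37))
    etiv <- stats::rnorm(n, etiv_mean, etiv_sd)
    g <- stats::rnorm(n, 1, subject_global_sd)

    st <- rep(NA_character_, n)
    if (co$n_pd > 0)
      st[seq_len(co$n_pd)] <- sample(st_names, co$n_pd, replace = TRUE,
                                     prob = prev)
    scale_k <- ifelse(is.na(st), 1,
                      vapply(st, function(s)
                        if (is.na(s)) 1 else subtypes[[s]]$global_scale,
                        numeric(1)))
    shift_k <- ifelse(is.na(st), 0,
                      vapply(st, function(s)
                        if (is.na(s)) 0 else subtypes[[s]]$age_shift,
                        numeric(1)))
    age <- round(clamp(ifelse(group == "PD",
                              stats::rnorm(n, 62, 9) + shift_k,
                              stats::rnorm(n, 65, 9)), 35, 90), 2)

    s_tot <- g * scale_k
    base <- matrix(ref$mean, n, length(rois), byrow = TRUE) +
      outer(etiv - etiv_mean, b_vol)
    pattern <- matrix(0, n, length(rois), dimnames = list(NULL, rois))
    for (k in seq_len(n)) {
      if (!is.na(st[k])) {
        sp <- subtypes[[st[k]]]
        if (length(sp$pattern_rois))
          pattern[k, sp$pattern_rois] <- sp$pattern_effect
      }
    }
    vals <- base * s_tot -
      pattern * matrix(ref$sd, n, length(rois), byrow = TRUE) +
      outer(as.numeric(fs == 1.5), field_off) +
      matrix(coh_off, n, length(rois), byrow = TRUE) +
      matrix(stats::rnorm(n * length(rois)), n) *
        matrix(noise_sd * ref$sd, n, length(rois), byrow = TRUE)
    dimnames(vals) <- list(ids, rois)

    wm_hypo <- stats::rlnorm(n, log(1000), 0.5) * (etiv / etiv_mean) *
      (1 + 3 * pmax(0, 1 - s_tot))
    atrophy <- 1 - scale_k  # severity couples to clinical scores
    dur <- ifelse(group == "PD", round(stats::rexp(n, 1 / co$duration_mean), 2),
                  NA_real_)
    medicated <- ifelse(group == "PD",
                        stats::rbinom(n, 1, co$medicated_rate) == 1, NA)
    hy <- ifelse(group == "PD",
                 sample(c(1, 1.5, 2, 2.5, 3, 4), n, replace = TRUE,
                        prob = c(0.30, 0.01, 0.55, 0.02, 0.10, 0.02)),
                 NA_real_)
    updrs3 <- ifelse(group == "PD",
                     pmax(0, round(stats::rnorm(n, 18, 8) + 25 * atrophy)),
                     NA_real_)
    moca <- round(clamp(ifelse(group == "PD",
                               stats::rnorm(n, 27.5, 2) - 6 * atrophy,
                               stats::rnorm(n, 27.5, 1.5)), 0, 30))
    mci <- ifelse(group == "PD",
                  stats::rbinom(n, 1, stats::plogis(-2.2 + 5 * atrophy)) == 1,
                  stats::rbinom(n, 1, 0.08) == 1)
    depression <- ifelse(group == "PD", stats::rbinom(n, 1, 0.2) == 1, NA)
    rbd <- ifelse(group == "PD", stats::rbinom(n, 1, 0.35) == 1, NA)
    pigd <- ifelse(group == "PD", stats::rbinom(n, 1, 0.27) == 1, NA)

    subj_list[[co$name]] <- data.frame(
      subject_id = ids, group = group, cohort = co$name, field_strength = fs,
      age = age, sex = sex,
      education = round(clamp(stats::rnorm(n, 15, 3), 6, 22)),
      disease_duration = dur, medicated = medicated, hy_stage = hy,
      updrs3 = updrs3, moca = moca, mci = mci, depression = depression,
      rbd = rbd, pigd = pigd, etiv = etiv, wm_hypo = wm_hypo,
      stringsAsFactors = FALSE)
    roi_list[[co$name]] <- vals
    truth_subtype <- c(truth_subtype, stats::setNames(st, ids))
    subject_global <- c(subject_global, stats::setNames(g, ids))
  }

  subjects <- do.call(rbind, c(subj_list, list(make.row.names = FALSE)))
  attr(subjects, "cohorts") <- cohorts
  attr(subjects, "subtype") <- truth_subtype[!is.na(truth_subtype)]
  roi <- roi_matrix(do.call(rbind, roi_list))
  truth <- list(subtype = truth_subtype[!is.na(truth_subtype)],
                cohort_offsets = cohort_offsets, field_offset = field_off,
                hc_mean = ref$mean, hc_sd = ref$sd,
                subject_global = subject_global,
                subtypes = subtypes, seed = as.integer(seed))
  list(subjects = subjects, roi = roi, truth = truth)
}

#' Generate longitudinal motor and cognitive visits
#'
#' For every PD subject belonging to a cohort flagged `has_longitudinal`,
#' draws `n_visits` rows at times `0, interval, 2*interval, ...` with
#' `score = baseline + slope * time + subject_intercept + noise`, where the
#' subject random intercept is `N(0, intercept_sd)` and the noise
#' `N(0, visit_noise_sd)`. UPDRS-III is clipped at 0 from below; MoCA to
#' \[0, 30\]. Attrition is a per-visit dropout probability: once a subject
#' drops, all later visits are missing (monotone missingness).
#'
#' @param subjects subject table from [generate_dataset()] (carries the cohort
#'   specs as an attribute) or any table with `subject_id`, `group`, `cohort`,
#'   `updrs3`, `moca` columns.
#' @param subtypes the subtype list used at generation (provides slopes).
#' @param seed integer seed.
#' @param truth ground-truth list from [generate_dataset()] (provides the
#'   subject-to-subtype map); defaults to matching by the generator's labels.
#' @param dropout per-visit dropout probability after baseline.
#' @param visit_noise_sd residual visit-level noise (score points).
#' @param intercept_sd sd of the subject random intercept (score points).
#' @param cohorts optional list of [cohort_spec()]; defaults to the attribute
#'   stored on `subjects`.
#' @return data.frame with columns `subject_id`, `visit`, `time`, `updrs3`,
#'   `moca`.
#' @export
generate_longitudinal <- function(subjects, subtypes, seed, truth = NULL,
                                  dropout = 0.1, visit_noise_sd = 3,
                                  intercept_sd = 2, cohorts = NULL) {
  if (missing(seed)) stop("`seed` is required")
  if (is.null(cohorts)) cohorts <- attr(subjects, "cohorts")
  if (is.null(cohorts)) stop("cohort specs not found; pass `cohorts`")
  if (inherits(subtypes, "subtype_spec")) subtypes <- list(subtypes)
  names(cohorts) <- vapply(cohorts, `[[`, character(1), "name")
  names(subtypes) <- vapply(subtypes, `[[`, character(1), "name")
  st_map <- if (!is.null(truth)) truth$subtype else attr(subjects, "subtype")
  if (is.null(st_map)) stop("subject-to-subtype map not available; pass `truth`")

  set.seed(as.integer(seed))
  rows <- list()
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    if (s$group != "PD") next
    co <- cohorts[[s$cohort]]
    if (is.null(co) || !isTRUE(co$has_longitudinal)) next
    if (co$visit_interval < 0) stop("negative visit interval")
    sp <- subtypes[[st_map[[s$subject_id]]]]
    nv <- co$n_visits
    times <- (seq_len(nv) - 1) * co$visit_interval
    keep <- nv
    if (dropout > 0 && nv > 1) {
      drops <- stats::rbinom(nv - 1, 1, dropout)
      keep <- if (any(drops == 1)) which(drops == 1)[1] else nv
    }
    b_i <- stats::rnorm(1, 0, intercept_sd)
    up0 <- if (is.na(s$updrs3)) 20 else s$updrs3
    mo0 <- if (is.na(s$moca)) 27 else s$moca
    t_keep <- times[seq_len(keep)]
    up <- pmax(0, up0 + sp$updrs_slope * t_keep + b_i +
                 stats::rnorm(keep, 0, visit_noise_sd))
    mo <- clamp(mo0 + sp$moca_slope * t_keep + b_i +
                  stats::rnorm(keep, 0, visit_noise_sd), 0, 30)
    rows[[s$subject_id]] <- data.frame(
      subject_id = s$subject_id, visit = seq_len(keep), time = t_keep,
      updrs3 = up, moca = mo, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(subject_id = character(), visit = integer(),
                      time = numeric(), updrs3 = numeric(), moca = numeric()))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write a synthetic dataset to disk
#'
#' Subject and visit tables and the ROI matrix are written as UTF-8 CSV with a
#' header row; ground truth as JSON.
#'
#' @param dataset list from [generate_dataset()].
#' @param dir output directory (created if missing).
#' @param visits optional visit table from [generate_longitudinal()].
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir, visits = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(subjects = file.path(dir, "subjects.csv"),
             roi = file.path(dir, "roi_matrix.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(dataset$subjects, paths["subjects"], row.names = FALSE)
  utils::write.csv(data.frame(subject_id = rownames(dataset$roi$values),
                              dataset$roi$values, check.names = FALSE),
                   paths["roi"], row.names = FALSE)
  tr <- dataset$truth
  tr$subtypes <- lapply(tr$subtypes, unclass)
  jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE, digits = NA)
  if (!is.null(visits)) {
    paths["visits"] <- file.path(dir, "visits.csv")
    utils::write.csv(visits, paths["visits"], row.names = FALSE)
  }
  invisible(paths)
}

#' Read a generator configuration from YAML or JSON
#'
#' The file mirrors the fields of [cohort_spec()] and [subtype_spec()] under
#' top-level keys `cohorts` and `subtypes`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return List with elements `cohorts` and `subtypes`.
#' @export
read_generator_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  list(
    cohorts = lapply(cfg$cohorts, function(x) do.call(cohort_spec, x)),
    subtypes = lapply(cfg$subtypes, function(x) {
      x$pattern_rois <- as.character(unlist(x$pattern_rois))
      do.call(subtype_spec, x)
    })
  )
}
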
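small_cohorts <- function() {
  list(cohort_spec("A", 60, 40, field_strength_mix = 0.6, offset_sd = 0.5,
                   has_longitudinal = TRUE, n_visits = 4),
       cohort_spec("B", 60, 30, field_strength_mix = 0.3, offset_sd = 0.5))
}

test_that("generation is deterministic and reproduces the study-scale counts", {
  ds1 <- generate_dataset(small_cohorts(), severity_subtypes(), seed = 7)
  ds2 <- generate_dataset(small_cohorts(), severity_subtypes(), seed = 7)
  expect_identical(ds1$roi$values, ds2$roi$values)
  expect_identical(ds1$subjects, ds2$subjects)
  ds3 <- generate_dataset(small_cohorts(), severity_subtypes(), seed = 8)
  expect_false(identical(ds1$roi$values, ds3$roi$values))

  full <- generate_dataset(study_cohorts(), severity_subtypes(), seed = 1)
  expect_equal(sum(full$subjects$group == "PD"), 633)
  expect_equal(sum(full$subjects$group == "HC"), 233)
  expect_equal(dim(full$roi$values), c(866, 41))
  expect_true(all(full$subjects$etiv > 0))
  expect_true(all(full$subjects$wm_hypo >= 0))
  # every PD subject has exactly one planted label; HC none
  pd <- full$subjects$subject_id[full$subjects$group == "PD"]
  expect_setequal(names(full$truth$subtype), pd)
})

test_that("null configuration leaves PD and HC distributions matched", {
  null_st <- list(subtype_spec("null", 1, global_scale = 1))
  n_sig <- 0L
  n_tot <- 0L
  for (s in 1:20) {
    ds <- generate_dataset(list(cohort_spec("A", 60, 60, offset_sd = 0)),
                           null_st, seed = 100 + s)
    pd <- ds$subjects$group == "PD"
    p <- apply(ds$roi$values, 2, function(col)
      stats::t.test(col[pd], col[!pd])$p.value)
    n_sig <- n_sig + sum(p < 0.01)
    n_tot <- n_tot + length(p)
  }
  expect_gte(1 - n_sig / n_tot, 0.95)
})

test_that("severity gradient yields strictly decreasing mean thickness", {
  st <- list(subtype_spec("a", 1 / 3, global_scale = 1.0),
             subtype_spec("b", 1 / 3, global_scale = 0.9),
             subtype_spec("c", 1 / 3, global_scale = 0.8))
  ds <- generate_dataset(list(cohort_spec("A", 600, 100)), st, seed = 3)
  pd <- ds$subjects$group == "PD"
  mt <- rowMeans(ds$roi$values[pd, dk_cortical_rois()])
  means <- tapply(mt, ds$truth$subtype[ds$subjects$subject_id[pd]], mean)
  expect_true(means["a"] > means["b"] && means["b"] > means["c"])
})

test_that("volumes increase with eTIV and WM-hypo with atrophy burden", {
  st <- list(subtype_spec("mild", 0.5, global_scale = 1),
             subtype_spec("severe", 0.5, global_scale = 0.7))
  ds <- generate_dataset(list(cohort_spec("A", 300, 150)), st, seed = 5)
  hc <- ds$subjects$group == "HC"
  r <- cor(ds$subjects$etiv[hc], ds$roi$values[hc, "thalamus"])
  expect_gt(r, 0.3)
  pd_ids <- ds$subjects$subject_id[ds$subjects$group == "PD"]
  wm <- ds$subjects$wm_hypo[match(pd_ids, ds$subjects$subject_id)]
  st_lab <- ds$truth$subtype[pd_ids]
  expect_gt(median(wm[st_lab == "severe"]), median(wm[st_lab == "mild"]))
})

test_that("invalid configurations are rejected", {
  expect_error(generate_dataset(small_cohorts(),
                                list(subtype_spec("a", 0.5)), seed = 1),
               "sum to 1")
  expect_error(subtype_spec("a", 1, pattern_rois = "not_a_roi"),
               "unknown ROI")
  expect_error(subtype_spec("a", 1, global_scale = 0), "positive")
  expect_error(generate_dataset(list(), severity_subtypes(), seed = 1),
               "at least one cohort")
  expect_error(generate_dataset(small_cohorts(), severity_subtypes()),
               "seed")
})

test_that("longitudinal visits follow the planted slopes", {
  co <- list(cohort_spec("L", 40, 0, has_longitudinal = TRUE, n_visits = 7,
                         visit_interval = 1))
  st <- list(subtype_spec("only", 1, updrs_slope = 2, moca_slope = -0.3))
  ds <- generate_dataset(co, st, seed = 9)

  # no attrition, zero noise: 7 rows each and exact per-subject OLS slope
  vis <- generate_longitudinal(ds$subjects, st, seed = 9, truth = ds$truth,
                               dropout = 0, visit_noise_sd = 0,
                               intercept_sd = 2)
  expect_equal(nrow(vis), 40 * 7)
  expect_true(all(tapply(vis$time, vis$subject_id, length) == 7))
  expect_true(all(sort(unique(vis$time)) == 0:6))
  slopes <- vapply(split(vis, vis$subject_id), function(d)
    unname(coef(lm(updrs3 ~ time, d))[2]), numeric(1))
  expect_equal(unname(slopes), rep(2, 40), tolerance = 1e-10)

  # noisy Monte-Carlo: mean per-subject OLS slope close to the planted value
  co200 <- list(cohort_spec("L", 200, 0, has_longitudinal = TRUE,
                            n_visits = 7))
  ds200 <- generate_dataset(co200, st, seed = 10)
  mean_slopes <- vapply(1:10, function(s) {
    v <- generate_longitudinal(ds200$subjects, st, seed = 20 + s,
                               truth = ds200$truth, dropout = 0,
                               visit_noise_sd = 3)
    mean(vapply(split(v, v$subject_id), function(d)
      unname(coef(lm(updrs3 ~ time, d))[2]), numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(mean_slopes) - 2), 0.3)

  # attrition is monotone
  vis_d <- generate_longitudinal(ds$subjects, st, seed = 11,
                                 truth = ds$truth, dropout = 0.3)
  per <- tapply(vis_d$visit, vis_d$subject_id, max)
  counts <- tapply(vis_d$visit, vis_d$subject_id, length)
  expect_equal(unname(per), unname(counts))  # no gaps: visits 1..last
  expect_lt(mean(counts), 7)
  expect_error(cohort_spec("L", 40, 0, visit_interval = -1),
               "non-negative")
  bad_co <- cohort_spec("L", 40, 0, has_longitudinal = TRUE)
  bad_co$visit_interval <- -1  # corrupted spec caught at generation time
  expect_error(generate_longitudinal(ds$subjects, st, seed = 1,
                                     truth = ds$truth,
                                     cohorts = list(bad_co)),
               "negative visit interval")
})

test_that("dataset round-trips through CSV/JSON and YAML config parses", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(small_cohorts(), typicality_subtypes(), seed = 4)
  vis <- generate_longitudinal(ds$subjects, typicality_subtypes(), seed = 4,
                               truth = ds$truth)
  paths <- write_dataset(ds, dir, visits = vis)
  expect_true(all(file.exists(paths)))
  roi_in <- utils::read.csv(paths["roi"], check.names = FALSE)
  expect_equal(as.matrix(roi_in[, -1]), ds$roi$values,
               ignore_attr = TRUE, tolerance = 1e-12)

  cfg_path <- file.path(dir, "gen.yaml")
  writeLines(c(
    "cohorts:",
    "  - name: A",
    "    n_pd: 30",
    "    n_hc: 10",
    "subtypes:",
    "  - name: alpha",
    "    prevalence: 0.5",
    "    global_scale: 0.9",
    "  - name: beta",
    "    prevalence: 0.5",
    "    pattern_rois: [cuneus, putamen]",
    "    pattern_effect: 1.0"), cfg_path)
  cfg <- read_generator_config(cfg_path)
  expect_length(cfg$cohorts, 1)
  expect_equal(cfg$subtypes[[2]]$pattern_rois, c("cuneus", "putamen"))
  ds_cfg <- generate_dataset(cfg$cohorts, cfg$subtypes, seed = 2)
  expect_equal(nrow(ds_cfg$subjects), 40)
})
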
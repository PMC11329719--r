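toy_matrix <- function(vals, ids = paste0("s", seq_len(nrow(vals)))) {
  rois <- all_rois()[seq_len(ncol(vals))]
  dimnames(vals) <- list(ids, rois)
  roi_matrix(vals)
}

test_that("continuous residual fit recovers an exact line and centers at the
           reference covariate mean", {
  x <- c(1, 2, 3)
  y <- matrix(c(2, 4, 6), 3, 1)
  rm <- toy_matrix(cbind(y, 2.5, 2.5))  # pad to >= 1 feature of each kind
  m <- fit_residual_adjustment(rm, c(1, 2, 3), rep(TRUE, 3),
                               type = "continuous", features = "bankssts")
  expect_equal(unname(m$coef$slope["bankssts"]), 2)
  expect_equal(m$coef$x_ref_mean, 2)
  # applying removes the covariate-explained part around the reference mean
  adj <- apply_residual_adjustment(rm, m, c(1, 2, 3))
  expect_equal(unname(adj$values[, "bankssts"]), c(4, 4, 4))
})

test_that("fitted slope on a null covariate stays near zero (n = 1000)", {
  set.seed(31)
  n <- 1000
  vals <- matrix(rnorm(n * 3, mean = 2.5, sd = 0.15), n, 3)
  rm <- toy_matrix(vals)
  cov <- rnorm(n)
  m <- fit_residual_adjustment(rm, cov, rep(TRUE, n), type = "continuous")
  expect_true(all(abs(m$coef$slope) < 0.05))
})

test_that("categorical offsets are recovered and reference level unchanged", {
  true_off <- 0.2
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 400
    lev <- sample(c("ref", "other"), n, replace = TRUE)
    vals <- matrix(rnorm(n * 2, 2.5, 0.15), n, 2)
    vals[lev == "other", ] <- vals[lev == "other", ] + true_off
    rm <- toy_matrix(vals)
    m <- fit_residual_adjustment(rm, lev, rep(TRUE, n),
                                 type = "categorical", ref_level = "ref")
    se <- 0.15 * sqrt(1 / sum(lev == "ref") + 1 / sum(lev == "other"))
    all(abs(m$coef$offsets["other", ] - true_off) < 2 * se)
  }, logical(1))
  expect_gte(sum(hits), 8)

  set.seed(99)
  n <- 60
  lev <- rep(c("ref", "other"), each = n / 2)
  rm <- toy_matrix(matrix(rnorm(n * 2, 2.5, 0.1), n, 2))
  m <- fit_residual_adjustment(rm, lev, rep(TRUE, n), type = "categorical",
                               ref_level = "ref")
  adj <- apply_residual_adjustment(rm, m, lev)
  expect_equal(adj$values[lev == "ref", ], rm$values[lev == "ref", ])
})

test_that("residual adjustment is idempotent up to refit noise", {
  set.seed(17)
  n <- 300
  cov <- rnorm(n, 0, 2)
  vals <- matrix(2.5 + 0.3 * cov + rnorm(n * 4, 0, 0.1), n, 4)
  rm <- toy_matrix(vals)
  m1 <- fit_residual_adjustment(rm, cov, rep(TRUE, n), type = "continuous")
  a1 <- apply_residual_adjustment(rm, m1, cov)
  m2 <- fit_residual_adjustment(a1, cov, rep(TRUE, n), type = "continuous")
  a2 <- apply_residual_adjustment(a1, m2, cov)
  expect_lt(max(abs(a2$values - a1$values)), 1e-10)
  # residual correlation with covariate is ~ 0 in the reference group
  expect_true(all(abs(cor(cov, a1$values)) < 0.05))
})

test_that("fit guards: tiny reference, constant covariate, feature mismatch", {
  rm <- toy_matrix(matrix(rnorm(20 * 2, 2.5, 0.1), 20, 2))
  expect_error(fit_residual_adjustment(rm, rnorm(20), 1:2,
                                       type = "continuous"), ">= 3")
  expect_error(fit_residual_adjustment(rm, rep(1, 20), rep(TRUE, 20),
                                       type = "continuous"), "constant")
  m <- fit_residual_adjustment(rm, rnorm(20), rep(TRUE, 20),
                               type = "continuous")
  rm_other <- roi_matrix(matrix(rnorm(10), 5, 2,
                                dimnames = list(paste0("t", 1:5),
                                                c("cuneus", "insula"))))
  expect_error(apply_residual_adjustment(rm_other, m, rnorm(5)),
               "not present")
})

test_that("severity adjustment normalizes rows exactly and is scale
           invariant", {
  set.seed(5)
  n <- 40
  vals <- cbind(matrix(rnorm(n * 34, 2.5, 0.15), n, 34),
                matrix(rnorm(n * 7, 3000, 300), n, 7))
  dimnames(vals) <- list(paste0("s", 1:n), all_rois())
  rm <- roi_matrix(vals)
  adj <- severity_adjust(rm)
  th <- adj$values[, dk_cortical_rois()]
  expect_lt(max(abs(rowMeans(th) - 1)), 1e-12)
  vo <- adj$values[, subcortical_rois()]
  expect_lt(max(abs(rowSums(vo) - 1)), 1e-12)

  # uniform thickness: all ratios exactly 1
  vals1 <- vals
  vals1[1, dk_cortical_rois()] <- 2.4
  expect_equal(unname(severity_adjust(roi_matrix(vals1))$values[
    1, dk_cortical_rois()]), rep(1, 34))

  # two subjects differing only by a global factor give identical rows
  vals2 <- vals
  vals2[2, ] <- 0.9 * vals2[1, ]
  adj2 <- severity_adjust(roi_matrix(vals2))
  expect_equal(adj2$values[2, ], adj2$values[1, ], tolerance = 1e-12)

  # per-subject global rescaling of the whole input leaves output unchanged
  g <- runif(n, 0.7, 1.3)
  adj3 <- severity_adjust(roi_matrix(vals * g))
  expect_equal(adj3$values, adj$values, tolerance = 1e-10)

  vals_bad <- vals
  vals_bad[3, dk_cortical_rois()] <- -vals_bad[3, dk_cortical_rois()]
  expect_error(severity_adjust(roi_matrix(vals_bad)), "non-positive")
})

test_that("full chain removes planted field-strength and cohort offsets", {
  co <- list(cohort_spec("A", 160, 90, field_strength_mix = 0.6,
                         offset_sd = 0.5),
             cohort_spec("B", 160, 90, field_strength_mix = 0.4,
                         offset_sd = 0.5),
             cohort_spec("C", 100, 0, field_strength_mix = 0.5,
                         offset_sd = 0.5))
  st <- list(subtype_spec("only", 1, global_scale = 0.9))
  ds <- generate_dataset(co, st, seed = 21)
  inp <- build_clustering_input(ds$roi, ds$subjects, mode = "unadjusted")
  th <- dk_cortical_rois()
  fs <- ds$subjects$field_strength
  hc <- ds$subjects$group == "HC"

  # mean thickness gap between field strengths, averaged over features:
  # planted 0.1 mm, residual gap must be far below it
  gap_pre <- mean(colMeans(ds$roi$values[fs == 1.5, th]) -
                    colMeans(ds$roi$values[fs == 3, th]))
  gap_post <- mean(colMeans(inp$values[hc & fs == 1.5, th]) -
                     colMeans(inp$values[hc & fs == 3, th]))
  expect_gt(abs(gap_pre), 0.05)
  expect_lt(abs(gap_post), 0.02)

  # HC cohort means agree after the chain (offsets removed)
  for (r in sample(th, 5)) {
    m_a <- mean(inp$values[hc & ds$subjects$cohort == "A", r])
    m_b <- mean(inp$values[hc & ds$subjects$cohort == "B", r])
    expect_lt(abs(m_a - m_b), 4 * 0.15 * sqrt(2 / 90))
  }

  # planted cohort offset direction is annihilated (projection remnant)
  off <- ds$truth$cohort_offsets[["B"]] - ds$truth$cohort_offsets[["A"]]
  gap_vec <- colMeans(inp$values[ds$subjects$cohort == "B", ]) -
    colMeans(inp$values[ds$subjects$cohort == "A", ])
  remnant <- abs(sum(gap_vec * off) / sum(off * off))
  expect_lt(remnant, 0.2)

  expect_error(build_clustering_input(ds$roi,
                                      transform(ds$subjects,
                                                group = "PD"), "unadjusted"),
               "no HC")
})

test_that("adjusted mode forces equal per-subject mean thickness across
           planted subtypes while unadjusted preserves the gradient", {
  st <- list(subtype_spec("a", 0.5, global_scale = 1.0),
             subtype_spec("b", 0.5, global_scale = 0.8))
  ds <- generate_dataset(list(cohort_spec("A", 200, 100,
                                          field_strength_mix = 0.5)),
                         st, seed = 23)
  pd <- ds$subjects$group == "PD"
  lab <- ds$truth$subtype[ds$subjects$subject_id[pd]]

  un <- build_clustering_input(ds$roi, ds$subjects, mode = "unadjusted")
  mt_un <- rowMeans(un$values[pd, dk_cortical_rois()])
  expect_gt(mean(mt_un[lab == "a"]) - mean(mt_un[lab == "b"]), 0.3)

  ad <- build_clustering_input(ds$roi, ds$subjects, mode = "adjusted")
  mt_ad <- rowMeans(ad$values[pd, dk_cortical_rois()])
  expect_equal(mean(mt_ad[lab == "a"]) - mean(mt_ad[lab == "b"]), 0)
  expect_equal(ad$adjustments, c("field_strength", "etiv", "severity"))
})
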
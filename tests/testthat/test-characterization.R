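test_that("Kruskal-Wallis matches the rank formula and handles degeneracy", {
  # {1,2} vs {3,4}: H = 12/(4*5) * (3^2/2 + 7^2/2) - 3*5 = 2.4
  kw <- kruskal_wallis(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(kw$statistic, 2.4)
  expect_equal(kw$df, 1)

  # symmetric duplicate groups: equal rank sums, H = 0
  kw0 <- kruskal_wallis(c(5, 9, 5, 9), c("a", "a", "b", "b"))
  expect_equal(kw0$statistic, 0)

  # identical values everywhere: degenerate, flagged
  kwd <- kruskal_wallis(rep(3, 8), rep(c("a", "b"), 4))
  expect_true(kwd$degenerate)
  expect_equal(kwd$statistic, 0)

  # random instances (with ties) vs the direct-rank oracle
  for (s in 1:10) {
    set.seed(400 + s)
    g <- sample(c("a", "b", "c"), 15, replace = TRUE)
    while (length(unique(g)) < 3) g <- sample(c("a", "b", "c"), 15, TRUE)
    v <- sample(1:6, 15, replace = TRUE)
    if (length(unique(v)) == 1) next
    expect_equal(kruskal_wallis(v, g)$statistic, naive_kruskal(v, g),
                 tolerance = 1e-10)
  }
  # pairwise deletion
  kw_na <- kruskal_wallis(c(1, 2, NA, 3, 4), c("a", "a", "a", "b", "b"))
  expect_equal(kw_na$n, 4)
  expect_error(kruskal_wallis(1:4, rep("a", 4)), ">= 2")
})

test_that("chi-square is plain Pearson: zero on proportional tables,
           hand value on a diagonal table", {
  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  expect_equal(chi_square_table(prop)$statistic, 0)
  hand <- chi_square_table(rbind(c(10, 0), c(0, 10)))
  expect_equal(hand$statistic, 20)
  expect_equal(hand$df, 1)
  expect_error(chi_square_table(rbind(c(-1, 2), c(3, 4))), "negative")
  expect_error(chi_square_table(rbind(c(0, 0), c(3, 4))), "totals")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  for (s in 1:10) {
    set.seed(500 + s)
    p <- runif(sample(3:20, 1))
    expect_equal(bh_fdr(p), naive_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("post-hoc comparisons find exactly the shifted group", {
  hits <- vapply(1:10, function(s) {
    set.seed(600 + s)
    v <- c(rnorm(100), rnorm(100), rnorm(100, 5))
    g <- rep(c("g1", "g2", "g3"), each = 100)
    om <- kruskal_wallis(v, g)
    ph <- posthoc_pairwise(v, g, om$p, "continuous")
    pairs <- paste(ph$group1, ph$group2)
    setequal(pairs, c("g1 g3", "g2 g3"))
  }, logical(1))
  expect_gte(sum(hits), 9)

  # identical groups: omnibus non-significant, empty set with warning
  set.seed(61)
  v <- rnorm(60)
  g <- rep(c("a", "b"), 30)
  expect_warning(ph0 <- posthoc_pairwise(v, g, 0.8, "continuous"),
                 "not significant")
  expect_equal(nrow(ph0), 0)

  # two groups: reduces to the omnibus decision
  v2 <- c(rnorm(50), rnorm(50, 3))
  g2 <- rep(c("a", "b"), each = 50)
  om2 <- kruskal_wallis(v2, g2)
  ph2 <- posthoc_pairwise(v2, g2, om2$p, "continuous")
  expect_equal(nrow(ph2), 1)

  # categorical route
  set.seed(62)
  cat_v <- c(sample(c("x", "y"), 100, TRUE, prob = c(0.9, 0.1)),
             sample(c("x", "y"), 100, TRUE, prob = c(0.5, 0.5)),
             sample(c("x", "y"), 100, TRUE, prob = c(0.9, 0.1)))
  cat_g <- rep(c("g1", "g2", "g3"), each = 100)
  om3 <- chi_square_table(table(cat_g, cat_v))
  ph3 <- posthoc_pairwise(cat_v, cat_g, om3$p, "categorical")
  expect_true(all(grepl("g2", paste(ph3$group1, ph3$group2))))
})

test_that("effect-size maps detect a planted deficit and control the null", {
  base <- generate_dataset(list(cohort_spec("A", 0, 100, offset_sd = 0)),
                           list(subtype_spec("x", 1)), seed = 71)
  hc_ids <- base$subjects$subject_id

  # planted d = 1.2 in one ROI
  set.seed(72)
  ref <- hc_reference()
  n <- 100
  vals <- matrix(rnorm(n * 41), n, 41,
                 dimnames = list(paste0("c", 1:n), all_rois()))
  vals <- sweep(sweep(vals, 2, ref$sd, "*"), 2, ref$mean, "+")
  vals[, "precuneus"] <- vals[, "precuneus"] - 1.2 * ref$sd["precuneus"]
  cl_subj <- data.frame(subject_id = rownames(vals), group = "PD",
                        cohort = "A", field_strength = 3,
                        age = round(rnorm(n, 63, 8), 1), sex = "M",
                        etiv = rnorm(n, 1.5e6, 1.5e5), wm_hypo = 1000)
  allm <- roi_matrix(rbind(base$roi$values, vals))
  alls <- rbind(base$subjects[names(cl_subj)], cl_subj)
  em <- effect_size_map(allm, alls, rownames(vals), hc_ids)
  expect_equal(nrow(em), 41)
  prec <- em[em$roi == "precuneus", ]
  expect_true(prec$significant)
  expect_lt(abs(prec$d - 1.2), 0.25)
  expect_gt(prec$d, 0)  # positive d = more atrophy in the cluster

  # identical groups: no significant ROI, d masked everywhere
  em0 <- effect_size_map(base$roi, base$subjects, hc_ids[1:50],
                         hc_ids[51:100])
  expect_false(any(em0$significant))
  expect_true(all(is.na(em0$d)))
  expect_error(effect_size_map(base$roi, base$subjects, hc_ids[1:5],
                               character(0)), "empty")
})

test_that("null clusters rarely produce significant ROI maps (FDR control)", {
  ds <- generate_dataset(list(cohort_spec("A", 0, 120, offset_sd = 0)),
                         list(subtype_spec("x", 1)), seed = 73)
  ids <- ds$subjects$subject_id
  n_with_hit <- 0L
  for (s in 1:20) {
    set.seed(700 + s)
    cl <- sample(ids, 40)
    em <- effect_size_map(ds$roi, ds$subjects, cl, setdiff(ids, cl))
    if (any(em$significant)) n_with_hit <- n_with_hit + 1L
  }
  expect_lte(n_with_hit / 20, 0.10 + 1e-9)
})

test_that("transition tables cross-tabulate solutions with chi-square and
           ARI", {
  ids <- paste0("s", 1:20)
  la <- setNames(rep(1:2, each = 10), ids)
  tt <- transition_table(la, la)
  expect_equal(tt$ari, 1)
  expect_equal(unname(diag(tt$table)), c(10, 10))
  expect_equal(tt$statistic, 20)
  expect_equal(tt$df, 1)

  # independent random labelings have ARI ~ 0
  set.seed(81)
  aris <- vapply(1:10, function(s) {
    ids6 <- paste0("s", 1:600)
    a <- setNames(sample(1:3, 600, TRUE), ids6)
    b <- setNames(sample(1:8, 600, TRUE), ids6)
    transition_table(a, b)$ari
  }, numeric(1))
  expect_lt(max(abs(aris)), 0.05)

  # excluded (NA) members are dropped from the intersection
  lb <- la
  lb[1:3] <- NA
  expect_equal(transition_table(la, lb)$n, 17)
  expect_error(transition_table(la, setNames(rep(NA_integer_, 20), ids)),
               "no common")
})

test_that("the characterization battery routes variables to the right test", {
  ds <- generate_dataset(list(cohort_spec("A", 120, 40),
                              cohort_spec("B", 80, 30)),
                         severity_subtypes(), seed = 91)
  pd_ids <- ds$subjects$subject_id[ds$subjects$group == "PD"]
  truth_lab <- factor(ds$truth$subtype[pd_ids])
  labels <- setNames(as.integer(truth_lab), pd_ids)
  rep_tab <- characterize_clusters(ds$subjects, labels)
  expect_true(all(c("age", "updrs3", "wm_hypo_ratio", "sex", "mci") %in%
                    rep_tab$variable))
  expect_equal(rep_tab$test[rep_tab$variable == "age"], "kruskal_wallis")
  expect_equal(rep_tab$test[rep_tab$variable == "sex"], "chi_square")
  expect_true(all(rep_tab$p >= 0 & rep_tab$p <= 1))
  expect_true(all(rep_tab$n <= length(pd_ids)))
  # age is coupled to severity by design, so the omnibus must fire
  expect_lt(rep_tab$p[rep_tab$variable == "age"], 0.05)
  expect_lt(rep_tab$p[rep_tab$variable == "wm_hypo_ratio"], 0.05)
})
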
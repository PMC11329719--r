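#' Kruskal-Wallis rank test across clusters
#'
#' Rank-based omnibus comparison of a continuous variable across >= 2 groups,
#' with tie correction; the statistic H is referred to a chi-square
#' distribution with `groups - 1` degrees of freedom. Missing values are
#' removed pairwise. If every value is identical across all groups the test
#' is degenerate: H is reported as 0 with a flag.
#'
#' @param values numeric vector.
#' @param groups group labels aligned with `values`.
#' @return List with `statistic` (H), `df`, `p`, `n`, `degenerate`.
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need >= 2 non-empty groups")
  if (length(unique(values)) == 1)
    return(list(statistic = 0, df = nlevels(groups) - 1, p = 1,
                n = length(values), degenerate = TRUE))
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, n = length(values), degenerate = FALSE)
}

#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson statistic `sum((O - E)^2 / E)` with
#' `df = (r - 1)(c - 1)`; no continuity correction (the convention under
#' which the reference cross-tabulations reproduce).
#'
#' @param counts r x c matrix of non-negative counts.
#' @return List with `statistic`, `df`, `p`, `n`.
#' @export
chi_square_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("row/column totals must be positive")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, n = sum(counts))
}

#' Post-hoc pairwise comparisons after a significant omnibus test
#'
#' Continuous variables: Dunn-type rank comparisons on the pooled ranks with
#' tie correction, adjusted with Holm's method. Categorical variables:
#' pairwise 2 x c Pearson chi-square tests, Holm-adjusted. Returns the pairs
#' below the adjusted two-sided alpha of 0.05. Calling without a significant
#' omnibus result returns an empty set with a warning.
#'
#' @param values numeric vector (continuous) or vector of categories.
#' @param groups group labels.
#' @param omnibus_p p value of the omnibus test.
#' @param type `"continuous"` or `"categorical"`.
#' @param alpha significance level for the adjusted p values.
#' @return data.frame with columns `group1`, `group2`, `p_adjusted` for the
#'   significant pairs (attribute `"all_pairs"` holds every comparison).
#' @export
posthoc_pairwise <- function(values, groups, omnibus_p,
                             type = c("continuous", "categorical"),
                             alpha = 0.05) {
  type <- match.arg(type)
  empty <- data.frame(group1 = character(), group2 = character(),
                      p_adjusted = numeric())
  if (is.na(omnibus_p) || omnibus_p >= alpha) {
    warning("omnibus test not significant; no post-hoc comparisons")
    return(empty)
  }
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(factor(groups[ok]))
  labs <- levels(groups)
  pairs <- utils::combn(labs, 2)

  if (type == "continuous") {
    r <- rank(values)
    N <- length(r)
    ties <- table(values)
    tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
    v0 <- N * (N + 1) / 12 - tie_corr
    rbar <- tapply(r, groups, mean)
    nn <- tapply(r, groups, length)
    p_raw <- apply(pairs, 2, function(pr) {
      z <- (rbar[pr[1]] - rbar[pr[2]]) /
        sqrt(v0 * (1 / nn[pr[1]] + 1 / nn[pr[2]]))
      2 * stats::pnorm(-abs(z))
    })
  } else {
    p_raw <- apply(pairs, 2, function(pr) {
      sub <- groups %in% pr
      tab <- table(droplevels(groups[sub]), values[sub])
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA_real_)
      suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
    })
  }
  p_adj <- stats::p.adjust(p_raw, method = "holm")
  all_pairs <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                          p_raw = p_raw, p_adjusted = p_adj)
  sig <- all_pairs[!is.na(p_adj) & p_adj < alpha,
                   c("group1", "group2", "p_adjusted")]
  rownames(sig) <- NULL
  attr(sig, "all_pairs") <- all_pairs
  sig
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted q values with monotonicity enforcement, as applied over
#' the 41 per-ROI tests of the effect-size maps.
#'
#' @param p vector of p values in \[0, 1\].
#' @return Vector of adjusted q values.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-ROI atrophy effect sizes of a cluster versus healthy controls
#'
#' For each of the 41 ROIs, fits the ANCOVA
#' `measure ~ group + age + field_strength + cohort` (plus `etiv` for volume
#' features), collects the group p values over all ROIs, adjusts them with
#' Benjamini-Hochberg, and computes Cohen's d on age-adjusted measures with
#' the pooled-sd convention. The sign is oriented so positive d means more
#' atrophy (lower thickness or volume) in the cluster than in HC. d is masked
#' (`NA`) wherever q >= 0.05. Covariates that are constant within the
#' compared subjects are dropped automatically; ROIs with a singular design
#' are flagged unestimable.
#'
#' @param matrix an [roi_matrix()] (harmonization state of your choosing; the
#'   reference analysis uses hemisphere-averaged raw measures and lets the
#'   model covary field strength, cohort and eTIV).
#' @param subjects subject table aligned with the matrix rows.
#' @param cluster_ids subject ids of the cluster.
#' @param hc_ids subject ids of the control group (non-empty).
#' @param q_threshold FDR threshold masking d (default 0.05).
#' @return data.frame with one row per ROI: `roi`, `kind`, `d`, `d_unmasked`,
#'   `p`, `q`, `significant`, `estimable`.
#' @export
effect_size_map <- function(matrix, subjects, cluster_ids, hc_ids,
                            q_threshold = 0.05) {
  stopifnot(inherits(matrix, "roi_matrix"))
  if (!length(hc_ids)) stop("HC group is empty")
  ids <- c(cluster_ids, hc_ids)
  if (!all(ids %in% rownames(matrix$values)))
    stop("unknown subject id(s) in cluster/HC sets")
  sub <- subjects[match(ids, subjects$subject_id), ]
  X <- matrix$values[ids, , drop = FALSE]
  grp <- factor(rep(c("cluster", "HC"), c(length(cluster_ids),
                                          length(hc_ids))),
                levels = c("HC", "cluster"))

  res <- lapply(colnames(X), function(roi) {
    dat <- data.frame(y = X[, roi], grp = grp, age = sub$age,
                      fs = factor(sub$field_strength),
                      cohort = factor(sub$cohort), etiv = sub$etiv)
    rhs <- c("grp", "age")
    if (nlevels(droplevels(dat$fs)) > 1) rhs <- c(rhs, "fs")
    if (nlevels(droplevels(dat$cohort)) > 1) rhs <- c(rhs, "cohort")
    if (matrix$kind[[roi]] == "volume") rhs <- c(rhs, "etiv")
    fit <- try(stats::lm(stats::reformulate(rhs, "y"), data = dat),
               silent = TRUE)
    p <- NA_real_
    estimable <- FALSE
    if (!inherits(fit, "try-error")) {
      co <- summary(fit)$coefficients
      if ("grpcluster" %in% rownames(co) &&
          is.finite(co["grpcluster", 4])) {
        p <- co["grpcluster", 4]
        estimable <- TRUE
      }
    }
    # Cohen's d on age-adjusted measures, pooled sd, positive = more atrophy
    r <- stats::resid(stats::lm(y ~ age, data = dat))
    m_hc <- mean(r[grp == "HC"]); m_cl <- mean(r[grp == "cluster"])
    n1 <- sum(grp == "HC"); n2 <- sum(grp == "cluster")
    sp <- sqrt(((n1 - 1) * stats::var(r[grp == "HC"]) +
                  (n2 - 1) * stats::var(r[grp == "cluster"])) /
                 (n1 + n2 - 2))
    d <- if (sp > 0) (m_hc - m_cl) / sp else 0
    data.frame(roi = roi, kind = unname(matrix$kind[[roi]]),
               d_unmasked = d, p = p, estimable = estimable)
  })
  out <- do.call(rbind, res)
  out$q <- NA_real_
  est <- out$estimable
  out$q[est] <- bh_fdr(out$p[est])
  out$significant <- !is.na(out$q) & out$q < q_threshold
  out$d <- ifelse(out$significant, out$d_unmasked, NA_real_)
  out[, c("roi", "kind", "d", "d_unmasked", "p", "q", "significant",
          "estimable")]
}

#' Cross-tabulate two cluster solutions and test their independence
#'
#' Builds the r x c contingency table of joint assignments over the common
#' (non-excluded) subjects, computes the Pearson chi-square test of
#' independence, and the adjusted Rand index as the chance-corrected overlap
#' summary.
#'
#' @param labels_a,labels_b named label vectors or `cluster_solution`
#'   objects; `NA` labels (excluded subjects) are dropped.
#' @return List with `table`, `statistic`, `df`, `p`, `ari`, `n`.
#' @export
transition_table <- function(labels_a, labels_b) {
  la <- if (inherits(labels_a, "cluster_solution")) labels_a$labels else labels_a
  lb <- if (inherits(labels_b, "cluster_solution")) labels_b$labels else labels_b
  common <- intersect(names(la)[!is.na(la)], names(lb)[!is.na(lb)])
  if (!length(common)) stop("no common labeled subjects")
  tab <- table(A = la[common], B = lb[common])
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab, statistic = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value,
       ari = mclust::adjustedRandIndex(la[common], lb[common]),
       n = length(common))
}

#' Characterize clusters on demographic and clinical variables
#'
#' Runs the battery used to profile the PD clusters: Kruskal-Wallis for
#' continuous variables, Pearson chi-square for categorical ones (each with
#' pairwise deletion of missing values), followed by post-hoc pairwise
#' comparisons when the omnibus test is significant. The WM-hypo burden is
#' compared as the `wm_hypo / etiv` ratio.
#'
#' @param subjects subject table.
#' @param solution `cluster_solution` (or named label vector) over the PD
#'   subjects.
#' @param continuous,categorical variable names to test; defaults cover age,
#'   disease duration, education, UPDRS-III, MoCA, WM-hypo ratio, sex, H&Y,
#'   medication, MCI, depression, RBD, PIGD, cohort.
#' @param alpha omnibus significance level gating the post-hocs.
#' @return A `characterization_report`: data.frame with one row per variable
#'   (`variable`, `test`, `statistic`, `df`, `p`, `n`, `posthoc`), the
#'   post-hoc details in attribute `"posthoc"`.
#' @export
characterize_clusters <- function(subjects, solution,
                                  continuous = c("age", "disease_duration",
                                                 "education", "updrs3",
                                                 "moca", "wm_hypo_ratio"),
                                  categorical = c("sex", "hy_stage",
                                                  "medicated", "mci",
                                                  "depression", "rbd",
                                                  "pigd", "cohort"),
                                  alpha = 0.05) {
  labels <- if (inherits(solution, "cluster_solution")) solution$labels
            else solution
  keep <- names(labels)[!is.na(labels)]
  sub <- subjects[match(keep, subjects$subject_id), ]
  cl <- factor(labels[keep])
  sub$wm_hypo_ratio <- wm_hypo_ratio(sub$wm_hypo, sub$etiv)

  rows <- list()
  ph_details <- list()
  for (v in continuous) {
    if (!v %in% names(sub)) next
    vals <- sub[[v]]
    if (all(is.na(vals))) next
    kw <- kruskal_wallis(vals, cl)
    ph <- if (kw$p < alpha)
      posthoc_pairwise(vals, cl, kw$p, "continuous", alpha) else NULL
    rows[[v]] <- data.frame(variable = v, test = "kruskal_wallis",
                            statistic = kw$statistic, df = kw$df, p = kw$p,
                            n = kw$n,
                            posthoc = .fmt_pairs(ph))
    ph_details[[v]] <- ph
  }
  for (v in categorical) {
    if (!v %in% names(sub)) next
    vals <- sub[[v]]
    ok <- !is.na(vals)
    if (!any(ok)) next
    tab <- table(cl[ok], vals[ok])
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2) next
    cs <- chi_square_table(tab)
    ph <- if (cs$p < alpha)
      posthoc_pairwise(vals[ok], cl[ok], cs$p, "categorical", alpha) else NULL
    rows[[v]] <- data.frame(variable = v, test = "chi_square",
                            statistic = cs$statistic, df = cs$df, p = cs$p,
                            n = cs$n, posthoc = .fmt_pairs(ph))
    ph_details[[v]] <- ph
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "posthoc") <- ph_details
  class(out) <- c("characterization_report", class(out))
  out
}

.fmt_pairs <- function(ph) {
  if (is.null(ph) || !nrow(ph)) return("")
  paste(sprintf("cl%s vs cl%s", ph$group1, ph$group2), collapse = "; ")
}
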
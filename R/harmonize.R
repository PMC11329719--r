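#' Fit a reference-group residual adjustment
#'
#' The residual method removes the part of each feature explained by a nuisance
#' covariate, with coefficients estimated in a designated reference/estimation
#' group only. For a continuous covariate (e.g. eTIV) an ordinary
#' least-squares line is fit per feature on the reference subjects; applying
#' the model subtracts `slope * (x - mean(x_reference))`, so the feature keeps
#' its level and reference subjects are unchanged on average. For a
#' categorical covariate (field strength, cohort) per-level mean offsets are
#' estimated relative to a designated reference level; applying subtracts the
#' offset of the subject's level, leaving reference-level subjects untouched.
#'
#' @param matrix an [roi_matrix()].
#' @param covariate per-subject covariate, aligned with the matrix rows
#'   (numeric for continuous, anything coercible to factor for categorical).
#' @param reference_mask logical/integer/character subject subset on which
#'   coefficients are estimated (e.g. the HC group).
#' @param type `"auto"` (default: numeric covariate with > 6 distinct values
#'   is continuous), `"continuous"` or `"categorical"`.
#' @param ref_level reference level for categorical covariates; defaults to
#'   the most frequent level within the estimation group.
#' @param features optional column subset the adjustment applies to (e.g.
#'   volume features only for eTIV); default all.
#' @param strata optional per-subject stratum labels (categorical covariates
#'   only): level offsets are computed on stratum-centered values, so a
#'   nuisance factor whose composition differs between covariate levels
#'   (e.g. the PD/HC case mix of cohorts) does not leak into the offsets.
#' @param name tag recorded in the matrix provenance when applied.
#' @return An `adjustment_model` object.
#' @export
fit_residual_adjustment <- function(matrix, covariate, reference_mask,
                                    type = c("auto", "continuous",
                                             "categorical"),
                                    ref_level = NULL, features = NULL,
                                    strata = NULL, name = NULL) {
  stopifnot(inherits(matrix, "roi_matrix"))
  type <- match.arg(type)
  X <- matrix$values
  if (length(covariate) != nrow(X))
    stop("covariate length must match subject count")
  if (is.null(features)) features <- colnames(X)
  if (!all(features %in% colnames(X))) stop("unknown feature(s) requested")
  ref_idx <- seq_len(nrow(X))[reference_mask]
  if (length(ref_idx) < 3) stop("reference subset must have >= 3 subjects")

  if (type == "auto")
    type <- if (is.numeric(covariate) &&
                length(unique(covariate)) > 6) "continuous" else "categorical"

  if (type == "continuous") {
    x <- as.numeric(covariate)[ref_idx]
    if (stats::sd(x) == 0) stop("covariate is constant in the reference group")
    xc <- x - mean(x)
    Y <- X[ref_idx, features, drop = FALSE]
    slope <- as.numeric(crossprod(xc, sweep(Y, 2, colMeans(Y))) / sum(xc^2))
    names(slope) <- features
    coef <- list(slope = slope, x_ref_mean = mean(x))
    n_used <- stats::setNames(rep(length(ref_idx), length(features)), features)
  } else {
    f <- factor(covariate)
    f_ref <- droplevels(f[ref_idx])
    if (nlevels(f_ref) < 2)
      stop("covariate is constant in the estimation group")
    if (is.null(ref_level)) {
      tab <- table(f_ref)
      ref_level <- names(tab)[which.max(tab)]
    }
    if (!ref_level %in% levels(f_ref))
      stop("reference level absent from the estimation group")
    Y <- X[ref_idx, features, drop = FALSE]
    f_rel <- stats::relevel(f_ref, ref = ref_level)
    if (is.null(strata)) {
      mref <- colMeans(Y[f_ref == ref_level, , drop = FALSE])
      offsets <- matrix(0, nlevels(f_ref), length(features),
                        dimnames = list(levels(f_ref), features))
      for (l in levels(f_ref))
        offsets[l, ] <- colMeans(Y[f_ref == l, , drop = FALSE]) - mref
    } else {
      # two-way additive model y ~ level + stratum, solved jointly for all
      # features: unbiased level offsets under unbalanced designs (e.g. a
      # cohort without controls), unlike raw or stratum-centered means
      if (length(strata) != nrow(X))
        stop("strata length must match subject count")
      st <- factor(strata[ref_idx])
      M <- stats::model.matrix(~ f_rel + st)
      B <- solve(crossprod(M), crossprod(M, Y))
      offsets <- matrix(0, nlevels(f_ref), length(features),
                        dimnames = list(levels(f_ref), features))
      for (l in setdiff(levels(f_rel), ref_level))
        offsets[l, ] <- B[paste0("f_rel", l), ]
    }
    coef <- list(offsets = offsets, ref_level = ref_level)
    n_used <- table(f_ref)
  }
  structure(list(type = type, coef = coef, features = features,
                 n_reference = length(ref_idx), n_used = n_used,
                 name = name %||% type),
            class = "adjustment_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a fitted residual adjustment to all subjects
#'
#' `value_out = value_in - predicted_shift(covariate)` for every subject (PD
#' and HC alike); see [fit_residual_adjustment()] for the shift definition.
#' Features not covered by the model pass through unchanged. A provenance tag
#' is appended to the matrix.
#'
#' @param matrix an [roi_matrix()].
#' @param model an `adjustment_model`.
#' @param covariate per-subject covariate values, aligned with the matrix rows.
#' @return The adjusted [roi_matrix()].
#' @export
apply_residual_adjustment <- function(matrix, model, covariate) {
  stopifnot(inherits(matrix, "roi_matrix"),
            inherits(model, "adjustment_model"))
  X <- matrix$values
  if (!all(model$features %in% colnames(X)))
    stop("model features not present in matrix")
  if (length(covariate) != nrow(X))
    stop("covariate length must match subject count")
  feats <- model$features
  if (model$type == "continuous") {
    xc <- as.numeric(covariate) - model$coef$x_ref_mean
    X[, feats] <- X[, feats, drop = FALSE] - outer(xc, model$coef$slope)
  } else {
    lev <- as.character(covariate)
    known <- lev %in% rownames(model$coef$offsets)
    if (any(!known))
      stop("covariate level(s) not in model: ",
           paste(unique(lev[!known]), collapse = ", "))
    X[, feats] <- X[, feats, drop = FALSE] - model$coef$offsets[lev, feats,
                                                                drop = FALSE]
  }
  roi_matrix(X, matrix$kind, c(matrix$adjustments, model$name))
}

#' Severity (global atrophy) normalization at the individual level
#'
#' Divides each cortical thickness value by the subject's mean over the 34
#' thickness features and each (eTIV-adjusted) volume by the subject's total
#' gray-matter volume (sum over the 7 volume features). After this step every
#' subject's mean thickness ratio is exactly 1, so between-subject differences
#' in overall atrophy are removed and only the regional pattern (typicality)
#' remains. Output is invariant to any per-subject global rescaling of the
#' input.
#'
#' @param matrix an [roi_matrix()] with both feature kinds; volumes should
#'   already be eTIV-adjusted.
#' @return The normalized [roi_matrix()].
#' @export
severity_adjust <- function(matrix) {
  stopifnot(inherits(matrix, "roi_matrix"))
  th <- thickness_cols(matrix)
  vo <- volume_cols(matrix)
  if (!length(th) || !length(vo))
    stop("matrix must contain both thickness and volume features")
  X <- matrix$values
  mean_th <- rowMeans(X[, th, drop = FALSE])
  tot_gm <- rowSums(X[, vo, drop = FALSE])
  if (any(mean_th <= 0) || any(tot_gm <= 0))
    stop("non-positive per-subject normalizer (mean thickness or total GM ",
         "volume); severity adjustment requires level-preserving inputs")
  X[, th] <- X[, th, drop = FALSE] / mean_th
  X[, vo] <- X[, vo, drop = FALSE] / tot_gm
  roi_matrix(X, matrix$kind, c(matrix$adjustments, "severity"))
}

#' Build the clustering input matrix for one analysis mode
#'
#' Applies the fixed harmonization chain: (1) field-strength offsets (1.5 T vs
#' 3 T), estimated on the HC group; (2) eTIV residual slopes on the volume
#' features, estimated on the HC group; (3) cohort offsets relative to the
#' largest (reference) cohort, estimated on all subjects by default because
#' one cohort may lack controls; and, for `mode = "adjusted"`, (4) the
#' per-subject severity normalization. The returned matrix covers all subjects
#' (PD and HC); clustering itself is run on the PD rows.
#'
#' @param matrix an [roi_matrix()] of raw hemisphere-averaged features.
#' @param subjects subject table aligned with the matrix rows (columns
#'   `subject_id`, `group`, `cohort`, `field_strength`, `etiv`).
#' @param mode `"unadjusted"` or `"adjusted"` (severity-normalized).
#' @param ref_cohort reference cohort for the cohort offsets; default the
#'   largest cohort.
#' @param cohort_estimation `"all"` (default) or `"hc"`: subjects used to
#'   estimate cohort offsets.
#' @param fs_ref_level reference field-strength level; default the most
#'   frequent level among HC.
#' @return An [roi_matrix()] with attribute `"models"` (the fitted adjustment
#'   chain, in application order).
#' @export
build_clustering_input <- function(matrix, subjects,
                                   mode = c("unadjusted", "adjusted"),
                                   ref_cohort = NULL,
                                   cohort_estimation = c("all", "hc"),
                                   fs_ref_level = NULL) {
  stopifnot(inherits(matrix, "roi_matrix"))
  mode <- match.arg(mode)
  cohort_estimation <- match.arg(cohort_estimation)
  if (!all(rownames(matrix$values) == subjects$subject_id))
    stop("matrix rows and subject table must be aligned by subject_id")
  hc <- subjects$group == "HC"
  if (!any(hc)) stop("no HC subjects available as reference group")
  if (any(is.na(subjects$etiv))) stop("missing eTIV")
  models <- list()

  # a single-field-strength sample needs (and permits) no field adjustment
  if (length(unique(subjects$field_strength[hc])) > 1 &&
      length(unique(subjects$field_strength)) > 1) {
    m_fs <- fit_residual_adjustment(matrix, subjects$field_strength,
                                    reference_mask = hc,
                                    type = "categorical",
                                    ref_level = fs_ref_level,
                                    name = "field_strength")
    matrix <- apply_residual_adjustment(matrix, m_fs,
                                        subjects$field_strength)
    models$field_strength <- m_fs
  }

  volf <- colnames(matrix$values)[matrix$kind == "volume"]
  m_etiv <- fit_residual_adjustment(matrix, subjects$etiv,
                                    reference_mask = hc, type = "continuous",
                                    features = volf, name = "etiv")
  matrix <- apply_residual_adjustment(matrix, m_etiv, subjects$etiv)
  models$etiv <- m_etiv

  if (length(unique(subjects$cohort)) > 1) {
    if (is.null(ref_cohort)) {
      tab <- table(subjects$cohort)
      ref_cohort <- names(tab)[which.max(tab)]
    }
    est <- if (cohort_estimation == "hc") hc else rep(TRUE, nrow(subjects))
    # group-centered estimation: cohorts differ in PD/HC case mix (one may
    # lack controls entirely), and raw cohort means would absorb the disease
    # effect of that imbalance
    m_coh <- fit_residual_adjustment(matrix, subjects$cohort,
                                     reference_mask = est,
                                     type = "categorical",
                                     ref_level = ref_cohort,
                                     strata = subjects$group,
                                     name = "cohort")
    matrix <- apply_residual_adjustment(matrix, m_coh, subjects$cohort)
    models$cohort <- m_coh
  }

  if (mode == "adjusted") matrix <- severity_adjust(matrix)
  attr(matrix, "models") <- models
  attr(matrix, "mode") <- mode
  matrix
}

#' Serialize a fitted adjustment chain to JSON
#'
#' @param models list of `adjustment_model` objects (e.g. the `"models"`
#'   attribute of [build_clustering_input()]'s result).
#' @param path output path.
#' @export
write_adjustment_chain <- function(models, path) {
  ser <- lapply(models, function(m) {
    list(name = m$name, type = m$type, n_reference = m$n_reference,
         coef = if (m$type == "continuous")
           list(slope = as.list(m$coef$slope), x_ref_mean = m$coef$x_ref_mean)
         else
           list(ref_level = m$coef$ref_level,
                offsets = apply(m$coef$offsets, 1, as.list, simplify = FALSE)))
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
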
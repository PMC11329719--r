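#' Adjusted Rand index between a clustering and the planted truth
#'
#' Chance-corrected agreement between a label vector and the generator's
#' ground-truth subtype assignment, computed over the common subjects.
#'
#' @param labels named label vector or `cluster_solution`.
#' @param truth ground-truth list from [generate_dataset()] or a named
#'   subtype vector.
#' @return Adjusted Rand index (1 = identical partitions, ~0 = chance).
#' @export
planted_ari <- function(labels, truth) {
  la <- if (inherits(labels, "cluster_solution")) labels$labels else labels
  tr <- if (is.list(truth)) truth$subtype else truth
  common <- intersect(names(la)[!is.na(la)], names(tr))
  if (!length(common)) stop("no common subjects between labels and truth")
  mclust::adjustedRandIndex(la[common], tr[common])
}

config_hash <- function(x) {
  # polynomial rolling hash (mod 2^31 - 1) over the deparsed configuration;
  # stable across sessions, short enough for filenames
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the end-to-end subtyping analysis
#'
#' Orchestrates the full pipeline for one or both analysis modes: builds the
#' harmonized clustering input ([build_clustering_input()]), runs the
#' random-forest / MDS / average-linkage engine on the PD subjects
#' ([rf_cluster_pipeline()]), selects the number of clusters by validity-index
#' ensemble vote ([ensemble_vote()]), applies the minimum-cluster-size filter
#' ([filter_small_clusters()]), characterizes the retained clusters
#' ([characterize_clusters()], [effect_size_map()]), cross-tabulates the two
#' modes ([transition_table()]) when both are run, optionally re-runs the
#' clustering within each cohort to summarize overlap with the whole-sample
#' solution, and fits longitudinal trajectories when a visit table is given.
#'
#' @param subjects subject table (all groups).
#' @param roi raw hemisphere-averaged [roi_matrix()] aligned with `subjects`.
#' @param modes character subset of `c("unadjusted", "adjusted")`.
#' @param seed integer seed (mandatory; governs the forests).
#' @param n_trees forest size per mode.
#' @param d embedding dimension.
#' @param k_range candidate cluster counts for the vote.
#' @param min_size minimum retained cluster size.
#' @param visits optional visit table for trajectory fits.
#' @param cohort_validation re-run clustering per cohort and report overlap
#'   (skipped with a notice when only one cohort or too few PD subjects).
#' @param min_cohort_n minimum PD count for a per-cohort re-run.
#' @param effect_maps compute per-cluster ROI effect-size maps vs HC.
#' @param out_dir optional directory; artifacts are written as CSV/JSON, each
#'   filename carrying the configuration hash so reruns with a changed
#'   configuration never overwrite earlier outputs.
#' @return A `subtyping_run`: list with one entry per mode (`input`,
#'   `engine`, `vote`, `solution`, `characterization`, `effect_maps`,
#'   `cohort_validation`, `trajectories`), plus `transition` across modes,
#'   `config`, `config_hash`, and `log`.
#' @export
run_subtyping <- function(subjects, roi, modes = c("unadjusted", "adjusted"),
                          seed, n_trees = 2000, d = 3, k_range = 2:15,
                          min_size = 10, visits = NULL,
                          cohort_validation = TRUE, min_cohort_n = 30,
                          effect_maps = TRUE, out_dir = NULL) {
  if (missing(seed)) stop("`seed` is required")
  modes <- match.arg(modes, several.ok = TRUE)
  config <- list(modes = modes, seed = seed, n_trees = n_trees, d = d,
                 k_range = range(k_range), min_size = min_size,
                 cohort_validation = cohort_validation)
  hash <- config_hash(config)
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  note("config hash %s; seed %d; n_trees %d; d %d", hash, seed, n_trees, d)

  pd_ids <- subjects$subject_id[subjects$group == "PD"]
  hc_ids <- subjects$subject_id[subjects$group == "HC"]
  results <- list()

  for (mode in modes) {
    stage <- sprintf("[%s]", mode)
    res <- tryCatch({
      input <- build_clustering_input(roi, subjects, mode = mode)
      note("%s harmonization chain: %s", stage,
           paste(input$adjustments, collapse = " -> "))
      x_pd <- input$values[pd_ids, , drop = FALSE]
      eng <- rf_cluster_pipeline(x_pd, n_trees = n_trees, seed = seed, d = d)
      vote <- ensemble_vote(eng$embedding$points, eng$tree,
                            k_range = k_range)
      note("%s vote winner k = %d (runner-up %s)", stage, vote$winner,
           ifelse(is.na(vote$runner_up), "none", vote$runner_up))
      labels <- cut_tree(eng$tree, vote$winner)
      solution <- filter_small_clusters(labels, min_size = min_size)
      note("%s retained %d cluster(s); excluded sizes: %s", stage,
           solution$k,
           if (nrow(solution$excluded))
             paste(solution$excluded$size, collapse = ", ") else "none")
      characterization <- characterize_clusters(subjects, solution)
      emaps <- NULL
      if (effect_maps && length(hc_ids)) {
        emaps <- lapply(seq_len(solution$k), function(cl) {
          ids <- names(solution$labels)[!is.na(solution$labels) &
                                          solution$labels == cl]
          effect_size_map(roi, subjects, ids, hc_ids)
        })
        names(emaps) <- paste0("cl", seq_len(solution$k))
      }
      cv <- NULL
      if (cohort_validation) {
        cohorts <- unique(subjects$cohort[subjects$group == "PD"])
        if (length(cohorts) < 2) {
          note("%s per-cohort validation skipped: single cohort", stage)
        } else {
          cv <- list()
          for (co in cohorts) {
            ids <- subjects$subject_id[subjects$group == "PD" &
                                         subjects$cohort == co]
            if (length(ids) < min_cohort_n) {
              note("%s cohort %s skipped (n = %d < %d)", stage, co,
                   length(ids), min_cohort_n)
              next
            }
            eng_c <- rf_cluster_pipeline(input$values[ids, , drop = FALSE],
                                         n_trees = n_trees, seed = seed,
                                         d = d)
            vote_c <- ensemble_vote(
              eng_c$embedding$points, eng_c$tree,
              k_range = k_range[k_range <= length(ids) - 1])
            lab_c <- cut_tree(eng_c$tree, vote_c$winner)
            ov <- mclust::adjustedRandIndex(lab_c, labels[ids])
            note("%s cohort %s: k = %d, overlap ARI = %.3f", stage, co,
                 vote_c$winner, ov)
            cv[[co]] <- list(k = vote_c$winner, labels = lab_c, ari = ov)
          }
        }
      }
      traj <- NULL
      if (!is.null(visits) && nrow(visits)) {
        traj <- list(
          updrs3 = try(fit_trajectory(visits, solution, "updrs3", subjects),
                       silent = TRUE),
          moca = try(fit_trajectory(visits, solution, "moca", subjects),
                     silent = TRUE))
      }
      list(input = input, engine = eng, vote = vote, solution = solution,
           characterization = characterization, effect_maps = emaps,
           cohort_validation = cv, trajectories = traj)
    }, error = function(e) {
      stop("stage ", stage, " failed: ", conditionMessage(e), call. = FALSE)
    })
    results[[mode]] <- res
  }

  transition <- NULL
  if (all(c("unadjusted", "adjusted") %in% names(results)))
    transition <- transition_table(results$unadjusted$solution,
                                   results$adjusted$solution)

  run <- structure(list(results = results, transition = transition,
                        config = config, config_hash = hash,
                        log = log_lines),
                   class = "subtyping_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.subtyping_run <- function(x, ...) {
  cat("<subtyping_run>", x$config_hash, "\n")
  for (m in names(x$results))
    cat(sprintf("  %s: k = %d retained (vote winner %d)\n", m,
                x$results[[m]]$solution$k, x$results[[m]]$vote$winner))
  if (!is.null(x$transition))
    cat(sprintf("  transition: chi2 = %.3f (df %d), ARI = %.3f\n",
                x$transition$statistic, x$transition$df, x$transition$ari))
  invisible(x)
}

#' Write the artifacts of a subtyping run
#'
#' Labels, vote scores, embeddings and characterization tables as CSV, the
#' log and configuration as JSON, every filename carrying the config hash.
#'
#' @param run a `subtyping_run`.
#' @param out_dir output directory (created if missing).
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- run$config_hash
  fp <- function(...) file.path(out_dir, sprintf(...))
  for (m in names(run$results)) {
    r <- run$results[[m]]
    utils::write.csv(
      data.frame(subject_id = names(r$solution$labels),
                 cluster = r$solution$labels),
      fp("labels_%s_%s.csv", m, h), row.names = FALSE)
    utils::write.csv(
      data.frame(subject_id = rownames(r$engine$embedding$points),
                 r$engine$embedding$points),
      fp("embedding_%s_%s.csv", m, h), row.names = FALSE)
    utils::write.csv(as.data.frame(r$characterization),
                     fp("characterization_%s_%s.csv", m, h),
                     row.names = FALSE)
    utils::write.csv(t(r$vote$scores), fp("vote_scores_%s_%s.csv", m, h))
    if (!is.null(r$effect_maps))
      utils::write.csv(
        do.call(rbind, Map(cbind, cluster = names(r$effect_maps),
                           r$effect_maps)),
        fp("effect_maps_%s_%s.csv", m, h), row.names = FALSE)
  }
  jsonlite::write_json(list(config = run$config, log = run$log),
                       fp("run_%s.json", h), auto_unbox = TRUE)
  invisible(out_dir)
}
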
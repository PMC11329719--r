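#' Read and validate a subject table
#'
#' Accepts CSV or TSV (auto-detected by file extension; decimal point only)
#' with one row per subject. Required columns: `subject_id`, `group` (PD/HC),
#' `cohort`, `field_strength`, `age`, `sex`, `etiv`. All clinical columns are
#' optional and kept as missing when absent or unparseable. Field strength is
#' normalized from strings such as `"1.5T"` / `"3T"` to numeric 1.5 / 3.0.
#' Rows violating hard invariants (non-positive eTIV, MoCA outside 0-30,
#' unknown group) are dropped and listed in the validation report.
#'
#' @param path path to a `.csv` or `.tsv`/`.txt` file.
#' @return data.frame of typed subject records with attribute
#'   `"validation_report"` (a data.frame of dropped rows and reasons).
#' @export
read_subject_table <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = TRUE,
                           colClasses = "character")
  required <- c("subject_id", "group", "cohort", "field_strength", "age",
                "sex", "etiv")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(raw$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(raw$subject_id[duplicated(raw$subject_id)]),
               collapse = ", "))

  num <- function(x) suppressWarnings(as.numeric(x))
  flag <- function(x) {
    x <- tolower(trimws(x))
    out <- rep(NA, length(x))
    out[x %in% c("true", "t", "1", "yes", "y")] <- TRUE
    out[x %in% c("false", "f", "0", "no", "n")] <- FALSE
    out
  }
  fs <- num(gsub("(?i)\\s*T$", "", trimws(raw$field_strength), perl = TRUE))
  fs[!fs %in% c(1.5, 3.0)] <- NA

  opt_num <- function(col) if (col %in% names(raw)) num(raw[[col]]) else NA_real_
  opt_flag <- function(col) if (col %in% names(raw)) flag(raw[[col]]) else NA

  rec <- data.frame(
    subject_id = raw$subject_id,
    group = toupper(trimws(raw$group)),
    cohort = raw$cohort,
    field_strength = fs,
    age = num(raw$age),
    sex = toupper(trimws(raw$sex)),
    education = opt_num("education"),
    disease_duration = opt_num("disease_duration"),
    medicated = opt_flag("medicated"),
    hy_stage = opt_num("hy_stage"),
    updrs3 = opt_num("updrs3"),
    moca = opt_num("moca"),
    mci = opt_flag("mci"),
    depression = opt_flag("depression"),
    rbd = opt_flag("rbd"),
    pigd = opt_flag("pigd"),
    etiv = num(raw$etiv),
    wm_hypo = opt_num("wm_hypo"),
    stringsAsFactors = FALSE)

  reasons <- character(nrow(rec))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reasons[cond] <<- ifelse(nzchar(reasons[cond]),
                             paste(reasons[cond], why, sep = "; "), why)
  }
  bad(!rec$group %in% c("PD", "HC"), "group must be PD or HC")
  bad(is.na(rec$etiv) | rec$etiv <= 0, "etiv must be > 0")
  bad(is.na(rec$age), "age missing or unparseable")
  bad(is.na(rec$field_strength), "field_strength must be 1.5 or 3")
  bad(!is.na(rec$moca) & (rec$moca < 0 | rec$moca > 30),
      "moca outside [0, 30]")
  drop <- nzchar(reasons)
  report <- data.frame(subject_id = rec$subject_id[drop],
                       reason = reasons[drop], stringsAsFactors = FALSE)
  out <- rec[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "validation_report") <- report
  out
}

#' Write a subject table to CSV/TSV
#'
#' Round-trips with [read_subject_table()] at full precision.
#'
#' @param subjects subject data.frame.
#' @param path output path; `.tsv` extension selects tab separation.
#' @export
write_subject_table <- function(subjects, path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(subjects, path, sep = sep, row.names = FALSE,
                     quote = TRUE, na = "")
  invisible(path)
}

#' Average left and right hemisphere columns into the 41-ROI panel
#'
#' Takes a wide table with `lh_<roi>` / `rh_<roi>` column pairs for every ROI
#' in [all_rois()] and returns the hemisphere-averaged [roi_matrix()]:
#' `value = (lh + rh) / 2`.
#'
#' @param wide data.frame or matrix with a `subject_id` column (or row names)
#'   and paired hemisphere columns.
#' @return An [roi_matrix()] with 41 columns.
#' @export
average_hemispheres <- function(wide) {
  wide <- as.data.frame(wide, stringsAsFactors = FALSE)
  if ("subject_id" %in% names(wide)) {
    ids <- as.character(wide$subject_id)
    wide <- wide[, setdiff(names(wide), "subject_id"), drop = FALSE]
  } else if (!is.null(rownames(wide))) {
    ids <- rownames(wide)
  } else stop("`wide` needs a subject_id column or row names")

  rois <- all_rois()
  lh <- paste0("lh_", rois)
  rh <- paste0("rh_", rois)
  have_l <- lh %in% names(wide)
  have_r <- rh %in% names(wide)
  unpaired <- rois[xor(have_l, have_r)]
  if (length(unpaired))
    stop("unpaired hemisphere column(s) for: ",
         paste(unpaired, collapse = ", "))
  present <- rois[have_l & have_r]
  if (length(present) < length(rois))
    stop("missing hemisphere pair(s) for: ",
         paste(setdiff(rois, present), collapse = ", "))
  vals <- (as.matrix(wide[, lh, drop = FALSE]) +
             as.matrix(wide[, rh, drop = FALSE])) / 2
  dimnames(vals) <- list(ids, rois)
  roi_matrix(vals)
}

#' White-matter-hypointensity burden as a fraction of intracranial volume
#'
#' @param wm_hypo WM-hypointensity volume (mm^3), or a subject record
#'   (data.frame row / list) with `wm_hypo` and `etiv` fields.
#' @param etiv estimated total intracranial volume (mm^3); must be positive.
#' @return Dimensionless ratio `wm_hypo / etiv`.
#' @export
wm_hypo_ratio <- function(wm_hypo, etiv = NULL) {
  if (is.null(etiv)) {
    rec <- wm_hypo
    wm_hypo <- rec$wm_hypo
    etiv <- rec$etiv
  }
  if (any(!is.na(etiv) & etiv <= 0)) stop("etiv must be > 0")
  wm_hypo / etiv
}
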
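# Per-patient paired cohort table and the subgroup comparison layer.

COHORT_COLUMNS <- c("id", "air_supine", "air_prone",
                    "distortion_supine", "distortion_prone",
                    "likert_supine", "likert_prone")

#' Construct a cohort table
#'
#' One row per patient with paired supine/prone posterior-half distortion
#' (mm), proximal rectal air (cm^3) and rectal-air Likert scores (1..5).
#'
#' @param df Data frame with columns
#'   `id, air_supine, air_prone, distortion_supine, distortion_prone,
#'   likert_supine, likert_prone`; extra rater-wise score columns are
#'   allowed if prefixed `likert_`.
#' @return A `cohort_table` (data.frame subclass).
#' @export
cohort_table <- function(df) {
  missing <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing))
    dd_stop(sprintf("missing cohort column(s): %s",
                    paste(missing, collapse = ", ")),
            "dwidistort_schema_error")
  unknown <- setdiff(names(df), COHORT_COLUMNS)
  unknown <- unknown[!startsWith(unknown, "likert_")]
  if (length(unknown))
    dd_stop(sprintf("unknown cohort column(s): %s",
                    paste(unknown, collapse = ", ")),
            "dwidistort_schema_error")
  num <- c("air_supine", "air_prone", "distortion_supine", "distortion_prone")
  for (cn in num) {
    if (!all(is.finite(df[[cn]])) || any(df[[cn]] < 0))
      dd_stop(sprintf("column %s must be finite and non-negative", cn),
              "dwidistort_validation_error")
  }
  for (cn in grep("^likert_", names(df), value = TRUE)) {
    if (!all(is_wholenumber(df[[cn]])) || any(df[[cn]] < 1 | df[[cn]] > 5))
      dd_stop(sprintf("column %s must hold Likert scores in 1..5", cn),
              "dwidistort_validation_error")
  }
  structure(as.data.frame(df), class = c("cohort_table", "data.frame"))
}

#' Read a cohort table from CSV
#'
#' @param path CSV path with the [cohort_table()] schema.
#' @return A `cohort_table`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    dd_stop(sprintf("file not found: %s", path), "dwidistort_format_error")
  cohort_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a cohort table to CSV
#'
#' @param cohort A [cohort_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

SCORE_COLUMNS <- c("subject", "rater", "item", "score")

#' Read an ordinal score table
#'
#' Delimited text with columns `subject, rater, item, score`; unknown
#' columns are rejected and scores must lie on the declared scale.
#'
#' @param path CSV path.
#' @param scale Numeric vector of allowed scores (default `1:5`).
#' @return Validated data.frame of score records.
#' @export
read_score_table <- function(path, scale = 1:5) {
  if (!file.exists(path))
    dd_stop(sprintf("file not found: %s", path), "dwidistort_format_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(SCORE_COLUMNS, names(df))
  if (length(missing))
    dd_stop(sprintf("missing score column(s): %s",
                    paste(missing, collapse = ", ")),
            "dwidistort_schema_error")
  unknown <- setdiff(names(df), SCORE_COLUMNS)
  if (length(unknown))
    dd_stop(sprintf("unknown score column(s): %s",
                    paste(unknown, collapse = ", ")),
            "dwidistort_schema_error")
  if (!all(df$score %in% scale))
    dd_stop(sprintf("score(s) outside declared scale {%s}",
                    paste(range(scale), collapse = "..")),
            "dwidistort_validation_error")
  df
}

paired_summary <- function(supine, prone) {
  ms <- median_iqr(supine); mp <- median_iqr(prone)
  wt <- withCallingHandlers(
    wilcoxon_signed_rank(supine, prone),
    warning = function(w) invokeRestart("muffleWarning"))
  list(supine = ms, prone = mp, p_value = wt$p.value)
}

#' Whole-cohort and high-air-subgroup paired comparisons
#'
#' Compares posterior distortion and proximal air between positions for the
#' whole cohort and for the subgroup with supine proximal air above
#' `v_thresh` (the logistic air threshold), each with median/IQR
#' descriptives and a paired Wilcoxon signed-rank p-value.  Also emits the
#' long-format scatter table of air versus distortion by position.
#'
#' @param cohort A [cohort_table()].
#' @param v_thresh Air-volume threshold in cm^3 defining the subgroup
#'   (default 4).
#' @return Object of class `cohort_summary`: `whole` and `subgroup`
#'   comparison lists (subgroup has `evaluable = FALSE` and `NA` p-values
#'   when fewer than 5 patients qualify), `v_thresh`, `n`, `n_subgroup`,
#'   and `scatter`.
#' @export
subgroup_compare <- function(cohort, v_thresh = 4) {
  stopifnot(inherits(cohort, "cohort_table"))
  compare_block <- function(tab) {
    list(distortion = paired_summary(tab$distortion_supine,
                                     tab$distortion_prone),
         air = paired_summary(tab$air_supine, tab$air_prone))
  }
  sub <- cohort[cohort$air_supine > v_thresh, ]
  subgroup <- if (nrow(sub) >= 5L) {
    c(compare_block(sub), evaluable = TRUE)
  } else {
    list(distortion = NULL, air = NULL, evaluable = FALSE)
  }
  scatter <- rbind(
    data.frame(id = cohort$id, position = "supine",
               air_cm3 = cohort$air_supine,
               distortion_mm = cohort$distortion_supine),
    data.frame(id = cohort$id, position = "prone",
               air_cm3 = cohort$air_prone,
               distortion_mm = cohort$distortion_prone))
  structure(list(whole = compare_block(cohort), subgroup = subgroup,
                 v_thresh = v_thresh, n = nrow(cohort),
                 n_subgroup = nrow(sub), scatter = scatter),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  fmt <- function(b, what, unit) {
    sprintf("  %-11s supine %.2f (%.2f-%.2f) vs prone %.2f (%.2f-%.2f) %s, p = %.3g",
            what, b$supine["median"], b$supine["q1"], b$supine["q3"],
            b$prone["median"], b$prone["q1"], b$prone["q3"], unit, b$p_value)
  }
  cat(sprintf("<cohort_summary> n = %d, subgroup (supine air > %.3g cm^3): n = %d\n",
              x$n, x$v_thresh, x$n_subgroup))
  cat("whole cohort:\n")
  cat(fmt(x$whole$distortion, "distortion", "mm"), "\n")
  cat(fmt(x$whole$air, "air", "cm^3"), "\n")
  if (isTRUE(x$subgroup$evaluable)) {
    cat("subgroup:\n")
    cat(fmt(x$subgroup$distortion, "distortion", "mm"), "\n")
    cat(fmt(x$subgroup$air, "air", "cm^3"), "\n")
  } else {
    cat("subgroup: not evaluable (fewer than 5 patients)\n")
  }
  invisible(x)
}
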
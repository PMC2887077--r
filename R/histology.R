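#' Within-biopsy differential histology score
#'
#' The differential score of a biopsy is its portal inflammation grade minus
#' its fibrosis stage, both ordinal 0-3 pathologist scores. Positive values
#' indicate inflammation-predominant histology, negative values
#' fibrosis-predominant histology.
#'
#' @param inflammation_grade integer vector of inflammation grades (0-3).
#' @param fibrosis_stage integer vector of fibrosis stages (0-3), same length.
#' @return Integer vector of signed differential scores in -3..3.
#' @examples
#' differentialScore(3, 1)  # +2, inflammation-predominant
#' differentialScore(0, 3)  # -3, fibrosis-predominant
#' @export
differentialScore <- function(inflammation_grade, fibrosis_stage) {
  .checkScoreVector(inflammation_grade, "inflammation_grade")
  .checkScoreVector(fibrosis_stage, "fibrosis_stage")
  if (length(inflammation_grade) != length(fibrosis_stage)) {
    stop("'inflammation_grade' and 'fibrosis_stage' must have the same length")
  }
  as.integer(inflammation_grade) - as.integer(fibrosis_stage)
}

.checkScoreVector <- function(x, field) {
  if (length(x) < 1L || !is.numeric(x) || anyNA(x) ||
      any(x != as.integer(x)) || any(x < 0L | x > 3L)) {
    stop(sprintf("'%s' must contain integer scores in 0..3", field))
  }
  invisible(TRUE)
}

#' Assign biopsies to histology-predominant groups
#'
#' Labels each subject `"inflammation"` when its differential score (grade
#' minus stage) is at least `threshold`, `"fibrosis"` when it is at most
#' `-threshold`, and `"mixed"` otherwise. The study's seed groups use
#' `threshold = 2`; the sensitivity variant uses `threshold = 1`.
#'
#' @param scores `data.frame` with columns `subject_id`,
#'   `inflammation_grade`, `fibrosis_stage` (extra columns are ignored).
#' @param threshold positive integer in 1..3.
#' @return A `data.frame` (class `"histology_groups"`) with columns
#'   `subject_id`, `inflammation_grade`, `fibrosis_stage`, `differential`,
#'   `label`, `threshold_used`; group counts are available through
#'   [histologyCounts()].
#' @examples
#' tab <- data.frame(subject_id = c("a", "b", "c"),
#'                   inflammation_grade = c(3, 1, 0),
#'                   fibrosis_stage = c(1, 1, 2))
#' g <- assignHistologyGroups(tab, threshold = 2)
#' histologyCounts(g)
#' @export
assignHistologyGroups <- function(scores, threshold = 2) {
  if (!is.data.frame(scores) || nrow(scores) < 1L) {
    stop("'scores' must be a nonempty data.frame")
  }
  needed <- c("subject_id", "inflammation_grade", "fibrosis_stage")
  missing <- setdiff(needed, names(scores))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !threshold %in% c(1, 2, 3)) {
    stop("'threshold' must be 1, 2 or 3")
  }
  if (anyDuplicated(scores$subject_id)) {
    stop("duplicate subject IDs: ",
         paste(unique(scores$subject_id[duplicated(scores$subject_id)]),
               collapse = ", "))
  }
  d <- differentialScore(scores$inflammation_grade, scores$fibrosis_stage)
  label <- ifelse(d >= threshold, "inflammation",
                  ifelse(d <= -threshold, "fibrosis", "mixed"))
  out <- data.frame(subject_id = as.character(scores$subject_id),
                    inflammation_grade = as.integer(scores$inflammation_grade),
                    fibrosis_stage = as.integer(scores$fibrosis_stage),
                    differential = d,
                    label = label,
                    threshold_used = as.integer(threshold),
                    stringsAsFactors = FALSE)
  class(out) <- c("histology_groups", "data.frame")
  out
}

#' Group counts of a histology partition
#'
#' @param groups result of [assignHistologyGroups()].
#' @return Named integer vector `c(n_inflammation, n_fibrosis, n_mixed)`;
#'   the three counts sum to the number of subjects.
#' @export
histologyCounts <- function(groups) {
  if (!inherits(groups, "histology_groups")) {
    stop("'groups' must come from assignHistologyGroups()")
  }
  c(n_inflammation = sum(groups$label == "inflammation"),
    n_fibrosis = sum(groups$label == "fibrosis"),
    n_mixed = sum(groups$label == "mixed"))
}
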
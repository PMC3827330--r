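#' UK grade-point schemes
#'
#' Point schemes for the UK secondary-school qualifications used throughout
#' the cohorts: pre-2010 A-levels (A = 10, B = 8, C = 6, D = 4, E = 2,
#' anything else 0, so best-three has a 30-point ceiling), GCSEs with the A*
#' grade (A* = 6 down to F = 0), and 1990-era GCSE/O-levels (A = 5 down to
#' F = 0, no A*).
#'
#' @param name one of `"alevel_pre2010"`, `"gcse_astar"`, `"gcse_1990"`.
#' @return an object of class `grade_scheme`: a list with `name`,
#'   `letter_to_points` (named integer vector, points strictly decreasing
#'   along the grade order), and `max_points_per_subject`.
#' @export
#' @examples
#' grade_scheme("alevel_pre2010")$letter_to_points
grade_scheme <- function(name = c("alevel_pre2010", "gcse_astar", "gcse_1990")) {
  name <- match.arg(name)
  pts <- switch(name,
    alevel_pre2010 = c(A = 10L, B = 8L, C = 6L, D = 4L, E = 2L),
    gcse_astar = c("A*" = 6L, A = 5L, B = 4L, C = 3L, D = 2L, E = 1L, F = 0L),
    gcse_1990 = c(A = 5L, B = 4L, C = 3L, D = 2L, E = 1L, F = 0L))
  structure(
    list(name = name, letter_to_points = pts,
         max_points_per_subject = max(pts)),
    class = "grade_scheme")
}

#' @export
print.grade_scheme <- function(x, ...) {
  cat("Grade scheme:", x$name, "\n")
  print(x$letter_to_points)
  invisible(x)
}

grade_points <- function(letters, scheme) {
  letters <- toupper(trimws(as.character(letters)))
  unknown <- setdiff(unique(letters), names(scheme$letter_to_points))
  if (length(unknown))
    stop(sprintf("unknown grade letter(s) %s for scheme '%s'",
                 paste(sQuote(unknown), collapse = ", "), scheme$name),
         call. = FALSE)
  unname(scheme$letter_to_points[letters])
}

#' Best-three A-level points
#'
#' Sum of the three highest A-level grade points under the pre-2010 scheme
#' (A = 10 ... E = 2), giving a score with a maximum of 30. Candidates with
#' fewer than three gradeable A-levels get `NA` rather than a partial sum,
#' matching the convention of reporting the score only for candidates with
#' three or more A-levels. General Studies is excluded by default.
#'
#' @param grades character vector of grade letters, or a data frame with
#'   columns `subject` and `grade`.
#' @param exclude_general_studies drop subjects named "General Studies"
#'   (case-insensitive) before scoring; only possible with data-frame input.
#' @param scheme a [grade_scheme()]; default pre-2010 A-level.
#' @return integer score (maximum 30 under the default scheme), or `NA` if
#'   fewer than three gradeable subjects remain.
#' @export
#' @examples
#' best_three_alevel_points(c("A", "A", "A"))        # 30
#' best_three_alevel_points(c("A", "A", "B", "C"))   # 28
best_three_alevel_points <- function(grades, exclude_general_studies = TRUE,
                                     scheme = grade_scheme("alevel_pre2010")) {
  if (is.data.frame(grades)) {
    stopifnot(all(c("subject", "grade") %in% names(grades)))
    if (exclude_general_studies)
      grades <- grades[tolower(trimws(grades$subject)) != "general studies", ,
                       drop = FALSE]
    grades <- grades$grade
  }
  grades <- grades[!is.na(grades)]
  if (length(grades) < 3L) return(NA_integer_)
  pts <- grade_points(grades, scheme)
  as.integer(sum(sort(pts, decreasing = TRUE)[1:3]))
}

#' GCSE/O-level summary scores
#'
#' Mean points per subject, total points across all subjects taken, and the
#' number of subjects, under a given grade-point scheme.
#'
#' @param grades character vector of grade letters (one per subject).
#' @param scheme a [grade_scheme()]; default the A*-bearing GCSE scheme.
#' @return named list `mean`, `total`, `count`; all `NA` for an empty grade
#'   list (no subjects is missing data, not a zero score).
#' @export
#' @examples
#' gcse_scores(rep("A*", 10))   # mean 6, total 60, count 10
gcse_scores <- function(grades, scheme = grade_scheme("gcse_astar")) {
  grades <- grades[!is.na(grades)]
  if (length(grades) == 0L)
    return(list(mean = NA_real_, total = NA_real_, count = NA_integer_))
  pts <- grade_points(grades, scheme)
  list(mean = mean(pts), total = sum(pts), count = length(pts))
}

#' Z-scores, optionally within groups
#'
#' Standardizes a numeric column to mean 0 and sample SD 1, within each level
#' of an optional grouping column (e.g. examination year, so that cohorts
#' sitting different papers become comparable). Missing values propagate and
#' are excluded from the group moments.
#'
#' @param values numeric vector.
#' @param groups optional grouping vector of the same length.
#' @return numeric vector of z-scores, same length and order as `values`.
#' @export
zscore <- function(values, groups = NULL) {
  values <- as.numeric(values)
  if (is.null(groups)) groups <- rep(1L, length(values))
  if (length(groups) != length(values))
    stop("'groups' must match 'values' in length", call. = FALSE)
  out <- rep(NA_real_, length(values))
  for (g in unique(groups[!is.na(values)])) {
    idx <- which(groups == g & !is.na(values))
    if (length(idx) < 2L)
      stop(sprintf("group '%s' has fewer than 2 non-missing values", g),
           call. = FALSE)
    s <- stats::sd(values[idx])
    if (!is.finite(s) || s == 0)
      stop(sprintf("group '%s' has zero spread; z-scores undefined", g),
           call. = FALSE)
    out[idx] <- (values[idx] - mean(values[idx])) / s
  }
  out
}

#' Combine O-level and GCSE mean grades into one standardized variable
#'
#' For cohorts straddling the O-level to GCSE transition, mean points per
#' subject on each examination type are z-scored over their own takers and
#' then coalesced into a single column. People with both examination types
#' are an error: mixed takers are excluded upstream because the two point
#' scales are not directly comparable.
#'
#' @param mean_gcse,mean_olevel numeric vectors of equal length; each person
#'   must have at most one of the two non-missing.
#' @return numeric vector: the within-type z-score of whichever mean the
#'   person has, `NA` if neither.
#' @export
combine_olevel_gcse <- function(mean_gcse, mean_olevel) {
  if (length(mean_gcse) != length(mean_olevel))
    stop("inputs must have equal length", call. = FALSE)
  both <- which(!is.na(mean_gcse) & !is.na(mean_olevel))
  if (length(both))
    stop(sprintf("%d person(s) have both GCSE and O-level means (e.g. row %d); mixed takers must be excluded upstream",
                 length(both), both[1]), call. = FALSE)
  out <- rep(NA_real_, length(mean_gcse))
  for (col in list(mean_gcse, mean_olevel)) {
    idx <- which(!is.na(col))
    if (length(idx)) out[idx] <- zscore(col)[idx]
  }
  out
}

#' Derive secondary-school scores from a long table of subject grades
#'
#' Reads (or takes) a long-format table with columns `person_id`,
#' `exam_type` (`"A-level"`, `"GCSE"`, or `"O-level"`), `subject`, `grade`,
#' and returns one row per person with the derived scores used downstream:
#' `best3_alevel`, `mean_gcse`, `total_gcse`, `n_gcse`.
#'
#' @param grades data frame or path to a CSV file with the four columns above.
#' @param gcse_scheme scheme for GCSE rows; default the A* scheme.
#' @return data frame with columns `person_id`, `best3_alevel`, `mean_gcse`,
#'   `total_gcse`, `n_gcse`.
#' @export
score_grades_table <- function(grades, gcse_scheme = grade_scheme("gcse_astar")) {
  if (is.character(grades))
    grades <- utils::read.csv(grades, stringsAsFactors = FALSE)
  need <- c("person_id", "exam_type", "subject", "grade")
  miss <- setdiff(need, names(grades))
  if (length(miss))
    stop("grades table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ids <- unique(grades$person_id)
  out <- data.frame(person_id = ids, best3_alevel = NA_integer_,
                    mean_gcse = NA_real_, total_gcse = NA_real_,
                    n_gcse = NA_integer_)
  for (i in seq_along(ids)) {
    g <- grades[grades$person_id == ids[i], , drop = FALSE]
    al <- g[g$exam_type == "A-level", , drop = FALSE]
    if (nrow(al)) {
      if (anyDuplicated(al$subject))
        stop("duplicate A-level subjects for person ", ids[i], call. = FALSE)
      out$best3_alevel[i] <- best_three_alevel_points(al)
    }
    gc <- g[g$exam_type %in% c("GCSE", "O-level"), , drop = FALSE]
    if (nrow(gc)) {
      sc <- gcse_scores(gc$grade, gcse_scheme)
      out$mean_gcse[i] <- sc$mean
      out$total_gcse[i] <- sc$total
      out$n_gcse[i] <- sc$count
    }
  }
  out
}
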
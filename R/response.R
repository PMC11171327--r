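#' Response categories
#'
#' The ordinal five-level response scale used in preclinical xenograft
#' testing, from worst to best: progressive disease (PD), stable disease
#' (SD), partial response (PR), complete response (CR), maintained complete
#' response (MCR).  Ordinal codes run 0 (PD) to 4 (MCR).  PR, CR and MCR are
#' objective responses.
#'
#' @format Character vector of the five category labels in ordinal order.
#' @export
RESPONSE_LEVELS <- c("PD", "SD", "PR", "CR", "MCR")

response_call <- function(category) {
  category <- match.arg(category, RESPONSE_LEVELS)
  structure(list(category = category,
                 ordinal = match(category, RESPONSE_LEVELS) - 1L,
                 objective = category %in% c("PR", "CR", "MCR")),
            class = "response_call")
}

#' @export
print.response_call <- function(x, ...) {
  cat(sprintf("%s (ordinal %d%s)\n", x$category, x$ordinal,
              if (x$objective) ", objective response" else ""))
  invisible(x)
}

# Length of the longest run of TRUE restricted to positions where `after`
# is also TRUE (runs must lie wholly in the `after` region).
longest_true_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Classify one animal's tumor response
#'
#' Applies the five-level response rules to a volume trajectory, with
#' precedence MCR > CR > PR > SD > PD so exactly one category is assigned:
#' \itemize{
#'   \item MCR: no measurable tumor for at least three consecutive readings,
#'     all recorded after treatment has been completed;
#'   \item CR: tumor unmeasurable at least twice during the study
#'     (consecutively or intermittently), MCR not met;
#'   \item PR: at least 50% regression from baseline at some point
#'     (min relative volume <= 0.5), neither CR nor MCR met;
#'   \item SD: less than 50% regression throughout and no more than 25%
#'     growth at the end of study (final relative volume <= 1.25);
#'   \item PD: less than 50% regression throughout and more than 25% growth
#'     at the end of study.
#' }
#' "End of study" is the animal's last available reading, which for animals
#' whose tumor quadrupled is the termination reading.  An isolated single
#' unmeasurable reading is not CR; with precedence it classifies as PR (the
#' regression is at least 50% at that reading).
#'
#' @param traj A [trajectory()]; needs at least two readings.
#' @param measurable_min Volume at or below which a reading counts as
#'   unmeasurable.  Default 0: only a volume recorded as exactly 0 is
#'   unmeasurable.
#' @return A `"response_call"`: list with `category`, `ordinal` (0-4), and
#'   `objective` (logical).
#' @examples
#' classify_animal(trajectory(c(0, 7, 14, 21), c(100, 40, 80, 120)))  # PR
#' @export
classify_animal <- function(traj, measurable_min = 0) {
  stopifnot(inherits(traj, "trajectory"), measurable_min >= 0)
  if (length(traj$days) < 2L)
    stop("cannot classify a trajectory with a single reading", call. = FALSE)
  v <- traj$volumes
  r <- relative_volumes(traj)
  unmeasurable <- v <= measurable_min

  post_treatment <- traj$days > traj$treatment_end_day
  if (longest_true_run(unmeasurable & post_treatment) >= 3L)
    return(response_call("MCR"))
  if (sum(unmeasurable) >= 2L)
    return(response_call("CR"))
  if (min(r) <= 0.5)
    return(response_call("PR"))
  if (r[length(r)] <= 1.25)
    return(response_call("SD"))
  response_call("PD")
}

#' Aggregate per-animal calls to a group response
#'
#' The group category is the median of the per-animal ordinal codes; a
#' half-integer median is rounded down, toward the worse response
#' (pessimistic convention).  The objective flag is recomputed from the
#' resulting category.
#'
#' @param calls List of `"response_call"` objects (at least one).
#' @param arm Arm label attached to the result.
#' @return A `"group_response"`: list with `arm`, `per_animal`,
#'   `group_category` (a `"response_call"`), and `n_animals`.
#' @export
classify_group <- function(calls, arm = "arm") {
  if (!length(calls))
    stop("cannot aggregate an empty list of response calls", call. = FALSE)
  ords <- vapply(calls, function(x) x$ordinal, integer(1))
  med <- floor(stats::median(ords))
  structure(list(arm = arm, per_animal = calls,
                 group_category = response_call(RESPONSE_LEVELS[med + 1L]),
                 n_animals = length(calls)),
            class = "group_response")
}

#' @export
print.group_response <- function(x, ...) {
  cat(sprintf("Arm %s (n = %d): %s%s\n", x$arm, x$n_animals,
              x$group_category$category,
              if (x$group_category$objective) " (objective response)" else ""))
  invisible(x)
}

#' Count objective responses across models
#'
#' An objective response is a group-level PR, CR or MCR.  Accepts
#' `"group_response"` objects, `"response_call"` objects, or bare category
#' strings (as printed in an activity table).
#'
#' @param groups List (or character vector) of per-model activity calls.
#' @return Integer count of objective responders.
#' @examples
#' objective_response_count(c("MCR", "CR", "MCR", "PR", "PR", "PD"))  # 5
#' @export
objective_response_count <- function(groups) {
  cat_of <- function(g) {
    if (inherits(g, "group_response")) g$group_category$category
    else if (inherits(g, "response_call")) g$category
    else match.arg(as.character(g), RESPONSE_LEVELS)
  }
  cats <- vapply(groups, cat_of, character(1))
  sum(cats %in% c("PR", "CR", "MCR"))
}

#' Classify every animal in a cohort and summarize by arm
#'
#' @param trajs List of [trajectory()] objects.
#' @param measurable_min Passed to [classify_animal()].
#' @return A list with `per_animal` (data.frame: model, arm, animal_id,
#'   category, objective) and `groups` (one `"group_response"` per arm, in
#'   order of first appearance).
#' @export
classify_cohort <- function(trajs, measurable_min = 0) {
  calls <- lapply(trajs, classify_animal, measurable_min = measurable_min)
  df <- data.frame(
    model = vapply(trajs, `[[`, character(1), "model_id"),
    arm = vapply(trajs, `[[`, character(1), "arm"),
    animal_id = vapply(trajs, `[[`, character(1), "animal_id"),
    category = vapply(calls, `[[`, character(1), "category"),
    objective = vapply(calls, `[[`, logical(1), "objective"),
    stringsAsFactors = FALSE)
  arms <- unique(df$arm)
  groups <- lapply(arms, function(a) classify_group(calls[df$arm == a], arm = a))
  names(groups) <- arms
  list(per_animal = df, groups = groups)
}
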
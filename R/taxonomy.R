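#' @useDynLib wristfunc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd quantile rnorm runif fft predict coef lm
#' @importFrom utils read.csv write.csv
NULL

# Category vocabularies, in the order they are reported.
TYPE_LEVELS <- c("Sedentary", "Locomotion", "Lifestyle", "SFE")
INTENSITY_LEVELS <- c("Low", "Light", "Moderate")
GROUP_LEVELS <- c("LPP", "HPP")

#' Canonicalize an activity name
#'
#' Uppercases and collapses internal whitespace so that lookups are
#' insensitive to case and irregular spacing in the printed labels.
#'
#' @param x character vector of activity names.
#' @return canonical names, same length.
#' @export
canonical_activity_name <- function(x) {
  x <- toupper(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Load the activity catalog
#'
#' The catalog maps each of the 33 standardized laboratory activities to its
#' activity-type category (Sedentary, Locomotion, Lifestyle, SFE) and
#' intensity category (Low, Light, Moderate). The default file shipped with
#' the package encodes the study battery; an alternative file with the same
#' columns may be supplied.
#'
#' @param path optional path to a delimited file with columns
#'   `activity_name`, `type_category`, `intensity_category`.
#' @return data.frame with canonicalized activity names.
#' @export
activity_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "activity_catalog.csv", package = "wristfunc")
  }
  cat_df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("activity_name", "type_category", "intensity_category")
  if (!all(need %in% names(cat_df))) {
    stop("catalog must have columns: ", paste(need, collapse = ", "))
  }
  cat_df$activity_name <- canonical_activity_name(cat_df$activity_name)
  if (anyDuplicated(cat_df$activity_name)) {
    stop("catalog contains duplicate activity names")
  }
  bad_type <- setdiff(unique(cat_df$type_category), TYPE_LEVELS)
  bad_int <- setdiff(unique(cat_df$intensity_category), INTENSITY_LEVELS)
  if (length(bad_type)) stop("unknown type categories: ", paste(bad_type, collapse = ", "))
  if (length(bad_int)) stop("unknown intensity categories: ", paste(bad_int, collapse = ", "))
  cat_df
}

#' Assign the physical performance group from an SPPB score
#'
#' The Short Physical Performance Battery summary score ranges 0--12;
#' scores of 9 or below define the low physical performance (LPP) group,
#' scores above 9 the high physical performance (HPP) group.
#'
#' @param sppb_score integer vector, each in 0--12.
#' @return character vector of "LPP"/"HPP".
#' @export
assign_group <- function(sppb_score) {
  if (length(sppb_score) == 0) stop("sppb_score is empty")
  if (!is.numeric(sppb_score) || any(!is.finite(sppb_score))) {
    stop("sppb_score must be a finite integer in 0-12")
  }
  if (any(sppb_score != round(sppb_score))) {
    stop("sppb_score must be an integer")
  }
  if (any(sppb_score < 0 | sppb_score > 12)) {
    stop("sppb_score out of range 0-12")
  }
  ifelse(sppb_score <= 9, "LPP", "HPP")
}

#' Map an activity name to its type and intensity categories
#'
#' @param activity_name character vector; matched case/whitespace
#'   insensitively against the catalog.
#' @param catalog catalog data.frame from [activity_catalog()].
#' @return data.frame with columns `activity_name`, `type_category`,
#'   `intensity_category`, one row per input.
#' @export
map_activity <- function(activity_name, catalog = activity_catalog()) {
  key <- canonical_activity_name(activity_name)
  idx <- match(key, catalog$activity_name)
  if (anyNA(idx)) {
    stop(
      "unknown activity: ", paste(unique(key[is.na(idx)]), collapse = ", "),
      "; valid names: ", paste(catalog$activity_name, collapse = ", ")
    )
  }
  data.frame(
    activity_name = key,
    type_category = catalog$type_category[idx],
    intensity_category = catalog$intensity_category[idx],
    stringsAsFactors = FALSE
  )
}

#' Enumerate the full grid of model configurations
#'
#' The experiment grid crosses task kind, target class, algorithm and cohort:
#' 4 binary type tasks x 2 algorithms x 3 cohorts (24), 3 binary intensity
#' tasks x 2 x 3 (18), one multiclass individual-activity task with boosted
#' trees only x 3 cohorts (3), and energy-expenditure regression x 2 x 3 (6),
#' 51 configurations in total, in deterministic
#' (kind, class, algorithm, cohort) order.
#'
#' @return data.frame with columns `task_kind`, `positive_class`,
#'   `algorithm`, `cohort`.
#' @export
enumerate_model_configs <- function() {
  algos <- c("boosted_trees", "l1_linear")
  cohorts <- c("LPP", "HPP", "ALL")
  grid_for <- function(kind, classes, algorithms) {
    g <- expand.grid(
      cohort = cohorts, algorithm = algorithms, positive_class = classes,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    data.frame(
      task_kind = kind,
      positive_class = g$positive_class,
      algorithm = g$algorithm,
      cohort = g$cohort,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(
    grid_for("binary_type", TYPE_LEVELS, algos),
    grid_for("binary_intensity", INTENSITY_LEVELS, algos),
    grid_for("multiclass_activity", NA_character_, "boosted_trees"),
    grid_for("regression_ee", NA_character_, algos)
  )
  rownames(out) <- NULL
  out
}

#' Construct a single task specification
#'
#' @param task_kind one of binary_type, binary_intensity,
#'   multiclass_activity, regression_ee.
#' @param positive_class target category for binary tasks, else `NA`.
#' @param algorithm "boosted_trees" or "l1_linear".
#' @param cohort "LPP", "HPP" or "ALL".
#' @return a `task_spec` list.
#' @export
task_spec <- function(task_kind, positive_class = NA_character_,
                      algorithm = "boosted_trees", cohort = "ALL") {
  task_kind <- match.arg(task_kind, c(
    "binary_type", "binary_intensity",
    "multiclass_activity", "regression_ee"
  ))
  algorithm <- match.arg(algorithm, c("boosted_trees", "l1_linear"))
  cohort <- match.arg(cohort, c("LPP", "HPP", "ALL"))
  if (task_kind == "binary_type" && !positive_class %in% TYPE_LEVELS) {
    stop("binary_type positive_class must be one of ", paste(TYPE_LEVELS, collapse = ", "))
  }
  if (task_kind == "binary_intensity" && !positive_class %in% INTENSITY_LEVELS) {
    stop("binary_intensity positive_class must be one of ", paste(INTENSITY_LEVELS, collapse = ", "))
  }
  if (task_kind == "multiclass_activity" && algorithm != "boosted_trees") {
    stop("multiclass_activity supports boosted_trees only")
  }
  if (task_kind %in% c("multiclass_activity", "regression_ee")) {
    positive_class <- NA_character_
  }
  structure(
    list(
      task_kind = task_kind, positive_class = positive_class,
      algorithm = algorithm, cohort = cohort
    ),
    class = "task_spec"
  )
}

#' @export
format.task_spec <- function(x, ...) {
  cls <- if (is.na(x$positive_class)) "" else paste0(":", x$positive_class)
  paste0(x$task_kind, cls, "/", x$algorithm, "/", x$cohort)
}

#' @export
print.task_spec <- function(x, ...) {
  cat("<task_spec> ", format(x), "\n", sep = "")
  invisible(x)
}
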
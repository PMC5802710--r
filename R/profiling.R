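#' Nearest-rank empirical percentile
#'
#' The order statistic at rank `ceiling(q * n)` of the sample: an actual
#' observed value, which makes the flagged fraction within the reference
#' sample exact (`ceiling(q n) / n` when there are no ties) and the cutoff
#' invariant under strictly increasing transforms of the measure.
#'
#' @param x Numeric sample.
#' @param q Level in (0, 1).
#' @return One element of `x`.
#' @keywords internal
nearest_rank <- function(x, q) {
  n <- length(x)
  sort(x)[min(n, max(1L, ceiling(q * n)))]
}

cutoff_one <- function(x, q, direction, estimator) {
  if (estimator == "nearest-rank") {
    # upper cutoff mirrors the lower: the ceiling(q*n)-th largest value
    if (direction == "flag-low") nearest_rank(x, q) else -nearest_rank(-x, q)
  } else {
    lev <- if (direction == "flag-low") q else 1 - q
    unname(stats::quantile(x, lev, type = 7))
  }
}

#' Derive per-measure cutoffs from the control population
#'
#' For every configured measure, takes the control group's empirical
#' percentile at level `q` (deviant tail low) or `1 - q` (deviant tail high).
#' The default estimator is the nearest-rank order statistic; see
#' [profiling_config()] for the interpolated alternative. A measure that is
#' constant across all controls yields a degenerate cutoff — under the
#' inclusive comparison rule every animal tying the constant is flagged — so a
#' warning is raised and recorded on the returned object rather than silently
#' dropping the measure (dropping would change m and hence the k-of-m
#' criterion).
#'
#' @param control A `behavior_table` containing only control-group rows.
#' @param config A [profiling_config()].
#' @return An object of class `cutoff_set`: a list with `cutoffs` (data.frame
#'   `measure`, `direction`, `cutoff`), `q`, `control_n`, `estimator`,
#'   `inclusive` and `warnings`.
#' @export
#' @examples
#' cfg <- profiling_config(measures = list(measure_spec("m1", "cm", "flag-low")),
#'                         k = 1, min_control_n = 10)
#' ctrl <- as_behavior_table(
#'   data.frame(animal_id = as.character(1:10), group = "control", m1 = 1:10),
#'   cfg)
#' compute_cutoffs(ctrl, cfg)
compute_cutoffs <- function(control, config) {
  stopifnot(inherits(config, "profiling_config"))
  control <- as_behavior_table(as.data.frame(control), config)
  if (!all(control$group == config$control_group)) {
    stop(sprintf("control table contains non-control rows (expected group '%s')",
                 config$control_group), call. = FALSE)
  }
  n <- nrow(control)
  if (n < config$min_control_n) {
    stop(sprintf("control group too small for percentile cutoffs: n = %d < %d",
                 n, config$min_control_n), call. = FALSE)
  }
  nm <- measure_names(config)
  dir <- measure_directions(config)
  cut <- numeric(length(nm))
  warn <- character(0)
  for (i in seq_along(nm)) {
    v <- control[[nm[i]]]
    if (length(unique(v)) == 1L) {
      msg <- sprintf(
        "measure '%s' is constant (%g) across controls; inclusive flagging will flag every tying animal",
        nm[i], v[1L])
      warning(msg, call. = FALSE)
      warn <- c(warn, msg)
    }
    cut[i] <- cutoff_one(v, config$q, dir[i], config$estimator)
  }
  structure(
    list(cutoffs = data.frame(measure = nm, direction = unname(dir),
                              cutoff = cut, stringsAsFactors = FALSE),
         q = config$q, control_n = n, estimator = config$estimator,
         inclusive = config$inclusive, warnings = warn),
    class = "cutoff_set")
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat(sprintf("<cutoff_set> q = %.2f from %s controls (%s, %s comparisons)\n",
              x$q, format(x$control_n), x$estimator,
              if (x$inclusive) "inclusive" else "strict"))
  print(x$cutoffs, row.names = FALSE)
  if (length(x$warnings)) cat("warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Flag deviant measures for every animal
#'
#' Compares each animal's value on each measure with the control-derived
#' cutoff: a flag-low measure is deviant when the value is at or below the
#' cutoff, a flag-high measure when at or above it (strict `<` / `>` when the
#' cutoff set was built with `inclusive = FALSE`).
#'
#' @param table A `behavior_table` (any groups).
#' @param cutoffs A [compute_cutoffs()] result.
#' @return A logical matrix, one row per animal (rownames = `animal_id`), one
#'   column per measure; `TRUE` = deviant.
#' @export
flag_animals <- function(table, cutoffs) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  if (!is.data.frame(table)) stop("'table' must be a data.frame", call. = FALSE)
  nm <- cutoffs$cutoffs$measure
  absent <- setdiff(nm, names(table))
  if (length(absent)) {
    stop("table is missing measure(s) present in the cutoff set: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  flags <- matrix(FALSE, nrow(table), length(nm),
                  dimnames = list(table$animal_id, nm))
  for (i in seq_along(nm)) {
    v <- table[[nm[i]]]
    cut <- cutoffs$cutoffs$cutoff[i]
    flags[, i] <- if (cutoffs$cutoffs$direction[i] == "flag-low") {
      if (cutoffs$inclusive) v <= cut else v < cut
    } else {
      if (cutoffs$inclusive) v >= cut else v > cut
    }
  }
  flags
}

#' Classify a flag vector under the k-of-m criterion
#'
#' @param flags Logical vector, one entry per configured measure.
#' @param config A [profiling_config()].
#' @return A list with `deviation_count` (number of deviant measures) and
#'   `affected` (`TRUE` when `deviation_count >= k`).
#' @export
#' @examples
#' classify_flags(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
#'                profiling_config())  # 4 of 7 deviant -> affected
classify_flags <- function(flags, config) {
  stopifnot(inherits(config, "profiling_config"))
  if (!is.logical(flags) || length(flags) != length(config$measures)) {
    stop(sprintf("'flags' must be a logical vector of length %d",
                 length(config$measures)), call. = FALSE)
  }
  dc <- sum(flags)
  list(deviation_count = dc, affected = dc >= config$k)
}

#' Profile every animal and tally affected counts per group
#'
#' Runs the full CBC classification: flags each animal on every measure
#' against the control cutoffs, applies the k-of-m criterion, and tallies
#' (n, n_affected) per group. The control group is profiled against its own
#' cutoffs like every other group (no leave-one-out), so its affected
#' proportion is an ordinary, reportable quantity.
#'
#' @param table A `behavior_table` holding all groups.
#' @param cutoffs A [compute_cutoffs()] result.
#' @param config A [profiling_config()]. When `config$groups` is set, any
#'   group label absent from it is a validation error.
#' @return A list of class `profiling_result` with
#'   \describe{
#'     \item{profiles}{data.frame: `animal_id`, `group`, one 0/1 column
#'       `flag_<measure>` per measure, `deviation_count`, `affected`.}
#'     \item{distributions}{data.frame: `group`, `n`, `n_affected`,
#'       `prop_affected`, one row per group (groups with no rows get n = 0).}
#'   }
#' @export
profile_groups <- function(table, cutoffs, config) {
  stopifnot(inherits(config, "profiling_config"))
  table <- as_behavior_table(as.data.frame(table), config)
  group_levels <- if (!is.null(config$groups)) {
    unknown <- setdiff(unique(table$group), config$groups$group)
    if (length(unknown)) {
      stop("unknown group label(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    config$groups$group
  } else {
    unique(table$group)
  }
  flags <- flag_animals(table, cutoffs)
  dc <- as.integer(rowSums(flags))
  affected <- dc >= config$k
  profiles <- data.frame(animal_id = table$animal_id, group = table$group,
                         stringsAsFactors = FALSE)
  for (m in colnames(flags)) profiles[[paste0("flag_", m)]] <- as.integer(flags[, m])
  profiles$deviation_count <- dc
  profiles$affected <- affected
  n <- vapply(group_levels, function(g) sum(table$group == g), integer(1))
  na <- vapply(group_levels, function(g) sum(affected[table$group == g]), integer(1))
  distributions <- data.frame(group = group_levels, n = unname(n),
                              n_affected = unname(na),
                              prop_affected = ifelse(n > 0, na / n, 0),
                              stringsAsFactors = FALSE, row.names = NULL)
  structure(list(profiles = profiles, distributions = distributions),
            class = "profiling_result")
}

#' @export
print.profiling_result <- function(x, ...) {
  cat(sprintf("<profiling_result> %d animals\n", nrow(x$profiles)))
  print(x$distributions, row.names = FALSE)
  invisible(x)
}

#' Closed-form false-positive rate of the k-of-m criterion
#'
#' If every one of m measures flags independently with probability `q`, the
#' probability that an unaffected animal is classified affected is the
#' binomial upper tail `P(X >= k)`, `X ~ Binomial(m, q)`. With the defaults
#' (m = 7, k = 4, q = 0.2) this is about 0.0334 — the k-of-m rule keeps the
#' nominal per-measure 20% tail from flooding the classification.
#'
#' @param m Number of measures.
#' @param k Affected criterion.
#' @param q Per-measure flag probability.
#' @return A probability.
#' @export
#' @examples
#' kofm_null_rate()  # 0.033344
kofm_null_rate <- function(m = 7L, k = 4L, q = 0.20) {
  stopifnot(m >= 1L, k >= 1L, k <= m, q > 0, q < 1)
  stats::pbinom(k - 1L, m, q, lower.tail = FALSE)
}
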
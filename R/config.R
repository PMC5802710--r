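#' Declare one behavioral measure
#'
#' A measure specification names one per-animal summary measure (e.g. distance
#' covered in the open arms) and states which tail of the control
#' distribution counts as deviant. Anxiety-like deviation in the elevated plus
#' maze (EPM) usually means *low* open-arm activity, so most EPM measures are
#' `"flag-low"`; a measure where anxious animals score *high* (e.g. time spent
#' in the closed arms) is `"flag-high"`.
#'
#' @param name Measure name; must match a column of the behavior table.
#' @param units Free-text units (`"cm"`, `"s"`, `"ratio"`). Informational.
#' @param direction `"flag-low"` if values at or below the lower percentile
#'   cutoff are deviant, `"flag-high"` if values at or above the upper
#'   percentile cutoff are deviant.
#' @return An object of class `measure_spec`.
#' @seealso [profiling_config()], [default_epm_measures()]
#' @export
#' @examples
#' measure_spec("open_arm_duration", "s", "flag-low")
measure_spec <- function(name, units = "", direction = c("flag-low", "flag-high")) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("'name' must be a single non-empty string", call. = FALSE)
  }
  direction <- match.arg(direction)
  structure(list(name = name, units = as.character(units)[1L],
                 direction = direction),
            class = "measure_spec")
}

#' @export
print.measure_spec <- function(x, ...) {
  cat(sprintf("<measure> %s [%s], deviant tail: %s\n",
              x$name, x$units, x$direction))
  invisible(x)
}

#' Default seven-measure EPM panel
#'
#' A plausible panel of seven distance/duration EPM measures used for k-of-m
#' profiling: open- and closed-arm distance and duration, total distance, and
#' the two open/closed anxiety indices (lower ratios = higher anxiety). This
#' panel is a documented stand-in: studies differ in which seven distance and
#' duration measures they profile, and the panel is fully configurable.
#'
#' @return A list of seven [measure_spec()] objects.
#' @export
default_epm_measures <- function() {
  list(
    measure_spec("open_arm_distance",      "cm",    "flag-low"),
    measure_spec("open_arm_duration",      "s",     "flag-low"),
    measure_spec("closed_arm_distance",    "cm",    "flag-low"),
    measure_spec("closed_arm_duration",    "s",     "flag-high"),
    measure_spec("total_distance",         "cm",    "flag-low"),
    measure_spec("distance_anxiety_index", "ratio", "flag-low"),
    measure_spec("duration_anxiety_index", "ratio", "flag-low")
  )
}

#' Profiling configuration
#'
#' Bundles everything the cutoff-behavioral-criteria (CBC) pipeline needs to
#' know: the measure panel, the percentile level `q` used for the control
#' cutoffs, the k-of-m affected criterion, the control group label, optional
#' group metadata for the two-way ANOVA, and the reference proportions for the
#' goodness-of-fit tests.
#'
#' @param measures List of [measure_spec()] objects (the m measures).
#' @param q Percentile level in (0, 1); cutoffs are taken at level `q`
#'   (flag-low) or `1 - q` (flag-high) of the control distribution.
#' @param k Affected criterion: an animal is affected when it is deviant on at
#'   least `k` of the m measures. Must satisfy `1 <= k <= m`.
#' @param control_group Group label of the reference (unstressed, untreated)
#'   population the cutoffs are derived from.
#' @param groups Optional `data.frame` with columns `group`, `stress`, `drug`
#'   mapping every group label to its two design factors; required for the
#'   pipeline's ANOVA stage and used to validate group labels.
#' @param reference Length-2 numeric, reference (affected, unaffected)
#'   proportions for the goodness-of-fit test; defaults to 20:80, the
#'   proportion of controls expected at or beyond a 20th-percentile cutoff.
#' @param baseline_group Optional group label; when set, the pipeline also
#'   tests every other group against this group's empirical affected
#'   proportion rounded to two decimals.
#' @param responses Character vector of measure names analyzed by the ANOVA
#'   stage.
#' @param min_control_n Smallest control group accepted for cutoff
#'   derivation; percentiles from tiny reference samples are refused.
#' @param inclusive Logical; if `TRUE` (default) comparisons with the cutoff
#'   are inclusive (`<=` / `>=`), so the control animal defining the cutoff is
#'   itself flagged.
#' @param estimator Percentile estimator, `"nearest-rank"` (the order
#'   statistic at rank `ceiling(q * n)`; default) or `"interpolated"`
#'   (type-7 interpolated quantile).
#' @return An object of class `profiling_config`.
#' @export
#' @examples
#' cfg <- profiling_config()
#' measure_names(cfg)
profiling_config <- function(measures = default_epm_measures(),
                             q = 0.20,
                             k = 4L,
                             control_group = "control",
                             groups = NULL,
                             reference = c(affected = 0.20, unaffected = 0.80),
                             baseline_group = NULL,
                             responses = c("total_distance",
                                           "distance_anxiety_index",
                                           "duration_anxiety_index"),
                             min_control_n = 10L,
                             inclusive = TRUE,
                             estimator = c("nearest-rank", "interpolated")) {
  if (inherits(measures, "measure_spec")) measures <- list(measures)
  if (!is.list(measures) || length(measures) == 0L ||
      !all(vapply(measures, inherits, logical(1), "measure_spec"))) {
    stop("'measures' must be a non-empty list of measure_spec objects",
         call. = FALSE)
  }
  nm <- vapply(measures, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate measure names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0 || q >= 1) {
    stop("'q' must be a single number in (0, 1)", call. = FALSE)
  }
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > length(measures)) {
    stop(sprintf("'k' must be an integer in [1, %d]", length(measures)),
         call. = FALSE)
  }
  reference <- check_reference(reference)
  if (!is.null(groups)) {
    if (!is.data.frame(groups) || !all(c("group", "stress", "drug") %in% names(groups))) {
      stop("'groups' must be a data.frame with columns group, stress, drug",
           call. = FALSE)
    }
    groups[] <- lapply(groups, as.character)
    if (anyDuplicated(groups$group)) {
      stop("duplicate group labels in 'groups'", call. = FALSE)
    }
    if (!control_group %in% groups$group) {
      stop(sprintf("control group '%s' missing from 'groups'", control_group),
           call. = FALSE)
    }
    if (!is.null(baseline_group) && !baseline_group %in% groups$group) {
      stop(sprintf("baseline group '%s' missing from 'groups'", baseline_group),
           call. = FALSE)
    }
  }
  min_control_n <- as.integer(min_control_n)
  if (is.na(min_control_n) || min_control_n < 2L) {
    stop("'min_control_n' must be an integer >= 2", call. = FALSE)
  }
  estimator <- match.arg(estimator)
  structure(
    list(measures = measures, q = q, k = k,
         control_group = as.character(control_group)[1L],
         groups = groups, reference = reference,
         baseline_group = if (is.null(baseline_group)) NULL else as.character(baseline_group)[1L],
         responses = as.character(responses),
         min_control_n = min_control_n,
         inclusive = isTRUE(inclusive),
         estimator = estimator),
    class = "profiling_config")
}

# reference proportions: two positive numbers summing to 1
check_reference <- function(reference) {
  reference <- as.numeric(reference)
  if (length(reference) != 2L || any(!is.finite(reference)) ||
      any(reference <= 0) || any(reference >= 1)) {
    stop("'reference' must be two proportions in (0, 1)", call. = FALSE)
  }
  if (abs(sum(reference) - 1) > 1e-8) {
    stop("'reference' proportions must sum to 1", call. = FALSE)
  }
  names(reference) <- c("affected", "unaffected")
  reference
}

#' @export
print.profiling_config <- function(x, ...) {
  cat(sprintf("<profiling_config> %d measures, q = %.2f, criterion k >= %d\n",
              length(x$measures), x$q, x$k))
  cat(sprintf("  control group: %s; reference %.0f:%.0f; estimator: %s (%s)\n",
              x$control_group, 100 * x$reference[1], 100 * x$reference[2],
              x$estimator, if (x$inclusive) "inclusive" else "strict"))
  for (m in x$measures) {
    cat(sprintf("  - %-24s [%s] %s\n", m$name, m$units, m$direction))
  }
  invisible(x)
}

#' Names and deviant directions of the configured measures
#'
#' @param config A [profiling_config()].
#' @return `measure_names()`: character vector of measure names;
#'   `measure_directions()`: named character vector of `"flag-low"`/
#'   `"flag-high"`.
#' @export
measure_names <- function(config) {
  stopifnot(inherits(config, "profiling_config"))
  vapply(config$measures, `[[`, character(1), "name")
}

#' @rdname measure_names
#' @export
measure_directions <- function(config) {
  stopifnot(inherits(config, "profiling_config"))
  d <- vapply(config$measures, `[[`, character(1), "direction")
  names(d) <- measure_names(config)
  d
}

#' Read a profiling configuration from a YAML file
#'
#' The file declares the measure panel (name, units, direction), the
#' percentile level, the k-of-m criterion, the control group, the group ->
#' (stress, drug) design map, the goodness-of-fit reference proportions, and
#' optionally a baseline group and the ANOVA response measures. Fields left
#' out fall back to the [profiling_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A [profiling_config()].
#' @export
read_profiling_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$measures)) {
    args$measures <- lapply(y$measures, function(m) {
      if (is.null(m$name) || is.null(m$direction)) {
        stop("each configured measure needs 'name' and 'direction'",
             call. = FALSE)
      }
      measure_spec(m$name, if (is.null(m$units)) "" else m$units, m$direction)
    })
  }
  if (!is.null(y$percentile_level)) args$q <- y$percentile_level
  if (!is.null(y$criterion_k))      args$k <- y$criterion_k
  if (!is.null(y$control_group))    args$control_group <- y$control_group
  if (!is.null(y$reference))        args$reference <- unlist(y$reference)
  if (!is.null(y$baseline_group))   args$baseline_group <- y$baseline_group
  if (!is.null(y$responses))        args$responses <- unlist(y$responses)
  if (!is.null(y$min_control_n))    args$min_control_n <- y$min_control_n
  if (!is.null(y$inclusive))        args$inclusive <- y$inclusive
  if (!is.null(y$estimator))        args$estimator <- y$estimator
  if (!is.null(y$groups)) {
    args$groups <- do.call(rbind, lapply(y$groups, function(g) {
      if (is.null(g$label) || is.null(g$stress) || is.null(g$drug)) {
        stop("each group entry needs 'label', 'stress' and 'drug'",
             call. = FALSE)
      }
      data.frame(group = g$label, stress = g$stress, drug = g$drug,
                 stringsAsFactors = FALSE)
    }))
  }
  do.call(profiling_config, args)
}

#' Write a profiling configuration to a YAML file
#'
#' @param config A [profiling_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiling_config <- function(config, path) {
  stopifnot(inherits(config, "profiling_config"))
  y <- list(
    measures = lapply(config$measures, function(m) {
      list(name = m$name, units = m$units, direction = m$direction)
    }),
    percentile_level = config$q,
    criterion_k = config$k,
    control_group = config$control_group,
    reference = as.list(as.numeric(config$reference)),
    responses = as.list(config$responses),
    min_control_n = config$min_control_n,
    inclusive = config$inclusive,
    estimator = config$estimator
  )
  if (!is.null(config$baseline_group)) y$baseline_group <- config$baseline_group
  if (!is.null(config$groups)) {
    y$groups <- lapply(seq_len(nrow(config$groups)), function(i) {
      list(label = config$groups$group[i],
           stress = config$groups$stress[i],
           drug = config$groups$drug[i])
    })
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Configuration for the six-group juvenile-stress study design
#'
#' The default study layout: a 2 (stress: control, JVS) x 3 (drug: none,
#' fluoxetine since juvenility, fluoxetine in adulthood) design, profiled with
#' the seven-measure EPM panel at q = 0.20 and k = 4, goodness-of-fit tested
#' against 20:80, with the untreated JVS group available as an optional
#' 35:65-style baseline.
#'
#' @return A [profiling_config()] with the six-group design map attached.
#' @export
jvs_study_config <- function() {
  profiling_config(
    groups = data.frame(
      group  = c("control", "control_FLXjuv", "control_FLXadlt",
                 "JVS", "JVS_FLXjuv", "JVS_FLXadlt"),
      stress = c("control", "control", "control", "JVS", "JVS", "JVS"),
      drug   = c("none", "FLXjuv", "FLXadlt", "none", "FLXjuv", "FLXadlt"),
      stringsAsFactors = FALSE),
    baseline_group = "JVS")
}
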
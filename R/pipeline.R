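#' Run the full profiling pipeline
#'
#' Orchestrates the two-stage analysis: first the averaged-group two-way
#' ANOVA (stress x drug, Bonferroni post hoc on the drug factor) on each
#' configured response measure, then individual behavioral profiling —
#' control cutoffs, per-animal k-of-m classification, per-group
#' goodness-of-fit tests against the configured reference and, when a
#' baseline group is configured, against that group's empirical affected
#' proportion rounded to two decimals.
#'
#' Outputs written to `output_dir`: `profiles.csv` (per-animal flags and
#' classification), `stats.json` (machine-readable report), `summary.txt`
#' (human-readable summary), `run.log`. The JSON report contains no
#' timestamps, so re-running on identical inputs reproduces it byte for byte.
#' On any stage failure, partial outputs are removed and an error naming the
#' stage is thrown.
#'
#' @param config A [profiling_config()] or path to a YAML configuration.
#' @param input A `behavior_table` or path to a behavior-table CSV.
#' @param output_dir Directory for the outputs (created if needed); `NULL`
#'   skips writing and just returns the report.
#' @return An object of class `pipeline_report` (invisibly when writing).
#' @export
run_pipeline <- function(config, input, output_dir = NULL) {
  stage <- "configuration"
  report <- tryCatch({
    cfg <- if (inherits(config, "profiling_config")) config else read_profiling_config(config)
    config_path <- if (is.character(config)) config else NA_character_

    stage <- "ingest"
    tab <- if (is.character(input)) read_behavior_table(input, cfg) else
      as_behavior_table(as.data.frame(input), cfg)
    input_path <- if (is.character(input)) input else NA_character_

    stage <- "group statistics (ANOVA)"
    anova <- list()
    posthoc <- list()
    if (!is.null(cfg$groups)) {
      unknown <- setdiff(unique(tab$group), cfg$groups$group)
      if (length(unknown)) {
        stop("unknown group label(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
      }
      i <- match(tab$group, cfg$groups$group)
      d <- as.data.frame(tab)
      d$stress <- cfg$groups$stress[i]
      d$drug <- cfg$groups$drug[i]
      for (resp in intersect(cfg$responses, names(d))) {
        a <- anova_two_way(d, resp, "stress", "drug")
        anova[[resp]] <- a
        if (length(unique(d$drug)) >= 2L) {
          posthoc[[resp]] <- bonferroni_posthoc(d, resp, "drug", error = a)
        }
      }
    }

    stage <- "cutoff derivation"
    control <- tab[tab$group == cfg$control_group, , drop = FALSE]
    warnings_seen <- character(0)
    cutoffs <- withCallingHandlers(
      compute_cutoffs(as_behavior_table(control, cfg), cfg),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen, conditionMessage(w))
        invokeRestart("muffleWarning")
      })

    stage <- "profiling"
    prof <- profile_groups(tab, cutoffs, cfg)

    stage <- "goodness of fit"
    gof <- lapply(seq_len(nrow(prof$distributions)), function(i) {
      d <- prof$distributions[i, ]
      if (d$n == 0L) return(NULL)
      gof_test(d$n_affected, d$n, cfg$reference)
    })
    names(gof) <- prof$distributions$group
    gof <- Filter(Negate(is.null), gof)

    gof_baseline <- list()
    if (!is.null(cfg$baseline_group)) {
      b <- prof$distributions[prof$distributions$group == cfg$baseline_group, ]
      if (nrow(b) == 1L && b$n > 0L) {
        p_base <- round(b$n_affected / b$n, 2L)
        if (p_base > 0 && p_base < 1) {
          for (i in seq_len(nrow(prof$distributions))) {
            d <- prof$distributions[i, ]
            if (d$group == cfg$baseline_group || d$n == 0L) next
            gof_baseline[[d$group]] <-
              gof_test(d$n_affected, d$n, c(p_base, 1 - p_base))
          }
        } else {
          warnings_seen <- c(warnings_seen, sprintf(
            "baseline group '%s' has a degenerate affected proportion (%.2f); baseline tests skipped",
            cfg$baseline_group, p_base))
        }
      }
    }

    structure(
      list(config = cfg, config_path = config_path, input_path = input_path,
           cutoffs = cutoffs, profiles = prof$profiles,
           distributions = prof$distributions, gof = gof,
           gof_baseline = gof_baseline, anova = anova, posthoc = posthoc,
           warnings = c(warnings_seen, cutoffs$warnings),
           version = as.character(utils::packageVersion("cbcprofiler"))),
      class = "pipeline_report")
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  if (!is.null(output_dir)) {
    written <- character(0)
    tryCatch({
      if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
      pf <- file.path(output_dir, "profiles.csv")
      utils::write.csv(report$profiles, pf, row.names = FALSE, quote = FALSE)
      written <- c(written, pf)
      sj <- file.path(output_dir, "stats.json")
      jsonlite::write_json(report_to_list(report), sj, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      written <- c(written, sj)
      st <- file.path(output_dir, "summary.txt")
      writeLines(format_report(report), st)
      written <- c(written, st)
      lg <- file.path(output_dir, "run.log")
      writeLines(c(
        sprintf("cbcprofiler %s", report$version),
        sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
        if (!is.na(report$config_path)) sprintf("config: %s (md5 %s)",
          report$config_path, unname(tools::md5sum(report$config_path))),
        if (!is.na(report$input_path)) sprintf("input: %s (md5 %s)",
          report$input_path, unname(tools::md5sum(report$input_path))),
        sprintf("animals: %d, groups: %d", nrow(report$profiles),
                nrow(report$distributions)),
        if (length(report$warnings)) paste("warning:", report$warnings)
      ), lg)
      written <- c(written, lg)
    }, error = function(e) {
      unlink(written)
      stop("pipeline failed at stage 'report output': ",
           conditionMessage(e), call. = FALSE)
    })
    return(invisible(report))
  }
  report
}

# serializable view of the report (no lm fits, stable field order)
report_to_list <- function(report) {
  cfg <- report$config
  list(
    version = report$version,
    config = list(
      measures = lapply(cfg$measures, function(m)
        list(name = m$name, units = m$units, direction = m$direction)),
      percentile_level = cfg$q, criterion_k = cfg$k,
      control_group = cfg$control_group,
      reference = as.list(as.numeric(cfg$reference)),
      baseline_group = cfg$baseline_group,
      estimator = cfg$estimator, inclusive = cfg$inclusive),
    cutoffs = report$cutoffs$cutoffs,
    control_n = report$cutoffs$control_n,
    distributions = report$distributions,
    gof = lapply(report$gof, gof_to_list),
    gof_baseline = lapply(report$gof_baseline, gof_to_list),
    anova = lapply(report$anova, function(a)
      list(ss_type = a$ss_type, effects = a$effects,
           df_residual = a$df_residual, ms_residual = a$ms_residual)),
    posthoc = report$posthoc,
    warnings = report$warnings)
}

gof_to_list <- function(g) {
  list(chi2 = g$chi2, df = g$df, p = g$p,
       observed = as.list(as.integer(g$observed)),
       expected = as.list(as.numeric(g$expected)),
       reference = as.list(as.numeric(g$reference)))
}

format_report <- function(report) {
  out <- c(sprintf("cbcprofiler %s — cutoff behavioral criteria report",
                   report$version), "")
  out <- c(out, sprintf(
    "Cutoffs from %d '%s' animals at the %.0fth percentile (%s, %s); affected = deviant on >= %d of %d measures.",
    report$cutoffs$control_n, report$config$control_group,
    100 * report$config$q, report$cutoffs$estimator,
    if (report$cutoffs$inclusive) "inclusive" else "strict",
    report$config$k, length(report$config$measures)), "")
  for (resp in names(report$anova)) {
    a <- report$anova[[resp]]
    out <- c(out, sprintf("Two-way ANOVA (type %s SS) on %s:", a$ss_type, resp))
    for (i in seq_len(nrow(a$effects))) {
      out <- c(out, sprintf("  %-14s F(%d,%d) = %.2f, p = %.4g",
                            a$effects$effect[i], a$effects$df[i],
                            a$df_residual, a$effects$F[i], a$effects$p[i]))
    }
  }
  if (length(report$anova)) out <- c(out, "")
  out <- c(out, "Affected:unaffected distributions:")
  for (i in seq_len(nrow(report$distributions))) {
    d <- report$distributions[i, ]
    g <- report$gof[[d$group]]
    out <- c(out, sprintf(
      "  %-18s %2d/%2d affected (%.0f%%)%s", d$group, d$n_affected, d$n,
      100 * d$prop_affected,
      if (!is.null(g)) sprintf("; X2(1) = %.2f vs %.0f:%.0f, p = %.4g",
                               g$chi2, 100 * g$reference[1],
                               100 * g$reference[2], g$p) else ""))
  }
  if (length(report$gof_baseline)) {
    out <- c(out, "", sprintf("Versus baseline group '%s':",
                              report$config$baseline_group))
    for (g in names(report$gof_baseline)) {
      b <- report$gof_baseline[[g]]
      out <- c(out, sprintf("  %-18s X2(1) = %.2f vs %.0f:%.0f, p = %.4g",
                            g, b$chi2, 100 * b$reference[1],
                            100 * b$reference[2], b$p))
    }
  }
  if (length(report$warnings)) {
    out <- c(out, "", paste("warning:", report$warnings))
  }
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}
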
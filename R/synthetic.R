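# run code under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

#' Log-normal measure model for synthetic EPM cohorts
#'
#' Five primitive EPM quantities are modeled as log-normal: distance and
#' duration in the open arms, distance and duration in the closed arms, and
#' distance on the center platform. Locations are typical of a 5-minute test
#' on a 110 cm maze (a rat covers on the order of 1-2 kCm, spends most of the
#' time in the closed arms). `worsen` is the per-measure exponent on
#' `(1 + delta)` applied to affected animals: positive exponents divide the
#' measure (pushed low), negative exponents multiply it (pushed high, e.g.
#' closed-arm duration).
#'
#' @return A data.frame with columns `measure`, `log_mean`, `log_sd`,
#'   `worsen`.
#' @export
default_measure_model <- function() {
  data.frame(
    measure  = c("open_arm_distance", "open_arm_duration",
                 "closed_arm_distance", "closed_arm_duration",
                 "center_distance"),
    log_mean = log(c(250, 45, 900, 190, 150)),
    log_sd   = c(0.60, 0.70, 0.35, 0.25, 0.40),
    worsen   = c(1, 1, 0.5, -0.25, 0.5),
    stringsAsFactors = FALSE)
}

#' Specify a synthetic cohort
#'
#' Declares the group structure (label, size, latent affected fraction), the
#' effect size separating affected animals from the base population, the
#' latent equicorrelation between measures, the primitive measure model, and
#' the seed. With `derive_epm = TRUE` (default) the generated table carries
#' the seven-measure EPM panel — total distance and the two open/closed
#' anxiety indices are derived from the primitives — plus the primitives
#' themselves; with `derive_epm = FALSE` the table carries exactly the
#' primitive measures, which are then mutually independent when `rho = 0`.
#'
#' @param groups data.frame with columns `label`, `n`, `pi_affected`.
#' @param delta Multiplicative effect size (> 0): an affected animal's measure
#'   is scaled by `(1 + delta)^(-worsen)`, moving every measure toward its
#'   deviant tail.
#' @param rho Latent equicorrelation in `[0, 1)` between the primitive
#'   measures (Gaussian copula with a single shared factor).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the spec.
#' @param measure_model data.frame as in [default_measure_model()].
#' @param derive_epm Logical, see above.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, delta = 1.5, rho = 0.3, seed = 1L,
                        measure_model = default_measure_model(),
                        derive_epm = TRUE) {
  problems <- character(0)
  if (!is.data.frame(groups) || !all(c("label", "n", "pi_affected") %in% names(groups))) {
    stop("'groups' must be a data.frame with columns label, n, pi_affected",
         call. = FALSE)
  }
  groups$label <- as.character(groups$label)
  groups$n <- as.integer(groups$n)
  if (anyDuplicated(groups$label)) problems <- c(problems, "duplicate group labels")
  if (any(is.na(groups$n)) || any(groups$n < 0L) || sum(groups$n) < 1L) {
    problems <- c(problems, "group sizes must be non-negative integers summing to >= 1")
  }
  if (any(!is.finite(groups$pi_affected)) || any(groups$pi_affected < 0) ||
      any(groups$pi_affected > 1)) {
    problems <- c(problems, "pi_affected must lie in [0, 1]")
  }
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0) {
    problems <- c(problems, "delta must be a single number > 0")
  }
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho < 0 || rho >= 1) {
    problems <- c(problems, "rho must lie in [0, 1)")
  }
  if (!is.data.frame(measure_model) ||
      !all(c("measure", "log_mean", "log_sd", "worsen") %in% names(measure_model)) ||
      any(measure_model$log_sd <= 0)) {
    problems <- c(problems, "measure_model must have columns measure, log_mean, log_sd (> 0), worsen")
  }
  if (isTRUE(derive_epm) && is.data.frame(measure_model) &&
      !all(c("open_arm_distance", "open_arm_duration", "closed_arm_distance",
             "closed_arm_duration", "center_distance") %in% measure_model$measure)) {
    problems <- c(problems, "derive_epm = TRUE requires the five standard EPM primitives")
  }
  if (length(problems)) {
    stop("invalid cohort spec:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(list(groups = groups, delta = delta, rho = rho,
                 seed = as.integer(seed), measure_model = measure_model,
                 derive_epm = isTRUE(derive_epm)),
            class = "cohort_spec")
}

#' Generate a synthetic EPM cohort
#'
#' For each animal: a latent affected status is drawn Bernoulli(pi_affected);
#' latent standard normals with equicorrelation `rho` (one shared factor) are
#' exponentiated into positive, right-skewed primitive measures; affected
#' animals' measures are scaled by `(1 + delta)^(-worsen)` toward their
#' deviant tails; total distance (open + closed + center) and the two
#' open/closed anxiety indices are derived when `derive_epm = TRUE`. The
#' result is deterministic given the spec (including its seed).
#'
#' The true latent labels are attached as `attr(, "latent")` (a data.frame
#' `animal_id`, `group`, `affected_true`) for parameter-recovery studies;
#' the profiling pipeline never reads them.
#'
#' @param spec A [cohort_spec()].
#' @return A `behavior_table`-shaped data.frame (validate with
#'   [as_behavior_table()] under your configuration).
#' @export
#' @examples
#' spec <- cohort_spec(data.frame(label = c("control", "JVS"), n = c(30, 31),
#'                                pi_affected = c(0, 0.35)), seed = 42)
#' tab <- generate_cohort(spec)
#' head(tab)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  mm <- spec$measure_model
  p <- nrow(mm)
  with_local_seed(spec$seed, {
    pieces <- lapply(seq_len(nrow(spec$groups)), function(gi) {
      lab <- spec$groups$label[gi]
      n <- spec$groups$n[gi]
      if (n == 0L) return(NULL)
      affected <- stats::rbinom(n, 1L, spec$groups$pi_affected[gi]) == 1L
      shared <- stats::rnorm(n)
      z <- sqrt(spec$rho) * shared +
        sqrt(1 - spec$rho) * matrix(stats::rnorm(n * p), n, p)
      vals <- exp(sweep(sweep(z, 2L, mm$log_sd, `*`), 2L, mm$log_mean, `+`))
      shift <- (1 + spec$delta)^(-mm$worsen)
      vals[affected, ] <- sweep(vals[affected, , drop = FALSE], 2L, shift, `*`)
      colnames(vals) <- mm$measure
      tab <- data.frame(animal_id = sprintf("%s_%03d", lab, seq_len(n)),
                        group = lab, stringsAsFactors = FALSE)
      tab <- cbind(tab, as.data.frame(vals))
      tab$.affected_true <- affected
      tab
    })
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    latent <- data.frame(animal_id = out$animal_id, group = out$group,
                         affected_true = out$.affected_true,
                         stringsAsFactors = FALSE)
    out$.affected_true <- NULL
    if (spec$derive_epm) {
      out$total_distance <- out$open_arm_distance + out$closed_arm_distance +
        out$center_distance
      out$distance_anxiety_index <- out$open_arm_distance / out$closed_arm_distance
      out$duration_anxiety_index <- out$open_arm_duration / out$closed_arm_duration
    }
    attr(out, "latent") <- latent
    attr(out, "spec") <- spec
    class(out) <- c("behavior_table", class(out))
    out
  })
}

#' Theoretical cutoffs for a primitive-measure cohort spec
#'
#' Exact population quantiles of the base (unaffected) log-normal measures,
#' usable in place of control-sample cutoffs when the per-measure flag rate
#' must be held at exactly `q` — e.g. when checking the classifier's
#' closed-form null rate. Only defined for primitive measures
#' (`derive_epm = FALSE`): derived measures (totals, ratios) have no
#' closed-form quantiles.
#'
#' @param spec A [cohort_spec()] with `derive_epm = FALSE`.
#' @param config A [profiling_config()] whose measures all appear in the
#'   spec's measure model.
#' @return A `cutoff_set` with `control_n = Inf`.
#' @export
theoretical_cutoffs <- function(spec, config) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(config, "profiling_config"))
  if (spec$derive_epm) {
    stop("theoretical cutoffs require derive_epm = FALSE (primitive measures only)",
         call. = FALSE)
  }
  nm <- measure_names(config)
  absent <- setdiff(nm, spec$measure_model$measure)
  if (length(absent)) {
    stop("configured measure(s) not in the measure model: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  dir <- measure_directions(config)
  i <- match(nm, spec$measure_model$measure)
  lev <- ifelse(dir == "flag-low", config$q, 1 - config$q)
  cut <- stats::qlnorm(lev, spec$measure_model$log_mean[i],
                       spec$measure_model$log_sd[i])
  structure(
    list(cutoffs = data.frame(measure = nm, direction = unname(dir),
                              cutoff = unname(cut), stringsAsFactors = FALSE),
         q = config$q, control_n = Inf, estimator = "theoretical",
         inclusive = config$inclusive, warnings = character(0)),
    class = "cutoff_set")
}

#' Correct a classified proportion for known misclassification rates
#'
#' The fraction classified affected is a biased estimate of the latent
#' affected fraction: unaffected animals are classified affected at the
#' false-positive rate of the k-of-m rule and affected animals are missed at
#' `1 - sensitivity`. The standard misclassification (Rogan-Gladen)
#' correction inverts `E[p_hat] = pi * sens + (1 - pi) * fp`:
#' `pi_hat = (p_hat - fp) / (sens - fp)`, truncated to `[0, 1]`.
#'
#' @param n_affected Classified affected count.
#' @param n Group size.
#' @param fp False-positive rate; defaults to the closed-form
#'   [kofm_null_rate()] for independent measures at the default panel.
#' @param sensitivity Probability an affected animal is classified affected
#'   (1 under strong separation).
#' @return Estimated latent affected fraction in `[0, 1]`.
#' @export
recover_affected_fraction <- function(n_affected, n, fp = kofm_null_rate(),
                                      sensitivity = 1) {
  stopifnot(n >= 1, n_affected >= 0, n_affected <= n,
            fp >= 0, fp < sensitivity, sensitivity <= 1)
  pmin(1, pmax(0, (n_affected / n - fp) / (sensitivity - fp)))
}

#' Generate the six-group juvenile-stress study layout
#'
#' A ready-made synthetic study with the canonical 2 x 3 design and group
#' sizes (control = 30, control + FLXjuv = 12, control + FLXadlt = 12,
#' JVS = 31, JVS + FLXjuv = 19, JVS + FLXadlt = 12; 116 animals). Latent
#' affected fractions were calibrated once by simulation so that the expected
#' *classified* affected proportions under the default effect size and
#' correlation approximate 0.20, 0.08, 0.17, 0.35, 0.11 and 0.58 — the
#' affected rates characteristic of this design, where juvenile stress raises
#' the affected proportion and only fluoxetine given from juvenility restores
#' it to the control level.
#'
#' @param seed Integer seed.
#' @param delta,rho Effect size and latent equicorrelation passed to
#'   [cohort_spec()].
#' @return A `behavior_table` of 116 animals with latent labels attached (see
#'   [generate_cohort()]).
#' @export
generate_jvs_study <- function(seed = 1L, delta = 2.5, rho = 0.45) {
  groups <- data.frame(
    label = c("control", "control_FLXjuv", "control_FLXadlt",
              "JVS", "JVS_FLXjuv", "JVS_FLXadlt"),
    n = c(30L, 12L, 12L, 31L, 19L, 12L),
    pi_affected = c(0.12, 0.00, 0.08, 0.31, 0.00, 0.59),
    stringsAsFactors = FALSE)
  generate_cohort(cohort_spec(groups, delta = delta, rho = rho, seed = seed))
}

#' Write a synthetic cohort with its latent-label sidecar
#'
#' Writes the cohort as a standard behavior-table CSV plus a JSON sidecar
#' recording the true latent labels and the generating spec. The sidecar is
#' for recovery studies only; the profiling pipeline never reads it.
#'
#' @param cohort A [generate_cohort()] result.
#' @param path Output CSV path; the sidecar is written next to it as
#'   `<path>.latent.json`.
#' @param config A [profiling_config()] used to validate the table on the way
#'   out.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, config) {
  write_behavior_table(cohort, path, config)
  spec <- attr(cohort, "spec")
  sidecar <- list(
    latent = attr(cohort, "latent"),
    spec = list(groups = spec$groups, delta = spec$delta, rho = spec$rho,
                seed = spec$seed, derive_epm = spec$derive_epm,
                measure_model = spec$measure_model))
  jsonlite::write_json(sidecar, paste0(path, ".latent.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
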
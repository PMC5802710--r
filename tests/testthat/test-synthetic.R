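two_group_spec <- function(seed = 1, ...) {
  cohort_spec(data.frame(label = c("control", "jvs"), n = c(30, 31),
                         pi_affected = c(0, 0.35)), seed = seed, ...)
}

# 7 independent primitive measures (one flag-high), for null-rate and
# recovery designs where flags must be independent at rho = 0
independent_model <- function() {
  data.frame(measure = paste0("m", 1:7),
             log_mean = log(c(250, 45, 900, 190, 150, 0.3, 0.25)),
             log_sd = c(0.6, 0.7, 0.35, 0.25, 0.4, 0.5, 0.5),
             worsen = c(1, 1, 0.5, -0.5, 0.5, 1, 1),
             stringsAsFactors = FALSE)
}

independent_config <- function(q = 0.2, k = 4L) {
  profiling_config(
    measures = lapply(1:7, function(i) {
      measure_spec(paste0("m", i), "",
                   if (i == 4) "flag-high" else "flag-low")
    }),
    q = q, k = k, min_control_n = 3L)
}

test_that("cohort generation is deterministic in the seed and leaves the RNG alone", {
  s <- two_group_spec(seed = 99)
  t1 <- generate_cohort(s)
  set.seed(123)
  t2 <- generate_cohort(s)
  after <- runif(1)
  set.seed(123)
  expect_equal(runif(1), after)  # caller's stream undisturbed
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "latent"), attr(t2, "latent"))
  t3 <- generate_cohort(two_group_spec(seed = 100))
  expect_false(identical(t1$open_arm_distance, t3$open_arm_distance))
})

test_that("generated measures are positive and ratio indices equal their quotients", {
  tab <- generate_cohort(two_group_spec(seed = 5))
  cfg <- jvs_study_config()
  for (m in measure_names(cfg)) expect_true(all(tab[[m]] > 0))
  expect_identical(tab$distance_anxiety_index,
                   tab$open_arm_distance / tab$closed_arm_distance)
  expect_identical(tab$duration_anxiety_index,
                   tab$open_arm_duration / tab$closed_arm_duration)
  expect_identical(tab$total_distance,
                   tab$open_arm_distance + tab$closed_arm_distance +
                     tab$center_distance)
  # validates as a behavior table under the default panel
  expect_s3_class(as_behavior_table(as.data.frame(tab), profiling_config()),
                  "behavior_table")
})

test_that("invalid cohort specs are rejected with the violations listed", {
  g <- data.frame(label = "a", n = 10, pi_affected = 0.5)
  expect_error(cohort_spec(g, rho = 1), "rho")
  expect_error(cohort_spec(g, delta = 0), "delta")
  expect_error(cohort_spec(data.frame(label = "a", n = 10, pi_affected = 1.2)),
               "pi_affected")
  expect_error(cohort_spec(data.frame(label = c("a", "a"),
                                      n = c(5, 5), pi_affected = 0)),
               "duplicate")
  # several violations are reported together
  expect_error(cohort_spec(g, rho = 2, delta = -1), "rho.*|delta.*")
})

test_that("affected animals are shifted toward every measure's deviant tail", {
  spec <- cohort_spec(data.frame(label = "g", n = 4000, pi_affected = 0.5),
                      delta = 2.5, rho = 0, seed = 21)
  tab <- generate_cohort(spec)
  aff <- attr(tab, "latent")$affected_true
  cfg <- profiling_config()
  dirs <- measure_directions(cfg)
  for (m in names(dirs)) {
    lo <- median(tab[[m]][aff]) < median(tab[[m]][!aff])
    expect_identical(lo, dirs[[m]] == "flag-low")
  }
})

test_that("raising the effect size weakly raises the classified-affected fraction", {
  cfg <- independent_config()
  rates <- vapply(c(0.5, 1.5, 3), function(delta) {
    spec <- cohort_spec(data.frame(label = "g", n = 4000, pi_affected = 0.5),
                        delta = delta, rho = 0, seed = 31,
                        measure_model = independent_model(),
                        derive_epm = FALSE)
    tab <- generate_cohort(spec)  # common random numbers via the shared seed
    cuts <- theoretical_cutoffs(spec, cfg)
    mean(rowSums(flag_animals(tab, cuts)) >= cfg$k)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("null classification rate hits the binomial tail at rho = 0 and q at rho -> 1", {
  cfg <- independent_config()
  null_rate <- function(rho, n = 20000, seed = 41) {
    spec <- cohort_spec(data.frame(label = "g", n = n, pi_affected = 0),
                        delta = 1, rho = rho, seed = seed,
                        measure_model = independent_model(),
                        derive_epm = FALSE)
    tab <- generate_cohort(spec)
    mean(rowSums(flag_animals(tab, theoretical_cutoffs(spec, cfg))) >= cfg$k)
  }
  tail_rate <- kofm_null_rate(7, 4, 0.2)
  expect_equal(tail_rate, sum(dbinom(4:7, 7, 0.2)), tolerance = 1e-12)
  r0 <- null_rate(0)
  expect_lt(abs(r0 - tail_rate), 3 * sqrt(tail_rate * (1 - tail_rate) / 20000))
  # with all-flag-low measures and rho -> 1 every flag co-occurs: rate -> q
  cfg_low <- independent_config()
  model_low <- independent_model(); model_low$worsen <- abs(model_low$worsen)
  cfg_low$measures[[4]] <- measure_spec("m4", "", "flag-low")
  spec1 <- cohort_spec(data.frame(label = "g", n = 20000, pi_affected = 0),
                       delta = 1, rho = 0.999, seed = 43,
                       measure_model = model_low, derive_epm = FALSE)
  tab1 <- generate_cohort(spec1)
  r1 <- mean(rowSums(flag_animals(tab1, theoretical_cutoffs(spec1, cfg_low))) >= 4)
  expect_lt(abs(r1 - 0.2), 0.02)
})

test_that("the six-group study has the canonical design sizes", {
  tab <- generate_jvs_study(seed = 7)
  expect_equal(nrow(tab), 116L)
  counts <- table(tab$group)
  expect_equal(as.integer(counts[c("control", "control_FLXjuv",
                                   "control_FLXadlt", "JVS", "JVS_FLXjuv",
                                   "JVS_FLXadlt")]),
               c(30L, 12L, 12L, 31L, 19L, 12L))
  expect_false(anyDuplicated(tab$animal_id) > 0)
})

test_that("cohorts round-trip through the CSV + latent sidecar writer", {
  cfg <- jvs_study_config()
  tab <- generate_jvs_study(seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(tab, f, cfg)
  back <- read_behavior_table(f, cfg)
  expect_equal(back$total_distance, tab$total_distance)
  sidecar <- jsonlite::read_json(paste0(f, ".latent.json"), simplifyVector = TRUE)
  expect_equal(sidecar$latent$affected_true,
               attr(tab, "latent")$affected_true)
  expect_equal(sidecar$spec$seed, 3L)
})

test_that("misclassification correction inverts the classifier bias", {
  fp <- kofm_null_rate()
  # E[p_hat] = pi*sens + (1-pi)*fp inverts exactly at the expectation
  for (pi in c(0, 0.2, 0.35, 0.8)) {
    p_hat <- pi * 1 + (1 - pi) * fp
    expect_equal(recover_affected_fraction(round(p_hat * 1e6), 1e6),
                 pi, tolerance = 1e-5)
  }
  expect_equal(recover_affected_fraction(0, 100), 0)
  expect_equal(recover_affected_fraction(100, 100), 1)
  expect_error(recover_affected_fraction(5, 10, fp = 0.5, sensitivity = 0.4))
})
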
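# independent oracle: classify one animal by direct per-measure comparison
# against quantile(type = 1) percentiles (nearest-rank), written separately
# from the package's vectorized path
oracle_classify <- function(control_values, animal_values, directions, q, k) {
  flags <- logical(length(directions))
  for (j in seq_along(directions)) {
    if (directions[j] == "flag-low") {
      cut <- unname(quantile(control_values[, j], q, type = 1))
      flags[j] <- animal_values[j] <= cut
    } else {
      cut <- unname(-quantile(-control_values[, j], q, type = 1))
      flags[j] <- animal_values[j] >= cut
    }
  }
  list(flags = flags, affected = sum(flags) >= k)
}

test_that("nearest-rank cutoffs on a value ladder flag exactly the 20% tail", {
  # lower tail
  cfg <- config1("flag-low")
  ctrl <- make_table(matrix(1:10, 10, 1), config = cfg)
  cuts <- compute_cutoffs(ctrl, cfg)
  expect_equal(cuts$cutoffs$cutoff, 2)
  expect_equal(mean(flag_animals(ctrl, cuts)), 0.2)

  # mirrored upper tail
  cfg_hi <- config1("flag-high")
  ctrl_hi <- make_table(matrix(1:10, 10, 1), config = cfg_hi)
  cuts_hi <- compute_cutoffs(ctrl_hi, cfg_hi)
  expect_equal(cuts_hi$cutoffs$cutoff, 9)
  expect_equal(mean(flag_animals(ctrl_hi, cuts_hi)), 0.2)
})

test_that("a constant control measure warns and flags every tying animal", {
  cfg <- config1("flag-low")
  ctrl <- make_table(matrix(5, 8, 1), config = cfg)
  expect_warning(cuts <- compute_cutoffs(ctrl, cfg), "constant")
  expect_equal(cuts$cutoffs$cutoff, 5)
  expect_length(cuts$warnings, 1L)
  expect_true(all(flag_animals(ctrl, cuts)))
})

test_that("control flagged fraction is ceiling(q*n)/n without ties, any q and n", {
  for (seed in 1:3) {
    for (q in c(0.1, 0.2, 0.33, 0.5)) {
      for (n in c(7, 10, 23, 30)) {
        cfg <- profiling_config(
          measures = list(measure_spec("m1", "", "flag-low"),
                          measure_spec("m2", "", "flag-high")),
          q = q, k = 1L, min_control_n = 3L)
        ctrl <- random_table(n, cfg, seed = seed * 100 + n)
        cuts <- compute_cutoffs(ctrl, cfg)
        fl <- flag_animals(ctrl, cuts)
        expect_equal(unname(colMeans(fl)),
                     rep(ceiling(q * n) / n, 2L),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("boundary comparisons are inclusive by default and strict on request", {
  cfg <- config1("flag-low")
  ctrl <- make_table(matrix(1:10, 10, 1), config = cfg)
  cuts <- compute_cutoffs(ctrl, cfg)
  at_cutoff <- make_table(matrix(2, 1, 1), group = "test", config = cfg)
  expect_true(flag_animals(at_cutoff, cuts)[1, 1])

  cfg_strict <- config1("flag-low", inclusive = FALSE)
  cuts_strict <- compute_cutoffs(ctrl, cfg_strict)
  expect_false(flag_animals(at_cutoff, cuts_strict)[1, 1])
  # values at the control median never flag
  mid <- make_table(matrix(5.5, 1, 1), group = "test", config = cfg)
  expect_false(flag_animals(mid, cuts)[1, 1])
})

test_that("flags are invariant under strictly increasing transforms per measure", {
  cfg <- config_generic(3L, k = 2L,
                        directions = c("flag-low", "flag-high", "flag-low"))
  transforms <- list(function(x) exp(x), function(x) x^3 + 2,
                     function(x) log(x + 1), function(x) 7 * x + 0.5)
  for (seed in 1:5) {
    ctrl <- random_table(15, cfg, seed = seed)
    subj <- random_table(10, cfg, groups = "test", seed = seed + 500)
    base_flags <- flag_animals(subj, compute_cutoffs(ctrl, cfg))
    for (tr in transforms) {
      ctrl2 <- ctrl; subj2 <- subj
      for (m in measure_names(cfg)) {
        ctrl2[[m]] <- tr(ctrl[[m]])
        subj2[[m]] <- tr(subj[[m]])
      }
      flags2 <- flag_animals(subj2, compute_cutoffs(ctrl2, cfg))
      expect_identical(flags2, base_flags)
    }
  }
})

test_that("k-of-m classification matches the spec cases", {
  cfg <- profiling_config()  # m = 7, k = 4
  expect_true(classify_flags(rep(c(TRUE, FALSE), c(4, 3)), cfg)$affected)
  expect_false(classify_flags(rep(c(TRUE, FALSE), c(3, 4)), cfg)$affected)
  expect_true(classify_flags(rep(TRUE, 7), cfg)$affected)
  expect_equal(classify_flags(rep(c(TRUE, FALSE), c(4, 3)), cfg)$deviation_count, 4)
  expect_error(classify_flags(rep(TRUE, 6), cfg), "length 7")
})

test_that("classification agrees with direct enumeration on small instances", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(3:8, 1)
    k <- sample(1:3, 1)
    q <- runif(1, 0.1, 0.45)
    dirs <- sample(c("flag-low", "flag-high"), 3, replace = TRUE)
    cfg <- config_generic(3L, k = k, directions = dirs, q = q)
    ctrl_vals <- matrix(rlnorm(5 * 3), 5, 3)
    subj_vals <- matrix(rlnorm(n * 3), n, 3)
    ctrl <- make_table(ctrl_vals, config = cfg)
    subj <- make_table(subj_vals, group = "test", config = cfg)
    cuts <- compute_cutoffs(ctrl, cfg)
    flags <- flag_animals(subj, cuts)
    for (i in seq_len(n)) {
      oracle <- oracle_classify(ctrl_vals, subj_vals[i, ], dirs, q, k)
      expect_identical(unname(flags[i, ]), oracle$flags)
      expect_identical(classify_flags(flags[i, ], cfg)$affected, oracle$affected)
    }
  }
})

test_that("raising k never increases, and raising q never decreases, deviance", {
  base <- config_generic(7L, k = 1L)
  ctrl <- random_table(20, base, seed = 11)
  subj <- random_table(15, base, groups = "test", seed = 12)

  counts_at <- function(cfg) {
    rowSums(flag_animals(subj, compute_cutoffs(ctrl, cfg)))
  }
  dc <- counts_at(base)
  prev_affected <- 15L
  for (k in 1:7) {
    n_aff <- sum(dc >= k)
    expect_lte(n_aff, prev_affected)
    prev_affected <- n_aff
  }
  prev_dc <- rep(0L, 15)
  for (q in c(0.1, 0.2, 0.3, 0.5, 0.7)) {
    dc_q <- counts_at(config_generic(7L, k = 1L, q = q))
    expect_true(all(dc_q >= prev_dc))
    prev_dc <- dc_q
  }
})

test_that("profile_groups tallies per group, handles empty groups, scales with duplication", {
  cfg <- config_generic(7L, k = 4L,
                        groups = data.frame(group = c("control", "jvs", "ghost"),
                                            stress = c("c", "j", "g"),
                                            drug = "none"),
                        control_group = "control")
  tab <- random_table(30, cfg, groups = rep(c("control", "jvs"), 15), seed = 3)
  cuts <- compute_cutoffs(
    as_behavior_table(tab[tab$group == "control", ], cfg), cfg)
  res <- profile_groups(tab, cuts, cfg)
  expect_setequal(res$distributions$group, c("control", "jvs", "ghost"))
  expect_equal(sum(res$distributions$n), nrow(tab))
  ghost <- res$distributions[res$distributions$group == "ghost", ]
  expect_equal(ghost$n, 0L)
  expect_equal(ghost$n_affected, 0L)
  expect_equal(res$profiles$deviation_count,
               as.integer(rowSums(flag_animals(tab, cuts))))

  # doubling every animal doubles every count when cutoffs are held fixed
  tab2 <- as.data.frame(tab)
  dup <- tab2
  dup$animal_id <- paste0(dup$animal_id, "_copy")
  doubled <- as_behavior_table(rbind(tab2, dup), cfg)
  res2 <- profile_groups(doubled, cuts, cfg)
  expect_equal(res2$distributions$n, 2L * res$distributions$n)
  expect_equal(res2$distributions$n_affected, 2L * res$distributions$n_affected)

  # unknown labels are a validation error
  bad <- tab2
  bad$group[1] <- "martian"
  expect_error(profile_groups(as_behavior_table(bad, cfg), cuts, cfg), "martian")
})

test_that("cutoff derivation refuses tiny or contaminated reference groups", {
  cfg <- config_generic(2L, k = 1L)  # min_control_n = 3
  small <- random_table(2, cfg, seed = 9)
  expect_error(compute_cutoffs(small, cfg), "too small")
  mixed <- random_table(10, cfg, groups = rep(c("control", "jvs"), 5), seed = 9)
  expect_error(compute_cutoffs(mixed, cfg), "non-control")
})
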
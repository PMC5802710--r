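#' Reference goodness-of-fit statistics of the motivating six-group study
#'
#' The reported group sizes and chi-squared goodness-of-fit statistics of the
#' juvenile-stress / fluoxetine EPM study the default configuration mirrors:
#' six groups tested against the 20:80 control reference, and the two
#' fluoxetine-treated JVS groups additionally tested against the untreated
#' JVS group's 35:65 affected:unaffected baseline. These numbers are inputs to
#' [verify_reference_stats()], which demonstrates that the statistics are
#' internally consistent: every integer affected count is recoverable from
#' its printed statistic, and the recovered counts reproduce the companion
#' baseline statistics.
#'
#' @return A list with `reference` (the 20:80 proportions), `baseline` (the
#'   35:65 proportions), `groups` (data.frame `group`, `n`, `chi2_vs_control`)
#'   and `baseline_tests` (data.frame `group`, `chi2_vs_baseline`,
#'   `printed_dp`).
#' @export
jvs_reference_stats <- function() {
  list(
    reference = c(affected = 0.20, unaffected = 0.80),
    baseline = c(affected = 0.35, unaffected = 0.65),
    groups = data.frame(
      group = c("control", "control_FLXjuv", "control_FLXadlt",
                "JVS", "JVS_FLXjuv", "JVS_FLXadlt"),
      n = c(30L, 12L, 12L, 31L, 19L, 12L),
      chi2_vs_control = c(0, 1.02, 0.08, 4.65, 1.07, 11.02),
      stringsAsFactors = FALSE),
    baseline_tests = data.frame(
      group = c("JVS_FLXjuv", "JVS_FLXadlt"),
      chi2_vs_baseline = c(5, 2.87),
      # "5" was printed as an integer; "2.87" to two decimals
      printed_dp = c(0L, 2L),
      stringsAsFactors = FALSE)
  )
}

#' Verify the internal consistency of the reference statistics
#'
#' Runs the inversion/cross-consistency suite on [jvs_reference_stats()]:
#' (1) for every group, exhaustively recovers the integer affected count(s)
#' whose 20:80 goodness-of-fit statistic rounds to the reported value and
#' checks the recovery is unique; (2) re-tests the recovered counts of the
#' two fluoxetine-treated JVS groups against the 35:65 baseline and checks
#' the companion reported statistics are reproduced at their printed
#' precision.
#'
#' @param stats A statistics bundle shaped like [jvs_reference_stats()]
#'   (the default).
#' @return A data.frame of class `verification_table` with one row per check:
#'   `check`, `group`, `expected`, `observed`, `pass`; overall success in
#'   `attr(, "pass")`.
#' @export
#' @examples
#' v <- verify_reference_stats()
#' attr(v, "pass")
verify_reference_stats <- function(stats = jvs_reference_stats()) {
  rows <- list()
  counts <- rep(NA_integer_, nrow(stats$groups))
  names(counts) <- stats$groups$group
  for (i in seq_len(nrow(stats$groups))) {
    g <- stats$groups$group[i]
    n <- stats$groups$n[i]
    hit <- invert_gof(stats$groups$chi2_vs_control[i], n, stats$reference)
    ok <- length(hit) == 1L
    if (ok) counts[g] <- hit
    rows[[length(rows) + 1L]] <- data.frame(
      check = "unique count recovered from 20:80 statistic", group = g,
      expected = "1 count",
      observed = if (length(hit)) paste(hit, collapse = ",") else "none",
      pass = ok, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(stats$baseline_tests))) {
    g <- stats$baseline_tests$group[i]
    printed <- stats$baseline_tests$chi2_vs_baseline[i]
    dp <- stats$baseline_tests$printed_dp[i]
    if (is.na(counts[g])) {
      rows[[length(rows) + 1L]] <- data.frame(
        check = "recovered count reproduces 35:65 statistic", group = g,
        expected = format(printed), observed = "count not recovered",
        pass = FALSE, stringsAsFactors = FALSE)
      next
    }
    chi2 <- gof_test(counts[g], stats$groups$n[stats$groups$group == g],
                     stats$baseline)$chi2
    ok <- abs(round(chi2, dp) - printed) < 1e-9
    rows[[length(rows) + 1L]] <- data.frame(
      check = "recovered count reproduces 35:65 statistic", group = g,
      expected = format(printed), observed = format(round(chi2, max(dp, 2L))),
      pass = ok, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "counts") <- counts
  attr(out, "pass") <- all(out$pass)
  class(out) <- c("verification_table", class(out))
  out
}

#' @export
print.verification_table <- function(x, ...) {
  cat("reference-statistic consistency checks:\n")
  print(as.data.frame(x[, c("check", "group", "expected", "observed", "pass")]),
        row.names = FALSE)
  cat(if (attr(x, "pass")) "ALL CHECKS PASSED\n" else "MISMATCHES FOUND\n")
  invisible(x)
}
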
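#' Two-way fixed-effects ANOVA on a behavioral measure
#'
#' Fits `response ~ A * B` by least squares and partitions the sums of
#' squares. The default is Type III SS with sum-to-zero contrasts, the
#' convention of mainstream point-and-click statistics software for
#' unbalanced factorial designs; Type II and sequential Type I are available.
#' F for each effect is its mean square over the residual mean square. When an
#' effect's SS is exactly 0 (e.g. all observations identical) its F is
#' reported as 0 with p = 1 rather than 0/0.
#'
#' @param data A `data.frame` (typically a behavior table joined to its
#'   design factors) with the response and both factor columns.
#' @param response Name of the numeric response column.
#' @param factor_a,factor_b Names of the two factor columns (e.g. stress and
#'   drug treatment).
#' @param ss_type `"III"` (default), `"II"` or `"I"`.
#' @return An object of class `anova_result`: data.frame `effects` (`effect`,
#'   `ss`, `df`, `F`, `p`), plus `df_residual`, `ms_residual`, `ss_residual`
#'   and the underlying `lm` fit.
#' @export
anova_two_way <- function(data, response, factor_a, factor_b,
                          ss_type = c("III", "II", "I")) {
  ss_type <- match.arg(ss_type)
  if (!is.data.frame(data)) stop("'data' must be a data.frame", call. = FALSE)
  for (col in c(response, factor_a, factor_b)) {
    if (!col %in% names(data)) stop("column not found: ", col, call. = FALSE)
  }
  d <- data.frame(.y = as.numeric(data[[response]]),
                  .a = factor(data[[factor_a]]),
                  .b = factor(data[[factor_b]]))
  if (any(!is.finite(d$.y))) stop("response contains non-finite values", call. = FALSE)
  cells <- table(d$.a, d$.b)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("empty design cell: %s = '%s', %s = '%s'",
                 factor_a, rownames(cells)[empty[1L]],
                 factor_b, colnames(cells)[empty[2L]]), call. = FALSE)
  }
  df_res <- nrow(d) - nlevels(d$.a) * nlevels(d$.b)
  if (df_res < 1L) {
    stop("no residual degrees of freedom: every cell needs >= 1 observation and at least one cell >= 2",
         call. = FALSE)
  }
  # a factor collapsed to one level carries no df; drop it from the model so
  # the remaining factor's one-way analysis is reproduced exactly
  in_model <- c(a = nlevels(d$.a) > 1L, b = nlevels(d$.b) > 1L)
  rhs <- if (all(in_model)) ".a * .b" else if (in_model["a"]) ".a" else
    if (in_model["b"]) ".b" else "1"
  contr <- list(.a = "contr.sum", .b = "contr.sum")[in_model]
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = d,
                   contrasts = if (length(contr)) contr else NULL)
  # car refuses a zero residual SS; sequential SS are then exact (all terms 0)
  degenerate <- sum(stats::residuals(fit)^2) <
    1e-10 * max(1, sum((d$.y - mean(d$.y))^2))
  tab <- if (ss_type == "I" || rhs == "1" || degenerate) {
    # a perfect fit triggers a reliability warning; the F values are
    # normalized below, so the table itself is all that is needed
    as.data.frame(suppressWarnings(stats::anova(fit)))
  } else {
    as.data.frame(car::Anova(fit, type = ss_type))
  }
  rn <- rownames(tab)
  pick <- function(term) tab[match(term, rn), , drop = FALSE]
  res <- pick("Residuals")
  ss_res <- res[["Sum Sq"]]
  ms_res <- ss_res / res[["Df"]]
  eff_terms <- c(".a", ".b", ".a:.b")
  eff_names <- c(factor_a, factor_b, paste0(factor_a, ":", factor_b))
  ss <- vapply(eff_terms, function(t) {
    v <- pick(t)[["Sum Sq"]]
    if (length(v) == 0L || is.na(v)) 0 else v
  }, numeric(1))
  df <- vapply(eff_terms, function(t) {
    v <- pick(t)[["Df"]]
    if (length(v) == 0L || is.na(v)) 0 else v
  }, numeric(1))
  # an effect SS that is zero up to rounding (e.g. all observations
  # identical) is reported as F = 0, p = 1 rather than 0/0
  ss_tot <- sum((d$.y - mean(d$.y))^2)
  zero_ss <- ss <= 1e-12 * max(1, ss_tot)
  ss[zero_ss] <- 0
  f <- rep(0, length(ss))
  p <- rep(1, length(ss))
  live <- !zero_ss & df > 0
  f[live] <- (ss[live] / df[live]) / ms_res
  p[live] <- stats::pf(f[live], df[live], res[["Df"]], lower.tail = FALSE)
  structure(
    list(effects = data.frame(effect = eff_names, ss = unname(ss),
                              df = as.integer(df), F = unname(f), p = unname(p),
                              stringsAsFactors = FALSE),
         df_residual = as.integer(res[["Df"]]), ss_residual = ss_res,
         ms_residual = ms_res, ss_type = ss_type, response = response,
         fit = fit),
    class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("two-way ANOVA (type %s SS) on %s\n", x$ss_type, x$response))
  e <- x$effects
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %-20s F(%d,%d) = %.4g, p = %.4g\n",
                e$effect[i], e$df[i], x$df_residual, e$F[i], e$p[i]))
  }
  invisible(x)
}

#' Bonferroni-adjusted pairwise comparisons for one factor
#'
#' All pairwise two-sample t comparisons between the levels of `factor_name`,
#' using a pooled error term: by default the residual mean square of the
#' supplied two-way ANOVA (so the post hoc tests share the omnibus error), or
#' the one-way pooled within-level variance when no fit is supplied. Raw
#' p-values are Bonferroni-adjusted over the number of pairwise comparisons
#' and capped at 1.
#'
#' @param data A `data.frame` with the response and factor columns.
#' @param response Name of the numeric response column.
#' @param factor_name Name of the factor column whose levels are compared.
#' @param error An optional [anova_two_way()] result supplying the pooled
#'   error term and its df.
#' @param alpha Significance level for the `significant` flag.
#' @return A data.frame with one row per level pair: `level_1`, `level_2`,
#'   `diff`, `t`, `df`, `p`, `p_adj`, `significant`.
#' @export
bonferroni_posthoc <- function(data, response, factor_name, error = NULL,
                               alpha = 0.05) {
  if (!is.data.frame(data)) stop("'data' must be a data.frame", call. = FALSE)
  for (col in c(response, factor_name)) {
    if (!col %in% names(data)) stop("column not found: ", col, call. = FALSE)
  }
  y <- as.numeric(data[[response]])
  g <- factor(data[[factor_name]])
  if (nlevels(g) < 2L) stop("factor needs >= 2 levels", call. = FALSE)
  ns <- tapply(y, g, length)
  if (any(is.na(ns) | ns < 1L)) stop("every factor level needs >= 1 observation", call. = FALSE)
  means <- tapply(y, g, mean)
  if (!is.null(error)) {
    stopifnot(inherits(error, "anova_result"))
    mse <- error$ms_residual
    df <- error$df_residual
  } else {
    df <- length(y) - nlevels(g)
    if (df < 1L) stop("no residual degrees of freedom for the pooled error", call. = FALSE)
    mse <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / df
  }
  pairs <- utils::combn(levels(g), 2L)
  ncmp <- ncol(pairs)
  out <- data.frame(level_1 = pairs[1L, ], level_2 = pairs[2L, ],
                    stringsAsFactors = FALSE)
  out$diff <- as.numeric(means[out$level_1] - means[out$level_2])
  se <- as.numeric(sqrt(mse * (1 / ns[out$level_1] + 1 / ns[out$level_2])))
  # a zero mean difference is t = 0 even when the pooled error is also zero
  out$t <- ifelse(out$diff == 0, 0, out$diff / se)
  out$df <- df
  out$p <- 2 * stats::pt(-abs(out$t), df)
  out$p_adj <- pmin(1, out$p * ncmp)
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}
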
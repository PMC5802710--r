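#' Validate a per-animal behavior table
#'
#' A behavior table has one row per animal: an `animal_id` column (unique,
#' read as character), a `group` label column, and one numeric column per
#' configured measure. Validation enforces the table contract: every
#' configured measure present, all values finite and non-negative, no
#' duplicate animal ids, no missing values. Extra columns are kept untouched.
#'
#' @param x A `data.frame`.
#' @param config A [profiling_config()] naming the required measures.
#' @return `x` with class `behavior_table` prepended.
#' @export
as_behavior_table <- function(x, config) {
  stopifnot(inherits(config, "profiling_config"))
  if (!is.data.frame(x)) stop("behavior table must be a data.frame", call. = FALSE)
  required <- c("animal_id", "group", measure_names(config))
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("behavior table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$animal_id <- as.character(x$animal_id)
  x$group <- as.character(x$group)
  if (anyDuplicated(x$animal_id)) {
    stop("duplicate animal_id: ",
         paste(unique(x$animal_id[duplicated(x$animal_id)]), collapse = ", "),
         call. = FALSE)
  }
  for (m in measure_names(config)) {
    v <- x[[m]]
    if (!is.numeric(v)) {
      stop(sprintf("measure column '%s' is not numeric", m), call. = FALSE)
    }
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf("measure '%s' has missing or non-finite values (row %s)",
                   m, paste(bad, collapse = ", ")), call. = FALSE)
    }
    if (any(v < 0)) {
      stop(sprintf("measure '%s' has negative values (row %s)",
                   m, paste(which(v < 0), collapse = ", ")), call. = FALSE)
    }
  }
  if (!inherits(x, "behavior_table")) class(x) <- c("behavior_table", class(x))
  x
}

#' Read a behavior table from CSV
#'
#' Expects a comma-separated file (UTF-8, header row) with columns
#' `animal_id`, `group`, and one column per configured measure; column order
#' does not matter and extra columns are retained. Numeric parsing is
#' locale-fixed (dot decimal separator). A row missing any configured measure
#' is rejected: the k-of-m criterion is only meaningful when every animal is
#' scored on all m measures, and silent imputation would change it.
#'
#' @param path Path to a CSV file.
#' @param config A [profiling_config()].
#' @return A validated `behavior_table`.
#' @export
#' @seealso [write_behavior_table()]
read_behavior_table <- function(path, config) {
  stopifnot(inherits(config, "profiling_config"))
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  required <- c("animal_id", "group", measure_names(config))
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("'%s' is missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (m in measure_names(config)) {
    v <- suppressWarnings(as.numeric(raw[[m]]))
    bad <- which(is.na(v) & !is.na(raw[[m]]) & nzchar(trimws(raw[[m]])))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                   raw[[m]][bad[1L]], m, bad[1L]), call. = FALSE)
    }
    na <- which(is.na(v))
    if (length(na)) {
      stop(sprintf("missing value in column '%s', row %d", m, na[1L]),
           call. = FALSE)
    }
    raw[[m]] <- v
  }
  as_behavior_table(raw, config)
}

#' Write a behavior table to CSV
#'
#' Values are written at full double precision (17 significant digits) so
#' that [read_behavior_table()] re-ingests the table losslessly and a second
#' write of the re-read table is byte-identical.
#'
#' @param table A `behavior_table` (or plain `data.frame` satisfying the
#'   contract).
#' @param path Output path.
#' @param config A [profiling_config()]; the table is validated before
#'   writing.
#' @return `path`, invisibly.
#' @export
write_behavior_table <- function(table, path, config) {
  table <- as_behavior_table(as.data.frame(table), config)
  out <- as.data.frame(table)
  for (j in names(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' @export
print.behavior_table <- function(x, ...) {
  cat(sprintf("<behavior_table> %d animals, %d groups (%s)\n",
              nrow(x), length(unique(x$group)),
              paste(unique(x$group), collapse = ", ")))
  NextMethod()
}
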
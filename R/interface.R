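#' Read a meta-analysis dataset from CSV
#'
#' Two schemas are supported.  Arm level (`schema = "arm_level"`): columns
#' `study_id, n_treat, mean_treat, sd_treat, n_control, mean_control,
#' sd_control`; rows are converted to effect records with [md_effect()] or
#' [smd_effect()] according to `measure`.  Effect level
#' (`schema = "effect_level"`): columns `study_id, estimate, variance,
#' n_treat, n_control` and optionally `sd_treat, sd_control`.
#'
#' The 24-study obsessive-compulsive-disorder example dataset (SMD,
#' effect-level schema) ships with the package:
#' `system.file("extdata", "ocd_smd.csv", package = "remeta")`.
#'
#' @param path CSV file path.
#' @param schema `"effect_level"` or `"arm_level"`.
#' @param measure `"SMD"` or `"MD"`.
#' @return An [effect_records()] data frame with a `provenance` attribute.
#' @export
#' @examples
#' path <- system.file("extdata", "ocd_smd.csv", package = "remeta")
#' ocd <- read_dataset(path, "effect_level", "SMD")
#' nrow(ocd)
read_dataset <- function(path, schema = c("effect_level", "arm_level"),
                         measure = c("SMD", "MD")) {
  schema <- match.arg(schema)
  measure <- match.arg(measure)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- if (schema == "effect_level")
    c("study_id", "estimate", "variance", "n_treat", "n_control")
  else
    c("study_id", "n_treat", "mean_treat", "sd_treat",
      "n_control", "mean_control", "sd_control")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0) stop("empty dataset: ", path, call. = FALSE)
  rec <- if (schema == "effect_level") {
    bad <- which(!is.finite(df$variance) | df$variance <= 0)
    if (length(bad))
      stop("nonpositive variance in row(s) ", paste(bad, collapse = ", "),
           call. = FALSE)
    bad <- which(df$n_treat < 2 | df$n_control < 2)
    if (length(bad))
      stop("arm size below 2 in row(s) ", paste(bad, collapse = ", "),
           call. = FALSE)
    effect_records(df$estimate, df$variance, df$n_treat, df$n_control,
                   measure = measure,
                   sd_treat = if ("sd_treat" %in% names(df)) df$sd_treat,
                   sd_control = if ("sd_control" %in% names(df)) df$sd_control,
                   study = df$study_id)
  } else {
    make <- if (measure == "MD") md_effect else smd_effect
    rows <- lapply(seq_len(nrow(df)), function(i) {
      r <- tryCatch(
        make(arm_summary(df$n_treat[i], df$mean_treat[i], df$sd_treat[i]),
             arm_summary(df$n_control[i], df$mean_control[i],
                         df$sd_control[i]),
             study = df$study_id[i]),
        error = function(e)
          stop(sprintf("row %d (study %s): %s", i, df$study_id[i],
                       conditionMessage(e)), call. = FALSE))
      r
    })
    out <- do.call(rbind.data.frame, rows)
    attr(out, "measure") <- measure
    class(out) <- c("effect_records", "data.frame")
    out$study <- df$study_id
    out
  }
  attr(rec, "provenance") <- path
  rec
}

#' Write effect records to CSV (effect-level schema)
#'
#' Full-precision round trip partner of [read_dataset()].
#'
#' @param records An [effect_records()] data frame.
#' @param path Output file.
#' @export
write_dataset <- function(records, path) {
  check_records(records, min_k = 1L, caller = "write_dataset")
  df <- data.frame(study_id = records$study,
                   estimate = records$estimate,
                   variance = records$variance,
                   n_treat = records$n_treat,
                   n_control = records$n_control,
                   sd_treat = records$sd_treat,
                   sd_control = records$sd_control)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' One-call analysis report
#'
#' Runs the requested tau-squared point and interval estimators and pooled
#' combinations on a dataset and collects everything in a tidy table plus
#' a formatted text report (four decimals, one row per method, matching
#' the layout used throughout the package documentation).  This is a thin
#' wrapper around [remeta()].
#'
#' @param records An [effect_records()] data frame.
#' @param ... Passed to [remeta()] (`tau2`, `ci`, `pool`, `level`).
#' @return The fitted `"remeta"` object; its `$table` element is the tidy
#'   data frame, written to `csv` if given.
#' @param csv Optional path: write the tidy table there.
#' @export
analyze <- function(records, ..., csv = NULL) {
  fit <- remeta(records, ...)
  if (!is.null(csv)) utils::write.csv(fit$table, csv, row.names = FALSE)
  fit
}
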
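# Cohort CSV round-trip and configuration files.

#' Read and validate a cohort CSV
#'
#' Expects the header `id,disease,age,sex,mo,sc,ua,pd,ad,vas` with an
#' optional `utility` column. All row-level validation problems are collected
#' and reported together with their line numbers (line 1 is the header).
#' When `utility` is absent it is recomputed from `value_set`.
#'
#' @param path CSV file path.
#' @param value_set [value_set()] used to score states when the `utility`
#'   column is missing; defaults to the England set in that case.
#' @return A validated cohort data frame (class `cohort`).
#' @export
read_cohort <- function(path, value_set = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "disease", "age", "sex", names(EQ5D_DIMS), "vas")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("cohort file is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  line <- seq_len(nrow(df)) + 1L  # CSV line numbers (header is line 1)
  problems <- character(0)
  note <- function(bad, msg) {
    if (any(bad)) {
      problems <<- c(problems,
                     sprintf("line %d: %s", line[bad], msg[if (length(msg) > 1) bad else 1]))
    }
  }
  note(!df$disease %in% DISEASES,
       sprintf("unknown disease label '%s'", df$disease))
  for (cc in names(EQ5D_DIMS)) {
    lev <- suppressWarnings(as.numeric(df[[cc]]))
    note(is.na(lev) | lev != round(lev) | lev < 1 | lev > 5,
         sprintf("%s level '%s' outside 1-5", EQ5D_DIMS[[cc]], df[[cc]]))
  }
  vas <- suppressWarnings(as.numeric(df$vas))
  note(!is.na(df$vas) & (is.na(vas) | vas < 0 | vas > 100),
       sprintf("vas '%s' outside 0-100", df$vas))
  dup <- duplicated(df$id) | duplicated(df$id, fromLast = TRUE)
  note(dup, sprintf("duplicate id '%s'", df$id))
  if (length(problems)) {
    stop("invalid cohort file:\n  ", paste(problems, collapse = "\n  "))
  }
  for (cc in names(EQ5D_DIMS)) df[[cc]] <- as.integer(df[[cc]])
  df$vas <- as.integer(df$vas)
  if (!"utility" %in% names(df)) {
    if (is.null(value_set)) value_set <- value_set_england()
    df$utility <- apply_value_set(df, value_set)
  }
  class(df) <- c("cohort", "data.frame")
  df
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: writes `id,disease,age,sex,mo,sc,ua,pd,ad,vas,utility`.
#'
#' @param cohort cohort data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cols <- c("id", "disease", "age", "sex", names(EQ5D_DIMS), "vas", "utility")
  utils::write.csv(cohort[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Recognised keys: `horizon_years`, `discount_rate`, `attainment`,
#' `sensitivity_grid`, `target_utility`, `aging_decrement`, `utility_bounds`.
#' Missing keys take the [sim_config()] defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown simulation config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, raw)
}
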
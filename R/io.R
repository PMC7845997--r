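#' @title File formats and the pipeline configuration
#'
#' @description Readers and writers for the package's plain-text formats:
#' sequence catalogs (TSV with `sequence_id` and `pattern` columns), trial
#' tables (CSV with the columns of [behavior_metrics], optionally renamed
#' via a column map), and deterministic CSV outputs with a provenance
#' header. All files are UTF-8 with "." as decimal separator; positions are
#' 1-based throughout.
#' @name cli_io
NULL

#' Read a sequence catalog
#'
#' TSV with header columns `sequence_id` and `pattern`. Rows whose pattern
#' is not a non-empty string over `{A,B}` are rejected with their line
#' numbers reported in a warning; canonical forms are added alongside the
#' original labelling.
#'
#' @param path TSV file path.
#' @return data.frame with `sequence_id`, `pattern` (as stored) and
#'   `canonical`.
#' @export
read_sequences <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sequence_id", "pattern") %in% names(df)))
    stop("sequence catalog needs columns 'sequence_id' and 'pattern'",
         call. = FALSE)
  if (!nrow(df)) stop("empty sequence catalog", call. = FALSE)
  bad <- !grepl("^[AB]+$", df$pattern)
  if (any(bad)) {
    warning(sprintf("rejected %d row(s) with invalid patterns (lines %s)",
                    sum(bad),
                    paste(which(bad) + 1L, collapse = ", ")))
    df <- df[!bad, , drop = FALSE]
  }
  if (!nrow(df)) stop("no valid patterns in catalog", call. = FALSE)
  df$canonical <- canonicalize_sequence(df$pattern)
  df
}

#' Read a trial table
#'
#' CSV with the trial-table columns of [behavior_metrics]. Deposited data
#' files may use different column names; `column_map` renames them
#' (`c(theirs = "ours")`). Missing optional columns `experiment` and
#' `modality` are filled with defaults. Malformed rows (bad pattern, bad
#' deviant type) are rejected with line numbers.
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector mapping file columns
#'   to schema columns.
#' @return A validated trial table.
#' @export
read_trials <- function(path, column_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!is.null(column_map)) {
    for (from in names(column_map)) {
      if (from %in% names(df))
        names(df)[names(df) == from] <- column_map[[from]]
    }
  }
  if (!"experiment" %in% names(df)) df$experiment <- "unknown"
  if (!"modality" %in% names(df)) df$modality <- "auditory"
  miss <- setdiff(.trial_cols, names(df))
  if (length(miss))
    stop("trial table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- !grepl("^[AB]+$", df$pattern) |
    !df$deviant_type %in% c("none", "sequence", "super") |
    (df$deviant_type != "none" & is.na(df$deviant_position))
  if (any(bad)) {
    warning(sprintf("rejected %d malformed trial row(s) (lines %s)",
                    sum(bad),
                    paste(utils::head(which(bad) + 1L, 20L), collapse = ", ")))
    df <- df[!bad, , drop = FALSE]
  }
  if (!nrow(df)) stop("no valid trials in file", call. = FALSE)
  df$responded <- as.logical(df$responded)
  df$rt_ms <- as.numeric(df$rt_ms)
  df[, union(.trial_cols, names(df)), drop = FALSE]
}

#' Write a table deterministically with a provenance header
#'
#' CSV preceded by `#`-comment lines recording the package version and a
#' hash of the run configuration, so identical inputs yield identical
#' files.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param config Optional list echoed (hashed) into the header.
#' @return Invisibly, `path`.
#' @export
write_table <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("binlot"))
  writeLines(sprintf("# binlot %s", ver), con)
  if (!is.null(config)) {
    js <- jsonlite::toJSON(config, auto_unbox = TRUE)
    writeLines(sprintf("# config_hash %s",
                       sum(utf8ToInt(as.character(js)) *
                             seq_along(utf8ToInt(as.character(js)))) %%
                         .Machine$integer.max), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read back a table written by [write_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run configuration
#'
#' Bundles the analysis constants. The defaults reproduce the published
#' pipeline: instruction weight 2 and unit digit weight, surprise padding
#' 0.01, 2.5 SD trimming and exclusion multipliers, and the 200-2500 ms
#' hit window. Every override is echoed into the run log by the pipeline
#' command.
#'
#' @param instruction_weight,padding,trim_sd,exclude_sd,window,seed
#'   Analysis constants.
#' @return A list of class `run_config`.
#' @export
run_config <- function(instruction_weight = 2, padding = 0.01,
                       trim_sd = 2.5, exclude_sd = 2.5,
                       window = c(200, 2500), seed = 1L) {
  structure(list(instruction_weight = instruction_weight, padding = padding,
                 trim_sd = trim_sd, exclude_sd = exclude_sd,
                 window = window, seed = as.integer(seed)),
            class = "run_config")
}
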
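#' Read and write the pipeline's tabular formats
#'
#' `interactions.csv` holds one decided contest per row (year, actor_id,
#' recipient_id, winner_id); `ranks.csv` holds one individual-year per row
#' (year, individual_id, sex, rank, optionally entry_year, exit_year).
#' Transition matrices travel as small plain-text files, either JSON or
#' `key = value` lines with keys `p_hh`, `p_hl`, `p_lh`, `p_ll`.
#'
#' @param path File path.
#' @return `read_interactions()` / `read_ranks()` return tibbles;
#'   `read_transition_matrix()` returns a [transition_matrix()].
#' @name mobidom-io
NULL

#' @rdname mobidom-io
#' @export
read_interactions <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          year = readr::col_integer(),
                          .default = readr::col_character()
                        ))
  check_columns(df, c("year", "actor_id", "recipient_id", "winner_id"),
                "interactions file")
  df
}

#' @rdname mobidom-io
#' @export
read_ranks <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("year", "individual_id", "sex", "rank"), "ranks file")
  dplyr::mutate(df, year = as.integer(.data$year), rank = as.integer(.data$rank),
                individual_id = as.character(.data$individual_id),
                sex = as.character(.data$sex))
}

#' @rdname mobidom-io
#' @export
read_transition_matrix <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (any(grepl("^\\s*\\{", txt))) {
    vals <- jsonlite::fromJSON(paste(txt, collapse = "\n"))
  } else {
    kv <- txt[grepl("=", txt, fixed = TRUE)]
    parts <- strsplit(kv, "=", fixed = TRUE)
    vals <- lapply(parts, function(p) as.numeric(trimws(p[2])))
    names(vals) <- tolower(vapply(parts, function(p) trimws(p[1]), character(1)))
  }
  needed <- c("p_hh", "p_hl", "p_lh", "p_ll")
  names(vals) <- tolower(names(vals))
  if (!all(needed %in% names(vals))) {
    abort(sprintf("matrix file %s must define p_hh, p_hl, p_lh, p_ll", path))
  }
  transition_matrix(vals$p_hh, vals$p_hl, vals$p_lh, vals$p_ll)
}

#' Write a simulated group history to CSV
#'
#' Writes `interactions.csv`, `ranks.csv` (with entry/exit years joined in)
#' and `config.json` into a directory, the on-disk form the file-input mode
#' of [run_analysis()] reads back.
#'
#' @param history A [simulate_group()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_history <- function(history, dir) {
  if (!inherits(history, "group_history")) {
    abort("`history` must be a group_history")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(history$interactions, file.path(dir, "interactions.csv"))
  ranks <- dplyr::left_join(
    history$ranks,
    dplyr::select(history$individuals, "individual_id", "entry_year", "exit_year"),
    by = "individual_id"
  )
  readr::write_csv(ranks, file.path(dir, "ranks.csv"))
  jsonlite::write_json(unclass(history$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
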
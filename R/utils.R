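# internal helpers

# sample() treats a length-1 numeric vector as 1:x; this never does
resample <- function(x, size = 1L, ...) {
  x[sample.int(length(x), size = size, ...)]
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x == trunc(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x <= 1
}

is_rate <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0
}

# required-column check for data-frame-first interfaces
check_columns <- function(df, cols, arg = deparse(substitute(df))) {
  if (!is.data.frame(df)) {
    abort(sprintf("`%s` must be a data frame", arg))
  }
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf(
      "`%s` is missing required column%s: %s",
      arg, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# ranks within one (sex, year) must be exactly 1..N
check_rank_permutation <- function(ranks) {
  bad <- ranks |>
    dplyr::group_by(.data$sex, .data$year) |>
    dplyr::summarise(
      ok = isTRUE(all(sort(.data$rank) == seq_along(.data$rank))),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad)) {
    abort(sprintf(
      "ranks are not a 1..N permutation for %d (sex, year) group(s), e.g. sex=%s year=%s",
      nrow(bad), bad$sex[1], bad$year[1]
    ))
  }
  invisible(ranks)
}
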
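#' Validate interaction and rank inputs
#'
#' Checks the tabular inputs for schema problems, rank-permutation integrity
#' per (sex, year), internal record consistency, and cross-file identifier
#' consistency. All violations are collected and returned, not just the
#' first.
#'
#' @param interactions Interaction records (year, actor_id, recipient_id,
#'   winner_id), or `NULL` to validate ranks alone.
#' @param ranks Rank table (year, individual_id, sex, rank).
#' @return A tibble of violations (scope, year, sex, issue, detail); zero
#'   rows when the inputs are clean.
#' @export
validate_inputs <- function(interactions = NULL, ranks = NULL) {
  v <- list()
  add <- function(scope, issue, detail, year = NA_integer_, sex = NA_character_) {
    v[[length(v) + 1L]] <<- tibble::tibble(
      scope = scope, year = as.integer(year), sex = sex,
      issue = issue, detail = detail
    )
  }

  if (!is.null(ranks)) {
    missing <- setdiff(c("year", "individual_id", "sex", "rank"), names(ranks))
    if (length(missing)) {
      add("ranks", "missing_columns", paste(missing, collapse = ", "))
    } else {
      dup <- ranks |>
        dplyr::count(.data$individual_id, .data$year) |>
        dplyr::filter(.data$n > 1)
      for (i in seq_len(nrow(dup))) {
        add("ranks", "duplicate_individual_year",
            sprintf("%s appears %d times", dup$individual_id[i], dup$n[i]),
            year = dup$year[i])
      }
      groups <- ranks |> dplyr::distinct(.data$sex, .data$year)
      for (i in seq_len(nrow(groups))) {
        g <- ranks[ranks$sex == groups$sex[i] & ranks$year == groups$year[i], ]
        expected <- seq_len(nrow(g))
        if (!all(sort(g$rank) == expected)) {
          bad <- setdiff(g$rank, expected)
          dup_rank <- g$rank[duplicated(g$rank)]
          add("ranks", "rank_not_permutation",
              sprintf("ranks {%s}%s", paste(sort(g$rank), collapse = ","),
                      if (length(dup_rank)) sprintf(" (rank %s duplicated)",
                                                    paste(unique(dup_rank), collapse = ","))
                      else ""),
              year = groups$year[i], sex = groups$sex[i])
        }
      }
    }
  }

  if (!is.null(interactions)) {
    missing <- setdiff(c("year", "actor_id", "recipient_id", "winner_id"),
                       names(interactions))
    if (length(missing)) {
      add("interactions", "missing_columns", paste(missing, collapse = ", "))
    } else {
      self_fight <- which(interactions$actor_id == interactions$recipient_id)
      for (i in self_fight) {
        add("interactions", "actor_equals_recipient",
            sprintf("row %d: %s", i, interactions$actor_id[i]),
            year = interactions$year[i])
      }
      bad_w <- which(interactions$winner_id != interactions$actor_id &
                       interactions$winner_id != interactions$recipient_id)
      for (i in bad_w) {
        add("interactions", "winner_not_participant",
            sprintf("row %d: winner %s", i, interactions$winner_id[i]),
            year = interactions$year[i])
      }
      if (!is.null(ranks) &&
          all(c("year", "individual_id", "sex") %in% names(ranks))) {
        key <- paste(ranks$individual_id, ranks$year)
        sex_of <- setNames(ranks$sex, ranks$individual_id)
        for (i in seq_len(nrow(interactions))) {
          yr <- interactions$year[i]
          a <- interactions$actor_id[i]
          b <- interactions$recipient_id[i]
          absent <- c(a, b)[!(paste(c(a, b), yr) %in% key)]
          for (id in absent) {
            add("cross", "participant_absent_from_ranks",
                sprintf("row %d: %s not ranked in year %d", i, id, yr),
                year = yr)
          }
          if (!length(absent) && !is.na(sex_of[a]) && !is.na(sex_of[b]) &&
              sex_of[[a]] != sex_of[[b]]) {
            add("cross", "mixed_sex_dyad",
                sprintf("row %d: %s (%s) vs %s (%s)", i, a, sex_of[[a]],
                        b, sex_of[[b]]),
                year = yr)
          }
        }
      }
    }
  }

  if (!length(v)) {
    return(tibble::tibble(scope = character(), year = integer(),
                          sex = character(), issue = character(),
                          detail = character()))
  }
  dplyr::bind_rows(v)
}
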
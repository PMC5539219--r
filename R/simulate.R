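#' Simulate a longitudinal group history
#'
#' Generates an annual-census history of a group with two sex-separate linear
#' dominance hierarchies, together with per-year decided agonistic contests.
#' The update cycle from one census to the next is fixed:
#'
#' 1. **Departures** — each animal leaves with probability `departure_rate`;
#'    which animals leave is sampled without replacement with weight
#'    `(N - rank + 1)^departure_rank_bias`, so departures concentrate at high
#'    ranks when the bias is positive. Survivors close rank gaps upward.
#' 2. **Immigration** — a Poisson(`immigration_rate`) number of new adults
#'    enter each sex-hierarchy at a rank drawn uniformly from
#'    `ceiling(N/2) .. N + 1` (the lower half); animals at or below the entry
#'    rank shift down one.
#' 3. **Endogenous moves** — each animal independently moves with probability
#'    `move_probability`, in a random processing order. Direction is upward
#'    with probability `up_given_move`; magnitude is 1 or 2 (equiprobable)
#'    unless `large_jump_probability` fires, in which case it is uniform on
#'    `3 .. max_jump`. A move is a removal-and-reinsertion at the target rank
#'    (truncated at the ends of the hierarchy), so ranks always remain a
#'    permutation of `1..N`; animals between origin and target shift by one.
#' 4. **Contests** — from the post-update order, each same-sex dyad has a
#'    Poisson(`interactions_per_dyad_per_year`) number of decided contests;
#'    the higher-ranked animal wins each with probability `p_dominant_win`.
#'    The winner is recorded as the actor (aggressor).
#'
#' Year 1 is the initial census (contests are generated for it as well).
#' All randomness flows through one stream seeded from `config$seed`, so
#' identical configurations reproduce identical histories; the caller's RNG
#' state is left untouched.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `group_history`: a list with tibbles
#'   `individuals` (individual_id, sex, entry_year, exit_year),
#'   `ranks` (year, individual_id, sex, rank; rank 1 = alpha),
#'   `interactions` (year, actor_id, recipient_id, winner_id),
#'   plus the `config`.
#' @examples
#' h <- simulate_group(sim_config(n_years = 5, init_adults_per_sex = 4,
#'                                interactions_per_dyad_per_year = 2, seed = 1))
#' head(h$ranks)
#' @export
simulate_group <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created with sim_config()")
  }
  withr::with_seed(config$seed, simulate_group_impl(config))
}

simulate_group_impl <- function(config) {
  sexes <- c("M", "F")
  n0 <- config$init_adults_per_sex

  # per-sex state: character vector of ids, position = rank
  orders <- list(
    M = sprintf("M%03d", seq_len(n0)),
    F = sprintf("F%03d", seq_len(n0))
  )
  next_id <- c(M = n0 + 1L, F = n0 + 1L)
  entry <- setNames(rep(1L, 2 * n0), c(orders$M, orders$F))
  exit <- entry # updated as years pass

  rank_rows <- vector("list", config$n_years * 2L)
  contest_rows <- vector("list", config$n_years * 2L)

  snapshot <- function(year, sex) {
    o <- orders[[sex]]
    if (!length(o)) return(NULL)
    tibble::tibble(year = year, individual_id = o, sex = sex,
                   rank = seq_along(o))
  }

  for (year in seq_len(config$n_years)) {
    if (year > 1L) {
      for (sex in sexes) {
        o <- orders[[sex]]
        n <- length(o)
        # (1) departures, rank-biased
        if (n > 0L && config$departure_rate > 0) {
          n_dep <- rbinom(1L, n, config$departure_rate)
          if (n_dep > 0L) {
            w <- (n - seq_len(n) + 1)^config$departure_rank_bias
            dep <- resample(seq_len(n), size = n_dep, prob = w)
            o <- o[-dep]
          }
        }
        # (2) immigration into the lower half
        n_imm <- rpois(1L, config$immigration_rate)
        if (n_imm > 0L) {
          for (k in seq_len(n_imm)) {
            id <- sprintf("%s%03d", sex, next_id[[sex]])
            next_id[[sex]] <- next_id[[sex]] + 1L
            n_cur <- length(o)
            pos <- resample(seq.int(ceiling(n_cur / 2) + (n_cur == 0),
                                    n_cur + 1L))
            o <- append(o, id, after = pos - 1L)
            entry[[id]] <- year
          }
        }
        # (3) endogenous moves, random processing order
        n <- length(o)
        if (n > 1L && config$move_probability > 0) {
          movers <- o[runif(n) < config$move_probability]
          if (length(movers) > 1L) movers <- resample(movers, length(movers))
          for (id in movers) {
            r <- match(id, o)
            up <- runif(1L) < config$up_given_move
            mag <- if (runif(1L) < config$large_jump_probability) {
              resample(seq.int(3L, config$max_jump))
            } else {
              resample(1:2)
            }
            target <- if (up) max(1L, r - mag) else min(length(o), r + mag)
            if (target != r) {
              o <- append(o[-r], id, after = target - 1L)
            }
          }
        }
        orders[[sex]] <- o
        exit[o] <- year
      }
    } else {
      for (sex in sexes) exit[orders[[sex]]] <- year
    }

    for (sex in sexes) {
      exit[orders[[sex]]] <- year
      rank_rows[[(year - 1L) * 2L + match(sex, sexes)]] <- snapshot(year, sex)
      contest_rows[[(year - 1L) * 2L + match(sex, sexes)]] <-
        contests_for_order(orders[[sex]], config, year)
    }
  }

  ranks <- dplyr::bind_rows(rank_rows)
  interactions <- dplyr::bind_rows(contest_rows)
  individuals <- tibble::tibble(
    individual_id = names(entry),
    sex = substr(names(entry), 1L, 1L),
    entry_year = as.integer(entry),
    exit_year = as.integer(exit[names(entry)])
  ) |> dplyr::arrange(.data$sex, .data$individual_id)

  structure(
    list(individuals = individuals, ranks = ranks,
         interactions = interactions, config = config),
    class = "group_history"
  )
}

# decided contests for one sex-hierarchy in one year (uses current RNG stream)
contests_for_order <- function(order, config, year) {
  n <- length(order)
  if (n < 2L || config$interactions_per_dyad_per_year <= 0) return(NULL)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  hi <- order[idx[, 1L]] # smaller rank number = higher status
  lo <- order[idx[, 2L]]
  n_c <- rpois(length(hi), config$interactions_per_dyad_per_year)
  w_hi <- rbinom(length(hi), n_c, config$p_dominant_win)
  winner <- c(rep(hi, w_hi), rep(lo, n_c - w_hi))
  loser <- c(rep(lo, w_hi), rep(hi, n_c - w_hi))
  if (!length(winner)) return(NULL)
  tibble::tibble(year = year, actor_id = winner, recipient_id = loser,
                 winner_id = winner)
}

#' Generate decided contests for a known rank order
#'
#' Standalone access to the contest model used by [simulate_group()]: each
#' dyad fights a Poisson-distributed number of decided contests and the
#' higher-ranked animal wins each with probability `p_dominant_win`.
#'
#' @param order Character vector of individual identifiers from rank 1
#'   (alpha) downward, or a data frame with columns `individual_id` and
#'   `rank`.
#' @param config A [sim_config()]; only `interactions_per_dyad_per_year` and
#'   `p_dominant_win` are used, plus `seed` when `seed = NULL`.
#' @param year Year label stamped on the records.
#' @param seed Optional seed overriding `config$seed`.
#' @return A tibble of records (year, actor_id, recipient_id, winner_id);
#'   the winner is always the actor.
#' @examples
#' recs <- generate_contests(c("A", "B", "C"),
#'                           sim_config(interactions_per_dyad_per_year = 5,
#'                                      p_dominant_win = 1, seed = 7))
#' table(recs$winner_id)
#' @export
generate_contests <- function(order, config, year = 1L, seed = NULL) {
  if (is.data.frame(order)) {
    check_columns(order, c("individual_id", "rank"), "order")
    order <- order$individual_id[order(order$rank)]
  }
  order <- as.character(order)
  if (length(order) < 2L) abort("`order` must contain at least 2 individuals")
  if (anyDuplicated(order)) abort("`order` contains duplicated identifiers")
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created with sim_config()")
  }
  out <- withr::with_seed(
    seed %||% config$seed,
    contests_for_order(order, config, as.integer(year))
  )
  out %||% tibble::tibble(year = integer(), actor_id = character(),
                          recipient_id = character(), winner_id = character())
}

#' @export
print.group_history <- function(x, ...) {
  cat(sprintf(
    "<group_history> %d years, %d individuals (%d M / %d F), %d interaction records\n",
    max(x$ranks$year), nrow(x$individuals),
    sum(x$individuals$sex == "M"), sum(x$individuals$sex == "F"),
    nrow(x$interactions)
  ))
  invisible(x)
}
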
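#' Build a win:loss matrix from agonistic interaction records
#'
#' Tallies decided dyadic contests into a square matrix whose cell (i, j) is
#' the number of wins of individual i over individual j. The matrix is the
#' input to reversal-minimizing rank ordering ([find_rank_order()]).
#'
#' @param records Data frame of decided interactions with columns
#'   `actor_id`, `recipient_id`, `winner_id` (one row per contest; an
#'   optional `year` column is ignored — filter beforehand for annual
#'   matrices).
#' @param individuals Character vector of identifiers defining the matrix
#'   axes (may include animals with no records).
#' @return A `win_loss_matrix`: an integer matrix with individual ids as
#'   dimnames and zero diagonal.
#' @examples
#' recs <- tibble::tibble(actor_id = "A", recipient_id = "B", winner_id = "A")
#' build_win_loss_matrix(recs, c("A", "B", "C"))
#' @export
build_win_loss_matrix <- function(records, individuals) {
  check_columns(records, c("actor_id", "recipient_id", "winner_id"), "records")
  individuals <- as.character(individuals)
  if (anyDuplicated(individuals)) abort("`individuals` contains duplicates")

  if (nrow(records)) {
    same <- records$actor_id == records$recipient_id
    if (any(same)) {
      abort(sprintf("record(s) %s have actor == recipient",
                    paste(head(which(same), 5), collapse = ", ")))
    }
    bad_winner <- records$winner_id != records$actor_id &
      records$winner_id != records$recipient_id
    if (any(bad_winner)) {
      abort(sprintf("record(s) %s name a winner who is not a participant",
                    paste(head(which(bad_winner), 5), collapse = ", ")))
    }
    unknown <- !(records$actor_id %in% individuals) |
      !(records$recipient_id %in% individuals)
    if (any(unknown)) {
      abort(sprintf("record(s) %s name individuals outside `individuals`",
                    paste(head(which(unknown), 5), collapse = ", ")))
    }
  }

  loser <- ifelse(records$winner_id == records$actor_id,
                  records$recipient_id, records$actor_id)
  m <- table(factor(records$winner_id, levels = individuals),
             factor(loser, levels = individuals))
  m <- matrix(as.integer(m), nrow = length(individuals),
              dimnames = list(individuals, individuals))
  structure(m, class = c("win_loss_matrix", class(m)))
}

#' Count reversals of a win:loss matrix under a candidate rank order
#'
#' A reversal is a win by a lower-ranked individual over a higher-ranked one.
#' After rearranging the matrix rows/columns into the candidate order, the
#' reversal count is the sum of all below-diagonal cells.
#'
#' @param matrix A [build_win_loss_matrix()] result (or any square named
#'   count matrix with zero diagonal).
#' @param order Character vector permuting the matrix's individuals, rank 1
#'   first.
#' @return Nonnegative number of reversal interactions.
#' @examples
#' m <- build_win_loss_matrix(
#'   tibble::tibble(actor_id = c("A", "C"), recipient_id = c("B", "A"),
#'                  winner_id = c("A", "C")),
#'   c("A", "B", "C"))
#' count_reversals(m, c("A", "B", "C"))
#' @export
count_reversals <- function(matrix, order) {
  ids <- rownames(matrix)
  order <- as.character(order)
  if (!setequal(order, ids) || length(order) != length(ids)) {
    abort("`order` must be a permutation of the matrix's individuals")
  }
  p <- unclass(matrix)[order, order, drop = FALSE]
  sum(p[lower.tri(p)])
}

#' Derive a rank order by minimizing the number of reversals
#'
#' Rearranges the win:loss matrix to minimize the total number of wins by
#' lower-ranked over higher-ranked individuals. For `N <= 9` active
#' individuals the global minimum is found exactly (dynamic programming over
#' subsets, equivalent to exhaustive enumeration of all orders); for larger
#' matrices a seeded pairwise-swap hill climb with random restarts is used
#' and the result is flagged `method = "heuristic"`.
#'
#' Ties among equally minimal orders are broken deterministically: prefer the
#' order whose rank-1 individual has the larger total win count, then rank 2,
#' and so on; remaining ties go to the lexicographically smaller identifier.
#' Individuals appearing in no interaction at all are placed last in
#' lexicographic order and listed in the result's `unobserved` field.
#'
#' @param matrix A `win_loss_matrix`.
#' @param exact_limit Largest N solved exactly (default 9; `9! = 362880`
#'   orders).
#' @param restarts Random restarts for the heuristic (at least 20 are used).
#' @param seed Seed for the heuristic's random restarts.
#' @return A `rank_order` object: list with `order` (ids, rank 1 = alpha),
#'   `reversals` (exact count for the returned order), `method`
#'   (`"exhaustive"` or `"heuristic"`), and `unobserved`.
#' @examples
#' recs <- tibble::tibble(
#'   actor_id = c(rep("A", 6), rep("B", 4), rep("C", 3)),
#'   recipient_id = c(rep("B", 5), "C", rep("C", 4), rep("A", 3)),
#'   winner_id = c(rep("A", 6), rep("B", 4), rep("C", 3)))
#' find_rank_order(build_win_loss_matrix(recs, c("A", "B", "C")))
#' @export
find_rank_order <- function(matrix, exact_limit = 9L, restarts = 20L,
                            seed = 1L) {
  ids <- rownames(matrix)
  if (is.null(ids) || nrow(matrix) < 1L) {
    abort("`matrix` must be a named square matrix with >= 1 individual")
  }
  m <- unclass(matrix)

  involved <- rowSums(m) + colSums(m) > 0
  active <- ids[involved]
  silent <- sort(ids[!involved])

  if (length(active) <= 1L) {
    ord <- c(active, silent)
    if (!length(active)) ord <- silent
    return(new_rank_order(ord, 0, "exhaustive", silent))
  }

  ma <- m[active, active, drop = FALSE]
  if (length(active) <= exact_limit) {
    ord <- exact_min_reversal_order(ma)
    method <- "exhaustive"
  } else {
    ord <- heuristic_min_reversal_order(ma, restarts = max(20L, restarts),
                                        seed = seed)
    method <- "heuristic"
  }
  full <- c(ord, silent)
  new_rank_order(full, count_reversals(matrix, full), method, silent)
}

new_rank_order <- function(order, reversals, method, unobserved) {
  structure(
    list(order = order, reversals = reversals, method = method,
         unobserved = unobserved),
    class = "rank_order"
  )
}

# Exact minimum-reversal order via suffix DP over subsets.
# f(S) = min reversals attainable arranging set S as the bottom |S| ranks,
#      = min over i in S of (wins of S\{i} members over i) + f(S\{i}),
# where i is the highest-ranked member of S. Reconstruction is greedy from
# the full set, applying the documented tie-break.
exact_min_reversal_order <- function(m) {
  n <- nrow(m)
  ids <- rownames(m)
  full <- bitwShiftL(1L, n) - 1L
  f <- rep(NA_real_, full + 1L)
  f[1L] <- 0 # empty set (mask 0 at index 1)

  members <- lapply(0:full, function(mask) which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) > 0L))
  for (mask in 1:full) {
    mem <- members[[mask + 1L]]
    best <- Inf
    for (i in mem) {
      rest <- mem[mem != i]
      cost <- sum(m[rest, i]) + f[bitwAnd(mask, bitwNot(bitwShiftL(1L, i - 1L))) + 1L]
      if (cost < best) best <- cost
    }
    f[mask + 1L] <- best
  }

  # greedy reconstruction with tie-breaking
  wins_total <- rowSums(m)
  lex_rank <- rank(ids, ties.method = "first")
  order_idx <- integer(n)
  mask <- full
  for (pos in seq_len(n)) {
    mem <- members[[mask + 1L]]
    cost <- vapply(mem, function(i) {
      rest <- mem[mem != i]
      sum(m[rest, i]) + f[bitwAnd(mask, bitwNot(bitwShiftL(1L, i - 1L))) + 1L]
    }, numeric(1))
    cand <- mem[cost == min(cost)]
    if (length(cand) > 1L) {
      cand <- cand[wins_total[cand] == max(wins_total[cand])]
      if (length(cand) > 1L) cand <- cand[which.min(lex_rank[cand])]
    }
    i <- cand[1L]
    order_idx[pos] <- i
    mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, i - 1L)))
  }
  ids[order_idx]
}

# Pairwise-swap hill climbing with random restarts; deterministic given seed.
heuristic_min_reversal_order <- function(m, restarts, seed) {
  n <- nrow(m)
  ids <- rownames(m)
  climb <- function(ord) {
    rev_n <- count_reversals(m, ord)
    repeat {
      improved <- FALSE
      for (i in seq_len(n - 1L)) {
        for (j in seq.int(i + 1L, n)) {
          cand <- ord
          cand[c(i, j)] <- cand[c(j, i)]
          r <- count_reversals(m, cand)
          if (r < rev_n) {
            ord <- cand
            rev_n <- r
            improved <- TRUE
          }
        }
      }
      if (!improved) return(list(order = ord, reversals = rev_n))
    }
  }
  withr::with_seed(seed, {
    # one informed start (descending total wins), the rest random
    starts <- c(
      list(ids[order(-rowSums(m), ids)]),
      replicate(restarts - 1L, resample(ids, n), simplify = FALSE)
    )
    best <- NULL
    for (s in starts) {
      res <- climb(s)
      if (is.null(best) || res$reversals < best$reversals) best <- res
    }
    best$order
  })
}

#' Infer annual rank orders from interaction records
#'
#' Splits records by year and sex and applies [find_rank_order()] to each
#' annual win:loss matrix, producing a longitudinal rank table ready for the
#' mobility and stratification stages.
#'
#' @param interactions Data frame with columns `year`, `actor_id`,
#'   `recipient_id`, `winner_id`.
#' @param roster Data frame mapping `individual_id` to `sex`; with optional
#'   `entry_year` / `exit_year` columns, animals present but unrecorded in a
#'   year are still ranked (placed last, see [find_rank_order()]). Without
#'   them, presence in a year is taken from the records.
#' @param ... Passed to [find_rank_order()].
#' @return A tibble (year, individual_id, sex, rank, reversals, method).
#' @export
infer_ranks <- function(interactions, roster, ...) {
  check_columns(interactions, c("year", "actor_id", "recipient_id", "winner_id"),
                "interactions")
  check_columns(roster, c("individual_id", "sex"), "roster")
  sex_of <- setNames(roster$sex, roster$individual_id)
  has_window <- all(c("entry_year", "exit_year") %in% names(roster))

  out <- list()
  for (yr in sort(unique(interactions$year))) {
    recs <- interactions[interactions$year == yr, , drop = FALSE]
    for (sx in sort(unique(roster$sex))) {
      if (has_window) {
        present <- roster$individual_id[roster$sex == sx &
                                          roster$entry_year <= yr &
                                          roster$exit_year >= yr]
      } else {
        here <- unique(c(recs$actor_id, recs$recipient_id))
        present <- here[sex_of[here] == sx]
      }
      if (!length(present)) next
      recs_sx <- recs[recs$actor_id %in% present & recs$recipient_id %in% present, ,
                      drop = FALSE]
      ro <- find_rank_order(build_win_loss_matrix(recs_sx, present), ...)
      out[[length(out) + 1L]] <- tibble::tibble(
        year = yr, individual_id = ro$order, sex = sx,
        rank = seq_along(ro$order), reversals = ro$reversals,
        method = ro$method
      )
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.rank_order <- function(x, ...) {
  cat(sprintf("<rank_order> %d individuals, %g reversals (%s)\n",
              length(x$order), x$reversals, x$method))
  cat("  ", paste(x$order, collapse = " > "), "\n")
  if (length(x$unobserved)) {
    cat("  unobserved (placed last):", paste(x$unobserved, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname find_rank_order
#' @param x A `rank_order` object.
#' @exportS3Method
tidy.rank_order <- function(x, ...) {
  tibble::tibble(
    rank = seq_along(x$order),
    individual_id = x$order,
    observed = !(x$order %in% x$unobserved)
  )
}
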
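# Shared fixtures and independent oracles, all built in code.

# The 3-individual worked example: A beats B 5x, B beats C 4x, C beats A 3x,
# A beats C once. Reversal-minimal order is A > B > C with 3 reversals.
worked_example_records <- function() {
  tibble::tibble(
    actor_id = c(rep("A", 5), rep("B", 4), rep("C", 3), "A"),
    recipient_id = c(rep("B", 5), rep("C", 4), rep("A", 3), "C"),
    winner_id = c(rep("A", 5), rep("B", 4), rep("C", 3), "A")
  )
}

worked_example_matrix <- function() {
  build_win_loss_matrix(worked_example_records(), c("A", "B", "C"))
}

# The three published annual stratum transition matrices.
published_matrices <- function() {
  list(
    male = transition_matrix(0.9570, 0.0430, 0.1854, 0.8146),
    female = transition_matrix(0.9184, 0.0816, 0.1985, 0.8015),
    combined = transition_matrix(0.9375, 0.0625, 0.1922, 0.8078)
  )
}

# The published stratification table (horizon, H-H, L-L per cohort).
published_table <- function() {
  tibble::tribble(
    ~cohort, ~horizon, ~h_h, ~l_l,
    "male", 2L, 0.9238, 0.6715,
    "male", 4L, 0.8784, 0.4759,
    "male", 8L, 0.8353, 0.2902,
    "male", 16L, 0.8146, 0.2011,
    "male", 32L, 0.8117, 0.1886,
    "female", 2L, 0.8597, 0.6586,
    "female", 4L, 0.7870, 0.4817,
    "female", 8L, 0.7298, 0.3424,
    "female", 16L, 0.7107, 0.2949,
    "female", 32L, 0.7088, 0.2912,
    "combined", 2L, 0.8909, 0.6646,
    "combined", 4L, 0.8303, 0.4783,
    "combined", 8L, 0.7779, 0.3173,
    "combined", 16L, 0.7568, 0.2523,
    "combined", 32L, 0.7546, 0.2455
  )
}

# Random win:loss matrix with ids shuffled away from the true order.
random_wl_matrix <- function(n, max_count = 6) {
  ids <- sample(paste0("ind", sprintf("%02d", seq_len(n))))
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      a <- sample(0:max_count, 1)
      b <- sample(0:max_count, 1)
      m[i, j] <- a
      m[j, i] <- b
    }
  }
  structure(m, class = c("win_loss_matrix", class(m)))
}

# Independent brute-force oracle: enumerate every permutation and tally
# below-diagonal wins with plain loops (no package code).
all_permutations <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      perm_rec <- function(v) {
        if (length(v) <= 1) return(matrix(v, nrow = max(1, length(v))))
        do.call(rbind, lapply(seq_along(v), function(i) {
          cbind(v[i], perm_rec(v[-i]))
        }))
      }
      cache[[key]] <<- perm_rec(seq_len(n))
    }
    cache[[key]]
  }
})

brute_force_reversals <- function(m, perm_idx) {
  # perm_idx: integer vector, rank position -> matrix row index
  total <- 0
  n <- length(perm_idx)
  for (pos_hi in seq_len(n - 1)) {
    for (pos_lo in seq.int(pos_hi + 1, n)) {
      total <- total + m[perm_idx[pos_lo], perm_idx[pos_hi]]
    }
  }
  total
}

brute_force_min_reversals <- function(m) {
  perms <- all_permutations(nrow(m))
  min(apply(perms, 1, function(p) brute_force_reversals(unclass(m), p)))
}

# Long-run expectation oracle: one very long history under identical update
# rules (contests off — they do not feed back into rank dynamics), pooled.
longrun_stats <- function(config, years = 3000L, seed = 20090L) {
  cfg <- config
  cfg$n_years <- as.integer(years)
  cfg$interactions_per_dyad_per_year <- 0
  cfg$seed <- as.integer(seed)
  h <- simulate_group(cfg)
  pairs <- rank_pairs(h$ranks)
  tc <- classify_transitions(pairs)
  fit <- fit_mobility(pairs)
  list(
    same_frac = tc$n_same / tc$n,
    up_frac = tc$n_up / (tc$n_up + tc$n_down),
    rate = fit$rate,
    n = tc$n
  )
}

# A small, fully valid longitudinal rank table built by hand:
# 4 males, 4 years, one up-move (C overtakes B in year 3).
tiny_ranks <- function() {
  tibble::tibble(
    year = rep(1:4, each = 4),
    individual_id = c("A", "B", "C", "D",
                      "A", "B", "C", "D",
                      "A", "C", "B", "D",
                      "A", "C", "B", "D"),
    sex = "M",
    rank = rep(1:4, times = 4)
  )
}
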
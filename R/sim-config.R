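#' Simulation configuration for a longitudinal group history
#'
#' Bundles and validates every parameter of the group simulator. The defaults
#' describe a small matrilineal macaque group — two sex-separate linear
#' hierarchies of about eight adults each, observed annually for 30 years —
#' with rank-biased departures, immigration into the lower half of the
#' hierarchy, occasional endogenous rank moves, and frequent decided dyadic
#' contests. At these defaults the *emergent* pooled annual statistics sit at
#' the regularities typical of such groups: roughly 2:1 stay/change, roughly
#' 3:1 upward/downward movement among changes, and most changes within two
#' ranks. Because departures, immigration, and the displacement side of every
#' remove-and-reinsert move all shift survivors' ranks, these pooled fractions
#' are emergent properties of the whole system, not direct copies of
#' `move_probability` and `up_given_move`.
#'
#' @param n_years Number of annual censuses to simulate.
#' @param init_adults_per_sex Number of adults per sex-hierarchy in year 1
#'   (must be at least 2 so dyads exist).
#' @param adult_age_threshold Age (years) at which an animal counts as adult.
#'   Recorded for provenance; the simulator works directly with adults.
#' @param departure_rate Per-individual annual probability of leaving the
#'   group (death or emigration).
#' @param departure_rank_bias Dimensionless exponent `>= 0` controlling how
#'   strongly departures concentrate at high ranks: the sampling weight of
#'   the animal at rank r in a hierarchy of N is `(N - r + 1)^bias`. Zero
#'   means uniform.
#' @param immigration_rate Expected number of new adults entering each
#'   sex-hierarchy per year (Poisson). New animals enter at a rank drawn
#'   uniformly from the lower half, `ceiling(N/2) .. N + 1`.
#' @param move_probability Annual per-individual probability of an endogenous
#'   rank move (a challenge won or lost), applied on top of the demographic
#'   rank shifts.
#' @param up_given_move Probability that an endogenous move is upward.
#' @param large_jump_probability Probability that an endogenous move has
#'   magnitude of at least 3 ranks (otherwise 1 or 2, equiprobable).
#' @param max_jump Largest endogenous move magnitude (rank units, `>= 3`).
#' @param interactions_per_dyad_per_year Expected number of decided agonistic
#'   contests per same-sex dyad per year (Poisson).
#' @param p_dominant_win Probability that the higher-ranked member of a dyad
#'   wins a decided contest.
#' @param seed Integer seed; identical config + seed reproduces the history
#'   byte for byte.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_group()]
#' @examples
#' cfg <- sim_config(n_years = 5, init_adults_per_sex = 4, seed = 42)
#' cfg$move_probability
#' @export
sim_config <- function(n_years = 30L,
                       init_adults_per_sex = 8L,
                       adult_age_threshold = 7,
                       departure_rate = 0.045,
                       departure_rank_bias = 5,
                       immigration_rate = 0.36,
                       move_probability = 0.025,
                       up_given_move = 0.75,
                       large_jump_probability = 0.35,
                       max_jump = 5L,
                       interactions_per_dyad_per_year = 20,
                       p_dominant_win = 0.9,
                       seed = 1L) {
  cfg <- list(
    n_years = as.integer(n_years),
    init_adults_per_sex = as.integer(init_adults_per_sex),
    adult_age_threshold = adult_age_threshold,
    departure_rate = departure_rate,
    departure_rank_bias = departure_rank_bias,
    immigration_rate = immigration_rate,
    move_probability = move_probability,
    up_given_move = up_given_move,
    large_jump_probability = large_jump_probability,
    max_jump = as.integer(max_jump),
    interactions_per_dyad_per_year = interactions_per_dyad_per_year,
    p_dominant_win = p_dominant_win,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_years, min = 1)) {
    abort("`n_years` must be a positive integer")
  }
  if (!is_count(cfg$init_adults_per_sex, min = 2)) {
    abort("`init_adults_per_sex` must be an integer >= 2 (no dyads otherwise)")
  }
  for (p in c("departure_rate", "move_probability", "up_given_move",
              "large_jump_probability", "p_dominant_win")) {
    if (!is_prob(cfg[[p]])) abort(sprintf("`%s` must be a probability in [0, 1]", p))
  }
  for (r in c("departure_rank_bias", "immigration_rate",
              "interactions_per_dyad_per_year")) {
    if (!is_rate(cfg[[r]])) abort(sprintf("`%s` must be a nonnegative number", r))
  }
  if (!is_count(cfg$max_jump, min = 3)) {
    abort("`max_jump` must be an integer >= 3")
  }
  if (!is_count(cfg$seed, min = -Inf)) {
    abort("`seed` must be an integer")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) cat(sprintf("  %-30s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
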
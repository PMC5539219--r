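#' Assign adults to upper and lower strata, with half-scores at odd sizes
#'
#' Splits each (sex, year) hierarchy into upper (H) and lower (L) strata of
#' equal size. With an even number of adults the top half gets weight 1 in H;
#' with an odd number the middle-ranking individual receives two half-scores,
#' one for each stratum, so the stratum totals are always N/2.
#'
#' @param ranks Rank table (year, individual_id, sex, rank), rank 1 = alpha.
#' @param sex Optional restriction to one sex-hierarchy.
#' @return The input rows with columns `weight_h` and `weight_l` added
#'   (each in {0, 0.5, 1}, summing to 1 per individual-year).
#' @examples
#' ranks <- tibble::tibble(year = 1, individual_id = letters[1:5],
#'                         sex = "F", rank = 1:5)
#' assign_strata(ranks)
#' @export
assign_strata <- function(ranks, sex = NULL) {
  check_columns(ranks, c("year", "individual_id", "sex", "rank"), "ranks")
  if (!is.null(sex)) ranks <- ranks[ranks$sex %in% sex, , drop = FALSE]
  check_rank_permutation(ranks)
  ranks |>
    dplyr::group_by(.data$sex, .data$year) |>
    dplyr::mutate(
      weight_h = dplyr::case_when(
        dplyr::n() %% 2 == 1 & .data$rank == (dplyr::n() + 1) / 2 ~ 0.5,
        .data$rank <= dplyr::n() / 2 ~ 1,
        TRUE ~ 0
      ),
      weight_l = 1 - .data$weight_h
    ) |>
    dplyr::ungroup() |>
    tibble::as_tibble()
}

#' Construct a 2x2 stratum transition matrix
#'
#' Builds a validated row-stochastic matrix over the strata {H, L}, either
#' directly from four probabilities or from fractional transition counts
#' (which are row-normalized).
#'
#' @param p_hh,p_hl,p_lh,p_ll Transition probabilities (each row must sum
#'   to 1): stay high, high-to-low, low-to-high, stay low.
#' @param counts Optional 2x2 matrix of fractional transition counts from
#'   which the probabilities were estimated.
#' @return A `transition_matrix` object: list with `p` (2x2 matrix, dimnames
#'   H/L) and `counts` (2x2 matrix or `NULL`).
#' @examples
#' transition_matrix(0.9375, 0.0625, 0.1922, 0.8078)
#' @export
transition_matrix <- function(p_hh, p_hl, p_lh, p_ll, counts = NULL) {
  p <- matrix(c(p_hh, p_hl, p_lh, p_ll), nrow = 2, byrow = TRUE,
              dimnames = list(c("H", "L"), c("H", "L")))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("transition probabilities must lie in [0, 1]")
  }
  if (any(abs(rowSums(p) - 1) > 1e-9)) {
    abort("each row of the transition matrix must sum to 1 (tolerance 1e-9)")
  }
  if (!is.null(counts)) {
    counts <- matrix(as.numeric(counts), nrow = 2,
                     dimnames = list(c("H", "L"), c("H", "L")))
    if (any(counts < 0)) abort("transition counts must be nonnegative")
  }
  structure(list(p = p, counts = counts), class = "transition_matrix")
}

#' @rdname transition_matrix
#' @param m A plain 2x2 matrix (rows H, L) to convert.
#' @export
as_transition_matrix <- function(m, counts = NULL) {
  if (!is.matrix(m) || !all(dim(m) == 2L)) abort("`m` must be a 2x2 matrix")
  transition_matrix(m[1, 1], m[1, 2], m[2, 1], m[2, 2], counts = counts)
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix>\n")
  print(round(x$p, 4))
  if (!is.null(x$counts)) {
    cat(sprintf("  (from %.1f fractional transition counts)\n", sum(x$counts)))
  }
  invisible(x)
}

#' @rdname transition_matrix
#' @param x A `transition_matrix`.
#' @exportS3Method
tidy.transition_matrix <- function(x, ...) {
  out <- tibble::tibble(
    from = rep(c("H", "L"), each = 2), to = rep(c("H", "L"), 2),
    probability = as.vector(t(x$p))
  )
  if (!is.null(x$counts)) out$count <- as.vector(t(x$counts))
  out
}

#' Estimate the stratum transition matrix from consecutive-year weights
#'
#' For every individual present in years t and t + 1 (within its sex),
#' adds the product `weight_origin(t) x weight_destination(t + 1)` to each of
#' the four cells, so a middle-ranking animal (half-score in each stratum)
#' contributes fractionally to all cells it could have moved between.
#' Animals exiting the group contribute nothing. Rows of the resulting
#' fractional count matrix are normalized to probabilities.
#'
#' @param assignment An [assign_strata()] tibble (needs year, individual_id,
#'   sex, weight_h, weight_l).
#' @return A [transition_matrix()] carrying the fractional counts.
#' @export
estimate_transition_matrix <- function(assignment) {
  check_columns(assignment,
                c("year", "individual_id", "sex", "weight_h", "weight_l"),
                "assignment")
  nxt <- dplyr::transmute(assignment,
    individual_id = .data$individual_id, sex = .data$sex,
    year = .data$year - 1L,
    wh1 = .data$weight_h, wl1 = .data$weight_l
  )
  joined <- dplyr::inner_join(assignment, nxt,
                              by = c("individual_id", "sex", "year"))
  if (!nrow(joined)) abort("no consecutive-year transitions observed")
  counts <- matrix(c(
    sum(joined$weight_h * joined$wh1), sum(joined$weight_h * joined$wl1),
    sum(joined$weight_l * joined$wh1), sum(joined$weight_l * joined$wl1)
  ), nrow = 2, byrow = TRUE, dimnames = list(c("H", "L"), c("H", "L")))
  if (any(rowSums(counts) == 0)) {
    abort("a stratum has no outgoing transition mass: matrix not estimable")
  }
  p <- counts / rowSums(counts)
  transition_matrix(p[1, 1], p[1, 2], p[2, 1], p[2, 2], counts = counts)
}

#' Pool fractional transition counts across cohorts
#'
#' Combines transition matrices by summing their fractional counts before
#' renormalizing (the maximum-likelihood combination), rather than averaging
#' probabilities.
#'
#' @param ... `transition_matrix` objects carrying counts.
#' @return A pooled [transition_matrix()].
#' @export
pool_transition_matrices <- function(...) {
  ms <- list(...)
  if (any(vapply(ms, function(m) is.null(m$counts), logical(1)))) {
    abort("all matrices must carry fractional counts to be pooled")
  }
  counts <- Reduce(`+`, lapply(ms, `[[`, "counts"))
  p <- counts / rowSums(counts)
  transition_matrix(p[1, 1], p[1, 2], p[2, 1], p[2, 2], counts = counts)
}

#' n-step transition matrix by repeated squaring
#'
#' @param tm A [transition_matrix()].
#' @param n Positive integer horizon (years).
#' @return The exact n-step `transition_matrix`.
#' @examples
#' cm <- transition_matrix(0.9375, 0.0625, 0.1922, 0.8078)
#' matrix_power(cm, 2)$p
#' @export
matrix_power <- function(tm, n) {
  if (!inherits(tm, "transition_matrix")) {
    abort("`tm` must be a transition_matrix")
  }
  if (!is_count(n, min = 1)) abort("`n` must be a positive integer")
  n <- as.integer(n)
  result <- diag(2)
  base <- tm$p
  while (n > 0L) {
    if (n %% 2L == 1L) result <- result %*% base
    base <- base %*% base
    n <- n %/% 2L
  }
  dimnames(result) <- dimnames(tm$p)
  # renormalize away accumulated floating-point drift (never exceeds ~1e-15)
  as_transition_matrix(result / rowSums(result))
}

#' Stationary distribution of a two-state stratum chain
#'
#' Closed form for an irreducible aperiodic 2-state chain:
#' `pi_H = p_LH / (p_HL + p_LH)`, `pi_L = 1 - pi_H`. These are the limiting
#' probabilities the powered matrix's rows approach.
#'
#' @param tm A [transition_matrix()] with both off-diagonal entries positive
#'   (otherwise a stratum is absorbing) and not both diagonals zero
#'   (otherwise the chain is periodic).
#' @return Named numeric vector `c(H = pi_H, L = pi_L)`.
#' @examples
#' stationary_distribution(transition_matrix(0.9, 0.1, 0.1, 0.9))
#' @export
stationary_distribution <- function(tm) {
  if (!inherits(tm, "transition_matrix")) {
    abort("`tm` must be a transition_matrix")
  }
  p <- tm$p
  if (p["H", "L"] == 0 || p["L", "H"] == 0) {
    side <- if (p["H", "L"] == 0) "H (p_HL = 0)" else "L (p_LH = 0)"
    abort(sprintf(
      "chain is not irreducible: stratum %s is absorbing, no limiting probabilities",
      side
    ))
  }
  if (p["H", "H"] == 0 && p["L", "L"] == 0) {
    abort("chain is periodic (both diagonal entries zero): no limiting probabilities")
  }
  pi_h <- p["L", "H"] / (p["H", "L"] + p["L", "H"])
  c(H = unname(pi_h), L = unname(1 - pi_h))
}

#' First doubling horizon at which the chain has stabilized
#'
#' Powers the transition matrix over doubling horizons and returns the first
#' at which both diagonal elements are within `tol` of their limiting
#' probabilities — the operational criterion for when the stratification
#' process has reached its stable state.
#'
#' @param tm A [transition_matrix()].
#' @param tol Stabilization tolerance on the diagonal elements (default
#'   0.001).
#' @param horizons Increasing integer horizons to test (default the doubling
#'   sequence 2, 4, ..., 1024).
#' @return A one-row tibble (horizon, dev_hh, dev_ll, tol); `horizon` is
#'   `NA` (with a warning) if no tested horizon meets the criterion.
#' @examples
#' convergence_horizon(transition_matrix(0.9375, 0.0625, 0.1922, 0.8078))
#' @export
convergence_horizon <- function(tm, tol = 0.001, horizons = 2^(1:10)) {
  if (!is.numeric(tol) || tol <= 0) abort("`tol` must be positive")
  pi_ <- stationary_distribution(tm)
  for (n in horizons) {
    pn <- matrix_power(tm, n)$p
    dev_hh <- abs(pn["H", "H"] - pi_[["H"]])
    dev_ll <- abs(pn["L", "L"] - pi_[["L"]])
    if (max(dev_hh, dev_ll) < tol) {
      return(tibble::tibble(horizon = as.integer(n), dev_hh = dev_hh,
                            dev_ll = dev_ll, tol = tol))
    }
  }
  warn(sprintf("no horizon up to %d meets the %g criterion", max(horizons), tol))
  tibble::tibble(horizon = NA_integer_, dev_hh = dev_hh, dev_ll = dev_ll,
                 tol = tol)
}

#' Social stratification table over doubling horizons
#'
#' The diagonal (H-H and L-L) elements of each cohort's n-step transition
#' matrix at the doubling horizons — the probabilities of still being in the
#' same stratum n years on, which approach the limiting probabilities as n
#' grows.
#'
#' @param matrices Named list of [transition_matrix()] objects, one per
#'   cohort (for example `male`, `female`, `combined`).
#' @param horizons Integer horizons (default 2, 4, 8, 16, 32 years).
#' @param digits Decimal places for the reported probabilities (default 4,
#'   as such tables are conventionally printed); `NULL` for full precision.
#' @return A tibble (cohort, horizon, h_h, l_l).
#' @examples
#' cm <- transition_matrix(0.9375, 0.0625, 0.1922, 0.8078)
#' stratification_table(list(combined = cm))
#' @export
stratification_table <- function(matrices, horizons = c(2, 4, 8, 16, 32),
                                 digits = 4) {
  if (!length(matrices) || is.null(names(matrices)) ||
      any(!nzchar(names(matrices)))) {
    abort("`matrices` must be a named list of transition_matrix objects")
  }
  rows <- list()
  for (cohort in names(matrices)) {
    for (n in horizons) {
      pn <- matrix_power(matrices[[cohort]], n)$p
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cohort = cohort, horizon = as.integer(n),
        h_h = pn["H", "H"], l_l = pn["L", "L"]
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(digits)) {
    out <- dplyr::mutate(out, h_h = round(.data$h_h, digits),
                         l_l = round(.data$l_l, digits))
  }
  out
}
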
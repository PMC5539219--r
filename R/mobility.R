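#' Consecutive-year rank pairs
#'
#' Extracts one (R_t, R_t1) pair per individual per pair of consecutive years
#' in which it holds a rank — the individual-year sample underlying the
#' mobility rate and the transition classification. Animals absent in year
#' t + 1 contribute nothing for year t (they are censored, not a transition).
#'
#' @param ranks Data frame (year, individual_id, sex, rank), rank 1 = alpha.
#' @param sex Optional label (`"M"`/`"F"`) restricting the table to one
#'   sex-hierarchy; `NULL` keeps both (transitions still pair within sex).
#' @return A tibble (individual_id, sex, year, r_t, r_t1).
#' @export
rank_pairs <- function(ranks, sex = NULL) {
  check_columns(ranks, c("year", "individual_id", "sex", "rank"), "ranks")
  if (!is.null(sex)) ranks <- ranks[ranks$sex %in% sex, , drop = FALSE]
  nxt <- dplyr::transmute(ranks,
    individual_id = .data$individual_id, sex = .data$sex,
    year = .data$year - 1L, r_t1 = .data$rank
  )
  ranks |>
    dplyr::select("individual_id", "sex", "year", r_t = "rank") |>
    dplyr::inner_join(nxt, by = c("individual_id", "sex", "year")) |>
    dplyr::arrange(.data$sex, .data$individual_id, .data$year) |>
    tibble::as_tibble()
}

#' Annual social mobility rate from the rank-on-rank regression
#'
#' Fits the ordinary least-squares regression of rank in year t + 1 on rank
#' in year t across individual-years. The annual mobility rate is `1 - b`,
#' where `b` is the slope: a perfectly rigid hierarchy has b = 1 and rate 0.
#' Significance is assessed through Pearson's r.
#'
#' @param pairs A [rank_pairs()] tibble (needs columns `r_t`, `r_t1`).
#' @param df_method Degrees of freedom convention for the correlation test:
#'   `"n-2"` (the standard, default) or `"n-1"` (as sometimes reported in
#'   field studies).
#' @return A `mobility_fit` object wrapping the `lm` fit with fields
#'   `slope`, `intercept`, `rate` (= 1 - slope exactly), `r`, `n`, `df`,
#'   `p_value`, `residuals`.
#' @examples
#' p <- tibble::tibble(r_t = c(1, 2, 3), r_t1 = c(2, 1, 3))
#' glance(fit_mobility(p))
#' @export
fit_mobility <- function(pairs, df_method = c("n-2", "n-1")) {
  check_columns(pairs, c("r_t", "r_t1"), "pairs")
  df_method <- match.arg(df_method)
  n <- nrow(pairs)
  if (n < 3L) abort("need at least 3 rank pairs to fit the regression")
  if (var(pairs$r_t) == 0) {
    abort("all R(t) values are identical: the slope is undefined")
  }
  fit <- lm(r_t1 ~ r_t, data = pairs)
  b <- unname(coef(fit)[["r_t"]])
  r <- suppressWarnings(stats::cor(pairs$r_t, pairs$r_t1))
  df <- if (df_method == "n-2") n - 2L else n - 1L
  # two-tailed p from the t transform of r (guard the perfect-fit boundary)
  p_value <- if (is.na(r) || abs(r) >= 1) 0 else {
    tt <- r * sqrt(df / (1 - r^2))
    2 * pt(-abs(tt), df)
  }
  structure(
    list(
      slope = b, intercept = unname(coef(fit)[[1L]]), rate = 1 - b,
      r = r, n = n, df = df, p_value = p_value,
      residuals = unname(residuals(fit)), lm = fit, pairs = tibble::as_tibble(pairs)
    ),
    class = "mobility_fit"
  )
}

#' @export
print.mobility_fit <- function(x, ...) {
  cat(sprintf(
    "<mobility_fit> n = %d individual-years\n  slope b = %.4f, rate 1 - b = %.4f, r = %.4f (df = %d, p = %.3g)\n",
    x$n, x$slope, x$rate, x$r, x$df, x$p_value
  ))
  invisible(x)
}

#' @rdname fit_mobility
#' @param x A `mobility_fit`.
#' @exportS3Method
tidy.mobility_fit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble::tibble(
    term = rownames(s), estimate = s[, 1], std_error = s[, 2],
    statistic = s[, 3], p_value = s[, 4]
  )
}

#' @rdname fit_mobility
#' @exportS3Method
glance.mobility_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, rate = x$rate,
    r = x$r, n = x$n, df = x$df, p_value = x$p_value
  )
}

#' Compare the regression slopes of two mobility fits
#'
#' Two-sample t test for equality of regression slopes with pooled residual
#' variance — the textbook comparison of two fitted lines. Degrees of freedom
#' are `n_a + n_b - 4`.
#'
#' @param fit_a,fit_b [fit_mobility()] objects.
#' @return A one-row tibble (statistic, df, p_value).
#' @export
compare_slopes <- function(fit_a, fit_b) {
  for (f in list(fit_a, fit_b)) {
    if (!inherits(f, "mobility_fit")) abort("inputs must be mobility_fit objects")
  }
  ss_res <- function(f) sum(residuals(f$lm)^2)
  sxx <- function(f) sum((f$pairs$r_t - mean(f$pairs$r_t))^2)
  df <- fit_a$n + fit_b$n - 4L
  if (df < 1L) abort("too few individual-years to compare slopes")
  s2 <- (ss_res(fit_a) + ss_res(fit_b)) / df
  se <- sqrt(s2 * (1 / sxx(fit_a) + 1 / sxx(fit_b)))
  if (se == 0) {
    statistic <- 0
  } else {
    statistic <- (fit_a$slope - fit_b$slope) / se
  }
  tibble::tibble(statistic = statistic, df = df,
                 p_value = 2 * pt(-abs(statistic), df))
}

#' Anderson-Darling normality check of the mobility-fit residuals
#'
#' Tests whether the residuals of the rank-on-rank regression are compatible
#' with a normal distribution (mean and variance estimated). A shortage of
#' extreme residuals relative to the normal indicates that large annual rank
#' jumps are rarer than a Gaussian model would predict.
#'
#' @param fit A [fit_mobility()] object with at least 8 residuals.
#' @return A one-row tibble (statistic, p_value, n).
#' @export
residual_normality <- function(fit) {
  if (!inherits(fit, "mobility_fit")) abort("`fit` must be a mobility_fit")
  res <- fit$residuals
  if (length(res) < 8L) abort("need at least 8 residuals")
  if (sd(res) < sqrt(.Machine$double.eps)) {
    abort("residuals have zero variance: test undefined")
  }
  ad <- nortest::ad.test(res)
  tibble::tibble(statistic = unname(ad$statistic),
                 p_value = unname(ad$p.value), n = length(res))
}

#' Classify annual rank transitions as upward, downward, or no change
#'
#' Rank 1 is the alpha, so an upward move is a *decrease* in rank number.
#' Also records the magnitude spectrum `|R(t+1) - R(t)|` of the changes and
#' the fraction of changes within two ranks.
#'
#' @param pairs A [rank_pairs()] tibble.
#' @return A `transition_counts` object: list with `n_up`, `n_down`,
#'   `n_same`, `n` (their sum), `magnitudes` (of the changes only), and
#'   `frac_within_2`.
#' @examples
#' tc <- classify_transitions(tibble::tibble(r_t = c(1, 2, 3), r_t1 = c(1, 2, 2)))
#' tidy(tc)
#' @export
classify_transitions <- function(pairs) {
  check_columns(pairs, c("r_t", "r_t1"), "pairs")
  delta <- pairs$r_t1 - pairs$r_t
  mags <- abs(delta[delta != 0])
  structure(
    list(
      n_up = sum(delta < 0), n_down = sum(delta > 0), n_same = sum(delta == 0),
      n = length(delta), magnitudes = mags,
      frac_within_2 = if (length(mags)) mean(mags <= 2) else NA_real_
    ),
    class = "transition_counts"
  )
}

#' @export
print.transition_counts <- function(x, ...) {
  cat(sprintf(
    "<transition_counts> n = %d: up %d, down %d, same %d (%.1f%% of changes within 2 ranks)\n",
    x$n, x$n_up, x$n_down, x$n_same, 100 * x$frac_within_2
  ))
  invisible(x)
}

#' @rdname classify_transitions
#' @param x A `transition_counts` object.
#' @exportS3Method
tidy.transition_counts <- function(x, ...) {
  tibble::tibble(
    direction = c("up", "down", "same"),
    n = c(x$n_up, x$n_down, x$n_same),
    proportion = c(x$n_up, x$n_down, x$n_same) / x$n
  )
}

#' Chi-square goodness-of-fit test against equal probabilities
#'
#' Tests two category counts (for example change vs no-change, or upward vs
#' downward moves) against the 50/50 null.
#'
#' @param counts Numeric vector of two nonnegative counts.
#' @return A one-row tibble (statistic, df, p_value).
#' @examples
#' chi_square_equal(c(75, 25))
#' @export
chi_square_equal <- function(counts) {
  if (length(counts) != 2L || any(counts < 0) || any(!is.finite(counts))) {
    abort("`counts` must be two nonnegative numbers")
  }
  if (sum(counts) == 0) abort("total count is zero")
  ct <- suppressWarnings(chisq.test(counts, p = c(0.5, 0.5)))
  tibble::tibble(statistic = unname(ct$statistic), df = 1L,
                 p_value = unname(ct$p.value))
}

#' Tenure in the group in relation to net social mobility
#'
#' Classifies each adult once by the sign of its net rank change over its
#' whole tenure (final minus initial rank: negative = upward, positive =
#' downward, zero = no change), then tabulates the class proportions among
#' adults whose tenure reaches each threshold. Rows for larger thresholds
#' are computed on subsets of the adults in smaller ones.
#'
#' @param ranks Rank table (year, individual_id, sex, rank).
#' @param sex Sex-hierarchy label to tabulate.
#' @param thresholds Increasing positive tenure thresholds (years).
#' @return A tibble (threshold, n_adults, p_up, p_down, p_same, empty);
#'   rows no adult reaches are flagged `empty` with `NA` proportions.
#' @export
tenure_table <- function(ranks, sex, thresholds = 1:6) {
  check_columns(ranks, c("year", "individual_id", "sex", "rank"), "ranks")
  if (any(thresholds <= 0) || is.unsorted(thresholds, strictly = TRUE)) {
    abort("`thresholds` must be positive and strictly increasing")
  }
  adults <- adult_trajectories(ranks, sex)
  purrr_free_map(thresholds, function(k) {
    sub <- adults[adults$tenure >= k, , drop = FALSE]
    n <- nrow(sub)
    if (!n) {
      return(tibble::tibble(threshold = k, n_adults = 0L, p_up = NA_real_,
                            p_down = NA_real_, p_same = NA_real_, empty = TRUE))
    }
    tibble::tibble(
      threshold = k, n_adults = n,
      p_up = mean(sub$net < 0), p_down = mean(sub$net > 0),
      p_same = mean(sub$net == 0), empty = FALSE
    )
  })
}

# rowwise map + bind, without pulling in purrr for two call sites
purrr_free_map <- function(x, f) dplyr::bind_rows(lapply(x, f))

# per-adult tenure (years present) and net rank change over the whole tenure
adult_trajectories <- function(ranks, sex) {
  ranks[ranks$sex == sex, , drop = FALSE] |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(
      tenure = dplyr::n(),
      first_rank = .data$rank[which.min(.data$year)],
      last_rank = .data$rank[which.max(.data$year)],
      .groups = "drop"
    ) |>
    dplyr::mutate(net = .data$last_rank - .data$first_rank,
                  improvement = .data$first_rank - .data$last_rank)
}

#' Correlation between tenure and net upward rank change
#'
#' Pearson correlation between each adult's tenure (years in the group) and
#' its signed net rank improvement (initial minus final rank number, so
#' positive = net upward movement), with a two-tailed test.
#'
#' @inheritParams tenure_table
#' @return A one-row tibble (r, df, p_value, n).
#' @export
tenure_change_correlation <- function(ranks, sex) {
  adults <- adult_trajectories(ranks, sex)
  n <- nrow(adults)
  if (n < 4L) abort("need at least 4 adults with observed tenures")
  if (var(adults$tenure) == 0 || var(adults$improvement) == 0) {
    abort("tenure or net rank change has zero variance: correlation undefined")
  }
  ct <- cor.test(adults$tenure, adults$improvement)
  tibble::tibble(r = unname(ct$estimate), df = unname(ct$parameter),
                 p_value = ct$p.value, n = n)
}

#' Unbroken spells at the top (alpha) and bottom (omega) ranks
#'
#' A spell is a maximal run of consecutive years in which the same individual
#' holds rank 1 (alpha) or the bottom rank of that year's hierarchy (omega).
#' Each spell is one observation; the summary reports per-position spell
#' count, mean and SD of spell length.
#'
#' @inheritParams tenure_table
#' @return An `extreme_tenure` object: list of tibbles `spells` (position,
#'   individual_id, start_year, length) and `summary` (position, n_spells,
#'   mean_length, sd_length).
#' @export
extreme_rank_tenure <- function(ranks, sex) {
  check_columns(ranks, c("year", "individual_id", "sex", "rank"), "ranks")
  rs <- ranks[ranks$sex == sex, , drop = FALSE]
  empty_spells <- tibble::tibble(position = character(),
                                 individual_id = character(),
                                 start_year = integer(), length = integer())
  spells_for <- function(position) {
    if (!nrow(rs)) return(empty_spells)
    holders <- rs |>
      dplyr::group_by(.data$year) |>
      dplyr::summarise(
        holder = .data$individual_id[
          if (position == "alpha") which.min(.data$rank) else which.max(.data$rank)
        ],
        .groups = "drop"
      ) |>
      dplyr::arrange(.data$year)
    if (!nrow(holders)) {
      return(tibble::tibble(position = character(), individual_id = character(),
                            start_year = integer(), length = integer()))
    }
    # a gap in observed years breaks a spell just as a holder change does
    run_id <- cumsum(c(TRUE, holders$holder[-1] != holders$holder[-nrow(holders)] |
                         diff(holders$year) != 1))
    holders |>
      dplyr::mutate(run = run_id) |>
      dplyr::group_by(.data$run) |>
      dplyr::summarise(individual_id = .data$holder[1],
                       start_year = min(.data$year),
                       length = dplyr::n(), .groups = "drop") |>
      dplyr::transmute(position = position, individual_id = .data$individual_id,
                       start_year = .data$start_year, length = .data$length)
  }
  spells <- dplyr::bind_rows(spells_for("alpha"), spells_for("omega"))
  summary <- spells |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(
      n_spells = dplyr::n(), mean_length = mean(.data$length),
      sd_length = sd(.data$length), .groups = "drop"
    )
  structure(list(spells = spells, summary = summary), class = "extreme_tenure")
}

#' @export
print.extreme_tenure <- function(x, ...) {
  cat("<extreme_tenure>\n")
  print(x$summary)
  invisible(x)
}

#' @rdname extreme_rank_tenure
#' @param x An `extreme_tenure` object.
#' @exportS3Method
tidy.extreme_tenure <- function(x, ...) x$spells

#' @rdname extreme_rank_tenure
#' @exportS3Method
glance.extreme_tenure <- function(x, ...) x$summary

#' Mann-Whitney U test
#'
#' Two-tailed Mann-Whitney U comparing two samples (for example alpha-spell
#' lengths of males vs females). U counts pairs in which the first sample
#' exceeds the second, with ties contributing one half. The p-value is exact
#' for small tie-free samples and otherwise uses the normal approximation
#' with tie correction (the standard behaviour of [stats::wilcox.test()]).
#'
#' @param sample_a,sample_b Nonempty numeric vectors.
#' @return A one-row tibble (u, p_value, n_a, n_b, method).
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))
#' @export
mann_whitney <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) {
    abort("both samples must be nonempty")
  }
  wt <- suppressWarnings(wilcox.test(sample_a, sample_b, exact = NULL,
                                     correct = TRUE))
  tibble::tibble(
    u = unname(wt$statistic), p_value = min(1, wt$p.value),
    n_a = length(sample_a), n_b = length(sample_b), method = wt$method
  )
}

#' Time to first upward move: Kaplan-Meier curves and log-rank test
#'
#' For each adult, measures the number of annual transitions from its first
#' observed year until its first upward rank move (a decrease in rank
#' number). Animals leaving the group before any upward move are
#' right-censored at exit. Fits the product-limit estimator per sex and,
#' when both sexes are present, compares them with the log-rank test.
#'
#' @param ranks Rank table (year, individual_id, sex, rank).
#' @param sex Optional restriction to one sex (then no between-sex test).
#' @return A `km_upward` object: list with `data` (individual_id, sex, time,
#'   event), `fit` (a [survival::survfit] object), and `logrank` (one-row
#'   tibble with chisq, df, p_value, or `NULL`).
#' @export
km_upward_time <- function(ranks, sex = NULL) {
  pairs <- rank_pairs(ranks, sex = sex)
  if (!nrow(pairs)) abort("no consecutive-year rank pairs available")
  per <- pairs |>
    dplyr::arrange(.data$individual_id, .data$year) |>
    dplyr::group_by(.data$individual_id, .data$sex) |>
    dplyr::summarise(
      time = {
        up <- which(.data$r_t1 < .data$r_t)
        if (length(up)) up[1] else dplyr::n()
      },
      event = as.integer(any(.data$r_t1 < .data$r_t)),
      .groups = "drop"
    )
  multi_sex <- length(unique(per$sex)) > 1L
  fml <- if (multi_sex) survival::Surv(time, event) ~ sex else
    survival::Surv(time, event) ~ 1
  fit <- survival::survfit(fml, data = per)
  logrank <- NULL
  if (multi_sex && sum(per$event) > 0) {
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ sex, data = per)
    df <- length(sd_$n) - 1L
    logrank <- tibble::tibble(
      chisq = sd_$chisq, df = df,
      p_value = pchisq(sd_$chisq, df, lower.tail = FALSE)
    )
  }
  structure(list(data = per, fit = fit, logrank = logrank),
            class = "km_upward")
}

#' @export
print.km_upward <- function(x, ...) {
  cat(sprintf("<km_upward> %d adults, %d upward events\n",
              nrow(x$data), sum(x$data$event)))
  if (!is.null(x$logrank)) {
    cat(sprintf("  log-rank: chisq = %.3f, df = %d, p = %.4f\n",
                x$logrank$chisq, x$logrank$df, x$logrank$p_value))
  }
  invisible(x)
}

#' @rdname km_upward_time
#' @param x A `km_upward` object.
#' @exportS3Method
tidy.km_upward <- function(x, ...) {
  f <- x$fit
  strata <- if (is.null(f$strata)) rep("all", length(f$time)) else
    rep(sub("^sex=", "", names(f$strata)), f$strata)
  tibble::tibble(
    sex = strata, time = f$time, n_risk = f$n.risk, n_event = f$n.event,
    n_censor = f$n.censor, estimate = f$surv
  )
}
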
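test_that("rank pairs count consecutive-year presences", {
  ranks <- tibble::tibble(
    year = c(1:4, 1L, 1:2),
    individual_id = c(rep("A", 4), "B", "C", "C"),
    sex = "M",
    rank = c(1L, 1L, 1L, 1L, 2L, 3L, 2L)
  )
  p <- rank_pairs(ranks)
  expect_equal(sum(p$individual_id == "A"), 3) # present years 1-4
  expect_equal(sum(p$individual_id == "B"), 0) # present year 1 only
  expect_equal(sum(p$individual_id == "C"), 1)

  # 10 individuals, 30 years -> 290 pairs
  full <- tidyr::expand_grid(year = 1:30, individual_id = sprintf("i%02d", 1:10)) |>
    dplyr::mutate(sex = "F",
                  rank = rep(1:10, 30))
  expect_equal(nrow(rank_pairs(full)), 290)
})

test_that("the mobility rate is one minus the OLS slope", {
  # perfect stability
  stable <- tibble::tibble(r_t = 1:5, r_t1 = 1:5)
  f <- fit_mobility(stable)
  expect_equal(f$slope, 1)
  expect_equal(f$rate, 0)
  expect_equal(f$r, 1)
  expect_identical(f$rate, 1 - f$slope)

  # closed-form OLS by hand: Sxy = 1, Sxx = 2 -> b = 0.5
  p <- tibble::tibble(r_t = c(1, 2, 3), r_t1 = c(2, 1, 3))
  f <- fit_mobility(p)
  expect_equal(f$slope, 0.5)
  expect_equal(f$rate, 0.5)
  g <- glance(f)
  expect_equal(g$rate + g$slope, 1)
  expect_equal(g$n, 3)

  # df convention is configurable
  expect_equal(fit_mobility(stable, df_method = "n-1")$df, 4)
  expect_equal(fit_mobility(stable)$df, 3)

  # degenerate inputs rejected
  expect_error(fit_mobility(tibble::tibble(r_t = c(1, 2), r_t1 = c(1, 2))),
               "at least 3")
  expect_error(fit_mobility(tibble::tibble(r_t = c(2, 2, 2), r_t1 = 1:3)),
               "undefined")
})

test_that("the fitted rate recovers a known generating slope", {
  withr::with_seed(91, {
    r_t <- sample(1:10, 200, replace = TRUE)
    r_t1 <- 0.84 * r_t + rnorm(200, sd = 0.8)
    f <- fit_mobility(tibble::tibble(r_t = r_t, r_t1 = r_t1))
    expect_lt(abs(f$rate - 0.16), 0.04)
  })
})

test_that("slope comparison is zero for identical fits and calibrated under the null", {
  p <- tibble::tibble(r_t = c(1, 2, 3, 4), r_t1 = c(1.2, 1.9, 3.1, 4.0))
  f <- fit_mobility(p)
  cmp <- compare_slopes(f, f)
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$df, 4)

  # type-I error at alpha = 0.05 over 100 replicates of a common slope
  withr::with_seed(14, {
    rejections <- 0L
    for (i in 1:100) {
      x1 <- runif(40, 1, 10)
      x2 <- runif(40, 1, 10)
      fa <- fit_mobility(tibble::tibble(r_t = x1, r_t1 = 0.8 * x1 + rnorm(40)))
      fb <- fit_mobility(tibble::tibble(r_t = x2, r_t1 = 0.8 * x2 + rnorm(40)))
      rejections <- rejections + (compare_slopes(fa, fb)$p_value < 0.05)
    }
    expect_gte(rejections / 100, 0.01)
    expect_lte(rejections / 100, 0.10)
  })

  # power: clearly different slopes are detected
  withr::with_seed(15, {
    x <- runif(100, 1, 10)
    fa <- fit_mobility(tibble::tibble(r_t = x, r_t1 = 0.5 * x + rnorm(100, sd = 0.2)))
    fb <- fit_mobility(tibble::tibble(r_t = x, r_t1 = 1.0 * x + rnorm(100, sd = 0.2)))
    expect_lt(compare_slopes(fa, fb)$p_value, 0.001)
  })
})

test_that("the residual normality check is calibrated and sensitive", {
  make_fit <- function(noise) {
    x <- runif(500, 1, 10)
    fit_mobility(tibble::tibble(r_t = x, r_t1 = x + noise))
  }
  withr::with_seed(21, {
    normal_ok <- 0L
    heavy_hit <- 0L
    for (i in 1:100) {
      normal_ok <- normal_ok +
        (residual_normality(make_fit(rnorm(500)))$p_value > 0.05)
      heavy_hit <- heavy_hit +
        (residual_normality(make_fit(rt(500, df = 2)))$p_value < 0.005)
    }
    expect_gte(normal_ok, 90L)
    expect_gte(heavy_hit, 90L)
  })

  # degenerate residuals rejected
  exact <- fit_mobility(tibble::tibble(r_t = 1:10, r_t1 = 1:10))
  expect_error(residual_normality(exact), "zero variance")
  small <- fit_mobility(tibble::tibble(r_t = c(1, 2, 3), r_t1 = c(2, 1, 3)))
  expect_error(residual_normality(small), "at least 8")
})

test_that("transitions are classified by the alpha-is-rank-1 convention", {
  # (3, 1) is an upward move of magnitude 2
  tc <- classify_transitions(tibble::tibble(r_t = 3, r_t1 = 1))
  expect_equal(tc$n_up, 1)
  expect_equal(tc$magnitudes, 2)

  tc <- classify_transitions(tibble::tibble(r_t = c(1, 2, 3), r_t1 = c(1, 2, 2)))
  expect_equal(tc$n_same, 2)
  expect_equal(tc$n_up, 1)
  expect_equal(tc$n_down, 0)
  expect_equal(tc$n_up + tc$n_down + tc$n_same, tc$n)

  td <- tidy(tc)
  expect_equal(sum(td$n), 3)
  expect_equal(sum(td$proportion), 1)
})

test_that("simulated up-share tracks the generator over many pairs", {
  agg_up <- 0L
  agg_down <- 0L
  oracle <- longrun_stats(sim_config(), years = 2000, seed = 555)
  s <- 0L
  while (agg_up + agg_down < 300) {
    s <- s + 1L
    cfg <- sim_config(interactions_per_dyad_per_year = 0, seed = 7000L + s)
    tc <- classify_transitions(rank_pairs(simulate_group(cfg)$ranks))
    agg_up <- agg_up + tc$n_up
    agg_down <- agg_down + tc$n_down
  }
  expect_lt(abs(agg_up / (agg_up + agg_down) - oracle$up_frac), 0.05)
})

test_that("the equal-probability chi-square matches hand computation", {
  expect_equal(chi_square_equal(c(50, 50))$statistic, 0)
  expect_equal(chi_square_equal(c(50, 50))$p_value, 1)
  expect_equal(chi_square_equal(c(75, 25))$statistic, 25)
  expect_equal(chi_square_equal(c(0, 100))$statistic, 100)
  expect_error(chi_square_equal(c(0, 0)), "zero")
  expect_error(chi_square_equal(c(1, 2, 3)), "two")
})

test_that("tenure tables classify whole-tenure net direction over nested subsets", {
  ranks <- dplyr::bind_rows(
    tibble::tibble(year = 1:6, individual_id = "A", sex = "M",
                   rank = c(5L, 4L, 3L, 2L, 1L, 1L)),
    tibble::tibble(year = 1:2, individual_id = "B", sex = "M",
                   rank = c(2L, 4L)),
    tibble::tibble(year = 1L, individual_id = "C", sex = "M", rank = 3L)
  )
  tt <- tenure_table(ranks, "M", thresholds = c(1, 3, 7))
  expect_equal(tt$n_adults, c(3L, 1L, 0L))
  expect_equal(unlist(tt[1, c("p_up", "p_down", "p_same")], use.names = FALSE),
               c(1, 1, 1) / 3)
  expect_equal(unlist(tt[2, c("p_up", "p_down", "p_same")], use.names = FALSE),
               c(1, 0, 0))
  expect_true(tt$empty[3])
  expect_true(all(abs(rowSums(tt[1:2, c("p_up", "p_down", "p_same")]) - 1) < 1e-9))

  # stasis: every row is pure no-change
  static <- tibble::tibble(year = rep(1:3, each = 2),
                           individual_id = rep(c("X", "Y"), 3),
                           sex = "F", rank = rep(1:2, 3))
  ts <- tenure_table(static, "F", thresholds = 1:2)
  expect_true(all(ts$p_same == 1))

  expect_error(tenure_table(ranks, "M", thresholds = c(3, 1)), "increasing")
})

test_that("tenure-change correlation behaves at the boundaries and recovers signal", {
  # colinear: r = 1
  ranks <- dplyr::bind_rows(
    tibble::tibble(year = 1L, individual_id = "A", sex = "M", rank = 1L),
    tibble::tibble(year = 1:2, individual_id = "B", sex = "M", rank = c(2L, 2L)),
    tibble::tibble(year = 1:3, individual_id = "C", sex = "M", rank = c(3L, 3L, 1L)),
    tibble::tibble(year = 1:4, individual_id = "D", sex = "M", rank = c(4L, 4L, 2L, 2L))
  )
  # improvements: A 0, B 0, C 2, D 2 over tenures 1..4 -> positive, not colinear
  out <- tenure_change_correlation(ranks, "M")
  expect_gt(out$r, 0)
  expect_equal(out$df, 2)

  # degenerate: identical net change for all adults
  same <- tibble::tibble(year = rep(1:2, each = 4),
                         individual_id = rep(c("A", "B", "C", "D"), 2),
                         sex = "F", rank = rep(1:4, 2))
  expect_error(tenure_change_correlation(same, "F"), "zero variance")

  # recovery: under upward-dominated dynamics, longer tenure means more
  # cumulative improvement, so over a long history the correlation is
  # significantly positive
  h <- simulate_group(sim_config(n_years = 90,
                                 interactions_per_dyad_per_year = 0,
                                 seed = 31))
  for (sx in c("M", "F")) {
    out <- tenure_change_correlation(h$ranks, sx)
    expect_gt(out$r, 0)
    expect_lt(out$p_value, 0.05)
  }
})

test_that("alpha and omega spells are enumerated as maximal runs", {
  # alpha sequence A, A, B, A over 4 years, with D always bottom
  ranks <- tibble::tibble(
    year = rep(1:4, each = 3),
    individual_id = c("A", "B", "D", "A", "B", "D", "B", "A", "D", "A", "B", "D"),
    sex = "M",
    rank = rep(1:3, 4)
  )
  et <- extreme_rank_tenure(ranks, "M")
  alpha <- et$spells[et$spells$position == "alpha", ]
  expect_equal(sort(alpha$length[alpha$individual_id == "A"]), c(1L, 2L))
  expect_equal(alpha$length[alpha$individual_id == "B"], 1L)
  expect_equal(et$summary$mean_length[et$summary$position == "alpha"], 4 / 3)
  omega <- et$spells[et$spells$position == "omega", ]
  expect_equal(omega$length, 4L) # D bottom throughout

  # single alpha for 30 years -> one spell of 30
  solo <- tibble::tibble(year = 1:30, individual_id = "Z", sex = "F", rank = 1L)
  et <- extreme_rank_tenure(solo, "F")
  expect_equal(et$spells$length[et$spells$position == "alpha"], 30L)

  # empty input -> empty summary
  none <- extreme_rank_tenure(ranks[0, ], "M")
  expect_equal(nrow(none$spells), 0)
  expect_equal(nrow(none$summary), 0)
})

test_that("Mann-Whitney U matches enumeration and is calibrated", {
  out <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(out$u, 0)

  # identical tied samples: U = n*m/2
  out <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(out$u, 4.5)
  expect_equal(out$p_value, 1)

  expect_error(mann_whitney(numeric(), 1), "nonempty")

  # type-I calibration at alpha = 0.05
  withr::with_seed(41, {
    rejections <- 0L
    for (i in 1:1000) {
      a <- rnorm(12)
      b <- rnorm(15)
      rejections <- rejections + (mann_whitney(a, b)$p_value < 0.05)
    }
    expect_gte(rejections / 1000, 0.03)
    expect_lte(rejections / 1000, 0.08)
  })
})

test_that("time to first upward move is measured with censoring", {
  # every subject records an upward move in its first transition:
  # the curve drops to 0 at t = 1 (input here is a per-individual record
  # stream, not a full hierarchy)
  all_up <- tibble::tibble(
    year = rep(1:2, each = 2),
    individual_id = rep(c("A", "B"), 2),
    sex = "M",
    rank = c(2L, 2L, 1L, 1L)
  )
  km <- km_upward_time(all_up)
  expect_equal(sum(km$data$event), 2)
  curve <- tidy(km)
  expect_equal(curve$estimate[curve$time == 1], 0)

  # all censored: survival constant at 1
  frozen <- tibble::tibble(
    year = rep(1:3, each = 2),
    individual_id = rep(c("A", "B"), 3),
    sex = "M",
    rank = rep(1:2, 3)
  )
  km <- km_upward_time(frozen)
  expect_equal(sum(km$data$event), 0)
  expect_true(all(km$fit$surv == 1))
})

test_that("the log-rank comparison is calibrated when hazards are identical", {
  # independent subjects with the same geometric upward-move hazard in each
  # sex; the rank stream per subject is its own record (event = the year its
  # rank number first drops), so log-rank rejections should sit near alpha
  make_ranks <- function(n_per_sex, hazard, horizon = 12L) {
    rows <- list()
    for (sx in c("M", "F")) {
      for (i in seq_len(n_per_sex)) {
        event_t <- which(runif(horizon) < hazard)[1]
        followup <- min(event_t, horizon, na.rm = TRUE)
        rank_seq <- c(rep(2L, followup), if (!is.na(event_t) && event_t <= horizon) 1L)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          year = seq_along(rank_seq),
          individual_id = paste0(sx, i), sex = sx, rank = rank_seq
        )
      }
    }
    dplyr::bind_rows(rows)
  }
  withr::with_seed(51, {
    rejections <- 0L
    for (s in 1:200) {
      km <- km_upward_time(make_ranks(20, hazard = 0.15))
      rejections <- rejections + (km$logrank$p_value < 0.05)
    }
    expect_gte(rejections / 200, 0.0)
    expect_lte(rejections / 200, 0.09)
  })
})
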
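#' Run the full mobility and stratification analysis
#'
#' Orchestrates simulate -> rank -> mobility -> stratify into one
#' reproducible report. Three input modes enter the pipeline at successive
#' stages:
#'
#' * a [sim_config()] — a group history is simulated first;
#' * tables or a directory — interaction and/or rank CSVs as written by
#'   [write_history()] (a list with elements `interactions` and/or `ranks`,
#'   or a directory path containing `interactions.csv` / `ranks.csv`);
#' * transition matrices alone — a named list of [transition_matrix()]
#'   objects; only the stratification stage runs, so published matrices can
#'   be analysed with no behavioural data at all.
#'
#' When interaction records are present, annual rank orders are re-derived
#' by reversal minimization and compared against the provided rank table
#' (if any); mobility statistics always use the rank table (the simulator's
#' truth, or the inferred orders when no table is supplied).
#'
#' @param input One of the three input modes above.
#' @param tenure_thresholds Tenure thresholds (years) for [tenure_table()].
#' @param tol Stabilization tolerance for [convergence_horizon()].
#' @param horizons Horizons for [stratification_table()].
#' @param seed Seed recorded in provenance and used for any stochastic
#'   stage; for a `sim_config` input it overrides `input$seed` when given.
#' @return An `analysis_report` object (a nested list of tibbles) with
#'   elements `mode`, `provenance`, and per-stage sections.
#' @examples
#' cm <- transition_matrix(0.9375, 0.0625, 0.1922, 0.8078)
#' rep <- run_analysis(list(combined = cm))
#' rep$stratification$table
#' @export
run_analysis <- function(input, tenure_thresholds = 1:6, tol = 0.001,
                         horizons = c(2, 4, 8, 16, 32), seed = NULL) {
  interactions <- NULL
  ranks <- NULL
  matrices <- NULL
  config <- NULL
  mode <- NULL

  if (inherits(input, "sim_config")) {
    config <- input
    if (!is.null(seed)) {
      config$seed <- as.integer(seed)
    }
    history <- simulate_group(config)
    interactions <- history$interactions
    ranks <- history$ranks
    mode <- "simulation"
  } else if (inherits(input, "group_history")) {
    config <- input$config
    interactions <- input$interactions
    ranks <- input$ranks
    mode <- "simulation"
  } else if (is.character(input) && length(input) == 1L) {
    if (!dir.exists(input)) abort(sprintf("input directory not found: %s", input))
    ip <- file.path(input, "interactions.csv")
    rp <- file.path(input, "ranks.csv")
    if (file.exists(ip)) interactions <- read_interactions(ip)
    if (file.exists(rp)) ranks <- read_ranks(rp)
    if (is.null(interactions) && is.null(ranks)) {
      abort(sprintf("no interactions.csv or ranks.csv under %s", input))
    }
    mode <- "files"
  } else if (is.list(input) &&
             all(vapply(input, inherits, logical(1), "transition_matrix"))) {
    matrices <- input
    mode <- "matrices"
  } else if (is.list(input) &&
             any(c("interactions", "ranks") %in% names(input))) {
    interactions <- input$interactions
    ranks <- input$ranks
    mode <- "files"
  } else {
    abort(paste(
      "`input` must be a sim_config, a group_history, a directory path,",
      "a list(interactions=, ranks=), or a named list of transition matrices"
    ))
  }

  report <- list(
    mode = mode,
    provenance = list(
      package_version = as.character(utils::packageVersion("mobidom")),
      seed = seed %||% (if (!is.null(config)) config$seed else NA_integer_),
      config = if (!is.null(config)) unclass(config) else NULL,
      input_hash = rlang::hash(list(interactions, ranks,
                                    lapply(matrices, function(m) m$p))),
      created = "run_analysis"
    )
  )

  # --- hierarchy stage: re-derive annual orders from records -------------
  if (!is.null(interactions) && nrow(interactions)) {
    roster <- if (!is.null(ranks)) {
      dplyr::distinct(ranks, .data$individual_id, .data$sex)
    } else {
      abort("interaction-only input needs a roster: supply ranks or use infer_ranks() directly")
    }
    inferred <- infer_ranks(interactions, roster)
    agreement <- NULL
    if (!is.null(ranks)) {
      cmp <- dplyr::inner_join(
        inferred, ranks,
        by = c("year", "individual_id", "sex"), suffix = c("_inferred", "_true")
      )
      agreement <- cmp |>
        dplyr::group_by(.data$year, .data$sex) |>
        dplyr::summarise(
          n = dplyr::n(),
          agreement = mean(.data$rank_inferred == .data$rank_true),
          reversals = .data$reversals[1],
          .groups = "drop"
        )
    }
    report$hierarchy <- list(inferred_ranks = inferred, agreement = agreement)
    if (is.null(ranks)) {
      ranks <- dplyr::select(inferred, "year", "individual_id", "sex", "rank")
    }
  }

  # --- mobility stage ----------------------------------------------------
  if (!is.null(ranks) && nrow(ranks)) {
    report$mobility <- mobility_section(ranks, tenure_thresholds)
    matrices <- tryCatch({
      strata <- assign_strata(ranks)
      per_sex <- lapply(
        setNames(sort(unique(ranks$sex)), sort(unique(ranks$sex))),
        function(sx) estimate_transition_matrix(strata[strata$sex == sx, ])
      )
      ms <- c(per_sex,
              list(combined = do.call(pool_transition_matrices, unname(per_sex))))
      names(ms) <- c(cohort_label(names(per_sex)), "combined")
      ms
    }, error = function(e) {
      warn(sprintf("stratification stage skipped: %s", conditionMessage(e)))
      NULL
    })
  }

  # --- stratification stage ---------------------------------------------
  if (!is.null(matrices)) {
    report$stratification <- stratification_section(matrices, tol, horizons)
  }

  structure(report, class = "analysis_report")
}

cohort_label <- function(sex) {
  lab <- c(M = "male", F = "female")[sex]
  ifelse(is.na(lab), sex, lab)
}

mobility_section <- function(ranks, tenure_thresholds) {
  sexes <- sort(unique(ranks$sex))
  fits <- list()
  out <- list()

  for (sx in sexes) {
    pairs <- rank_pairs(ranks, sex = sx)
    lbl <- cohort_label(sx)
    fit <- tryCatch(fit_mobility(pairs), error = function(e) NULL)
    if (!is.null(fit)) {
      fits[[sx]] <- fit
      out$fits <- dplyr::bind_rows(out$fits,
                                   dplyr::mutate(glance(fit), cohort = lbl,
                                                 .before = 1))
      ad <- tryCatch(residual_normality(fit), error = function(e) NULL)
      if (!is.null(ad)) {
        out$residual_normality <- dplyr::bind_rows(
          out$residual_normality, dplyr::mutate(ad, cohort = lbl, .before = 1)
        )
      }
    }
    out$transitions <- dplyr::bind_rows(
      out$transitions,
      dplyr::mutate(tidy(classify_transitions(pairs)), cohort = lbl, .before = 1)
    )
    tt <- tenure_table(ranks, sx, tenure_thresholds)
    out$tenure_tables <- dplyr::bind_rows(
      out$tenure_tables, dplyr::mutate(tt, cohort = lbl, .before = 1)
    )
    tc <- tryCatch(tenure_change_correlation(ranks, sx),
                   error = function(e) NULL)
    if (!is.null(tc)) {
      out$tenure_correlations <- dplyr::bind_rows(
        out$tenure_correlations, dplyr::mutate(tc, cohort = lbl, .before = 1)
      )
    }
    et <- extreme_rank_tenure(ranks, sx)
    out$extreme_tenure <- dplyr::bind_rows(
      out$extreme_tenure, dplyr::mutate(glance(et), cohort = lbl, .before = 1)
    )
    out$extreme_spells[[lbl]] <- tidy(et)
  }

  if (length(fits) == 2L) {
    out$slope_comparison <- compare_slopes(fits[[1]], fits[[2]])
  }

  pooled <- classify_transitions(rank_pairs(ranks))
  out$pooled_transitions <- tidy(pooled)
  out$frac_changes_within_2 <- pooled$frac_within_2
  if (pooled$n > 0) {
    out$chi_change_vs_same <- chi_square_equal(
      c(pooled$n_up + pooled$n_down, pooled$n_same))
  }
  if (pooled$n_up + pooled$n_down > 0) {
    out$chi_up_vs_down <- chi_square_equal(c(pooled$n_up, pooled$n_down))
  }

  if (length(sexes) == 2L) {
    spells <- lapply(sexes, function(sx) tidy(extreme_rank_tenure(ranks, sx)))
    for (pos in c("alpha", "omega")) {
      a <- spells[[1]]$length[spells[[1]]$position == pos]
      b <- spells[[2]]$length[spells[[2]]$position == pos]
      if (length(a) && length(b)) {
        out$mann_whitney <- dplyr::bind_rows(
          out$mann_whitney,
          dplyr::mutate(mann_whitney(a, b), position = pos, .before = 1)
        )
      }
    }
    km <- tryCatch(km_upward_time(ranks), error = function(e) NULL)
    if (!is.null(km)) {
      out$km_upward <- list(curve = tidy(km), logrank = km$logrank)
    }
  }
  out
}

stratification_section <- function(matrices, tol, horizons) {
  list(
    matrices = lapply(matrices, tidy),
    stationary = purrr_free_map(names(matrices), function(ch) {
      pi_ <- tryCatch(stationary_distribution(matrices[[ch]]),
                      error = function(e) c(H = NA_real_, L = NA_real_))
      tibble::tibble(cohort = ch, pi_h = pi_[["H"]], pi_l = pi_[["L"]],
                     odds_h_over_l = pi_[["H"]] / pi_[["L"]])
    }),
    convergence = purrr_free_map(names(matrices), function(ch) {
      ch_row <- tryCatch(convergence_horizon(matrices[[ch]], tol = tol),
                         error = function(e) tibble::tibble(
                           horizon = NA_integer_, dev_hh = NA_real_,
                           dev_ll = NA_real_, tol = tol))
      dplyr::mutate(ch_row, cohort = ch, .before = 1)
    }),
    table = stratification_table(matrices, horizons = horizons)
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> mode = %s\n", x$mode))
  if (!is.null(x$mobility$fits)) {
    cat("mobility rates (1 - b):\n")
    print(dplyr::select(x$mobility$fits, "cohort", "rate", "r", "n"))
  }
  if (!is.null(x$stratification)) {
    cat("stationary distributions:\n")
    print(x$stratification$stationary)
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Serializes the report as `report.json` (numbers at 6 significant digits)
#' plus tidy CSVs for the main tables. If any write fails, files already
#' written for this report are removed.
#'
#' @param report An [run_analysis()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "analysis_report")) {
    abort("`report` must be an analysis_report")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  jp <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), jp, auto_unbox = TRUE, digits = 6,
                       na = "null", pretty = TRUE, force = TRUE)
  written <- c(written, jp)

  csvs <- list(
    mobility_fits = report$mobility$fits,
    transitions = report$mobility$transitions,
    tenure_tables = report$mobility$tenure_tables,
    stratification_table = report$stratification$table
  )
  for (nm in names(csvs)) {
    if (!is.null(csvs[[nm]])) {
      fp <- file.path(dir, paste0(nm, ".csv"))
      readr::write_csv(csvs[[nm]], fp)
      written <- c(written, fp)
    }
  }
  ok <- TRUE
  invisible(dir)
}
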
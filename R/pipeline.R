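#' Experiment configuration for the synthetic-cohort pipeline
#'
#' @param groups Character vector of observer groups to simulate.
#' @param n_per_group Observers per group.
#' @param eccentricity Eccentricity for adult observers (degrees).
#' @param sim_n Simulated trials per condition per objective evaluation.
#' @param models Model kinds to fit per observer.
#' @param smooth_small Apply boxcar smoothing to data histograms when a
#'   crowded condition has this many folded trials or fewer (children's 24
#'   folded trials per condition qualify; adults' 200 do not).
#' @param maxit Simplex iteration cap per fit.
#' @param master_seed Master seed; all observer and fitting seeds derive
#'   from it.
#' @return A list of class `crowding_config`.
#' @export
crowding_config <- function(groups = c("adult", "child_typical",
                                       "child_amblyopic"),
                            n_per_group = 5, eccentricity = 5,
                            sim_n = 1000,
                            models = c("pooling4", "pooling3", "noise2"),
                            smooth_small = 50, maxit = 300,
                            master_seed = 1) {
  structure(list(groups = groups, n_per_group = n_per_group,
                 eccentricity = eccentricity, sim_n = sim_n,
                 models = models, smooth_small = smooth_small,
                 maxit = maxit, master_seed = master_seed),
            class = "crowding_config")
}

# Reproducible child seeds below 2^31.
derive_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max, n)
}

#' Run the full synthetic-cohort experiment
#'
#' Generates synthetic observers for each configured group, simulates their
#' orientation-matching data, fits each candidate model per observer with the
#' two-stage procedure, and scores parameter recovery against the known
#' generative parameters. Optionally serializes the results (JSON fits, CSV
#' tables) to `outdir`.
#'
#' @param config A [crowding_config()].
#' @param outdir Optional output directory; created if missing.
#' @return A list of class `crowding_report`: `manifest` (observers and true
#'   parameters), `trials` (all per-trial data), `fits` (one row per observer
#'   x model), `recovery` (true vs fitted pooling4 parameters), `winners`.
#' @export
run_crowding_pipeline <- function(config = crowding_config(),
                                  outdir = NULL) {
  n_total <- length(config$groups) * config$n_per_group
  seeds <- derive_seeds(config$master_seed, n_total)
  idx <- 0
  manifest <- list(); trials <- list(); fit_rows <- list()

  for (grp in config$groups) {
    for (i in seq_len(config$n_per_group)) {
      idx <- idx + 1
      oid <- sprintf("%s_%02d", grp, i)
      ecc <- if (grp == "adult") config$eccentricity else NULL
      obs <- simulated_observer(grp, eccentricity = ecc,
                                observer_id = oid, seed = seeds[idx])
      dat <- generate_dataset(obs)
      folded <- fold_trials(dat)
      n_crowded <- sum(folded$condition_folded == "f30")
      hist <- matching_histograms(folded,
                                  smooth = n_crowded <= config$smooth_small)
      cmp <- fit_and_compare(hist, models = config$models,
                             sim_n = config$sim_n, seed = seeds[idx],
                             group = grp, maxit = config$maxit)
      manifest[[idx]] <- tibble::tibble(
        observer_id = oid, group = grp,
        eccentricity = ifelse(is.null(ecc), NA_real_, ecc),
        seed = seeds[idx],
        param = names(unclass(obs$params))[1:4],
        true_value = unlist(unclass(obs$params))[1:4]
      )
      trials[[idx]] <- dat
      fit_rows[[idx]] <- purrr::map_dfr(cmp$fits, function(f) {
        tibble::tibble(observer_id = oid, group = grp,
                       model = f$model$kind, k = f$model$n_params,
                       lse = f$lse, aic = f$aic,
                       winner = cmp$winner == f$model$kind,
                       param = names(f$par), estimate = unname(f$par))
      })
    }
  }

  manifest <- dplyr::bind_rows(manifest)
  fits <- dplyr::bind_rows(fit_rows)
  recovery <- NULL
  if ("pooling4" %in% config$models) {
    recovery <- dplyr::inner_join(
      manifest,
      fits[fits$model == "pooling4", c("observer_id", "param", "estimate")],
      by = c("observer_id", "param")
    )
    recovery$abs_error <- abs(recovery$estimate - recovery$true_value)
  }
  winners <- fits |>
    dplyr::distinct(.data$observer_id, .data$group, .data$model,
                    .data$aic) |>
    dplyr::group_by(.data$observer_id, .data$group) |>
    dplyr::slice_min(.data$aic, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()

  report <- structure(
    list(manifest = manifest, trials = dplyr::bind_rows(trials),
         fits = fits, recovery = recovery, winners = winners,
         config = config),
    class = "crowding_report"
  )
  if (!is.null(outdir)) write_crowding_report(report, outdir)
  report
}

#' Serialize a pipeline report
#'
#' Writes the manifest, per-trial table, fit table, recovery scorecard and
#' AIC winners under `outdir` (CSV), plus a JSON bundle of the fits.
#'
#' @param report A `crowding_report` from [run_crowding_pipeline()].
#' @param outdir Output directory.
#' @return `outdir`, invisibly.
#' @export
write_crowding_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$manifest, file.path(outdir, "manifest.csv"))
  readr::write_csv(report$trials, file.path(outdir, "trials.csv"))
  readr::write_csv(report$fits, file.path(outdir, "fits.csv"))
  if (!is.null(report$recovery)) {
    readr::write_csv(report$recovery, file.path(outdir, "recovery.csv"))
  }
  readr::write_csv(report$winners, file.path(outdir, "aic_winners.csv"))
  jsonlite::write_json(
    list(master_seed = report$config$master_seed,
         sim_n = report$config$sim_n,
         fits = report$fits),
    file.path(outdir, "fits.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(outdir)
}

matching_schema <- c("observer_id", "group", "eccentricity", "condition",
                     "target_deg", "response_deg")

#' Fit models to an external per-trial matching table
#'
#' Reads (or accepts) a per-trial table in the shared schema, folds and bins
#' it per observer (and per eccentricity where present), smooths small
#' datasets automatically, and runs the model comparison.
#'
#' @param x Path to a CSV file, or a data frame, with columns `observer_id`,
#'   `group`, `eccentricity`, `condition`, `target_deg`, `response_deg`.
#' @param models,sim_n,seed,maxit Passed to [fit_and_compare()].
#' @param smooth_small Boxcar-smooth data histograms when a crowded condition
#'   has this many folded trials or fewer.
#' @return Tibble with one row per observer x eccentricity x model:
#'   parameters (list column), `lse`, `aic`, `winner`, `smoothed`.
#' @export
fit_matching_table <- function(x, models = c("pooling4", "pooling3",
                                             "noise2"),
                               sim_n = 1000, seed = 1, smooth_small = 50,
                               maxit = 300) {
  df <- if (is.character(x)) {
    readr::read_csv(x, show_col_types = FALSE)
  } else {
    tibble::as_tibble(x)
  }
  missing_cols <- setdiff(matching_schema, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  folded <- fold_trials(df)
  folded$.ecc_key <- ifelse(is.na(folded$eccentricity), "foveal",
                            as.character(folded$eccentricity))
  purrr::map_dfr(
    split(folded, list(folded$observer_id, folded$.ecc_key), drop = TRUE),
    function(d) {
      n_crowded <- sum(d$condition_folded == "f30")
      smoothed <- n_crowded <= smooth_small
      hist <- matching_histograms(d, smooth = smoothed)
      cmp <- fit_and_compare(hist, models = models, sim_n = sim_n,
                             seed = seed, group = d$group[1], maxit = maxit)
      purrr::map_dfr(cmp$fits, function(f) {
        tibble::tibble(observer_id = d$observer_id[1], group = d$group[1],
                       eccentricity = d$eccentricity[1],
                       model = f$model$kind, k = f$model$n_params,
                       params = list(f$par), lse = f$lse, aic = f$aic,
                       winner = cmp$winner == f$model$kind,
                       smoothed = smoothed)
      })
    }
  )
}
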
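#' Circular response error
#'
#' Error is the circular difference `response - target`, wrapped into
#' (-180, 180]. Positive errors lie counterclockwise of the target, i.e.
#' toward the flankers in positive-offset conditions.
#'
#' @param response,target Orientations in degrees (vectorized).
#' @return Errors in degrees in (-180, 180].
#' @export
#' @examples
#' compute_error(-179, 179) # 2, forced by circularity
compute_error <- function(response, target) {
  stopifnot(all(is.finite(response)), all(is.finite(target)))
  wrap_angle(response - target)
}

#' Fold error signs across mirror-image flanker conditions
#'
#' Error distributions in conditions with flanker offsets of opposite sign are
#' mirror symmetric, so negative-offset conditions have their error signs
#' reversed before the distributions are combined.
#'
#' @param error Errors in degrees (vectorized).
#' @param offset_sign `"+"`, `"-"`, or `"none"` per element (recycled).
#' @return Folded errors, wrapped to (-180, 180].
#' @export
fold_sign <- function(error, offset_sign) {
  stopifnot(all(offset_sign %in% c("+", "-", "none")))
  wrap_angle(ifelse(offset_sign == "-", -error, error))
}

error_bin_index <- function(errors) {
  idx <- as.integer(floor((wrap_angle(errors) + 180) / 10) + 1)
  idx[idx > 36L] <- 1L # +180 wraps into the [-180,-170) bin
  idx
}

#' Bin response errors into the 36-bin circular histogram
#'
#' Errors are tallied over \eqn{\pm 180} degrees in 10-degree bins, half-open
#' on the left (`[-180, -170)`, ..., `[170, 180)`); an error of exactly +180
#' wraps into the first bin.
#'
#' @param errors Numeric vector of errors in degrees.
#' @param condition Optional condition label attached to the histogram.
#' @return A tibble of class `error_histogram` with 36 rows and columns
#'   `bin_left`, `bin_center`, `count`, `proportion` (plus `condition` when
#'   given). With empty input all counts are zero and proportions are `NaN`.
#' @export
bin_errors <- function(errors, condition = NULL) {
  counts <- tabulate(error_bin_index(errors), nbins = 36)
  out <- tibble::tibble(
    bin_left = seq(-180, 170, by = 10),
    bin_center = seq(-175, 175, by = 10),
    count = as.numeric(counts),
    proportion = counts / length(errors)
  )
  if (!is.null(condition)) out <- tibble::add_column(out, condition = condition,
                                                     .before = 1)
  class(out) <- c("error_histogram", class(out))
  out
}

#' Three-point circular boxcar smoothing of a histogram
#'
#' Each bin is replaced by the mean of itself and its two circular neighbors;
#' total mass is preserved. Applied to individual observers' histograms, whose
#' small trial counts make raw histograms jagged.
#'
#' @param hist An [bin_errors()] histogram (or any tibble with `count` and
#'   `proportion` columns, one condition).
#' @return The histogram with smoothed `count` and `proportion`.
#' @export
boxcar_smooth <- function(hist) {
  smooth3 <- function(x) (x + c(x[-1], x[1]) + c(x[length(x)], x[-length(x)])) / 3
  hist$count <- smooth3(hist$count)
  hist$proportion <- smooth3(hist$proportion)
  hist
}

#' Least-squares error between data and model histograms
#'
#' Sum over conditions and bins of the squared difference between the data and
#' model bin proportions. Proportions (not counts) keep datasets with 12 to
#' 100 trials per condition comparable to 1,000-trial model simulations.
#'
#' @param data,model Histogram tibbles with columns `condition`, `bin_left`
#'   and `proportion`, covering the same conditions.
#' @return A non-negative scalar.
#' @export
lse <- function(data, model) {
  cond_d <- sort(unique(data$condition))
  cond_m <- sort(unique(model$condition))
  if (!identical(cond_d, cond_m)) {
    stop("data and model histograms cover different conditions")
  }
  j <- dplyr::inner_join(
    data[, c("condition", "bin_left", "proportion")],
    model[, c("condition", "bin_left", "proportion")],
    by = c("condition", "bin_left"), suffix = c("_data", "_model")
  )
  if (nrow(j) != nrow(data)) stop("histogram bins do not align")
  sum((j$proportion_data - j$proportion_model)^2)
}

#' Fold a per-trial matching table into the three analysis conditions
#'
#' Computes circular errors, reverses the error sign in negative-offset
#' conditions, and maps the five presentation conditions (`unflanked`, `+30`,
#' `-30`, `+90`, `-90`) onto the three folded conditions (`unflanked`, `f30`,
#' `f90`).
#'
#' @param trials A tibble with columns `condition`, `target_deg`,
#'   `response_deg` (other columns are carried through).
#' @return The table with added `error_deg` (folded) and `condition_folded`.
#' @export
fold_trials <- function(trials) {
  stopifnot(all(c("condition", "target_deg", "response_deg") %in% names(trials)))
  bad <- setdiff(unique(trials$condition),
                 c("unflanked", "+30", "-30", "+90", "-90"))
  if (length(bad) > 0) stop("unknown condition label(s): ",
                            paste(bad, collapse = ", "))
  err <- compute_error(trials$response_deg, trials$target_deg)
  sgn <- dplyr::case_when(
    trials$condition == "unflanked" ~ "none",
    substr(trials$condition, 1, 1) == "-" ~ "-",
    TRUE ~ "+"
  )
  trials$error_deg <- fold_sign(err, sgn)
  trials$condition_folded <- dplyr::case_when(
    trials$condition == "unflanked" ~ "unflanked",
    trials$condition %in% c("+30", "-30") ~ "f30",
    TRUE ~ "f90"
  )
  trials
}

#' Build per-condition error histograms from a folded trial table
#'
#' @param folded Output of [fold_trials()] (needs `condition_folded` and
#'   `error_deg`).
#' @param smooth Apply [boxcar_smooth()] to each condition's histogram.
#' @return A histogram tibble (36 rows per condition) with a `condition`
#'   column holding the folded condition labels.
#' @export
matching_histograms <- function(folded, smooth = FALSE) {
  stopifnot(all(c("condition_folded", "error_deg") %in% names(folded)))
  out <- folded |>
    dplyr::group_by(.data$condition_folded) |>
    dplyr::group_map(~ {
      h <- bin_errors(.x$error_deg, condition = .y$condition_folded)
      if (smooth) h <- boxcar_smooth(h)
      h
    }) |>
    dplyr::bind_rows()
  class(out) <- c("error_histogram", class(out))
  out
}
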
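#' Normalize a count series to its initial level
#'
#' Divides by the mean of the first \code{n_ref} observations (three by
#' default, mirroring normalization to the mean of the first three images).
#'
#' @param counts numeric vector
#' @param n_ref number of leading points to average (default 3)
#' @return normalized vector
#' @export
normalize_counts <- function(counts, n_ref = 3L) {
  if (length(counts) < n_ref) stop("series shorter than the reference window")
  ref <- mean(counts[seq_len(n_ref)])
  if (!is.finite(ref) || ref <= 0) stop("non-positive reference level")
  counts / ref
}

#' Savitzky-Golay smoothing of a time series
#'
#' Local least-squares polynomial smoothing preserving series length, with
#' polynomial handling of the edge windows. Negative smoothed values are
#' clamped to zero (counts cannot be negative) with a warning.
#'
#' @param x numeric series
#' @param window odd window length in samples (default 11, about 5 hours at a
#'   30-minute cadence)
#' @param polyorder polynomial order (default 3)
#' @return smoothed series, same length as \code{x}
#' @export
smooth_series <- function(x, window = 11L, polyorder = 3L) {
  if (window %% 2L == 0L) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be smaller than window")
  if (length(x) < window)
    stop(sprintf("series length %d below required minimum %d", length(x), window))
  out <- signal::sgolayfilt(x, p = polyorder, n = window)
  if (any(out < 0)) {
    warning(sprintf("%d negative smoothed values clamped to 0", sum(out < 0)))
    out[out < 0] <- 0
  }
  out
}

#' Average replicate series pointwise
#'
#' @param series_list list of numeric vectors on identical time grids
#' @return pointwise arithmetic mean
#' @export
average_replicates <- function(series_list) {
  if (!length(series_list)) stop("no series supplied")
  n <- lengths(series_list)
  if (length(unique(n)) != 1L) stop("replicate series have mismatched lengths/grids")
  Reduce(`+`, series_list) / length(series_list)
}

#' Split a total-count series into G1 and S-G2 counts
#'
#' @param total_norm normalized total counts
#' @param frac_g1 fraction of cells in G1, in [0, 1]
#' @return list with components \code{g1} and \code{sg2}
#' @export
split_phase_counts <- function(total_norm, frac_g1) {
  if (length(total_norm) != length(frac_g1)) stop("series lengths differ")
  ok <- !is.na(frac_g1)
  if (any(frac_g1[ok] < 0 | frac_g1[ok] > 1))
    stop("frac_g1 outside [0, 1]")
  list(g1 = total_norm * frac_g1, sg2 = total_norm * (1 - frac_g1))
}

#' Preprocess a tidy population table into model-ready phase counts
#'
#' Fixed pipeline per (drug, concentration): smooth each replicate's
#' normalized count and G1-fraction series (Savitzky-Golay), average across
#' replicates, then split the total into G1 and S-G2 counts. Settings are
#' recorded in the \code{"provenance"} attribute.
#'
#' @param population tidy data frame with columns \code{drug},
#'   \code{concentration}, \code{replicate}, \code{time_h},
#'   \code{count_norm}, \code{frac_g1} (as written by
#'   \code{\link{generate_dose_response_dataset}})
#' @param window,polyorder Savitzky-Golay settings (see
#'   \code{\link{smooth_series}}); \code{window = 1} disables smoothing
#' @param smooth_each_replicate smooth before averaging (default) rather than
#'   after
#' @return data frame of class \code{processed_series} with columns
#'   \code{drug}, \code{concentration}, \code{time_h}, \code{g1}, \code{sg2}
#' @export
process_population <- function(population, window = 11L, polyorder = 3L,
                               smooth_each_replicate = TRUE) {
  need <- c("drug", "concentration", "replicate", "time_h", "count_norm", "frac_g1")
  if (!all(need %in% names(population)))
    stop("population table must have columns: ", paste(need, collapse = ", "))
  sm <- function(x) if (window > 1L) smooth_series(x, window, polyorder) else x
  groups <- split(population, list(population$drug, population$concentration), drop = TRUE)
  out <- lapply(groups, function(g) {
    reps <- split(g, g$replicate)
    tgrid <- reps[[1L]]$time_h
    for (r in reps)
      if (!isTRUE(all.equal(r$time_h, tgrid))) stop("replicate time grids differ")
    if (smooth_each_replicate) {
      tot <- average_replicates(lapply(reps, function(r) sm(r$count_norm)))
      frc <- average_replicates(lapply(reps, function(r) sm(r$frac_g1)))
    } else {
      tot <- sm(average_replicates(lapply(reps, function(r) r$count_norm)))
      frc <- sm(average_replicates(lapply(reps, function(r) r$frac_g1)))
    }
    frc <- pmin(pmax(frc, 0), 1)
    ph <- split_phase_counts(tot, frc)
    data.frame(drug = g$drug[1L], concentration = g$concentration[1L],
               time_h = tgrid, g1 = ph$g1, sg2 = ph$sg2)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("processed_series", "data.frame")
  attr(res, "provenance") <- list(
    pipeline = "normalize > smooth > average > split",
    window = window, polyorder = polyorder,
    smooth_each_replicate = smooth_each_replicate
  )
  res
}
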
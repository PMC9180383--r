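# Emission trajectories: a baseline path frozen at current emissions and a
# policy path that steps down linearly inside piecewise segments.

#' A linear reduction segment of an emission trajectory
#'
#' Levels are expressed as fractions of the base-period emission level
#' (1 = current emissions). Within a segment the policy path moves from
#' `start_level` at `start_period_index` to `end_level` at
#' `end_period_index` in equal per-period steps.
#'
#' @param start_period_index,end_period_index 1-based indices into the
#'   scenario's period axis, strictly increasing.
#' @param start_level,end_level Positive fractions of base emissions;
#'   `end_level <= start_level` (reduction plans only).
#' @return An object of class `bpthia_segment`.
#' @export
trajectory_segment <- function(start_period_index, end_period_index,
                               start_level, end_level) {
  assert_scalar_number(start_period_index, "start_period_index", min = 1)
  assert_scalar_number(end_period_index, "end_period_index", min = 1)
  if (end_period_index <= start_period_index) {
    abort_validation("end_period_index must exceed start_period_index.")
  }
  assert_scalar_number(start_level, "start_level")
  assert_scalar_number(end_level, "end_level")
  if (start_level <= 0 || end_level <= 0) {
    abort_validation("segment levels must be positive.")
  }
  if (end_level > start_level) {
    abort_validation("end_level exceeds start_level: only reduction plans are supported.")
  }
  structure(list(start_period_index = start_period_index,
                 end_period_index = end_period_index,
                 start_level = start_level, end_level = end_level),
            class = "bpthia_segment")
}

#' Build policy and baseline emission trajectories
#'
#' The baseline path keeps each region at its base emission level in every
#' period. The policy path follows the reduction `segments`, which must
#' tile the period axis: the first segment starts at index 1 with the base
#' level, and each segment starts where the previous one ends (same index,
#' same level). Regional paths scale proportionally from regional base
#' emissions.
#'
#' @param base Named numeric vector, region id -> base emissions (grams
#'   TEQ, > 0).
#' @param segments List of [trajectory_segment()] objects.
#' @param periods Tibble with columns `id`, `start_year`, `end_year` (only
#'   `id` and row order are used).
#' @return Tibble with columns `region`, `period`, `path`
#'   (`"policy"`/`"baseline"`), `grams`.
#' @examples
#' periods <- tibble::tibble(id = as.character(1:11),
#'                           start_year = 1:11, end_year = 1:11)
#' segs <- list(trajectory_segment(1, 7, 1, 0.5),
#'              trajectory_segment(7, 11, 0.5, 0.1))
#' build_trajectory(c(taiwan = 57.8), segs, periods)
#' @export
build_trajectory <- function(base, segments, periods) {
  if (is.null(names(base)) || any(base <= 0)) {
    abort_validation("base must be a named vector of positive gram amounts.")
  }
  assert_cols(periods, "id", "periods")
  n <- nrow(periods)
  if (length(segments) == 0) abort_validation("at least one segment is required.")
  for (s in segments) stopifnot(inherits(s, "bpthia_segment"))

  if (segments[[1]]$start_period_index != 1) {
    abort_validation("the first segment must start at period index 1.")
  }
  if (abs(segments[[1]]$start_level - 1) > 1e-12) {
    abort_validation("the first segment must start at the base level (fraction 1).")
  }
  last <- segments[[length(segments)]]
  if (last$end_period_index != n) {
    abort_validation(sprintf(
      "segments must tile the period axis: last segment ends at index %d, not %d.",
      last$end_period_index, n))
  }
  if (length(segments) > 1) {
    for (k in 2:length(segments)) {
      prev <- segments[[k - 1]]; cur <- segments[[k]]
      if (cur$start_period_index != prev$end_period_index) {
        abort_validation(sprintf(
          "segment gap/overlap between indices %d and %d.",
          prev$end_period_index, cur$start_period_index))
      }
      if (abs(cur$start_level - prev$end_level) > 1e-12) {
        abort_validation("segment levels are discontinuous at a boundary.")
      }
    }
  }

  frac <- numeric(n)
  frac[1] <- 1
  for (s in segments) {
    idx <- s$start_period_index:s$end_period_index
    steps <- length(idx) - 1
    frac[idx] <- s$start_level + (s$end_level - s$start_level) *
      (seq_along(idx) - 1) / steps
  }

  dplyr::bind_rows(lapply(names(base), function(r) {
    dplyr::bind_rows(
      tibble::tibble(region = r, period = periods$id, path = "policy",
                     grams = base[[r]] * frac),
      tibble::tibble(region = r, period = periods$id, path = "baseline",
                     grams = base[[r]])
    )
  }))
}
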
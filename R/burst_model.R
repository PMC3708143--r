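#' sparsesynergy: sparse muscle synergies from locomotor EMG burst phases
#'
#' Muscle bursts recorded during locomotion are summarized by their onset and
#' offset phases within a normalized step cycle and clustered in the
#' (onset, offset) phase plane. A synergy ("sparse" because it contains only a
#' handful of bursts, not a weighting over all muscles) is an equivalence class
#' of bursts whose +/-1 SD rectangles overlap along the inter-centroid axis.
#' The package covers the full analysis chain: phase normalization, outlier
#' screening, associative clustering (unconstrained, two-stage, and constrained
#' to a reference composition), direct-component activation profiles,
#' bivariate-normal ellipse summaries, condition statistics, and a synthetic
#' burst generator with planted ground truth.
#'
#' @keywords internal
"_PACKAGE"

VALID_CONDITIONS <- c("unobstructed", "lead", "trail")

#' Convert an event time to step-cycle phase
#'
#' The step cycle runs from one onset of the reference muscle to the next and
#' is normalized to unit length. Events after the cycle start get positive
#' phase, events before it negative phase; the cycle start itself is phase 0.
#'
#' @param event_time event time (ms), vectorized.
#' @param cycle_start reference-muscle onset opening the cycle (ms).
#' @param cycle_end next reference-muscle onset (ms); must exceed `cycle_start`.
#' @return numeric phase(s), dimensionless fraction of the cycle.
#' @examples
#' phase_normalize(1500, 1000, 2000) # 0.5
#' phase_normalize(900, 1000, 2000)  # -0.1, pre-reference event
#' @export
phase_normalize <- function(event_time, cycle_start, cycle_end) {
  if (any(cycle_end <= cycle_start)) {
    stop("invalid cycle: cycle_end must be greater than cycle_start")
  }
  (event_time - cycle_start) / (cycle_end - cycle_start)
}

#' Cycle markers from reference-muscle onsets
#'
#' @param reference_onsets strictly increasing onset times (ms) of the
#'   reference muscle; at least two are needed to define one cycle.
#' @param reference_muscle name of the reference muscle.
#' @return object of class `cycle_markers`.
#' @export
cycle_markers <- function(reference_onsets, reference_muscle = "Br") {
  reference_onsets <- as.numeric(reference_onsets)
  if (length(reference_onsets) < 2L) {
    stop("need at least two reference onsets to define a cycle")
  }
  if (any(diff(reference_onsets) <= 0)) {
    stop("reference onsets must be strictly increasing")
  }
  structure(
    list(reference_muscle = reference_muscle, reference_onsets = reference_onsets),
    class = "cycle_markers"
  )
}

#' Assign raw burst times to step cycles and normalize to phase
#'
#' Each burst is assigned to the cycle whose window
#' `[start - 0.5 * duration, end - 0.5 * duration)` contains its onset, so that
#' bursts beginning up to half a cycle before the reference onset are kept with
#' that cycle and acquire negative onset phase. Bursts outside every window are
#' dropped (their count is reported in the `dropped` attribute). Within each
#' cycle, bursts of the same muscle are numbered by ascending onset to form
#' labels such as `"Bic(1)"`; occurrence indices are then reconciled across
#' cycles by matching each burst to the nearest modal onset phase so that the
#' same label always denotes the same period of activity.
#'
#' @param bursts data.frame with columns `muscle`, `onset_ms`, `offset_ms`
#'   and optionally `magnitude`.
#' @param markers a [cycle_markers()] object.
#' @param condition condition label for all rows (free-form; the three
#'   canonical ones are `"unobstructed"`, `"lead"`, `"trail"`).
#' @param animal_id animal identifier for all rows.
#' @return a burst table (see [burst_table()]) with attribute `dropped` giving
#'   the number of bursts outside all cycle windows.
#' @export
assign_cycles <- function(bursts, markers, condition, animal_id) {
  stopifnot(inherits(markers, "cycle_markers"))
  req <- c("muscle", "onset_ms", "offset_ms")
  if (!all(req %in% names(bursts))) {
    stop("bursts must have columns: ", paste(req, collapse = ", "))
  }
  on <- markers$reference_onsets
  ncyc <- length(on) - 1L
  starts <- on[-length(on)]
  ends <- on[-1L]
  durs <- ends - starts

  cyc <- rep(NA_integer_, nrow(bursts))
  for (k in seq_len(ncyc)) {
    lo <- starts[k] - 0.5 * durs[k]
    hi <- ends[k] - 0.5 * durs[k]
    hit <- is.na(cyc) & bursts$onset_ms >= lo & bursts$onset_ms < hi
    cyc[hit] <- k
  }
  dropped <- sum(is.na(cyc))
  if (dropped > 0L) {
    warning(sprintf("%d burst(s) outside all cycle windows were dropped", dropped))
  }
  keep <- !is.na(cyc)
  b <- bursts[keep, , drop = FALSE]
  cyc <- cyc[keep]

  onset_ph <- phase_normalize(b$onset_ms, starts[cyc], ends[cyc])
  offset_ph <- phase_normalize(b$offset_ms, starts[cyc], ends[cyc])

  # per-cycle occurrence index by ascending onset
  occ <- integer(nrow(b))
  for (key in unique(paste(b$muscle, cyc))) {
    idx <- which(paste(b$muscle, cyc) == key)
    occ[idx] <- rank(onset_ph[idx], ties.method = "first")
  }
  # reconcile across cycles: anchor occurrence slots at the modal pattern's
  # mean onsets, then snap each burst to the nearest slot (order-preserving)
  for (m in unique(b$muscle)) {
    idx <- which(b$muscle == m)
    counts <- table(tapply(idx, cyc[idx], length))
    modal <- as.integer(names(counts)[which.max(counts)])
    full <- idx[cyc[idx] %in% as.integer(names(which(tapply(idx, cyc[idx], length) == modal)))]
    slot_means <- tapply(onset_ph[full], occ[full], mean)
    for (k in unique(cyc[idx])) {
      ik <- idx[cyc[idx] == k]
      if (length(ik) == modal) next
      ik <- ik[order(onset_ph[ik])]
      slots <- as.integer(names(slot_means))
      chosen <- integer(0)
      for (i in seq_along(ik)) {
        avail <- setdiff(slots, chosen)
        avail <- avail[avail >= if (length(chosen)) max(chosen) + 1L else 1L]
        if (!length(avail)) avail <- max(slots) + seq_len(modal)  # overflow slots
        d <- abs(slot_means[as.character(avail)] - onset_ph[ik[i]])
        d[is.na(d)] <- Inf
        pick <- avail[which.min(d)]
        chosen <- c(chosen, pick)
        occ[ik[i]] <- pick
      }
    }
  }

  out <- data.frame(
    animal_id = rep(animal_id, nrow(b)),
    muscle = b$muscle,
    burst_label = sprintf("%s(%d)", b$muscle, occ),
    condition = rep(condition, nrow(b)),
    cycle_index = cyc,
    onset = onset_ph,
    offset = offset_ph,
    magnitude = if ("magnitude" %in% names(b)) b$magnitude else NA_real_,
    stringsAsFactors = FALSE
  )
  out <- burst_table(out)
  attr(out, "dropped") <- dropped
  out
}

#' Validate a burst observation table
#'
#' One row per muscle burst per step cycle. Required columns:
#' `animal_id`, `muscle`, `burst_label`, `condition`, `cycle_index`,
#' `onset`, `offset`, `magnitude` (`magnitude` may be `NA`).
#' Row invariants: `offset > onset`, `onset` in (-1, 1),
#' `offset - onset < 1`, `magnitude >= 0` when present.
#'
#' @param df data.frame of burst observations.
#' @return the validated data.frame with class `burst_table`.
#' @export
burst_table <- function(df) {
  req <- c("animal_id", "muscle", "burst_label", "condition",
           "cycle_index", "onset", "offset")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!"magnitude" %in% names(df)) df$magnitude <- NA_real_
  bad <- which(!(df$offset > df$onset) |
                 df$onset <= -1 | df$onset >= 1 |
                 (df$offset - df$onset) >= 1 |
                 (!is.na(df$magnitude) & df$magnitude < 0))
  if (length(bad)) {
    stop("invalid burst row(s): ", paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "")
  }
  df <- df[, c(req, "magnitude")]
  class(df) <- c("burst_table", "data.frame")
  df
}

#' Envelope trace container
#'
#' Rectified EMG envelope sampled at 1 kHz (1-ms bins), with marked burst
#' boundaries used for magnitude computation. `samples[i]` covers the time bin
#' `[i - 1, i)` ms.
#'
#' @param muscle muscle name.
#' @param samples non-negative amplitudes at 1-ms spacing.
#' @param burst_bounds data.frame with columns `onset_ms`, `offset_ms`
#'   (integers, within the trace extent, `onset_ms < offset_ms`).
#' @return object of class `envelope_trace`.
#' @export
envelope_trace <- function(muscle, samples, burst_bounds) {
  samples <- as.numeric(samples)
  if (any(samples < 0)) stop("envelope samples must be non-negative")
  stopifnot(all(c("onset_ms", "offset_ms") %in% names(burst_bounds)))
  if (any(burst_bounds$onset_ms >= burst_bounds$offset_ms)) {
    stop("each burst bound must satisfy onset_ms < offset_ms")
  }
  if (any(burst_bounds$onset_ms < 0) || any(burst_bounds$offset_ms > length(samples))) {
    stop("burst bounds outside trace extent")
  }
  structure(
    list(muscle = muscle, samples = samples, burst_bounds = burst_bounds),
    class = "envelope_trace"
  )
}

#' Duration-normalized burst magnitude
#'
#' Integrates the envelope over the burst's 1-ms bins in `[onset_ms, offset_ms)`
#' and divides by the burst duration in ms, i.e. the mean per-ms activity. The
#' normalization makes the measure independent of burst duration: a constant
#' envelope of amplitude a yields a regardless of how long the burst lasts.
#'
#' @param trace an [envelope_trace()].
#' @param bound_index which row of `trace$burst_bounds` to use.
#' @return mean rectified amplitude per ms (arbitrary units).
#' @export
burst_magnitude <- function(trace, bound_index) {
  stopifnot(inherits(trace, "envelope_trace"))
  bb <- trace$burst_bounds[bound_index, ]
  on_ms <- bb$onset_ms
  off_ms <- bb$offset_ms
  if (off_ms - on_ms < 1) stop("invalid burst: duration must be >= 1 ms")
  idx <- seq.int(floor(on_ms) + 1L, floor(off_ms))
  sum(trace$samples[idx]) / (off_ms - on_ms)
}
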
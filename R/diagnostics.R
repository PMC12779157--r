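#' Classification thresholds
#'
#' One config object for every rule threshold used by the diagnostics.
#'
#' @param contraction activation level below which a segment counts as
#'   contracting (on `theta`; must lie in `(theta_o, 1)`).
#' @param depth_min minimum peak contraction depth `1 - min(theta)` for the
#'   trajectory to count as having any contractile response.
#' @param slope_min onset-time slope magnitude (tau per unit chi) below
#'   which repetitive events are called synchronous; `NULL` means one
#'   output step per unit chi.
#' @param sustained_dwell_frac fraction of the run a segment must stay
#'   contracted, without re-relaxation, to count as sustained.
#' @param sustained_seg_frac fraction of segments that must be sustained.
#' @param sign_consistency fraction of matched cycles whose slope sign must
#'   agree for an antegrade/retrograde call.
#' @return A named list of thresholds.
#' @export
classification_thresholds <- function(contraction = 0.7, depth_min = 0.05,
                                      slope_min = NULL,
                                      sustained_dwell_frac = 0.5,
                                      sustained_seg_frac = 0.8,
                                      sign_consistency = 0.8) {
  list(contraction = contraction, depth_min = depth_min,
       slope_min = slope_min,
       sustained_dwell_frac = sustained_dwell_frac,
       sustained_seg_frac = sustained_seg_frac,
       sign_consistency = sign_consistency)
}

#' Detect contraction events
#'
#' Threshold-crossing events on the muscle activation field (or, as a
#' secondary option, on the area field for FLIP-style CSA maps): an event
#' opens when the field falls below `threshold` and closes when it recovers
#' above it, with linearly interpolated crossing times. Events still open
#' at the end of the run are discarded; a below-threshold start opens an
#' event at the first output time.
#'
#' @param traj an `eso_trajectory` from [eso_simulate()].
#' @param threshold crossing level on the chosen field.
#' @param field `"theta"` (default; works identically in coupled and
#'   prescribed modes) or `"alpha"`.
#' @return A tibble with one row per event: `segment`, `chi`, `onset`,
#'   `offset`, `depth` (`1 - min(field)/reference` within the event, with
#'   reference 1 for `theta` and the segment's initial value for `alpha`).
#' @export
detect_contractions <- function(traj, threshold = 0.7, field = "theta") {
  stopifnot(inherits(traj, "eso_trajectory"), field %in% c("theta", "alpha"))
  M <- traj[[field]]
  times <- traj$times
  if (length(times) < 2) stop("trajectory must cover > 1 output step",
                              call. = FALSE)
  if (field == "theta") {
    stopifnot(threshold > traj$params$theta_o, threshold < 1)
  }
  out <- vector("list", ncol(M))
  for (s in seq_len(ncol(M))) {
    v <- M[, s]
    ref <- if (field == "theta") 1 else v[1]
    below <- v < threshold
    d <- diff(below)
    dn <- which(d == 1)           # crossing downward between dn and dn+1
    up <- which(d == -1)
    onsets <- times[dn] + (times[dn + 1] - times[dn]) *
      (threshold - v[dn]) / (v[dn + 1] - v[dn])
    offsets <- times[up] + (times[up + 1] - times[up]) *
      (threshold - v[up]) / (v[up + 1] - v[up])
    if (below[1]) onsets <- c(times[1], onsets)
    n <- min(length(onsets), length(offsets))
    if (n == 0) next
    onsets <- onsets[seq_len(n)]
    offsets <- offsets[seq_len(n)]
    depth <- vapply(seq_len(n), function(k) {
      idx <- times >= onsets[k] & times <= offsets[k]
      1 - min(v[idx]) / ref
    }, 0)
    out[[s]] <- tibble::tibble(segment = s, chi = traj$chi[s],
                               onset = onsets, offset = offsets,
                               depth = depth)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(tibble::tibble(segment = integer(), chi = numeric(),
                          onset = numeric(), offset = numeric(),
                          depth = numeric()))
  }
  do.call(rbind, out)
}

#' Contraction frequency at one segment
#'
#' `(number of onsets - 1) / (last onset - first onset)` within the
#' analysis window, in cycles per unit tau.
#'
#' @param events event tibble from [detect_contractions()].
#' @param segment segment index to analyse; `NULL` uses all rows of
#'   `events` (assumed pre-filtered to one segment).
#' @param window `c(lo, hi)` analysis window on onset times.
#' @return Scalar frequency.
#' @export
contraction_frequency <- function(events, segment = NULL,
                                  window = c(-Inf, Inf)) {
  if (!is.null(segment)) events <- events[events$segment == segment, ]
  on <- sort(events$onset)
  on <- on[on >= window[1] & on <= window[2]]
  if (length(on) < 2) stop("insufficient events (need >= 2 onsets)",
                           call. = FALSE)
  (length(on) - 1) / (on[length(on)] - on[1])
}

# Match events across segments into cycles by wavefront tracking: the
# segment with the most events seeds the cycle set; walking outward, each
# neighbouring segment contributes, per cycle, its event nearest the
# neighbour's matched onset, accepted within half a median period.
match_cycles <- function(events) {
  segs <- sort(unique(events$segment))
  if (!length(segs)) {
    return(list(onset = matrix(numeric(0), 0, 0),
                offset = matrix(numeric(0), 0, 0), chi = numeric(0)))
  }
  by_seg <- split(events[order(events$onset), ], events$segment[order(events$onset)])
  counts <- vapply(by_seg, nrow, 0L)
  period <- stats::median(unlist(lapply(by_seg, function(e) diff(e$onset))))
  if (!is.finite(period)) period <- Inf
  seed <- segs[which.max(counts)]
  ncyc <- max(counts)
  onset <- matrix(NA_real_, ncyc, length(segs))
  offset <- matrix(NA_real_, ncyc, length(segs))
  js <- match(seed, segs)
  e <- by_seg[[as.character(seed)]]
  onset[seq_len(nrow(e)), js] <- e$onset
  offset[seq_len(nrow(e)), js] <- e$offset
  walk <- function(idx_range) {
    ref <- onset[, js]
    for (j in idx_range) {
      e <- by_seg[[as.character(segs[j])]]
      used <- rep(FALSE, nrow(e))
      for (k in seq_len(ncyc)) {
        if (is.na(ref[k])) next
        d <- abs(e$onset - ref[k])
        d[used] <- Inf
        m <- which.min(d)
        if (length(m) && is.finite(d[m]) && d[m] <= period / 2) {
          onset[k, j] <<- e$onset[m]
          offset[k, j] <<- e$offset[m]
          used[m] <- TRUE
          ref[k] <- e$onset[m]
        }
      }
    }
  }
  if (js < length(segs)) walk((js + 1):length(segs))
  if (js > 1) walk((js - 1):1)
  keep <- rowSums(!is.na(onset)) > 0
  list(onset = onset[keep, , drop = FALSE],
       offset = offset[keep, , drop = FALSE],
       chi = events$chi[match(segs, events$segment)], period = period)
}

#' Propagation profile of matched contraction cycles
#'
#' Matches events across segments into cycles, then fits, per cycle, a
#' least-squares line of onset time against position chi. A positive slope
#' means the rostral end leads (antegrade propagation); negative means
#' retrograde. Also reports the relative standard deviation of
#' adjacent-segment onset delays per cycle (phase-lag constancy: ~0 in a
#' phase-locked travelling wave).
#'
#' The fit excludes the rostral boundary layer (`chi < chi_min`): the
#' rostral-most oscillator has no upstream coupling by the boundary rule,
#' so it sits outside the phase-locked wave, and the one-sided sensory
#' kernel breaks translational symmetry over roughly the kernel reach
#' `x_s` of tube length.
#'
#' @param events event tibble from [detect_contractions()].
#' @param min_segments minimum matched segments for a cycle to be fitted.
#' @param chi_min rostral cut: segments with `chi < chi_min` are excluded
#'   from the slope/delay fits (they still appear in `events`).
#' @return A tibble with one row per matched cycle: `cycle`, `slope`,
#'   `r_squared`, `n_segments`, `delay_mean`, `delay_rsd`.
#' @export
propagation_profile <- function(events, min_segments = 3, chi_min = 0.1) {
  events <- events[events$chi >= chi_min, , drop = FALSE]
  m <- match_cycles(events)
  ncyc <- nrow(m$onset)
  if (ncyc == 0) {
    return(tibble::tibble(cycle = integer(), slope = numeric(),
                          r_squared = numeric(), n_segments = integer(),
                          delay_mean = numeric(), delay_rsd = numeric()))
  }
  rows <- lapply(seq_len(ncyc), function(k) {
    on <- m$onset[k, ]
    ok <- !is.na(on)
    if (sum(ok) < min_segments) return(NULL)
    fit <- stats::lm(on[ok] ~ m$chi[ok])
    sl <- unname(coef(fit)[2])
    ss_tot <- sum((on[ok] - mean(on[ok]))^2)
    r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
    adj <- which(ok[-length(ok)] & ok[-1])     # adjacent matched pairs
    delays <- on[adj + 1] - on[adj]
    dm <- mean(delays)
    rsd <- if (length(delays) > 1 && abs(dm) > 1e-12) {
      stats::sd(delays) / abs(dm)
    } else {
      NA_real_
    }
    tibble::tibble(cycle = k, slope = sl, r_squared = r2,
                   n_segments = sum(ok), delay_mean = dm, delay_rsd = rsd)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(tibble::tibble(cycle = integer(), slope = numeric(),
                          r_squared = numeric(), n_segments = integer(),
                          delay_mean = numeric(), delay_rsd = numeric()))
  }
  do.call(rbind, rows)
}

#' Overlap metric
#'
#' Counts cycles in which the rostral-most contracting segment re-activates
#' (cycle k+1 onset) before the caudal-most contracting segment has
#' completed cycle k — the signature of overlapping contractions.
#'
#' @param events event tibble from [detect_contractions()].
#' @return Integer count.
#' @export
overlap_metric <- function(events) {
  m <- match_cycles(events)
  ncyc <- nrow(m$onset)
  if (ncyc < 2) return(0L)
  segs_with <- which(colSums(!is.na(m$onset)) > 0)
  r <- segs_with[1]
  cc <- segs_with[length(segs_with)]
  n <- 0L
  for (k in seq_len(ncyc - 1)) {
    if (!is.na(m$onset[k + 1, r]) && !is.na(m$offset[k, cc]) &&
        m$onset[k + 1, r] < m$offset[k, cc]) {
      n <- n + 1L
    }
  }
  n
}

#' Bag pressure trace at a probe location
#'
#' Time series of the non-dimensional pressure `p = alpha/theta - 1`
#' linearly interpolated at `chi_probe`, emulating a pressure sensor inside
#' the distending bag.
#'
#' @param traj an `eso_trajectory` in full coupled mode.
#' @param chi_probe probe position in `[0, 1]`.
#' @return A tibble with columns `tau` and `p`.
#' @export
bag_pressure_trace <- function(traj, chi_probe = 0.5) {
  stopifnot(inherits(traj, "eso_trajectory"),
            chi_probe >= 0, chi_probe <= 1)
  if (traj$scenario$mode != "coupled") {
    stop("bag pressure requires a full coupled-mode trajectory",
         call. = FALSE)
  }
  chi <- traj$chi
  j <- findInterval(chi_probe, chi, all.inside = TRUE)
  w <- (chi_probe - chi[j]) / (chi[j + 1] - chi[j])
  tibble::tibble(tau = traj$times,
                 p = (1 - w) * traj$p[, j] + w * traj$p[, j + 1])
}

#' Classify a trajectory into the clinical pattern vocabulary
#'
#' Deterministic rule cascade over the muscle activation field:
#' \enumerate{
#'   \item \strong{absent} if the peak contraction depth anywhere stays
#'     below `depth_min`;
#'   \item \strong{sustained} if most segments stay contracted, without
#'     re-relaxation, for most of the run;
#'   \item with repetitive matched cycles: \strong{synchronous} if the
#'     onset-time slope magnitude is below `slope_min`; \strong{RAC}
#'     (repetitive antegrade contractions) for consistently positive slope
#'     without overlap; \strong{overlapping} for antegrade slope with
#'     rostral re-activation before caudal completion;
#'     \strong{retrograde} for consistently negative slope;
#'   \item \strong{disordered} otherwise.
#' }
#'
#' @param traj an `eso_trajectory`.
#' @param thresholds a [classification_thresholds()] list.
#' @return An `eso_pattern` object: `label`, `events` (tibble),
#'   `profile` (per-cycle slopes tibble), `overlap`, `frequency` (median
#'   over segments), `max_depth`, `sustained_seg_frac`, `thresholds`.
#' @export
classify_pattern <- function(traj, thresholds = classification_thresholds()) {
  stopifnot(inherits(traj, "eso_trajectory"))
  th <- thresholds
  if (is.null(th$slope_min)) {
    th$slope_min <- stats::median(diff(traj$times))
  }
  depth <- 1 - apply(traj$theta, 2, min)
  max_depth <- max(depth)
  duration <- max(traj$times) - min(traj$times)
  d_tau <- stats::median(diff(traj$times))
  # longest uninterrupted contracted dwell per segment, as run fraction
  dwell <- apply(traj$theta < th$contraction, 2, function(b) {
    r <- rle(b)
    if (!any(r$values)) 0 else max(r$lengths[r$values]) * d_tau / duration
  })
  sus_frac <- mean(dwell >= th$sustained_dwell_frac)
  events <- detect_contractions(traj, threshold = th$contraction)
  profile <- propagation_profile(events)
  overlap <- overlap_metric(events)
  counts <- if (nrow(events)) table(events$segment) else integer(0)
  med_events <- if (length(counts)) stats::median(as.integer(counts)) else 0
  freq <- tryCatch({
    segs <- as.integer(names(counts)[counts >= 2])
    stats::median(vapply(segs, function(s) {
      contraction_frequency(events, segment = s)
    }, 0))
  }, error = function(e) NA_real_)

  # directional cycles: slopes below slope_min (notably the near-synchronous
  # start-up transient under uniform distension) carry no direction
  directional <- profile[abs(profile$slope) >= th$slope_min, , drop = FALSE]
  label <- if (max_depth < th$depth_min) {
    "absent"
  } else if (sus_frac >= th$sustained_seg_frac) {
    "sustained"
  } else if (med_events >= 2 && nrow(profile) >= 2) {
    if (nrow(directional) == 0) {
      "synchronous"
    } else {
      frac_pos <- mean(directional$slope > 0)
      frac_neg <- mean(directional$slope < 0)
      if (frac_pos >= th$sign_consistency) {
        if (overlap > 0) "overlapping" else "RAC"
      } else if (frac_neg >= th$sign_consistency) {
        "retrograde"
      } else {
        "disordered"
      }
    }
  } else {
    "disordered"
  }
  structure(list(label = label, events = events, profile = profile,
                 overlap = overlap, frequency = freq, max_depth = max_depth,
                 sustained_seg_frac = sus_frac, med_events = med_events,
                 thresholds = th, scenario = traj$scenario$name),
            class = "eso_pattern")
}

#' @export
print.eso_pattern <- function(x, ...) {
  cat("<eso_pattern>", x$scenario, "->", x$label, "\n")
  cat(sprintf(
    "  events: %d | median/segment: %.3g | freq: %.4g cycles per tau\n",
    nrow(x$events), x$med_events, x$frequency))
  if (nrow(x$profile)) {
    cat(sprintf("  onset slope (median): %.4g | overlap: %d | depth: %.3g\n",
                stats::median(x$profile$slope), x$overlap, x$max_depth))
  }
  invisible(x)
}
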
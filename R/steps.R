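#' Net displacement of a track
#'
#' Straight-line distance (km) from the first fix to every fix, the standard
#' summary for distinguishing residency, migration and dispersal.
#'
#' @param track data.frame with `timestamp`, `x`, `y` (one animal,
#'   time-ordered).
#' @return data.frame with `timestamp` and `nd_km`.
#' @export
net_displacement <- function(track) {
  if (nrow(track) < 1) stop("empty track")
  data.frame(timestamp = track$timestamp,
             nd_km = sqrt((track$x - track$x[1])^2 +
                            (track$y - track$y[1])^2) / 1000)
}

#' Label fixes with biological-season windows
#'
#' Each fix receives one logical column per calendar window (windows may
#' overlap: a late-July fix is both `summer_residency` and
#' `spring_movement`), plus a single `phase` label used for steps, with
#' movement windows taking precedence over residency and spring before
#' autumn.
#'
#' @param track telemetry data.frame with a `timestamp` column.
#' @param calendar data.frame as from [default_phase_calendar()].
#' @return `track` with added logical window columns and `phase`.
#' @export
assign_phase <- function(track, calendar = default_phase_calendar()) {
  if (any(calendar$end < calendar$start))
    stop("malformed calendar window: end before start")
  md <- format(track$timestamp, "%m-%d")
  phase <- rep("other", nrow(track))
  for (k in seq_len(nrow(calendar))) {
    inw <- md >= calendar$start[k] & md <= calendar$end[k]
    track[[calendar$name[k]]] <- inw
    if (calendar$kind[k] == "residency") phase[inw & phase == "other"] <-
        calendar$name[k]
  }
  for (k in which(calendar$kind == "movement")) {
    inw <- track[[calendar$name[k]]]
    phase[inw & !(phase %in% calendar$name[calendar$kind == "movement"])] <-
      calendar$name[k]
  }
  track$phase <- phase
  track
}

# wrap an angle difference into (-180, 180]
.wrap_angle <- function(a) {
  a <- a %% 360
  a[which(a > 180)] <- a[which(a > 180)] - 360
  a[which(a <= -180)] <- a[which(a <= -180)] + 360
  a
}

#' Derive movement steps from telemetry fixes
#'
#' A step is the straight segment between two consecutive fixes of one
#' animal; it carries length (m), duration (min), speed (m/min), absolute
#' bearing, the bearing of the preceding step, and the signed turn angle in
#' (-180, 180] (NA for the first step of a track). Steps spanning a data gap
#' longer than `max_gap_factor` times the nominal interval are discarded;
#' each step takes the phase of its start fix.
#'
#' @param track telemetry data.frame (may contain several animals); must be
#'   time-ordered within animal and free of duplicate timestamps.
#' @param calendar phase calendar for labelling.
#' @param max_gap_factor gap-screening multiplier (default 2).
#' @param nominal_interval nominal fix interval in minutes; default: the
#'   per-track modal interval.
#' @return data.frame of steps.
#' @export
compute_steps <- function(track, calendar = default_phase_calendar(),
                          max_gap_factor = 2, nominal_interval = NULL) {
  track <- assign_phase(track, calendar)
  if (is.null(track$animal_id)) track$animal_id <- "animal1"
  out <- lapply(split(track, track$animal_id), function(tr) {
    tr <- tr[order(tr$timestamp), ]
    if (nrow(tr) < 2) return(NULL)
    if (any(duplicated(tr$timestamp)))
      stop("duplicate timestamps in track for animal ", tr$animal_id[1])
    n <- nrow(tr)
    dx <- diff(tr$x); dy <- diff(tr$y)
    dur <- as.numeric(difftime(tr$timestamp[-1], tr$timestamp[-n],
                               units = "mins"))
    len <- sqrt(dx^2 + dy^2)
    bearing <- atan2(dy, dx) * 180 / pi
    prev_bearing <- c(NA_real_, bearing[-(n - 1)])
    turn <- .wrap_angle(bearing - prev_bearing)
    turn[1] <- NA_real_
    st <- data.frame(
      animal_id = tr$animal_id[1],
      t_start = tr$timestamp[-n], t_end = tr$timestamp[-1],
      x1 = tr$x[-n], y1 = tr$y[-n], x2 = tr$x[-1], y2 = tr$y[-1],
      length = len, duration = dur, speed = len / dur,
      bearing = bearing, prev_bearing = prev_bearing, turn_angle = turn,
      phase = tr$phase[-n],
      stringsAsFactors = FALSE)
    for (wn in calendar$name) st[[wn]] <- tr[[wn]][-n]  # start-fix windows
    nom <- if (is.null(nominal_interval)) {
      tab <- table(dur); as.numeric(names(tab)[which.max(tab)])
    } else nominal_interval
    st[st$duration <= max_gap_factor * nom, , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Subsample an equal number of steps per animal
#'
#' Uniform draws without replacement, seeded; animals with fewer than `n`
#' steps keep everything (with a warning), so every animal contributes with
#' equal weight up to availability.
#'
#' @param steps step data.frame with `animal_id`.
#' @param n target steps per animal.
#' @param seed integer seed.
#' @return subsampled step data.frame.
#' @export
subsample_steps <- function(steps, n, seed = 1) {
  stopifnot(n > 0)
  set.seed(seed)
  parts <- lapply(split(seq_len(nrow(steps)), steps$animal_id), function(ix) {
    if (length(ix) <= n) {
      if (length(ix) < n)
        warning(sprintf("animal %s has only %d steps (< %d); keeping all",
                        steps$animal_id[ix[1]], length(ix), n))
      ix
    } else sample(ix, n)
  })
  out <- steps[sort(unlist(parts, use.names = FALSE)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Broken-stick threshold of movement rates
#'
#' Separates short foraging/resting moves from long directional travel: bins
#' speeds into `n_bins` equal-width bins over the 0.1-99.9 percentile range,
#' takes the natural log of the nonzero bin frequencies, and fits a
#' continuous two-segment linear model of log-frequency on bin midpoint by
#' exhaustive search over interior bin boundaries. The RSS-minimising
#' breakpoint is the threshold speed.
#'
#' @param speeds numeric vector of movement rates (m/min), length >= 100.
#' @param n_bins number of histogram bins (>= 6; default 50).
#' @return a `broken_stick_fit`: `threshold` (m/min), `slopes` (below,
#'   above), `rss`, `degenerate`, plus the binned data.
#' @export
broken_stick_threshold <- function(speeds, n_bins = 50) {
  speeds <- speeds[is.finite(speeds)]
  if (length(speeds) < 100) stop("need at least 100 speeds")
  if (n_bins < 6) stop("need at least 6 bins")
  qr_ <- quantile(speeds, c(0.001, 0.999), names = FALSE)
  if (diff(qr_) <= 0)
    return(structure(list(threshold = qr_[1], slopes = c(NA, NA), rss = NA,
                          degenerate = TRUE, bins = NULL),
                     class = "broken_stick_fit"))
  breaks <- seq(qr_[1], qr_[2], length.out = n_bins + 1)
  inr <- speeds[speeds >= breaks[1] & speeds <= breaks[length(breaks)]]
  counts <- hist(inr, breaks = breaks, plot = FALSE)$counts
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  keep <- counts > 0
  x <- mids[keep]; y <- log(counts[keep])

  # candidates: interior bin boundaries with >= 3 occupied bins on each side
  cand <- breaks[-c(1, length(breaks))]
  cand <- cand[vapply(cand, function(cc)
    sum(x < cc) >= 3 && sum(x >= cc) >= 3, TRUE)]
  if (length(cand) == 0)
    stop("fewer than 3 occupied bins on one side of every candidate breakpoint")

  fits <- lapply(cand, function(cc) {
    X <- cbind(1, x, pmax(x - cc, 0))
    f <- lm.fit(X, y)
    list(rss = sum(f$residuals^2), coef = f$coefficients)
  })
  rss <- vapply(fits, `[[`, 0, "rss")
  best <- which.min(rss)
  co <- fits[[best]]$coef
  lin <- lm.fit(cbind(1, x), y)
  rss_line <- sum(lin$residuals^2)
  degenerate <- rss_line < 1e-10 || abs(co[3]) < 1e-8 ||
    (rss_line - rss[best]) / max(rss_line, 1e-12) < 1e-9
  structure(list(threshold = cand[best],
                 slopes = c(below = unname(co[2]),
                            above = unname(co[2] + co[3])),
                 rss = rss[best], degenerate = degenerate,
                 bins = data.frame(mid = x, log_freq = y)),
            class = "broken_stick_fit")
}

#' @export
print.broken_stick_fit <- function(x, ...) {
  cat(sprintf(
    "<broken_stick_fit> threshold %.3f m/min; slopes %.3f / %.3f%s\n",
    x$threshold, x$slopes[1], x$slopes[2],
    if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Retain steps faster than the broken-stick threshold
#'
#' Strictly greater than: a step exactly at the threshold is a foraging
#' move.
#'
#' @param steps step data.frame with a `speed` column.
#' @param fit a `broken_stick_fit` (must be non-degenerate).
#' @return filtered step data.frame.
#' @export
filter_long_steps <- function(steps, fit) {
  stopifnot(inherits(fit, "broken_stick_fit"))
  if (isTRUE(fit$degenerate))
    stop("broken-stick fit is degenerate (single movement regime); ",
         "inspect the speed distribution before filtering")
  steps[steps$speed > fit$threshold, , drop = FALSE]
}
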
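# Single-particle detection, greedy mutual-nearest-neighbour linking, and
# residency (off-rate) / mobility (diffusion coefficient) estimation.

#' Detect diffraction-limited particles in one frame
#'
#' The frame is Gaussian-smoothed (matched filter at roughly the PSF scale),
#' local maxima above `median + threshold_mads * MAD` of the smoothed image
#' are kept, and each is refined to the intensity-weighted centroid of its
#' 5x5 neighbourhood in the raw background-subtracted frame. The reported
#' intensity is the background-subtracted 5x5 sum.
#'
#' @param frame numeric matrix (rows = y).
#' @param threshold_mads robust threshold in MAD units (default 5).
#' @param sigma_px smoothing sigma in pixels (default 1).
#' @param border candidates closer than this to the edge are dropped, px.
#' @return data.frame with 0-based sub-pixel `x_px`, `y_px` and
#'   `intensity_au`.
#' @export
detect_particles <- function(frame, threshold_mads = 5, sigma_px = 1,
                             border = 3) {
  if (!all(is.finite(frame))) stop("frame must be finite-valued")
  sm <- EBImage::gblur(frame, sigma = sigma_px)
  thr <- median(sm) + threshold_mads * mad(sm)
  cand <- which(local_maxima(sm) & sm > thr, arr.ind = TRUE)
  empty <- data.frame(x_px = numeric(), y_px = numeric(),
                      intensity_au = numeric())
  if (!nrow(cand)) return(empty)
  nr <- nrow(frame); nc <- ncol(frame)
  inb <- cand[, 1] > border & cand[, 1] <= nr - border &
    cand[, 2] > border & cand[, 2] <= nc - border
  cand <- cand[inb, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  bg <- median(frame)
  out <- t(vapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    rr <- (r - 2):(r + 2); cc <- (c - 2):(c + 2)
    w <- pmax(frame[rr, cc] - bg, 0)
    tot <- sum(w)
    cy <- if (tot > 0) sum(rr * rowSums(w)) / tot else r
    cx <- if (tot > 0) sum(cc * colSums(w)) / tot else c
    c(cx - 1, cy - 1, sum(frame[rr, cc] - bg))
  }, numeric(3)))
  data.frame(x_px = out[, 1], y_px = out[, 2], intensity_au = out[, 3])
}

#' Link per-frame detections into trajectories
#'
#' Greedy mutual-nearest-neighbour linking within `max_displacement_um`;
#' tracks survive gaps up to `max_gap` frames. When the assignment is
#' ambiguous (a second candidate also lies within the search radius, as for
#' crossing particles) the tracks involved are terminated rather than
#' guessed.
#'
#' @param detections list (one element per frame) of data.frames from
#'   [detect_particles()].
#' @param max_displacement_um search radius per frame, um.
#' @param max_gap frames a track may go undetected (default 1).
#' @param pixel_size um per pixel.
#' @param frame_interval s per frame.
#' @return data.frame with `track_id`, `frame`, `x_um`, `y_um`,
#'   `intensity_au` sorted by track and frame.
#' @export
link_trajectories <- function(detections, max_displacement_um = 0.3,
                              max_gap = 1, pixel_size = 0.1,
                              frame_interval = 1 / 63) {
  max_disp_px <- max_displacement_um / pixel_size
  next_id <- 1L
  active <- list()   # each: list(id, x, y, last_frame, rows)
  done <- list()
  for (f in seq_along(detections)) {
    det <- detections[[f]]
    nd <- if (is.null(det)) 0L else nrow(det)
    na <- length(active)
    link_det <- rep(NA_integer_, nd)   # detection -> active index
    if (na && nd) {
      ax <- vapply(active, `[[`, numeric(1), "x")
      ay <- vapply(active, `[[`, numeric(1), "y")
      dmat <- sqrt(outer(det$x_px, ax, "-")^2 + outer(det$y_px, ay, "-")^2)
      within <- dmat <= max_disp_px
      amb_det <- rowSums(within) > 1      # detection sees several tracks
      amb_act <- colSums(within) > 1      # track sees several detections
      for (d in seq_len(nd)) {
        if (amb_det[d]) next
        a <- which(within[d, ])
        if (length(a) != 1) next
        if (amb_act[a]) next
        # mutual nearest neighbour by construction (single candidates)
        link_det[d] <- a
      }
      # ambiguity: terminate every track involved
      for (a in which(amb_act)) active[[a]]$terminated <- TRUE
      for (d in which(amb_det)) {
        for (a in which(within[d, ])) active[[a]]$terminated <- TRUE
      }
    }
    new_active <- list()
    linked_act <- link_det[!is.na(link_det)]
    for (a in seq_len(na)) {
      tr <- active[[a]]
      if (a %in% linked_act && !isTRUE(tr$terminated)) {
        d <- which(link_det == a)
        tr$x <- det$x_px[d]; tr$y <- det$y_px[d]; tr$last_frame <- f
        tr$rows[[length(tr$rows) + 1]] <-
          c(f, det$x_px[d], det$y_px[d], det$intensity_au[d])
        new_active[[length(new_active) + 1]] <- tr
      } else if (!isTRUE(tr$terminated) && f - tr$last_frame <= max_gap) {
        new_active[[length(new_active) + 1]] <- tr
      } else {
        done[[length(done) + 1]] <- tr
      }
    }
    for (d in seq_len(nd)) {
      if (!is.na(link_det[d])) next
      tr <- list(id = next_id, x = det$x_px[d], y = det$y_px[d],
                 last_frame = f,
                 rows = list(c(f, det$x_px[d], det$y_px[d],
                               det$intensity_au[d])))
      next_id <- next_id + 1L
      new_active[[length(new_active) + 1]] <- tr
    }
    active <- new_active
  }
  done <- c(done, active)
  if (!length(done))
    return(data.frame(track_id = integer(), frame = integer(),
                      x_um = numeric(), y_um = numeric(),
                      intensity_au = numeric()))
  out <- do.call(rbind, lapply(done, function(tr) {
    m <- do.call(rbind, tr$rows)
    data.frame(track_id = tr$id, frame = as.integer(m[, 1]),
               x_um = (m[, 2] + 0.5) * pixel_size,
               y_um = (m[, 3] + 0.5) * pixel_size,
               intensity_au = m[, 4])
  }))
  out[order(out$track_id, out$frame), ]
}

#' Detect and link particles across a whole movie
#'
#' @param movie a [tirf_movie()].
#' @param threshold_mads,sigma_px see [detect_particles()].
#' @param max_displacement_um,max_gap see [link_trajectories()].
#' @return data.frame of tracks (see [link_trajectories()]).
#' @export
track_movie <- function(movie, threshold_mads = 5, sigma_px = 1,
                        max_displacement_um = 0.3, max_gap = 1) {
  nt <- dim(movie$frames)[3]
  dets <- lapply(seq_len(nt), function(f)
    detect_particles(movie$frames[, , f], threshold_mads, sigma_px))
  link_trajectories(dets, max_displacement_um, max_gap,
                    movie$pixel_size, movie$frame_interval)
}

#' Trajectory presence times
#'
#' Duration convention: `n_frames * frame_interval` (presence time; a
#' particle seen in one frame has lived for about one frame interval).
#'
#' @param tracks data.frame with `track_id` and `frame`.
#' @param frame_interval s per frame.
#' @return Named numeric vector of durations, s.
#' @export
track_durations <- function(tracks, frame_interval) {
  as.numeric(table(tracks$track_id)) * frame_interval
}

#' Off-rate from left-truncated exponential dwell times
#'
#' Maximum-likelihood exponential rate for dwell times observed above a
#' truncation threshold: `k = 1 / (mean(d) - min_duration)` over durations
#' `d > min_duration`, with a bootstrap percentile confidence interval.
#'
#' @param durations_s dwell times, s.
#' @param min_duration_s left-truncation threshold, s.
#' @param n_boot bootstrap replicates (default 200).
#' @param conf confidence level.
#' @param min_events minimum number of retained dwells (default 20).
#' @return List with `rate` (1/s), `ci`, `n`, `mean_dwell_s`.
#' @export
estimate_off_rate <- function(durations_s, min_duration_s = 0,
                              n_boot = 200, conf = 0.95, min_events = 20) {
  d <- durations_s[durations_s > min_duration_s]
  if (length(d) < min_events)
    stop(sprintf("only %d dwells above the truncation threshold; need >= %d",
                 length(d), min_events))
  est <- function(x) 1 / (mean(x) - min_duration_s)
  k <- est(d)
  boots <- vapply(seq_len(n_boot), function(i)
    est(sample(d, replace = TRUE)), numeric(1))
  alpha <- (1 - conf) / 2
  list(rate = k, ci = unname(quantile(boots, c(alpha, 1 - alpha))),
       n = length(d), mean_dwell_s = mean(d))
}

# Ensemble MSD for lags 1..n_lags using actual frame differences, so
# gap-bridged tracks contribute correctly.
ensemble_msd <- function(tracks, n_lags) {
  ids <- unique(tracks$track_id)
  ss <- numeric(n_lags); nn <- integer(n_lags)
  for (id in ids) {
    tr <- tracks[tracks$track_id == id, ]
    nf <- nrow(tr)
    if (nf < 2) next
    for (i in seq_len(nf - 1)) {
      for (i2 in (i + 1):nf) {
        l <- tr$frame[i2] - tr$frame[i]
        if (l > n_lags) break
        ss[l] <- ss[l] + (tr$x_um[i2] - tr$x_um[i])^2 +
          (tr$y_um[i2] - tr$y_um[i])^2
        nn[l] <- nn[l] + 1L
      }
    }
  }
  data.frame(lag = seq_len(n_lags), msd = ifelse(nn > 0, ss / nn, NA_real_),
             n_pairs = nn)
}

#' Diffusion coefficient from the ensemble mean-squared displacement
#'
#' Fits a weighted line `MSD(tau) = intercept + 4 D tau` through the first
#' `n_lags` lags; the intercept absorbs (static) localization noise. Only
#' trajectories with at least `n_lags + 1` frames contribute.
#'
#' @param tracks data.frame with `track_id`, `frame`, `x_um`, `y_um`.
#' @param frame_interval s per frame.
#' @param n_lags number of lags fitted (default 4).
#' @param n_boot bootstrap replicates over tracks for the CI (default 100).
#' @param conf confidence level.
#' @return List with `D` (um^2/s), `intercept` (um^2), `ci`, `msd` table,
#'   `n_tracks`, `r_squared`.
#' @export
estimate_diffusion <- function(tracks, frame_interval, n_lags = 4,
                               n_boot = 100, conf = 0.95) {
  len <- table(tracks$track_id)
  keep <- names(len)[len >= n_lags + 1]
  if (!length(keep)) stop("no trajectories long enough for the MSD fit")
  sub <- tracks[tracks$track_id %in% keep, ]
  msd <- ensemble_msd(sub, n_lags)
  fit_D <- function(m) {
    tau <- m$lag * frame_interval
    fit <- lm(msd ~ tau, data = data.frame(msd = m$msd, tau = tau),
              weights = m$n_pairs)
    coef(fit)
  }
  cf <- fit_D(msd)
  tau <- msd$lag * frame_interval
  pred <- cf[1] + cf[2] * tau
  r2 <- 1 - sum(msd$n_pairs * (msd$msd - pred)^2) /
    sum(msd$n_pairs * (msd$msd - weighted.mean(msd$msd, msd$n_pairs))^2)
  ids <- unique(sub$track_id)
  boots <- vapply(seq_len(n_boot), function(i) {
    pick <- sample(ids, replace = TRUE)
    res <- do.call(rbind, lapply(seq_along(pick), function(j) {
      tr <- sub[sub$track_id == pick[j], ]
      tr$track_id <- j
      tr
    }))
    fit_D(ensemble_msd(res, n_lags))[2] / 4
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(D = unname(cf[2] / 4), intercept = unname(cf[1]),
       ci = unname(quantile(boots, c(alpha, 1 - alpha))),
       msd = msd, n_tracks = length(ids), r_squared = r2)
}
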
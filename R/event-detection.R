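# Endocytic-site detection: per-pixel standard-deviation projection of the
# movie, robust thresholding of local maxima, and ROI trace extraction
# (5x5 measurement core, 1.5-um-diameter background region excluding the
# core). Pixel coordinates at the interface are 0-based, centre-of-pixel.

#' Per-pixel temporal standard deviation of a movie
#'
#' Regions with large intensity fluctuations over the video (endocytic
#' events) appear as bright spots in this projection.
#'
#' @param movie a [tirf_movie()].
#' @return Matrix (same spatial shape as one frame) of per-pixel sample SDs.
#' @export
std_projection <- function(movie) {
  stopifnot(inherits(movie, "tirf_movie"))
  d <- dim(movie$frames)
  if (d[3] < 2) stop("std_projection needs at least 2 frames")
  m <- matrix(movie$frames, d[1] * d[2], d[3])
  mu <- rowMeans(m)
  ss <- rowSums(m * m)
  v <- pmax((ss - d[3] * mu^2) / (d[3] - 1), 0)
  matrix(sqrt(v), d[1], d[2])
}

local_maxima <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- img
  keep <- matrix(TRUE, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    keep <- keep & img >= pad[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx)]
  }
  keep
}

#' Detect candidate endocytic sites in a projection image
#'
#' Local maxima above `median + threshold_mads * MAD` of the projection are
#' retained and non-maximum-suppressed at `min_separation_um`. Detections are
#' refined to the intensity-weighted centroid of their 5x5 neighbourhood and
#' snapped back to the nearest pixel. Sites whose background regions are
#' contaminated by a neighbouring detection (separation within the
#' background diameter) are flagged `overlap`; sites whose 5x5 core would
#' leave the frame are flagged `edge`.
#'
#' @param projection matrix from [std_projection()].
#' @param threshold_mads robust threshold in MAD units (default 6).
#' @param min_separation_um non-maximum suppression radius, um.
#' @param pixel_size um per pixel.
#' @param core_half_width half-width of the measurement core in pixels
#'   (2 for a 5x5 core).
#' @param background_diameter_um diameter of the background region, um.
#' @return data.frame with 0-based pixel coordinates `x_px`, `y_px`,
#'   projection `value` and logical flags `overlap`, `edge`.
#' @export
detect_event_sites <- function(projection, threshold_mads = 6,
                               min_separation_um = 0.5, pixel_size = 0.1,
                               core_half_width = 2,
                               background_diameter_um = 1.5) {
  if (!all(is.finite(projection))) stop("projection must be finite-valued")
  thr <- median(projection) + threshold_mads * mad(projection)
  cand <- which(local_maxima(projection) & projection > thr, arr.ind = TRUE)
  empty <- data.frame(x_px = integer(), y_px = integer(), value = numeric(),
                      overlap = logical(), edge = logical())
  if (!nrow(cand)) return(empty)
  vals <- projection[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; vals <- vals[ord]
  # non-maximum suppression
  min_sep_px <- min_separation_um / pixel_size
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1):nrow(cand)
      dd <- sqrt((cand[j, 1] - cand[i, 1])^2 + (cand[j, 2] - cand[i, 2])^2)
      keep[j][dd < min_sep_px] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]; vals <- vals[keep]
  nr <- nrow(projection); nc <- ncol(projection)
  # centroid refinement (5x5, above-median weights), snap to nearest pixel
  ref <- t(vapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    rr <- max(1, r - 2):min(nr, r + 2)
    cc <- max(1, c - 2):min(nc, c + 2)
    w <- pmax(projection[rr, cc, drop = FALSE] - median(projection), 0)
    if (sum(w) <= 0) return(c(r, c))
    c(sum(rr * rowSums(w)) / sum(w), sum(cc * colSums(w)) / sum(w))
  }, numeric(2)))
  row_px <- pmin(pmax(round(ref[, 1]), 1), nr)
  col_px <- pmin(pmax(round(ref[, 2]), 1), nc)
  edge <- row_px - core_half_width < 1 | row_px + core_half_width > nr |
    col_px - core_half_width < 1 | col_px + core_half_width > nc
  bg_d_px <- background_diameter_um / pixel_size
  overlap <- rep(FALSE, length(row_px))
  if (length(row_px) > 1) {
    d <- as.matrix(dist(cbind(row_px, col_px)))
    diag(d) <- Inf
    overlap <- apply(d, 1, min) <= bg_d_px
  }
  data.frame(x_px = col_px - 1L, y_px = row_px - 1L, value = vals,
             overlap = overlap, edge = edge)
}

#' Extract raw core and background traces for one ROI
#'
#' The core trace is the per-frame sum over the `(2h+1) x (2h+1)` core; the
#' background trace is the per-frame mean per pixel over the circular
#' background region (default 1.5 um diameter) excluding the core square.
#'
#' @param movie a [tirf_movie()].
#' @param x_px,y_px 0-based pixel coordinates of the ROI centre.
#' @param core_half_width core half-width in pixels (default 2: 5x5 core).
#' @param background_diameter_um background region diameter, um.
#' @return List with `core` (AU sums), `background` (AU per pixel),
#'   `n_core_px`, `n_background_px`, `edge_clipped` flag and the frame
#'   interval.
#' @export
extract_roi_trace <- function(movie, x_px, y_px, core_half_width = 2,
                              background_diameter_um = 1.5) {
  stopifnot(inherits(movie, "tirf_movie"))
  d <- dim(movie$frames)
  nr <- d[1]; nc <- d[2]; nt <- d[3]
  r0 <- y_px + 1L; c0 <- x_px + 1L
  if (r0 < 1 || r0 > nr || c0 < 1 || c0 > nc)
    stop("ROI centre outside the frame")
  h <- core_half_width
  edge_clipped <- (r0 - h < 1 || r0 + h > nr || c0 - h < 1 || c0 + h > nc)
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  in_core <- abs(rows - r0) <= h & abs(cols - c0) <= h
  bg_r_px <- background_diameter_um / 2 / movie$pixel_size
  in_bg <- ((rows - r0)^2 + (cols - c0)^2) <= bg_r_px^2 & !in_core
  if (!any(in_bg))
    stop("ROI background region is empty (fully clipped); trace uncorrectable")
  m <- matrix(movie$frames, nr * nc, nt)
  list(core = colSums(m[which(in_core), , drop = FALSE]),
       background = colMeans(m[which(in_bg), , drop = FALSE]),
       n_core_px = sum(in_core),
       n_background_px = sum(in_bg),
       edge_clipped = edge_clipped,
       frame_interval = movie$frame_interval)
}
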
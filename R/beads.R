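# Bead velocimetry: spot detection, nearest-neighbor track linking, and the
# displacement/step filters applied before speed export.

# separable 2D Gaussian blur of a matrix (edge-replicated)
blur2d <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  w <- gauss_kernel(sigma_px)
  r <- (length(w) - 1L) %/% 2L
  conv1 <- function(mat) {     # along rows (first index)
    n <- nrow(mat)
    out <- matrix(0, n, ncol(mat))
    for (t in seq_along(w)) {
      idx <- pmin(pmax(seq_len(n) + (t - r - 1L), 1L), n)
      out <- out + w[t] * mat[idx, , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(m))))
}

#' Detect bead spots in timelapse frames
#'
#' Band-pass (difference of Gaussians at the bead scale) plus local-maximum
#' detection with sub-pixel centroid refinement. The quality score is the
#' band-pass peak response normalized by the frame's robust intensity scale.
#'
#' @param frames list of 2D intensity matrices (pixel grid), or 3D array.
#' @param pixel_size micrometers per pixel.
#' @param diameter expected bead diameter in micrometers (default 10).
#' @param intensity_threshold minimum raw intensity at the peak (default 0:
#'   disabled).
#' @param quality_threshold minimum quality score (default 0: disabled).
#' @return a `spot_set`: list (per frame) of data frames `x, y` (micrometers),
#'   `intensity`, `quality`.
#' @export
detect_spots <- function(frames, pixel_size, diameter = 10,
                         intensity_threshold = 0, quality_threshold = 0) {
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  stopifnot(diameter > 0)
  d_px <- diameter / pixel_size
  if (d_px > min(dim(frames[[1]])))
    stop("bead diameter larger than the image")
  s1 <- d_px / 2.355          # sigma matched to the bead size
  s2 <- 1.6 * s1
  spots <- lapply(frames, function(fr) {
    bp <- blur2d(fr, s1) - blur2d(fr, s2)
    scale <- max(stats::mad(as.vector(bp)), 1e-12)
    nr <- nrow(bp); nc <- ncol(bp)
    # local maxima over a 3x3 neighborhood
    shift2 <- function(m, di, dj) {
      i <- pmin(pmax(seq_len(nr) + di, 1L), nr)
      j <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
      m[i, j, drop = FALSE]
    }
    ismax <- bp > 0
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ismax <- ismax & (bp >= shift2(bp, di, dj))
    }
    idx <- which(ismax, arr.ind = TRUE)
    if (!nrow(idx)) return(data.frame(x = numeric(0), y = numeric(0),
                                      intensity = numeric(0),
                                      quality = numeric(0)))
    quality <- bp[idx] / scale
    intensity <- fr[idx]
    keep <- intensity >= intensity_threshold & quality >= quality_threshold
    idx <- idx[keep, , drop = FALSE]
    quality <- quality[keep]; intensity <- intensity[keep]
    # sub-pixel centroid over a window of the band-passed response,
    # re-centered once to remove window-asymmetry bias
    r <- max(2L, round(d_px))
    xs <- ys <- numeric(nrow(idx))
    for (s in seq_len(nrow(idx))) {
      ci <- idx[s, 1]; cj <- idx[s, 2]
      for (pass in 1:2) {
        i0 <- max(1L, ci - r); i1 <- min(nr, ci + r)
        j0 <- max(1L, cj - r); j1 <- min(nc, cj + r)
        wnd <- pmax(bp[i0:i1, j0:j1, drop = FALSE], 0)
        tot <- max(sum(wnd), 1e-300)
        xs[s] <- sum(wnd * (i0:i1)) / tot
        ys[s] <- sum(t(wnd) * (j0:j1)) / tot
        ci <- as.integer(round(xs[s])); cj <- as.integer(round(ys[s]))
      }
    }
    # pixel centers at (i - 0.5) * pixel_size
    data.frame(x = (xs - 0.5) * pixel_size, y = (ys - 0.5) * pixel_size,
               intensity = intensity, quality = quality)
  })
  structure(list(spots = spots, pixel_size = pixel_size,
                 diameter = diameter), class = "spot_set")
}

#' Link spots into tracks
#'
#' Greedy frame-to-frame assignment of mutually nearest spots, with no link
#' allowed beyond `max_step`; tracks observed in fewer than `min_frames`
#' frames are discarded. Each spot joins at most one track.
#'
#' @param spots a `spot_set` from [detect_spots()], or a list of `x, y`
#'   data frames in micrometers.
#' @param frame_interval seconds between frames.
#' @param max_step maximum allowed displacement between consecutive frames,
#'   micrometers (default 150).
#' @param min_frames minimum number of frames per track (default 3).
#' @return a `track_set`: list of data frames `frame, t, x, y`.
#' @export
link_tracks <- function(spots, frame_interval, max_step = 150,
                        min_frames = 3L) {
  sl <- if (inherits(spots, "spot_set")) spots$spots else spots
  nfr <- length(sl)
  if (nfr < min_frames)
    return(structure(list(tracks = list(), frame_interval = frame_interval),
                     class = "track_set"))
  # active tracks: list of data frames; last row = current head
  tracks <- list()
  active <- integer(0)      # indices into `tracks` with head in current frame
  prev <- sl[[1]]
  if (nrow(prev)) {
    for (s in seq_len(nrow(prev))) {
      tracks[[length(tracks) + 1L]] <-
        data.frame(frame = 1L, t = 0, x = prev$x[s], y = prev$y[s])
      active <- c(active, length(tracks))
    }
  }
  for (f in 2:nfr) {
    cur <- sl[[f]]
    n_new <- nrow(cur)
    assigned_new <- rep(FALSE, n_new)
    next_active <- integer(0)
    if (length(active) && n_new) {
      heads <- do.call(rbind, lapply(tracks[active], function(tr)
        tr[nrow(tr), c("x", "y")]))
      dmat <- sqrt(outer(heads$x, cur$x, "-")^2 +
                   outer(heads$y, cur$y, "-")^2)
      dmat[dmat > max_step] <- Inf
      # mutual nearest neighbors, greedily by increasing distance
      repeat {
        m <- which.min(dmat)
        if (!length(m) || !is.finite(dmat[m])) break
        hi <- (m - 1L) %% nrow(dmat) + 1L
        sj <- (m - 1L) %/% nrow(dmat) + 1L
        ti <- active[hi]
        tracks[[ti]] <- rbind(tracks[[ti]],
                              data.frame(frame = f,
                                         t = (f - 1) * frame_interval,
                                         x = cur$x[sj], y = cur$y[sj]))
        assigned_new[sj] <- TRUE
        next_active <- c(next_active, ti)
        dmat[hi, ] <- Inf
        dmat[, sj] <- Inf
      }
    }
    # unassigned spots start new tracks
    if (n_new) {
      for (sj in which(!assigned_new)) {
        tracks[[length(tracks) + 1L]] <-
          data.frame(frame = f, t = (f - 1) * frame_interval,
                     x = cur$x[sj], y = cur$y[sj])
        next_active <- c(next_active, length(tracks))
      }
    }
    active <- next_active
  }
  keep <- vapply(tracks, nrow, integer(1)) >= min_frames
  structure(list(tracks = tracks[keep], frame_interval = frame_interval),
            class = "track_set")
}

#' Filter tracks by net displacement and summarize speeds
#'
#' Tracks whose net displacement (start to end) is below `min_displacement`
#' are removed; a track at exactly the threshold is kept. The mean speed of
#' each surviving track is its path length divided by its duration.
#'
#' @param tracks a `track_set` from [link_tracks()].
#' @param min_displacement displacement gate in micrometers (default 125).
#' @return a `track_summary`: the filtered `track_set` plus a data frame
#'   `track_id, n_frames, displacement, path_length, duration, mean_speed`
#'   (micrometers and seconds).
#' @export
filter_and_summarize <- function(tracks, min_displacement = 125) {
  stopifnot(inherits(tracks, "track_set"))
  rows <- list()
  kept <- list()
  for (tr in tracks$tracks) {
    disp <- sqrt((tr$x[nrow(tr)] - tr$x[1])^2 + (tr$y[nrow(tr)] - tr$y[1])^2)
    if (disp < min_displacement) next
    seg <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    dur <- tr$t[nrow(tr)] - tr$t[1]
    kept[[length(kept) + 1L]] <- tr
    rows[[length(rows) + 1L]] <- data.frame(
      track_id = length(kept), n_frames = nrow(tr),
      displacement = disp, path_length = sum(seg), duration = dur,
      mean_speed = sum(seg) / dur)
  }
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(0), n_frames = integer(0),
               displacement = numeric(0), path_length = numeric(0),
               duration = numeric(0), mean_speed = numeric(0))
  structure(list(tracks = kept, summary = summary,
                 frame_interval = tracks$frame_interval),
            class = "track_summary")
}

#' @export
print.track_summary <- function(x, ...) {
  cat(sprintf("track_summary: %d tracks, mean speed %.4g um/s\n",
              nrow(x$summary),
              if (nrow(x$summary)) mean(x$summary$mean_speed) else NA))
  invisible(x)
}
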
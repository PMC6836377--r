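#' Segment the animal body from an intensity image
#'
#' Thresholds the body channel (Otsu's method by default, or a fixed
#' threshold), fills holes, and keeps the largest connected foreground
#' component, assumed to be the single animal in the frame. The body must be
#' brighter than the background; invert dark-body brightfield images first.
#'
#' Rasters are ordinary R matrices indexed \code{[row, column]}, 1-based,
#' origin at the top-left; this convention is used by every imaging function
#' in the package.
#'
#' @param body_channel numeric intensity matrix (finite, non-negative).
#' @param method \code{"otsu"} or a single numeric fixed threshold (pixels
#'   strictly above it are foreground).
#' @return list with \code{mask} (logical matrix), \code{a_w_px} (its pixel
#'   count) and \code{threshold} (the value used).
#' @export
segment_body <- function(body_channel, method = "otsu") {
  check_raster(body_channel)
  thr <- resolve_threshold(body_channel, method)
  fg <- body_channel > thr
  if (!any(fg)) stop("no body detected")
  fg <- EBImage::fillHull(fg)
  lab <- EBImage::bwlabel(fg)
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) == 0) stop("no body detected")
  mask <- matrix(lab == which.max(sizes), nrow(body_channel))
  list(mask = mask, a_w_px = sum(mask), threshold = thr)
}

check_raster <- function(m) {
  if (!is.matrix(m) || !is.numeric(m) || length(m) == 0)
    stop("raster must be a non-empty numeric matrix")
  if (any(!is.finite(m)) || any(m < 0))
    stop("raster intensities must be finite and non-negative")
  invisible(m)
}

# Otsu on the image's own intensity range (scale invariant), or a fixed
# numeric threshold. Constant images have no Otsu threshold; return the
# constant so nothing is foreground.
resolve_threshold <- function(img, method) {
  if (is.numeric(method) && length(method) == 1) return(method)
  if (!identical(method, "otsu"))
    stop("'method' must be \"otsu\" or a single numeric threshold")
  rg <- range(img)
  if (diff(rg) == 0) return(rg[1])
  EBImage::otsu(img, range = rg)
}

#' Quantify food intake from a two-channel image pair
#'
#' Implements the feeding index: \code{A_w} is the projected whole-body area
#' (pixel count of the segmented body), \code{A_f} the binarized fluorescence
#' area counted only inside the body mask (ingested food; stray background
#' speckle is excluded), and \code{feeding_index = A_f / A_w}.
#'
#' @param pair an \code{\link{image_pair}}, or a list with numeric matrices
#'   \code{body} and \code{fluo} of equal dimensions.
#' @param body_method,fluo_method threshold choice per channel:
#'   \code{"otsu"} or a fixed numeric threshold (see
#'   \code{\link{segment_body}}).
#' @return an object of class \code{feeding_result}: \code{a_w_px},
#'   \code{a_f_px}, \code{feeding_index} (exactly \code{a_f_px / a_w_px},
#'   in [0, 1] since fluorescence is restricted to the body), and the
#'   thresholds used.
#' @examples
#' pair <- render_feeding_image(c(60, 24), 0.25, noise_sd = 0, seed = 3)
#' quantify_feeding(pair)
#' @export
quantify_feeding <- function(pair, body_method = "otsu", fluo_method = "otsu") {
  stopifnot(is.list(pair), !is.null(pair$body), !is.null(pair$fluo))
  check_raster(pair$fluo)
  if (!all(dim(pair$body) == dim(pair$fluo)))
    stop("body and fluorescence channels must have equal dimensions")
  seg <- segment_body(pair$body, body_method)
  # an empty fluorescence channel has nothing above background
  fthr <- if (diff(range(pair$fluo)) == 0) Inf
          else resolve_threshold(pair$fluo, fluo_method)
  a_f <- sum(pair$fluo > fthr & seg$mask)
  structure(list(a_w_px = seg$a_w_px, a_f_px = a_f,
                 feeding_index = a_f / seg$a_w_px,
                 body_threshold = seg$threshold,
                 fluo_threshold = fthr),
            class = "feeding_result")
}

#' @export
print.feeding_result <- function(x, ...) {
  cat(sprintf("<feeding_result> A_w = %d px, A_f = %d px, feeding index = %.4f\n",
              x$a_w_px, x$a_f_px, x$feeding_index))
  cat(sprintf("  thresholds: body %.4g, fluorescence %.4g\n",
              x$body_threshold, x$fluo_threshold))
  invisible(x)
}

#' Track the animal centroid through a binary video
#'
#' For each frame, the position is the centroid of the largest foreground
#' blob, converted to arena-centered mm (x rightward, y upward; the raster
#' center maps to the origin). Frames with no foreground are gap-filled by
#' linear interpolation and flagged; more than 50% empty frames is a
#' tracking failure.
#'
#' @param frames logical or numeric array (height x width x n_frames);
#'   non-zero pixels are foreground.
#' @param dt frame interval, s.
#' @param pixel_size_mm mm per pixel (> 0).
#' @param animal_id identifier for the output trajectory.
#' @param arena optional \code{\link{arena_spec}} attached to the result.
#' @return a \code{\link{trajectory}}; its \code{interpolated} field flags
#'   gap-filled samples.
#' @export
track_centroid <- function(frames, dt, pixel_size_mm, animal_id = "animal",
                           arena = NULL) {
  stopifnot(length(dim(frames)) == 3, dt > 0, pixel_size_mm > 0)
  n <- dim(frames)[3]
  nr <- dim(frames)[1]; ncl <- dim(frames)[2]
  rows <- cols <- rep(NA_real_, n)
  for (f in seq_len(n)) {
    fr <- frames[, , f] != 0
    if (!any(fr)) next
    lab <- EBImage::bwlabel(fr)
    sizes <- tabulate(lab[lab > 0])
    keep <- lab == which.max(sizes)
    idx <- which(keep)
    rows[f] <- mean(((idx - 1) %% nr) + 1)
    cols[f] <- mean(((idx - 1) %/% nr) + 1)
  }
  empty <- is.na(rows)
  if (mean(empty) > 0.5)
    stop(sprintf("tracking failure: %d of %d frames empty", sum(empty), n))
  if (any(empty)) {
    tt <- seq_len(n)
    rows <- stats::approx(tt[!empty], rows[!empty], tt, rule = 2)$y
    cols <- stats::approx(tt[!empty], cols[!empty], tt, rule = 2)$y
  }
  x_mm <- (cols - (ncl + 1) / 2) * pixel_size_mm
  y_mm <- ((nr + 1) / 2 - rows) * pixel_size_mm
  trajectory(animal_id, times = (seq_len(n) - 1) * dt,
             x_mm = x_mm, y_mm = y_mm, arena = arena,
             interpolated = empty)
}

#' Rasterize a trajectory into a binary video
#'
#' Draws a filled disc at each sample position on a canvas covering the
#' arena, producing the kind of binary stack \code{\link{track_centroid}}
#' consumes. Used to validate the tracking round trip.
#'
#' @param traj a \code{\link{trajectory}} with an arena.
#' @param px_per_mm raster resolution (default 5 px/mm).
#' @param disc_radius_px radius of the drawn animal, px.
#' @return logical array (height x width x n_samples).
#' @export
rasterize_trajectory <- function(traj, px_per_mm = 5, disc_radius_px = 6) {
  stopifnot(inherits(traj, "trajectory"), !is.null(traj$arena))
  arena <- traj$arena
  if (arena$shape == "circle") {
    wmm <- hmm <- arena$diameter_mm
  } else {
    wmm <- arena$width_mm; hmm <- arena$height_mm
  }
  ncl <- ceiling(wmm * px_per_mm) + 2 * disc_radius_px + 2
  nr <- ceiling(hmm * px_per_mm) + 2 * disc_radius_px + 2
  n <- length(traj$times)
  frames <- array(FALSE, dim = c(nr, ncl, n))
  dr <- disc_radius_px
  off <- (-dr):dr
  disc <- outer(off, off, function(a, b) a^2 + b^2 <= dr^2)
  for (f in seq_len(n)) {
    ccol <- round(traj$x_mm[f] * px_per_mm + (ncl + 1) / 2)
    crow <- round((nr + 1) / 2 - traj$y_mm[f] * px_per_mm)
    rs <- crow + off; cs <- ccol + off
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= ncl
    frames[rs[ok_r], cs[ok_c], f] <- disc[ok_r, ok_c]
  }
  frames
}

#' Build a kymograph from a line scan through a video
#'
#' Samples the intensity profile along a line segment in every frame (the
#' classic line scan placed perpendicular to a row of cilia): row \code{t} of
#' the kymograph is the profile in frame \code{t}, averaged across
#' \code{width_px} parallel offsets perpendicular to the line.
#'
#' @param video a \code{\link{cilia_video}} or a numeric array
#'   (height x width x n_frames) plus \code{fps}.
#' @param line numeric length-4: \code{c(row0, col0, row1, col1)} endpoints
#'   in pixel indices (1-based). Both endpoints must be in bounds.
#' @param width_px number of parallel scan lines averaged (odd integer >= 1).
#' @param fps frames/s (taken from a \code{cilia_video} if missing).
#' @return an object of class \code{kymograph}: \code{matrix}
#'   (n_frames x line length), \code{fps}, \code{line}.
#' @export
build_kymograph <- function(video, line, width_px = 1, fps = NULL) {
  if (inherits(video, "cilia_video")) {
    fps <- video$fps
    frames <- video$frames
  } else {
    frames <- video
    if (is.null(fps)) stop("'fps' is required for a bare array")
  }
  stopifnot(length(dim(frames)) == 3, length(line) == 4,
            width_px >= 1, width_px == round(width_px))
  nr <- dim(frames)[1]; ncl <- dim(frames)[2]; nf <- dim(frames)[3]
  r0 <- line[1]; c0 <- line[2]; r1 <- line[3]; c1 <- line[4]
  if (any(c(r0, r1) < 1) || any(c(r0, r1) > nr) ||
      any(c(c0, c1) < 1) || any(c(c0, c1) > ncl))
    stop("line endpoints out of frame bounds")
  len <- max(abs(r1 - r0), abs(c1 - c0)) + 1
  rr <- round(seq(r0, r1, length.out = len))
  cc <- round(seq(c0, c1, length.out = len))
  # unit perpendicular for width averaging
  dl <- sqrt((r1 - r0)^2 + (c1 - c0)^2)
  if (dl == 0) { pr <- 0; pc <- 0 } else {
    pr <- -(c1 - c0) / dl; pc <- (r1 - r0) / dl
  }
  offs <- seq_len(width_px) - (width_px + 1) / 2
  mat <- matrix(0, nf, len)
  for (o in offs) {
    ro <- pmin(pmax(round(rr + o * pr), 1), nr)
    co <- pmin(pmax(round(cc + o * pc), 1), ncl)
    lin <- (co - 1) * nr + ro            # within-frame linear index
    for (f in seq_len(nf))
      mat[f, ] <- mat[f, ] + frames[, , f][lin]
  }
  mat <- mat / length(offs)
  structure(list(matrix = mat, fps = fps,
                 line = c(r0, c0, r1, c1), width_px = width_px),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d frames x %d positions at %g fps\n",
              nrow(x$matrix), ncol(x$matrix), x$fps))
  invisible(x)
}

#' Estimate ciliary beat frequency from a kymograph
#'
#' Takes the magnitude spectrum of each (mean-subtracted) kymograph column,
#' averages the spectra, and locates the dominant peak in (0, fps/2) with
#' parabolic interpolation of the log magnitudes around the peak bin for
#' sub-bin resolution.
#'
#' @param kymo a \code{\link{kymograph}} spanning at least two beat periods.
#' @return estimated beat frequency in Hz.
#' @export
estimate_beat_frequency <- function(kymo) {
  stopifnot(inherits(kymo, "kymograph"))
  M <- kymo$matrix
  n <- nrow(M)
  sds <- apply(M, 2, stats::sd)
  keep <- sds > 1e-12 * max(1, mean(abs(M)))
  if (!any(keep)) stop("no periodic signal: kymograph is flat")
  Mc <- sweep(M[, keep, drop = FALSE], 2, colMeans(M[, keep, drop = FALSE]))
  spec <- rowMeans(abs(stats::mvfft(Mc))^2)
  half <- floor(n / 2)
  if (half < 3) stop("kymograph too short for spectral estimation")
  bins <- 2:half                       # skip DC
  k <- bins[which.max(spec[bins])]
  # parabolic interpolation on log power around the peak
  delta <- 0
  if (k > 2 && k < half) {
    lp <- log(spec[(k - 1):(k + 1)] + .Machine$double.xmin)
    den <- lp[1] - 2 * lp[2] + lp[3]
    if (is.finite(den) && den < 0) delta <- 0.5 * (lp[1] - lp[3]) / den
    delta <- max(min(delta, 0.5), -0.5)
  }
  freq <- (k - 1 + delta) * kymo$fps / n
  if (freq <= 0 || freq >= kymo$fps / 2)
    stop("no periodic signal in (0, fps/2)")
  freq
}
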
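#' Render a synthetic two-channel feeding image with known ground truth
#'
#' Draws one elliptical "animal" on a dark background in the body channel and
#' fills a known fraction of its pixels with a bright, connected, blobby
#' region in the fluorescence channel (emulating dye-labeled food spread
#' through the gut branches). The pair stores the exact ground-truth pixel
#' counts, so the rendered fill fraction equals \code{a_f_px / a_w_px} within
#' one pixel of rounding.
#'
#' The body is rendered brighter than the background (foreground = above
#' threshold). Brightfield photographs with a dark body on a light background
#' should be inverted before analysis.
#'
#' @param body_axes_px integer pair: full axis lengths of the body ellipse in
#'   pixels (e.g. \code{c(100, 40)}).
#' @param fill_fraction target fraction of body pixels that fluoresce, in
#'   [0, 1].
#' @param noise_sd Gaussian background noise SD added to both channels
#'   (intensity units on a [0, 1] scale; >= 0).
#' @param seed integer seed.
#' @param margin_px background margin around the ellipse, default 15.
#' @return an object of class \code{image_pair}: list with \code{body}
#'   and \code{fluo} intensity matrices (equal dimensions, non-negative) and
#'   \code{ground_truth} (\code{a_w_px}, \code{a_f_px},
#'   \code{fill_fraction}).
#' @examples
#' pair <- render_feeding_image(c(60, 24), fill_fraction = 0.25,
#'                              noise_sd = 0, seed = 7)
#' pair$ground_truth$a_f_px / pair$ground_truth$a_w_px
#' @export
render_feeding_image <- function(body_axes_px, fill_fraction, noise_sd = 0.02,
                                 seed = 1, margin_px = 15) {
  stopifnot(length(body_axes_px) == 2, all(body_axes_px >= 4))
  if (!is.numeric(fill_fraction) || length(fill_fraction) != 1 ||
      !is.finite(fill_fraction) || fill_fraction < 0 || fill_fraction > 1)
    stop("'fill_fraction' must lie in [0, 1]")
  stopifnot(noise_sd >= 0)
  set.seed(as.integer(seed))
  a <- body_axes_px[1] / 2; b <- body_axes_px[2] / 2
  nc <- ceiling(body_axes_px[1]) + 2 * margin_px   # columns (x)
  nr <- ceiling(body_axes_px[2]) + 2 * margin_px   # rows (y)
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  row <- matrix(seq_len(nr), nr, nc)
  body <- ((col - cx) / a)^2 + ((row - cy) / b)^2 <= 1
  a_w <- sum(body)
  if (a_w == 0) stop("body ellipse does not fit the canvas")

  target <- round(fill_fraction * a_w)
  lit <- grow_blob(body, target)
  a_f <- sum(lit)

  bg <- 0.10; body_level <- 0.80; fluo_level <- 0.90
  body_ch <- matrix(bg, nr, nc); body_ch[body] <- body_level
  fluo_ch <- matrix(0, nr, nc); fluo_ch[lit] <- fluo_level
  if (noise_sd > 0) {
    body_ch <- body_ch + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
    fluo_ch <- fluo_ch + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
    body_ch[body_ch < 0] <- 0; fluo_ch[fluo_ch < 0] <- 0
  }
  structure(list(body = body_ch, fluo = fluo_ch,
                 ground_truth = list(a_w_px = a_w, a_f_px = a_f,
                                     fill_fraction = fill_fraction)),
            class = "image_pair")
}

# Grow a connected region of `target` pixels inside `mask` by randomized
# breadth-first accretion from a seed near the mask centroid. Produces the
# branched/blobby shapes typical of gut fluorescence.
grow_blob <- function(mask, target) {
  nr <- nrow(mask); nc <- ncol(mask)
  lit <- matrix(FALSE, nr, nc)
  if (target <= 0) return(lit)
  idx <- which(mask)
  if (target >= length(idx)) { lit[idx] <- TRUE; return(lit) }
  rows <- ((idx - 1) %% nr) + 1; cols <- ((idx - 1) %/% nr) + 1
  cr <- round(mean(rows)); cc <- round(mean(cols))
  seed_i <- idx[which.min((rows - cr)^2 + (cols - cc)^2)]
  lit[seed_i] <- TRUE
  frontier <- neighbors_in(seed_i, mask, lit)
  n_lit <- 1L
  while (n_lit < target && length(frontier) > 0) {
    pick <- frontier[sample.int(length(frontier), 1L)]
    frontier <- frontier[frontier != pick]
    if (lit[pick]) next
    lit[pick] <- TRUE; n_lit <- n_lit + 1L
    frontier <- c(frontier, neighbors_in(pick, mask, lit))
  }
  lit
}

neighbors_in <- function(i, mask, lit) {
  nr <- nrow(mask)
  r <- ((i - 1) %% nr) + 1; c <- ((i - 1) %/% nr) + 1
  cand <- c(if (r > 1) i - 1, if (r < nr) i + 1,
            if (c > 1) i - nr, if (c < ncol(mask)) i + nr)
  cand[mask[cand] & !lit[cand]]
}

#' @export
print.image_pair <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf("<image_pair> %d x %d px; ground truth A_w = %d, A_f = %d (fill %.3f)\n",
              nrow(x$body), ncol(x$body), gt$a_w_px, gt$a_f_px, gt$fill_fraction))
  invisible(x)
}

#' Parameters of the synthetic cilia scene
#'
#' @param beat_hz ciliary beat frequency, Hz (> 0).
#' @param fps frame rate, frames/s (default 240, the acquisition rate of the
#'   live-imaging assay). Must exceed twice \code{beat_hz} (Nyquist).
#' @param duration_s clip length, s; at least two full beat cycles.
#' @param n_cilia number of cilia in the row (>= 1).
#' @param pixel_noise_sd Gaussian pixel noise SD (intensity units, >= 0).
#' @param seed integer seed.
#' @return an object of class \code{cilia_scene_params}.
#' @export
cilia_scene_params <- function(beat_hz, fps = 240, duration_s = 1,
                               n_cilia = 8, pixel_noise_sd = 0, seed = 1) {
  stopifnot(beat_hz > 0, fps > 0, duration_s > 0, n_cilia >= 1,
            pixel_noise_sd >= 0)
  if (fps <= 2 * beat_hz)
    stop("fps must exceed 2 * beat_hz (aliasing)")
  if (duration_s * fps < 2 * fps / beat_hz)
    stop("clip must span at least 2 full beat cycles")
  structure(list(beat_hz = beat_hz, fps = fps, duration_s = duration_s,
                 n_cilia = n_cilia, pixel_noise_sd = pixel_noise_sd,
                 seed = as.integer(seed)),
            class = "cilia_scene_params")
}

#' Render a synthetic video of beating cilia
#'
#' Frames contain a horizontal row of short bright filaments anchored on a
#' base line; each filament's tip extends and retracts sinusoidally at
#' \code{beat_hz} with a per-cilium phase offset, mimicking a metachronal
#' row seen side-on in phase contrast. A vertical line scan through the row
#' therefore oscillates with period \code{fps / beat_hz} frames.
#'
#' @param params a \code{\link{cilia_scene_params}}.
#' @return an object of class \code{cilia_video}: list with \code{frames}
#'   (array height x width x n_frames), \code{fps}, \code{base_row},
#'   \code{cilium_cols} (column of each cilium) and ground-truth
#'   \code{beat_hz}.
#' @export
render_cilia_video <- function(params) {
  stopifnot(inherits(params, "cilia_scene_params"))
  set.seed(params$seed)
  n_frames <- round(params$duration_s * params$fps)
  spacing <- 6L
  width <- spacing * (params$n_cilia + 1L)
  len0 <- 10; amp <- 5
  height <- as.integer(ceiling(len0 + amp + 8))
  base_row <- height - 2L
  cols <- spacing * seq_len(params$n_cilia)
  phases <- stats::runif(params$n_cilia, 0, 2 * pi)
  frames <- array(0, dim = c(height, width, n_frames))
  tt <- (seq_len(n_frames) - 1L) / params$fps
  for (f in seq_len(n_frames)) {
    img <- matrix(0, height, width)
    lens <- len0 + amp * sin(2 * pi * params$beat_hz * tt[f] + phases)
    for (i in seq_len(params$n_cilia)) {
      tip <- base_row - round(lens[i])
      img[tip:base_row, cols[i]] <- 1
    }
    frames[, , f] <- img
  }
  if (params$pixel_noise_sd > 0) {
    frames <- frames + array(stats::rnorm(length(frames), 0, params$pixel_noise_sd),
                             dim = dim(frames))
    frames[frames < 0] <- 0
  }
  structure(list(frames = frames, fps = params$fps, base_row = base_row,
                 cilium_cols = cols, beat_hz = params$beat_hz,
                 params = params),
            class = "cilia_video")
}

#' @export
print.cilia_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cilia_video> %d frames of %d x %d px at %g fps; ground-truth beat %g Hz\n",
              d[3], d[1], d[2], x$fps, x$beat_hz))
  invisible(x)
}
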
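#' Write and read trajectory CSV
#'
#' Trajectories interchange as CSV with header columns \code{animal_id},
#' \code{time_s}, \code{x_mm}, \code{y_mm} (decimal point, UTF-8).
#'
#' @param tracks a \code{\link{track_set}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_set"))
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @param arena an \code{\link{arena_spec}} attached to each trajectory
#'   (or \code{NULL}).
#' @param group_label condition name for the resulting track set.
#' @export
read_tracks_csv <- function(path, arena = NULL, group_label = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "time_s", "x_mm", "y_mm")
  if (!all(need %in% names(df)))
    stop("tracks CSV must have columns ", paste(need, collapse = ", "))
  trajs <- lapply(split(df, df$animal_id), function(d) {
    d <- d[order(d$time_s), ]
    trajectory(d$animal_id[1], d$time_s, d$x_mm, d$y_mm, arena = arena)
  })
  track_set(unname(trajs), group_label = group_label)
}

#' Read and write arena YAML
#'
#' Arena geometry interchanges as a YAML mapping with the fields of
#' \code{\link{arena_spec}} (\code{shape}, dimensions, \code{food_xy_mm} or
#' \code{light_edge}, \code{reach_radius_mm}, start-region options).
#'
#' @param path YAML file.
#' @return an \code{\link{arena_spec}}.
#' @export
read_arena_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  arena_from_list(y)
}

#' @rdname read_arena_yaml
#' @param arena an \code{\link{arena_spec}}.
#' @export
write_arena_yaml <- function(arena, path) {
  stopifnot(inherits(arena, "arena_spec"))
  y <- unclass(arena)
  y <- y[!vapply(y, is.null, logical(1))]
  yaml::write_yaml(y, path)
  invisible(path)
}

arena_from_list <- function(y) {
  known <- names(formals(arena_spec))
  bad <- setdiff(names(y), known)
  if (length(bad) > 0)
    stop("unknown arena field(s): ", paste(bad, collapse = ", "))
  if (!is.null(y$food_xy_mm)) y$food_xy_mm <- as.numeric(unlist(y$food_xy_mm))
  do.call(arena_spec, y)
}

#' Read and write grayscale images and stacks
#'
#' 8/16-bit grayscale TIFF or PNG, chosen by file extension. Multi-frame
#' stacks use multi-page TIFF or a directory of ordered PNG/TIFF files.
#' Intensities are scaled to [0, 1] on read. Matrices are \code{[row, col]},
#' origin top-left.
#'
#' @param path image file (\code{.tif}, \code{.tiff} or \code{.png}).
#' @return \code{read_image}: a numeric matrix.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image extension: ", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]   # take first channel
  img
}

#' @rdname read_image
#' @param img numeric matrix with values in [0, 1] (clamped on write).
#' @export
write_image <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 16),
    png = png::writePNG(img, path),
    stop("unsupported image extension: ", ext))
  invisible(path)
}

#' @rdname read_image
#' @return \code{read_stack}: a numeric array (height x width x n_frames).
#' @export
read_stack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) stop("no image files in directory: ", path)
    frames <- lapply(files, read_image)
  } else {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("tif", "tiff"))
      stop("a stack must be a multi-page TIFF or a directory of images")
    frames <- tiff::readTIFF(path, all = TRUE)
    frames <- lapply(frames, function(f) if (length(dim(f)) == 3) f[, , 1] else f)
  }
  d <- dim(frames[[1]])
  arr <- array(0, dim = c(d[1], d[2], length(frames)))
  for (i in seq_along(frames)) arr[, , i] <- frames[[i]]
  arr
}

#' @rdname read_image
#' @param stack numeric array (height x width x n_frames) in [0, 1].
#' @export
write_stack <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3)
  stack <- pmin(pmax(stack, 0), 1)
  frames <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  invisible(path)
}

#' Write counts CSV (batch, week, count)
#'
#' @param counts data.frame as from \code{\link{simulate_population}}.
#' @param path output file.
#' @export
write_counts_csv <- function(counts, path) {
  utils::write.csv(counts[, c("batch", "week", "count")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_csv
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("batch", "week", "count")
  if (!all(need %in% names(df)))
    stop("counts CSV must have columns ", paste(need, collapse = ", "))
  df[, need]
}
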
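#' Frame sequences
#'
#' A `frame_sequence` holds a time-ordered stack of equal-shaped 8-bit
#' grayscale frames together with a uniform frame rate. Frames are stored as
#' an integer array with dimensions `(rows, cols, n_frames)` and values in
#' 0..255; pixel coordinates are 0-based `(row, col)` with the origin at the
#' top-left corner.
#'
#' @param frames An integer array `(rows, cols, n_frames)` with values in
#'   0..255, or a list of equal-shaped numeric matrices (values in `[0, 1]`
#'   or 0..255, auto-detected).
#' @param fps Frames per second (positive scalar).
#' @return An object of class `frame_sequence` with elements `frames`
#'   (integer array) and `fps`.
#' @examples
#' f <- matrix(sample(0:255, 64 * 64, TRUE), 64)
#' seq <- frame_sequence(list(f, f), fps = 30)
#' n_frames(seq)
#' @export
frame_sequence <- function(frames, fps) {
  assert_scalar_pos(fps, "fps")
  if (is.list(frames)) {
    if (length(frames) < 2L) stop_bad_input("a frame sequence needs at least 2 frames")
    dims <- dim(frames[[1]])
    if (is.null(dims) || length(dims) != 2L)
      stop_bad_input("frames must be 2-D matrices")
    for (f in frames)
      if (!identical(dim(f), dims))
        stop_bad_input("all frames must have identical dimensions")
    arr <- array(unlist(frames, use.names = FALSE), c(dims, length(frames)))
    if (max(arr) <= 1) arr <- arr * 255
    frames <- arr
  }
  if (length(dim(frames)) != 3L)
    stop_bad_input("frames must be a 3-D array (rows, cols, n_frames)")
  if (dim(frames)[3] < 2L) stop_bad_input("a frame sequence needs at least 2 frames")
  storage.mode(frames) <- "integer"
  structure(list(frames = frames, fps = as.numeric(fps)),
            class = "frame_sequence")
}

#' @rdname frame_sequence
#' @param seq A `frame_sequence`.
#' @export
n_frames <- function(seq) dim(seq$frames)[3]

#' @rdname frame_sequence
#' @param i Frame index (1-based).
#' @return `frame_at()` returns one frame as a numeric matrix in `[0, 1]`.
#' @export
frame_at <- function(seq, i) {
  seq$frames[, , i] / 255
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_sequence> %d frames of %dx%d px @ %.6g fps (%.1f s)\n",
              d[3], d[1], d[2], x$fps, d[3] / x$fps))
  invisible(x)
}

#' Write and read a frame stack
#'
#' Frames are written losslessly as numbered 8-bit grayscale PNGs
#' (`frame_000001.png`, ...) plus a JSON sidecar `clip.json` holding the
#' frame rate and frame count. `read_frames()` validates that all numbered
#' frames are present, share one shape, and that the sidecar declares `fps`.
#'
#' @param seq A [frame_sequence()].
#' @param path Directory to write into (created if needed) / read from.
#' @return `write_frames()` returns `path` invisibly; `read_frames()` a
#'   [frame_sequence()].
#' @export
write_frames <- function(seq, path) {
  if (!inherits(seq, "frame_sequence")) stop_bad_input("seq must be a frame_sequence")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  nf <- n_frames(seq)
  for (i in seq_len(nf)) {
    png::writePNG(seq$frames[, , i] / 255,
                  file.path(path, sprintf("frame_%06d.png", i)))
  }
  jsonlite::write_json(list(fps = seq$fps, n_frames = nf),
                       file.path(path, "clip.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  sidecar <- file.path(path, "clip.json")
  if (!file.exists(sidecar))
    stop_bad_input("missing sidecar clip.json in ", path)
  meta <- jsonlite::read_json(sidecar)
  if (is.null(meta$fps))
    stop_bad_input("sidecar clip.json lacks required field 'fps'")
  if (is.null(meta$n_frames))
    stop_bad_input("sidecar clip.json lacks required field 'n_frames'")
  nf <- as.integer(meta$n_frames)
  files <- file.path(path, sprintf("frame_%06d.png", seq_len(nf)))
  missing <- !file.exists(files)
  if (any(missing))
    stop_bad_input("missing frame file(s): ",
                   paste(basename(files[missing])[seq_len(min(3, sum(missing)))],
                         collapse = ", "))
  frames <- vector("list", nf)
  dims <- NULL
  for (i in seq_len(nf)) {
    img <- png::readPNG(files[i])
    if (length(dim(img)) == 3L) img <- img[, , 1]
    if (is.null(dims)) dims <- dim(img)
    if (!identical(dim(img), dims))
      stop_bad_input("inconsistent frame dimensions at frame ", i)
    frames[[i]] <- round(img * 255)
  }
  frame_sequence(array(unlist(frames), c(dims, nf)), fps = as.numeric(meta$fps))
}
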
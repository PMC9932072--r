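# Movie container and multi-page TIFF I/O.

#' TIRF movie container
#'
#' A frames x height x width array of camera counts or calibrated photons,
#' with the frame interval attached. Pixel coordinates used throughout the
#' package are 0-based with pixel centers at integers and the origin at the
#' top-left pixel.
#'
#' @param data 3-D numeric array `[frame, row (y), column (x)]`.
#' @param frame_interval Seconds per frame (default 0.15).
#' @param units `"counts"` (raw camera) or `"photons"` (calibrated).
#' @return An object of class `tirf_movie`.
#' @export
tirf_movie <- function(data, frame_interval = 0.15, units = c("counts", "photons")) {
  units <- match.arg(units)
  stopifnot(is.array(data), length(dim(data)) == 3L, dim(data)[1L] >= 1L,
            frame_interval > 0)
  structure(list(data = data, frame_interval = frame_interval, units = units),
            class = "tirf_movie")
}

#' @export
print.tirf_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("tirf_movie: %d frames of %dx%d px (%s), %.3g s/frame\n",
              d[1L], d[2L], d[3L], x$units, x$frame_interval))
  invisible(x)
}

#' @export
dim.tirf_movie <- function(x) dim(x$data)

#' Time-average image of a movie
#'
#' @param movie A [tirf_movie()].
#' @return height x width matrix.
#' @export
time_average <- function(movie) {
  stopifnot(inherits(movie, "tirf_movie"))
  d <- dim(movie$data)
  matrix(colMeans(matrix(movie$data, d[1L], d[2L] * d[3L])), d[2L], d[3L])
}

#' Read a multi-page TIFF stack as a movie
#'
#' @param path TIFF file (16-bit unsigned counts).
#' @param frame_interval Seconds per frame.
#' @param units Unit flag for the returned movie.
#' @return A [tirf_movie()].
#' @export
read_movie_tiff <- function(path, frame_interval = 0.15, units = "counts") {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1L]])
  data <- array(0, dim = c(length(pages), d[1L], d[2L]))
  for (f in seq_along(pages)) data[f, , ] <- pages[[f]]
  tirf_movie(data, frame_interval = frame_interval, units = units)
}

#' Write a movie as a 16-bit multi-page TIFF
#'
#' Counts are stored as 16-bit unsigned integers.
#'
#' @param movie A [tirf_movie()] in counts.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "tirf_movie"))
  d <- dim(movie$data)
  pages <- lapply(seq_len(d[1L]), function(f) {
    m <- movie$data[f, , ]
    pmin(pmax(m, 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
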
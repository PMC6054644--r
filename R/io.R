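# Plain-text interchange: CSV for trajectories/records/run tables, JSON
# sidecars for parameters, optional multi-page TIFF export of image stacks.

#' Read and write ground-truth state trajectories
#'
#' CSV with columns \code{time, kind, position} plus a JSON sidecar
#' (\code{<path>.json}) holding the force label and flags.
#'
#' @param st a \code{state_trajectory}.
#' @param path CSV file path.
#' @return \code{write_state_trajectory}: the path, invisibly;
#'   \code{read_state_trajectory}: the trajectory.
#' @export
write_state_trajectory <- function(st, path) {
  utils::write.csv(as.data.frame(st), path, row.names = FALSE)
  meta <- list(force = attr(st, "force"),
               censored = isTRUE(attr(st, "censored")),
               truncated = isTRUE(attr(st, "truncated")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_state_trajectory
#' @export
read_state_trajectory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  structure(df,
            force = meta$force,
            censored = isTRUE(meta$censored),
            truncated = isTRUE(meta$truncated),
            class = c("state_trajectory", "data.frame"))
}

#' Read and write force-clamp position records as CSV
#'
#' Columns \code{time, position, force}; the configuration travels in a
#' JSON sidecar so a re-read record can be analyzed with the same
#' geometry.
#'
#' @param record a \code{position_record} with rendered samples.
#' @param path CSV file path.
#' @export
write_record_csv <- function(record, path) {
  if (is.null(record$position)) {
    stop("record has no rendered samples", call. = FALSE)
  }
  n <- length(record$position)
  utils::write.csv(
    data.frame(time = (seq_len(n) - 1L) * record$dt,
               position = record$position,
               force = record$force),
    path, row.names = FALSE)
  jsonlite::write_json(unclass(record$config), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_record_csv
#' @export
read_record_csv <- function(path) {
  df <- utils::read.csv(path)
  side <- paste0(path, ".json")
  cfg <- if (file.exists(side)) {
    do.call(clamp_config, jsonlite::read_json(side, simplifyVector = TRUE))
  } else NULL
  dt <- stats::median(diff(df$time))
  structure(list(position = df$position, force = df$force, dt = dt,
                 duration = max(df$time) + dt, config = cfg,
                 model = NULL, truth = NULL),
            class = "position_record")
}

#' Export an image stack as a multi-page TIFF
#'
#' Intensities are rescaled to [0, 1] as required by 16-bit TIFF output;
#' the ground-truth table, when present, is written next to it as CSV.
#' Requires the optional \pkg{tiff} package.
#'
#' @param stack an \code{image_stack}.
#' @param path TIFF file path.
#' @export
write_image_stack <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to write TIFF stacks",
         call. = FALSE)
  }
  fr <- stack$frames
  top <- max(fr, 1)
  pages <- lapply(seq_len(dim(fr)[1L]), function(f) fr[f, , ] / top)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  if (!is.null(stack$ground_truth)) {
    utils::write.csv(stack$ground_truth,
                     paste0(tools::file_path_sans_ext(path),
                            "_ground_truth.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' @param path TIFF file path.
#' @param pixel_size nm per pixel to attach to the stack.
#' @param frame_interval seconds per frame.
#' @export
read_image_stack <- function(path, pixel_size = 91, frame_interval = 0.1) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to read TIFF stacks",
         call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  frames <- array(0, dim = c(length(pages), nrow(pages[[1L]]),
                             ncol(pages[[1L]])))
  for (f in seq_along(pages)) frames[f, , ] <- pages[[f]]
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, psf_sigma = NULL,
                 ground_truth = NULL),
            class = "image_stack")
}
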
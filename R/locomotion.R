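# Pixel-change locomotion index: thresholded frame differencing, and
# sum-conserving resampling from the 30 Hz video clock onto 20 Hz imaging
# bins.

#' Pixel-change motion index
#'
#' For each consecutive pair of grayscale frames, counts the pixels whose
#' absolute intensity change strictly exceeds the threshold (default 10
#' gray units, removing baseline pixel fluctuations).
#'
#' @param frames grayscale stack: `height x width x n` array, or a list of
#'   equally sized matrices.
#' @param threshold gray-unit change threshold (strict inequality).
#' @return integer vector of length `n - 1` of supra-threshold pixel
#'   counts.
#' @export
motion_index <- function(frames, threshold = 10) {
  if (is.list(frames)) {
    dims <- lapply(frames, dim)
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
      abort("all frames must have identical dimensions")
    }
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  if (length(dim(frames)) != 3) abort("frames must be a height x width x n stack")
  n <- dim(frames)[3]
  if (n < 2) abort("need at least 2 frames")
  vapply(seq_len(n - 1), function(i) {
    sum(abs(frames[, , i + 1] - frames[, , i]) > threshold)
  }, integer(1))
}

#' Resample a motion trace onto imaging-clock bins
#'
#' Converts per-frame-pair motion counts on the video clock (30 Hz) to
#' uniform bins on the imaging clock (20 bins/s) by duration-weighted
#' allocation: each source interval's count is split across the imaging
#' bins it overlaps in proportion to overlap, so total motion is conserved
#' exactly.
#'
#' @param counts per-frame-pair motion counts (from [motion_index()]).
#' @param clock `clock_map` from the video/behavioral clock to the imaging
#'   clock.
#' @param source_fps video frame rate, Hz (default 30).
#' @param bin_rate imaging bin rate, bins/second (default 20).
#' @param source_start time of the first video frame on the video clock.
#' @return data.frame `bin_time` (bin start, imaging clock), `motion_index`
#'   (class `motion_trace`).
#' @export
resample_motion <- function(counts, clock = identity_clock_map(),
                            source_fps = 30, bin_rate = 20, source_start = 0) {
  if (!length(counts)) abort("empty motion trace")
  if (any(!is.finite(counts))) abort("non-finite motion counts")
  n <- length(counts)
  # source interval i covers [start + (i-1)/fps, start + i/fps) on the video
  # clock; map both edges to the imaging clock
  s <- to_imaging_time(source_start + (seq_len(n) - 1) / source_fps, clock)
  e <- to_imaging_time(source_start + seq_len(n) / source_fps, clock)
  first_bin <- floor(min(s) * bin_rate)
  last_bin <- ceiling(max(e) * bin_rate) - 1
  bins <- first_bin:last_bin
  acc <- numeric(length(bins))
  for (i in seq_len(n)) {
    if (counts[i] == 0) next
    b1 <- floor(s[i] * bin_rate); b2 <- ceiling(e[i] * bin_rate) - 1
    for (b in b1:b2) {
      lo <- max(s[i], b / bin_rate); hi <- min(e[i], (b + 1) / bin_rate)
      if (hi > lo) {
        acc[b - first_bin + 1] <- acc[b - first_bin + 1] +
          counts[i] * (hi - lo) / (e[i] - s[i])
      }
    }
  }
  out <- data.frame(bin_time = bins / bin_rate, motion_index = acc)
  class(out) <- c("motion_trace", "data.frame")
  attr(out, "bin_rate") <- bin_rate
  attr(out, "source_fps") <- source_fps
  out
}
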
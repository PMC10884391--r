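#' PET frame schedule
#'
#' Ordered, non-overlapping acquisition frames defined by start and end times
#' in seconds.
#'
#' @param frame_start,frame_end Numeric vectors of frame start/end times (s).
#' @return An object of class `frame_schedule`.
#' @export
frame_schedule <- function(frame_start, frame_end) {
  frame_start <- as.numeric(frame_start)
  frame_end <- as.numeric(frame_end)
  if (length(frame_start) != length(frame_end) || length(frame_start) == 0L)
    stop("frame_start and frame_end must be nonempty and equal length")
  if (any(!is.finite(frame_start)) || any(!is.finite(frame_end)))
    stop("frame times must be finite")
  if (any(frame_end <= frame_start))
    stop("every frame must end after it starts")
  if (any(diff(frame_start) <= 0))
    stop("frame starts must be strictly increasing")
  if (any(frame_start[-1L] < frame_end[-length(frame_end)]))
    stop("frames must not overlap")
  structure(list(frame_start = frame_start, frame_end = frame_end),
            class = "frame_schedule")
}

#' Number of frames, durations and midpoints
#' @param sched A [frame_schedule()].
#' @export
n_frames <- function(sched) length(sched$frame_start)

#' @rdname n_frames
#' @export
frame_durations <- function(sched) sched$frame_end - sched$frame_start

#' @rdname n_frames
#' @export
frame_midpoints <- function(sched) (sched$frame_start + sched$frame_end) / 2

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %g-%g s\n", n_frames(x),
              x$frame_start[1], x$frame_end[n_frames(x)]))
  invisible(x)
}

#' The short-protocol liver acquisition schedule
#'
#' Five-minute dynamic acquisition of 16 frames (12 x 5 s followed by
#' 4 x 60 s, ending at 300 s).  With `include_static = TRUE`, a 17th 1-min
#' static frame centred at 60 min post-injection (3570-3630 s) is appended,
#' as used for parametric imaging.
#'
#' @param include_static Append the 60-min static frame?
#' @return A [frame_schedule()].
#' @export
default_schedule <- function(include_static = FALSE) {
  start <- c(seq(0, 55, by = 5), seq(60, 240, by = 60))
  end <- c(seq(5, 60, by = 5), seq(120, 300, by = 60))
  if (include_static) {
    start <- c(start, 3570)
    end <- c(end, 3630)
  }
  frame_schedule(start, end)
}

#' Time-activity curve
#'
#' Frame-mean tissue concentrations on an acquisition schedule, with
#' per-frame fitting weights.
#'
#' @param schedule A [frame_schedule()].
#' @param c Frame-mean concentrations (kBq/mL), one per frame.
#' @param w Nonnegative fitting weights, one per frame.  Defaults to the
#'   frame durations (seconds), which down-weights the short, noisy early
#'   frames in proportion to their acquisition time.
#' @return An object of class `tac`.
#' @export
tac <- function(schedule, c, w = frame_durations(schedule)) {
  stopifnot(inherits(schedule, "frame_schedule"))
  c <- as.numeric(c)
  w <- as.numeric(w)
  nf <- n_frames(schedule)
  if (length(c) != nf || length(w) != nf)
    stop("`c` and `w` must have one value per frame")
  if (any(!is.finite(c)) || any(!is.finite(w)))
    stop("concentrations and weights must be finite")
  if (any(w < 0)) stop("weights must be nonnegative")
  structure(list(schedule = schedule, c = c, w = w), class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %d frames, range %.3g-%.3g kBq/mL\n",
              n_frames(x$schedule), min(x$c), max(x$c)))
  invisible(x)
}

#' Read / write TACs as CSV
#'
#' Four-column CSV: `frame_start_s, frame_end_s, conc, weight`.
#'
#' @param path File path.
#' @export
read_tac_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("frame_start_s", "frame_end_s", "conc", "weight")
  if (!all(need %in% names(d)))
    stop("TAC CSV needs columns ", paste(need, collapse = ", "))
  tac(frame_schedule(d$frame_start_s, d$frame_end_s), d$conc, d$weight)
}

#' @rdname read_tac_csv
#' @param x A [tac()] to write.
#' @export
write_tac_csv <- function(x, path) {
  stopifnot(inherits(x, "tac"))
  utils::write.csv(
    data.frame(frame_start_s = x$schedule$frame_start,
               frame_end_s = x$schedule$frame_end,
               conc = x$c, weight = x$w),
    path, row.names = FALSE)
  invisible(path)
}
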
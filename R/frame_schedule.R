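#' Build a dynamic PET frame schedule from phase definitions
#'
#' A dynamic acquisition is described by phases, each contributing a number of
#' consecutive frames of equal duration. The default protocol for a 45-minute
#' [18F]-NaF hip acquisition is 12 frames of 10 s, then 6 frames of 30 s, then
#' 10 frames of 4 min (28 frames in total).
#'
#' @param phases list of length-2 numeric vectors `c(count, duration_s)`, in
#'   acquisition order.
#' @return A `frame_schedule`: a data frame with columns `frame`, `start_s`,
#'   `duration_s`, `mid_s` and `mid_min`, contiguous from t = 0.
#' @examples
#' sched <- make_frame_schedule(list(c(12, 10), c(6, 30), c(10, 240)))
#' nrow(sched)                      # 28
#' sum(sched$duration_s) / 60       # 45 min
#' @export
make_frame_schedule <- function(phases = list(c(12, 10), c(6, 30), c(10, 240))) {
  if (length(phases) == 0L) stop("phase list is empty", call. = FALSE)
  phases <- lapply(phases, unlist)   # tolerate YAML-style nested lists
  counts <- vapply(phases, `[`, numeric(1), 1L)
  durs <- vapply(phases, `[`, numeric(1), 2L)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("phase counts must be integers >= 1", call. = FALSE)
  }
  if (any(durs <= 0)) stop("frame durations must be > 0", call. = FALSE)
  duration_s <- rep(durs, counts)
  start_s <- cumsum(c(0, duration_s[-length(duration_s)]))
  out <- data.frame(
    frame = seq_along(duration_s),
    start_s = start_s,
    duration_s = duration_s,
    mid_s = start_s + duration_s / 2
  )
  out$mid_min <- out$mid_s / 60
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' Read/write a frame schedule as CSV
#'
#' Columns `frame`, `start_s`, `duration_s` are stored; mid-times are
#' recomputed on read.
#' @param sched a `frame_schedule`.
#' @param path file path.
#' @rdname frame_schedule_io
#' @export
write_frame_schedule <- function(sched, path) {
  utils::write.csv(sched[, c("frame", "start_s", "duration_s")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname frame_schedule_io
#' @export
read_frame_schedule <- function(path) {
  df <- utils::read.csv(path)
  df$mid_s <- df$start_s + df$duration_s / 2
  df$mid_min <- df$mid_s / 60
  class(df) <- c("frame_schedule", "data.frame")
  validate_frame_schedule(df)
}

validate_frame_schedule <- function(sched) {
  stopifnot(is.data.frame(sched),
            all(c("frame", "start_s", "duration_s", "mid_s") %in% names(sched)))
  if (any(sched$duration_s <= 0)) stop("frame durations must be > 0", call. = FALSE)
  ends <- sched$start_s + sched$duration_s
  if (nrow(sched) > 1 &&
      max(abs(sched$start_s[-1] - ends[-nrow(sched)])) > 1e-9) {
    stop("frames must be contiguous", call. = FALSE)
  }
  sched
}
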
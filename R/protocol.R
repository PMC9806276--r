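# Wire protocol between the vision computer and the valve microcontroller,
# plus actuation-limit shaping. A decision vector travels as one short
# byte frame:
#
#   [ 0xAA | n_valves | payload (ceil(n/8) bytes) | checksum ]
#
# payload bit 0 of byte 0 is valve 0 (leftmost), LSB-first; checksum is
# the XOR of the n_valves byte and all payload bytes. The solenoid valves
# have a maximum complete open/close cycling frequency (10 Hz for the
# reference hardware), and small weeds need a guaranteed base opening
# time, so requested per-frame schedules are shaped by apply_rate_limit()
# before actuation; shaping only ever extends or merges open intervals.

PROTO_START <- as.raw(0xAA)

#' Encode a decision vector as a protocol frame
#'
#' @param bits 0/1 vector (a `decision_vector` or plain integer vector)
#'   of length 1 to 255.
#' @return a raw vector of `3 + ceiling(n/8)` bytes.
#' @examples
#' encode_valve_frame(rep(0L, 8))  # aa 08 00 08
#' @export
encode_valve_frame <- function(bits) {
  bits <- as.integer(unclass(bits))
  n <- length(bits)
  if (n < 1L || n > 255L) {
    stop_config("decision vector length must be between 1 and 255",
                class = "spotspray_encode_error")
  }
  if (any(is.na(bits)) || any(bits != 0L & bits != 1L)) {
    stop_config("decision vector must contain only 0 and 1",
                class = "spotspray_encode_error")
  }
  n_bytes <- ceiling(n / 8)
  padded <- c(as.logical(bits), rep(FALSE, n_bytes * 8 - n))
  payload <- packBits(padded, type = "raw")
  checksum <- Reduce(xor, payload, as.raw(n))
  c(PROTO_START, as.raw(n), payload, checksum)
}

frame_error <- function(code, msg) {
  stop(structure(
    class = c(paste0("spotspray_", code, "_error"),
              "spotspray_frame_error", "error", "condition"),
    list(message = msg, code = code, call = NULL)))
}

#' Decode a protocol frame
#'
#' Inverse of [encode_valve_frame()]: `decode_valve_frame(encode_valve_frame(v))`
#' is `v` for every decision vector. Malformed frames raise classed
#' conditions (all inheriting `spotspray_frame_error`) with distinct
#' codes: `start` (bad start byte), `length` (truncated / oversized /
#' zero valves), `checksum` (corrupt).
#'
#' @param frame a raw vector.
#' @return an integer 0/1 `decision_vector`.
#' @export
decode_valve_frame <- function(frame) {
  stopifnot(is.raw(frame))
  if (length(frame) < 1L || frame[1] != PROTO_START) {
    frame_error("start", "bad start byte")
  }
  if (length(frame) < 4L) frame_error("length", "truncated frame")
  n <- as.integer(frame[2])
  if (n < 1L) frame_error("length", "frame declares zero valves")
  n_bytes <- ceiling(n / 8)
  if (length(frame) != 3L + n_bytes) {
    frame_error("length", sprintf("expected %d bytes, got %d",
                                  3L + n_bytes, length(frame)))
  }
  payload <- frame[3:(2L + n_bytes)]
  checksum <- Reduce(xor, payload, as.raw(n))
  if (checksum != frame[length(frame)]) frame_error("checksum", "bad checksum")
  bits <- as.integer(rawToBits(payload))[seq_len(n)]
  structure(bits, class = "decision_vector")
}

#' Fail-safe frame consumer
#'
#' Models the microcontroller's receive policy: a valid frame updates the
#' valve state; on a malformed frame the previous state is held, but
#' after `max_hold` consecutive bad frames all valves close (fail-safe).
#'
#' @param n_valves number of valves.
#' @param max_hold bad frames tolerated before closing everything
#'   (default 3).
#' @return a function `consume(frame)` returning the current 0/1 valve
#'   state after processing `frame`.
#' @export
valve_consumer <- function(n_valves, max_hold = 3L) {
  state <- rep(0L, n_valves)
  bad <- 0L
  function(frame) {
    ok <- tryCatch({
      v <- decode_valve_frame(frame)
      TRUE
    }, spotspray_frame_error = function(e) FALSE)
    if (ok) {
      state <<- as.integer(unclass(v))
      bad <<- 0L
    } else {
      bad <<- bad + 1L
      if (bad > max_hold) state <<- rep(0L, n_valves)
    }
    state
  }
}

# merge sorted intervals (matrix cols open, close); gap <= 0 merges
merge_intervals <- function(iv) {
  if (nrow(iv) <= 1L) return(iv)
  out <- iv[1, , drop = FALSE]
  for (i in 2:nrow(iv)) {
    if (iv[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

#' Shape a requested valve schedule to the hardware's limits
#'
#' Converts a per-frame decision stream into per-valve open intervals and
#' enforces two actuation limits: every open interval lasts at least
#' `min_open_s` (closes are postponed), and complete open/close cycles
#' occur at most `max_freq` per second (an open that would start sooner
#' than `1/max_freq` after the previous one is merged with it, keeping
#' the valve open across the gap). Both operations only extend or merge
#' intervals, so the shaped schedule always covers the requested one.
#'
#' @param requests list of decision vectors (one per frame) or a
#'   frames-by-valves 0/1 matrix.
#' @param fps frame rate of the request stream.
#' @param max_freq maximum complete valve cycles per second (default 10).
#' @param min_open_s minimum open duration in seconds (default 0.1, one
#'   full cycle at 10 Hz).
#' @return an object of class `valve_timeline`: a list with one
#'   `open`/`close` two-column matrix per valve, plus the shaping
#'   parameters.
#' @export
apply_rate_limit <- function(requests, fps, max_freq = 10, min_open_s = 0.1) {
  check_positive(fps, "fps")
  check_positive(max_freq, "max_freq")
  if (min_open_s < 0) stop_config("`min_open_s` must be non-negative")
  if (is.list(requests)) {
    requests <- do.call(rbind, lapply(requests, function(v) as.integer(unclass(v))))
  }
  stopifnot(is.matrix(requests))
  dt <- 1 / fps
  min_gap <- 1 / max_freq
  per_valve <- lapply(seq_len(ncol(requests)), function(j) {
    on <- which(requests[, j] == 1L)
    if (!length(on)) {
      return(matrix(numeric(), ncol = 2,
                    dimnames = list(NULL, c("open", "close"))))
    }
    iv <- cbind(open = (on - 1) * dt, close = on * dt)
    iv <- merge_intervals(iv)
    iv[, 2] <- pmax(iv[, 2], iv[, 1] + min_open_s)
    iv <- merge_intervals(iv)
    # rate limit: successive opening instants >= 1/max_freq apart
    out <- iv[1, , drop = FALSE]
    if (nrow(iv) > 1) {
      for (i in 2:nrow(iv)) {
        if (iv[i, 1] - out[nrow(out), 1] < min_gap) {
          out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
        } else {
          out <- rbind(out, iv[i, , drop = FALSE])
        }
      }
    }
    out
  })
  structure(list(intervals = per_valve, fps = fps, max_freq = max_freq,
                 min_open_s = min_open_s,
                 duration_s = nrow(requests) * dt),
            class = "valve_timeline")
}

#' @export
print.valve_timeline <- function(x, ...) {
  n_open <- vapply(x$intervals, nrow, integer(1))
  cat(sprintf("<valve_timeline> %d valves over %.2f s, %d open intervals total\n",
              length(x$intervals), x$duration_s, sum(n_open)))
  invisible(x)
}

#' Is a time instant covered by a valve's open intervals?
#' @param timeline a [apply_rate_limit()] result.
#' @param valve 1-based valve index.
#' @param t time(s) in seconds.
#' @return logical vector, TRUE where the valve is open at `t`.
#' @export
valve_open_at <- function(timeline, valve, t) {
  iv <- timeline$intervals[[valve]]
  vapply(t, function(ti) any(iv[, 1] <= ti & ti < iv[, 2]), logical(1))
}
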
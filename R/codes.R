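#' Binary modulation codes and target layouts
#'
#' A c-VEP speller modulates every target with the same pseudorandom binary
#' sequence, each target using a different circular shift.  The sequence of
#' choice is a maximal-length LFSR sequence (m-sequence): its cyclic
#' autocorrelation in the +/-1 mapping equals the sequence length at lag 0 and
#' exactly -1 everywhere else, so the shifted copies are maximally
#' distinguishable.  This file owns the code generator, the shift scheme and
#' the trial timeline constants.
#'
#' @name codes
NULL

#' Construct a binary modulation code
#'
#' @param bits Integer vector of 0/1 values.
#' @param refresh_rate Stimulus refresh rate in Hz (one bit per frame).
#' @param degree,taps,init_state Optional LFSR provenance, recorded for
#'   session logs.
#' @return An object of class `binary_code` with fields `bits`,
#'   `refresh_rate`, `bit_duration`.
#' @export
binary_code <- function(bits, refresh_rate = 60, degree = NULL, taps = NULL,
                        init_state = NULL) {
  bits <- as.integer(bits)
  if (length(bits) < 2L || !all(bits %in% c(0L, 1L))) {
    stop("`bits` must be a vector of 0/1 values with length >= 2")
  }
  structure(
    list(bits = bits, refresh_rate = refresh_rate,
         bit_duration = 1 / refresh_rate,
         degree = degree, taps = taps, init_state = init_state),
    class = "binary_code"
  )
}

#' @export
print.binary_code <- function(x, ...) {
  cat(sprintf("<binary_code> %d bits @ %g Hz (%d ones / %d zeros)\n",
              length(x$bits), x$refresh_rate,
              sum(x$bits), sum(1L - x$bits)))
  invisible(x)
}

#' @export
length.binary_code <- function(x) length(x$bits)

#' Generate a maximal-length LFSR sequence (m-sequence)
#'
#' Runs a Fibonacci LFSR of the given degree and verifies that the state
#' sequence has full period `2^degree - 1`; shorter periods mean the feedback
#' taps do not correspond to a primitive polynomial and are rejected.
#'
#' @param degree LFSR register length m; the sequence has length `2^m - 1`.
#' @param taps Feedback tap positions (subset of `1:degree`).  The default
#'   `c(6, 5)` is a primitive pair for degree 6.
#' @param init_state Initial register contents, any nonzero 0/1 vector of
#'   length `degree`.
#' @param refresh_rate Stimulus refresh rate in Hz.
#' @return A [binary_code()] of length `2^degree - 1`.
#' @export
generate_msequence <- function(degree = 6, taps = c(6, 5),
                               init_state = rep(1L, degree),
                               refresh_rate = 60) {
  stopifnot(degree >= 2, degree <= 16)
  taps <- sort(unique(as.integer(taps)))
  if (any(taps < 1L) || any(taps > degree)) {
    stop("taps must lie in 1..degree")
  }
  init_state <- as.integer(init_state)
  if (length(init_state) != degree || !all(init_state %in% c(0L, 1L))) {
    stop("init_state must be a 0/1 vector of length `degree`")
  }
  if (all(init_state == 0L)) stop("init_state must be nonzero")

  n <- 2L^degree - 1L
  state <- init_state
  bits <- integer(n)
  seen <- character(n)
  for (i in seq_len(n)) {
    key <- paste(state, collapse = "")
    if (key %in% seen[seq_len(i - 1L)]) {
      stop("invalid taps: LFSR period shorter than 2^degree - 1 ",
           "(not a primitive polynomial)")
    }
    seen[i] <- key
    bits[i] <- state[degree]
    fb <- sum(state[taps]) %% 2L
    state <- c(fb, state[-degree])
  }
  if (!identical(state, init_state)) {
    stop("invalid taps: LFSR did not return to its initial state ",
         "after 2^degree - 1 steps")
  }
  code <- binary_code(bits, refresh_rate = refresh_rate, degree = degree,
                      taps = taps, init_state = init_state)
  validate_msequence(code)
  code
}

#' Check the m-sequence invariants of a code
#'
#' Verifies balance (`2^(m-1)` ones, `2^(m-1) - 1` zeros) and the two-valued
#' cyclic autocorrelation: in the +/-1 mapping the autocorrelation is `n` at
#' lag 0 and exactly -1 at every nonzero lag, checked exhaustively.
#'
#' @param code A [binary_code()].
#' @param quiet If `TRUE`, return `FALSE` instead of erroring on failure.
#' @return `TRUE` invisibly (or `FALSE` when `quiet = TRUE` and a check fails).
#' @export
validate_msequence <- function(code, quiet = FALSE) {
  stopifnot(inherits(code, "binary_code"))
  bits <- code$bits
  n <- length(bits)
  fail <- function(msg) {
    if (quiet) return(invisible(FALSE))
    stop(msg, call. = FALSE)
  }
  m <- log2(n + 1)
  if (m != round(m)) return(fail("length is not 2^m - 1"))
  if (sum(bits) != (n + 1L) / 2L) {
    return(fail(sprintf("unbalanced code: %d ones, expected %d",
                        sum(bits), (n + 1L) / 2L)))
  }
  ac <- code_autocorrelation(code)
  if (any(abs(ac[-1] + 1) > 1e-9)) {
    return(fail("cyclic autocorrelation is not two-valued (-1 off-peak)"))
  }
  invisible(TRUE)
}

#' Cyclic autocorrelation of a code in the +/-1 mapping
#'
#' @param code A [binary_code()].
#' @return Numeric vector of length `length(code)`; element `l + 1` is the
#'   autocorrelation at lag `l` (unnormalized dot product).
#' @export
code_autocorrelation <- function(code) {
  s <- 2 * code$bits - 1
  n <- length(s)
  vapply(0:(n - 1L), function(l) sum(s * rotate_delay(s, l)), numeric(1))
}

#' Circularly delay a vector
#'
#' `rotate_delay(x, s)[i] == x[(i - s - 1) mod n + 1]`: the content moves
#' `s` positions later in time (wrap-around).  Negative `s` advances.
#'
#' @param x A vector.
#' @param s Integer shift in elements.
#' @return The delayed vector.
#' @export
rotate_delay <- function(x, s) {
  n <- length(x)
  s <- ((s %% n) + n) %% n
  if (s == 0) return(x)
  c(x[(n - s + 1):n], x[1:(n - s)])
}

#' Shift a code for a given target
#'
#' Target `k` flashes the base code delayed by `bit_lag * k` bits (target 0
#' has no shift).  This delay convention is used consistently by the
#' simulator and the template classifier; decoding a trial amounts to
#' identifying the delay.
#'
#' @param code A [binary_code()].
#' @param k Target index, `0 <= k < n_targets`.
#' @param layout A [target_layout()] supplying `n_targets` and `bit_lag`.
#' @return A [binary_code()] with the delayed bit sequence.
#' @export
shift_code <- function(code, k, layout = target_layout()) {
  stopifnot(inherits(code, "binary_code"))
  if (length(k) != 1L || k < 0 || k >= layout$n_targets || k != round(k)) {
    stop(sprintf("target index k must be in 0..%d", layout$n_targets - 1L))
  }
  out <- code
  out$bits <- rotate_delay(code$bits, layout$bit_lag * as.integer(k))
  out
}

#' Convert a bit count to an EEG sample count
#'
#' @param n_bits Number of stimulus bits.
#' @param fs EEG sampling rate in Hz; must be an exact multiple of `refresh`.
#' @param refresh Stimulus refresh rate in Hz.
#' @return `n_bits * fs / refresh` as an integer.
#' @export
bits_to_samples <- function(n_bits, fs = 600, refresh = 60) {
  stopifnot(n_bits >= 0, fs > 0, refresh > 0)
  if (fs %% refresh != 0) {
    stop("fs must be divisible by refresh (non-integer samples per bit)")
  }
  as.integer(n_bits * (fs / refresh))
}

#' Target layout: circular-shift multiplexing and character map
#'
#' 32 targets select the letters A-Z, underscore and the digits 1-5; in
#' free-spelling mode the last target is replaced by a backspace character
#' ("Ö") used to delete the previous letter.  Consecutive targets are
#' separated by `bit_lag` bits of circular shift, so target `k` uses shift
#' `bit_lag * k` (all distinct modulo the code length for the defaults).
#'
#' @param n_targets Number of selectable targets.
#' @param bit_lag Circular shift between consecutive targets, in bits.
#' @param code_length Modulation code length in bits.
#' @param backspace If `TRUE`, the last target's character becomes the
#'   backspace symbol.
#' @return An object of class `target_layout` with a `table` tibble
#'   (`target`, `shift_bits`, `char`).
#' @export
target_layout <- function(n_targets = 32, bit_lag = 2, code_length = 63,
                          backspace = FALSE) {
  stopifnot(n_targets >= 2, bit_lag >= 1, code_length >= n_targets)
  shifts <- (bit_lag * (0:(n_targets - 1L))) %% code_length
  if (anyDuplicated(shifts)) {
    stop("target shifts are not distinct modulo the code length")
  }
  chars <- default_char_map(n_targets)
  if (backspace) chars[n_targets] <- "Ö"
  structure(
    list(n_targets = as.integer(n_targets), bit_lag = as.integer(bit_lag),
         code_length = as.integer(code_length), backspace = backspace,
         table = tibble::tibble(target = 0:(n_targets - 1L),
                                shift_bits = as.integer(shifts),
                                char = chars)),
    class = "target_layout"
  )
}

default_char_map <- function(n_targets) {
  pool <- c(LETTERS, "_", as.character(1:9))
  if (n_targets > length(pool)) {
    pool <- c(pool, sprintf("#%d", seq_len(n_targets - length(pool))))
  }
  pool[seq_len(n_targets)]
}

#' @export
print.target_layout <- function(x, ...) {
  cat(sprintf("<target_layout> %d targets, %d-bit lag, code length %d%s\n",
              x$n_targets, x$bit_lag, x$code_length,
              if (x$backspace) ", backspace enabled" else ""))
  invisible(x)
}

#' Character associated with a target (and the reverse lookup)
#'
#' @param layout A [target_layout()].
#' @param k Target index (0-based).
#' @return For `target_char`, a single character; for `char_target`, the
#'   0-based target index of `ch`.
#' @export
target_char <- function(layout, k) {
  stopifnot(all(k >= 0), all(k < layout$n_targets))
  layout$table$char[k + 1L]
}

#' @rdname target_char
#' @param ch A single character present in the layout.
#' @export
char_target <- function(layout, ch) {
  idx <- match(ch, layout$table$char)
  if (anyNA(idx)) {
    stop(sprintf("character(s) not in layout: %s",
                 paste(ch[is.na(idx)], collapse = ", ")))
  }
  layout$table$target[idx]
}

#' Index of the backspace target, or NA if the layout has none
#' @param layout A [target_layout()].
#' @export
backspace_target <- function(layout) {
  if (!layout$backspace) return(NA_integer_)
  layout$n_targets - 1L
}

#' Trial timeline constants
#'
#' One selection comprises a 1.05 s stimulation period (63 bits at 60 Hz),
#' a 150 ms feedback highlight and a break of about 0.85 s before the next
#' stimulation, giving a nominal selection period of 1.9 s.
#'
#' @param stimulation_s,pause_s,feedback_s Durations in seconds.
#' @return A list with the three durations and `trial_s`, the nominal
#'   selection period (`stimulation_s + pause_s`; the feedback highlight
#'   falls inside the pause).
#' @export
trial_timing <- function(stimulation_s = 63 / 60, pause_s = 0.85,
                         feedback_s = 0.15) {
  list(stimulation_s = stimulation_s, pause_s = pause_s,
       feedback_s = feedback_s, trial_s = stimulation_s + pause_s)
}

#' Serialize a code or layout to JSON (and back)
#'
#' Bits are stored as a compact 0/1 string; the shift table is explicit.
#'
#' @param code A [binary_code()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
code_to_json <- function(code, path = NULL) {
  obj <- list(bits = paste(code$bits, collapse = ""),
              refresh_rate = code$refresh_rate,
              degree = code$degree, taps = code$taps,
              init_state = code$init_state)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname code_to_json
#' @param json JSON string or file path produced by [code_to_json()].
#' @export
code_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  bits <- as.integer(strsplit(obj$bits, "")[[1]])
  binary_code(bits, refresh_rate = obj$refresh_rate,
              degree = obj$degree, taps = obj$taps,
              init_state = obj$init_state)
}

#' @rdname code_to_json
#' @param layout A [target_layout()].
#' @export
layout_to_json <- function(layout, path = NULL) {
  obj <- list(n_targets = layout$n_targets, bit_lag = layout$bit_lag,
              code_length = layout$code_length, backspace = layout$backspace,
              shift_bits = layout$table$shift_bits,
              char = layout$table$char)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname code_to_json
#' @export
layout_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  lay <- target_layout(n_targets = obj$n_targets, bit_lag = obj$bit_lag,
                       code_length = obj$code_length,
                       backspace = obj$backspace)
  lay$table$char <- obj$char
  lay
}
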
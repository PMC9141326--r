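#' Specify a two-timescale synthetic sensory environment
#'
#' An agent reads a vector of sensory bits once per sensation--action cycle.
#' The vector is partitioned into a fast sector of \code{n1} bits, resampled
#' uniformly at random every cycle (characteristic timescale = 1 cycle), and
#' a slow sector of \code{n2} bits whose state persists for \code{tau2}
#' cycles on average. Two change schedules are supported: \code{"periodic"}
#' changes the slow sector exactly every \code{round(tau2)} cycles (making
#' energy-ledger comparisons exact), while \code{"geometric"} changes it
#' independently each cycle with probability \code{1/tau2} (making them
#' statistical, with mean inter-change interval \code{tau2}).
#'
#' @param n1 Number of fast-sector bits (non-negative integer).
#' @param n2 Number of slow-sector bits (non-negative integer);
#'   \code{n1 + n2 >= 1}.
#' @param tau2 Mean number of cycles between slow-sector changes (>= 1).
#' @param schedule \code{"periodic"} or \code{"geometric"}.
#' @param cycles Total number of sensation--action cycles (>= 1).
#' @param seed Integer seed; identical specs with identical seeds generate
#'   bitwise-identical streams.
#' @return An object of class \code{"stream_spec"}.
#' @seealso [generate_stream()]
#' @export
stream_spec <- function(n1, n2, tau2, schedule = c("periodic", "geometric"),
                        cycles, seed = 1L) {
  n1 <- check_scalar(n1, "n1", lower = 0, integer = TRUE)
  n2 <- check_scalar(n2, "n2", lower = 0, integer = TRUE)
  if (n1 + n2 < 1L) stop_field("n1", "n1 + n2 must be at least 1")
  tau2 <- check_scalar(tau2, "tau2", lower = 1)
  schedule <- match.arg(schedule)
  cycles <- check_scalar(cycles, "cycles", lower = 1, integer = TRUE)
  seed <- check_scalar(seed, "seed", integer = TRUE)
  structure(list(n1 = n1, n2 = n2, tau2 = tau2, schedule = schedule,
                 cycles = cycles, seed = seed),
            class = "stream_spec")
}

#' Generate a two-timescale sensory bit stream
#'
#' Realises the environment described by a [stream_spec()]: the fast sector
#' is resampled uniformly at random on every cycle; the slow sector is
#' resampled only on change cycles. Change cycles are the multiples of
#' \code{round(tau2)} under the periodic schedule, or occur with per-cycle
#' probability \code{1/tau2} under the geometric schedule. The first cycle
#' always counts as a change (the initial slow state must be read once).
#'
#' @param spec A [stream_spec()].
#' @return An object of class \code{"input_stream"}: a list with the
#'   \code{spec}, a \code{cycles x (n1+n2)} integer matrix \code{frames}
#'   (fast bits in columns \code{1..n1}, slow bits after), and a logical
#'   vector \code{change_flags} marking cycles where the slow sector differs
#'   from the previous cycle.
#' @examples
#' s <- generate_stream(stream_spec(4, 4, tau2 = 4, "periodic", cycles = 12))
#' which(s$change_flags)  # cycles 1, 5, 9 (1-based; multiples of 4, 0-based)
#' @export
generate_stream <- function(spec) {
  if (!inherits(spec, "stream_spec")) stop_field("spec", "not a stream_spec")
  n <- spec$n1 + spec$n2
  frames <- matrix(0L, nrow = spec$cycles, ncol = n)
  with_seed(substream_seed(spec$seed, "envstream"), {
    if (spec$n1 > 0) {
      frames[, seq_len(spec$n1)] <-
        matrix(sample(0:1, spec$cycles * spec$n1, replace = TRUE),
               nrow = spec$cycles)
    }
    change <- if (spec$schedule == "periodic") {
      period <- max(1L, as.integer(round(spec$tau2)))
      ((seq_len(spec$cycles) - 1L) %% period) == 0L
    } else {
      c(TRUE, stats::runif(spec$cycles - 1L) < 1 / spec$tau2)
    }
    if (spec$n2 > 0) {
      s2 <- integer(spec$n2)
      cols <- spec$n1 + seq_len(spec$n2)
      for (t in seq_len(spec$cycles)) {
        if (change[t]) s2 <- sample(0:1, spec$n2, replace = TRUE)
        frames[t, cols] <- s2
      }
      # a resample may reproduce the previous state; flags record actual
      # change events (resampling), which is what the detector pays for
    }
    structure(list(spec = spec, frames = frames, change_flags = change),
              class = "input_stream")
  })
}

#' @export
print.input_stream <- function(x, ...) {
  cat(sprintf(
    "<input_stream> %d cycles, n1=%d fast + n2=%d slow bits, tau2=%g (%s), %d slow-sector changes\n",
    x$spec$cycles, x$spec$n1, x$spec$n2, x$spec$tau2, x$spec$schedule,
    sum(x$change_flags)))
  invisible(x)
}

#' Convert a stream to a data frame (CSV-ready)
#'
#' Columns: \code{cycle} (0-based), \code{s1_bits} and \code{s2_bits} as
#' bitstrings, \code{s2_changed} (0/1).
#'
#' @param x An \code{input_stream}.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @export
as.data.frame.input_stream <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  bits_to_str <- function(m) {
    if (ncol(m) == 0) return(rep("", nrow(m)))
    apply(m, 1, paste0, collapse = "")
  }
  s1 <- x$frames[, seq_len(x$spec$n1), drop = FALSE]
  s2 <- x$frames[, x$spec$n1 + seq_len(x$spec$n2), drop = FALSE]
  data.frame(cycle = seq_len(x$spec$cycles) - 1L,
             s1_bits = bits_to_str(s1),
             s2_bits = bits_to_str(s2),
             s2_changed = as.integer(x$change_flags),
             stringsAsFactors = FALSE)
}
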
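# Start/stop-codon gating of codon streams, and percussion highlighting.
#
# A stop codon silences the audio of the reading frame in which it occurs
# (the stop slot itself is a rest); depending on the mode the frame stays
# silent until an in-frame ATG, or additionally resumes after a fixed number
# of silent codons. An ATG reaching a silent frame is mapped to a regular
# note and switches the audio back on. Silenced slots become rests, never
# deleted, so gating never changes the onset schedule.

START_CODON <- "ATG"
STOP_CODONS <- c("TGA", "TAA", "TAG")

GATE_MODES <- c("restart-on-atg", "silent-until-atg", "restart-after-10",
                "ignore")

codon_class_of <- function(motif) {
  ifelse(motif == START_CODON, "start",
         ifelse(motif %in% STOP_CODONS, "stop", "normal"))
}

#' Gate a codon stream with the start/stop-codon state machine
#'
#' Modes:
#' \describe{
#'   \item{restart-on-atg}{(default) frames start audible unless the first
#'     codon is a stop; a stop silences the frame until an in-frame ATG.}
#'   \item{silent-until-atg}{as above, but frames start silent until the
#'     first in-frame ATG.}
#'   \item{restart-after-10}{frames start audible; after a stop, audio
#'     resumes unconditionally at the `(restart_window + 1)`-th following
#'     codon (no ATG required; an earlier ATG also resumes it), the counter
#'     resetting on each new stop.}
#'   \item{ignore}{no gating; stop codons sound as normal codons.}
#' }
#'
#' @param stream A codon `motif_stream` (3-bp motifs; see [parse_codons()]).
#' @param mode One of the four gate modes above.
#' @param restart_window Codons of silence before resumption under
#'   `restart-after-10` (default 10).
#' @return A `gated_stream`: the input stream whose slots gain `audible`
#'   (logical) and `codon_class` (`start`/`stop`/`normal`) columns. Slot
#'   count and positions are unchanged.
#' @export
gate_stream <- function(stream, mode = GATE_MODES, restart_window = 10L) {
  mode <- match.arg(mode)
  stopifnot(inherits(stream, "motif_stream"), restart_window >= 1L)
  if (stream$motif_size != 3L)
    stop("gating applies to codon (3-bp) streams only", call. = FALSE)
  motifs <- stream$slots$motif
  cls <- codon_class_of(motifs)
  n <- length(motifs)
  audible <- logical(n)
  if (mode == "ignore") {
    audible[] <- TRUE
  } else {
    on <- mode != "silent-until-atg"
    since_stop <- NA_integer_  # codons elapsed since the most recent stop
    for (i in seq_len(n)) {
      if (cls[i] == "stop") {
        audible[i] <- FALSE
        on <- FALSE
        since_stop <- 0L
      } else {
        if (!on) {
          if (cls[i] == "start") {
            on <- TRUE
          } else if (mode == "restart-after-10" && !is.na(since_stop) &&
                     since_stop >= restart_window) {
            on <- TRUE
          }
        }
        audible[i] <- on
        if (!is.na(since_stop)) since_stop <- since_stop + 1L
      }
    }
  }
  stream$slots$audible <- audible
  stream$slots$codon_class <- cls
  stream$gate_mode <- mode
  class(stream) <- c("gated_stream", class(stream))
  stream
}

#' @export
print.gated_stream <- function(x, ...) {
  cat(sprintf("<gated_stream> frame %d, %d slot(s), %d audible, mode '%s'\n",
              x$frame, nrow(x$slots), sum(x$slots$audible), x$gate_mode))
  invisible(x)
}

# General MIDI drum keys for the highlight sounds.
DRUM_MAP <- data.frame(
  motif = c("ATG", "TGA", "TAA", "TAG"),
  drum = c("Electric Snare", "Crash Cymbal 1", "Chinese Cymbal", "Ride Bell"),
  drum_key = c(40L, 49L, 52L, 53L),
  stringsAsFactors = FALSE
)

#' Percussion highlight events for start/stop codons
#'
#' Emits one percussion event per ATG / TGA / TAA / TAG codon slot across
#' the given streams, irrespective of the slot's audibility and additional
#' to the melodic note: ATG as an Electric Snare, TGA a Crash Cymbal, TAA a
#' Chinese Cymbal, TAG the Ride Bell.
#'
#' @param streams A codon `motif_stream`/`gated_stream` or a list of them
#'   (all three frames for the reading-frame algorithm; the single parsed
#'   frame otherwise).
#' @param enabled If `FALSE`, returns an empty event set.
#' @return Data frame with `frame`, `base_position`, `motif`, `codon_class`,
#'   `drum`, `drum_key`.
#' @export
highlight_events <- function(streams, enabled = TRUE) {
  if (inherits(streams, "motif_stream")) streams <- list(streams)
  empty <- data.frame(frame = integer(), base_position = integer(),
                      motif = character(), codon_class = character(),
                      drum = character(), drum_key = integer(),
                      stringsAsFactors = FALSE)
  if (!enabled) return(empty)
  out <- lapply(streams, function(st) {
    if (st$motif_size != 3L)
      stop("highlighting applies to codon-based algorithms only", call. = FALSE)
    hit <- st$slots$motif %in% DRUM_MAP$motif
    if (!any(hit)) return(empty)
    m <- match(st$slots$motif[hit], DRUM_MAP$motif)
    data.frame(frame = st$frame,
               base_position = st$slots$base_position[hit],
               motif = st$slots$motif[hit],
               codon_class = codon_class_of(st$slots$motif[hit]),
               drum = DRUM_MAP$drum[m], drum_key = DRUM_MAP$drum_key[m],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$base_position, out$frame), , drop = FALSE]
}
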
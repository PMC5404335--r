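# Score assembly: merge per-frame streams into a single timed event list.
#
# Timing is anchored to base positions: an event sounds at
# (base_position - 1) / tempo_bp_s seconds. For the three-reading-frame
# algorithm this 1-bp stagger of codon starts is what produces the
# characteristic arpeggiated triplet phrasing — frame f contributes events
# at base positions congruent to f modulo 3 — and silencing a frame leaves
# rest beats in place of its instrument without shifting anything else.

INSTRUMENTS <- c("piano", "guitar", "organ")  # instrument slots 1-3

new_score <- function(events, percussion, tempo_bp_s, algorithm,
                      seq_length, scale) {
  events <- events[order(events$onset_s, events$frame), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, percussion = percussion,
                 tempo_bp_s = tempo_bp_s, algorithm = algorithm,
                 seq_length = seq_length, scale = scale,
                 total_span_s = seq_length / tempo_bp_s),
            class = "sonification_score")
}

#' @export
print.sonification_score <- function(x, ...) {
  n_note <- sum(x$events$event_type == "note")
  n_rest <- sum(x$events$event_type == "rest")
  cat(sprintf(paste0("<sonification_score> '%s': %d note(s), %d rest(s), ",
                     "%d percussion hit(s)\n  %d bp at %g bp/s = %.1f s\n"),
              x$algorithm, n_note, n_rest,
              if (is.null(x$percussion)) 0L else nrow(x$percussion),
              x$seq_length, x$tempo_bp_s, x$total_span_s))
  invisible(x)
}

# Events of one (possibly gated) stream. Slots with NA identifiers
# (ambiguous motifs) and inaudible slots become rests.
stream_events <- function(stream, scale, tempo_bp_s, duration_s) {
  sl <- stream$slots
  audible <- if ("audible" %in% names(sl)) sl$audible else rep(TRUE, nrow(sl))
  audible <- audible & !is.na(sl$identifier)
  cls <- if ("codon_class" %in% names(sl)) sl$codon_class else
    rep("n/a", nrow(sl))
  pitch <- rep(NA_integer_, nrow(sl))
  if (any(audible))
    pitch[audible] <- identifier_to_pitch(scale, sl$identifier[audible])
  data.frame(
    onset_s = (sl$base_position - 1) / tempo_bp_s,
    duration_s = duration_s,
    frame = stream$frame,
    base_position = sl$base_position,
    motif = sl$motif,
    identifier = sl$identifier,
    midi_pitch = pitch,
    instrument = INSTRUMENTS[stream$instrument_slot],
    event_type = ifelse(audible, "note", "rest"),
    codon_class = cls,
    stringsAsFactors = FALSE
  )
}

#' Interlace gated reading-frame streams into a score
#'
#' Frames are offset by one base, so their codon starts alternate and the
#' pooled events form an arpeggiated triplet. Each frame plays its own
#' instrument (frame 1 piano, 2 guitar, 3 organ). The nominal note duration
#' is one base (1/tempo seconds) so concurrent frames do not overlap;
#' `sustain` stretches it for listenability without moving onsets.
#'
#' @param gated_frames List of 1-3 `gated_stream`s with distinct frames.
#' @param scale A [build_scale()] mapping shared by the instruments.
#' @param tempo_bp_s Sonification rate in base pairs per second (default 6).
#' @param highlight Optional percussion events ([highlight_events()]).
#' @param sustain Note-duration multiplier (default 1).
#' @return A `sonification_score`.
#' @export
interlace <- function(gated_frames, scale = NULL, tempo_bp_s = 6,
                      highlight = NULL, sustain = 1) {
  if (inherits(gated_frames, "motif_stream")) gated_frames <- list(gated_frames)
  frames <- vapply(gated_frames, `[[`, integer(1L), "frame")
  if (anyDuplicated(frames))
    stop("duplicate frame indices in interlace()", call. = FALSE)
  if (is.null(scale))
    scale <- build_scale(base_midi_note = default_base_note(
      max(vapply(gated_frames, `[[`, integer(1L), "step_range"))))
  dur <- sustain / tempo_bp_s
  ev <- do.call(rbind, lapply(gated_frames, stream_events,
                              scale = scale, tempo_bp_s = tempo_bp_s,
                              duration_s = dur))
  L <- max(ev$base_position + 2L)  # codon streams: last covered base
  perc <- finish_percussion(highlight, tempo_bp_s, dur)
  new_score(ev, perc, tempo_bp_s, "reading-frames", L, scale)
}

finish_percussion <- function(highlight, tempo_bp_s, dur) {
  if (is.null(highlight) || nrow(highlight) == 0L) return(NULL)
  highlight$onset_s <- (highlight$base_position - 1) / tempo_bp_s
  highlight$duration_s <- dur
  highlight
}

#' Schedule a single motif stream as a score
#'
#' Used by the mono / di / tri-nucleotide and protein-sequence algorithms
#' (and both streams of the di-nucleotide pairs variant): onsets at
#' `(base_position - 1) / tempo`, duration one motif, so the base-pair rate
#' is the same across algorithms.
#'
#' @param streams A `motif_stream` or list of them (distinct instrument
#'   slots).
#' @param scale A [build_scale()] mapping; defaults to the stream's step
#'   range placed as high as the 128-note range allows.
#' @param tempo_bp_s Base pairs per second (default 6).
#' @param algorithm Label stored on the score.
#' @param highlight Optional percussion events.
#' @return A `sonification_score`.
#' @export
schedule_single_stream <- function(streams, scale = NULL, tempo_bp_s = 6,
                                   algorithm = "mono", highlight = NULL) {
  if (inherits(streams, "motif_stream")) streams <- list(streams)
  if (is.null(scale))
    scale <- build_scale(base_midi_note = default_base_note(
      max(vapply(streams, `[[`, integer(1L), "step_range"))))
  k <- streams[[1L]]$motif_size
  ev <- do.call(rbind, lapply(streams, stream_events, scale = scale,
                              tempo_bp_s = tempo_bp_s,
                              duration_s = k / tempo_bp_s))
  L <- max(ev$base_position + k - 1L)
  perc <- finish_percussion(highlight, tempo_bp_s, k / tempo_bp_s)
  new_score(ev, perc, tempo_bp_s, algorithm, L, scale)
}

#' Minimal period of an identifier stream
#'
#' Smallest p >= 1 such that `x[i] == x[i + p]` for every valid i, found by
#' brute-force scan; the period of the repeating note pattern a listener
#' hears. A homopolymer stream has period 1; a stream with all-distinct
#' values has period `length(x)`.
#'
#' @param x Non-empty vector (identifiers; `NA`s compare equal to `NA`).
#' @return Integer period.
#' @export
minimal_period <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty identifier stream", call. = FALSE)
  key <- ifelse(is.na(x), "<NA>", as.character(x))  # NA matches NA
  for (p in seq_len(n))
    if (all(key[seq_len(n - p)] == key[seq_len(n - p) + p])) return(p)
  n
}

#' Silent sections of a score
#'
#' Maximal time intervals, of at least `min_gap_s`, during which no audible
#' melodic note is sounding in any frame (percussion highlights are ignored:
#' they may still strike inside a silent passage).
#'
#' @param score A `sonification_score`.
#' @param min_gap_s Minimum section length in seconds (> 0).
#' @return Data frame with `start_s`, `end_s` (possibly zero rows).
#' @export
silent_sections <- function(score, min_gap_s = 1) {
  stopifnot(inherits(score, "sonification_score"), min_gap_s > 0)
  notes <- score$events[score$events$event_type == "note", , drop = FALSE]
  span <- score$total_span_s
  if (nrow(notes) == 0L)
    return(data.frame(start_s = 0, end_s = span))
  notes <- notes[order(notes$onset_s), , drop = FALSE]
  gaps <- data.frame(start_s = numeric(), end_s = numeric())
  # leading gap, gaps between note coverage, trailing gap
  cov_end <- 0
  for (i in seq_len(nrow(notes))) {
    if (notes$onset_s[i] > cov_end)
      gaps <- rbind(gaps, data.frame(start_s = cov_end,
                                     end_s = notes$onset_s[i]))
    cov_end <- max(cov_end, notes$onset_s[i] + notes$duration_s[i])
  }
  if (span > cov_end)
    gaps <- rbind(gaps, data.frame(start_s = cov_end, end_s = span))
  gaps[gaps$end_s - gaps$start_s >= min_gap_s, , drop = FALSE]
}

# ---- high-level front door --------------------------------------------------

ALGORITHMS <- c("mono", "di", "di-pairs", "tri", "protein", "reading-frames")

#' Sonify a DNA sequence
#'
#' Runs one of the six sonification algorithms end to end and returns a
#' timed score renderable to MIDI ([write_midi()]) or to a note-event table
#' ([write_event_table()]).
#'
#' Algorithms: `mono` (4 notes), `di` (16), `di-pairs` (two staggered
#' 16-note streams on two instruments), `tri` (64, non-degenerate),
#' `protein` (codons collapsed to 20 notes by the genetic code) and
#' `reading-frames` (all three frames as degenerate codon streams on piano,
#' guitar and organ, with start/stop gating). Start/stop gating applies only
#' to `reading-frames`; percussion highlighting of start/stop codons only to
#' the codon-based algorithms (`tri`, `protein`, `reading-frames`).
#'
#' @param seq A [dna_seq()], raw base string, or path handled upstream.
#' @param algorithm One of the six algorithm names.
#' @param gate Gate mode for `reading-frames` (see [gate_stream()]).
#' @param highlight Sonify start/stop codons with percussion.
#' @param tempo_bp_s Base pairs per second (default 6).
#' @param key_root Key root pitch class (default 0 = C).
#' @param intervals Scale intervals (default blues scale `3,2,1,1,3,2`).
#' @param base_midi_note Octave placement of identifier 1; default per
#'   algorithm is the highest multiple of 12 keeping every pitch <= 127.
#' @param restart_window Silent codons before resumption under
#'   `restart-after-10`.
#' @param sustain Duration multiplier for reading-frame notes.
#' @return A `sonification_score`.
#' @examples
#' sc <- sonify(tandem_repeat("CCATT", 12), algorithm = "reading-frames",
#'              gate = "ignore")
#' sc
#' @export
sonify <- function(seq, algorithm = ALGORITHMS,
                   gate = GATE_MODES, highlight = FALSE,
                   tempo_bp_s = 6, key_root = 0L,
                   intervals = c(3L, 2L, 1L, 1L, 3L, 2L),
                   base_midi_note = NULL, restart_window = 10L,
                   sustain = 1) {
  algorithm <- match.arg(algorithm)
  gate <- match.arg(gate)
  seq <- as_dna_seq(seq)
  if (highlight && !algorithm %in% c("tri", "protein", "reading-frames"))
    stop("highlighting start/stop codons requires a codon-based algorithm ",
         "(tri, protein or reading-frames), not '", algorithm, "'",
         call. = FALSE)
  mk_scale <- function(step_range) build_scale(
    key_root, intervals,
    if (is.null(base_midi_note))
      default_base_note(step_range, key_root, intervals)
    else base_midi_note)

  switch(algorithm,
    mono = schedule_single_stream(parse_mono(seq), mk_scale(4L),
                                  tempo_bp_s, "mono"),
    di = schedule_single_stream(parse_di(seq), mk_scale(16L),
                                tempo_bp_s, "di"),
    "di-pairs" = {
      streams <- parse_di_pairs(seq)
      schedule_single_stream(streams, mk_scale(16L), tempo_bp_s, "di-pairs")
    },
    tri = {
      st <- parse_codons(seq, 1L)
      schedule_single_stream(st, mk_scale(64L), tempo_bp_s, "tri",
                             highlight = highlight_events(st, highlight))
    },
    protein = {
      st <- parse_codons(seq, 1L)
      stp <- apply_degenerate(st)
      schedule_single_stream(stp, mk_scale(stp$step_range), tempo_bp_s,
                             "protein",
                             highlight = highlight_events(st, highlight))
    },
    "reading-frames" = {
      streams <- lapply(1:3, function(f) apply_degenerate(parse_codons(seq, f)))
      gated <- lapply(streams, gate_stream, mode = gate,
                      restart_window = restart_window)
      interlace(gated, mk_scale(streams[[1L]]$step_range), tempo_bp_s,
                highlight = highlight_events(streams, highlight),
                sustain = sustain)
    })
}
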
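# Standard MIDI File (SMF format 1) serialization.
#
# Layout: one conductor track carrying the tempo, one track per melodic
# instrument slot in use, and one percussion track (channel 10) when
# highlight events are present. One beat is one codon (three bases), so at
# the default 6 bp/s a beat lasts 0.5 s; onsets are quantized to the tick
# grid (480 ticks per beat by default, i.e. 160 ticks per base). Rests
# produce no messages. Rendering is deterministic: identical score and
# config give a byte-identical file.

#' MIDI render configuration
#'
#' @param ticks_per_beat SMF division (default 480).
#' @param programs General MIDI program numbers for the three melodic
#'   instrument slots (defaults: Acoustic Grand Piano 0, Nylon Guitar 24,
#'   Drawbar Organ 16).
#' @param channels Zero-based MIDI channels for slots 1-3 (default 0, 1, 2).
#' @param percussion_channel Zero-based drum channel (default 9, i.e. MIDI
#'   channel 10).
#' @param velocity Note-on velocity 1-127 (default 96).
#' @return A `render_config` object.
#' @export
render_config <- function(ticks_per_beat = 480L,
                          programs = c(piano = 0L, guitar = 24L, organ = 16L),
                          channels = c(0L, 1L, 2L),
                          percussion_channel = 9L,
                          velocity = 96L) {
  stopifnot(ticks_per_beat >= 24L, all(programs %in% 0:127),
            all(channels %in% 0:15), percussion_channel %in% 0:15,
            velocity %in% 1:127,
            !percussion_channel %in% channels)
  structure(list(ticks_per_beat = as.integer(ticks_per_beat),
                 programs = programs, channels = as.integer(channels),
                 percussion_channel = as.integer(percussion_channel),
                 velocity = as.integer(velocity)),
            class = "render_config")
}

# ---- byte helpers ----------------------------------------------------------

uint32_be <- function(x) as.raw(c(x %/% 16777216L, (x %/% 65536L) %% 256L,
                                  (x %/% 256L) %% 256L, x %% 256L))
uint16_be <- function(x) as.raw(c(x %/% 256L, x %% 256L))

# variable-length quantity (7 bits per byte, high bit = continuation)
vlq_encode <- function(x) {
  stopifnot(x >= 0)
  bytes <- x %% 128L
  x <- x %/% 128L
  while (x > 0L) {
    bytes <- c(x %% 128L, bytes)
    x <- x %/% 128L
  }
  n <- length(bytes)
  if (n > 1L) bytes[seq_len(n - 1L)] <- bytes[seq_len(n - 1L)] + 128L
  as.raw(bytes)
}

smf_track <- function(event_bytes) {
  c(charToRaw("MTrk"), uint32_be(length(event_bytes)), event_bytes)
}

# events: data.frame(tick, bytes = list of raw); emits delta-encoded stream
# with an end-of-track meta at the final tick
encode_events <- function(events, end_tick) {
  out <- raw(0)
  t <- 0L
  if (nrow(events) > 0L) {
    for (i in seq_len(nrow(events))) {
      out <- c(out, vlq_encode(events$tick[i] - t), events$bytes[[i]])
      t <- events$tick[i]
    }
  }
  c(out, vlq_encode(max(end_tick - t, 0L)), as.raw(c(0xFF, 0x2F, 0x00)))
}

#' Write a score as a standard MIDI file
#'
#' @param score A [sonify()] score.
#' @param path Output path (`.mid`).
#' @param config A [render_config()].
#' @return Number of bytes written, invisibly.
#' @export
write_midi <- function(score, path, config = render_config()) {
  stopifnot(inherits(score, "sonification_score"),
            inherits(config, "render_config"))
  tpb <- config$ticks_per_beat
  sec_per_beat <- 3 / score$tempo_bp_s     # one beat = one codon
  tick_of <- function(s) as.integer(round(s / sec_per_beat * tpb))

  notes <- score$events[score$events$event_type == "note", , drop = FALSE]
  if (nrow(notes) > 0L && any(notes$midi_pitch > 127L | notes$midi_pitch < 0L))
    stop("MIDI pitch out of 0-127", call. = FALSE)
  end_tick <- tick_of(score$total_span_s)

  # conductor track: tempo meta (microseconds per beat)
  usec <- as.integer(round(sec_per_beat * 1e6))
  tempo_ev <- data.frame(tick = 0L)
  tempo_ev$bytes <- list(as.raw(c(0xFF, 0x51, 0x03, usec %/% 65536L,
                                  (usec %/% 256L) %% 256L, usec %% 256L)))
  tracks <- list(smf_track(encode_events(tempo_ev, end_tick)))

  slots <- sort(unique(match(notes$instrument, INSTRUMENTS)))
  for (slot in slots) {
    ch <- config$channels[slot]
    ns <- notes[notes$instrument == INSTRUMENTS[slot], , drop = FALSE]
    on_t <- tick_of(ns$onset_s)
    off_t <- pmax(tick_of(ns$onset_s + ns$duration_s), on_t + 1L)
    ev <- data.frame(tick = c(0L, on_t, off_t),
                     prio = c(-1L, rep(1L, nrow(ns)), rep(0L, nrow(ns))))
    ev$bytes <- c(list(as.raw(c(0xC0 + ch, config$programs[slot]))),
                  lapply(seq_len(nrow(ns)), function(i)
                    as.raw(c(0x90 + ch, ns$midi_pitch[i], config$velocity))),
                  lapply(seq_len(nrow(ns)), function(i)
                    as.raw(c(0x80 + ch, ns$midi_pitch[i], 0L))))
    ev <- ev[order(ev$tick, ev$prio), , drop = FALSE]  # offs before ons
    tracks <- c(tracks, list(smf_track(encode_events(ev, end_tick))))
  }

  pc <- score$percussion
  if (!is.null(pc) && nrow(pc) > 0L) {
    ch <- config$percussion_channel
    on_t <- tick_of(pc$onset_s)
    off_t <- pmax(tick_of(pc$onset_s + pc$duration_s), on_t + 1L)
    ev <- data.frame(tick = c(on_t, off_t),
                     prio = c(rep(1L, nrow(pc)), rep(0L, nrow(pc))))
    ev$bytes <- c(lapply(seq_len(nrow(pc)), function(i)
                    as.raw(c(0x90 + ch, pc$drum_key[i], config$velocity))),
                  lapply(seq_len(nrow(pc)), function(i)
                    as.raw(c(0x80 + ch, pc$drum_key[i], 0L))))
    ev <- ev[order(ev$tick, ev$prio), , drop = FALSE]
    tracks <- c(tracks, list(smf_track(encode_events(ev, end_tick))))
  }

  header <- c(charToRaw("MThd"), uint32_be(6L), uint16_be(1L),
              uint16_be(length(tracks)), uint16_be(tpb))
  bytes <- c(header, unlist(tracks))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(bytes, con)
  invisible(length(bytes))
}

# ---- reader ----------------------------------------------------------------

vlq_decode <- function(bytes, pos) {
  val <- 0L
  repeat {
    b <- as.integer(bytes[pos]); pos <- pos + 1L
    val <- val * 128L + (b %% 128L)
    if (b < 128L) break
  }
  list(value = val, pos = pos)
}

#' Read a standard MIDI file
#'
#' Parses an SMF (format 0 or 1) into per-track event tables. Note-on
#' messages with velocity 0 are reported as note-offs, and running status is
#' handled, so files from other writers parse too.
#'
#' @param path Path to a `.mid` file.
#' @return List with `format`, `division`, `tempo_usec_per_beat` and
#'   `tracks`: one data frame per track with columns `tick`, `type`
#'   (`note_on`/`note_off`/`program`/`other`), `channel`, `data1`, `data2`.
#' @export
read_midi <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  stopifnot(rawToChar(bytes[1:4]) == "MThd")
  fmt <- as.integer(bytes[9]) * 256L + as.integer(bytes[10])
  ntrk <- as.integer(bytes[11]) * 256L + as.integer(bytes[12])
  division <- as.integer(bytes[13]) * 256L + as.integer(bytes[14])
  pos <- 15L
  tempo <- NA_integer_
  tracks <- vector("list", ntrk)
  for (k in seq_len(ntrk)) {
    stopifnot(rawToChar(bytes[pos:(pos + 3L)]) == "MTrk")
    len <- sum(as.integer(bytes[pos + 4:7]) * c(16777216L, 65536L, 256L, 1L))
    pos <- pos + 8L
    end <- pos + len
    tick <- 0L
    status <- NA_integer_
    rows <- list()
    while (pos < end) {
      d <- vlq_decode(bytes, pos); pos <- d$pos
      tick <- tick + d$value
      b <- as.integer(bytes[pos])
      if (b >= 128L) { status <- b; pos <- pos + 1L } # else running status
      if (status == 0xFF) {
        type <- as.integer(bytes[pos]); pos <- pos + 1L
        ml <- vlq_decode(bytes, pos); pos <- ml$pos
        if (type == 0x51)
          tempo <- sum(as.integer(bytes[pos + 0:2]) * c(65536L, 256L, 1L))
        pos <- pos + ml$value
        status <- NA_integer_  # meta/sysex cancel running status
      } else if (status %in% c(0xF0, 0xF7)) {
        ml <- vlq_decode(bytes, pos); pos <- ml$pos
        pos <- pos + ml$value
        status <- NA_integer_
      } else {
        hi <- status %/% 16L
        ch <- status %% 16L
        n_data <- if (hi %in% c(0xC, 0xD)) 1L else 2L
        d1 <- as.integer(bytes[pos])
        d2 <- if (n_data == 2L) as.integer(bytes[pos + 1L]) else NA_integer_
        pos <- pos + n_data
        type <- if (hi == 0x9 && d2 > 0L) "note_on"
                else if (hi == 0x9 || hi == 0x8) "note_off"
                else if (hi == 0xC) "program" else "other"
        rows[[length(rows) + 1L]] <-
          data.frame(tick = tick, type = type, channel = ch,
                     data1 = d1, data2 = d2, stringsAsFactors = FALSE)
      }
    }
    tracks[[k]] <- if (length(rows)) do.call(rbind, rows) else
      data.frame(tick = integer(), type = character(), channel = integer(),
                 data1 = integer(), data2 = integer(), stringsAsFactors = FALSE)
  }
  list(format = fmt, division = division, tempo_usec_per_beat = tempo,
       tracks = tracks)
}

#' Note-on events of a parsed MIDI file
#'
#' @param midi Result of [read_midi()].
#' @return Data frame of note-on events across tracks: `track`, `tick`,
#'   `channel`, `pitch`, `velocity`, sorted by `(tick, track)`.
#' @export
midi_notes <- function(midi) {
  out <- do.call(rbind, lapply(seq_along(midi$tracks), function(k) {
    tr <- midi$tracks[[k]]
    tr <- tr[tr$type == "note_on", , drop = FALSE]
    if (nrow(tr) == 0L) return(NULL)
    data.frame(track = k, tick = tr$tick, channel = tr$channel,
               pitch = tr$data1, velocity = tr$data2)
  }))
  if (is.null(out))
    return(data.frame(track = integer(), tick = integer(),
                      channel = integer(), pitch = integer(),
                      velocity = integer()))
  out[order(out$tick, out$track), , drop = FALSE]
}
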
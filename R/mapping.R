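# Motif-identifier parsing and the identifier -> pitch scale mapping.
#
# Every algorithm reduces the sequence to a stream of motif identifiers
# (1-based), which a scale mapping turns into MIDI pitches. Identifier 1
# always lands on the root note of the key; the default scale is a six-note
# blues scale (semitone intervals 3, 2, 1, 1, 3, 2 within each 12-semitone
# octave), so identifier 7 is the root one octave up, and so on.

BASE_ORDER <- c("G", "A", "T", "C")

#' Build a scale mapping
#'
#' @param key_root Pitch class of the key root, 0-11 (0 = C, default).
#' @param intervals Positive semitone intervals between consecutive scale
#'   degrees; must sum to 12. Default `c(3, 2, 1, 1, 3, 2)` (blues scale).
#' @param base_midi_note MIDI note of identifier 1 before the key offset;
#'   must satisfy `(base_midi_note %% 12) == 0` so that identifier 1 has the
#'   key root's pitch class. Default 60 (middle C octave).
#' @return A `scale_mapping` object.
#' @examples
#' sc <- build_scale()
#' identifier_to_pitch(sc, 1:6)  # 60 63 65 66 67 70
#' @export
build_scale <- function(key_root = 0L, intervals = c(3L, 2L, 1L, 1L, 3L, 2L),
                        base_midi_note = 60L) {
  stopifnot(key_root %in% 0:11, all(intervals >= 1L),
            base_midi_note %in% 0:127, base_midi_note %% 12L == 0L)
  if (sum(intervals) != 12L)
    stop("scale intervals must sum to 12 (one octave), got ",
         sum(intervals), call. = FALSE)
  structure(list(
    key_root = as.integer(key_root),
    intervals = as.integer(intervals),
    degree_offsets = c(0L, cumsum(as.integer(intervals))[-length(intervals)]),
    degrees_per_octave = length(intervals),
    base_midi_note = as.integer(base_midi_note)
  ), class = "scale_mapping")
}

#' Map motif identifiers to MIDI pitches
#'
#' Identifier i sits at 0-based scale degree `(i - 1) %% d` in octave
#' `(i - 1) %/% d`, where d is the number of degrees per octave (6 for the
#' default blues scale). Pitch = base + key root + 12 * octave + degree
#' offset. `NA` identifiers (ambiguous motifs) map to `NA`.
#'
#' @param scale A [build_scale()] mapping.
#' @param identifier Vector of positive integers (or `NA`).
#' @return Integer MIDI pitches in 0-127; errors on overflow.
#' @export
identifier_to_pitch <- function(scale, identifier) {
  stopifnot(inherits(scale, "scale_mapping"))
  ok <- !is.na(identifier)
  if (any(identifier[ok] < 1L)) stop("identifiers must be >= 1", call. = FALSE)
  d <- scale$degrees_per_octave
  i0 <- identifier - 1L
  pitch <- scale$base_midi_note + scale$key_root +
    12L * (i0 %/% d) + scale$degree_offsets[(i0 %% d) + 1L]
  if (any(pitch[ok] > 127L))
    stop(sprintf("identifier %d maps to pitch %d > 127; lower base_midi_note",
                 max(identifier[ok]), max(pitch[ok])), call. = FALSE)
  as.integer(pitch)
}

# Largest multiple of 12 keeping the top identifier of an algorithm within
# the 128-note MIDI range (the 64-step algorithm therefore starts at 0,
# spanning roughly ten octaves).
default_base_note <- function(step_range, key_root = 0L,
                              intervals = c(3L, 2L, 1L, 1L, 3L, 2L)) {
  probe <- build_scale(key_root, intervals, 0L)
  top <- identifier_to_pitch(probe, as.integer(step_range))
  12L * ((127L - top) %/% 12L)
}

# ---- motif identifier assignment -------------------------------------------

# Lexicographic identifier over base order G, A, T, C: GG..G = 1.
motif_identifier <- function(motifs, k) {
  idx <- function(ch) match(ch, BASE_ORDER)  # NA for sentinel bases
  id <- integer(length(motifs))
  for (j in seq_len(k)) {
    d <- idx(substr(motifs, j, j))
    id <- id * 4L + (d - 1L)
  }
  ifelse(is.na(id), NA_integer_, id + 1L)
}

#' All motifs of a given size in identifier order
#'
#' @param k Motif size in bp (1, 2 or 3).
#' @return Character vector of the 4^k motifs; element i has identifier i.
#' @export
enumerate_motifs <- function(k) {
  stopifnot(k %in% 1:3)
  grids <- rev(rep(list(BASE_ORDER), k))
  do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
}

new_motif_stream <- function(frame, base_position, motif, identifier,
                             motif_size, step_range, instrument_slot = 1L) {
  structure(list(
    frame = as.integer(frame),
    motif_size = as.integer(motif_size),
    step_range = as.integer(step_range),
    instrument_slot = as.integer(instrument_slot),
    slots = data.frame(base_position = as.integer(base_position),
                       motif = motif, identifier = as.integer(identifier),
                       stringsAsFactors = FALSE)
  ), class = "motif_stream")
}

#' @export
print.motif_stream <- function(x, ...) {
  cat(sprintf("<motif_stream> frame %d, %d-bp motifs, %d slot(s), step range %d\n",
              x$frame, x$motif_size, nrow(x$slots), x$step_range))
  invisible(x)
}

# Shared k-mer chopper: adjacent, non-overlapping motifs from a start base;
# trailing bases that do not fill a motif are dropped.
chop <- function(seq, k, start) {
  L <- seq$length
  n <- (L - start + 1L) %/% k
  if (n < 1L)
    stop(sprintf("sequence too short (%d bp) for %d-bp motifs from base %d",
                 L, k, start), call. = FALSE)
  pos <- start + k * (seq_len(n) - 1L)
  motifs <- substring(seq$bases, pos, pos + k - 1L)
  list(pos = pos, motifs = motifs)
}

#' Parse mono-nucleotides
#'
#' One slot per base; identifiers 1-4 in base order G, A, T, C, so a
#' sequence exercises at most four notes.
#'
#' @param seq A [dna_seq()] or raw string.
#' @return A `motif_stream`.
#' @export
parse_mono <- function(seq) {
  seq <- as_dna_seq(seq)
  ch <- chop(seq, 1L, 1L)
  new_motif_stream(1L, ch$pos, ch$motifs, motif_identifier(ch$motifs, 1L),
                   motif_size = 1L, step_range = 4L)
}

#' Parse di-nucleotides
#'
#' Adjacent non-overlapping 2-bp motifs starting at base `1 + offset`;
#' identifiers 1-16, lexicographic over base order G, A, T, C.
#'
#' @param seq A [dna_seq()] or raw string.
#' @param offset 0 (default) or 1: shift of the sonification frame.
#' @return A `motif_stream` (frame `1 + offset`).
#' @export
parse_di <- function(seq, offset = 0L) {
  stopifnot(offset %in% c(0L, 1L))
  seq <- as_dna_seq(seq)
  ch <- chop(seq, 2L, 1L + offset)
  new_motif_stream(1L + offset, ch$pos, ch$motifs,
                   motif_identifier(ch$motifs, 2L),
                   motif_size = 2L, step_range = 16L,
                   instrument_slot = 1L + offset)
}

#' Parse di-nucleotides in two staggered frames
#'
#' The second stream advances the whole sonification frame by one base and
#' plays on a second instrument, roughly doubling the number of notes;
#' dimers shared between the frames map to equal identifiers.
#'
#' @param seq A [dna_seq()] or raw string (length >= 3).
#' @return A list of two `motif_stream`s (offsets 0 and 1).
#' @export
parse_di_pairs <- function(seq) {
  seq <- as_dna_seq(seq)
  list(parse_di(seq, 0L), parse_di(seq, 1L))
}

#' Parse codons in a reading frame
#'
#' Adjacent non-overlapping 3-bp motifs starting at base `frame`;
#' identifiers 1-64 (non-degenerate), lexicographic over base order
#' G, A, T, C. Use [apply_degenerate()] to collapse to genetic-code classes.
#'
#' @param seq A [dna_seq()] or raw string.
#' @param frame Reading frame, 1, 2 or 3 (frame f starts at base f).
#' @return A `motif_stream`.
#' @export
parse_codons <- function(seq, frame = 1L) {
  stopifnot(frame %in% 1:3)
  seq <- as_dna_seq(seq)
  ch <- chop(seq, 3L, as.integer(frame))
  new_motif_stream(frame, ch$pos, ch$motifs, motif_identifier(ch$motifs, 3L),
                   motif_size = 3L, step_range = 64L,
                   instrument_slot = as.integer(frame))
}

# ---- degenerate (genetic-code) mapping -------------------------------------

#' Degenerate codon table
#'
#' Maps all 64 codons to 21 classes — the 20 amino acids plus one stop
#' class — following the standard genetic code, and assigns each class a
#' motif identifier. The anchors of the default assignment: Met(ATG) is
#' identifier 1 (root note, C in the key of C), Asp (GAC/GAT) identifier 3
#' (an F), the stop class identifier 5 (a G, the pitch TGA receives when
#' stops are sonified as normal codons). The remaining 18 amino acids fill
#' the free identifiers in alphabetical order of one-letter code.
#'
#' @param met Identifier for Met/ATG (default 1).
#' @param asp Identifier for Asp (default 3).
#' @param stop_id Identifier for the stop class (default 5).
#' @return A `codon_table`: data frame with `codon`, `class` (one-letter
#'   amino acid or `"*"`), `identifier`.
#' @export
codon_table <- function(met = 1L, asp = 3L, stop_id = 5L) {
  gc <- Biostrings::GENETIC_CODE  # named chr: codon -> one-letter aa or "*"
  classes <- sort(unique(gc))                       # "*" plus 20 aa letters
  stopifnot(length(classes) == 21L)
  ids <- integer(length(classes)); names(ids) <- classes
  ids[["M"]] <- met; ids[["D"]] <- asp; ids[["*"]] <- stop_id
  rest <- setdiff(classes, c("M", "D", "*"))        # alphabetical already
  free <- setdiff(seq_len(21L), c(met, asp, stop_id))
  stopifnot(length(free) == length(rest))
  ids[rest] <- free
  structure(data.frame(codon = names(gc), class = unname(gc),
                       identifier = unname(ids[gc]),
                       stringsAsFactors = FALSE),
            class = c("codon_table", "data.frame"))
}

#' Degenerate identifier of codons
#'
#' Synonymous codons share an identifier; stop codons return the stop
#' class's identifier. `NA` for motifs containing ambiguous bases.
#'
#' @param codon Character vector of 3-bp motifs.
#' @param table A [codon_table()].
#' @return Integer identifiers.
#' @export
degenerate_identifier <- function(codon, table = codon_table()) {
  table$identifier[match(codon, table$codon)]
}

#' Collapse a codon stream to genetic-code classes
#'
#' Replaces the 64-step identifiers of a [parse_codons()] stream with the
#' degenerate identifiers of the 20-note mapping.
#'
#' @param stream A codon `motif_stream`.
#' @param table A [codon_table()].
#' @return The stream with degenerate identifiers (step range 21).
#' @export
apply_degenerate <- function(stream, table = codon_table()) {
  stopifnot(inherits(stream, "motif_stream"), stream$motif_size == 3L)
  stream$slots$identifier <- degenerate_identifier(stream$slots$motif, table)
  stream$step_range <- max(table$identifier)
  stream
}

#' Export a motif -> identifier -> pitch mapping table
#'
#' @param motif_size 1, 2 or 3; for `degenerate = TRUE` the 3-bp codon table.
#' @param degenerate Use the genetic-code mapping for codons.
#' @param scale A [build_scale()] mapping (its base determines the octave).
#' @param path Optional TSV output path.
#' @return Data frame with `motif`, `identifier`, `midi_pitch` (invisibly if
#'   written to `path`).
#' @export
mapping_table <- function(motif_size = 3L, degenerate = FALSE,
                          scale = build_scale(
                            base_midi_note = default_base_note(
                              if (degenerate) 21L else 4L^motif_size)),
                          path = NULL) {
  motifs <- enumerate_motifs(motif_size)
  id <- if (degenerate) degenerate_identifier(motifs)
        else motif_identifier(motifs, motif_size)
  tab <- data.frame(motif = motifs, identifier = id,
                    midi_pitch = identifier_to_pitch(scale, id),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
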
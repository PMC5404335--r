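# Generators for the classes of test sequences used throughout: simple
# homopolymers, tandem repeats (telomeric TTAGGG, alphoid CCATT, AT- or
# GC-only units), mutated variants, and G-backbone constructs carrying stop
# codons in chosen reading frames.

#' Homopolymer sequence
#'
#' @param base One of `"G"`, `"A"`, `"T"`, `"C"`.
#' @param n Length in bp (>= 1).
#' @param id Identifier.
#' @return A [dna_seq()].
#' @examples
#' homopolymer("G", 6)$bases  # "GGGGGG"
#' @export
homopolymer <- function(base, n, id = paste0(base, "-sequence")) {
  stopifnot(base %in% c("G", "A", "T", "C"), n >= 1L)
  dna_seq(strrep(base, n), id = id)
}

#' Tandem repeat sequence
#'
#' Repeats a unit a given number of times, e.g. the telomeric hexanucleotide
#' `TTAGGG` or the alphoid pentanucleotide `CCATT`.
#'
#' @param unit Non-empty GATC string.
#' @param copies Number of copies (>= 1).
#' @param id Identifier.
#' @return A [dna_seq()].
#' @examples
#' tandem_repeat("TTAGGG", 2)$bases  # "TTAGGGTTAGGG"
#' @export
tandem_repeat <- function(unit, copies,
                          id = sprintf("(%s)x%d", unit, copies)) {
  stopifnot(is.character(unit), nchar(unit) >= 1L, copies >= 1L)
  if (grepl("[^GATC]", toupper(unit))) stop("unit must be GATC-only", call. = FALSE)
  dna_seq(strrep(toupper(unit), copies), id = id)
}

#' Mutation specification
#'
#' @param kind `"substitution"`, `"insertion"` or `"deletion"`.
#' @param position 1-based bp position at which the edit applies.
#' @param bases Replacement/inserted bases (substitution and insertion).
#' @param length For substitution: number of reference bases replaced
#'   (default 1); for deletion: number of bases removed (default 1).
#' @return A `mutation_spec` object.
#' @export
mutation_spec <- function(kind = c("substitution", "insertion", "deletion"),
                          position, bases = NULL, length = 1L) {
  kind <- match.arg(kind)
  stopifnot(position >= 1L, length >= 1L)
  if (kind != "deletion") {
    if (is.null(bases) || nchar(bases) == 0L)
      stop(kind, " requires non-empty bases", call. = FALSE)
    if (grepl("[^GATC]", toupper(bases)))
      stop("mutation bases must be GATC-only", call. = FALSE)
    bases <- toupper(bases)
  }
  structure(list(kind = kind, position = as.integer(position),
                 bases = bases, length = as.integer(length)),
            class = "mutation_spec")
}

#' Apply mutations to a sequence
#'
#' Specs are applied left-to-right in list order; each position is
#' interpreted against the current (already mutated) sequence, so a length
#' change made by an earlier edit shifts the coordinates seen by later ones.
#' A substitution replacing k bases by m bases changes the length by m - k —
#' e.g. replacing the `T` at position 1 of `TTAGGG` by `AG` gives `AGTAGGG`.
#'
#' @param seq A [dna_seq()] or raw string.
#' @param specs A `mutation_spec` or list of them.
#' @return The mutated [dna_seq()].
#' @export
apply_mutations <- function(seq, specs) {
  seq <- as_dna_seq(seq)
  if (inherits(specs, "mutation_spec")) specs <- list(specs)
  s <- seq$bases
  for (sp in specs) {
    L <- nchar(s)
    if (sp$position > L)
      stop(sprintf("mutation position %d beyond sequence length %d",
                   sp$position, L), call. = FALSE)
    pre <- substr(s, 1L, sp$position - 1L)
    s <- switch(sp$kind,
      substitution = {
        if (sp$position + sp$length - 1L > L)
          stop("substitution runs past sequence end", call. = FALSE)
        paste0(pre, sp$bases, substr(s, sp$position + sp$length, L))
      },
      insertion = paste0(pre, sp$bases, substr(s, sp$position, L)),
      deletion = {
        if (sp$position + sp$length - 1L > L)
          stop("deletion runs past sequence end", call. = FALSE)
        paste0(pre, substr(s, sp$position + sp$length, L))
      })
  }
  dna_seq(s, id = paste0(seq$id, "|mut"))
}

#' G-backbone sequence with stop codons in chosen reading frames
#'
#' Builds a G homopolymer carrying one stop codon (default `TAA`) embedded at
#' a codon boundary of each requested reading frame, separated by
#' `pad_codons` all-G codons, and optionally followed by an in-frame-1 `ATG`
#' after all stops. The injected codon positions (1-based bp of the codon's
#' first base) are returned alongside the sequence.
#'
#' Frame f starts at base f, so a codon boundary of frame f lies at base
#' positions congruent to f modulo 3.
#'
#' @param frames Subset of `c(1, 2, 3)`: frames to receive a stop codon.
#' @param pad_codons All-G codons between injected features (>= 1).
#' @param start_in_frame1 If `TRUE`, append an `ATG` at a frame-1 codon
#'   boundary after all stops.
#' @param stop_codon The stop codon to inject (default `"TAA"`).
#' @return A list with elements `seq` ([dna_seq()]), `stop_positions` (named
#'   by frame) and `start_position` (or `NA`).
#' @export
stop_codon_sequence <- function(frames = 1L, pad_codons = 3L,
                                start_in_frame1 = FALSE,
                                stop_codon = "TAA") {
  stopifnot(all(frames %in% 1:3), pad_codons >= 1L,
            stop_codon %in% c("TAA", "TAG", "TGA"))
  frames <- sort(unique(as.integer(frames)))
  s <- strrep("G", 3L * pad_codons)
  stop_pos <- integer(0)
  for (f in frames) {
    # advance to the next codon boundary of frame f strictly after current end
    pos <- nchar(s) + 1L
    while ((pos - f) %% 3L != 0L) pos <- pos + 1L
    s <- paste0(s, strrep("G", pos - nchar(s) - 1L), stop_codon,
                strrep("G", 3L * pad_codons))
    stop_pos <- c(stop_pos, pos)
  }
  names(stop_pos) <- as.character(frames)
  start_pos <- NA_integer_
  if (start_in_frame1) {
    pos <- nchar(s) + 1L
    while ((pos - 1L) %% 3L != 0L) pos <- pos + 1L
    s <- paste0(s, strrep("G", pos - nchar(s) - 1L), "ATG",
                strrep("G", 3L * pad_codons))
    start_pos <- pos
  }
  # injections are sequential, so a later stop can never overwrite an earlier
  # one; verify anyway so construction errors surface here
  for (i in seq_along(stop_pos))
    stopifnot(substr(s, stop_pos[i], stop_pos[i] + 2L) == stop_codon)
  list(seq = dna_seq(s, id = sprintf("G-with-stop-frames-%s",
                                     paste(frames, collapse = ""))),
       stop_positions = stop_pos, start_position = start_pos)
}
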
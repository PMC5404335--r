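#' Validated DNA sequence
#'
#' Constructs a `dna_seq` object: an upper-case DNA string over the alphabet
#' G/A/T/C (plus `N` as the ambiguity sentinel in lenient mode) together with
#' an identifier. All parsing functions in the package read the sequence in
#' the 5' to 3' direction.
#'
#' @param bases Character scalar of bases (already normalized; see
#'   [clean_sequence()] for normalization of raw input).
#' @param id Identifier label for the sequence.
#' @param n_ambiguous Number of ambiguous positions replaced by `N` during
#'   cleaning (bookkeeping only).
#' @return An object of class `dna_seq` with fields `id`, `bases`, `length`.
#' @export
dna_seq <- function(bases, id = "seq", n_ambiguous = 0L) {
  stopifnot(is.character(bases), length(bases) == 1L)
  if (nchar(bases) < 1L)
    stop("sequence '", id, "' is empty after cleaning", call. = FALSE)
  if (grepl("[^GATCN]", bases))
    stop("sequence contains characters outside GATCN; use clean_sequence()",
         call. = FALSE)
  structure(
    list(id = as.character(id), bases = bases, length = nchar(bases),
         n_ambiguous = as.integer(n_ambiguous)),
    class = "dna_seq"
  )
}

#' @export
print.dna_seq <- function(x, ...) {
  preview <- if (x$length > 60L) paste0(substr(x$bases, 1L, 57L), "...") else x$bases
  cat(sprintf("<dna_seq> %s (%d bp)\n  %s\n", x$id, x$length, preview))
  if (x$n_ambiguous > 0L)
    cat(sprintf("  %d ambiguous base(s) replaced by N\n", x$n_ambiguous))
  invisible(x)
}

#' @export
length.dna_seq <- function(x) x$length

# Accept either a dna_seq or a raw string everywhere downstream.
as_dna_seq <- function(x, mode = "lenient") {
  if (inherits(x, "dna_seq")) return(x)
  clean_sequence(x, mode = mode)
}

#' Normalize and validate a raw base string
#'
#' Uppercases, converts RNA `U` to `T`, and strips whitespace and digits
#' (so pasted sequence with coordinates is accepted). What happens to any
#' remaining non-GATC character depends on `mode`:
#' \describe{
#'   \item{strict}{the first offending character is reported with its 1-based
#'     position (after stripping) and an error is raised;}
#'   \item{lenient}{each offending character is replaced by the sentinel `N`.
#'     Any motif containing an `N` later renders as a rest, and the number of
#'     replacements is recorded on the object and reported as a warning.}
#' }
#'
#' @param raw Character scalar: raw sequence text.
#' @param mode `"lenient"` (default) or `"strict"`.
#' @param id Identifier for the resulting sequence.
#' @return A [dna_seq()] object.
#' @examples
#' clean_sequence("gg g\n3 ttt")$bases  # "GGGTTT"
#' clean_sequence("AUGC")$bases         # "ATGC"
#' @export
clean_sequence <- function(raw, mode = c("lenient", "strict"), id = "seq") {
  mode <- match.arg(mode)
  stopifnot(is.character(raw), length(raw) == 1L)
  s <- toupper(raw)
  s <- gsub("[[:space:][:digit:]]", "", s)
  s <- gsub("U", "T", s, fixed = TRUE)
  if (nchar(s) == 0L)
    stop("sequence '", id, "' is empty after cleaning", call. = FALSE)
  bad <- gregexpr("[^GATC]", s)[[1L]]
  n_bad <- if (bad[1L] == -1L) 0L else length(bad)
  if (n_bad > 0L) {
    if (mode == "strict") {
      pos <- bad[1L]
      stop(sprintf("invalid base '%s' at position %d in sequence '%s'",
                   substr(s, pos, pos), pos, id), call. = FALSE)
    }
    warning(sprintf("%d ambiguous base(s) in '%s' replaced by N (will render as rests)",
                    n_bad, id), call. = FALSE)
    s <- gsub("[^GATC]", "N", s)
  }
  dna_seq(s, id = id, n_ambiguous = n_bad)
}

#' Read DNA sequences from a FASTA file
#'
#' Reads a (multi-record, wrapped or unwrapped) FASTA file and normalizes
#' every record through [clean_sequence()]. Record order is preserved.
#'
#' @param path Path to a FASTA file with at least one record.
#' @param mode Validation mode passed to [clean_sequence()].
#' @return A list of [dna_seq()] objects.
#' @export
read_fasta <- function(path, mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  if (!file.exists(path))
    stop("FASTA file not found: ", path, call. = FALSE)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L)
    stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(recs))
  mapply(function(s, id) clean_sequence(s, mode = mode, id = id),
         as.character(recs), ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs A `dna_seq` or list of `dna_seq` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "dna_seq")) seqs <- list(seqs)
  set <- Biostrings::BStringSet(vapply(seqs, `[[`, character(1L), "bases"))
  names(set) <- vapply(seqs, `[[`, character(1L), "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a score as a tab-separated note-event table
#'
#' One row per event (melodic notes, rests, and percussion highlights), with
#' columns `onset_s`, `duration_s`, `frame`, `base_position` (1-based),
#' `motif`, `identifier`, `midi_pitch` (empty for rests and percussion),
#' `instrument`, `event_type` (`note`/`rest`/`percussion`) and `codon_class`
#' (`start`/`stop`/`normal`/`n/a`). Rows are sorted by `(onset_s, frame)`.
#'
#' @param score A [sonify()] score.
#' @param path Output path for the TSV.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(score, path) {
  tab <- event_table(score)
  if (nrow(tab) == 0L) stop("score has no events", call. = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Event table of a score as a data frame
#'
#' @inheritParams write_event_table
#' @return A data frame, one row per event (see [write_event_table()]).
#' @export
event_table <- function(score) {
  stopifnot(inherits(score, "sonification_score"))
  ev <- score$events
  mel <- data.frame(
    onset_s = ev$onset_s, duration_s = ev$duration_s, frame = ev$frame,
    base_position = ev$base_position, motif = ev$motif,
    identifier = ev$identifier,
    midi_pitch = ifelse(ev$event_type == "note", ev$midi_pitch, NA_integer_),
    instrument = ev$instrument, event_type = ev$event_type,
    codon_class = ev$codon_class, stringsAsFactors = FALSE
  )
  pc <- score$percussion
  if (!is.null(pc) && nrow(pc) > 0L) {
    perc <- data.frame(
      onset_s = pc$onset_s, duration_s = pc$duration_s, frame = pc$frame,
      base_position = pc$base_position, motif = pc$motif,
      identifier = NA_integer_, midi_pitch = NA_integer_,
      instrument = pc$drum, event_type = "percussion",
      codon_class = pc$codon_class, stringsAsFactors = FALSE
    )
    mel <- rbind(mel, perc)
  }
  mel[order(mel$onset_s, mel$frame), , drop = FALSE]
}
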
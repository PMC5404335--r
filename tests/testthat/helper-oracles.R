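# Independent oracles used by the tests; deliberately naive.

# Period of the frame-1 codon identifier stream of a tandem repeat with
# primitive p-bp unit, by the phase argument: codon i covers bases
# 3(i-1)+1..3i, and the base pattern has period p, so the codon stream
# repeats after lcm(p, 3) bases = lcm(p, 3)/3 codons.
lcm2 <- function(a, b) a * b / gcd2(a, b)
gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
oracle_repeat_period <- function(unit_len) lcm2(unit_len, 3) / 3

# Brute-force interlace: independently list every frame's events with their
# own onsets, pool, and sort by (onset, frame). Returns onset/frame/pitch of
# audible notes only.
oracle_interlace_notes <- function(gated_frames, scale, tempo_bp_s) {
  rows <- do.call(rbind, lapply(gated_frames, function(g) {
    sl <- g$slots
    data.frame(onset = (sl$base_position - 1) / tempo_bp_s,
               frame = g$frame,
               pitch = ifelse(sl$audible & !is.na(sl$identifier),
                              identifier_to_pitch(scale, sl$identifier),
                              NA_integer_))
  }))
  rows <- rows[!is.na(rows$pitch), , drop = FALSE]
  rows <- rows[order(rows$onset, rows$frame), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

# Random GATC sequence of length n (callers fix the RNG seed).
random_bases <- function(n) paste(sample(c("G", "A", "T", "C"), n,
                                         replace = TRUE), collapse = "")
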
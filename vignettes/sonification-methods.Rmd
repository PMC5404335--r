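---
title: "How sonifyDNA turns sequence into sound: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How sonifyDNA turns sequence into sound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonifyDNA)
```

## The model

`sonifyDNA` treats a DNA sequence as a time series to be rendered as sound.
The model has three layers:

1. **Motif parsing.** The sequence is read 5'→3' and chopped into adjacent,
   non-overlapping motifs of 1, 2 or 3 bp; trailing bases that do not fill a
   motif are dropped. Each motif gets an integer identifier: for the
   non-degenerate algorithms, the lexicographic rank over the base order
   G, A, T, C (so GG…G is always identifier 1); for the degenerate codon
   algorithms, the genetic-code class (amino acid or stop) of the codon.
2. **Pitch mapping.** Identifier *i* becomes a MIDI pitch on a configurable
   scale, by default a six-note blues scale (intervals 3, 2, 1, 1, 3, 2
   semitones per octave) in the key of C: identifier 1 is the key root,
   identifiers wrap into higher octaves every six steps. This is a pure
   auditory-display mapping, chosen for discriminability rather than
   musicality: every motif class keeps its own pitch, with no note-reduction
   tricks.
3. **Scheduling.** An event sounds at `(base_position - 1) / tempo` seconds.
   For the three-reading-frame algorithm, frames 1–3 start at bases 1, 2
   and 3, so their codon starts interleave one base apart and the pooled
   stream is an arpeggiated triplet (piano, guitar, organ). This 1-bp
   stagger *is* the arpeggiation: no separate arpeggio timer exists, which
   is the only scheme that simultaneously yields the triplet phrasing and
   the "note separated by two rest beats" texture when two frames are
   silenced.

The biological reading: the three concurrent codon streams emulate the
three possible translation frames, and the start/stop gating mimics — very
loosely — initiation and termination. An uninterrupted frame is the audible
signature of an open reading frame; scattered stops in all frames (typical
of non-coding or AT-rich sequence) produce sparse, silence-ridden displays.
No promoter context, Kozak context or codon usage enters the model.

## Start/stop gating

Gating is a per-frame state machine over codon classes (ATG = start;
TGA/TAA/TAG = stop). A stop codon silences its own frame from the stop slot
onward — the stop slot itself is a rest — and leaves other frames untouched.
Silenced slots become rests, never deletions, so gating can never shift the
onset schedule (a property the tests enforce). The four modes:

* `restart-on-atg` (default): frames start audible (unless the very first
  codon is a stop); a silent frame re-arms on the next in-frame ATG, and
  that ATG slot itself sounds (it is a Met note as well as a switch).
* `silent-until-atg`: identical machine, but the initial state is silent.
* `restart-after-10`: after a stop, audio resumes unconditionally at the
  11th following codon (`restart_window = 10`, configurable), the counter
  resetting on each new stop; an ATG inside the window also resumes it. We
  read the mode names as exclusive: `restart-on-atg` does *not* carry the
  10-codon timer, which keeps the two modes distinguishable on ATG-free
  sequence (AT-only repeats stay silent forever under one, resume under the
  other).
* `ignore`: no gating; stops sound as ordinary codons.

Percussion highlighting is orthogonal to gating: when enabled, every
ATG/TGA/TAA/TAG codon slot fires a drum hit (Electric Snare / Crash /
Chinese Cymbal / Ride Bell, General MIDI keys 40/49/52/53) regardless of
whether its frame is audible — that is what makes stop clusters in silenced
frames detectable. For `reading-frames` all three frames are scanned; for
the single-frame codon algorithms only the parsed frame (there is no other
frame in their streams). Highlighting is rejected for `mono` and `di`,
which have no codons.

## The degenerate codon table

The genetic code has 21 classes (20 amino acids + stop). The identifier
assignment is anchored at three audible landmarks: Met/ATG = identifier 1
(the root, a C in the key of C), Asp = 3 (an F), stop = 5 (a G — the pitch
a TGA takes when stops are sonified as normal codons). The remaining 18
amino acids fill the free identifiers 1–21 in alphabetical order of
one-letter code. Only the three anchors are semantically meaningful; the
alphabetical fill is an arbitrary but fixed convention, exposed through
`codon_table()` for anyone who wants a different layout. The codon→class
map itself is taken from the standard genetic code (`Biostrings`), never
retyped.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `tempo_bp_s` | 6 | bases/s | slow enough to perceive individual notes; a 1 kb sequence ≈ 2.8 min |
| `intervals` | 3,2,1,1,3,2 | semitones | six-note blues scale; must sum to 12 |
| `key_root` | 0 (C) | pitch class | anchors identifier 1 |
| `base_midi_note` | per algorithm | MIDI note | largest multiple of 12 keeping the top identifier ≤ 127, so the 64-step algorithm spans ~10 octaves from MIDI 0 while the 4-step one sits in a single high octave; override per call to match an instrument's register |
| `restart_window` | 10 | codons | resumption delay of `restart-after-10` |
| `sustain` | 1 | × 1 bp | note length for reading-frame notes; 1 bp keeps concurrent frames from overlapping |
| velocity, programs, drum keys | 96; 0/24/16; 40/49/52/53 | GM numbers | General MIDI realization of piano/guitar/organ and the four named drums |

MIDI timing uses one beat per codon (0.5 s at 6 bp/s), 480 ticks per beat,
so one base is 160 ticks and every onset lands exactly on the tick grid at
the default tempo; at other tempi onsets are rounded to the nearest tick.

## Degenerate inputs and numerical choices

* Cleaning uppercases, maps RNA U→T, strips whitespace/digits. In `strict`
  mode any other character is an error naming the 1-based offending
  position; in `lenient` mode (default) it becomes the sentinel `N` and any
  motif containing an `N` renders as a rest, with a warning count. Lenient
  is the default so long real-world sequences with occasional ambiguity
  codes stay playable.
* Sequences shorter than one motif (per frame) are an error, not an empty
  score.
* A note-off is always scheduled at least one tick after its note-on, so
  zero-length notes cannot arise from rounding.
* `minimal_period` is a brute-force scan (smallest `p` with
  `x[i] == x[i+p]` for all valid `i`); streams here are a few hundred
  elements, so O(n²) is irrelevant and the transparency is worth it. `NA`
  identifiers compare equal to `NA` so ambiguous motifs do not destroy
  periodicity.
* `silent_sections` measures gaps in melodic note coverage only; percussion
  may strike inside a "silent" section by design.

## What the fixture generator emulates — and what it does not

The generator builds the *classes* of sequence the displays are meant to
distinguish: homopolymers (`homopolymer`), tandem repeats with known unit
length (`tandem_repeat` — telomeric TTAGGG, alphoid-style CCATT, AT- or
GC-only 8-bp units), point and frameshift mutations at stated coordinates
(`apply_mutations`, applied left-to-right against the current sequence),
and G-backbone constructs with stop codons planted at chosen frame
boundaries (`stop_codon_sequence`, default stop TAA, optionally followed by
an in-frame-1 ATG). These make every gating and periodicity behavior
testable from first principles: the expected codon-stream period of a
primitive p-bp repeat is lcm(p, 3)/3 by a phase argument, and the tests
check the brute-force scan against that closed form.

What the fixtures do **not** reproduce: real genes. A genuine exon, rRNA
or telomeric clone carries base composition, codon-usage bias and mutation
spectra that the synthetic constructs lack, so passing tests show the
*mechanisms* (frame silencing, restart windows, repeat periods, frameshift
re-mapping) are correct — not that any particular published display is
reproduced note for note. Users supply real sequences as FASTA.

## Problem sizes

The test-suite and acceptance computations run at desk scale by design:
repeats of 9–50 copies (60–300 bp), gating constructs under 100 codons,
random-sequence properties at 60–120 bp over ~10 replicates with fixed
seeds. Every behavior checked is length-invariant (periods, state-machine
transitions, schedule arithmetic), so nothing is gained by larger inputs.

## Known limitations

* Forward strand only; no reverse-complement display.
* Standard genetic code only (no mitochondrial or plastid variants).
* One note per motif — no chords, dynamics, or duration coding; this is an
  analytical display, deliberately minimal.
* MIDI output is symbolic; audio rendering (WAV/MP3) is left to external
  synthesizers.
* `sonify_file` processes a single FASTA record per run.
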
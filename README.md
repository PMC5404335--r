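# sonifyDNA

Sonification of DNA sequences into MIDI auditory displays.

Visual inspection of a DNA sequence is poor at revealing reading-frame
structure, tandem-repeat periodicity, and frameshifts. `sonifyDNA` maps a
sequence onto sound so those features become audible: open reading frames
play as uninterrupted melodic lines, stop codons switch instruments off,
repeats produce strict rhythmic cycles, and a frameshift is heard as the
repeating phrase jumping to different notes. The output is a standard MIDI
file (playable in any sequencer) plus a machine-readable note-event table,
so the displays can be both listened to and analysed numerically. It is
aimed at teaching and at exploratory inspection of short sequences (on the
order of a kilobase, a few minutes of audio).

## The mapping

Each algorithm chops the sequence 5'→3' into adjacent, non-overlapping
motifs and assigns each motif an identifier *i* ≥ 1, which becomes a pitch
on a six-note blues scale (semitone intervals 3, 2, 1, 1, 3, 2 within each
octave) in the key of C:

    pitch(i) = base + 12 * ((i - 1) div 6) + offset[(i - 1) mod 6],
    offset = (0, 3, 5, 6, 7, 10)

so identifier 1 is the key root and identifier 7 the root an octave up. The
six algorithms differ in the motif space:

| algorithm        | motif | identifiers | frames (instruments) |
|------------------|-------|-------------|----------------------|
| `mono`           | 1 bp  | 4           | 1                    |
| `di`             | 2 bp  | 16          | 1                    |
| `di-pairs`       | 2 bp  | 16          | 2 (staggered 1 bp)   |
| `tri`            | 3 bp  | 64          | 1                    |
| `protein`        | 3 bp  | 20 + stop   | 1 (genetic-code degenerate) |
| `reading-frames` | 3 bp  | 20 + stop   | 3 (piano, guitar, organ) |

Under the degenerate mappings synonymous codons share a note; the table is
anchored so ATG (Met) sounds a C, GAC/GAT (Asp) an F and the stop class a G.
For `reading-frames` the three frames are staggered by one base, giving an
arpeggiated triplet at the default rate of 6 bp/s, and stop codons gate
their own frame's audio: modes `restart-on-atg` (default),
`silent-until-atg`, `restart-after-10` (resume after 10 silent codons) and
`ignore`. Start/stop codons can additionally be struck on percussion
(snare for ATG; crash, Chinese cymbal and ride bell for TGA, TAA, TAG).

## Worked example

```r
library(sonifyDNA)

telomere <- tandem_repeat("TTAGGG", 50, id = "human-telomeric")
mutated  <- apply_mutations(telomere,
                            mutation_spec("substitution", 79, "AG"))
score <- sonify(mutated, algorithm = "reading-frames", gate = "ignore")
score
#> <sonification_score> 'reading-frames': 299 note(s), 0 rest(s), 0 percussion hit(s)
#>   301 bp at 6 bp/s = 50.2 s

# the 6-bp repeat cycles every 2 codons per frame -- until the frameshift
ids <- parse_codons(telomere, 1)$slots$identifier
minimal_period(ids)
#> [1] 2

write_midi(score, "telomere.mid")        # standard MIDI file, 3 instruments
write_event_table(score, "telomere.tsv") # one row per note/rest
```

The `minimal_period` of 2 codons (6 bp) is the audible two-triplet cycle of
an invariant telomeric repeat; after the substitution at bp 79 (one base
replaced by two) the downstream phrase re-maps to different pitches — the
audible signature of a frameshift.

The same pipeline runs from a shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","sonifydna",package="sonifyDNA"))') \
    --fixture telomere --copies 50 --gate ignore --midi-out telomere.mid
```

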
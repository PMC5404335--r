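test_that("interlaced homopolymer frames form a same-pitch triplet cycle", {
  sc <- sonify(homopolymer("G", 30), "reading-frames", gate = "ignore")
  notes <- sc$events[sc$events$event_type == "note", ]
  expect_equal(length(unique(notes$midi_pitch)), 1)  # same note, 3 instruments
  # frame f sounds at base positions congruent to f mod 3
  expect_true(all(notes$base_position %% 3 == notes$frame %% 3))
  # one event per covered base position, onsets spaced one base apart
  expect_equal(diff(sort(unique(notes$onset_s))),
               rep(1 / 6, length(unique(notes$onset_s)) - 1))
  expect_equal(unique(notes$instrument[notes$frame == 1]), "piano")
  expect_equal(unique(notes$instrument[notes$frame == 2]), "guitar")
  expect_equal(unique(notes$instrument[notes$frame == 3]), "organ")
})

test_that("two silenced frames leave notes separated by two rest beats", {
  fx <- stop_codon_sequence(c(2L, 3L), pad_codons = 2)
  sc <- sonify(fx$seq, "reading-frames", gate = "restart-on-atg")
  tail_start <- max(fx$stop_positions) + 3
  tail_ev <- sc$events[sc$events$base_position >= tail_start, ]
  expect_setequal(tail_ev$event_type[tail_ev$frame == 1], "note")
  expect_setequal(tail_ev$event_type[tail_ev$frame != 1], "rest")
  solo <- tail_ev[tail_ev$event_type == "note", ]
  expect_true(all(abs(diff(solo$onset_s) - 3 / 6) < 1e-9))  # every 3rd beat
})

test_that("interlace matches the brute-force pooling oracle", {
  set.seed(17)
  for (i in 1:5) {
    s <- dna_seq(random_bases(66))
    gated <- lapply(1:3, function(f)
      gate_stream(apply_degenerate(parse_codons(s, f)), "restart-on-atg"))
    scale <- build_scale(base_midi_note = 84L)
    sc <- interlace(gated, scale, tempo_bp_s = 6)
    got <- sc$events[sc$events$event_type == "note",
                     c("onset_s", "frame", "midi_pitch")]
    names(got) <- c("onset", "frame", "pitch")
    rownames(got) <- NULL
    expect_equal(got, oracle_interlace_notes(gated, scale, 6))
  }
  expect_error(interlace(list(gate_stream(parse_codons("GGGGGG", 1), "ignore"),
                              gate_stream(parse_codons("GGGGGG", 1), "ignore"))),
               "duplicate frame")
})

test_that("onset schedule depends on sequence and tempo, never on gating", {
  s <- dna_seq(paste0(strrep("G", 15), "TAA", strrep("G", 30)))
  onsets <- lapply(c("ignore", "restart-on-atg", "silent-until-atg",
                     "restart-after-10"), function(m) {
    ev <- sonify(s, "reading-frames", gate = m)$events
    ev[order(ev$frame, ev$base_position), c("onset_s", "frame",
                                            "base_position")]
  })
  for (k in 2:4) expect_equal(onsets[[k]], onsets[[1]])
})

test_that("single-stream scheduling keeps the 6 bp/s rate across motif sizes", {
  s <- homopolymer("G", 60)
  mono <- sonify(s, "mono")
  expect_equal(max(mono$events$onset_s), 59 / 6)  # ~9.833 s
  expect_equal(mono$total_span_s, 10)
  tri <- sonify(s, "tri")
  expect_equal(nrow(tri$events), 20)
  expect_equal(unique(tri$events$duration_s), 0.5)
  expect_equal(tri$total_span_s, 10)
  # tempo rescales everything linearly
  fast <- sonify(s, "mono", tempo_bp_s = 12)
  expect_equal(fast$total_span_s, 5)
})

test_that("minimal_period finds the audible repeat length", {
  ids <- parse_codons(tandem_repeat("CCATT", 12), 1)$slots$identifier
  expect_equal(minimal_period(ids), 5)  # 5 codons = 15 bp
  expect_equal(minimal_period(rep(3L, 40)), 1)
  expect_equal(minimal_period(c(4L, 8L, 15L, 16L)), 4)
  expect_equal(minimal_period(c(1L, 2L, 1L, 2L, 1L)), 2)
  expect_error(minimal_period(integer(0)), "empty")
})

test_that("silent_sections finds gated gaps and nothing else", {
  full <- sonify(homopolymer("G", 60), "reading-frames", gate = "ignore")
  expect_equal(nrow(silent_sections(full, 0.5)), 0)
  # all frames stopped -> exactly one terminal section
  fx <- stop_codon_sequence(1:3, pad_codons = 4)
  sc <- sonify(fx$seq, "reading-frames")
  gaps <- silent_sections(sc, 0.5)
  expect_equal(nrow(gaps), 1)
  expect_equal(gaps$end_s, sc$total_span_s)
  # the section starts once the last audible note has decayed
  notes <- sc$events[sc$events$event_type == "note", ]
  expect_equal(gaps$start_s, max(notes$onset_s + notes$duration_s))
  # restart-after-10 turns the terminal gap into an interior one
  long <- dna_seq(paste0(strrep("G", 30), "TAA", strrep("G", 60)))
  sc2 <- sonify(long, "reading-frames", gate = "restart-after-10")
  gaps2 <- silent_sections(sc2, 0.5)
  expect_equal(nrow(gaps2), 0)  # frames 2,3 keep playing throughout
})

test_that("a point substitution changes at most 3 melodic events per frame", {
  set.seed(29)
  for (i in 1:6) {
    base <- random_bases(90)
    pos <- sample(90, 1)
    alt <- apply_mutations(dna_seq(base),
                           mutation_spec("substitution", pos,
                                         sample(c("G", "A", "T", "C"), 1)))
    a <- sonify(dna_seq(base), "reading-frames", gate = "ignore")$events
    b <- sonify(alt, "reading-frames", gate = "ignore")$events
    for (f in 1:3) {
      pa <- a$midi_pitch[a$frame == f]
      pb <- b$midi_pitch[b$frame == f]
      expect_lte(sum(pa != pb, na.rm = TRUE), 3)
    }
  }
})
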
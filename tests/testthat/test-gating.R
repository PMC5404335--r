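test_that("a frame-1 stop silences only frame 1, from the stop slot onward", {
  fx <- stop_codon_sequence(1L, pad_codons = 4)
  gated <- lapply(1:3, function(f)
    gate_stream(parse_codons(fx$seq, f), "restart-on-atg"))
  g1 <- gated[[1]]$slots
  stop_idx <- which(g1$codon_class == "stop")
  expect_length(stop_idx, 1)
  expect_true(all(g1$audible[seq_len(stop_idx - 1)]))
  expect_false(any(g1$audible[stop_idx:nrow(g1)]))  # stop slot itself rests
  for (f in 2:3) expect_true(all(gated[[f]]$slots$audible))
})

test_that("stops in all frames silence everything; ATG restarts its frame", {
  fx <- stop_codon_sequence(1:3, pad_codons = 4, start_in_frame1 = TRUE)
  gated <- lapply(1:3, function(f)
    gate_stream(parse_codons(fx$seq, f), "restart-on-atg"))
  # after the last stop and before the ATG, no frame is audible
  last_stop <- max(fx$stop_positions)
  for (f in 1:3) {
    sl <- gated[[f]]$slots
    mid <- sl$base_position > last_stop + 2 &
      sl$base_position < fx$start_position
    expect_false(any(sl$audible[mid]))
  }
  # the restarting ATG slot itself sounds, and frame 1 stays on after it
  sl1 <- gated[[1]]$slots
  atg <- which(sl1$base_position == fx$start_position)
  expect_equal(sl1$codon_class[atg], "start")
  expect_true(all(sl1$audible[atg:nrow(sl1)]))
  # frames 2 and 3 have no ATG and stay silent to the end
  for (f in 2:3) {
    sl <- gated[[f]]$slots
    expect_false(any(sl$audible[sl$base_position > last_stop + 2]))
  }
})

test_that("restart-after-10 resumes after exactly the window, reset by stops", {
  s <- dna_seq(paste0(strrep("G", 30), "TAA", strrep("G", 60)))
  g <- gate_stream(parse_codons(s, 1), "restart-after-10")
  sl <- g$slots
  stop_idx <- which(sl$codon_class == "stop")
  after <- sl$audible[(stop_idx + 1):nrow(sl)]
  expect_equal(which(after)[1] - 1, 10)  # 10 rest slots, then audible
  expect_true(all(after[11:length(after)]))
  # a second stop inside the window resets the counter
  s2 <- dna_seq(paste0(strrep("G", 30), "TAA", strrep("G", 9), "TAA",
                       strrep("G", 60)))
  g2 <- gate_stream(parse_codons(s2, 1), "restart-after-10")
  sl2 <- g2$slots
  second_stop <- max(which(sl2$codon_class == "stop"))
  after2 <- sl2$audible[(second_stop + 1):nrow(sl2)]
  expect_equal(which(after2)[1] - 1, 10)
  expect_false(any(sl2$audible[(second_stop - 3):second_stop]))
  # a configurable window is honoured
  g3 <- gate_stream(parse_codons(s, 1), "restart-after-10",
                    restart_window = 3)
  after3 <- g3$slots$audible[(stop_idx + 1):nrow(g3$slots)]
  expect_equal(which(after3)[1] - 1, 3)
})

test_that("silent-until-atg starts silent and switches on at the first ATG", {
  s <- dna_seq(paste0(strrep("G", 12), "ATG", strrep("G", 12)))
  g <- gate_stream(parse_codons(s, 1), "silent-until-atg")
  sl <- g$slots
  atg <- which(sl$codon_class == "start")
  expect_false(any(sl$audible[seq_len(atg - 1)]))
  expect_true(all(sl$audible[atg:nrow(sl)]))
  # with no ATG anywhere the frame never sounds
  g2 <- gate_stream(parse_codons(homopolymer("G", 30), 1), "silent-until-atg")
  expect_false(any(g2$slots$audible))
})

test_that("a leading stop codon silences the frame from its first slot", {
  g <- gate_stream(parse_codons("TAAGGGGGG", 1), "restart-on-atg")
  expect_false(g$slots$audible[1])
})

test_that("gating invariants hold on random sequences", {
  set.seed(5)
  modes <- c("restart-on-atg", "silent-until-atg", "restart-after-10",
             "ignore")
  for (i in 1:10) {
    st <- parse_codons(dna_seq(random_bases(90)), 1)
    for (m in modes) {
      g <- gate_stream(st, m)
      # rest-preservation: slot count and positions never change
      expect_equal(nrow(g$slots), nrow(st$slots))
      expect_equal(g$slots$base_position, st$slots$base_position)
    }
    expect_true(all(gate_stream(st, "ignore")$slots$audible))
  }
  # modes agree when there are no stop codons
  st <- parse_codons(tandem_repeat("GCCGCGGC", 10), 1)  # GC-only: no stops
  expect_equal(gate_stream(st, "restart-on-atg")$slots$audible,
               gate_stream(st, "restart-after-10")$slots$audible)
  expect_true(all(gate_stream(st, "restart-on-atg")$slots$audible))
  expect_false(any(gate_stream(st, "silent-until-atg")$slots$audible))
  # monotonicity: injecting a stop never increases the audible count
  set.seed(9)
  for (i in 1:8) {
    base <- random_bases(60)
    st0 <- parse_codons(dna_seq(base), 1)
    k <- sample(seq_len(nrow(st0$slots)), 1)
    mutated <- paste0(substr(base, 1, 3 * (k - 1)), "TAA",
                      substr(base, 3 * k + 1, 60))
    st1 <- parse_codons(dna_seq(mutated), 1)
    for (m in setdiff(modes, "ignore"))
      expect_lte(sum(gate_stream(st1, m)$slots$audible),
                 sum(gate_stream(st0, m)$slots$audible))
  }
})

test_that("highlight events map start/stop codons to their drums", {
  st <- parse_codons("ATGTGA", 1)
  ev <- highlight_events(st)
  expect_equal(ev$drum, c("Electric Snare", "Crash Cymbal 1"))
  expect_equal(ev$drum_key, c(40, 49))
  expect_equal(ev$base_position, c(1, 4))
  # no start/stop codons -> empty; disabled -> empty
  expect_equal(nrow(highlight_events(parse_codons("GGGGGG", 1))), 0)
  expect_equal(nrow(highlight_events(st, enabled = FALSE)), 0)
  # one Chinese Cymbal per TAA slot
  st2 <- parse_codons(tandem_repeat("TAA", 7), 1)
  ev2 <- highlight_events(st2)
  expect_equal(nrow(ev2), 7)
  expect_equal(unique(ev2$drum), "Chinese Cymbal")
  # emitted irrespective of audibility: a gated (silent) stream still fires
  g <- gate_stream(st2, "restart-on-atg")
  expect_equal(nrow(highlight_events(g)), 7)
  expect_error(highlight_events(parse_di("GGGG")), "codon-based")
})
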
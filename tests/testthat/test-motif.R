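# Degenerate-motif parsing and scanning.

test_that("the channel pore pattern parses into its nine elements", {
  p <- parse_pattern("[S,T]-x-x-T-x-G-[Y,F,L]-G-[D,E]", "CH-6", "VG-channel")
  expect_length(p$elements, 9L)
  kinds <- vapply(p$elements, `[[`, character(1), "kind")
  expect_equal(kinds, c("residue_set", "wildcard", "wildcard", "residue_set",
                        "wildcard", "residue_set", "residue_set",
                        "residue_set", "residue_set"))
  expect_setequal(p$elements[[1]]$residues, c("S", "T"))
  expect_setequal(p$elements[[7]]$residues, c("Y", "F", "L"))
  expect_setequal(p$elements[[9]]$residues, c("D", "E"))
  # the printed form juxtaposes "xT": same element list
  p2 <- parse_pattern("[S,T]-x-xT-x-G-[Y,F,L]-G-[D,E]", "CH-6", "VG-channel")
  expect_equal(p2$elements, p$elements)
})

test_that("bounded repeats and comma-free brackets parse", {
  p <- parse_pattern("G-x-G-x-x-G-x(n)-[DE]", "KEA-11", "KEA",
                     x_n_min = 2L, x_n_max = 7L)
  expect_length(p$elements, 8L)
  gap <- p$elements[[7]]
  expect_equal(gap$kind, "gap")
  expect_equal(gap$min_gap, 2L)
  expect_equal(gap$max_gap, 7L)
  expect_setequal(p$elements[[8]]$residues, c("D", "E"))
  # numeric repeat forms
  expect_equal(parse_pattern("A-x(3)-C")$elements[[2]]$max_gap, 3L)
  expect_equal(parse_pattern("A-x(2,5)-C")$elements[[2]]$min_gap, 2L)
})

test_that("malformed patterns raise errors naming the offending token", {
  expect_error(parse_pattern("[A,G"), "unbalanced bracket")
  expect_error(parse_pattern("A-[]-C"), "empty bracket group")
  expect_error(parse_pattern("A-[B,J]-C"), "non-amino-acid")
  expect_error(parse_pattern("A-x(-C"), "malformed repeat")
  expect_error(parse_pattern("A-x(9,2)-C"), "malformed repeat")
  expect_error(parse_pattern(""), "non-empty")
  err <- tryCatch(parse_pattern("G-[A,G-Y"), error = conditionMessage)
  expect_match(err, "token 2")
})

test_that("the canned library loads all 11 motifs with their families", {
  lib <- motif_library()
  expect_length(lib, 11L)
  fams <- vapply(lib, `[[`, character(1), "family")
  expect_equal(as.integer(table(fams)[c("HAK/KT/KUP", "VG-channel", "HKT",
                                        "KEA")]),
               c(5L, 3L, 2L, 1L))
  # stray "(" of the KEA motif is stripped; gap bounds are configurable
  expect_length(lib[["KEA-11"]]$elements, 8L)
  lib2 <- motif_library(x_n_min = 4L, x_n_max = 9L)
  expect_equal(lib2[["KEA-11"]]$elements[[7]]$max_gap, 9L)
})

test_that("scanning finds the selectivity-filter motif where planted", {
  p6 <- motif_library()[["CH-6"]]
  h <- scan_sequence("STATVGYGD", p6)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 0L)
  expect_equal(h$end, 9L)
  expect_equal(h$matched_text, "STATVGYGD")
  expect_equal(nrow(scan_sequence("AAAA", p6)), 0L)
  h2 <- scan_sequence("STATVGYGDSTATVGYGD", p6)
  expect_equal(h2$start, c(0L, 9L))
  expect_equal(h2$end, c(9L, 18L))
  expect_equal(nrow(scan_sequence("", p6)), 0L)
})

test_that("every reported hit satisfies the hit invariants", {
  lib <- motif_library()
  set.seed(404)
  seq <- paste0(random_seq(40, AA20), "STATVGYGD", random_seq(40, AA20))
  for (p in lib) {
    h <- scan_sequence(seq, p, sequence_id = "s")
    if (nrow(h) == 0L) next
    expect_true(all(h$start >= 0 & h$start < h$end & h$end <= nchar(seq)))
    expect_equal(h$matched_text,
                 substring(seq, h$start + 1L, h$end))
    for (i in seq_len(nrow(h))) {
      re <- scan_sequence(h$matched_text[[i]], p)
      expect_true(any(re$start == 0L))
    }
  }
})

test_that("the ambiguity letter X matches wildcards and gaps only", {
  p6 <- motif_library()[["CH-6"]]
  expect_equal(nrow(scan_sequence("SXATVGYGD", p6)), 1L)  # X at wildcard
  expect_equal(nrow(scan_sequence("XTATVGYGD", p6)), 0L)  # X at [S,T]
  kea <- motif_library()[["KEA-11"]]
  expect_equal(nrow(scan_sequence("GAGAAGXXXD", kea)), 1L)  # X in the gap
  expect_error(scan_sequence("STATVGYG*", p6), "letters")
})

test_that("scanner agrees exactly with the brute-force oracle", {
  set.seed(101)
  for (i in 1:200) {
    p <- random_pattern()
    s <- random_seq(sample(20:120, 1L))
    got <- scan_sequence(s, p)[, c("start", "end")]
    want <- brute_scan(s, p)
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)),
                 info = sprintf("instance %d", i))
  }
})

test_that("mode 'all' enumerates every admissible gap combination", {
  set.seed(77)
  for (i in 1:40) {
    p <- random_pattern()
    s <- random_seq(sample(15:50, 1L))
    got <- scan_sequence(s, p, mode = "all")[, c("start", "end")]
    want <- brute_scan_all(s, p)
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
  }
})

test_that("planted gap-free motifs are always hit over the full interval", {
  set.seed(202)
  lib <- motif_library()
  gapfree <- lib[names(lib) != "KEA-11"]
  for (i in 1:50) {
    p <- gapfree[[sample(length(gapfree), 1L)]]
    m <- sample_motif(p)
    left <- sample(0:60, 1L)
    seq <- paste0(random_seq(left, AA20), m, random_seq(sample(0:60, 1L), AA20))
    h <- scan_sequence(seq, p)
    at <- h[h$start == left, , drop = FALSE]
    expect_equal(nrow(at), 1L)
    expect_equal(at$end, left + nchar(m))
  }
})

test_that("prepending residues shifts hit coordinates exactly", {
  set.seed(303)
  p6 <- motif_library()[["CH-6"]]
  for (i in 1:20) {
    seq <- paste0(random_seq(30, AA20), "STATVGYGD", random_seq(30, AA20))
    k <- sample(1:25, 1L)
    padded <- paste0(random_seq(k, AA20), seq)
    h0 <- scan_sequence(seq, p6)
    h1 <- scan_sequence(padded, p6)
    h1 <- h1[h1$start >= k, , drop = FALSE]
    expect_equal(h1$start, h0$start + k)
    expect_equal(h1$end, h0$end + k)
  }
})

test_that("proteome scanning unions per-sequence hits and checks ids", {
  p6 <- motif_library()["CH-6"]
  recs <- c(a = "STATVGYGDAAAA", b = "AAAAAAA")
  h <- scan_proteome(recs, p6)
  expect_equal(unique(h$sequence_id), "a")
  expect_equal(nrow(h), 1L)
  expect_equal(nrow(scan_proteome(character(0), p6)), 0L)
  dup <- c("STAT", "AAAA"); names(dup) <- c("x", "x")
  expect_error(scan_proteome(dup, p6), "duplicate")
})

test_that("motif language sampling produces strings the pattern matches", {
  set.seed(55)
  lib <- motif_library()
  for (p in lib) {
    for (i in 1:5) {
      m <- sample_motif(p)
      expect_true(any(scan_sequence(m, p)$start == 0L),
                  info = p$pattern_id)
    }
  }
})
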
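# Family assignment, span curation, and the end-to-end screen.

mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(sequence_id = r[[1]], pattern_id = r[[2]], family = r[[3]],
               start = as.integer(r[[4]]), end = as.integer(r[[5]]),
               matched_text = "", stringsAsFactors = FALSE)))
}

test_that("motif-count policy gates candidacy per family", {
  lib <- motif_library()
  hits <- mk_hits(list("s1", "HAK-1", "HAK/KT/KUP", 10, 19),
                  list("s1", "HAK-2", "HAK/KT/KUP", 60, 67),
                  list("s1", "HAK-4", "HAK/KT/KUP", 120, 132),
                  list("s2", "KEA-11", "KEA", 5, 30),
                  list("s3", "HAK-3", "HAK/KT/KUP", 7, 17))
  cand <- assign_family(hits, lib)
  c1 <- cand[cand$sequence_id == "s1", ]
  expect_equal(c1$curation, "kept")
  expect_equal(c1$n_motifs_matched, 3L)
  expect_equal(c1$outermost_span, 122L)
  expect_equal(cand$curation[cand$sequence_id == "s2"], "kept")  # KEA >= 1
  expect_equal(cand$curation[cand$sequence_id == "s3"],
               "discarded_motifs")  # 1 of 5 HAK patterns
  expect_error(assign_family(hits, lib, policy = c(Unknown = 1L)),
               "unknown family")
})

test_that("tandem-pore chains resolve to TPK/KCO, single-pore to channels", {
  lib <- motif_library()
  two_pore <- mk_hits(list("tp", "CH-6", "VG-channel", 10, 19),
                      list("tp", "CH-8", "VG-channel", 40, 51),
                      list("tp", "CH-6", "VG-channel", 80, 89))
  cand <- assign_family(two_pore, lib)
  expect_equal(cand$curation[cand$family == "TPK/KCO"], "kept")
  expect_equal(cand$curation[cand$family == "VG-channel"],
               "discarded_motifs")
  one_pore <- mk_hits(list("vg", "CH-6", "VG-channel", 10, 19),
                      list("vg", "CH-7", "VG-channel", 40, 48),
                      list("vg", "CH-8", "VG-channel", 80, 91))
  cand <- assign_family(one_pore, lib)
  expect_equal(cand$curation[cand$family == "VG-channel"], "kept")
  expect_equal(cand$curation[cand$family == "TPK/KCO"], "discarded_motifs")
})

test_that("span curation applies the 70% rule with an inclusive boundary", {
  cand <- data.frame(
    sequence_id = c("a", "b", "c"), family = "HAK/KT/KUP",
    n_motifs_matched = 3L, n_hits = 3L, span_start = 0L,
    span_end = c(400L, 300L, 350L),
    outermost_span = c(400L, 300L, 350L), curation = "kept",
    stringsAsFactors = FALSE)
  out <- curate_by_span(cand, list("HAK/KT/KUP" = c(450, 550)))
  expect_equal(out$curation, c("kept", "discarded_span", "kept"))
  expect_equal(out$ref_mean_span, rep(500, 3))
  expect_error(curate_by_span(cand, list()), "empty reference set")
})

test_that("span verdicts are invariant to candidate and reference order", {
  set.seed(12)
  cand <- data.frame(
    sequence_id = sprintf("s%02d", 1:10), family = "KEA",
    n_motifs_matched = 1L, n_hits = 1L, span_start = 0L,
    span_end = sample(20:40, 10), curation = "kept",
    stringsAsFactors = FALSE)
  cand$outermost_span <- cand$span_end
  refs <- list(KEA = c(30, 34, 38))
  a <- curate_by_span(cand, refs)
  b <- curate_by_span(cand[sample(10), ], list(KEA = rev(refs$KEA)))
  b <- b[match(a$sequence_id, b$sequence_id), ]
  expect_equal(a$curation, b$curation)
})

test_that("screening recovers exactly the planted full-length members", {
  sim <- simulate_proteome(
    family_sizes = c("HAK/KT/KUP" = 4L, "VG-channel" = 3L, "TPK/KCO" = 2L,
                     "HKT" = 2L, "KEA" = 3L),
    n_truncated = 14L, n_random = 30L, seed = 97L)
  res <- screen_proteome(sim$proteome, sim$refs, sim$ref_families)
  sc <- screen_scores(res$kept, sim$truth$roles)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
  expect_true(sc$family_ok)
  # truncated decoys fail the span rule, never the kept set
  trunc <- sim$truth$roles$sequence_id[sim$truth$roles$role == "truncated"]
  verdicts <- res$candidates[res$candidates$sequence_id %in% trunc, ]
  expect_true(all(verdicts$curation != "kept"))
})

test_that("with no decoys, screening recall is 1", {
  sim <- simulate_proteome(
    family_sizes = c("HAK/KT/KUP" = 3L, "KEA" = 2L),
    n_truncated = 0L, n_random = 0L, seed = 31L)
  res <- screen_proteome(sim$proteome, sim$refs, sim$ref_families)
  sc <- screen_scores(res$kept, sim$truth$roles)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)
})

test_that("candidate annotations carry the physicochemical columns", {
  sim <- simulate_proteome(family_sizes = c("HKT" = 2L), n_truncated = 0L,
                           n_random = 2L, seed = 8L)
  res <- screen_proteome(sim$proteome, sim$refs, sim$ref_families)
  cand <- res$candidates
  expect_true(all(c("length_aa", "mw_da", "pi", "n_tmds") %in% names(cand)))
  expect_true(all(cand$outermost_span <= cand$length_aa))
  expect_true(all(cand$mw_da > 0 & cand$pi > 0 & cand$pi < 14))
  tf <- tempfile(fileext = ".tsv")
  write_candidates_tsv(cand, tf)
  back <- read.delim(tf)
  expect_equal(nrow(back), nrow(cand))
  expect_equal(back$span_start_1based, cand$span_start + 1L)
})
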
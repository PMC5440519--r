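# NG86 Ka/Ks, duplication-mode classification, and clock dating.

test_that("NG86 reproduces the hand-counted glycine case", {
  # 10 glycine codons GGT: the third position is fully synonymous (all
  # GGN encode Gly), the first and second fully nonsynonymous, so
  # S = 10, N = 20. One GGT->GGC change: Sd = 1, pS = 0.1, and
  # ks = -(3/4) ln(1 - 4*0.1/3) = 0.1073.
  a <- strrep("GGT", 10)
  b <- paste0(strrep("GGT", 9), "GGC")
  r <- ng86_ka_ks(a, b)
  expect_equal(r$S, 10)
  expect_equal(r$N, 20)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$ps, 0.1)
  expect_equal(round(r$ks, 4), 0.1073)
  expect_equal(r$ka, 0)
})

test_that("NG86 is symmetric and zero on identical sequences", {
  set.seed(41)
  cds <- paste(sample(kinventory:::sense_codons(), 60, replace = TRUE),
               collapse = "")
  r0 <- ng86_ka_ks(cds, cds)
  expect_equal(r0$ks, 0)
  expect_equal(r0$ka, 0)
  sim <- simulate_duplicated_cds(n_codons = 80L, k_star = 0.15, seed = 42L)
  ab <- ng86_ka_ks(sim$cds[[1]], sim$cds[[2]])
  ba <- ng86_ka_ks(sim$cds[[2]], sim$cds[[1]])
  expect_equal(ab$ks, ba$ks)
  expect_equal(ab$ka, ba$ka)
  expect_equal(ab$S, ba$S)
})

test_that("NG86 rejects malformed input and saturated proportions", {
  expect_error(ng86_ka_ks("GGTG", "GGTA"), "divisible")
  expect_error(ng86_ka_ks("GGT", "GGTGGT"), "lengths differ")
  expect_error(ng86_ka_ks("TAA", "TAA"), "stop codon")
  # force pS >= 0.75: every third position differs within 4-fold codons
  a <- strrep("GGT", 12)
  b <- strrep("GGA", 12)
  expect_error(ng86_ka_ks(a, b), class = "ng86_saturation")
})

test_that("pathway averaging weights multi-difference codons evenly", {
  # CTA (Leu) vs TTG (Leu): positions 1 and 3 differ; both pathways pass
  # through Leu codons (TTA, CTG), so both steps are synonymous.
  d <- kinventory:::codon_pair_diffs("CTA", "TTG")
  expect_equal(unname(d), c(2, 0))
  # AAA (Lys) vs AGG (Arg): pathways AAA->AGA(Arg)->AGG(Arg) and
  # AAA->AAG(Lys)->AGG(Arg) each count 1 synonymous + 1 nonsynonymous.
  d2 <- kinventory:::codon_pair_diffs("AAA", "AGG")
  expect_equal(unname(d2), c(1, 1))
  # embedded in a longer CDS the counts add to the totals
  a <- paste0(strrep("GGT", 10), "CTA")
  b <- paste0(strrep("GGT", 10), "TTG")
  r <- ng86_ka_ks(a, b)
  expect_equal(r$Sd, 2)
  expect_equal(r$Nd, 0)
})

test_that("codon alignment back-threads the protein alignment onto CDS", {
  # identical proteins, no gaps: alignment is the identity
  al <- codon_align("ATGGCTGCT", "ATGGCAGCA")
  expect_equal(al$cds_a, "ATGGCTGCT")
  expect_equal(al$cds_b, "ATGGCAGCA")
  # an internal codon deletion introduces one protein gap; the gapped
  # codon column is dropped pairwise
  a <- "ATGAAATTTGGGCCC"   # M K F G P
  b <- "ATGAAAGGGCCC"      # M K G P
  al2 <- codon_align(a, b)
  expect_equal(nchar(al2$cds_a), nchar(al2$cds_b))
  expect_equal(al2$cds_a, "ATGAAAGGGCCC")
  expect_equal(al2$cds_b, "ATGAAAGGGCCC")
})

test_that("duplication dating applies T = Ks / 2 lambda exactly", {
  expect_equal(date_duplication(0, 6.1e-9), 0)
  expect_equal(date_duplication(0.122, 6.1e-9), 10)
  expect_equal(date_duplication(0.122, "slow"), 10)
  expect_equal(date_duplication(0.2, 1.5e-8), 0.2 / 3e-8 / 1e6)
  expect_equal(date_duplication(0.4, 6.1e-9),
               2 * date_duplication(0.2, 6.1e-9))
  expect_error(date_duplication(0.1, 0), "positive")
  expect_error(date_duplication(-0.1, 6.1e-9), "non-negative")
  expect_equal(unname(clock_rates()["fast"]), 1.5e-8)
})

test_that("tandem and segmental classification follows gene order", {
  gene_order <- data.frame(
    gene = c("a", "b", "c", "d", "e"),
    chromosome = c("Chr1", "Chr1", "Chr1", "Chr2", "Chr2"),
    rank = c(1L, 2L, 50L, 10L, 11L), stringsAsFactors = FALSE)
  blocks <- data.frame(chrom_1 = "Chr1", start_1 = 40L, end_1 = 60L,
                       chrom_2 = "Chr2", start_2 = 5L, end_2 = 15L,
                       stringsAsFactors = FALSE)
  expect_equal(classify_duplication("a", "b", gene_order), "tandem")
  expect_equal(classify_duplication("c", "d", gene_order, blocks),
               "segmental")
  expect_equal(classify_duplication("d", "c", gene_order, blocks),
               "segmental")  # region order swapped
  expect_equal(classify_duplication("a", "c", gene_order), "unclassified")
  expect_error(classify_duplication("a", "zz", gene_order), "missing")
  # boundary: exactly tandem_max_intervening intervening genes still tandem
  go2 <- data.frame(gene = c("p", "q"), chromosome = "Chr3",
                    rank = c(1L, 7L), stringsAsFactors = FALSE)
  expect_equal(classify_duplication("p", "q", go2), "tandem")
  go3 <- data.frame(gene = c("p", "q"), chromosome = "Chr3",
                    rank = c(1L, 8L), stringsAsFactors = FALSE)
  expect_equal(classify_duplication("p", "q", go3), "unclassified")
})

test_that("block mean Ks averages defined pairs and counts saturated ones", {
  p1 <- list(strrep("GGT", 10), paste0(strrep("GGT", 9), "GGC"))  # ks 0.1073
  p2 <- list(strrep("GGT", 10), strrep("GGT", 10))                # ks 0
  sat <- list(strrep("GGT", 12), strrep("GGA", 12))               # saturated
  r <- block_mean_ks(list(p1, p2))
  expect_equal(r$mean_ks, (0.107326 + 0) / 2, tolerance = 1e-5)
  expect_equal(r$n_saturated, 0L)
  r2 <- block_mean_ks(list(p1, sat))
  expect_equal(r2$n_used, 1L)
  expect_equal(r2$n_saturated, 1L)
  expect_equal(r2$mean_ks, 0.107326, tolerance = 1e-5)
  r3 <- block_mean_ks(list(p1))
  expect_equal(r3$mean_ks, 0.107326, tolerance = 1e-5)
  expect_error(block_mean_ks(list(sat)), "saturated")
})

test_that("simulated synonymous divergence is recovered by NG86", {
  ks <- vapply(1:30, function(i) {
    sim <- simulate_duplicated_cds(n_codons = 300L, k_star = 0.1,
                                   seed = 1000L + i)
    ng86_ka_ks(sim$cds[[1]], sim$cds[[2]])$ks
  }, numeric(1))
  expect_lt(abs(mean(ks) - 0.1) / 0.1, 0.1)
  # k* = 0 leaves the pair identical
  s0 <- simulate_duplicated_cds(n_codons = 100L, k_star = 0, seed = 3L)
  expect_equal(s0$cds[[1]], s0$cds[[2]])
})

test_that("the paralog pair table combines mode, rates, and ages", {
  dup <- simulate_paralog_set(n_pairs = 4L, n_codons = 150L, k_star = 0.1,
                              seed = 17L)
  tab <- paralog_pair_table(dup$pairs, dup$cds, dup$gene_order, dup$blocks)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$mode, dup$truth$pairs$mode)
  expect_true(all(tab$ks >= 0))
  expect_equal(tab$t_mya, tab$ks / (2 * 6.1e-9) / 1e6)
  expect_true(all(!tab$saturated))
})
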
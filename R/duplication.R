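# Paralog-pair classification (tandem vs segmental), Nei-Gojobori (1986)
# Ka/Ks estimation with Jukes-Cantor correction, and molecular-clock dating
# of duplication events (T = Ks / 2 lambda).

NT4 <- c("T", "C", "A", "G")

# Package-local cache for the codon tables (built once, deterministically).
.ng86_env <- new.env(parent = emptyenv())

codon_aa <- function(codon) Biostrings::GENETIC_CODE[[codon]]

sense_codons <- function() {
  all <- names(Biostrings::GENETIC_CODE)
  all[Biostrings::GENETIC_CODE != "*"]
}

# Fraction of synonymous sites per codon: for each of the three positions,
# the share of the three possible single-nucleotide changes that preserve
# the amino acid. Changes to stop codons count as nonsynonymous.
codon_syn_sites <- function() {
  if (!is.null(.ng86_env$syn_sites)) return(.ng86_env$syn_sites)
  codons <- sense_codons()
  s <- vapply(codons, function(cd) {
    chars <- strsplit(cd, "")[[1]]
    aa <- codon_aa(cd)
    total <- 0
    for (pos in 1:3) {
      for (nt in setdiff(NT4, chars[[pos]])) {
        alt <- chars; alt[[pos]] <- nt
        alt_aa <- codon_aa(paste(alt, collapse = ""))
        if (alt_aa != "*" && alt_aa == aa) total <- total + 1
      }
    }
    total / 3
  }, numeric(1))
  names(s) <- codons
  .ng86_env$syn_sites <- s
  s
}

# Synonymous single-nucleotide neighbours of each sense codon; used by the
# synonymous-only CDS evolver.
codon_syn_neighbours <- function() {
  if (!is.null(.ng86_env$syn_nb)) return(.ng86_env$syn_nb)
  codons <- sense_codons()
  nb <- lapply(codons, function(cd) {
    chars <- strsplit(cd, "")[[1]]
    aa <- codon_aa(cd)
    out <- character()
    for (pos in 1:3) {
      for (nt in setdiff(NT4, chars[[pos]])) {
        alt <- chars; alt[[pos]] <- nt
        alt_cd <- paste(alt, collapse = "")
        if (codon_aa(alt_cd) == aa) out <- c(out, alt_cd)
      }
    }
    out
  })
  names(nb) <- codons
  .ng86_env$syn_nb <- nb
  nb
}

# Synonymous/nonsynonymous difference counts for one codon pair, averaging
# with equal weight over the d! mutational pathways for codons differing at
# d positions. Pathways passing through a stop codon are excluded; if every
# pathway is excluded, all pathways are used.
codon_pair_diffs <- function(codon_a, codon_b) {
  key <- paste0(codon_a, codon_b)
  cached <- .ng86_env$pair_cache[[key]]
  if (!is.null(cached)) return(cached)
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  pos <- which(a != b)
  res <- if (length(pos) == 0L) c(sd = 0, nd = 0) else {
    paths <- if (length(pos) == 1L) list(pos) else {
      perms <- function(v) {
        if (length(v) <= 1L) return(list(v))
        out <- list()
        for (i in seq_along(v))
          for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[[i]], p)
        out
      }
      perms(pos)
    }
    walk <- function(order) {
      cur <- a; sd <- 0; nd <- 0
      for (p in order) {
        nxt <- cur; nxt[[p]] <- b[[p]]
        aa1 <- codon_aa(paste(cur, collapse = ""))
        aa2 <- codon_aa(paste(nxt, collapse = ""))
        if (aa2 == "*" || aa1 == "*") return(NULL)
        if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    }
    counted <- Filter(Negate(is.null), lapply(paths, walk))
    if (length(counted) == 0L) {
      walk_all <- function(order) {
        cur <- a; sd <- 0; nd <- 0
        for (p in order) {
          nxt <- cur; nxt[[p]] <- b[[p]]
          aa1 <- codon_aa(paste(cur, collapse = ""))
          aa2 <- codon_aa(paste(nxt, collapse = ""))
          if (aa1 != "*" && aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        c(sd = sd, nd = nd)
      }
      counted <- lapply(paths, walk_all)
    }
    colMeans(do.call(rbind, counted))
  }
  if (is.null(.ng86_env$pair_cache))
    .ng86_env$pair_cache <- new.env(parent = emptyenv())
  .ng86_env$pair_cache[[key]] <- res
  res
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length must be divisible by 3")
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Nei-Gojobori (1986) Ka/Ks
#'
#' Counts fractional synonymous (S) and nonsynonymous (N) sites per codon
#' (averaged over the two sequences), counts synonymous and nonsynonymous
#' differences with equal-weight pathway averaging for codons differing at
#' more than one position, and applies the Jukes-Cantor correction
#' `d = -(3/4) log(1 - (4/3) p)` to the proportions `pS = Sd/S` and
#' `pN = Nd/N`.
#'
#' @param cds_a,cds_b Codon-aligned CDS strings: equal length, divisible by
#'   3, no internal stop codons. Codon pairs containing a gap or ambiguity
#'   are not accepted here; align first with [codon_align()].
#' @return Named list `ka`, `ks`, `pn`, `ps`, `S`, `N`, `Sd`, `Nd`.
#'   A proportion of 0.75 or more makes the correction undefined and raises
#'   a condition of class `ng86_saturation`.
#' @examples
#' a <- strrep("GGT", 10)
#' b <- paste0(strrep("GGT", 9), "GGC")
#' ng86_ka_ks(a, b)$ks  # 0.1073
#' @export
ng86_ka_ks <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) stop("CDS lengths differ")
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  valid <- sense_codons()
  if (!all(ca %in% valid) || !all(cb %in% valid))
    stop("CDS contains a stop codon or non-ACGT characters")
  sites <- codon_syn_sites()
  S <- (sum(sites[ca]) + sum(sites[cb])) / 2
  N <- 3 * length(ca) - S
  diffs <- vapply(seq_along(ca), function(i) codon_pair_diffs(ca[[i]], cb[[i]]),
                  numeric(2))
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p, what) {
    if (p >= 0.75) {
      cond <- structure(
        class = c("ng86_saturation", "error", "condition"),
        list(message = sprintf("%s proportion %.3f >= 0.75: saturated, Jukes-Cantor correction undefined",
                               what, p), call = sys.call(-1)))
      stop(cond)
    }
    -0.75 * log(1 - 4 * p / 3)
  }
  list(ka = jc(pn, "nonsynonymous"), ks = jc(ps, "synonymous"),
       pn = pn, ps = ps, S = S, N = N, Sd = Sd, Nd = Nd)
}

#' Codon-align two CDS via their protein global alignment
#'
#' Translates both CDS, aligns the proteins globally (BLOSUM62, affine
#' gaps), back-threads the alignment onto the nucleotide sequences, and
#' drops codon columns that are gapped in either sequence (pairwise
#' deletion).
#'
#' @param cds_a,cds_b CDS strings (length divisible by 3, no internal
#'   stops).
#' @inheritParams global_identity
#' @return List with gap-free codon-aligned `cds_a` and `cds_b`.
#' @export
codon_align <- function(cds_a, cds_b, gap_open = 10, gap_extend = 1) {
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  pa <- paste(vapply(ca, codon_aa, character(1)), collapse = "")
  pb <- paste(vapply(cb, codon_aa, character(1)), collapse = "")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = "BLOSUM62", gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  arow <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  brow <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ia <- 0L; ib <- 0L
  keep_a <- integer(); keep_b <- integer()
  for (k in seq_along(arow)) {
    if (arow[[k]] != "-") ia <- ia + 1L
    if (brow[[k]] != "-") ib <- ib + 1L
    if (arow[[k]] != "-" && brow[[k]] != "-") {
      keep_a <- c(keep_a, ia); keep_b <- c(keep_b, ib)
    }
  }
  list(cds_a = paste(ca[keep_a], collapse = ""),
       cds_b = paste(cb[keep_b], collapse = ""))
}

#' Molecular-clock rate presets
#'
#' Two published synonymous clock rates commonly used for dating plant
#' duplication events, in substitutions per synonymous site per year.
#'
#' @return Named numeric vector: `fast` = 1.5e-8 (the classic eudicot
#'   rate), `slow` = 6.1e-9 (the legume-calibrated rate; the pipeline
#'   default).
#' @export
clock_rates <- function() c(fast = 1.5e-8, slow = 6.1e-9)

#' Date a duplication event from Ks
#'
#' `T = Ks / (2 lambda)`, reported in million years (Mya).
#'
#' @param ks Synonymous substitutions per synonymous site (>= 0).
#' @param lambda Clock rate in substitutions/synonymous site/year, or the
#'   name of a [clock_rates()] preset.
#' @return Age in Mya.
#' @examples
#' date_duplication(0.122, 6.1e-9)  # 10 Mya
#' @export
date_duplication <- function(ks, lambda = "slow") {
  if (is.character(lambda)) lambda <- clock_rates()[[lambda]]
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be positive")
  if (any(ks < 0)) stop("ks must be non-negative")
  ks / (2 * lambda) / 1e6
}

#' Classify a paralog pair as tandem or segmental
#'
#' Tandem iff both genes lie on the same chromosome with at most
#' `tandem_max_intervening` genes between their ordinal positions;
#' otherwise segmental if the two genes fall in the two regions of a
#' declared duplicated block; otherwise unclassified. Synteny blocks are
#' supplied, not inferred.
#'
#' @param gene_a,gene_b Gene ids.
#' @param gene_order data.frame with columns `gene`, `chromosome`, `rank`
#'   (ordinal position along the chromosome).
#' @param blocks Optional data.frame of duplicated blocks with columns
#'   `chrom_1`, `start_1`, `end_1`, `chrom_2`, `start_2`, `end_2` (rank
#'   coordinates, inclusive).
#' @param tandem_max_intervening Maximum intervening genes for a tandem
#'   call (default 5).
#' @return `"tandem"`, `"segmental"`, or `"unclassified"`.
#' @export
classify_duplication <- function(gene_a, gene_b, gene_order, blocks = NULL,
                                 tandem_max_intervening = 5L) {
  idx <- match(c(gene_a, gene_b), gene_order$gene)
  if (anyNA(idx))
    stop(sprintf("gene missing from order index: %s",
                 c(gene_a, gene_b)[is.na(idx)][[1]]))
  ca <- gene_order$chromosome[[idx[[1]]]]
  cb <- gene_order$chromosome[[idx[[2]]]]
  ra <- gene_order$rank[[idx[[1]]]]
  rb <- gene_order$rank[[idx[[2]]]]
  if (ca == cb && abs(ra - rb) - 1L <= tandem_max_intervening)
    return("tandem")
  if (!is.null(blocks) && nrow(blocks)) {
    in_region <- function(chr, r, bc, bs, be) chr == bc & r >= bs & r <= be
    for (i in seq_len(nrow(blocks))) {
      b <- blocks[i, ]
      fwd <- in_region(ca, ra, b$chrom_1, b$start_1, b$end_1) &&
             in_region(cb, rb, b$chrom_2, b$start_2, b$end_2)
      rev <- in_region(cb, rb, b$chrom_1, b$start_1, b$end_1) &&
             in_region(ca, ra, b$chrom_2, b$start_2, b$end_2)
      if (fwd || rev) return("segmental")
    }
  }
  "unclassified"
}

#' Mean Ks of the pairs inside a duplicated block
#'
#' Arithmetic mean over pairs whose Ks is defined; saturated pairs (those
#' raising `ng86_saturation`) are excluded and counted.
#'
#' @param cds_pairs List of two-element lists/character vectors, each a
#'   codon-aligned CDS pair.
#' @return List with `mean_ks`, `n_used`, `n_saturated`, and the per-pair
#'   `ks` values (NA where saturated).
#' @export
block_mean_ks <- function(cds_pairs) {
  ks <- vapply(cds_pairs, function(p) {
    tryCatch(ng86_ka_ks(p[[1]], p[[2]])$ks,
             ng86_saturation = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(ks))) stop("all pairs in block are saturated")
  list(mean_ks = mean(ks, na.rm = TRUE), n_used = sum(!is.na(ks)),
       n_saturated = sum(is.na(ks)), ks = ks)
}

#' Analyze a set of paralog pairs
#'
#' Codon-aligns each CDS pair, estimates Ka/Ks, classifies the duplication
#' mode, and dates the event.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param cds Named character vector of CDS sequences.
#' @param gene_order,blocks,tandem_max_intervening See
#'   [classify_duplication()].
#' @param lambda Clock rate or preset name (see [date_duplication()]).
#' @return data.frame with mode, ka, ks, t_mya and a `saturated` flag per
#'   pair.
#' @export
paralog_pair_table <- function(pairs, cds, gene_order, blocks = NULL,
                               tandem_max_intervening = 5L,
                               lambda = "slow") {
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$gene_a[[i]]; b <- pairs$gene_b[[i]]
    al <- codon_align(cds[[a]], cds[[b]])
    est <- tryCatch(ng86_ka_ks(al$cds_a, al$cds_b),
                    ng86_saturation = function(e) NULL)
    mode <- classify_duplication(a, b, gene_order, blocks,
                                 tandem_max_intervening)
    data.frame(
      gene_a = a, gene_b = b, mode = mode,
      ka = if (is.null(est)) NA_real_ else est$ka,
      ks = if (is.null(est)) NA_real_ else est$ks,
      t_mya = if (is.null(est)) NA_real_ else date_duplication(est$ks, lambda),
      saturated = is.null(est), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
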
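# Exon lengths, intron phases, and conserved-exon detection within
# duplicated pairs and across whole families.
#
# The intron phase after coding exon i is (sum of the first i exon lengths)
# mod 3: the number of nucleotides the intron falls into the interrupted
# codon. Conserved phases across members indicate shared exon ancestry.

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param chromosome Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (`start`, `end`) of coding exons in
#'   0-based half-open genomic coordinates, given in transcription order
#'   (5' to 3'; minus-strand models therefore list descending coordinates).
#' @return Object of class `GeneModel`.
#' @export
gene_model <- function(gene_id, chromosome, strand, exons) {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, "end"] <= exons[, "start"]))
    stop("exons must have end > start (0-based half-open)")
  ord <- order(exons[, "start"])
  genomic <- exons[ord, , drop = FALSE]
  if (nrow(genomic) > 1L &&
      any(genomic[-1L, "start"] < genomic[-nrow(genomic), "end"]))
    stop(sprintf("overlapping exons in gene %s", gene_id))
  total <- sum(exons[, "end"] - exons[, "start"])
  structure(list(gene_id = gene_id, chromosome = chromosome,
                 strand = strand, exons = exons,
                 frame_ok = total %% 3L == 0L),
            class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s%s): %d coding exon(s), %d nt%s\n",
              x$gene_id, x$chromosome, x$strand, nrow(x$exons),
              sum(x$exons[, "end"] - x$exons[, "start"]),
              if (x$frame_ok) "" else " [length not divisible by 3]"))
  invisible(x)
}

#' Exon lengths and intron phases of a gene model
#'
#' @param model A [gene_model()].
#' @return Object of class `ExonStructure`: list with `gene_id`,
#'   `exon_lengths` (nt, transcription order) and `intron_phases` (0/1/2,
#'   one per intron: cumulative coding length before the intron mod 3).
#' @export
exon_structure <- function(model) {
  lens <- as.integer(model$exons[, "end"] - model$exons[, "start"])
  phases <- if (length(lens) > 1L)
    as.integer(cumsum(lens)[-length(lens)] %% 3L) else integer(0)
  structure(list(gene_id = model$gene_id, exon_lengths = lens,
                 intron_phases = phases),
            class = "ExonStructure")
}

# Phase context of every exon: the phase of the flanking introns, with
# terminal exons marked. Two exons "match" iff their lengths are equal and
# their 5' contexts agree (compared only between non-first exons) and their
# 3' contexts agree (non-last exons); a terminal exon can only match a
# terminal exon on that side.
exon_keys <- function(structure) {
  n <- length(structure$exon_lengths)
  p5 <- c("start", as.character(structure$intron_phases))
  p3 <- c(as.character(structure$intron_phases), "end")
  paste(structure$exon_lengths, p5, p3, sep = "|")
}

#' Matched exons between two gene structures
#'
#' Longest common subsequence over the two exon lists, where two exons
#' match iff they have equal length and the same flanking splice-phase
#' context (5' intron phase for non-first exons, 3' intron phase for
#' non-last). Order-preserving and symmetric.
#'
#' @param a,b `ExonStructure` objects.
#' @param tolerance Allowed absolute length difference in nt (default 0:
#'   exact "same nucleotide number" matching).
#' @return data.frame with `index_a`, `index_b`, `length_a`, `length_b` per
#'   matched exon pair (zero rows when nothing matches).
#' @export
conserved_exons_pair <- function(a, b, tolerance = 0L) {
  ka <- strsplit(exon_keys(a), "|", fixed = TRUE)
  kb <- strsplit(exon_keys(b), "|", fixed = TRUE)
  n <- length(ka); m <- length(kb)
  match_ij <- function(i, j) {
    abs(a$exon_lengths[[i]] - b$exon_lengths[[j]]) <= tolerance &&
      ka[[i]][[2]] == kb[[j]][[2]] && ka[[i]][[3]] == kb[[j]][[3]]
  }
  L <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      L[i + 1L, j + 1L] <- if (match_ij(i, j)) L[i, j] + 1L
        else max(L[i, j + 1L], L[i + 1L, j])
    }
  }
  # backtrace
  ia <- integer(); ib <- integer()
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    if (match_ij(i, j) && L[i + 1L, j + 1L] == L[i, j] + 1L) {
      ia <- c(i, ia); ib <- c(j, ib); i <- i - 1L; j <- j - 1L
    } else if (L[i, j + 1L] >= L[i + 1L, j]) i <- i - 1L else j <- j - 1L
  }
  data.frame(index_a = ia, index_b = ib,
             length_a = a$exon_lengths[ia], length_b = b$exon_lengths[ib])
}

#' Family-conserved exons
#'
#' An exon (a length with its splice-phase context) is family-conserved
#' when at least `min_fraction` of the members carry a matching exon.
#' Members lacking a reported exon are listed by id.
#'
#' @param structures List of `ExonStructure` objects (at least 2).
#' @param min_fraction Member fraction threshold (default 0.9, reflecting
#'   "conserved in all members except ..." style reporting).
#' @return data.frame with `exon_length`, `phase5`, `phase3`, `fraction`,
#'   and `absent_from` (comma-separated member ids), sorted by decreasing
#'   fraction then length.
#' @export
family_conserved_exons <- function(structures, min_fraction = 0.9) {
  if (length(structures) < 2L) stop("need at least 2 structures")
  ids <- vapply(structures, function(s) s$gene_id, character(1))
  keysets <- lapply(structures, function(s) unique(exon_keys(s)))
  all_keys <- unique(unlist(keysets))
  rows <- lapply(all_keys, function(k) {
    has <- vapply(keysets, function(ks) k %in% ks, logical(1))
    frac <- mean(has)
    if (frac < min_fraction) return(NULL)
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(exon_length = as.integer(parts[[1]]), phase5 = parts[[2]],
               phase3 = parts[[3]], fraction = frac,
               absent_from = paste(ids[!has], collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L)
    return(data.frame(exon_length = integer(), phase5 = character(),
                      phase3 = character(), fraction = numeric(),
                      absent_from = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(-out$fraction, out$exon_length), , drop = FALSE]
}

#' Write an exon-structure table
#'
#' One row per exon: gene, exon index (transcription order), length in nt,
#' and the 5'/3' intron phases ("start"/"end" for terminal exons).
#'
#' @param structures List of `ExonStructure` objects.
#' @param path Output TSV path.
#' @export
write_structures_tsv <- function(structures, path) {
  rows <- lapply(structures, function(s) {
    n <- length(s$exon_lengths)
    data.frame(gene_id = s$gene_id, exon_index = seq_len(n),
               length_nt = s$exon_lengths,
               phase_5prime = c("start", as.character(s$intron_phases)),
               phase_3prime = c(as.character(s$intron_phases), "end"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
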
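# Physicochemical annotations reported for each screened candidate:
# average-mass molecular weight, isoelectric point, and a Kyte-Doolittle
# transmembrane-segment count.

# Average (isotope-abundance-weighted) residue masses in daltons.
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_AVG_MASS <- 18.0153

# Kyte-Doolittle hydropathy index.
KD_INDEX <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, E = -3.5, Q = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Protein molecular weight (average mass)
#'
#' Sum of residue average masses plus one water. Additive:
#' `MW(ab) = MW(a) + MW(b) - 18.0153`.
#'
#' @param seq Protein sequence of standard residues.
#' @return Mass in daltons.
#' @examples
#' molecular_weight("G")  # 75.07
#' @export
molecular_weight <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("sequence must be a non-empty string")
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!(chars %in% names(AA_AVG_MASS)))
  if (length(bad))
    stop(sprintf("non-standard residue '%s' at position %d",
                 chars[[bad[[1]]]], bad[[1]]))
  sum(AA_AVG_MASS[chars]) + WATER_AVG_MASS
}

load_pka_table <- function(path = system.file("extdata", "pka_table.tsv",
                                              package = "kinventory")) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Isoelectric point
#'
#' pH at which the net charge crosses zero, from the Henderson-Hasselbalch
#' sum over the two termini and the D, E, C, Y (acidic) and H, K, R (basic)
#' side chains, solved by bisection on pH 0..14.
#'
#' @param seq Protein sequence (non-empty). Residues without an entry in the
#'   pKa table contribute no charge.
#' @param tol Bisection tolerance in pH units (default 0.01).
#' @return pI as a pH value.
#' @examples
#' isoelectric_point("A")  # ~6.02: midpoint of the two terminal pKa values
#' @export
isoelectric_point <- function(seq, tol = 0.01) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("sequence must be a non-empty string")
  pka <- load_pka_table()
  chars <- strsplit(seq, "")[[1]]
  counts <- table(chars)
  groups <- data.frame(pka = numeric(), charge = numeric(), n = numeric())
  for (i in seq_len(nrow(pka))) {
    g <- pka$group[[i]]
    n <- if (g %in% c("Nterm", "Cterm")) 1 else
      if (g %in% names(counts)) as.numeric(counts[[g]]) else 0
    if (n > 0)
      groups <- rbind(groups,
                      data.frame(pka = pka$pka[[i]], charge = pka$charge[[i]],
                                 n = n))
  }
  net <- function(ph) {
    pos <- groups$charge > 0
    sum(groups$n[pos] / (1 + 10^(ph - groups$pka[pos]))) -
      sum(groups$n[!pos] / (1 + 10^(groups$pka[!pos] - ph)))
  }
  lo <- 0; hi <- 14
  while (hi - lo > tol / 2) {
    mid <- (lo + hi) / 2
    if (net(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Count predicted transmembrane segments
#'
#' Hydropathy heuristic: slides a window over the Kyte-Doolittle index,
#' marks window positions whose mean is at or above `threshold`, merges
#' marked runs separated by fewer than `merge_gap` positions, and counts
#' the resulting runs. A deterministic, self-contained stand-in for an HMM
#' topology predictor; its use here is order-of-magnitude annotation of
#' candidates (polytopic transporters vs soluble decoys).
#'
#' @param seq Protein sequence. `X` is assigned hydropathy 0.
#' @param window Window length in residues (default 19, a typical
#'   transmembrane helix span).
#' @param threshold Window-mean hydropathy cutoff (default 1.6).
#' @param merge_gap Runs closer than this many residues are merged
#'   (default 5).
#' @return Integer segment count (0 for sequences shorter than `window`).
#' @export
count_tmds <- function(seq, window = 19L, threshold = 1.6, merge_gap = 5L) {
  validate_protein(seq)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < window) return(0L)
  kd <- ifelse(chars %in% names(KD_INDEX), KD_INDEX[chars], 0)
  cs <- cumsum(c(0, kd))
  means <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
  hot <- means >= threshold
  if (!any(hot)) return(0L)
  r <- rle(hot)
  # merge hot runs separated by short cold runs
  if (length(r$lengths) > 2L) {
    for (i in seq_along(r$values)) {
      if (!r$values[[i]] && i > 1L && i < length(r$values) &&
          r$lengths[[i]] < merge_gap)
        r$values[[i]] <- TRUE
    }
    hot <- inverse.rle(r)
    r <- rle(hot)
  }
  sum(r$values)
}
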
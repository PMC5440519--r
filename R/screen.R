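# Turning motif hits into curated family candidates.
#
# A sequence becomes a candidate for family F when it matches at least
# policy(F) distinct patterns of F. Candidates are then curated by the
# outermost-motif span rule: a candidate is kept only if its span (first hit
# start to last hit end) is at least `fraction` (default 0.70) of the mean
# outermost span of the family's reference proteins, computed by the same
# scanner. Nothing is deleted: every candidate carries a verdict.

#' Build family candidates from motif hits
#'
#' @param hits Hit data.frame from [scan_proteome()].
#' @param library Motif library used for the scan (defines which patterns
#'   belong to which family; the channel pore motifs are shared between the
#'   voltage-gated and TPK/KCO screens).
#' @param policy Named integer vector: minimum number of distinct matched
#'   patterns per family. Defaults to the screen policy in
#'   [default_config()]. Families named in `policy` but absent from the
#'   library are a configuration error.
#' @param pore_pattern Pattern id of the channel pore motif; a sequence that
#'   qualifies for both channel families is tandem-pore (TPK/KCO) iff it
#'   carries at least two hits of this motif in one chain.
#' @return data.frame with one row per (sequence, family) candidacy:
#'   `sequence_id`, `family`, `n_motifs_matched`, `n_hits`, `outermost_span`,
#'   `span_start`, `span_end` and a preliminary `curation` verdict (`kept`
#'   or `discarded_motifs`). Sequences with at least one hit of a family
#'   appear even when below policy.
#' @export
assign_family <- function(hits, library,
                          policy = default_config()$motif_policy,
                          pore_pattern = "CH-6") {
  fam_sets <- family_pattern_ids(library)
  unknown <- setdiff(names(policy), names(fam_sets))
  if (length(unknown))
    stop(sprintf("policy names unknown family: %s", unknown[[1]]))
  rows <- list()
  for (sid in unique(hits$sequence_id)) {
    h <- hits[hits$sequence_id == sid, , drop = FALSE]
    for (fam in names(policy)) {
      fh <- h[h$pattern_id %in% fam_sets[[fam]], , drop = FALSE]
      if (nrow(fh) == 0L) next
      n_pat <- length(unique(fh$pattern_id))
      ok <- n_pat >= policy[[fam]]
      if (fam == "TPK/KCO")
        ok <- ok && sum(fh$pattern_id == pore_pattern) >= 2L
      if (fam == "VG-channel" && sum(fh$pattern_id == pore_pattern) >= 2L)
        ok <- FALSE  # tandem-pore chains resolve to TPK/KCO
      rows[[length(rows) + 1L]] <- data.frame(
        sequence_id = sid, family = fam, n_motifs_matched = n_pat,
        n_hits = nrow(fh), span_start = min(fh$start), span_end = max(fh$end),
        outermost_span = max(fh$end) - min(fh$start),
        curation = if (ok) "kept" else "discarded_motifs",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(sequence_id = character(), family = character(),
                      n_motifs_matched = integer(), n_hits = integer(),
                      span_start = integer(), span_end = integer(),
                      outermost_span = integer(), curation = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$sequence_id, out$family), , drop = FALSE]
}

#' Outermost-motif spans of a reference set
#'
#' Scans reference proteins with the library and records, per sequence, the
#' span from the first to the last hit of its family's patterns. These
#' spans are the yardstick of the 70% curation rule.
#'
#' @param refs Named character vector of reference protein sequences.
#' @param ref_families Named character vector mapping reference ids to their
#'   (known) families.
#' @param library Motif library.
#' @return Named list: family -> numeric vector of reference spans.
#' @export
reference_spans <- function(refs, ref_families, library) {
  hits <- scan_proteome(refs, library)
  fam_sets <- family_pattern_ids(library)
  out <- list()
  for (sid in names(refs)) {
    fam <- ref_families[[sid]]
    fh <- hits[hits$sequence_id == sid &
                 hits$pattern_id %in% fam_sets[[fam]], , drop = FALSE]
    if (nrow(fh) == 0L) next
    out[[fam]] <- c(out[[fam]], max(fh$end) - min(fh$start))
  }
  out
}

#' Curate candidates by the outermost-span rule
#'
#' A candidate already passing the motif-count policy is kept iff its
#' outermost span is at least `fraction` times the mean reference span of
#' its family (boundary inclusive: the rule discards strictly shorter
#' sequences). Verdicts are recorded; no rows are removed.
#'
#' @param candidates Output of [assign_family()].
#' @param ref_spans Output of [reference_spans()].
#' @param fraction Span fraction threshold (default 0.70).
#' @return `candidates` with updated `curation` and added `ref_mean_span`.
#' @export
curate_by_span <- function(candidates, ref_spans, fraction = 0.70) {
  if (nrow(candidates) == 0L) {
    candidates$ref_mean_span <- numeric(0)
    return(candidates)
  }
  need <- unique(candidates$family[candidates$curation == "kept"])
  missing <- setdiff(need, names(ref_spans))
  if (length(missing))
    stop(sprintf("empty reference set for family %s", missing[[1]]))
  candidates$ref_mean_span <- vapply(candidates$family, function(f) {
    if (f %in% names(ref_spans)) mean(ref_spans[[f]]) else NA_real_
  }, numeric(1))
  sel <- candidates$curation == "kept" &
    candidates$outermost_span < fraction * candidates$ref_mean_span
  candidates$curation[sel] <- "discarded_span"
  candidates
}

#' Resolve multi-family candidacies to one family per sequence
#'
#' Among kept candidacies of one sequence, prefers the family with the most
#' distinct matched motifs, then the larger outermost span, then the
#' lexicographically smaller family name. (The tandem-pore vs voltage-gated
#' split is already resolved during [assign_family()].)
#'
#' @param candidates Curated candidate table.
#' @return Subset of `candidates` with one kept row per sequence.
#' @export
resolve_candidates <- function(candidates) {
  kept <- candidates[candidates$curation == "kept", , drop = FALSE]
  if (nrow(kept) == 0L) return(kept)
  kept <- kept[order(kept$sequence_id, -kept$n_motifs_matched,
                     -kept$outermost_span, kept$family), , drop = FALSE]
  kept[!duplicated(kept$sequence_id), , drop = FALSE]
}

#' Screen a proteome end to end
#'
#' Scan, family assignment, span curation, resolution, and physicochemical
#' annotation in one call.
#'
#' @param proteome Named character vector of protein sequences.
#' @param refs,ref_families Reference proteins and their family labels for
#'   the span rule.
#' @param library Motif library (default [motif_library()]).
#' @param policy Motif-count policy.
#' @param fraction Span fraction (default 0.70).
#' @return List with `hits`, `candidates` (all candidacies with verdicts and
#'   annotations: `length_aa`, `mw_da`, `pi`, `n_tmds`), and `kept` (one
#'   resolved row per kept sequence).
#' @export
screen_proteome <- function(proteome, refs, ref_families,
                            library = motif_library(),
                            policy = default_config()$motif_policy,
                            fraction = 0.70) {
  hits <- scan_proteome(proteome, library)
  cand <- assign_family(hits, library, policy = policy)
  spans <- reference_spans(refs, ref_families, library)
  cand <- curate_by_span(cand, spans, fraction = fraction)
  if (nrow(cand)) {
    cand$length_aa <- nchar(proteome[cand$sequence_id])
    cand$mw_da <- vapply(proteome[cand$sequence_id], molecular_weight,
                         numeric(1), USE.NAMES = FALSE)
    cand$pi <- vapply(proteome[cand$sequence_id], isoelectric_point,
                      numeric(1), USE.NAMES = FALSE)
    cand$n_tmds <- vapply(proteome[cand$sequence_id], count_tmds,
                          integer(1), USE.NAMES = FALSE)
  }
  list(hits = hits, candidates = cand, kept = resolve_candidates(cand))
}

#' Write the candidate table
#'
#' Columns mirror a family-inventory supplement: id, family, length (aa),
#' MW (kDa), pI, TMD count, motif count, outermost span (aa, 1-based
#' inclusive start/end) and verdict.
#'
#' @param candidates Annotated candidate table from [screen_proteome()].
#' @param path Output TSV path.
#' @export
write_candidates_tsv <- function(candidates, path) {
  out <- data.frame(
    sequence_id = candidates$sequence_id, family = candidates$family,
    length_aa = candidates$length_aa,
    mw_kda = round(candidates$mw_da / 1000, 2),
    pi = round(candidates$pi, 2), n_tmds = candidates$n_tmds,
    n_motifs = candidates$n_motifs_matched,
    span_start_1based = candidates$span_start + 1L,
    span_end_1based = candidates$span_end,
    outermost_span_aa = candidates$outermost_span,
    verdict = candidates$curation, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
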
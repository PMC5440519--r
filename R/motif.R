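# Degenerate protein-motif dialect: parsing and scanning.
#
# Patterns are written in the PROSITE-like dialect used for K+ transporter
# family screens, e.g. "[S,T]-x-xT-x-G-[Y,F,L]-G-[D,E]": bracket groups are
# residue alternatives (commas optional), "x" matches any one residue, and
# "x(n)" is a bounded run of arbitrary residues. Elements may be separated by
# "-", whitespace, or nothing (characters inside one token are consecutive
# elements). All coordinates are 0-based half-open internally; report writers
# emit 1-based inclusive.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Parse a degenerate protein motif pattern
#'
#' Turns a pattern string such as `"[S,T]-x-xT-x-G-[Y,F,L]-G-[D,E]"` into an
#' ordered list of elements. Three element kinds exist: `residue_set` (a
#' bracket group or a single residue letter), `wildcard` (`x`, one arbitrary
#' residue), and `gap` (`x(n)`, a bounded run of arbitrary residues).
#'
#' Hyphens and whitespace are both accepted as separators, bracket groups may
#' be written with or without commas (`[A,G]` and `[DE]` are equivalent), and
#' characters juxtaposed inside one token are consecutive elements (`xT` is a
#' wildcard followed by Thr). The repeat count in `x(n)` may be the literal
#' letter `n` (bounds taken from `x_n_min`/`x_n_max`), a single integer
#' (`x(3)`), or a range (`x(2,5)`).
#'
#' @param text Pattern string.
#' @param pattern_id Short label for the pattern (e.g. `"HAK-1"`).
#' @param family Family the pattern screens for.
#' @param x_n_min,x_n_max Gap bounds substituted for the literal `n` in
#'   `x(n)`. Defaults 1 and 30: the repeat must terminate, and 30 residues
#'   spans plausible inter-motif linkers.
#' @return An object of class `MotifPattern`: a list with `pattern_id`,
#'   `family`, `elements` (each a list with `kind`, and `residues` or
#'   `min_gap`/`max_gap`), and `source_text`.
#' @examples
#' p <- parse_pattern("[S,T]-x-xT-x-G-[Y,F,L]-G-[D,E]", "CH-6", "VG-channel")
#' length(p$elements)  # 9
#' @export
parse_pattern <- function(text, pattern_id = "pat", family = NA_character_,
                          x_n_min = 1L, x_n_max = 30L) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("pattern text must be a non-empty string")
  if (x_n_min < 0L || x_n_max < x_n_min)
    stop("gap bounds must satisfy 0 <= x_n_min <= x_n_max")
  tokens <- strsplit(trimws(text), "[-[:space:]]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  elements <- list()
  for (ti in seq_along(tokens)) {
    tok <- tokens[[ti]]
    chars <- strsplit(tok, "")[[1]]
    i <- 1L
    while (i <= length(chars)) {
      ch <- chars[[i]]
      if (ch == "[") {
        j <- i
        while (j <= length(chars) && chars[[j]] != "]") j <- j + 1L
        if (j > length(chars))
          stop(sprintf("unbalanced bracket in token %d ('%s')", ti, tok))
        grp <- if (j > i + 1L) chars[(i + 1L):(j - 1L)] else character(0)
        grp <- grp[grp != ","]
        if (length(grp) == 0L)
          stop(sprintf("empty bracket group in token %d ('%s')", ti, tok))
        bad <- setdiff(grp, AA20)
        if (length(bad))
          stop(sprintf("non-amino-acid letter '%s' in token %d ('%s')",
                       bad[[1]], ti, tok))
        elements[[length(elements) + 1L]] <-
          list(kind = "residue_set", residues = unique(grp))
        i <- j + 1L
      } else if (ch == "x") {
        if (i < length(chars) && chars[[i + 1L]] == "(") {
          j <- i + 1L
          while (j <= length(chars) && chars[[j]] != ")") j <- j + 1L
          if (j > length(chars))
            stop(sprintf("malformed repeat in token %d ('%s')", ti, tok))
          inner <- paste(chars[(i + 2L):(j - 1L)], collapse = "")
          if (inner == "n") {
            lo <- as.integer(x_n_min); hi <- as.integer(x_n_max)
          } else if (grepl("^[0-9]+$", inner)) {
            lo <- hi <- as.integer(inner)
          } else if (grepl("^[0-9]+,[0-9]+$", inner)) {
            b <- as.integer(strsplit(inner, ",")[[1]])
            lo <- b[[1]]; hi <- b[[2]]
            if (hi < lo)
              stop(sprintf("malformed repeat in token %d ('%s')", ti, tok))
          } else {
            stop(sprintf("malformed repeat in token %d ('%s')", ti, tok))
          }
          elements[[length(elements) + 1L]] <-
            list(kind = "gap", min_gap = lo, max_gap = hi)
          i <- j + 1L
        } else {
          elements[[length(elements) + 1L]] <- list(kind = "wildcard")
          i <- i + 1L
        }
      } else if (ch %in% AA20) {
        elements[[length(elements) + 1L]] <-
          list(kind = "residue_set", residues = ch)
        i <- i + 1L
      } else {
        stop(sprintf("non-amino-acid letter '%s' in token %d ('%s')",
                     ch, ti, tok))
      }
    }
  }
  if (length(elements) == 0L) stop("pattern contains no elements")
  structure(list(pattern_id = pattern_id, family = family,
                 elements = elements, source_text = text),
            class = "MotifPattern")
}

#' @export
print.MotifPattern <- function(x, ...) {
  cat(sprintf("MotifPattern %s (%s): %d elements\n  %s\n",
              x$pattern_id, x$family, length(x$elements), x$source_text))
  invisible(x)
}

# Compile a MotifPattern to a PCRE fragment. Wildcards and gaps match any
# uppercase letter (including the ambiguity letter X); residue sets match
# only their listed residues, so X never satisfies a residue set. Gap
# quantifiers are lazy: the shortest admissible gap is taken at each start.
motif_regex <- function(pattern) {
  parts <- vapply(pattern$elements, function(el) {
    switch(el$kind,
      residue_set = if (length(el$residues) == 1L) el$residues else
        paste0("[", paste(el$residues, collapse = ""), "]"),
      wildcard = "[A-Z]",
      gap = sprintf("[A-Z]{%d,%d}?", el$min_gap, el$max_gap))
  }, character(1))
  paste(parts, collapse = "")
}

validate_protein <- function(seq) {
  if (length(seq) != 1L || !is.character(seq))
    stop("sequence must be a single string")
  if (nzchar(seq) && grepl(sprintf("[^%sX]", paste(AA20, collapse = "")), seq))
    stop("sequence contains letters outside the 20 amino acids plus X")
}

empty_hits <- function() {
  data.frame(sequence_id = character(), pattern_id = character(),
             family = character(), start = integer(), end = integer(),
             matched_text = character(), stringsAsFactors = FALSE)
}

#' Scan one protein sequence for a motif
#'
#' Tries every start position of `seq`. In mode `"first_per_position"` (the
#' default, and the behaviour of the screening pipeline) at most one hit is
#' reported per matching start, taking the shortest admissible gap lengths;
#' in mode `"all"` every admissible match (all gap-length combinations) is
#' enumerated.
#'
#' @param seq Protein sequence string (standard residues; `X` is tolerated
#'   and matches wildcard and gap positions only, never a residue set).
#' @param pattern A [parse_pattern()] result.
#' @param mode `"first_per_position"` or `"all"`.
#' @param sequence_id Identifier recorded in the hit table.
#' @return A data.frame of hits with columns `sequence_id`, `pattern_id`,
#'   `family`, `start`, `end` (0-based half-open), `matched_text`, sorted by
#'   `start`. Zero rows if there is no match.
#' @examples
#' p6 <- parse_pattern("[S,T]-x-xT-x-G-[Y,F,L]-G-[D,E]", "CH-6", "VG-channel")
#' scan_sequence("STATVGYGD", p6)$matched_text  # "STATVGYGD"
#' @export
scan_sequence <- function(seq, pattern,
                          mode = c("first_per_position", "all"),
                          sequence_id = NA_character_) {
  mode <- match.arg(mode)
  validate_protein(seq)
  if (!inherits(pattern, "MotifPattern")) stop("pattern must be a MotifPattern")
  if (!nzchar(seq)) return(empty_hits())
  if (mode == "first_per_position") {
    rx <- sprintf("(?=(%s))", motif_regex(pattern))
    m <- gregexpr(rx, seq, perl = TRUE)[[1]]
    if (m[[1]] == -1L) return(empty_hits())
    starts <- as.integer(attr(m, "capture.start")[, 1L])
    lens <- as.integer(attr(m, "capture.length")[, 1L])
    keep <- starts > 0L
    starts <- starts[keep]; lens <- lens[keep]
    if (length(starts) == 0L) return(empty_hits())
    out <- data.frame(
      sequence_id = sequence_id, pattern_id = pattern$pattern_id,
      family = pattern$family, start = starts - 1L,
      end = starts - 1L + lens,
      matched_text = substring(seq, starts, starts + lens - 1L),
      stringsAsFactors = FALSE)
  } else {
    chars <- strsplit(seq, "")[[1]]
    n <- length(chars)
    rows <- list()
    for (s in seq_len(n)) {
      for (e in match_ends(chars, pattern$elements, s)) {
        rows[[length(rows) + 1L]] <- c(s, e)
      }
    }
    if (length(rows) == 0L) return(empty_hits())
    se <- do.call(rbind, rows)
    out <- data.frame(
      sequence_id = sequence_id, pattern_id = pattern$pattern_id,
      family = pattern$family, start = se[, 1L] - 1L, end = se[, 2L],
      matched_text = substring(seq, se[, 1L], se[, 2L]),
      stringsAsFactors = FALSE)
  }
  out[order(out$start, out$end), , drop = FALSE]
}

# All end positions (1-based inclusive) at which `elements` can be matched
# starting at 1-based position `pos`. Recursive; used only by mode = "all"
# (the lookahead regex path covers first_per_position).
match_ends <- function(chars, elements, pos) {
  if (length(elements) == 0L) return(pos - 1L)
  el <- elements[[1L]]
  rest <- elements[-1L]
  n <- length(chars)
  if (el$kind == "residue_set") {
    if (pos > n || !(chars[[pos]] %in% el$residues)) return(integer())
    match_ends(chars, rest, pos + 1L)
  } else if (el$kind == "wildcard") {
    if (pos > n) return(integer())
    match_ends(chars, rest, pos + 1L)
  } else {
    ends <- integer()
    for (g in el$min_gap:el$max_gap) {
      if (pos + g - 1L > n) break
      ends <- c(ends, match_ends(chars, rest, pos + g))
    }
    sort(unique(ends))
  }
}

#' Scan a set of protein records with a motif library
#'
#' @param records Named character vector of protein sequences (names are
#'   sequence ids) as returned by [read_protein_fasta()].
#' @param library List of [parse_pattern()] objects, e.g. [motif_library()].
#' @param mode Passed to [scan_sequence()].
#' @return A data.frame of hits (union of per-sequence scans); sequences with
#'   no hit contribute no rows. Deterministic: rows ordered by record order,
#'   then library order, then position.
#' @export
scan_proteome <- function(records, library,
                          mode = "first_per_position") {
  if (length(records) == 0L) return(empty_hits())
  ids <- names(records)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("records must be a named character vector")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sequence id: %s", ids[duplicated(ids)][[1]]))
  if (inherits(library, "MotifPattern")) library <- list(library)
  out <- vector("list", length(records) * length(library))
  k <- 0L
  for (i in seq_along(records)) {
    for (p in library) {
      k <- k + 1L
      out[[k]] <- scan_sequence(records[[i]], p, mode = mode,
                                sequence_id = ids[[i]])
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' The canned K+ transporter motif library
#'
#' Loads the eleven family-diagnostic degenerate motifs used for the
#' genome-wide screen: five for HAK/KT/KUP, three for the K+ channel pore
#' region (shared by voltage-gated and tandem-pore TPK/KCO candidates;
#' pattern CH-6 covers the TVGYGD selectivity filter), two for HKT and one
#' for KEA. The library ships as a plain-text file; a stray opening
#' parenthesis printed at the head of the KEA motif is stripped as a
#' typographical artifact before parsing, and the space inside motifs 1 and
#' 3 is read as plain adjacency of the two bracket groups.
#'
#' @param x_n_min,x_n_max Bounds substituted for the unbounded `x(n)` repeat
#'   in the KEA motif (defaults 1 and 30; see [parse_pattern()]).
#' @param path Library file; defaults to the copy shipped with the package.
#' @return Named list of `MotifPattern` objects keyed by pattern id.
#' @export
motif_library <- function(x_n_min = 1L, x_n_max = 30L,
                          path = system.file("extdata", "motif_library.tsv",
                                             package = "kinventory")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  pats <- lapply(seq_len(nrow(tab)), function(i) {
    txt <- sub("^\\(", "", tab$pattern[[i]])  # stray "(" in the KEA motif
    parse_pattern(txt, pattern_id = tab$pattern_id[[i]],
                  family = tab$family[[i]],
                  x_n_min = x_n_min, x_n_max = x_n_max)
  })
  names(pats) <- tab$pattern_id
  pats
}

# Pattern ids belonging to each screened family. The three channel pore
# motifs are shared between the voltage-gated and TPK/KCO screens.
family_pattern_ids <- function(library) {
  ids <- names(library)
  fams <- vapply(library, function(p) p$family, character(1))
  sets <- split(ids, fams)
  if ("VG-channel" %in% names(sets)) sets[["TPK/KCO"]] <- sets[["VG-channel"]]
  sets
}

#' Write a motif hit table
#'
#' Emits 1-based inclusive coordinates (columns `start_1based`,
#' `end_1based`), the external convention of all report writers.
#'
#' @param hits Hit data.frame from [scan_proteome()].
#' @param path Output TSV path.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- data.frame(sequence_id = hits$sequence_id,
                    pattern_id = hits$pattern_id, family = hits$family,
                    start_1based = hits$start + 1L, end_1based = hits$end,
                    matched_text = hits$matched_text,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample one string from a motif's language
#'
#' Draws uniformly within residue sets, uniformly over the 20 standard
#' residues at wildcard positions, and (unless `gap_len` pins it) uniformly
#' over admissible gap lengths. Used by the synthetic-proteome generator.
#'
#' @param pattern A `MotifPattern`.
#' @param gap_len Optional fixed length for gap elements.
#' @return A string matching `pattern`.
#' @export
sample_motif <- function(pattern, gap_len = NULL) {
  paste(vapply(pattern$elements, function(el) {
    switch(el$kind,
      residue_set = sample(el$residues, 1L),
      wildcard = sample(AA20, 1L),
      gap = {
        g <- if (is.null(gap_len)) sample(el$min_gap:el$max_gap, 1L)
             else max(el$min_gap, min(el$max_gap, gap_len))
        paste(sample(AA20, g, replace = TRUE), collapse = "")
      })
  }, character(1)), collapse = "")
}
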
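# Independent oracles used across the suite. The brute-force motif matcher
# deliberately shares no code with the package's scanner: it walks every
# start position and every admissible gap length by plain recursion.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# All admissible end positions (1-based inclusive) for `elements` starting
# at 1-based `pos` of the character vector `chars`.
brute_ends <- function(chars, elements, pos) {
  if (length(elements) == 0L) return(pos - 1L)
  el <- elements[[1L]]
  if (el$kind == "residue_set") {
    if (pos > length(chars)) return(integer())
    if (!(chars[[pos]] %in% el$residues)) return(integer())
    return(brute_ends(chars, elements[-1L], pos + 1L))
  }
  if (el$kind == "wildcard") {
    if (pos > length(chars)) return(integer())
    return(brute_ends(chars, elements[-1L], pos + 1L))
  }
  out <- integer()
  for (g in el$min_gap:el$max_gap) {
    if (pos + g - 1L > length(chars)) break
    out <- c(out, brute_ends(chars, elements[-1L], pos + g))
  }
  sort(unique(out))
}

# Brute-force scan: one row per matching start position, shortest end.
brute_scan <- function(seq, pattern) {
  chars <- strsplit(seq, "")[[1]]
  rows <- list()
  for (s in seq_along(chars)) {
    ends <- brute_ends(chars, pattern$elements, s)
    if (length(ends))
      rows[[length(rows) + 1L]] <- c(start = s - 1L, end = min(ends))
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(), end = integer()))
  as.data.frame(do.call(rbind, rows))
}

# Brute-force scan enumerating every admissible (start, end).
brute_scan_all <- function(seq, pattern) {
  chars <- strsplit(seq, "")[[1]]
  rows <- list()
  for (s in seq_along(chars)) {
    for (e in brute_ends(chars, pattern$elements, s))
      rows[[length(rows) + 1L]] <- c(start = s - 1L, end = e)
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(), end = integer()))
  as.data.frame(do.call(rbind, rows))
}

# Random small pattern over a reduced alphabet (matches then occur by
# chance in random sequences over the same alphabet).
random_pattern <- function(alphabet = c("A", "C", "D", "G", "S", "T"),
                           n_elements = sample(3:6, 1L)) {
  els <- lapply(seq_len(n_elements), function(i) {
    kind <- sample(c("residue_set", "wildcard", "gap"), 1L,
                   prob = c(0.6, 0.25, 0.15))
    switch(kind,
      residue_set = list(kind = "residue_set",
                         residues = sample(alphabet,
                                           sample(1:3, 1L))),
      wildcard = list(kind = "wildcard"),
      gap = {
        lo <- sample(0:2, 1L)
        list(kind = "gap", min_gap = lo, max_gap = lo + sample(0:3, 1L))
      })
  })
  structure(list(pattern_id = "rand", family = "test", elements = els,
                 source_text = "<random>"), class = "MotifPattern")
}

random_seq <- function(n, alphabet = c("A", "C", "D", "G", "S", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Screening precision/recall of a screen result against a proteome truth.
screen_scores <- function(kept, truth_roles) {
  members <- truth_roles$sequence_id[truth_roles$role == "member"]
  list(precision = if (nrow(kept)) mean(kept$sequence_id %in% members) else NA,
       recall = mean(members %in% kept$sequence_id),
       family_ok = all(kept$family ==
                         truth_roles$family[match(kept$sequence_id,
                                                  truth_roles$sequence_id)]))
}
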
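# Readers and writers for the standard formats, plus pipeline configuration.

#' Read a protein FASTA
#'
#' Line wrapping is normalized; ids are the first whitespace-delimited token
#' of each header; record order is preserved.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sequence id in %s: %s", path,
                 ids[duplicated(ids)][[1]]))
  out <- as.character(x)
  names(out) <- ids
  out
}

#' Read a nucleotide (CDS) FASTA
#'
#' @inheritParams read_protein_fasta
#' @return Named character vector of sequences.
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sequence id in %s: %s", path,
                 ids[duplicated(ids)][[1]]))
  out <- as.character(x)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param type `"AA"` or `"DNA"`.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::AAStringSet(seqs)
       else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

gff3_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(sprintf("(?:^|;)%s=([^;]+)", key), attrs))
  vapply(m, function(v) if (length(v) == 2L) v[[2]] else NA_character_,
         character(1))
}

#' Read gene models from GFF3
#'
#' Minimal GFF3 reader for gene/mRNA/CDS features. 1-based closed
#' coordinates are converted to the internal 0-based half-open convention;
#' CDS features are grouped per isoform via their `Parent` attribute and the
#' isoform with the longest total CDS is kept per gene (configurable to the
#' first listed). Exons are returned in transcription order (reversed for
#' minus-strand models).
#'
#' @param path GFF3 file.
#' @param isoform `"longest"` (default) or `"first"`.
#' @return A named list of `GeneModel` objects (see [gene_model()]).
#' @export
read_gff3 <- function(path, isoform = c("longest", "first")) {
  isoform <- match.arg(isoform)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop(sprintf("malformed GFF3 line %d: %d columns (expected 9)",
                 lineno[which(nf != 9L)[[1]]], nf[nf != 9L][[1]]))
  tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tab) <- c("seqid", "source", "type", "start", "end", "score",
                  "strand", "phase", "attributes")
  tab$start <- as.integer(tab$start); tab$end <- as.integer(tab$end)

  mrna <- tab[tab$type == "mRNA", , drop = FALSE]
  mrna_id <- gff3_attr(mrna$attributes, "ID")
  mrna_gene <- gff3_attr(mrna$attributes, "Parent")
  mrna_gene[is.na(mrna_gene)] <- mrna_id[is.na(mrna_gene)]

  cds <- tab[tab$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) return(list())
  parent <- gff3_attr(cds$attributes, "Parent")
  orphan <- is.na(parent) | !(parent %in% mrna_id)
  if (any(orphan)) {
    warning(sprintf("skipping %d CDS feature(s) without a known mRNA parent",
                    sum(orphan)))
    cds <- cds[!orphan, , drop = FALSE]
    parent <- parent[!orphan]
  }
  if (nrow(cds) == 0L) return(list())

  models <- list()
  for (g in unique(mrna_gene)) {
    isos <- mrna_id[mrna_gene == g]
    isos <- isos[isos %in% parent]
    if (length(isos) == 0L) next
    if (isoform == "longest" && length(isos) > 1L) {
      totals <- vapply(isos, function(tr) {
        rows <- cds[parent == tr, , drop = FALSE]
        sum(rows$end - rows$start + 1L)
      }, numeric(1))
      isos <- isos[order(-totals, isos)][1L]
    } else {
      isos <- isos[1L]
    }
    rows <- cds[parent == isos, , drop = FALSE]
    rows <- rows[order(rows$start), , drop = FALSE]
    strand <- rows$strand[[1L]]
    exons <- cbind(start = rows$start - 1L, end = rows$end)  # 0-based half-open
    if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
    models[[g]] <- gene_model(gene_id = g, chromosome = rows$seqid[[1L]],
                              strand = strand, exons = exons)
  }
  models
}

#' Read a TPM expression matrix
#'
#' TSV with gene ids in the first column and condition labels in the header.
#'
#' @param path TSV file.
#' @return Numeric matrix, genes x conditions.
#' @export
read_tpm_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (anyDuplicated(tab[[1]])) stop("duplicate gene ids in TPM matrix")
  if (anyDuplicated(colnames(tab)[-1])) stop("duplicate condition labels")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  colnames(m) <- colnames(tab)[-1]
  if (any(m < 0)) stop("negative TPM values")
  m
}

#' Default pipeline configuration
#'
#' One list holding every tunable of the inventory pipeline: the motif
#' library gap bounds, motif-count policy, the 70% outermost-span curation
#' fraction, the >80% ortholog identity threshold, the TPM > 1 expressed
#' filter, the tandem-duplicate window, the synonymous clock rate preset,
#' the root seed, and the synthetic-data generator parameters.
#'
#' @param seed Root seed; all pipeline randomness derives from it.
#' @param outdir Report directory used by [run_inventory()].
#' @return Config list.
#' @export
default_config <- function(seed = 1L, outdir = "inventory_report") {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    x_n_min = 1L, x_n_max = 30L,
    motif_policy = c("HAK/KT/KUP" = 2L, "VG-channel" = 2L, "TPK/KCO" = 2L,
                     "HKT" = 2L, "KEA" = 1L),
    span_fraction = 0.70,
    identity_threshold = 80,
    tpm_threshold = 1.0,
    tandem_max_intervening = 5L,
    lambda_preset = "slow",
    gap_open = 10, gap_extend = 1,
    conserved_exon_fraction = 0.9,
    simulate = list(
      family_sizes = c("HAK/KT/KUP" = 29L, "VG-channel" = 16L,
                       "TPK/KCO" = 9L, "HKT" = 4L, "KEA" = 12L),
      n_truncated = 70L, n_random = 200L,
      n_clades = 6L, clade_queries = 10L, clade_refs = 2L,
      n_cds_pairs = 8L, cds_codons = 300L, k_star = 0.2,
      n_structure_pairs = 5L,
      tpm_conditions = c("RH_12HAI", "RH_12HAI_mock", "RH_24HAI",
                         "RH_24HAI_mock", "RH_48HAI", "RH_48HAI_mock"),
      tpm_planted = 6L, tpm_boost = 50,
      ortho_species = c("Gmax", "Pvul", "Athal", "Vvin", "Ptri")
    )
  )
}

#' Read / write a pipeline configuration
#'
#' YAML round-trip is lossless for the fields of [default_config()].
#'
#' @param path YAML file.
#' @param config Config list.
#' @name config_io
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  for (nm in c("motif_policy", "seed", "x_n_min", "x_n_max",
               "tandem_max_intervening"))
    base[[nm]] <- if (is.list(base[[nm]])) unlist(base[[nm]]) else base[[nm]]
  for (nm in c("family_sizes", "tpm_conditions", "ortho_species"))
    if (is.list(base$simulate[[nm]]))
      base$simulate[[nm]] <- unlist(base$simulate[[nm]])
  base
}

#' @rdname config_io
#' @export
write_config <- function(config, path) {
  # named atomic vectors nested in a list lose their names in YAML;
  # serialize them as maps
  config$motif_policy <- as.list(config$motif_policy)
  config$simulate$family_sizes <- as.list(config$simulate$family_sizes)
  yaml::write_yaml(config, path)
  invisible(path)
}

# Deterministic sub-seed derivation: every stage draws from its own stream
# so inserting a stage never perturbs the others. Kept below 2^31.
derive_seed <- function(seed, stage) {
  offs <- c(proteome = 101L, clades = 211L, cds = 307L, structure = 401L,
            tpm = 503L, ortho = 601L, scan = 701L)
  as.integer((as.numeric(seed) * 1000 + offs[[stage]]) %% 2147483629)
}
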
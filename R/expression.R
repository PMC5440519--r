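# TPM-based expression filtering, treated-vs-mock contrasts, and per-clade
# expression models (the maximally expressed gene and its condition).

#' Expressed-gene filter
#'
#' Genes with TPM strictly greater than `threshold` in at least one
#' condition. Monotone: raising the threshold never adds genes.
#'
#' @param matrix Numeric TPM matrix, genes x conditions.
#' @param threshold TPM cutoff (default 1; strict `>`).
#' @return Character vector of gene ids, in matrix row order.
#' @export
expressed_genes <- function(matrix, threshold = 1.0) {
  if (any(matrix < 0)) stop("TPM values must be non-negative")
  rownames(matrix)[apply(matrix, 1L, function(r) any(r > threshold))]
}

#' Per-clade expression models
#'
#' For every (family, clade), finds the argmax of TPM over (gene,
#' condition) among genes passing the expressed filter. Ties are broken by
#' lexicographic gene id, then condition order, and flagged. Clades whose
#' genes all fail the filter are reported as `no expression`.
#'
#' @param matrix Numeric TPM matrix, genes x conditions.
#' @param clades data.frame with columns `gene_id`, `family`, `clade`.
#'   Matrix genes without a clade are reported in the `unassigned`
#'   attribute, not an error.
#' @param threshold Expressed-gene TPM cutoff (default 1).
#' @return data.frame with one row per (family, clade): `gene_id`,
#'   `condition`, `tpm`, `n_expressed`, `tie` (logical), `expressed`
#'   (comma-separated expressed gene list). `gene_id`/`condition` are NA
#'   and `tpm` 0 for clades with no expression. Sorted by family, clade.
#' @export
clade_expression_model <- function(matrix, clades, threshold = 1.0) {
  expressed <- expressed_genes(matrix, threshold)
  unassigned <- setdiff(rownames(matrix), clades$gene_id)
  conds <- colnames(matrix)
  key <- paste(clades$family, clades$clade, sep = "\r")
  groups <- split(clades$gene_id, key)
  groups <- groups[order(names(groups))]
  rows <- lapply(names(groups), function(k) {
    fam_clade <- strsplit(k, "\r", fixed = TRUE)[[1]]
    genes <- sort(intersect(groups[[k]], rownames(matrix)))
    exp_genes <- intersect(genes, expressed)
    base <- data.frame(family = fam_clade[[1]], clade = fam_clade[[2]],
                       stringsAsFactors = FALSE)
    if (length(exp_genes) == 0L)
      return(cbind(base, data.frame(
        gene_id = NA_character_, condition = NA_character_, tpm = 0,
        n_expressed = 0L, tie = FALSE, expressed = "",
        status = "no expression", stringsAsFactors = FALSE)))
    sub <- matrix[exp_genes, , drop = FALSE]
    mx <- max(sub)
    hits <- which(sub == mx, arr.ind = TRUE)
    # lexicographic gene id, then condition order
    ord <- order(rownames(sub)[hits[, "row"]], hits[, "col"])
    top <- hits[ord[[1]], , drop = FALSE]
    cbind(base, data.frame(
      gene_id = rownames(sub)[top[[1, "row"]]],
      condition = conds[[top[[1, "col"]]]], tpm = mx,
      n_expressed = length(exp_genes), tie = nrow(hits) > 1L,
      expressed = paste(exp_genes, collapse = ","),
      status = "expressed", stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "unassigned") <- unassigned
  out
}

#' Treated-vs-mock log ratios
#'
#' `log2((TPM_treated + 1) / (TPM_mock + 1))` per gene and timepoint, with
#' a fixed pseudo-count of 1 so the contrast is finite for silent genes.
#'
#' @param matrix Numeric TPM matrix, genes x conditions.
#' @param pairing data.frame with columns `treated` and `mock` naming
#'   matrix columns; each treated label maps to exactly one mock label.
#' @return Numeric matrix, genes x treated labels.
#' @export
treated_vs_mock <- function(matrix, pairing) {
  if (anyDuplicated(pairing$treated))
    stop("each treated label must appear once in the pairing")
  missing <- setdiff(c(pairing$treated, pairing$mock), colnames(matrix))
  if (length(missing))
    stop(sprintf("unpaired condition label not in matrix: %s", missing[[1]]))
  out <- sapply(seq_len(nrow(pairing)), function(i) {
    log2((matrix[, pairing$treated[[i]]] + 1) /
           (matrix[, pairing$mock[[i]]] + 1))
  })
  out <- base::matrix(out, nrow = nrow(matrix),
                      dimnames = list(rownames(matrix), pairing$treated))
  out
}

#' Write expression models
#'
#' TSV plus JSON mirroring the per-family, per-clade model structure
#' (family, clade, maximally expressed gene, condition, TPM).
#'
#' @param models Output of [clade_expression_model()].
#' @param path_tsv,path_json Output paths (either may be NULL to skip).
#' @export
write_expression_models <- function(models, path_tsv = NULL,
                                    path_json = NULL) {
  if (!is.null(path_tsv))
    utils::write.table(models, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(models, path_json, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(models)
}
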
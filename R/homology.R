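# Pairwise global identity, neighbor-joining clade assignment against
# reference anchors, and identity-threshold ortholog clustering.

#' Global percent identity of two proteins
#'
#' Needleman-Wunsch global alignment with affine gaps on BLOSUM62; identity
#' is matches over alignment length (gap columns included) times 100, i.e.
#' PID1. Symmetric in its arguments.
#'
#' @param seq_a,seq_b Protein sequences (non-empty).
#' @param gap_open,gap_extend Affine gap penalties (defaults 10 and 1).
#' @return Percent identity in \[0, 100\].
#' @examples
#' global_identity("ACDE", "ACDF")  # 75
#' @export
global_identity <- function(seq_a, seq_b, gap_open = 10, gap_extend = 1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = "BLOSUM62", gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  Biostrings::pid(al, type = "PID1")
}

#' All-vs-all identity matrix
#'
#' @param seqs Named character vector of protein sequences.
#' @inheritParams global_identity
#' @return Symmetric matrix of percent identities with 100 on the diagonal.
#' @export
identity_matrix <- function(seqs, gap_open = 10, gap_extend = 1) {
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- global_identity(seqs[[i]], seqs[[j]],
                                            gap_open, gap_extend)
    }
  }
  m
}

#' p-distance matrix from an alignment
#'
#' `d = 1 - matches / compared columns` with pairwise deletion of columns
#' where either row carries a gap (`-`).
#'
#' @param aln Named character vector of equal-length aligned rows.
#' @return Symmetric distance matrix.
#' @export
p_distance_matrix <- function(aln) {
  lens <- nchar(aln)
  if (length(unique(lens)) != 1L) stop("aligned rows must have equal length")
  chars <- do.call(rbind, strsplit(aln, ""))
  rownames(chars) <- names(aln)
  n <- nrow(chars)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq_len(n)[-seq_len(i)]) {
      ok <- chars[i, ] != "-" & chars[j, ] != "-"
      if (!any(ok))
        stop(sprintf("no comparable columns between %s and %s",
                     names(aln)[[i]], names(aln)[[j]]))
      d[i, j] <- d[j, i] <- 1 - sum(chars[i, ok] == chars[j, ok]) / sum(ok)
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a symmetric distance matrix. Negative
#' branch-length estimates (which NJ can produce on non-additive input) are
#' clamped to zero and the clamped total is recorded in the
#' `clamped_negative` attribute.
#'
#' @param d Square symmetric numeric matrix with at least 3 taxa, or a
#'   `dist` object.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  tr <- ape::nj(as.dist(d))
  neg <- tr$edge.length < 0
  clamped <- -sum(tr$edge.length[neg])
  tr$edge.length[neg] <- 0
  attr(tr, "clamped_negative") <- clamped
  tr
}

#' Assign clade labels by nearest reference leaf
#'
#' Every unlabeled leaf receives the clade label of the reference leaf at
#' minimum patristic (path) distance. Exact ties are broken by the smaller
#' enclosing clade (fewer leaves under the query/reference MRCA), then by
#' the lexicographically smaller label.
#'
#' @param tree `phylo` tree containing query and reference leaves.
#' @param ref_labels Named character vector: reference leaf -> clade label.
#' @return data.frame with `gene_id` and `clade` for every non-reference
#'   leaf.
#' @export
assign_clades <- function(tree, ref_labels) {
  refs <- names(ref_labels)
  if (length(refs) == 0L) stop("no reference leaves supplied")
  missing <- setdiff(refs, tree$tip.label)
  if (length(missing))
    stop(sprintf("reference leaf not in tree: %s", missing[[1]]))
  queries <- setdiff(tree$tip.label, refs)
  pd <- ape::cophenetic.phylo(tree)
  out <- lapply(queries, function(q) {
    dq <- pd[q, refs]
    best <- refs[dq <= min(dq) + 1e-12]
    if (length(best) > 1L) {
      # leaves under the MRCA of query and each tied reference
      sizes <- vapply(best, function(r) {
        node <- ape::getMRCA(tree, c(q, r))
        length(ape::extract.clade(tree, node)$tip.label)
      }, numeric(1))
      best <- best[order(sizes, ref_labels[best])]
    }
    data.frame(gene_id = q, clade = unname(ref_labels[[best[[1]]]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Cluster orthologs at an identity threshold
#'
#' Builds a graph with an edge wherever identity is strictly greater than
#' `threshold` and takes connected components as ortholog clusters. The
#' Venn summary counts clusters per species-membership pattern.
#'
#' @param identity Symmetric percent-identity matrix; row/col names are
#'   gene ids.
#' @param species Named character vector: gene id -> species.
#' @param threshold Identity threshold (default 80; strictly greater).
#' @return List with `clusters` (data.frame `cluster_id`, `gene_id`,
#'   `species`) and `venn` (data.frame `pattern`, `n_clusters`).
#' @export
cluster_orthologs <- function(identity, species, threshold = 80) {
  ids <- rownames(identity)
  if (is.null(ids)) stop("identity matrix must carry gene ids as dimnames")
  if (!all(ids %in% names(species))) stop("every gene needs a species")
  adj <- identity > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  member <- comp$membership[ids]
  # stable cluster ids: numbered by first member in input order
  first <- !duplicated(member)
  relabel <- stats::setNames(seq_len(sum(first)), member[first])
  cl <- unname(relabel[as.character(member)])
  clusters <- data.frame(cluster_id = cl, gene_id = ids,
                         species = unname(species[ids]),
                         stringsAsFactors = FALSE)
  patterns <- vapply(split(clusters$species, clusters$cluster_id),
                     function(s) paste(sort(unique(s)), collapse = "&"),
                     character(1))
  venn <- as.data.frame(table(pattern = patterns), stringsAsFactors = FALSE)
  names(venn) <- c("pattern", "n_clusters")
  list(clusters = clusters, venn = venn)
}
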
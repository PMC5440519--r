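# Identity, distances, neighbor joining, clade assignment, clustering.

test_that("global identity matches the dynamic-programming count", {
  expect_equal(global_identity("ACDE", "ACDE"), 100)
  expect_equal(global_identity("ACDE", "ACDF"), 75)
  set.seed(5)
  for (i in 1:5) {
    a <- random_seq(sample(10:40, 1), AA20)
    b <- random_seq(sample(10:40, 1), AA20)
    expect_equal(global_identity(a, b), global_identity(b, a))
  }
  expect_error(global_identity("", "ACD"), "non-empty")
})

test_that("p-distance agrees with a hand count and handles gaps pairwise", {
  aln <- c(r1 = "ACDEFGHIKL",
           r2 = "ACDEFGHIKV",   # 1 difference in 10
           r3 = "ACDEF-HIKL")   # gap column dropped for pairs with r3
  d <- p_distance_matrix(aln)
  expect_equal(d["r1", "r2"], 0.1)
  expect_equal(d["r1", "r3"], 0)
  expect_equal(d["r2", "r3"], 1 / 9)
  expect_equal(diag(d), c(r1 = 0, r2 = 0, r3 = 0))
  expect_equal(p_distance_matrix(c(a = "AAAA", b = "CCCC"))["a", "b"], 1)
  expect_error(p_distance_matrix(c(a = "A-", b = "-A")), "comparable")
  expect_error(p_distance_matrix(c(a = "AA", b = "AAA")), "equal length")
})

test_that("neighbor joining reconstructs an additive 4-taxon tree exactly", {
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- d["B", "A"] <- 3
  d["C", "D"] <- d["D", "C"] <- 7
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  tr <- nj_tree(d)
  # split AB|CD: patristic distances reproduce the input exactly
  pd <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(pd, d, tolerance = 1e-9)
  # leaf branch lengths A=1, B=2, C=3, D=4, internal 1
  leaf_edges <- tr$edge[, 2] <= 4
  bl <- tr$edge.length[leaf_edges]
  names(bl) <- tr$tip.label[tr$edge[leaf_edges, 2]]
  expect_equal(bl[c("A", "B", "C", "D")], c(A = 1, B = 2, C = 3, D = 4))
  expect_equal(tr$edge.length[!leaf_edges], 1)
})

test_that("neighbor joining rejects malformed input and resolves 3 taxa", {
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  tr <- nj_tree(d3)
  expect_equal(ape::Ntip(tr), 3L)
  bad <- d3; bad[1, 2] <- 9
  expect_error(nj_tree(bad), "symmetric")
  expect_error(nj_tree(d3[1:2, 1:2]), "at least 3")
})

test_that("permuting taxa permutes leaves but keeps the topology", {
  set.seed(9)
  tr0 <- ape::rtree(6, br = function(n) runif(n, 0.2, 1))
  d <- ape::cophenetic.phylo(tr0)
  perm <- sample(rownames(d))
  t1 <- nj_tree(d)
  t2 <- nj_tree(d[perm, perm])
  expect_setequal(t2$tip.label, t1$tip.label)
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
})

test_that("clade labels propagate from the nearest reference", {
  # star-ish tree with two labeled references and one query grafted at
  # zero distance from the Ia reference
  tr <- ape::read.tree(text = "((refIa:0.0,q1:0.0):1,(refII:0.5,q2:0.4):1);")
  asg <- assign_clades(tr, c(refIa = "Ia", refII = "II"))
  expect_equal(asg$clade[asg$gene_id == "q1"], "Ia")
  expect_equal(asg$clade[asg$gene_id == "q2"], "II")
  expect_error(assign_clades(tr, c(absent = "Ia")), "not in tree")
  # equidistant references with the same label: the tie is irrelevant
  tr2 <- ape::read.tree(text = "((r1:1,q:1):1,(r2:1,x:9):1);")
  asg2 <- assign_clades(tr2, c(r1 = "V", r2 = "V"))
  expect_equal(asg2$clade[asg2$gene_id == "q"], "V")
})

test_that("planted clades are recovered from evolved sequences", {
  cl <- simulate_clade_sequences(n_clades = 3L, queries_per_clade = 6L,
                                 seed = 13L)
  tree <- nj_tree(p_distance_matrix(cl$alignment))
  asg <- assign_clades(tree, cl$ref_labels)
  m <- merge(asg, cl$truth$clades, by = "gene_id")
  expect_gte(mean(m$clade.x == m$clade.y), 0.95)
})

test_that("ortholog clustering partitions genes with a strict threshold", {
  ids <- c("g1", "g2", "g3", "g4")
  idm <- matrix(40, 4, 4, dimnames = list(ids, ids))
  diag(idm) <- 100
  idm["g1", "g2"] <- idm["g2", "g1"] <- 95
  idm["g3", "g4"] <- idm["g4", "g3"] <- 85
  sp <- c(g1 = "A", g2 = "B", g3 = "A", g4 = "C")
  cl <- cluster_orthologs(idm, sp, 80)
  expect_equal(max(cl$clusters$cluster_id), 2L)
  expect_setequal(cl$clusters$gene_id, ids)  # a partition covers everyone
  expect_equal(sum(cl$venn$n_clusters), 2L)
  # boundary: an edge at exactly the threshold does not join (g3-g4 at 85
  # still does)
  idm2 <- idm; idm2["g1", "g2"] <- idm2["g2", "g1"] <- 80
  cl2 <- cluster_orthologs(idm2, sp, 80)
  expect_equal(max(cl2$clusters$cluster_id), 3L)
  # threshold 100 on distinct sequences: all singletons
  cl3 <- cluster_orthologs(idm, sp, 100)
  expect_equal(max(cl3$clusters$cluster_id), 4L)
})

test_that("clustering is order-invariant and monotone in the threshold", {
  or <- simulate_ortholog_families(n_families = 2L,
                                   species = c("Gmax", "Pvul", "Athal"),
                                   seed = 23L)
  idm <- identity_matrix(or$seqs)
  base <- cluster_orthologs(idm, or$species, 80)
  expect_equal(max(base$clusters$cluster_id), 2L)
  set.seed(1)
  perm <- sample(rownames(idm))
  shuf <- cluster_orthologs(idm[perm, perm], or$species, 80)
  # same partition as sets of member sets
  part <- function(cl) unname(lapply(
    split(cl$clusters$gene_id, cl$clusters$cluster_id), sort))
  expect_setequal(part(shuf), part(base))
  # raising the threshold only splits, never merges
  for (thr in c(85, 90, 97, 99.9)) {
    finer <- cluster_orthologs(idm, or$species, thr)
    for (grp in part(finer)) {
      holder <- vapply(part(base), function(g) all(grp %in% g), logical(1))
      expect_equal(sum(holder), 1L)
    }
  }
})
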
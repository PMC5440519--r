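# Seed-deterministic generators for every input the inventory pipeline
# consumes, with planted ground truth. Each generator records its seed and
# parameters in the truth object it returns; regenerating with the same
# seed reproduces identical output.

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

# Uniform integer in [lo, hi]; safe when lo == hi (sample() would otherwise
# treat a length-1 numeric as 1:n).
sample_range <- function(lo, hi) if (lo >= hi) as.integer(lo) else
  sample(lo:hi, 1L)

mutate_protein <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  k <- round(rate * length(chars))
  if (k == 0L) return(seq)
  pos <- sample(length(chars), k)
  for (p in pos) chars[[p]] <- sample(setdiff(AA20, chars[[p]]), 1L)
  paste(chars, collapse = "")
}

# Motif plan per family: which patterns are planted, in order, along a
# member chain. The tandem-pore family carries the pore motif twice.
family_motif_plan <- function() {
  list("HAK/KT/KUP" = c("HAK-1", "HAK-2", "HAK-3", "HAK-4", "HAK-5"),
       "VG-channel" = c("CH-7", "CH-6", "CH-8"),
       "TPK/KCO"    = c("CH-6", "CH-8", "CH-6"),
       "HKT"        = c("HKT-9", "HKT-10"),
       "KEA"        = c("KEA-11"))
}

# Sample one motif instance; KEA gap linkers avoid D/E so the scanner's
# shortest-gap match reports exactly the planted gap length.
plant_motif <- function(pattern, gap_len) {
  paste(vapply(pattern$elements, function(el) {
    switch(el$kind,
      residue_set = sample(el$residues, 1L),
      wildcard = sample(AA20, 1L),
      gap = {
        g <- max(el$min_gap, min(el$max_gap, gap_len))
        paste(sample(setdiff(AA20, c("D", "E")), g, replace = TRUE),
              collapse = "")
      })
  }, character(1)), collapse = "")
}

# Assemble flank + motif/spacer chain + flank; returns the sequence and the
# planted (pattern_id, start, end) table (0-based half-open).
assemble_member <- function(library, plan, spacer_range, flank_range,
                            kea_gap_range) {
  flank5 <- sample_range(flank_range[[1]], flank_range[[2]])
  parts <- random_protein(flank5)
  pos <- flank5
  planted <- list()
  for (i in seq_along(plan)) {
    if (i > 1L) {
      sp <- sample_range(spacer_range[[1]], spacer_range[[2]])
      parts <- c(parts, random_protein(sp))
      pos <- pos + sp
    }
    gap_len <- sample_range(kea_gap_range[[1]], kea_gap_range[[2]])
    m <- plant_motif(library[[plan[[i]]]], gap_len)
    parts <- c(parts, m)
    planted[[i]] <- data.frame(pattern_id = plan[[i]], start = pos,
                               end = pos + nchar(m), stringsAsFactors = FALSE)
    pos <- pos + nchar(m)
  }
  flank3 <- sample(flank_range[[1]]:flank_range[[2]], 1L)
  parts <- c(parts, random_protein(flank3))
  list(seq = paste(parts, collapse = ""), planted = do.call(rbind, planted))
}

# Does the scan of `seq` yield exactly the planted (pattern_id, start) set?
hits_exactly <- function(seq, library, planted) {
  hits <- scan_proteome(c(q = seq), library)
  got <- sort(paste(hits$pattern_id, hits$start))
  want <- sort(paste(planted$pattern_id, planted$start))
  identical(got, want)
}

#' Simulate a proteome with planted family members and decoys
#'
#' Members are random flanks around strings sampled from their family's
#' motif languages at realistic inter-motif spacings; truncated decoys
#' carry the same motifs at compressed spacings so their outermost span
#' falls below 70% of the reference span; random decoys carry no motif
#' match at all. Flanks and linkers are resampled until each sequence's
#' scanned hit set is exactly the planted set, so the recorded truth is
#' exact. A reference set (fixed canonical spacing) is generated per family
#' for the span-curation yardstick.
#'
#' @param family_sizes Named integer vector of member counts per family
#'   (defaults: 29 HAK/KT/KUP, 16 voltage-gated, 9 TPK/KCO, 4 HKT, 12 KEA).
#' @param n_truncated Total truncated decoys, allocated across families
#'   proportionally to `family_sizes`.
#' @param n_random Random decoys with no planted motifs.
#' @param n_refs Reference proteins per family.
#' @param seed Generator seed.
#' @param library Motif library.
#' @return List with `proteome` (named vector: members, truncated decoys,
#'   random decoys), `refs`, `ref_families`, and `truth` (role table,
#'   planted hit table, parameters, seed).
#' @export
simulate_proteome <- function(family_sizes = default_config()$simulate$family_sizes,
                              n_truncated = 70L, n_random = 200L,
                              n_refs = 3L, seed = 1L,
                              library = motif_library()) {
  set.seed(seed)
  plan <- family_motif_plan()
  fams <- names(family_sizes)
  member_spacer <- c(30L, 60L); member_flank <- c(40L, 80L)
  member_gap <- c(20L, 30L)
  trunc_spacer <- c(2L, 6L); trunc_flank <- c(15L, 30L)
  trunc_gap <- c(1L, 5L)
  fam_code <- c("HAK/KT/KUP" = "HAK", "VG-channel" = "VGK", "TPK/KCO" = "TPK",
                "HKT" = "HKT", "KEA" = "KEA")

  proteome <- character(); roles <- list(); planted_all <- list()
  gen_one <- function(id, fam, spacer, flank, gap, role) {
    for (try in 1:100) {
      a <- assemble_member(library, plan[[fam]], spacer, flank, gap)
      if (hits_exactly(a$seq, library, a$planted)) {
        proteome[[id]] <<- a$seq
        roles[[length(roles) + 1L]] <<- data.frame(
          sequence_id = id, family = fam, role = role,
          stringsAsFactors = FALSE)
        a$planted$sequence_id <- id
        planted_all[[length(planted_all) + 1L]] <<- a$planted
        return(invisible(NULL))
      }
    }
    stop(sprintf("could not assemble a clean sequence for %s after 100 tries", id))
  }

  for (fam in fams) {
    for (i in seq_len(family_sizes[[fam]]))
      gen_one(sprintf("%s_m%02d", fam_code[[fam]], i), fam,
              member_spacer, member_flank, member_gap, "member")
  }
  trunc_per_fam <- round(n_truncated * family_sizes / sum(family_sizes))
  for (fam in fams) {
    for (i in seq_len(trunc_per_fam[[fam]]))
      gen_one(sprintf("%s_t%02d", fam_code[[fam]], i), fam,
              trunc_spacer, trunc_flank, trunc_gap, "truncated")
  }
  for (i in seq_len(n_random)) {
    id <- sprintf("DEC%03d", i)
    for (try in 1:100) {
      s <- random_protein(sample(150:400, 1L))
      if (nrow(scan_proteome(stats::setNames(s, id), library)) == 0L) {
        proteome[[id]] <- s
        roles[[length(roles) + 1L]] <- data.frame(
          sequence_id = id, family = NA_character_, role = "random_decoy",
          stringsAsFactors = FALSE)
        break
      }
      if (try == 100L) stop("could not generate a motif-free decoy")
    }
  }

  refs <- character(); ref_families <- character()
  for (fam in fams) {
    for (i in seq_len(n_refs)) {
      id <- sprintf("REF_%s_%d", fam_code[[fam]], i)
      for (try in 1:100) {
        a <- assemble_member(library, plan[[fam]], c(45L, 45L), c(50L, 50L),
                             c(25L, 25L))
        if (hits_exactly(a$seq, library, a$planted)) {
          refs[[id]] <- a$seq
          ref_families[[id]] <- fam
          break
        }
        if (try == 100L) stop("could not assemble a clean reference")
      }
    }
  }

  list(proteome = proteome, refs = refs, ref_families = ref_families,
       truth = list(
         roles = do.call(rbind, c(roles, list(make.row.names = FALSE))),
         planted_hits = do.call(rbind,
                                c(planted_all, list(make.row.names = FALSE))),
         params = list(family_sizes = as.list(family_sizes),
                       n_truncated = n_truncated, n_random = n_random,
                       n_refs = n_refs),
         seed = seed))
}

#' Simulate aligned sequences from clade-specific ancestors
#'
#' A base ancestor is mutated independently per clade (ancestor divergence
#' `ancestor_d`), and clade members are mutated copies of their clade
#' ancestor (`within_d`). Substitution-only, so the sequences remain
#' aligned. With the defaults the between-clade distance is at least three
#' times the within-clade distance.
#'
#' @param n_clades Number of clades.
#' @param queries_per_clade,refs_per_clade Members per clade.
#' @param length Sequence length (aa).
#' @param within_d Per-member substitution fraction from the clade ancestor
#'   (default 0.05).
#' @param ancestor_d Per-clade substitution fraction from the base ancestor
#'   (default 0.25).
#' @param family Family label recorded in the truth.
#' @param seed Generator seed.
#' @return List with `alignment` (named vector, references first),
#'   `ref_labels` (reference id -> clade), and `truth` (gene -> clade,
#'   parameters, seed).
#' @export
simulate_clade_sequences <- function(n_clades = 4L, queries_per_clade = 10L,
                                     refs_per_clade = 2L, length = 300L,
                                     within_d = 0.05, ancestor_d = 0.25,
                                     family = "HAK/KT/KUP", seed = 1L) {
  set.seed(seed)
  base <- random_protein(length)
  clade_names <- as.character(utils::as.roman(seq_len(n_clades)))
  aln <- character(); ref_labels <- character(); truth <- list()
  for (ci in seq_len(n_clades)) {
    anc <- mutate_protein(base, ancestor_d)
    for (r in seq_len(refs_per_clade)) {
      id <- sprintf("REF_%s_%d", clade_names[[ci]], r)
      aln[[id]] <- mutate_protein(anc, within_d)
      ref_labels[[id]] <- clade_names[[ci]]
    }
    for (q in seq_len(queries_per_clade)) {
      id <- sprintf("Q_%s_%02d", clade_names[[ci]], q)
      aln[[id]] <- mutate_protein(anc, within_d)
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = id, clade = clade_names[[ci]], family = family,
        stringsAsFactors = FALSE)
    }
  }
  list(alignment = aln, ref_labels = ref_labels,
       truth = list(clades = do.call(rbind,
                                     c(truth, list(make.row.names = FALSE))),
                    params = list(n_clades = n_clades,
                                  queries_per_clade = queries_per_clade,
                                  refs_per_clade = refs_per_clade,
                                  length = length, within_d = within_d,
                                  ancestor_d = ancestor_d),
                    seed = seed))
}

random_cds <- function(n_codons) {
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

# Apply a Poisson number of synonymous-only substitutions (expectation
# k_star * S) to a codon vector. Events pick a (codon, target) uniformly
# among all synonymous single-nucleotide changes, so the expected number of
# events per synonymous site is k_star. Synonymous changes never create a
# stop codon.
evolve_synonymous <- function(codons, k_star) {
  nb <- codon_syn_neighbours()
  sites <- codon_syn_sites()
  S <- sum(sites[codons])
  n_events <- stats::rpois(1L, k_star * S)
  w <- lengths(nb[codons])
  for (e in seq_len(n_events)) {
    i <- sample.int(length(codons), 1L, prob = w)
    codons[[i]] <- sample(nb[[codons[[i]]]], 1L)
    w[[i]] <- length(nb[[codons[[i]]]])
  }
  codons
}

#' Simulate a duplicated CDS pair with controlled synonymous divergence
#'
#' Generates an ancestral stop-free CDS and applies synonymous-only
#' substitutions at expected divergence `k_star` per synonymous site, then
#' places the pair either adjacently on one chromosome (tandem) or on two
#' chromosomes inside a declared duplicated block (segmental).
#'
#' @param n_codons CDS length in codons.
#' @param k_star Expected synonymous substitutions per synonymous site.
#' @param mode `"tandem"` or `"segmental"`.
#' @param pair_id Stem for the two gene ids.
#' @param seed Generator seed.
#' @return List with `cds` (named vector of 2), `gene_order` rows, `blocks`
#'   (NULL for tandem), and `truth`.
#' @export
simulate_duplicated_cds <- function(n_codons = 300L, k_star = 0.2,
                                    mode = c("tandem", "segmental"),
                                    pair_id = "PAIR1", seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  anc <- split_codons(random_cds(n_codons))
  der <- evolve_synonymous(anc, k_star)
  ga <- paste0(pair_id, "a"); gb <- paste0(pair_id, "b")
  cds <- stats::setNames(c(paste(anc, collapse = ""),
                           paste(der, collapse = "")), c(ga, gb))
  if (mode == "tandem") {
    gene_order <- data.frame(gene = c(ga, gb), chromosome = "Chr1",
                             rank = c(10L, 11L), stringsAsFactors = FALSE)
    blocks <- NULL
  } else {
    gene_order <- data.frame(gene = c(ga, gb), chromosome = c("Chr1", "Chr2"),
                             rank = c(10L, 25L), stringsAsFactors = FALSE)
    blocks <- data.frame(chrom_1 = "Chr1", start_1 = 5L, end_1 = 15L,
                         chrom_2 = "Chr2", start_2 = 20L, end_2 = 30L,
                         stringsAsFactors = FALSE)
  }
  list(cds = cds, gene_order = gene_order, blocks = blocks,
       truth = list(pair = c(ga, gb), mode = mode, k_star = k_star,
                    n_codons = n_codons, seed = seed))
}

#' Simulate a set of paralog pairs on a small genome layout
#'
#' Convenience wrapper placing `n_pairs` duplicated CDS pairs (alternating
#' tandem/segmental) on a toy chromosome layout with filler genes, for the
#' pipeline's duplication stage.
#'
#' @param n_pairs Number of pairs.
#' @param n_codons,k_star Passed per pair to the CDS evolver.
#' @param seed Generator seed.
#' @return List with `cds`, `pairs`, `gene_order`, `blocks`, `truth`.
#' @export
simulate_paralog_set <- function(n_pairs = 8L, n_codons = 300L,
                                 k_star = 0.2, seed = 1L) {
  set.seed(seed)
  cds <- character(); pairs <- list(); order_rows <- list(); blocks <- list()
  truth <- list()
  for (p in seq_len(n_pairs)) {
    mode <- if (p %% 2L == 1L) "tandem" else "segmental"
    anc <- split_codons(random_cds(n_codons))
    der <- evolve_synonymous(anc, k_star)
    ga <- sprintf("P%02da", p); gb <- sprintf("P%02db", p)
    cds[[ga]] <- paste(anc, collapse = "")
    cds[[gb]] <- paste(der, collapse = "")
    pairs[[p]] <- data.frame(gene_a = ga, gene_b = gb,
                             stringsAsFactors = FALSE)
    if (mode == "tandem") {
      chr <- sprintf("Chr%d", p)
      order_rows[[p]] <- data.frame(gene = c(ga, gb), chromosome = chr,
                                    rank = c(3L, 5L), stringsAsFactors = FALSE)
    } else {
      ca <- sprintf("Chr%d", p); cb <- sprintf("Chr%dB", p)
      order_rows[[p]] <- data.frame(gene = c(ga, gb), chromosome = c(ca, cb),
                                    rank = c(10L, 40L),
                                    stringsAsFactors = FALSE)
      blocks[[length(blocks) + 1L]] <- data.frame(
        chrom_1 = ca, start_1 = 8L, end_1 = 12L,
        chrom_2 = cb, start_2 = 38L, end_2 = 42L, stringsAsFactors = FALSE)
    }
    truth[[p]] <- data.frame(gene_a = ga, gene_b = gb, mode = mode,
                             k_star = k_star, stringsAsFactors = FALSE)
  }
  list(cds = cds,
       pairs = do.call(rbind, c(pairs, list(make.row.names = FALSE))),
       gene_order = do.call(rbind, c(order_rows,
                                     list(make.row.names = FALSE))),
       blocks = do.call(rbind, c(blocks, list(make.row.names = FALSE))),
       truth = list(pairs = do.call(rbind,
                                    c(truth, list(make.row.names = FALSE))),
                    seed = seed, k_star = k_star, n_codons = n_codons))
}

# A random exon length in [lo, hi] congruent to `residue` mod 3.
spacer_len <- function(lo, hi, residue = 0L) {
  v <- seq(lo, hi)
  v <- v[v %% 3L == residue %% 3L]
  v[sample.int(length(v), 1L)]
}

#' Simulate gene-model pairs sharing template exons
#'
#' Every pair of genes shares a full exon chain: pair-specific spacer exons
#' interleaved with the family's template exons. Spacer exon lengths are
#' multiples of 3 (the last one adjusts the total to a multiple of 3), so
#' the template exons keep the same splice-phase context in every member.
#' Perturbation lengthens one template exon by 3 nt (frame-preserving) in
#' `n_perturb` members, creating the "conserved in all except ..." pattern.
#'
#' @param templates Template exon lengths in nt (default the 260/52/254
#'   family profile).
#' @param n_pairs Number of duplicated gene pairs (2 genes each).
#' @param n_perturb Number of members carrying a perturbed template exon.
#' @param intron_length Fixed intron length in nt.
#' @param seed Generator seed.
#' @return List with `models` (GeneModel list), `structures`
#'   (ExonStructure list), `gff` (GFF3 text lines), and `truth` (template
#'   exon indices per gene, perturbed members, parameters, seed).
#' @export
simulate_gene_models <- function(templates = c(260L, 52L, 254L),
                                 n_pairs = 5L, n_perturb = 0L,
                                 intron_length = 100L, seed = 1L) {
  set.seed(seed)
  n_members <- 2L * n_pairs
  if (n_perturb > n_members) stop("more perturbations than members")
  perturbed <- if (n_perturb > 0L)
    sort(sample(n_members, n_perturb)) else integer(0)
  k <- length(templates)
  total_t <- sum(templates)
  models <- list(); truth_rows <- list(); perturb_rows <- list()
  member <- 0L
  for (p in seq_len(n_pairs)) {
    spacers <- vapply(seq_len(k - 1L), function(i)
      spacer_len(60L, 300L, 0L), integer(1))
    first <- spacer_len(60L, 300L, 0L)
    last <- spacer_len(60L, 300L, (3L - total_t %% 3L) %% 3L)
    chain <- integer(0)
    template_idx <- integer(0)
    chain <- c(chain, first)
    for (i in seq_len(k)) {
      chain <- c(chain, templates[[i]])
      template_idx <- c(template_idx, length(chain))
      if (i < k) chain <- c(chain, spacers[[i]])
    }
    chain <- c(chain, last)
    for (copy in c("a", "b")) {
      member <- member + 1L
      lens <- chain
      if (member %in% perturbed) {
        ti <- sample(k, 1L)
        lens[[template_idx[[ti]]]] <- lens[[template_idx[[ti]]]] + 3L
        perturb_rows[[length(perturb_rows) + 1L]] <- data.frame(
          gene_id = sprintf("G%02d%s", p, copy), template_index = ti,
          stringsAsFactors = FALSE)
      }
      gid <- sprintf("G%02d%s", p, copy)
      strand <- if (member %% 2L == 0L) "-" else "+"
      start0 <- 10000L * member
      # lay the chain along the transcription direction: on the minus
      # strand the first transcribed exon sits at the highest coordinates
      glens <- if (strand == "+") lens else rev(lens)
      gstarts <- start0 + cumsum(c(0L, utils::head(glens, -1L) +
                                       intron_length))
      gex <- cbind(start = gstarts, end = gstarts + glens)
      exons <- if (strand == "+") gex else
        gex[rev(seq_len(nrow(gex))), , drop = FALSE]
      models[[gid]] <- gene_model(gid, "Chr1", strand, exons)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        gene_id = gid, pair = p,
        template_indices = paste(template_idx, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  structures <- lapply(models, exon_structure)
  list(models = models, structures = structures,
       gff = gene_models_to_gff3(models),
       truth = list(
         members = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))),
         perturbed = if (length(perturb_rows))
           do.call(rbind, c(perturb_rows, list(make.row.names = FALSE)))
         else NULL,
         params = list(templates = templates, n_pairs = n_pairs,
                       n_perturb = n_perturb,
                       intron_length = intron_length),
         seed = seed))
}

#' Serialize gene models to GFF3 text
#'
#' Emits gene/mRNA/CDS features with 1-based closed coordinates and correct
#' CDS phase fields.
#'
#' @param models Named list of GeneModel objects.
#' @return Character vector of GFF3 lines.
#' @export
gene_models_to_gff3 <- function(models) {
  lines <- "##gff-version 3"
  for (m in models) {
    ex <- m$exons  # transcription order
    lens <- ex[, "end"] - ex[, "start"]
    phases <- (3L - c(0L, cumsum(lens)[-length(lens)]) %% 3L) %% 3L
    gmin <- min(ex[, "start"]) + 1L; gmax <- max(ex[, "end"])
    tid <- paste0(m$gene_id, ".1")
    lines <- c(lines,
      sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              m$chromosome, gmin, gmax, m$strand, m$gene_id),
      sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              m$chromosome, gmin, gmax, m$strand, tid, m$gene_id))
    ord <- order(ex[, "start"])
    for (i in ord) {
      lines <- c(lines,
        sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
                m$chromosome, ex[[i, "start"]] + 1L, ex[[i, "end"]],
                m$strand, phases[[i]], tid, tid))
    }
  }
  lines
}

#' Simulate a TPM matrix with planted expression maxima
#'
#' Log-normal background (median TPM about 2), a fraction of silent genes
#' (every cell below 1), and `n_planted` boosted cells, one per selected
#' clade, each guaranteed to be its clade's maximum.
#'
#' @param clades data.frame with `gene_id`, `family`, `clade` (e.g. the
#'   truth of [simulate_clade_sequences()]).
#' @param conditions Condition labels (default the six root-hair
#'   treated/mock labels).
#' @param n_planted Number of planted (gene, condition) maxima, each in a
#'   distinct clade.
#' @param boost Multiplier applied to the clade's background maximum
#'   (must exceed 1; default 50).
#' @param silent_fraction Fraction of non-planted genes made silent.
#' @param sdlog Log-normal spread of the background (default 0.5).
#' @param seed Generator seed.
#' @return List with `matrix`, and `truth` (`planted` data.frame, silent
#'   gene ids, parameters, seed).
#' @export
simulate_tpm <- function(clades,
                         conditions = default_config()$simulate$tpm_conditions,
                         n_planted = 6L, boost = 50, silent_fraction = 0.15,
                         sdlog = 0.5, seed = 1L) {
  if (boost <= 1) stop("boost must exceed 1")
  set.seed(seed)
  genes <- clades$gene_id
  n <- length(genes)
  m <- matrix(stats::rlnorm(n * length(conditions), meanlog = log(2),
                            sdlog = sdlog),
              nrow = n, dimnames = list(genes, conditions))
  clade_key <- paste(clades$family, clades$clade, sep = "\r")
  uniq <- unique(clade_key)
  if (n_planted > length(uniq))
    stop("n_planted exceeds the number of clades")
  target_clades <- sample(uniq, n_planted)
  planted <- list()
  for (ck in target_clades) {
    cg <- genes[clade_key == ck]
    g <- sample(cg, 1L)
    cond <- sample(conditions, 1L)
    m[g, cond] <- boost * max(m[cg, , drop = FALSE])
    planted[[length(planted) + 1L]] <- data.frame(
      gene_id = g, condition = cond, tpm = m[g, cond],
      stringsAsFactors = FALSE)
  }
  planted <- do.call(rbind, c(planted, list(make.row.names = FALSE)))
  free <- setdiff(genes, planted$gene_id)
  silent <- sample(free, round(silent_fraction * length(free)))
  for (g in silent)
    m[g, ] <- stats::runif(length(conditions), 0, 0.9)
  list(matrix = m,
       truth = list(planted = planted, silent = silent,
                    params = list(conditions = conditions,
                                  n_planted = n_planted, boost = boost,
                                  silent_fraction = silent_fraction,
                                  sdlog = sdlog),
                    seed = seed))
}

#' Simulate species-tagged ortholog families
#'
#' Each family descends from its own random ancestor; every species
#' contributes one member per family, mutated at `within_d` so that
#' within-family identity stays high (about 95% at the default) while
#' between-family identity stays far below the clustering threshold.
#'
#' @param n_families Number of families (default 2).
#' @param species Species codes contributing one member each.
#' @param length Protein length.
#' @param within_d Within-family substitution fraction (default 0.025).
#' @param seed Generator seed.
#' @return List with `seqs`, `species` (gene -> species), and `truth`
#'   (gene -> family, parameters, seed).
#' @export
simulate_ortholog_families <- function(n_families = 2L,
                                       species = c("Gmax", "Pvul", "Athal",
                                                   "Vvin", "Ptri"),
                                       length = 200L, within_d = 0.025,
                                       seed = 1L) {
  set.seed(seed)
  seqs <- character(); sp_map <- character(); rows <- list()
  for (f in seq_len(n_families)) {
    anc <- random_protein(length)
    for (sp in species) {
      id <- sprintf("%s_fam%d", sp, f)
      seqs[[id]] <- mutate_protein(anc, within_d)
      sp_map[[id]] <- sp
      rows[[length(rows) + 1L]] <- data.frame(gene_id = id, family = f,
                                              species = sp,
                                              stringsAsFactors = FALSE)
    }
  }
  list(seqs = seqs, species = sp_map,
       truth = list(members = do.call(rbind,
                                      c(rows, list(make.row.names = FALSE))),
                    params = list(n_families = n_families, length = length,
                                  within_d = within_d),
                    seed = seed))
}
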
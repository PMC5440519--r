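# The orchestrating run: screen -> curate -> clades -> duplication ->
# structure -> clusters -> expression, writing one report directory.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Small deterministic config fingerprint for the run log.
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Run the full inventory pipeline
#'
#' Runs all stages and writes one report directory under `config$outdir`:
#' motif hits, candidate table with verdicts, resolved kept assignments,
#' clade tree and assignments, paralog pair table (mode, Ka, Ks, age in
#' Mya), exon structures and family-conserved exons, ortholog clusters with
#' a Venn summary, expression models, and a run log carrying a config
#' fingerprint and the seeds. Reruns with the same config are
#' byte-identical in every table (the log excluded: it records wall-clock
#' time).
#'
#' With `config$inputs` unset (the default) every input is generated by the
#' synthetic-data module from `config$seed`, each stage consuming its own
#' derived seed. Supply file paths in `config$inputs` to run on real data:
#' `proteome`, `refs`, `ref_families` (TSV: sequence_id, family) for
#' screening; `alignment` (FASTA) and `ref_labels` (TSV: sequence_id,
#' clade) for clade assignment; `cds` (FASTA), `pairs`, `gene_order`,
#' optionally `blocks` (TSVs) for duplication; `gff3` for gene structure;
#' `ortho` (FASTA) and `ortho_species` (TSV: sequence_id, species) for
#' clustering; `tpm` (TSV) for expression. A stage whose inputs are absent
#' is skipped with a logged notice; a stage that errors aborts the run with
#' the stage name and cause.
#'
#' @param config Configuration list from [default_config()] (possibly
#'   edited) or [read_config()].
#' @return Invisibly, a list with every completed stage's in-memory result
#'   and the report directory path.
#' @export
run_inventory <- function(config = default_config()) {
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("kinventory run, seed %d, config %s",
                         config$seed, config_hash(config)))
  note <- function(msg) log_lines <<- c(log_lines, msg)
  results <- list(outdir = outdir)
  sim <- config$simulate
  inputs <- config$inputs
  simulate_all <- is.null(inputs)
  has <- function(...) all(c(...) %in% names(inputs))
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop(sprintf("%s stage failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  library <- motif_library(config$x_n_min, config$x_n_max)

  # --- screening -----------------------------------------------------------
  if (simulate_all || has("proteome", "refs", "ref_families")) {
    results <- c(results, run_stage("screening", function() {
      if (simulate_all) {
        prot <- simulate_proteome(family_sizes = sim$family_sizes,
                                  n_truncated = sim$n_truncated,
                                  n_random = sim$n_random,
                                  seed = derive_seed(config$seed, "proteome"),
                                  library = library)
        proteome <- prot$proteome; refs <- prot$refs
        ref_families <- prot$ref_families
      } else {
        prot <- NULL
        proteome <- read_protein_fasta(inputs$proteome)
        refs <- read_protein_fasta(inputs$refs)
        rf <- utils::read.delim(inputs$ref_families,
                                stringsAsFactors = FALSE)
        ref_families <- stats::setNames(rf[[2]], rf[[1]])
      }
      screen <- screen_proteome(proteome, refs, ref_families,
                                library = library,
                                policy = config$motif_policy,
                                fraction = config$span_fraction)
      write_hits_tsv(screen$hits, file.path(outdir, "motif_hits.tsv"))
      write_candidates_tsv(screen$candidates,
                           file.path(outdir, "candidates.tsv"))
      write_tsv(screen$kept[, c("sequence_id", "family", "n_motifs_matched",
                                "outermost_span")],
                file.path(outdir, "kept_assignments.tsv"))
      note(sprintf("screen: %d kept of %d candidates",
                   nrow(screen$kept), nrow(screen$candidates)))
      list(proteome_sim = prot, screen = screen)
    }))
  } else note("screen: skipped (no proteome inputs)")

  # --- clade assignment ----------------------------------------------------
  if (simulate_all || has("alignment", "ref_labels")) {
    results <- c(results, run_stage("clade", function() {
      if (simulate_all) {
        cl <- simulate_clade_sequences(n_clades = sim$n_clades,
                                       queries_per_clade = sim$clade_queries,
                                       refs_per_clade = sim$clade_refs,
                                       seed = derive_seed(config$seed,
                                                          "clades"))
        alignment <- cl$alignment; ref_labels <- cl$ref_labels
      } else {
        cl <- NULL
        alignment <- read_protein_fasta(inputs$alignment)
        rl <- utils::read.delim(inputs$ref_labels, stringsAsFactors = FALSE)
        ref_labels <- stats::setNames(rl[[2]], rl[[1]])
      }
      tree <- nj_tree(p_distance_matrix(alignment))
      assignments <- assign_clades(tree, ref_labels)
      ape::write.tree(tree, file.path(outdir, "clade_tree.nwk"))
      write_tsv(assignments, file.path(outdir, "clade_assignments.tsv"))
      note(sprintf("clades: %d genes assigned to %d clades",
                   nrow(assignments), length(unique(assignments$clade))))
      list(clade_sim = cl, tree = tree, clade_assignments = assignments)
    }))
  } else note("clades: skipped (no alignment inputs)")

  # --- duplication ---------------------------------------------------------
  if (simulate_all || has("cds", "pairs", "gene_order")) {
    results <- c(results, run_stage("duplication", function() {
      if (simulate_all) {
        dup <- simulate_paralog_set(n_pairs = sim$n_cds_pairs,
                                    n_codons = sim$cds_codons,
                                    k_star = sim$k_star,
                                    seed = derive_seed(config$seed, "cds"))
        cds <- dup$cds; pairs <- dup$pairs
        gene_order <- dup$gene_order; blocks <- dup$blocks
      } else {
        dup <- NULL
        cds <- read_cds_fasta(inputs$cds)
        pairs <- utils::read.delim(inputs$pairs, stringsAsFactors = FALSE)
        gene_order <- utils::read.delim(inputs$gene_order,
                                        stringsAsFactors = FALSE)
        blocks <- if (has("blocks"))
          utils::read.delim(inputs$blocks, stringsAsFactors = FALSE)
          else NULL
      }
      pair_tab <- paralog_pair_table(pairs, cds, gene_order, blocks,
                                     config$tandem_max_intervening,
                                     lambda = config$lambda_preset)
      write_tsv(pair_tab, file.path(outdir, "paralog_pairs.tsv"))
      note(sprintf("duplication: %d pairs, mean Ks %.3f",
                   nrow(pair_tab), mean(pair_tab$ks, na.rm = TRUE)))
      list(dup_sim = dup, pair_table = pair_tab)
    }))
  } else note("duplication: skipped (no CDS inputs)")

  # --- gene structure ------------------------------------------------------
  if (simulate_all || has("gff3")) {
    results <- c(results, run_stage("gene structure", function() {
      if (simulate_all) {
        gm <- simulate_gene_models(n_pairs = sim$n_structure_pairs,
                                   seed = derive_seed(config$seed,
                                                      "structure"))
        gff_path <- file.path(outdir, "gene_models.gff3")
        writeLines(gm$gff, gff_path)
      } else {
        gm <- NULL
        gff_path <- inputs$gff3
      }
      models <- read_gff3(gff_path)
      structures <- lapply(models, exon_structure)
      conserved <- family_conserved_exons(structures,
                                          config$conserved_exon_fraction)
      write_structures_tsv(structures,
                           file.path(outdir, "exon_structures.tsv"))
      write_tsv(conserved, file.path(outdir, "conserved_exons.tsv"))
      note(sprintf("structure: %d models, %d family-conserved exons",
                   length(structures), nrow(conserved)))
      list(structure_sim = gm, structures = structures,
           conserved = conserved)
    }))
  } else note("structure: skipped (no GFF3 input)")

  # --- ortholog clustering -------------------------------------------------
  if (simulate_all || has("ortho", "ortho_species")) {
    results <- c(results, run_stage("ortholog", function() {
      if (simulate_all) {
        ortho <- simulate_ortholog_families(species = sim$ortho_species,
                                            seed = derive_seed(config$seed,
                                                               "ortho"))
        seqs <- ortho$seqs; species <- ortho$species
      } else {
        ortho <- NULL
        seqs <- read_protein_fasta(inputs$ortho)
        sp <- utils::read.delim(inputs$ortho_species,
                                stringsAsFactors = FALSE)
        species <- stats::setNames(sp[[2]], sp[[1]])
      }
      idm <- identity_matrix(seqs, config$gap_open, config$gap_extend)
      clust <- cluster_orthologs(idm, species, config$identity_threshold)
      write_tsv(clust$clusters, file.path(outdir, "ortholog_clusters.tsv"))
      write_tsv(clust$venn, file.path(outdir, "ortholog_venn.tsv"))
      jsonlite::write_json(clust, file.path(outdir, "ortholog_clusters.json"),
                           dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      note(sprintf("clusters: %d", max(clust$clusters$cluster_id)))
      list(ortho_sim = ortho, identity = idm, clusters = clust)
    }))
  } else note("clusters: skipped (no ortholog inputs)")

  # --- expression ----------------------------------------------------------
  clades_known <- !is.null(results$clade_assignments) || simulate_all
  if ((simulate_all || has("tpm")) && clades_known) {
    results <- c(results, run_stage("expression", function() {
      if (simulate_all) {
        clades <- results$clade_sim$truth$clades
        tpm <- simulate_tpm(clades, conditions = sim$tpm_conditions,
                            n_planted = sim$tpm_planted,
                            boost = sim$tpm_boost,
                            seed = derive_seed(config$seed, "tpm"))
        mat <- tpm$matrix
        mat_out <- data.frame(gene_id = rownames(mat), mat,
                              check.names = FALSE, stringsAsFactors = FALSE)
        write_tsv(mat_out, file.path(outdir, "tpm_matrix.tsv"))
      } else {
        tpm <- NULL
        mat <- read_tpm_matrix(inputs$tpm)
        clades <- results$clade_assignments
        clades$family <- if ("family" %in% names(clades)) clades$family
          else "unspecified"
      }
      models <- clade_expression_model(mat, clades, config$tpm_threshold)
      write_expression_models(models,
                              file.path(outdir, "expression_models.tsv"),
                              file.path(outdir, "expression_models.json"))
      note(sprintf("expression: %d clade models, %d with expression",
                   nrow(models), sum(models$status == "expressed")))
      list(tpm_sim = tpm, expression_models = models)
    }))
  } else note("expression: skipped (no TPM matrix)")

  writeLines(c(log_lines,
               sprintf("completed at %s",
                       format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
             file.path(outdir, "run_log.txt"))
  invisible(results)
}
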
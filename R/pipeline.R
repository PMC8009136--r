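# Orchestration: run the analysis stages from one declarative config
# with reproducibility metadata (config hash, seed) in a run manifest.

PIPELINE_KEYS <- c("alignments", "tree", "genomes", "annotations",
                   "ingroup", "outgroup", "stages", "gap_threshold",
                   "n_boot", "seed", "ir_min_len", "out_dir",
                   "equilibrium_taxa", "equilibrium_scope", "gene_states")

#' Validate a pipeline configuration
#'
#' @param config named list, or path to a YAML file. Recognized keys:
#'   `alignments` (named list or directory of per-gene FASTA files),
#'   `tree` (Newick path), `genomes`/`annotations` (FASTA / feature-table
#'   paths, optional), `ingroup` (tip labels of the heterotrophic
#'   clade), `outgroup` (tip label), `stages` (subset of
#'   `c("structure","fit","ancestral","equilibrium","contexts","losses")`),
#'   `gene_states` (TSV of taxon x gene states for the losses stage),
#'   `gap_threshold`, `n_boot`, `seed`, `ir_min_len`,
#'   `equilibrium_taxa`, `equilibrium_scope`, `out_dir`.
#' @return the validated config (invisibly usable by [run_pipeline()]).
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  required <- c("alignments", "tree", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("missing config keys: ", paste(missing, collapse = ", "))
  if (is.character(config$tree) && !file.exists(config$tree))
    stop("tree file not found: ", config$tree)
  defaults <- list(stages = c("fit", "ancestral", "equilibrium"),
                   gap_threshold = 0.5, n_boot = 200L, seed = 1L,
                   ir_min_len = 1000L, equilibrium_scope = "terminal_branch")
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  config
}

#' Run the analysis pipeline
#'
#' Stages run in dependency order: genome structure/gene matrix (when
#' genomes are given), alignment loading + gap filtering +
#' concatenation, GTR+Gamma fit, ancestral reconstruction, equilibrium
#' AT estimation with bootstrap CIs, context spectra, gene-loss
#' parsimony. Every report is written as TSV/JSON under `out_dir`
#' together with a run manifest carrying the config hash and seed.
#'
#' @param config see [validate_pipeline_config()].
#' @return (invisibly) a list of stage results; reports under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  results <- list()

  # resolve alignments: directory of FASTAs or named list of paths
  aln_paths <- config$alignments
  if (is.character(aln_paths) && length(aln_paths) == 1L &&
      dir.exists(aln_paths)) {
    files <- list.files(aln_paths, pattern = "\\.(fa|fasta|fna)$",
                        full.names = TRUE)
    aln_paths <- stats::setNames(as.list(files),
                                 sub("\\.[^.]*$", "", basename(files)))
  }
  alns <- lapply(aln_paths, load_alignment)
  filtered <- lapply(alns, function(a)
    filter_gap_columns(a, config$gap_threshold)$alignment)
  concat <- concatenate_alignments(filtered)
  write_partition_map(concat, file.path(out, "partitions.tsv"))
  results$alignment <- concat

  tree <- if (inherits(config$tree, "phylo")) config$tree
          else ape::read.tree(config$tree)

  if ("fit" %in% config$stages) {
    fit <- fit_gtr(concat, tree)
    results$fit <- fit
    ape::write.tree(fit$tree, file.path(out, "fitted_tree.nwk"))
  }
  if ("ancestral" %in% config$stages) {
    fit <- results$fit
    if (is.null(fit)) stop("stage 'ancestral' requires stage 'fit'")
    recon <- reconstruct_ancestral(concat, fit$tree, fit$model,
                                   outgroup = config$outgroup)
    results$recon <- recon
    write_ancestral_fasta(recon, file.path(out, "ancestral_map.fasta"))
    utils::write.table(branch_counts_table(recon),
                       file.path(out, "branch_counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if ("equilibrium" %in% config$stages) {
    if (is.null(results$recon)) stop("stage 'equilibrium' requires 'ancestral'")
    taxa <- config$equilibrium_taxa
    if (is.null(taxa)) taxa <- config$ingroup
    if (is.null(taxa)) taxa <- setdiff(tree$tip.label, config$outgroup)
    rows <- lapply(taxa, function(tx) {
      est <- bootstrap_equilibrium(concat, tree, results$fit$model, tx,
                                   scope = config$equilibrium_scope,
                                   n_boot = config$n_boot,
                                   seed = config$seed,
                                   outgroup = config$outgroup)
      data.frame(taxon = tx, alpha_eq = est$alpha_eq, k1 = est$k1,
                 k2 = est$k2, ci_low = est$ci[1], ci_high = est$ci[2],
                 n_boot = est$n_boot, n_skipped = est$n_skipped)
    })
    eq <- do.call(rbind, rows)
    utils::write.table(eq, file.path(out, "equilibrium_at.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$equilibrium <- eq
  }
  if ("losses" %in% config$stages) {
    if (is.null(config$gene_states))
      stop("stage 'losses' requires a 'gene_states' TSV")
    tab <- utils::read.delim(config$gene_states, stringsAsFactors = FALSE)
    st <- as.matrix(tab[, -1L])
    rownames(st) <- tab[[1L]]
    gmx <- gene_matrix(st, partial_taxa = rownames(st))
    rows <- lapply(colnames(st), function(g) {
      r <- parsimony_reconstruct(gmx, tree, g)
      d <- parsimony_reconstruct(gmx, tree, g, coding = "dollo")
      data.frame(gene = g, fitch_changes = r$min_changes,
                 independent_losses = r$n_independent_losses,
                 mpr_count = r$mpr_count,
                 dollo_losses = d$n_independent_losses)
    })
    losses <- do.call(rbind, rows)
    utils::write.table(losses, file.path(out, "gene_losses.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_gene_matrix_nexus(gmx, file.path(out, "gene_matrix.nex"))
    results$losses <- losses
  }
  if ("structure" %in% config$stages) {
    if (is.null(config$genomes)) stop("stage 'structure' requires 'genomes'")
    files <- list.files(config$genomes, pattern = "\\.(fa|fasta|fna)$",
                        full.names = TRUE)
    rows <- lapply(files, function(f) {
      set <- Biostrings::readBStringSet(f)
      rec <- plastome(as.character(set[[1L]]),
                      data.frame(gene = character(0), start = integer(0),
                                 end = integer(0), strand = character(0),
                                 kind = character(0)),
                      id = sub("\\.[^.]*$", "", basename(f)))
      p <- detect_ir(rec, min_len = config$ir_min_len)
      data.frame(genome = rec$id, total_len = p$total_len,
                 lsc_len = p$lsc_len, ssc_len = p$ssc_len,
                 ir_len = p$ir_len, gc_content = p$gc_content)
    })
    struct <- do.call(rbind, rows)
    utils::write.table(struct, file.path(out, "structure.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$structure <- struct
  }
  if ("contexts" %in% config$stages) {
    if (is.null(results$recon)) stop("stage 'contexts' requires 'ancestral'")
    br <- clade_branches(results$recon$tree,
                         intersect(config$ingroup,
                                   results$recon$tree$tip.label))
    ctx <- synonymous_context_frequencies(results$recon, br,
                                           strand_merged = TRUE)
    utils::write.table(ctx$table, file.path(out, "context_spectrum.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$contexts <- ctx
  }

  cfg_file <- file.path(out, "config_used.yaml")
  cfg_out <- config
  if (inherits(cfg_out$tree, "phylo")) cfg_out$tree <- "<phylo object>"
  if (is.list(cfg_out$alignments)) cfg_out$alignments <- names(aln_paths)
  yaml::write_yaml(cfg_out[order(names(cfg_out))], cfg_file)
  manifest <- list(package = "plastevol",
                   version = as.character(utils::packageVersion("plastevol")),
                   seed = config$seed,
                   config_md5 = unname(tools::md5sum(cfg_file)),
                   stages = config$stages,
                   n_taxa = n_taxa(concat), n_sites = n_sites(concat))
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
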
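# End-to-end orchestration of the synthetic analysis: simulate gene
# families, classify gene models, compute divergence, build trees, reconcile
# and scan for selection, then write publication-style summary tables.
# Stages are idempotent given identical inputs and seeds; outputs carry no
# timestamps so unchanged reruns are byte-identical.

#' Default pipeline configuration
#'
#' @param seed Master seed; per-stage seeds are derived deterministically.
#' @param outdir Output directory.
#' @param n_families Number of simulated gene families per family label.
#' @param n_codons Codons per alignment.
#' @param dup_rate,loss_rate,pseudo_rate Birth-death rates.
#' @param stages Character vector of stages to run, in dependency order.
#' @return Named list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L, outdir = "chemevolve_out",
                                    n_families = 6L, n_codons = 150L,
                                    dup_rate = 0.3, loss_rate = 0.1,
                                    pseudo_rate = 0.1,
                                    stages = c("simulate", "annotate", "divergence",
                                               "trees", "reconcile", "selection",
                                               "report")) {
  list(seed = as.integer(seed), outdir = outdir,
       n_families = as.integer(n_families), n_codons = as.integer(n_codons),
       dup_rate = dup_rate, loss_rate = loss_rate, pseudo_rate = pseudo_rate,
       kappa = 2, background_omega = 0.2,
       reference_species = "Dmel",
       frac_threshold = 0.20, tm_threshold = 1L,
       support_threshold = 0.9, dup_cost = 1.5, loss_cost = 1.0,
       beb_threshold = 0.95, stages = stages)
}

#' Load a pipeline configuration from YAML
#'
#' Missing keys are filled from [default_pipeline_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return Config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  base <- default_pipeline_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0L) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  base[names(user)] <- user
  base$seed <- as.integer(base$seed)
  base
}

stage_seed <- function(config, stage) {
  offsets <- c(simulate = 101L, annotate = 211L, divergence = 307L,
               trees = 401L, reconcile = 503L, selection = 601L, report = 701L)
  (config$seed * 1009L + offsets[[stage]]) %% 2147483647L
}

log_stage <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full synthetic analysis pipeline
#'
#' Stages run in dependency order (simulate, annotate, divergence, trees,
#' reconcile, selection, report); stages omitted from `config$stages` are
#' skipped and downstream stages consume the cached artifacts in
#' `config$outdir`. A manifest echoing the configuration is written alongside
#' the outputs.
#'
#' @param config List from [default_pipeline_config()] or
#'   [read_pipeline_config()], or a path to a YAML config.
#' @return Invisibly, a list of the principal artifacts (paths and tables).
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sp_tree <- melanogaster_group_tree()
  artifacts <- list()

  sim_rds <- file.path(outdir, "simulation")
  dir.create(sim_rds, showWarnings = FALSE)

  if ("simulate" %in% config$stages) {
    log_stage("simulate", sprintf("%d families, %d codons, seed %d",
                                  config$n_families, config$n_codons,
                                  stage_seed(config, "simulate")))
    seed0 <- stage_seed(config, "simulate")
    for (fam in seq_len(config$n_families)) {
      truth <- simulate_gene_family(sp_tree, config$dup_rate, config$loss_rate,
                                    config$pseudo_rate, seed = seed0 + fam)
      cfg <- sim_config(seed = seed0 + fam, species_tree = sp_tree,
                        n_codons = config$n_codons, kappa = config$kappa,
                        site_classes = data.frame(prop = 1,
                                                  omega = config$background_omega))
      ev <- evolve_codons(truth, cfg, seed = seed0 + 1000L + fam)
      if (is.null(ev) || nrow(ev$alignment) < 2L) next
      fam_name <- sprintf("fam%02d", fam)
      write_codon_fasta(ev$alignment, file.path(sim_rds, paste0(fam_name, ".fasta")))
      if (!is.null(truth$gene_tree)) {
        writeLines(write_newick(truth$gene_tree),
                   file.path(sim_rds, paste0(fam_name, ".nwk")))
      }
      # build CDS per gene: ATG + evolved codons + TAA, lesion for pseudogenes
      set.seed(seed0 + 2000L + fam)
      genes <- rownames(ev$alignment)
      meta <- data.frame(gene = genes,
                         species = sub("_[^_]*$", "", genes),
                         family = fam_name,
                         true_pseudo = genes %in% truth$pseudo_leaves,
                         lesion = NA_character_, stringsAsFactors = FALSE)
      cds_lines <- character(0)
      for (g in genes) {
        cds <- paste0("ATG", paste0(ev$alignment[g, ], collapse = ""), "TAA")
        if (g %in% truth$pseudo_leaves) {
          pos <- sample(2:floor(0.5 * (config$n_codons + 1)), 1)
          les <- inject_lesions(cds, "premature_stop", position = pos)
          cds <- les$cds
          meta$lesion[meta$gene == g] <- sprintf("premature_stop@%d", pos)
        }
        cds_lines <- c(cds_lines, paste0(">", g), cds)
      }
      writeLines(cds_lines, file.path(sim_rds, paste0(fam_name, "_cds.fasta")))
      utils::write.table(meta, file.path(sim_rds, paste0(fam_name, "_truth.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(truth$losses, file.path(sim_rds, paste0(fam_name, "_losses.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }

  fam_files <- sort(list.files(sim_rds, pattern = "_cds\\.fasta$"))
  fam_names <- sub("_cds\\.fasta$", "", fam_files)

  read_family <- function(fam_name) {
    seqs <- Biostrings::readDNAStringSet(file.path(sim_rds, paste0(fam_name, "_cds.fasta")))
    cds <- stats::setNames(as.character(seqs), names(seqs))
    truth <- utils::read.table(file.path(sim_rds, paste0(fam_name, "_truth.tsv")),
                               sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    tree_file <- file.path(sim_rds, paste0(fam_name, ".nwk"))
    tree <- if (file.exists(tree_file)) parse_newick(readLines(tree_file)) else NULL
    list(cds = cds, truth = truth, tree = tree)
  }

  if ("annotate" %in% config$stages) {
    log_stage("annotate", sprintf("classifying %d families", length(fam_names)))
    models <- NULL
    for (fam_name in fam_names) {
      fd <- read_family(fam_name)
      # reference: an intact copy, preferring the reference species
      ref_ids <- fd$truth$gene[!fd$truth$true_pseudo]
      if (length(ref_ids) == 0L) next
      pref <- ref_ids[sub("_[^_]*$", "", ref_ids) == config$reference_species]
      ref_id <- if (length(pref) > 0L) pref[1] else ref_ids[1]
      ref_prot <- translate_cds(fd$cds[[ref_id]])$protein
      for (g in names(fd$cds)) {
        cl <- classify_gene_model(fd$cds[[g]], ref_prot,
                                  frac_threshold = config$frac_threshold,
                                  tm_threshold = config$tm_threshold)
        models <- rbind(models, data.frame(
          id = g, species = sub("_[^_]*$", "", g), family = fam_name,
          status = cl$status, stringsAsFactors = FALSE))
      }
    }
    repertoire <- summarize_repertoire(models)
    utils::write.table(models, file.path(outdir, "gene_models.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(repertoire, file.path(outdir, "repertoire.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    artifacts$repertoire <- repertoire
  }

  if ("divergence" %in% config$stages) {
    log_stage("divergence", "NG86 dN/dS against reference species")
    recs <- NULL
    for (fam_name in fam_names) {
      fd <- read_family(fam_name)
      intact <- fd$truth$gene[!fd$truth$true_pseudo]
      ref <- intact[sub("_[^_]*$", "", intact) == config$reference_species]
      if (length(ref) == 0L) next
      ref <- ref[1]
      ref_prot <- translate_cds(fd$cds[[ref]])$protein
      ref_cds <- substr(fd$cds[[ref]], 1, nchar(fd$cds[[ref]]) - 3)
      for (g in setdiff(intact, ref)) {
        prot <- translate_cds(fd$cds[[g]])$protein
        cds <- substr(fd$cds[[g]], 1, nchar(fd$cds[[g]]) - 3)
        rec <- tryCatch(
          divergence_record(g, sub("_[^_]*$", "", g), prot, cds,
                            ref_prot, ref_cds, family = fam_name),
          error = function(e) NULL)
        recs <- rbind(recs, rec)
      }
    }
    if (!is.null(recs)) {
      utils::write.table(recs, file.path(outdir, "divergence.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      artifacts$divergence <- recs
    }
  }

  if ("trees" %in% config$stages) {
    log_stage("trees", "NJ trees on JTT distances")
    for (fam_name in fam_names) {
      fd <- read_family(fam_name)
      intact <- fd$truth$gene[!fd$truth$true_pseudo]
      if (length(intact) < 4L) next
      prots <- vapply(fd$cds[intact], function(x) translate_cds(x)$protein, character(1))
      n <- length(prots)
      D <- matrix(0, n, n, dimnames = list(names(prots), names(prots)))
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i < j) D[i, j] <- D[j, i] <- jtt_ml_distance(prots[i], prots[j])
      }
      tr <- nj_tree(D)
      writeLines(write_newick(tr), file.path(outdir, paste0(fam_name, "_nj.nwk")))
    }
  }

  if ("reconcile" %in% config$stages) {
    log_stage("reconcile", "duplication-loss reconciliation")
    rec_rows <- NULL
    copy_tab <- NULL
    for (fam_name in fam_names) {
      fd <- read_family(fam_name)
      if (is.null(fd$tree) || ape::Ntip(fd$tree) < 3L) next
      rec <- reconcile_tree(fd$tree, sp_tree, dup_cost = config$dup_cost,
                            loss_cost = config$loss_cost)
      rec_rows <- rbind(rec_rows, data.frame(
        family = fam_name, n_leaves = ape::Ntip(fd$tree),
        n_dup = rec$n_dup, n_loss = rec$n_loss, cost = rec$cost,
        stringsAsFactors = FALSE))
      counts <- table(factor(fd$truth$species[!fd$truth$true_pseudo],
                             levels = sp_tree$tip.label))
      gl <- infer_gains_losses(stats::setNames(as.integer(counts), names(counts)), sp_tree)
      copy_tab <- rbind(copy_tab, data.frame(family = fam_name,
                                             total_change = gl$total_change))
    }
    if (!is.null(rec_rows)) {
      utils::write.table(rec_rows, file.path(outdir, "reconciliation.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      artifacts$reconciliation <- rec_rows
    }
    if (!is.null(copy_tab)) {
      utils::write.table(copy_tab, file.path(outdir, "copy_number_changes.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }

  if ("selection" %in% config$stages) {
    log_stage("selection", "branch-site scan (intact genes only)")
    sets <- list()
    for (fam_name in fam_names) {
      fd <- read_family(fam_name)
      if (is.null(fd$tree)) next
      intact <- fd$truth$gene[!fd$truth$true_pseudo]
      if (length(intact) < 3L) next
      aln <- read_codon_fasta(file.path(sim_rds, paste0(fam_name, ".fasta")))
      aln <- aln[intersect(rownames(aln), intact), , drop = FALSE]
      tr <- fd$tree
      drop <- setdiff(tr$tip.label, rownames(aln))
      if (length(drop) > 0L) tr <- ape::drop.tip(tr, drop)
      if (is.null(tr) || ape::Ntip(tr) < 3L || !ape::is.binary(tr)) next
      aln <- aln[tr$tip.label, , drop = FALSE]
      sets[[fam_name]] <- list(alignment = aln, tree = tr)
    }
    if (length(sets) > 0L) {
      res <- scan_gene_sets(sets)
      utils::write.table(res, file.path(outdir, "selection_scan.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      artifacts$selection <- res
    }
  }

  if ("report" %in% config$stages) {
    log_stage("report", "writing manifest")
    manifest <- c(list(package_version = as.character(utils::packageVersion("chemevolve")),
                       r_version = paste(R.version$major, R.version$minor, sep = ".")),
                  config)
    yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  }
  invisible(artifacts)
}
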
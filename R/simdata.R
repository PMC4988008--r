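# Synthetic-data generator: gene-family birth-death histories along a
# species tree (Gillespie events: duplication, loss, pseudogenization),
# codon-alignment evolution under MG94xHKY site-class mixtures with optional
# episodic selection on designated branches, and disruptive lesion injection
# for classifier testing. Seeds are mandatory; no hidden global RNG state.

#' Simulation configuration
#'
#' Validates and bundles the simulator's parameters.
#'
#' @param seed Integer seed (mandatory).
#' @param species_tree Rooted binary `phylo` with positive branch lengths in
#'   expected substitutions per codon site.
#' @param dup_rate,loss_rate,pseudo_rate Event rates per lineage per unit
#'   branch length (>= 0).
#' @param n_codons Alignment length in codons (> 0).
#' @param kappa Transition/transversion ratio (> 0).
#' @param site_classes data.frame with columns `prop`, `omega` and optional
#'   `omega_fg` (foreground omega; defaults to `omega`); proportions must sum
#'   to 1 and omegas be >= 0.
#' @param foreground_branches Integer edge indices (rows of
#'   `species_tree$edge`) carrying the elevated class.
#' @param codon_freqs 61 sense-codon frequencies summing to 1 (default
#'   uniform).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed, species_tree, dup_rate = 0, loss_rate = 0,
                       pseudo_rate = 0, n_codons = 300L, kappa = 2,
                       site_classes = data.frame(prop = 1, omega = 0.2),
                       foreground_branches = integer(0),
                       codon_freqs = rep(1 / 61, 61)) {
  if (missing(seed) || !is.numeric(seed)) stop("seed is mandatory")
  check_rooted_binary(species_tree, "species tree")
  if (is.null(species_tree$edge.length) || any(species_tree$edge.length <= 0))
    stop("species tree must have positive branch lengths")
  if (any(c(dup_rate, loss_rate, pseudo_rate) < 0)) stop("rates must be >= 0")
  if (n_codons < 1L) stop("n_codons must be positive")
  if (kappa <= 0) stop("kappa must be > 0")
  if (abs(sum(site_classes$prop) - 1) > 1e-12) stop("site-class proportions must sum to 1")
  if (any(site_classes$omega < 0)) stop("omega must be >= 0")
  if (is.null(site_classes$omega_fg)) site_classes$omega_fg <- site_classes$omega
  if (length(codon_freqs) != 61L || abs(sum(codon_freqs) - 1) > 1e-8)
    stop("codon_freqs must be 61 sense-codon frequencies summing to 1")
  if (any(codon_freqs < 0)) stop("codon_freqs must be non-negative")
  structure(list(seed = as.integer(seed), species_tree = species_tree,
                 dup_rate = dup_rate, loss_rate = loss_rate,
                 pseudo_rate = pseudo_rate, n_codons = as.integer(n_codons),
                 kappa = kappa, site_classes = site_classes,
                 foreground_branches = foreground_branches,
                 codon_freqs = codon_freqs),
            class = "sim_config")
}

#' Simulate a gene-family birth-death history along a species tree
#'
#' Each gene lineage evolves along the species tree; duplication, loss and
#' pseudogenization occur as Poisson processes with exponential waiting times
#' (Gillespie). Pseudogenized copies persist as vestiges (they speciate but
#' have no further events, and evolve neutrally thereafter); lost copies are
#' deleted, with the loss recorded on the species-tree edge where it
#' happened.
#'
#' @param species_tree Rooted binary `phylo`, positive branch lengths.
#' @param dup_rate,loss_rate,pseudo_rate Event rates per lineage per unit
#'   branch length.
#' @param seed Integer seed.
#' @return List of class `gene_family_truth`: `gene_tree` (phylo with
#'   node labels "D"/"S", NULL if extinct), `lineage` (the internal recursive
#'   structure used by [evolve_codons()]), `n_dup`, `losses` (per
#'   species-edge counts), `pseudo_leaves` (leaf labels), `leaf_species`.
#' @export
simulate_gene_family <- function(species_tree, dup_rate, loss_rate,
                                 pseudo_rate, seed) {
  check_rooted_binary(species_tree, "species tree")
  if (is.null(species_tree$edge.length)) stop("species tree has no branch lengths")
  set.seed(as.integer(seed))
  ntip <- ape::Ntip(species_tree)
  ch <- tree_children(species_tree)
  edge_of_child <- integer(ntip + species_tree$Nnode)
  edge_of_child[species_tree$edge[, 2]] <- seq_len(nrow(species_tree$edge))
  counters <- new.env(parent = emptyenv())
  losses <- integer(nrow(species_tree$edge))
  lam <- c(dup_rate, loss_rate, pseudo_rate)
  lam_tot <- sum(lam)

  add_time <- function(node, dt, neutral) {
    if (is.null(node)) return(NULL)
    node$blen <- node$blen + dt
    if (neutral) node$neutral_tail <- node$neutral_tail + dt
    node
  }
  at_node <- function(v, active) {
    if (v <= ntip) {
      sp <- species_tree$tip.label[v]
      k <- (if (is.null(counters[[sp]])) 0L else counters[[sp]]) + 1L
      assign(sp, k, envir = counters)
      return(list(type = "leaf", label = paste0(sp, "_", k), species = sp,
                  blen = 0, neutral_tail = 0, pseudo = !active))
    }
    kids <- list()
    for (cv in ch[[v]]) {
      res <- evolve(cv, species_tree$edge.length[edge_of_child[cv]], active)
      if (!is.null(res)) kids[[length(kids) + 1L]] <- res
    }
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) return(kids[[1]])
    list(type = "spec", blen = 0, neutral_tail = 0, children = kids)
  }
  evolve <- function(v, t_rem, active) {
    ei <- edge_of_child[v]
    t_used <- 0
    while (active && lam_tot > 0) {
      dt <- stats::rexp(1, lam_tot)
      if (t_used + dt >= t_rem) break
      t_used <- t_used + dt
      ev <- sample.int(3L, 1L, prob = lam)
      if (ev == 2L) {            # loss
        losses[ei] <<- losses[ei] + 1L
        return(NULL)
      } else if (ev == 3L) {     # pseudogenization
        node <- evolve_rest(v, t_rem - t_used, FALSE)
        return(add_time(node, t_used, neutral = FALSE))
      } else {                   # duplication
        l <- evolve_rest(v, t_rem - t_used, TRUE)
        r <- evolve_rest(v, t_rem - t_used, TRUE)
        if (is.null(l) && is.null(r)) return(NULL)
        if (is.null(l)) return(add_time(r, t_used, FALSE))
        if (is.null(r)) return(add_time(l, t_used, FALSE))
        return(list(type = "dup", blen = t_used, neutral_tail = 0,
                    children = list(l, r)))
      }
    }
    node <- at_node(v, active)
    add_time(node, t_rem - t_used, neutral = !active)
  }
  # continuing along the same species edge after an event
  evolve_rest <- function(v, t_rem, active) {
    if (!active) {
      node <- at_node(v, FALSE)
      return(add_time(node, t_rem, neutral = TRUE))
    }
    evolve(v, t_rem, TRUE)
  }

  rt <- root_node(species_tree)
  lineage <- at_node(rt, TRUE)
  gene_tree <- NULL
  pseudo_leaves <- character(0)
  leaf_species <- character(0)
  n_dup <- 0L
  if (!is.null(lineage)) {
    to_newick <- function(node) {
      if (node$type == "leaf") {
        if (node$pseudo) pseudo_leaves <<- c(pseudo_leaves, node$label)
        leaf_species[node$label] <<- node$species
        return(sprintf("%s:%.10g", node$label, node$blen))
      }
      if (node$type == "dup") n_dup <<- n_dup + 1L
      lab <- if (node$type == "dup") "D" else "S"
      sprintf("(%s)%s:%.10g",
              paste(vapply(node$children, to_newick, character(1)), collapse = ","),
              lab, node$blen)
    }
    nw <- paste0(to_newick(lineage), ";")
    if (lineage$type == "leaf") {
      gene_tree <- NULL  # single surviving copy: no tree to build
    } else {
      gene_tree <- parse_newick(nw)
    }
  }
  loss_df <- data.frame(edge = seq_along(losses),
                        child = species_tree$edge[, 2],
                        n_losses = losses)
  structure(list(gene_tree = gene_tree, lineage = lineage, n_dup = n_dup,
                 losses = loss_df, pseudo_leaves = pseudo_leaves,
                 leaf_species = leaf_species,
                 species_tree = species_tree),
            class = "gene_family_truth")
}

# sample child codon states given parent states and a transition matrix
sample_states <- function(parent_states, P) {
  out <- integer(length(parent_states))
  for (s in unique(parent_states)) {
    idx <- which(parent_states == s)
    out[idx] <- sample.int(61L, length(idx), replace = TRUE, prob = P[s, ])
  }
  out
}

#' Evolve a codon alignment along a simulated gene-family history
#'
#' Sites are assigned to classes by the configured proportions; each branch
#' segment uses the site's class omega, except neutrally evolving
#' (post-pseudogenization) segments which use omega = 1. The root sequence is
#' drawn from the configured codon frequencies; stop codons cannot arise (the
#' state space is the 61 sense codons).
#'
#' @param truth A `gene_family_truth` from [simulate_gene_family()].
#' @param config A `sim_config` (its species tree is ignored here; rates,
#'   classes and frequencies are used).
#' @param seed Integer seed.
#' @return List with `alignment` (codon matrix, one row per extant gene) and
#'   `site_class` (integer class per site); NULL if the family is extinct.
#' @export
evolve_codons <- function(truth, config, seed) {
  if (is.null(truth$lineage)) return(NULL)
  set.seed(as.integer(seed))
  n <- config$n_codons
  cls <- config$site_classes
  site_class <- sample.int(nrow(cls), n, replace = TRUE, prob = cls$prop)
  mu <- mixture_flux(config$kappa, cls$omega, cls$prop, config$codon_freqs)
  eigs <- lapply(cls$omega, function(om) {
    mg94_eigen(build_mg94(config$kappa, om, config$codon_freqs, flux = mu))
  })
  eig_neutral <- mg94_eigen(build_mg94(config$kappa, 1, config$codon_freqs, flux = mu))

  root_states <- sample.int(61L, n, replace = TRUE, prob = config$codon_freqs)
  rows <- list()
  descend <- function(node, states) {
    t_sel <- node$blen - node$neutral_tail
    for (ci in seq_len(nrow(cls))) {
      idx <- which(site_class == ci)
      if (length(idx) == 0L) next
      P <- transition_probs(eigs[[ci]], t_sel)
      if (node$neutral_tail > 0) {
        P <- P %*% transition_probs(eig_neutral, node$neutral_tail)
      }
      states[idx] <- sample_states(states[idx], P)
    }
    if (node$type == "leaf") {
      rows[[node$label]] <<- states
    } else {
      for (k in node$children) descend(k, states)
    }
    invisible(NULL)
  }
  descend(truth$lineage, root_states)
  aln <- do.call(rbind, rows)
  aln <- matrix(sense_codons()[aln], nrow = nrow(aln),
                dimnames = list(names(rows), NULL))
  list(alignment = aln, site_class = site_class)
}

#' Simulate a codon alignment on a fixed tree with optional foreground
#' selection
#'
#' The workhorse for testing the selection machinery: sites fall into
#' classes with background omega and (on designated foreground branches)
#' foreground omega.
#'
#' @param tree Rooted `phylo` with branch lengths (expected substitutions
#'   per codon site).
#' @param n_codons Number of codon sites.
#' @param kappa Transition/transversion ratio.
#' @param site_classes data.frame `prop`, `omega`, optional `omega_fg`.
#' @param fg_edges Integer edge indices of foreground branches.
#' @param codon_freqs 61 codon frequencies (default uniform).
#' @param seed Integer seed.
#' @return List with `alignment` (codon matrix) and `site_class`.
#' @export
sim_codon_alignment <- function(tree, n_codons, kappa = 2,
                                site_classes = data.frame(prop = 1, omega = 0.2),
                                fg_edges = integer(0),
                                codon_freqs = rep(1 / 61, 61), seed = 1L) {
  set.seed(as.integer(seed))
  if (is.null(site_classes$omega_fg)) site_classes$omega_fg <- site_classes$omega
  cls <- site_classes
  site_class <- sample.int(nrow(cls), n_codons, replace = TRUE, prob = cls$prop)
  mu <- mixture_flux(kappa, cls$omega, cls$prop, codon_freqs)
  eig_for <- function(om) mg94_eigen(build_mg94(kappa, om, codon_freqs, flux = mu))
  eig_bg <- lapply(cls$omega, eig_for)
  eig_fg <- lapply(seq_len(nrow(cls)), function(i) {
    if (cls$omega_fg[i] == cls$omega[i]) eig_bg[[i]] else eig_for(cls$omega_fg[i])
  })
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  states <- matrix(0L, nn, n_codons)
  rt <- root_node(tree)
  states[rt, ] <- sample.int(61L, n_codons, replace = TRUE, prob = codon_freqs)
  for (ei in order(node_depths(tree)[tree$edge[, 2]])) {
    u <- tree$edge[ei, 1]; v <- tree$edge[ei, 2]
    eigs <- if (ei %in% fg_edges) eig_fg else eig_bg
    for (ci in seq_len(nrow(cls))) {
      idx <- which(site_class == ci)
      if (length(idx) == 0L) next
      P <- transition_probs(eigs[[ci]], tree$edge.length[ei])
      states[v, idx] <- sample_states(states[u, idx], P)
    }
  }
  aln <- matrix(sense_codons()[states[seq_len(ntip), , drop = FALSE]],
                nrow = ntip, dimnames = list(tree$tip.label, NULL))
  list(alignment = aln, site_class = site_class)
}

#' Inject a disruptive lesion into a coding sequence
#'
#' Kinds: `start_loss` (ATG -> GTG), `premature_stop` (codon at `position`
#' replaced by TAA), `frameshift` (single-nucleotide deletion at nucleotide
#' `position`). The returned truth label is the fraction of the reference
#' protein lost when the lesioned CDS is translated to the first stop
#' (start losses are rescued at the next in-frame ATG, measured from the
#' reference N terminus).
#'
#' @param cds CDS beginning with ATG, ending with a stop codon, no internal
#'   stops.
#' @param kind Lesion kind.
#' @param position Codon index (premature_stop) or nucleotide index
#'   (frameshift); ignored for start_loss.
#' @return List with `cds` (lesioned DNA), `kind`, `position`,
#'   `fraction_lost`.
#' @export
inject_lesions <- function(cds, kind = c("start_loss", "premature_stop", "frameshift"),
                           position = NULL) {
  kind <- match.arg(kind)
  cds <- toupper(cds)
  cods <- split_codons(cds)
  ncod <- length(cods)
  if (cods[1] != "ATG") stop("CDS must begin with ATG")
  if (!is_stop_codon(cods[ncod])) stop("CDS must end with a stop codon")
  if (any(is_stop_codon(cods[-ncod]))) stop("CDS has internal stop codons")
  L <- ncod - 1L  # reference protein length

  if (kind == "premature_stop") {
    if (is.null(position) || position < 2L || position > L)
      stop("premature stop position must be a codon index in [2, ", L, "]")
    cods[position] <- "TAA"
    out <- paste0(cods, collapse = "")
    frac <- 1 - (position - 1) / L
  } else if (kind == "start_loss") {
    cods[1] <- "GTG"
    out <- paste0(cods, collapse = "")
    nxt <- which(cods == "ATG")
    nxt <- nxt[nxt > 1L & nxt <= L]
    frac <- if (length(nxt) == 0L) 1 else (nxt[1] - 1) / L
  } else {
    if (is.null(position) || position < 4L || position > 3L * L)
      stop("frameshift position must be a nucleotide index in [4, ", 3L * L, "]")
    out <- paste0(substr(cds, 1L, position - 1L),
                  substr(cds, position + 1L, nchar(cds)))
    trunc_len <- nchar(out) - nchar(out) %% 3L
    tr <- translate_cds(substr(out, 1L, trunc_len))
    frac <- 1 - nchar(tr$protein) / L
  }
  list(cds = out, kind = kind, position = position, fraction_lost = frac)
}

#' Write a codon alignment as FASTA
#'
#' @param alignment Codon matrix.
#' @param path Output file.
#' @export
write_codon_fasta <- function(alignment, path) {
  lines <- character(0)
  for (i in seq_len(nrow(alignment))) {
    lines <- c(lines, paste0(">", rownames(alignment)[i]),
               paste0(alignment[i, ], collapse = ""))
  }
  writeLines(lines, path)
}

#' Read a gap-free codon FASTA into a codon matrix
#'
#' @param path FASTA file of equal-length, gap-free coding sequences.
#' @return Codon matrix.
#' @export
read_codon_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  codon_matrix_from_dna(stats::setNames(as.character(seqs), names(seqs)))
}
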
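# Gene-model annotation: translation, transmembrane-segment prediction
# (Kyte-Doolittle hydropathy), pseudogene classification under the
# ">=20 % protein loss AND >=1 lost TM domain" rule, repertoire bookkeeping,
# reciprocal-best-hit orthogroups, lost-lineage calls and gene nomenclature.

#' Translate a coding sequence
#'
#' Standard genetic code. A trailing stop codon is dropped; an internal stop
#' truncates the protein and is flagged with its codon index.
#'
#' @param cds DNA string, length divisible by 3, ACGT alphabet.
#' @return List with `protein`, `internal_stop` (logical) and `stop_codon`
#'   (1-based codon index of the first internal stop, NA if none).
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (grepl("[^ACGT]", cds)) stop("CDS contains non-ACGT characters")
  cods <- split_codons(cds)
  aa <- unname(Biostrings::GENETIC_CODE[cods])
  stops <- which(aa == "*")
  n <- length(cods)
  if (length(stops) == 0L) {
    return(list(protein = paste0(aa, collapse = ""), internal_stop = FALSE,
                stop_codon = NA_integer_))
  }
  first <- stops[1]
  if (first == n) {
    list(protein = paste0(aa[-n], collapse = ""), internal_stop = FALSE,
         stop_codon = NA_integer_)
  } else {
    list(protein = paste0(aa[seq_len(first - 1L)], collapse = ""),
         internal_stop = TRUE, stop_codon = first)
  }
}

# Kyte-Doolittle (1982) hydropathy scale
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

#' Predict transmembrane segments by sliding-window hydropathy
#'
#' Kyte-Doolittle window means (window 19) are assigned to window centres;
#' runs of centres at or above the threshold are extended by half a window on
#' each side, merged when separated by fewer than `merge_gap` residues, and
#' filtered to a minimum length. A deterministic stand-in for neural topology
#' predictors, adequate for the highly hydrophobic 7-TM chemoreceptors.
#'
#' @param protein Protein sequence.
#' @param window Window size (odd, default 19).
#' @param threshold Mean-hydropathy threshold (default 1.6).
#' @param min_len Minimum segment length in residues (default 15).
#' @param merge_gap Merge segments separated by fewer than this many
#'   residues (default 5).
#' @return data.frame with columns `start`, `end`, `mean_hydropathy`; zero
#'   rows (with a warning) when the protein is shorter than the window.
#' @export
predict_tm_segments <- function(protein, window = 19L, threshold = 1.6,
                                min_len = 15L, merge_gap = 5L) {
  aa <- strsplit(toupper(protein), "")[[1]]
  L <- length(aa)
  empty <- data.frame(start = integer(0), end = integer(0),
                      mean_hydropathy = numeric(0))
  if (L < window) {
    warning("protein shorter than window (", L, " < ", window, ")")
    return(empty)
  }
  h <- KD_SCALE[aa]
  h[is.na(h)] <- 0
  cs <- cumsum(c(0, h))
  half <- (window - 1L) %/% 2L
  centers <- (half + 1L):(L - half)
  wmean <- (cs[centers + half + 1L] - cs[centers - half]) / window
  pass <- wmean >= threshold
  if (!any(pass)) return(empty)
  # runs of passing centres
  runs <- rle(pass)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seg <- data.frame(start = pmax(1L, centers[starts[runs$values]] - half),
                    end = pmin(L, centers[ends[runs$values]] + half))
  # merge close segments
  if (nrow(seg) > 1L) {
    keep <- list(seg[1, ])
    for (i in 2:nrow(seg)) {
      last <- keep[[length(keep)]]
      if (seg$start[i] - last$end - 1L < merge_gap) {
        keep[[length(keep)]]$end <- seg$end[i]
      } else {
        keep[[length(keep) + 1L]] <- seg[i, ]
      }
    }
    seg <- do.call(rbind, keep)
  }
  seg <- seg[seg$end - seg$start + 1L >= min_len, , drop = FALSE]
  if (nrow(seg) == 0L) return(empty)
  seg$mean_hydropathy <- vapply(seq_len(nrow(seg)), function(i) {
    mean(h[seg$start[i]:seg$end[i]])
  }, numeric(1))
  rownames(seg) <- NULL
  seg
}

# Translate from the first in-frame ATG at or after codon `from`; returns the
# protein up to (not including) the first stop, and the rescue codon index.
rescue_start <- function(cods) {
  atg <- which(cods == "ATG")
  if (length(atg) == 0L) return(list(protein = "", rescue_at = NA_integer_))
  k <- atg[1]
  tr <- translate_cds(paste0(cods[k:length(cods)], collapse = ""))
  list(protein = tr$protein, rescue_at = k)
}

#' Classify a candidate gene model as intact, pseudogene or partial
#'
#' Disruptions (mutated start codon, premature stop, frameshift) are detected
#' from the candidate CDS. The candidate is a pseudogene when a disruption
#' causes loss of at least `frac_threshold` (default 20 %) of the reference
#' protein and, under the conjunctive rule, loss of at least `tm_threshold`
#' (default 1) transmembrane segments relative to the intact reference
#' homolog. Candidates missing >= 20 % of the reference without any lesion
#' (assembly truncation) are classified `partial`.
#'
#' Mutated start codons are rescued at the next in-frame ATG, with the lost
#' fraction measured from the reference N terminus.
#'
#' @param cds Candidate coding sequence (possibly lesioned; a frameshifted
#'   CDS may have length not divisible by 3).
#' @param reference_protein Intact homolog protein (TM-predictable).
#' @param rule `"conjunctive"` (default: fraction AND TM loss required) or
#'   `"either"`.
#' @param frac_threshold,tm_threshold Rule thresholds.
#' @return List with `status` ("intact", "pseudogene" or "partial"),
#'   `lesions` (data.frame kind/position/fraction_lost/tm_lost) and
#'   `protein` (the translated, possibly truncated product).
#' @export
classify_gene_model <- function(cds, reference_protein, rule = c("conjunctive", "either"),
                                frac_threshold = 0.20, tm_threshold = 1L) {
  rule <- match.arg(rule)
  if (is.null(reference_protein) || nchar(reference_protein) == 0L)
    stop("empty reference protein")
  ref_len <- nchar(reference_protein)
  ref_tm <- nrow(predict_tm_segments(reference_protein))

  cds <- toupper(cds)
  lesions <- data.frame(kind = character(0), position = integer(0),
                        fraction_lost = numeric(0), tm_lost = integer(0),
                        stringsAsFactors = FALSE)
  frameshift <- nchar(cds) %% 3L != 0L
  if (frameshift) {
    # read in frame 0; the shifted tail will usually hit a stop
    cds_f <- substr(cds, 1L, nchar(cds) - nchar(cds) %% 3L)
  } else {
    cds_f <- cds
  }
  cods <- split_codons(cds_f)
  start_lost <- cods[1] != "ATG"

  if (start_lost) {
    res <- rescue_start(cods)
    protein <- res$protein
    position <- 1L
    kind <- "start_loss"
  } else {
    tr <- translate_cds(cds_f)
    protein <- tr$protein
    position <- if (tr$internal_stop) tr$stop_codon else NA_integer_
    kind <- if (tr$internal_stop) "premature_stop" else NA_character_
  }
  if (frameshift) {
    kind <- "frameshift"
    if (is.na(position)) position <- nchar(cds_f) %/% 3L
  }

  fraction_lost <- max(0, 1 - nchar(protein) / ref_len)
  cand_tm <- if (nchar(protein) >= 19L) nrow(predict_tm_segments(protein)) else 0L
  tm_lost <- max(0L, ref_tm - cand_tm)

  has_lesion <- start_lost || frameshift || !is.na(position)
  if (has_lesion) {
    lesions <- data.frame(kind = kind, position = position,
                          fraction_lost = fraction_lost, tm_lost = tm_lost,
                          stringsAsFactors = FALSE)
    hit <- if (rule == "conjunctive") {
      fraction_lost >= frac_threshold && tm_lost >= tm_threshold
    } else {
      fraction_lost >= frac_threshold || tm_lost >= tm_threshold
    }
    status <- if (hit) "pseudogene" else "intact"
  } else if (fraction_lost >= frac_threshold) {
    status <- "partial"
  } else {
    status <- "intact"
  }
  list(status = status, lesions = lesions, protein = protein)
}

#' Repertoire bookkeeping per species and family
#'
#' Counts loci, functional genes, pseudogenes and splice variants per
#' (species, family) cell. Partial models are excluded from both loci and
#' functional counts. Identities: `functional = loci - pseudogenes`;
#' `total_functional_proteins = functional - genes_with_splice_variants +
#' splice_variants`. Percent pseudogenes is rounded to one decimal.
#'
#' @param models data.frame with columns `id`, `species`, `family`, `status`
#'   (intact / pseudogene / partial).
#' @param splice_table Optional data.frame with columns `id`, `n_isoforms`
#'   (> 1) listing genes with alternative splicing.
#' @return data.frame, one row per (species, family).
#' @export
summarize_repertoire <- function(models, splice_table = NULL) {
  cols <- c("species", "family", "loci", "functional_genes", "pseudogenes",
            "genes_with_splice_variants", "splice_variants",
            "total_functional_proteins", "pct_pseudogenes")
  if (is.null(models) || nrow(models) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(vector(length = 0L)), length(cols)), cols))
    return(out)
  }
  stopifnot(all(c("id", "species", "family", "status") %in% names(models)))
  counted <- models[models$status != "partial", ]
  cells <- unique(counted[, c("species", "family")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- counted[counted$species == cells$species[i] &
                     counted$family == cells$family[i], ]
    loci <- nrow(sub)
    pseudo <- sum(sub$status == "pseudogene")
    functional <- loci - pseudo
    if (!is.null(splice_table) && nrow(splice_table) > 0L) {
      sp <- splice_table[splice_table$id %in% sub$id[sub$status == "intact"], , drop = FALSE]
      n_spliced <- nrow(sp)
      n_iso <- as.integer(sum(sp$n_isoforms))
    } else {
      n_spliced <- 0L; n_iso <- 0L
    }
    data.frame(species = cells$species[i], family = cells$family[i],
               loci = loci, functional_genes = functional, pseudogenes = pseudo,
               genes_with_splice_variants = n_spliced, splice_variants = n_iso,
               total_functional_proteins = functional - n_spliced + n_iso,
               pct_pseudogenes = round(100 * pseudo / loci, 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Assign orthogroups by reciprocal best hits
#'
#' All-vs-all global alignment scores between every pair of species; a pair
#' of genes is an RBH edge when each is the other's best-scoring hit in the
#' partner species (ties broken by lexicographic gene id). Connected
#' components of the RBH graph are the orthogroups.
#'
#' @param proteomes Named list (one element per species) of named character
#'   vectors of protein sequences; names are gene ids, unique across species.
#' @param family Optional family label carried through to the output.
#' @return data.frame with columns `og_id`, `gene_id`, `species`, `family`.
#' @export
assign_orthogroups <- function(proteomes, family = NA_character_) {
  if (length(proteomes) < 2L) stop("need at least two species")
  all_ids <- unlist(lapply(proteomes, names), use.names = FALSE)
  if (anyDuplicated(all_ids)) stop("duplicate gene ids across proteomes")
  species_of <- rep(names(proteomes), vapply(proteomes, length, integer(1)))
  names(species_of) <- all_ids
  seqs <- unlist(proteomes, use.names = FALSE)
  names(seqs) <- all_ids

  score_pair <- function(x, y) global_protein_align(x, y)$score
  # best hit of gene g in species sp
  best_hit <- function(g, sp) {
    targets <- sort(names(proteomes[[sp]]))  # lexicographic tie-break
    sc <- vapply(targets, function(t) score_pair(seqs[[g]], seqs[[t]]), numeric(1))
    targets[which.max(sc)]
  }
  # union-find over genes
  parent <- stats::setNames(all_ids, all_ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  union_ <- function(x, y) { rx <- find(x); ry <- find(y); if (rx != ry) parent[[rx]] <<- ry }

  spp <- names(proteomes)
  for (i in seq_along(spp)) for (j in seq_along(spp)) {
    if (i >= j) next
    for (g in sort(names(proteomes[[spp[i]]]))) {
      h <- best_hit(g, spp[j])
      if (best_hit(h, spp[i]) == g) union_(g, h)
    }
  }
  roots <- vapply(all_ids, find, character(1))
  comp <- split(all_ids, roots)
  comp <- comp[order(vapply(comp, function(x) sort(x)[1], character(1)))]
  do.call(rbind, lapply(seq_along(comp), function(k) {
    data.frame(og_id = sprintf("OG%04d", k), gene_id = sort(comp[[k]]),
               species = unname(species_of[sort(comp[[k]])]), family = family,
               stringsAsFactors = FALSE)
  }))
}

#' Call lost lineages per species
#'
#' An orthogroup is lost in a species when that species has no intact member
#' (members absent entirely, or all pseudogene/partial).
#'
#' @param og_table data.frame with columns `og_id`, `gene_id`, `species`.
#' @param statuses Named character vector: gene id -> status.
#' @param species All species to evaluate (default: those present in
#'   `og_table`).
#' @param partial_is_intact Treat partial models as intact (default FALSE).
#' @return data.frame with columns `species`, `og_id`.
#' @export
call_lost_lineages <- function(og_table, statuses, species = NULL,
                               partial_is_intact = FALSE) {
  if (is.null(species)) species <- sort(unique(og_table$species))
  ok_status <- if (partial_is_intact) c("intact", "partial") else "intact"
  miss <- setdiff(og_table$gene_id, names(statuses))
  if (length(miss) > 0L) stop("missing statuses for: ", paste(miss, collapse = ", "))
  out <- NULL
  for (og in unique(og_table$og_id)) {
    members <- og_table[og_table$og_id == og, ]
    for (sp in species) {
      ids <- members$gene_id[members$species == sp]
      if (length(ids) == 0L || !any(statuses[ids] %in% ok_status)) {
        out <- rbind(out, data.frame(species = sp, og_id = og,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) out <- data.frame(species = character(0), og_id = character(0))
  out
}

SPECIES_TAGS <- c(suzukii = "Dsuz", biarmipes = "Dbia", takahashii = "Dtak",
                  melanogaster = "Dmel", ananassae = "Dana", erecta = "Dere",
                  sechellia = "Dsec", simulans = "Dsim", yakuba = "Dyak")

#' Build a gene name under the chemoreceptor nomenclature
#'
#' `"D"` + first three letters of the specific epithet, the homolog name,
#' `-N` for members of multi-copy duplications, and a trailing `P` for
#' pseudogenes (e.g. `DsuzOr23a-2`, `DsuzOr67aP`).
#'
#' @param homolog Homolog/lineage name, e.g. `"Or23a"`.
#' @param species Specific epithet (e.g. `"suzukii"`) or a known 4-letter
#'   tag (e.g. `"Dsuz"`).
#' @param copy_index Copy number within the duplication, or NA for a single
#'   copy.
#' @param is_pseudo Append the pseudogene suffix.
#' @return Character scalar.
#' @export
name_gene <- function(homolog, species, copy_index = NA_integer_, is_pseudo = FALSE) {
  if (species %in% SPECIES_TAGS) {
    tag <- species
  } else if (species %in% names(SPECIES_TAGS)) {
    tag <- SPECIES_TAGS[[species]]
  } else if (grepl("^D[a-z]{3}$", species)) {
    tag <- species
  } else {
    stop("unknown species: ", species)
  }
  nm <- paste0(tag, homolog)
  if (!is.na(copy_index)) nm <- paste0(nm, "-", copy_index)
  if (is_pseudo) nm <- paste0(nm, "P")
  nm
}
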
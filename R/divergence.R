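# Pairwise divergence proxies: global protein alignment, percent identity,
# codon-alignment threading, and per-family divergence summaries with
# Wilcoxon comparisons. Alignment itself is delegated to
# Biostrings::pairwiseAlignment (Needleman-Wunsch, affine gaps).

aa_alphabet <- function() {
  c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
}

check_protein <- function(x, name = "sequence") {
  if (nchar(x) == 0L) stop(name, " is empty")
  chars <- strsplit(toupper(x), "")[[1]]
  bad <- setdiff(chars, aa_alphabet())
  if (length(bad) > 0L) stop(name, " contains non-amino-acid characters: ",
                             paste(unique(bad), collapse = ", "))
  invisible(TRUE)
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gap costs
#' (open 10, extend 1), as used throughout the package for reciprocal-best-hit
#' orthology and percent-identity computation.
#'
#' @param a,b Protein sequences (character scalars, 20-letter alphabet).
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @return List with aligned strings `a_aln`, `b_aln` and the alignment
#'   `score`.
#' @export
global_protein_align <- function(a, b, gap_open = 10, gap_extend = 1) {
  check_protein(a, "a"); check_protein(b, "b")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_extend)
  list(a_aln = as.character(Biostrings::alignedPattern(aln)),
       b_aln = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

#' Percent identity of an aligned protein pair
#'
#' @param alignment List with `a_aln`, `b_aln` (equal-length aligned strings),
#'   as returned by [global_protein_align()].
#' @param count_gap_columns Include gap columns in the denominator (default
#'   TRUE: identity = identical residues / full alignment length).
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(alignment, count_gap_columns = TRUE) {
  a <- strsplit(alignment$a_aln, "")[[1]]
  b <- strsplit(alignment$b_aln, "")[[1]]
  if (length(a) != length(b)) stop("aligned strings differ in length")
  if (length(a) == 0L) stop("zero-length alignment")
  ident <- sum(a == b & a != "-")
  denom <- if (count_gap_columns) length(a) else sum(a != "-" & b != "-")
  100 * ident / denom
}

#' Thread coding sequences onto a protein alignment
#'
#' Replaces each aligned residue by its source codon (PAL2NAL-style); gap
#' characters become `---`. Each protein must equal the translation of its
#' CDS (trailing stop codon allowed and dropped).
#'
#' @param alignment List with `a_aln`, `b_aln`.
#' @param cds_a,cds_b Ungapped coding sequences.
#' @return List with codon-aligned DNA strings `a_codon`, `b_codon`.
#' @export
thread_codon_alignment <- function(alignment, cds_a, cds_b) {
  thread_one <- function(prot_aln, cds, label) {
    cods <- split_codons(toupper(cds))
    if (!is_stop_codon(cods[length(cods)])) {
      # no trailing stop; use as is
    } else {
      cods <- cods[-length(cods)]
    }
    res <- strsplit(prot_aln, "")[[1]]
    out <- character(length(res))
    k <- 0L
    for (i in seq_along(res)) {
      if (res[i] == "-") {
        out[i] <- "---"
      } else {
        k <- k + 1L
        if (k > length(cods)) stop("protein alignment longer than CDS for ", label)
        aa <- codon_aa(cods[k])
        if (aa != res[i]) {
          stop("translation mismatch for ", label, " at residue ", k,
               ": codon ", cods[k], " is ", aa, ", alignment has ", res[i])
        }
        out[i] <- cods[k]
      }
    }
    if (k != length(cods)) stop("CDS longer than aligned protein for ", label)
    paste0(out, collapse = "")
  }
  list(a_codon = thread_one(alignment$a_aln, cds_a, "a"),
       b_codon = thread_one(alignment$b_aln, cds_b, "b"))
}

#' Full divergence record for one gene against its outgroup homolog
#'
#' Aligns the proteins, threads the codon alignment, and computes percent
#' identity and NG86 quantities.
#'
#' @param gene_id Identifier recorded in the output.
#' @param species Species tag of the focal gene.
#' @param protein,cds Focal gene protein and CDS.
#' @param outgroup_protein,outgroup_cds Outgroup homolog (e.g. the
#'   D. melanogaster gene).
#' @param family Gene family label ("Or" or "Gr").
#' @return One-row data.frame with pct_id and all NG86 fields.
#' @export
divergence_record <- function(gene_id, species, protein, cds,
                              outgroup_protein, outgroup_cds, family = NA_character_) {
  aln <- global_protein_align(protein, outgroup_protein)
  pct <- percent_identity(aln)
  cod <- thread_codon_alignment(aln, cds, outgroup_cds)
  ng <- ng86_pair(cod$a_codon, cod$b_codon)
  data.frame(gene_id = gene_id, species = species, family = family,
             pct_id = pct, S = ng$S, N = ng$N, Sd = ng$Sd, Nd = ng$Nd,
             pS = ng$pS, pN = ng$pN, dS = ng$dS, dN = ng$dN,
             dn_ds = ng$ratio, saturated = ng$saturated,
             stringsAsFactors = FALSE)
}

#' Summaries and rank tests over a table of divergence records
#'
#' Computes mean dN, dS and dN/dS per species x family cell, paired Wilcoxon
#' signed-rank tests between species within a family (paired on shared gene
#' ids), and unpaired rank-sum tests between families within a species.
#'
#' @param records data.frame as produced by rbind-ing [divergence_record()]
#'   rows.
#' @return List with `means` (data.frame), `between_species` (paired tests),
#'   `between_families` (unpaired tests).
#' @export
divergence_summary <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  records <- records[order(records$species, records$family, records$gene_id), ]
  cell <- interaction(records$species, records$family, drop = TRUE)
  means <- do.call(rbind, lapply(split(records, cell), function(df) {
    data.frame(species = df$species[1], family = df$family[1], n = nrow(df),
               mean_pct_id = mean(df$pct_id, na.rm = TRUE),
               mean_dN = mean(df$dN, na.rm = TRUE),
               mean_dS = mean(df$dS, na.rm = TRUE),
               mean_dn_ds = mean(df$dn_ds, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(means) <- NULL

  stats_cols <- c("dN", "dS", "dn_ds")
  between_species <- NULL
  for (fam in unique(records$family)) {
    sub <- records[records$family == fam, ]
    spp <- unique(sub$species)
    if (length(spp) < 2L) next
    for (i in seq_along(spp)) for (j in seq_along(spp)) {
      if (i >= j) next
      a <- sub[sub$species == spp[i], ]
      b <- sub[sub$species == spp[j], ]
      shared <- intersect(a$gene_id, b$gene_id)
      if (length(shared) < 1L) next
      for (colname in stats_cols) {
        va <- a[[colname]][match(shared, a$gene_id)]
        vb <- b[[colname]][match(shared, b$gene_id)]
        ok <- !is.na(va) & !is.na(vb)
        if (sum(ok) < 1L) next
        w <- wilcoxon_signed_rank(va[ok], vb[ok])
        between_species <- rbind(between_species, data.frame(
          family = fam, species_a = spp[i], species_b = spp[j],
          statistic_name = colname, n = w$n, W = w$W, p = w$p,
          stringsAsFactors = FALSE))
      }
    }
  }

  between_families <- NULL
  fams <- unique(records$family)
  if (length(fams) >= 2L) {
    for (sp in unique(records$species)) {
      sub <- records[records$species == sp, ]
      for (i in seq_along(fams)) for (j in seq_along(fams)) {
        if (i >= j) next
        for (colname in stats_cols) {
          va <- sub[[colname]][sub$family == fams[i]]
          vb <- sub[[colname]][sub$family == fams[j]]
          va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
          if (length(va) < 1L || length(vb) < 1L) next
          w <- wilcoxon_rank_sum(va, vb)
          between_families <- rbind(between_families, data.frame(
            species = sp, family_a = fams[i], family_b = fams[j],
            statistic_name = colname, U = w$U, p = w$p,
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  list(means = means, between_species = between_species,
       between_families = between_families)
}
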
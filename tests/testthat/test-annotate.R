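# Translation, TM prediction, pseudogene classification, repertoire
# bookkeeping, orthogroups, lost lineages and nomenclature

test_that("translation handles trailing and internal stops", {
  expect_equal(translate_cds("ATGTTTTAA")$protein, "MF")
  tr <- translate_cds("ATGTAAAAA")
  expect_equal(tr$protein, "M")
  expect_true(tr$internal_stop)
  expect_equal(tr$stop_codon, 2L)
  expect_error(translate_cds("ATGX"), "non-ACGT|divisible")
  expect_error(translate_cds("ATGA"), "divisible")

  # random ORF agrees with the Biostrings translation oracle
  set.seed(3)
  cods <- sample(setdiff(sense_codons(), c()), 300, replace = TRUE)
  cds <- paste0(cods, collapse = "")
  expect_equal(translate_cds(cds)$protein,
               as.character(Biostrings::translate(Biostrings::DNAString(cds))))
})

test_that("TM segments follow hydropathy windows", {
  expect_equal(nrow(predict_tm_segments(strrep("L", 30))), 1L)
  seg <- predict_tm_segments(strrep("L", 30))
  expect_gte(seg$end - seg$start + 1, 25)
  expect_equal(nrow(predict_tm_segments(strrep("D", 30))), 0L)
  expect_warning(short <- predict_tm_segments("LLLL"), "shorter")
  expect_equal(nrow(short), 0L)
  expect_equal(nrow(predict_tm_segments(synthetic_7tm_protein())), 7L)
})

test_that("pseudogene rule is conjunctive by default and switchable", {
  ref <- synthetic_7tm_protein()
  cds <- paste0(reverse_translate(ref), "TAA")
  L <- nchar(ref)

  # premature stop losing ~50 %: both thresholds exceeded -> pseudogene
  les <- inject_lesions(cds, "premature_stop", position = floor(L / 2))
  cl <- classify_gene_model(les$cds, ref)
  expect_equal(cl$status, "pseudogene")
  expect_gte(cl$lesions$fraction_lost, 0.2)
  expect_gte(cl$lesions$tm_lost, 1)

  # premature stop losing ~10 %: below the >= 20 % rule -> intact
  les2 <- inject_lesions(cds, "premature_stop", position = ceiling(0.92 * L))
  expect_equal(classify_gene_model(les2$cds, ref)$status, "intact")

  # >= 20 % lost but zero TM segments lost -> intact under conjunctive rule,
  # pseudogene under either-sufficient
  # reference with a long hydrophilic C-terminal tail
  ref_tail <- paste0(strrep("L", 25), strrep("D", 75))
  cds_tail <- paste0("ATG", reverse_translate(ref_tail), "TAA")
  ref_tail_full <- paste0("M", ref_tail)
  les3 <- inject_lesions(cds_tail, "premature_stop",
                         position = floor(0.7 * nchar(ref_tail_full)))
  cl3 <- classify_gene_model(les3$cds, ref_tail_full)
  expect_equal(cl3$lesions$tm_lost, 0)
  expect_gte(cl3$lesions$fraction_lost, 0.2)
  expect_equal(cl3$status, "intact")
  expect_equal(classify_gene_model(les3$cds, ref_tail_full, rule = "either")$status,
               "pseudogene")

  # assembly truncation without lesion -> partial
  trunc <- substr(cds, 1, 3 * floor(0.6 * L))
  trunc <- substr(trunc, 1, nchar(trunc) - nchar(trunc) %% 3)
  cl4 <- classify_gene_model(trunc, ref)
  expect_equal(cl4$status, "partial")
  expect_error(classify_gene_model(cds, ""), "empty")
})

test_that("start-loss rescue measures loss from the reference N terminus", {
  # protein with an internal Met at 40 % of length
  prot <- paste0("M", strrep("L", 39), "M", strrep("L", 60))
  cds <- paste0(reverse_translate(prot), "TAA")
  les <- inject_lesions(cds, "start_loss")
  expect_equal(les$fraction_lost, 40 / 101, tolerance = 1e-9)
  cl <- classify_gene_model(les$cds, prot)
  expect_equal(cl$lesions$kind, "start_loss")
  expect_equal(cl$lesions$fraction_lost, 40 / 101, tolerance = 1e-9)
})

test_that("repertoire arithmetic identities hold", {
  mk <- function(species, family, n_intact, n_pseudo) {
    data.frame(id = paste0(species, family, seq_len(n_intact + n_pseudo)),
               species = species, family = family,
               status = c(rep("intact", n_intact), rep("pseudogene", n_pseudo)),
               stringsAsFactors = FALSE)
  }
  models <- rbind(mk("Dsuz", "Or", 62, 9), mk("Dsuz", "Gr", 71, 3))
  splice <- data.frame(id = c("DsuzOr1", "DsuzOr2", "DsuzGr1", "DsuzGr2", "DsuzGr3"),
                       n_isoforms = c(3, 3, 5, 4, 4))
  rep_tab <- summarize_repertoire(models, splice)
  or_row <- rep_tab[rep_tab$family == "Or", ]
  expect_equal(or_row$loci, 71)
  expect_equal(or_row$functional_genes, 62)
  expect_equal(or_row$total_functional_proteins, 66)
  expect_equal(or_row$pct_pseudogenes, 12.7)
  gr_row <- rep_tab[rep_tab$family == "Gr", ]
  expect_equal(gr_row$functional_genes, 71)
  expect_equal(gr_row$total_functional_proteins, 81)
  # identities on every row
  expect_equal(rep_tab$functional_genes, rep_tab$loci - rep_tab$pseudogenes)
  expect_equal(rep_tab$total_functional_proteins,
               rep_tab$functional_genes - rep_tab$genes_with_splice_variants +
                 rep_tab$splice_variants)
  # partials excluded from loci
  models2 <- rbind(models, data.frame(id = "DsuzOrX", species = "Dsuz",
                                      family = "Or", status = "partial"))
  expect_equal(summarize_repertoire(models2, splice)[1, "loci"],
               rep_tab[1, "loci"])
  expect_equal(nrow(summarize_repertoire(models[0, ])), 0L)
})

test_that("reciprocal-best-hit orthogroups are symmetric and sane", {
  set.seed(9)
  base <- vapply(1:3, function(i) {
    paste0(sample(aa_alphabet(), 60, replace = TRUE), collapse = "")
  }, character(1))
  mutate <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    idx <- sample(length(v), k)
    v[idx] <- sample(aa_alphabet(), k, replace = TRUE)
    paste0(v, collapse = "")
  }
  proteomes <- list(
    A = setNames(vapply(base, mutate, character(1), k = 3),
                 paste0("A_g", 1:3)),
    B = setNames(vapply(base, mutate, character(1), k = 3),
                 paste0("B_g", 1:3)))
  ogs <- assign_orthogroups(proteomes)
  expect_equal(length(unique(ogs$og_id)), 3L)
  # permuting species order changes no memberships
  ogs2 <- assign_orthogroups(rev(proteomes))
  key <- function(x) sort(vapply(split(x$gene_id, x$og_id),
                                 function(g) paste(sort(g), collapse = "+"),
                                 character(1)))
  expect_equal(key(ogs), key(ogs2))
  expect_error(assign_orthogroups(list(A = c(g1 = "MKL"))), "two species")
})

test_that("lost lineages require absence of any intact member", {
  og <- data.frame(og_id = c("OG1", "OG1", "OG2", "OG2", "OG3"),
                   gene_id = c("a1", "b1", "a2", "b2", "a3"),
                   species = c("A", "B", "A", "B", "A"))
  st <- c(a1 = "intact", b1 = "intact", a2 = "intact", b2 = "pseudogene",
          a3 = "intact")
  lost <- call_lost_lineages(og, st, species = c("A", "B"))
  expect_true(all(c("OG2", "OG3") %in% lost$og_id[lost$species == "B"]))
  expect_equal(nrow(lost[lost$species == "A", ]), 0L)
})

test_that("lost-lineage calls reproduce the reported suzukii/biarmipes pattern", {
  # presence/absence mirroring the reported losses: Or74a, Or85a, Or98b lost
  # in Dsuz; Or33c lost in Dbia; all other lineages intact everywhere
  lineages <- c("Or74a", "Or85a", "Or98b", "Or33c", "Or42b", "Or67a")
  rows <- NULL; st <- character(0)
  for (li in lineages) {
    for (sp in c("Dsuz", "Dbia", "Dtak")) {
      id <- paste0(sp, li)
      pseudo <- (sp == "Dsuz" && li %in% c("Or74a", "Or85a", "Or98b")) ||
        (sp == "Dbia" && li == "Or33c")
      rows <- rbind(rows, data.frame(og_id = li, gene_id = id, species = sp))
      st[id] <- if (pseudo) "pseudogene" else "intact"
    }
  }
  lost <- call_lost_lineages(rows, st)
  expect_setequal(lost$og_id[lost$species == "Dsuz"], c("Or74a", "Or85a", "Or98b"))
  expect_setequal(lost$og_id[lost$species == "Dbia"], "Or33c")
  expect_equal(sum(lost$species == "Dtak"), 0L)
})

test_that("gene nomenclature follows the prefix/suffix rules", {
  expect_equal(name_gene("Or23a", "suzukii", copy_index = 2), "DsuzOr23a-2")
  expect_equal(name_gene("Or67a", "suzukii", is_pseudo = TRUE), "DsuzOr67aP")
  expect_equal(name_gene("Gr59d", "takahashii", copy_index = 1), "DtakGr59d-1")
  expect_equal(name_gene("Or1", "Dbia"), "DbiaOr1")
  expect_error(name_gene("Or1", "unknownia"), "unknown species")
})
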
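# Gene-family birth-death simulator, codon evolution and lesion injection

test_that("degenerate rates give one intact copy per species", {
  sp <- melanogaster_group_tree()
  fam <- simulate_gene_family(sp, 0, 0, 0, seed = 1)
  expect_equal(length(fam$leaf_species), 9L)
  expect_equal(sort(unname(fam$leaf_species)), sort(sp$tip.label))
  expect_equal(fam$n_dup, 0L)
  expect_equal(sum(fam$losses$n_losses), 0L)
  expect_equal(length(fam$pseudo_leaves), 0L)
  # gene tree topologically identical to the species tree
  gt <- fam$gene_tree
  gt$tip.label <- sub("_1$", "", gt$tip.label)
  expect_equal(canonical_topology(gt), canonical_topology(sp))
})

test_that("simulation is bytewise deterministic in the seed", {
  sp <- melanogaster_group_tree()
  f1 <- simulate_gene_family(sp, 0.3, 0.15, 0.1, seed = 33)
  f2 <- simulate_gene_family(sp, 0.3, 0.15, 0.1, seed = 33)
  expect_identical(f1, f2)
  cfg <- sim_config(seed = 33, species_tree = sp, n_codons = 40)
  e1 <- evolve_codons(f1, cfg, seed = 34)
  e2 <- evolve_codons(f2, cfg, seed = 34)
  expect_identical(e1, e2)
  f3 <- simulate_gene_family(sp, 0.3, 0.15, 0.1, seed = 34)
  expect_false(identical(f1$leaf_species, f3$leaf_species) &&
                 identical(f1$n_dup, f3$n_dup) &&
                 identical(write_newick(f1$gene_tree), write_newick(f3$gene_tree)))
})

test_that("rate-zero guarantees hold across many replicates", {
  sp <- melanogaster_group_tree()
  for (seed in 1:10) {
    fam <- simulate_gene_family(sp, 0.4, 0, 0.3, seed = seed)
    expect_equal(sum(fam$losses$n_losses), 0L)   # loss_rate 0 -> no losses
    fam2 <- simulate_gene_family(sp, 0.4, 0.3, 0, seed = seed)
    expect_equal(length(fam2$pseudo_leaves), 0L) # pseudo_rate 0 -> no pseudo
  }
})

test_that("birth-process expectation matches the closed form", {
  # single branch of length 5 at dup rate 0.2: E[copies] = e^{0.2 * 5} = e
  one <- parse_newick("(tip:5,other:0.000001);")
  nrep <- 400
  copies <- vapply(seq_len(nrep), function(s) {
    fam <- simulate_gene_family(one, 0.2, 0, 0, seed = 10000 + s)
    sum(fam$leaf_species == "tip")
  }, numeric(1))
  mc_se <- stats::sd(copies) / sqrt(nrep)
  expect_lt(abs(mean(copies) - exp(1)), 4 * mc_se + 0.05)
})

test_that("codon evolution tracks branch length and root frequencies", {
  # observed differing-codon fraction matches the model expectation computed
  # with a series-summation matrix exponential (independent of the eigen path)
  two <- parse_newick("(a:0.3,b:0.0000001);")
  n <- 8000
  sim <- sim_codon_alignment(two, n, kappa = 2,
                             site_classes = data.frame(prop = 1, omega = 1),
                             seed = 77)
  pi <- rep(1 / 61, 61)
  m <- build_mg94(2, 1, pi)
  P <- oracle_expm(m$Q, 0.3)
  p_diff_expect <- 1 - sum(pi * diag(P))
  obs <- mean(sim$alignment["a", ] != sim$alignment["b", ])
  se <- sqrt(p_diff_expect * (1 - p_diff_expect) / n)
  expect_lt(abs(obs - p_diff_expect), 4 * se)

  # long-run codon usage converges to codon_freqs (chi-square GOF not
  # rejected at alpha = 0.01)
  counts <- table(factor(sim$alignment["b", ], levels = sense_codons()))
  gof <- stats::chisq.test(counts, p = pi)
  expect_gt(gof$p.value, 0.01)

  # zero branch lengths: all rows identical
  z <- parse_newick("(a:0,b:0);")
  simz <- sim_codon_alignment(z, 50, seed = 5)
  expect_identical(simz$alignment["a", ], simz$alignment["b", ])
})

test_that("pseudogenized copies evolve neutrally afterwards", {
  # two-species tree with a long branch; force pseudogenization via high rate
  sp <- parse_newick("(A:2,B:2);")
  found <- FALSE
  for (seed in 1:50) {
    fam <- simulate_gene_family(sp, 0, 0, 0.5, seed = seed)
    if (length(fam$pseudo_leaves) > 0) { found <- TRUE; break }
  }
  expect_true(found)
  cfg <- sim_config(seed = 1, species_tree = sp, n_codons = 2000,
                    site_classes = data.frame(prop = 1, omega = 0.05))
  ev <- evolve_codons(fam, cfg, seed = 2)
  # the pseudogene row must be more diverged from its sibling than an
  # intact pair would be (neutral tail accelerates nonsynonymous change)
  expect_true(all(fam$pseudo_leaves %in% rownames(ev$alignment)))
})

test_that("sim_config validates its invariants", {
  sp <- melanogaster_group_tree()
  expect_error(sim_config(species_tree = sp), "seed")
  expect_error(sim_config(1, sp, site_classes = data.frame(prop = c(0.5, 0.4),
                                                           omega = c(1, 1))),
               "sum to 1")
  expect_error(sim_config(1, sp, dup_rate = -1), ">= 0")
  expect_error(sim_config(1, sp, codon_freqs = rep(1 / 64, 64)), "61")
  st_nolen <- parse_newick("(A,B);")
  expect_error(sim_config(1, st_nolen), "branch lengths")
})

test_that("lesion injection produces the documented truth labels", {
  prot <- synthetic_7tm_protein()
  cds <- paste0(reverse_translate(prot), "TAA")
  L <- nchar(prot)

  mid <- floor(L / 2)
  les <- inject_lesions(cds, "premature_stop", position = mid)
  expect_equal(les$fraction_lost, 1 - (mid - 1) / L)
  expect_lt(abs(les$fraction_lost - 0.5), 1.5 / L)
  tr <- translate_cds(substr(les$cds, 1, 3 * (nchar(les$cds) %/% 3)))
  expect_equal(nchar(tr$protein), mid - 1L)

  # frameshift near the 3' end loses < 20 %: classifier calls intact
  fs <- inject_lesions(cds, "frameshift", position = 3 * L - 10)
  expect_lt(fs$fraction_lost, 0.2)
  expect_equal(classify_gene_model(fs$cds, prot)$status, "intact")

  expect_error(inject_lesions(cds, "premature_stop", position = 10000),
               "position")
  expect_error(inject_lesions("AAATTTTAA", "premature_stop", 2), "ATG")
})

test_that("codon alignments write and read back through FASTA", {
  sp <- parse_newick("(a:0.1,b:0.1);")
  sim <- sim_codon_alignment(sp, 30, seed = 3)
  path <- tempfile(fileext = ".fasta")
  write_codon_fasta(sim$alignment, path)
  back <- read_codon_fasta(path)
  expect_identical(back, sim$alignment[rownames(back), , drop = FALSE])
  unlink(path)
})
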
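# Tree building, bootstrap, rooting, the BS-1/2/3 duplication criterion,
# exclusion series and nomenclature.

test_that("NJ recovers additive distances and ignores input order", {
  labs <- c("A", "B", "C", "D")
  d <- matrix(c(0, 2, 4, 4,
                2, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4, 4, dimnames = list(labs, labs))
  tr <- nj_tree(d)
  # split AB|CD with internal branch 2 and external branches 1
  expect_true(ape::is.monophyletic(ape::root(tr, "A"), c("C", "D")))
  pd <- ape::cophenetic.phylo(tr)[labs, labs]
  expect_equal(unname(pd), unname(d), tolerance = 1e-9)
  # permuting the taxa leaves the topology invariant
  perm <- c("C", "A", "D", "B")
  tr2 <- nj_tree(d[perm, perm])
  expect_equal(ape::dist.topo(tr, tr2), structure(0, names = "PH85"),
               ignore_attr = TRUE)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2,
                              dimnames = list(c("A", "B"), c("A", "B")))),
               "3 taxa")
  dbad <- d; dbad[1, 2] <- 3
  expect_error(nj_tree(dbad), "symmetric")
})

test_that("NJ path lengths reproduce random additive matrices", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(5:8, 1)
    src <- ape::rtree(n)
    d <- ape::cophenetic.phylo(src)
    got <- ape::cophenetic.phylo(nj_tree(d))[rownames(d), colnames(d)]
    expect_equal(got, d, tolerance = 1e-6)
  }
})

test_that("codon-column bootstrap is reproducible and certain on clean data", {
  set.seed(5)
  cfg <- sim_config(n_genes = 6, codons_per_gene = 300, seed = 5)
  truth <- simulate_history(cfg)
  seqs <- simulate_sequences(truth, cfg)
  fam <- table(sub(".*_f(\\d+)c.*", "\\1", seqs$gene_id))
  f <- names(fam)[fam >= 5][1]
  s <- with(seqs[grepl(paste0("_f", f, "c"), seqs$gene_id), ],
            stats::setNames(sequence, gene_id))
  b1 <- bootstrap_supports(s, replicates = 50, seed = 9)
  b2 <- bootstrap_supports(s, replicates = 50, seed = 9)
  expect_identical(b1$node.label, b2$node.label)
  # well-separated clades at 300 codons: every measurable edge near-certain
  sup <- suppressWarnings(as.numeric(b1$node.label))
  expect_true(all(sup[!is.na(sup)] >= 95))
  expect_error(bootstrap_supports(s[1:3]), "fewer than 4")
})

test_that("outgroup rooting preserves leaves and bipartition supports", {
  tr <- ape::read.tree(text = "((A_g1:1,B_g1:1)95:0.5,(A_g2:1,B_g2:1)88:0.5,C_g1:2);")
  rt <- root_by_outgroup(tr, "C_g1")
  expect_true(ape::is.rooted(rt))
  expect_setequal(rt$tip.label, tr$tip.label)
  # the (A_g1,B_g1) clade keeps its 95 support after rooting
  ntip <- ape::Ntip(rt)
  mrca <- ape::getMRCA(rt, c("A_g1", "B_g1"))
  expect_equal(rt$node.label[mrca - ntip], "95")
  expect_error(root_by_outgroup(tr, "Z_g9"), "lookup error")
})

test_that("the BS-1/2/3 rule classifies shared and lineage-specific calls", {
  # two child clades spanning the same two lineages, all supports high:
  # a fully supported shared duplication
  tr <- ape::read.tree(text = paste0(
    "(((Vitvi_g1:1,Solly_g1:1)100:1,(Vitvi_g2:1,Solly_g2:1)100:1)99:1,Out_g1:3);"))
  calls <- detect_duplications(root_by_outgroup(tr, "Out_g1"))
  sh <- calls[calls$classification == "shared", ]
  expect_equal(nrow(sh), 1L)
  expect_equal(c(sh$bs1, sh$bs2, sh$bs3), c(99, 100, 100))
  expect_true(sh$supported)

  # same species on both sides only once: species-specific
  tr2 <- ape::read.tree(text =
    "(((SpA_g1:1,SpA_g2:1)100:1,SpB_g1:2)100:1,Out_g1:3);")
  calls2 <- detect_duplications(root_by_outgroup(tr2, "Out_g1"))
  expect_equal(calls2$classification, "species_specific")
  expect_true(calls2$supported)  # leaf children count as 100 by convention

  # low child-clade supports fail the threshold
  tr3 <- ape::read.tree(text = paste0(
    "(((Vitvi_g1:1,Solly_g1:1)45:1,(Vitvi_g2:1,Solly_g2:1)38:1)95:1,Out_g1:3);"))
  calls3 <- detect_duplications(root_by_outgroup(tr3, "Out_g1"))
  expect_false(any(calls3$supported))
  # the same tree passes a laxer threshold
  calls3b <- detect_duplications(root_by_outgroup(tr3, "Out_g1"), threshold = 30)
  expect_true(any(calls3b$supported))
})

test_that("duplication calls are invariant to child ordering", {
  tr_lr <- ape::read.tree(text = paste0(
    "(((SpA_g1:1,SpB_g1:1)90:1,(SpA_g2:1,SpB_g2:1)97:1)95:1,Out_g1:3);"))
  tr_rl <- ape::read.tree(text = paste0(
    "(((SpA_g2:1,SpB_g2:1)97:1,(SpA_g1:1,SpB_g1:1)90:1)95:1,Out_g1:3);"))
  c1 <- detect_duplications(root_by_outgroup(tr_lr, "Out_g1"))
  c2 <- detect_duplications(root_by_outgroup(tr_rl, "Out_g1"))
  sh1 <- c1[c1$classification == "shared", ]
  sh2 <- c2[c2$classification == "shared", ]
  expect_equal(sort(c(sh1$bs2, sh1$bs3)), sort(c(sh2$bs2, sh2$bs3)))
  expect_equal(sh1$bs1, sh2$bs1)
  expect_equal(sh1$supported, sh2$supported)
})

test_that("missing species mapping is an error", {
  tr <- ape::read.tree(text = "((SpA_g1:1,SpB_g1:1)90:1,Out_g1:3);")
  rt <- root_by_outgroup(tr, "Out_g1")
  expect_error(detect_duplications(rt, species = c(SpA_g1 = "SpA")),
               "mapping error")
})

test_that("exclusion of a near-WGD early-diverging lineage rescues support", {
  # SpC branches off just before the planted WGD; with short sequences its
  # single gene attaches inconsistently across replicates and depresses the
  # supports around the duplication node.  Excluding it recovers a clean,
  # fully supported shared call, mirroring the basal-lineage exclusion
  # practice on real trees.
  cfg <- sim_config(
    species_tree = "(((SpA:0.05,SpB:0.05)AB:0.348,SpC:0.398)ABC:0.202,Out:0.75)R;",
    wgd_events = data.frame(branch = "AB", pos = 0.005 / 0.348, retention = 1.0,
                            label = "wgd"),
    n_genes = 3, codons_per_gene = 60, omega = 0.2, seed = 21)
  truth <- simulate_history(cfg)
  seqs <- simulate_sequences(truth, cfg)
  fam1 <- seqs[grepl("_f001", seqs$gene_id), ]
  s <- stats::setNames(fam1$sequence, fam1$gene_id)
  og <- grep("^Out", names(s), value = TRUE)
  res <- run_exclusion_series(
    s, list(baseline = character(0), no_C = "SpC"),
    outgroup = og, threshold = 90, replicates = 100, seed = 31)
  expect_equal(res$comparison$analysis, c("baseline", "no_C"))
  # the exclusion run recovers the shared duplication with full support
  expect_gt(res$comparison$n_supported_shared[res$comparison$analysis == "no_C"], 0L)
  # excluding the outgroup is a usage error; unknown taxa only warn
  expect_error(run_exclusion_series(s, list(x = "Out"), outgroup = og),
               "usage error")
  expect_warning(
    run_exclusion_series(s, list(x = "Nosuch"), outgroup = og,
                         replicates = 10, seed = 1),
    "absent")
})

test_that("subfamily nomenclature reproduces the published letter scheme", {
  tr <- ape::read.tree(text = paste0(
    "(((At_VOZ1:1,(Vitvi_g1:1,(Poptr_g1:1,Poptr_g2:1)90:1)90:1)90:1,",
    "(At_VOZ2:1,(Vitvi_g2:1,(Poptr_g3:1,Poptr_g4:1)90:1)90:1)90:1)90:1,",
    "Ambtr_g9:3);"))
  nm <- assign_subfamily_names(tr, c(At_VOZ1 = 1, At_VOZ2 = 2))
  lookup <- stats::setNames(nm$name, nm$gene_id)
  # one gene per subfamily: A and B
  expect_equal(unname(lookup["Vitvi_g1"]), "Vitvi_VOZ1A")
  expect_equal(unname(lookup["Vitvi_g2"]), "Vitvi_VOZ2B")
  # two genes per subfamily: 1A/1C and 2B/2D
  expect_setequal(unname(lookup[c("Poptr_g1", "Poptr_g2")]),
                  c("Poptr_VOZ1A", "Poptr_VOZ1C"))
  expect_setequal(unname(lookup[c("Poptr_g3", "Poptr_g4")]),
                  c("Poptr_VOZ2B", "Poptr_VOZ2D"))
  # single-copy species: bare family name without digit or suffix
  expect_equal(unname(lookup["Ambtr_g9"]), "Ambtr_VOZ")
  # names are unique over classified genes (injective naming)
  expect_false(anyDuplicated(nm$name[nm$classified]) > 0)
  expect_error(assign_subfamily_names(tr, c(Nope_g1 = 1)), "lookup error")
})
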
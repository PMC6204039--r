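# I/O layer: FASTA validation, gene models from GFF3/BED, Newick supports,
# intron phases, edge-list export.

write_fasta <- function(ids, seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

test_that("read_cds_fasta validates frame, stops, and isoform policy", {
  p <- write_fasta(c("SpA_g1", "SpA_g2"),
                   c("ATGGCTGCT", "ATGGCTGCTTAA"))  # second has terminal stop
  cds <- read_cds_fasta(p)
  expect_s3_class(cds, "cds_set")
  expect_equal(nrow(cds), 2L)
  expect_equal(cds$sequence[2], "ATGGCTGCT")  # terminal stop stripped
  expect_equal(cds$species, c("SpA", "SpA"))

  # isoform selection keeps the longest sequence per gene stem
  p2 <- write_fasta(c("SpA_geneX.1", "SpA_geneX.2", "SpA_geneY.1"),
                    c(strrep("ATGGCTGCTGCA", 25),  # 300 nt
                      strrep("ATGGCTGCTGCA", 37),  # 444 nt: wins
                      "ATGGCT"))
  longest <- read_cds_fasta(p2, isoform_policy = "longest")
  expect_equal(nrow(longest), 2L)
  expect_equal(nchar(longest$sequence[longest$gene_id == "SpA_geneX.2"]), 444L)
  expect_false("SpA_geneX.1" %in% longest$gene_id)
  # idempotent: applying the policy to its own output changes nothing
  again <- cds_set(longest$gene_id, longest$sequence, isoform_policy = "longest")
  expect_equal(again$gene_id, longest$gene_id)

  # 301 nt is out of frame
  p3 <- write_fasta("SpA_bad", paste0(strrep("ATG", 100), "A"))
  expect_error(read_cds_fasta(p3), "frame error")
  # internal stop is rejected
  p4 <- write_fasta("SpA_stop", "ATGTAAGCT")
  expect_error(read_cds_fasta(p4), "internal stop")
  # empty file is a format error
  p5 <- tempfile(fileext = ".fasta"); file.create(p5)
  expect_error(read_cds_fasta(p5), "format error|read")
})

test_that("GFF3 gene models convert coordinates, order exons, assign ranks", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tCDS\t1\t99\t.\t+\t0\tID=cds1;Parent=SpA_g1",
    "chr1\tsrc\tCDS\t201\t300\t.\t-\t0\tID=cds2a;Parent=SpA_g2",
    "chr1\tsrc\tCDS\t401\t500\t.\t-\t0\tID=cds2b;Parent=SpA_g2",
    "chr1\tsrc\tCDS\t91\t120\t.\t+\t0\tID=cds3;Parent=SpA_g3"),
    gff)
  gm <- read_gene_models(gff, format = "gff3")
  g1 <- gm[gm$gene_id == "SpA_g1", ]
  expect_equal(c(g1$start, g1$end), c(0, 99))        # GFF3 1..99 -> (0, 99]
  expect_equal(g1$exon_cds_lengths[[1]], 99L)
  # minus strand: downstream segment first in transcript orientation
  g2 <- gm[gm$gene_id == "SpA_g2", ]
  expect_equal(g2$exon_cds_lengths[[1]], c(100L, 100L))
  expect_equal(g2$strand, "-")
  # ranks follow start order along the chromosome
  expect_equal(gm$rank[match(c("SpA_g1", "SpA_g3", "SpA_g2"), gm$gene_id)],
               c(0L, 1L, 2L))
  # round trip back to GFF3 coordinates is exact
  expect_equal(g1$start + 1, 1)
  expect_equal(g1$end, 99)

  # overlapping CDS segments within one gene are invalid
  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tCDS\t1\t99\t.\t+\t0\tID=x1;Parent=SpA_bad",
               "chr1\tsrc\tCDS\t50\t120\t.\t+\t0\tID=x2;Parent=SpA_bad"), bad)
  expect_error(read_gene_models(bad, format = "gff3"), "overlapping")
})

test_that("BED gene models use 0-based half-open coordinates directly", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr2\t0\t90\tSpB_g1\t0\t+",
               "chr2\t500\t620\tSpB_g2\t0\t-"), bed)
  gm <- read_gene_models(bed, format = "bed")
  expect_equal(gm$start, c(0, 500))
  expect_equal(gm$end, c(90, 620))
  expect_equal(gm$rank, c(0L, 1L))
  expect_equal(gm$exon_cds_lengths[[1]], 90L)
})

test_that("Newick trees parse with supports in declared units", {
  p <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1)95:0.5,C:2);", p)
  tr <- read_tree_newick(p, support_units = "bootstrap")
  expect_equal(ape::Ntip(tr), 3L)
  expect_true("95" %in% tr$node.label)
  expect_equal(attr(tr, "support_units"), "bootstrap")
  # no supports at all is fine
  p2 <- tempfile(fileext = ".nwk"); writeLines("(A,B);", p2)
  tr2 <- read_tree_newick(p2)
  expect_equal(ape::Ntip(tr2), 2L)
  # a bootstrap-range value is invalid under posterior units
  expect_error(read_tree_newick(p, support_units = "posterior"),
               "validation error")
  # malformed newick
  p3 <- tempfile(fileext = ".nwk"); writeLines("((A,B);", p3)
  expect_error(read_tree_newick(p3))
})

test_that("intron phases are cumulative coding length mod 3", {
  expect_equal(compute_intron_phases(c(99, 150, 100, 200)), c(0L, 0L, 1L))
  expect_equal(compute_intron_phases(150), integer(0))
  expect_equal(compute_intron_phases(c(100, 100)), 1L)
  # partition invariance: the final cumulative sum only depends on the total
  set.seed(42)
  for (i in 1:20) {
    total <- sample(30:300, 1) * 3 + sample(0:2, 1)
    cuts <- sort(sample(seq_len(total - 1), sample(1:5, 1)))
    lens <- diff(c(0, cuts, total))
    ph <- compute_intron_phases(lens)
    expect_equal(sum(lens) %% 3, total %% 3)
    if (length(ph)) expect_true(all(ph %in% 0:2))
  }
})

test_that("edge lists are deterministic and format-correct", {
  blocks <- list(structure(list(
    id = "B1", chrom_a = "c1", chrom_b = "c2", orientation = "same",
    score = 10,
    n_anchors = 2L,
    anchors = data.frame(gene_a = c("X_a", "X_b"), gene_b = c("Y_a", "Y_b"),
                         rank_a = 1:2, rank_b = 1:2, similarity = 5)),
    class = "synteny_block"))
  net <- build_locus_network(blocks, c("X_a", "Y_a", "Z_c"))
  f1 <- tempfile(); f2 <- tempfile()
  write_edge_list(net, f1)
  write_edge_list(net, f2)
  expect_identical(readLines(f1), readLines(f2))
  tab <- utils::read.delim(f1)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$weight, log1p(10))
  # empty network: header only
  f3 <- tempfile()
  write_edge_list(build_locus_network(list(), "X_a"), f3)
  expect_equal(length(readLines(f3)), 1L)
  # SIF flavour
  f4 <- tempfile()
  write_edge_list(net, f4, format = "sif")
  expect_match(readLines(f4), "synteny")
})
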
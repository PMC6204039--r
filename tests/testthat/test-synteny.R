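# Synteny chaining, syntelog extraction and the locus network.

mk_anchors <- function(ra, rb, sim = 10) {
  data.frame(gene_a = paste0("A_g", seq_along(ra)),
             gene_b = paste0("B_g", seq_along(ra)),
             rank_a = ra, rank_b = rb, similarity = sim,
             stringsAsFactors = FALSE)
}

test_that("perfectly collinear anchors chain into one block", {
  b <- chain_anchors(mk_anchors(10:14, 5:9))
  expect_length(b, 1L)
  expect_equal(b[[1]]$orientation, "same")
  expect_equal(b[[1]]$n_anchors, 5L)
  expect_equal(b[[1]]$score, 50)  # five anchors, no gaps
  # within-block monotonicity invariant
  expect_true(all(diff(b[[1]]$anchors$rank_a) > 0))
  expect_true(all(diff(b[[1]]$anchors$rank_b) > 0))
})

test_that("strictly decreasing second ranks give an inverted block", {
  b <- chain_anchors(mk_anchors(1:5, 9:5))
  expect_length(b, 1L)
  expect_equal(b[[1]]$orientation, "inverted")
  expect_true(all(diff(b[[1]]$anchors$rank_b) < 0))
})

test_that("gaps are penalised and bounded", {
  # a 1-rank hole costs gap_penalty per skipped rank on each genome
  b <- chain_anchors(mk_anchors(c(1, 2, 3, 4, 6), c(1, 2, 3, 4, 6)))
  expect_equal(b[[1]]$score, 50 - 2)
  # a hole beyond max_gap_ranks splits the run (and both halves die
  # under min_anchors)
  far <- mk_anchors(c(1:5, 40:44), c(1:5, 40:44))
  b2 <- chain_anchors(far, max_gap_ranks = 5, min_anchors = 5)
  expect_length(b2, 2L)
  expect_true(all(vapply(b2, function(x) x$n_anchors, 0L) == 5L))
})

test_that("DP chaining equals the exhaustive oracle on random instances", {
  set.seed(303)
  for (i in 1:120) {
    n <- sample(4:9, 1)
    anch <- mk_anchors(sample(1:15, n), sample(1:15, n),
                       sim = round(stats::runif(n, 1, 10), 2))
    params <- list(max_gap = sample(c(3L, 25L), 1), min_anchors = sample(2:3, 1),
                   gap_penalty = sample(c(0.5, 1), 1))
    ora <- oracle_best_chain(anch, params$max_gap, params$min_anchors,
                             params$gap_penalty)
    got <- chain_anchors(anch, max_gap_ranks = params$max_gap,
                         min_anchors = params$min_anchors,
                         gap_penalty = params$gap_penalty)
    if (is.null(ora)) {
      expect_length(got, 0L)
    } else {
      expect_gt(length(got), 0L)
      expect_equal(got[[1]]$score, ora, tolerance = 1e-9)
    }
  }
})

test_that("block score is invariant under swapping the genome labels", {
  anch <- mk_anchors(c(2, 4, 6, 8, 10), c(1, 2, 3, 5, 6))
  b_ab <- chain_anchors(anch)
  swapped <- data.frame(gene_a = anch$gene_b, gene_b = anch$gene_a,
                        rank_a = anch$rank_b, rank_b = anch$rank_a,
                        similarity = anch$similarity)
  b_ba <- chain_anchors(swapped)
  expect_equal(b_ab[[1]]$score, b_ba[[1]]$score)
  expect_equal(b_ab[[1]]$orientation, b_ba[[1]]$orientation)
})

test_that("anchors spanning several chromosome pairs must be partitioned", {
  anch <- mk_anchors(1:5, 1:5)
  anch$chrom_a <- c("c1", "c1", "c2", "c2", "c2")
  anch$chrom_b <- "c9"
  expect_error(chain_anchors(anch), "partition")
})

test_that("syntelog extraction unions blocks containing the focal gene", {
  mk_block <- function(id, ga, gb) {
    structure(list(id = id, chrom_a = "c1", chrom_b = "c2",
                   orientation = "same", score = 10,
                   n_anchors = length(ga),
                   anchors = data.frame(gene_a = ga, gene_b = gb,
                                        rank_a = seq_along(ga),
                                        rank_b = seq_along(ga),
                                        similarity = 5)),
              class = "synteny_block")
  }
  b1 <- mk_block("B1", paste0("A_g", 1:7), paste0("B_g", 1:7))
  b2 <- mk_block("B2", paste0("A_g", 5:9), paste0("B_g", 5:9))
  b3 <- mk_block("B3", paste0("A_x", 1:5), paste0("B_x", 1:5))
  # focal gene in one 7-anchor block: all 7 pairs, including the focal one
  out1 <- extract_flanking_syntelogs(list(b1, b3), "A_g3")
  expect_equal(nrow(out1), 7L)
  expect_true("A_g3" %in% out1$gene_a)
  # two overlapping blocks: union without duplicates
  out2 <- extract_flanking_syntelogs(list(b1, b2, b3), "A_g5")
  expect_equal(nrow(out2), 9L)
  # absent focal gene: empty result, not an error
  expect_equal(nrow(extract_flanking_syntelogs(list(b1), "A_nope")), 0L)
})

test_that("locus network weights are log-transformed block scores", {
  mk_block <- function(ga, gb, score) {
    structure(list(id = paste0("B", score), chrom_a = "c1", chrom_b = "c2",
                   orientation = "same", score = score, n_anchors = length(ga),
                   anchors = data.frame(gene_a = ga, gene_b = gb,
                                        rank_a = seq_along(ga),
                                        rank_b = seq_along(ga),
                                        similarity = 5)),
              class = "synteny_block")
  }
  focal <- c("A_v1", "B_v1", "C_v1")
  tri <- list(mk_block(c("A_v1", "A_x"), c("B_v1", "B_x"), 10),
              mk_block(c("A_v1", "A_x"), c("C_v1", "C_x"), 10),
              mk_block(c("B_v1", "B_x"), c("C_v1", "C_x"), 10))
  net <- build_locus_network(tri, focal)
  expect_equal(igraph::ecount(net), 3L)
  expect_true(all(abs(igraph::E(net)$weight - log1p(10)) < 1e-12))
  expect_equal(locus_degree(net, "A_v1"), 2L)
  # parallel blocks keep the max-weight edge
  par2 <- list(mk_block(c("A_v1", "A_x"), c("B_v1", "B_x"), 10),
               mk_block(c("A_v1", "A_y"), c("B_v1", "B_y"), 20))
  net2 <- build_locus_network(par2, c("A_v1", "B_v1"))
  expect_equal(igraph::ecount(net2), 1L)
  expect_equal(igraph::E(net2)$weight, log(21))
  # no blocks: nodes only; unknown locus is a lookup error
  net0 <- build_locus_network(list(), focal)
  expect_equal(igraph::ecount(net0), 0L)
  expect_equal(locus_degree(net0, "A_v1"), 0L)
  expect_error(locus_degree(net0, "Z_q"), "lookup error")
})

test_that("chain_all_anchors partitions by chromosome pair via loci", {
  loci <- data.frame(
    gene_id = c(paste0("A_g", 1:6), paste0("B_g", 1:6)),
    chromosome = rep(c("a1", "b1"), each = 6),
    rank = c(0:5, 0:5))
  anch <- data.frame(gene_a = paste0("A_g", 1:6),
                     gene_b = paste0("B_g", 1:6), similarity = 10)
  blocks <- chain_all_anchors(anch, loci, min_anchors = 3)
  expect_length(blocks, 1L)
  expect_equal(blocks[[1]]$n_anchors, 6L)
  expect_error(chain_all_anchors(
    data.frame(gene_a = "A_g1", gene_b = "Z_g1", similarity = 1), loci),
    "lookup error")
})
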
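# Collinearity: chain homolog anchor pairs into synteny blocks by dynamic
# programming, extract syntelog pairs flanking focal loci, and build the
# cross-genome locus network.

# Best-scoring chain among anchors sorted by rank_a, with strictly
# increasing rank_b (orientation "same"; "inverted" is handled by negating
# rank_b), per-step rank gaps bounded by max_gap_ranks, score
# sum(similarity) - gap_penalty * (rank gaps), and at least min_anchors
# anchors.  DP state carries the chain length capped at min_anchors so the
# length constraint is exact.
.best_chain <- function(ra, rb, sim, max_gap, min_anchors, gap_penalty) {
  n <- length(ra)
  ord <- order(ra, rb)
  ra <- ra[ord]; rb <- rb[ord]; sim <- sim[ord]
  cap <- max(1L, min_anchors)
  score <- matrix(-Inf, n, cap)      # score[j, c]: best chain ending at j, capped length c
  back <- matrix(0L, n, cap)
  score[, 1L] <- sim
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      ga <- ra[j] - ra[i] - 1L
      gb <- rb[j] - rb[i] - 1L
      if (ra[i] >= ra[j] || rb[i] >= rb[j]) next
      if (ga > max_gap || gb > max_gap) next
      pen <- gap_penalty * (ga + gb)
      for (ci in seq_len(cap)) {
        if (!is.finite(score[i, ci])) next
        cj <- min(ci + 1L, cap)
        cand <- score[i, ci] + sim[j] - pen
        if (cand > score[j, cj]) {
          score[j, cj] <- cand
          back[j, cj] <- i + n * (ci - 1L)  # encode (i, ci)
        }
      }
    }
  }
  if (all(!is.finite(score[, cap]))) return(NULL)
  j <- which.max(score[, cap])
  best <- score[j, cap]
  chain <- integer(0)
  ci <- cap
  while (j > 0L) {
    chain <- c(j, chain)
    code <- back[j, ci]
    if (code == 0L) break
    ci <- (code - 1L) %/% n + 1L
    j <- (code - 1L) %% n + 1L
  }
  list(idx = ord[chain], score = best)
}

#' Chain anchor pairs into collinear synteny blocks
#'
#' Iterated dynamic-programming chaining in the MCScan family's style: the
#' maximal-scoring chain (per orientation) is extracted, its anchors
#' removed, and chaining repeated until no chain with at least
#' \code{min_anchors} anchors remains.  Within a block the gene ranks are
#' strictly increasing in genome A and strictly increasing (orientation
#' \code{"same"}) or strictly decreasing (\code{"inverted"}) in genome B.
#' Chain score is \code{sum(similarity) - gap_penalty * (rank gaps)}; gaps
#' are measured in gene-rank units, which is robust to intergenic-length
#' variation.
#'
#' @param anchors data frame with columns \code{gene_a}, \code{gene_b},
#'   \code{rank_a}, \code{rank_b}, \code{similarity} (all anchors must share
#'   one chromosome pair; optional \code{chrom_a}/\code{chrom_b} columns are
#'   checked).  E-value significance filtering is assumed done upstream.
#' @param max_gap_ranks largest allowed rank gap between consecutive anchors
#'   (default 25).
#' @param min_anchors minimum anchors per block (default 5).
#' @param gap_penalty score penalty per skipped rank (default 1).
#' @param chrom_a,chrom_b chromosome labels recorded on the blocks.
#' @return list of \code{synteny_block} objects: \code{id}, \code{chrom_a},
#'   \code{chrom_b}, \code{orientation}, \code{score}, \code{n_anchors} and
#'   the \code{anchors} data frame in chain order.
#' @export
chain_anchors <- function(anchors, max_gap_ranks = 25L, min_anchors = 5L,
                          gap_penalty = 1.0, chrom_a = NA, chrom_b = NA) {
  need <- c("gene_a", "gene_b", "rank_a", "rank_b", "similarity")
  if (!all(need %in% names(anchors)))
    stop("usage error: anchors need columns ", paste(need, collapse = ", "))
  if (!is.null(anchors$chrom_a) &&
      (length(unique(anchors$chrom_a)) > 1L ||
       length(unique(anchors$chrom_b)) > 1L))
    stop("usage error: anchors span multiple chromosome pairs; partition first")
  if (!is.null(anchors$chrom_a) && nrow(anchors)) {
    chrom_a <- anchors$chrom_a[1L]; chrom_b <- anchors$chrom_b[1L]
  }
  anchors <- anchors[!duplicated(anchors[, c("rank_a", "rank_b")]), , drop = FALSE]
  blocks <- list()
  remaining <- anchors
  while (nrow(remaining) >= min_anchors) {
    same <- .best_chain(remaining$rank_a, remaining$rank_b,
                        remaining$similarity, max_gap_ranks, min_anchors,
                        gap_penalty)
    inv <- .best_chain(remaining$rank_a, -remaining$rank_b,
                       remaining$similarity, max_gap_ranks, min_anchors,
                       gap_penalty)
    if (is.null(same) && is.null(inv)) break
    pick_inv <- is.null(same) || (!is.null(inv) && inv$score > same$score)
    ch <- if (pick_inv) inv else same
    blk <- list(id = paste0("B", length(blocks) + 1L),
                chrom_a = chrom_a, chrom_b = chrom_b,
                orientation = if (pick_inv) "inverted" else "same",
                score = ch$score,
                n_anchors = length(ch$idx),
                anchors = remaining[ch$idx, , drop = FALSE])
    class(blk) <- "synteny_block"
    blocks[[length(blocks) + 1L]] <- blk
    remaining <- remaining[-ch$idx, , drop = FALSE]
  }
  blocks
}

#' Chain anchors across all chromosome pairs
#'
#' Joins anchor pairs to gene loci, partitions them by chromosome pair and
#' runs [chain_anchors()] on each partition.
#'
#' @param anchors data frame with \code{gene_a}, \code{gene_b},
#'   \code{similarity}.
#' @param loci a \code{gene_models} data frame (or any frame with
#'   \code{gene_id}, \code{chromosome}, \code{rank}).
#' @param ... chaining parameters passed to [chain_anchors()].
#' @return flat list of \code{synteny_block}s with unique ids.
#' @export
chain_all_anchors <- function(anchors, loci, ...) {
  pos <- stats::setNames(seq_len(nrow(loci)), loci$gene_id)
  miss <- setdiff(unique(c(anchors$gene_a, anchors$gene_b)), names(pos))
  if (length(miss))
    stop("lookup error: anchors reference unknown loci: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  ca <- loci$chromosome[pos[anchors$gene_a]]
  cb <- loci$chromosome[pos[anchors$gene_b]]
  # orient each anchor so side A carries the lexicographically smaller chromosome
  flip <- ca > cb
  ga <- ifelse(flip, anchors$gene_b, anchors$gene_a)
  gb <- ifelse(flip, anchors$gene_a, anchors$gene_b)
  tab <- data.frame(gene_a = ga, gene_b = gb,
                    chrom_a = pmin(ca, cb), chrom_b = pmax(ca, cb),
                    rank_a = loci$rank[pos[ga]], rank_b = loci$rank[pos[gb]],
                    similarity = anchors$similarity,
                    stringsAsFactors = FALSE)
  blocks <- list()
  for (part in split(tab, paste(tab$chrom_a, tab$chrom_b, sep = "\r"))) {
    bl <- chain_anchors(part, ...)
    for (b in bl) {
      b$id <- paste0("B", length(blocks) + 1L)
      blocks[[length(blocks) + 1L]] <- b
    }
  }
  blocks
}

#' Syntelog pairs flanking a focal gene
#'
#' Returns the anchor pairs of every block in which the focal gene is one of
#' the anchored genes — the "syntelogs": adjacent duplicated genes residing
#' in sister blocks around the focal locus.  Pairs appearing in several
#' overlapping blocks are deduplicated; the focal pair itself is included.
#'
#' @param blocks list of \code{synteny_block}s.
#' @param focal_gene gene identifier (or vector of identifiers).
#' @return data frame with \code{gene_a}, \code{gene_b}, \code{similarity},
#'   \code{block_id}; zero rows when the focal gene anchors no block.
#' @export
extract_flanking_syntelogs <- function(blocks, focal_gene) {
  out <- list()
  for (b in blocks) {
    hit <- any(b$anchors$gene_a %in% focal_gene |
               b$anchors$gene_b %in% focal_gene)
    if (!hit) next
    df <- b$anchors[, c("gene_a", "gene_b", "similarity")]
    df$block_id <- b$id
    out[[length(out) + 1L]] <- df
  }
  if (!length(out))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      similarity = numeric(0), block_id = character(0)))
  out <- do.call(rbind, out)
  key <- paste(pmin(out$gene_a, out$gene_b), pmax(out$gene_a, out$gene_b))
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the cross-genome locus network
#'
#' Focal loci are connected when they reside in the two segments of some
#' synteny block; the edge weight is the log-transformed block score,
#' \code{log(1 + score)}.  Parallel blocks linking the same pair keep the
#' maximum-weight edge; self-loops are never created.
#'
#' @param blocks list of \code{synteny_block}s.
#' @param focal_loci character vector of focal gene identifiers.
#' @param loci optional \code{gene_models} frame; when given, residence of a
#'   focal locus in a block segment is judged by chromosome and rank span,
#'   otherwise by anchor membership.
#' @return an undirected weighted \code{igraph} with all focal loci as nodes.
#' @export
build_locus_network <- function(blocks, focal_loci, loci = NULL) {
  edges <- list()
  side_members <- function(b, side) {
    genes <- b$anchors[[paste0("gene_", side)]]
    if (is.null(loci)) return(intersect(focal_loci, genes))
    rk <- b$anchors[[paste0("rank_", side)]]
    ch <- b[[paste0("chrom_", side)]]
    sel <- loci$gene_id %in% focal_loci & loci$chromosome == ch &
      loci$rank >= min(rk) & loci$rank <= max(rk)
    loci$gene_id[sel]
  }
  for (b in blocks) {
    u <- side_members(b, "a")
    v <- side_members(b, "b")
    if (!length(u) || !length(v)) next
    grid <- expand.grid(u = u, v = v, stringsAsFactors = FALSE)
    grid <- grid[grid$u != grid$v, , drop = FALSE]
    if (!nrow(grid)) next
    grid$w <- log1p(b$score)
    edges[[length(edges) + 1L]] <- grid
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE) +
    igraph::vertices(focal_loci)
  if (length(edges)) {
    e <- do.call(rbind, edges)
    key <- paste(pmin(e$u, e$v), pmax(e$u, e$v))
    e <- e[order(key, -e$w), ]
    e <- e[!duplicated(paste(pmin(e$u, e$v), pmax(e$u, e$v))), , drop = FALSE]
    g <- igraph::add_edges(g, rbind(e$u, e$v), weight = e$w)
  }
  g
}

#' Degree of a focal locus in the network
#' @param network an \code{igraph} locus network.
#' @param locus gene identifier present in the network.
#' @return integer count of incident edges.
#' @export
locus_degree <- function(network, locus) {
  if (!locus %in% igraph::V(network)$name)
    stop("lookup error: locus not in network: ", locus)
  unname(igraph::degree(network, locus))
}
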
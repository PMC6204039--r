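# Ground-truthed gene-family simulator: species trees with planted WGDs,
# fractionated duplicate gene orders, and codon sequences whose pairwise
# synonymous divergence equals known path lengths.
#
# Sequences evolve per position, not under a full codon model: ancestral
# codons are drawn from a restricted set whose third positions are 4-fold
# degenerate and whose first/second positions admit only nonsynonymous
# in-set changes.  Third positions then substitute as a Jukes-Cantor
# process at the branch's synonymous rate and first/second positions at
# omega times that rate, so a pair at true synonymous path distance d has
# third-position difference probability exactly (3/4)(1 - exp(-4d/3)) and
# the NG86 + JC estimate is an unbiased (up to binomial noise) recovery
# of d.  Stop codons are never created.

# codon prefixes (positions 1-2) used by the simulator; every in-set
# prefix keeps the third position 4-fold degenerate, every single-nt
# in-set prefix change is nonsynonymous, and no extra synonymous
# first/second-position neighbours exist for any in-set codon
.sim_prefixes <- c("GC", "GG", "CC", "TC", "AC", "GT")  # A G P S T V
.sim_prefix_nbr <- list(c(3L, 5L, 4L, 2L, 6L),  # GC: CC AC TC GG GT
                        c(1L, 6L),              # GG: GC GT
                        c(5L, 1L, 4L),          # CC: AC GC TC
                        c(5L, 3L, 1L),          # TC: AC CC GC
                        c(3L, 1L, 4L),          # AC: CC GC TC
                        c(1L, 2L))              # GT: GC GG

#' Simulation configuration
#'
#' The defaults are the package's reference study conditions: two species
#' plus an outgroup, with two WGDs planted on the ancestral branch so that
#' surviving duplicate pairs sit at true pairwise synonymous distances 1.0
#' (ancient event) and 0.3 (recent event), each duplicate independently
#' retained with probability 0.8, over 200 gene families of 300 codons.
#'
#' @param species_tree Newick string or \code{phylo}; branch lengths are
#'   expected synonymous substitutions per synonymous site.
#' @param wgd_events data frame with columns \code{branch} (tip or internal
#'   node label naming the edge above that node), \code{pos} (position along
#'   the edge in \[0,1\], parent to child), \code{retention} (per-duplicate
#'   retention probability) and \code{label}.
#' @param n_genes ancestral gene count (families).
#' @param codons_per_gene codons per gene (>= 30 recommended; below that the
#'   NG86 variance makes recovery tests meaningless and a warning is given).
#' @param omega nonsynonymous/synonymous rate ratio.
#' @param seed integer seed.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(species_tree = "((SpA:0.05,SpB:0.05)AB:0.55,Out:0.6)R;",
                       wgd_events = data.frame(
                         branch = c("AB", "AB"),
                         pos = c(2 / 11, 9 / 11),
                         retention = c(0.8, 0.8),
                         label = c("wgd_ancient", "wgd_recent")),
                       n_genes = 200L, codons_per_gene = 300L,
                       omega = 0.2, seed = 1L) {
  tr <- if (inherits(species_tree, "phylo")) species_tree else
    ape::read.tree(text = species_tree)
  if (is.null(tr)) stop("config error: unparsable species tree")
  if (!is.null(wgd_events) && nrow(wgd_events)) {
    stopifnot(all(wgd_events$pos >= 0 & wgd_events$pos <= 1),
              all(wgd_events$retention >= 0 & wgd_events$retention <= 1))
    known <- c(tr$tip.label, tr$node.label)
    bad <- setdiff(wgd_events$branch, known)
    if (length(bad))
      stop("config error: WGD on unknown branch: ", paste(bad, collapse = ", "))
  }
  stopifnot(n_genes >= 1L, omega >= 0)
  if (codons_per_gene < 30L)
    warning("codons_per_gene < 30: NG86 variance too large for recovery tests")
  out <- list(tree = tr, wgd_events = wgd_events, n_genes = as.integer(n_genes),
              codons_per_gene = as.integer(codons_per_gene), omega = omega,
              seed = as.integer(seed))
  class(out) <- "sim_config"
  out
}

# resolve a branch label to the ape node id it subtends
.branch_node <- function(tr, label) {
  i <- match(label, tr$tip.label)
  if (!is.na(i)) return(i)
  j <- match(label, tr$node.label)
  if (is.na(j)) stop("config error: unknown branch label ", label)
  ape::Ntip(tr) + j
}

#' Simulate a WGD history over the species tree
#'
#' Genes evolve down the species tree.  At each WGD the entire gene order is
#' duplicated onto a new chromosome and each duplicate is independently
#' retained with the event's retention probability (fractionation is i.i.d.
#' per duplicate; the pre-existing copy always survives).  At speciations
#' every lineage is inherited by both daughters.  The returned truth records
#' the full event log, per-species ordered gene lists, the true gene tree of
#' every family and every pairwise true synonymous distance.
#'
#' @param cfg a [sim_config()].
#' @return list of class \code{sim_truth} with \code{nodes},
#'   \code{genomes}, \code{event_log}, \code{true_pairs},
#'   \code{gene_trees} (Newick strings) and the \code{config}.
#' @export
simulate_history <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  tr <- cfg$tree
  ntip <- ape::Ntip(tr)
  depth <- ape::node.depth.edgelength(tr)
  root <- ntip + 1L
  ev <- cfg$wgd_events
  ev_by_child <- if (!is.null(ev) && nrow(ev)) {
    child <- vapply(ev$branch, .branch_node, 0L, tr = tr)
    split(cbind(ev, child = child), child)
  } else list()

  env <- new.env(parent = emptyenv())
  env$parent <- integer(0); env$depth <- numeric(0)
  env$kind <- character(0); env$label <- character(0); env$family <- integer(0)
  env$event_log <- list()
  env$genomes <- list()
  new_nodes <- function(parents, d, kind, label, family) {
    k <- length(parents)
    ids <- length(env$parent) + seq_len(k)
    env$parent <- c(env$parent, parents)
    env$depth <- c(env$depth, rep(d, k))
    env$kind <- c(env$kind, rep(kind, k))
    env$label <- c(env$label, rep_len(label, k))
    env$family <- c(env$family, family)
    ids
  }

  fam_roots <- new_nodes(rep(0L, cfg$n_genes), 0, "root", "root",
                         seq_len(cfg$n_genes))
  genome0 <- list(list(name = "chr1", holder = fam_roots,
                       family = seq_len(cfg$n_genes)))

  apply_wgd <- function(genome, e, d_event) {
    n_chr <- length(genome)
    for (ci in seq_len(n_chr)) {
      chr <- genome[[ci]]
      n <- length(chr$holder)
      retained <- stats::runif(n) < e$retention
      env$event_log[[length(env$event_log) + 1L]] <- data.frame(
        event = e$label, chrom = chr$name, family = chr$family,
        retained = retained, stringsAsFactors = FALSE)
      if (any(retained)) {
        splits <- new_nodes(chr$holder[retained], d_event, "wgd", e$label,
                            chr$family[retained])
        chr$holder[retained] <- splits
        genome[[ci]] <- chr
        genome[[length(genome) + 1L]] <-
          list(name = paste0(chr$name, ".", e$label),
               holder = splits, family = chr$family[retained])
      }
    }
    genome
  }

  walk <- function(node, genome) {
    if (node <= ntip) {                       # species tip: materialise genes
      sp <- tr$tip.label[node]
      counters <- integer(cfg$n_genes)
      glist <- list()
      for (chr in genome) {
        ids <- character(length(chr$holder))
        for (i in seq_along(chr$holder)) {
          f <- chr$family[i]
          counters[f] <- counters[f] + 1L
          ids[i] <- sprintf("%s_f%03dc%d", sp, f, counters[f])
        }
        new_nodes(chr$holder, depth[node], "tip", ids, chr$family)
        glist[[chr$name]] <- ids
      }
      env$genomes[[sp]] <- glist
      return(invisible(NULL))
    }
    kids <- tr$edge[tr$edge[, 1L] == node, 2L]
    for (child in kids) {
      g <- genome
      key <- as.character(child)
      if (!is.null(ev_by_child[[key]])) {
        evs <- ev_by_child[[key]]
        evs <- evs[order(evs$pos), , drop = FALSE]
        for (r in seq_len(nrow(evs))) {
          d_event <- depth[node] + evs$pos[r] * (depth[child] - depth[node])
          g <- apply_wgd(g, evs[r, ], d_event)
        }
      }
      if (child > ntip) {                     # speciation at `child`
        g <- lapply(g, function(chr) {
          chr$holder <- new_nodes(chr$holder, depth[child], "spec",
                                  if (is.null(tr$node.label)) "spec" else
                                    tr$node.label[child - ntip],
                                  chr$family)
          chr
        })
      }
      walk(child, g)
    }
  }
  walk(root, genome0)

  # tip labels live in env$label for kind == "tip"
  nodes <- data.frame(id = seq_along(env$parent), parent = env$parent,
                      depth = env$depth, kind = env$kind, label = env$label,
                      family = env$family, stringsAsFactors = FALSE)
  truth <- list(nodes = nodes,
                genomes = env$genomes,
                event_log = do.call(rbind, env$event_log),
                config = cfg)
  truth$true_pairs <- .true_pairs(nodes)
  truth$gene_trees <- .family_newicks(nodes)
  class(truth) <- "sim_truth"
  truth
}

# all pairwise true distances within families, typed by the MRCA split
.true_pairs <- function(nodes) {
  res <- list()
  for (f in unique(nodes$family[nodes$kind == "tip"])) {
    tips <- nodes[nodes$kind == "tip" & nodes$family == f, ]
    if (nrow(tips) < 2L) next
    paths <- lapply(tips$id, function(id) {
      anc <- id
      while (nodes$parent[anc[length(anc)]] != 0L)
        anc <- c(anc, nodes$parent[anc[length(anc)]])
      anc
    })
    for (i in seq_len(nrow(tips) - 1L)) {
      for (j in (i + 1L):nrow(tips)) {
        common <- intersect(paths[[i]], paths[[j]])
        mrca <- common[which.max(nodes$depth[common])]
        d <- nodes$depth[tips$id[i]] + nodes$depth[tips$id[j]] -
          2 * nodes$depth[mrca]
        res[[length(res) + 1L]] <- data.frame(
          gene_a = tips$label[i], gene_b = tips$label[j], family = f,
          distance = d,
          type = if (nodes$kind[mrca] == "wgd") "paralog" else "ortholog",
          event = if (nodes$kind[mrca] == "wgd") nodes$label[mrca] else NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Newick per family from the node table, unary chains contracted,
# internal supports written as 100 (the truth is exact)
.family_newicks <- function(nodes) {
  fams <- sort(unique(nodes$family))
  vapply(fams, function(f) {
    nf <- nodes[nodes$family == f, ]
    child_map <- split(nf$id, nf$parent)
    rec <- function(id, from_depth) {
      row <- nodes[id, ]
      if (row$kind == "tip")
        return(sprintf("%s:%.6f", row$label, row$depth - from_depth))
      ch <- child_map[[as.character(id)]]
      if (length(ch) == 1L) return(rec(ch, from_depth))  # contract unary
      inner <- paste(vapply(ch, rec, "", from_depth = row$depth),
                     collapse = ",")
      sprintf("(%s)100:%.6f", inner, row$depth - from_depth)
    }
    # descend to the first branching node (the gene-tree root; stem dropped)
    top <- nf$id[nf$parent == 0L]
    repeat {
      if (nodes$kind[top] == "tip") break
      ch <- child_map[[as.character(top)]]
      if (length(ch) > 1L) break
      top <- ch
    }
    if (nodes$kind[top] == "tip")
      return(sprintf("(%s:0.0);", nodes$label[top]))
    ch <- child_map[[as.character(top)]]
    inner <- paste(vapply(ch, rec, "", from_depth = nodes$depth[top]),
                   collapse = ",")
    sprintf("(%s);", inner)
  }, "")
}

#' Simulate codon sequences along the true gene trees
#'
#' See the module notes: third positions evolve as Jukes-Cantor at the
#' branch synonymous rate; first/second positions change among a restricted
#' nonsynonymous prefix set at \code{omega} times that rate; stop codons are
#' never created and the expected NG86 Ks of a pair equals its true
#' synonymous path distance.
#'
#' @param truth a \code{sim_truth} from [simulate_history()].
#' @param cfg the same [sim_config()].
#' @return a \code{cds_set} of extant gene sequences.
#' @export
simulate_sequences <- function(truth, cfg) {
  stopifnot(inherits(truth, "sim_truth"), inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed + 1L)
  L <- cfg$codons_per_gene
  omega <- cfg$omega
  nodes <- truth$nodes
  child_map <- split(nodes$id, nodes$parent)
  ids <- character(0); seqs <- character(0)
  evolve_pos3 <- function(p3, dd) {
    if (dd <= 0) return(p3)
    p_change <- 0.75 * (1 - exp(-4 * dd / 3))
    chg <- stats::runif(L) < p_change
    if (any(chg))
      p3[chg] <- (p3[chg] - 1L + sample.int(3L, sum(chg), replace = TRUE)) %% 4L + 1L
    p3
  }
  evolve_prefix <- function(pf, dd) {
    if (dd <= 0 || omega <= 0) return(pf)
    n_ev <- stats::rpois(L, 2 * omega * dd)
    for (i in which(n_ev > 0L)) {
      for (k in seq_len(n_ev[i])) {
        nbr <- .sim_prefix_nbr[[pf[i]]]
        pf[i] <- nbr[sample.int(length(nbr), 1L)]
      }
    }
    pf
  }
  walk <- function(id, pf, p3) {
    row <- nodes[id, ]
    if (row$kind == "tip") {
      ids <<- c(ids, row$label)
      seqs <<- c(seqs, paste0(paste0(.sim_prefixes[pf], .nt[p3]), collapse = ""))
      return(invisible(NULL))
    }
    for (ch in child_map[[as.character(id)]]) {
      dd <- nodes$depth[ch] - row$depth
      walk(ch, evolve_prefix(pf, dd), evolve_pos3(p3, dd))
    }
  }
  for (root_id in nodes$id[nodes$parent == 0L]) {
    pf <- sample.int(6L, L, replace = TRUE)
    p3 <- sample.int(4L, L, replace = TRUE)
    walk(root_id, pf, p3)
  }
  cds_set(ids, seqs)
}

#' Write a simulated dataset to disk
#'
#' Emits the five file kinds the pipeline consumes: CDS FASTA, BED6 gene
#' orders, an anchor TSV (true homolog pairs, similarity = 50 - true
#' distance floored at 1), the true gene trees as Newick (supports 100) and
#' a truth JSON, plus a manifest with MD5 checksums.  Identical seeds give
#' byte-identical files.
#'
#' @param truth a \code{sim_truth}.
#' @param seqs the matching \code{cds_set}.
#' @param outdir output directory (created if needed).
#' @return manifest data frame (\code{file}, \code{kind}, \code{md5}).
#' @export
emit_dataset <- function(truth, seqs, outdir) {
  if (!dir.exists(outdir))
    if (!dir.create(outdir, recursive = TRUE))
      stop("I/O error: cannot create ", outdir)
  L <- truth$config$codons_per_gene
  spacing <- 3L * L + 100L

  fa <- file.path(outdir, "cds.fasta")
  dna <- Biostrings::DNAStringSet(stats::setNames(seqs$sequence, seqs$gene_id))
  Biostrings::writeXStringSet(dna, fa)

  bed <- file.path(outdir, "genes.bed")
  rows <- list()
  for (sp in names(truth$genomes)) {
    for (chrom in names(truth$genomes[[sp]])) {
      genes <- truth$genomes[[sp]][[chrom]]
      if (!length(genes)) next
      i0 <- seq_along(genes) - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = paste0(sp, "_", chrom), start = i0 * spacing,
        end = i0 * spacing + 3L * L, name = genes, score = 0L, strand = "+",
        stringsAsFactors = FALSE)
    }
  }
  bed_df <- do.call(rbind, rows)
  utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  anch <- file.path(outdir, "anchors.tsv")
  adf <- data.frame(gene_a = truth$true_pairs$gene_a,
                    gene_b = truth$true_pairs$gene_b,
                    similarity = pmax(1, 50 - truth$true_pairs$distance))
  utils::write.table(adf, anch, sep = "\t", quote = FALSE, row.names = FALSE)

  nwk <- file.path(outdir, "trees.nwk")
  writeLines(truth$gene_trees, nwk)

  tj <- file.path(outdir, "truth.json")
  jsonlite::write_json(list(event_log = truth$event_log,
                            true_pairs = truth$true_pairs,
                            genomes = truth$genomes,
                            n_genes = truth$config$n_genes,
                            codons_per_gene = L,
                            omega = truth$config$omega,
                            seed = truth$config$seed),
                       tj, digits = NA, auto_unbox = TRUE, pretty = TRUE)

  files <- c(cds_fasta = fa, gene_bed = bed, anchors_tsv = anch,
             trees_newick = nwk, truth_json = tj)
  manifest <- data.frame(file = basename(files), kind = names(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest
}
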
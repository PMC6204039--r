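# Gene-tree work: NJ building for the synthetic path, codon-column
# bootstrap, outgroup rooting, support-based duplication detection
# (the BS-1/BS-2/BS-3 criterion), taxon-exclusion series and subfamily
# nomenclature.

#' Species code of a gene identifier
#'
#' Gene identifiers are species-prefixed; the species code is the part
#' before the first underscore.
#' @param gene_id character vector.
#' @export
species_of <- function(gene_id) sub("_.*$", "", gene_id)

#' Neighbour-joining tree from a distance matrix
#'
#' Standard neighbour joining ([ape::nj()]) with the taxa pre-sorted
#' lexicographically so the result is invariant to input order; negative
#' branch lengths are clamped to zero.
#'
#' @param d symmetric non-negative distance matrix with labelled rows.
#' @return unrooted \code{phylo}.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("validation error: distance matrix needs labels")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("validation error: distance matrix not symmetric")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# NG86-style distances between rows of an integer codon matrix
# (taxa x codon columns, entries 1..64).  type "total" uses the combined
# substitution proportion (Sd+Nd)/(S+N) with JC correction (a stable
# overall distance for topology work); "ks"/"ka" use the class-specific
# proportions.  Saturated or pathway-blocked comparisons are clamped to
# max_dist so NJ always receives finite input.
codon_dist_matrix <- function(M, type = c("total", "ks", "ka"), max_dist = 8) {
  type <- match.arg(type)
  n <- nrow(M)
  tab <- ng86_path_tables()
  sites <- ng86_site_table()
  d <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- M[i, ]; b <- M[j, ]
      sd <- tab$sd[cbind(a, b)]
      ok <- !is.na(sd)
      L <- sum(ok)
      if (L == 0L) { d[i, j] <- d[j, i] <- max_dist; next }
      Sd <- sum(sd[ok])
      Nd <- sum(tab$nd[cbind(a, b)][ok])
      S <- sum((sites[a[ok]] + sites[b[ok]]) / 2)
      p <- switch(type,
                  total = (Sd + Nd) / (3 * L),
                  ks = if (S > 0) Sd / S else NA_real_,
                  ka = if (3 * L - S > 0) Nd / (3 * L - S) else NA_real_)
      dd <- jc_correct(p)
      d[i, j] <- d[j, i] <- if (is.na(dd)) max_dist else min(dd, max_dist)
    }
  }
  d
}

#' NJ tree with codon-column bootstrap supports
#'
#' Builds a neighbour-joining tree from NG86 codon distances on a gapless
#' family alignment, then resamples codon columns with replacement
#' ([ape::boot.phylo()]), rebuilding the NJ tree per replicate; node labels
#' are the percentage of replicates containing each original bipartition.
#'
#' @param seqs named character vector of equal-length in-frame CDS (one
#'   alignment spanning all leaves; the resampling unit is the codon column).
#' @param replicates bootstrap replicates (default 100; the literature-scale
#'   1000 is a parameter away).
#' @param seed integer seed; identical seeds give identical supports.
#' @param dist_type distance flavour passed to the internal NG86 distance.
#' @return unrooted \code{phylo} with \code{node.label} percentages and
#'   attribute \code{support_units = "bootstrap"}.
#' @export
bootstrap_supports <- function(seqs, replicates = 100L, seed = 1L,
                               dist_type = "total") {
  if (length(seqs) < 4L) stop("supports undefined: fewer than 4 leaves")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("validation error: sequences must be aligned (equal length)")
  M <- t(vapply(seqs, function(s) codon_index(codon_split(s)),
                integer(lens[1L] / 3L)))
  rownames(M) <- names(seqs)
  build <- function(mat) nj_tree(codon_dist_matrix(mat, dist_type))
  tr <- build(M)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cnt <- ape::boot.phylo(tr, M, build, B = replicates, rooted = FALSE,
                         quiet = TRUE)
  sup <- round(100 * cnt / replicates, 1)
  sup[1L] <- NA  # root bipartition of an unrooted tree is trivial
  tr$node.label <- as.character(sup)
  attr(tr, "support_units") <- "bootstrap"
  tr
}

#' Root a gene tree on an outgroup leaf
#'
#' Places the root at the midpoint of the outgroup's pendant edge.  Support
#' labels are re-attached to the clades they subtend
#' (\code{edgelabel = TRUE} in [ape::root()]).
#'
#' @param t a \code{phylo}.
#' @param outgroup leaf label.
#' @return rooted \code{phylo}.
#' @export
root_by_outgroup <- function(t, outgroup) {
  if (!outgroup %in% t$tip.label)
    stop("lookup error: outgroup not in tree: ", outgroup)
  units <- attr(t, "support_units")
  ntip0 <- ape::Ntip(t)
  root0 <- ntip0 + 1L
  kids0 <- t$edge[t$edge[, 1L] == root0, 2L]
  if (ape::is.rooted(t) && length(kids0) == 2L &&
      match(outgroup, t$tip.label) %in% kids0) {
    rt <- t   # already rooted on the outgroup's pendant edge
  } else {
    rt <- ape::root(t, outgroup = outgroup, resolve.root = TRUE,
                    edgelabel = TRUE)
  }
  # split the outgroup's pendant edge at its midpoint
  root_node <- ape::Ntip(rt) + 1L
  kids <- rt$edge[rt$edge[, 1L] == root_node, 2L]
  og <- match(outgroup, rt$tip.label)
  if (og %in% kids && length(kids) == 2L && !is.null(rt$edge.length)) {
    e_og <- which(rt$edge[, 1L] == root_node & rt$edge[, 2L] == og)
    e_in <- which(rt$edge[, 1L] == root_node & rt$edge[, 2L] != og)
    tot <- sum(rt$edge.length[c(e_og, e_in)])
    rt$edge.length[e_og] <- tot / 2
    rt$edge.length[e_in] <- tot / 2
  }
  attr(rt, "support_units") <- units
  rt
}

.node_support <- function(t, node, ntip) {
  if (node <= ntip) return(100)  # a leaf is not an estimated clade
  lab <- t$node.label[node - ntip]
  val <- suppressWarnings(as.numeric(lab))
  val
}

.clade_tips <- function(t, node, ntip) {
  if (node <= ntip) return(t$tip.label[node])
  kids <- t$edge[t$edge[, 1L] == node, 2L]
  unlist(lapply(kids, .clade_tips, t = t, ntip = ntip))
}

#' Support-based duplication detection (BS-1/BS-2/BS-3)
#'
#' Every internal node of a rooted gene tree whose two child clades share at
#' least one species is a candidate duplication.  BS-1 is the support of the
#' node itself (the clade containing both children), BS-2 and BS-3 the
#' supports of the two child clades (leaf children count as 100 by
#' convention).  A call is \code{supported} when all three values meet the
#' threshold, \code{shared} when the child clades share two or more species
#' and \code{species_specific} when they share exactly one.  For posterior
#' units use \code{threshold = 0.95}.
#'
#' For a duplication at the root (whose own bipartition is trivial after
#' outgroup rooting), BS-1 falls back to the support of the
#' outgroup-adjacent bipartition and the call is flagged \code{at_root}.
#'
#' @param t rooted \code{phylo} with numeric \code{node.label} supports.
#' @param species map from gene id to species: a function or a named
#'   character vector; defaults to [species_of()].
#' @param threshold minimum support for all of BS-1/2/3 (default 90).
#' @return data frame of class \code{duplication_calls}: \code{node},
#'   \code{bs1}, \code{bs2}, \code{bs3}, \code{species_left},
#'   \code{species_right}, \code{n_shared}, \code{classification},
#'   \code{supported}, \code{at_root}.
#' @export
detect_duplications <- function(t, species = species_of, threshold = 90) {
  if (!ape::is.rooted(t)) stop("tree must be rooted")
  ntip <- ape::Ntip(t)
  spmap <- if (is.function(species)) {
    species(t$tip.label)
  } else {
    miss <- setdiff(t$tip.label, names(species))
    if (length(miss))
      stop("mapping error: no species for leaves: ",
           paste(utils::head(miss, 5L), collapse = ", "))
    unname(species[t$tip.label])
  }
  sp_of_tip <- stats::setNames(spmap, t$tip.label)
  root_node <- ntip + 1L
  rows <- list()
  for (node in (ntip + 1L):(ntip + t$Nnode)) {
    kids <- t$edge[t$edge[, 1L] == node, 2L]
    if (length(kids) < 2L) next
    combs <- utils::combn(kids, 2L)
    for (k in seq_len(ncol(combs))) {
      k1 <- combs[1L, k]; k2 <- combs[2L, k]
      sp1 <- unique(sp_of_tip[.clade_tips(t, k1, ntip)])
      sp2 <- unique(sp_of_tip[.clade_tips(t, k2, ntip)])
      shared <- intersect(sp1, sp2)
      if (length(shared) == 0L) next
      at_root <- node == root_node
      bs1 <- if (at_root) {
        # the root's own bipartition is trivial; use the outgroup-adjacent
        # bipartition, i.e. the support of the internal child clade(s)
        sib <- t$edge[t$edge[, 1L] == root_node, 2L]
        sib <- sib[sib > ntip]
        if (length(sib)) {
          cand <- vapply(sib, .node_support, 0, t = t, ntip = ntip)
          if (all(is.na(cand))) NA_real_ else min(cand, na.rm = TRUE)
        } else NA_real_
      } else .node_support(t, node, ntip)
      if (!at_root && is.na(bs1) && t$edge[match(node, t$edge[, 2L]), 1L] == root_node) {
        sibs <- setdiff(t$edge[t$edge[, 1L] == root_node, 2L], node)
        if (all(sibs <= ntip)) {
          # child of the root with only leaf siblings: its bipartition is the
          # outgroup's pendant split, trivially present in every replicate
          bs1 <- 100
          at_root <- TRUE
        }
      }
      bs2 <- .node_support(t, k1, ntip)
      bs3 <- .node_support(t, k2, ntip)
      supported <- !anyNA(c(bs1, bs2, bs3)) && min(bs1, bs2, bs3) >= threshold
      rows[[length(rows) + 1L]] <- data.frame(
        node = node, bs1 = bs1, bs2 = bs2, bs3 = bs3,
        species_left = paste(sort(sp1), collapse = ","),
        species_right = paste(sort(sp2), collapse = ","),
        n_shared = length(shared),
        classification = if (length(shared) >= 2L) "shared" else "species_specific",
        supported = supported, at_root = at_root,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node = integer(0), bs1 = numeric(0), bs2 = numeric(0),
               bs3 = numeric(0), species_left = character(0),
               species_right = character(0), n_shared = integer(0),
               classification = character(0), supported = logical(0),
               at_root = logical(0))
  class(out) <- c("duplication_calls", "data.frame")
  out
}

#' Taxon-exclusion series for duplication support
#'
#' Re-runs tree building, rooting and duplication detection after pruning
#' each exclusion set of species, mirroring the practice of dropping
#' early-diverging lineages whose single genes attach inside one subgenome
#' clade and depress child-clade supports.
#'
#' @param seqs named equal-length CDS vector (the synthetic path), or
#'   \code{NULL} when \code{trees} supplies prebuilt trees.
#' @param exclusion_sets named list of character vectors of species codes to
#'   drop (an empty vector reproduces the baseline).
#' @param outgroup outgroup gene id (must survive every exclusion).
#' @param threshold support threshold for [detect_duplications()].
#' @param replicates,seed bootstrap parameters for the synthetic path.
#' @param trees optional named list of prebuilt unrooted \code{phylo}
#'   (same names as \code{exclusion_sets}) read from external inference.
#' @return list with per-analysis \code{calls} and a \code{comparison}
#'   data frame (analysis, n_calls, n_supported_shared).
#' @export
run_exclusion_series <- function(seqs, exclusion_sets, outgroup,
                                 threshold = 90, replicates = 100L, seed = 1L,
                                 trees = NULL) {
  if (!length(names(exclusion_sets)))
    names(exclusion_sets) <- paste0("analysis_", seq_along(exclusion_sets))
  all_species <- if (!is.null(seqs)) unique(species_of(names(seqs))) else NULL
  calls <- list()
  for (an in names(exclusion_sets)) {
    excl <- exclusion_sets[[an]]
    if (species_of(outgroup) %in% excl)
      stop("usage error: exclusion set '", an, "' removes the outgroup")
    if (!is.null(trees)) {
      tr <- trees[[an]]
      if (is.null(tr)) stop("no tree supplied for analysis ", an)
    } else {
      absent <- setdiff(excl, all_species)
      if (length(absent))
        warning("exclusion set '", an, "' names absent taxa: ",
                paste(absent, collapse = ", "))
      keep <- seqs[!species_of(names(seqs)) %in% excl]
      if (length(keep) < 4L)
        stop("usage error: exclusion leaves fewer than 4 taxa in ", an)
      tr <- bootstrap_supports(keep, replicates = replicates, seed = seed)
    }
    rooted <- root_by_outgroup(tr, outgroup)
    calls[[an]] <- detect_duplications(rooted, threshold = threshold)
  }
  comparison <- data.frame(
    analysis = names(calls),
    n_calls = vapply(calls, nrow, 0L),
    n_supported_shared = vapply(calls, function(d)
      sum(d$supported & d$classification == "shared"), 0L),
    row.names = NULL)
  list(calls = calls, comparison = comparison)
}

#' Subfamily nomenclature from anchor genes
#'
#' Each gene is assigned the subfamily of the smallest clade containing it
#' and at least one anchor gene (e.g. the experimentally named members of
#' the family in the reference species); genes whose smallest such clade
#' mixes anchors of different subfamilies stay unclassified.  Within a
#' species and subfamily, letter suffixes follow the tree's tip order:
#' subfamily 1 takes A, C, E, ...; subfamily 2 takes B, D, F, ....  A
#' species with exactly one family member keeps the bare family name
#' (no digit, no suffix).
#'
#' @param t rooted \code{phylo}.
#' @param anchors named integer/character vector: anchor gene id ->
#'   subfamily digit, e.g. \code{c(At_VOZ1 = 1, Os_VOZ1 = 1, At_VOZ2 = 2)}.
#' @param family_prefix family name used in the output (default "VOZ").
#' @return data frame: \code{gene_id}, \code{species}, \code{subfamily},
#'   \code{name}, \code{classified}.
#' @export
assign_subfamily_names <- function(t, anchors, family_prefix = "VOZ") {
  ntip <- ape::Ntip(t)
  anchor_ids <- names(anchors)
  if (!any(anchor_ids %in% t$tip.label))
    stop("lookup error: no anchor gene present in tree")
  parent <- integer(ntip + t$Nnode)
  parent[t$edge[, 2L]] <- t$edge[, 1L]
  clade_cache <- new.env(parent = emptyenv())
  tips_below <- function(node) {
    key <- as.character(node)
    if (!is.null(clade_cache[[key]])) return(clade_cache[[key]])
    val <- .clade_tips(t, node, ntip)
    clade_cache[[key]] <- val
    val
  }
  subfam <- rep(NA_integer_, ntip)
  for (i in seq_len(ntip)) {
    gid <- t$tip.label[i]
    if (gid %in% anchor_ids) { subfam[i] <- as.integer(anchors[[gid]]); next }
    node <- parent[i]
    while (node != 0L) {
      hit <- intersect(tips_below(node), anchor_ids)
      if (length(hit)) {
        fams <- unique(as.integer(anchors[hit]))
        if (length(fams) == 1L) subfam[i] <- fams
        break
      }
      node <- if (node == ntip + 1L) 0L else parent[node]
    }
  }
  # tip order of the rooted tree (cladewise traversal = plotted order)
  ord_edges <- ape::reorder.phylo(t, "cladewise")$edge[, 2L]
  tip_order <- ord_edges[ord_edges <= ntip]
  sp <- species_of(t$tip.label)
  n_members <- table(sp)
  name <- rep(NA_character_, ntip)
  counters <- list()
  for (i in tip_order) {
    if (n_members[[sp[i]]] == 1L) {   # single-copy species: bare family name
      name[i] <- paste0(sp[i], "_", family_prefix)
      next
    }
    if (is.na(subfam[i])) next
    key <- paste(sp[i], subfam[i])
    k <- if (is.null(counters[[key]])) 1L else counters[[key]] + 1L
    counters[[key]] <- k
    letter <- LETTERS[if (subfam[i] == 1L) 2L * k - 1L else 2L * k]
    name[i] <- paste0(sp[i], "_", family_prefix, subfam[i], letter)
  }
  data.frame(gene_id = t$tip.label, species = sp, subfamily = subfam,
             name = name, classified = !is.na(name),
             stringsAsFactors = FALSE)
}
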
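# Readers/writers for the external representations the pipeline touches:
# CDS FASTA, gene models (GFF3 / BED), Newick trees with support labels,
# and TSV/SIF edge lists.  Internal coordinates are 0-based half-open;
# conversion happens only at the I/O boundary.

#' Read in-frame coding sequences from a FASTA file
#'
#' Sequences are validated as in-frame CDS over \{A,C,G,T\}: the length must
#' be divisible by 3 and no internal stop codon is allowed under the standard
#' genetic code.  A terminal stop codon is stripped rather than rejected.
#' Gene identifiers are the first whitespace-delimited token of each header
#' and must be species-prefixed (\code{"Vitvi_VOZ1A"}); the species code is
#' the part before the first underscore.
#'
#' @param path path to a FASTA file with at least one record.
#' @param isoform_policy \code{"longest"} keeps, for records sharing a gene
#'   stem (the identifier up to the last \code{"."}-separated suffix, the
#'   Phytozome isoform convention), only the longest sequence;
#'   \code{"all"} keeps every record.
#' @return a \code{cds_set}: data frame with columns \code{gene_id},
#'   \code{species}, \code{sequence}.
#' @export
read_cds_fasta <- function(path, isoform_policy = c("longest", "all")) {
  isoform_policy <- match.arg(isoform_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- Biostrings::readDNAStringSet(path)
  if (length(dna) == 0L) stop("format error: no FASTA records in ", path)
  ids <- vapply(strsplit(names(dna), "\\s+"), `[`, "", 1L)
  seqs <- as.character(dna)
  cds_set(ids, seqs, isoform_policy = isoform_policy)
}

#' Construct and validate a set of CDS records
#'
#' @param gene_id character vector of species-prefixed gene identifiers.
#' @param sequence in-frame nucleotide strings.
#' @param isoform_policy see [read_cds_fasta()].
#' @return a \code{cds_set} data frame.
#' @export
cds_set <- function(gene_id, sequence, isoform_policy = "all") {
  stopifnot(length(gene_id) == length(sequence))
  sequence <- toupper(sequence)
  bad_alpha <- grepl("[^ACGT]", sequence)
  if (any(bad_alpha))
    stop("validation error: non-ACGT characters in record(s): ",
         paste(gene_id[bad_alpha], collapse = ", "))
  bad_frame <- nchar(sequence) %% 3L != 0L
  if (any(bad_frame))
    stop("frame error: length not divisible by 3 in record(s): ",
         paste(gene_id[bad_frame], collapse = ", "))
  aa <- codon_aa()
  for (i in seq_along(sequence)) {
    cod <- codon_index(codon_split(sequence[i]))
    a <- aa[cod]
    n <- length(a)
    if (n > 1L && a[n] == "*") {           # strip terminal stop
      sequence[i] <- substr(sequence[i], 1L, 3L * (n - 1L))
      a <- a[-n]
    }
    if (any(a == "*"))
      stop("validation error: internal stop codon in record ", gene_id[i])
  }
  if (isoform_policy == "longest") {
    stem <- sub("\\.[^.]*$", "", gene_id)
    keep <- unlist(lapply(split(seq_along(gene_id), stem), function(ii) {
      ii[which.max(nchar(sequence[ii]))]
    }), use.names = FALSE)
    keep <- sort(keep)
    gene_id <- gene_id[keep]
    sequence <- sequence[keep]
  }
  if (anyDuplicated(gene_id))
    stop("validation error: duplicated gene_id in CDS set")
  out <- data.frame(gene_id = gene_id,
                    species = sub("_.*$", "", gene_id),
                    sequence = sequence,
                    stringsAsFactors = FALSE)
  class(out) <- c("cds_set", "data.frame")
  out
}

#' Read gene models from GFF3 or BED
#'
#' CDS segments are grouped per gene, converted to the internal 0-based
#' half-open convention (GFF3 is 1-based inclusive; BED is already 0-based
#' half-open), and exon coding lengths are ordered in transcript
#' orientation (reversed for minus-strand genes).  Genes are ranked along
#' each chromosome by start position (ranks 0..n-1).
#'
#' @param path input file.
#' @param format \code{"gff3"} (CDS features grouped by \code{Parent}, or by
#'   \code{ID} when no Parent is present) or \code{"bed"} (BED12 blocks as
#'   exons; BED6 as a single exon).
#' @return a \code{gene_models} data frame with columns \code{gene_id},
#'   \code{species}, \code{chromosome}, \code{start}, \code{end},
#'   \code{strand}, \code{rank} and list column \code{exon_cds_lengths}.
#' @export
read_gene_models <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gdf <- as.data.frame(gr)
    gdf <- gdf[gdf$type == "CDS", , drop = FALSE]
    if (nrow(gdf) == 0L) stop("format error: no CDS features in ", path)
    parent <- if (!is.null(gdf$Parent) && any(lengths(gdf$Parent) > 0L)) {
      vapply(gdf$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, "")
    } else gdf$ID
    if (anyNA(parent)) stop("format error: CDS feature without Parent/ID")
    starts0 <- gdf$start - 1L  # 1-based inclusive -> 0-based half-open
    ends0 <- gdf$end
    chrom <- as.character(gdf$seqnames)
    strand <- as.character(gdf$strand)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    gdf <- as.data.frame(gr)
    parent <- gdf$name
    chrom <- as.character(gdf$seqnames)
    strand <- as.character(gdf$strand)
    blocks <- tryCatch(gr$blocks, error = function(e) NULL)
    if (!is.null(blocks)) {
      # BED12: expand blocks (1-based relative within the record) to exons
      res <- vector("list", nrow(gdf))
      for (i in seq_len(nrow(gdf))) {
        bl <- as.data.frame(blocks[[i]])
        off <- gdf$start[i] - 1L
        res[[i]] <- data.frame(gene = parent[i], chrom = chrom[i],
                               strand = strand[i],
                               s0 = off + bl$start - 1L,
                               e0 = off + bl$end)
      }
      res <- do.call(rbind, res)
      parent <- res$gene; chrom <- res$chrom; strand <- res$strand
      starts0 <- res$s0
      ends0 <- res$e0
    } else {
      starts0 <- gdf$start - 1L  # rtracklayer converts BED to 1-based
      ends0 <- gdf$end
    }
  }
  strand[!strand %in% c("+", "-")] <- "+"
  ord <- order(parent, starts0)
  df <- data.frame(gene = parent, chrom = chrom, strand = strand,
                   s0 = starts0, e0 = ends0)[ord, ]
  by_gene <- split(df, df$gene)
  models <- lapply(by_gene, function(g) {
    if (nrow(g) > 1L && any(g$s0[-1L] < g$e0[-nrow(g)]))
      stop("validation error: overlapping CDS segments in gene ", g$gene[1L])
    lens <- g$e0 - g$s0
    if (any(lens <= 0L))
      stop("validation error: empty CDS segment in gene ", g$gene[1L])
    if (g$strand[1L] == "-") lens <- rev(lens)  # 5'->3' transcript order
    list(gene_id = g$gene[1L], chromosome = g$chrom[1L], strand = g$strand[1L],
         start = min(g$s0), end = max(g$e0), exon_cds_lengths = as.integer(lens))
  })
  out <- data.frame(
    gene_id = vapply(models, `[[`, "", "gene_id"),
    species = sub("_.*$", "", vapply(models, `[[`, "", "gene_id")),
    chromosome = vapply(models, `[[`, "", "chromosome"),
    start = vapply(models, `[[`, 0, "start"),
    end = vapply(models, `[[`, 0, "end"),
    strand = vapply(models, `[[`, "", "strand"),
    stringsAsFactors = FALSE)
  out$exon_cds_lengths <- lapply(models, `[[`, "exon_cds_lengths")
  out <- out[order(out$chromosome, out$start, out$gene_id), ]
  out$rank <- as.integer(stats::ave(out$start, out$chromosome,
                                    FUN = seq_along)) - 1L
  rownames(out) <- NULL
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Read a gene tree in Newick format
#'
#' Internal node labels, when numeric, are interpreted as supports in the
#' declared units (bootstrap percentages in \[0,100\] or posterior
#' probabilities in \[0,1\]).  Missing branch lengths default to 0.
#'
#' @param path Newick file.
#' @param support_units \code{"bootstrap"} or \code{"posterior"}.
#' @return an [ape::read.tree()] \code{phylo} object with attribute
#'   \code{support_units}.
#' @export
read_tree_newick <- function(path, support_units = c("bootstrap", "posterior")) {
  support_units <- match.arg(support_units)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("parse error: ", conditionMessage(e)))
  if (is.null(tr)) stop("parse error: malformed Newick in ", path)
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  if (!is.null(tr$node.label)) {
    sup <- suppressWarnings(as.numeric(tr$node.label))
    num <- !is.na(sup)
    hi <- if (support_units == "bootstrap") 100 else 1
    if (any(num & (sup < 0 | sup > hi)))
      stop("validation error: support outside [0, ", hi, "] for ",
           support_units, " units")
  }
  attr(tr, "support_units") <- support_units
  tr
}

#' Intron phases of a gene model
#'
#' Phase i is the cumulative coding length of exons 1..i modulo 3; the
#' result has one entry per intron (exon count minus one).  The conserved
#' pattern of the focal family in this package's motivating analyses is
#' \code{c(0, 0, 1)} for four-exon genes.
#'
#' @param exon_cds_lengths positive integer vector of per-exon coding
#'   lengths in 5'->3' transcript order (or a \code{gene_models} row).
#' @return integer vector of phases in \{0, 1, 2\}.
#' @export
compute_intron_phases <- function(exon_cds_lengths) {
  if (is.list(exon_cds_lengths)) exon_cds_lengths <- unlist(exon_cds_lengths)
  stopifnot(length(exon_cds_lengths) >= 1L, all(exon_cds_lengths > 0))
  n <- length(exon_cds_lengths)
  if (n == 1L) return(integer(0))
  as.integer(cumsum(exon_cds_lengths)[-n] %% 3L)
}

#' Write a locus network as an edge list
#'
#' Rows are ordered lexicographically (and each edge's endpoints sorted), so
#' repeated writes of the same network are byte-identical.
#'
#' @param network an \code{igraph} locus network (see [build_locus_network()]).
#' @param path output file.
#' @param format \code{"tsv"} (node_a, node_b, weight) or \code{"sif"}
#'   (Cytoscape simple-interaction format, relation \code{synteny}).
#' @export
write_edge_list <- function(network, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  el <- igraph::as_data_frame(network, what = "edges")
  if (nrow(el) > 0L) {
    a <- pmin(el$from, el$to)
    b <- pmax(el$from, el$to)
    w <- el$weight
    ord <- order(a, b)
    el <- data.frame(node_a = a[ord], node_b = b[ord], weight = w[ord])
  } else {
    el <- data.frame(node_a = character(0), node_b = character(0),
                     weight = numeric(0))
  }
  if (format == "tsv") {
    utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- if (nrow(el)) paste(el$node_a, "synteny", el$node_b) else character(0)
    writeLines(lines, path)
  }
  invisible(path)
}
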
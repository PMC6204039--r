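# Pairwise Ka/Ks estimation: protein-guided codon alignment followed by
# Nei-Gojobori (1986) counting with Jukes-Cantor multiple-hit correction,
# then the saturation (Ks > 2) and GC3 (> 0.75, grass taxa) filters.

#' Global protein alignment with affine gaps
#'
#' A standard Needleman-Wunsch global alignment (BLOSUM62, affine gap
#' penalties), computed by [Biostrings::pairwiseAlignment()].  The alignment
#' only has to be consistent, not identical to any particular aligner:
#' downstream Ks estimation consumes codon columns, and externally aligned
#' proteins may be supplied to [back_translate()] directly.
#'
#' @param a,b amino-acid strings over the 20-letter alphabet.
#' @param gap_opening,gap_extension affine gap penalties (positive costs).
#' @param matrix substitution matrix name (from Biostrings).
#' @return list with gapped strings \code{a}, \code{b} and \code{score}.
#' @export
align_proteins_global <- function(a, b, gap_opening = 10, gap_extension = 0.5,
                                  matrix = "BLOSUM62") {
  for (s in c(a, b)) {
    if (nchar(s) == 0L) stop("empty protein sequence")
    if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", s))
      stop("alphabet error: invalid residue in protein sequence")
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = matrix, gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global")
  list(a = as.character(Biostrings::alignedPattern(al)),
       b = as.character(Biostrings::alignedSubject(al)),
       score = Biostrings::score(al))
}

#' Back-translate a protein alignment onto its source CDS pair
#'
#' Each residue column is replaced by the source codon; gap columns become
#' \code{"---"}.  Translating each CDS must reproduce the ungapped protein
#' exactly, otherwise a consistency error naming the offending column is
#' raised.
#'
#' @param aln list with gapped protein strings \code{a} and \code{b} of equal
#'   length (as returned by [align_proteins_global()]).
#' @param cds_a,cds_b in-frame CDS strings (terminal stop already stripped).
#' @return a \code{codon_alignment}: list with character vectors \code{a},
#'   \code{b} of aligned codons (gaps as \code{"---"}).
#' @export
back_translate <- function(aln, cds_a, cds_b) {
  ga <- strsplit(aln$a, "")[[1L]]
  gb <- strsplit(aln$b, "")[[1L]]
  if (length(ga) != length(gb)) stop("gapped strings of unequal length")
  fill <- function(gapped, cds, which) {
    cods <- codon_split(cds)
    aas <- codon_aa()[codon_index(cods)]
    res <- length(gapped)
    out <- character(res)
    j <- 0L
    for (i in seq_len(res)) {
      if (gapped[i] == "-") { out[i] <- "---"; next }
      j <- j + 1L
      if (j > length(cods) || aas[j] != gapped[i])
        stop("consistency error: translation mismatch for sequence ", which,
             " at alignment column ", i)
      out[i] <- cods[j]
    }
    if (j != length(cods))
      stop("consistency error: CDS ", which, " longer than aligned protein")
    out
  }
  out <- list(a = fill(ga, cds_a, "a"), b = fill(gb, cds_b, "b"))
  class(out) <- "codon_alignment"
  out
}

#' Nei-Gojobori substitution counts for a codon alignment
#'
#' Synonymous/nonsynonymous site counts (S, N) are averaged over the two
#' sequences from per-codon neighbour enumeration with mutations to stop
#' codons excluded from the denominator.  Difference counts (Sd, Nd) average
#' over all orderings of the substitution pathway for multi-difference codon
#' pairs; pathways through stop codons are excluded.  Columns containing a
#' gap, an ambiguous base, a stop codon, or a pair whose every pathway
#' crosses a stop are skipped whole.
#'
#' @param aln a \code{codon_alignment}.
#' @return list of class \code{ng_counts} with fields \code{S}, \code{N},
#'   \code{Sd}, \code{Nd}, \code{L} (compared codons) and \code{skipped}.
#' @export
ng86_counts <- function(aln) {
  ia <- codon_index(aln$a)
  ib <- codon_index(aln$b)
  aa <- codon_aa()
  usable <- !is.na(ia) & !is.na(ib) & aa[ia] != "*" & aa[ib] != "*"
  tab <- ng86_path_tables()
  sites <- ng86_site_table()
  sd_col <- rep(NA_real_, length(ia))
  sd_col[usable] <- tab$sd[cbind(ia[usable], ib[usable])]
  usable <- usable & !is.na(sd_col)   # drop stop-locked pathway pairs
  L <- sum(usable)
  if (L == 0L) stop("empty comparison: no usable codon columns")
  S <- sum((sites[ia[usable]] + sites[ib[usable]]) / 2)
  out <- list(S = S,
              N = 3 * L - S,
              Sd = sum(tab$sd[cbind(ia[usable], ib[usable])]),
              Nd = sum(tab$nd[cbind(ia[usable], ib[usable])]),
              L = L,
              skipped = length(ia) - L)
  class(out) <- "ng_counts"
  out
}

#' Jukes-Cantor distance from a difference proportion
#'
#' Returns \code{NA} (the saturation sentinel) when \code{p >= 3/4}, where
#' the correction is undefined.
#' @param p proportion of differing sites in \[0, 1\].
#' @export
jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 / 3 * p))
}

#' Third-position GC content of a CDS
#' @param seq in-frame CDS string.
#' @return fraction of G+C at codon third positions.
#' @export
gc3_content <- function(seq) {
  third <- substring(seq, seq(3L, nchar(seq), 3L), seq(3L, nchar(seq), 3L))
  mean(third %in% c("G", "C"))
}

#' Ka/Ks estimate from Nei-Gojobori counts
#'
#' Applies the Jukes-Cantor correction to the synonymous and nonsynonymous
#' difference proportions.  GC3 is computed on the ungapped full CDS of the
#' two genes (stable under alignment choice) and averaged.
#'
#' @param counts an \code{ng_counts} object.
#' @param cds_a,cds_b the source CDS strings (for GC3).
#' @param gene_a,gene_b identifiers carried into the result.
#' @return one-row data frame of class \code{ks_estimate}: \code{gene_a},
#'   \code{gene_b}, \code{pS}, \code{pN}, \code{ks}, \code{ka}, \code{gc3},
#'   \code{saturated}.  \code{ks}/\code{ka} are \code{NA} when saturated.
#' @export
ks_estimate <- function(counts, cds_a, cds_b, gene_a = "a", gene_b = "b") {
  if (counts$S <= 0 || counts$N <= 0)
    stop("degenerate comparison: S or N is zero")
  pS <- counts$Sd / counts$S
  pN <- counts$Nd / counts$N
  out <- data.frame(gene_a = gene_a, gene_b = gene_b,
                    pS = pS, pN = pN,
                    ks = jc_correct(pS), ka = jc_correct(pN),
                    gc3 = (gc3_content(cds_a) + gc3_content(cds_b)) / 2,
                    L = counts$L,
                    saturated = pS >= 0.75,
                    stringsAsFactors = FALSE)
  class(out) <- c("ks_estimate", "data.frame")
  out
}

#' Pairwise Ks for a table of gene pairs
#'
#' Runs the full protein alignment -> back-translation -> NG86 -> correction
#' chain for every pair.  The Ks estimate is symmetric in the pair order.
#'
#' @param cds a \code{cds_set}.
#' @param pairs data frame with columns \code{gene_a}, \code{gene_b}.
#' @return data frame of stacked [ks_estimate()] rows.
#' @export
ks_pairs <- function(cds, pairs) {
  seqs <- stats::setNames(cds$sequence, cds$gene_id)
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(seqs))
  if (length(missing))
    stop("lookup error: genes absent from CDS set: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- seqs[[pairs$gene_a[i]]]
    b <- seqs[[pairs$gene_b[i]]]
    aln <- align_proteins_global(translate_cds(a), translate_cds(b))
    cal <- back_translate(aln, a, b)
    res[[i]] <- ks_estimate(ng86_counts(cal), a, b,
                            pairs$gene_a[i], pairs$gene_b[i])
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Filter Ks estimates for saturation and GC3 bias
#'
#' Pairs with \code{ks > max_ks} or a saturated correction are removed
#' (synonymous sites saturated).  Pairs with mean GC3 above
#' \code{gc3_cutoff} are removed only when both genes belong to
#' \code{gc3_taxa} — the GC3 bias correction applied to the grass lineages,
#' whose codon third positions are strongly GC-shifted.  Every rejection is
#' logged with its reason.
#'
#' @param estimates data frame of [ks_estimate()] rows.
#' @param max_ks saturation cutoff (default 2.0).
#' @param gc3_cutoff GC3 cutoff (default 0.75).
#' @param gc3_taxa character vector of species codes subject to the GC3
#'   filter (default the rice and sorghum codes).
#' @return list with \code{retained} and \code{rejected} (the latter with a
#'   \code{reason} column over \{KS_GT_MAX, SATURATED, GC3_HIGH\}).
#' @export
filter_ks_pairs <- function(estimates, max_ks = 2.0, gc3_cutoff = 0.75,
                            gc3_taxa = c("Orysa", "Sorbi")) {
  if (is.null(estimates) || nrow(estimates) == 0L)
    return(list(retained = estimates,
                rejected = cbind(estimates, reason = character(0))))
  sp_a <- sub("_.*$", "", estimates$gene_a)
  sp_b <- sub("_.*$", "", estimates$gene_b)
  reason <- rep(NA_character_, nrow(estimates))
  reason[!is.na(estimates$ks) & estimates$ks > max_ks] <- "KS_GT_MAX"
  reason[estimates$saturated | is.na(estimates$ks)] <- "SATURATED"
  gc3_scope <- sp_a %in% gc3_taxa & sp_b %in% gc3_taxa
  reason[is.na(reason) & gc3_scope & estimates$gc3 > gc3_cutoff] <- "GC3_HIGH"
  keep <- is.na(reason)
  rejected <- estimates[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(retained = estimates[keep, , drop = FALSE], rejected = rejected)
}
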
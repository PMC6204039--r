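# Independent brute-force oracles used to validate the package's NG86
# counting and anchor chaining.  Deliberately written character-by-character
# against Biostrings::GENETIC_CODE, with no shared code or lookup tables.

.ora_nts <- c("A", "C", "G", "T")
.ora_gc <- Biostrings::GENETIC_CODE

# synonymous sites of one codon: per position, fraction of the non-stop
# single-nucleotide changes that preserve the amino acid
oracle_syn_sites <- function(cod) {
  s <- 0
  for (p in 1:3) {
    cur <- substr(cod, p, p)
    variants <- character(0)
    for (x in setdiff(.ora_nts, cur)) {
      v <- cod
      substr(v, p, p) <- x
      variants <- c(variants, v)
    }
    ok <- .ora_gc[variants] != "*"
    if (any(ok))
      s <- s + sum(.ora_gc[variants[ok]] == .ora_gc[cod]) / sum(ok)
  }
  s
}

# every stop-free substitution pathway between two codons, as (syn, nonsyn)
# step counts; enumeration by recursive choice of which differing position
# to change next (equivalent to all orderings)
oracle_paths <- function(from, to) {
  df <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  if (!length(df)) return(list(c(s = 0, n = 0)))
  out <- list()
  for (p in df) {
    mid <- from
    substr(mid, p, p) <- substr(to, p, p)
    if (.ora_gc[[mid]] == "*") next
    step_syn <- .ora_gc[[mid]] == .ora_gc[[from]]
    for (rest in oracle_paths(mid, to))
      out[[length(out) + 1L]] <- c(s = unname(rest[["s"]] + step_syn),
                                   n = unname(rest[["n"]] + !step_syn))
  }
  out
}

# full NG86 counts for two aligned codon vectors; returns NULL when no
# column is usable
oracle_ng86 <- function(ca, cb) {
  S <- Sd <- Nd <- 0
  L <- 0L
  for (i in seq_along(ca)) {
    a <- ca[i]; b <- cb[i]
    if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b)) next
    if (.ora_gc[a] == "*" || .ora_gc[b] == "*") next
    paths <- oracle_paths(a, b)
    if (!length(paths)) next
    L <- L + 1L
    S <- S + (oracle_syn_sites(a) + oracle_syn_sites(b)) / 2
    Sd <- Sd + mean(vapply(paths, `[[`, 0, "s"))
    Nd <- Nd + mean(vapply(paths, `[[`, 0, "n"))
  }
  if (L == 0L) return(NULL)
  list(S = S, N = 3 * L - S, Sd = Sd, Nd = Nd, L = L)
}

# exhaustive best chain: enumerate every subsequence of the anchors (sorted
# by rank_a), keep those that are monotone, gap-bounded and long enough,
# and return the best achievable score
oracle_best_chain <- function(anchors, max_gap, min_anchors, gap_penalty) {
  n <- nrow(anchors)
  ord <- order(anchors$rank_a, anchors$rank_b)
  ra <- anchors$rank_a[ord]; rb <- anchors$rank_b[ord]
  sim <- anchors$similarity[ord]
  best <- -Inf
  score_chain <- function(idx, rbx) {
    if (any(diff(ra[idx]) <= 0) || any(diff(rbx[idx]) <= 0)) return(NA_real_)
    ga <- diff(ra[idx]) - 1L
    gb <- diff(rbx[idx]) - 1L
    if (any(ga > max_gap) || any(gb > max_gap)) return(NA_real_)
    sum(sim[idx]) - gap_penalty * (sum(ga) + sum(gb))
  }
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) < min_anchors) next
    for (rbx in list(rb, -rb)) {
      sc <- score_chain(idx, rbx)
      if (!is.na(sc) && sc > best) best <- sc
    }
  }
  if (is.finite(best)) best else NULL
}

# random non-stop codons
random_codons <- function(n) {
  cods <- names(.ora_gc)[.ora_gc != "*"]
  sample(cods, n, replace = TRUE)
}

make_codon_aln <- function(a, b) structure(list(a = a, b = b),
                                           class = "codon_alignment")
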
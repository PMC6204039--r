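# Codon-level machinery shared by the Ks engine, the tree builder and the
# simulator.  All tables are derived once from Biostrings::GENETIC_CODE and
# cached in a package-local environment; codons are addressed as integers
# 1..64 (index = 16*(p1-1) + 4*(p2-1) + p3 over the alphabet A,C,G,T).

.wgd_cache <- new.env(parent = emptyenv())

.nt <- c("A", "C", "G", "T")

#' @keywords internal
codon_index <- function(codons) {
  m <- match(unlist(strsplit(codons, "")), .nt)
  m <- matrix(m, nrow = 3L)
  ifelse(colSums(is.na(m)) > 0L, NA_integer_,
         16L * (m[1L, ] - 1L) + 4L * (m[2L, ] - 1L) + m[3L, ])
}

#' @keywords internal
index_codon <- function(idx) {
  i <- idx - 1L
  paste0(.nt[i %/% 16L + 1L], .nt[(i %/% 4L) %% 4L + 1L], .nt[i %% 4L + 1L])
}

all_codons <- function() index_codon(1:64)

#' Amino acid (one-letter) per codon index, "*" for stops.
#' @keywords internal
codon_aa <- function() {
  if (is.null(.wgd_cache$aa)) {
    gc <- Biostrings::GENETIC_CODE
    .wgd_cache$aa <- unname(gc[all_codons()])
  }
  .wgd_cache$aa
}

#' Split an in-frame CDS string into codons.
#' @keywords internal
codon_split <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate an in-frame CDS string (standard code).
#' @keywords internal
translate_cds <- function(seq) {
  aa <- codon_aa()[codon_index(codon_split(seq))]
  if (anyNA(aa)) stop("non-ACGT characters in coding sequence")
  paste(aa, collapse = "")
}

# The three single-nucleotide neighbours of codon `idx` at position `pos`.
.codon_neighbours <- function(idx, pos) {
  i <- idx - 1L
  digit <- switch(pos, i %/% 16L, (i %/% 4L) %% 4L, i %% 4L)
  step <- switch(pos, 16L, 4L, 1L)
  others <- setdiff(0:3, digit)
  idx + step * (others - digit)
}

#' Per-codon synonymous site counts (Nei-Gojobori).
#'
#' For each codon position the three possible single-nucleotide changes are
#' enumerated; changes creating a stop codon are excluded from the
#' denominator.  A position contributes `n_syn / n_valid` synonymous sites
#' (0 when every change creates a stop), so every codon carries 3 sites
#' split between the synonymous and nonsynonymous classes.
#' @keywords internal
ng86_site_table <- function() {
  if (!is.null(.wgd_cache$sites)) return(.wgd_cache$sites)
  aa <- codon_aa()
  s <- rep(NA_real_, 64L)
  for (idx in 1:64) {
    if (aa[idx] == "*") next
    tot <- 0
    for (pos in 1:3) {
      nb <- .codon_neighbours(idx, pos)
      ok <- aa[nb] != "*"
      if (any(ok)) tot <- tot + sum(aa[nb][ok] == aa[idx]) / sum(ok)
    }
    s[idx] <- tot
  }
  .wgd_cache$sites <- s
  s
}

# Pathway-averaged synonymous/nonsynonymous difference counts for every
# ordered codon pair.  Codon pairs differing at k positions are scored by
# enumerating all k! substitution orders; pathways passing through a stop
# codon are dropped, the remainder averaged.  The rare pairs whose every
# pathway crosses a stop are marked NA and skipped by the caller.
.perms <- list(`1` = matrix(1L, 1, 1),
               `2` = rbind(c(1L, 2L), c(2L, 1L)),
               `3` = rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

.codon_digits <- function(idx) {
  i <- idx - 1L
  c(i %/% 16L, (i %/% 4L) %% 4L, i %% 4L)
}

ng86_path_tables <- function() {
  if (!is.null(.wgd_cache$sd)) return(list(sd = .wgd_cache$sd, nd = .wgd_cache$nd))
  aa <- codon_aa()
  sd <- matrix(NA_real_, 64, 64)
  nd <- matrix(NA_real_, 64, 64)
  steps <- c(16L, 4L, 1L)
  for (a in 1:64) {
    if (aa[a] == "*") next
    da <- .codon_digits(a)
    for (b in a:64) {
      if (aa[b] == "*") next
      db <- .codon_digits(b)
      diff_pos <- which(da != db)
      k <- length(diff_pos)
      if (k == 0L) { sd[a, b] <- nd[a, b] <- 0; next }
      perms <- .perms[[as.character(k)]]
      syn_tot <- nsyn_tot <- 0
      n_ok <- 0L
      for (r in seq_len(nrow(perms))) {
        cur <- a
        syn <- nsyn <- 0L
        ok <- TRUE
        for (p in perms[r, seq_len(k)]) {
          pos <- diff_pos[p]
          nxt <- cur + steps[pos] * (db[pos] - .codon_digits(cur)[pos])
          if (aa[nxt] == "*") { ok <- FALSE; break }
          if (aa[nxt] == aa[cur]) syn <- syn + 1L else nsyn <- nsyn + 1L
          cur <- nxt
        }
        if (ok) { syn_tot <- syn_tot + syn; nsyn_tot <- nsyn_tot + nsyn; n_ok <- n_ok + 1L }
      }
      if (n_ok > 0L) {
        sd[a, b] <- sd[b, a] <- syn_tot / n_ok
        nd[a, b] <- nd[b, a] <- nsyn_tot / n_ok
      }
    }
  }
  .wgd_cache$sd <- sd
  .wgd_cache$nd <- nd
  list(sd = sd, nd = nd)
}
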
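# End-to-end orchestration: synteny -> syntelog extraction -> Ks (with
# filters) -> dating (CI, KDE peaks, WGD matching) and, when trees are
# supplied, duplication calls.  Every stage persists a plain TSV so
# externally computed trees or anchors can be substituted at any cut point.

.default_params <- function() {
  list(max_ks = 2.0, gc3_cutoff = 0.75, gc3_taxa = c("Orysa", "Sorbi"),
       max_gap_ranks = 25L, min_anchors = 5L, gap_penalty = 1.0,
       threshold = 90, bandwidth = "silverman", min_density_frac = 0.25,
       paralogs_only = TRUE)
}

#' Run the WGD-tracing pipeline
#'
#' @param config a list (or path to a JSON file) with entries:
#'   \describe{
#'     \item{cds}{path to the CDS FASTA (required).}
#'     \item{gene_models, gene_models_format}{gene model file and its format
#'       (\code{"bed"} or \code{"gff3"}; required).}
#'     \item{anchors}{path to the anchor TSV: \code{gene_a}, \code{gene_b},
#'       \code{similarity} (required).}
#'     \item{focal_genes}{character vector of focal gene ids, or a file with
#'       one id per line (required).}
#'     \item{trees, outgroup}{optional multi-Newick file of gene trees plus
#'       the outgroup species code or gene id; enables duplication calls.}
#'     \item{reference}{optional reference-table CSV (default: packaged).}
#'     \item{scope}{optional species filter for reference matching.}
#'     \item{params}{overrides of the stage parameters (see Details).}
#'     \item{seed}{integer seed (default 1).}
#'     \item{outdir}{output directory for per-stage TSVs and the JSON
#'       report (required).}
#'   }
#'
#' @details Stage parameters and defaults: \code{max_ks} 2.0,
#'   \code{gc3_cutoff} 0.75, \code{gc3_taxa} the grass codes
#'   (\code{Orysa}, \code{Sorbi}), \code{max_gap_ranks} 25,
#'   \code{min_anchors} 5, \code{gap_penalty} 1, \code{threshold} 90,
#'   \code{bandwidth} \code{"silverman"}, \code{min_density_frac} 0.25,
#'   \code{paralogs_only} \code{TRUE} (date only within-genome duplicate
#'   pairs; cross-species syntelogs stay in the syntelog table but are not
#'   part of the Ks sample).
#'   The run is deterministic given \code{seed}; the report echoes the full
#'   effective parameter set and conserves pair totals
#'   (pairs in = retained + rejected).
#'
#' @return the run report (list of class \code{wgd_report}), invisibly also
#'   written as \code{report.json} in \code{outdir}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  for (field in c("cds", "gene_models", "anchors", "focal_genes", "outdir"))
    if (is.null(config[[field]]))
      stop("usage error: config missing required field '", field, "'")
  for (field in c("cds", "gene_models", "anchors"))
    if (!file.exists(config[[field]]))
      stop("usage error: input file not found: ", config[[field]])
  params <- utils::modifyList(.default_params(), config$params %||% list())
  seed <- config$seed %||% 1L
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  set.seed(seed)
  stage <- "load_inputs"
  report <- list(params = params, seed = seed)
  fail <- function(e) {
    writeLines(paste0("FAILED at stage: ", stage, "\n", conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop("pipeline aborted at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    cds <- read_cds_fasta(config$cds)
    loci <- read_gene_models(config$gene_models,
                             format = config$gene_models_format %||% "bed")
    anchors <- utils::read.delim(config$anchors, stringsAsFactors = FALSE)
    focal <- config$focal_genes
    if (length(focal) == 1L && file.exists(focal)) focal <- readLines(focal)
    refs <- wgd_reference(config$reference)

    stage <<- "synteny"
    blocks <- chain_all_anchors(anchors, loci,
                                max_gap_ranks = params$max_gap_ranks,
                                min_anchors = params$min_anchors,
                                gap_penalty = params$gap_penalty)
    blk_df <- do.call(rbind, lapply(blocks, function(b) data.frame(
      block_id = b$id, chrom_a = b$chrom_a, chrom_b = b$chrom_b,
      orientation = b$orientation, n_anchors = b$n_anchors, score = b$score,
      stringsAsFactors = FALSE)))
    if (is.null(blk_df))
      blk_df <- data.frame(block_id = character(0), chrom_a = character(0),
                           chrom_b = character(0), orientation = character(0),
                           n_anchors = integer(0), score = numeric(0))
    utils::write.table(blk_df, file.path(outdir, "blocks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    stage <<- "syntelogs"
    syntelogs <- extract_flanking_syntelogs(blocks, focal)
    utils::write.table(syntelogs, file.path(outdir, "syntelogs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    network <- build_locus_network(blocks, focal, loci)
    write_edge_list(network, file.path(outdir, "locus_network.tsv"))

    stage <<- "ks"
    ks_input <- syntelogs
    if (isTRUE(params$paralogs_only))
      # duplication ages come from within-genome duplicate pairs
      ks_input <- ks_input[species_of(ks_input$gene_a) ==
                             species_of(ks_input$gene_b), , drop = FALSE]
    est <- ks_pairs(cds, ks_input)
    filt <- filter_ks_pairs(est, max_ks = params$max_ks,
                            gc3_cutoff = params$gc3_cutoff,
                            gc3_taxa = params$gc3_taxa)
    utils::write.table(filt$retained, file.path(outdir, "ks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(filt$rejected, file.path(outdir, "ks_rejections.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <<- "dating"
    ksv <- filt$retained$ks
    ci <- if (length(ksv)) mean_ci(ksv) else NULL
    peaks <- if (length(ksv) >= 2L)
      kde_peaks(ksv, bandwidth = params$bandwidth,
                min_density_frac = params$min_density_frac) else NULL
    matches <- if (!is.null(peaks) && nrow(peaks))
      match_wgd(peaks, refs, ci = ci, scope = config$scope) else NULL
    if (!is.null(peaks))
      utils::write.table(peaks, file.path(outdir, "peaks.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    if (!is.null(matches))
      utils::write.table(matches, file.path(outdir, "matches.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)

    calls <- NULL
    if (!is.null(config$trees)) {
      stage <<- "genetree"
      trees <- ape::read.tree(config$trees)
      if (inherits(trees, "phylo")) trees <- list(trees)
      call_list <- list()
      for (k in seq_along(trees)) {
        tr <- trees[[k]]
        og <- config$outgroup
        if (!is.null(og) && !og %in% tr$tip.label) {
          hit <- tr$tip.label[species_of(tr$tip.label) == og]
          og <- if (length(hit) == 1L) hit else NULL
        }
        rooted <- if (!is.null(og)) root_by_outgroup(tr, og) else tr
        if (!ape::is.rooted(rooted)) next
        cl <- detect_duplications(rooted, threshold = params$threshold)
        if (nrow(cl)) { cl$tree <- k; call_list[[length(call_list) + 1L]] <- cl }
      }
      calls <- if (length(call_list)) do.call(rbind, call_list) else NULL
      if (!is.null(calls))
        utils::write.table(calls, file.path(outdir, "duplication_calls.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }

    stage <<- "report"
    report$counts <- list(
      anchors_in = nrow(anchors), blocks = length(blocks),
      syntelog_pairs = nrow(syntelogs),
      ks_pairs_in = nrow(est), ks_retained = nrow(filt$retained),
      ks_rejected = nrow(filt$rejected))
    report$rejections <- if (nrow(filt$rejected))
      as.list(table(filt$rejected$reason)) else list()
    report$ci <- if (!is.null(ci)) unclass(ci) else NULL
    report$peaks <- if (!is.null(peaks)) as.data.frame(peaks) else NULL
    report$matches <- matches
    report$duplications <- if (!is.null(calls)) list(
      n_calls = nrow(calls),
      n_supported_shared = sum(calls$supported & calls$classification == "shared"),
      n_supported_specific = sum(calls$supported &
                                   calls$classification == "species_specific")) else NULL
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }, error = fail)
  class(report) <- "wgd_report"
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
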
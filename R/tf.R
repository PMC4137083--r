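## Convert a 0-based half-open BED-like data frame to GRanges.
bedlike_to_granges <- function(x) {
  if (inherits(x, "GRanges")) return(x)
  needed <- c("chrom", "start", "end", "name")
  if (!all(needed %in% names(x))) {
    stop("BED-like data frame needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(x$end <= x$start)) stop("BED intervals need end > start", call. = FALSE)
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand)
  gr$name <- as.character(x$name)
  gr
}

#' Strand-aware regulatory windows around gene models
#'
#' A gene's window covers its body plus \code{upstream} bases past the 5'
#' end and \code{downstream} bases past the 3' end, so for a minus-strand
#' gene the upstream extension lies to the right. Windows are clipped at
#' position 1.
#'
#' @param models gene models as a \code{GRanges} (with a \code{name}
#'   metadata column) or a 0-based BED-like data frame.
#' @param upstream bases beyond the 5' end (default 10000).
#' @param downstream bases beyond the 3' end (default 3000).
#' @return \code{GRanges} of windows, one per gene, named by gene.
#' @export
gene_windows <- function(models, upstream = 10000, downstream = 3000) {
  gr <- bedlike_to_granges(models)
  plus <- as.character(GenomicRanges::strand(gr)) != "-"
  ext_left <- ifelse(plus, upstream, downstream)
  ext_right <- ifelse(plus, downstream, upstream)
  win <- gr
  GenomicRanges::start(win) <- pmax(1L, GenomicRanges::start(gr) - ext_left)
  GenomicRanges::end(win) <- GenomicRanges::end(gr) + ext_right
  win
}

#' Assign binding sites to candidate target genes
#'
#' A binding site (named by its transcription factor) is assigned to every
#' gene whose regulatory window it overlaps by at least one base: the gene
#' body (exons and introns), 10 kb past the 5' end or 3 kb past the 3' end
#' by default. A site may hit several genes; sites outside every window are
#' assigned to none.
#'
#' @param sites binding sites as \code{GRanges} (metadata column
#'   \code{name} = TF id) or 0-based BED-like data frame.
#' @param models gene models (see \code{\link{gene_windows}}).
#' @param upstream,downstream window extensions in bases.
#' @param universe optional gene set candidates are restricted to (the
#'   network genes).
#' @return Named list: TF id -> sorted character vector of candidate
#'   target genes.
#' @export
assign_tf_candidates <- function(sites, models, upstream = 10000,
                                 downstream = 3000, universe = NULL) {
  sgr <- bedlike_to_granges(sites)
  win <- gene_windows(models, upstream, downstream)
  hits <- GenomicRanges::findOverlaps(sgr, win, minoverlap = 1L,
                                      ignore.strand = TRUE)
  tf <- sgr$name[S4Vectors::queryHits(hits)]
  gene <- win$name[S4Vectors::subjectHits(hits)]
  if (!is.null(universe)) {
    keep <- gene %in% universe
    tf <- tf[keep]; gene <- gene[keep]
  }
  if (!length(tf)) return(stats::setNames(list(), character(0)))
  lapply(split(gene, tf), function(g) sort(unique(g)))
}

#' Filter candidate targets by co-expression with their TF
#'
#' A candidate is retained when its expression profile is positively
#' correlated with the TF's (Pearson \code{r >= r_min}) and the correlation
#' is significant after BH correction across all candidate pairs of the run
#' (\code{q < q_max}, one-sided test of r > 0 on the t distribution). TFs
#' absent from the expression matrix are dropped with a warning;
#' zero-variance profiles skip the pair with a warning. TFs retaining no
#' target are dropped from the final list.
#'
#' @param candidates named list TF -> candidate genes (from
#'   \code{\link{assign_tf_candidates}}).
#' @param expression numeric matrix, genes in rows (rownames), conditions
#'   in columns; at least 3 conditions.
#' @param r_min minimum Pearson correlation (default 0.5).
#' @param q_max BH FDR threshold (default 0.05).
#' @return Object of class \code{tf_targets}: list with \code{pairs} (data
#'   frame \code{tf}, \code{gene}, \code{r}, \code{p_value}, \code{q_value},
#'   \code{kept}), \code{targets} (named list of retained target sets) and
#'   \code{candidates}.
#' @export
coexpression_filter <- function(candidates, expression, r_min = 0.5,
                                q_max = 0.05) {
  expression <- as.matrix(expression)
  if (ncol(expression) < 3L) {
    stop("expression matrix needs at least 3 conditions", call. = FALSE)
  }
  missing_tf <- setdiff(names(candidates), rownames(expression))
  if (length(missing_tf)) {
    warning("dropping TF(s) absent from the expression matrix: ",
            paste(missing_tf, collapse = ", "), call. = FALSE)
    candidates <- candidates[setdiff(names(candidates), missing_tf)]
  }
  rows <- list()
  skipped <- 0L
  for (tf in names(candidates)) {
    x <- expression[tf, ]
    for (gene in setdiff(candidates[[tf]], tf)) {
      if (!gene %in% rownames(expression)) { skipped <- skipped + 1L; next }
      y <- expression[gene, ]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) { skipped <- skipped + 1L; next }
      r <- stats::cor(x, y)
      m <- length(x)
      tval <- r * sqrt((m - 2) / max(1 - r^2, .Machine$double.eps))
      p <- max(stats::pt(tval, df = m - 2, lower.tail = FALSE), 1e-300)
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, gene = gene, r = r, p_value = p, stringsAsFactors = FALSE)
    }
  }
  if (skipped) {
    warning(skipped, " candidate pair(s) skipped (gene missing from the ",
            "expression matrix or zero-variance profile)", call. = FALSE)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tf = character(0), gene = character(0), r = numeric(0),
               p_value = numeric(0))
  if (nrow(pairs)) {
    pairs$q_value <- bh_fdr(pairs$p_value)
    pairs$kept <- pairs$r >= r_min & pairs$q_value < q_max
  } else {
    pairs$q_value <- numeric(0)
    pairs$kept <- logical(0)
  }
  kept <- pairs[pairs$kept, , drop = FALSE]
  targets <- lapply(split(kept$gene, kept$tf), function(g) sort(unique(g)))
  targets <- targets[vapply(targets, length, integer(1)) > 0L]
  structure(list(pairs = pairs, targets = targets, candidates = candidates),
            class = "tf_targets")
}

#' @export
print.tf_targets <- function(x, ...) {
  cat("TF target sets:", length(x$targets), "TF(s) with targets",
      sprintf("(%d candidate pairs tested)\n", nrow(x$pairs)))
  invisible(x)
}

#' Enrichment of TF targets within communities
#'
#' Tests each community for over-representation of each TF's target set
#' (one-sided Fisher, BH across the family) and flags pairs with
#' \code{q < alpha} and at least \code{min_overlap} targets in the
#' community. Also summarizes, per TF, how many communities it is enriched
#' in, distinguishing community-specific TFs from those shared by several
#' communities.
#'
#' @param communities an \code{mcode_communities} object or named list.
#' @param tf_targets a \code{tf_targets} object or named list TF -> genes.
#' @param background the network gene universe.
#' @param min_community_size smallest community tested (default 5).
#' @param min_overlap minimum targets within the community (default 5).
#' @param alpha FDR level (default 0.05).
#' @return List with \code{enrichment} (see
#'   \code{\link{enrich_communities}}) and \code{tf_summary} (data frame
#'   \code{tf}, \code{n_enriched_communities}, \code{shared}).
#' @export
tf_enrichment <- function(communities, tf_targets, background,
                          min_community_size = 5, min_overlap = 5,
                          alpha = 0.05) {
  sets <- if (inherits(tf_targets, "tf_targets")) tf_targets$targets else tf_targets
  sets <- lapply(sets, function(s) intersect(s, background))
  sets <- sets[vapply(sets, length, integer(1)) > 0L]
  res <- enrich_communities(communities, sets, background,
                            min_community_size = min_community_size,
                            min_overlap = min_overlap, alpha = alpha)
  hit <- res[res$significant, , drop = FALSE]
  counts <- table(factor(hit$set_id, levels = names(sets)))
  tf_summary <- data.frame(tf = names(counts),
                           n_enriched_communities = as.integer(counts),
                           shared = as.integer(counts) > 1L,
                           stringsAsFactors = FALSE)
  list(enrichment = res, tf_summary = tf_summary)
}
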
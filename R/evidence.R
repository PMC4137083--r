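#' Combine per-channel evidence scores into one confidence score
#'
#' Integrates independent evidence channels (genomic context, experiments,
#' co-expression, prior knowledge, ...) into a single interaction confidence
#' using the STRING-style probabilistic combination: each channel score is
#' first corrected for the prior probability of a random pair interacting,
#' the corrected scores are combined as one minus the product of their
#' complements, and the prior is added back at the end. Channels listed in
#' \code{excluded} (e.g. text mining) are dropped before combination.
#'
#' @param scores numeric vector of channel scores, each in \[0, 1\].
#' @param prior prior interaction probability in \[0, 1); channel scores at
#'   or below the prior contribute nothing after correction. Default 0.041.
#' @param excluded integer indices of channels to drop before combination.
#' @return A single combined score in \[0, 1\]. Returns 0 when no channel
#'   exceeds the prior.
#' @examples
#' combine_channel_scores(c(0.5, 0.6), prior = 0)  # 1 - 0.5*0.4 = 0.8
#' combine_channel_scores(c(0.9, 0.3, 0.99), prior = 0.041, excluded = 3)
#' @export
combine_channel_scores <- function(scores, prior = 0.041, excluded = integer(0)) {
  if (!is.numeric(scores) || anyNA(scores) || any(scores < 0 | scores > 1)) {
    stop("channel scores must be numeric values in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(prior) || length(prior) != 1L || prior < 0 || prior >= 1) {
    stop("'prior' must be a single value in [0, 1)", call. = FALSE)
  }
  if (length(excluded)) scores <- scores[-excluded]
  if (!length(scores)) return(0)
  s <- pmax(0, (scores - prior) / (1 - prior))
  if (all(s == 0)) return(0)
  cprime <- 1 - prod(1 - s)
  cprime * (1 - prior) + prior
}

## Row-wise combination over a score matrix (one row per gene pair).
## exp(sum(log1p(-s))) handles s' = 1 cleanly (-Inf -> product 0).
combine_score_matrix <- function(scores, prior = 0.041, excluded = integer(0)) {
  scores <- as.matrix(scores)
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    stop("channel scores must be numeric values in [0, 1]", call. = FALSE)
  }
  if (length(excluded)) scores <- scores[, -excluded, drop = FALSE]
  if (ncol(scores) == 0L) return(rep(0, nrow(scores)))
  s <- (scores - prior) / (1 - prior)
  s[s < 0] <- 0  # pmax would drop the dim attributes
  cprime <- 1 - exp(rowSums(log1p(-s)))
  out <- cprime * (1 - prior) + prior
  out[rowSums(s) == 0] <- 0
  out
}

#' Add a combined score column to an evidence table
#'
#' @param evidence data frame with columns \code{gene_a}, \code{gene_b} and
#'   one numeric column per evidence channel.
#' @param prior prior interaction probability (see
#'   \code{\link{combine_channel_scores}}).
#' @param exclude_channels character vector of channel column names to drop
#'   before combination (the analysis discards the text-mining channel).
#' @return The evidence table with a \code{combined} column appended.
#' @export
combine_evidence <- function(evidence, prior = 0.041, exclude_channels = character(0)) {
  chan <- setdiff(names(evidence), c("gene_a", "gene_b", "combined"))
  if (!all(exclude_channels %in% chan)) {
    stop("unknown channel(s): ",
         paste(setdiff(exclude_channels, chan), collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(chan, exclude_channels)
  evidence$combined <- combine_score_matrix(evidence[keep], prior = prior)
  evidence
}

validate_pairs <- function(evidence) {
  if (!all(c("gene_a", "gene_b") %in% names(evidence))) {
    stop("evidence table must have 'gene_a' and 'gene_b' columns", call. = FALSE)
  }
  a <- as.character(evidence$gene_a)
  b <- as.character(evidence$gene_b)
  if (any(a == b)) stop("self-pairs are not allowed", call. = FALSE)
  if (any(a > b)) {
    stop("pairs must be in canonical order (gene_a < gene_b)", call. = FALSE)
  }
  key <- paste(a, b, sep = "\t")
  if (anyDuplicated(key)) {
    stop("duplicate gene pair(s) in evidence table: ",
         key[duplicated(key)][1L], call. = FALSE)
  }
  invisible(evidence)
}

#' Build the thresholded interactome from a combined-score evidence table
#'
#' Keeps edges whose combined score passes the high-confidence cutoff
#' (inclusive, i.e. a score exactly at the cutoff is kept) and whose two
#' endpoints both belong to the gene universe. Universe genes left without
#' any passing edge become degree-0 nodes (singletons) that
#' \code{\link{remove_singletons}} subsequently strips.
#'
#' @param evidence data frame with \code{gene_a}, \code{gene_b} and a
#'   \code{combined} column (see \code{\link{combine_evidence}}).
#' @param cutoff minimum combined score for a high-confidence edge
#'   (default 0.7, kept with \code{>=} semantics).
#' @param universe character vector of genes the network is restricted to;
#'   \code{NULL} means all genes appearing in the table.
#' @return An object of class \code{interactome}: a list with \code{nodes},
#'   an \code{edges} data frame (\code{gene_a}, \code{gene_b},
#'   \code{score}) and \code{singletons_removed}.
#' @export
build_interactome <- function(evidence, cutoff = 0.7, universe = NULL) {
  validate_pairs(evidence)
  if (is.null(evidence$combined)) {
    stop("evidence table has no 'combined' column; run combine_evidence() first",
         call. = FALSE)
  }
  if (!is.null(universe)) {
    universe <- unique(as.character(universe))
    if (length(universe) == 0L) stop("gene universe is empty", call. = FALSE)
  }
  a <- as.character(evidence$gene_a)
  b <- as.character(evidence$gene_b)
  keep <- evidence$combined >= cutoff
  if (!is.null(universe)) keep <- keep & a %in% universe & b %in% universe
  edges <- data.frame(gene_a = a[keep], gene_b = b[keep],
                      score = evidence$combined[keep],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- if (is.null(universe)) sort(unique(c(a, b))) else sort(universe)
  structure(list(nodes = nodes, edges = edges,
                 singletons_removed = character(0)),
            class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat("Interactome:", length(x$nodes), "genes,", nrow(x$edges), "interactions")
  if (length(x$singletons_removed)) {
    cat(" (", length(x$singletons_removed), " singletons removed)", sep = "")
  }
  cat("\n")
  invisible(x)
}

interactome_degrees <- function(net) {
  d <- table(factor(c(net$edges$gene_a, net$edges$gene_b), levels = net$nodes))
  stats::setNames(as.integer(d), names(d))
}

#' Remove genes with no interactions from an interactome
#'
#' Degree-0 nodes are moved to \code{singletons_removed}; the edge set is
#' unchanged.
#'
#' @param net an \code{interactome}.
#' @return The interactome without singleton nodes.
#' @export
remove_singletons <- function(net) {
  stopifnot(inherits(net, "interactome"))
  deg <- interactome_degrees(net)
  drop <- names(deg)[deg == 0L]
  net$nodes <- setdiff(net$nodes, drop)
  net$singletons_removed <- sort(unique(c(net$singletons_removed, drop)))
  net
}

#' Convert an interactome to an igraph object
#'
#' @param net an \code{interactome}.
#' @return An undirected \pkg{igraph} graph whose edges carry the combined
#'   score as the \code{score} attribute.
#' @export
interactome_graph <- function(net) {
  stopifnot(inherits(net, "interactome"))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  g
}

#' Connected components of an interactome, largest first
#'
#' @param net an \code{interactome} (typically after
#'   \code{\link{remove_singletons}}) or an igraph graph.
#' @return data frame (\code{gene}, \code{component_id}) where component 1
#'   is the largest; ties are broken by the lexicographically smallest
#'   member gene.
#' @export
connected_components <- function(net) {
  g <- if (inherits(net, "interactome")) interactome_graph(net) else net
  comp <- igraph::components(g)
  nms <- igraph::V(g)$name
  smallest <- vapply(seq_len(comp$no),
                     function(i) min(nms[comp$membership == i]), character(1))
  ord <- order(-comp$csize, smallest)
  relabel <- integer(comp$no)
  relabel[ord] <- seq_len(comp$no)
  out <- data.frame(gene = nms, component_id = relabel[comp$membership],
                    stringsAsFactors = FALSE)
  out[order(out$component_id, out$gene), , drop = FALSE]
}

#' Fit a power law to the degree distribution
#'
#' Scale-free networks have degree frequencies following
#' \eqn{f(k) \propto k^{\alpha}} with negative \eqn{\alpha}. The default fit
#' is ordinary least squares on (log10 degree, log10 frequency) over degrees
#' with nonzero frequency, the convention of Cytoscape-style network
#' analyzers; \code{method = "ml"} gives a discrete maximum-likelihood
#' (Hill-type) estimate of the exponent instead.
#'
#' @param x an \code{interactome}, an igraph graph, or a vector of node
#'   degrees.
#' @param method \code{"ols"} (default) or \code{"ml"}.
#' @return An object of class \code{degree_fit} with fields \code{alpha}
#'   (the fitted exponent, \code{NA} when fewer than 3 distinct degrees are
#'   available), \code{r_squared}, \code{points} and \code{defined}.
#' @export
fit_power_law <- function(x, method = c("ols", "ml")) {
  method <- match.arg(method)
  deg <- if (inherits(x, "interactome")) {
    interactome_degrees(x)
  } else if (inherits(x, "igraph")) {
    igraph::degree(x)
  } else {
    as.numeric(x)
  }
  deg <- deg[deg >= 1]
  tab <- table(deg)
  k <- as.numeric(names(tab))
  f <- as.numeric(tab)
  points <- data.frame(degree = k, frequency = f)
  if (length(k) < 3L) {
    return(structure(list(alpha = NA_real_, r_squared = NA_real_,
                          points = points, method = method, defined = FALSE),
                     class = "degree_fit"))
  }
  if (method == "ols") {
    fit <- stats::lm(log10(f) ~ log10(k))
    alpha <- unname(stats::coef(fit)[2L])
    # lm warns on exact log-linear input ("essentially perfect fit")
    r2 <- suppressWarnings(summary(fit)$r.squared)
  } else {
    # discrete Hill estimator with kmin = 1 (Clauset-style, continuous approx.)
    alpha <- -(1 + length(deg) / sum(log(deg / 0.5)))
    r2 <- NA_real_
  }
  structure(list(alpha = alpha, r_squared = r2, points = points,
                 method = method, defined = TRUE),
            class = "degree_fit")
}

#' @export
print.degree_fit <- function(x, ...) {
  if (!x$defined) {
    cat("Degree fit: undefined (< 3 distinct degrees)\n")
  } else {
    cat(sprintf("Degree power-law fit (%s): alpha = %.3f", x$method, x$alpha))
    if (!is.na(x$r_squared)) cat(sprintf(", r^2 = %.3f", x$r_squared))
    cat("\n")
  }
  invisible(x)
}
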
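#' Interaction Strength between two communities
#'
#' IS is the observed number of edges running between two disjoint gene
#' communities divided by the number expected under a network-level null.
#' The default null is the global edge density of the gene-wise network:
#' expected = \eqn{n_i n_j \rho} with \eqn{\rho = 2E / (N(N-1))}. A
#' configuration-model variant (expected = \eqn{d_i d_j / 2E}, with
#' \eqn{d_i} the summed degree of community i) is available via
#' \code{null = "configuration"}. IS is symmetric and 0 exactly when no
#' inter-community edge exists.
#'
#' @param net the gene-wise \code{interactome} (or igraph graph).
#' @param comm_i,comm_j character vectors of member genes; must be disjoint
#'   and non-empty.
#' @param null \code{"global_density"} (default) or \code{"configuration"}.
#' @return A non-negative number.
#' @export
interaction_strength <- function(net, comm_i, comm_j,
                                 null = c("global_density", "configuration")) {
  null <- match.arg(null)
  comm_i <- unique(as.character(comm_i))
  comm_j <- unique(as.character(comm_j))
  if (!length(comm_i) || !length(comm_j)) {
    stop("communities must be non-empty", call. = FALSE)
  }
  if (length(intersect(comm_i, comm_j))) {
    stop("communities overlap: ", intersect(comm_i, comm_j)[1L], call. = FALSE)
  }
  edges <- if (inherits(net, "interactome")) {
    net$edges[, c("gene_a", "gene_b")]
  } else {
    el <- igraph::as_edgelist(net)
    data.frame(gene_a = el[, 1], gene_b = el[, 2], stringsAsFactors = FALSE)
  }
  N <- if (inherits(net, "interactome")) length(net$nodes) else igraph::vcount(net)
  E <- nrow(edges)
  obs <- sum((edges$gene_a %in% comm_i & edges$gene_b %in% comm_j) |
             (edges$gene_a %in% comm_j & edges$gene_b %in% comm_i))
  if (obs == 0L) return(0)
  expected <- if (null == "global_density") {
    rho <- 2 * E / (N * (N - 1))
    length(comm_i) * length(comm_j) * rho
  } else {
    deg <- table(c(edges$gene_a, edges$gene_b))
    di <- sum(deg[names(deg) %in% comm_i])
    dj <- sum(deg[names(deg) %in% comm_j])
    di * dj / (2 * E)
  }
  obs / expected
}

#' Build the community-wise network
#'
#' Nodes are communities; an edge joins two communities exactly when at
#' least one gene-wise edge runs between them, annotated with the raw
#' inter-edge count and the Interaction Strength. All communities are
#' reported as nodes; only those with at least \code{min_size} genes enter
#' super-community detection downstream.
#'
#' @param net the gene-wise \code{interactome}.
#' @param communities an \code{mcode_communities} object or named list.
#' @param min_size minimum community size for super-community detection
#'   (default 5).
#' @param null null model passed to \code{\link{interaction_strength}}.
#' @return Object of class \code{community_graph}: list with \code{nodes}
#'   (data frame \code{community_id}, \code{size}), \code{edges} (data
#'   frame \code{comm_i}, \code{comm_j}, \code{inter_edges}, \code{IS}),
#'   \code{global_density} and \code{min_size}.
#' @export
build_community_graph <- function(net, communities, min_size = 5,
                                  null = c("global_density", "configuration")) {
  null <- match.arg(null)
  comm <- communities_as_sets(communities)
  all_members <- unlist(comm, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    stop("communities overlap: ", all_members[duplicated(all_members)][1L],
         call. = FALSE)
  }
  edges <- net$edges
  N <- length(net$nodes)
  E <- nrow(edges)
  rho <- 2 * E / (N * (N - 1))
  sizes <- vapply(comm, length, integer(1))
  memb <- stats::setNames(rep(names(comm), sizes), all_members)
  ca <- memb[edges$gene_a]
  cb <- memb[edges$gene_b]
  between <- !is.na(ca) & !is.na(cb) & ca != cb
  if (any(between)) {
    lo <- pmin(ca[between], cb[between])
    hi <- pmax(ca[between], cb[between])
    cnt <- table(paste(lo, hi, sep = "\r"))
    parts <- strsplit(names(cnt), "\r", fixed = TRUE)
    comm_i <- vapply(parts, `[[`, character(1), 1L)
    comm_j <- vapply(parts, `[[`, character(1), 2L)
    inter <- as.integer(cnt)
    expected <- if (null == "global_density") {
      sizes[comm_i] * sizes[comm_j] * rho
    } else {
      deg <- table(c(edges$gene_a, edges$gene_b))
      dsum <- vapply(comm, function(m) sum(deg[names(deg) %in% m]), numeric(1))
      dsum[comm_i] * dsum[comm_j] / (2 * E)
    }
    edf <- data.frame(comm_i = comm_i, comm_j = comm_j,
                      inter_edges = inter, IS = inter / expected,
                      stringsAsFactors = FALSE)
    edf <- edf[order(edf$comm_i, edf$comm_j), , drop = FALSE]
    rownames(edf) <- NULL
  } else {
    edf <- data.frame(comm_i = character(0), comm_j = character(0),
                      inter_edges = integer(0), IS = numeric(0))
  }
  structure(list(nodes = data.frame(community_id = names(comm),
                                    size = unname(sizes),
                                    stringsAsFactors = FALSE),
                 edges = edf, global_density = rho, min_size = min_size),
            class = "community_graph")
}

#' @export
print.community_graph <- function(x, ...) {
  cat("Community-wise network:", nrow(x$nodes), "communities,",
      nrow(x$edges), "interactions (IS > 0)\n")
  invisible(x)
}

#' Detect super-communities
#'
#' Re-applies MCODE to the unweighted topology of the community-wise
#' network, restricted to communities with at least \code{min_size} genes;
#' IS magnitudes are ignored (an edge exists iff IS > 0).
#'
#' @param cg a \code{community_graph}.
#' @param params \code{\link{mcode_params}} (same defaults as the gene-wise
#'   stage).
#' @param min_size minimum member-community size; defaults to the value
#'   stored in \code{cg}.
#' @return data frame (\code{supercommunity_id}, \code{community_id},
#'   \code{n_genes}), empty when no super-community exists.
#' @export
detect_supercommunities <- function(cg, params = mcode_params(),
                                    min_size = cg$min_size) {
  stopifnot(inherits(cg, "community_graph"))
  keep <- cg$nodes$community_id[cg$nodes$size >= min_size]
  edges <- cg$edges[cg$edges$comm_i %in% keep & cg$edges$comm_j %in% keep, ,
                    drop = FALSE]
  # zero-padded labels keep lexicographic tie-breaking aligned with ids
  pad <- function(id) sprintf("c%06d", as.integer(id))
  g <- igraph::graph_from_data_frame(
    data.frame(from = pad(edges$comm_i), to = pad(edges$comm_j)),
    directed = FALSE, vertices = data.frame(name = sort(pad(keep))))
  scs <- mcode(g, params)
  if (!length(scs)) {
    return(data.frame(supercommunity_id = integer(0),
                      community_id = character(0), n_genes = integer(0)))
  }
  size_of <- stats::setNames(cg$nodes$size, pad(cg$nodes$community_id))
  unpad <- stats::setNames(cg$nodes$community_id, pad(cg$nodes$community_id))
  do.call(rbind, lapply(scs, function(z) {
    data.frame(supercommunity_id = z$id,
               community_id = unname(unpad[z$members]),
               n_genes = unname(size_of[z$members]),
               stringsAsFactors = FALSE)
  }))
}
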
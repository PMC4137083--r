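#' MCODE parameters
#'
#' Defaults follow the clusterMaker implementation of MCODE: degree cutoff 2,
#' node score cutoff 0.2, 2-core filter, maximum search depth 100, haircut
#' on, fluff off.
#'
#' @param include_loops count self-loops in the vertex-weight density
#'   (default \code{FALSE}).
#' @param degree_cutoff minimum degree for a vertex to receive a nonzero
#'   weight (default 2).
#' @param node_score_cutoff expansion threshold as a fractional deviation
#'   from the seed weight, in \[0, 1\] (default 0.2): a neighbor joins a
#'   growing complex when its weight is at least
#'   \code{seed_weight * (1 - node_score_cutoff)}.
#' @param k_core discard complexes not containing a k-core (default 2).
#' @param max_depth maximum breadth-first expansion depth from the seed
#'   (default 100).
#' @param haircut iteratively remove degree-1 vertices from each complex
#'   (default \code{TRUE}).
#' @param fluff add boundary neighbors whose closed-neighborhood density
#'   exceeds \code{fluff_cutoff} (default \code{FALSE}); fluffed vertices
#'   may be shared between complexes.
#' @param fluff_cutoff density threshold for fluff, in \[0, 1\].
#' @return A list of class \code{mcode_params}.
#' @export
mcode_params <- function(include_loops = FALSE, degree_cutoff = 2,
                         node_score_cutoff = 0.2, k_core = 2,
                         max_depth = 100, haircut = TRUE,
                         fluff = FALSE, fluff_cutoff = 0.2) {
  p <- list(include_loops = isTRUE(include_loops),
            degree_cutoff = as.integer(degree_cutoff),
            node_score_cutoff = node_score_cutoff,
            k_core = as.integer(k_core),
            max_depth = as.integer(max_depth),
            haircut = isTRUE(haircut),
            fluff = isTRUE(fluff),
            fluff_cutoff = fluff_cutoff)
  if (p$degree_cutoff < 0 || p$k_core < 0 || p$max_depth < 0) {
    stop("MCODE numeric parameters must be non-negative", call. = FALSE)
  }
  if (p$node_score_cutoff < 0 || p$node_score_cutoff > 1) {
    stop("'node_score_cutoff' must be in [0, 1]", call. = FALSE)
  }
  if (p$fluff_cutoff < 0 || p$fluff_cutoff > 1) {
    stop("'fluff_cutoff' must be in [0, 1]", call. = FALSE)
  }
  structure(p, class = "mcode_params")
}

as_mcode_graph <- function(x, include_loops = FALSE) {
  g <- if (inherits(x, "interactome")) interactome_graph(x) else x
  stopifnot(inherits(g, "igraph"))
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- sprintf("v%05d", seq_len(igraph::vcount(g)))
  }
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = !include_loops)
}

## density of an igraph subgraph; loops counted only when include_loops
subgraph_density <- function(sub, include_loops = FALSE) {
  n <- igraph::vcount(sub)
  if (n < 2L) return(0)
  el <- igraph::as_edgelist(sub, names = FALSE)
  loops <- sum(el[, 1] == el[, 2])
  plain <- nrow(el) - loops
  denom <- n * (n - 1) / 2 + if (include_loops) n else 0
  (plain + if (include_loops) loops else 0) / denom
}

#' MCODE vertex weights (core-clustering coefficient)
#'
#' The weight of a vertex is \code{k * density} of the highest k-core of its
#' closed neighborhood, where \code{k} is that core's order. Vertices whose
#' degree falls below \code{degree_cutoff} get weight 0.
#'
#' @param net an \code{interactome} or igraph graph.
#' @param params an \code{\link{mcode_params}} object.
#' @return Named numeric vector of vertex weights.
#' @export
mcode_vertex_weights <- function(net, params = mcode_params()) {
  g <- as_mcode_graph(net, params$include_loops)
  gs <- igraph::simplify(g)           # loop-free view for degrees and cores
  n <- igraph::vcount(gs)
  w <- stats::setNames(numeric(n), igraph::V(gs)$name)
  deg <- igraph::degree(gs)
  adj <- igraph::adjacent_vertices(gs, igraph::V(gs))
  for (i in seq_len(n)) {
    if (deg[i] < params$degree_cutoff) next
    nb <- c(i, as.integer(adj[[i]]))
    sub <- igraph::induced_subgraph(gs, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax < 1L) next
    core_sub <- igraph::induced_subgraph(sub, which(core == kmax))
    if (params$include_loops) {
      core_full <- igraph::induced_subgraph(
        as_mcode_graph(g, TRUE),
        match(igraph::V(core_sub)$name, igraph::V(g)$name))
      dens <- subgraph_density(core_full, TRUE)
    } else {
      dens <- subgraph_density(core_sub, FALSE)
    }
    w[i] <- kmax * dens
  }
  w
}

#' Predict raw MCODE complexes by seeded greedy expansion
#'
#' Seeds are visited in decreasing weight order (ties broken by gene id).
#' From an unassigned seed, a breadth-first expansion includes unassigned
#' neighbors whose weight is at least
#' \code{seed_weight * (1 - node_score_cutoff)}, up to \code{max_depth}
#' levels. Each vertex is assigned to at most one complex.
#'
#' @param net an \code{interactome} or igraph graph.
#' @param weights vertex weights from \code{\link{mcode_vertex_weights}}.
#' @param params an \code{\link{mcode_params}} object.
#' @return List of raw complexes, each a list with \code{seed} and sorted
#'   \code{members}.
#' @export
mcode_predict_complexes <- function(net, weights, params = mcode_params()) {
  g <- as_mcode_graph(net, FALSE)
  nms <- igraph::V(g)$name
  w <- weights[nms]
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  order_idx <- order(-w, nms)
  assigned <- logical(length(nms))
  complexes <- list()
  for (s in order_idx) {
    if (assigned[s]) next
    threshold <- w[s] * (1 - params$node_score_cutoff)
    assigned[s] <- TRUE
    members <- s
    frontier <- s
    depth <- 0L
    while (length(frontier) && depth < params$max_depth) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in as.integer(adj[[v]])) {
          if (!assigned[u] && w[u] >= threshold) {
            assigned[u] <- TRUE
            nxt <- c(nxt, u)
          }
        }
      }
      members <- c(members, nxt)
      frontier <- nxt
      depth <- depth + 1L
    }
    complexes[[length(complexes) + 1L]] <-
      list(seed = nms[s], members = sort(nms[members]))
  }
  complexes
}

#' Post-process raw complexes into scored communities
#'
#' Complexes lacking a \code{k_core}-core are discarded; haircut iteratively
#' strips degree-1 vertices of the complex subgraph; fluff optionally adds
#' dense boundary neighbors (which may be shared). The complex score is
#' density times size of the final subgraph, and communities are renumbered
#' by descending score.
#'
#' @param complexes raw complexes from \code{\link{mcode_predict_complexes}}.
#' @param net the graph the complexes were predicted on.
#' @param params an \code{\link{mcode_params}} object.
#' @return Object of class \code{mcode_communities}: list of communities,
#'   each with \code{id}, \code{members}, \code{score}, \code{seed}.
#' @export
mcode_postprocess <- function(complexes, net, params = mcode_params()) {
  g <- as_mcode_graph(net, FALSE)
  nms <- igraph::V(g)$name
  out <- list()
  for (cx in complexes) {
    members <- cx$members
    if (length(members) < 2L) next
    sub <- igraph::induced_subgraph(g, match(members, nms))
    if (params$k_core > 0L) {
      if (max(igraph::coreness(sub)) < params$k_core) next
    }
    if (params$haircut) {
      keep <- igraph::coreness(sub) >= 2L
      if (sum(keep) < 2L) next
      sub <- igraph::induced_subgraph(sub, which(keep))
      members <- igraph::V(sub)$name
    }
    if (params$fluff) {
      idx <- match(members, nms)
      boundary <- setdiff(unique(unlist(
        igraph::adjacent_vertices(g, idx))), idx)
      add <- character(0)
      for (b in boundary) {
        nb <- c(b, as.integer(igraph::adjacent_vertices(g, b)[[1]]))
        dens <- subgraph_density(igraph::induced_subgraph(g, nb))
        if (dens > params$fluff_cutoff) add <- c(add, nms[b])
      }
      members <- sort(unique(c(members, add)))
      sub <- igraph::induced_subgraph(g, match(members, nms))
    }
    if (length(members) < 2L) next
    score <- subgraph_density(sub) * length(members)
    out[[length(out) + 1L]] <- list(members = sort(members), score = score,
                                    seed = cx$seed)
  }
  if (length(out)) {
    sizes <- vapply(out, function(z) length(z$members), integer(1))
    first <- vapply(out, function(z) z$members[1L], character(1))
    scores <- vapply(out, function(z) z$score, numeric(1))
    ord <- order(-scores, -sizes, first)
    out <- out[ord]
    for (i in seq_along(out)) out[[i]]$id <- i
    out <- lapply(out, function(z) z[c("id", "members", "score", "seed")])
  }
  structure(out, class = "mcode_communities")
}

#' Detect densely connected communities with MCODE
#'
#' From-scratch implementation of the Molecular Complex Detection algorithm:
#' core-clustering-coefficient vertex weighting, seeded greedy expansion and
#' haircut/fluff post-processing. Edge weights are ignored (the algorithm is
#' topological); ties in seed order and expansion are broken
#' lexicographically by gene id, so results are independent of input row
#' order.
#'
#' @param net an \code{interactome} or igraph graph.
#' @param params an \code{\link{mcode_params}} object.
#' @return An \code{mcode_communities} object (see
#'   \code{\link{mcode_postprocess}}).
#' @export
mcode <- function(net, params = mcode_params()) {
  w <- mcode_vertex_weights(net, params)
  raw <- mcode_predict_complexes(net, w, params)
  mcode_postprocess(raw, net, params)
}

#' @export
print.mcode_communities <- function(x, ...) {
  sizes <- vapply(x, function(z) length(z$members), integer(1))
  cat("MCODE communities:", length(x), "\n")
  if (length(x)) {
    cat(sprintf("  sizes: min %d, median %s, max %d; mean %.1f\n",
                min(sizes), format(stats::median(sizes)), max(sizes),
                mean(sizes)))
  }
  invisible(x)
}

#' Community membership as a data frame
#'
#' @param communities an \code{mcode_communities} object.
#' @return data frame (\code{gene}, \code{community_id},
#'   \code{complex_score}).
#' @export
community_membership <- function(communities) {
  if (!length(communities)) {
    return(data.frame(gene = character(0), community_id = integer(0),
                      complex_score = numeric(0)))
  }
  do.call(rbind, lapply(communities, function(z) {
    data.frame(gene = z$members, community_id = z$id,
               complex_score = z$score, stringsAsFactors = FALSE)
  }))
}

#' Community summary table
#'
#' @param communities an \code{mcode_communities} object.
#' @return data frame (\code{community_id}, \code{size}, \code{score},
#'   \code{seed_gene}).
#' @export
community_summary <- function(communities) {
  if (!length(communities)) {
    return(data.frame(community_id = integer(0), size = integer(0),
                      score = numeric(0), seed_gene = character(0)))
  }
  do.call(rbind, lapply(communities, function(z) {
    data.frame(community_id = z$id, size = length(z$members),
               score = z$score, seed_gene = z$seed, stringsAsFactors = FALSE)
  }))
}

## named list gene-set view of communities, used by enrichment
communities_as_sets <- function(communities) {
  if (inherits(communities, "mcode_communities")) {
    sets <- lapply(communities, `[[`, "members")
    names(sets) <- vapply(communities, function(z) as.character(z$id),
                          character(1))
    sets
  } else if (is.list(communities)) {
    if (is.null(names(communities))) {
      names(communities) <- as.character(seq_along(communities))
    }
    lapply(communities, as.character)
  } else {
    stop("'communities' must be an mcode_communities object or a named list",
         call. = FALSE)
  }
}
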
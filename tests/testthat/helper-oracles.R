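## Independent oracles and small fixture builders used across the suite.

## Brute-force MCODE vertex weight: enumerate every subset of the closed
## neighborhood to find the highest k-core, independent of igraph::coreness.
brute_vertex_weight <- function(A, v, degree_cutoff = 2) {
  deg <- rowSums(A)
  if (deg[v] < degree_cutoff) return(0)
  nb <- c(v, which(A[v, ] > 0))
  An <- A[nb, nb, drop = FALSE]
  ns <- length(nb)
  bits <- 2^(0:(ns - 1))
  best_k <- 0L
  for (mask in 1:(2^ns - 1)) {
    S <- which(bitwAnd(mask, bits) > 0)
    if (length(S) < 2) next
    k <- min(rowSums(An[S, S, drop = FALSE]))
    if (k > best_k) best_k <- k
  }
  if (best_k < 1) return(0)
  core <- logical(ns)
  for (mask in 1:(2^ns - 1)) {
    S <- which(bitwAnd(mask, bits) > 0)
    if (length(S) < 2) next
    if (min(rowSums(An[S, S, drop = FALSE])) >= best_k) core[S] <- TRUE
  }
  nc <- sum(core)
  best_k * (sum(An[core, core]) / 2) / (nc * (nc - 1) / 2)
}

## Hypergeometric upper tail by direct enumeration of the probability terms
## with exact binomial coefficients (no distribution function involved).
## Returns P(X >= k) for all k = 0..n at fixed (N, K, n).
hyper_tail_enum <- function(N, K, n) {
  j <- 0:n
  terms <- choose(K, j) * choose(N - K, n - j) / choose(N, n)
  rev(cumsum(rev(terms)))
}

## Literal transcription of the three voting-rule sentences.
literal_vote <- function(A, B) {
  if (A > B + 1) return("ciliary")
  if (B > A + 1) return("centrosomal")
  if (abs(A - B) <= 1) return("unknown")
  stop("unreachable")
}

## Interactome fixture from a plain edge data frame.
make_net <- function(edges, nodes = NULL) {
  a <- pmin(edges[[1]], edges[[2]])
  b <- pmax(edges[[1]], edges[[2]])
  if (is.null(nodes)) nodes <- sort(unique(c(a, b)))
  structure(list(nodes = sort(nodes),
                 edges = data.frame(gene_a = a, gene_b = b,
                                    score = if (ncol(edges) >= 3) edges[[3]] else 1,
                                    stringsAsFactors = FALSE),
                 singletons_removed = character(0)),
            class = "interactome")
}

## Named igraph on letter-style vertex ids.
lgraph <- function(edge_vec, n = NULL) {
  g <- igraph::make_graph(edge_vec, directed = FALSE)
  if (!is.null(n)) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::V(g)$name <- sprintf("v%02d", seq_len(igraph::vcount(g)))
  g
}

## Adjusted Rand index between a predicted community membership and the
## planted partition over the given genes; unassigned / background genes get
## unique singleton labels on each side.
partition_ari <- function(genes, membership_df, truth_partition) {
  pred <- membership_df$community_id[match(genes, membership_df$gene)]
  pred[is.na(pred)] <- -seq_len(sum(is.na(pred)))
  truth <- truth_partition[genes]
  truth[is.na(truth)] <- -1e6 - seq_len(sum(is.na(truth)))
  mclust::adjustedRandIndex(pred, truth)
}

## One synthetic run pushed through evidence integration + MCODE.
sim_to_communities <- function(seed, ...) {
  cfg <- sim_config(seed = seed, ...)
  u <- generate_universe(cfg)
  ev <- combine_evidence(generate_evidence(u$universe, u$truth, cfg))
  net <- remove_singletons(build_interactome(ev, 0.7, u$universe$gene))
  list(cfg = cfg, universe = u$universe, truth = u$truth, net = net,
       communities = mcode(net))
}
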
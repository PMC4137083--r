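#' One-sided Fisher (hypergeometric upper-tail) p-value
#'
#' Probability of observing at least \code{k} genes from a set of size
#' \code{K} in a draw of \code{n} genes from a background of \code{N},
#' i.e. \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, n). Exact;
#' vectorized over its arguments.
#'
#' @param k overlap count.
#' @param n community (draw) size.
#' @param K gene-set size within the background.
#' @param N background size.
#' @return p-value(s) in (0, 1\].
#' @examples
#' fisher_one_sided(17, 65, 76, 1695)  # well below 0.01
#' @export
fisher_one_sided <- function(k, n, K, N) {
  bad <- is.na(k) | is.na(n) | is.na(K) | is.na(N) |
    k < 0 | n < 0 | K < 0 | N < 0 | k > pmin(n, K) | n > N | K > N
  if (any(bad)) {
    stop("inconsistent 2x2 counts: need 0 <= k <= min(n, K) and n, K <= N",
         call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Standard BH false-discovery-rate adjustment; input order is preserved.
#'
#' @param p vector of p-values in (0, 1\].
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Gene-set enrichment of communities against a set collection
#'
#' One one-sided Fisher test per (community, gene set) pair, with sets first
#' intersected with the background and BH correction applied across the
#' whole family of tests (one family per collection per run, matching a
#' per-analysis FDR of 0.05). Communities smaller than
#' \code{min_community_size} are not tested.
#'
#' @param communities an \code{mcode_communities} object or named list of
#'   gene vectors.
#' @param sets named list of gene sets (e.g. from \code{\link{read_gmt}}).
#' @param background character vector of background genes (the network
#'   genes); every community member must belong to it.
#' @param min_community_size smallest community tested (default 5).
#' @param min_overlap minimum overlap \code{k} required, in addition to
#'   \code{q < alpha}, for the \code{significant} flag (default 0; TF-target
#'   tests use 5).
#' @param alpha FDR significance level (default 0.05).
#' @return data frame of class \code{enrichment_result} with columns
#'   \code{community_id}, \code{set_id}, \code{k}, \code{n}, \code{K},
#'   \code{N}, \code{p_value}, \code{q_value}, \code{significant}.
#' @export
enrich_communities <- function(communities, sets, background,
                               min_community_size = 5, min_overlap = 0,
                               alpha = 0.05) {
  comm <- communities_as_sets(communities)
  background <- unique(as.character(background))
  if (length(background) == 0L) stop("background is empty", call. = FALSE)
  for (id in names(comm)) {
    out <- setdiff(comm[[id]], background)
    if (length(out)) {
      stop("community ", id, " contains gene(s) outside the background: ",
           out[1L], call. = FALSE)
    }
  }
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("'sets' must be a named list", call. = FALSE)
  }
  sets_bg <- lapply(sets, function(s) intersect(unique(as.character(s)), background))
  empty <- vapply(sets_bg, length, integer(1)) == 0L
  if (any(empty)) {
    warning("skipping ", sum(empty),
            " gene set(s) disjoint from the background: ",
            paste(utils::head(names(sets_bg)[empty], 3L), collapse = ", "),
            call. = FALSE)
    sets_bg <- sets_bg[!empty]
  }
  comm <- comm[vapply(comm, length, integer(1)) >= min_community_size]
  N <- length(background)
  rows <- vector("list", length(comm) * length(sets_bg))
  i <- 0L
  for (cid in names(comm)) {
    members <- comm[[cid]]
    n <- length(members)
    for (sid in names(sets_bg)) {
      s <- sets_bg[[sid]]
      i <- i + 1L
      rows[[i]] <- data.frame(
        community_id = cid, set_id = sid,
        k = length(intersect(members, s)), n = n, K = length(s), N = N,
        stringsAsFactors = FALSE)
    }
  }
  if (i == 0L) {
    res <- data.frame(community_id = character(0), set_id = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p_value = numeric(0),
                      q_value = numeric(0), significant = logical(0))
    class(res) <- c("enrichment_result", class(res))
    return(res)
  }
  res <- do.call(rbind, rows[seq_len(i)])
  res$p_value <- fisher_one_sided(res$k, res$n, res$K, res$N)
  res$q_value <- bh_fdr(res$p_value)
  res$significant <- res$q_value < alpha & res$k >= min_overlap
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", class(res))
  res
}
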
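#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions for a fully synthetic run of the pipeline:
#' a gene universe with planted dense communities, multi-channel interaction
#' evidence, per-experiment localization flags, GO-like annotations with
#' planted enrichments, and TF regulons with binding sites and correlated
#' expression. A single RNG stream is seeded once by
#' \code{\link{generate_universe}}; the generators draw from it in the
#' documented order universe, evidence, experiments, annotations, TF data,
#' curated sets, so identical configurations produce byte-identical outputs.
#'
#' @param n_genes number of genes in the universe (default 300).
#' @param community_sizes sizes of the disjoint planted blocks
#'   (default \code{c(8, 10, 12, 15)}).
#' @param p_intra probability an intra-block pair carries (high-score)
#'   evidence (default 0.9).
#' @param p_inter probability for between-block and background pairs
#'   (default 0.01).
#' @param n_channels evidence channels (default 4).
#' @param channel_noise_sd Gaussian noise added to channel scores before
#'   clipping to \[0, 1\] (default 0.05).
#' @param n_terms GO-like terms, at least one per planted block
#'   (default 30).
#' @param n_ciliary_exp ciliary-group experiments (default 10).
#' @param n_centrosomal_exp centrosomal-group experiments (default 7).
#' @param flip_prob probability an experiment flag is flipped (default
#'   0.05).
#' @param n_tfs transcription factors with planted regulons; at most one per
#'   planted block so regulons stay disjoint (default: the number of blocks,
#'   capped at 4).
#' @param n_conditions expression conditions (default 30).
#' @param expr_noise_sd noise sd around the TF latent profile for true
#'   targets (default 0.5; expected target-TF correlation
#'   \eqn{1/\sqrt{1 + sd^2}}).
#' @param p_spurious_site probability a non-target gene receives an
#'   in-window binding site for a random TF (default 0.02), so the
#'   co-expression filter has false candidates to reject.
#' @param seed integer RNG seed.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 300, community_sizes = c(8, 10, 12, 15),
                       p_intra = 0.9, p_inter = 0.01, n_channels = 4,
                       channel_noise_sd = 0.05, n_terms = 30,
                       n_ciliary_exp = 10, n_centrosomal_exp = 7,
                       flip_prob = 0.05, n_tfs = NULL, n_conditions = 30,
                       expr_noise_sd = 0.5, p_spurious_site = 0.02,
                       seed = 1) {
  if (is.null(n_tfs)) n_tfs <- min(4L, length(community_sizes))
  cfg <- list(n_genes = as.integer(n_genes),
              community_sizes = as.integer(community_sizes),
              p_intra = p_intra, p_inter = p_inter,
              n_channels = as.integer(n_channels),
              channel_noise_sd = channel_noise_sd,
              n_terms = as.integer(n_terms),
              n_ciliary_exp = as.integer(n_ciliary_exp),
              n_centrosomal_exp = as.integer(n_centrosomal_exp),
              flip_prob = flip_prob, n_tfs = as.integer(n_tfs),
              n_conditions = as.integer(n_conditions),
              expr_noise_sd = expr_noise_sd,
              p_spurious_site = p_spurious_site,
              seed = as.integer(seed))
  fail <- function(field, why) {
    stop("invalid sim_config field '", field, "': ", why, call. = FALSE)
  }
  if (cfg$n_genes < 1) fail("n_genes", "must be a positive count")
  if (any(cfg$community_sizes < 1)) {
    fail("community_sizes", "must be positive counts")
  }
  if (sum(cfg$community_sizes) > cfg$n_genes) {
    fail("community_sizes", "sum exceeds n_genes")
  }
  for (f in c("p_intra", "p_inter", "flip_prob", "p_spurious_site")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) fail(f, "must be a probability in [0, 1]")
  }
  if (cfg$channel_noise_sd < 0) fail("channel_noise_sd", "must be non-negative")
  if (cfg$expr_noise_sd < 0) fail("expr_noise_sd", "must be non-negative")
  for (f in c("n_channels", "n_terms", "n_ciliary_exp", "n_centrosomal_exp",
              "n_tfs", "n_conditions")) {
    if (cfg[[f]] < 1) fail(f, "must be a positive count")
  }
  if (cfg$n_terms < length(cfg$community_sizes)) {
    fail("n_terms", "need at least one term per planted block")
  }
  if (cfg$n_tfs > length(cfg$community_sizes)) {
    fail("n_tfs", "at most one TF per planted block (regulons must be disjoint)")
  }
  if (is.na(cfg$seed)) fail("seed", "must be an integer")
  structure(cfg, class = "sim_config")
}

#' Generate the synthetic gene universe and ground truth
#'
#' Seeds the global RNG stream with \code{cfg$seed} and creates
#' \code{n_genes} genes with stable lexicographic ids (\code{g0001}, ...),
#' planted block assignments, true localizations (blocks alternate ciliary /
#' centrosomal; background genes are ciliary, centrosomal or neither at
#' 0.3/0.3/0.4), planted TF regulons (each TF, itself a background gene,
#' truly regulates one planted block plus two background genes) and the
#' planted (block, term) enrichment pairs.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return List with \code{universe} (data frame \code{gene}, \code{block},
#'   \code{localization}) and \code{truth} (list: \code{partition},
#'   \code{localization}, \code{regulons}, \code{enriched_terms},
#'   \code{tf_genes}).
#' @export
generate_universe <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  width <- max(4L, nchar(as.character(cfg$n_genes)))
  genes <- sprintf(paste0("g%0", width, "d"), seq_len(cfg$n_genes))
  nb <- length(cfg$community_sizes)
  block <- rep(NA_integer_, cfg$n_genes)
  in_blocks <- sample(cfg$n_genes, sum(cfg$community_sizes))
  block[in_blocks] <- rep(seq_len(nb), cfg$community_sizes)
  loc <- rep(NA_character_, cfg$n_genes)
  block_loc <- rep(c("ciliary", "centrosomal"), length.out = nb)
  loc[!is.na(block)] <- block_loc[block[!is.na(block)]]
  bg <- which(is.na(block))
  loc[bg] <- sample(c("ciliary", "centrosomal", "background"),
                    length(bg), replace = TRUE, prob = c(0.3, 0.3, 0.4))
  if (length(bg) < cfg$n_tfs) {
    stop("invalid sim_config field 'n_tfs': more TFs than background genes",
         call. = FALSE)
  }
  tf_genes <- sort(genes[sample(bg, cfg$n_tfs)])
  regulons <- list()
  used_extra <- character(0)
  for (j in seq_len(cfg$n_tfs)) {
    b <- j  # one planted block per TF keeps regulons disjoint
    pool <- setdiff(genes[bg], c(tf_genes, used_extra))
    extra <- sample(pool, min(2L, length(pool)))
    used_extra <- c(used_extra, extra)
    regulons[[tf_genes[j]]] <- sort(c(genes[which(block == b)], extra))
  }
  enriched_terms <- data.frame(block = seq_len(nb),
                               term = sprintf("T%03d", seq_len(nb)),
                               stringsAsFactors = FALSE)
  universe <- data.frame(gene = genes, block = block, localization = loc,
                         stringsAsFactors = FALSE)
  truth <- list(partition = stats::setNames(block, genes),
                localization = stats::setNames(loc, genes),
                regulons = regulons,
                enriched_terms = enriched_terms,
                tf_genes = tf_genes)
  list(universe = universe, truth = truth)
}

#' Generate multi-channel interaction evidence with planted communities
#'
#' Every intra-block gene pair carries evidence with probability
#' \code{p_intra}, drawing its channel scores from Beta(8, 2) (mean 0.8) and
#' guaranteeing a pre-noise combined score of at least 0.7; all other pairs
#' carry evidence with probability \code{p_inter}, drawing channel scores
#' from Beta(2, 8) (mean 0.2), so the 0.7 cutoff sees scores on both sides.
#' Gaussian noise (\code{channel_noise_sd}) is then added and scores are
#' clipped to \[0, 1\]. Pairs are canonical (gene_a < gene_b), unique, never
#' self-pairs. Call directly after \code{\link{generate_universe}} (shared
#' RNG stream).
#'
#' @param universe,truth from \code{\link{generate_universe}}.
#' @param cfg the \code{\link{sim_config}}.
#' @return Evidence data frame: \code{gene_a}, \code{gene_b},
#'   \code{channel_01} ... \code{channel_k}.
#' @export
generate_evidence <- function(universe, truth, cfg) {
  genes <- universe$gene
  n <- length(genes)
  ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- sequence((n - 1L):1L) + ii
  blk <- universe$block
  intra <- !is.na(blk[ii]) & !is.na(blk[jj]) & blk[ii] == blk[jj]
  # draw order: presence (intra then inter), intra scores, inter scores, noise
  present <- logical(length(ii))
  present[intra] <- stats::runif(sum(intra)) < cfg$p_intra
  present[!intra] <- stats::runif(sum(!intra)) < cfg$p_inter
  ki <- which(present & intra)
  kb <- which(present & !intra)
  k <- cfg$n_channels
  sc_i <- matrix(stats::rbeta(length(ki) * k, 8, 2), ncol = k)
  if (length(ki)) {
    # guarantee planted pairs clear the cutoff before noise
    comb <- combine_score_matrix(sc_i)
    low <- comb < 0.72
    sc_i[low, 1L] <- pmax(sc_i[low, 1L], 0.75)
  }
  sc_b <- matrix(stats::rbeta(length(kb) * k, 2, 8), ncol = k)
  scores <- rbind(sc_i, sc_b)[order(c(ki, kb)), , drop = FALSE]
  if (cfg$channel_noise_sd > 0) {
    scores <- scores + stats::rnorm(length(scores), sd = cfg$channel_noise_sd)
    scores[scores < 0] <- 0
    scores[scores > 1] <- 1
  }
  keep <- sort(c(ki, kb))
  ev <- data.frame(gene_a = genes[ii[keep]], gene_b = genes[jj[keep]],
                   stringsAsFactors = FALSE)
  colnames(scores) <- sprintf("channel_%02d", seq_len(k))
  cbind(ev, as.data.frame(scores))
}

#' Generate per-experiment localization flags
#'
#' Binary matrix of genes by experiments: a truly ciliary gene is flagged in
#' each ciliary-group experiment with probability \code{1 - flip_prob} and
#' in each centrosomal-group experiment with probability \code{flip_prob}
#' (symmetric for centrosomal genes); background genes are flagged with
#' probability \code{flip_prob} everywhere.
#'
#' @param universe,truth from \code{\link{generate_universe}}.
#' @param cfg the \code{\link{sim_config}}.
#' @return data frame: \code{gene}, \code{cil_01..}, \code{cen_01..}
#'   with 0/1 entries.
#' @export
generate_localization_experiments <- function(universe, truth, cfg) {
  n <- nrow(universe)
  loc <- universe$localization
  p_flag <- function(group) {
    # probability of a positive flag in an experiment of `group`
    ifelse(loc == group, 1 - cfg$flip_prob, cfg$flip_prob)
  }
  draw <- function(p, m) {
    matrix(as.integer(stats::runif(n * m) < rep(p, m)), nrow = n)
  }
  cil <- draw(p_flag("ciliary"), cfg$n_ciliary_exp)
  cen <- draw(p_flag("centrosomal"), cfg$n_centrosomal_exp)
  colnames(cil) <- sprintf("cil_%02d", seq_len(cfg$n_ciliary_exp))
  colnames(cen) <- sprintf("cen_%02d", seq_len(cfg$n_centrosomal_exp))
  cbind(data.frame(gene = universe$gene, stringsAsFactors = FALSE),
        as.data.frame(cil), as.data.frame(cen))
}

#' Generate GO-like annotation sets with planted enrichments
#'
#' One term per planted block draws 75\% of the block plus 3 random outside
#' genes, which forces a one-sided Fisher p below 0.001 against the full
#' universe by construction; the remaining terms are uniform random sets of
#' 10-30 genes.
#'
#' @param universe,truth from \code{\link{generate_universe}}.
#' @param cfg the \code{\link{sim_config}}.
#' @return Named list of gene sets (names \code{T001}, ...), with a
#'   \code{description} attribute.
#' @export
generate_annotations <- function(universe, truth, cfg) {
  genes <- universe$gene
  nb <- length(cfg$community_sizes)
  sets <- vector("list", cfg$n_terms)
  names(sets) <- sprintf("T%03d", seq_len(cfg$n_terms))
  desc <- character(cfg$n_terms)
  for (b in seq_len(nb)) {
    members <- genes[which(universe$block == b)]
    core <- sample(members, ceiling(0.75 * length(members)))
    extra <- sample(setdiff(genes, members), 3L)
    sets[[b]] <- sort(c(core, extra))
    desc[b] <- sprintf("planted enrichment for block %d", b)
  }
  for (t in seq.int(nb + 1L, length.out = cfg$n_terms - nb)) {
    size <- sample(10:30, 1L)
    sets[[t]] <- sort(sample(genes, min(size, length(genes))))
    desc[t] <- "uniform background term"
  }
  attr(sets, "description") <- stats::setNames(desc, names(sets))
  sets
}

#' Generate gene models, TF binding sites and an expression matrix
#'
#' Gene models are non-overlapping stranded 10 kb intervals on a synthetic
#' chromosome separated by 30 kb gaps, so regulatory windows (10 kb
#' upstream, 3 kb downstream) never overlap. Each true regulon target gets
#' one binding site inside its gene body; decoy sites fall in gap centres,
#' outside every window; with probability \code{p_spurious_site} a
#' non-target gene gets an in-window site for a random TF. Expression ties
#' each true target to its TF's profile through a shared latent factor
#' (weight 1) plus Gaussian noise; all other genes are independent
#' standard-normal profiles.
#'
#' @param universe,truth from \code{\link{generate_universe}}.
#' @param cfg the \code{\link{sim_config}}.
#' @param n_decoys decoy sites outside all windows (default 50).
#' @return List with \code{models} and \code{sites} (\code{GRanges}) and
#'   \code{expression} (genes x conditions matrix).
#' @export
generate_tf_data <- function(universe, truth, cfg, n_decoys = 50) {
  genes <- universe$gene
  n <- length(genes)
  gene_len <- 10000L
  gap <- 30000L
  start0 <- 30000L + (seq_len(n) - 1L) * (gene_len + gap)  # 0-based
  models <- GenomicRanges::GRanges(
    seqnames = "chrS",
    ranges = IRanges::IRanges(start = start0 + 1L, width = gene_len),
    strand = rep(c("+", "-"), length.out = n))
  models$name <- genes
  # true-target sites inside the gene body
  site_tf <- character(0); site_start0 <- integer(0)
  for (tf in names(truth$regulons)) {
    tg <- match(truth$regulons[[tf]], genes)
    site_tf <- c(site_tf, rep(tf, length(tg)))
    site_start0 <- c(site_start0, start0[tg] + 100L)
  }
  # spurious in-window sites on non-target genes (exercises the filter)
  spur <- which(stats::runif(n) < cfg$p_spurious_site)
  for (i in spur) {
    tf <- sample(names(truth$regulons), 1L)
    if (genes[i] %in% truth$regulons[[tf]] || genes[i] == tf) next
    site_tf <- c(site_tf, tf)
    site_start0 <- c(site_start0, start0[i] + 200L)
  }
  # decoys in gap centres: >= 4 kb clear of any window on either side
  decoy_gene <- sample(n, min(n_decoys, n), replace = n_decoys > n)
  site_tf <- c(site_tf, sample(names(truth$regulons), length(decoy_gene),
                               replace = TRUE))
  site_start0 <- c(site_start0, start0[decoy_gene] + gene_len + 14990L)
  sites <- GenomicRanges::GRanges(
    seqnames = "chrS",
    ranges = IRanges::IRanges(start = site_start0 + 1L, width = 20L),
    strand = "*")
  sites$name <- site_tf
  # expression: latent TF profiles drawn first, then target noise, then rest
  m <- cfg$n_conditions
  expr <- matrix(NA_real_, nrow = n, ncol = m,
                 dimnames = list(genes, sprintf("cond_%02d", seq_len(m))))
  latent <- matrix(stats::rnorm(cfg$n_tfs * m), nrow = cfg$n_tfs,
                   dimnames = list(truth$tf_genes, NULL))
  for (tf in truth$tf_genes) {
    expr[tf, ] <- latent[tf, ]
    for (g in truth$regulons[[tf]]) {
      expr[g, ] <- latent[tf, ] + stats::rnorm(m, sd = cfg$expr_noise_sd)
    }
  }
  rest <- rownames(expr)[!stats::complete.cases(expr)]
  expr[rest, ] <- stats::rnorm(length(rest) * m)
  list(models = models, sites = sites, expression = expr)
}

#' Run the full synthetic-data generator
#'
#' Calls the individual generators in their documented fixed order on one
#' RNG stream seeded from the configuration, then draws the curated
#' localization sets (40\% of truly centrosomal genes as the centrosome
#' database, 40\% of truly ciliary genes as the GO-cilium set, 15\% of all
#' genes as nuclear).
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return List: \code{config}, \code{universe}, \code{truth},
#'   \code{evidence}, \code{experiments}, \code{annotations}, \code{tf}
#'   (models, sites, expression), \code{curated} (centrosome_db, go_cilium,
#'   nuclear).
#' @export
simulate_ccci <- function(cfg = sim_config()) {
  u <- generate_universe(cfg)
  evidence <- generate_evidence(u$universe, u$truth, cfg)
  experiments <- generate_localization_experiments(u$universe, u$truth, cfg)
  annotations <- generate_annotations(u$universe, u$truth, cfg)
  tf <- generate_tf_data(u$universe, u$truth, cfg)
  pick <- function(pool, frac) {
    if (!length(pool)) return(character(0))
    sort(sample(pool, max(1L, round(frac * length(pool)))))
  }
  curated <- list(
    centrosome_db = pick(u$universe$gene[u$universe$localization == "centrosomal"], 0.4),
    go_cilium = pick(u$universe$gene[u$universe$localization == "ciliary"], 0.4),
    nuclear = pick(u$universe$gene, 0.15))
  list(config = cfg, universe = u$universe, truth = u$truth,
       evidence = evidence, experiments = experiments,
       annotations = annotations, tf = tf, curated = curated)
}
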
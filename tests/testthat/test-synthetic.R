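test_that("configuration invariants are enforced with the offending field named", {
  expect_error(sim_config(n_genes = 10, community_sizes = c(8, 8)),
               "community_sizes")
  expect_error(sim_config(p_intra = 1.2), "p_intra")
  expect_error(sim_config(flip_prob = -0.1), "flip_prob")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(channel_noise_sd = -1), "channel_noise_sd")
  expect_error(sim_config(n_terms = 2, community_sizes = c(5, 5, 5)), "n_terms")
})

test_that("the universe has the configured counts and is seed-deterministic", {
  cfg <- sim_config(n_genes = 100, community_sizes = c(10, 10), seed = 1)
  u <- generate_universe(cfg)
  expect_equal(nrow(u$universe), 100L)
  expect_equal(sum(!is.na(u$universe$block)), 20L)
  expect_equal(u$universe$gene, sort(u$universe$gene))  # stable lexicographic ids
  u2 <- generate_universe(cfg)
  expect_identical(u$universe, u2$universe)
  expect_identical(u$truth, u2$truth)
})

test_that("identical configurations produce byte-identical files", {
  cfg <- sim_config(n_genes = 80, community_sizes = c(8, 8), seed = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(simulate_ccci(cfg), d1)
  write_simulation(simulate_ccci(cfg), d2)
  files <- list.files(d1)
  expect_true(length(files) >= 10)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("degenerate probabilities force exactly the intra-block pairs", {
  cfg <- sim_config(n_genes = 50, community_sizes = c(8, 10), p_intra = 1,
                    p_inter = 0, channel_noise_sd = 0, seed = 3)
  u <- generate_universe(cfg)
  ev <- generate_evidence(u$universe, u$truth, cfg)
  expect_equal(nrow(ev), choose(8, 2) + choose(10, 2))
  blk <- u$truth$partition
  expect_true(all(blk[ev$gene_a] == blk[ev$gene_b]))
  ev <- combine_evidence(ev)
  expect_true(all(ev$combined >= 0.7))
  expect_true(all(ev$gene_a < ev$gene_b))
  expect_equal(anyDuplicated(paste(ev$gene_a, ev$gene_b)), 0L)
})

test_that("scores stay in [0, 1] and intra-edge counts match the binomial expectation", {
  cfg <- sim_config(seed = 11)
  u <- generate_universe(cfg)
  ev <- generate_evidence(u$universe, u$truth, cfg)
  ch <- as.matrix(ev[grep("^channel", names(ev))])
  expect_true(all(ch >= 0 & ch <= 1))
  blk <- u$truth$partition
  intra_pairs <- sum(choose(cfg$community_sizes, 2))
  n_intra <- sum(!is.na(blk[ev$gene_a]) & !is.na(blk[ev$gene_b]) &
                 blk[ev$gene_a] == blk[ev$gene_b])
  expected <- cfg$p_intra * intra_pairs
  sd3 <- 3 * sqrt(intra_pairs * cfg$p_intra * (1 - cfg$p_intra))
  expect_lt(abs(n_intra - expected), sd3 + 1e-9)
})

test_that("experiment flags are binary and noiseless flags are clean", {
  cfg <- sim_config(n_genes = 60, community_sizes = c(8, 8), flip_prob = 0,
                    seed = 9)
  u <- generate_universe(cfg)
  invisible(generate_evidence(u$universe, u$truth, cfg))
  exps <- generate_localization_experiments(u$universe, u$truth, cfg)
  m <- as.matrix(exps[, -1])
  expect_true(all(m %in% c(0L, 1L)))
  cil <- u$universe$gene[u$truth$localization == "ciliary"]
  A <- rowSums(exps[match(cil, exps$gene), grep("^cil", names(exps))])
  B <- rowSums(exps[match(cil, exps$gene), grep("^cen", names(exps))])
  expect_true(all(A == cfg$n_ciliary_exp))
  expect_true(all(B == 0))
})

test_that("annotations are closed over the universe with planted terms enriched", {
  cfg <- sim_config(seed = 23)
  u <- generate_universe(cfg)
  invisible(generate_evidence(u$universe, u$truth, cfg))
  invisible(generate_localization_experiments(u$universe, u$truth, cfg))
  sets <- generate_annotations(u$universe, u$truth, cfg)
  expect_length(sets, cfg$n_terms)
  expect_true(all(unlist(sets) %in% u$universe$gene))
  N <- cfg$n_genes
  for (b in seq_along(cfg$community_sizes)) {
    members <- u$universe$gene[which(u$universe$block == b)]
    s <- sets[[sprintf("T%03d", b)]]
    p <- fisher_one_sided(length(intersect(members, s)), length(members),
                          length(s), N)
    expect_lt(p, 0.001)
  }
})

test_that("null term p-values are super-uniform across resimulations", {
  # Fisher p-values are discrete, hence conservative: P(p <= t) <= t. Check
  # the empirical CDF of a uniform term's p-value against that bound.
  set.seed(77)
  genes <- sprintf("g%03d", 1:150)
  comm <- genes[1:12]
  pvals <- replicate(1000, {
    s <- sample(genes, 20)
    fisher_one_sided(length(intersect(comm, s)), 12, 20, 150)
  })
  for (t in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    se <- sqrt(t * (1 - t) / 1000)
    expect_lte(mean(pvals <= t), t + 3 * se)
  }
})

test_that("TF data respect window geometry and the latent-factor correlation", {
  cfg <- sim_config(seed = 29)
  u <- generate_universe(cfg)
  invisible(generate_evidence(u$universe, u$truth, cfg))
  invisible(generate_localization_experiments(u$universe, u$truth, cfg))
  invisible(generate_annotations(u$universe, u$truth, cfg))
  tf <- generate_tf_data(u$universe, u$truth, cfg)
  expect_true(all(GenomicRanges::width(tf$models) > 0))
  expect_true(all(GenomicRanges::width(tf$sites) > 0))
  # decoys sit in gap centres, assigned to no gene even ignoring the universe
  cand <- assign_tf_candidates(tf$sites, tf$models)
  n_assigned <- sum(lengths(cand))
  n_true <- sum(lengths(u$truth$regulons))
  expect_gte(n_assigned, n_true)             # trues + occasional spurious
  expect_lt(n_assigned, length(tf$sites))    # decoys dropped
  # expected target-TF correlation 1/sqrt(1 + sd^2) ~ 0.89 at sd 0.5
  r <- unlist(lapply(names(u$truth$regulons), function(t)
    apply(tf$expression[u$truth$regulons[[t]], , drop = FALSE], 1,
          stats::cor, y = tf$expression[t, ])))
  expect_gt(mean(r), 0.5)
})
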
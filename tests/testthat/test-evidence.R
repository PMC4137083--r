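test_that("channel combination matches the prior-corrected product formula", {
  expect_equal(combine_channel_scores(0.8, prior = 0), 0.8)
  expect_equal(combine_channel_scores(c(0.5, 0.6), prior = 0), 0.8)

  # hand-evaluated formula with the text-mining channel excluded
  s <- c(0.9, 0.3, 0.99); prior <- 0.041
  sp <- pmax(0, (s[1:2] - prior) / (1 - prior))
  expected <- (1 - prod(1 - sp)) * (1 - prior) + prior
  expect_equal(combine_channel_scores(s, prior = prior, excluded = 3), expected)

  # scores at or below the prior contribute nothing
  expect_equal(combine_channel_scores(c(0.041, 0.02), prior = 0.041), 0)
  expect_error(combine_channel_scores(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(combine_channel_scores(0.5, prior = 1), "prior")
})

test_that("combination is monotone, permutation-invariant, and exclusion never raises it", {
  set.seed(42)
  for (i in 1:25) {
    s <- runif(sample(2:6, 1))
    base <- combine_channel_scores(s, prior = 0.041)
    expect_equal(combine_channel_scores(sample(s), prior = 0.041), base)
    j <- sample(length(s), 1)
    bumped <- s; bumped[j] <- min(1, bumped[j] + runif(1, 0, 1 - bumped[j]))
    expect_gte(combine_channel_scores(bumped, prior = 0.041), base - 1e-12)
    expect_lte(combine_channel_scores(s, prior = 0.041, excluded = j), base + 1e-12)
  }
  # matrix path agrees with the scalar path
  m <- matrix(runif(40), ncol = 4)
  expect_equal(cccinet:::combine_score_matrix(m, prior = 0.041),
               apply(m, 1, combine_channel_scores, prior = 0.041))
})

test_that("interactome thresholding uses >= semantics and the universe filter", {
  ev <- data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "x"),
                   combined = c(0.7, 0.69, 0.9))
  net <- build_interactome(ev, cutoff = 0.7, universe = c("a", "b", "c"))
  expect_equal(nrow(net$edges), 1L)             # 0.7 kept, 0.69 dropped, x outside
  expect_equal(net$edges$gene_a, "a")
  expect_setequal(net$nodes, c("a", "b", "c"))

  all_low <- data.frame(gene_a = "a", gene_b = "b", combined = 0.69)
  empty <- build_interactome(all_low, 0.7, universe = c("a", "b", "c"))
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(sort(remove_singletons(empty)$singletons_removed), c("a", "b", "c"))

  expect_error(build_interactome(ev, 0.7, universe = character(0)), "empty")
  dup <- data.frame(gene_a = c("a", "a"), gene_b = c("b", "b"), combined = 1)
  expect_error(build_interactome(dup, 0.7), "duplicate")
  selfp <- data.frame(gene_a = "a", gene_b = "a", combined = 1)
  expect_error(build_interactome(selfp, 0.7), "self")
  noncanon <- data.frame(gene_a = "b", gene_b = "a", combined = 1)
  expect_error(build_interactome(noncanon, 0.7), "canonical")
})

test_that("singleton removal drops exactly the degree-0 nodes", {
  net <- make_net(data.frame(a = "a", b = "b"), nodes = c("a", "b", "c"))
  out <- remove_singletons(net)
  expect_equal(out$singletons_removed, "c")
  expect_setequal(out$nodes, c("a", "b"))
  expect_equal(nrow(out$edges), 1L)
  expect_identical(remove_singletons(out)$nodes, out$nodes)  # idempotent
})

test_that("connected components are labelled largest-first and cover all nodes", {
  tri2 <- make_net(data.frame(a = c("a", "b", "c", "x", "y", "z"),
                              b = c("b", "c", "a", "y", "z", "x")))
  comp <- connected_components(tri2)
  expect_equal(as.integer(table(comp$component_id)), c(3L, 3L))
  expect_equal(comp$component_id[comp$gene == "a"], 1L)  # tie broken by smallest id

  path5 <- make_net(data.frame(a = c("a", "b", "c", "d"),
                               b = c("b", "c", "d", "e")))
  expect_equal(unique(connected_components(path5)$component_id), 1L)

  # planted blocks with p_inter = 0 give one component per block
  cfg <- sim_config(n_genes = 60, community_sizes = c(8, 10), p_intra = 1,
                    p_inter = 0, channel_noise_sd = 0, seed = 7)
  u <- generate_universe(cfg)
  ev <- combine_evidence(generate_evidence(u$universe, u$truth, cfg))
  net <- remove_singletons(build_interactome(ev, 0.7, u$universe$gene))
  comp <- connected_components(net)
  expect_equal(max(comp$component_id), 2L)
  expect_equal(nrow(comp), length(net$nodes))  # components cover all nodes
  blk <- u$truth$partition[comp$gene]
  expect_true(all(tapply(comp$component_id, blk, function(x) length(unique(x))) == 1))
})

test_that("power-law fit recovers exact log-linear degree frequencies", {
  deg1 <- rep(c(1, 10, 100), c(100, 10, 1))
  fit1 <- fit_power_law(deg1)
  expect_equal(fit1$alpha, -1, tolerance = 1e-12)
  expect_equal(fit1$r_squared, 1, tolerance = 1e-12)

  deg2 <- rep(c(1, 2, 4, 8), c(64, 16, 4, 1))
  expect_equal(fit_power_law(deg2)$alpha, -2, tolerance = 1e-9)

  few <- fit_power_law(rep(c(1, 2), c(5, 3)))
  expect_false(few$defined)
  expect_true(is.na(few$alpha))

  set.seed(11)
  ba <- igraph::sample_pa(2000, m = 3, directed = FALSE)
  alpha <- fit_power_law(igraph::degree(ba))$alpha
  expect_gte(alpha, -3.5)
  expect_lte(alpha, -1.5)
})
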
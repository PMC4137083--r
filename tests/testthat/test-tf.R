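## 0-based BED-like fixtures: one + strand gene at [20000, 30000), one -
## strand gene at [60000, 70000)
tf_models <- data.frame(chrom = "chrS", start = c(20000L, 60000L),
                        end = c(30000L, 70000L), name = c("gp", "gm"),
                        strand = c("+", "-"))

test_that("window assignment honours the 10 kb / 3 kb strand-aware limits", {
  sites <- data.frame(
    chrom = "chrS",
    start = c(15000L, 33900L, 25000L, 0L,     62000L, 70500L, 49500L),
    end   = c(15020L, 33920L, 25020L, 20L,    62020L, 70520L, 49520L),
    name  = c("tfA",  "tfA",  "tfB",  "tfB",  "tfC",  "tfC",  "tfC"))
  cand <- assign_tf_candidates(sites, tf_models)
  expect_equal(cand$tfA, "gp")       # 5 kb upstream in, 3.9 kb downstream out
  expect_equal(cand$tfB, "gp")       # gene-body site in; 20 kb upstream out
  # minus strand: downstream window is left of start (3 kb), upstream right of
  # end (10 kb): 70.5 kb site is 0.5 kb past the 5' end -> in; 49.5 kb site is
  # 10.5 kb before the 3' end -> out
  expect_equal(cand$tfC, "gm")

  # boundary: a + strand site overlapping the window by exactly 1 bp is kept
  edge <- data.frame(chrom = "chrS", start = 9999L, end = 10001L, name = "tfE")
  expect_equal(assign_tf_candidates(edge, tf_models)$tfE, "gp")
  gone <- data.frame(chrom = "chrS", start = 9980L, end = 10000L, name = "tfE")
  expect_length(assign_tf_candidates(gone, tf_models), 0L)
})

test_that("window assignment is invariant under coordinate mirroring", {
  set.seed(8)
  L <- 200000L
  models <- data.frame(chrom = "chrS", start = c(20000L, 100000L),
                       end = c(30000L, 110000L), name = c("g1", "g2"),
                       strand = c("+", "-"))
  sites <- data.frame(chrom = "chrS",
                      start = sort(sample(0:(L - 20L), 40)),
                      name = sprintf("tf%d", sample(3, 40, replace = TRUE)))
  sites$end <- sites$start + 20L
  mirror <- function(d) {
    out <- d
    out$start <- L - d$end
    out$end <- L - d$start
    if ("strand" %in% names(d)) out$strand <- ifelse(d$strand == "+", "-", "+")
    out
  }
  a <- assign_tf_candidates(sites, models)
  b <- assign_tf_candidates(mirror(sites), mirror(models))
  expect_equal(a[order(names(a))], b[order(names(b))])
})

test_that("co-expression filter keeps correlated targets and is monotone in r_min", {
  set.seed(15)
  m <- 30
  z <- rnorm(m)
  expr <- rbind(tf1 = z,
                same = z,                      # r = 1
                near = z + rnorm(m, sd = 1e-4),
                anti = -z,
                noise = rnorm(m),
                flat = rep(1, m))
  colnames(expr) <- sprintf("c%02d", 1:m)
  cand <- list(tf1 = c("same", "near", "anti", "noise", "flat"))
  expect_warning(res <- coexpression_filter(cand, expr), "zero-variance")
  expect_setequal(res$targets$tf1, c("same", "near"))
  expect_equal(res$pairs$r[res$pairs$gene == "same"], 1)
  expect_gt(res$pairs$r[res$pairs$gene == "near"], 0.999)
  expect_false("flat" %in% res$pairs$gene)

  # monotone: raising r_min never adds a target
  strict <- suppressWarnings(coexpression_filter(cand, expr, r_min = 0.9))
  expect_true(all(unlist(strict$targets) %in% unlist(res$targets)))
  # targets are a subset of candidates
  expect_true(all(res$targets$tf1 %in% cand$tf1))

  expect_warning(coexpression_filter(list(ghost = "same"), expr), "absent")
  expect_error(coexpression_filter(cand, expr[, 1:2]), "3 conditions")
})

test_that("TF-target enrichment needs at least 5 targets in the community", {
  bg <- sprintf("g%02d", 1:40)
  comm <- list("1" = bg[1:10], "2" = bg[11:20])
  tfsets <- list(big = bg[1:8],     # 8 targets in community 1
                 small = c(bg[1:4], bg[25:32]))  # only 4 in community 1
  res <- tf_enrichment(comm, tfsets, bg)
  hit <- res$enrichment[res$enrichment$significant, ]
  expect_equal(hit$set_id, "big")
  expect_equal(hit$community_id, "1")
  small_row <- res$enrichment[res$enrichment$set_id == "small" &
                              res$enrichment$community_id == "1", ]
  expect_equal(small_row$k, 4L)
  expect_false(small_row$significant)   # never flagged below 5 targets
  expect_equal(res$tf_summary$n_enriched_communities[res$tf_summary$tf == "big"], 1L)
})

test_that("planted regulons flow through sites + co-expression to enrichment", {
  cfg <- sim_config(seed = 17)
  u <- generate_universe(cfg)
  invisible(generate_evidence(u$universe, u$truth, cfg))
  invisible(generate_localization_experiments(u$universe, u$truth, cfg))
  invisible(generate_annotations(u$universe, u$truth, cfg))
  tf <- generate_tf_data(u$universe, u$truth, cfg)
  cand <- assign_tf_candidates(tf$sites, tf$models, universe = u$universe$gene)
  # every true target is a candidate of its TF
  for (t in names(u$truth$regulons)) {
    expect_true(all(u$truth$regulons[[t]] %in% cand[[t]]))
  }
  tg <- coexpression_filter(cand, tf$expression)
  blocks <- split(u$universe$gene, u$universe$block)
  res <- tf_enrichment(blocks, tg, u$universe$gene)
  hits <- res$enrichment[res$enrichment$significant, ]
  # each TF's planted block (block j for TF j, by construction) is enriched
  tfs <- sort(names(u$truth$regulons))
  for (j in seq_along(tfs)) {
    expect_true(any(hits$set_id == tfs[j] & hits$community_id == as.character(j)))
  }
})
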
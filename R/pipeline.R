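#' Default pipeline configuration
#'
#' Settings for an end-to-end run: input file paths (those produced by
#' \code{\link{write_simulation}} by default), the evidence cutoff and
#' prior, excluded channels, MCODE parameters, enrichment thresholds,
#' localization file paths and TF window/correlation parameters.
#'
#' @param datadir directory holding the input files.
#' @param outdir directory results are written to.
#' @param seed seed for the (optional) simulate stage.
#' @param ... overrides for any configuration field.
#' @return A named list.
#' @export
pipeline_config <- function(datadir, outdir = file.path(datadir, "results"),
                            seed = 1, ...) {
  cfg <- list(
    datadir = datadir,
    outdir = outdir,
    seed = seed,
    simulate = TRUE,
    sim = list(),
    evidence_file = file.path(datadir, "evidence.tsv"),
    universe_file = file.path(datadir, "universe.txt"),
    annotations_file = file.path(datadir, "annotations.gmt"),
    experiments_file = file.path(datadir, "experiments.tsv"),
    centrosome_db_file = file.path(datadir, "centrosome_db.txt"),
    go_cilium_file = file.path(datadir, "go_cilium.txt"),
    nuclear_file = file.path(datadir, "nuclear.txt"),
    gene_models_file = file.path(datadir, "gene_models.bed"),
    tf_sites_file = file.path(datadir, "tf_sites.bed"),
    expression_file = file.path(datadir, "expression.tsv"),
    cutoff = 0.7,
    prior = 0.041,
    exclude_channels = character(0),
    mcode = mcode_params(),
    min_community_size = 5,
    enrichment_alpha = 0.05,
    enrichment_min_overlap = 0,
    tf_upstream = 10000,
    tf_downstream = 3000,
    tf_r_min = 0.5,
    tf_q_max = 0.05,
    tf_min_overlap = 5)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown pipeline configuration field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(over)] <- over
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file; fields override \code{\link{pipeline_config}}
#'   defaults. Must contain \code{datadir}.
#' @return A configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y$datadir)) stop("config must set 'datadir'", call. = FALSE)
  base <- pipeline_config(y$datadir)
  if (!is.null(y$mcode)) y$mcode <- do.call(mcode_params, y$mcode)
  base[names(y)] <- y
  base
}

require_file <- function(path, what) {
  if (!file.exists(path)) {
    stop("missing ", what, " file: ", path, call. = FALSE)
  }
  path
}

#' Run one pipeline stage
#'
#' Stages read their inputs from files and write TSV outputs into
#' \code{cfg$outdir}, so each stage is independently invocable with the same
#' results as within \code{\link{run_pipeline}}.
#'
#' @param stage one of \code{"simulate"}, \code{"build"}, \code{"cluster"},
#'   \code{"enrich"}, \code{"localize"}, \code{"supercomm"}, \code{"tf"}.
#' @param cfg a \code{\link{pipeline_config}} list.
#' @return The stage's main result, invisibly for file-writing stages.
#' @export
run_stage <- function(stage, cfg) {
  stage <- match.arg(stage, c("simulate", "build", "cluster", "enrich",
                              "localize", "supercomm", "tf"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outdir, f)
  load_net <- function() {
    edges <- utils::read.delim(require_file(out("interactome.tsv"),
                                            "interactome"),
                               stringsAsFactors = FALSE)
    nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
    structure(list(nodes = nodes,
                   edges = data.frame(gene_a = edges$gene_a,
                                      gene_b = edges$gene_b,
                                      score = edges$score,
                                      stringsAsFactors = FALSE),
                   singletons_removed = character(0)),
              class = "interactome")
  }
  load_communities <- function() {
    memb <- utils::read.delim(require_file(out("communities.tsv"),
                                           "communities"),
                              stringsAsFactors = FALSE)
    split(memb$gene, as.character(memb$community_id))
  }

  switch(stage,
    simulate = {
      sim <- simulate_ccci(do.call(sim_config, c(cfg$sim, list(seed = cfg$seed))))
      write_simulation(sim, cfg$datadir)
      invisible(sim)
    },
    build = {
      ev <- read_evidence(require_file(cfg$evidence_file, "evidence"))
      universe <- read_gene_list(require_file(cfg$universe_file, "universe"))
      ev <- combine_evidence(ev, prior = cfg$prior,
                             exclude_channels = cfg$exclude_channels)
      net <- build_interactome(ev, cutoff = cfg$cutoff, universe = universe)
      net <- remove_singletons(net)
      comp <- connected_components(net)
      fit <- fit_power_law(net)
      write_tsv_atomic(net$edges, out("interactome.tsv"))
      write_tsv_atomic(comp, out("components.tsv"))
      write_gene_list(net$singletons_removed, out("singletons.txt"))
      attr(net, "components") <- comp
      attr(net, "degree_fit") <- fit
      invisible(net)
    },
    cluster = {
      net <- load_net()
      communities <- mcode(net, cfg$mcode)
      write_tsv_atomic(community_membership(communities), out("communities.tsv"))
      write_tsv_atomic(community_summary(communities),
                       out("communities_summary.tsv"))
      invisible(communities)
    },
    enrich = {
      net <- load_net()
      comm <- load_communities()
      sets <- read_gmt(require_file(cfg$annotations_file, "annotations"))
      res <- enrich_communities(comm, sets, net$nodes,
                                min_community_size = cfg$min_community_size,
                                min_overlap = cfg$enrichment_min_overlap,
                                alpha = cfg$enrichment_alpha)
      write_tsv_atomic(res, out("enrichment.tsv"))
      invisible(res)
    },
    localize = {
      net <- load_net()
      loc <- annotate_localization(
        genes = net$nodes,
        centrosome_curated = read_gene_list(require_file(cfg$centrosome_db_file,
                                                         "centrosome db")),
        cilium_curated = read_gene_list(require_file(cfg$go_cilium_file,
                                                     "GO cilium")),
        nuclear_set = read_gene_list(require_file(cfg$nuclear_file, "nuclear")),
        experiments = read_experiments(require_file(cfg$experiments_file,
                                                    "experiments")))
      write_tsv_atomic(loc, out("localization.tsv"))
      invisible(loc)
    },
    supercomm = {
      net <- load_net()
      comm <- load_communities()
      cg <- build_community_graph(net, comm,
                                  min_size = cfg$min_community_size)
      scs <- detect_supercommunities(cg)
      write_tsv_atomic(cg$edges, out("community_graph.tsv"))
      write_tsv_atomic(scs, out("supercommunities.tsv"))
      invisible(list(graph = cg, supercommunities = scs))
    },
    tf = {
      net <- load_net()
      comm <- load_communities()
      sites <- read_bed(require_file(cfg$tf_sites_file, "TF sites"))
      models <- read_bed(require_file(cfg$gene_models_file, "gene models"))
      expr <- read_expression(require_file(cfg$expression_file, "expression"))
      cand <- assign_tf_candidates(sites, models,
                                   upstream = cfg$tf_upstream,
                                   downstream = cfg$tf_downstream,
                                   universe = net$nodes)
      targets <- coexpression_filter(cand, expr, r_min = cfg$tf_r_min,
                                     q_max = cfg$tf_q_max)
      res <- tf_enrichment(comm, targets, net$nodes,
                           min_community_size = cfg$min_community_size,
                           min_overlap = cfg$tf_min_overlap,
                           alpha = cfg$enrichment_alpha)
      write_gmt(targets$targets, out("tf_targets.gmt"))
      write_tsv_atomic(res$enrichment, out("tf_enrichment.tsv"))
      write_tsv_atomic(res$tf_summary, out("tf_summary.tsv"))
      invisible(c(res, list(targets = targets)))
    })
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> build -> cluster -> enrich -> localize ->
#' supercomm -> tf and writes a machine-readable run summary
#' (\code{run_summary.json}) with per-stage counts alongside the stage
#' outputs. Reruns with the same configuration produce identical summaries.
#'
#' @param cfg a \code{\link{pipeline_config}} list or path to a YAML file.
#' @param quiet suppress progress messages.
#' @return The run summary list, invisibly.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  say <- function(...) if (!quiet) message(...)
  stages <- c(if (isTRUE(cfg$simulate)) "simulate",
              "build", "cluster", "enrich", "localize", "supercomm", "tf")
  results <- list()
  for (st in stages) {
    say("[", st, "] running")
    results[[st]] <- withCallingHandlers(
      tryCatch(run_stage(st, cfg),
               error = function(e) {
                 stop("pipeline stage '", st, "' failed: ",
                      conditionMessage(e), call. = FALSE)
               }),
      warning = function(w) {
        say("[", st, "] warning: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  net <- results$build
  comp <- attr(net, "components")
  fit <- attr(net, "degree_fit")
  communities <- results$cluster
  sizes <- vapply(communities, function(z) length(z$members), integer(1))
  scs <- results$supercomm$supercommunities
  summary <- list(
    genes = length(net$nodes),
    interactions = nrow(net$edges),
    singletons = length(net$singletons_removed),
    components = if (nrow(comp)) max(comp$component_id) else 0L,
    largest_component = if (nrow(comp)) sum(comp$component_id == 1L) else 0L,
    degree_alpha = fit$alpha,
    communities = length(communities),
    mean_community_size = if (length(sizes)) mean(sizes) else NA_real_,
    community_graph_edges = nrow(results$supercomm$graph$edges),
    supercommunities = if (nrow(scs)) max(scs$supercommunity_id) else 0L,
    enriched_pairs = sum(results$enrich$significant),
    localization_calls = as.list(table(results$localize$call)),
    nuclear_genes = sum(results$localize$nuclear),
    tfs_with_targets = length(results$tf$targets$targets),
    tf_enriched_pairs = sum(results$tf$enrichment$significant),
    config = cfg[setdiff(names(cfg), "mcode")])
  tmp <- tempfile(tmpdir = cfg$outdir, fileext = ".tmp")
  jsonlite::write_json(summary, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, file.path(cfg$outdir, "run_summary.json"))
  say("pipeline complete: ", summary$genes, " genes, ",
      summary$interactions, " interactions, ",
      summary$communities, " communities, ",
      summary$supercommunities, " super-communities")
  invisible(summary)
}
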
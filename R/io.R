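## Atomic TSV writer: write to a temp file in the same directory, then rename.
write_tsv_atomic <- function(x, path, row.names = FALSE) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.table(x, tmp, sep = "\t", quote = FALSE,
                     row.names = row.names, col.names = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a per-pair evidence table
#'
#' @param path TSV with header \code{gene_a}, \code{gene_b} and one numeric
#'   column per evidence channel.
#' @return data frame.
#' @export
read_evidence <- function(path) {
  if (!file.exists(path)) stop("evidence file not found: ", path, call. = FALSE)
  ev <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_pairs(ev)
  ev
}

#' Read / write GMT gene-set collections
#'
#' GMT is the tab-separated gene-set format: term, description, then member
#' genes.
#'
#' @param path file path.
#' @return \code{read_gmt}: named list of gene sets with a
#'   \code{description} attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  attr(sets, "description") <-
    stats::setNames(vapply(parts, `[[`, character(1), 2L), names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene sets.
#' @param descriptions optional character vector of term descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "description")
    if (is.null(descriptions)) {
      descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
    }
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Read / write one-gene-per-line sets
#'
#' @param path file path.
#' @return character vector of genes.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path, call. = FALSE)
  x <- readLines(path)
  x[nzchar(x)]
}

#' @rdname read_gene_list
#' @param genes character vector.
#' @export
write_gene_list <- function(genes, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(as.character(genes), tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Read / write BED6 interval files
#'
#' Thin wrappers around \pkg{rtracklayer}; BED is 0-based half-open on disk,
#' \code{GRanges} 1-based closed in memory.
#'
#' @param path file path.
#' @return \code{read_bed}: a \code{GRanges} with a \code{name} column.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  rtracklayer::import(path, format = "BED")
}

#' @rdname read_bed
#' @param gr a \code{GRanges} with a \code{name} metadata column.
#' @export
write_bed <- function(gr, path) {
  if (is.null(gr$score)) gr$score <- 0
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  rtracklayer::export(gr, tmp, format = "BED")
  file.rename(tmp, path)
  invisible(path)
}

#' Read / write expression matrices
#'
#' @param path TSV, genes in rows (first column \code{gene}), conditions in
#'   columns.
#' @return numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_expression
#' @param expression numeric matrix with gene rownames.
#' @export
write_expression <- function(expression, path) {
  df <- data.frame(gene = rownames(expression), expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_atomic(df, path)
}

#' Read an experiment-membership matrix
#'
#' @param path TSV with a \code{gene} column and one 0/1 column per
#'   experiment.
#' @return data frame.
#' @export
read_experiments <- function(path) {
  if (!file.exists(path)) stop("experiments file not found: ", path, call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write all synthetic-data files for a simulated run
#'
#' Serializes a \code{\link{simulate_ccci}} result: \code{evidence.tsv},
#' \code{experiments.tsv}, \code{annotations.gmt}, \code{gene_models.bed},
#' \code{tf_sites.bed}, \code{expression.tsv}, \code{universe.txt}, curated
#' sets (\code{centrosome_db.txt}, \code{go_cilium.txt}, \code{nuclear.txt})
#' and \code{truth.json}. Identical configurations yield byte-identical
#' files.
#'
#' @param sim result of \code{\link{simulate_ccci}}.
#' @param outdir output directory (created if needed).
#' @return \code{outdir}, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_tsv_atomic(sim$evidence, p("evidence.tsv"))
  write_tsv_atomic(sim$experiments, p("experiments.tsv"))
  write_gmt(sim$annotations, p("annotations.gmt"))
  write_bed(sim$tf$models, p("gene_models.bed"))
  write_bed(sim$tf$sites, p("tf_sites.bed"))
  write_expression(sim$tf$expression, p("expression.tsv"))
  write_gene_list(sim$universe$gene, p("universe.txt"))
  write_gene_list(sim$curated$centrosome_db, p("centrosome_db.txt"))
  write_gene_list(sim$curated$go_cilium, p("go_cilium.txt"))
  write_gene_list(sim$curated$nuclear, p("nuclear.txt"))
  truth <- sim$truth
  truth$partition <- as.list(truth$partition[!is.na(truth$partition)])
  truth$localization <- as.list(truth$localization)
  tmp <- tempfile(tmpdir = outdir, fileext = ".tmp")
  jsonlite::write_json(truth, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, p("truth.json"))
  invisible(outdir)
}
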
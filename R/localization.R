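#' Experiment-voting sub-localization rule
#'
#' Compares, per gene, the number of ciliary-group high-throughput
#' experiments in which it was detected (A) against the number of
#' centrosomal-group experiments (B). A margin greater than one decides the
#' call; a difference of 0 or 1 leaves the gene unknown.
#'
#' @param A count(s) of ciliary-group experiments containing the gene.
#' @param B count(s) of centrosomal-group experiments containing the gene.
#' @return Character vector over \code{c("ciliary", "centrosomal",
#'   "unknown")}.
#' @examples
#' vote_localization(3, 1)  # "ciliary"
#' vote_localization(2, 1)  # "unknown"
#' @export
vote_localization <- function(A, B) {
  if (anyNA(A) || anyNA(B) || any(A < 0) || any(B < 0)) {
    stop("experiment counts must be non-negative", call. = FALSE)
  }
  ifelse(A > B + 1, "ciliary", ifelse(B > A + 1, "centrosomal", "unknown"))
}

#' Annotate gene sub-localization: curated sets first, then voting
#'
#' Curated annotations take precedence: genes in the centrosome database are
#' called centrosomal, then genes annotated ciliary (GO cilium) are called
#' ciliary; a gene in both curated sets is left unknown (unresolved) with a
#' warning. Remaining genes are voted on their experiment counts. The
#' nuclear flag is orthogonal to the ciliary/centrosomal call.
#'
#' @param genes character vector of genes to annotate.
#' @param centrosome_curated curated centrosomal gene set.
#' @param cilium_curated curated ciliary gene set.
#' @param nuclear_set genes with reported nuclear localization.
#' @param experiments data frame with a \code{gene} column and one 0/1
#'   column per experiment; genes missing from it are treated as absent
#'   from every experiment, with a warning.
#' @param ciliary_cols,centrosomal_cols names of the experiment columns in
#'   each group; by default columns starting with \code{"cil"} and
#'   \code{"cen"}.
#' @return data frame (\code{gene}, \code{call}, \code{provenance},
#'   \code{A}, \code{B}, \code{nuclear}).
#' @export
annotate_localization <- function(genes, centrosome_curated, cilium_curated,
                                  nuclear_set, experiments,
                                  ciliary_cols = NULL, centrosomal_cols = NULL) {
  genes <- as.character(genes)
  if (is.null(ciliary_cols)) {
    ciliary_cols <- grep("^cil", names(experiments), value = TRUE)
  }
  if (is.null(centrosomal_cols)) {
    centrosomal_cols <- grep("^cen", names(experiments), value = TRUE)
  }
  if (!length(ciliary_cols) || !length(centrosomal_cols)) {
    stop("could not identify ciliary/centrosomal experiment columns",
         call. = FALSE)
  }
  idx <- match(genes, experiments$gene)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " gene(s) missing from the experiment matrix; ",
            "treated as absent from every experiment", call. = FALSE)
  }
  count_in <- function(cols) {
    m <- as.matrix(experiments[cols])
    out <- rep(0L, length(genes))
    out[!is.na(idx)] <- as.integer(rowSums(m[idx[!is.na(idx)], , drop = FALSE]))
    out
  }
  A <- count_in(ciliary_cols)
  B <- count_in(centrosomal_cols)
  in_cen <- genes %in% centrosome_curated
  in_cil <- genes %in% cilium_curated
  conflict <- in_cen & in_cil
  if (any(conflict)) {
    warning(sum(conflict), " gene(s) present in both curated sets; ",
            "left as unknown (unresolved)", call. = FALSE)
  }
  call <- vote_localization(A, B)
  provenance <- rep("voted", length(genes))
  call[in_cil] <- "ciliary"; provenance[in_cil] <- "curated_go_cilium"
  call[in_cen] <- "centrosomal"; provenance[in_cen] <- "curated_centrosome_db"
  call[conflict] <- "unknown"; provenance[conflict] <- "unresolved"
  data.frame(gene = genes, call = call, provenance = provenance,
             A = A, B = B, nuclear = genes %in% nuclear_set,
             stringsAsFactors = FALSE)
}
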
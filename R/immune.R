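# Expression-derived immune and pathway indices. The expression matrix is
# log2(x + 1) scale throughout; linear values are recovered as 2^v - 1.

expr_linear <- function(v) pmax(2^v - 1, 0)

#' Cytolytic index (CYT)
#'
#' Geometric mean of the linear-scale GZMA and PRF1 transcript levels, a
#' measure of CD8+ T-cell cytotoxicity. An offset of 0.01 is added to each
#' linear value before the geometric mean so zero expression yields a
#' finite floor of 0.01.
#'
#' @param expr log2(x+1) expression matrix, genes x samples.
#' @param genes the two cytolytic effector genes (default GZMA and PRF1).
#' @param offset pseudo-count added on the linear scale (default 0.01).
#' @return named numeric vector of per-sample CYT values (>= offset).
#' @export
cyt_index <- function(expr, genes = c("GZMA", "PRF1"), offset = 0.01) {
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  lin <- expr_linear(expr[genes, , drop = FALSE]) + offset
  exp(colMeans(log(lin)))
}

#' Single-sample gene-set enrichment (ssGSEA) score
#'
#' Rank-based per-sample enrichment of a gene set, as used by
#' expression-derived immune-infiltration scores. Genes are ranked by
#' expression within each sample (descending, average ranks for ties); the
#' score is the sum over the ranked list of the difference between the
#' weighted in-set cumulative distribution (weights rank^alpha) and the
#' uniform out-of-set cumulative distribution. Being rank-based, the score
#' is invariant under monotone transforms of one sample's expression.
#'
#' @param expr log2 expression matrix, genes x samples.
#' @param gene_set character vector of gene symbols; at least half must be
#'   present in the matrix.
#' @param alpha rank-weighting exponent (default 0.25).
#' @return named numeric vector of per-sample scores.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25) {
  gene_set <- unique(gene_set)
  if (!length(gene_set)) stop("empty gene set")
  present <- intersect(gene_set, rownames(expr))
  if (!length(present)) stop("gene set has no genes in the expression matrix")
  if (length(present) < length(gene_set) / 2)
    stop("fewer than 50% of gene set present in expression matrix (",
         length(present), "/", length(gene_set), ")")
  n <- nrow(expr)
  in_set <- rownames(expr) %in% present
  n_out <- n - sum(in_set)
  apply(expr, 2, function(v) {
    r <- rank(v, ties.method = "average")   # largest value -> rank n
    ord <- order(r, decreasing = TRUE)
    inn <- in_set[ord]
    if (n_out == 0L) return(0)              # degenerate: set covers all genes
    w <- r[ord]^alpha
    w[!inn] <- 0
    cum_in <- cumsum(w) / sum(w)
    cum_out <- cumsum(!inn) / n_out
    sum(cum_in - cum_out)
  })
}

#' Mean z-score over a gene set
#'
#' Each gene is standardised across samples (z-score); the per-sample score
#' is the mean z over the set's genes. Genes with constant expression are
#' dropped with a warning. The cohort mean of the scores is 0 by
#' construction.
#'
#' @inheritParams ssgsea_score
#' @return named numeric vector of per-sample mean z-scores.
#' @export
geneset_mean_z <- function(expr, gene_set) {
  gene_set <- unique(gene_set)
  if (!length(gene_set)) stop("empty gene set")
  present <- intersect(gene_set, rownames(expr))
  if (length(present) < length(gene_set) / 2)
    stop("fewer than 50% of gene set present in expression matrix")
  sub <- expr[present, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant-expression gene(s): ",
            paste(present[sds == 0], collapse = ", "))
    sub <- sub[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
    if (!nrow(sub)) stop("all set genes constant; z-scores undefined")
  }
  z <- (sub - rowMeans(sub)) / sds
  colMeans(z)
}

#' Per-sample immune and pathway scores for a cohort
#'
#' Convenience wrapper computing CYT, the ssGSEA immune score for the
#' packaged (synthetic stand-in) immune gene set or a user set, and mean-z
#' scores for any further sets.
#'
#' @param expr log2 expression matrix.
#' @param immune_set character vector for the ssGSEA immune score; default
#'   loads the packaged synthetic immune set.
#' @param z_sets optional named list of gene sets scored by
#'   [geneset_mean_z()].
#' @return data.frame: sample_id, cyt, immune_ssgsea, one column per z set.
#' @export
immune_scores <- function(expr, immune_set = NULL, z_sets = NULL) {
  if (is.null(immune_set))
    immune_set <- read_gene_sets(hrd_extdata("immune_geneset_synthetic.gmt"))[[1]]
  out <- data.frame(sample_id = colnames(expr),
                    cyt = unname(cyt_index(expr)),
                    immune_ssgsea = unname(ssgsea_score(expr, immune_set)),
                    stringsAsFactors = FALSE)
  for (nm in names(z_sets))
    out[[nm]] <- unname(geneset_mean_z(expr, z_sets[[nm]]))
  out
}
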
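#' Canonical 96 substitution channels
#'
#' Channel order is the COSMIC convention: substitution classes C>A, C>G,
#' C>T, T>A, T>C, T>G, each crossed with the 16 flanking-base contexts in
#' lexicographic order, labelled like `A[C>A]A`.
#'
#' @return character vector of length 96.
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    unlist(lapply(bases, function(l)
      paste0(l, "[", s, "]", vapply(bases, identity, ""))))))
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(x) {
  vapply(strsplit(x, ""), function(b)
    paste(rev(unname(REVCOMP[b])), collapse = ""), "")
}

#' Build a 96-channel mutation catalogue
#'
#' Bins single-nucleotide variants into the 96 trinucleotide substitution
#' channels. Variants whose reference base is a purine (A or G) are
#' reverse-complemented onto the pyrimidine strand first, per the COSMIC
#' convention. Non-SNVs and records whose context is missing, contains N,
#' or whose middle base disagrees with the reference are skipped with a
#' message reporting the count.
#'
#' @param variants variant data.frame (see [read_variants()]); only rows
#'   with single-base `ref` and `alt` and a usable `tri_context` are binned.
#' @param sample_id optional sample to subset to; default uses all rows.
#' @param quiet suppress the skipped-record message.
#' @return named integer vector of length 96 (class `mutation_catalog`),
#'   summing to the number of usable SNVs.
#' @export
build_catalog <- function(variants, sample_id = NULL, quiet = FALSE) {
  if (!is.null(sample_id))
    variants <- variants[variants$sample_id == sample_id, , drop = FALSE]
  chans <- sbs_channels()
  counts <- stats::setNames(integer(96), chans)
  if (nrow(variants) == 0L) return(structure(counts, class = "mutation_catalog"))
  is_snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    variants$ref %in% names(REVCOMP) & variants$alt %in% names(REVCOMP)
  v <- variants[is_snv, , drop = FALSE]
  ctx <- v$tri_context
  ok <- !is.na(ctx) & nchar(ctx) == 3L & !grepl("[^ACGT]", ctx) &
    substr(ctx, 2, 2) == v$ref
  n_skip <- sum(!ok) + sum(!is_snv)
  if (n_skip > 0 && !quiet)
    message(n_skip, " record(s) skipped while building catalogue (non-SNV or unusable context)")
  v <- v[ok, , drop = FALSE]
  if (nrow(v) > 0L) {
    ref <- v$ref; alt <- v$alt; tri <- v$tri_context
    pur <- ref %in% c("A", "G")
    ref[pur] <- unname(REVCOMP[v$ref[pur]])
    alt[pur] <- unname(REVCOMP[v$alt[pur]])
    tri[pur] <- revcomp(v$tri_context[pur])
    lab <- paste0(substr(tri, 1, 1), "[", ref, ">", alt, "]", substr(tri, 3, 3))
    tab <- table(factor(lab, levels = chans))
    counts <- counts + as.integer(tab)
    names(counts) <- chans
  }
  structure(counts, class = "mutation_catalog")
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat("96-channel mutation catalogue:", sum(x), "SNVs,",
      sum(x > 0), "non-zero channels\n")
  invisible(x)
}

#' Build catalogues for every sample in a cohort
#'
#' @param variants variant data.frame.
#' @return integer matrix, 96 channels x samples.
#' @export
build_catalog_matrix <- function(variants) {
  ids <- sort(unique(variants$sample_id))
  m <- vapply(ids, function(s) as.integer(build_catalog(variants, s, quiet = TRUE)),
              integer(96))
  rownames(m) <- sbs_channels()
  colnames(m) <- ids
  m
}
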
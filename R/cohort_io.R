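CONSEQUENCES <- c("stop_gained", "frameshift", "splice_donor",
                  "splice_acceptor", "missense", "other")
PTV_CONSEQUENCES <- c("stop_gained", "frameshift", "splice_donor",
                      "splice_acceptor")
STUDY_GENES <- c("PALB2", "BRCA1", "BRCA2")

VARIANT_COLS <- c("sample_id", "chrom", "pos", "ref", "alt", "gene",
                  "consequence", "origin", "vaf_tumour", "vaf_germline",
                  "tri_context")
SEGMENT_COLS <- c("sample_id", "chrom", "start", "end", "cn_major", "cn_minor")

#' Normalise chromosome names
#'
#' Strips any `chr` prefix so that mixed dialects (`chr17` vs `17`) compare
#' equal. The canonical internal form carries no prefix.
#'
#' @param x character vector of chromosome names.
#' @return character vector without `chr` prefixes.
#' @export
norm_chrom <- function(x) sub("^chr", "", as.character(x))

#' Read variant calls
#'
#' Reads per-sample germline and somatic variant calls from either a tab
#' separated table or a VCF. The TSV dialect has columns `sample_id`,
#' `chrom`, `pos` (1-based), `ref`, `alt`, `gene`, `consequence`, `origin`,
#' `vaf_tumour`, `vaf_germline` and optional `tri_context` (the reference
#' trinucleotide centred on the variant). The VCF dialect requires INFO keys
#' `GENE`, `CSQ` (consequence) and `ORIGIN`, and per-sample `AD` allele
#' depths from which VAF = alt / (ref + alt) is computed; genotype columns
#' named `TUMOUR`/`TUMOR` and `GERMLINE`/`NORMAL` supply the two VAFs.
#'
#' Records violating the invariants (position >= 1, ref != alt, VAFs in
#' \[0,1\], trinucleotide context of length 3 with the middle base matching
#' the reference for SNVs, consequence among the recognised terms) are
#' dropped with a message reporting how many were rejected.
#'
#' @param path path to the variant file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return a `data.frame` of validated variant records with columns
#'   `r paste(VARIANT_COLS, collapse = ", ")`.
#' @export
read_variants <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("variant file not found: ", path)
  raw <- if (dialect == "tsv") read_variants_tsv(path) else read_variants_vcf(path)
  if (nrow(raw) == 0L) stop("no parseable variant records in ", path)
  validate_variants(raw, context = path)
}

read_variants_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- setdiff(setdiff(VARIANT_COLS, "tri_context"), names(df))
  if (length(need))
    stop("malformed variant table, missing columns: ",
         paste(need, collapse = ", "))
  if (is.null(df$tri_context)) df$tri_context <- NA_character_
  df <- df[, VARIANT_COLS]
  df$pos <- suppressWarnings(as.integer(df$pos))
  for (v in c("vaf_tumour", "vaf_germline"))
    df[[v]] <- suppressWarnings(as.numeric(df[[v]]))
  df$tri_context[df$tri_context %in% c("", ".", "NA")] <- NA_character_
  df
}

read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)   # single record drops to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(data.frame())
  gene <- vcfR::extract.info(vcf, "GENE")
  csq <- vcfR::extract.info(vcf, "CSQ")
  origin <- vcfR::extract.info(vcf, "ORIGIN")
  ad <- vcfR::extract.gt(vcf, "AD")
  vaf_from_ad <- function(col) {
    if (is.null(col)) return(rep(NA_real_, nrow(fix)))
    parts <- strsplit(col, ",", fixed = TRUE)
    vapply(parts, function(p) {
      d <- suppressWarnings(as.numeric(p))
      if (length(d) < 2 || anyNA(d) || sum(d[1:2]) == 0) return(NA_real_)
      d[2] / (d[1] + d[2])
    }, numeric(1))
  }
  samp_cols <- colnames(ad)
  tum <- samp_cols[toupper(samp_cols) %in% c("TUMOUR", "TUMOR")]
  grm <- samp_cols[toupper(samp_cols) %in% c("GERMLINE", "NORMAL")]
  sample_id <- vcfR::extract.info(vcf, "SAMPLE")
  if (all(is.na(sample_id))) sample_id <- rep(basename(path), nrow(fix))
  data.frame(
    sample_id = sample_id,
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    gene = gene, consequence = csq, origin = origin,
    vaf_tumour = if (length(tum)) vaf_from_ad(ad[, tum[1]]) else NA_real_,
    vaf_germline = if (length(grm)) vaf_from_ad(ad[, grm[1]]) else NA_real_,
    tri_context = NA_character_,
    stringsAsFactors = FALSE
  )
}

validate_variants <- function(df, context = "input") {
  df$chrom <- norm_chrom(df$chrom)
  is_snv <- nchar(df$ref) == 1L & nchar(df$alt) == 1L
  ok_ctx <- is.na(df$tri_context) |
    (nchar(df$tri_context) == 3L &
       (!is_snv | substr(df$tri_context, 2, 2) == df$ref))
  ok_vaf <- function(v) is.na(v) | (v >= 0 & v <= 1)
  ok <- !is.na(df$pos) & df$pos >= 1L &
    !is.na(df$ref) & !is.na(df$alt) & df$ref != df$alt &
    df$consequence %in% CONSEQUENCES &
    df$origin %in% c("germline", "somatic") &
    ok_vaf(df$vaf_tumour) & ok_vaf(df$vaf_germline) & ok_ctx
  n_bad <- sum(!ok)
  if (n_bad > 0)
    message(n_bad, " variant record(s) rejected while reading ", context)
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0L) stop("no valid variant records in ", context)
  rownames(df) <- NULL
  df
}

#' Read allele-specific copy-number segments
#'
#' Reads a Sequenza-style segment table. Accepted column spellings are
#' `chromosome`/`chrom`, `start.pos`/`start`, `end.pos`/`end`, `A`/`cn_major`
#' and `B`/`cn_minor`, plus `sample_id` (or a single-sample file with the
#' sample given by `sample_id=`). Rows where the minor copy number exceeds
#' the major are swapped with a warning (a tolerated dialect quirk); within
#' each sample and chromosome segments are returned sorted and any
#' overlapping pair raises an error naming it.
#'
#' @param path path to the segment TSV.
#' @param sample_id sample name used when the file has no `sample_id` column.
#' @return a `data.frame` with columns
#'   `r paste(SEGMENT_COLS, collapse = ", ")`, 1-based inclusive coordinates.
#' @export
read_segments <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("segment file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(df)) return(df[[nm]])
    stop("segment table missing column (one of): ", paste(c(...), collapse = "/"))
  }
  out <- data.frame(
    sample_id = if ("sample_id" %in% names(df)) as.character(df$sample_id)
                else if (!is.null(sample_id)) sample_id
                else stop("segment table has no sample_id column and none was supplied"),
    chrom = norm_chrom(pick("chromosome", "chrom")),
    start = as.integer(pick("start.pos", "start")),
    end = as.integer(pick("end.pos", "end")),
    cn_major = as.integer(pick("A", "cn_major")),
    cn_minor = as.integer(pick("B", "cn_minor")),
    stringsAsFactors = FALSE
  )
  validate_segments(out)
}

validate_segments <- function(seg) {
  if (any(is.na(seg$start) | is.na(seg$end) | seg$start > seg$end))
    stop("segment with start > end or missing coordinates")
  if (any(is.na(seg$cn_major) | is.na(seg$cn_minor) |
          seg$cn_major < 0 | seg$cn_minor < 0))
    stop("segment with missing or negative copy number")
  swap <- seg$cn_minor > seg$cn_major
  if (any(swap)) {
    warning(sum(swap), " segment(s) had minor > major copy number; swapped")
    tmp <- seg$cn_major[swap]
    seg$cn_major[swap] <- seg$cn_minor[swap]
    seg$cn_minor[swap] <- tmp
  }
  ord <- order(seg$sample_id, seg$chrom, seg$start)
  seg <- seg[ord, , drop = FALSE]
  key <- paste(seg$sample_id, seg$chrom)
  same <- key[-1] == key[-length(key)]
  olap <- which(same & seg$start[-1] <= seg$end[-nrow(seg)])
  if (length(olap)) {
    i <- olap[1]
    stop(sprintf("overlapping segments in sample %s chrom %s: [%d,%d] and [%d,%d]",
                 seg$sample_id[i], seg$chrom[i],
                 seg$start[i], seg$end[i], seg$start[i + 1], seg$end[i + 1]))
  }
  rownames(seg) <- NULL
  seg
}

#' Read a gene-by-sample expression matrix
#'
#' First column holds gene symbols, remaining columns one sample each;
#' values are log2-scale expression. Duplicated gene or sample labels and
#' missing cells are errors.
#'
#' @param path path to the TSV.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene symbols: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample ids in expression matrix")
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)
    stop("missing expression values at e.g. gene ", genes[idx[1, 1]],
         ", sample ", colnames(m)[idx[1, 2]])
  }
  rownames(m) <- genes
  m
}

#' Read the chromosome map
#'
#' Columns: `chrom`, `length`, `centromere_start`, `centromere_end`
#' (1-based inclusive). Validates 0 < centromere_start <= centromere_end
#' <= length.
#'
#' @param path path to the TSV.
#' @return a `data.frame` keyed by normalised chromosome name.
#' @export
read_chrom_map <- function(path) {
  if (!file.exists(path)) stop("chromosome map not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- setdiff(c("chrom", "length", "centromere_start", "centromere_end"),
                  names(df))
  if (length(need)) stop("chrom map missing columns: ", paste(need, collapse = ", "))
  df$chrom <- norm_chrom(df$chrom)
  bad <- !(df$centromere_start > 0 &
             df$centromere_start <= df$centromere_end &
             df$centromere_end <= df$length)
  if (any(bad))
    stop("invalid centromere interval for chromosome(s): ",
         paste(df$chrom[bad], collapse = ", "))
  if (anyDuplicated(df$chrom)) stop("duplicate chromosomes in map")
  rownames(df) <- df$chrom
  df
}

#' Read gene sets in GMT format
#'
#' @param path path to a GMT file (name, description, genes...).
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("gene set file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) stop("malformed GMT line: ", f[1])
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
  if (anyDuplicated(names(sets))) stop("duplicate gene set names")
  sets
}

#' Write a table with a fixed column order
#'
#' All pipeline TSV outputs go through this helper so that identical inputs
#' produce byte-identical files.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_table
#' @param m expression matrix as returned by [read_expression()].
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(df, path)
}

#' Read a signature matrix
#'
#' A TSV with the 96 channel labels in the first column (canonical order,
#' e.g. `A[C>A]A`) and one column of probabilities per signature. Columns
#' must each sum to 1 within 1e-6.
#'
#' @param path path to the TSV.
#' @return 96 x K numeric matrix with channel rownames.
#' @export
read_signature_matrix <- function(path) {
  m <- read_expression(path)
  validate_signature_matrix(m)
}

validate_signature_matrix <- function(m) {
  chans <- sbs_channels()
  if (nrow(m) != 96L) stop("signature matrix must have 96 rows")
  if (!identical(rownames(m), chans)) {
    if (!setequal(rownames(m), chans))
      stop("signature matrix rows are not the 96 canonical channels")
    m <- m[chans, , drop = FALSE]
  }
  if (any(m < 0)) stop("negative entries in signature matrix")
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-6))
    stop("signature column(s) do not sum to 1: ",
         paste(colnames(m)[abs(cs - 1) > 1e-6], collapse = ", "))
  m
}

#' Packaged resource paths
#'
#' Convenience accessors for the synthetic resources shipped with the
#' package: a reduced 22-autosome chromosome map, a synthetic 96 x 13
#' signature matrix (stand-in profiles named after the breast-cancer
#' signature panel; substitute a real COSMIC matrix for real analyses), and
#' a synthetic immune gene set.
#'
#' @param file file name under `extdata`.
#' @return path to the installed file.
#' @export
hrd_extdata <- function(file) {
  p <- system.file("extdata", file, package = "hrdcohort")
  if (p == "") stop("packaged file not found: ", file)
  p
}
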
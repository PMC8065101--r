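# Carrier grouping and biallelic-status resolution for PALB2/BRCA1/BRCA2
# protein-truncating-variant (PTV) tumours. A tumour is biallelic when both
# gene copies are disrupted: a PTV plus loss of the wild-type allele (locus
# LOH) or a second somatic PTV.

#' Classify a variant consequence
#'
#' PTVs are stop-gain, frameshift and canonical splice-site variants.
#'
#' @param consequence consequence string (one per call).
#' @return `"ptv"`, `"missense"` or `"other"`.
#' @export
classify_consequence <- function(consequence) {
  if (!all(consequence %in% CONSEQUENCES))
    stop("unknown consequence: ",
         paste(setdiff(consequence, CONSEQUENCES), collapse = ", "))
  ifelse(consequence %in% PTV_CONSEQUENCES, "ptv",
         ifelse(consequence == "missense", "missense", "other"))
}

#' Assign a sample's carrier group
#'
#' Precedence follows the cohort design: any germline PTV in PALB2, BRCA1 or
#' BRCA2 assigns the (gene, germline) group; otherwise any somatic PTV
#' assigns (gene, somatic); otherwise a missense variant in a studied gene
#' excludes the sample (`excluded_missense`); otherwise `non_carrier`.
#' PTVs in two different studied genes raise an error rather than being
#' silently resolved.
#'
#' @param variants variant data.frame rows for a single sample.
#' @return list with `gene` (or NA), `origin` (or NA), `group` (one of
#'   `"PALB2"`, `"BRCA1"`, `"BRCA2"`, `"excluded_missense"`,
#'   `"non_carrier"`), and `somatic_second_hit` (TRUE when a carrier also
#'   has a distinct somatic PTV in the same gene).
#' @export
assign_carrier_group <- function(variants) {
  if (length(unique(variants$sample_id)) > 1L)
    stop("assign_carrier_group expects variants from a single sample")
  sv <- variants[variants$gene %in% STUDY_GENES, , drop = FALSE]
  none <- list(gene = NA_character_, origin = NA_character_,
               group = "non_carrier", somatic_second_hit = FALSE)
  if (nrow(sv) == 0L) return(none)
  cls <- classify_consequence(sv$consequence)
  ptv <- sv[cls == "ptv", , drop = FALSE]
  if (nrow(ptv) > 0L) {
    genes <- unique(ptv$gene)
    if (length(genes) > 1L)
      stop("PTVs in multiple studied genes (", paste(genes, collapse = ", "),
           ") for sample ", sv$sample_id[1])
    origin <- if (any(ptv$origin == "germline")) "germline" else "somatic"
    n_somatic <- sum(ptv$origin == "somatic")
    second <- (origin == "germline" && n_somatic >= 1L) ||
      (origin == "somatic" && n_somatic >= 2L)
    return(list(gene = genes, origin = origin, group = genes,
                somatic_second_hit = second))
  }
  if (any(cls == "missense"))
    return(list(gene = sv$gene[cls == "missense"][1], origin = NA_character_,
                group = "excluded_missense", somatic_second_hit = FALSE))
  none
}

#' Locus LOH from allele-specific copy number
#'
#' The locus has LOH when the ASCN segment containing it has minor copy
#' number zero; `"unknown"` when no segment overlaps the locus.
#'
#' @param segments segment data.frame for one sample.
#' @param chrom,pos locus coordinates (taken from the variant itself).
#' @return `"loh"`, `"no_loh"` or `"unknown"`.
#' @export
call_locus_loh_ascn <- function(segments, chrom, pos) {
  chrom <- norm_chrom(chrom)
  hit <- segments[segments$chrom == chrom & segments$start <= pos &
                    segments$end >= pos, , drop = FALSE]
  if (nrow(hit) == 0L) return("unknown")
  if (hit$cn_minor[1] == 0L) "loh" else "no_loh"
}

#' Locus LOH from the tumour/germline allele-fraction shift
#'
#' LOH is called when the variant allele fraction in the tumour exceeds the
#' germline allele fraction by more than 20 percentage points (strictly
#' greater than an absolute difference of 0.20). Either fraction missing
#' yields `"unknown"`.
#'
#' @param vaf_tumour,vaf_germline allele fractions in \[0,1\].
#' @param delta threshold on the absolute difference (default 0.20).
#' @return `"loh"`, `"no_loh"` or `"unknown"`.
#' @export
call_locus_loh_vaf <- function(vaf_tumour, vaf_germline, delta = 0.20) {
  if (is.na(vaf_tumour) || is.na(vaf_germline)) return("unknown")
  if (vaf_tumour - vaf_germline > delta) "loh" else "no_loh"
}

#' Resolve biallelic vs monoallelic status from combined evidence
#'
#' Resolution rule: a somatic second hit is biallelic outright. Otherwise
#' the two locus-LOH calls (ASCN and VAF shift) decide when they agree; when
#' they disagree, shallow whole-genome copy-number state breaks the tie
#' (biallelic iff `swgs_state == "loss"`). Any unresolved combination
#' (either method `"unknown"`, or disagreement without a usable tie-break)
#' is monoallelic with an `insufficient_evidence` flag, since downstream
#' analyses dichotomise. Somatic-only carriers, for which the
#' germline-vs-tumour VAF rule is inapplicable, are handled upstream in
#' [classify_cohort()], where the ASCN call alone decides.
#'
#' @param ascn_loh,vaf_loh tri-state calls (`"loh"`, `"no_loh"`,
#'   `"unknown"`).
#' @param somatic_second_hit logical.
#' @param swgs_state `"loss"`, `"neutral_or_gain"` or `"unknown"` (optional
#'   shallow-WGS state, consulted only on disagreement).
#' @return list with `status` (`"biallelic"`/`"monoallelic"`) and `flags`
#'   (character, possibly `"insufficient_evidence"`).
#' @export
resolve_allelic_status <- function(ascn_loh, vaf_loh,
                                   somatic_second_hit = FALSE,
                                   swgs_state = "unknown") {
  tri <- c("loh", "no_loh", "unknown")
  stopifnot(ascn_loh %in% tri, vaf_loh %in% tri,
            swgs_state %in% c("loss", "neutral_or_gain", "unknown"))
  if (isTRUE(somatic_second_hit))
    return(list(status = "biallelic", flags = character(0)))
  known <- c(ascn_loh, vaf_loh)[c(ascn_loh, vaf_loh) != "unknown"]
  if (length(known) == 2L) {
    if (ascn_loh == vaf_loh)
      return(list(status = if (ascn_loh == "loh") "biallelic" else "monoallelic",
                  flags = character(0)))
    # disagreement: sWGS tie-break
    if (swgs_state == "loss")
      return(list(status = "biallelic", flags = "swgs_tiebreak"))
    if (swgs_state == "neutral_or_gain")
      return(list(status = "monoallelic", flags = "swgs_tiebreak"))
    return(list(status = "monoallelic", flags = "insufficient_evidence"))
  }
  list(status = "monoallelic", flags = "insufficient_evidence")
}

#' Somatic driver-mutation prevalence per carrier group
#'
#' Fraction of samples in each carrier group harbouring at least one
#' somatic variant in each driver gene (any consequence), as in an
#' oncoplot prevalence track.
#'
#' @param variants cohort variant data.frame.
#' @param classification data.frame from [classify_cohort()].
#' @param driver_genes genes to tabulate (default TP53 and PIK3CA).
#' @return data.frame: carrier_group, gene, n_mutated, n_group, prevalence.
#' @export
driver_prevalence <- function(variants, classification,
                              driver_genes = c("TP53", "PIK3CA")) {
  groups <- unique(classification$carrier_group)
  rows <- list()
  for (g in groups) {
    ids <- classification$sample_id[classification$carrier_group == g]
    for (dg in driver_genes) {
      mut <- unique(variants$sample_id[variants$gene == dg &
                                         variants$origin == "somatic"])
      n_mut <- sum(ids %in% mut)
      rows[[length(rows) + 1L]] <- data.frame(
        carrier_group = g, gene = dg, n_mutated = n_mut,
        n_group = length(ids), prevalence = n_mut / length(ids),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Classify every sample of a cohort
#'
#' Runs carrier grouping and allelic-status resolution across a cohort.
#' For germline carriers the locus is the germline PTV's own position; for
#' somatic-only carriers the germline-vs-tumour VAF rule is inapplicable and
#' the ASCN call alone (or a second somatic PTV) decides.
#'
#' @param variants cohort variant data.frame.
#' @param segments cohort segment data.frame.
#' @param swgs optional named vector mapping sample_id to a shallow-WGS
#'   state at the gene locus (`"loss"`/`"neutral_or_gain"`/`"unknown"`).
#' @param all_samples optional character vector of sample ids with no
#'   variant rows (classified `non_carrier`).
#' @param vaf_delta threshold for [call_locus_loh_vaf()].
#' @return data.frame: sample_id, carrier_group, origin, allelic_status,
#'   ascn_loh, vaf_loh, somatic_second_hit, swgs_state, flags.
#' @export
classify_cohort <- function(variants, segments, swgs = NULL,
                            all_samples = NULL, vaf_delta = 0.20) {
  ids <- sort(unique(c(variants$sample_id, all_samples)))
  rows <- lapply(ids, function(s) {
    v <- variants[variants$sample_id == s, , drop = FALSE]
    grp <- assign_carrier_group(v)
    out <- data.frame(sample_id = s, carrier_group = grp$group,
                      origin = grp$origin, allelic_status = NA_character_,
                      ascn_loh = NA_character_, vaf_loh = NA_character_,
                      somatic_second_hit = grp$somatic_second_hit,
                      swgs_state = NA_character_, flags = "",
                      stringsAsFactors = FALSE)
    if (!grp$group %in% STUDY_GENES) return(out)
    ptv <- v[v$gene == grp$gene &
               classify_consequence(v$consequence) == "ptv", , drop = FALSE]
    lead <- if (any(ptv$origin == "germline"))
      ptv[ptv$origin == "germline", , drop = FALSE][1, ] else ptv[1, ]
    seg_s <- segments[segments$sample_id == s, , drop = FALSE]
    ascn <- call_locus_loh_ascn(seg_s, lead$chrom, lead$pos)
    vafc <- if (lead$origin == "germline")
      call_locus_loh_vaf(lead$vaf_tumour, lead$vaf_germline, vaf_delta)
    else "unknown"
    sw <- if (!is.null(swgs) && s %in% names(swgs)) swgs[[s]] else "unknown"
    res <- if (lead$origin == "somatic" && !grp$somatic_second_hit) {
      # no germline VAF exists, so the ASCN call alone decides
      if (ascn == "loh") list(status = "biallelic", flags = "ascn_only")
      else if (ascn == "no_loh") list(status = "monoallelic", flags = "ascn_only")
      else list(status = "monoallelic", flags = "insufficient_evidence")
    } else {
      resolve_allelic_status(ascn, vafc, grp$somatic_second_hit, sw)
    }
    out$allelic_status <- res$status
    out$ascn_loh <- ascn
    out$vaf_loh <- vafc
    out$swgs_state <- sw
    out$flags <- paste(res$flags, collapse = ";")
    out
  })
  do.call(rbind, rows)
}
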
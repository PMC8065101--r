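# Synthetic-cohort generator. Emulates a PTV breast-cancer cohort: three
# protein-truncating-variant carrier groups (PALB2/BRCA1/BRCA2, germline
# and somatic) with biallelic subsets, several hundred non-carriers,
# per-stratum SNV burdens, signature-3 weight, scar-event rates, locus LOH
# with the matching tumour-VAF shift, and immune-gene elevation in BRCA1
# tumours. Every file it writes passes the corresponding reader's
# validation and a ground-truth table supports recovery testing.
#
# Implanted scar events are isolated from each other and from the diploid
# baseline by uncovered gaps wider than the LST smoothing length, so each
# event contributes exactly one count to exactly one score and noise-free
# recovery is exact.

GENE_LOCI <- data.frame(
  gene = c("PALB2", "BRCA1", "BRCA2"),
  chrom = c("16", "17", "13"),
  pos = c(23646191L, 41245000L, 32907000L),
  stringsAsFactors = FALSE
)

#' Default generator configuration
#'
#' Group sizes, biallelic subsets, per-stratum SNV-count medians (negative
#' binomial), signature-3 mean weights, scar-event medians (Poisson) and
#' expression effects default to the emulated cohort's conditions;
#' monoallelic scar medians default to fixed intermediate values.
#'
#' @param seed integer seed driving all randomness.
#' @param ... overrides for any default listed below.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # germline / somatic PTV carriers and biallelic subsets per gene
    n_germline = c(PALB2 = 6L, BRCA1 = 10L, BRCA2 = 11L),
    n_somatic = c(PALB2 = 3L, BRCA1 = 6L, BRCA2 = 3L),
    n_biallelic = c(PALB2 = 3L, BRCA1 = 7L, BRCA2 = 7L),
    # one PALB2 tumour is biallelic via a somatic second hit, the rest via LOH
    n_second_hit = c(PALB2 = 1L, BRCA1 = 0L, BRCA2 = 0L),
    n_noncarrier = 500L,
    # somatic SNV count medians per stratum (negative binomial, dispersion 1)
    snv_median = c(biallelic_PALB2 = 125, biallelic_BRCA1 = 146,
                   biallelic_BRCA2 = 214, monoallelic_PALB2 = 74,
                   monoallelic_BRCA1 = 42, monoallelic_BRCA2 = 68,
                   non_carrier = 46),
    nb_dispersion = 1.0,
    # mean signature-3 weight per stratum (Beta-distributed per sample)
    sig3_mean = c(biallelic_PALB2 = 0.489, biallelic_BRCA1 = 0.444,
                  biallelic_BRCA2 = 0.395, monoallelic_PALB2 = 0.188,
                  monoallelic_BRCA1 = 0.151, monoallelic_BRCA2 = 0.306,
                  non_carrier = 0.082),
    sig3_concentration = 30,
    # scar event medians per stratum (Poisson rates)
    scar_rates = list(
      biallelic_PALB2 = c(loh = 14, tai = 27, lst = 22),
      biallelic_BRCA1 = c(loh = 19, tai = 26, lst = 26),
      biallelic_BRCA2 = c(loh = 13, tai = 19, lst = 21),
      monoallelic_PALB2 = c(loh = 8, tai = 12, lst = 10),
      monoallelic_BRCA1 = c(loh = 8, tai = 12, lst = 10),
      monoallelic_BRCA2 = c(loh = 8, tai = 12, lst = 10),
      non_carrier = c(loh = 6, tai = 9, lst = 7)),
    purity = 0.7,
    vaf_noise_sd = 0.02,
    # expression model
    n_filler_genes = 260L,
    expr_sd = 1.0,
    immune_effect_brca1 = 1.5,     # log2 shift on immune genes in BRCA1 tumours
    gene_dosage_effect = -1.5,     # log2 shift of the mutated gene itself
    # driver mutation probabilities per carrier group
    driver_rates = list(
      TP53 = c(PALB2 = 1 / 9, BRCA1 = 10 / 16, BRCA2 = 6 / 14,
               non_carrier = 0.3),
      PIK3CA = c(PALB2 = 2 / 9, BRCA1 = 4 / 16, BRCA2 = 2 / 14,
                 non_carrier = 0.3)),
    signature_path = NULL,          # default: packaged synthetic matrix
    chrom_map_path = NULL           # default: packaged 22-autosome map
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "cohort_config")
}

# negative-binomial mean whose median equals `target` at the given size
nb_mu_for_median <- function(target, size) {
  lo <- 1; hi <- 10 * target + 10
  while (hi - lo > 1e-3) {
    mid <- (lo + hi) / 2
    if (stats::qnbinom(0.5, size = size, mu = mid) < target) lo <- mid else hi <- mid
  }
  hi
}

#' Sample mutation channels from a signature mixture
#'
#' Multinomial draws over the 96 channels from the spectrum
#' `signatures %*% weights` plus a flat background carrying any remaining
#' `1 - sum(weights)` mass.
#'
#' @param weights named non-negative vector of signature weights summing to
#'   at most 1; names must be signature columns.
#' @param signatures 96 x K signature matrix.
#' @param n number of draws.
#' @return character vector of `n` channel labels.
#' @export
spectrum_sampler <- function(weights, signatures, n) {
  if (any(weights < 0)) stop("negative signature weight")
  if (sum(weights) > 1 + 1e-9) stop("signature weights sum above 1")
  if (n == 0L) return(character(0))
  missing <- setdiff(names(weights), colnames(signatures))
  if (length(missing)) stop("unknown signature(s): ", paste(missing, collapse = ", "))
  mix <- rep((1 - sum(weights)) / 96, 96)
  if (length(weights))
    mix <- mix + as.vector(signatures[, names(weights), drop = FALSE] %*% weights)
  sample(sbs_channels(), n, replace = TRUE, prob = mix)
}

channel_decode <- function(channels) {
  data.frame(ref = substr(channels, 3, 3),
             alt = substr(channels, 5, 5),
             tri = paste0(substr(channels, 1, 1), substr(channels, 3, 3),
                          substr(channels, 7, 7)),
             stringsAsFactors = FALSE)
}

clamp01 <- function(x) pmin(pmax(x, 0.01), 0.99)

# --- interval bookkeeping for scar-event placement -------------------------

subtract_interval <- function(free, s, e) {
  out <- list()
  for (iv in free) {
    if (e < iv[1] || s > iv[2]) { out[[length(out) + 1L]] <- iv; next }
    if (iv[1] < s) out[[length(out) + 1L]] <- c(iv[1], s - 1)
    if (iv[2] > e) out[[length(out) + 1L]] <- c(e + 1, iv[2])
  }
  out
}

# find the largest free stretch lying inside a single arm
best_arm_interval <- function(free_by_chrom, chrom_map) {
  best <- NULL
  for (chrom in names(free_by_chrom)) {
    cm <- chrom_map[chrom, ]
    arms <- list(c(1, cm$centromere_start - 1), c(cm$centromere_end + 1, cm$length))
    for (iv in free_by_chrom[[chrom]]) {
      for (arm in arms) {
        s <- max(iv[1], arm[1]); e <- min(iv[2], arm[2])
        if (s > e) next
        if (is.null(best) || (e - s) > (best$e - best$s))
          best <- list(chrom = chrom, s = s, e = e)
      }
    }
  }
  best
}

# does [s, e] lie entirely within one free interval?
is_free <- function(free, s, e) {
  for (iv in free) if (s >= iv[1] && e <= iv[2]) return(TRUE)
  FALSE
}

# Place one sample's scar events; returns list(segments=..., counts=...).
# `locus` (chrom, pos, loh) reserves a clean segment over the germline PTV
# locus for carrier samples: (2,0) when the wild-type allele is lost, (1,1)
# otherwise, so the ASCN locus call reflects the intended ground truth.
place_scar_events <- function(chrom_map, n_loh, n_tai, n_lst,
                              locus = NULL, margin = 3.2e6) {
  chroms <- rownames(chrom_map)
  free <- stats::setNames(lapply(chrom_map$length, function(L) list(c(1, L))),
                          chroms)
  segs <- list()
  add_seg <- function(chrom, s, e, a, b)
    segs[[length(segs) + 1L]] <<- data.frame(chrom = chrom, start = as.integer(s),
                                             end = as.integer(e),
                                             cn_major = a, cn_minor = b,
                                             stringsAsFactors = FALSE)
  # locus reservation first so nothing else can cover it
  placed_loh <- 0L
  if (!is.null(locus)) {
    half <- 8e6
    s <- locus$pos - half; e <- locus$pos + half
    free[[locus$chrom]] <- subtract_interval(free[[locus$chrom]],
                                             s - margin, e + margin)
    if (locus$loh) {
      add_seg(locus$chrom, s, e, 2L, 0L)
      placed_loh <- 1L
      n_loh <- max(n_loh, 1L)
    } else {
      add_seg(locus$chrom, s, e, 1L, 1L)
    }
  }
  # telomeric allelic imbalance events: one per chromosome end
  tel <- expand.grid(chrom = chroms, side = c("p", "q"),
                     stringsAsFactors = FALSE)
  tel <- tel[sample.int(nrow(tel)), ]
  placed_tai <- 0L
  for (i in seq_len(nrow(tel))) {
    if (placed_tai >= n_tai) break
    chrom <- tel$chrom[i]; side <- tel$side[i]
    cm <- chrom_map[chrom, ]
    arm_len <- if (side == "p") cm$centromere_start - 1 else cm$length - cm$centromere_end
    len <- round(stats::runif(1, 11.2e6, 13e6))
    if (len + margin + 1e6 > arm_len) next
    if (side == "p") {
      s <- 1; e <- len
      if (!is_free(free[[chrom]], s, e + margin)) next
      free[[chrom]] <- subtract_interval(free[[chrom]], s, e + margin)
    } else {
      e <- cm$length; s <- e - len + 1
      if (!is_free(free[[chrom]], s - margin, e)) next
      free[[chrom]] <- subtract_interval(free[[chrom]], s - margin, e)
    }
    add_seg(chrom, s, e, 2L, 1L)
    placed_tai <- placed_tai + 1L
  }
  if (placed_tai < n_tai)
    stop("implanted TAI events exceed genome capacity")
  # interior LOH and LST events into the largest remaining arm stretch
  draws <- c(rep("loh", n_loh - placed_loh), rep("lst", n_lst))
  for (ev in draws) {
    need <- if (ev == "loh") round(stats::runif(1, 15.6e6, 18e6)) else 21e6
    slot <- best_arm_interval(free, chrom_map)
    if (is.null(slot) || (slot$e - slot$s + 1) < need + 2 * margin)
      stop("implanted ", toupper(ev), " events exceed genome capacity")
    s <- slot$s + margin
    if (ev == "loh") {
      add_seg(slot$chrom, s, s + need - 1, 2L, 0L)
    } else {
      add_seg(slot$chrom, s, s + 10.5e6 - 1, 1L, 1L)
      add_seg(slot$chrom, s + 10.5e6, s + 21e6 - 1, 2L, 1L)
    }
    free[[slot$chrom]] <- subtract_interval(free[[slot$chrom]],
                                            slot$s, s + need - 1 + margin)
  }
  # diploid baseline over whatever stayed uncovered
  for (chrom in chroms)
    for (iv in free[[chrom]])
      if (iv[2] - iv[1] + 1 >= 1e6) add_seg(chrom, iv[1], iv[2], 1L, 1L)
  list(segments = do.call(rbind, segs),
       counts = c(loh = n_loh, tai = n_tai, lst = n_lst))
}

IMMUNE_GENES <- c("CD8A", "CD3D", "CD3E", "CD2", "GZMB", "GZMK", "GZMH",
                  "PRF1", "NKG7", "KLRB1", "KLRD1", "CCL5", "CXCL9",
                  "CXCL10", "IDO1", "LAG3", "TIGIT", "CTLA4", "PDCD1", "IFNG")

#' Generate a synthetic cohort
#'
#' Writes, under `dir`: `variants.tsv`, `segments.tsv`, `expression.tsv`,
#' `chrom_map.tsv`, `cohort_table.tsv`, `ground_truth.tsv` and
#' `config.txt`, all in the dialects the package readers consume, fully
#' reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the in-memory objects (`variants`,
#'   `segments`, `expression`, `chrom_map`, `cohort_table`,
#'   `ground_truth`) and `paths`.
#' @export
generate_cohort <- function(config = cohort_config(), dir) {
  stopifnot(inherits(config, "cohort_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed)
  chrom_map <- read_chrom_map(config$chrom_map_path %||%
                                hrd_extdata("chrom_map_synthetic.tsv"))
  sigs <- read_signature_matrix(config$signature_path %||%
                                  hrd_extdata("signatures_synthetic.tsv"))
  sig3 <- grep("3$", colnames(sigs), value = TRUE)[1]
  sig1 <- colnames(sigs)[1]
  size <- 1 / config$nb_dispersion
  nb_mu <- vapply(config$snv_median, nb_mu_for_median, 0, size = size)

  # ---- sample roster with ground-truth strata -----------------------------
  roster <- list()
  for (g in STUDY_GENES) {
    ng <- config$n_germline[[g]]; ns <- config$n_somatic[[g]]
    nb <- config$n_biallelic[[g]]; nsh <- config$n_second_hit[[g]]
    ids <- sprintf("%s_%s%02d", g, c(rep("G", ng), rep("S", ns)),
                   c(seq_len(ng), seq_len(ns)))
    origin <- c(rep("germline", ng), rep("somatic", ns))
    status <- rep("monoallelic", ng + ns)
    mech <- rep("none", ng + ns)
    if (nb > nsh) mech[seq_len(nb - nsh)] <- "loh"
    if (nsh > 0) mech[(nb - nsh + 1):nb] <- "second_hit"
    status[seq_len(nb)] <- "biallelic"
    roster[[g]] <- data.frame(sample_id = ids, gene = g, origin = origin,
                              allelic_status = status, mechanism = mech,
                              stringsAsFactors = FALSE)
  }
  nc_ids <- sprintf("NC%03d", seq_len(config$n_noncarrier))
  roster$non_carrier <- data.frame(sample_id = nc_ids, gene = "non_carrier",
                                   origin = NA_character_,
                                   allelic_status = NA_character_,
                                   mechanism = "none", stringsAsFactors = FALSE)
  roster <- do.call(rbind, roster)
  rownames(roster) <- NULL
  roster$stratum <- ifelse(roster$gene == "non_carrier", "non_carrier",
                           paste(roster$allelic_status, roster$gene, sep = "_"))

  # ---- per-sample variants, segments, ground truth ------------------------
  var_rows <- list()
  seg_rows <- list()
  truth_rows <- list()
  add_var <- function(...) var_rows[[length(var_rows) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  pur <- config$purity
  noise <- function(n = 1) stats::rnorm(n, 0, config$vaf_noise_sd)

  for (i in seq_len(nrow(roster))) {
    r <- roster[i, ]
    s <- r$sample_id
    locus_loh <- r$mechanism == "loh"
    # germline / somatic PTV at the gene locus
    if (r$gene != "non_carrier") {
      loc <- GENE_LOCI[GENE_LOCI$gene == r$gene, ]
      cons <- sample(c("stop_gained", "frameshift"), 1)
      ref <- if (cons == "frameshift") "GA" else "G"
      alt <- if (cons == "frameshift") "G" else "A"
      if (r$origin == "germline") {
        vg <- clamp01(0.5 + noise())
        vt <- clamp01(if (locus_loh) 0.5 + pur / 2 + noise() else 0.5 + noise())
        add_var(sample_id = s, chrom = loc$chrom, pos = loc$pos, ref = ref,
                alt = alt, gene = r$gene, consequence = cons,
                origin = "germline", vaf_tumour = vt, vaf_germline = vg,
                tri_context = NA_character_)
      } else {
        vt <- clamp01(pur / 2 + noise())
        add_var(sample_id = s, chrom = loc$chrom, pos = loc$pos, ref = ref,
                alt = alt, gene = r$gene, consequence = cons,
                origin = "somatic", vaf_tumour = vt, vaf_germline = 0,
                tri_context = NA_character_)
      }
      if (r$mechanism == "second_hit") {
        add_var(sample_id = s, chrom = loc$chrom, pos = loc$pos + 50L,
                ref = "C", alt = "T", gene = r$gene,
                consequence = "stop_gained", origin = "somatic",
                vaf_tumour = clamp01(pur / 2 + noise()), vaf_germline = 0,
                tri_context = "ACG")
      }
      # driver mutations
      for (drv in names(config$driver_rates)) {
        if (stats::runif(1) < config$driver_rates[[drv]][[r$gene]])
          add_var(sample_id = s, chrom = "1", pos = 7570000L, ref = "C",
                  alt = "G", gene = drv, consequence = "missense",
                  origin = "somatic", vaf_tumour = clamp01(pur / 2 + noise()),
                  vaf_germline = 0, tri_context = "ACA")
      }
    } else {
      for (drv in names(config$driver_rates)) {
        if (stats::runif(1) < config$driver_rates[[drv]][["non_carrier"]])
          add_var(sample_id = s, chrom = "1", pos = 7570000L, ref = "C",
                  alt = "G", gene = drv, consequence = "missense",
                  origin = "somatic", vaf_tumour = clamp01(pur / 2 + noise()),
                  vaf_germline = 0, tri_context = "ACA")
      }
    }
    # somatic SNV catalogue from the stratum's signature mixture
    n_snv <- stats::rnbinom(1, size = size, mu = nb_mu[[r$stratum]])
    m3 <- config$sig3_mean[[r$stratum]]
    k <- config$sig3_concentration
    w3 <- stats::rbeta(1, m3 * k, (1 - m3) * k)
    # HRD signature plus an ageing-like background; weights sum to 1 so the
    # emitted spectrum lies in the span of the fitting panel
    weights <- stats::setNames(c(w3, 1 - w3), c(sig3, sig1))
    if (n_snv > 0) {
      chan <- spectrum_sampler(weights, sigs, n_snv)
      dec <- channel_decode(chan)
      flip <- stats::runif(n_snv) < 0.5   # emit half on the purine strand
      dec$ref[flip] <- unname(REVCOMP[dec$ref[flip]])
      dec$alt[flip] <- unname(REVCOMP[dec$alt[flip]])
      dec$tri[flip] <- revcomp(dec$tri[flip])
      chrom <- sample(rownames(chrom_map), n_snv, replace = TRUE,
                      prob = chrom_map$length)
      pos <- floor(stats::runif(n_snv, 1, chrom_map[chrom, "length"]))
      add_var(sample_id = s, chrom = chrom, pos = as.integer(pos),
              ref = dec$ref, alt = dec$alt, gene = "OTHER",
              consequence = "other", origin = "somatic",
              vaf_tumour = clamp01(pur / 2 + noise(n_snv)),
              vaf_germline = 0, tri_context = dec$tri)
    }
    # scar events; Poisson draws truncated at the genome's physical
    # capacity (telomere count for TAI, arm space for interior events),
    # which bounds real scores the same way
    rates <- config$scar_rates[[r$stratum]]
    n_tai_draw <- min(stats::rpois(1, rates[["tai"]]),
                      2L * nrow(chrom_map) - 6L)
    n_loh_draw <- stats::rpois(1, rates[["loh"]])
    n_lst_draw <- stats::rpois(1, rates[["lst"]])
    while (n_loh_draw + n_lst_draw > 60L) {
      if (n_lst_draw >= n_loh_draw) n_lst_draw <- n_lst_draw - 1L
      else n_loh_draw <- n_loh_draw - 1L
    }
    ev <- place_scar_events(
      chrom_map,
      n_loh = n_loh_draw,
      n_tai = n_tai_draw,
      n_lst = n_lst_draw,
      locus = if (r$gene %in% STUDY_GENES) {
        loc <- GENE_LOCI[GENE_LOCI$gene == r$gene, ]
        list(chrom = loc$chrom, pos = loc$pos, loh = locus_loh)
      } else NULL)
    seg <- ev$segments
    seg$sample_id <- s
    seg_rows[[length(seg_rows) + 1L]] <- seg[, SEGMENT_COLS]
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      sample_id = s, carrier_group = r$gene,
      origin = r$origin, allelic_status = r$allelic_status,
      mechanism = r$mechanism, locus_loh = locus_loh,
      n_snv = n_snv, sig3_weight = w3,
      loh_events = ev$counts[["loh"]], tai_events = ev$counts[["tai"]],
      lst_events = ev$counts[["lst"]], purity = pur,
      stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, var_rows)
  segments <- validate_segments(do.call(rbind, seg_rows))
  truth <- do.call(rbind, truth_rows)

  # ---- expression matrix --------------------------------------------------
  filler <- sprintf("GENE%03d", seq_len(config$n_filler_genes))
  genes <- unique(c("GZMA", IMMUNE_GENES, STUDY_GENES, filler))
  base <- stats::runif(length(genes), 2, 8)
  names(base) <- genes
  expr <- matrix(stats::rnorm(length(genes) * nrow(roster), mean = base,
                              sd = config$expr_sd),
                 nrow = length(genes), dimnames = list(genes, roster$sample_id))
  imm <- c("GZMA", IMMUNE_GENES)
  brca1_ids <- roster$sample_id[roster$gene == "BRCA1"]
  expr[imm, brca1_ids] <- expr[imm, brca1_ids] + config$immune_effect_brca1
  for (g in STUDY_GENES) {
    ids <- roster$sample_id[roster$gene == g & roster$origin == "germline"]
    expr[g, ids] <- expr[g, ids] + config$gene_dosage_effect
  }
  expr <- round(pmax(expr, 0), 4)

  # ---- cohort table -------------------------------------------------------
  er <- ifelse(roster$gene == "BRCA1",
               sample(c("pos", "neg"), nrow(roster), TRUE, c(0.2, 0.8)),
               sample(c("pos", "neg"), nrow(roster), TRUE, c(0.6, 0.4)))
  cohort_table <- data.frame(
    sample_id = roster$sample_id,
    er = er,
    pr = sample(c("pos", "neg"), nrow(roster), TRUE),
    her2 = sample(c("pos", "neg"), nrow(roster), TRUE, c(0.2, 0.8)),
    grade = sample(c("1", "2", "3"), nrow(roster), TRUE, c(0.1, 0.4, 0.5)),
    stringsAsFactors = FALSE)

  # ---- write everything ---------------------------------------------------
  paths <- list(
    variants = file.path(dir, "variants.tsv"),
    segments = file.path(dir, "segments.tsv"),
    expression = file.path(dir, "expression.tsv"),
    chrom_map = file.path(dir, "chrom_map.tsv"),
    cohort_table = file.path(dir, "cohort_table.tsv"),
    ground_truth = file.path(dir, "ground_truth.tsv"),
    config = file.path(dir, "config.txt"))
  write_table(variants, paths$variants)
  seg_out <- data.frame(sample_id = segments$sample_id,
                        chromosome = segments$chrom,
                        start.pos = segments$start, end.pos = segments$end,
                        A = segments$cn_major, B = segments$cn_minor,
                        check.names = FALSE, stringsAsFactors = FALSE)
  write_table(seg_out, paths$segments)
  write_expression(expr, paths$expression)
  cm_out <- data.frame(chrom = rownames(chrom_map),
                       length = chrom_map$length,
                       centromere_start = chrom_map$centromere_start,
                       centromere_end = chrom_map$centromere_end)
  write_table(cm_out, paths$chrom_map)
  write_table(cohort_table, paths$cohort_table)
  write_table(truth, paths$ground_truth)
  scalars <- config[vapply(config, function(x)
    is.atomic(x) && length(x) == 1L, TRUE)]
  writeLines(paste0(names(scalars), "=", unlist(scalars)), paths$config)

  invisible(list(variants = variants, segments = segments, expression = expr,
                 chrom_map = chrom_map, cohort_table = cohort_table,
                 ground_truth = truth, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
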
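# Shared fixtures, built in code at test time.

# toy genome: two chromosomes with central centromeres
toy_map <- function() {
  df <- data.frame(chrom = c("1", "2"),
                   length = c(100e6, 200e6),
                   centromere_start = c(45e6, 95e6),
                   centromere_end = c(55e6, 105e6))
  rownames(df) <- df$chrom
  df
}

seg <- function(chrom, start, end, a, b, sample_id = "S1") {
  data.frame(sample_id = sample_id, chrom = as.character(chrom),
             start = as.integer(start), end = as.integer(end),
             cn_major = as.integer(a), cn_minor = as.integer(b),
             stringsAsFactors = FALSE)
}

segs <- function(...) do.call(rbind, list(...))

variant_row <- function(sample_id = "S1", chrom = "16", pos = 23646191L,
                        ref = "G", alt = "A", gene = "PALB2",
                        consequence = "stop_gained", origin = "germline",
                        vaf_tumour = 0.5, vaf_germline = 0.5,
                        tri_context = NA_character_) {
  data.frame(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, gene = gene, consequence = consequence,
             origin = origin, vaf_tumour = vaf_tumour,
             vaf_germline = vaf_germline, tri_context = tri_context,
             stringsAsFactors = FALSE)
}

# hand-counted scar fixtures: list(segments, expected c(loh, tai, lst))
# chromosome 1: 100 Mb, centromere 45-55 Mb; chromosome 2: 200 Mb, 95-105 Mb
scar_fixtures <- function() {
  M <- 1e6
  list(
    loh_interior_20mb = list(
      segs(seg(1, 1 * M, 21 * M, 2, 0)), c(1, 0, 0)),
    loh_whole_chromosome = list(
      segs(seg(1, 1, 100 * M, 2, 0)), c(0, 0, 0)),
    loh_two_adjacent_10mb = list(
      segs(seg(1, 1 * M, 11 * M - 1, 1, 0), seg(1, 11 * M, 21 * M - 1, 1, 0)),
      c(1, 0, 0)),
    loh_14mb_too_short = list(
      segs(seg(1, 1 * M, 15 * M - 1, 2, 0)), c(0, 0, 0)),
    loh_exactly_15mb_not_counted = list(
      segs(seg(1, 1 * M, 16 * M - 1, 2, 0)), c(0, 0, 0)),
    homozygous_deletion_not_loh = list(
      segs(seg(1, 1 * M, 21 * M, 0, 0)), c(0, 0, 0)),
    loh_telomeric_also_tai = list(
      segs(seg(1, 1, 20 * M, 2, 0)), c(1, 1, 0)),
    tai_p_15mb = list(
      segs(seg(1, 1, 15 * M, 2, 1)), c(0, 1, 0)),
    tai_interior_not_counted = list(
      segs(seg(1, 5 * M, 20 * M, 2, 1)), c(0, 0, 0)),
    tai_q_telomere = list(
      segs(seg(1, 85 * M + 1, 100 * M, 2, 1)), c(0, 1, 0)),
    tai_crossing_centromere = list(
      segs(seg(1, 40 * M, 100 * M, 2, 1)), c(0, 0, 0)),
    tai_10mb_too_short = list(
      segs(seg(1, 1, 10 * M, 2, 1)), c(0, 0, 0)),
    tai_exactly_11mb = list(
      segs(seg(1, 1, 11 * M, 2, 1)), c(0, 1, 0)),
    tai_both_ends = list(
      segs(seg(1, 1, 15 * M, 2, 1), seg(1, 88 * M + 1, 100 * M, 2, 1)),
      c(0, 2, 0)),
    tai_merged_two_states = list(
      segs(seg(1, 1, 8 * M, 3, 1), seg(1, 8 * M + 1, 16 * M, 2, 1)),
      c(0, 1, 0)),
    lst_one_breakpoint = list(
      segs(seg(2, 1 * M, 21 * M - 1, 1, 1), seg(2, 21 * M, 41 * M - 1, 2, 1)),
      c(0, 0, 1)),
    lst_smoothed_flanks_merge = list(
      segs(seg(2, 1 * M, 21 * M - 1, 1, 1), seg(2, 21 * M, 23 * M - 1, 3, 0),
           seg(2, 23 * M, 43 * M - 1, 1, 1)),
      c(0, 0, 0)),
    lst_middle_flank_short = list(
      segs(seg(2, 1 * M, 21 * M - 1, 1, 1), seg(2, 21 * M, 29 * M - 1, 2, 1),
           seg(2, 29 * M, 49 * M - 1, 2, 2)),
      c(0, 0, 0)),
    lst_two_breakpoints = list(
      segs(seg(2, 1 * M, 21 * M - 1, 1, 1), seg(2, 21 * M, 33 * M - 1, 2, 1),
           seg(2, 33 * M, 53 * M - 1, 1, 1)),
      c(0, 0, 2)),
    lst_gap_too_wide = list(
      segs(seg(2, 1 * M, 21 * M - 1, 1, 1), seg(2, 26 * M, 46 * M - 1, 2, 1)),
      c(0, 0, 0)),
    lst_small_segment_removed_gap_ok = list(
      segs(seg(2, 1 * M, 21 * M - 1, 1, 1), seg(2, 21 * M, 23 * M - 1, 5, 5),
           seg(2, 23 * M, 43 * M - 1, 2, 1)),
      c(0, 0, 1)),
    lst_across_centromere_no_breakpoint = list(
      segs(seg(1, 25 * M, 44 * M, 1, 1), seg(1, 56 * M, 76 * M, 2, 1)),
      c(0, 0, 0)),
    multi_chromosome_combined = list(
      segs(seg(1, 1 * M, 21 * M, 2, 0),
           seg(2, 1 * M, 21 * M - 1, 1, 1), seg(2, 21 * M, 41 * M - 1, 2, 1)),
      c(1, 0, 1)),
    empty_segment_list = list(
      seg(1, 1, 1, 1, 1)[0, ], c(0, 0, 0))
  )
}

# small synthetic cohort shared across test files (generated once per run)
.tiny_cohort_cache <- new.env(parent = emptyenv())
tiny_cohort <- function(seed = 101, noise_free = TRUE) {
  key <- paste0("c", seed, "_", noise_free)
  if (!is.null(.tiny_cohort_cache[[key]])) return(.tiny_cohort_cache[[key]])
  dir <- file.path(tempdir(), paste0("tiny_cohort_", key))
  cfg <- cohort_config(seed = seed, n_noncarrier = 8L,
                       vaf_noise_sd = if (noise_free) 0 else 0.02)
  res <- suppressMessages(generate_cohort(cfg, dir))
  res$dir <- dir
  .tiny_cohort_cache[[key]] <- res
  res
}

# full enumeration oracle for the two-sided Mann-Whitney p value
mw_enum_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(length(pooled), nx)
  U_all <- apply(combs, 2, function(idx)
    sum(rank(pooled)[idx]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  # two-sided: fraction of labelings at least as extreme as observed
  mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-9)
}

catalog_from_channels <- function(ch)
  as.integer(table(factor(ch, levels = sbs_channels())))

# exhaustive 0.01-resolution grid search over the weight simplex (K <= 3)
grid_oracle_sse <- function(spectrum, S) {
  k <- ncol(S)
  best <- Inf
  if (k == 2) {
    for (i in 0:100) {
      w <- c(i, 100 - i) / 100
      best <- min(best, sum((spectrum - as.vector(S %*% w))^2))
    }
  } else if (k == 3) {
    for (i in 0:100) for (j in 0:(100 - i)) {
      w <- c(i, j, 100 - i - j) / 100
      best <- min(best, sum((spectrum - as.vector(S %*% w))^2))
    }
  } else stop("oracle supports K <= 3")
  best
}
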
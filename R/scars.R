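# Genomic scar scores from allele-specific copy number: counts of large
# LOH regions, telomeric allelic imbalances and large-scale state
# transitions, plus their sum (HRD-sum), a genomic proxy for homologous
# recombination deficiency.
#
# Runs of same-status segments are merged only when abutting (gap <= 1 bp);
# run length is end - start + 1 on 1-based inclusive coordinates.

merge_runs <- function(seg, keep) {
  # collapse abutting TRUE-flagged segments into runs; returns start/end
  runs <- list()
  i <- 1L
  n <- nrow(seg)
  while (i <= n) {
    if (!keep[i]) { i <- i + 1L; next }
    s <- seg$start[i]; e <- seg$end[i]
    while (i < n && keep[i + 1L] && seg$start[i + 1L] <= e + 1L) {
      i <- i + 1L
      e <- max(e, seg$end[i])
    }
    runs[[length(runs) + 1L]] <- c(s, e)
    i <- i + 1L
  }
  if (!length(runs)) return(data.frame(start = integer(0), end = integer(0)))
  m <- do.call(rbind, runs)
  data.frame(start = m[, 1], end = m[, 2])
}

chrom_row <- function(chrom_map, chrom) {
  chrom <- norm_chrom(chrom)
  if (!chrom %in% rownames(chrom_map))
    stop("chromosome absent from chromosome map: ", chrom)
  chrom_map[chrom, ]
}

#' LOH scar score
#'
#' Counts maximal runs of minor copy number zero (with at least one major
#' copy retained) longer than `min_len`, excluding runs spanning an entire
#' chromosome. Abutting qualifying segments are merged before the length
#' test.
#'
#' @param segments segment data.frame for one sample.
#' @param chrom_map chromosome map (see [read_chrom_map()]).
#' @param min_len minimum run length in bp (default 15 Mb).
#' @return non-negative integer count.
#' @export
score_loh <- function(segments, chrom_map, min_len = 15e6) {
  total <- 0L
  for (chrom in unique(segments$chrom)) {
    cm <- chrom_row(chrom_map, chrom)
    seg <- segments[segments$chrom == chrom, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    runs <- merge_runs(seg, seg$cn_minor == 0L & seg$cn_major >= 1L)
    if (!nrow(runs)) next
    len <- runs$end - runs$start + 1
    whole <- runs$start <= 1L & runs$end >= cm$length
    total <- total + sum(len > min_len & !whole)
  }
  total
}

#' Telomeric allelic imbalance (TAI) score
#'
#' Counts merged allelic-imbalance runs (major != minor copy number) that
#' reach a chromosome end, stay on one side of the centromere interval,
#' span less than the whole chromosome, and are at least `min_len` long.
#'
#' @inheritParams score_loh
#' @param min_len minimum run length in bp (default 11 Mb).
#' @return non-negative integer count.
#' @export
score_tai <- function(segments, chrom_map, min_len = 11e6) {
  total <- 0L
  for (chrom in unique(segments$chrom)) {
    cm <- chrom_row(chrom_map, chrom)
    seg <- segments[segments$chrom == chrom, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    runs <- merge_runs(seg, seg$cn_major != seg$cn_minor)
    if (!nrow(runs)) next
    len <- runs$end - runs$start + 1
    at_p <- runs$start <= 1L & runs$end < cm$centromere_start
    at_q <- runs$end >= cm$length & runs$start > cm$centromere_end
    whole <- runs$start <= 1L & runs$end >= cm$length
    total <- total + sum((at_p | at_q) & !whole & len >= min_len)
  }
  total
}

split_at_centromere <- function(seg, cm) {
  # split segments overlapping the centromere; the part inside is dropped
  out <- list()
  for (i in seq_len(nrow(seg))) {
    s <- seg$start[i]; e <- seg$end[i]
    if (e < cm$centromere_start || s > cm$centromere_end) {
      out[[length(out) + 1L]] <- seg[i, ]
      next
    }
    if (s < cm$centromere_start) {
      row <- seg[i, ]; row$end <- cm$centromere_start - 1L
      out[[length(out) + 1L]] <- row
    }
    if (e > cm$centromere_end) {
      row <- seg[i, ]; row$start <- cm$centromere_end + 1L
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) return(seg[0, ])
  do.call(rbind, out)
}

smooth_arm <- function(arm, smooth_len) {
  # drop short segments, then merge identical-state neighbours separated by
  # less than smooth_len
  arm <- arm[arm$end - arm$start + 1 >= smooth_len, , drop = FALSE]
  if (nrow(arm) < 2L) return(arm)
  out <- arm[1, ]
  for (i in 2:nrow(arm)) {
    last <- nrow(out)
    gap <- arm$start[i] - out$end[last] - 1
    if (gap < smooth_len && arm$cn_major[i] == out$cn_major[last] &&
        arm$cn_minor[i] == out$cn_minor[last]) {
      out$end[last] <- arm$end[i]
    } else {
      out <- rbind(out, arm[i, ])
    }
  }
  out
}

#' Large-scale state transition (LST) score
#'
#' Per chromosome arm (segments overlapping the centromere are split at its
#' boundaries): segments shorter than `smooth_len` are removed, adjacent
#' segments with identical allele-specific state are merged, and the score
#' counts breakpoints whose flanking segments are each at least `min_len`
#' long and separated by less than `smooth_len`.
#'
#' @inheritParams score_loh
#' @param smooth_len smoothing length in bp (default 3 Mb).
#' @param min_len minimum flank length in bp (default 10 Mb).
#' @return non-negative integer count.
#' @export
score_lst <- function(segments, chrom_map, smooth_len = 3e6, min_len = 10e6) {
  total <- 0L
  for (chrom in unique(segments$chrom)) {
    cm <- chrom_row(chrom_map, chrom)
    seg <- split_at_centromere(segments[segments$chrom == chrom, , drop = FALSE], cm)
    if (!nrow(seg)) next
    mid <- (seg$start + seg$end) / 2
    for (arm_sel in list(mid < cm$centromere_start, mid > cm$centromere_end)) {
      arm <- seg[arm_sel, , drop = FALSE]
      arm <- arm[order(arm$start), , drop = FALSE]
      arm <- smooth_arm(arm, smooth_len)
      if (nrow(arm) < 2L) next
      len <- arm$end - arm$start + 1
      gap <- arm$start[-1] - arm$end[-nrow(arm)] - 1
      ok <- len[-length(len)] >= min_len & len[-1] >= min_len & gap < smooth_len
      total <- total + sum(ok)
    }
  }
  total
}

#' All three scar scores for one sample
#'
#' @inheritParams score_loh
#' @param sample_id label carried into the result.
#' @return data.frame row: sample_id, loh, tai, lst, hrd_sum.
#' @export
score_sample <- function(segments, chrom_map, sample_id = NA_character_) {
  loh <- score_loh(segments, chrom_map)
  tai <- score_tai(segments, chrom_map)
  lst <- score_lst(segments, chrom_map)
  data.frame(sample_id = sample_id, loh = loh, tai = tai, lst = lst,
             hrd_sum = loh + tai + lst, stringsAsFactors = FALSE)
}

#' Scar scores for every sample of a cohort
#'
#' @param segments cohort segment data.frame.
#' @param chrom_map chromosome map.
#' @return data.frame, one row per sample.
#' @export
score_cohort <- function(segments, chrom_map) {
  ids <- sort(unique(segments$sample_id))
  do.call(rbind, lapply(ids, function(s)
    score_sample(segments[segments$sample_id == s, , drop = FALSE],
                 chrom_map, s)))
}
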
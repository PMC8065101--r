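test_that("consequence classification separates PTVs, missense and other", {
  expect_equal(classify_consequence("stop_gained"), "ptv")
  expect_equal(classify_consequence("splice_acceptor"), "ptv")
  expect_equal(classify_consequence("missense"), "missense")
  expect_equal(classify_consequence("other"), "other")
  expect_error(classify_consequence("synonymous"), "unknown consequence")
})

test_that("carrier grouping follows germline > somatic > missense precedence", {
  # germline PTV plus somatic PTV in the same gene: germline group with a
  # recorded second hit
  v <- rbind(variant_row(origin = "germline"),
             variant_row(pos = 23646241, consequence = "frameshift",
                         ref = "GA", alt = "G", origin = "somatic"))
  g <- assign_carrier_group(v)
  expect_equal(g$group, "PALB2")
  expect_equal(g$origin, "germline")
  expect_true(g$somatic_second_hit)

  # missense only: excluded
  g <- assign_carrier_group(variant_row(consequence = "missense"))
  expect_equal(g$group, "excluded_missense")

  # nothing in the studied genes
  g <- assign_carrier_group(variant_row(gene = "TP53",
                                        consequence = "missense"))
  expect_equal(g$group, "non_carrier")

  # somatic-only PTV
  g <- assign_carrier_group(variant_row(origin = "somatic",
                                        vaf_germline = 0))
  expect_equal(g$group, "PALB2")
  expect_equal(g$origin, "somatic")
  expect_false(g$somatic_second_hit)

  # PTVs in two studied genes: surfaced, not silently resolved
  v <- rbind(variant_row(gene = "PALB2"),
             variant_row(gene = "BRCA1", chrom = "17", pos = 41245000))
  expect_error(assign_carrier_group(v), "multiple studied genes")
})

test_that("locus LOH calls from ASCN and from the VAF shift", {
  s <- segs(seg(16, 23e6, 24e6, 2, 0), seg(16, 30e6, 40e6, 1, 1))
  expect_equal(call_locus_loh_ascn(s, "16", 23646191), "loh")
  expect_equal(call_locus_loh_ascn(s, "16", 35e6), "no_loh")
  expect_equal(call_locus_loh_ascn(s, "16", 25e6), "unknown")  # segment gap

  expect_equal(call_locus_loh_vaf(0.75, 0.50), "loh")      # 0.25 > 0.20
  expect_equal(call_locus_loh_vaf(0.65, 0.50), "no_loh")   # 0.15 <= 0.20
  expect_equal(call_locus_loh_vaf(0.70, 0.50), "no_loh")   # boundary: strict
  expect_equal(call_locus_loh_vaf(0.70, NA), "unknown")
})

test_that("allelic status resolution covers all 54 evidence combinations", {
  tri <- c("loh", "no_loh", "unknown")
  sw <- c("loss", "neutral_or_gain", "unknown")
  grid <- expand.grid(ascn = tri, vaf = tri, hit = c(TRUE, FALSE),
                      swgs = sw, stringsAsFactors = FALSE)
  expect_equal(nrow(grid), 54L)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    res <- resolve_allelic_status(g$ascn, g$vaf, g$hit, g$swgs)
    expect_true(res$status %in% c("biallelic", "monoallelic"))
    # independent statement of the rule
    expected <- if (g$hit) "biallelic"
      else if (g$ascn == "loh" && g$vaf == "loh") "biallelic"
      else if (g$ascn == "no_loh" && g$vaf == "no_loh") "monoallelic"
      else if (g$ascn %in% c("loh", "no_loh") && g$vaf %in% c("loh", "no_loh")) {
        if (g$swgs == "loss") "biallelic" else "monoallelic"
      } else "monoallelic"
    expect_equal(res$status, expected,
                 info = paste(g$ascn, g$vaf, g$hit, g$swgs))
  }
})

test_that("adding LOH evidence never flips biallelic to monoallelic", {
  tri <- c("loh", "no_loh", "unknown")
  sw <- c("loss", "neutral_or_gain", "unknown")
  stronger <- function(v) unique(c(v, "loh"))   # upgrade any call to loh
  for (ascn in tri) for (vaf in tri) for (hit in c(FALSE, TRUE)) for (s in sw) {
    before <- resolve_allelic_status(ascn, vaf, hit, s)$status
    if (before != "biallelic") next
    for (a2 in stronger(ascn)) for (v2 in stronger(vaf)) {
      after <- resolve_allelic_status(a2, v2, hit, s)$status
      expect_equal(after, "biallelic",
                   info = paste(ascn, vaf, hit, s, "->", a2, v2))
    }
  }
})

test_that("cohort classification recovers generator ground truth when noise-free", {
  co <- tiny_cohort()
  cls <- suppressMessages(
    classify_cohort(co$variants, co$segments,
                    all_samples = co$ground_truth$sample_id))
  m <- merge(co$ground_truth, cls, by = "sample_id",
             suffixes = c(".true", ".called"))
  carriers <- m[m$carrier_group.true %in% c("PALB2", "BRCA1", "BRCA2"), ]
  expect_equal(carriers$allelic_status.called, carriers$allelic_status.true)
  non <- m[m$carrier_group.true == "non_carrier", ]
  expect_true(all(non$carrier_group.called == "non_carrier"))
  # the second-hit tumour is biallelic even without locus LOH
  sh <- m[m$mechanism == "second_hit", ]
  expect_true(all(sh$allelic_status.called == "biallelic"))
  expect_true(all(sh$somatic_second_hit))
})

test_that("driver prevalence counts mutated samples per group", {
  v <- suppressMessages(read_variants(hrd_extdata("ptv_variants_synthetic.tsv")))
  s <- read_segments(hrd_extdata("ptv_segments_synthetic.tsv"))
  cls <- classify_cohort(v, s)
  dp <- driver_prevalence(v, cls)
  expect_equal(dp$prevalence[dp$carrier_group == "PALB2" & dp$gene == "TP53"],
               1 / 9)
  expect_equal(dp$prevalence[dp$carrier_group == "BRCA1" & dp$gene == "TP53"],
               10 / 16)
})
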
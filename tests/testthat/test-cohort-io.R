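test_that("variant TSV rows map to validated records and bad rows are rejected", {
  f <- tempfile(fileext = ".tsv")
  df <- rbind(
    variant_row("S1", "chr16", 23646191, "G", "A", "PALB2", "stop_gained",
                "germline", 0.48, 0.50),
    variant_row("S2", "16", 0, "G", "A", "PALB2", "stop_gained",
                "germline", 0.5, 0.5),          # pos 0: invariant violation
    variant_row("S3", "16", 100, "G", "G", "PALB2", "stop_gained",
                "germline", 0.5, 0.5),          # ref == alt
    variant_row("S4", "16", 100, "C", "T", "PALB2", "weird_csq",
                "germline", 0.5, 0.5))          # unknown consequence
  write_table(df, f)
  expect_message(v <- read_variants(f), "3 variant record\\(s\\) rejected")
  expect_equal(nrow(v), 1L)
  expect_equal(v$consequence, "stop_gained")
  expect_equal(v$chrom, "16")   # chr prefix normalised away
  expect_equal(v$vaf_tumour, 0.48)
})

test_that("VCF dialect yields VAF = alt depth over total depth", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"c\">",
    "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"o\">",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"s\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOUR\tGERMLINE",
    paste0("16\t23646191\t.\tG\tA\t.\tPASS\t",
           "GENE=PALB2;CSQ=stop_gained;ORIGIN=germline;SAMPLE=S1\tAD\t30,30\t30,30"))
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  v <- read_variants(f, dialect = "vcf")
  expect_equal(v$vaf_tumour, 0.5)   # 30 / (30 + 30)
  expect_equal(v$gene, "PALB2")
  expect_equal(v$pos, 23646191L)
})

test_that("segment reader sorts, swaps B>A with a warning, rejects overlaps", {
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = "S1", chromosome = c("chr1", "chr1"),
                   start.pos = c(2000000, 1), end.pos = c(3000000, 1000000),
                   A = c(2, 1), B = c(1, 2))
  write_table(df, f)
  expect_warning(s <- read_segments(f), "minor > major")
  expect_equal(s$start, c(1L, 2000000L))           # returned sorted
  expect_equal(s$cn_major[1], 2L)                  # swapped to canonical form
  expect_equal(s$cn_minor[1], 1L)

  bad <- data.frame(sample_id = "S1", chromosome = "1",
                    start.pos = c(1, 500), end.pos = c(1000, 1500),
                    A = c(1, 1), B = c(1, 1))
  write_table(bad, f)
  expect_error(read_segments(f), "overlapping segments in sample S1")
})

test_that("expression matrix round-trips and rejects duplicates and gaps", {
  m <- matrix(c(1.5, 2.25, 3.125, 4), 2,
              dimnames = list(c("G1", "G2"), c("A", "B")))
  f <- tempfile(fileext = ".tsv")
  write_expression(m, f)
  expect_identical(read_expression(f), m)   # round-trip identity

  dup <- data.frame(gene = c("G1", "G1"), A = c(1, 2))
  write_table(dup, f)
  expect_error(read_expression(f), "duplicate gene symbols")

  gap <- data.frame(gene = c("G1", "G2"), A = c(1, NA))
  write_table(gap, f)
  expect_error(read_expression(f), "missing expression values")
})

test_that("chromosome map validation enforces centromere bounds", {
  f <- tempfile(fileext = ".tsv")
  good <- data.frame(chrom = "1", length = 100, centromere_start = 40,
                     centromere_end = 60)
  write_table(good, f)
  expect_equal(read_chrom_map(f)$length, 100)
  bad <- good
  bad$centromere_end <- 120   # beyond chromosome length
  write_table(bad, f)
  expect_error(read_chrom_map(f), "invalid centromere")
})

test_that("signature matrix and gene set readers validate their formats", {
  sigs <- read_signature_matrix(hrd_extdata("signatures_synthetic.tsv"))
  expect_equal(dim(sigs), c(96L, 13L))
  expect_equal(unname(colSums(sigs)), rep(1, 13), tolerance = 1e-6)
  expect_identical(rownames(sigs), sbs_channels())
  bad <- sigs
  bad[1, 1] <- bad[1, 1] + 0.1
  expect_error(hrdcohort:::validate_signature_matrix(bad), "do not sum to 1")

  sets <- read_gene_sets(hrd_extdata("immune_geneset_synthetic.gmt"))
  expect_equal(length(sets), 1L)
  expect_true(all(c("CD8A", "PRF1") %in% sets[[1]]))
})

test_that("readers are deterministic for identical input files", {
  co <- tiny_cohort()
  v1 <- suppressMessages(read_variants(co$paths$variants))
  v2 <- suppressMessages(read_variants(co$paths$variants))
  expect_identical(v1, v2)
  expect_identical(read_segments(co$paths$segments),
                   read_segments(co$paths$segments))
})
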
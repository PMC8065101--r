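# Pipeline orchestration: each stage reads the fixed-name cohort files,
# writes its TSV outputs and a parameter log, and "all" chains every stage
# into a per-sample summary table (the tabular analogue of a cohort
# phenobar). All randomness flows from one top-level seed, split
# deterministically per stage, so a repeated run is byte-identical.

PIPELINE_STAGES <- c("simulate", "classify", "signatures", "scars",
                     "immune", "compare", "all")

pipeline_defaults <- function() {
  list(vaf_loh_delta = 0.20, min_snvs = 15, weight_cutoff = 0.06,
       refit_tol = 1e-3, n_controls = 30, iters = 1000,
       signature_path = NULL, immune_set_path = NULL)
}

log_lines <- function(path, lines) {
  con <- file(path, "a")
  on.exit(close(con))
  writeLines(lines, con)
}

load_inputs <- function(dir, what) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing input: ", p)
    p
  }
  out <- list()
  if ("variants" %in% what) out$variants <- read_variants(need("variants.tsv"))
  if ("segments" %in% what) out$segments <- read_segments(need("segments.tsv"))
  if ("expression" %in% what) out$expression <- read_expression(need("expression.tsv"))
  if ("chrom_map" %in% what) out$chrom_map <- read_chrom_map(need("chrom_map.tsv"))
  if ("cohort_table" %in% what) {
    p <- file.path(dir, "cohort_table.tsv")
    out$cohort_table <- if (file.exists(p))
      utils::read.delim(p, stringsAsFactors = FALSE) else NULL
  }
  out
}

all_sample_ids <- function(dir, inputs) {
  if (!is.null(inputs$cohort_table)) return(inputs$cohort_table$sample_id)
  sort(unique(c(inputs$variants$sample_id, inputs$segments$sample_id)))
}

#' Run a pipeline stage
#'
#' Stages: `simulate` (write a synthetic cohort into `out_dir`),
#' `classify`, `signatures`, `scars`, `immune`, `compare` (each reads the
#' cohort files in `input_dir` and writes its TSV into `out_dir`), and
#' `all` (simulate when `input_dir` is NULL, then chain every stage and
#' write the per-sample `summary.tsv`). A `log.txt` in `out_dir` records
#' every threshold used, the seed and record counts.
#'
#' @param stage one of `r paste(PIPELINE_STAGES, collapse = ", ")`.
#' @param input_dir directory with `variants.tsv`, `segments.tsv`,
#'   `expression.tsv`, `chrom_map.tsv` (and optionally
#'   `cohort_table.tsv`); ignored by `simulate`.
#' @param out_dir output directory, created if needed.
#' @param seed top-level seed.
#' @param config named list overriding thresholds: `vaf_loh_delta`,
#'   `min_snvs`, `weight_cutoff`, `refit_tol`, `n_controls`, `iters`,
#'   `signature_path`, `immune_set_path`.
#' @return invisibly, a named list of the stage's result objects.
#' @export
pipeline_run <- function(stage, input_dir = NULL, out_dir, seed = 1L,
                         config = list()) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  cfg <- pipeline_defaults()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(config)] <- config
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  logf <- file.path(out_dir, "log.txt")
  if (file.exists(logf)) unlink(logf)
  log_lines(logf, c(paste0("stage=", stage), paste0("seed=", seed),
                    paste0(names(cfg)[!vapply(cfg, is.null, TRUE)], "=",
                           unlist(cfg[!vapply(cfg, is.null, TRUE)]))))

  if (stage == "simulate") {
    res <- generate_cohort(cohort_config(seed = seed), out_dir)
    log_lines(logf, c(paste0("n_samples=", nrow(res$ground_truth)),
                      paste0("n_variants=", nrow(res$variants)),
                      paste0("n_segments=", nrow(res$segments))))
    return(invisible(list(cohort = res)))
  }
  if (stage == "all" && is.null(input_dir)) {
    sim_dir <- file.path(out_dir, "cohort")
    generate_cohort(cohort_config(seed = seed), sim_dir)
    input_dir <- sim_dir
  }

  sigs <- read_signature_matrix(cfg$signature_path %||%
                                  hrd_extdata("signatures_synthetic.tsv"))
  immune_set <- if (!is.null(cfg$immune_set_path))
    read_gene_sets(cfg$immune_set_path)[[1]]
  else read_gene_sets(hrd_extdata("immune_geneset_synthetic.gmt"))[[1]]

  run_classify <- function(inp) {
    cls <- classify_cohort(inp$variants, inp$segments,
                           all_samples = all_sample_ids(input_dir, inp),
                           vaf_delta = cfg$vaf_loh_delta)
    write_table(cls, file.path(out_dir, "classification.tsv"))
    log_lines(logf, paste0("n_classified=", nrow(cls)))
    cls
  }
  run_signatures <- function(inp) {
    cat_m <- build_catalog_matrix(inp$variants)
    exp_df <- refit_cohort(cat_m, sigs, min_snvs = cfg$min_snvs,
                           weight_cutoff = cfg$weight_cutoff,
                           tol = cfg$refit_tol)
    write_table(data.frame(channel = rownames(cat_m), cat_m,
                           check.names = FALSE),
                file.path(out_dir, "catalog.tsv"))
    write_table(exp_df, file.path(out_dir, "exposures.tsv"))
    log_lines(logf, paste0("n_insufficient_snvs=", sum(exp_df$insufficient)))
    exp_df
  }
  run_scars <- function(inp) {
    sc <- score_cohort(inp$segments, inp$chrom_map)
    write_table(sc, file.path(out_dir, "scars.tsv"))
    sc
  }
  run_immune <- function(inp) {
    im <- immune_scores(inp$expression, immune_set = immune_set)
    write_table(im, file.path(out_dir, "immune.tsv"))
    im
  }

  if (stage == "classify") {
    inp <- load_inputs(input_dir, c("variants", "segments", "cohort_table"))
    return(invisible(list(classification = run_classify(inp))))
  }
  if (stage == "signatures") {
    inp <- load_inputs(input_dir, "variants")
    return(invisible(list(exposures = run_signatures(inp))))
  }
  if (stage == "scars") {
    inp <- load_inputs(input_dir, c("segments", "chrom_map"))
    return(invisible(list(scars = run_scars(inp))))
  }
  if (stage == "immune") {
    inp <- load_inputs(input_dir, "expression")
    return(invisible(list(immune = run_immune(inp))))
  }

  # compare and all need everything
  inp <- load_inputs(input_dir, c("variants", "segments", "expression",
                                  "chrom_map", "cohort_table"))
  cls <- run_classify(inp)
  expo <- run_signatures(inp)
  sc <- run_scars(inp)
  im <- run_immune(inp)

  ids <- cls$sample_id
  n_snv <- table(factor(inp$variants$sample_id[inp$variants$origin == "somatic"],
                        levels = ids))
  sig3_col <- grep("3$", colnames(expo), value = TRUE)[1]
  metric_tab <- data.frame(
    sample_id = ids,
    snv_count = as.numeric(n_snv[ids]),
    sig3 = expo[[sig3_col]][match(ids, expo$sample_id)],
    loh = sc$loh[match(ids, sc$sample_id)],
    tai = sc$tai[match(ids, sc$sample_id)],
    lst = sc$lst[match(ids, sc$sample_id)],
    hrd_sum = sc$hrd_sum[match(ids, sc$sample_id)],
    cyt = im$cyt[match(ids, im$sample_id)],
    immune_ssgsea = im$immune_ssgsea[match(ids, im$sample_id)],
    stringsAsFactors = FALSE)

  comp <- list()
  for (metric in c("snv_count", "sig3", "loh", "tai", "lst", "hrd_sum",
                   "cyt", "immune_ssgsea")) {
    vals <- stats::setNames(metric_tab[[metric]], metric_tab$sample_id)
    comp[[metric]] <- summarize_groups(
      vals, cls, metric = metric,
      summary = if (metric == "sig3") "mean" else "median",
      seed = seed, n_controls = cfg$n_controls, iters = cfg$iters)
  }
  comparisons <- do.call(rbind, comp)
  rownames(comparisons) <- NULL
  comparisons$seed <- seed
  write_table(comparisons, file.path(out_dir, "comparisons.tsv"))

  if (stage == "compare")
    return(invisible(list(comparisons = comparisons)))

  summary_tab <- cbind(
    data.frame(sample_id = ids,
               carrier_group = cls$carrier_group,
               allelic_status = cls$allelic_status,
               stringsAsFactors = FALSE),
    metric_tab[, -1])
  write_table(summary_tab, file.path(out_dir, "summary.tsv"))
  log_lines(logf, paste0("n_summary_rows=", nrow(summary_tab)))
  invisible(list(classification = cls, exposures = expo, scars = sc,
                 immune = im, comparisons = comparisons,
                 summary = summary_tab))
}
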
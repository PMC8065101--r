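# Group comparison statistics: two-sided Mann-Whitney U (exact when
# feasible), Pearson chi-square, and the bootstrap size-correction in which
# each carrier stratum is compared against repeated random subsamples of 30
# non-carrier controls and the median of the iteration p values is reported.

#' Two-sided Mann-Whitney U test
#'
#' U is the rank-sum statistic for `x` relative to `y`. The p value uses
#' the exact null distribution (via [stats::pwilcox()]) when
#' `length(x) * length(y) <= 400` and there are no ties, and otherwise the
#' normal approximation with tie and continuity correction — the same
#' conventions as [stats::wilcox.test()], against which this function is
#' cross-checked in the test suite.
#'
#' @param x,y numeric vectors, each non-empty.
#' @return list with `U`, `p` (two-sided) and `exact` (logical).
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stop("empty input to Mann-Whitney test")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  exact <- (nx * ny <= 400) && !has_ties
  if (exact) {
    p <- if (U > nx * ny / 2)
      stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE)
    else stats::pwilcox(U, nx, ny)
    p <- min(2 * p, 1)
  } else {
    z <- U - nx * ny / 2
    sigma <- sqrt((nx * ny / 12) *
                    ((nx + ny + 1) -
                       sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1))))
    z <- (z - sign(z) * 0.5) / sigma
    p <- min(2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)), 1)
  }
  list(U = unname(U), p = p, exact = exact)
}

#' Pearson chi-square test without continuity correction
#'
#' @param tab contingency table (matrix of counts).
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in contingency table")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Bootstrap size-corrected Mann-Whitney comparison
#'
#' Corrects for the imbalance between a small carrier stratum and a large
#' non-carrier pool: at each iteration `n_controls` controls are sampled
#' from the pool without replacement, a two-sided Mann-Whitney p value is
#' computed against the carrier values, and the median over all iterations
#' is the corrected p.
#'
#' @param carrier_vals numeric carrier-stratum values.
#' @param noncarrier_pool numeric non-carrier values (length >=
#'   `n_controls`).
#' @param n_controls controls sampled per iteration (default 30).
#' @param iters iterations (default 1000).
#' @param seed mandatory integer seed; the global RNG state is restored on
#'   exit.
#' @return list with `p_corrected` (median iteration p), `p_iter` (all
#'   iteration p values), `n_controls`, `iters`, `seed`.
#' @export
bootstrap_compare <- function(carrier_vals, noncarrier_pool, n_controls = 30,
                              iters = 1000, seed) {
  if (missing(seed)) stop("bootstrap_compare requires a seed")
  if (length(noncarrier_pool) < n_controls)
    stop("non-carrier pool smaller than n_controls (",
         length(noncarrier_pool), " < ", n_controls, ")")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  p_iter <- vapply(seq_len(iters), function(i) {
    ctrl <- sample(noncarrier_pool, n_controls)
    mann_whitney_u(carrier_vals, ctrl)$p
  }, numeric(1))
  list(p_corrected = stats::median(p_iter), p_iter = p_iter,
       n_controls = n_controls, iters = iters, seed = seed)
}

#' Stratified group comparisons against non-carriers
#'
#' For each carrier stratum (gene x allelic status) of a classified cohort,
#' summarises a per-sample metric and tests it against the non-carrier
#' reference with the raw Mann-Whitney test and the bootstrap-corrected
#' version. Empty strata are omitted with a message.
#'
#' @param values named numeric vector, names are sample ids.
#' @param classification data.frame from [classify_cohort()].
#' @param metric name recorded in the output.
#' @param summary `"median"` (counts and scores) or `"mean"` (signature
#'   proportions).
#' @param seed seed for [bootstrap_compare()]; each stratum uses
#'   `seed + stratum index`.
#' @param n_controls,iters passed to [bootstrap_compare()].
#' @return data.frame: metric, stratum, n, n_reference, group_summary,
#'   reference_summary, p_raw, p_bootstrap, test.
#' @export
summarize_groups <- function(values, classification, metric = "metric",
                             summary = c("median", "mean"), seed = 1L,
                             n_controls = 30, iters = 1000) {
  summary <- match.arg(summary)
  sfun <- if (summary == "median") stats::median else mean
  cls <- classification
  ref_ids <- cls$sample_id[cls$carrier_group == "non_carrier"]
  ref <- values[intersect(ref_ids, names(values))]
  ref <- ref[!is.na(ref)]
  if (!length(ref)) stop("no non-carrier reference values")
  strata <- expand.grid(gene = STUDY_GENES,
                        status = c("biallelic", "monoallelic"),
                        stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(strata))) {
    g <- strata$gene[i]; st <- strata$status[i]
    ids <- cls$sample_id[cls$carrier_group == g &
                           !is.na(cls$allelic_status) &
                           cls$allelic_status == st]
    vals <- values[intersect(ids, names(values))]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) {
      message("stratum omitted (no values): ", g, " ", st)
      next
    }
    raw <- mann_whitney_u(vals, ref)
    boot <- if (length(ref) >= n_controls)
      bootstrap_compare(vals, ref, n_controls, iters, seed + i)$p_corrected
    else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      metric = metric, stratum = paste(g, st, sep = "_"),
      n = length(vals), n_reference = length(ref),
      group_summary = sfun(vals), reference_summary = sfun(ref),
      p_raw = raw$p, p_bootstrap = boot, test = "mann_whitney",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
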
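# Greedy forward refit of a mutation catalogue against a fixed signature
# matrix. Each iteration golden-section-searches, for every signature, the
# weight increment that most reduces the squared error between the observed
# spectrum and the renormalised reconstruction, applies the single best
# increment, and stops when the SSE improvement falls below `tol`.

golden_section <- function(f, lo, hi, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c_ <- b - gr * (b - a); d_ <- a + gr * (b - a)
  fc <- f(c_); fd <- f(d_)
  while (abs(b - a) > tol) {
    if (fc < fd) { b <- d_; d_ <- c_; fd <- fc; c_ <- b - gr * (b - a); fc <- f(c_) }
    else { a <- c_; c_ <- d_; fc <- fd; d_ <- a + gr * (b - a); fd <- f(d_) }
  }
  x <- (a + b) / 2
  list(x = x, fx = f(x))
}

refit_sse <- function(w, sigs, spectrum) {
  s <- sum(w)
  recon <- if (s > 0) as.vector(sigs %*% w) / s else rep(0, nrow(sigs))
  sum((spectrum - recon)^2)
}

#' Refit signature exposures to a mutation catalogue
#'
#' Decomposes a 96-channel catalogue into non-negative weights over a fixed
#' signature matrix by greedy forward selection with golden-section line
#' search, the refitting strategy popularised for per-sample COSMIC
#' signature analysis. The catalogue is normalised to a probability
#' spectrum and seeded with the single best-matching signature; at each
#' subsequent iteration the single signature increment (found by
#' golden-section search per signature) that most reduces the sum of
#' squared errors between the spectrum and the normalised weighted
#' reconstruction is applied; iteration stops when the SSE improvement
#' drops below `tol`. Final weights are normalised to sum
#' to 1 and weights below `weight_cutoff` are zeroed without
#' renormalisation, so reported weights may sum to less than 1.
#'
#' Catalogues with fewer than `min_snvs` mutations are not refit: the
#' result carries `insufficient = TRUE` and `NA` weights, mirroring the
#' practice of excluding low-burden samples from signature analysis.
#'
#' @param catalog integer vector of 96 channel counts
#'   (see [build_catalog()]).
#' @param signatures 96 x K signature probability matrix; columns must sum
#'   to 1 (see [read_signature_matrix()]).
#' @param min_snvs minimum catalogue total required to refit (default 15).
#' @param weight_cutoff weights below this are zeroed after fitting
#'   (default 0.06).
#' @param tol stop when an iteration improves SSE by less than this
#'   (default 1e-3).
#' @return an object of class `sig_refit`: list with `weights` (named K
#'   vector), `residual_sse` (SSE of the final thresholded reconstruction),
#'   `fitted_sse` (SSE at convergence before thresholding), `n_snvs`,
#'   `insufficient`, `sse_path` (per-iteration SSE, non-increasing).
#' @export
refit_exposures <- function(catalog, signatures, min_snvs = 15,
                            weight_cutoff = 0.06, tol = 1e-3) {
  signatures <- validate_signature_matrix(as.matrix(signatures))
  catalog <- as.numeric(catalog)
  if (length(catalog) != 96L) stop("catalogue must have 96 channels")
  if (any(catalog < 0)) stop("negative catalogue counts")
  n <- sum(catalog)
  k <- ncol(signatures)
  empty <- stats::setNames(rep(NA_real_, k), colnames(signatures))
  if (n < min_snvs) {
    return(structure(list(weights = empty, residual_sse = NA_real_,
                          n_snvs = n, insufficient = TRUE,
                          sse_path = numeric(0)),
                     class = "sig_refit"))
  }
  spectrum <- catalog / n
  w <- stats::setNames(rep(0, k), colnames(signatures))
  # seed with the best single signature: the empty reconstruction is not a
  # spectrum, so the tol-based stop only applies from the first refinement
  sse_j <- vapply(seq_len(k), function(j)
    sum((spectrum - signatures[, j])^2), numeric(1))
  j0 <- which.min(sse_j)
  w[j0] <- 1
  sse <- sse_j[j0]
  path <- sse
  repeat {
    best <- list(sse = sse, j = NA_integer_, x = NA_real_)
    for (j in seq_len(k)) {
      gs <- golden_section(function(x) {
        wj <- w; wj[j] <- wj[j] + x
        refit_sse(wj, signatures, spectrum)
      }, 0, 1)
      if (gs$fx < best$sse) best <- list(sse = gs$fx, j = j, x = gs$x)
    }
    if (is.na(best$j) || sse - best$sse < tol) break
    w[best$j] <- w[best$j] + best$x
    sse <- best$sse
    path <- c(path, sse)
  }
  fitted_sse <- sse
  if (sum(w) > 0) w <- w / sum(w)
  w[w < weight_cutoff] <- 0
  recon <- as.vector(signatures %*% w)
  structure(list(weights = w,
                 residual_sse = sum((spectrum - recon)^2),
                 fitted_sse = fitted_sse,
                 n_snvs = n, insufficient = FALSE, sse_path = path),
            class = "sig_refit")
}

#' @export
print.sig_refit <- function(x, ...) {
  if (x$insufficient) {
    cat("Signature refit: insufficient SNVs (", x$n_snvs, ")\n", sep = "")
    return(invisible(x))
  }
  cat("Signature refit on", x$n_snvs, "SNVs; residual SSE",
      format(x$residual_sse, digits = 4), "\n")
  nz <- x$weights[x$weights > 0]
  if (length(nz)) print(round(sort(nz, decreasing = TRUE), 3))
  invisible(x)
}

#' @export
summary.sig_refit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Refit every sample of a catalogue matrix
#'
#' @param catalogs 96 x samples count matrix (see [build_catalog_matrix()]).
#' @inheritParams refit_exposures
#' @return data.frame with one row per sample: `sample_id`, `n_snvs`,
#'   `insufficient`, one weight column per signature, `residual_sse`.
#' @export
refit_cohort <- function(catalogs, signatures, min_snvs = 15,
                         weight_cutoff = 0.06, tol = 1e-3) {
  fits <- lapply(colnames(catalogs), function(s)
    refit_exposures(catalogs[, s], signatures, min_snvs, weight_cutoff, tol))
  wts <- do.call(rbind, lapply(fits, function(f) f$weights))
  out <- data.frame(sample_id = colnames(catalogs),
                    n_snvs = vapply(fits, function(f) f$n_snvs, 0),
                    insufficient = vapply(fits, function(f) f$insufficient, TRUE),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(wts))
  out$residual_sse <- vapply(fits, function(f) f$residual_sse, 0)
  rownames(out) <- NULL
  out
}

#' Per-group mean signature exposure
#'
#' Arithmetic mean of per-sample signature weights within each group,
#' excluding samples flagged insufficient. Errors on an empty group.
#'
#' @param exposures data.frame from [refit_cohort()].
#' @param grouping named character vector or factor mapping `sample_id` to
#'   a group label.
#' @return data.frame: group x signature mean weights with group sizes.
#' @export
group_mean_exposure <- function(exposures, grouping) {
  g <- grouping[exposures$sample_id]
  if (anyNA(g)) stop("grouping missing for sample(s): ",
                     paste(exposures$sample_id[is.na(g)], collapse = ", "))
  keep <- !exposures$insufficient
  exposures <- exposures[keep, , drop = FALSE]
  g <- factor(g[keep])
  if (any(table(g) == 0) || nlevels(g) == 0) stop("empty group in exposure averaging")
  sig_cols <- setdiff(names(exposures),
                      c("sample_id", "n_snvs", "insufficient", "residual_sse"))
  means <- stats::aggregate(exposures[, sig_cols, drop = FALSE],
                            by = list(group = g), FUN = mean)
  means$n <- as.integer(table(g)[as.character(means$group)])
  means
}
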
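bin_index <- function(values, bin_width = 5) {
  if (any(values < 0 | values > 100, na.rm = TRUE))
    stop("metric values must be in [0,100]", call. = FALSE)
  nbin <- as.integer(ceiling(100 / bin_width))
  # left-closed right-open bins; the last bin is closed at 100
  idx <- pmin(floor(values / bin_width) + 1L, nbin)
  idx
}

#' Histogram of a per-alignment metric in 5%-wide bins
#'
#' Bins are left-closed, right-open over [0,100) with the final bin closed
#' at 100; counts are reported for the whole pool and for the FIC subset.
#'
#' @param metrics data.frame from [compute_alignment_metrics()].
#' @param metric_name one of "q", "q_int", "a_iden", "a_sim", "i_iden",
#'   "i_sim" (or any numeric column present). Rows with NA in the metric
#'   (e.g. interface metrics of non-FIC alignments) are dropped.
#' @param bin_width bin width in percent (default 5).
#' @return a `metric_histogram`: data.frame with `bin_lo`, `bin_hi`,
#'   `bin_center`, `counts_all`, `counts_fic`, plus attributes
#'   `metric_name` and `pool_size`.
#' @export
metric_histogram <- function(metrics, metric_name, bin_width = 5) {
  if (!metric_name %in% names(metrics))
    stop("unknown metric: ", metric_name, call. = FALSE)
  v <- metrics[[metric_name]]
  fic <- metrics$is_fic %||% rep(FALSE, length(v))
  keep <- !is.na(v)
  v <- v[keep]; fic <- fic[keep]
  edges <- seq(0, 100, by = bin_width)
  if (edges[length(edges)] < 100) edges <- c(edges, 100)
  nbin <- length(edges) - 1L
  idx <- bin_index(v, bin_width)
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    bin_center = (edges[-length(edges)] + edges[-1]) / 2,
                    counts_all = tabulate(idx, nbin),
                    counts_fic = tabulate(idx[fic], nbin))
  attr(out, "metric_name") <- metric_name
  attr(out, "pool_size") <- length(v)
  class(out) <- c("metric_histogram", "data.frame")
  out
}

#' Probability of full interface coverage per metric bin
#'
#' For each 5%-wide bin of the chosen metric (alignment identity or
#' similarity), the probability that an alignment in that bin is FIC:
#' N_FIC(bin) / N_all(bin). Bins with no alignments are undefined (NA),
#' not zero.
#'
#' @inheritParams metric_histogram
#' @param metric_name "a_iden" or "a_sim" (any numeric column accepted).
#' @param window bin width in percent (default 5).
#' @return a `fic_curve`: data.frame with `bin_lo`, `bin_hi`, `bin_center`,
#'   `n_all`, `n_fic`, `probability`; attribute `metric_name`.
#' @export
fic_probability <- function(metrics, metric_name = "a_iden", window = 5) {
  if (nrow(metrics) == 0L) stop("empty pool", call. = FALSE)
  h <- metric_histogram(metrics, metric_name, bin_width = window)
  prob <- ifelse(h$counts_all > 0, h$counts_fic / h$counts_all, NA_real_)
  out <- data.frame(bin_lo = h$bin_lo, bin_hi = h$bin_hi,
                    bin_center = h$bin_center,
                    n_all = h$counts_all, n_fic = h$counts_fic,
                    probability = prob)
  attr(out, "metric_name") <- metric_name
  class(out) <- c("fic_curve", "data.frame")
  out
}

#' Least-squares polynomial fit to a FIC probability curve
#'
#' Ordinary least squares of probability against bin center, each defined
#' bin weighted by its occupancy n_all; empty bins are excluded, not
#' imputed.
#'
#' @param curve a `fic_curve` from [fic_probability()].
#' @param degree polynomial degree (default 3).
#' @param weighted weight bins by n_all (default TRUE).
#' @return list with `coefficients` (ascending powers, length degree+1),
#'   `degree`, `rss` (weighted residual sum of squares), `n_bins` used, and
#'   `fitted` values at the used bin centers.
#' @export
fit_fic_curve <- function(curve, degree = 3L, weighted = TRUE) {
  ok <- !is.na(curve$probability)
  if (sum(ok) < degree + 1L)
    stop("need at least degree+1 defined bins (have ", sum(ok), ")",
         call. = FALSE)
  x <- curve$bin_center[ok]; y <- curve$probability[ok]
  w <- if (weighted) curve$n_all[ok] else rep(1, sum(ok))
  fit <- stats::lm(y ~ poly(x, degree, raw = TRUE), weights = w)
  beta <- unname(stats::coef(fit))
  res <- y - stats::fitted(fit)
  list(coefficients = beta, degree = as.integer(degree),
       rss = sum(w * res^2), n_bins = sum(ok),
       fitted = unname(stats::fitted(fit)))
}

#' Evaluate a fitted polynomial
#'
#' @param coefficients coefficients in ascending powers.
#' @param x points to evaluate at.
#' @return numeric vector.
#' @export
eval_polynomial <- function(coefficients, x) {
  drop(outer(x, seq_along(coefficients) - 1, "^") %*% coefficients)
}

#' Per-complex FIC summary
#'
#' Classifies each target complex by whether at least one FIC alignment
#' exists for both of its chains, exactly one, or neither. Complexes listed
#' in `complexes` but absent from the pool count as "none" (the case of a
#' target with no homologous sequences found).
#'
#' @param metrics data.frame from [compute_alignment_metrics()] with
#'   `complex_id` and `chain` columns.
#' @param complexes optional data.frame (`complex_id`, `chain`) enumerating
#'   every chain of every complex in the data set; defaults to the chains
#'   seen in `metrics`. An alignment referencing a complex missing from
#'   `complexes` is an error.
#' @param class_labels optional named character vector mapping complex_id
#'   to a functional class; adds per-class totals.
#' @return list with `summaries` (data.frame: complex_id, fic_both,
#'   fic_one, fic_none, plus one count column per chain seen) and `totals`
#'   (data.frame of both/one/none counts, overall and per class).
#' @export
count_fic_by_complex <- function(metrics, complexes = NULL,
                                 class_labels = NULL) {
  if (is.null(metrics$complex_id) || is.null(metrics$chain))
    stop("metrics must carry complex_id and chain columns", call. = FALSE)
  if (is.null(complexes))
    complexes <- unique(metrics[, c("complex_id", "chain")])
  unknown <- setdiff(unique(metrics$complex_id),
                     unique(complexes$complex_id))
  if (length(unknown) > 0L)
    stop("alignment(s) reference unknown complex: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  ids <- sort(unique(complexes$complex_id))
  rows <- lapply(ids, function(cid) {
    chains <- sort(unique(complexes$chain[complexes$complex_id == cid]))
    nfic <- vapply(chains, function(ch)
      sum(metrics$is_fic[metrics$complex_id == cid & metrics$chain == ch]),
      numeric(1))
    have <- sum(nfic > 0)
    data.frame(complex_id = cid,
               fic_both = have >= length(chains) & length(chains) >= 2,
               fic_one = have >= 1 & have < max(2, length(chains)),
               fic_none = have == 0,
               n_fic_alignments = sum(nfic), stringsAsFactors = FALSE)
  })
  summaries <- do.call(rbind, rows)
  tally <- function(s) data.frame(n = nrow(s), both = sum(s$fic_both),
                                  one = sum(s$fic_one),
                                  none = sum(s$fic_none))
  totals <- cbind(class = "all", tally(summaries))
  if (!is.null(class_labels)) {
    for (cl in sort(unique(class_labels))) {
      sub <- summaries[summaries$complex_id %in%
                         names(class_labels)[class_labels == cl], ,
                       drop = FALSE]
      totals <- rbind(totals, cbind(class = cl, tally(sub)))
    }
  }
  list(summaries = summaries, totals = totals)
}
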
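#' Precision-recall curve and average precision
#'
#' Thresholds are the unique prediction scores (no fixed grid). At each
#' threshold a pair is called positive when its score is greater than or
#' equal to the threshold; precision is `tp/(tp+fp)` and recall is
#' `tp/(tp+fn)`. Average precision is the step sum
#' `sum_k (r_k - r_{k-1}) p_k` with `r_0 = 0`, over thresholds in
#' decreasing score order.
#'
#' @param scores finite numeric prediction scores.
#' @param labels binary labels (0/1), at least one positive.
#' @return list with `thresholds`, `precision`, `recall` (one entry per
#'   unique score, decreasing threshold order) and `average_precision`.
#' @export
precision_recall <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (any(!is.finite(scores))) stop("scores must be finite")
  n_pos <- sum(labels == 1)
  if (n_pos == 0L) stop("need at least one positive label")
  ord <- order(-scores)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  # keep the last index of each tied score block
  keep <- which(diff(c(s, -Inf)) != 0)
  tp <- tp[keep]; fp <- fp[keep]
  thr <- s[keep]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  ap <- sum(diff(c(0, recall)) * precision)
  list(thresholds = thr, precision = precision, recall = recall,
       average_precision = ap)
}

#' @describeIn precision_recall average precision only.
#' @export
average_precision <- function(scores, labels)
  precision_recall(scores, labels)$average_precision

# precision as a single-valued function of recall: keep the max precision
# at each unique recall (interpolation needs single-valued x)
.curve_points <- function(recall, precision) {
  o <- order(recall, -precision)
  r <- recall[o]; p <- precision[o]
  keep <- !duplicated(r)
  list(x = r[keep], y = p[keep])
}

# linear interpolation onto grid with linear (or flat) extrapolation from
# the two nearest points at each end
.interp_curve <- function(recall, precision, grid,
                          extrapolation = c("linear", "flat")) {
  extrapolation <- match.arg(extrapolation)
  pts <- .curve_points(recall, precision)
  x <- pts$x; y <- pts$y
  if (length(x) == 1L) {
    message("repetition with a single precision-recall point; ",
            "extrapolated as constant")
    return(rep(y, length(grid)))
  }
  out <- stats::approx(x, y, xout = grid, method = "linear", ties = "ordered",
                       rule = 2)$y
  if (extrapolation == "linear") {
    lo <- grid < x[1L]
    if (any(lo)) {
      sl <- (y[2L] - y[1L]) / (x[2L] - x[1L])
      out[lo] <- y[1L] + sl * (grid[lo] - x[1L])
    }
    hi <- grid > x[length(x)]
    if (any(hi)) {
      nx <- length(x)
      sl <- (y[nx] - y[nx - 1L]) / (x[nx] - x[nx - 1L])
      out[hi] <- y[nx] + sl * (grid[hi] - x[nx])
    }
    out <- pmin(pmax(out, 0), 1)
  }
  out
}

#' Aggregate repeated precision-recall curves onto a fixed recall grid
#'
#' Each repetition's precision is treated as a function of recall, linearly
#' interpolated (and extrapolated) onto `K` evenly spaced recall levels in
#' `[0, 1]`. Reports the mean precision per grid point, a confidence
#' interval for the mean (asymptotic normal by default:
#' `mean +/- sd * z_{0.975} / sqrt(n_reps)`; or a bootstrap over
#' repetitions), and a prediction band given by the 5th and 95th
#' percentiles of the per-repetition values.
#'
#' @param curves list of repetitions, each a list with numeric `recall` and
#'   `precision` (as produced by [precision_recall()]) and optionally
#'   `average_precision`.
#' @param K number of recall grid points (>= 2), default 200.
#' @param conf confidence level for the mean, default 0.95.
#' @param ci `"asymptotic"` or `"bootstrap"` (bootstrap of repetitions).
#' @param extrapolation `"linear"` (default) or `"flat"` extension beyond a
#'   repetition's observed recall range.
#' @param n_boot,boot_seed bootstrap replicates and seed (bootstrap CI only).
#' @param band_probs percentiles for the prediction band.
#' @return a `pr_summary`: list with `recall_grid`, `precision` (reps x K
#'   matrix), `mean`, `ci_lower`, `ci_upper`, `band_lower`, `band_upper`,
#'   `average_precision` (per repetition), `n_reps`.
#' @export
interpolate_and_band <- function(curves, K = 200L, conf = 0.95,
                                 ci = c("asymptotic", "bootstrap"),
                                 extrapolation = c("linear", "flat"),
                                 n_boot = 1000L, boot_seed = 1L,
                                 band_probs = c(0.05, 0.95)) {
  ci <- match.arg(ci)
  extrapolation <- match.arg(extrapolation)
  if (length(curves) < 2L) stop("need at least two repetitions")
  if (K < 2L) stop("`K` must be >= 2")
  grid <- seq(0, 1, length.out = K)
  P <- t(vapply(curves, function(cv)
    .interp_curve(cv$recall, cv$precision, grid, extrapolation),
    numeric(K)))
  mu <- colMeans(P)
  n <- nrow(P)
  if (ci == "asymptotic") {
    half <- apply(P, 2L, stats::sd) * stats::qnorm(1 - (1 - conf) / 2) / sqrt(n)
    ci_lower <- mu - half
    ci_upper <- mu + half
  } else {
    boots <- .with_seed(boot_seed, {
      vapply(seq_len(n_boot), function(b)
        colMeans(P[sample.int(n, n, replace = TRUE), , drop = FALSE]),
        numeric(K))
    })
    qs <- apply(boots, 1L, stats::quantile,
                probs = c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    ci_lower <- qs[1L, ]
    ci_upper <- qs[2L, ]
  }
  band <- apply(P, 2L, stats::quantile, probs = band_probs, names = FALSE)
  ap <- vapply(curves, function(cv) {
    if (!is.null(cv$average_precision)) cv$average_precision else NA_real_
  }, numeric(1))
  structure(list(recall_grid = grid, precision = P, mean = mu,
                 ci_lower = ci_lower, ci_upper = ci_upper,
                 band_lower = band[1L, ], band_upper = band[2L, ],
                 average_precision = ap, n_reps = n, conf = conf, ci = ci),
            class = "pr_summary")
}

#' @export
print.pr_summary <- function(x, ...) {
  cat(sprintf(
    "pr_summary: %d repetitions, %d-point recall grid; mean AP %.3f (sd %.3f)\n",
    x$n_reps, length(x$recall_grid), mean(x$average_precision, na.rm = TRUE),
    stats::sd(x$average_precision)))
  invisible(x)
}

#' Per-receptor recall and precision at a decision threshold
#'
#' Calls are positive when score >= `threshold`. Receptors with no test
#' pair are omitted; precision is `NA` for receptors with no positive
#' prediction and recall is `NA` for receptors with no test positive.
#'
#' @param scores,labels numeric scores and binary labels per test pair.
#' @param pairs data frame with `ligand`, `receptor` for the same rows.
#' @param threshold decision threshold in (0, 1).
#' @return data frame with per-receptor `tp`, `fp`, `fn`, `tn`,
#'   `precision`, `recall`, `n_known`.
#' @export
per_receptor_metrics <- function(scores, labels, pairs, threshold = 0.5) {
  if (!(threshold > 0 && threshold < 1)) stop("`threshold` must be in (0, 1)")
  pairs <- .as_pairs(pairs)
  call <- as.integer(scores >= threshold)
  labels <- as.integer(labels)
  recs <- unique(pairs$receptor)
  rows <- lapply(recs, function(r) {
    i <- pairs$receptor == r
    tp <- sum(call[i] == 1L & labels[i] == 1L)
    fp <- sum(call[i] == 1L & labels[i] == 0L)
    fn <- sum(call[i] == 0L & labels[i] == 1L)
    tn <- sum(call[i] == 0L & labels[i] == 0L)
    data.frame(receptor = r, n_known = sum(i), tp = tp, fp = fp, fn = fn,
               tn = tn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Number of receptors to assay until the first true activator
#'
#' For each ligand with at least one positive test label, receptors are
#' ranked by decreasing predicted score (ties broken by the receptor's
#' position in `receptor_order`); the count is the 1-based rank of the
#' first true positive. Ligands with no positive label are excluded and
#' reported in the `excluded` attribute.
#'
#' @param scores,labels scores and binary labels per (ligand, receptor)
#'   test pair.
#' @param pairs data frame with `ligand`, `receptor` for the same rows.
#' @param receptor_order optional character vector fixing the tie-break
#'   order of receptors; defaults to sorted unique receptor identifiers.
#' @return named integer vector of counts per ligand, with attribute
#'   `excluded` listing ligands that had no positive label.
#' @export
tests_to_first_hit <- function(scores, labels, pairs, receptor_order = NULL) {
  pairs <- .as_pairs(pairs)
  labels <- as.integer(labels)
  if (is.null(receptor_order)) receptor_order <- sort(unique(pairs$receptor))
  ligands <- unique(pairs$ligand)
  counts <- integer(0)
  excluded <- character(0)
  for (l in ligands) {
    i <- which(pairs$ligand == l)
    if (!any(labels[i] == 1L)) {
      excluded <- c(excluded, l)
      next
    }
    ord <- i[order(-scores[i], match(pairs$receptor[i], receptor_order))]
    counts[[l]] <- which(labels[ord] == 1L)[1L]
  }
  structure(counts, excluded = excluded)
}

#' Compare paired tests-to-first-hit counts between two methods
#'
#' Ordinary least squares of `counts_a` on `counts_b` over paired
#' ligand-repetition units, plus the ratio of means (a summary of the
#' average reduction factor).
#'
#' @param counts_a,counts_b paired numeric count vectors (same units).
#' @return list with `intercept`, `slope`, `mean_ratio`
#'   (`mean(counts_a)/mean(counts_b)`) and `n`.
#' @export
compare_test_counts <- function(counts_a, counts_b) {
  a <- as.numeric(counts_a)
  b <- as.numeric(counts_b)
  if (length(a) != length(b)) stop("count vectors must be paired")
  if (length(a) < 2L) stop("need at least two paired counts")
  fit <- stats::lm(a ~ b)
  co <- stats::coef(fit)
  list(intercept = unname(co[1L]),
       slope = unname(if (length(co) > 1L) co[2L] else NA_real_),
       mean_ratio = mean(a) / mean(b), n = length(a))
}
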
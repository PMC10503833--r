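# Reference-based state label transfer, signature scoring, subset-frequency
# decomposition, moderated-t differential expression, state-frequency test.

#' Build per-state centroids over marker genes
#'
#' Computes, for each reference state, the per-gene mean of log2-scaled
#' normalized counts over that state's cells, restricted to the marker gene
#' panel. The resulting centroids are the reference for supervised
#' correlation-based classification of query cells.
#'
#' @param counts gene x cell count matrix (sparse or dense).
#' @param labels named character vector, barcode -> state, covering the
#'   matrix columns.
#' @param marker_genes character vector of marker genes (must be present in
#'   the matrix).
#' @param min_correlation minimum Pearson correlation for a query cell to be
#'   assigned (default 0.7, excluding low-quality alignments).
#' @param target library-size normalization target (see [lognorm()]).
#' @return object of class `state_reference`: list with `marker_genes`,
#'   `centroids` (gene x state matrix), `min_correlation`, `target`.
#' @export
build_centroids <- function(counts, labels, marker_genes,
                            min_correlation = 0.7, target = NULL) {
  missing_genes <- setdiff(marker_genes, rownames(counts))
  if (length(missing_genes))
    stop("parameter error: marker genes absent from matrix: ",
         paste(utils::head(missing_genes, 5L), collapse = ", "))
  labels <- labels[colnames(counts)]
  if (anyNA(labels)) stop("parameter error: unlabeled reference cells")
  tab <- table(labels)
  small <- names(tab)[tab < 2L]
  if (length(small))
    stop("parameter error: state(s) with < 2 cells: ",
         paste(small, collapse = ", "))
  if (length(tab) < 2L) stop("parameter error: need >= 2 states")
  libs <- Matrix::colSums(counts)
  if (is.null(target)) target <- stats::median(libs[libs > 0])
  ln <- lognorm(counts, target = target)[marker_genes, , drop = FALSE]
  states <- sort(names(tab))
  centroids <- vapply(states, function(s)
    Matrix::rowMeans(ln[, labels == s, drop = FALSE]),
    numeric(length(marker_genes)))
  rownames(centroids) <- marker_genes
  out <- list(marker_genes = marker_genes, centroids = centroids,
              min_correlation = min_correlation, target = target)
  class(out) <- "state_reference"
  out
}

#' @export
print.state_reference <- function(x, ...) {
  cat("State reference: ", ncol(x$centroids), " states over ",
      length(x$marker_genes), " marker genes (min r = ",
      x$min_correlation, ")\n", sep = "")
  invisible(x)
}

#' Classify query cells by centroid correlation
#'
#' Each query cell's log2-scaled marker-gene vector is correlated (Pearson)
#' with every reference centroid; the cell takes the best-correlated state's
#' label, or `"unassigned"` when the best correlation falls below the
#' reference's `min_correlation` floor. Marker genes missing from the query
#' are imputed as zero with a warning; zero-variance cells are unassigned.
#' Ties break lexicographically by state name.
#'
#' @param counts query gene x cell count matrix.
#' @param reference a `state_reference` from [build_centroids()].
#' @return data.frame (barcode, label, best_r), one row per query cell.
#' @export
classify_cells <- function(counts, reference) {
  mg <- reference$marker_genes
  missing_genes <- setdiff(mg, rownames(counts))
  q <- lognorm(counts, target = reference$target)
  if (length(missing_genes)) {
    warning("classify_cells: ", length(missing_genes),
            " marker gene(s) missing from query; imputed as 0")
    pad <- Matrix::Matrix(0, length(missing_genes), ncol(q), sparse = TRUE,
                          dimnames = list(missing_genes, colnames(q)))
    q <- rbind(q, pad)
  }
  q <- as.matrix(q[mg, , drop = FALSE])
  cvar <- apply(q, 2L, stats::var)
  states <- colnames(reference$centroids)
  labels <- rep("unassigned", ncol(q))
  best_r <- rep(NA_real_, ncol(q))
  ok <- which(cvar > 0)
  if (length(ok)) {
    r <- stats::cor(q[, ok, drop = FALSE], reference$centroids)
    # ties: first index among lexicographically sorted state names
    ord <- order(states)
    r_sorted <- r[, ord, drop = FALSE]
    pick <- apply(r_sorted, 1L, which.max)
    best <- r_sorted[cbind(seq_along(pick), pick)]
    lab <- states[ord][pick]
    lab[best < reference$min_correlation] <- "unassigned"
    labels[ok] <- lab
    best_r[ok] <- best
  }
  data.frame(barcode = colnames(q), label = labels, best_r = best_r,
             stringsAsFactors = FALSE)
}

#' Gene-signature score with expression-matched background
#'
#' Scores each cell as the mean log-normalized expression of the signature
#' genes minus the mean over a background gene set matched for expression
#' level: all genes are binned by dataset-wide mean expression into
#' `n_background_bins` bins and, for every signature gene,
#' `background_size_per_gene` genes are drawn (seeded) from its bin. The
#' subtraction controls for per-cell library quality and complexity, so
#' scores are comparable across cells; they are meaningful comparatively,
#' not as absolute values.
#'
#' @param counts gene x cell count matrix.
#' @param genes signature gene names; genes absent from the matrix are
#'   dropped with a warning.
#' @param n_background_bins,background_size_per_gene binning controls.
#' @param seed integer seed for the background draw.
#' @param target normalization target (see [lognorm()]).
#' @return named numeric vector of per-cell scores.
#' @export
signature_score <- function(counts, genes, n_background_bins = 25L,
                            background_size_per_gene = 50L, seed = 1L,
                            target = NULL) {
  present <- intersect(genes, rownames(counts))
  if (length(present) == 0L)
    stop("parameter error: no signature gene present in the matrix")
  if (length(present) < length(genes))
    warning("signature_score: ", length(genes) - length(present),
            " signature gene(s) absent; dropped")
  ln <- lognorm(counts, target = target)
  avg <- Matrix::rowMeans(ln)
  bins <- cut(rank(avg, ties.method = "first"),
              breaks = n_background_bins, labels = FALSE)
  names(bins) <- rownames(ln)
  set.seed(seed)
  bg <- unique(unlist(lapply(present, function(g) {
    pool <- setdiff(names(bins)[bins == bins[g]], present)
    if (!length(pool)) pool <- setdiff(names(bins), present)
    sample(pool, min(background_size_per_gene, length(pool)))
  })))
  sig_mean <- Matrix::colMeans(ln[present, , drop = FALSE])
  bg_mean <- Matrix::colMeans(ln[bg, , drop = FALSE])
  out <- sig_mean - bg_mean
  names(out) <- colnames(counts)
  out
}

#' Decompose cell-state frequencies of a sorted mixed subset
#'
#' Corrects the state-frequency vector of a mixed sorted population for the
#' contribution of a contaminating pure population: the pure population's
#' proportions, scaled by the contamination fraction `alpha`, are subtracted
#' and the result is clipped at zero and renormalized. `alpha = 1`
#' reproduces literal subtraction of the unmixed subset's proportions.
#'
#' @param f_mixed,f_pure named state-fraction vectors over the same states,
#'   each summing to 1.
#' @param alpha contamination fraction in `[0, 1]`.
#' @return corrected named fraction vector summing to 1.
#' @export
subset_frequency_decomposition <- function(f_mixed, f_pure, alpha = 1) {
  if (!setequal(names(f_mixed), names(f_pure)))
    stop("parameter error: state sets differ")
  f_pure <- f_pure[names(f_mixed)]
  if (abs(sum(f_mixed) - 1) > 1e-6 || abs(sum(f_pure) - 1) > 1e-6)
    stop("parameter error: fraction vectors must sum to 1")
  if (alpha < 0 || alpha > 1) stop("parameter error: alpha outside [0, 1]")
  corrected <- pmax(f_mixed - alpha * f_pure, 0)
  if (sum(corrected) <= 0)
    stop("degenerate decomposition: all corrected entries are zero")
  corrected / sum(corrected)
}

# Newton solve of trigamma(y) = x, vectorized; used for the method-of-moments
# prior degrees of freedom.
.trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-8) break
  }
  y
}

#' Differential expression with a moderated (empirical Bayes) t-test
#'
#' Two-group comparison on log2-scaled normalized counts. Per-gene variances
#' are shrunk toward a common prior variance: the prior degrees of freedom
#' and scale are estimated by method of moments from the distribution of
#' log sample variances (matching the scaled-F hierarchical model), and the
#' posterior variance is the degrees-of-freedom-weighted average of prior
#' and observed variance. Fold change is the ratio of group means on the
#' linear normalized scale. A gene is called differentially expressed when
#' its absolute fold exceeds `fold_threshold` and its Benjamini-Hochberg
#' adjusted p-value falls below `alpha`.
#'
#' @param counts_a,counts_b gene x cell count matrices for the two groups
#'   (same gene set, >= 3 cells each).
#' @param fold_threshold linear-scale absolute fold cutoff (> 1).
#' @param alpha adjusted-p cutoff in (0, 1).
#' @param use_log_fold compute fold as 2^(difference of log2 means) instead
#'   of the ratio of linear means.
#' @param target normalization target shared by both groups.
#' @return data.frame (gene, mean_a, mean_b, fold, abs_fold, t, df, raw_p,
#'   adj_p, is_deg).
#' @export
differential_expression <- function(counts_a, counts_b, fold_threshold = 1.2,
                                    alpha = 0.05, use_log_fold = FALSE,
                                    target = NULL) {
  if (ncol(counts_a) < 3L || ncol(counts_b) < 3L)
    stop("parameter error: each group needs >= 3 cells")
  if (!identical(rownames(counts_a), rownames(counts_b)))
    stop("parameter error: gene sets differ between groups")
  stopifnot(fold_threshold > 1, alpha > 0, alpha < 1)
  libs <- c(Matrix::colSums(counts_a), Matrix::colSums(counts_b))
  if (is.null(target)) target <- stats::median(libs[libs > 0])
  la <- as.matrix(lognorm(counts_a, target = target))
  lb <- as.matrix(lognorm(counts_b, target = target))
  na <- ncol(la); nb <- ncol(lb)

  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- rowSums((la - ma)^2) / (na - 1L)
  vb <- rowSums((lb - mb)^2) / (nb - 1L)
  d <- na + nb - 2L
  s2 <- ((na - 1L) * va + (nb - 1L) * vb) / d

  # method-of-moments fit of the scaled-F model on log variances
  pos <- s2 > 0
  z <- log(s2[pos])
  e <- z - digamma(d / 2) + log(d / 2)
  ev <- stats::var(e) - trigamma(d / 2)
  if (is.na(ev) || ev <= 0) {
    d0 <- Inf
    s02 <- exp(mean(e))
  } else {
    d0 <- 2 * .trigamma_inverse(ev)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  s2_post <- if (is.finite(d0)) (d0 * s02 + d * s2) / (d0 + d) else
    rep(s02, length(s2))
  df_total <- if (is.finite(d0)) d + d0 else Inf

  tstat <- (ma - mb) / sqrt(s2_post * (1 / na + 1 / nb))
  raw_p <- 2 * stats::pt(-abs(tstat), df = df_total)
  raw_p[s2_post == 0 & ma == mb] <- 1
  adj_p <- stats::p.adjust(raw_p, method = "BH")

  # fold on the linear normalized scale
  lin_a <- rowMeans(2^la - 1)
  lin_b <- rowMeans(2^lb - 1)
  eps <- 1e-9
  fold <- if (use_log_fold) 2^(ma - mb) else
    (lin_a + eps) / (lin_b + eps)
  abs_fold <- pmax(fold, 1 / fold)

  out <- data.frame(
    gene = rownames(counts_a), mean_a = lin_a, mean_b = lin_b,
    fold = fold, abs_fold = abs_fold, t = tstat, df = df_total,
    raw_p = raw_p, adj_p = adj_p,
    is_deg = abs_fold > fold_threshold & adj_p < alpha,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Chi-square test of state-frequency differences
#'
#' Pearson chi-square on the 2 x k contingency table of per-state cell
#' counts for two samples; states with zero total count are dropped with a
#' warning (reducing the degrees of freedom).
#'
#' @param counts_a,counts_b named per-state cell counts over the same
#'   states.
#' @return list with `chi2`, `df`, `p_value`.
#' @export
state_frequency_test <- function(counts_a, counts_b) {
  if (!setequal(names(counts_a), names(counts_b)))
    stop("parameter error: state sets differ")
  counts_b <- counts_b[names(counts_a)]
  tot <- counts_a + counts_b
  if (any(tot == 0)) {
    warning("state_frequency_test: dropping state(s) with zero total count: ",
            paste(names(tot)[tot == 0], collapse = ", "))
    keep <- tot > 0
    counts_a <- counts_a[keep]
    counts_b <- counts_b[keep]
  }
  if (length(counts_a) < 2L)
    stop("parameter error: need >= 2 states with nonzero counts")
  tab <- rbind(counts_a, counts_b)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}
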
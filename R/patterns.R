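log2p1 <- function(x) log2(unclass(x) + 1)

#' Sample-sample Pearson correlation matrix
#'
#' Pearson correlation between sample columns on log2(x + 1)-transformed
#' expression; the standard sample-similarity QC.
#'
#' @param expr an [expression_matrix()].
#' @return symmetric samples x samples correlation matrix, unit diagonal.
#' @export
sample_correlation_matrix <- function(expr) {
  if (ncol(expr) < 2) stop("need >= 2 samples")
  x <- log2p1(expr)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant sample, correlation undefined: ",
         colnames(x)[sds == 0][1L])
  r <- stats::cor(x)
  diag(r) <- 1
  r
}

#' PCA embedding of samples
#'
#' Projects centered log2(x + 1) expression onto the top principal
#' components. Component signs are fixed so each component's
#' largest-magnitude gene loading is positive, making embeddings reproducible.
#'
#' @param expr an [expression_matrix()].
#' @param n_components number of components (<= number of samples).
#' @return list with `scores` (samples x components), `variance_explained`
#'   (fractions, non-increasing), `loadings` (genes x components).
#' @export
pca_embedding <- function(expr, n_components = 3) {
  if (n_components > ncol(expr))
    stop("n_components exceeds number of samples")
  x <- t(log2p1(expr))                      # samples x genes
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x, nu = n_components, nv = n_components)
  for (j in seq_len(n_components)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  dimnames(scores) <- list(colnames(expr), paste0("PC", seq_len(n_components)))
  loadings <- sv$v
  dimnames(loadings) <- list(rownames(expr), colnames(scores))
  ve <- sv$d^2 / sum(sv$d^2)
  list(scores = scores, variance_explained = ve[seq_len(n_components)],
       loadings = loadings)
}

# standardize gene rows to zero mean, unit variance; constant rows -> NA rows
standardize_rows <- function(x) {
  m <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  out <- (x - m) / s
  out[s == 0, ] <- NA_real_
  out
}

# two-sided correlation-test p-value, t statistic with df = n - 2;
# preserves dim/dimnames of matrix input
cor_test_p <- function(r, n) {
  rc <- pmin(1 - 1e-15, pmax(-1 + 1e-15, as.vector(r)))
  t <- rc * sqrt((n - 2) / (1 - rc^2))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  if (!is.null(dim(r))) {
    dim(p) <- dim(r)
    dimnames(p) <- dimnames(r)
  }
  p
}

#' K-means expression-pattern clustering with Bonferroni assignment
#'
#' Standardizes gene profiles, runs K-means (fixed seed, multiple restarts,
#' best inertia kept), then assigns each gene to its best-correlated centroid
#' only when the Bonferroni-adjusted correlation-test p-value (family size =
#' genes x k by default) is below `alpha`. Genes failing the test, and
#' constant genes, stay unassigned. Cluster labels are canonicalized by
#' descending cluster size, ties by lexicographically smallest member gene.
#'
#' @param expr an [expression_matrix()] restricted to the genes of interest
#'   (typically the differentially expressed genes).
#' @param k number of clusters (default 30).
#' @param seed RNG seed for K-means initialization.
#' @param nstart K-means restarts.
#' @param alpha assignment threshold on the adjusted p (strict `<`).
#' @param family `"genes_by_k"` (m = genes x k) or `"genes"` (m = genes).
#' @return list of class `"pattern_clustering"`: `centroids` (k x samples,
#'   standardized), `assignment` data.frame (gene, cluster or NA, r,
#'   p_adjusted), `k`.
#' @export
kmeans_patterns <- function(expr, k = 30, seed = 1L, nstart = 25,
                            alpha = 0.05, family = c("genes_by_k", "genes")) {
  family <- match.arg(family)
  x <- standardize_rows(log2p1(expr))
  ok <- !is.na(x[, 1L])
  if (sum(ok) < k) stop("need >= k non-constant genes")
  km <- with_seed(seed, stats::kmeans(x[ok, , drop = FALSE], centers = k,
                                      nstart = nstart, iter.max = 100))
  cent <- standardize_rows(km$centers)
  if (anyNA(cent)) cent[is.na(cent)] <- 0   # degenerate flat centroid
  n <- ncol(x)
  r_mat <- stats::cor(t(x[ok, , drop = FALSE]), t(cent))
  best <- max.col(r_mat, ties.method = "first")
  r_best <- r_mat[cbind(seq_len(nrow(r_mat)), best)]
  m <- if (family == "genes_by_k") sum(ok) * k else sum(ok)
  p_adj <- pmin(1, cor_test_p(r_best, n) * m)
  assigned <- ifelse(p_adj < alpha, best, NA_integer_)

  # canonical labels: by descending member count, then smallest member gene
  genes_ok <- rownames(expr)[ok]
  sizes <- tabulate(assigned, nbins = k)
  first_gene <- vapply(seq_len(k), function(c) {
    g <- genes_ok[!is.na(assigned) & assigned == c]
    if (length(g)) min(g) else "\uFFFF"
  }, character(1))
  ord <- order(-sizes, first_gene)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  cent <- cent[ord, , drop = FALSE]
  rownames(cent) <- paste0("C", seq_len(k))
  assignment <- data.frame(gene = rownames(expr),
                           cluster = NA_integer_, r = NA_real_,
                           p_adjusted = NA_real_, stringsAsFactors = FALSE)
  assignment$cluster[ok] <- relabel[assigned]
  assignment$r[ok] <- r_best
  assignment$p_adjusted[ok] <- p_adj
  structure(list(centroids = cent, assignment = assignment, k = k),
            class = "pattern_clustering")
}

#' @export
print.pattern_clustering <- function(x, ...) {
  n_assigned <- sum(!is.na(x$assignment$cluster))
  cat(sprintf("pattern_clustering: k = %d, %d/%d genes assigned\n", x$k,
              n_assigned, nrow(x$assignment)))
  invisible(x)
}

#' Stage-enriched gene sets over a contiguous stage window
#'
#' A gene belongs to a window (e.g., oocyte-only, or oocyte through 4-cell)
#' when it is detected (stage-mean FPKM > `on_threshold`) in every window
#' stage, its window mean is at least `fold` times its outside mean, and its
#' outside mean stays at or below `on_threshold`.
#'
#' @param fpkm an [expression_matrix()] of kind `"fpkm"`.
#' @param design a [stage_design()].
#' @param window contiguous run of stage labels in stage order.
#' @param on_threshold detection threshold.
#' @param fold minimum inside/outside mean ratio.
#' @return list of class `"stage_enriched_set"`: `window`, `genes`.
#' @export
stage_enriched_genes <- function(fpkm, design, window, on_threshold = 0.1,
                                 fold = 5) {
  lv <- attr(design, "stage_levels")
  if (!length(window)) stop("empty stage window")
  idx <- match(window, lv)
  if (anyNA(idx)) stop("unknown stage in window: ", window[is.na(idx)][1L])
  if (!all(diff(sort(idx)) == 1))
    stop("window must be a contiguous run of stages")
  stage_mean <- sapply(lv, function(s)
    rowMeans(fpkm[, stage_samples(design, s), drop = FALSE]))
  inside <- stage_mean[, window, drop = FALSE]
  outside <- stage_mean[, setdiff(lv, window), drop = FALSE]
  det_in <- rowSums(inside > on_threshold) == length(window)
  m_in <- rowMeans(inside)
  m_out <- if (ncol(outside)) rowMeans(outside) else rep(0, nrow(fpkm))
  keep <- det_in & m_out <= on_threshold & m_in >= fold * pmax(m_out, 1e-12)
  structure(list(window = window, genes = rownames(fpkm)[keep]),
            class = "stage_enriched_set")
}

#' @export
print.stage_enriched_set <- function(x, ...) {
  cat(sprintf("stage_enriched_set [%s]: %d genes\n",
              paste(x$window, collapse = "->"), length(x$genes)))
  invisible(x)
}
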
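#' Genes detected at a stage
#'
#' A gene counts as detected at a stage when its mean FPKM across that stage's
#' samples is strictly greater than the detection threshold (default 0.1).
#'
#' @param fpkm an [expression_matrix()] of kind `"fpkm"`.
#' @param design a [stage_design()].
#' @param stage stage label.
#' @param threshold detection threshold (strict `>`).
#' @return character vector of detected gene IDs.
#' @export
detected_genes <- function(fpkm, design, stage, threshold = 0.1) {
  if (expr_kind(fpkm) != "fpkm") stop("detected_genes expects FPKM values")
  smp <- stage_samples(design, stage)
  m <- rowMeans(fpkm[, smp, drop = FALSE])
  rownames(fpkm)[m > threshold]
}

#' Expression-sum percentile pre-filter
#'
#' Keeps genes whose summed expression across the compared samples is strictly
#' greater than the given percentile of those sums (default the 25th).
#' The percentile uses linear interpolation between order statistics
#' (`stats::quantile` type 7); the convention is fixed and documented rather
#' than assumed.
#'
#' @param counts an [expression_matrix()].
#' @param samples sample IDs to sum over (>= 2).
#' @param percentile percentile in [0, 1); default 0.25.
#' @return character vector of retained gene IDs.
#' @export
percentile_filter <- function(counts, samples, percentile = 0.25) {
  if (nrow(counts) == 0) stop("empty expression matrix")
  if (length(samples) < 2) stop("need >= 2 samples")
  sums <- rowSums(counts[, samples, drop = FALSE])
  cut <- stats::quantile(sums, percentile, type = 7, names = FALSE)
  keep <- rownames(counts)[sums > cut]
  if (!length(keep))
    warning("percentile filter removed every gene (all sums equal?)")
  keep
}

#' Median-of-ratios size factors
#'
#' The DESeq-default normalization: each sample's factor is the median over
#' genes (those with nonzero counts in every sample) of the ratio of the
#' sample's count to the gene's geometric mean. Factors are rescaled so their
#' geometric mean is 1.
#'
#' @param counts an [expression_matrix()] of counts.
#' @return named numeric vector of positive size factors.
#' @export
estimate_size_factors <- function(counts) {
  logc <- log(unclass(counts))
  finite_rows <- rowSums(is.finite(logc)) == ncol(counts)
  if (!any(finite_rows))
    stop("no gene has nonzero counts in every sample; size factors undefined")
  loggeo <- rowMeans(logc[finite_rows, , drop = FALSE])
  ratio <- exp(logc[finite_rows, , drop = FALSE] - loggeo)
  sf <- apply(ratio, 2, stats::median)
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

# Pooled method-of-moments dispersion per gene, with a trend fitted by a
# robust regression of log dispersion on log mean; final dispersion is the
# maximum of the gene-wise value and the trend (conservative).
estimate_dispersions <- function(counts, sf, group, floor = 1e-8) {
  q <- sweep(unclass(counts), 2, sf, "/")
  groups <- unique(group)
  mu <- rowMeans(q)
  resid2 <- 0
  for (g in groups) {
    cols <- which(group == g)
    qg <- q[, cols, drop = FALSE]
    resid2 <- resid2 + rowSums((qg - rowMeans(qg))^2)
  }
  df <- ncol(q) - length(groups)
  if (df < 1) return(rep(floor, nrow(counts)))
  v <- resid2 / df
  xi <- mean(1 / sf)
  raw <- (v - mu * xi) / mu^2
  raw[!is.finite(raw)] <- floor
  genewise <- pmax(raw, floor)
  use <- raw > floor & mu > 0
  fitted <- rep(floor, nrow(counts))
  if (sum(use) >= 10) {
    fit <- MASS::rlm(log(genewise[use]) ~ log(mu[use]), maxit = 50)
    pred <- cbind(1, log(pmax(mu, .Machine$double.xmin))) %*% stats::coef(fit)
    fitted <- pmax(exp(as.vector(pred)), floor)
  }
  pmax(genewise, fitted)
}

#' Exact-style negative-binomial test between two sample groups
#'
#' For each gene, conditions on the observed total count across both groups
#' and computes a two-sided exact-style p-value: enumerate every split of the
#' total between the groups, with each group's sum modeled as negative
#' binomial (mean proportional to its summed size factors; dispersion the
#' maximum of a pooled method-of-moments estimate and a mean-dispersion
#' trend), and sum the probabilities of all splits no more probable than the
#' observed one. Genes with zero counts throughout get p = 1.
#'
#' @param counts an [expression_matrix()] of counts.
#' @param group_a,group_b disjoint sample ID vectors.
#' @param size_factors optional named size factors; estimated from the two
#'   groups' columns when `NULL`.
#' @param dispersion optional fixed dispersion (scalar or per-gene) overriding
#'   estimation.
#' @param alpha significance threshold used only to label directions.
#' @return data.frame of class `"de_result"` with columns gene, mean_a,
#'   mean_b (normalized), log2fc, pvalue, direction.
#' @export
nb_test <- function(counts, group_a, group_b, size_factors = NULL,
                    dispersion = NULL, alpha = 0.05) {
  if (length(intersect(group_a, group_b)))
    stop("groups overlap: ", intersect(group_a, group_b)[1L])
  if (!length(group_a) || !length(group_b))
    stop("each group needs >= 1 sample")
  cols <- c(group_a, group_b)
  if (!all(cols %in% colnames(counts)))
    stop("unknown sample: ", setdiff(cols, colnames(counts))[1L])
  sub <- unclass(counts)[, cols, drop = FALSE]
  if (is.null(size_factors)) {
    size_factors <- tryCatch(
      estimate_size_factors(expression_matrix(sub, "counts")),
      error = function(e) stats::setNames(rep(1, length(cols)), cols))
  }
  sf <- size_factors[cols]
  grp <- rep(c("a", "b"), c(length(group_a), length(group_b)))
  if (is.null(dispersion))
    dispersion <- estimate_dispersions(sub, sf, grp)
  disp <- rep_len(dispersion, nrow(sub))

  ia <- which(grp == "a"); ib <- which(grp == "b")
  SA <- sum(sf[ia]); SB <- sum(sf[ib])
  SA2 <- sum(sf[ia]^2); SB2 <- sum(sf[ib]^2)
  kA <- rowSums(sub[, ia, drop = FALSE])
  kB <- rowSums(sub[, ib, drop = FALSE])
  mean_a <- kA / SA
  mean_b <- kB / SB
  pv <- vapply(seq_len(nrow(sub)), function(i)
    nb_exact_p(kA[i], kB[i], SA, SB, SA2, SB2, disp[i]), numeric(1))
  lfc <- log2((mean_b + 0.5) / (mean_a + 0.5))
  dir <- ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none"))
  structure(data.frame(gene = rownames(sub), mean_a = mean_a, mean_b = mean_b,
                       log2fc = lfc, pvalue = pv, direction = dir,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("de_result", "data.frame"), alpha = alpha)
}

# Conditional exact NB p-value for one gene: split total T = kA + kB over the
# two groups; group sums are NB with means mu*S and sizes S^2/(alpha*S2)
# (variance mu*S + alpha*mu^2*S2, matching summed per-sample NB variances).
nb_exact_p <- function(kA, kB, SA, SB, SA2, SB2, alpha) {
  T <- kA + kB
  if (T == 0) return(1)
  mu <- T / (SA + SB)
  sizeA <- SA^2 / (alpha * SA2)
  sizeB <- SB^2 / (alpha * SB2)
  muA <- mu * SA; muB <- mu * SB
  if (T <= 50000) {
    a <- 0:T
  } else {
    sd <- sqrt(muA + muA^2 / sizeA + muB + muB^2 / sizeB)
    a <- max(0, floor(muA / (muA + muB) * T - 20 * sd)):
         min(T, ceiling(muA / (muA + muB) * T + 20 * sd))
    a <- union(a, kA)  # observed split always enumerated
  }
  logp <- stats::dnbinom(a, size = sizeA, mu = muA, log = TRUE) +
          stats::dnbinom(T - a, size = sizeB, mu = muB, log = TRUE)
  obs <- logp[match(kA, a)]
  keep <- logp <= obs + 1e-7
  tot <- logsumexp(logp)
  min(1, exp(logsumexp(logp[keep]) - tot))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Consecutive-stage differential expression
#'
#' For each adjacent pair of stages in the design's stage order: apply the
#' expression-sum percentile pre-filter over the pair's samples, then the
#' exact-style NB test; genes with p strictly below `alpha` are flagged, with
#' up/down taken from the fold-change sign (later stage relative to earlier).
#'
#' @param counts an [expression_matrix()] of counts.
#' @param design a [stage_design()] with >= 2 stages.
#' @param alpha significance threshold (strict `<`).
#' @param percentile pre-filter percentile, see [percentile_filter()].
#' @return list of class `"consecutive_de"`: per transition a list with
#'   `stage_a`, `stage_b`, `result` (the full [nb_test()] table over filtered
#'   genes), `de_genes`, `n_up`, `n_down`.
#' @export
consecutive_stage_de <- function(counts, design, alpha = 0.05,
                                 percentile = 0.25) {
  lv <- attr(design, "stage_levels")
  if (length(lv) < 2) stop("need >= 2 stages for consecutive comparisons")
  out <- vector("list", length(lv) - 1L)
  for (i in seq_len(length(lv) - 1L)) {
    sa <- stage_samples(design, lv[i])
    sb <- stage_samples(design, lv[i + 1L])
    keep <- percentile_filter(counts, c(sa, sb), percentile)
    res <- nb_test(expression_matrix(unclass(counts)[keep, c(sa, sb),
                                                     drop = FALSE], "counts"),
                   sa, sb, alpha = alpha)
    sig <- res$pvalue < alpha
    out[[i]] <- list(stage_a = lv[i], stage_b = lv[i + 1L], result = res,
                     de_genes = res$gene[sig],
                     n_up = sum(sig & res$direction == "up"),
                     n_down = sum(sig & res$direction == "down"))
  }
  names(out) <- paste(lv[-length(lv)], lv[-1L], sep = "->")
  structure(out, class = "consecutive_de", alpha = alpha)
}

#' @export
print.consecutive_de <- function(x, ...) {
  cat("consecutive-stage differential expression (alpha =",
      attr(x, "alpha"), ")\n")
  for (tr in x)
    cat(sprintf("  %s -> %s: %d tested, %d up, %d down\n", tr$stage_a,
                tr$stage_b, nrow(tr$result), tr$n_up, tr$n_down))
  invisible(x)
}

#' Construct a qPCR Ct table
#'
#' @param data data.frame with columns gene, sample, ct.
#' @param reference_gene internal-control gene, whose Ct must be present for
#'   every sample.
#' @param calibrator_sample the calibrator (e.g., the pooled-stages sample).
#' @return data.frame of class `"ct_table"`.
#' @export
ct_table <- function(data, reference_gene, calibrator_sample) {
  stopifnot(all(c("gene", "sample", "ct") %in% names(data)))
  samples <- unique(data$sample)
  ref_samples <- data$sample[data$gene == reference_gene]
  if (!all(samples %in% ref_samples))
    stop("reference gene '", reference_gene, "' missing Ct for sample: ",
         setdiff(samples, ref_samples)[1L])
  if (!calibrator_sample %in% samples)
    stop("calibrator sample not in table: ", calibrator_sample)
  structure(data, reference_gene = reference_gene,
            calibrator_sample = calibrator_sample,
            class = c("ct_table", "data.frame"))
}

#' Relative expression by the 2^-ddCt method
#'
#' dCt = Ct(gene) - Ct(reference) within each sample; ddCt = dCt(sample) -
#' dCt(calibrator); relative expression = 2^-ddCt.
#'
#' @param ct a [ct_table()].
#' @param gene target gene.
#' @param sample sample of interest.
#' @return relative expression (positive real).
#' @export
relative_expression_ddct <- function(ct, gene, sample) {
  ref <- attr(ct, "reference_gene")
  cal <- attr(ct, "calibrator_sample")
  ct_of <- function(g, s) {
    v <- ct$ct[ct$gene == g & ct$sample == s]
    if (length(v) != 1L || is.na(v))
      stop("missing Ct for gene '", g, "' in sample '", s, "'")
    v
  }
  dct_s <- ct_of(gene, sample) - ct_of(ref, sample)
  dct_c <- ct_of(gene, cal) - ct_of(ref, cal)
  2^-(dct_s - dct_c)
}
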
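#' Soft-threshold adjacency matrix
#'
#' Connection weights a(i, j) = |corr(i, j)|^beta with Pearson correlation of
#' gene profiles across samples (on log2(x + 1) values by default). The
#' network is unsigned; the diagonal is zeroed by convention so connectivity
#' sums exclude self-edges.
#'
#' @param expr an [expression_matrix()] (genes x samples) or plain matrix.
#' @param beta soft-threshold power (>= 1).
#' @param log_transform apply log2(x + 1) before correlating.
#' @return genes x genes adjacency matrix in [0, 1] with attribute `beta`.
#' @export
soft_adjacency <- function(expr, beta = 6, log_transform = TRUE) {
  if (beta < 1) stop("beta must be >= 1")
  if (ncol(expr) < 3) stop("need >= 3 samples")
  x <- if (log_transform) log2p1(expr) else unclass(expr)
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    warning("constant gene(s), correlations set to 0: ",
            paste(utils::head(rownames(x)[sds == 0], 3), collapse = ", "))
  r <- suppressWarnings(stats::cor(t(x)))
  r[!is.finite(r)] <- 0
  a <- abs(r)^beta
  diag(a) <- 0
  attr(a, "beta") <- beta
  a
}

#' Pick the soft-threshold power by the scale-free topology criterion
#'
#' Returns the smallest candidate beta whose connectivity distribution fits a
#' power law with signed R^2 at or above `r2_target`; falls back to 6 with a
#' warning when no candidate qualifies.
#'
#' @param expr expression input as in [soft_adjacency()].
#' @param candidates candidate powers, non-empty.
#' @param r2_target scale-free model fit target.
#' @param log_transform passed to the correlation step.
#' @return list with `beta`, and `fit_table` (beta, r_squared, mean_k).
#' @export
pick_beta <- function(expr, candidates = c(1:10, seq(12, 20, 2)),
                      r2_target = 0.8, log_transform = TRUE) {
  if (!length(candidates)) stop("empty candidate list")
  x <- if (log_transform) log2p1(expr) else unclass(expr)
  r <- suppressWarnings(stats::cor(t(x)))
  r[!is.finite(r)] <- 0
  absr <- abs(r)
  diag(absr) <- 0
  fit <- data.frame(beta = candidates, r_squared = NA_real_, mean_k = NA_real_)
  for (i in seq_along(candidates)) {
    k <- rowSums(absr^candidates[i])
    fit$mean_k[i] <- mean(k)
    fit$r_squared[i] <- scale_free_r2(k)
  }
  ok <- which(fit$r_squared >= r2_target)
  if (length(ok)) {
    beta <- candidates[min(ok)]
  } else {
    warning("no candidate beta reached scale-free R^2 >= ", r2_target,
            "; using default 6")
    beta <- 6
  }
  list(beta = beta, fit_table = fit)
}

# signed scale-free fit: R^2 of log10 p(k) ~ log10 k over connectivity bins,
# negated when the slope is positive (anti-scale-free)
scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(0)
  cuts <- seq(min(k), max(k), length.out = n_bins + 1)   # equal-width bins
  bin <- cut(k, cuts, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- tapply(k, bin, length) / length(k)
  keep <- !is.na(dk) & pk > 0
  if (sum(keep) < 3) return(0)
  fit <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
  r2 <- summary(fit)$r.squared
  if (stats::coef(fit)[2L] > 0) -r2 else r2
}

#' Topological overlap matrix
#'
#' W(i, j) = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) for i != j, where
#' l_ij sums a_id * a_dj over shared neighbours d and k_i is node i's
#' connectivity; W(i, i) = 1. For a fully isolated pair (k_i = k_j = 0,
#' a_ij = 0) the value is 0.
#'
#' @param adj adjacency matrix from [soft_adjacency()] (zero diagonal,
#'   values in [0, 1]).
#' @return symmetric TOM in [0, 1] with unit diagonal.
#' @export
topological_overlap <- function(adj) {
  a <- unclass(adj)
  if (any(a < 0 | a > 1)) stop("adjacency values must lie in [0, 1]")
  diag(a) <- 0
  l <- a %*% a                       # diag(a)=0 makes d != i,j automatic
  k <- rowSums(a)
  mink <- outer(k, k, pmin)
  w <- (l + a) / (mink + 1 - a)
  diag(w) <- 1
  w
}

#' TOM dissimilarity
#' @param tom a topological overlap matrix.
#' @return D = 1 - W with zero diagonal.
#' @export
tom_distance <- function(tom) {
  d <- 1 - tom
  diag(d) <- 0
  d
}

#' Cut an average-linkage dendrogram into modules
#'
#' Hierarchical clustering (average linkage) of the distance matrix, followed
#' by an adaptive tree cut: branches are split top-down while the subtree is
#' either higher than the static cut height (`cut_height_frac` x the top merge
#' height) or shows a pronounced merge-height gap with two viable
#' sub-branches; a branch whose top merge sits below the cut height and has
#' no such gap becomes a module. Branches smaller than `min_module_size` are
#' left unassigned ("grey").
#'
#' @param distance symmetric dissimilarity matrix with gene dimnames.
#' @param min_module_size smallest admissible module (default 30).
#' @param cut_height_frac static cut as a fraction of the top merge height.
#' @param split_gap relative merge-height gap that forces a split.
#' @return named character vector: gene -> module label ("ME1", "ME2", ... by
#'   decreasing size; "grey" for unassigned), with the hclust tree as
#'   attribute `tree`.
#' @export
cluster_and_cut <- function(distance, min_module_size = 30,
                            cut_height_frac = 0.99, split_gap = 0.2) {
  genes <- rownames(distance)
  n <- length(genes)
  labels <- stats::setNames(rep("grey", n), genes)
  if (n < min_module_size) {
    warning("fewer genes than min_module_size; all grey")
    return(labels)
  }
  h <- stats::hclust(stats::as.dist(distance), method = "average")
  cut_height <- cut_height_frac * max(h$height)

  node_leaves <- function(node) {
    # node > 0: merge index; node < 0: leaf -node
    if (node < 0) return(-node)
    out <- integer(0)
    stack <- node
    while (length(stack)) {
      nd <- stack[length(stack)]; stack <- stack[-length(stack)]
      ch <- h$merge[nd, ]
      for (c in ch) {
        if (c < 0) out <- c(out, -c) else stack <- c(stack, c)
      }
    }
    out
  }
  node_height <- function(node) if (node < 0) 0 else h$height[node]

  clusters <- list()
  recurse <- function(node) {
    leaves <- node_leaves(node)
    if (length(leaves) < min_module_size) return(invisible())
    if (node < 0) return(invisible())
    ch <- h$merge[node, ]
    hh <- node_height(node)
    child_h <- vapply(ch, node_height, numeric(1))
    gap_split <- (hh - max(child_h)) > split_gap * hh &&
      all(vapply(ch, function(c) length(node_leaves(c)), integer(1)) >=
            min_module_size)
    if (hh <= cut_height && !gap_split) {
      clusters[[length(clusters) + 1L]] <<- leaves
    } else {
      for (c in ch) recurse(c)
    }
  }
  recurse(nrow(h$merge))              # root
  if (length(clusters)) {
    ord <- order(-lengths(clusters),
                 vapply(clusters, function(i) min(genes[i]), character(1)))
    clusters <- clusters[ord]
    for (i in seq_along(clusters))
      labels[clusters[[i]]] <- paste0("ME", i)
  }
  attr(labels, "tree") <- h
  labels
}

#' Module eigengene
#'
#' The first principal component of the standardized module expression: the
#' unit-norm right singular vector of the genes x samples matrix after
#' row-standardization, with sign chosen so it correlates positively with the
#' module's mean standardized profile.
#'
#' @param expr module expression (genes x samples), an [expression_matrix()]
#'   or plain matrix.
#' @param log_transform apply log2(x + 1) first.
#' @return list with `eigengene` (named unit-norm vector over samples) and
#'   `var_explained` (fraction in [0, 1]).
#' @export
module_eigengene <- function(expr, log_transform = TRUE) {
  if (nrow(expr) < 1) stop("empty module")
  if (ncol(expr) < 2) stop("need >= 2 samples")
  x <- if (log_transform) log2p1(expr) else unclass(expr)
  z <- standardize_rows(x)
  z <- z[!is.na(z[, 1L]), , drop = FALSE]
  if (!nrow(z)) stop("all module genes constant; eigengene undefined")
  sv <- svd(z)
  v1 <- sv$v[, 1L]
  mean_prof <- colMeans(z)
  s <- sum(v1 * mean_prof)
  if (s < 0) v1 <- -v1
  names(v1) <- colnames(x)
  list(eigengene = v1, var_explained = sv$d[1L]^2 / sum(sv$d^2))
}

#' Build a module set from labels
#'
#' Collects genes by module label, computes each module's eigengene, and
#' returns the standard container used by the stage-specific, preservation
#' and overlap analyses. The reserved label "grey" marks unassigned genes.
#'
#' @param expr full [expression_matrix()].
#' @param labels named gene -> module label vector (e.g. [cluster_and_cut()]).
#' @param log_transform passed to [module_eigengene()].
#' @return object of class `"module_set"`: `modules` (named list of gene
#'   vectors), `eigengenes` (samples x modules), `var_explained`, `labels`.
#' @export
module_set <- function(expr, labels, log_transform = TRUE) {
  labels <- labels[rownames(expr)]
  ids <- setdiff(sort(unique(labels)), "grey")
  ids <- ids[order(-vapply(ids, function(m) sum(labels == m), integer(1)), ids)]
  modules <- lapply(ids, function(m) rownames(expr)[labels == m])
  names(modules) <- ids
  eg <- matrix(NA_real_, nrow = ncol(expr), ncol = length(ids),
               dimnames = list(colnames(expr), ids))
  ve <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (m in ids) {
    me <- module_eigengene(unclass(expr)[modules[[m]], , drop = FALSE],
                           log_transform = log_transform)
    eg[, m] <- me$eigengene
    ve[m] <- me$var_explained
  }
  structure(list(modules = modules, eigengenes = eg, var_explained = ve,
                 labels = labels),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d modules, %d genes assigned, %d grey\n",
              length(x$modules), sum(lengths(x$modules)),
              sum(x$labels == "grey")))
  for (m in names(x$modules))
    cat(sprintf("  %s: %d genes (VE %.2f)\n", m, length(x$modules[[m]]),
                x$var_explained[[m]]))
  invisible(x)
}

#' Merge modules with correlated eigengenes
#'
#' Iteratively merges the module pair with the highest eigengene correlation
#' strictly above `merge_threshold`, recomputing the merged module's
#' eigengene after every merge, until no pair qualifies. Ties pick the
#' lexicographically smallest module-ID pair; the merged module keeps the
#' larger member's ID (smaller ID on a size tie).
#'
#' @param mods a [module_set()].
#' @param expr the full expression matrix the modules came from.
#' @param merge_threshold strict correlation threshold (default 0.7).
#' @param log_transform passed to [module_eigengene()].
#' @return a merged [module_set()].
#' @export
merge_modules <- function(mods, expr, merge_threshold = 0.7,
                          log_transform = TRUE) {
  modules <- mods$modules
  repeat {
    if (length(modules) < 2) break
    eg <- sapply(names(modules), function(m)
      module_eigengene(unclass(expr)[modules[[m]], , drop = FALSE],
                       log_transform = log_transform)$eigengene)
    cm <- stats::cor(eg)
    diag(cm) <- -Inf
    best <- max(cm)
    if (!(best > merge_threshold)) break
    idx <- which(cm == best, arr.ind = TRUE)
    pairs <- t(apply(idx, 1, function(i) sort(colnames(cm)[i])))
    pairs <- unique(pairs)
    pick <- pairs[order(pairs[, 1L], pairs[, 2L])[1L], ]
    a <- pick[1L]; b <- pick[2L]
    keep <- if (length(modules[[a]]) >= length(modules[[b]])) a else b
    drop <- setdiff(c(a, b), keep)
    modules[[keep]] <- sort(c(modules[[keep]], modules[[drop]]))
    modules[[drop]] <- NULL
  }
  labels <- stats::setNames(rep("grey", nrow(expr)), rownames(expr))
  for (m in names(modules)) labels[modules[[m]]] <- m
  module_set(expr, labels, log_transform = log_transform)
}

#' Refine module membership by kME
#'
#' The membership-refinement pass of the dynamic cut (analogous to its PAM
#' stage): every assigned gene moves to the module whose eigengene it
#' correlates with most, when that beats its current kME; modules falling
#' below `min_module_size` afterwards dissolve to grey. Eigengenes are then
#' recomputed.
#'
#' @param mods a [module_set()].
#' @param expr the expression matrix the modules came from.
#' @param min_module_size smallest surviving module.
#' @param log_transform passed through.
#' @return the refined [module_set()].
#' @export
reassign_by_kme <- function(mods, expr, min_module_size = 30,
                            log_transform = TRUE) {
  if (length(mods$modules) < 2) return(mods)
  x <- if (log_transform) log2p1(expr) else unclass(expr)
  kme <- suppressWarnings(stats::cor(t(x), mods$eigengenes))
  kme[!is.finite(kme)] <- -1
  labels <- mods$labels
  assigned <- names(labels)[labels != "grey"]
  best <- colnames(kme)[max.col(kme[assigned, , drop = FALSE],
                                ties.method = "first")]
  cur <- kme[cbind(assigned, labels[assigned])]
  top <- kme[cbind(assigned, best)]
  labels[assigned] <- ifelse(top > cur, best, labels[assigned])
  for (m in unique(labels[labels != "grey"]))
    if (sum(labels == m) < min_module_size) labels[labels == m] <- "grey"
  module_set(expr, labels, log_transform = log_transform)
}

#' Detect co-expression modules end-to-end
#'
#' Full network pipeline: soft adjacency (beta chosen by the scale-free
#' criterion when `"auto"`), topological overlap, TOM dissimilarity,
#' average-linkage clustering with the adaptive tree cut, eigengenes, and
#' eigengene-correlation merging.
#'
#' @param expr an [expression_matrix()].
#' @param beta `"auto"` or a fixed power.
#' @param min_module_size,merge_threshold,cut_height_frac,split_gap see
#'   [cluster_and_cut()] and [merge_modules()].
#' @param log_transform apply log2(x + 1) throughout.
#' @return a [module_set()] with attributes `beta` and `tom` (the TOM).
#' @export
detect_modules <- function(expr, beta = "auto", min_module_size = 30,
                           merge_threshold = 0.7, cut_height_frac = 0.99,
                           split_gap = 0.2, log_transform = TRUE) {
  if (identical(beta, "auto"))
    beta <- pick_beta(expr, log_transform = log_transform)$beta
  adj <- soft_adjacency(expr, beta, log_transform = log_transform)
  tom <- topological_overlap(adj)
  labels <- cluster_and_cut(tom_distance(tom), min_module_size,
                            cut_height_frac, split_gap)
  mods <- module_set(expr, labels, log_transform = log_transform)
  merged <- merge_modules(mods, expr, merge_threshold,
                          log_transform = log_transform)
  refined <- reassign_by_kme(merged, expr, min_module_size,
                             log_transform = log_transform)
  attr(refined, "beta") <- beta
  attr(refined, "tom") <- tom
  refined
}
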
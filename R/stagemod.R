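#' Stage-specific module calls via stage-indicator correlation
#'
#' For every module and stage, correlates the module eigengene with the
#' stage's unit indicator vector (1 for the stage's samples, 0 elsewhere);
#' p-values come from the t statistic with n_samples - 2 degrees of freedom.
#' A module is called specific to the stage with the largest positive r among
#' the stages with p strictly below `alpha`; modules with no qualifying stage
#' stay unlabeled. Over-expression is required, so negative correlations
#' never qualify.
#'
#' @param mods a [module_set()] with eigengenes over all samples.
#' @param design a [stage_design()] with >= 2 stages.
#' @param alpha significance threshold (strict `<`).
#' @return data.frame of class `"stage_specific_calls"`: one row per module
#'   (module_id, stage or NA, r, p), with the full module x stage r and p
#'   matrices as attributes `r_matrix`, `p_matrix`.
#' @export
stage_specific_modules <- function(mods, design, alpha = 0.05) {
  lv <- attr(design, "stage_levels")
  if (length(lv) < 2) stop("need >= 2 stages")
  eg <- mods$eigengenes
  if (!nrow(eg)) stop("module set has no eigengenes")
  samples <- rownames(eg)
  n <- length(samples)
  ind <- sapply(lv, function(s) as.numeric(design$stage[
    match(samples, design$sample)] == s))
  r_mat <- matrix(NA_real_, ncol(eg), length(lv),
                  dimnames = list(colnames(eg), lv))
  for (m in colnames(eg)) {
    e <- eg[, m]
    if (stats::sd(e) == 0) {
      warning("constant eigengene for module ", m, "; left unlabeled")
      next
    }
    r_mat[m, ] <- as.vector(stats::cor(e, ind))
  }
  p_mat <- cor_test_p(r_mat, n)
  calls <- data.frame(module_id = colnames(eg), stage = NA_character_,
                      r = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(calls))) {
    r <- r_mat[i, ]; p <- p_mat[i, ]
    ok <- which(!is.na(r) & r > 0 & p < alpha)
    if (length(ok)) {
      best <- ok[which.max(r[ok])]
      calls$stage[i] <- lv[best]
      calls$r[i] <- r[best]
      calls$p[i] <- p[best]
    }
  }
  structure(calls, r_matrix = r_mat, p_matrix = p_mat, alpha = alpha,
            class = c("stage_specific_calls", "data.frame"))
}

#' Module-membership (kME) scores and hub genes
#'
#' kME is the Pearson correlation of each member gene's profile with the
#' module eigengene; hub genes are those with kME strictly greater than the
#' threshold (default 0.9), sorted by kME descending (ties by gene ID).
#'
#' @param mods a [module_set()].
#' @param expr the expression matrix the modules came from.
#' @param module_id which module.
#' @param kme_threshold strict hub threshold.
#' @param log_transform apply log2(x + 1) as in the network build.
#' @return data.frame (gene_id, module_id, kME, is_hub) sorted by kME.
#' @export
hub_genes <- function(mods, expr, module_id, kme_threshold = 0.9,
                      log_transform = TRUE) {
  if (!module_id %in% names(mods$modules))
    stop("unknown module: ", module_id)
  genes <- mods$modules[[module_id]]
  x <- if (log_transform) log2p1(expr) else unclass(expr)
  e <- mods$eigengenes[, module_id]
  kme <- suppressWarnings(as.vector(stats::cor(t(x[genes, , drop = FALSE]),
                                               e)))
  kme[!is.finite(kme)] <- 0
  out <- data.frame(gene_id = genes, module_id = module_id, kME = kme,
                    is_hub = kme > kme_threshold, stringsAsFactors = FALSE)
  out[order(-out$kME, out$gene_id), , drop = FALSE]
}

#' kME table for every module
#' @inheritParams hub_genes
#' @return row-bound [hub_genes()] tables across all modules.
#' @export
module_kme_table <- function(mods, expr, kme_threshold = 0.9,
                             log_transform = TRUE) {
  do.call(rbind, c(lapply(names(mods$modules), function(m)
    hub_genes(mods, expr, m, kme_threshold, log_transform)),
    list(make.row.names = FALSE)))
}

#' Export the top-connection hub network of a module
#'
#' Restricts the weight matrix (TOM by default) to the top `n_hubs` hub genes
#' by kME, ranks their pairwise weights descending (ties broken by
#' lexicographic node pair) and keeps the top `n_edges` edges; the edge list
#' is written in the sorted VisANT dialect of [write_edge_list()] when `path`
#' is given.
#'
#' @param hub_table a [hub_genes()] table for one module.
#' @param weights symmetric gene x gene weight matrix (TOM or adjacency).
#' @param n_hubs,n_edges top-list sizes (defaults 150 / 200).
#' @param path optional output file.
#' @return data.frame (gene_a, gene_b, weight), ranked.
#' @export
hub_network_export <- function(hub_table, weights, n_hubs = 150,
                               n_edges = 200, path = NULL) {
  hubs <- hub_table$gene_id[hub_table$is_hub]
  hubs <- utils::head(hubs, n_hubs)        # table already kME-sorted
  if (length(hubs) < 2) {
    warning("fewer than 2 hub genes; empty edge list")
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    w <- weights[hubs, hubs, drop = FALSE]
    pairs <- which(upper.tri(w), arr.ind = TRUE)
    edges <- data.frame(gene_a = pmin(hubs[pairs[, 1L]], hubs[pairs[, 2L]]),
                        gene_b = pmax(hubs[pairs[, 1L]], hubs[pairs[, 2L]]),
                        weight = w[pairs], stringsAsFactors = FALSE)
    edges <- edges[order(-edges$weight, edges$gene_a, edges$gene_b), ,
                   drop = FALSE]
    edges <- utils::head(edges, n_edges)
    rownames(edges) <- NULL
  }
  if (!is.null(path)) write_edge_list(edges, path)
  edges
}

#' Validate hub genes across datasets via ortholog groups
#'
#' A hub gene is validated when its ortholog group appears among the hubs of
#' a same-stage stage-specific module in at least one other dataset.
#'
#' @param hub_sets named list (one element per dataset) of data.frames with
#'   columns gene_id and stage (the stage-specific label of the hub's
#'   module).
#' @param map an [ortholog_map()]; `species` tags must equal the dataset
#'   names.
#' @return data.frame per (dataset, stage): n_hubs, n_validated,
#'   pct_validated, n_unmapped.
#' @export
validate_hubs_across_datasets <- function(hub_sets, map) {
  stopifnot(length(hub_sets) >= 2, !is.null(names(hub_sets)))
  key <- function(sp, genes) {
    i <- match(paste(sp, genes), paste(map$species, map$gene_id))
    map$group_id[i]
  }
  out <- list()
  for (ds in names(hub_sets)) {
    tab <- hub_sets[[ds]]
    grp <- key(ds, tab$gene_id)
    unmapped <- is.na(grp)
    others <- setdiff(names(hub_sets), ds)
    other_keys <- unlist(lapply(others, function(o) {
      ot <- hub_sets[[o]]
      paste(ot$stage, key(o, ot$gene_id))
    }))
    validated <- !unmapped & paste(tab$stage, grp) %in% other_keys
    for (s in unique(tab$stage)) {
      sel <- tab$stage == s
      out[[length(out) + 1L]] <- data.frame(
        dataset = ds, stage = s, n_hubs = sum(sel),
        n_validated = sum(validated & sel),
        pct_validated = 100 * sum(validated & sel) / max(1, sum(sel & !unmapped)),
        n_unmapped = sum(unmapped & sel), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
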
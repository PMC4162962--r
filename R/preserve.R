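# Pair ref-species genes with test-species genes through ortholog groups.
# Groups contributing more than one gene on a side use the first listed gene
# (HomoloGene-style maps are overwhelmingly 1:1 within species).
ortholog_pairs <- function(map, ref_species, test_species) {
  a <- map[map$species == ref_species, , drop = FALSE]
  b <- map[map$species == test_species, , drop = FALSE]
  a <- a[!duplicated(a$group_id), , drop = FALSE]
  b <- b[!duplicated(b$group_id), , drop = FALSE]
  common <- intersect(a$group_id, b$group_id)
  data.frame(group_id = common,
             ref_gene = a$gene_id[match(common, a$group_id)],
             test_gene = b$gene_id[match(common, b$group_id)],
             stringsAsFactors = FALSE)
}

#' Categorize a preservation Z-summary
#'
#' Strong if Z >= 10, weak-moderate if 2 <= Z < 10, none if Z < 2.
#' @param z numeric Zsummary value(s).
#' @return character vector of categories.
#' @export
preservation_category <- function(z) {
  ifelse(is.na(z), NA_character_,
         ifelse(z >= 10, "strong",
                ifelse(z >= 2, "weak-moderate", "none")))
}

# four preservation statistics for one gene set (rows of ref_x / test_x are
# the paired genes, already log-transformed)
preservation_stats <- function(ref_x, test_x, beta) {
  cr <- suppressWarnings(stats::cor(t(ref_x)))
  ct <- suppressWarnings(stats::cor(t(test_x)))
  cr[!is.finite(cr)] <- 0
  ct[!is.finite(ct)] <- 0
  ut <- upper.tri(cr)
  ar <- abs(cr)^beta; at <- abs(ct)^beta
  diag(ar) <- 0; diag(at) <- 0
  k_ref <- rowSums(ar); k_test <- rowSums(at)
  c(mean_cor = mean(abs(ct[ut])),
    mean_adj = mean(at[ut]),
    cor_kim = safe_cor(k_ref, k_test),
    cor_cor = safe_cor(cr[ut], ct[ut]))
}

safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Permutation module-preservation Z statistics
#'
#' Measures, for each module defined in the reference dataset, whether its
#' density and connectivity pattern reappear in a test dataset. Observed
#' statistics on the module's ortholog-mapped genes — mean intramodular
#' |correlation|, mean adjacency, ref-vs-test correlation of intramodular
#' connectivity, and ref-vs-test correlation of the vectorized correlation
#' matrices — are standardized against `nPerm` random same-size gene sets
#' drawn (without replacement, excluding the module's own genes) from the
#' common ortholog background:
#' Zdensity = median(Z_meanCor, Z_meanAdj), Zconnectivity = median(Z_kIM,
#' Z_corCor), Zsummary = (Zdensity + Zconnectivity) / 2.
#'
#' @param ref_expr,test_expr [expression_matrix()]s for the two datasets.
#' @param modules named list of gene vectors (reference-species IDs), or a
#'   [module_set()].
#' @param map an [ortholog_map()] covering both species.
#' @param ref_species,test_species species tags in `map`; default the first
#'   two tags in order of appearance.
#' @param beta soft power used for adjacency inside the statistics.
#' @param nPerm permutation count (default 200).
#' @param min_expr expression floor defining a commonly expressed ortholog
#'   (mean value strictly above it in both datasets).
#' @param seed RNG seed; results are deterministic given it.
#' @param log_transform apply log2(x + 1).
#' @return data.frame of class `"preservation_report"`: module_id, size,
#'   Zdensity, Zconnectivity, Zsummary, category, nPerm, seed. Modules with
#'   fewer than 3 background-mapped genes get category "untestable".
#' @export
preservation_z <- function(ref_expr, test_expr, modules, map,
                           ref_species = NULL, test_species = NULL,
                           beta = 6, nPerm = 200, seed = 1L, min_expr = 0.1,
                           log_transform = TRUE) {
  if (inherits(modules, "module_set")) modules <- modules$modules
  tags <- unique(map$species)
  ref_species <- ref_species %||% tags[1L]
  test_species <- test_species %||% setdiff(tags, ref_species)[1L]
  pairs <- ortholog_pairs(map, ref_species, test_species)
  pairs <- pairs[pairs$ref_gene %in% rownames(ref_expr) &
                 pairs$test_gene %in% rownames(test_expr), , drop = FALSE]
  # commonly expressed orthologs only: detected and non-constant in both
  # datasets, so the permutation null is drawn from comparable genes
  expr_ok <- rowMeans(unclass(ref_expr)[pairs$ref_gene, , drop = FALSE]) >
    min_expr &
    rowMeans(unclass(test_expr)[pairs$test_gene, , drop = FALSE]) > min_expr &
    apply(unclass(ref_expr)[pairs$ref_gene, , drop = FALSE], 1,
          stats::sd) > 0 &
    apply(unclass(test_expr)[pairs$test_gene, , drop = FALSE], 1,
          stats::sd) > 0
  pairs <- pairs[expr_ok, , drop = FALSE]
  if (nrow(pairs) < 30)
    stop("fewer than 30 commonly expressed ortholog-mapped genes")
  rx <- if (log_transform) log2p1(ref_expr) else unclass(ref_expr)
  tx <- if (log_transform) log2p1(test_expr) else unclass(test_expr)
  rx <- rx[pairs$ref_gene, , drop = FALSE]
  tx <- tx[pairs$test_gene, , drop = FALSE]
  background <- pairs$ref_gene

  reports <- lapply(names(modules), function(m) {
    mg <- intersect(modules[[m]], background)
    if (length(mg) < 3)
      return(data.frame(module_id = m, size = length(mg),
                        Zdensity = NA_real_, Zconnectivity = NA_real_,
                        Zsummary = NA_real_, category = "untestable",
                        nPerm = nPerm, seed = seed, stringsAsFactors = FALSE))
    mi <- match(mg, background)
    obs <- preservation_stats(rx[mi, , drop = FALSE], tx[mi, , drop = FALSE],
                              beta)
    pool <- setdiff(seq_along(background), mi)
    if (length(pool) < length(mi)) pool <- seq_along(background)
    perm <- with_seed(seed, {
      vapply(seq_len(nPerm), function(p) {
        pi <- sample(pool, length(mi))
        preservation_stats(rx[pi, , drop = FALSE], tx[pi, , drop = FALSE],
                           beta)
      }, numeric(4))
    })
    mu <- rowMeans(perm)
    sd <- apply(perm, 1, stats::sd)
    # a permutation statistic that is (numerically) constant carries no
    # evidence either way; its Z is 0 rather than 0/0
    z <- ifelse(sd < 1e-8, 0, (obs - mu) / sd)
    names(z) <- rownames(perm)
    zd <- stats::median(z[c("mean_cor", "mean_adj")])
    zc <- stats::median(z[c("cor_kim", "cor_cor")])
    zs <- (zd + zc) / 2
    data.frame(module_id = m, size = length(mg), Zdensity = zd,
               Zconnectivity = zc, Zsummary = zs,
               category = preservation_category(zs), nPerm = nPerm,
               seed = seed, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, c(reports, list(make.row.names = FALSE))),
            class = c("preservation_report", "data.frame"))
}

#' Assemble Zsummary values across dataset pairs into a heatmap table
#'
#' @param reports named list of [preservation_z()] reports (one per test
#'   dataset).
#' @param path optional TSV output path.
#' @return modules x datasets matrix of Zsummary (NA for untestable cells).
#' @export
preservation_heatmap_table <- function(reports, path = NULL) {
  stopifnot(length(reports) >= 1, !is.null(names(reports)))
  mods <- unique(unlist(lapply(reports, `[[`, "module_id")))
  tab <- matrix(NA_real_, length(mods), length(reports),
                dimnames = list(mods, names(reports)))
  for (d in names(reports)) {
    r <- reports[[d]]
    tab[r$module_id, d] <- r$Zsummary
  }
  if (!is.null(path)) {
    df <- data.frame(module_id = rownames(tab), tab, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tab
}
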
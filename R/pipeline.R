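#' Adjusted Rand index between two labelings
#'
#' Standard contingency-table form with the expected-index correction;
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param x,y label vectors of equal length (NA pairs dropped).
#' @return numeric ARI.
#' @export
adjusted_rand_index <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (!length(x)) return(NA_real_)
  tab <- table(x, y)
  n <- length(x)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Restrict an FPKM matrix to genes detected in at least one stage
#'
#' The standard pre-network filter: undetected (near-silent) genes carry no
#' usable correlation structure and are excluded before module detection.
#'
#' @param fpkm an [expression_matrix()] of kind `"fpkm"`.
#' @param design a [stage_design()].
#' @param threshold detection threshold, see [detected_genes()].
#' @return the row-subset [expression_matrix()].
#' @export
expressed_subset <- function(fpkm, design, threshold = 0.1) {
  genes <- unique(unlist(lapply(attr(design, "stage_levels"), function(s)
    detected_genes(fpkm, design, s, threshold))))
  expression_matrix(unclass(fpkm)[genes, , drop = FALSE], "fpkm")
}

#' Default pipeline configuration
#'
#' Collects every tunable of the synthetic walkthrough in one validated list:
#' the generator config plus DE alpha, pattern-cluster k, network beta and
#' cut/merge settings, hub thresholds, preservation permutations and the
#' global seed.
#'
#' @param sim a [sim_config()]; its seed is derived from `seed` when omitted.
#' @param alpha DE / stage-call significance threshold.
#' @param k pattern-cluster count.
#' @param beta `"auto"` or fixed soft power.
#' @param min_module_size,merge_threshold network cut/merge settings.
#' @param kme_threshold,n_hubs,n_edges hub settings.
#' @param preserve_fraction sister-species preserved-module fraction.
#' @param nPerm preservation permutations.
#' @param seed global seed.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = NULL, alpha = 0.05, k = 30, beta = "auto",
                            min_module_size = 30, merge_threshold = 0.7,
                            kme_threshold = 0.9, n_hubs = 150, n_edges = 200,
                            preserve_fraction = 1, nPerm = 200, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, k >= 2, min_module_size >= 2,
            merge_threshold >= 0, merge_threshold <= 1,
            kme_threshold >= 0, kme_threshold <= 1,
            preserve_fraction >= 0, preserve_fraction <= 1, nPerm >= 10)
  sim <- sim %||% sim_config(seed = seed)
  structure(list(sim = sim, alpha = alpha, k = k, beta = beta,
                 min_module_size = min_module_size,
                 merge_threshold = merge_threshold,
                 kme_threshold = kme_threshold, n_hubs = n_hubs,
                 n_edges = n_edges, preserve_fraction = preserve_fraction,
                 nPerm = nPerm, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full synthetic-data walkthrough
#'
#' Orchestrates simulate -> differential expression -> pattern clustering ->
#' network module detection -> stage-specific calls and hubs -> sister
#' species + preservation -> cross-species overlap, writing each stage's
#' tables under `out_dir` together with a manifest (parameters, seed, file
#' checksums). Re-running with the same config reproduces identical files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with every stage's in-memory result.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  say("[1/7] simulate: %d genes, %d stages x %d replicates",
      config$sim$n_genes, config$sim$n_stages, config$sim$n_replicates)
  sim <- simulate_dataset(config$sim)
  write_expression(sim$counts, file.path(out_dir, "counts.tsv"))
  write_expression(sim$fpkm, file.path(out_dir, "fpkm.tsv"))
  write_stage_design(sim$design, file.path(out_dir, "design.tsv"))
  truth_tab <- data.frame(gene_id = names(sim$truth$assignment),
                          module_id = ifelse(is.na(sim$truth$assignment),
                                             "none", sim$truth$assignment))
  utils::write.table(truth_tab, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  say("[2/7] differential expression (alpha = %g)", config$alpha)
  de <- consecutive_stage_de(sim$counts, sim$design, alpha = config$alpha)
  de_tab <- do.call(rbind, lapply(de, function(tr)
    cbind(transition = paste(tr$stage_a, tr$stage_b, sep = "->"),
          tr$result)))
  utils::write.table(de_tab, file.path(out_dir, "de.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  de_genes <- unique(unlist(lapply(de, `[[`, "de_genes")))

  say("[3/7] pattern clustering (k = %d, %d DE genes)", config$k,
      length(de_genes))
  pat <- NULL
  if (length(de_genes) >= config$k) {
    pat <- kmeans_patterns(
      expression_matrix(unclass(sim$fpkm)[de_genes, , drop = FALSE], "fpkm"),
      k = config$k, seed = config$seed)
    utils::write.table(pat$assignment, file.path(out_dir, "patterns.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else say("      skipped: fewer DE genes than k")

  say("[4/7] network module detection")
  net_expr <- expressed_subset(sim$fpkm, sim$design)
  mods <- detect_modules(net_expr, beta = config$beta,
                         min_module_size = config$min_module_size,
                         merge_threshold = config$merge_threshold)
  kme <- module_kme_table(mods, net_expr, config$kme_threshold)
  write_module_table(kme, file.path(out_dir, "modules.tsv"))
  eg <- data.frame(sample = rownames(mods$eigengenes), mods$eigengenes,
                   check.names = FALSE)
  utils::write.table(eg, file.path(out_dir, "eigengenes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  say("[5/7] stage-specific calls and hub networks (%d modules)",
      length(mods$modules))
  calls <- stage_specific_modules(mods, sim$design, alpha = config$alpha)
  utils::write.table(calls, file.path(out_dir, "stage_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tom <- attr(mods, "tom")
  for (m in names(mods$modules)) {
    ht <- hub_genes(mods, net_expr, m, config$kme_threshold)
    if (sum(ht$is_hub) >= 2)
      hub_network_export(ht, tom, config$n_hubs, config$n_edges,
                         file.path(out_dir, paste0("hub_edges_", m, ".tsv")))
  }

  say("[6/7] sister species (preserve_fraction = %g) + preservation Z (nPerm = %d)",
      config$preserve_fraction, config$nPerm)
  sister <- simulate_sister_species(sim$truth, config$preserve_fraction,
                                    seed = config$seed + 1000L)
  write_expression(sister$counts, file.path(out_dir, "sister_counts.tsv"))
  write_ortholog_map(sister$ortholog_map,
                     file.path(out_dir, "orthologs.tsv"))
  pres <- preservation_z(sim$fpkm, sister$fpkm, mods, sister$ortholog_map,
                         beta = if (identical(config$beta, "auto"))
                           attr(mods, "beta") else config$beta,
                         nPerm = config$nPerm, seed = config$seed)
  utils::write.table(pres, file.path(out_dir, "preservation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("[7/7] cross-species module overlap")
  sister_mods <- detect_modules(expressed_subset(sister$fpkm, sister$design),
                                beta = config$beta,
                                min_module_size = config$min_module_size,
                                merge_threshold = config$merge_threshold)
  bg <- common_ortholog_background(rownames(sim$fpkm),
                                   rownames(sister$fpkm),
                                   sister$ortholog_map)
  ovl <- overlap_matrix(mods, sister_mods, bg,
                        path = file.path(out_dir, "overlap.tsv"))

  files <- sort(list.files(out_dir, full.names = TRUE))
  files <- files[basename(files) != "manifest.tsv"]
  manifest <- data.frame(file = basename(files),
                         md5 = as.vector(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("done in %.1f s: %s", as.numeric(difftime(Sys.time(), t0, units = "secs")),
      out_dir)
  invisible(list(sim = sim, de = de, patterns = pat, modules = mods,
                 stage_calls = calls, sister = sister, preservation = pres,
                 overlap = ovl, out_dir = out_dir))
}
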
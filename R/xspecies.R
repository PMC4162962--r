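#' Common ortholog background for a species pair
#'
#' The ortholog groups with an expressed member in both species, plus each
#' species' gene-to-group lookup restricted to that background.
#'
#' @param expressed_a,expressed_b expressed gene IDs per species.
#' @param map an [ortholog_map()].
#' @param species_a,species_b species tags in `map`; default the first two
#'   tags in order of appearance.
#' @return list of class `"ortholog_background"`: `groups` (character),
#'   `genes_a`, `genes_b` (named group lookups for the expressed genes).
#' @export
common_ortholog_background <- function(expressed_a, expressed_b, map,
                                       species_a = NULL, species_b = NULL) {
  tags <- unique(map$species)
  species_a <- species_a %||% tags[1L]
  species_b <- species_b %||% setdiff(tags, species_a)[1L]
  ma <- map[map$species == species_a & map$gene_id %in% expressed_a, ]
  mb <- map[map$species == species_b & map$gene_id %in% expressed_b, ]
  groups <- intersect(unique(ma$group_id), unique(mb$group_id))
  if (!length(groups))
    stop("no common expressed ortholog groups between species '", species_a,
         "' and '", species_b, "'")
  ma <- ma[ma$group_id %in% groups, ]
  mb <- mb[mb$group_id %in% groups, ]
  structure(list(groups = sort(groups),
                 genes_a = stats::setNames(ma$group_id, ma$gene_id),
                 genes_b = stats::setNames(mb$group_id, mb$gene_id)),
            class = "ortholog_background")
}

module_groups <- function(genes, lookup, groups) {
  unique(lookup[intersect(genes, names(lookup))])
}

#' Hypergeometric module-overlap enrichment test
#'
#' Maps both modules into the shared ortholog-group background, counts the
#' intersecting groups, and computes the one-sided enrichment p-value
#' P(X >= observed) from the hypergeometric distribution over the 2x2 table
#' (in both / A only / B only / neither). -log10 p is floored at 1e-300
#' against underflow.
#'
#' @param module_a,module_b gene ID vectors for the two species' modules.
#' @param background an [common_ortholog_background()].
#' @return list of class `"overlap_cell"`: `intersection`, `p_value`,
#'   `neg_log10_p`, `n_a`, `n_b`, `n_background`; p is NA ("untestable")
#'   when either module is empty after background mapping.
#' @export
module_overlap_test <- function(module_a, module_b, background) {
  ga <- module_groups(module_a, background$genes_a, background$groups)
  gb <- module_groups(module_b, background$genes_b, background$groups)
  N <- length(background$groups)
  if (!length(ga) || !length(gb))
    return(structure(list(intersection = 0L, p_value = NA_real_,
                          neg_log10_p = NA_real_, n_a = length(ga),
                          n_b = length(gb), n_background = N),
                     class = "overlap_cell"))
  x <- length(intersect(ga, gb))
  p <- stats::phyper(x - 1L, length(ga), N - length(ga), length(gb),
                     lower.tail = FALSE)
  p <- min(1, max(p, 0))
  structure(list(intersection = x, p_value = p,
                 neg_log10_p = -log10(max(p, 1e-300)),
                 n_a = length(ga), n_b = length(gb), n_background = N),
            class = "overlap_cell")
}

#' All-pairs module-overlap table across two species
#'
#' @param modules_a,modules_b named lists of gene vectors (or
#'   [module_set()]s).
#' @param background an [common_ortholog_background()].
#' @param path optional TSV output (module_a, module_b, intersection,
#'   p_value, neg_log10_p per row).
#' @return data.frame of class `"overlap_matrix"`, one row per module pair,
#'   rows in the given module order.
#' @export
overlap_matrix <- function(modules_a, modules_b, background, path = NULL) {
  if (inherits(modules_a, "module_set")) modules_a <- modules_a$modules
  if (inherits(modules_b, "module_set")) modules_b <- modules_b$modules
  rows <- list()
  for (ma in names(modules_a)) {
    for (mb in names(modules_b)) {
      cell <- module_overlap_test(modules_a[[ma]], modules_b[[mb]],
                                  background)
      rows[[length(rows) + 1L]] <- data.frame(
        module_a = ma, module_b = mb, intersection = cell$intersection,
        p_value = cell$p_value, neg_log10_p = cell$neg_log10_p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  structure(out, class = c("overlap_matrix", "data.frame"))
}
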
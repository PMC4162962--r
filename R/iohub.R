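#' Construct a validated expression matrix
#'
#' An expression matrix is a genes x samples numeric matrix with unique row
#' (gene) and column (sample) names, non-negative values, and a `kind`
#' attribute that is either `"counts"` (integral values) or `"fpkm"`
#' (non-negative reals).
#'
#' @param values numeric matrix, genes in rows, samples in columns; must have
#'   unique non-empty dimnames.
#' @param kind `"counts"` or `"fpkm"`.
#' @return the matrix with class `"expression_matrix"` and attribute `kind`.
#' @export
expression_matrix <- function(values, kind = c("counts", "fpkm")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene (row) and sample (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ID: ",
         rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ID: ",
         colnames(values)[duplicated(colnames(values))][1L])
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop("negative value at gene '", rownames(values)[bad[1L]],
         "', sample '", colnames(values)[bad[2L]], "'")
  }
  if (kind == "counts" && any(abs(values - round(values)) > 1e-8)) {
    bad <- which(abs(values - round(values)) > 1e-8, arr.ind = TRUE)[1L, ]
    stop("non-integral count at gene '", rownames(values)[bad[1L]],
         "', sample '", colnames(values)[bad[2L]], "'")
  }
  structure(values, kind = kind, class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d genes x %d samples\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

expr_kind <- function(x) attr(x, "kind") %||% "fpkm"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default developmental stage labels
#'
#' The eight pre-implantation stages used throughout: oocyte through
#' blastocyst.
#' @return character vector of 8 ordered stage labels.
#' @export
default_stages <- function() {
  c("oocyte", "2-cell", "4-cell", "8-cell", "16-cell",
    "early_morula", "compact_morula", "blastocyst")
}

#' Construct a stage design
#'
#' Maps each sample to a developmental stage and replicate number; carries the
#' total order on stages.
#'
#' @param samples character vector of sample IDs.
#' @param stages character vector (same length) of stage labels.
#' @param stage_levels ordered unique stage labels; defaults to the order of
#'   first appearance in `stages`.
#' @return a data.frame (sample, stage, replicate) of class `"stage_design"`
#'   with attribute `stage_levels`.
#' @export
stage_design <- function(samples, stages,
                         stage_levels = unique(stages)) {
  if (length(samples) != length(stages))
    stop("samples and stages must have equal length")
  if (anyDuplicated(samples))
    stop("duplicate sample ID in design: ", samples[duplicated(samples)][1L])
  if (!all(stages %in% stage_levels))
    stop("stage not in stage_levels: ", setdiff(stages, stage_levels)[1L])
  if (!all(stage_levels %in% stages))
    stop("stage level with no sample: ", setdiff(stage_levels, stages)[1L])
  rep_no <- stats::ave(seq_along(samples), stages, FUN = seq_along)
  d <- data.frame(sample = samples, stage = stages, replicate = rep_no,
                  stringsAsFactors = FALSE)
  structure(d, stage_levels = stage_levels,
            class = c("stage_design", "data.frame"))
}

#' @export
print.stage_design <- function(x, ...) {
  lv <- attr(x, "stage_levels")
  cat(sprintf("stage_design: %d samples, %d stages (%s)\n",
              nrow(x), length(lv), paste(lv, collapse = " < ")))
  invisible(x)
}

stage_samples <- function(design, stage) {
  if (!stage %in% attr(design, "stage_levels"))
    stop("unknown stage: ", stage)
  design$sample[design$stage == stage]
}

#' Read an expression table
#'
#' Tab-delimited dialect: UTF-8, `#` comment lines, header row of sample IDs,
#' first column gene IDs, `.` decimal separator. Parsing is fail-fast: the
#' reader rejects duplicate IDs, negative values, non-numeric cells and (for
#' counts) non-integral values rather than coercing them.
#'
#' @param path file path.
#' @param kind `"counts"` or `"fpkm"`.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, kind = c("counts", "fpkm")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           check.names = FALSE, colClasses = "character",
                           quote = "")
  if (ncol(tab) < 2L) stop("expression table needs >= 1 sample column")
  genes <- tab[[1L]]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(genes, colnames(vals))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at gene '", genes[bad[1L]], "', sample '",
         colnames(num)[bad[2L]], "': '", vals[bad[1L], bad[2L]], "'")
  }
  expression_matrix(num, kind)
}

#' Write an expression table
#'
#' Inverse of [read_expression()]; write followed by read round-trips exactly
#' for matrices whose values print without loss at 15 significant digits.
#'
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr),
                   format(unclass(expr), trim = TRUE, digits = 15,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stage design table
#'
#' Tab-delimited columns `sample`, `stage`; stage order is the order of first
#' appearance unless a `# stages: a,b,c` comment header gives it explicitly.
#' @param path file path.
#' @return a [stage_design()].
#' @export
read_stage_design <- function(path) {
  lines <- readLines(path)
  lv <- NULL
  hdr <- grep("^#\\s*stages:", lines, value = TRUE)
  if (length(hdr))
    lv <- trimws(strsplit(sub("^#\\s*stages:", "", hdr[1L]), ",")[[1L]])
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  stage_design(tab$sample, tab$stage, stage_levels = lv %||% unique(tab$stage))
}

#' Write a stage design table
#' @param design a [stage_design()].
#' @param path output path.
#' @export
write_stage_design <- function(design, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# stages: ",
                    paste(attr(design, "stage_levels"), collapse = ",")), con)
  utils::write.table(design[, c("sample", "stage")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ortholog map
#'
#' Three tab-delimited columns: ortholog group ID, species tag, gene ID
#' (HomoloGene-style). A (species, gene) pair may appear in at most one group.
#'
#' @param path file path.
#' @return data.frame (group_id, species, gene_id) of class `"ortholog_map"`.
#' @export
read_ortholog_map <- function(path) {
  lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty ortholog map: ", path)
    return(ortholog_map(character(), character(), character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("ortholog map rows must have 3 tab-delimited fields; row ",
         which(lengths(parts) != 3L)[1L])
  m <- do.call(rbind, parts)
  ortholog_map(m[, 1L], m[, 2L], m[, 3L])
}

#' Construct a validated ortholog map
#' @param group_id,species,gene_id parallel character vectors.
#' @return data.frame of class `"ortholog_map"`.
#' @export
ortholog_map <- function(group_id, species, gene_id) {
  d <- data.frame(group_id = as.character(group_id),
                  species = as.character(species),
                  gene_id = as.character(gene_id),
                  stringsAsFactors = FALSE)
  d <- d[!duplicated(d), , drop = FALSE]
  key <- paste(d$species, d$gene_id, sep = "/")
  if (anyDuplicated(key))
    stop("gene mapped to two ortholog groups: ", key[duplicated(key)][1L])
  structure(d, class = c("ortholog_map", "data.frame"))
}

#' Write an ortholog map
#' @param map an [ortholog_map()].
#' @param path output path.
#' @export
write_ortholog_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a weighted edge list
#'
#' Tab-delimited `node1 node2 weight` rows, lexicographically sorted within
#' and across edges for byte-reproducible output; loadable by VisANT as a
#' weighted edge list. Self-edges are rejected; weights must lie in [0, 1].
#'
#' @param edges data.frame with columns gene_a, gene_b, weight.
#' @param path output path.
#' @export
write_edge_list <- function(edges, path) {
  stopifnot(all(c("gene_a", "gene_b", "weight") %in% names(edges)))
  if (nrow(edges)) {
    if (any(edges$gene_a == edges$gene_b))
      stop("self-edge rejected: ",
           edges$gene_a[edges$gene_a == edges$gene_b][1L])
    if (any(edges$weight < 0 | edges$weight > 1))
      stop("edge weight outside [0,1]: ",
           edges$weight[edges$weight < 0 | edges$weight > 1][1L])
    swap <- edges$gene_a > edges$gene_b
    tmp <- edges$gene_a[swap]
    edges$gene_a[swap] <- edges$gene_b[swap]
    edges$gene_b[swap] <- tmp
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# node1\tnode2\tweight", con)
  if (nrow(edges))
    writeLines(sprintf("%s\t%s\t%.10g", edges$gene_a, edges$gene_b,
                       edges$weight), con)
  invisible(path)
}

#' Write a module table
#'
#' Per-gene TSV with columns gene_id, module_id, kME, is_hub.
#' @param tab data.frame with those columns.
#' @param path output path.
#' @export
write_module_table <- function(tab, path) {
  stopifnot(all(c("gene_id", "module_id") %in% names(tab)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a module table written by [write_module_table()]
#' @param path file path.
#' @return data.frame.
#' @export
read_module_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
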
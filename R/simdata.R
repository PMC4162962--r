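#' Describe a planted co-expression module
#'
#' Planted modules give the generator its ground truth: a set of genes sharing
#' a stage archetype and a common latent factor whose weight (`loading`)
#' controls within-module correlation.
#'
#' Archetypes mirror the canonical pre-implantation dynamics: maternal decay
#' (`"decreasing"`), embryonic genome activation (`"increasing"`), transient
#' activation (`"transient"`), stable maternal/housekeeping transcripts
#' (`"constant"`), and single-stage peaks (`"stage_peak"` with `peak_stage`).
#'
#' @param module_id label.
#' @param size number of member genes (>= 3).
#' @param archetype one of `"increasing"`, `"decreasing"`, `"transient"`,
#'   `"constant"`, `"stage_peak"`.
#' @param loading correlation strength in [0, 1]: weight of the shared
#'   per-sample latent factor relative to gene-specific variation.
#' @param amplitude log2 effect size of the archetype.
#' @param peak_stage 1-based stage index, required for `"stage_peak"`.
#' @return a list of class `"planted_module"`.
#' @export
planted_module <- function(module_id, size, archetype, loading = 0.8,
                           amplitude = 3, peak_stage = NA_integer_) {
  archetype <- match.arg(archetype, c("increasing", "decreasing", "transient",
                                      "constant", "stage_peak"))
  if (size < 3) stop("module size must be >= 3")
  if (loading < 0 || loading > 1) stop("loading must be in [0, 1]")
  if (archetype == "stage_peak" && is.na(peak_stage))
    stop("stage_peak archetype requires peak_stage")
  structure(list(module_id = as.character(module_id), size = as.integer(size),
                 archetype = archetype, loading = loading,
                 amplitude = amplitude, peak_stage = as.integer(peak_stage)),
            class = "planted_module")
}

archetype_profile <- function(mod, n_stages) {
  s <- seq_len(n_stages)
  prof <- switch(mod$archetype,
    increasing = (s - 1) / (n_stages - 1),
    decreasing = (n_stages - s) / (n_stages - 1),
    transient  = {
      mid <- (n_stages + 1) / 2
      1 - abs(s - mid) / (mid - 1)
    },
    constant   = rep(0, n_stages),
    stage_peak = as.numeric(s == mod$peak_stage))
  # centered so amplitude shifts shape, not overall abundance
  prof - mean(prof)
}

#' Configure the synthetic staged-transcriptome generator
#'
#' Defaults emulate a single-embryo pre-implantation profiling design: 8
#' developmental stages x 2 replicates (16 samples), roughly half of all genes
#' detectable per stage, negative-binomial count noise, and five planted
#' stage-peaked co-expression modules.
#'
#' @param n_stages number of stages (>= 2); stage labels come from
#'   [default_stages()] when `n_stages` is 8.
#' @param n_replicates replicates per stage (>= 1).
#' @param n_genes total genes, at least the summed planted module sizes.
#' @param modules list of [planted_module()]s; `NULL` gives the default five
#'   stage-peaked modules of 50 genes (loading 0.8, amplitude 3) peaking at
#'   stages 1, 2, 4, 6 and 8.
#' @param dispersion negative-binomial dispersion (variance = mu + disp*mu^2);
#'   0 selects the deterministic limit where counts equal the rounded mean.
#' @param library_sizes per-sample positive scale factors (recycled).
#' @param background_mean mean count of an expressed background gene.
#' @param detect_fraction per-stage probability that a background gene is
#'   expressed at all in that stage (drives the detected-gene fraction).
#' @param sample_noise_sd log2-scale sd of the independent per-sample wobble
#'   added to background genes (biological noise beyond counting noise);
#'   0 leaves background genes with pure negative-binomial marginals.
#' @param seed integer seed; identical configs give identical output.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_stages = 8, n_replicates = 2, n_genes = 2000,
                       modules = NULL, dispersion = 0.1, library_sizes = 1,
                       background_mean = 50, detect_fraction = 0.5,
                       sample_noise_sd = 0.5, seed = 1L) {
  if (n_stages < 2) stop("n_stages must be >= 2")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (is.null(modules)) {
    peaks <- c(1L, 2L, 4L, 6L, 8L)
    peaks <- peaks[peaks <= n_stages]
    modules <- lapply(seq_along(peaks), function(i)
      planted_module(paste0("M", i), size = 50, archetype = "stage_peak",
                     loading = 0.8, amplitude = 3, peak_stage = peaks[i]))
  }
  planted <- sum(vapply(modules, `[[`, integer(1), "size"))
  if (n_genes < planted)
    stop("n_genes (", n_genes, ") smaller than total planted module size (",
         planted, ")")
  n_samples <- n_stages * n_replicates
  library_sizes <- rep_len(library_sizes, n_samples)
  if (any(library_sizes <= 0)) stop("library_sizes must all be > 0")
  if (any(vapply(modules, function(m)
    m$archetype == "stage_peak" && m$peak_stage > n_stages, logical(1))))
    stop("peak_stage beyond n_stages")
  structure(list(n_stages = as.integer(n_stages),
                 n_replicates = as.integer(n_replicates),
                 n_genes = as.integer(n_genes), modules = modules,
                 dispersion = dispersion, library_sizes = library_sizes,
                 background_mean = background_mean,
                 detect_fraction = detect_fraction,
                 sample_noise_sd = sample_noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

sim_stage_labels <- function(n_stages) {
  if (n_stages == 8L) default_stages() else paste0("stage", seq_len(n_stages))
}

# Core mean-model shared by simulate_dataset and simulate_sister_species.
# Returns list(counts matrix, design, truth data pieces). RNG state is the
# caller's responsibility.
sim_draw <- function(config, gene_prefix = "g", scramble_modules = character()) {
  S <- config$n_stages; R <- config$n_replicates
  n_samples <- S * R
  stages <- sim_stage_labels(S)
  sample_stage <- rep(stages, each = R)
  sample_ids <- paste0(sample_stage, "_r", rep(seq_len(R), times = S))
  stage_idx <- rep(seq_len(S), each = R)

  gene_ids <- sprintf("%s%05d", gene_prefix, seq_len(config$n_genes))
  assignment <- rep(NA_character_, config$n_genes)
  log2mu <- matrix(0, config$n_genes, n_samples)

  # gene-level baseline spread (lognormal abundances)
  base <- log2(config$background_mean) + stats::rnorm(config$n_genes, 0, 1)
  log2mu <- matrix(base, config$n_genes, n_samples)

  gi <- 1L
  profiles <- list()
  for (mod in config$modules) {
    idx <- gi:(gi + mod$size - 1L)
    gi <- gi + mod$size
    assignment[idx] <- mod$module_id
    prof <- archetype_profile(mod, S)
    profiles[[mod$module_id]] <- prof
    latent <- stats::rnorm(n_samples, 0, 1)          # shared factor, sd 1
    noise <- matrix(stats::rnorm(mod$size * n_samples), mod$size)
    if (mod$module_id %in% scramble_modules) {
      # structure destroyed: members keep baseline spread but get independent
      # profiles (no shared archetype, no shared factor)
      log2mu[idx, ] <- log2mu[idx, ] + 1.0 * noise
    } else {
      shared <- mod$amplitude * prof[stage_idx] + mod$loading * latent
      gene_part <- sqrt(1 - mod$loading^2) * noise
      log2mu[idx, ] <- log2mu[idx, ] +
        matrix(shared, mod$size, n_samples, byrow = TRUE) + gene_part
    }
  }

  # background genes: a detect_fraction of them expressed, the rest silent
  # (near-zero mean, hence undetected); independent per-sample wobble only,
  # so background carries no co-expression structure
  bg <- which(is.na(assignment))
  if (length(bg)) {
    expressed <- stats::runif(length(bg)) < config$detect_fraction
    log2mu[bg[!expressed], ] <- log2mu[bg[!expressed], , drop = FALSE] - 12
    if (config$sample_noise_sd > 0)
      log2mu[bg, ] <- log2mu[bg, , drop = FALSE] +
        matrix(stats::rnorm(length(bg) * n_samples, 0, config$sample_noise_sd),
               length(bg))
  }

  mu <- 2^log2mu * matrix(config$library_sizes, config$n_genes, n_samples,
                          byrow = TRUE)
  counts <- if (config$dispersion == 0) {
    round(mu)
  } else {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
           nrow(mu))
  }
  dimnames(counts) <- list(gene_ids, sample_ids)
  design <- stage_design(sample_ids, sample_stage, stage_levels = stages)
  list(counts = counts, design = design, assignment = assignment,
       profiles = profiles, gene_ids = gene_ids)
}

counts_to_fpkm <- function(counts, gene_length_kb = 1) {
  depth <- colSums(counts)
  depth[depth == 0] <- 1
  fpkm <- sweep(counts, 2, depth / 1e6, "/") / gene_length_kb
  expression_matrix(fpkm, "fpkm")
}

#' Simulate a staged-transcriptome dataset
#'
#' Draws negative-binomial counts around a log-scale mean model:
#' gene baseline + amplitude x stage archetype + loading-weighted shared
#' latent factor per planted module, scaled by per-sample library sizes.
#' The matching FPKM matrix is counts per million over unit gene lengths,
#' which preserves detection-rank structure.
#'
#' @param config a [sim_config()].
#' @return list with elements `counts` and `fpkm` ([expression_matrix()]s),
#'   `design` ([stage_design()]), and `truth` (class `"synthetic_truth"`:
#'   gene-to-module assignment, per-module archetype profiles, the config and
#'   seed used).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  drawn <- with_seed(config$seed, sim_draw(config))
  counts <- expression_matrix(drawn$counts, "counts")
  truth <- structure(list(assignment = stats::setNames(drawn$assignment,
                                                       drawn$gene_ids),
                          profiles = drawn$profiles, config = config,
                          seed = config$seed),
                     class = "synthetic_truth")
  list(counts = counts, fpkm = counts_to_fpkm(counts), design = drawn$design,
       truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d genes, %d planted modules (seed %d)\n",
              length(x$assignment), length(x$profiles), x$seed))
  invisible(x)
}

#' Simulate a sister-species dataset with controllable module preservation
#'
#' Regenerates the configured dataset under a new seed for a second species:
#' gene IDs are renamed, a one-group-per-gene ortholog map links the two
#' species, and a `preserve_fraction` of the planted modules keep their
#' archetype and loading while the rest lose all co-expression structure
#' (members become independent noise genes).
#'
#' @param truth a `"synthetic_truth"` from [simulate_dataset()].
#' @param preserve_fraction fraction of planted modules preserved, in [0, 1].
#' @param seed integer seed for the second species' draw.
#' @param species_tags length-2 character: species labels for the ortholog map.
#' @return list with `counts`, `fpkm`, `design`, `ortholog_map`, `truth`
#'   (the sister species' own truth; scrambled modules are unassigned), and
#'   `preserved_modules` (character vector of preserved module IDs).
#' @export
simulate_sister_species <- function(truth, preserve_fraction, seed,
                                    species_tags = c("speciesA", "speciesB")) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (preserve_fraction < 0 || preserve_fraction > 1)
    stop("preserve_fraction must be in [0, 1]")
  config <- truth$config
  mod_ids <- vapply(config$modules, `[[`, character(1), "module_id")
  n_keep <- round(preserve_fraction * length(mod_ids))
  keep <- with_seed(seed, sample(mod_ids, n_keep))
  scramble <- setdiff(mod_ids, keep)
  drawn <- with_seed(seed + 1L,
                     sim_draw(config, gene_prefix = "h",
                              scramble_modules = scramble))
  counts <- expression_matrix(drawn$counts, "counts")
  a_genes <- names(truth$assignment)
  map <- ortholog_map(
    group_id = rep(sprintf("og%05d", seq_along(a_genes)), 2L),
    species = rep(species_tags, each = length(a_genes)),
    gene_id = c(a_genes, drawn$gene_ids))
  assignment <- drawn$assignment
  assignment[assignment %in% scramble] <- NA_character_
  truth_b <- structure(list(assignment = stats::setNames(assignment,
                                                         drawn$gene_ids),
                            profiles = drawn$profiles[keep], config = config,
                            seed = seed),
                       class = "synthetic_truth")
  list(counts = counts, fpkm = counts_to_fpkm(counts), design = drawn$design,
       ortholog_map = map, truth = truth_b, preserved_modules = keep)
}
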
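test_that("stage-indicator correlations match a brute-force t-test oracle", {
  sim <- default_sim()
  mods <- default_modules()
  calls <- stage_specific_modules(mods, sim$design)
  r_mat <- attr(calls, "r_matrix")
  p_mat <- attr(calls, "p_matrix")
  samples <- rownames(mods$eigengenes)
  stages <- attr(sim$design, "stage_levels")
  set.seed(41)
  for (m in sample(colnames(mods$eigengenes), 3)) {
    for (s in sample(stages, 3)) {
      ind <- as.numeric(sim$design$stage[match(samples,
                                               sim$design$sample)] == s)
      ct <- cor.test(mods$eigengenes[, m], ind)
      expect_equal(r_mat[m, s], unname(ct$estimate), tolerance = 1e-10)
      expect_equal(p_mat[m, s], ct$p.value, tolerance = 1e-10)
    }
  }
  # assigned => significant positive correlation
  ok <- !is.na(calls$stage)
  expect_true(all(calls$r[ok] > 0) && all(calls$p[ok] < 0.05))
  # a stage-called module's eigengene peaks (in stage-mean) at that stage
  for (i in which(ok)) {
    eg <- mods$eigengenes[, calls$module_id[i]]
    sm <- tapply(eg, sim$design$stage[match(samples, sim$design$sample)],
                 mean)
    expect_equal(names(which.max(sm)), calls$stage[i])
  }
})

test_that("an indicator-shaped eigengene is assigned with r = 1", {
  d <- stage_design(paste0("s", 1:8), rep(paste0("st", 1:4), each = 2))
  ind <- as.numeric(d$stage == "st3")
  eg <- matrix(c(ind / sqrt(sum(ind^2)), rep(0.5, 8)), ncol = 2,
               dimnames = list(d$sample, c("Mpeak", "Mflat")))
  mods <- structure(list(modules = list(Mpeak = "g1", Mflat = "g2"),
                         eigengenes = eg,
                         var_explained = c(Mpeak = 1, Mflat = 1),
                         labels = c(g1 = "Mpeak", g2 = "Mflat")),
                    class = "module_set")
  expect_warning(calls <- stage_specific_modules(mods, d), "constant")
  expect_equal(calls$stage[calls$module_id == "Mpeak"], "st3")
  expect_equal(calls$r[calls$module_id == "Mpeak"], 1, tolerance = 1e-12)
  expect_true(is.na(calls$stage[calls$module_id == "Mflat"]))
})

test_that("hub calling is strict at the kME threshold and matches a scan", {
  sim <- default_sim()
  mods <- default_modules()
  ne <- default_net_expr()
  m <- names(mods$modules)[1]
  ht <- hub_genes(mods, ne, m)
  # brute-force kME scan
  x <- log2(unclass(ne) + 1)
  for (i in c(1, nrow(ht))) {
    expect_equal(ht$kME[i], cor(x[ht$gene_id[i], ],
                                mods$eigengenes[, m]), tolerance = 1e-12)
  }
  expect_true(all(ht$is_hub == (ht$kME > 0.9)))
  expect_true(!is.unsorted(rev(ht$kME)))
  # strictness: at a threshold equal to an attained kME, that gene is no hub
  thr <- ht$kME[3]
  ht2 <- hub_genes(mods, ne, m, kme_threshold = thr)
  expect_false(ht2$is_hub[ht2$gene_id == ht$gene_id[3]])
  # nesting under relaxation
  h95 <- ht$gene_id[hub_genes(mods, ne, m, 0.95)$is_hub]
  h90 <- ht$gene_id[hub_genes(mods, ne, m, 0.90)$is_hub]
  expect_true(all(h95 %in% h90))
  # a gene proportional to the eigengene scores kME 1 by construction
  expect_gt(max(ht$kME), 0.9)
})

test_that("hub-network export ranks edges and is byte-deterministic", {
  w <- matrix(0, 3, 3, dimnames = list(c("gA", "gB", "gC"),
                                       c("gA", "gB", "gC")))
  w["gA", "gB"] <- w["gB", "gA"] <- 0.9
  w["gA", "gC"] <- w["gC", "gA"] <- 0.8
  w["gB", "gC"] <- w["gC", "gB"] <- 0.7
  ht <- data.frame(gene_id = c("gA", "gB", "gC"), module_id = "M",
                   kME = c(0.99, 0.98, 0.97), is_hub = TRUE)
  edges <- hub_network_export(ht, w, n_hubs = 150, n_edges = 2)
  expect_equal(edges$weight, c(0.9, 0.8))
  expect_equal(edges$gene_a, c("gA", "gA"))

  all_edges <- hub_network_export(ht, w, n_hubs = 2, n_edges = 10)
  expect_equal(nrow(all_edges), 1L)     # only gA-gB among top-2 hubs

  # brute-force sort oracle on a random instance
  set.seed(42)
  n <- 12
  wr <- random_adjacency(n)
  htr <- data.frame(gene_id = rownames(wr), module_id = "M",
                    kME = seq(0.99, 0.91, length.out = n), is_hub = TRUE)
  er <- hub_network_export(htr, wr, n_hubs = n, n_edges = 20)
  ut <- which(upper.tri(wr), arr.ind = TRUE)
  oracle <- data.frame(a = rownames(wr)[ut[, 1]], b = rownames(wr)[ut[, 2]],
                       w = wr[ut])
  oracle <- oracle[order(-oracle$w), ][1:20, ]
  expect_equal(er$weight, oracle$w)

  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  hub_network_export(ht, w, n_edges = 2, path = p1)
  hub_network_export(ht, w, n_edges = 2, path = p2)
  expect_identical(readLines(p1), readLines(p2))

  lone <- ht[1, ]
  expect_warning(e0 <- hub_network_export(lone, w), "fewer than 2")
  expect_equal(nrow(e0), 0L)
})

test_that("hub validation counts same-stage ortholog overlap across datasets", {
  hubs <- data.frame(gene_id = c("b1", "b2", "b3"),
                     stage = c("oocyte", "oocyte", "blastocyst"))
  map <- ortholog_map(rep(c("og1", "og2", "og3"), 2),
                      rep(c("dsA", "dsB"), each = 3),
                      c("b1", "b2", "b3", "h1", "h2", "h3"))
  # duplicated dataset: everything validates
  dup <- validate_hubs_across_datasets(
    list(dsA = hubs, dsB = data.frame(gene_id = c("h1", "h2", "h3"),
                                      stage = hubs$stage)), map)
  expect_true(all(dup$pct_validated == 100))
  # disjoint hubs: nothing validates
  dis <- validate_hubs_across_datasets(
    list(dsA = hubs, dsB = data.frame(gene_id = "h3", stage = "oocyte")),
    map)
  a_rows <- dis[dis$dataset == "dsA", ]
  expect_true(all(a_rows$n_validated == 0))
})

test_that("hubs of preserved sister modules validate across species", {
  # near-noise-free regime: loading close to 1 and tiny dispersion make
  # essentially every member a hub in both species
  cfg <- sim_config(n_genes = 600, seed = 43, dispersion = 0.002,
                    modules = lapply(1:5, function(i)
                      planted_module(paste0("M", i), 50, "stage_peak",
                                     loading = 0.98,
                                     peak_stage = c(1, 2, 4, 6, 8)[i])))
  sim <- simulate_dataset(cfg)
  sis <- simulate_sister_species(sim$truth, 1, seed = 43)
  truth_mods <- truth_module_list(sim$truth)
  peak_stage <- vapply(sim$truth$config$modules, function(m)
    default_stages()[m$peak_stage], character(1))
  names(peak_stage) <- vapply(sim$truth$config$modules, `[[`, character(1),
                              "module_id")
  hub_stage_table <- function(expr, mods_list) {
    labels <- setNames(rep("grey", nrow(expr)), rownames(expr))
    for (m in names(mods_list)) labels[mods_list[[m]]] <- m
    ms <- module_set(expr, labels)
    do.call(rbind, lapply(names(ms$modules), function(m) {
      ht <- hub_genes(ms, expr, m)
      data.frame(gene_id = ht$gene_id[ht$is_hub], stage = peak_stage[[m]])
    }))
  }
  ha <- hub_stage_table(sim$fpkm, truth_mods)
  truth_b <- truth_module_list(sis$truth)
  hb <- hub_stage_table(sis$fpkm, truth_b)
  res <- validate_hubs_across_datasets(
    list(speciesA = ha, speciesB = hb), sis$ortholog_map)
  a_rows <- res[res$dataset == "speciesA", ]
  expect_gte(sum(a_rows$n_validated) / sum(a_rows$n_hubs), 0.9)
})
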
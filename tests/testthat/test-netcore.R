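test_that("soft adjacency matches the |Pearson|^beta oracle elementwise", {
  set.seed(31)
  em <- make_em(matrix(rexp(160, 0.1), 10), "fpkm")
  for (beta in c(1, 2, 6)) {
    a <- soft_adjacency(em, beta)
    x <- log2(unclass(em) + 1)
    for (i in 1:10) for (j in 1:10) {
      expected <- if (i == j) 0 else abs(cor(x[i, ], x[j, ]))^beta
      expect_equal(a[i, j], expected, tolerance = 1e-12)
    }
  }
  # exact correlations
  two <- make_em(rbind(2^(1:8) - 1, 2^(1:8) - 1), "fpkm")
  expect_equal(soft_adjacency(two, 6)[1, 2], 1)
  neg <- make_em(rbind(2^c(1, 2, 3, 4) - 1, 2^c(4, 3, 2, 1) - 1), "fpkm")
  expect_equal(soft_adjacency(neg, 2)[1, 2], 1)       # |-1|^2
  expect_error(soft_adjacency(em, 0.5), "beta")
})

test_that("TOM matches the brute-force triple loop and stays in [0, 1]", {
  set.seed(32)
  for (rep in 1:5) {
    a <- random_adjacency(15)
    w <- topological_overlap(a)
    expect_equal(w, brute_tom(a), tolerance = 1e-12)
    expect_true(all(w >= 0 & w <= 1 + 1e-12))
    expect_equal(w, t(w))
  }
  # two genes fully connected to each other only
  a2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("g1", "g2"),
                                                 c("g1", "g2")))
  expect_equal(topological_overlap(a2)[1, 2], 1)
  # complete graph: all overlaps are 1
  n <- 6
  ac <- matrix(1, n, n); diag(ac) <- 0
  dimnames(ac) <- list(paste0("g", 1:n), paste0("g", 1:n))
  wc <- topological_overlap(ac)
  expect_true(all(abs(wc - 1) < 1e-12))
  # isolated pair
  a0 <- matrix(0, 3, 3, dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  expect_equal(topological_overlap(a0)[1, 2], 0)
})

test_that("TOM distance is the unit complement", {
  set.seed(33)
  w <- topological_overlap(random_adjacency(10))
  d <- tom_distance(w)
  expect_equal(d, 1 - w, ignore_attr = TRUE)
  expect_equal(unname(diag(d)), rep(0, 10))
  expect_true(all(d >= -1e-12 & d <= 1 + 1e-12))
})

test_that("tree cut separates planted blocks and respects the size gate", {
  n <- 100
  d <- matrix(0.9, n, n)
  d[1:50, 1:50] <- 0.1
  d[51:100, 51:100] <- 0.1
  diag(d) <- 0
  dimnames(d) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  lab <- cluster_and_cut(d, min_module_size = 30)
  expect_equal(sort(unique(lab)), c("ME1", "ME2"))
  expect_equal(length(unique(lab[1:50])), 1L)
  expect_equal(length(unique(lab[51:100])), 1L)
  expect_false(lab[1] == lab[51])

  lab60 <- cluster_and_cut(d, min_module_size = 60)
  expect_true(all(lab60 == "grey"))

  flat <- matrix(0.5, 40, 40); diag(flat) <- 0
  dimnames(flat) <- list(sprintf("g%03d", 1:40), sprintf("g%03d", 1:40))
  expect_true(all(cluster_and_cut(flat, min_module_size = 10) == "grey"))
})

test_that("module eigengene matches an SVD oracle and its conventions", {
  set.seed(34)
  em <- make_em(matrix(rexp(480, 0.1), 30), "fpkm")
  me <- module_eigengene(em)
  x <- log2(unclass(em) + 1)
  z <- t(scale(t(x)))
  sv <- svd(z)
  expect_equal(abs(me$eigengene), abs(sv$v[, 1]), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(me$var_explained, sv$d[1]^2 / sum(sv$d^2), tolerance = 1e-10)
  expect_equal(sum(me$eigengene^2), 1)
  # sign convention: positively correlated with the module mean profile
  expect_gte(cor(me$eigengene, colMeans(z)), 0)

  single <- make_em(matrix(2^c(1, 5, 2, 4) - 1, 1), "fpkm")
  s <- module_eigengene(single)
  zs <- as.vector(scale(log2(unclass(single)[1, ] + 1)))
  expect_equal(unname(s$eigengene), zs / sqrt(sum(zs^2)))

  twin <- make_em(rbind(2^c(1, 5, 2, 4), 2^c(1, 5, 2, 4)), "fpkm")
  expect_equal(module_eigengene(twin)$var_explained, 1)
  const <- make_em(matrix(3, 2, 4), "fpkm")
  expect_error(module_eigengene(const), "constant")
})

test_that("module merging follows the strict 0.7 rule with recomputation", {
  set.seed(35)
  n_samp <- 16
  base1 <- rnorm(n_samp)
  mk_genes <- function(profile, n, noise) {
    t(replicate(n, profile + rnorm(n_samp, 0, noise)))
  }
  # two tightly related modules (eigengene r > 0.7) and one unrelated
  ga <- mk_genes(base1, 20, 0.4)
  gb <- mk_genes(base1, 20, 0.4)
  gc <- mk_genes(rnorm(n_samp), 20, 0.4)
  em <- make_em(2^rbind(ga, gb, gc), "fpkm")
  labels <- setNames(rep(c("A", "B", "C"), each = 20), rownames(em))
  mods <- module_set(em, labels)
  r_ab <- cor(mods$eigengenes[, "A"], mods$eigengenes[, "B"])
  expect_gt(r_ab, 0.7)
  merged <- merge_modules(mods, em)
  expect_equal(length(merged$modules), 2L)
  expect_setequal(merged$modules[[1]], rownames(em)[1:40])

  # strict boundary: at a threshold equal to the realized correlation,
  # nothing merges
  same <- merge_modules(mods, em, merge_threshold = r_ab)
  r_next <- max(cor(same$eigengenes)[upper.tri(diag(3))])
  expect_equal(length(same$modules), 3L)

  # trace oracle: hand-simulate the documented iterative procedure
  hand <- list(A = rownames(em)[1:20], B = rownames(em)[21:40],
               C = rownames(em)[41:60])
  repeat {
    eg <- sapply(hand, function(g)
      module_eigengene(unclass(em)[g, , drop = FALSE])$eigengene)
    cm <- cor(eg); diag(cm) <- -Inf
    if (max(cm) <= 0.7) break
    ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    nm <- sort(colnames(cm)[ij])
    keep <- if (length(hand[[nm[1]]]) >= length(hand[[nm[2]]]))
      nm[1] else nm[2]
    drop <- setdiff(nm, keep)
    hand[[keep]] <- sort(c(hand[[keep]], hand[[drop]]))
    hand[[drop]] <- NULL
  }
  expect_equal(lapply(merged$modules, sort)[order(names(merged$modules))],
               hand[order(names(hand))], ignore_attr = TRUE)
})

test_that("merge threshold is monotone in module count", {
  set.seed(36)
  sim <- simulate_dataset(sim_config(n_genes = 250, seed = 36))
  ne <- expressed_subset(sim$fpkm, sim$design)
  labels <- cluster_and_cut(tom_distance(topological_overlap(
    soft_adjacency(ne, 6))), min_module_size = 20)
  mods <- module_set(ne, labels)
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th)
    length(merge_modules(mods, ne, th)$modules), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("beta selection hits the scale-free target on modular data", {
  sim <- default_sim()
  pb <- pick_beta(expressed_subset(sim$fpkm, sim$design))
  expect_lte(pb$beta, 12)
  expect_gte(max(pb$fit_table$r_squared), 0.8)
  expect_error(pick_beta(sim$fpkm, candidates = numeric()), "empty")
  # fallback contract on structureless data
  noise <- simulate_dataset(sim_config(n_genes = 60, modules = list(),
                                       detect_fraction = 1, seed = 38))
  expect_warning(pb2 <- pick_beta(noise$fpkm, candidates = 1:2,
                                  r2_target = 0.999), "default 6")
  expect_equal(pb2$beta, 6)
})

test_that("full pipeline recovers planted modules with high fidelity", {
  sim <- default_sim()
  mods <- default_modules()
  truth <- sim$truth$assignment
  planted <- names(truth)[!is.na(truth)]
  ari <- adjusted_rand_index(truth[planted], mods$labels[planted])
  expect_gte(ari, 0.9)
})

test_that("the package ARI agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(39)
  for (i in 1:5) {
    x <- sample(letters[1:4], 60, replace = TRUE)
    y <- sample(letters[1:3], 60, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y))
  }
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
})
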
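# shared fixtures and independent oracles, built in code at test time

make_em <- function(values, kind = "fpkm", genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, kind)
}

# identity A/B ortholog map over a gene set (1 group per gene, both species)
identity_map <- function(genes_a, genes_b = genes_a,
                         species = c("A", "B")) {
  ortholog_map(rep(sprintf("og%05d", seq_along(genes_a)), 2),
               rep(species, c(length(genes_a), length(genes_b))),
               c(genes_a, genes_b))
}

# triple-loop TOM oracle, deliberately naive
brute_tom <- function(a) {
  n <- nrow(a)
  w <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (d in seq_len(n)) if (d != i && d != j) l <- l + a[i, d] * a[d, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    w[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  dimnames(w) <- dimnames(a)
  w
}

random_adjacency <- function(n) {
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  dimnames(a) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  a
}

# hypergeometric upper-tail oracle by direct combinatorial summation
brute_hyper_upper <- function(x, K, N, n) {
  j <- x:min(K, n)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# expensive shared fixtures, computed once per test run
.fix <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fix$sim)) .fix$sim <- simulate_dataset(sim_config(seed = 1))
  .fix$sim
}

default_modules <- function() {
  if (is.null(.fix$mods)) {
    sim <- default_sim()
    ne <- expressed_subset(sim$fpkm, sim$design)
    .fix$mods <- suppressWarnings(detect_modules(ne))
    .fix$net_expr <- ne
  }
  .fix$mods
}

default_net_expr <- function() {
  default_modules()
  .fix$net_expr
}

truth_module_list <- function(truth) {
  a <- truth$assignment
  split(names(a)[!is.na(a)], a[!is.na(a)])
}
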
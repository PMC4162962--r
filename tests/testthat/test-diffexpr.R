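design4 <- function() {
  stage_design(sprintf("s%02d", 1:4), rep(c("early", "late"), each = 2))
}

test_that("detection uses a strict FPKM threshold and matches a gene scan", {
  em <- make_em(rbind(rep(0.1, 4), rep(0.11, 4), c(0, 0, 5, 5)), "fpkm")
  d <- design4()
  det <- detected_genes(em, d, "early")
  expect_false("g001" %in% det)            # exactly 0.1 is NOT detected
  expect_true("g002" %in% det)
  expect_false("g003" %in% det)            # mean 0 in early

  set.seed(11)
  rm <- make_em(matrix(rexp(200, 5), 50), "fpkm")
  d2 <- stage_design(colnames(rm), rep("only", 4), "only")
  brute <- rownames(rm)[vapply(seq_len(nrow(rm)), function(i)
    mean(rm[i, ]) > 0.1, logical(1))]
  expect_setequal(detected_genes(rm, d2, "only"), brute)
  expect_error(detected_genes(rm, d2, "nope"), "unknown stage")
})

test_that("percentile filter keeps sums strictly above the interpolated cut", {
  cm <- make_em(matrix(c(1, 2, 3, 4, 0, 0, 0, 0), 4), "counts")
  # row sums 1,2,3,4; linear-interpolation 25th percentile = 1.75
  kept <- percentile_filter(cm, colnames(cm))
  expect_setequal(kept, c("g002", "g003", "g004"))

  all_eq <- make_em(matrix(2, 3, 2), "counts")
  expect_warning(kept2 <- percentile_filter(all_eq, colnames(all_eq)),
                 "every gene")
  expect_length(kept2, 0L)

  two <- make_em(matrix(c(0, 5, 0, 5), 2), "counts")
  expect_equal(percentile_filter(two, colnames(two)), "g002")

  # relaxing the percentile can only grow the kept set
  set.seed(12)
  rm <- make_em(matrix(rpois(300, 20), 100), "counts")
  k50 <- percentile_filter(rm, colnames(rm), 0.50)
  k25 <- percentile_filter(rm, colnames(rm), 0.25)
  k10 <- percentile_filter(rm, colnames(rm), 0.10)
  expect_true(all(k50 %in% k25) && all(k25 %in% k10))
})

test_that("size factors follow median-of-ratios with unit geometric mean", {
  a <- c(10, 20, 30, 40)
  same <- make_em(cbind(a, a), "counts")
  expect_equal(unname(estimate_size_factors(same)), c(1, 1))

  doubled <- make_em(cbind(a, 2 * a), "counts")
  expect_equal(unname(estimate_size_factors(doubled)),
               c(1 / sqrt(2), sqrt(2)))

  set.seed(13)
  cm <- make_em(matrix(rpois(200, 30) + 1, 50), "counts")
  sf <- estimate_size_factors(cm)
  # brute-force oracle
  geo <- exp(rowMeans(log(unclass(cm))))
  brute <- apply(unclass(cm) / geo, 2, median)
  brute <- brute / exp(mean(log(brute)))
  expect_equal(unname(sf), unname(brute))
  expect_equal(exp(mean(log(sf))), 1)

  # gene-order invariance, and proportional response to sample scaling
  perm <- make_em(unclass(cm)[sample(nrow(cm)), ], "counts",
                  genes = NULL, samples = colnames(cm))
  expect_equal(unname(estimate_size_factors(perm)), unname(sf))

  zero_row <- make_em(rbind(c(0, 1, 2, 3)), "counts")
  expect_error(estimate_size_factors(zero_row), "size factors undefined")
})

test_that("NB exact test: modal symmetric split gives p exactly 1", {
  cm <- make_em(matrix(c(5L, 5L, 5L, 5L), 1), "counts")
  sf <- setNames(rep(1, 4), colnames(cm))
  res <- nb_test(cm, colnames(cm)[1:2], colnames(cm)[3:4],
                 size_factors = sf, dispersion = 0.1)
  expect_identical(res$pvalue, 1)
})

test_that("NB exact test finds a strong shift with the right direction", {
  cm <- make_em(matrix(c(1000L, 1000L, 10L, 10L), 1), "counts")
  sf <- setNames(rep(1, 4), colnames(cm))
  res <- nb_test(cm, colnames(cm)[1:2], colnames(cm)[3:4],
                 size_factors = sf, dispersion = 0.1)
  expect_lt(res$pvalue, 1e-6)
  expect_identical(res$direction, "down")
})

test_that("NB test p-values are symmetric in group labels and monotone in effect", {
  set.seed(14)
  cm <- make_em(matrix(rnbinom(40, mu = 50, size = 10), 10), "counts")
  sf <- setNames(rep(1, 4), colnames(cm))
  ab <- nb_test(cm, colnames(cm)[1:2], colnames(cm)[3:4],
                size_factors = sf, dispersion = 0.1)
  ba <- nb_test(cm, colnames(cm)[3:4], colnames(cm)[1:2],
                size_factors = sf, dispersion = 0.1)
  expect_equal(ab$pvalue, ba$pvalue)

  base <- c(60L, 40L)
  p_grid <- vapply(c(1, 2, 4, 8), function(cc) {
    m <- make_em(matrix(c(base, as.integer(round(base * cc))), 1), "counts")
    nb_test(m, colnames(m)[1:2], colnames(m)[3:4],
            size_factors = setNames(rep(1, 4), colnames(m)),
            dispersion = 0.1)$pvalue
  }, numeric(1))
  expect_true(all(diff(p_grid) <= 1e-12))
  expect_error(nb_test(cm, colnames(cm)[1:2], colnames(cm)[2:3]), "overlap")
})

test_that("consecutive-stage DE flags a planted activation and controls the null", {
  # null: stage 2 duplicates stage 1 exactly
  set.seed(15)
  base <- matrix(rnbinom(2000 * 2, mu = 80, size = 10), 2000)
  cm <- make_em(cbind(base, base), "counts")
  d <- design4()
  de <- consecutive_stage_de(cm, d)
  expect_length(de, 1L)
  rate <- length(de[[1]]$de_genes) / nrow(de[[1]]$result)
  expect_lt(rate, 0.02)   # duplicated samples shrink dispersion-null signal

  # power: 100-gene activation, 4 stages
  set.seed(16)
  n <- 600
  mu <- matrix(60, n, 8)
  mu[1:100, 7:8] <- 60 * 2^4          # activation at stage 4 of 4
  cnt <- matrix(rnbinom(n * 8, mu = mu, size = 100), n)
  cm2 <- make_em(cnt, "counts")
  d2 <- stage_design(colnames(cm2), rep(paste0("st", 1:4), each = 2))
  de2 <- consecutive_stage_de(cm2, d2)
  tr <- de2[["st3->st4"]]
  up <- tr$result$gene[tr$result$pvalue < 0.05 & tr$result$direction == "up"]
  expect_gte(sum(sprintf("g%03d", 1:100) %in% up), 90)

  d1 <- stage_design(colnames(cm2), rep("one", 8), "one")
  expect_error(consecutive_stage_de(cm2, d1), ">= 2 stages")
})

test_that("ddCt relative expression reproduces its closed forms", {
  ct <- ct_table(data.frame(
    gene = c("tg", "ref", "tg", "ref", "tg", "ref"),
    sample = rep(c("cal", "s_eq", "s_down"), each = 2),
    ct = c(20, 18, 21, 19, 22, 19)), "ref", "cal")
  expect_equal(relative_expression_ddct(ct, "tg", "s_eq"), 1)      # ddCt 0
  expect_equal(relative_expression_ddct(ct, "tg", "s_down"), 0.5)  # ddCt 1
  ct2 <- ct_table(data.frame(
    gene = c("tg", "ref", "tg", "ref"),
    sample = rep(c("cal", "s_up"), each = 2),
    ct = c(20, 18, 20 - 3.321928, 18)), "ref", "cal")
  expect_equal(relative_expression_ddct(ct2, "tg", "s_up"), 10,
               tolerance = 1e-6)
  expect_error(relative_expression_ddct(ct, "nope", "s_eq"), "missing Ct")
  expect_error(ct_table(data.frame(gene = "tg", sample = "s1", ct = 20),
                        "ref", "s1"), "reference gene")
})
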
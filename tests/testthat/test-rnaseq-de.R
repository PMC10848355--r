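test_that("size factors are median-of-ratios", {
  m <- matrix(rpois(60, 50) + 1, 10, 6,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:6)))
  # sample 2 = exact doubling of sample 1
  m[, 2] <- 2L * m[, 1]
  sf <- size_factors(m)
  expect_equal(unname(sf[2] / sf[1]), 2)
  # identical samples -> all factors 1
  eqm <- matrix(rep(m[, 1], 4), 10, 4,
                dimnames = list(rownames(m), paste0("t", 1:4)))
  expect_equal(unname(size_factors(eqm)), rep(1, 4))
  # random matrix vs explicit-loop oracle
  set.seed(3)
  r <- matrix(rnbinom(200, mu = 80, size = 5) + 1L, 20, 10,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:10)))
  expect_equal(size_factors(r), size_factors_loop(r))
  r[, 3] <- 0L
  expect_error(size_factors(r), "all-zero sample")
})

test_that("BH adjustment equals the brute-force definition on small sets", {
  set.seed(4)
  for (rep in 1:20) {
    p <- runif(sample(2:8, 1))
    expect_equal(boomics:::bh_adjust(p), bh_brute(p))
  }
})

test_that("DE tests control type-I error on null data", {
  sim <- gen_counts(2000, c(A = 5, B = 5), frac_de = 0, dispersion_shape = Inf,
                    seed = 21)
  for (m in c("nb_exact", "nb_wald")) {
    de <- de_test(sim$counts, c("B", "A"), m)
    expect_lt(sum(de$p_adj < 0.1), 5)                 # essentially no DEGs
    expect_lt(abs(mean(de$p < 0.05) - 0.05), 0.02)    # raw p calibrated
    expect_true(all(de$p_adj >= de$p - 1e-12))
    expect_true(all((de$direction == "ns") == (de$p_adj >= 0.1)))
  }
})

test_that("identical counts in both groups give log2fc = 0", {
  m <- matrix(rep(c(5L, 9L, 13L, 0L), each = 6), 4, 6, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  cm <- count_matrix(m, setNames(rep(c("A", "B"), each = 3), colnames(m)))
  for (meth in c("nb_exact", "nb_wald")) {
    de <- de_test(cm, c("B", "A"), meth)
    expect_equal(de$log2fc, rep(0, 4))
    expect_equal(de$p[de$feature == "g4"], 1)  # all-zero feature
  }
})

test_that("planted effects are detected with high power", {
  sim <- gen_counts(2000, c(A = 5, B = 5), frac_de = 0.1, lfc_scale = 2,
                    dispersion_mean = 0.05, dispersion_shape = Inf, seed = 3)
  truth <- sim$truth$de_features[["B"]]
  for (m in c("nb_exact", "nb_wald")) {
    de <- de_test(sim$counts, c("B", "A"), m)
    sig <- de$feature[de$p_adj < 0.1]
    expect_gte(mean(truth %in% sig), 0.8)
    # empirical FDR within BH expectation plus Monte-Carlo slack
    expect_lte(mean(!(sig %in% truth)), 0.15)
  }
})

test_that("consensus is the sign-concordant intersection", {
  feats <- sprintf("g%02d", 1:30)
  set.seed(9)
  for (rep in 1:10) {
    lfcA <- setNames(rnorm(30), feats)
    lfcB <- setNames(lfcA + rnorm(30, 0, 0.8), feats)
    sigA <- sample(feats, 10)
    sigB <- sample(feats, 10)
    resA <- make_de(feats, sigA, lfcA)
    resB <- make_de(feats, sigB, lfcB)
    cons <- consensus(resA, resB, 0.1)
    # brute-force loop oracle
    up <- character(0); down <- character(0)
    for (f in feats) {
      if (f %in% sigA && f %in% sigB) {
        if (lfcA[f] > 0 && lfcB[f] > 0) up <- c(up, f)
        if (lfcA[f] < 0 && lfcB[f] < 0) down <- c(down, f)
      }
    }
    expect_setequal(cons$up, up)
    expect_setequal(cons$down, down)
    # symmetry
    swapped <- consensus(resB, resA, 0.1)
    expect_equal(cons$up, swapped$up)
    expect_equal(cons$down, swapped$down)
  }
  # idempotence and disjoint cases
  lfc <- setNames(rep(1, 30), feats)
  resA <- make_de(feats, feats[1:5], lfc)
  self <- consensus(resA, resA, 0.1)
  expect_setequal(c(self$up, self$down), feats[1:5])
  resC <- make_de(feats, feats[6:10], lfc)
  expect_length(c(consensus(resA, resC)$up, consensus(resA, resC)$down), 0)
  expect_error(consensus(resA, make_de(feats[1:10], feats[1:2], lfc)),
               "universes")
})

test_that("bookkeeping partitions before/after sets correctly", {
  bk <- bookkeeping(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(bk$normalized, "a")
  expect_equal(bk$persistent, c("b", "c"))
  expect_equal(bk$de_novo, "d")
  same <- bookkeeping(c("x", "y"), c("x", "y"))
  expect_length(same$normalized, 0)
  expect_length(same$de_novo, 0)
  disj <- bookkeeping(c("x"), c("y"))
  expect_length(disj$persistent, 0)
  # identities hold for random sets
  set.seed(2)
  pool <- sprintf("g%03d", 1:100)
  for (rep in 1:10) {
    b <- sample(pool, sample(0:50, 1))
    a <- sample(pool, sample(0:50, 1))
    g <- glance(bookkeeping(b, a))
    expect_equal(g$n_before, g$normalized + g$persistent)
    expect_equal(g$n_after, g$persistent + g$de_novo)
  }
})

test_that("direction counts summarize DE tables", {
  tbl <- tibble::tibble(direction = c("up", "up", "down", "ns"))
  cnt <- count_de_directions(tbl)
  expect_equal(cnt$up, 2)
  expect_equal(cnt$down, 1)
  expect_equal(cnt$total, 3)
})

test_that("size factors agree with the established implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(8)
  m <- matrix(rnbinom(500, mu = 100, size = 8) + 1L, 50, 10,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:10)))
  ours <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})
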
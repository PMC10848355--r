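test_that("trajectory categories match the hand truth table", {
  # all 16 before/after patterns over two groups, expectations enumerated by
  # hand from the category definitions
  cases <- list(
    list(b = c(F, F), a = c(F, F), want = "unchanged"),
    list(b = c(T, F), a = c(F, F), want = "normalized_after"),
    list(b = c(F, T), a = c(F, F), want = "normalized_after"),
    list(b = c(T, T), a = c(F, F), want = "normalized_after"),
    list(b = c(F, F), a = c(T, F), want = "de_novo"),
    list(b = c(F, F), a = c(F, T), want = "de_novo"),
    list(b = c(F, F), a = c(T, T), want = "de_novo"),
    list(b = c(T, F), a = c(T, F), want = "persistent"),
    list(b = c(T, F), a = c(F, T), want = "normalized_after"),
    list(b = c(T, F), a = c(T, T), want = "persistent"),
    list(b = c(F, T), a = c(T, F), want = "normalized_after"),
    list(b = c(F, T), a = c(F, T), want = "persistent"),
    list(b = c(F, T), a = c(T, T), want = "persistent"),
    list(b = c(T, T), a = c(T, F), want = "persistent"),
    list(b = c(T, T), a = c(F, T), want = "persistent"),
    list(b = c(T, T), a = c(T, T), want = "persistent")
  )
  for (cs in cases) {
    expect_equal(tf_category(cs$b, cs$a), cs$want)
  }
})

test_that("regulated_tfs assigns categories from per-group DE patterns", {
  feats <- c("tf1", "tf2", "tf3", "tf4", sprintf("g%02d", 1:10))
  db <- tf_regulon_db(tibble::tibble(
    tf = rep(c("tf1", "tf2", "tf3", "tf4"), each = 3),
    target = sprintf("g%02d", c(1:3, 4:6, 7:9, c(1, 5, 10))),
    source = "TRRUST"
  ))
  lfc <- setNames(rep(1, length(feats)), feats)
  de <- list(
    HP_before = make_de(feats, c("tf1", "tf2"), lfc),
    HP_after = make_de(feats, c("tf1"), lfc),
    MP_before = make_de(feats, c("tf2"), lfc),
    MP_after = make_de(feats, c("tf3"), lfc)
  )
  pats <- regulated_tfs(de, db)
  expect_setequal(pats$tf, c("tf1", "tf2", "tf3"))
  expect_equal(pats$category[pats$tf == "tf1"], "persistent")
  expect_equal(pats$category[pats$tf == "tf2"], "normalized_after")
  expect_equal(pats$category[pats$tf == "tf3"], "de_novo")
  # SOX21-like pattern: up before in both groups, normalized after
  de2 <- list(HP_before = make_de(feats, "tf4", lfc),
              HP_after = make_de(feats, character(0), lfc),
              MP_before = make_de(feats, "tf4", lfc),
              MP_after = make_de(feats, character(0), lfc))
  pats2 <- regulated_tfs(de2, db)
  expect_equal(pats2$category[pats2$tf == "tf4"], "normalized_after")
  # require = "all" empties the list when a TF misses one contrast
  expect_equal(nrow(regulated_tfs(de, db, require = "all")), 0)
  expect_error(regulated_tfs(de, db[0, ]), "empty")
})

test_that("target_matrix joins regulon targets with per-contrast log2FC", {
  feats <- sprintf("g%02d", 1:10)
  db <- tf_regulon_db(tibble::tibble(tf = "tfX",
                                     target = c("g01", "g02", "g03", "zz99"),
                                     source = "TRED"))
  tabs <- list(
    HP_before = make_de(feats, character(0), setNames(1:10, feats)),
    HP_after = make_de(feats, character(0), setNames(11:20, feats))
  )
  m <- suppressMessages(target_matrix("tfX", db, tabs))
  expect_equal(rownames(m), c("g01", "g02", "g03"))
  expect_equal(unname(m[, "HP_before"]), c(1, 2, 3))
  expect_equal(unname(m[, "HP_after"]), c(11, 12, 13))
  expect_error(target_matrix("nope", db, tabs), "not in database")
  dbe <- tf_regulon_db(tibble::tibble(tf = "tfY", target = "zz", source = "TRED"))
  expect_warning(suppressMessages(target_matrix("tfY", dbe, tabs)), "no measured")
})

test_that("Pearson-distance clustering recovers planted profiles", {
  contrasts <- c("HP_before", "HP_after", "MP_before", "MP_after")
  base <- rbind(c(3, 1, -1, -3),      # monotone decreasing
                c(1, -1, 1, -1),      # alternating
                c(-3, -1, 1, 3))      # monotone increasing
  set.seed(31)
  m <- base[rep(1:3, each = 4), ] + matrix(rnorm(48, 0, 0.05), 12)
  dimnames(m) <- list(sprintf("t%02d", 1:12), contrasts)
  cl <- cluster_targets(m, 3)
  mem <- tidy(cl)
  got <- mem$cluster[match(rownames(m), mem$target)]
  expect_equal(length(unique(got[1:4])), 1)
  expect_equal(length(unique(got[5:8])), 1)
  expect_equal(length(unique(got[9:12])), 1)
  expect_length(unique(got), 3)
  # invariance to row scaling and shifting (Pearson invariance)
  m2 <- m * 3 + 7
  cl2 <- cluster_targets(m2, 3)
  expect_equal(tidy(cl2)$cluster, mem$cluster)
  # k = 1 puts everything together
  expect_equal(unique(tidy(cluster_targets(m, 1))$cluster), 1L)
  # flat rows go to the reserve bucket
  mflat <- rbind(m, flat1 = rep(2, 4))
  clf <- cluster_targets(mflat, 3)
  expect_equal(tidy(clf)$cluster[tidy(clf)$target == "flat1"], 0L)
  expect_error(cluster_targets(m, 0), "k")
})

test_that("cluster trajectory report averages and flags down-after", {
  contrasts <- c("HP_before", "HP_after", "MP_before", "MP_after")
  m <- rbind(a1 = c(2, 0, 2, 0), a2 = c(2.2, 0.2, 1.8, -0.2),
             b1 = c(0, 2, 0, 2), b2 = c(-0.2, 1.8, 0.2, 2.2),
             c1 = c(1, 0.5, -1, 2), c2 = c(1.1, 0.4, -0.9, 2.1))
  colnames(m) <- contrasts
  cl <- cluster_targets(m, 3)
  rep_tbl <- cluster_trajectory_report(cl, m)
  mem <- tidy(cl)
  for (i in seq_len(nrow(rep_tbl))) {
    rows <- mem$target[mem$cluster == rep_tbl$cluster[i]]
    expect_equal(rep_tbl$mean_HP_before[i], mean(m[rows, "HP_before"]))
    expect_equal(rep_tbl$down_after[i],
                 mean(m[rows, "HP_after"]) < mean(m[rows, "HP_before"]) &&
                   mean(m[rows, "MP_after"]) < mean(m[rows, "MP_before"]))
  }
  cl_a <- rep_tbl$cluster[sapply(rep_tbl$cluster, function(k)
    "a1" %in% mem$target[mem$cluster == k])]
  expect_true(rep_tbl$down_after[rep_tbl$cluster == cl_a])
})

test_that("overlap utility computes Fisher enrichment", {
  uni <- sprintf("g%02d", 1:40)
  res <- overlap_fisher(uni[1:10], uni[1:10], uni)
  expect_equal(res$overlap, 10)
  expect_lt(res$p, 1e-6)
  null_res <- overlap_fisher(uni[1:10], uni[31:40], uni)
  expect_equal(null_res$overlap, 0)
  expect_equal(null_res$p, 1)
})
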
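test_that("hypergeometric ORA matches exhaustive enumeration", {
  # hand case N = 20, K = 5, n = 5, k = 4
  p_hand <- hyper_enum(4, 5, 5, 20)
  terms <- c("root", "t1")
  parents <- list(root = character(0), t1 = "root")
  universe <- sprintf("g%02d", 1:20)
  direct <- list(root = setdiff(universe, universe[1:5]), t1 = universe[1:5])
  dag <- ontology_dag(terms, parents, direct)
  query <- c(universe[1:4], universe[10])
  res <- ora(query, universe, dag, p_max = 1)
  expect_equal(res$p[res$term == "t1"], p_hand, tolerance = 1e-12)
  expect_equal(res$k[res$term == "t1"], 4)
  # more enumeration cases over a toy DAG
  dag2 <- toy_dag()
  uni2 <- dag2$annotations[["root"]]
  q2 <- dag2$annotations[["leaf"]]
  res2 <- ora(q2, uni2, dag2, p_max = 1)
  for (i in seq_len(nrow(res2))) {
    expect_equal(res2$p[i],
                 hyper_enum(res2$k[i], res2$K[i], res2$n[i], res2$N[i]),
                 tolerance = 1e-12)
  }
  # query exactly a term's genes -> that term is top-ranked
  expect_equal(res2$term[1], "leaf")
  expect_error(ora(c("zz"), uni2, dag2), "outside the universe")
  expect_equal(nrow(suppressMessages(ora(character(0), uni2, dag2))), 0)
})

test_that("information content is zero at the root and grows downward", {
  dag <- toy_dag()
  ic <- information_content(dag)
  expect_equal(unname(ic["root"]), 0)
  for (t in dag$terms) {
    for (p in dag$parents[[t]]) expect_gte(ic[t], ic[p])
  }
  # term holding half of an 8-gene corpus has ic log 2
  expect_equal(unname(ic["a"]), -log(6 / 8))  # a covers g1, g3, g4, g5-7
})

test_that("Resnik similarity equals the brute-force ancestor scan", {
  dag <- toy_dag()
  expect_equal(resnik(dag, "b", "leaf"), 0)  # only common ancestor is root
  mx <- max(dag$ic, na.rm = TRUE)
  expect_equal(resnik(dag, "leaf", "leaf"), unname(dag$ic["leaf"]) / mx)
  for (t1 in dag$terms) for (t2 in dag$terms) {
    expect_equal(resnik(dag, t1, t2), resnik_brute(dag, t1, t2))
    expect_equal(resnik(dag, t1, t2), resnik(dag, t2, t1))
    expect_gte(resnik(dag, t1, t2), 0)
    expect_lte(resnik(dag, t1, t2), 1)
  }
  # random generated DAG against the same oracle
  rdag <- gen_ontology(15, n_genes = 60, seed = 21)
  ts <- rdag$terms[!is.na(rdag$ic)]
  for (i in seq_len(10)) {
    pair <- sample(ts, 2)
    expect_equal(resnik(rdag, pair[1], pair[2]),
                 resnik_brute(rdag, pair[1], pair[2]))
  }
  m <- resnik_matrix(dag)
  expect_true(isSymmetric(m))
})

test_that("greedy pruning keeps the most significant of each redundant pair", {
  terms <- tibble::tibble(term = c("t1", "t2", "t3", "t4", "t5"),
                          p = c(0.001, 0.002, 0.01, 0.02, 0.05))
  sim <- diag(5); dimnames(sim) <- list(terms$term, terms$term)
  sim["t1", "t2"] <- sim["t2", "t1"] <- 0.95  # t2 redundant with t1
  sim["t3", "t4"] <- sim["t4", "t3"] <- 0.75  # t4 redundant with t3
  sim["t1", "t5"] <- sim["t5", "t1"] <- 0.69  # just under threshold
  # hand trace of the greedy pass: keep t1, drop t2, keep t3, drop t4, keep t5
  expect_equal(prune_redundant(terms, sim, 0.7), c("t1", "t3", "t5"))
  # identical duplicates leave one survivor
  dup <- tibble::tibble(term = c("a", "b"), p = c(0.01, 0.01))
  sdup <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(prune_redundant(dup, sdup, 0.7), "a")
  # all dissimilar -> all retained
  eye <- diag(5)
  dimnames(eye) <- dimnames(sim)
  expect_setequal(prune_redundant(terms, eye, 0.7), terms$term)
  # input order does not matter
  expect_equal(sort(prune_redundant(terms[5:1, ], sim, 0.7)),
               sort(prune_redundant(terms, sim, 0.7)))
})

test_that("binary cut recovers block structure", {
  mk <- function(truth, noise, seed) {
    set.seed(seed)
    n <- length(truth)
    s <- outer(truth, truth, function(a, b) as.numeric(a == b))
    e <- matrix(rnorm(n * n, 0, noise), n)
    s <- pmin(pmax(s + (e + t(e)) / 2, 0), 1)
    diag(s) <- 1
    dimnames(s) <- list(sprintf("t%02d", 1:n), sprintf("t%02d", 1:n))
    s
  }
  # two perfect blocks
  s2 <- mk(rep(1:2, each = 4), 0, 1)
  cl2 <- binary_cut(s2)
  expect_length(cl2$clusters, 2)
  expect_setequal(cl2$clusters[[1]], sprintf("t%02d", 1:4))
  # all-identical similarity collapses to one cluster
  s1 <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  expect_length(binary_cut(s1)$clusters, 1)
  # single term is a singleton cluster
  sone <- matrix(1, 1, 1, dimnames = list("t", "t"))
  expect_length(binary_cut(sone)$clusters, 1)
  # noisy planted 3-block matrix: adjusted Rand >= 0.9
  skip_if_not_installed("mclust")
  truth <- rep(1:3, c(3, 3, 2))
  s3 <- mk(truth, 0.05, 2)
  cl3 <- binary_cut(s3)
  mem <- tidy(cl3)
  got <- mem$cluster[match(rownames(s3), mem$term)]
  expect_gte(mclust::adjustedRandIndex(got, truth), 0.9)
  # partition property and permutation invariance
  expect_setequal(unlist(cl3$clusters), rownames(s3))
  perm <- sample(nrow(s3))
  clp <- binary_cut(s3[perm, perm])
  relabel <- function(cl) unname(split(cl$membership$term, cl$membership$cluster))
  expect_setequal(lapply(relabel(cl3), sort) |> sapply(paste, collapse = ","),
                  lapply(relabel(clp), sort) |> sapply(paste, collapse = ","))
})

test_that("display tables count genes, areas and ridge means", {
  dag <- toy_dag()
  uni <- dag$annotations[["root"]]
  res <- ora(dag$annotations[["a"]], uni, dag, p_max = 1)
  lfc <- setNames(seq(-1, 1, length.out = length(uni)), uni)
  sim <- resnik_matrix(dag, res$term)
  cl <- binary_cut(sim, p = setNames(res$p, res$term))
  tabs <- display_tables(res, cl, lfc = lfc)
  # a gene annotated to m enriched terms has frequency m
  for (i in seq_len(nrow(tabs$words))) {
    g <- tabs$words$gene[i]
    expect_equal(tabs$words$frequency[i],
                 sum(vapply(res$genes, function(gs) g %in% gs, logical(1))))
  }
  # cluster area equals member count
  area <- table(tabs$treemap$cluster)
  for (cl_id in names(area)) {
    expect_equal(unique(tabs$treemap$cluster_area[tabs$treemap$cluster == as.integer(cl_id)]),
                 as.integer(area[[cl_id]]))
  }
  # ridge mean is the arithmetic mean of member log2fc
  rid <- tabs$ridge
  for (t in unique(rid$term)) {
    expect_equal(unique(rid$mean_log2fc[rid$term == t]),
                 mean(rid$log2fc[rid$term == t]))
  }
})
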
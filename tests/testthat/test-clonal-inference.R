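test_that("binarize and truncal_set operate at the deep-seq cutoff", {
  af <- index_af_truth()
  pres <- binarize(af)
  expect_true(pres["DDR2", "A"])          # 36.4% present
  expect_false(pres["MLL3", "C"])
  expect_false(binarize(matrix(0.005, 1, 1,
                               dimnames = list("v", "l")))[1, 1])
  expect_equal(sum(binarize(matrix(0.4, 3, 2,
                                   dimnames = list(1:3, 1:2)),
                            threshold = 0.5)), 0)
  # variants present in every lesion; the five same-AF truncal genes are
  # a subset (DDR2 is also carried by every lesion, at varying AF)
  tr <- truncal_set(pres)
  expect_true(all(c("PCDH20", "OR4X1", "ALK", "DNPEP", "SH3TC2") %in% tr))
  expect_setequal(tr, c("PCDH20", "OR4X1", "ALK", "DNPEP", "SH3TC2", "DDR2"))
  pres2 <- pres; pres2["ALK", "C"] <- FALSE
  expect_false("ALK" %in% truncal_set(pres2))
  # single lesion: every present variant is truncal
  expect_equal(sort(truncal_set(pres[, "LN15", drop = FALSE])),
               sort(rownames(pres)))
  expect_error(binarize(af, threshold = 1.5), "threshold")
})

test_that("order_lesions recovers the index-patient clone tree", {
  tree <- order_lesions(index_af_truth())
  expect_s3_class(tree, "clone_tree")
  expect_equal(length(tree$nodes), 3)
  expect_true(all(c("C+D", "A", "LN15+LN17+LNA") %in% names(tree$nodes)))
  e <- tree$edges
  parents <- vapply(e, `[[`, "", "parent")
  children <- vapply(e, `[[`, "", "child")
  expect_equal(sort(paste(parents, "->", children)),
               sort(c("C+D -> A", "A -> LN15+LN17+LNA")))
  root_edge <- e[[which(parents == "C+D")]]
  expect_equal(root_edge$gained, "MLL3")
  expect_true("DDR2" %in% root_edge$increased)   # 36.4 vs 15.95 mean
  ln_edge <- e[[which(children == "LN15+LN17+LNA")]]
  expect_equal(ln_edge$gained, "PIK3CA")
  expect_true("MLL3" %in% ln_edge$increased)
})

test_that("increase_ratio is monotone and containment always holds", {
  af <- index_af_truth()
  n_arrows <- vapply(c(1.1, 1.5, 2, 3), function(r) {
    tr <- order_lesions(af, increase_ratio = r)
    sum(vapply(tr$edges, function(e) length(e$increased), 0L))
  }, 0L)
  expect_true(all(diff(n_arrows) <= 0))

  # random matrices: every edge's child set strictly contains the parent's;
  # tree is acyclic
  for (s in 1:20) {
    m <- withr::with_seed(s, matrix(stats::runif(5 * 4) *
                                      (stats::runif(5 * 4) > 0.4), 5, 4,
                                    dimnames = list(paste0("v", 1:5),
                                                    paste0("L", 1:4))))
    tr <- order_lesions(m)
    vs <- lapply(tr$nodes, `[[`, "variants")
    for (e in tr$edges) {
      expect_true(all(vs[[e$parent]] %in% vs[[e$child]]))
      expect_gt(length(vs[[e$child]]), length(vs[[e$parent]]))
    }
    # acyclicity via topological elimination
    ids <- names(tr$nodes)
    edges <- lapply(tr$edges, function(e) c(e$parent, e$child))
    while (length(ids) > 0) {
      has_in <- vapply(ids, function(i)
        any(vapply(edges, function(e) e[2] == i && e[1] %in% ids,
                   logical(1))), logical(1))
      expect_true(any(!has_in))   # a cycle would leave no source node
      ids <- ids[has_in]
    }
  }

  # degenerate: identical lesions collapse to one node, no edges
  same <- matrix(0.3, 3, 4, dimnames = list(paste0("v", 1:3),
                                            paste0("L", 1:4)))
  tr1 <- order_lesions(same)
  expect_equal(length(tr1$nodes), 1)
  expect_equal(length(tr1$edges), 0)
})

test_that("assign_sample places vectors at the deepest compatible node", {
  tree <- order_lesions(index_af_truth())
  genes <- rownames(index_af_truth())
  all8 <- stats::setNames(rep(0.4, 8), genes)
  expect_equal(assign_sample(all8, tree), "LN15+LN17+LNA")
  truncal_only <- stats::setNames(c(rep(0.3, 5), 0.3, 0, 0), genes)
  expect_equal(assign_sample(truncal_only, tree), "C+D")
  none <- stats::setNames(rep(0, 8), genes)
  expect_true(is.na(assign_sample(none, tree)))
  expect_error(assign_sample(all8[1:3], tree), "lacks")
})

test_that("planted tree topology is recovered from noisy deep-seq AFs", {
  # 100 seeds at depth 10,000: binomial resampling of the planted AF
  # matrix must reproduce the planted topology in >= 95 runs
  truth <- index_af_truth()
  target <- sort(c("C+D -> A", "A -> LN15+LN17+LNA"))
  ok <- vapply(1:100, function(s) {
    noisy <- truth
    for (i in seq_len(nrow(truth))) for (j in seq_len(ncol(truth))) {
      cnt <- simulate_deep_seq_counts(truth[i, j], 10000,
                                      seed = s * 1000 + i * 10 + j)
      noisy[i, j] <- cnt$mutant / cnt$total
    }
    tr <- order_lesions(noisy)
    edges <- sort(vapply(tr$edges, function(e)
      paste(e$parent, "->", e$child), ""))
    identical(edges, target)
  }, logical(1))
  expect_gte(sum(ok), 95)
})

test_that("clone-tree serializations are well formed", {
  tree <- order_lesions(index_af_truth())
  js <- jsonlite::fromJSON(clone_tree_json(tree), simplifyVector = FALSE)
  expect_length(js$nodes, 3)
  expect_length(js$edges, 2)
  dot <- clone_tree_dot(tree)
  expect_match(dot, "digraph")
  expect_match(dot, "\"C\\+D\" -> \"A\"")
})
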
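test_that("Gini impurity follows the weighted definition", {
  expect_equal(gini(c(1, 1, 1)), 0)
  expect_equal(gini(c(0, 0)), 0)
  expect_equal(gini(c(1, 0)), 0.5)
  expect_equal(gini(c(1, 1, 0, 0, 0, 0)), 4 / 9)
  expect_equal(gini(c(1, 0), weights = c(3, 1)), 1 - (3 / 4)^2 - (1 / 4)^2)
  expect_error(gini(numeric(0)), "empty")
})

test_that("best split maximizes impurity decrease with deterministic ties", {
  X <- matrix(c(0, 0, 2, 2), ncol = 1, dimnames = list(NULL, "c0"))
  sp <- best_split(X, c(0, 0, 1, 1))
  expect_equal(sp$threshold, 1)
  expect_equal(sp$decrease, 0.5)

  Xconst <- matrix(1, nrow = 4, ncol = 2, dimnames = list(NULL, c("c0", "c1")))
  expect_null(best_split(Xconst, c(0, 1, 0, 1)))

  # two perfect separators -> smallest feature id wins
  X2 <- matrix(c(0, 0, 1, 1, 0, 0, 1, 1), ncol = 2,
               dimnames = list(NULL, c("c0", "c1")))
  expect_equal(best_split(X2, c(0, 0, 1, 1))$feature, "c0")
})

test_that("the impurity-split threshold gates division strictly", {
  # balanced-weighted impurity 0.02 <= 0.03 -> single leaf even though a
  # split exists
  X <- matrix(c(0, 1), ncol = 1, dimnames = list(NULL, "c0"))
  t_low <- train_tree(X, c(0, 1), min_impurity_split = 0.5)
  expect_equal(t_low$type, "leaf")
  # root impurity 0.5 > 0.03 -> splits into pure leaves
  t_split <- train_tree(X, c(0, 1), min_impurity_split = 0.03)
  expect_equal(t_split$type, "split")
  expect_equal(t_split$left$impurity, 0)
  expect_equal(t_split$right$impurity, 0)

  # an unbalanced node whose weighted impurity is at most 0.03 stays a leaf:
  # 99 negatives + 1 positive unweighted -> gini = 2*0.01*0.99 = 0.0198
  X3 <- matrix(c(rep(0, 99), 5), ncol = 1, dimnames = list(NULL, "c0"))
  y3 <- c(rep(0, 99), 1)
  t3 <- train_tree(X3, y3, balanced = FALSE)
  expect_equal(t3$type, "leaf")
  expect_lt(t3$impurity, 0.03)
  # with class balancing the same node has impurity 0.5 and splits
  t3b <- train_tree(X3, y3, balanced = TRUE)
  expect_equal(t3b$type, "split")
})

test_that("a perfect single-feature separator trains to accuracy 1", {
  withr::with_seed(101, {
    X <- matrix(c(rpois(20, 0.3), rpois(20, 0.3) + 2), ncol = 1,
                dimnames = list(NULL, "c0"))
    X <- cbind(X, c9 = rpois(40, 1))
    y <- rep(c(0, 1), each = 20)
    X[1:20, 1] <- 0
    X[21:40, 1] <- 2
    tree <- train_tree(X, y)
    pred <- vapply(seq_len(nrow(X)), function(i) {
      leaf <- tree
      while (leaf$type == "split") {
        leaf <- if (X[i, leaf$feature] <= leaf$threshold) leaf$left else leaf$right
      }
      as.integer(leaf$positive_fraction > 0.5)
    }, 1L)
    expect_equal(pred, y)
    expect_equal(tree$feature, "c0")
  })
})

test_that("XOR-structured labels are solved at depth 2 with pure leaves", {
  X <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), ncol = 2,
              dimnames = list(NULL, c("c0", "c1")))
  y <- c(0, 1, 1, 0)
  tree <- train_tree(X, y)
  expect_equal(tree$type, "split")
  for (child in list(tree$left, tree$right)) {
    expect_equal(child$type, "split")
    expect_equal(child$left$impurity, 0)
    expect_equal(child$right$impurity, 0)
  }
})

test_that("per-genus training handles absent genera and is deterministic", {
  m <- matrix(c(1L, 0L, 0L, 1L), 2, dimnames = list(c("p1", "p2"), c("c0", "c1")))
  labels <- tibble::tibble(phage_id = c("p1", "p2"),
                           genus = c("Cronobacter", "Cronobacter"))
  expect_warning(
    suite <- train_suite(m, labels, genera = c("Cronobacter", "Yersinia")),
    "Yersinia"
  )
  expect_equal(suite$trees$Yersinia$type, "leaf")
  expect_equal(suite$trees$Yersinia$positive_fraction, 0)

  fit <- small_fit()
  again <- train_suite(fit$feature_matrix,
                       small_corpus()$labels[small_corpus()$labels$phage_id %in%
                                               fit$split$train_ids, ],
                       genera = fit$genera)
  expect_equal(again$trees, fit$suite$trees)
})

test_that("prediction returns every positive genus and validates dimensions", {
  leaf_pos <- list(type = "leaf", positive_fraction = 1, n_samples = 5,
                   impurity = 0)
  leaf_neg <- list(type = "leaf", positive_fraction = 0, n_samples = 5,
                   impurity = 0)
  split_on <- function(feat) list(type = "split", feature = feat,
                                  threshold = 0.5, impurity = 0.5,
                                  n_samples = 10, left = leaf_neg,
                                  right = leaf_pos)
  suite <- structure(list(
    trees = list(Citrobacter = split_on("c0"), Cronobacter = split_on("c0"),
                 Yersinia = split_on("c1")),
    columns = c("c0", "c1"),
    genera = c("Citrobacter", "Cronobacter", "Yersinia"),
    config = list(min_impurity_split = 0.03, balanced = TRUE)),
    class = "host_tree_suite")
  v <- c(c0 = 1L, c1 = 0L)
  pred <- predict_hosts(v, suite)
  expect_setequal(pred$genus, c("Citrobacter", "Cronobacter"))
  empty <- predict_hosts(c(c0 = 0L, c1 = 0L), suite)
  expect_equal(nrow(empty), 0)
  one <- predict_hosts(c(c0 = 0L, c1 = 7L), suite)
  expect_equal(one$genus, "Yersinia")
  expect_error(predict_hosts(c(c0 = 1L), suite), "columns do not match")
})

test_that("only nodes above the impurity threshold were divided", {
  fit <- small_fit()
  nodes <- tidy(fit$suite)
  splits <- nodes[nodes$type == "split", ]
  expect_gt(nrow(splits), 0)
  expect_true(all(splits$impurity > fit$config$min_impurity_split))
})

test_that("training accuracy is at least the weighted majority-class rate", {
  fit <- small_fit()
  labels <- small_corpus()$labels
  m <- fit$feature_matrix
  for (g in fit$genera) {
    y <- as.integer(rownames(m) %in% labels$phage_id[labels$genus == g])
    pred <- vapply(seq_len(nrow(m)), function(i) {
      leaf <- fit$suite$trees[[g]]
      while (leaf$type == "split") {
        leaf <- if (m[i, leaf$feature] <= leaf$threshold) leaf$left else leaf$right
      }
      as.integer(leaf$positive_fraction > 0.5)
    }, 1L)
    acc <- mean(pred == y)
    expect_gte(acc, max(mean(y), 1 - mean(y)))
  }
})

test_that("tidy and glance summarize the suite", {
  fit <- small_fit()
  nodes <- tidy(fit$suite)
  expect_true(all(c("genus", "node_id", "type", "feature", "impurity") %in%
                    names(nodes)))
  expect_setequal(unique(nodes$genus), fit$genera)
  g <- glance(fit$suite)
  expect_equal(g$n_trees, length(fit$genera))
  expect_equal(g$min_impurity_split, 0.03)
})

test_that("DOT export is well-formed and carries annotations", {
  leaf <- list(type = "leaf", positive_fraction = 0.9, n_samples = 4,
               impurity = 0.18)
  dot1 <- export_tree_dot(leaf, genus = "Cronobacter")
  expect_match(dot1, "^digraph")
  expect_equal(length(gregexpr("n1 \\[", dot1)[[1]]), 1)

  tree <- list(type = "split", feature = "c5", threshold = 0.5,
               impurity = 0.5, n_samples = 8,
               left = list(type = "leaf", positive_fraction = 0,
                           n_samples = 4, impurity = 0),
               right = list(type = "leaf", positive_fraction = 1,
                            n_samples = 4, impurity = 0))
  db <- structure(list(clusters = tibble::tibble(
    cluster_id = 5L, representative_id = "x_1", representative_seq = "MK",
    n_members = 2L, n_phages = 2L, prevalence = 0.5,
    annotation = "tail fiber"), membership = tibble::tibble(),
    config = align_config()), class = "cluster_db")
  dot <- export_tree_dot(tree, cluster_db = db, genus = "Cronobacter")
  expect_equal(length(gregexpr("label=", dot)[[1]]), 5) # 3 nodes + 2 edges
  expect_match(dot, "cluster 5 <= 0.5")
  expect_match(dot, "tail fiber")
  expect_match(dot, "\"true\"")
  f <- withr::local_tempfile(fileext = ".dot")
  export_tree_dot(tree, genus = "g", path = f)
  expect_true(file.exists(f))
})
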
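#' Gini impurity of a binary label vector
#'
#' `1 - p0^2 - p1^2` with weighted class shares; ranges from 0 (pure) to 0.5
#' (balanced).
#'
#' @param labels Vector of 0/1 labels (non-empty).
#' @param weights Optional positive case weights (default: equal).
#' @return Impurity in [0, 0.5].
#' @export
gini <- function(labels, weights = NULL) {
  if (length(labels) == 0) abort("gini of an empty label vector is undefined")
  stopifnot(all(labels %in% c(0, 1)))
  if (is.null(weights)) weights <- rep(1, length(labels))
  stopifnot(length(weights) == length(labels), all(weights > 0))
  w <- sum(weights)
  p1 <- sum(weights[labels == 1]) / w
  1 - p1^2 - (1 - p1)^2
}

#' Exhaustive best split of a node
#'
#' Scans every feature and every threshold at the midpoint between
#' consecutive distinct sorted values, maximizing the weighted Gini impurity
#' decrease. Ties go to the smallest feature index, then the smallest
#' threshold. Zero-decrease splits are admissible (so e.g. XOR-structured
#' labels are still separated over two levels); `NULL` is returned only when
#' every feature is constant at the node, i.e. no valid split exists.
#'
#' @param X Numeric matrix of feature values at the node (>= 2 rows).
#' @param y 0/1 labels.
#' @param weights Positive case weights (default: equal).
#' @return `NULL`, or a list with `feature` (column name), `feature_index`,
#'   `threshold`, and `decrease`.
#' @export
best_split <- function(X, y, weights = NULL) {
  stopifnot(is.matrix(X), nrow(X) >= 2, nrow(X) == length(y))
  if (is.null(weights)) weights <- rep(1, length(y))
  w_tot <- sum(weights)
  w1_tot <- sum(weights[y == 1])
  imp_parent <- 1 - (w1_tot / w_tot)^2 - (1 - w1_tot / w_tot)^2
  best <- NULL
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    ord <- order(v)
    vs <- v[ord]
    ws <- weights[ord]
    w1s <- ws * (y[ord] == 1)
    cw <- cumsum(ws)
    cw1 <- cumsum(w1s)
    n <- length(vs)
    cuts <- which(vs[-n] != vs[-1])
    for (c_idx in cuts) {
      wl <- cw[c_idx]; wl1 <- cw1[c_idx]
      wr <- w_tot - wl; wr1 <- w1_tot - wl1
      imp_l <- 1 - (wl1 / wl)^2 - (1 - wl1 / wl)^2
      imp_r <- 1 - (wr1 / wr)^2 - (1 - wr1 / wr)^2
      dec <- imp_parent - (wl * imp_l + wr * imp_r) / w_tot
      if (is.null(best) || dec > best$decrease + 1e-12) {
        best <- list(feature = colnames(X)[j], feature_index = j,
                     threshold = unname((vs[c_idx] + vs[c_idx + 1]) / 2),
                     decrease = dec)
      }
    }
  }
  best
}

build_tree_node <- function(X, y, weights, min_impurity_split) {
  w <- sum(weights)
  p1 <- sum(weights[y == 1]) / w
  imp <- 1 - p1^2 - (1 - p1)^2
  make_leaf <- function() {
    list(type = "leaf", positive_fraction = p1, n_samples = length(y),
         impurity = imp)
  }
  # a node splits only when its impurity strictly exceeds the threshold
  if (imp <= min_impurity_split || length(y) < 2) return(make_leaf())
  sp <- best_split(X, y, weights)
  if (is.null(sp)) return(make_leaf())
  left <- X[, sp$feature_index] <= sp$threshold
  list(
    type = "split", feature = sp$feature, threshold = sp$threshold,
    impurity = imp, n_samples = length(y),
    left = build_tree_node(X[left, , drop = FALSE], y[left], weights[left],
                           min_impurity_split),
    right = build_tree_node(X[!left, , drop = FALSE], y[!left], weights[!left],
                            min_impurity_split)
  )
}

#' Train a binary Gini decision tree
#'
#' Recursive CART with no depth or leaf-size limit: a node becomes a leaf
#' iff its (weighted) impurity is at or below `min_impurity_split`, it is
#' pure, or no split gives a positive impurity decrease. With
#' `balanced = TRUE` the positive class is re-weighted so total positive
#' weight equals total negative weight before training, which lets rare
#' genera clear the impurity-split threshold. Training is deterministic:
#' exhaustive split search with fixed tie-breaking and no randomness.
#'
#' @param X Integer feature matrix (rows = phages, named columns).
#' @param y 0/1 labels, one per row of `X`.
#' @param min_impurity_split Only nodes with impurity strictly greater than
#'   this value are divided; default 0.03.
#' @param balanced Balance class weights? Default `TRUE`.
#' @return The root node: a nested list of `split` and `leaf` nodes (left
#'   branch takes samples with feature value `<= threshold`).
#' @export
train_tree <- function(X, y, min_impurity_split = 0.03, balanced = TRUE) {
  stopifnot(is.matrix(X))
  if (nrow(X) != length(y)) abort("X and y lengths differ")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.integer(y)
  n <- length(y)
  n1 <- sum(y == 1)
  weights <- rep(1, n)
  if (balanced && n1 > 0 && n1 < n) {
    weights[y == 1] <- n / (2 * n1)
    weights[y == 0] <- n / (2 * (n - n1))
  }
  build_tree_node(X, y, weights, min_impurity_split)
}

#' Train one decision tree per host genus
#'
#' For each genus `g`, the label of phage `i` is 1 iff `g` is among its
#' admissible hosts; one tree is trained per genus on the shared feature
#' matrix. A genus without positive training phages yields a
#' constant-negative leaf and a warning.
#'
#' @param m Feature matrix (rows = training phages).
#' @param labels Host label tibble (`phage_id`, `genus`).
#' @param genera Genera to train (default: all in `labels`).
#' @param min_impurity_split,balanced See [train_tree()].
#' @return An object of class `host_tree_suite`: list with `trees` (named
#'   list of root nodes), `columns`, `genera`, and `config`.
#' @export
train_suite <- function(m, labels, genera = sort(unique(labels$genus)),
                        min_impurity_split = 0.03, balanced = TRUE) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  genera <- sort(unique(genera))
  trees <- lapply(genera, function(g) {
    pos <- labels$phage_id[labels$genus == g]
    y <- as.integer(rownames(m) %in% pos)
    if (sum(y) == 0) {
      warn(paste0("genus ", g, " has no positive training phages; ",
                  "training a constant-negative tree"))
      return(list(type = "leaf", positive_fraction = 0, n_samples = nrow(m),
                  impurity = 0))
    }
    train_tree(m, y, min_impurity_split = min_impurity_split,
               balanced = balanced)
  })
  names(trees) <- genera
  structure(
    list(trees = trees, columns = colnames(m), genera = genera,
         config = list(min_impurity_split = min_impurity_split,
                       balanced = balanced)),
    class = "host_tree_suite"
  )
}

route_tree <- function(node, vec) {
  while (node$type == "split") {
    node <- if (vec[[node$feature]] <= node$threshold) node$left else node$right
  }
  node
}

#' Predict admissible host genera
#'
#' Routes a feature vector down every genus tree; a genus is predicted iff
#' the reached leaf's positive fraction strictly exceeds
#' `decision_threshold`. A phage may receive several genera, one, or none.
#'
#' @param vectors A named integer vector over the suite's columns, or a
#'   matrix of such rows (rownames = phage ids).
#' @param suite A `host_tree_suite`.
#' @param decision_threshold Leaf positive-fraction cutoff; default 0.5.
#' @return A tibble (`phage_id`, `genus`), one row per predicted
#'   (phage, genus) pair; phages with no positive genus are absent.
#' @export
predict_hosts <- function(vectors, suite, decision_threshold = 0.5) {
  stopifnot(inherits(suite, "host_tree_suite"))
  if (is.null(dim(vectors))) {
    vectors <- matrix(vectors, nrow = 1,
                      dimnames = list("query", names(vectors)))
  }
  if (!setequal(colnames(vectors), suite$columns) ||
      length(colnames(vectors)) != length(suite$columns)) {
    abort("feature columns do not match the trained suite")
  }
  vectors <- vectors[, suite$columns, drop = FALSE]
  rows <- lapply(seq_len(nrow(vectors)), function(i) {
    vec <- vectors[i, ]
    hit <- vapply(suite$trees, function(tr) {
      route_tree(tr, vec)$positive_fraction > decision_threshold
    }, logical(1))
    if (!any(hit)) return(NULL)
    tibble(phage_id = rownames(vectors)[i], genus = names(hit)[hit])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) tibble(phage_id = character(0), genus = character(0)) else out
}

#' @export
predict.host_tree_suite <- function(object, newdata, decision_threshold = 0.5, ...) {
  predict_hosts(newdata, object, decision_threshold = decision_threshold)
}

tree_nodes_tbl <- function(node, id = 1L, depth = 0L) {
  if (node$type == "leaf") {
    return(tibble(node_id = id, depth = depth, type = "leaf",
                  feature = NA_character_, threshold = NA_real_,
                  impurity = node$impurity, n_samples = node$n_samples,
                  positive_fraction = node$positive_fraction))
  }
  left <- tree_nodes_tbl(node$left, id * 2L, depth + 1L)
  right <- tree_nodes_tbl(node$right, id * 2L + 1L, depth + 1L)
  dplyr::bind_rows(
    tibble(node_id = id, depth = depth, type = "split",
           feature = node$feature, threshold = node$threshold,
           impurity = node$impurity, n_samples = node$n_samples,
           positive_fraction = NA_real_),
    left, right
  )
}

#' @exportS3Method generics::tidy
tidy.host_tree_suite <- function(x, ...) {
  dplyr::bind_rows(lapply(x$genera, function(g) {
    dplyr::mutate(tree_nodes_tbl(x$trees[[g]]), genus = g, .before = 1)
  }))
}

#' @exportS3Method generics::glance
glance.host_tree_suite <- function(x, ...) {
  nodes <- tidy(x)
  tibble(
    n_trees = length(x$trees),
    n_features = length(x$columns),
    total_nodes = nrow(nodes),
    max_depth = max(nodes$depth),
    min_impurity_split = x$config$min_impurity_split,
    balanced = x$config$balanced
  )
}

#' @export
print.host_tree_suite <- function(x, ...) {
  cat("<host_tree_suite> ", length(x$trees), " genus trees over ",
      length(x$columns), " cluster features\n", sep = "")
  invisible(x)
}

dot_escape <- function(x) gsub("\"", "\\\\\"", x)

#' Export a genus tree as Graphviz DOT
#'
#' Internal nodes are labelled with the cluster id, split threshold,
#' impurity and sample count (plus the cluster annotation when the database
#' provides one); leaves with the decided class and positive fraction. Edge
#' labels are `true` (left, `<= threshold`) and `false`.
#'
#' @param tree A trained tree root (one element of a suite's `trees`), or a
#'   `host_tree_suite` together with `genus`.
#' @param cluster_db Optional `cluster_db` supplying annotations.
#' @param genus Genus name used in the digraph title.
#' @param path Optional output path; the DOT text is also returned.
#' @return DOT source as a single string (invisibly when `path` is given).
#' @export
export_tree_dot <- function(tree, cluster_db = NULL, genus = "host",
                            path = NULL) {
  if (inherits(tree, "host_tree_suite")) {
    stopifnot(genus %in% names(tree$trees))
    tree <- tree$trees[[genus]]
  }
  ann_for <- function(feature) {
    if (is.null(cluster_db)) return(NULL)
    cid <- as.integer(sub("^c", "", feature))
    a <- cluster_db$clusters$annotation[cluster_db$clusters$cluster_id == cid]
    if (length(a) == 1 && !is.na(a)) a else NULL
  }
  lines <- character(0)
  emit <- function(node, id) {
    if (node$type == "leaf") {
      cls <- if (node$positive_fraction > 0.5) "positive" else "negative"
      lab <- sprintf("%s\\np1=%.3f, n=%d", cls, node$positive_fraction,
                     node$n_samples)
      lines <<- c(lines, sprintf("  n%d [shape=box, label=\"%s\"];", id, lab))
      return()
    }
    lab <- sprintf("cluster %s <= %g\\nimpurity=%.3f, n=%d",
                   sub("^c", "", node$feature), node$threshold,
                   node$impurity, node$n_samples)
    ann <- ann_for(node$feature)
    if (!is.null(ann)) lab <- paste0(lab, "\\n", dot_escape(ann))
    lines <<- c(lines, sprintf("  n%d [label=\"%s\"];", id, lab))
    emit(node$left, id * 2L)
    emit(node$right, id * 2L + 1L)
    lines <<- c(lines,
                sprintf("  n%d -> n%d [label=\"true\"];", id, id * 2L),
                sprintf("  n%d -> n%d [label=\"false\"];", id, id * 2L + 1L))
  }
  emit(tree, 1L)
  dot <- paste(c(sprintf("digraph \"%s\" {", dot_escape(genus)),
                 "  node [fontname=\"Helvetica\"];", lines, "}"),
               collapse = "\n")
  if (!is.null(path)) {
    writeLines(dot, path)
    return(invisible(dot))
  }
  dot
}
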
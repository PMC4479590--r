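# From-scratch CART on the two movement metrics (distance_m, angle_deg):
# Gini-impurity growth, minimal cost-complexity (weakest-link) pruning,
# repeated stratified k-fold cross-validated risk by tree size, and size
# selection that insists on covering all behaviour classes.

FEATURES <- c("distance_m", "angle_deg")

#' Gini impurity of a class-count vector
#'
#' `1 - sum(p_i^2)` over class proportions.
#'
#' @param counts Non-negative class counts, total > 0.
#' @return Impurity in \[0, 1).
#' @export
gini_impurity <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop("class counts must have positive total")
  p <- counts / total
  1 - sum(p^2)
}

#' Best binary split of a sample set
#'
#' Exhaustive search over both features and every midpoint between
#' consecutive distinct sorted values, maximising the weighted Gini
#' decrease, subject to both children holding at least `min_leaf` samples.
#' Ties are broken deterministically: distance before angle, then the
#' smaller threshold.
#'
#' @param x Data frame with columns `distance_m` and `angle_deg`.
#' @param y Character vector of class labels.
#' @param classes Ordered class labels.
#' @param min_leaf Minimum samples per child.
#' @return `list(feature, threshold, gain)` or `NULL` when no positive-gain
#'   split exists.
#' @export
best_split <- function(x, y, classes, min_leaf = 5) {
  n <- length(y)
  if (n < 2 * min_leaf) return(NULL)
  yi <- match(y, classes)
  counts <- tabulate(yi, nbins = length(classes))
  g0 <- gini_impurity(counts)
  best <- NULL
  for (f in FEATURES) {
    v <- x[[f]]
    o <- order(v)
    vs <- v[o]
    Y <- matrix(0, n, length(classes))
    Y[cbind(seq_len(n), yi[o])] <- 1
    cum <- apply(Y, 2, cumsum)
    i <- seq_len(n - 1)
    ok <- vs[i] < vs[i + 1] & i >= min_leaf & (n - i) >= min_leaf
    if (!any(ok)) next
    i <- i[ok]
    left <- cum[i, , drop = FALSE]
    right <- sweep(-left, 2, counts, "+")
    gl <- 1 - rowSums((left / i)^2)
    gr <- 1 - rowSums((right / (n - i))^2)
    gain <- g0 - (i * gl + (n - i) * gr) / n
    j <- which.max(gain)           # first max = smallest threshold
    if (gain[j] > 1e-12 && (is.null(best) || gain[j] > best$gain + 1e-12)) {
      best <- list(feature = f,
                   threshold = (vs[i[j]] + vs[i[j] + 1]) / 2,
                   gain = gain[j])
    }
  }
  best
}

new_node <- function(id, counts, classes) {
  list(id = id, feature = NA_character_, threshold = NA_real_,
       left = NA_integer_, right = NA_integer_,
       counts = counts, pred = classes[which.max(counts)])
}

#' Grow an unrestricted CART tree
#'
#' Recursive binary splitting with the Gini criterion until no
#' positive-gain split exists or `min_leaf` would be violated; no depth
#' limit. Node ids are assigned in preorder with the root at 0. Every
#' node stores its class counts; its prediction is the majority class
#' (ties to the first class in class order).
#'
#' @param dataset A [labelled_dataset()] or a data frame of samples.
#' @param min_leaf Minimum samples per leaf (default 5).
#' @return An object of class `cart_tree`.
#' @export
grow_tree <- function(dataset, min_leaf = 5) {
  samples <- if (inherits(dataset, "labelled_dataset")) dataset$samples
             else dataset
  classes <- if (inherits(dataset, "labelled_dataset")) dataset$classes
             else sort(unique(samples$behaviour))
  if (is.null(samples) || nrow(samples) == 0) stop("empty dataset")
  if (any(is.na(samples$distance_m)) || any(is.na(samples$angle_deg)))
    stop("undefined features in training data; filter them first")
  nodes <- list()
  build <- function(rows) {
    id <- length(nodes)                 # preorder numbering, root = 0
    yi <- match(samples$behaviour[rows], classes)
    counts <- stats::setNames(tabulate(yi, nbins = length(classes)), classes)
    nodes[[id + 1]] <<- new_node(id, counts, classes)
    sp <- if (sum(counts > 0) > 1)
      best_split(samples[rows, FEATURES], samples$behaviour[rows],
                 classes, min_leaf) else NULL
    if (!is.null(sp)) {
      go_left <- samples[[sp$feature]][rows] <= sp$threshold
      l <- build(rows[go_left])
      r <- build(rows[!go_left])
      nodes[[id + 1]]$feature <<- sp$feature
      nodes[[id + 1]]$threshold <<- sp$threshold
      nodes[[id + 1]]$left <<- l
      nodes[[id + 1]]$right <<- r
    }
    id
  }
  build(seq_len(nrow(samples)))
  new_cart_tree(nodes, classes)
}

new_cart_tree <- function(nodes, classes) {
  structure(list(nodes = nodes, classes = classes,
                 n_terminal = sum(vapply(nodes,
                                         function(nd) is.na(nd$feature),
                                         logical(1)))),
            class = "cart_tree")
}

is_leaf <- function(nd) is.na(nd$feature)

#' @export
print.cart_tree <- function(x, ...) {
  cat(sprintf("<cart_tree> %d terminal nodes, classes: %s\n",
              x$n_terminal, paste(x$classes, collapse = ", ")))
  cat(export_rules(x), sep = "\n")
  invisible(x)
}

# Leaf-level predicted classes actually reachable in the tree.
leaf_classes <- function(tree) {
  unique(vapply(Filter(is_leaf, tree$nodes), `[[`, character(1), "pred"))
}

#' Predict behaviour classes with a CART tree
#'
#' Routes each sample down the tree: `feature <= threshold` goes left.
#' Undefined features are refused (the caller filters them).
#'
#' @param object A `cart_tree`.
#' @param newdata Data frame with columns `distance_m` and `angle_deg`.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.cart_tree <- function(object, newdata, ...) {
  if (inherits(newdata, "labelled_dataset")) newdata <- newdata$samples
  if (any(is.na(newdata$distance_m)) || any(is.na(newdata$angle_deg)))
    stop("undefined feature value; drop samples with undefined angles first")
  idx <- stats::setNames(seq_along(object$nodes),
                         vapply(object$nodes, `[[`, numeric(1), "id"))
  out <- character(nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    nd <- object$nodes[[idx[["0"]]]]
    while (!is_leaf(nd)) {
      go_left <- newdata[[nd$feature]][i] <= nd$threshold
      nd <- object$nodes[[idx[[as.character(if (go_left) nd$left
                                            else nd$right)]]]]
    }
    out[i] <- nd$pred
  }
  out
}

#' Export a tree as decision rules
#'
#' One line per leaf (left to right): the conjunction of threshold
#' comparisons on the path from the root, the predicted class, and the
#' training class counts at the leaf. The rules partition the feature
#' space, so exactly one rule applies to any sample.
#'
#' @param tree A `cart_tree`.
#' @return Character vector, one rule per terminal node.
#' @export
export_rules <- function(tree) {
  idx <- stats::setNames(seq_along(tree$nodes),
                         vapply(tree$nodes, `[[`, numeric(1), "id"))
  walk <- function(id, conds) {
    nd <- tree$nodes[[idx[[as.character(id)]]]]
    if (is_leaf(nd)) {
      lhs <- if (length(conds)) paste(conds, collapse = " & ") else "TRUE"
      cnt <- paste(sprintf("%s=%d", names(nd$counts), nd$counts),
                   collapse = ", ")
      return(sprintf("%s -> %s  [%s]", lhs, nd$pred, cnt))
    }
    c(walk(nd$left, c(conds, sprintf("%s <= %g", nd$feature, nd$threshold))),
      walk(nd$right, c(conds, sprintf("%s > %g", nd$feature, nd$threshold))))
  }
  walk(0, character(0))
}

# Per-node training misclassification counts needed for weakest-link
# pruning: leaf error R(t) and subtree error R(T_t), both as counts.
prune_stats <- function(tree) {
  idx <- stats::setNames(seq_along(tree$nodes),
                         vapply(tree$nodes, `[[`, numeric(1), "id"))
  stats_env <- new.env()
  walk <- function(id) {
    nd <- tree$nodes[[idx[[as.character(id)]]]]
    own_err <- sum(nd$counts) - max(nd$counts)
    if (is_leaf(nd)) {
      res <- list(sub_err = own_err, leaves = 1L)
    } else {
      l <- walk(nd$left); r <- walk(nd$right)
      res <- list(sub_err = l$sub_err + r$sub_err,
                  leaves = l$leaves + r$leaves)
    }
    assign(as.character(id), c(own_err = own_err, sub_err = res$sub_err,
                               leaves = res$leaves), envir = stats_env)
    res
  }
  walk(0)
  stats_env
}

# Collapse an internal node into a leaf, dropping its descendants.
collapse_node <- function(tree, collapse_ids) {
  idx <- stats::setNames(seq_along(tree$nodes),
                         vapply(tree$nodes, `[[`, numeric(1), "id"))
  keep <- new.env()
  walk <- function(id) {
    nd <- tree$nodes[[idx[[as.character(id)]]]]
    if (nd$id %in% collapse_ids) {
      nd$feature <- NA_character_; nd$threshold <- NA_real_
      nd$left <- NA_integer_; nd$right <- NA_integer_
    }
    assign(as.character(id), nd, envir = keep)
    if (!is_leaf(nd)) { walk(nd$left); walk(nd$right) }
  }
  walk(0)
  nodes <- lapply(sort(as.numeric(ls(keep))),
                  function(id) get(as.character(id), envir = keep))
  new_cart_tree(nodes, tree$classes)
}

#' Minimal cost-complexity (weakest-link) pruning path
#'
#' Iteratively collapses the internal node(s) with the smallest per-leaf
#' increase in training error, `g(t) = (R(t) - R(T_t)) / (|leaves| - 1)`,
#' producing the standard nested subtree sequence from the full tree down
#' to the root-only tree. Alphas are non-decreasing and each subtree is a
#' pruned version of its predecessor.
#'
#' @param tree A `cart_tree`.
#' @return An object of class `cc_path`: list of entries
#'   `list(alpha, n_terminal, tree)`.
#' @export
cost_complexity_path <- function(tree) {
  n_total <- sum(tree$nodes[[1]]$counts)
  path <- list(list(alpha = 0, n_terminal = tree$n_terminal, tree = tree))
  current <- tree
  while (current$n_terminal > 1) {
    st <- prune_stats(current)
    internal <- Filter(Negate(is_leaf), current$nodes)
    g <- vapply(internal, function(nd) {
      s <- get(as.character(nd$id), envir = st)
      (s[["own_err"]] - s[["sub_err"]]) / (s[["leaves"]] - 1) / n_total
    }, numeric(1))
    gmin <- min(g)
    ids <- vapply(internal, `[[`, numeric(1), "id")[g <= gmin + 1e-12]
    current <- collapse_node(current, ids)
    path[[length(path) + 1]] <- list(alpha = gmin,
                                     n_terminal = current$n_terminal,
                                     tree = current)
  }
  structure(path, class = "cc_path")
}

#' @export
print.cc_path <- function(x, ...) {
  cat("<cc_path>\n")
  print(data.frame(alpha = vapply(x, `[[`, numeric(1), "alpha"),
                   n_terminal = vapply(x, `[[`, numeric(1), "n_terminal")))
  invisible(x)
}

#' Prune a tree to (approximately) a target size
#'
#' Returns the subtree in the cost-complexity path whose number of terminal
#' nodes is closest to `n_target`; when two path sizes are equidistant the
#' smaller tree is returned.
#'
#' @param path A [cost_complexity_path()].
#' @param n_target Target number of terminal nodes.
#' @return A `cart_tree`.
#' @export
prune_to_size <- function(path, n_target) {
  sizes <- vapply(path, `[[`, numeric(1), "n_terminal")
  o <- order(abs(sizes - n_target), sizes)
  path[[o[1]]]$tree
}

#' Cross-validated misclassification risk by tree size
#'
#' Repeated, class-stratified k-fold cross-validation: per repeat the data
#' are shuffled (seeded) into k folds; for each fold a tree is grown on the
#' other k-1 folds, pruned along its own cost-complexity path to each
#' candidate size, and scored on the held-out fold. Candidate sizes are the
#' terminal-node counts realised by the cost-complexity path of the tree
#' grown on all the data (other sizes are unreachable by pruning). Risk
#' estimates are averaged over folds within a repeat and then over repeats;
#' `risk_sd` is the standard deviation across repeat means.
#'
#' @param dataset A [labelled_dataset()].
#' @param k Number of folds (default 10).
#' @param repeats Number of repeated CV runs averaged (default 10).
#' @param min_leaf Passed to [grow_tree()].
#' @param seed Optional seed for the fold shuffles.
#' @return Data frame `n_terminal`, `risk_mean`, `risk_sd` (class
#'   `risk_curve`), with the full-data tree and path in attributes
#'   `master_tree` and `path`.
#' @export
cv_risk <- function(dataset, k = 10, repeats = 10, min_leaf = 5,
                    seed = NULL) {
  samples <- dataset$samples
  y <- samples$behaviour
  n <- nrow(samples)
  stopifnot(n >= k)
  master <- grow_tree(dataset, min_leaf)
  path <- cost_complexity_path(master)
  sizes <- sort(unique(vapply(path, `[[`, numeric(1), "n_terminal")))
  cls_n <- table(y)
  if (any(cls_n < k))
    warning("class(es) with fewer than k samples (",
            paste(names(cls_n)[cls_n < k], collapse = ", "),
            "); stratified folds will not all contain every class")
  risk <- with_seed_if(seed, {
    vapply(seq_len(repeats), function(r) {
      fold <- integer(n)
      for (cl in names(cls_n)) {
        i <- which(y == cl)
        fold[i] <- sample(rep_len(seq_len(k), length(i)))
      }
      fold_risk <- vapply(seq_len(k), function(j) {
        train <- labelled_dataset(samples[fold != j, , drop = FALSE],
                                  classes = dataset$classes)
        test <- samples[fold == j, , drop = FALSE]
        if (nrow(test) == 0) return(rep(NA_real_, length(sizes)))
        fpath <- cost_complexity_path(grow_tree(train, min_leaf))
        vapply(sizes, function(s) {
          pred <- predict(prune_to_size(fpath, s), test)
          mean(pred != test$behaviour)
        }, numeric(1))
      }, numeric(length(sizes)))
      rowMeans(fold_risk, na.rm = TRUE)
    }, numeric(length(sizes)))
  })
  risk <- matrix(risk, nrow = length(sizes))
  out <- data.frame(n_terminal = sizes,
                    risk_mean = rowMeans(risk),
                    risk_sd = apply(risk, 1, stats::sd))
  attr(out, "master_tree") <- master
  attr(out, "path") <- path
  class(out) <- c("risk_curve", "data.frame")
  out
}

#' Select the tree size from a risk curve
#'
#' Chooses the size with the lowest cross-validated risk whose pruned tree
#' still has at least one leaf predicting each required class (ties broken
#' towards fewer terminal nodes). If no size covers all required classes,
#' the smallest-risk size among those with maximal coverage is returned
#' with a warning.
#'
#' @param curve A [cv_risk()] result.
#' @param path The matching [cost_complexity_path()].
#' @param required_classes Classes the pruned tree must be able to predict.
#' @return Selected number of terminal nodes (integer).
#' @export
select_size <- function(curve, path, required_classes) {
  stopifnot(nrow(curve) > 0)
  ord <- order(curve$risk_mean, curve$n_terminal)
  coverage <- integer(nrow(curve))
  for (i in ord) {
    covered <- intersect(required_classes,
                         leaf_classes(prune_to_size(path,
                                                    curve$n_terminal[i])))
    if (length(covered) == length(required_classes))
      return(as.integer(curve$n_terminal[i]))
    coverage[i] <- length(covered)
  }
  best <- ord[which.max(coverage[ord])]
  warning("no tree size covers all required classes; returning the ",
          "largest-coverage smallest-risk size")
  as.integer(curve$n_terminal[best])
}

#' Serialise a tree to JSON
#'
#' Writes nodes (ids, split features, thresholds, class counts, predicted
#' classes) and the class order.
#'
#' @param tree A `cart_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  jsonlite::write_json(
    list(classes = tree$classes,
         n_terminal = tree$n_terminal,
         nodes = lapply(tree$nodes, function(nd)
           list(id = nd$id, feature = nd$feature, threshold = nd$threshold,
                left = nd$left, right = nd$right,
                counts = as.list(nd$counts), predicted_class = nd$pred))),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
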
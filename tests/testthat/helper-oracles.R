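# Independent oracles and small fixture builders. Everything here is
# deliberately written without reusing the package's internals, so tests
# compare two routes to the same quantity.

# Haversine great-circle distance in metres (spherical earth).
haversine_m <- function(lon1, lat1, lon2, lat2, r = 6371008.8) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Brute-force best split: every feature, every midpoint between consecutive
# distinct sorted values, weighted Gini decrease computed from scratch.
oracle_best_split <- function(x, y, classes, min_leaf) {
  gini <- function(lab) {
    p <- table(factor(lab, levels = classes)) / length(lab)
    1 - sum(p^2)
  }
  n <- length(y)
  best <- NULL
  for (f in c("distance_m", "angle_deg")) {
    v <- x[[f]]
    for (thr in unique((head(sort(unique(v)), -1) +
                        sort(unique(v))[-1]) / 2)) {
      left <- v <= thr
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      gain <- gini(y) - (sum(left) * gini(y[left]) +
                         sum(!left) * gini(y[!left])) / n
      if (gain > 1e-12 &&
          (is.null(best) || gain > best$gain + 1e-12 ||
           (abs(gain - best$gain) <= 1e-12 && f == best$feature &&
            thr < best$threshold)))
        best <- list(feature = f, threshold = thr, gain = gain)
    }
  }
  best
}

# Random tiny labelled dataset (<= 12 samples, few distinct values).
random_tiny_dataset <- function(n = sample(4:12, 1), n_classes = sample(2:3, 1)) {
  data.frame(
    animal_id = "a",
    t_start = seq_len(n), t_end = seq_len(n) + 1,
    distance_m = sample(seq(0, 10, by = 2), n, replace = TRUE),
    angle_deg = sample(c(0, 45, 90, 135, 180), n, replace = TRUE),
    behaviour = sample(c("Foraging", "Walking", "Lying")[seq_len(n_classes)],
                       n, replace = TRUE),
    purity = "pure", stringsAsFactors = FALSE)
}

# Convert a cart_tree into an independent nested-list form.
as_nested <- function(tree) {
  ids <- vapply(tree$nodes, function(nd) nd$id, numeric(1))
  get_node <- function(id) tree$nodes[[match(id, ids)]]
  rec <- function(id) {
    nd <- get_node(id)
    if (is.na(nd$feature))
      return(list(counts = nd$counts, leaf = TRUE))
    list(counts = nd$counts, leaf = FALSE,
         left = rec(nd$left), right = rec(nd$right))
  }
  rec(0)
}

# All pruned subtrees of a nested tree, each summarised by
# (training error count, number of leaves).
oracle_all_subtrees <- function(node) {
  err <- sum(node$counts) - max(node$counts)
  collapsed <- list(list(err = err, leaves = 1))
  if (node$leaf) return(collapsed)
  combos <- list()
  for (l in oracle_all_subtrees(node$left))
    for (r in oracle_all_subtrees(node$right))
      combos[[length(combos) + 1]] <- list(err = l$err + r$err,
                                           leaves = l$leaves + r$leaves)
  c(collapsed, combos)
}

# Independent weakest-link pruning on the nested form: returns the
# (alpha, n_leaves, error) sequence.
oracle_weakest_link <- function(nested, n_total) {
  summarise <- function(node) {
    if (node$leaf)
      return(list(err = sum(node$counts) - max(node$counts), leaves = 1))
    l <- summarise(node$left); r <- summarise(node$right)
    list(err = l$err + r$err, leaves = l$leaves + r$leaves)
  }
  seqs <- list()
  current <- nested
  repeat {
    s <- summarise(current)
    seqs[[length(seqs) + 1]] <- list(n_leaves = s$leaves,
                                     err = s$err / n_total)
    if (s$leaves == 1) break
    # find min g over internal nodes
    min_g <- Inf
    walk_min <- function(node) {
      if (node$leaf) return(invisible())
      s <- summarise(node)
      own <- sum(node$counts) - max(node$counts)
      g <- (own - s$err) / (s$leaves - 1) / n_total
      if (g < min_g) min_g <<- g
      walk_min(node$left); walk_min(node$right)
    }
    walk_min(current)
    prune <- function(node) {
      if (node$leaf) return(node)
      s <- summarise(node)
      own <- sum(node$counts) - max(node$counts)
      g <- (own - s$err) / (s$leaves - 1) / n_total
      if (g <= min_g + 1e-12)
        return(list(counts = node$counts, leaf = TRUE))
      list(counts = node$counts, leaf = FALSE,
           left = prune(node$left), right = prune(node$right))
    }
    current <- prune(current)
    attr(seqs[[length(seqs)]], "alpha_next") <- min_g
  }
  seqs
}

# A small simulated open-field-like study for coupling tests.
tiny_study <- function(seed = 7, minutes = 60, fix_interval_s = 60) {
  cfg <- sim_config(seed = seed, fix_interval_s = fix_interval_s,
                    day_window = c(0, minutes * 60))
  simulate_study(cfg)
}

expect_same_tree <- function(a, b) {
  expect_equal(export_rules(a), export_rules(b))
}
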
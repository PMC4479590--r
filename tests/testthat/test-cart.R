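make_xy <- function(distance, angle, label) {
  data.frame(animal_id = "a", t_start = seq_along(distance),
             t_end = seq_along(distance) + 1,
             distance_m = distance, angle_deg = angle,
             behaviour = label, purity = "pure", stringsAsFactors = FALSE)
}

test_that("gini impurity follows 1 - sum(p^2)", {
  expect_equal(gini_impurity(c(A = 4)), 0)
  expect_equal(gini_impurity(c(A = 2, B = 2)), 0.5)
  expect_equal(gini_impurity(c(1, 1, 1, 1)), 0.75)
  expect_error(gini_impurity(c(A = 0, B = 0)), "positive total")
})

test_that("best_split finds the enumerated optimum with deterministic ties", {
  x <- make_xy(c(1, 2, 10, 11), c(90, 90, 90, 90),
               c("Foraging", "Foraging", "Walking", "Walking"))
  sp <- best_split(x, x$behaviour, c("Foraging", "Walking"), min_leaf = 1)
  expect_equal(sp$feature, "distance_m")
  expect_equal(sp$threshold, 6)
  expect_equal(sp$gain, 0.5)

  expect_null(best_split(x, rep("Foraging", 4), c("Foraging", "Walking"),
                         min_leaf = 1))

  withr::local_seed(5)
  for (i in 1:30) {
    d <- random_tiny_dataset()
    classes <- sort(unique(d$behaviour))
    got <- best_split(d, d$behaviour, classes, min_leaf = 1)
    want <- oracle_best_split(d, d$behaviour, classes, min_leaf = 1)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$gain, want$gain, tolerance = 1e-12)
      expect_equal(got$feature, want$feature)
      expect_equal(got$threshold, want$threshold)
    }
  }
})

test_that("trees grow to purity on separable data and respect min_leaf", {
  x <- make_xy(c(1, 2, 3, 20, 21, 22), rep(45, 6),
               rep(c("Lying", "Walking"), each = 3))
  tree <- grow_tree(labelled_dataset(x), min_leaf = 3)
  expect_equal(tree$n_terminal, 2)
  expect_equal(predict(tree, x), x$behaviour)

  pure <- grow_tree(labelled_dataset(make_xy(1:6, rep(10, 6),
                                             rep("Lying", 6))))
  expect_equal(pure$n_terminal, 1)

  # majority baseline never beats the grown tree on training data
  withr::local_seed(6)
  d <- random_tiny_dataset(n = 12)
  tree <- grow_tree(labelled_dataset(d), min_leaf = 2)
  acc <- mean(predict(tree, d) == d$behaviour)
  expect_gte(acc, max(table(d$behaviour)) / nrow(d))
})

test_that("children class counts sum to the parent's", {
  st <- tiny_study(seed = 12, minutes = 90)
  ds <- build_labelled_dataset(st$trajectory, st$truth_segments)
  tree <- grow_tree(ds)
  ids <- vapply(tree$nodes, function(nd) nd$id, numeric(1))
  for (nd in tree$nodes) {
    if (!is.na(nd$feature)) {
      l <- tree$nodes[[match(nd$left, ids)]]
      r <- tree$nodes[[match(nd$right, ids)]]
      expect_equal(l$counts + r$counts, nd$counts)
    }
    expect_equal(nd$pred, names(nd$counts)[which.max(nd$counts)])
  }
})

test_that("root split agrees with rpart on well-separated data", {
  withr::local_seed(7)
  n <- 120
  d <- make_xy(c(rnorm(n / 2, 3, 1), rnorm(n / 2, 40, 8)),
               runif(n, 0, 180),
               rep(c("Resting", "Walking"), each = n / 2))
  tree <- grow_tree(labelled_dataset(d), min_leaf = 5)
  rp <- rpart::rpart(behaviour ~ distance_m + angle_deg, data = d,
                     method = "class",
                     control = rpart::rpart.control(minsplit = 10,
                                                    minbucket = 5,
                                                    cp = 0, xval = 0))
  root <- tree$nodes[[1]]
  expect_equal(root$feature, as.character(rp$frame$var[1]))
  expect_equal(root$threshold, rp$splits[1, "index"], tolerance = 1e-8)
})

test_that("cost-complexity path is nested with non-decreasing alphas", {
  st <- tiny_study(seed = 13, minutes = 120)
  ds <- build_labelled_dataset(st$trajectory, st$truth_segments)
  tree <- grow_tree(ds)
  path <- cost_complexity_path(tree)
  alphas <- vapply(path, `[[`, numeric(1), "alpha")
  sizes <- vapply(path, `[[`, numeric(1), "n_terminal")
  expect_true(all(diff(alphas) >= -1e-12))
  expect_true(all(diff(sizes) < 0))
  expect_equal(sizes[length(sizes)], 1)
  # node-set inclusion: each subtree's ids are a subset of its predecessor's
  get_ids <- function(t) sort(vapply(t$nodes, function(nd) nd$id,
                                     numeric(1)))
  for (i in seq_along(path)[-1])
    expect_true(all(get_ids(path[[i]]$tree) %in% get_ids(path[[i - 1]]$tree)))
  # training accuracy non-decreasing in tree size along the path
  accs <- vapply(rev(seq_along(path)), function(i)
    mean(predict(path[[i]]$tree, ds$samples) == ds$samples$behaviour),
    numeric(1))
  expect_true(all(diff(accs) >= -1e-12))

  leaf <- grow_tree(labelled_dataset(make_xy(1:6, rep(0, 6),
                                             rep("Lying", 6))))
  lp <- cost_complexity_path(leaf)
  expect_length(lp, 1)
  expect_equal(lp[[1]]$alpha, 0)
})

test_that("pruning sequence matches an independent weakest-link oracle", {
  withr::local_seed(8)
  for (i in 1:20) {
    d <- random_tiny_dataset(n = 12)
    tree <- grow_tree(labelled_dataset(d), min_leaf = 1)
    path <- cost_complexity_path(tree)
    oracle <- oracle_weakest_link(as_nested(tree), nrow(d))
    expect_equal(vapply(path, `[[`, numeric(1), "n_terminal"),
                 vapply(oracle, `[[`, numeric(1), "n_leaves"))
    # every path entry is optimal among ALL pruned subtrees at its alpha
    subtrees <- oracle_all_subtrees(as_nested(tree))
    alphas <- vapply(path, `[[`, numeric(1), "alpha")
    for (j in seq_along(path)) {
      tr <- path[[j]]$tree
      err <- mean(predict(tr, d) != d$behaviour)
      a <- if (j == 1) 0 else (alphas[j] + 1e-9)
      cost <- err + a * path[[j]]$n_terminal
      best <- min(vapply(subtrees, function(s)
        s$err / nrow(d) + a * s$leaves, numeric(1)))
      expect_lte(cost, best + 1e-9)
    }
  }
})

test_that("prune_to_size picks the closest path size, ties to smaller", {
  x <- make_xy(c(1, 2, 3, 10, 11, 12, 30, 31, 32), rep(c(10, 90, 170), 3),
               rep(c("Lying", "Foraging", "Walking"), each = 3))
  tree <- grow_tree(labelled_dataset(x), min_leaf = 3)
  path <- cost_complexity_path(tree)
  sizes <- vapply(path, `[[`, numeric(1), "n_terminal")
  expect_equal(prune_to_size(path, max(sizes))$n_terminal, max(sizes))
  expect_equal(prune_to_size(path, 1)$n_terminal, 1)
  expect_equal(prune_to_size(path, 1000)$n_terminal, max(sizes))
  if (all(c(1, 3) %in% sizes) && !(2 %in% sizes))
    expect_equal(prune_to_size(path, 2)$n_terminal, 1)  # equidistant -> smaller
})

test_that("prediction routes <= to the left and matches exported rules", {
  x <- make_xy(c(1, 2, 10, 11), rep(45, 4),
               c("Foraging", "Foraging", "Walking", "Walking"))
  tree <- grow_tree(labelled_dataset(x), min_leaf = 1)
  thr <- tree$nodes[[1]]$threshold
  expect_equal(predict(tree, make_xy(thr, 45, "Foraging")), "Foraging")
  expect_error(predict(tree, make_xy(NA_real_, 45, "Foraging")),
               "undefined feature")

  st <- tiny_study(seed = 14, minutes = 120)
  ds <- build_labelled_dataset(st$trajectory, st$truth_segments)
  tree <- grow_tree(ds)
  rules <- export_rules(tree)
  expect_length(rules, tree$n_terminal)
  withr::local_seed(9)
  probe <- data.frame(distance_m = runif(200, 0, 80),
                      angle_deg = runif(200, 0, 180))
  conds <- sub(" -> .*$", "", rules)
  labels <- sub("  \\[.*$", "", sub("^.* -> ", "", rules))
  hits <- vapply(seq_len(nrow(probe)), function(i) {
    env <- list2env(as.list(probe[i, ]))
    which(vapply(conds, function(cc) eval(parse(text = cc), env),
                 logical(1)))
  }, integer(1))   # errors if a point satisfies != 1 rule
  expect_equal(labels[hits], predict(tree, probe))
})

test_that("cross-validated risk behaves like a misclassification estimate", {
  # separable three-class data: risk 0 at the separating size
  withr::local_seed(10)
  n <- 60
  x <- make_xy(c(rnorm(n, 2, .2), rnorm(n, 10, .2), rnorm(n, 40, .5)),
               runif(3 * n, 0, 180),
               rep(c("Lying", "Foraging", "Walking"), each = n))
  ds <- labelled_dataset(x)
  curve <- cv_risk(ds, k = 10, repeats = 2, seed = 42)
  expect_equal(min(curve$risk_mean), 0)
  expect_equal(curve$risk_mean[curve$n_terminal == 3], 0)
  # root-only risk equals 1 - max class frequency (here 2/3)
  expect_equal(curve$risk_mean[curve$n_terminal == 1], 2 / 3,
               tolerance = 0.02)

  # reproducible under a fixed seed; different seeds close in risk
  c2 <- cv_risk(ds, k = 10, repeats = 2, seed = 42)
  expect_identical(curve$risk_mean, c2$risk_mean)
  c3 <- cv_risk(ds, k = 10, repeats = 2, seed = 43)
  expect_true(all(abs(c3$risk_mean - curve$risk_mean) <=
                    3 * pmax(curve$risk_sd, 0.05)))
})

test_that("size selection requires class coverage and prefers small trees", {
  withr::local_seed(11)
  n <- 40
  x <- make_xy(c(rnorm(n, 2, .2), rnorm(n, 10, .2), rnorm(n, 40, .5)),
               runif(3 * n, 0, 180),
               rep(c("Lying", "Foraging", "Walking"), each = n))
  ds <- labelled_dataset(x)
  curve <- cv_risk(ds, k = 10, repeats = 2, seed = 1)
  path <- attr(curve, "path")
  size <- select_size(curve, path, c("Lying", "Foraging", "Walking"))
  expect_equal(size, 3)
  # a class the pruned tree cannot predict forces a larger size or warning
  expect_warning(select_size(curve, path,
                             c("Lying", "Foraging", "Walking", "Standing")),
                 "no tree size covers")
})

test_that("trees on open-field-like data use distance to isolate walking", {
  st <- tiny_study(seed = 15, minutes = 240)
  ds <- build_labelled_dataset(
    st$trajectory, st$truth_segments,
    pooling = c(Lying = "Resting", Standing = "Resting"))
  tree <- grow_tree(ds)
  path <- cost_complexity_path(tree)
  pruned <- prune_to_size(path, 3)
  rules <- export_rules(pruned)
  walking <- rules[grepl("-> Walking", rules)]
  resting <- rules[grepl("-> Resting", rules)]
  expect_true(length(walking) >= 1 && length(resting) >= 1)
  # Walking leaves sit behind a large-distance comparison,
  # Resting leaves behind a small-distance one
  expect_true(all(grepl("distance_m >", walking)))
  expect_true(all(grepl("distance_m <=", resting)))
})

test_that("tree JSON serialisation preserves structure and counts", {
  x <- make_xy(c(1, 2, 10, 11), rep(45, 4),
               c("Foraging", "Foraging", "Walking", "Walking"))
  tree <- grow_tree(labelled_dataset(x), min_leaf = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_tree_json(tree, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$n_terminal, tree$n_terminal)
  expect_equal(length(js$nodes), length(tree$nodes))
  expect_equal(js$nodes[[1]]$threshold, tree$nodes[[1]]$threshold)
  expect_equal(unlist(js$classes), tree$classes)
})
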
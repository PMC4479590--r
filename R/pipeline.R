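#' Experiment configuration
#'
#' Describes one end-to-end classification experiment: the data source
#' (a simulation configuration, or a fix table and observation log on
#' disk), the labelling mode and class handling, the CART settings, and the
#' seeds. Per-habitat and per-interval analyses are independent
#' experiments; a 12 s analysis of a 2 s track is expressed with
#' `subsample_factor = 6`.
#'
#' @param source A [sim_config()] or
#'   `list(fixes = <path>, observations = <path>)`.
#' @param mode Label mode for the classifier dataset, `"pure"` (default) or
#'   `"dominant"`.
#' @param class_filter Behaviours kept before pooling.
#' @param pooling Optional class pooling, e.g.
#'   `c(Lying = "Resting", Standing = "Resting")`.
#' @param subsample_factor Integer; subsample the trajectory before
#'   computing metrics (1 = none).
#' @param min_leaf,k,repeats CART and cross-validation settings.
#' @param n_perm Permutations for the movement-metric ANOVAs.
#' @param seed Seed for the half split, cross-validation and permutation
#'   tests (the simulation has its own seed in `source`).
#' @param habitat Free-form tag recorded in the dataset metadata.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(source,
                              mode = "pure",
                              class_filter = DOMINANT_BEHAVIOURS,
                              pooling = NULL,
                              subsample_factor = 1,
                              min_leaf = 5, k = 10, repeats = 10,
                              n_perm = 999,
                              seed = 1,
                              habitat = "open_field") {
  if (!inherits(source, "sim_config")) {
    stopifnot(is.list(source), all(c("fixes", "observations")
                                   %in% names(source)))
    if (!file.exists(source$fixes)) stop("no such file: ", source$fixes)
    if (!file.exists(source$observations))
      stop("no such file: ", source$observations)
  }
  structure(list(source = source, mode = mode, class_filter = class_filter,
                 pooling = pooling, subsample_factor = subsample_factor,
                 min_leaf = min_leaf, k = k, repeats = repeats,
                 n_perm = n_perm, seed = as.integer(seed),
                 habitat = habitat),
            class = "experiment_config")
}

#' Run a classification experiment end to end
#'
#' Simulates (or ingests) a tracking study, computes interval metrics,
#' couples them to the behaviour observations, splits the labelled data in
#' half (stratified), grows the reference tree on the training half, picks
#' the tree size by repeated k-fold cross-validation (smallest risk that
#' still differentiates all behaviours present), prunes, and validates on
#' the held-out half. Movement-metric permutation ANOVAs (distance and
#' angle by behaviour, with Bonferroni pairwise tests) are computed on the
#' training half. Identical configuration (including seeds) reproduces the
#' bundle bit-exactly.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; when given, all artifacts (labelled
#'   samples, risk curve, rules, tree JSON, confusion matrices, summary,
#'   run log) are written there.
#' @return Object of class `behaviour_experiment`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  if (inherits(config$source, "sim_config")) {
    study <- stage("simulate", simulate_study(config$source))
    traj <- study$trajectory
    segments <- study$truth_segments
  } else {
    trajs <- stage("ingest", read_fix_table(config$source$fixes))
    if (length(trajs) != 1)
      stop("stage 'ingest': expected a single-animal fix table; run one ",
           "experiment per animal")
    traj <- trajs[[1]]
    segments <- stage("ingest",
                      read_observation_log(config$source$observations))
  }
  if (config$subsample_factor > 1)
    traj <- stage("subsample",
                  subsample_trajectory(traj, config$subsample_factor))
  dataset <- stage("couple", build_labelled_dataset(
    traj, segments, mode = config$mode, class_filter = config$class_filter,
    pooling = config$pooling, metadata = list(habitat = config$habitat)))
  halves <- stage("split", split_half(dataset, seed = config$seed))
  training <- halves$training
  curve <- stage("cross-validate",
                 cv_risk(training, k = config$k, repeats = config$repeats,
                         min_leaf = config$min_leaf,
                         seed = config$seed + 1L))
  path <- attr(curve, "path")
  present <- intersect(dataset$classes,
                       unique(training$samples$behaviour))
  size <- stage("select-size", select_size(curve, path, present))
  tree <- stage("prune", prune_to_size(path, size))
  cm <- function(ds) confusion_matrix(ds$samples$behaviour,
                                      predict(tree, ds$samples),
                                      dataset$classes)
  cm_train <- stage("evaluate", cm(training))
  cm_valid <- stage("evaluate", cm(halves$validation))
  groups_of <- function(col) {
    s <- training$samples
    g <- split(s[[col]], s$behaviour)
    lapply(g[lengths(g) > 0], function(v) v[!is.na(v)])
  }
  anova <- stage("permutation-anova", withr::with_seed(config$seed + 2L, {
    dist_groups <- groups_of("distance_m")
    ang_groups <- groups_of("angle_deg")
    list(distance = permutation_anova(dist_groups, config$n_perm),
         angle = permutation_anova(ang_groups, config$n_perm),
         pairwise_distance = pairwise_permutation_tests(dist_groups,
                                                        config$n_perm),
         pairwise_angle = pairwise_permutation_tests(ang_groups,
                                                     config$n_perm))
  }))
  bundle <- structure(
    list(config = config, dataset = dataset, training = training,
         validation = halves$validation, risk_curve = curve,
         selected_size = size, tree = tree, rules = export_rules(tree),
         cm_training = cm_train, cm_validation = cm_valid,
         pct_training = percent_correct(cm_train),
         pct_validation = percent_correct(cm_valid),
         anova = anova,
         seeds = list(simulation = if (inherits(config$source, "sim_config"))
                        config$source$seed else NA,
                      split = config$seed, cv = config$seed + 1L,
                      anova = config$seed + 2L)),
    class = "behaviour_experiment")
  if (!is.null(out_dir)) write_experiment(bundle, out_dir)
  bundle
}

write_experiment <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_interval_samples(bundle$dataset, p("labelled_samples.csv"))
  write.csv(data.frame(n_terminal = bundle$risk_curve$n_terminal,
                       risk_mean = bundle$risk_curve$risk_mean,
                       risk_sd = bundle$risk_curve$risk_sd),
            p("risk_curve.csv"), row.names = FALSE)
  writeLines(bundle$rules, p("rules.txt"))
  write_tree_json(bundle$tree, p("tree.json"))
  write_confusion_csv(bundle$cm_training, p("confusion_training.csv"))
  write_confusion_csv(bundle$cm_validation, p("confusion_validation.csv"))
  jsonlite::write_json(
    list(seeds = bundle$seeds, selected_size = bundle$selected_size,
         classes = bundle$dataset$classes,
         n_samples = nrow(bundle$dataset$samples),
         mode = bundle$config$mode, habitat = bundle$config$habitat,
         subsample_factor = bundle$config$subsample_factor,
         min_leaf = bundle$config$min_leaf, k = bundle$config$k,
         repeats = bundle$config$repeats, n_perm = bundle$config$n_perm,
         package_version = as.character(utils::packageVersion("gpsbehaviour"))),
    p("run_log.json"), auto_unbox = TRUE, digits = NA, na = "null")
  summary_lines <- utils::capture.output(print(bundle))
  writeLines(summary_lines, p("summary.txt"))
  invisible(out_dir)
}

#' @export
print.behaviour_experiment <- function(x, ...) {
  cat("Behaviour classification experiment\n")
  cat(sprintf("  labelled samples: %d (%s mode), classes: %s\n",
              nrow(x$dataset$samples), x$config$mode,
              paste(x$dataset$classes, collapse = ", ")))
  cat(sprintf("  selected tree size: %d terminal nodes\n", x$selected_size))
  cat(sprintf("  training overall correct: %d%%\n", x$pct_training$overall))
  cat(sprintf("  validation overall correct: %d%%\n",
              x$pct_validation$overall))
  cat("  validation confusion matrix:\n")
  print(x$cm_validation)
  invisible(x)
}

#' Classify mixed-behaviour intervals with a trained tree
#'
#' Applies a tree trained on pure single-behaviour intervals to intervals
#' labelled with their dominant behaviour, and tabulates the confusion
#' matrix against the dominant labels. Restrict `dataset` to
#' `purity == "dominant"` rows to evaluate genuinely mixed intervals only.
#'
#' @param tree A `cart_tree` trained on compatible classes.
#' @param dataset A [labelled_dataset()] built in dominant mode.
#' @return A [confusion_matrix()].
#' @export
classify_mixed <- function(tree, dataset) {
  stopifnot(inherits(tree, "cart_tree"),
            inherits(dataset, "labelled_dataset"))
  extra <- setdiff(dataset$classes, tree$classes)
  if (length(extra))
    stop("dataset class '", extra[1], "' unknown to the tree")
  confusion_matrix(dataset$samples$behaviour,
                   predict(tree, dataset$samples), tree$classes)
}
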
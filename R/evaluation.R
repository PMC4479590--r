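#' Split a dataset in half for training and validation
#'
#' Disjoint, exhaustive 50/50 split; with an odd count the training half
#' receives the extra sample. With `stratify = TRUE` the split is carried
#' out within each class.
#'
#' @param dataset A [labelled_dataset()] or a data frame of samples.
#' @param seed Optional seed.
#' @param stratify Stratify by behaviour class (default `TRUE`).
#' @return List with elements `training` and `validation` of the same type
#'   as the input.
#' @export
split_half <- function(dataset, seed = NULL, stratify = TRUE) {
  samples <- if (inherits(dataset, "labelled_dataset")) dataset$samples
             else dataset
  n <- nrow(samples)
  stopifnot(n >= 2)
  train_idx <- with_seed_if(seed, {
    if (stratify) {
      unlist(lapply(split(seq_len(n), samples$behaviour), function(i) {
        i <- sample(i)
        i[seq_len(ceiling(length(i) / 2))]
      }), use.names = FALSE)
    } else {
      sample(n)[seq_len(ceiling(n / 2))]
    }
  })
  wrap <- function(rows) {
    s <- samples[rows, , drop = FALSE]
    rownames(s) <- NULL
    if (inherits(dataset, "labelled_dataset"))
      labelled_dataset(s, dataset$classes, dataset$metadata) else s
  }
  list(training = wrap(sort(train_idx)),
       validation = wrap(setdiff(seq_len(n), train_idx)))
}

#' Confusion matrix
#'
#' Square count matrix, rows = observed classes, columns = predicted.
#'
#' @param observed,predicted Equal-length label vectors.
#' @param classes Ordered class labels; every label must belong to it.
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(observed, predicted, classes) {
  stopifnot(length(observed) == length(predicted))
  bad <- setdiff(unique(c(observed, predicted)), classes)
  if (length(bad)) stop("label outside the class set: '", bad[1], "'")
  m <- table(factor(observed, levels = classes),
             factor(predicted, levels = classes))
  m <- matrix(as.integer(m), nrow = length(classes),
              dimnames = list(observed = classes, predicted = classes))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Percent correctly classified
#'
#' Per-class percent correct (`100 * diagonal / row total`) and overall
#' percent correct (`100 * trace / total`), rounded half-up to integers as
#' in the published confusion-matrix tables. A class with no observed
#' samples has an undefined per-class value (`NA`).
#'
#' @param cm A [confusion_matrix()].
#' @return List with `overall` (integer percent) and `per_class`
#'   (named integer percents, `NA` for empty rows).
#' @export
percent_correct <- function(cm) {
  total <- sum(cm)
  stopifnot(total > 0)
  row_tot <- rowSums(cm)
  per_class <- ifelse(row_tot > 0,
                      round_half_up(100 * diag(cm) / row_tot), NA_real_)
  list(overall = round_half_up(100 * sum(diag(cm)) / total),
       per_class = stats::setNames(per_class, rownames(cm)))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  pc <- percent_correct(x)
  m <- cbind(unclass(x), `Correct (%)` = pc$per_class)
  m <- rbind(m, `Overall (%)` = c(round_half_up(100 * colSums(x) / sum(x)),
                                  pc$overall))
  print(m, na.print = "-")
  invisible(x)
}

#' Write a confusion matrix as CSV
#'
#' Mirrors the published table layout: class-labelled rows and columns plus
#' a "Correct (%)" column and an "Overall (%)" row.
#'
#' @param cm A [confusion_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  pc <- percent_correct(cm)
  m <- cbind(as.data.frame(unclass(cm)), `Correct (%)` = pc$per_class)
  m <- rbind(m, `Overall (%)` = c(round_half_up(100 * colSums(cm) / sum(cm)),
                                  pc$overall))
  write.csv(cbind(observed = rownames(m), m), path, row.names = FALSE,
            na = "")
  invisible(path)
}

#' One-way ANOVA F statistic
#'
#' Classical between-group over within-group mean square. Returns `Inf`
#' when the within-group variance is zero but groups differ; errors when
#' both variances are zero (all values identical).
#'
#' @param groups List of numeric vectors, one per group.
#' @return The F statistic.
#' @export
one_way_F <- function(groups) {
  k <- length(groups)
  stopifnot(k >= 2, all(lengths(groups) >= 1))
  n <- sum(lengths(groups))
  if (n - 1 < 2) stop("need at least 2 total degrees of freedom")
  x <- unlist(groups, use.names = FALSE)
  grp <- rep(seq_len(k), lengths(groups))
  f_stat_grouped(x, grp, k, lengths(groups))
}

# F from a pooled sample and an integer group assignment; fast path reused
# by the permutation loop (group sums only).
f_stat_grouped <- function(x, grp, k, n_i) {
  n <- length(x)
  G <- sum(x)
  S <- rowsum(x, grp, reorder = TRUE)[, 1]
  ssb <- sum(S^2 / n_i) - G^2 / n
  sst <- sum(x^2) - G^2 / n
  ssw <- sst - ssb
  if (ssw <= 1e-12 * max(sst, 1)) {
    if (ssb <= 1e-12 * max(sst, 1))
      stop("zero between-group and within-group variance; F undefined")
    return(Inf)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

# All distinct assignments of the multiset of group labels to positions.
# Returns a matrix, one assignment per column. Only called when the count
# is small (exact permutation branch).
enumerate_assignments <- function(n_i) {
  k <- length(n_i)
  rec <- function(pos, remaining) {
    if (length(pos) == 0) return(matrix(integer(0), nrow = 0, ncol = 1))
    g <- which(remaining > 0)[1]
    if (sum(remaining > 0) == 1)
      return(matrix(rep(g, length(pos)), ncol = 1))
    picks <- combn(seq_along(pos), remaining[g])
    out <- list()
    for (j in seq_len(ncol(picks))) {
      sel <- picks[, j]
      rem <- remaining; rem[g] <- 0
      sub <- rec(pos[-sel], rem)
      block <- matrix(0L, nrow = length(pos), ncol = ncol(sub))
      block[sel, ] <- g
      block[-sel, ] <- sub
      out[[j]] <- block
    }
    do.call(cbind, out)
  }
  rec(seq_len(sum(n_i)), n_i)
}

#' Permutation ANOVA
#'
#' Label-permutation test on the one-way F statistic. With more requested
#' permutations than distinct label arrangements, the null distribution is
#' enumerated exactly and `p = #{F_perm >= F_obs} / #arrangements`;
#' otherwise `n_perm` random permutations are drawn (seeded) and
#' `p = (#{F_perm >= F_obs} + 1) / (n_perm + 1)`.
#'
#' @param groups Named (or unnamed) list of numeric vectors.
#' @param n_perm Number of random permutations (default 999).
#' @param seed Optional seed.
#' @return List of class `perm_anova`: `statistic`, `n_perm` (arrangements
#'   evaluated), `p_value`, `groups`, `exact`.
#' @export
permutation_anova <- function(groups, n_perm = 999, seed = NULL) {
  k <- length(groups)
  n_i <- lengths(groups)
  x <- unlist(groups, use.names = FALSE)
  grp <- rep(seq_len(k), n_i)
  f_obs <- f_stat_grouped(x, grp, k, n_i)
  thresh <- if (is.finite(f_obs)) f_obs * (1 - 1e-9) else Inf
  n_arr <- round(exp(lgamma(length(x) + 1) - sum(lgamma(n_i + 1))))
  if (n_arr <= n_perm) {
    A <- enumerate_assignments(n_i)
    fp <- apply(A, 2, function(g)
      tryCatch(f_stat_grouped(x, g, k, n_i), error = function(e) 0))
    p <- sum(fp >= thresh) / n_arr
    res <- list(statistic = f_obs, n_perm = n_arr, p_value = p,
                groups = names(groups), exact = TRUE)
  } else {
    exceed <- with_seed_if(seed, {
      sum(vapply(seq_len(n_perm), function(b) {
        fp <- tryCatch(f_stat_grouped(x, sample(grp), k, n_i),
                       error = function(e) 0)
        fp >= thresh
      }, logical(1)))
    })
    res <- list(statistic = f_obs, n_perm = n_perm,
                p_value = (exceed + 1) / (n_perm + 1),
                groups = names(groups), exact = FALSE)
  }
  class(res) <- "perm_anova"
  res
}

#' @export
print.perm_anova <- function(x, ...) {
  cat(sprintf("Permutation ANOVA: F = %.4g, p = %.4g (%s, %d permutations)\n",
              x$statistic, x$p_value,
              if (x$exact) "exact enumeration" else "sampled", x$n_perm))
  invisible(x)
}

#' Pairwise permutation tests with Bonferroni correction
#'
#' Runs [permutation_anova()] for every unordered pair of groups and
#' adjusts the raw p-values by the number of pairs (capped at 1).
#'
#' @inheritParams permutation_anova
#' @return Data frame `group_a`, `group_b`, `F`, `n_perm`, `p_raw`,
#'   `p_adjusted`.
#' @export
pairwise_permutation_tests <- function(groups, n_perm = 999, seed = NULL) {
  stopifnot(length(groups) >= 2)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  pairs <- combn(names(groups), 2)
  n_pairs <- ncol(pairs)
  with_seed_if(seed, {
    rows <- lapply(seq_len(n_pairs), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      r <- permutation_anova(groups[c(a, b)], n_perm)
      data.frame(group_a = a, group_b = b, F = r$statistic,
                 n_perm = r$n_perm, p_raw = r$p_value,
                 p_adjusted = min(1, r$p_value * n_pairs))
    })
    do.call(rbind, rows)
  })
}

#' Fraction of turning angles above a threshold
#'
#' Fraction of the (defined) turning angles of the selected classes that
#' exceed `threshold` degrees. Stationary behaviour recorded with iid GPS
#' positional error concentrates near 180 degrees, which is the artefact
#' this summary quantifies.
#'
#' @param samples A [labelled_dataset()] or a data frame of samples.
#' @param classes Classes to include (default: all).
#' @param threshold Degrees (default 90).
#' @return Fraction in \[0, 1\].
#' @export
fraction_above_angle <- function(samples, classes = NULL, threshold = 90) {
  if (inherits(samples, "labelled_dataset")) samples <- samples$samples
  if (!is.null(classes)) samples <- samples[samples$behaviour %in% classes, ]
  ang <- samples$angle_deg[!is.na(samples$angle_deg)]
  if (length(ang) == 0) stop("no defined turning angles in selection")
  mean(ang > threshold)
}
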
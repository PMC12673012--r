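# Random-forest classification of cell records and mixture-proportion
# estimation.  The ensemble itself is the reference implementation in the
# randomForest package (bagged CART trees, Gini splits, sqrt(p) feature
# subsets, majority vote); this module adds the record interface, the
# out-of-bag tree-count selection and the absolute-error scoring used for
# mixture deconvolution.

feature_columns <- function(records) {
  setdiff(names(records), "label")
}

#' Train a random-forest cell classifier
#'
#' @param records data.frame of cell records: feature columns (30
#'   normalized Mueller elements or 6 PFPs) plus a \code{label} factor
#' @param n_trees ensemble size
#' @param seed RNG seed (fixed seed gives identical forests)
#' @return object of class \code{rbc_forest}
#' @export
train_forest <- function(records, n_trees = 200, seed = NULL) {
  stopifnot(is.data.frame(records), "label" %in% names(records))
  y <- factor(records$label)
  if (nlevels(y) < 2)
    stop("training needs at least 2 classes, got ", nlevels(y))
  feats <- feature_columns(records)
  x <- as.matrix(records[, feats, drop = FALSE])
  rf <- with_seed(seed, randomForest::randomForest(x, y, ntree = n_trees))
  structure(list(rf = rf, features = feats, n_trees = n_trees,
                 classes = levels(y), seed = seed),
            class = "rbc_forest")
}

#' Out-of-bag accuracy versus ensemble size
#'
#' Trains once at the largest requested size and reads the cumulative
#' out-of-bag error for every smaller ensemble.  The selected tree count
#' is the smallest one whose OOB accuracy is within \code{plateau_tol} of
#' the maximum (the accuracy curve rises, then stabilizes); if no smaller
#' count reaches the plateau the maximum count is returned.
#'
#' @param records training records (as for \code{\link{train_forest}})
#' @param tree_counts increasing vector of ensemble sizes to evaluate
#' @param seed RNG seed
#' @param plateau_tol plateau tolerance on OOB accuracy (default 0.002)
#' @return list: \code{curve} (data.frame n_trees, oob_accuracy),
#'   \code{selected} tree count, \code{forest} (the full-size forest)
#' @export
oob_curve <- function(records, tree_counts = seq(10, 200, by = 10),
                      seed = NULL, plateau_tol = 0.002) {
  stopifnot(length(tree_counts) >= 1, all(diff(tree_counts) > 0))
  fit <- train_forest(records, n_trees = max(tree_counts), seed = seed)
  acc <- 1 - fit$rf$err.rate[tree_counts, "OOB"]
  sel <- tree_counts[which(acc >= max(acc) - plateau_tol)[1]]
  list(curve = data.frame(n_trees = tree_counts, oob_accuracy = acc),
       selected = sel, forest = fit)
}

#' Predict class proportions of a cell suspension
#'
#' @param forest \code{rbc_forest}
#' @param records data.frame of test records (same feature columns;
#'   \code{label}, if present, is ignored)
#' @param method \code{"vote"} (default): proportions are the frequencies
#'   of per-cell majority-vote labels; \code{"prob"}: mean of the per-cell
#'   class-probability votes
#' @return object of class \code{mixture_estimate}: \code{proportions}
#'   (named, sums to 1), \code{n_cells}, \code{feature_mode}
#' @export
predict_proportions <- function(forest, records,
                                method = c("vote", "prob")) {
  method <- match.arg(method)
  stopifnot(inherits(forest, "rbc_forest"))
  if (nrow(records) == 0) stop("empty test set")
  if (!all(forest$features %in% names(records)))
    stop("feature mode mismatch: classifier expects columns ",
         paste(setdiff(forest$features, names(records)), collapse = ", "))
  x <- as.matrix(records[, forest$features, drop = FALSE])
  if (method == "vote") {
    pred <- stats::predict(forest$rf, x)
    p <- as.numeric(table(factor(pred, levels = forest$classes)))
    p <- p / sum(p)
  } else {
    pr <- stats::predict(forest$rf, x, type = "prob")
    p <- colMeans(pr)[forest$classes]
  }
  names(p) <- forest$classes
  structure(list(proportions = p, n_cells = nrow(records),
                 feature_mode = length(forest$features), method = method),
            class = "mixture_estimate")
}

#' Absolute error of a mixture estimate
#'
#' \code{AE = sum_i |T_i - P_i|} over cell types; ranges over [0, 2] and
#' is 0 only for an exact match.
#'
#' @param true_props named numeric vector of true proportions (sums to 1)
#' @param est \code{mixture_estimate} or named proportion vector
#' @return scalar absolute error
#' @export
absolute_error <- function(true_props, est) {
  p <- if (inherits(est, "mixture_estimate")) est$proportions else est
  if (length(true_props) != length(p))
    stop("class count mismatch: ", length(true_props), " vs ", length(p))
  if (!is.null(names(true_props)) && !is.null(names(p))) {
    if (!setequal(names(true_props), names(p)))
      stop("class names mismatch")
    p <- p[names(true_props)]
  }
  stopifnot(abs(sum(true_props) - 1) < 1e-6, abs(sum(p) - 1) < 1e-6)
  sum(abs(true_props - p))
}
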
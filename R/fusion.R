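#' @title Decorrelated fusion forest
#' @description
#' The meta-level combiner: a 500-tree random forest over the selected
#' base-classifier votes and features, configured for maximal tree
#' decorrelation — exactly one uniformly sampled feature considered per
#' split, full-size bootstrap with replacement, cross-entropy splitting,
#' growth to purity, majority vote with the vote ratio as the AFib
#' probability.
#' @name fusion
NULL

#' Fusion forest configuration
#'
#' @param n_trees number of trees (default 500).
#' @param features_per_split features sampled at each node (default 1,
#'   which decorrelates the trees).
#' @param seed master seed.
#' @param vote_threshold probability threshold for the AFib call
#'   (default 0.5; a tie at exactly 0.5 is called AFib — the screening
#'   context favors sensitivity).
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(n_trees = 500L, features_per_split = 1L,
                          seed = 1L, vote_threshold = 0.5) {
  stopifnot(n_trees >= 1L, features_per_split >= 1L,
            vote_threshold >= 0, vote_threshold <= 1)
  structure(list(n_trees = as.integer(n_trees),
                 features_per_split = as.integer(features_per_split),
                 bootstrap_fraction = 1.0,
                 split_criterion = "cross-entropy",
                 grow_to_purity = TRUE,
                 seed = as.integer(seed),
                 vote_threshold = vote_threshold),
            class = "fusion_config")
}

#' Cross-validation plan
#'
#' @param n_repeats repetitions of the whole fold split (default 5).
#' @param n_folds folds per repetition (default 10).
#' @param seed seed for fold assignment.
#' @return A `cv_plan` list (stratified folds are always used).
#' @export
cv_plan <- function(n_repeats = 5L, n_folds = 10L, seed = 1L) {
  stopifnot(n_repeats >= 1L, n_folds >= 2L)
  structure(list(n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds),
                 stratified = TRUE, seed = as.integer(seed)),
            class = "cv_plan")
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin, so per-fold class counts differ by at most one record.
stratified_folds <- function(labels, n_folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Train the fusion forest
#'
#' @param table a labeled [meta_table()].
#' @param features names of the meta-features to fuse (e.g. from
#'   [top_k()]); default all columns.
#' @param config a [fusion_config()].
#' @param noisy how to treat noisy-labeled training records: `"exclude"`
#'   (default, binary training) or `"non_afib"` (map them to the negative
#'   class).
#' @return A `fusion_forest` model object carrying the trees, the
#'   configuration, the encoding map and the selected feature names.
#' @export
train_fusion <- function(table, features = NULL, config = fusion_config(),
                         noisy = c("exclude", "non_afib")) {
  stopifnot(inherits(table, "meta_table"), inherits(config, "fusion_config"))
  noisy <- match.arg(noisy)
  if (is.null(table$labels)) stop("training table has no labels")
  if (is.null(features)) features <- names(table$features)
  tab <- subset_meta_table(table, cols = features)
  if (noisy == "exclude") {
    tab <- filter_for_ranking(tab)
  } else {
    tab$labels[tab$labels == NOISY] <- NON_AFIB
    tab$labels <- droplevels(tab$labels)
  }
  y <- as.integer(tab$labels == AFIB)
  if (length(unique(y)) < 2L)
    stop("training set has a single class")
  if (min(table(y)) < 2L)
    stop("need at least 2 records per class")
  enc <- encode_votes(tab)
  fit <- fit_forest(enc$matrix, y, ntree = config$n_trees,
                    mtry = config$features_per_split, seed = config$seed,
                    groups = enc$map$feature, importance = FALSE)
  structure(list(trees = fit$trees, config = config,
                 encoding = enc$map, features = features,
                 types = tab$types, oob_error = fit$oob_error),
            class = "fusion_forest")
}

#' @export
print.fusion_forest <- function(x, ...) {
  cat(sprintf(paste0("<fusion_forest> %d trees, %d feature(s) [%s], ",
                     "mtry=%d, seed=%d, OOB error %.4f\n"),
              length(x$trees), length(x$features),
              paste(utils::head(x$features, 5), collapse = ", "),
              x$config$features_per_split, x$config$seed, x$oob_error))
  invisible(x)
}

encode_for_model <- function(model, table) {
  stopifnot(inherits(table, "meta_table"))
  missing <- setdiff(model$features, names(table$features))
  if (length(missing))
    stop("table is missing selected feature(s): ",
         paste(missing, collapse = ", "))
  tab <- subset_meta_table(table, cols = model$features)
  enc <- encode_votes(tab)
  if (!identical(enc$map$column, model$encoding$column))
    stop("encoded columns (", paste(enc$map$column, collapse = ","),
         ") do not match the model's encoding map")
  enc$matrix
}

#' AFib vote-ratio probabilities
#'
#' Each of the trees casts one vote; the probability is the fraction of
#' trees voting AFib, so every value is an integer multiple of
#' `1/n_trees`.
#'
#' @param model a [train_fusion()] model.
#' @param table a [meta_table()] containing all selected features.
#' @return numeric vector of `p_afib`, named by record id.
#' @export
predict_proba <- function(model, table) {
  stopifnot(inherits(model, "fusion_forest"))
  X <- encode_for_model(model, table)
  p <- forest_proba(model$trees, X)
  names(p) <- table$record_id
  p
}

#' Majority-vote AFib calls
#'
#' @param model a [train_fusion()] model.
#' @param table a [meta_table()].
#' @param threshold call AFib when `p_afib >= threshold` (default: the
#'   model's `vote_threshold`, 0.5; the exact tie is called AFib).
#' @return factor of rhythm calls, named by record id.
#' @export
predict_label <- function(model, table, threshold = NULL) {
  if (is.null(threshold)) threshold <- model$config$vote_threshold
  p <- predict_proba(model, table)
  out <- factor(ifelse(p >= threshold, AFIB, NON_AFIB),
                levels = RHYTHM_LEVELS)
  names(out) <- names(p)
  out
}

#' @export
predict.fusion_forest <- function(object, newdata,
                                  type = c("prob", "label"), ...) {
  type <- match.arg(type)
  if (type == "prob") predict_proba(object, newdata)
  else predict_label(object, newdata, ...)
}

#' Choose how many top-ranked features to fuse
#'
#' Evaluates the fusion forest over a grid of k (number of top-ranked
#' features) under repeated stratified cross-validation and picks the
#' smallest k whose mean F1 is within one standard deviation of the best
#' mean F1 (one-SD parsimony rule: a plain argmax is unstable between
#' statistically indistinguishable k).
#'
#' @param table a labeled [meta_table()] (noisy records are excluded).
#' @param ranking a `ranking_result` from [permutation_importance()].
#' @param k_grid integer vector of candidate k values.
#' @param plan a [cv_plan()] (default 5 x 10 stratified).
#' @param config a [fusion_config()]; per-fold forests reuse its settings.
#' @return list with `k` (chosen), `grid` (`data.frame` of per-k mean and
#'   SD F1 across all folds).
#' @export
select_k <- function(table, ranking, k_grid, plan = cv_plan(),
                     config = fusion_config()) {
  stopifnot(inherits(ranking, "ranking_result"), inherits(plan, "cv_plan"))
  tab <- filter_for_ranking(table)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 1L) || any(k_grid > nrow(ranking)))
    stop("k_grid outside [1, ", nrow(ranking), "]")
  y <- tab$labels
  f1s <- matrix(NA_real_, nrow = plan$n_repeats * plan$n_folds,
                ncol = length(k_grid))
  row <- 0L
  for (rep in seq_len(plan$n_repeats)) {
    fold_seed <- plan$seed + 1000L * rep
    fold <- stratified_folds(y, plan$n_folds, fold_seed)
    tries <- 0L
    while (any(vapply(seq_len(plan$n_folds), function(f)
      length(unique(y[fold != f])) < 2L, logical(1))) && tries < 100L) {
      tries <- tries + 1L
      fold_seed <- fold_seed + 1L
      message("re-drawing folds (single-class fold), sub-seed ", fold_seed)
      fold <- stratified_folds(y, plan$n_folds, fold_seed)
    }
    for (f in seq_len(plan$n_folds)) {
      row <- row + 1L
      train <- subset_meta_table(tab, rows = which(fold != f))
      test <- subset_meta_table(tab, rows = which(fold == f))
      for (ki in seq_along(k_grid)) {
        feats <- top_k(ranking, k_grid[ki])
        cfg <- config
        cfg$seed <- config$seed + 17L * row
        model <- train_fusion(train, feats, cfg)
        pred <- predict_label(model, test)
        f1s[row, ki] <- f1_binary(test$labels, pred)
      }
    }
  }
  grid <- data.frame(k = k_grid,
                     mean_f1 = colMeans(f1s, na.rm = TRUE),
                     sd_f1 = apply(f1s, 2, stats::sd, na.rm = TRUE))
  best <- which.max(grid$mean_f1)
  ok <- grid$mean_f1 >= grid$mean_f1[best] - grid$sd_f1[best]
  list(k = grid$k[which(ok)[1L]], grid = grid)
}

# F1 with AFib positive; NA when undefined (no positive calls or labels).
f1_binary <- function(labels, predictions) {
  tp <- sum(labels == AFIB & predictions == AFIB)
  fp <- sum(labels != AFIB & predictions == AFIB)
  fn <- sum(labels == AFIB & predictions != AFIB)
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

# ---- persistence -----------------------------------------------------------

FUSION_FOREST_FORMAT <- "afcf-fusion-forest/1"

#' Save / load a fusion forest as portable JSON text
#'
#' The serialization stores the tree node arrays, the configuration, the
#' encoding map and the seed under a versioned format header.
#'
#' @param model a `fusion_forest`.
#' @param path file path.
#' @return `write_fusion_forest`: `path`, invisibly;
#'   `read_fusion_forest`: the restored `fusion_forest`.
#' @export
write_fusion_forest <- function(model, path) {
  stopifnot(inherits(model, "fusion_forest"))
  payload <- list(format = FUSION_FOREST_FORMAT,
                  config = unclass(model$config),
                  features = model$features,
                  types = as.list(model$types),
                  encoding = model$encoding,
                  oob_error = model$oob_error,
                  trees = model$trees)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fusion_forest
#' @export
read_fusion_forest <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, FUSION_FOREST_FORMAT))
    stop("unrecognized model format: ", payload$format)
  trees <- lapply(payload$trees, function(t) {
    list(feature = as.integer(unlist(t$feature)),
         threshold = as.numeric(unlist(t$threshold)),
         left = as.integer(unlist(t$left)),
         right = as.integer(unlist(t$right)),
         leaf_class = as.integer(unlist(t$leaf_class)))
  })
  cfg <- payload$config
  config <- fusion_config(cfg$n_trees, cfg$features_per_split, cfg$seed,
                          cfg$vote_threshold)
  enc <- payload$encoding
  encoding <- data.frame(
    column = vapply(enc, function(r) r$column, character(1)),
    feature = vapply(enc, function(r) r$feature, character(1)),
    kind = vapply(enc, function(r) r$kind, character(1)),
    stringsAsFactors = FALSE)
  structure(list(trees = trees, config = config,
                 encoding = encoding,
                 features = unlist(payload$features),
                 types = unlist(payload$types),
                 oob_error = payload$oob_error),
            class = "fusion_forest")
}
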
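#' @title Meta-feature ranking by out-of-bag permutation importance
#' @description
#' Ranks base-classifier votes and ECG features by how much each degrades
#' a random forest's out-of-bag error when its values are permuted: the
#' larger the increase, the more the forest relied on it.
#' @name ranking
NULL

#' Drop noisy-labeled records before ranking
#'
#' Ranking (and fusion training) operate on the binary AFib vs non-AFib
#' problem; records with the expert label `noisy` are removed.
#'
#' @param table a labeled [meta_table()].
#' @return a [meta_table()] with binary labels.
#' @export
filter_for_ranking <- function(table) {
  stopifnot(inherits(table, "meta_table"))
  if (is.null(table$labels)) stop("table has no labels")
  keep <- which(table$labels != NOISY)
  if (!length(keep)) stop("no records left after removing noisy labels")
  out <- subset_meta_table(table, rows = keep)
  out$labels <- droplevels(out$labels)
  out
}

#' Permutation-importance ranking of meta-features
#'
#' Fits one random forest on the encoded design matrix (features sampled
#' per split = `floor(sqrt(p))`, trees grown to purity on full-size
#' bootstraps, cross-entropy splits) and scores each meta-feature by
#' classic per-tree out-of-bag permutation importance: within every tree's
#' out-of-bag set, the feature's encoded column block is permuted and the
#' increase in that tree's error recorded; importance is the mean increase
#' over trees. A one-hot-encoded categorical vote is permuted jointly.
#'
#' @param table a [meta_table()] with binary (noisy-filtered) labels; see
#'   [filter_for_ranking()].
#' @param n_trees number of trees (default 500).
#' @param seed master seed; tree-growing and permutation streams are
#'   derived from it independently.
#' @return A `ranking_result`: `data.frame` with `rank`, `feature`,
#'   `importance` (mean OOB error increase), sorted descending, ties
#'   broken by feature name; attributes `oob_error`, `forest_config`,
#'   `seed`.
#' @export
permutation_importance <- function(table, n_trees = 500L, seed = 1L) {
  stopifnot(inherits(table, "meta_table"))
  if (is.null(table$labels)) stop("table has no labels")
  if (any(table$labels == NOISY))
    stop("noisy-labeled records present; run filter_for_ranking() first")
  if (ncol(table$features) < 2L)
    stop("ranking needs at least 2 features")
  enc <- encode_votes(table)
  y <- as.integer(table$labels == AFIB)
  mtry <- max(1L, floor(sqrt(ncol(enc$matrix))))
  fit <- fit_forest(enc$matrix, y, ntree = n_trees, mtry = mtry,
                    seed = seed, groups = enc$map$feature,
                    importance = TRUE)
  feats <- unique(enc$map$feature)
  imp <- fit$importance
  ord <- order(-imp, feats)
  out <- data.frame(rank = seq_along(feats), feature = feats[ord],
                    importance = imp[ord], stringsAsFactors = FALSE)
  structure(out,
            class = c("ranking_result", "data.frame"),
            oob_error = fit$oob_error,
            forest_config = list(n_trees = n_trees, mtry = mtry),
            seed = seed)
}

#' Top-k features of a ranking
#'
#' @param result a `ranking_result` from [permutation_importance()].
#' @param k how many top-ranked feature names to return.
#' @return character vector of `k` feature names in ranked order.
#' @export
top_k <- function(result, k) {
  stopifnot(inherits(result, "ranking_result"))
  if (k < 1L || k > nrow(result))
    stop("k must be in [1, ", nrow(result), "], got ", k)
  result$feature[seq_len(k)]
}

#' Write a ranking to CSV (`rank,feature,importance`)
#'
#' @param result a `ranking_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
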
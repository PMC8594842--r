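# Internal interface to the compiled forest. `groups` maps encoded design
# columns to meta-features so permutation importance permutes a one-hot
# vote pair as one unit; y is 0/1 with 1 = AFib (positive class).
fit_forest <- function(X, y, ntree, mtry, seed, groups = NULL,
                       importance = FALSE) {
  stopifnot(is.matrix(X), length(y) == nrow(X), all(y %in% c(0, 1)))
  if (is.null(groups)) groups <- seq_len(ncol(X))
  groups <- as.integer(factor(groups, levels = unique(groups)))
  fit <- .forest_fit(X, as.integer(y), as.integer(ntree), as.integer(mtry),
                     as.integer(seed), groups - 1L, importance)
  fit$group_levels <- unique(groups)
  fit
}

forest_proba <- function(fit_trees, X) {
  .forest_votes(fit_trees, X)
}
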
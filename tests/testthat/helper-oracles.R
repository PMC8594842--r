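# Independent brute-force oracles: deliberately naive O(n^2) double loops,
# sharing no code with the package implementations they check.

# sample-entropy template-match counts (Chebyshev distance, matches at
# d <= r, self-matches excluded, first n-m templates at both lengths)
oracle_sampen_counts <- function(x, m, r) {
  N <- length(x) - m
  A <- 0L; B <- 0L
  for (i in 1:(N - 1)) {
    for (j in (i + 1):N) {
      db <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (db <= r) {
        B <- B + 1L
        da <- max(abs(x[i:(i + m)] - x[j:(j + m)]))
        if (da <= r) A <- A + 1L
      }
    }
  }
  list(A = A, B = B)
}

oracle_cosen <- function(x, m = 1, r = 30) {
  cnt <- oracle_sampen_counts(x, m, r)
  -log(cnt$A / cnt$B) + log(2 * r) - log(mean(x))
}

# fuzzy-entropy membership mean at one template length, baseline-removed
# templates, exponential membership
oracle_fuzzy_phi <- function(u, m, r, n_exp) {
  N <- length(u) - m
  tot <- 0; npair <- 0
  for (i in 1:(N - 1)) {
    ti <- u[i:(i + m - 1)]; ti <- ti - mean(ti)
    for (j in (i + 1):N) {
      tj <- u[j:(j + m - 1)]; tj <- tj - mean(tj)
      d <- max(abs(ti - tj))
      tot <- tot + exp(-(d / r)^n_exp)
      npair <- npair + 1
    }
  }
  tot / npair
}

oracle_nfen <- function(x, m = 1, n_exp = 2) {
  u <- x / mean(x)
  r <- 0.2 * sd(u)
  -log(oracle_fuzzy_phi(u, m + 1, r, n_exp) /
         oracle_fuzzy_phi(u, m, r, n_exp))
}

# AUC as pairwise concordance P(s+ > s-) + 0.5 P(s+ = s-)
oracle_auc <- function(labels, scores) {
  pos <- scores[as.character(labels) == "AFib"]
  neg <- scores[as.character(labels) != "AFib"]
  tot <- 0
  for (sp in pos) for (sn in neg)
    tot <- tot + (sp > sn) + 0.5 * (sp == sn)
  tot / (length(pos) * length(neg))
}

# random labeled vote table for property tests
random_meta_table <- function(n, n_cat = 2, n_cont = 1, seed = 1) {
  set.seed(seed)
  feats <- list()
  for (j in seq_len(n_cat))
    feats[[paste0("v", j)]] <- sample(c("AFib", "non-AFib", "noisy"),
                                      n, replace = TRUE,
                                      prob = c(0.3, 0.6, 0.1))
  for (j in seq_len(n_cont))
    feats[[paste0("s", j)]] <- runif(n)
  meta_table(sprintf("r%03d", seq_len(n)),
             as.data.frame(feats, stringsAsFactors = FALSE),
             labels = sample(c("AFib", "non-AFib"), n, replace = TRUE))
}
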
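#' @title Synthetic RR-series and classifier-ensemble generators
#' @description
#' Seeded generators emulating the data shapes the pipeline consumes:
#' (a) 30-second RR-interval series of named rhythms — respiration-
#' modulated sinus rhythm versus serially uncorrelated fibrillatory
#' intervals — and (b) ensembles of correlated base-classifier votes with
#' a continuous scorer, with label distributions matching the study
#' datasets (training 2317 non-AFib / 137 AFib / 78 noisy of 2532; test
#' 777 AFib / 3867 non-AFib of 4644) when exact counts are requested.
#' All generators are deterministic under one seed.
#' @name synthetic
NULL

# run expr under a temporary RNG state seeded with `seed`; restores the
# caller's RNG so generators do not perturb the session stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Default per-rhythm generator parameters
#'
#' Mean RR of 800 ms (75 bpm) for sinus rhythm, modulated by respiration
#' (0.25 Hz, 30 ms amplitude) and by the slower baroreflex Mayer wave
#' (0.10 Hz, 50 ms) with 10 ms white jitter — both oscillations are
#' standard constituents of sinus heart-rate variability, and the slow
#' component is what makes consecutive sinus beats strongly correlated.
#' Fibrillatory rhythms are i.i.d. log-normal with coefficient of
#' variation 0.25 around 700 ms (slow AFib: 1100 ms, constrained under
#' 60 bpm).
#'
#' @param rhythm one of `"sinus"`, `"afib"`, `"slow_afib"`, `"noisy_afib"`.
#' @return list of generator parameters.
#' @export
rhythm_defaults <- function(rhythm = c("sinus", "afib", "slow_afib",
                                       "noisy_afib")) {
  rhythm <- match.arg(rhythm)
  switch(rhythm,
         sinus = list(mean_rr_ms = 800, resp_freq_hz = 0.25,
                      resp_amp_ms = 30, lf_freq_hz = 0.10,
                      lf_amp_ms = 50, jitter_ms = 10),
         afib = list(mean_rr_ms = 700, cv = 0.25),
         slow_afib = list(mean_rr_ms = 1100, cv = 0.25),
         noisy_afib = list(mean_rr_ms = 700, cv = 0.25,
                           corruption_rate = 0.05))
}

#' Generate a synthetic RR-interval series
#'
#' `sinus`: base RR plus sinusoidal respiratory and Mayer-wave
#' modulation plus small white jitter (serially correlated, regular). `afib`: i.i.d. log-normal
#' intervals with high coefficient of variation (irregularly irregular,
#' serially uncorrelated). `slow_afib`: fibrillatory intervals rescaled so
#' the ventricular rate (60000 / mean RR) stays below 60 bpm by
#' construction. `noisy_afib`: fibrillatory intervals corrupted by
#' spurious beat detections (one interval split in two) and missed beats
#' (two intervals merged) at the given per-beat rate.
#'
#' @param rhythm rhythm name, see [rhythm_defaults()].
#' @param duration_s record length in seconds (default 30, the typical
#'   handheld single-lead record length).
#' @param mean_rr_ms target mean RR; default per rhythm.
#' @param seed RNG seed.
#' @param record_id record identifier.
#' @param ... overrides for the rhythm's default parameters.
#' @return An [rr_series()].
#' @examples
#' gen_rr("afib", seed = 7)
#' @export
gen_rr <- function(rhythm = c("sinus", "afib", "slow_afib", "noisy_afib"),
                   duration_s = 30, mean_rr_ms = NULL, seed = NULL,
                   record_id = NULL, ...) {
  rhythm <- match.arg(rhythm)
  par <- utils::modifyList(rhythm_defaults(rhythm), list(...))
  if (!is.null(mean_rr_ms)) par$mean_rr_ms <- mean_rr_ms
  if (par$mean_rr_ms <= 0 || duration_s <= 0)
    stop("nonpositive generator parameters")
  if (is.null(record_id))
    record_id <- paste0(rhythm, if (is.null(seed)) "" else paste0("_", seed))
  x <- with_seed(seed, {
    if (rhythm == "sinus") {
      t_ms <- 0
      out <- numeric(0)
      while (t_ms < duration_s * 1000) {
        rr <- par$mean_rr_ms +
          par$resp_amp_ms * sin(2 * pi * par$resp_freq_hz * t_ms / 1000) +
          par$lf_amp_ms * sin(2 * pi * par$lf_freq_hz * t_ms / 1000) +
          stats::rnorm(1, 0, par$jitter_ms)
        rr <- max(rr, 200)
        out <- c(out, rr)
        t_ms <- t_ms + rr
      }
      out
    } else {
      sdlog <- sqrt(log(1 + par$cv^2))
      meanlog <- log(par$mean_rr_ms) - sdlog^2 / 2
      n_guess <- ceiling(duration_s * 1000 / par$mean_rr_ms * 2) + 8
      draws <- stats::rlnorm(n_guess, meanlog, sdlog)
      out <- draws[cumsum(draws) <= duration_s * 1000]
      if (length(out) < 4) out <- draws[1:4]
      if (rhythm == "slow_afib")
        out <- out * (par$mean_rr_ms / mean(out))
      if (rhythm == "noisy_afib" && par$corruption_rate > 0) {
        n <- length(out)
        hit <- which(stats::runif(n) < par$corruption_rate)
        for (i in rev(hit)) {
          if (stats::runif(1) < 0.5 && length(out) > 4) {
            # missed beat: merge with the neighbour
            j <- min(i, length(out) - 1)
            out <- c(out[seq_len(j - 1)], out[j] + out[j + 1],
                     out[-seq_len(j + 1)])
          } else {
            # spurious detection: split the interval
            u <- stats::runif(1, 0.4, 0.6)
            j <- min(i, length(out))
            out <- c(out[seq_len(j - 1)], out[j] * u, out[j] * (1 - u),
                     out[-seq_len(j)])
          }
        }
      }
      out
    }
  })
  rr_series(x, record_id)
}

#' Default skill profiles for the synthetic vote ensemble
#'
#' Six categorical voters with per-class correct-call probabilities in the
#' range of strong published AFib detectors (sensitivity 0.88-0.96,
#' specificity 0.94-0.97), plus one continuous scorer.
#'
#' @return `data.frame` with one row per categorical voter: `name`,
#'   `sensitivity`, `specificity`.
#' @export
default_voter_skills <- function() {
  data.frame(name = paste0("alg", 1:6),
             sensitivity = c(0.96, 0.92, 0.92, 0.91, 0.90, 0.88),
             specificity = c(0.95, 0.97, 0.96, 0.96, 0.94, 0.95),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic ensemble of correlated classifier votes
#'
#' Each record carries a latent difficulty `d` (uniform on \[0,1\]) shared
#' by all voters; voter correctness probability decreases in `d` (on the
#' logit scale, weighted by `difficulty_weight`) and increases in the
#' voter's per-class skill, which induces correlated errors across
#' voters. The continuous scorer draws from class-conditional Beta
#' distributions shrunk toward 0.5 on difficult records. Class counts are
#' honored exactly when given (so fixtures match a stated distribution
#' verbatim), and record order is shuffled.
#'
#' @param counts named integer vector `c(non_afib=, afib=, noisy=)`;
#'   default is the study training profile `c(2317, 137, 78)`.
#' @param skills voter skill table, see [default_voter_skills()].
#' @param difficulty_weight logit-scale weight of the shared latent
#'   difficulty (0 = independent voter errors; default 2).
#' @param score_shrink how strongly difficulty pulls the continuous score
#'   toward 0.5 (default 0.5).
#' @param noisy_vote_rate probability a categorical voter emits a `noisy`
#'   call regardless of rhythm (default 0).
#' @param seed RNG seed.
#' @return A labeled [meta_table()] with the categorical vote columns, a
#'   `kardia_score` column in \[0,1\], and an attribute `difficulty`.
#' @examples
#' tab <- gen_ensemble(counts = c(non_afib = 50, afib = 10, noisy = 2),
#'                     seed = 1)
#' table(tab$labels)
#' @export
gen_ensemble <- function(counts = c(non_afib = 2317, afib = 137, noisy = 78),
                         skills = default_voter_skills(),
                         difficulty_weight = 2,
                         score_shrink = 0.5,
                         noisy_vote_rate = 0,
                         seed = NULL) {
  stopifnot(all(c("non_afib", "afib") %in% names(counts)))
  if (!"noisy" %in% names(counts)) counts["noisy"] <- 0L
  counts <- counts[c("non_afib", "afib", "noisy")]
  if (any(counts < 0) || sum(counts) < 2) stop("infeasible class counts")
  n <- sum(counts)
  with_seed(seed, {
    labels <- sample(rep(c(NON_AFIB, AFIB, NOISY), times = counts))
    d <- stats::runif(n)
    feats <- list()
    for (v in seq_len(nrow(skills))) {
      acc <- ifelse(labels == AFIB, skills$sensitivity[v],
                    skills$specificity[v])
      p_correct <- stats::plogis(stats::qlogis(acc) -
                                   difficulty_weight * (d - 0.5))
      correct <- stats::runif(n) < p_correct
      vote <- ifelse(labels == AFIB,
                     ifelse(correct, AFIB, NON_AFIB),
                     ifelse(correct, NON_AFIB, AFIB))
      # a noisy-labeled record has no rhythm ground truth: the vote is an
      # even coin between the two rhythm calls
      is_noisy <- labels == NOISY
      vote[is_noisy] <- ifelse(stats::runif(sum(is_noisy)) < 0.5,
                               AFIB, NON_AFIB)
      if (noisy_vote_rate > 0) {
        flip <- stats::runif(n) < noisy_vote_rate
        vote[flip] <- NOISY
      }
      feats[[skills$name[v]]] <- vote
    }
    s <- numeric(n)
    s[labels == AFIB] <- stats::rbeta(sum(labels == AFIB), 8, 2)
    s[labels == NON_AFIB] <- stats::rbeta(sum(labels == NON_AFIB), 2, 8)
    s[labels == NOISY] <- stats::rbeta(sum(labels == NOISY), 2, 2)
    s <- 0.5 + (s - 0.5) * (1 - score_shrink * d)
    feats$kardia_score <- s
    tab <- meta_table(sprintf("rec%05d", seq_len(n)),
                      as.data.frame(feats, stringsAsFactors = FALSE),
                      labels = labels, score_cols = "kardia_score")
    attr(tab, "difficulty") <- d
    tab
  })
}

#' Generate the complementary-experts scenario
#'
#' Embodies the hypothesis that each strong base algorithm is best on a
#' different subset of patients: records are partitioned into
#' `n_voters` subpopulations and voter `j` calls records of subpopulation
#' `j` correctly with probability `p_local` (near-perfect) but only
#' `p_global` elsewhere. No single voter can excel overall, while a fusion
#' that learns when to trust whom can.
#'
#' @param n number of records (at least 700).
#' @param seed RNG seed.
#' @param n_voters number of complementary voters (default 7).
#' @param p_local,p_global correct-call probabilities on / off the
#'   voter's own subpopulation (defaults 0.98 / 0.70).
#' @param prevalence AFib fraction (default 0.5; counts are exact).
#' @return A labeled [meta_table()] of binary votes with attribute
#'   `subpopulation`.
#' @export
gen_complementary_experts <- function(n = 2000, seed = NULL, n_voters = 7,
                                      p_local = 0.98, p_global = 0.70,
                                      prevalence = 0.5) {
  if (n < 700) stop("n must be at least 700, got ", n)
  n_pos <- round(n * prevalence)
  with_seed(seed, {
    labels <- sample(rep(c(AFIB, NON_AFIB), times = c(n_pos, n - n_pos)))
    subpop <- sample(seq_len(n_voters), n, replace = TRUE)
    feats <- list()
    for (j in seq_len(n_voters)) {
      p <- ifelse(subpop == j, p_local, p_global)
      correct <- stats::runif(n) < p
      feats[[paste0("expert", j)]] <-
        ifelse(correct, labels,
               ifelse(labels == AFIB, NON_AFIB, AFIB))
    }
    tab <- meta_table(sprintf("rec%05d", seq_len(n)),
                      as.data.frame(feats, stringsAsFactors = FALSE),
                      labels = labels)
    attr(tab, "subpopulation") <- subpop
    tab
  })
}
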
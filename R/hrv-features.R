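#' @title Heart-rate-variability features from RR intervals
#' @description
#' The 24 meta-level ECG features used alongside base-classifier votes:
#' time-domain statistics, lag-k RMSSD/RMeSSD variants, Lomb-Scargle
#' spectral band powers, coefficient of sample entropy (COSEn), normalized
#' fuzzy entropy (NFEn), a 3-beat heart-rate dispersion statistic (MAD),
#' and a Lorenz-plot AF-evidence score (AFEv). Heart rate is defined per
#' beat as 60000 / RR_ms; standard deviations use the n-1 denominator.
#' @name hrv_features
NULL

# ---- time domain -----------------------------------------------------------

#' Time-domain HRV features
#'
#' @param rr an [rr_series()] (or a numeric vector of RR intervals, ms).
#' @return Named list with `mRR`, `minRR`, `maxRR` (ms), `SDNN` (ms, sample
#'   SD), `mHR`, `medHR` (bpm), `PNN50` (percent of successive-difference
#'   magnitudes exceeding 50 ms).
#' @examples
#' time_domain_features(rr_series(c(800, 860, 870, 1000)))$PNN50
#' @export
time_domain_features <- function(rr) {
  rr <- as_rr_series(rr)
  x <- rr$intervals
  if (length(x) < 3L)
    stop("PNN50 needs at least 3 intervals, got ", length(x))
  hr <- 60000 / x
  d <- diff(x)
  list(mRR = mean(x), minRR = min(x), maxRR = max(x),
       SDNN = stats::sd(x),
       mHR = mean(hr), medHR = stats::median(hr),
       PNN50 = 100 * sum(abs(d) > 50) / length(d))
}

#' Root mean/median squared lag-k RR differences
#'
#' `RMSSD1..3` take the root of the *mean* squared difference at lag 1
#' (successive), 2 (every other) or 3 (every third interval); `RMeSSD1..3`
#' take the root of the *median* squared difference.
#'
#' @param rr an [rr_series()] or numeric vector (ms).
#' @param lag difference lag, one of 1, 2, 3.
#' @param center `"mean"` (RMSSD) or `"median"` (RMeSSD).
#' @return Non-negative scalar, ms.
#' @export
rmssd_family <- function(rr, lag = 1L, center = c("mean", "median")) {
  center <- match.arg(center)
  if (!lag %in% 1:3) stop("lag must be 1, 2 or 3, got ", lag)
  rr <- as_rr_series(rr)
  x <- rr$intervals
  n <- length(x)
  if (n < lag + 1L)
    stop("RMSSD at lag ", lag, " needs at least ", lag + 1L, " intervals")
  d <- x[(1L + lag):n] - x[1L:(n - lag)]
  sqrt(if (center == "mean") mean(d^2) else stats::median(d^2))
}

# ---- spectral --------------------------------------------------------------

# Classical normalized Lomb periodogram of an unevenly sampled series.
# times in s, values arbitrary units; returns power at each frequency (Hz).
lomb_power <- function(times, values, freqs) {
  y <- values - mean(values)
  s2 <- stats::var(values)
  if (s2 == 0) return(rep(0, length(freqs)))
  vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * times)), sum(cos(2 * w * times))) / (2 * w)
    ct <- cos(w * (times - tau)); st <- sin(w * (times - tau))
    (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2)) / (2 * s2)
  }, numeric(1))
}

#' Spectral HRV features (Lomb-Scargle)
#'
#' Band powers of the unevenly sampled tachogram (RR against cumulative
#' onset time) from a classical Lomb-Scargle periodogram, so no
#' resampling of the RR series is needed. LF band 0.04-0.15 Hz, HF band
#' 0.15-0.40 Hz.
#'
#' @param rr an [rr_series()] or numeric vector (ms).
#' @param oversample frequency-grid oversampling factor (grid spacing
#'   `1/(oversample * span)`).
#' @return Named list with raw band powers `LF`, `HF`, normalized fractions
#'   `LFn`, `HFn` (summing to 1 when LF+HF > 0), ratio `LF_HF` (`NA` when
#'   HF is zero) and logical `reliable` (`FALSE` for series shorter than
#'   30 intervals or spanning under 60 s).
#' @export
spectral_features <- function(rr, oversample = 4) {
  rr <- as_rr_series(rr)
  x <- rr$intervals
  t <- rr$onset_times
  span <- t[length(t)] - t[1L]
  reliable <- length(x) >= 30L && span >= 60
  if (length(x) < 4L || span <= 0)
    return(list(LF = NA_real_, HF = NA_real_, LFn = NA_real_,
                HFn = NA_real_, LF_HF = NA_real_, reliable = FALSE))
  df <- 1 / (oversample * span)
  freqs <- seq(df, 0.5, by = df)
  p <- lomb_power(t, x, freqs)
  lf <- sum(p[freqs >= 0.04 & freqs < 0.15]) * df
  hf <- sum(p[freqs >= 0.15 & freqs <= 0.40]) * df
  tot <- lf + hf
  list(LF = lf, HF = hf,
       LFn = if (tot > 0) lf / tot else NA_real_,
       HFn = if (tot > 0) hf / tot else NA_real_,
       LF_HF = if (hf > 0) lf / hf else NA_real_,
       reliable = reliable)
}

# ---- entropies -------------------------------------------------------------

# Chebyshev-distance template match counts for sample entropy.
# Uses the first n-m templates at both lengths m and m+1 (Richman-Moorman),
# self-matches excluded, matches counted at distance <= r.
sampen_counts <- function(x, m, r) {
  n <- length(x)
  N <- n - m
  if (N < 2L) stop("sample entropy needs at least m + 2 intervals")
  dm <- matrix(0, N, N)
  for (k in 0:(m - 1L)) {
    v <- x[(1L + k):(N + k)]
    dm <- pmax(dm, abs(outer(v, v, "-")))
  }
  ut <- upper.tri(dm)
  B <- sum(dm[ut] <= r)
  v <- x[(1L + m):(N + m)]
  dm1 <- pmax(dm, abs(outer(v, v, "-")))
  A <- sum(dm1[ut] <= r)
  list(A = A, B = B)
}

#' Coefficient of sample entropy (COSEn)
#'
#' Sample entropy of the RR series plus `ln(2r) - ln(mean RR)`, the
#' correction that makes short-series entropy comparable across heart
#' rates (the standard formulation for AF screening on brief RR records).
#'
#' @param rr an [rr_series()] or numeric vector (ms).
#' @param m template (embedding) length; default 1.
#' @param r match tolerance in ms; default 30.
#' @return COSEn value; `NA` (with a warning naming the cause) when no
#'   template pairs match at either length, leaving SampEn undefined.
#' @export
cosen <- function(rr, m = 1L, r = 30) {
  rr <- as_rr_series(rr)
  x <- rr$intervals
  cnt <- sampen_counts(x, m, r)
  if (cnt$A == 0L || cnt$B == 0L) {
    warning("COSEn undefined: zero template matches (A=", cnt$A,
            ", B=", cnt$B, ") at r=", r)
    return(NA_real_)
  }
  -log(cnt$A / cnt$B) + log(2 * r) - log(mean(x))
}

# Mean fuzzy membership over template pairs at length m (baseline-removed
# templates, Chebyshev distance, exponential membership).
fuzzy_phi <- function(x, m, r, n_exp) {
  n <- length(x)
  N <- n - m
  tm <- sapply(0:(m - 1L), function(k) x[(1L + k):(N + k)])
  tm <- matrix(tm, nrow = N) - rowMeans(matrix(tm, nrow = N))
  dm <- matrix(0, N, N)
  for (k in seq_len(m)) dm <- pmax(dm, abs(outer(tm[, k], tm[, k], "-")))
  mean(exp(-(dm[upper.tri(dm)] / r)^n_exp))
}

#' Normalized fuzzy entropy (NFEn)
#'
#' Fuzzy entropy with exponential membership on the mean-normalized RR
#' series: the series is divided by its mean (removing scale), templates
#' are baseline-removed, and similarity is the soft membership
#' `exp(-(d/r)^n_exp)` of Chebyshev distances.
#'
#' @param rr an [rr_series()] or numeric vector (ms).
#' @param m template length; default 1.
#' @param r match tolerance on the normalized series; default
#'   `0.2 * sd(rr / mean(rr))`.
#' @param n_exp membership exponent; default 2.
#' @return NFEn value; `NA` (with warning) for a zero-variance series,
#'   where the default tolerance degenerates.
#' @export
nfen <- function(rr, m = 1L, r = NULL, n_exp = 2) {
  rr <- as_rr_series(rr)
  x <- rr$intervals
  if (length(x) < m + 2L) stop("NFEn needs at least m + 2 intervals")
  u <- x / mean(x)
  if (is.null(r)) r <- 0.2 * stats::sd(u)
  if (!is.finite(r) || r <= 0) {
    warning("NFEn undefined: degenerate (zero-variance) series")
    return(NA_real_)
  }
  phi_m <- fuzzy_phi(u, m, r, n_exp)
  phi_m1 <- fuzzy_phi(u, m + 1L, r, n_exp)
  if (phi_m <= 0 || phi_m1 <= 0) {
    warning("NFEn undefined: vanishing membership sums")
    return(NA_real_)
  }
  -log(phi_m1 / phi_m)
}

# ---- MAD -------------------------------------------------------------------

#' Heart-rate dispersion over 3-beat windows (MAD)
#'
#' Over windows of three adjacent RR intervals, computes the sample
#' standard deviation of the per-beat heart rate (60000/RR, bpm) within
#' each window; MAD is the median of these window SDs.
#'
#' @param rr an [rr_series()] or numeric vector (ms); at least 5 intervals.
#' @param sliding windows slide by one beat (default); `FALSE` uses
#'   disjoint (non-overlapping) triples.
#' @return MAD in bpm.
#' @export
mad_feature <- function(rr, sliding = TRUE) {
  rr <- as_rr_series(rr)
  x <- rr$intervals
  n <- length(x)
  if (n < 5L) stop("MAD needs at least 5 intervals, got ", n)
  hr <- 60000 / x
  starts <- if (sliding) 1L:(n - 2L) else seq(1L, n - 2L, by = 3L)
  sds <- vapply(starts, function(i) stats::sd(hr[i:(i + 2L)]), numeric(1))
  stats::median(sds)
}

# ---- AF evidence (Lorenz plot) --------------------------------------------

# Segment mask constants for the delta-RR Lorenz plot, 40 ms quantization.
AFEV_BIN_MS <- 40
AFEV_ORIGIN_MS <- 80

#' Lorenz-plot AF evidence (AFEv)
#'
#' Integer irregularity score from the 2-D histogram of successive
#' RR-difference pairs (dRR_i, dRR_{i-1}), quantized to 40 ms bins.
#' Scattered occupancy away from the origin is evidence of fibrillatory
#' irregularity; a dense origin cluster indicates a regular rhythm; bins in
#' the opposite-sign near-antidiagonal zone carry the alternating
#' short-long signature of ectopy (PAC/bigeminy) and are penalized:
#'
#' `AFEv = IrregularityEvidence - OriginCount - 2 * PACEvidence`
#'
#' where IrregularityEvidence counts distinct occupied non-origin bins,
#' OriginCount counts *points* in the origin zone (|dRR| < 80 ms on both
#' axes) and PACEvidence counts distinct occupied ectopy-zone bins.
#'
#' @param rr an [rr_series()] or numeric vector (ms); at least 4 intervals.
#' @return Integer AFEv score.
#' @export
af_evidence <- function(rr) {
  rr <- as_rr_series(rr)
  x <- rr$intervals
  if (length(x) < 4L) stop("AFEv needs at least 4 intervals")
  d <- diff(x)
  dx <- d[-1L]                      # dRR_i
  dy <- d[-length(d)]               # dRR_{i-1}
  origin <- abs(dx) < AFEV_ORIGIN_MS & abs(dy) < AFEV_ORIGIN_MS
  bx <- round(dx / AFEV_BIN_MS)
  by <- round(dy / AFEV_BIN_MS)
  origin_count <- sum(origin)
  if (all(origin)) return(-origin_count)
  obx <- bx[!origin]; oby <- by[!origin]
  bins <- unique(paste(obx, oby))
  pac_bin <- function(b) {
    xy <- as.integer(strsplit(b, " ", fixed = TRUE)[[1L]])
    (sign(xy[1L]) * sign(xy[2L]) < 0) && abs(abs(xy[1L]) - abs(xy[2L])) <= 1L
  }
  pac <- sum(vapply(bins, pac_bin, logical(1)))
  as.integer(length(bins) - origin_count - 2L * pac)
}

# ---- full vector -----------------------------------------------------------

FEATURE_NAMES_LI <- c("mRR", "minRR", "maxRR", "medHR", "SDNN", "PNN50",
                      "RMSSD", "LF", "HF", "LF_HF", "COSEn1", "NFEn",
                      "MAD", "AFEv")
FEATURE_NAMES_KARDIA <- c("RMSSD1", "RMSSD2", "RMSSD3", "RMeSSD1",
                          "RMeSSD2", "RMeSSD3", "mHR", "COSEn2",
                          "CNNout", "RNNout")

#' Extract the full 24-feature vector from one RR series
#'
#' Computes all 22 RR-derived features; the two trained-network outputs
#' (`CNNout`, `RNNout`) cannot be derived from RR intervals and are
#' stand-ins: absent (`NA`) unless supplied. A feature whose own
#' preconditions fail yields `NA` for that feature only; the rest of the
#' vector is still populated. The same-named Li and Kardia features are
#' computed on the same RR stream here, so `RMSSD == RMSSD1` and
#' `COSEn1 == COSEn2` (in the original setting they differed only through
#' different upstream QRS detectors). `LF`/`HF` report the normalized band
#' fractions; raw powers are available from [spectral_features()].
#'
#' @param rr an [rr_series()] or numeric vector (ms).
#' @param include_stand_ins include `CNNout`/`RNNout` columns.
#' @param cnn_out,rnn_out optional stand-in values for the network outputs.
#' @return One-row `data.frame` with a `record_id` column plus 22 or 24
#'   feature columns.
#' @export
extract_all <- function(rr, include_stand_ins = FALSE,
                        cnn_out = NA_real_, rnn_out = NA_real_) {
  rr <- as_rr_series(rr)
  grab <- function(expr) tryCatch(suppressWarnings(expr),
                                  error = function(e) NA_real_)
  td <- grab(time_domain_features(rr))
  if (!is.list(td)) td <- as.list(rep(NA_real_, 7))
  names(td) <- c("mRR", "minRR", "maxRR", "SDNN", "mHR", "medHR", "PNN50")
  sp <- grab(spectral_features(rr))
  if (!is.list(sp)) sp <- list(LFn = NA_real_, HFn = NA_real_,
                               LF_HF = NA_real_)
  r1 <- grab(rmssd_family(rr, 1L, "mean"))
  out <- data.frame(
    record_id = rr$record_id,
    mRR = td$mRR, minRR = td$minRR, maxRR = td$maxRR, medHR = td$medHR,
    SDNN = td$SDNN, PNN50 = td$PNN50,
    RMSSD = r1,
    LF = sp$LFn, HF = sp$HFn, LF_HF = sp$LF_HF,
    COSEn1 = grab(cosen(rr)),
    NFEn = grab(nfen(rr)),
    MAD = grab(mad_feature(rr)),
    AFEv = grab(af_evidence(rr)),
    RMSSD1 = r1,
    RMSSD2 = grab(rmssd_family(rr, 2L, "mean")),
    RMSSD3 = grab(rmssd_family(rr, 3L, "mean")),
    RMeSSD1 = grab(rmssd_family(rr, 1L, "median")),
    RMeSSD2 = grab(rmssd_family(rr, 2L, "median")),
    RMeSSD3 = grab(rmssd_family(rr, 3L, "median")),
    mHR = td$mHR,
    COSEn2 = grab(cosen(rr)),
    stringsAsFactors = FALSE)
  if (include_stand_ins) {
    out$CNNout <- as.numeric(cnn_out)
    out$RNNout <- as.numeric(rnn_out)
  }
  out
}

#' Feature table for a list of RR series
#'
#' @param rr_list list of [rr_series()] objects.
#' @param ... passed to [extract_all()].
#' @return `data.frame`, one row per record.
#' @export
extract_features <- function(rr_list, ...) {
  do.call(rbind, lapply(rr_list, extract_all, ...))
}
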
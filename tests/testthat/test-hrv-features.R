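test_that("time-domain features match hand-computed values", {
  # constant series
  td <- time_domain_features(rr_series(rep(1000, 3)))
  expect_equal(td$mRR, 1000)
  expect_equal(td$SDNN, 0)
  expect_equal(td$mHR, 60)
  expect_equal(td$PNN50, 0)

  # successive differences 60, 10, 130 -> two of three exceed 50 ms
  td <- time_domain_features(rr_series(c(800, 860, 870, 1000)))
  expect_equal(td$PNN50, 100 * 2 / 3)

  td <- time_domain_features(rr_series(c(722, 855, 800)))
  expect_equal(td$minRR, 722)
  expect_equal(td$maxRR, 855)
  expect_equal(mean(c(722, 855)), 788.5)  # two-beat mean is plain arithmetic
  expect_equal(td$mRR, mean(c(722, 855, 800)))

  expect_error(time_domain_features(rr_series(c(800, 900))), "PNN50")
})

test_that("RMSSD family matches hand computation and validates lag", {
  x <- c(800, 850, 800, 850)
  expect_equal(rmssd_family(x, 1, "mean"), 50)    # diffs 50,-50,50
  expect_equal(rmssd_family(x, 2, "mean"), 0)     # diffs 0,0
  expect_equal(rmssd_family(x, 1, "median"), 50)
  for (lag in 1:3)
    for (ctr in c("mean", "median"))
      expect_equal(rmssd_family(rep(700, 10), lag, ctr), 0)
  expect_error(rmssd_family(x, 4), "lag")
  expect_error(rmssd_family(c(800, 900), 2), "at least 3")
})

test_that("spectral band powers localize sinusoidal modulation", {
  mk <- function(f) {
    t <- 0; out <- numeric(0)
    while (t < 120000) {
      rr <- 1000 + 50 * sin(2 * pi * f * t / 1000)
      out <- c(out, rr); t <- t + rr
    }
    rr_series(out)
  }
  lf_mod <- spectral_features(mk(0.10))
  hf_mod <- spectral_features(mk(0.30))
  expect_gt(lf_mod$LF_HF, 1)
  expect_lt(hf_mod$LF_HF, 1)
  expect_true(lf_mod$reliable)

  set.seed(11)
  noise <- rr_series(runif(300, 700, 1300))
  sp <- spectral_features(noise)
  expect_equal(sp$LFn + sp$HFn, 1, tolerance = 1e-9)
  expect_gte(sp$LF, 0)
  expect_gte(sp$HF, 0)

  # zero-variance tachogram: no band power, ratio is the NA sentinel
  flat <- spectral_features(rr_series(rep(1000, 40)))
  expect_true(is.na(flat$LF_HF))
})

test_that("COSEn matches its closed form and the brute-force oracle", {
  # constant series: all templates match, SampEn = 0
  expect_equal(cosen(rep(1000, 30)), log(60) - log(1000), tolerance = 1e-12)

  # scale invariance of matching when r scales with the series
  set.seed(3)
  x <- runif(80, 500, 1100)
  s1 <- afcf:::sampen_counts(x, 1, 30)
  s2 <- afcf:::sampen_counts(3 * x, 1, 90)
  expect_identical(s1, s2)

  # 40-beat alternans and random series against the O(n^2) oracle
  alt <- rep(c(800, 400), 20)
  expect_equal(cosen(alt), oracle_cosen(alt), tolerance = 1e-12)
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(20:200, 1)
    x <- runif(n, 400, 1200)
    expect_equal(cosen(x), oracle_cosen(x), tolerance = 1e-12)
  }
})

test_that("COSEn is the NA sentinel when no templates match", {
  # strictly increasing with huge steps: no pair within 30 ms
  x <- seq(400, by = 200, length.out = 12)
  expect_warning(v <- cosen(x), "undefined")
  expect_true(is.na(v))
})

test_that("NFEn is scale-invariant and matches the brute-force oracle", {
  set.seed(9)
  x <- runif(30, 500, 1100)
  expect_equal(nfen(x), nfen(7 * x), tolerance = 1e-12)
  expect_equal(nfen(x), oracle_nfen(x), tolerance = 1e-12)
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(20:200, 1)
    x <- runif(n, 400, 1200)
    expect_equal(nfen(x), oracle_nfen(x), tolerance = 1e-12)
  }
  expect_warning(v <- nfen(rep(800, 20)), "degenerate")
  expect_true(is.na(v))
})

test_that("MAD matches the all-windows hand computation", {
  expect_equal(mad_feature(rep(1000, 10)), 0)
  # HR 100,100,100,200,200,200: window SDs {0, 57.735, 57.735, 0}
  x <- c(600, 600, 600, 300, 300, 300)
  expect_equal(mad_feature(x), median(c(0, sd(c(100, 100, 200)),
                                        sd(c(100, 200, 200)), 0)),
               tolerance = 1e-9)
  expect_equal(mad_feature(x), 28.8675, tolerance = 1e-4)
  # disjoint windows: only {0, 0}
  expect_equal(mad_feature(x, sliding = FALSE), 0)
  expect_error(mad_feature(c(800, 900, 1000, 900)), "at least 5")
})

test_that("AFEv separates irregular from origin-dominated series", {
  # constant: every point in the origin zone
  expect_lte(af_evidence(rep(800, 32)), 0)
  expect_equal(af_evidence(rep(800, 32)), -30)  # 30 delta pairs at origin

  # irregular beats sinus in >= 95% of paired seeds
  wins <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    irr <- rr_series(runif(60, 400, 1200))
    sin_rr <- gen_rr("sinus", duration_s = 48, seed = seed)
    sin_rr <- rr_series(sin_rr$intervals[1:60])
    if (af_evidence(irr) > af_evidence(sin_rr)) wins <- wins + 1L
  }
  expect_gte(wins, 95)

  # bigeminy-like alternation occupies the ectopy zone, which is
  # penalized relative to plain irregularity evidence
  big <- rep(c(800, 400), 20)
  d <- diff(big)
  n_bins <- length(unique(paste(round(d[-1] / 40), round(d[-length(d)] / 40))))
  expect_lt(af_evidence(big), n_bins)
  expect_lt(af_evidence(big), 0)
})

test_that("extract_all populates the vector and degrades per feature", {
  v <- extract_all(rr_series(rep(1000, 60), "const"))
  expect_equal(v$SDNN, 0)
  expect_equal(v$PNN50, 0)
  expect_equal(v$RMSSD1, 0)
  expect_equal(v$RMSSD2, 0)
  expect_equal(v$RMeSSD3, 0)
  expect_equal(v$MAD, 0)
  expect_true(is.na(v$NFEn))  # degenerate, sentinel not an abort

  # same-stream identity between same-named Li and Kardia features
  rr <- gen_rr("afib", seed = 21)
  v <- extract_all(rr)
  expect_identical(v$RMSSD, v$RMSSD1)
  expect_identical(v$COSEn1, v$COSEn2)

  # stand-ins only on request
  expect_false("CNNout" %in% names(v))
  v2 <- extract_all(rr, include_stand_ins = TRUE, cnn_out = 0.7)
  expect_equal(v2$CNNout, 0.7)
  expect_true(is.na(v2$RNNout))
})

test_that("AFib series score higher than sinus on discriminative features", {
  d_cosen <- d_afev <- d_rmssd <- numeric(100)
  for (seed in 1:100) {
    a <- gen_rr("afib", seed = seed)
    s <- gen_rr("sinus", seed = seed)
    d_cosen[seed] <- cosen(a) - cosen(s)
    d_afev[seed] <- af_evidence(a) - af_evidence(s)
    d_rmssd[seed] <- rmssd_family(a) - rmssd_family(s)
  }
  expect_gt(median(d_cosen), 0)
  expect_gt(median(d_afev), 0)
  expect_gt(median(d_rmssd), 0)
})

test_that("features are scale-equivariant and shift-invariant", {
  for (seed in 1:20) {
    set.seed(seed)
    x <- runif(sample(30:80, 1), 500, 1100)
    c_ <- runif(1, 0.5, 3)
    td1 <- time_domain_features(x)
    td2 <- time_domain_features(c_ * x)
    expect_equal(td2$mRR, c_ * td1$mRR)
    expect_equal(td2$minRR, c_ * td1$minRR)
    expect_equal(td2$maxRR, c_ * td1$maxRR)
    expect_equal(td2$SDNN, c_ * td1$SDNN)
    expect_equal(td2$mHR, td1$mHR / c_)
    expect_equal(td2$medHR, td1$medHR / c_)
    expect_equal(rmssd_family(c_ * x, 2), c_ * rmssd_family(x, 2))
    expect_equal(nfen(c_ * x), nfen(x), tolerance = 1e-10)
  }
  # features depend only on the interval sequence (constructor carries no
  # absolute start time), so identical intervals give identical features
  expect_identical(extract_all(rr_series(c(800, 900, 850, 820, 790), "a"))[-1],
                   extract_all(rr_series(c(800, 900, 850, 820, 790), "b"))[-1])
})
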
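test_that("CinC label fusion maps the 4-symbol vocabulary", {
  expect_equal(as.character(fuse_cinc_labels("Normal")), "non-AFib")
  expect_equal(as.character(fuse_cinc_labels("Other")), "non-AFib")
  expect_equal(as.character(fuse_cinc_labels("AFib")), "AFib")
  expect_equal(as.character(fuse_cinc_labels("Noisy")), "noisy")
  expect_equal(as.character(fuse_cinc_labels(c("normal", "OTHER"))),
               c("non-AFib", "non-AFib"))
  expect_error(fuse_cinc_labels(c("Normal", "Sinus")), "Sinus")
})

test_that("rhythm label parsing accepts variants and rejects ambiguity", {
  expect_equal(as.character(parse_rhythm_label(c("AFIB", "non_afib",
                                                 "NonAFib", "NOISY"))),
               c("AFib", "non-AFib", "non-AFib", "noisy"))
  expect_error(parse_rhythm_label("A"), "'A'")
  expect_error(parse_rhythm_label("~"), "~")
  expect_error(parse_rhythm_label("N+O"))
})

test_that("vote encoding expands categoricals to indicator pairs", {
  tab <- meta_table(c("a", "b", "c"),
                    data.frame(v = c("AFib", "non-AFib", "noisy"),
                               s = c(0.9, 0.2, 0.5),
                               stringsAsFactors = FALSE),
                    score_cols = "s")
  enc <- encode_votes(tab)
  expect_equal(dim(enc$matrix), c(3, 3))
  expect_equal(unname(enc$matrix[, "v.is_afib"]), c(1, 0, 0))
  expect_equal(unname(enc$matrix[, "v.is_noisy"]), c(0, 0, 1))
  expect_equal(unname(enc$matrix[, "s"]), c(0.9, 0.2, 0.5))
  # 2 per categorical + 1 per continuous, always
  expect_equal(ncol(enc$matrix),
               2 * sum(tab$types == "categorical") +
                 sum(tab$types == "continuous"))
})

test_that("encode/decode round-trips random tables", {
  for (seed in 1:10) {
    tab <- random_meta_table(30, n_cat = 3, n_cont = 2, seed = seed)
    dec <- decode_votes(encode_votes(tab))
    for (nm in names(tab$features)) {
      if (tab$types[[nm]] == "categorical")
        expect_equal(as.character(dec[[nm]]),
                     as.character(tab$features[[nm]]))
      else expect_equal(dec[[nm]], tab$features[[nm]])
    }
  }
})

test_that("encoding refuses missing cells, naming the record", {
  tab <- random_meta_table(5, seed = 1)
  tab$features$s1[3] <- NA
  expect_error(encode_votes(tab), "r003")
})

test_that("meta-table validation catches duplicates and bad scores", {
  expect_error(meta_table(c("a", "a"),
                          data.frame(s = c(0.1, 0.2))), "duplicate")
  expect_error(meta_table(c("a", "b"),
                          data.frame(s = c(0.1, 1.2)),
                          score_cols = "s"), "outside")
})

test_that("labels/votes/predictions files round-trip through CSV", {
  labels <- data.frame(record_id = c("r1", "r2", "r3"),
                       label = c("AFib", "non-AFib", "noisy"),
                       stringsAsFactors = FALSE)
  votes <- data.frame(record_id = c("r1", "r2", "r3"),
                      alg1 = c("AFib", "non-AFib", "AFib"),
                      kardia_score = c(0.91, 0.05, 0.66),
                      stringsAsFactors = FALSE)
  preds <- data.frame(record_id = c("r1", "r2", "r3"),
                      p_afib = c(0.9, 0.1, 0.6),
                      predicted_label = c("AFib", "non-AFib", "AFib"),
                      stringsAsFactors = FALSE)
  lf <- tempfile(fileext = ".csv"); vf <- tempfile(fileext = ".csv")
  pf <- tempfile(fileext = ".csv")
  write.csv(labels, lf, row.names = FALSE, quote = FALSE)
  write.csv(votes, vf, row.names = FALSE, quote = FALSE)
  write_predictions(preds, pf)

  l2 <- read_labels(lf)
  expect_equal(as.character(l2$label), labels$label)
  v2 <- read_votes(vf)
  expect_equal(as.character(v2$alg1), votes$alg1)
  expect_equal(v2$kardia_score, votes$kardia_score)
  p2 <- read_predictions(pf)
  expect_equal(p2$p_afib, preds$p_afib)

  # meta-table write -> read is identity
  tab <- build_meta_table(v2, l2)
  vf2 <- tempfile(fileext = ".csv"); lf2 <- tempfile(fileext = ".csv")
  write_meta_table(tab, vf2, lf2)
  tab2 <- build_meta_table(read_votes(vf2), read_labels(lf2))
  expect_equal(tab2$features, tab$features)
  expect_equal(tab2$labels, tab$labels)
})

test_that("readers reject duplicated ids and out-of-range scores", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("record_id,label", "r1,AFib", "r1,noisy"), f)
  expect_error(read_labels(f), "r1")
  writeLines(c("record_id,p_afib,predicted_label", "r1,1.4,AFib"), f)
  expect_error(read_predictions(f), "0,1")
})

test_that("positional header mapping warns when names differ", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("id,rhythm", "r1,AFib"), f)
  expect_warning(l <- read_labels(f), "position")
  expect_equal(as.character(l$label), "AFib")
})

test_that("strict join rejects and lenient join drops unmatched records", {
  labels <- data.frame(record_id = c("r1", "r2", "r3", "r4"),
                       label = rep("non-AFib", 4), stringsAsFactors = FALSE)
  labels$label[1] <- "AFib"
  votes <- data.frame(record_id = c("r1", "r2", "r3"),
                      alg1 = c("AFib", "non-AFib", "non-AFib"),
                      stringsAsFactors = FALSE)
  l <- data.frame(record_id = labels$record_id,
                  label = parse_rhythm_label(labels$label),
                  stringsAsFactors = FALSE)
  expect_error(build_meta_table(votes, l, strict = TRUE), "r4")
  expect_message(tab <- build_meta_table(votes, l, strict = FALSE),
                 "dropped")
  expect_equal(length(tab$record_id), 3)
})
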
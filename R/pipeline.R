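#' @title End-to-end pipeline
#' @description
#' Wires every stage together: ingest or simulate the meta-table, rank the
#' meta-features, choose how many to fuse, train the fusion forest,
#' predict the test records, evaluate, and compute the screening burden.
#' Every stage's output is persisted to the artifact directory along with
#' a manifest (seeds, versions, artifact hashes).
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' Settings mirror the study defaults: 500-tree fusion forest with one
#' feature per split, noisy records excluded from ranking/training, seven
#' fused meta-features, 5x10 stratified cross-validation when k is chosen
#' from a grid, and a screening scenario of 100,000 ECGs/day at 0.5%
#' prevalence. Synthetic train/test ensembles follow the study's class
#' distributions.
#'
#' @param out_dir artifact directory.
#' @param seed master seed.
#' @return config list for [run_pipeline()].
#' @export
default_config <- function(out_dir = tempfile("afcf_run_"), seed = 1L) {
  list(out_dir = out_dir,
       seed = as.integer(seed),
       n_trees = 500L,
       features_per_split = 1L,
       k = 7L,
       k_grid = NULL,
       cv = list(n_repeats = 5L, n_folds = 10L),
       train = list(counts = c(non_afib = 2317, afib = 137, noisy = 78)),
       test = list(counts = c(non_afib = 3867, afib = 777, noisy = 0)),
       workload = list(volume_per_day = 100000L, prevalence = "0.5%"))
}

load_config <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  base <- default_config()
  cfg <- utils::modifyList(base, config)
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  cfg
}

load_table <- function(spec, seed) {
  if (!is.null(spec$votes)) {
    votes <- read_votes(spec$votes)
    labels <- if (!is.null(spec$labels)) read_labels(spec$labels)
    build_meta_table(votes, labels,
                     strict = is.null(spec$lenient) || !spec$lenient)
  } else if (!is.null(spec$counts)) {
    gen_ensemble(counts = unlist(spec$counts), seed = seed)
  } else {
    stop("table spec needs either file paths (votes/labels) or synthetic counts")
  }
}

#' Run the full fusion pipeline
#'
#' @param config a config list (see [default_config()]) or path to a YAML
#'   file with the same keys. `train`/`test` are either synthetic specs
#'   (`counts`) or file paths (`votes`, `labels`).
#' @return Invisibly, a list with the in-memory stage results (`ranking`,
#'   `model`, `predictions`, `report`, `workload`, `manifest`) and
#'   `out_dir`. On any stage failure, partially written artifacts are
#'   removed and the error names the failing stage.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(path) {
    written <<- c(written, path)
    path
  }
  stage <- "setup"
  result <- tryCatch({
    stage <- "ingest"
    train <- load_table(cfg$train, seed = cfg$seed)
    test <- load_table(cfg$test, seed = cfg$seed + 1L)

    stage <- "rank"
    train_bin <- filter_for_ranking(train)
    ranking <- permutation_importance(train_bin, n_trees = cfg$n_trees,
                                      seed = cfg$seed)
    write_ranking(ranking, emit(file.path(cfg$out_dir, "ranking.csv")))

    stage <- "select_k"
    if (!is.null(cfg$k_grid)) {
      sel <- select_k(train, ranking, cfg$k_grid,
                      plan = cv_plan(cfg$cv$n_repeats, cfg$cv$n_folds,
                                     seed = cfg$seed),
                      config = fusion_config(cfg$n_trees,
                                             cfg$features_per_split,
                                             seed = cfg$seed))
      k <- sel$k
      utils::write.csv(sel$grid,
                       emit(file.path(cfg$out_dir, "selection.csv")),
                       row.names = FALSE)
    } else {
      k <- min(cfg$k, nrow(ranking))
    }

    stage <- "train"
    model <- train_fusion(train, top_k(ranking, k),
                          fusion_config(cfg$n_trees, cfg$features_per_split,
                                        seed = cfg$seed))
    write_fusion_forest(model, emit(file.path(cfg$out_dir, "model.json")))

    stage <- "predict"
    p <- predict_proba(model, test)
    calls <- predict_label(model, test)
    preds <- data.frame(record_id = test$record_id, p_afib = p,
                        predicted_label = calls, stringsAsFactors = FALSE)
    write_predictions(preds, emit(file.path(cfg$out_dir, "preds.csv")))

    stage <- "evaluate"
    keep <- if (is.null(test$labels)) integer(0) else
      which(test$labels != NOISY)
    if (!length(keep)) stop("test table has no binary-labeled records")
    truth <- droplevels(test$labels[keep])
    cm <- confusion(truth, calls[keep])
    m <- metrics(cm)
    roc <- roc_auc(truth, p[keep])
    report <- list(counts = unclass(cm)[c("tp", "fn", "fp", "tn")],
                   metrics = unclass(m)[c("sensitivity", "specificity",
                                          "ppv", "npv", "f1", "fpr",
                                          "fnr")],
                   auc = roc$auc, roc_points = roc$points)
    jsonlite::write_json(report,
                         emit(file.path(cfg$out_dir, "report.json")),
                         auto_unbox = TRUE, digits = NA)

    stage <- "workload"
    voters <- names(test$features)[
      vapply(test$features, function(c) !is.numeric(c), logical(1))]
    best <- NULL
    for (v in voters) {
      votes <- test$features[[v]][keep]
      if (any(votes == NOISY)) votes[votes == NOISY] <- NON_AFIB
      vm <- metrics(confusion(truth, votes))
      if (is.null(best) || (!is.na(vm$f1) &&
                            (is.na(best$f1) || vm$f1 > best$f1)))
        best <- list(name = v, f1 = vm$f1, fpr = vm$fpr, fnr = vm$fnr)
    }
    wl <- compare_workload(
      scenario(cfg$workload$volume_per_day, cfg$workload$prevalence),
      rates_a = list(fpr = m$fpr, fnr = m$fnr),
      rates_b = list(fpr = best$fpr, fnr = best$fnr))
    jsonlite::write_json(
      list(scenario = unclass(wl$scenario),
           fusion = wl$a, best_single = c(list(name = best$name), wl$b),
           delta_fp = wl$delta_fp, delta_fn = wl$delta_fn),
      emit(file.path(cfg$out_dir, "workload.json")),
      auto_unbox = TRUE, digits = NA)

    stage <- "manifest"
    manifest <- list(
      package = "afcf",
      version = as.character(utils::packageVersion("afcf")),
      seed = cfg$seed,
      k = k,
      config = cfg[setdiff(names(cfg), "out_dir")],
      artifacts = as.list(tools::md5sum(sort(written))))
    jsonlite::write_json(manifest,
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)

    list(ranking = ranking, model = model, predictions = preds,
         report = report, workload = wl, manifest = manifest,
         out_dir = cfg$out_dir)
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}
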
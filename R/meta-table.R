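#' @title Meta-level feature table
#' @description
#' The records-by-meta-features table consumed by ranking and fusion:
#' categorical rhythm votes of base classifiers, continuous scores in
#' \[0,1\], numeric ECG features, and an optional expert label per record.
#' @name meta_table
NULL

#' Parse rhythm labels
#'
#' Case-insensitive parsing into the closed vocabulary
#' `{"AFib", "non-AFib", "noisy"}`. Common unambiguous variants
#' (`"afib"`, `"non_afib"`, `"nonafib"`, `"non afib"`) are accepted;
#' ambiguous shorthands (`"A"`, `"N+O"`, `"~"`) are rejected.
#'
#' @param x character vector.
#' @return factor with levels `AFib`, `non-AFib`, `noisy`.
#' @export
parse_rhythm_label <- function(x) {
  key <- gsub("[ _-]", "", tolower(as.character(x)))
  map <- c(afib = AFIB, nonafib = NON_AFIB, noisy = NOISY)
  out <- unname(map[key])
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop("unparseable rhythm label(s): ",
         paste0("'", unique(x[bad]), "'", collapse = ", "),
         " (first at row ", bad[1L], ")")
  factor(out, levels = RHYTHM_LEVELS)
}

#' Fuse 4-class CinC-style calls into the 3-class vocabulary
#'
#' Maps `Normal -> non-AFib`, `Other -> non-AFib`, `AFib -> AFib`,
#' `Noisy -> noisy` (non-AFib rhythms, whether normal or other, all become
#' the negative class).
#'
#' @param x character vector in the 4-symbol vocabulary
#'   `{Normal, Other, AFib, Noisy}` (case-insensitive).
#' @return factor with levels `AFib`, `non-AFib`, `noisy`.
#' @export
fuse_cinc_labels <- function(x) {
  key <- tolower(trimws(as.character(x)))
  map <- c(normal = NON_AFIB, other = NON_AFIB, afib = AFIB, noisy = NOISY)
  out <- unname(map[key])
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop("unknown CinC symbol(s): ",
         paste0("'", unique(x[bad]), "'", collapse = ", "),
         " (first at row ", bad[1L], ")")
  factor(out, levels = RHYTHM_LEVELS)
}

#' Construct a meta-level feature table
#'
#' @param record_id character vector of unique record identifiers.
#' @param features `data.frame` of meta-feature columns: factors/characters
#'   are treated as categorical rhythm votes (validated against the closed
#'   vocabulary), numerics as continuous features.
#' @param labels optional expert rhythm label per record.
#' @param score_cols names of continuous columns constrained to \[0,1\]
#'   (classifier scores); validated.
#' @return An object of class `meta_table`.
#' @export
meta_table <- function(record_id, features, labels = NULL,
                       score_cols = character()) {
  record_id <- as.character(record_id)
  if (anyDuplicated(record_id))
    stop("duplicate record_id: ",
         paste(unique(record_id[duplicated(record_id)]), collapse = ", "))
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(features) != length(record_id))
    stop("features has ", nrow(features), " rows for ",
         length(record_id), " record ids")
  if (anyDuplicated(names(features)))
    stop("duplicate feature column names")
  types <- vapply(features, function(col) {
    if (is.numeric(col)) "continuous" else "categorical"
  }, character(1))
  for (nm in names(features)[types == "categorical"])
    features[[nm]] <- parse_rhythm_label(features[[nm]])
  for (nm in intersect(score_cols, names(features))) {
    v <- features[[nm]]
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stop("score column '", nm, "' outside [0,1]")
  }
  if (!is.null(labels)) {
    if (length(labels) != length(record_id))
      stop("labels length mismatch")
    labels <- parse_rhythm_label(labels)
  }
  structure(list(record_id = record_id, features = features,
                 labels = labels, types = types),
            class = "meta_table")
}

#' @export
print.meta_table <- function(x, ...) {
  cat(sprintf("<meta_table> %d records, %d features (%d categorical, %d continuous)%s\n",
              length(x$record_id), ncol(x$features),
              sum(x$types == "categorical"), sum(x$types == "continuous"),
              if (is.null(x$labels)) "" else ", labeled"))
  if (!is.null(x$labels)) print(table(x$labels))
  invisible(x)
}

#' @export
dim.meta_table <- function(x) c(length(x$record_id), ncol(x$features))

subset_meta_table <- function(x, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_along(x$record_id)
  feats <- x$features
  if (!is.null(cols)) {
    missing <- setdiff(cols, names(feats))
    if (length(missing))
      stop("missing feature column(s): ", paste(missing, collapse = ", "))
    feats <- feats[cols]
  }
  meta_table(x$record_id[rows], feats[rows, , drop = FALSE],
             labels = if (is.null(x$labels)) NULL else x$labels[rows])
}

#' One-hot encode a meta-table into a numeric design matrix
#'
#' Each categorical vote column expands to two binary indicators
#' (`<name>.is_afib`, `<name>.is_noisy`, so `non-AFib` encodes as (0,0));
#' continuous columns pass through. Column order and the meta-feature each
#' encoded column belongs to are recorded in the encoding map, so that
#' downstream permutation importance can permute a vote's indicator pair
#' jointly.
#'
#' @param table a [meta_table()].
#' @return list with `matrix` (numeric, rownames = record ids), and `map`
#'   (`data.frame` with `column`, `feature`, `kind`).
#' @export
encode_votes <- function(table) {
  stopifnot(inherits(table, "meta_table"))
  cols <- list(); map <- list()
  for (nm in names(table$features)) {
    col <- table$features[[nm]]
    if (table$types[[nm]] == "categorical") {
      if (anyNA(col)) {
        i <- which(is.na(col))[1L]
        stop("missing vote in column '", nm, "' for record '",
             table$record_id[i], "'")
      }
      cols[[paste0(nm, ".is_afib")]] <- as.numeric(col == AFIB)
      cols[[paste0(nm, ".is_noisy")]] <- as.numeric(col == NOISY)
      map[[length(map) + 1L]] <- data.frame(
        column = paste0(nm, c(".is_afib", ".is_noisy")),
        feature = nm, kind = "categorical", stringsAsFactors = FALSE)
    } else {
      if (anyNA(col)) {
        i <- which(is.na(col))[1L]
        stop("missing value in column '", nm, "' for record '",
             table$record_id[i], "'")
      }
      cols[[nm]] <- as.numeric(col)
      map[[length(map) + 1L]] <- data.frame(
        column = nm, feature = nm, kind = "continuous",
        stringsAsFactors = FALSE)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- table$record_id
  list(matrix = m, map = do.call(rbind, map))
}

#' Decode an encoded design matrix back to vote labels
#'
#' Inverse of [encode_votes()] for the categorical columns.
#'
#' @param encoded the list returned by [encode_votes()].
#' @return `data.frame` of decoded meta-feature columns.
#' @export
decode_votes <- function(encoded) {
  map <- encoded$map
  m <- encoded$matrix
  out <- list()
  for (feat in unique(map$feature)) {
    sub <- map[map$feature == feat, ]
    if (sub$kind[1L] == "categorical") {
      afib <- m[, paste0(feat, ".is_afib")]
      noisy <- m[, paste0(feat, ".is_noisy")]
      lab <- rep(NON_AFIB, nrow(m))
      lab[afib == 1] <- AFIB
      lab[noisy == 1] <- NOISY
      out[[feat]] <- factor(lab, levels = RHYTHM_LEVELS)
    } else {
      out[[feat]] <- m[, feat]
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

# ---- CSV I/O ---------------------------------------------------------------

sniff_header <- function(df, expected, what) {
  if (!identical(tolower(names(df))[seq_along(expected)], expected)) {
    warning(what, ": header (", paste(names(df), collapse = ","),
            ") differs from expected (", paste(expected, collapse = ","),
            "); mapping columns by position")
  }
  names(df)[seq_along(expected)] <- expected
  df
}

#' Read a labels file (record_id, label)
#'
#' @param path CSV path with header; two columns, record id then rhythm
#'   label. Columns are mapped by position with a warning if the header
#'   names differ.
#' @return `data.frame` with `record_id`, `label` (factor).
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("labels file needs 2 columns, got ", ncol(df))
  df <- sniff_header(df, c("record_id", "label"), basename(path))
  df$record_id <- as.character(df$record_id)
  if (anyDuplicated(df$record_id))
    stop("duplicate record_id in labels: ",
         df$record_id[duplicated(df$record_id)][1L])
  data.frame(record_id = df$record_id,
             label = parse_rhythm_label(df$label),
             stringsAsFactors = FALSE)
}

#' Read a votes/scores file (record_id, one column per base algorithm)
#'
#' Character columns are parsed as categorical rhythm votes; numeric
#' columns are kept as continuous scores/features.
#'
#' @param path CSV path with header; first column is the record id.
#' @return `data.frame` with `record_id` plus the algorithm columns.
#' @export
read_votes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("votes file needs >= 2 columns")
  names(df)[1L] <- "record_id"
  df$record_id <- as.character(df$record_id)
  if (anyDuplicated(df$record_id))
    stop("duplicate record_id in votes: ",
         df$record_id[duplicated(df$record_id)][1L])
  for (nm in names(df)[-1L])
    if (!is.numeric(df[[nm]]))
      df[[nm]] <- parse_rhythm_label(df[[nm]])
  df
}

#' Read a predictions file (record_id, p_afib, predicted_label)
#'
#' @param path CSV path with header.
#' @return `data.frame` with `record_id`, `p_afib`, `predicted_label`.
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("predictions file needs 3 columns")
  df <- sniff_header(df, c("record_id", "p_afib", "predicted_label"),
                     basename(path))
  df$record_id <- as.character(df$record_id)
  if (anyDuplicated(df$record_id))
    stop("duplicate record_id in predictions: ",
         df$record_id[duplicated(df$record_id)][1L])
  if (any(df$p_afib < 0 | df$p_afib > 1, na.rm = TRUE))
    stop("p_afib outside [0,1]")
  df$predicted_label <- parse_rhythm_label(df$predicted_label)
  df
}

#' Write predictions to CSV (record_id, p_afib, predicted_label)
#'
#' @param df `data.frame` with those three columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(df, path) {
  stopifnot(all(c("record_id", "p_afib", "predicted_label") %in% names(df)))
  utils::write.csv(df[c("record_id", "p_afib", "predicted_label")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Join votes and labels into a meta-table
#'
#' @param votes `data.frame` from [read_votes()] (or equivalent).
#' @param labels optional `data.frame` from [read_labels()].
#' @param strict if `TRUE` (default) records present in only one input are
#'   an error; if `FALSE` they are dropped with a message.
#' @param score_cols passed to [meta_table()].
#' @return a [meta_table()].
#' @export
build_meta_table <- function(votes, labels = NULL, strict = TRUE,
                             score_cols = character()) {
  if (is.null(labels))
    return(meta_table(votes$record_id, votes[-1L],
                      score_cols = score_cols))
  only_v <- setdiff(votes$record_id, labels$record_id)
  only_l <- setdiff(labels$record_id, votes$record_id)
  if (length(only_v) || length(only_l)) {
    msg <- paste0(length(only_v), " record(s) only in votes, ",
                  length(only_l), " only in labels",
                  if (length(only_v)) paste0(" (e.g. '", only_v[1L], "')")
                  else paste0(" (e.g. '", only_l[1L], "')"))
    if (strict) stop("join mismatch: ", msg)
    message("lenient join dropped ", msg)
  }
  keep <- intersect(votes$record_id, labels$record_id)
  v <- votes[match(keep, votes$record_id), , drop = FALSE]
  l <- labels[match(keep, labels$record_id), , drop = FALSE]
  meta_table(keep, v[-1L], labels = l$label, score_cols = score_cols)
}

#' Write a meta-table's votes (and labels) to CSV
#'
#' @param table a [meta_table()].
#' @param votes_path output CSV for `record_id` + feature columns.
#' @param labels_path optional output CSV for `record_id,label`.
#' @return `votes_path`, invisibly.
#' @export
write_meta_table <- function(table, votes_path, labels_path = NULL) {
  df <- cbind(data.frame(record_id = table$record_id,
                         stringsAsFactors = FALSE),
              table$features)
  utils::write.csv(df, votes_path, row.names = FALSE, quote = FALSE)
  if (!is.null(labels_path) && !is.null(table$labels))
    utils::write.csv(data.frame(record_id = table$record_id,
                                label = table$labels),
                     labels_path, row.names = FALSE, quote = FALSE)
  invisible(votes_path)
}
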
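#' Sparse bipartite score tables and label sets
#'
#' A `score_table` holds one initial prediction score per (entity A, entity B)
#' pair — e.g. a mirDIP-style integrative miRNA–gene score in [0, 1] — together
#' with per-axis indices so that all pairs involving one miRNA (axis A) or one
#' gene (axis B) can be pulled out cheaply. The table is sparse: most possible
#' pairs are absent.
#'
#' @name score_store
NULL

new_score_table <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("a", "b", "score") %in% names(pairs)))
  pairs$a <- as.character(pairs$a)
  pairs$b <- as.character(pairs$b)
  rownames(pairs) <- NULL
  structure(
    list(
      pairs = pairs,
      index_a = split(seq_len(nrow(pairs)), pairs$a),
      index_b = split(seq_len(nrow(pairs)), pairs$b)
    ),
    class = "score_table"
  )
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf(
    "<score_table> %d pairs, %d A-entities, %d B-entities\n",
    nrow(x$pairs), length(x$index_a), length(x$index_b)
  ))
  invisible(x)
}

validate_score_table <- function(table) {
  p <- table$pairs
  if (anyDuplicated(paste0(p$a, "\r", p$b))) {
    stop("score_table contains duplicate (a, b) pairs", call. = FALSE)
  }
  if (!all(is.finite(p$score)) || any(p$score < 0) || any(p$score > 1)) {
    stop("score_table scores must be finite and in [0, 1]", call. = FALSE)
  }
  n_idx <- sum(lengths(table$index_a))
  if (n_idx != nrow(p) || sum(lengths(table$index_b)) != nrow(p)) {
    stop("score_table indices do not cover the pair list", call. = FALSE)
  }
  invisible(table)
}

#' Load a pairwise score table from TSV
#'
#' Reads a 3-column tab-separated file `entity_a<TAB>entity_b<TAB>score` with
#' scores in [0, 1]. Gzip input is read transparently.
#'
#' @param path Path to the TSV (optionally gzipped).
#' @param header Does the file carry a single header line? Default `FALSE`.
#' @param duplicates Policy for repeated (a, b) rows: `"error"` (default, a
#'   published score table has one score per pair) or `"keep-max"`.
#' @param clip If `TRUE`, scores outside [0, 1] are clipped instead of being
#'   an error.
#' @return A `score_table`.
#' @export
load_scores <- function(path, header = FALSE,
                        duplicates = c("error", "keep-max"),
                        clip = FALSE) {
  duplicates <- match.arg(duplicates)
  raw <- tryCatch(
    utils::read.delim(path, header = header, sep = "\t",
                      colClasses = "character",
                      stringsAsFactors = FALSE, quote = "",
                      comment.char = ""),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        stop("no pairs: ", path, call. = FALSE)
      }
      stop(e)
    })
  if (nrow(raw) == 0L) stop("no pairs: ", path, call. = FALSE)
  if (ncol(raw) < 3L) stop("score TSV needs >= 3 columns: ", path, call. = FALSE)
  score <- suppressWarnings(as.numeric(raw[[3L]]))
  bad <- which(!is.finite(score) | raw[[1L]] == "" | raw[[2L]] == "")
  if (length(bad)) {
    stop(sprintf("malformed row at line %d of %s",
                 bad[1L] + as.integer(header), path), call. = FALSE)
  }
  if (clip) {
    score <- pmin(pmax(score, 0), 1)
  } else if (any(score < 0 | score > 1)) {
    i <- which(score < 0 | score > 1)[1L]
    stop(sprintf("score outside [0,1] at line %d (%.6g); use clip = TRUE to clip",
                 i + as.integer(header), score[i]), call. = FALSE)
  }
  pairs <- data.frame(a = raw[[1L]], b = raw[[2L]], score = score,
                      stringsAsFactors = FALSE)
  key <- paste0(pairs$a, "\r", pairs$b)
  if (anyDuplicated(key)) {
    if (duplicates == "error") {
      stop(sprintf("duplicate (a,b) row at line %d",
                   which(duplicated(key))[1L] + as.integer(header)),
           call. = FALSE)
    }
    ord <- order(key, -pairs$score)
    pairs <- pairs[ord, , drop = FALSE]
    pairs <- pairs[!duplicated(key[ord]), , drop = FALSE]
  }
  validate_score_table(new_score_table(pairs))
}

#' Write a score table to TSV
#'
#' Scores are printed at full precision so that a load/write/load cycle
#' round-trips exactly.
#'
#' @param table A `score_table`.
#' @param path Output path; a `.gz` suffix writes gzip.
#' @export
write_scores <- function(table, path) {
  p <- table$pairs
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste(p$a, p$b, formatC(p$score, digits = 17, format = "g"),
                   sep = "\t"), con)
  invisible(path)
}

#' Load a validated-interaction label set from TSV
#'
#' Reads a 2- or 3-column file `entity_a<TAB>entity_b[<TAB>recency_tag]`. The
#' optional tag column (e.g. a database release label such as `"v8_new"`)
#' supports recency-based train/test splitting.
#'
#' @param path Path to the TSV (optionally gzipped).
#' @param header Does the file carry a header line? Default `FALSE`.
#' @return A `label_set`: list with `positives` (data.frame `a`, `b`, `tag`;
#'   `tag` is `NA` when absent) and `negatives` (same shape, empty until
#'   sampled).
#' @export
load_labels <- function(path, header = FALSE) {
  raw <- utils::read.delim(path, header = header, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (nrow(raw) == 0L) stop("no labels: ", path, call. = FALSE)
  tag <- if (ncol(raw) >= 3L) raw[[3L]] else NA_character_
  pos <- data.frame(a = raw[[1L]], b = raw[[2L]],
                    tag = tag, stringsAsFactors = FALSE)
  pos$tag[!is.na(pos$tag) & pos$tag == ""] <- NA_character_
  key <- paste0(pos$a, "\r", pos$b)
  if (anyDuplicated(key)) {
    per_pair_tags <- tapply(pos$tag, key, function(t) length(unique(t)))
    if (any(per_pair_tags > 1L)) {
      stop("pair listed twice with conflicting recency tags", call. = FALSE)
    }
    pos <- pos[!duplicated(key), , drop = FALSE]
  }
  rownames(pos) <- NULL
  new_label_set(pos)
}

new_label_set <- function(positives,
                          negatives = data.frame(a = character(),
                                                 b = character(),
                                                 stringsAsFactors = FALSE)) {
  if (is.null(positives$tag)) positives$tag <- NA_character_
  structure(list(positives = positives, negatives = negatives),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("<label_set> %d positives (%d tagged), %d negatives\n",
              nrow(x$positives), sum(!is.na(x$positives$tag)),
              nrow(x$negatives)))
  invisible(x)
}

pair_key <- function(a, b) paste0(a, "\r", b)

#' Filter a score table and label set to mutually consistent entries
#'
#' Drops B-side (gene-side) entities without at least one validated positive —
#' the One-to-All context requires at least one validated anchor per gene —
#' and drops labelled pairs that the score table never scored. A-side entities
#' are kept regardless (set `symmetric = TRUE` to filter both axes).
#'
#' @param table A `score_table`.
#' @param labels A `label_set`.
#' @param symmetric Also drop A-side entities without positives? Default `FALSE`.
#' @return List with the filtered `table`, `labels`, and a `report` of counts.
#' @export
filter_labels <- function(table, labels, symmetric = FALSE) {
  pos <- labels$positives
  keep_b <- unique(pos$b)
  p <- table$pairs
  drop_b <- setdiff(unique(p$b), keep_b)
  keep_rows <- p$b %in% keep_b
  if (symmetric) {
    keep_a <- unique(pos$a)
    keep_rows <- keep_rows & (p$a %in% keep_a)
  }
  p2 <- p[keep_rows, , drop = FALSE]
  scored <- pair_key(p2$a, p2$b)
  pos_keep <- pair_key(pos$a, pos$b) %in% scored
  pos2 <- pos[pos_keep, , drop = FALSE]
  if (nrow(pos2) == 0L) stop("filtering left zero positives", call. = FALSE)
  rownames(pos2) <- NULL
  list(
    table = new_score_table(p2),
    labels = new_label_set(pos2, labels$negatives),
    report = list(
      entities_b_removed = length(drop_b),
      pairs_removed = nrow(p) - nrow(p2),
      positives_removed = nrow(pos) - nrow(pos2)
    )
  )
}

#' All scored partners of one entity from one perspective
#'
#' @param table A `score_table`.
#' @param axis `"A"` (e.g. miRNA side) or `"B"` (e.g. gene side).
#' @param id Entity identifier on that axis.
#' @return data.frame with columns `partner`, `score` (order unspecified).
#' @export
entity_view <- function(table, axis = c("A", "B"), id) {
  axis <- match.arg(axis)
  idx <- if (axis == "A") table$index_a[[id]] else table$index_b[[id]]
  if (is.null(idx)) {
    stop(sprintf("unknown id '%s' on axis %s", id, axis), call. = FALSE)
  }
  p <- table$pairs[idx, , drop = FALSE]
  data.frame(partner = if (axis == "A") p$b else p$a,
             score = p$score, stringsAsFactors = FALSE)
}

#' Look up the stored score of specific pairs
#'
#' @param table A `score_table`.
#' @param a,b Character vectors of equal length.
#' @return Numeric vector of scores; error if any pair is unscored.
#' @export
pair_scores <- function(table, a, b) {
  key <- pair_key(table$pairs$a, table$pairs$b)
  m <- match(pair_key(a, b), key)
  if (anyNA(m)) {
    i <- which(is.na(m))[1L]
    stop(sprintf("pair (%s, %s) not present in score table", a[i], b[i]),
         call. = FALSE)
  }
  table$pairs$score[m]
}
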
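#' Construct an assignment set (one tool's per-read labels)
#'
#' @param tool_name label for the source tool.
#' @param read_ids character vector of unique read ids.
#' @param labels integer labels parallel to `read_ids`: a positive taxid,
#'   [UNCLASSIFIED] (0), or — for consensus outputs only — [UNKNOWN] (-1).
#' @return object of class `assignment_set` with fields `tool_name` and
#'   `assignments` (named integer vector, read_id -> label).
#' @export
assignment_set <- function(tool_name, read_ids, labels) {
  read_ids <- as.character(read_ids)
  labels <- as.integer(labels)
  if (length(read_ids) != length(labels))
    tv_parse_error("read_ids and labels differ in length")
  if (anyDuplicated(read_ids))
    tv_parse_error(sprintf("duplicate read id(s): %s",
                           paste(unique(read_ids[duplicated(read_ids)]), collapse = ", ")))
  if (anyNA(labels)) tv_parse_error("NA label")
  structure(list(tool_name = as.character(tool_name),
                 assignments = setNames(labels, read_ids)),
            class = "assignment_set")
}

#' @export
print.assignment_set <- function(x, ...) {
  a <- x$assignments
  cat(sprintf("assignment_set '%s': %d reads (%d unclassified)\n",
              x$tool_name, length(a), sum(a == UNCLASSIFIED)))
  invisible(x)
}

CLASSIFIER_DIALECTS <- c("kraken2", "centrifuge", "kaiju", "clark", "generic_tsv")

#' Parse one classifier's per-read output
#'
#' Supported dialects (column maps are bit-exact against each tool's
#' documented default output):
#' * `kraken2` — tab-separated, no header: C/U flag, read id, taxid,
#'   length, k-mer string; columns 1-3 consumed; "U" or taxid 0 means
#'   unclassified.
#' * `centrifuge` — tab-separated with a `readID` header row; columns
#'   readID, seqID, taxID, ...; a read may occupy several rows (multiple
#'   hits) and is collapsed to the LCA of its candidate taxids (a taxonomy
#'   is then required); seqID "unclassified" / taxID 0 means unclassified.
#' * `kaiju` — tab-separated, no header: C/U flag, read id, taxid.
#' * `clark` — CSV with header `Object_ID,Length,Assignment`; assignment
#'   "NA" means unclassified.
#' * `generic_tsv` — two tab-separated columns, no header: read id, taxid;
#'   taxid 0 means unclassified.
#'
#' Taxids absent from `tree` are demoted to UNCLASSIFIED with a warning
#' (`unknown_taxids = "unclassify"`, the default) or rejected
#' (`unknown_taxids = "error"`). With `tree = NULL` no check is done and the
#' centrifuge multi-hit collapse is unavailable.
#'
#' @param source file path or character vector of lines.
#' @param dialect one of `r paste(CLASSIFIER_DIALECTS, collapse=", ")`.
#' @param tool_name name recorded on the returned set.
#' @param tree optional `taxonomy_tree` for taxid validation and LCA collapse.
#' @param unknown_taxids policy for taxids missing from `tree`.
#' @return an `assignment_set`.
#' @export
parse_classifier_output <- function(source, dialect, tool_name,
                                    tree = NULL,
                                    unknown_taxids = c("unclassify", "error")) {
  dialect <- match.arg(dialect, CLASSIFIER_DIALECTS)
  unknown_taxids <- match.arg(unknown_taxids)
  lines <- if (length(source) == 1L && file.exists(source)) readLines(source) else source
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]

  parsed <- switch(dialect,
    kraken2 = parse_flagged(lines, lineno, sep = "\t", min_cols = 3L, dialect),
    kaiju = parse_flagged(lines, lineno, sep = "\t", min_cols = 3L, dialect),
    centrifuge = parse_centrifuge(lines, lineno),
    clark = parse_clark(lines, lineno),
    generic_tsv = parse_generic(lines, lineno)
  )

  reads <- parsed$read
  labels <- parsed$label

  if (anyDuplicated(reads)) {
    if (dialect == "centrifuge") {
      # multi-hit rows: collapse distinct classified taxids to their LCA
      if (is.null(tree))
        tv_parse_error("centrifuge multi-hit collapse requires a taxonomy tree")
      dt <- data.table::data.table(read = reads, label = labels)
      dt <- unique(dt)
      col <- dt[, .(label = {
        tx <- label[label > 0L]
        if (length(tx) == 0L) UNCLASSIFIED
        else if (length(tx) == 1L) tx
        else lca(tree, tx)
      }), by = read]
      reads <- col$read; labels <- col$label
    } else {
      dup <- duplicated(reads) | duplicated(reads, fromLast = TRUE)
      conflict <- stats::aggregate(labels[dup],
                                   by = list(read = reads[dup]),
                                   FUN = function(v) length(unique(v)))
      bad <- conflict$read[conflict$x > 1L]
      if (length(bad))
        tv_parse_error(sprintf("%s: duplicate read(s) with conflicting labels: %s",
                               dialect, paste(head(bad, 5L), collapse = ", ")))
      keep1 <- !duplicated(reads)
      reads <- reads[keep1]; labels <- labels[keep1]
    }
  }

  if (!is.null(tree)) {
    miss <- labels > 0L & is.na(match(labels, tree$taxid))
    if (any(miss)) {
      if (unknown_taxids == "error")
        tv_parse_error(sprintf("taxid(s) absent from taxonomy: %s",
                               paste(unique(labels[miss]), collapse = ", ")))
      warning(sprintf("%s (%s): %d read(s) with taxids absent from the taxonomy demoted to UNCLASSIFIED",
                      tool_name, dialect, sum(miss)))
      labels[miss] <- UNCLASSIFIED
    }
  }
  assignment_set(tool_name, reads, labels)
}

split_cols <- function(lines, lineno, sep, min_cols, dialect) {
  fields <- strsplit(lines, sep, fixed = TRUE)
  short <- which(lengths(fields) < min_cols)
  if (length(short))
    tv_parse_error(sprintf("%s line %d: expected >= %d columns",
                           dialect, lineno[short[1L]], min_cols))
  fields
}

as_taxid <- function(x, lineno, dialect) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v))
  if (length(bad))
    tv_parse_error(sprintf("%s line %d: non-integer taxid '%s'",
                           dialect, lineno[bad[1L]], x[bad[1L]]))
  v
}

# kraken2 / kaiju: C/U flag, read id, taxid
parse_flagged <- function(lines, lineno, sep, min_cols, dialect) {
  f <- split_cols(lines, lineno, sep, min_cols, dialect)
  flag <- vapply(f, `[[`, "", 1L)
  bad <- which(!flag %in% c("C", "U"))
  if (length(bad))
    tv_parse_error(sprintf("%s line %d: classified flag must be C or U, got '%s'",
                           dialect, lineno[bad[1L]], flag[bad[1L]]))
  read <- vapply(f, `[[`, "", 2L)
  rawtax <- vapply(f, `[[`, "", 3L)
  label <- integer(length(f))
  cl <- flag == "C"
  label[cl] <- as_taxid(rawtax[cl], lineno[cl], dialect)
  label[label < 0L] <- UNCLASSIFIED
  list(read = read, label = label)
}

parse_centrifuge <- function(lines, lineno) {
  if (length(lines) && startsWith(lines[1L], "readID")) {
    lines <- lines[-1L]; lineno <- lineno[-1L]
  }
  if (length(lines) == 0L) return(list(read = character(0), label = integer(0)))
  f <- split_cols(lines, lineno, "\t", 3L, "centrifuge")
  read <- vapply(f, `[[`, "", 1L)
  seqid <- vapply(f, `[[`, "", 2L)
  rawtax <- vapply(f, `[[`, "", 3L)
  label <- rep(UNCLASSIFIED, length(f))
  cl <- seqid != "unclassified"
  label[cl] <- as_taxid(rawtax[cl], lineno[cl], "centrifuge")
  label[label < 0L] <- UNCLASSIFIED
  list(read = read, label = label)
}

parse_clark <- function(lines, lineno) {
  if (length(lines) && grepl("^Object_ID", lines[1L], ignore.case = TRUE)) {
    lines <- lines[-1L]; lineno <- lineno[-1L]
  }
  if (length(lines) == 0L) return(list(read = character(0), label = integer(0)))
  f <- split_cols(lines, lineno, ",", 3L, "clark")
  read <- vapply(f, `[[`, "", 1L)
  rawtax <- trimws(vapply(f, function(x) x[[length(x)]], ""))
  label <- rep(UNCLASSIFIED, length(f))
  cl <- !rawtax %in% c("NA", "")
  label[cl] <- as_taxid(rawtax[cl], lineno[cl], "clark")
  label[label < 0L] <- UNCLASSIFIED
  list(read = read, label = label)
}

parse_generic <- function(lines, lineno) {
  f <- split_cols(lines, lineno, "\t", 2L, "generic_tsv")
  read <- vapply(f, `[[`, "", 1L)
  label <- as_taxid(vapply(f, `[[`, "", 2L), lineno, "generic_tsv")
  label[label < 0L] <- UNCLASSIFIED
  list(read = read, label = label)
}

#' Parse a ground-truth table
#'
#' Two- or three-column TSV without header: read id, true taxid, optional
#' out-of-reference flag in \{0, 1\} (default 0 = the species is present in
#' the reference databases).
#'
#' @param source file path or character vector of lines.
#' @return object of class `truth_set`: data.frame with columns `read_id`,
#'   `taxid`, `oor` (logical).
#' @export
parse_truth <- function(source) {
  lines <- if (length(source) == 1L && file.exists(source)) readLines(source) else source
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  f <- split_cols(lines, lineno, "\t", 2L, "truth")
  read <- vapply(f, `[[`, "", 1L)
  if (anyDuplicated(read))
    tv_parse_error(sprintf("truth: duplicate read id(s): %s",
                           paste(unique(read[duplicated(read)]), collapse = ", ")))
  taxid <- as_taxid(vapply(f, `[[`, "", 2L), lineno, "truth")
  flag <- vapply(f, function(x) if (length(x) >= 3L) x[[3L]] else "0", "")
  bad <- which(!flag %in% c("0", "1"))
  if (length(bad))
    tv_parse_error(sprintf("truth line %d: out-of-reference flag must be 0 or 1",
                           lineno[bad[1L]]))
  truth_set(read, taxid, flag == "1")
}

#' @rdname parse_truth
#' @param read_ids,taxids,oor vectors building a truth set in memory.
#' @export
truth_set <- function(read_ids, taxids, oor = logical(length(read_ids))) {
  read_ids <- as.character(read_ids)
  if (anyDuplicated(read_ids)) tv_parse_error("truth: duplicate read ids")
  structure(data.frame(read_id = read_ids, taxid = as.integer(taxids),
                       oor = as.logical(oor), stringsAsFactors = FALSE),
            class = c("truth_set", "data.frame"))
}

#' Write a truth set as a 3-column TSV
#' @param truth a `truth_set`.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  writeLines(sprintf("%s\t%d\t%d", truth$read_id, truth$taxid,
                     as.integer(truth$oor)), path)
  invisible(path)
}

#' Write an assignment set in a given classifier dialect
#'
#' Inverse of [parse_classifier_output()] for fixture emission; synthetic
#' filler values (length 150, score 0/1) populate columns the parser ignores.
#'
#' @param set an `assignment_set`.
#' @param path output path.
#' @param dialect output dialect, as in [parse_classifier_output()].
#' @export
write_assignment_file <- function(set, path, dialect = "generic_tsv") {
  dialect <- match.arg(dialect, CLASSIFIER_DIALECTS)
  a <- set$assignments[order(names(set$assignments), method = "radix")]
  reads <- names(a)
  tax <- unname(pmax(a, 0L))
  cl <- tax > 0L
  lines <- switch(dialect,
    kraken2 = sprintf("%s\t%s\t%d\t150\t0:0", ifelse(cl, "C", "U"), reads, tax),
    kaiju = sprintf("%s\t%s\t%d", ifelse(cl, "C", "U"), reads, tax),
    centrifuge = c("readID\tseqID\ttaxID\tscore\t2ndBestScore\thitLength\tqueryLength\tnumMatches",
                   sprintf("%s\t%s\t%d\t%d\t0\t150\t150\t1",
                           reads, ifelse(cl, sprintf("seq_%d", tax), "unclassified"),
                           tax, as.integer(cl))),
    clark = c("Object_ID,Length,Assignment",
              sprintf("%s,150,%s", reads, ifelse(cl, as.character(tax), "NA"))),
    generic_tsv = sprintf("%s\t%d", reads, tax)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a consensus result as a deterministic TSV
#'
#' Columns: `read_id`, `label` (taxid, or "U" for both UNCLASSIFIED and
#' UNKNOWN), `reason` ("" for a taxon, "unclassified" or "unknown_weight"
#' for "U"), `weight` (winning aggregate weight, when tallies were kept) and
#' `tie_resolved`. Rows are sorted by read id so identical inputs produce
#' byte-identical files.
#'
#' @param result a `consensus_result` from [merge_all()], or an
#'   `assignment_set` (then weight/tie columns are omitted).
#' @param path output path.
#' @export
write_consensus <- function(result, path) {
  if (inherits(result, "assignment_set")) {
    a <- result$assignments[order(names(result$assignments), method = "radix")]
    lab <- ifelse(a > 0L, as.character(a), "U")
    reason <- ifelse(a > 0L, "", ifelse(a == UNKNOWN, "unknown_weight", "unclassified"))
    lines <- c("read_id\tlabel\treason",
               sprintf("%s\t%s\t%s", names(a), lab, reason))
  } else {
    d <- result$details[order(result$details$read_id, method = "radix"), ]
    v <- d$verdict
    lab <- ifelse(v > 0L, as.character(v), "U")
    reason <- ifelse(v > 0L, "", ifelse(v == UNKNOWN, "unknown_weight", "unclassified"))
    lines <- c("read_id\tlabel\treason\tweight\ttie_resolved",
               sprintf("%s\t%s\t%s\t%s\t%d", d$read_id, lab, reason,
                       formatC(d$winning_weight, format = "g", digits = 12),
                       as.integer(d$tie_resolved)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a metrics report
#'
#' The report is the table produced by [evaluate_many()]: one row per
#' (tool, rank) with confusion counts and the four metrics. Undefined
#' precision/recall (zero denominator) is serialized as JSON `null` / TSV
#' `NA`, never as 0.
#'
#' @param metrics data.frame from [evaluate_many()].
#' @param path output path.
#' @param format "tsv" or "json".
#' @export
write_metrics <- function(metrics, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(metrics, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    num <- vapply(metrics, is.double, TRUE)
    out <- metrics
    out[num] <- lapply(out[num], function(x)
      ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 12)))
    lines <- c(paste(names(out), collapse = "\t"),
               do.call(sprintf, c(list(paste(rep("%s", ncol(out)), collapse = "\t")),
                                  lapply(out, as.character))))
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    df <- jsonlite::fromJSON(path)
    for (col in c("accuracy", "precision", "recall", "fpr"))
      if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
    df
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
    df
  }
}
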
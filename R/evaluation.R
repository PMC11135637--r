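#' Rank-resolved confusion counts
#'
#' Both the prediction and the truth are projected to `rank` before
#' comparison, so an over-specific call (say a subspecies under the right
#' species) still scores as correct at species level. Per read:
#'
#' * in-reference truth — projected prediction equals projected truth: TP;
#'   unclassified/unknown prediction: FN; any other taxon: FP.
#' * out-of-reference truth (species deliberately absent from the reference
#'   databases) — unclassified/unknown: TN; any taxon: FP.
#'
#' When no read is flagged out-of-reference this reduces to the TN-free
#' accounting of simulated data in which every read has a source organism.
#' Reads present in truth but absent from `assignments` count as
#' unclassified (hence FN, or TN when out-of-reference); reads assigned but
#' missing from truth are an error.
#'
#' @param assignments an `assignment_set` (a tool's or a consensus).
#' @param truth a `truth_set`.
#' @param rank evaluation rank on the ladder.
#' @param tree a `taxonomy_tree`.
#' @return object of class `rank_confusion`: list with `tp`, `fp`, `fn`,
#'   `tn`, `rank`, `n_total`.
#' @export
confusion_at_rank <- function(assignments, truth, rank, tree) {
  if (!inherits(truth, "truth_set")) tv_evaluation_error("truth must be a truth_set")
  extra <- setdiff(names(assignments$assignments), truth$read_id)
  if (length(extra))
    tv_evaluation_error(sprintf("read(s) in assignments missing from truth: %s",
                                paste(head(extra, 5L), collapse = ", ")))
  pred <- assignments$assignments[truth$read_id]
  pred[is.na(pred)] <- UNCLASSIFIED
  pred_proj <- project_taxids(tree, pred, rank)
  truth_proj <- project_taxids(tree, truth$taxid, rank)

  abst <- pred_proj == UNCLASSIFIED
  oor <- truth$oor
  tp <- sum(!oor & !abst & pred_proj == truth_proj)
  fn <- sum(!oor & abst)
  tn <- sum(oor & abst)
  fp <- nrow(truth) - tp - fn - tn
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 rank = rank, n_total = nrow(truth)),
            class = "rank_confusion")
}

#' The four evaluation metrics from confusion counts
#'
#' `accuracy = (TP + TN) / n`; `precision = TP / (TP + FP)`;
#' `recall = TP / (TP + FN)`; and the modified false-positive rate
#' `fpr = FP / n` — the proportion of all evaluated reads sent to a wrong
#' taxon, the appropriate redefinition when simulated reads admit no true
#' negatives. Precision and recall with a zero denominator are undefined
#' (`NA`), never 0, so pure abstainers are not silently rewarded.
#'
#' @param confusion a `rank_confusion`.
#' @return list of class `rank_metrics` with `accuracy`, `precision`,
#'   `recall`, `fpr` (each a real in \[0,1\] or `NA`).
#' @export
metrics <- function(confusion) {
  c0 <- confusion
  if (c0$n_total <= 0L) tv_evaluation_error("metrics need n_total > 0")
  structure(list(
    accuracy = (c0$tp + c0$tn) / c0$n_total,
    precision = if (c0$tp + c0$fp > 0L) c0$tp / (c0$tp + c0$fp) else NA_real_,
    recall = if (c0$tp + c0$fn > 0L) c0$tp / (c0$tp + c0$fn) else NA_real_,
    fpr = c0$fp / c0$n_total
  ), class = "rank_metrics")
}

#' Evaluate many assignment sets across ranks
#'
#' Applies [confusion_at_rank()] and [metrics()] over the cross product of
#' tools and ranks. Rows are ordered by tool name (radix sort) then by the
#' given rank order, so the result is invariant to the order the sets are
#' supplied in.
#'
#' @param sets list of `assignment_set`s (tools and/or consensus results'
#'   `$consensus`).
#' @param truth a `truth_set`.
#' @param ranks character vector of evaluation ranks.
#' @param tree a `taxonomy_tree`.
#' @return data.frame: tool, rank, tp, fp, fn, tn, n, accuracy, precision,
#'   recall, fpr.
#' @export
evaluate_many <- function(sets, truth, ranks, tree) {
  if (inherits(sets, "assignment_set")) sets <- list(sets)
  tools <- vapply(sets, function(s) s$tool_name, "")
  ord <- order(tools, method = "radix")
  rows <- list()
  for (i in ord) {
    for (r in ranks) {
      conf <- confusion_at_rank(sets[[i]], truth, r, tree)
      m <- metrics(conf)
      rows[[length(rows) + 1L]] <- data.frame(
        tool = tools[i], rank = r,
        tp = conf$tp, fp = conf$fp, fn = conf$fn, tn = conf$tn,
        n = conf$n_total,
        accuracy = m$accuracy, precision = m$precision,
        recall = m$recall, fpr = m$fpr,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.rank_confusion <- function(x, ...) {
  cat(sprintf("rank_confusion @ %s: TP=%d FP=%d FN=%d TN=%d (n=%d)\n",
              x$rank, x$tp, x$fp, x$fn, x$tn, x$n_total))
  invisible(x)
}

#' @export
print.rank_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  cat(sprintf("accuracy %s | precision %s | recall %s | fpr %s\n",
              fmt(x$accuracy), fmt(x$precision), fmt(x$recall), fmt(x$fpr)))
  invisible(x)
}
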
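#' Voting strategies
#'
#' `"recall"` (alias `"merge"`) is the high-recall strategy: unclassified
#' votes are simply excluded from the tally, so any classified vote can win.
#' `"precision"` (alias `"merge_p"`) is the high-precision strategy: all
#' votes count, abstentions accumulate under an UNKNOWN candidate, and the
#' read is called unknown when that candidate's aggregated weight beats
#' every taxon strictly.
#'
#' @keywords internal
#' @name strategies
NULL

canon_strategy <- function(strategy) {
  s <- match.arg(strategy, c("recall", "precision", "merge", "merge_p"))
  switch(s, merge = "recall", merge_p = "precision", s)
}

#' Validate a weight configuration
#'
#' @param weights named numeric vector, tool name -> nonnegative finite
#'   weight; at least one weight strictly positive.
#' @return the validated vector.
#' @export
weight_config <- function(weights) {
  w <- unlist(weights)
  if (is.null(names(w)) || any(!nzchar(names(w))))
    tv_config_error("weights must be named by tool")
  w <- setNames(as.numeric(w), names(w))
  if (any(!is.finite(w)) || any(w < 0))
    tv_config_error("weights must be finite and nonnegative")
  if (!any(w > 0))
    tv_config_error("at least one weight must be strictly positive")
  if (anyDuplicated(names(w)))
    tv_config_error("duplicate tool name in weights")
  w
}

#' Project a single vote to the target rank
#'
#' Classified labels are replaced by their ancestor at `target_rank`;
#' labels whose own rank is broader than the target (no ancestor at that
#' rank) become UNCLASSIFIED, as do UNCLASSIFIED votes themselves.
#'
#' @param tree a `taxonomy_tree`.
#' @param label a taxid or [UNCLASSIFIED].
#' @param target_rank evaluation rank.
#' @return projected taxid or [UNCLASSIFIED].
#' @export
project_vote <- function(tree, label, target_rank) {
  project_taxids(tree, label, target_rank)
}

#' Tally one read's weighted votes
#'
#' @param votes named integer vector: tool name -> label (taxid or
#'   [UNCLASSIFIED]). Every voting tool must have a weight.
#' @param weights weight configuration (see [weight_config()]).
#' @param strategy see [strategies].
#' @param target_rank rank at which votes are cast; `NULL` (with
#'   `project = FALSE`) tallies raw taxids.
#' @param tree a `taxonomy_tree`.
#' @param project project votes to `target_rank` before tallying (default);
#'   raw-taxid voting is available by switching this off.
#' @return named numeric vector of aggregate weights; names are taxids plus
#'   possibly `"UNKNOWN"`. Zero-weight tools contribute nothing.
#' @export
tally_votes <- function(votes, weights, strategy = "recall",
                        target_rank = "species", tree, project = TRUE) {
  strategy <- canon_strategy(strategy)
  weights <- weight_config(weights)
  miss <- setdiff(names(votes), names(weights))
  if (length(miss))
    tv_config_error(sprintf("no weight for tool(s): %s", paste(miss, collapse = ", ")))
  w <- weights[names(votes)]
  lab <- as.integer(votes)
  if (project) lab <- project_taxids(tree, lab, target_rank)
  keep <- w > 0
  lab <- lab[keep]; w <- w[keep]
  if (strategy == "recall") {
    w <- w[lab > 0L]; lab <- lab[lab > 0L]
  }
  if (length(lab) == 0L) return(setNames(numeric(0), character(0)))
  key <- ifelse(lab > 0L, as.character(lab), "UNKNOWN")
  tapply_sum <- tapply(w, key, sum)
  setNames(as.numeric(tapply_sum), names(tapply_sum))
}

#' Decide a read's consensus verdict from its tally
#'
#' The candidate with the highest aggregate weight wins. An empty tally
#' yields UNCLASSIFIED. Under the precision strategy the UNKNOWN candidate
#' must win by strict maximum; on a tie with a taxon the taxon prevails.
#' Taxa tied at the maximum are replaced by their lowest common ancestor
#' (verdict flagged `tie_resolved`); if that ancestor is the root the
#' verdict is UNCLASSIFIED.
#'
#' @param tally named numeric vector from [tally_votes()].
#' @param strategy see [strategies].
#' @param tree a `taxonomy_tree` (used for the LCA tie rule).
#' @return list with `verdict` (taxid, [UNCLASSIFIED] or [UNKNOWN]),
#'   `winning_weight`, `tie_resolved`.
#' @export
decide <- function(tally, strategy = "recall", tree) {
  strategy <- canon_strategy(strategy)
  if (length(tally) == 0L)
    return(list(verdict = UNCLASSIFIED, winning_weight = 0, tie_resolved = FALSE))
  wmax <- max(tally)
  winners <- names(tally)[tally == wmax]
  taxa <- suppressWarnings(as.integer(winners[winners != "UNKNOWN"]))
  if ("UNKNOWN" %in% winners && length(taxa) == 0L) {
    # UNKNOWN alone at the max: strict win over every taxon
    return(list(verdict = UNKNOWN, winning_weight = wmax, tie_resolved = FALSE))
  }
  if (length(taxa) == 1L)
    return(list(verdict = taxa, winning_weight = wmax, tie_resolved = FALSE))
  anc <- lca(tree, taxa)
  verdict <- if (anc == tree$root_taxid) UNCLASSIFIED else anc
  list(verdict = verdict, winning_weight = wmax, tie_resolved = TRUE)
}

#' Merge several classifiers' outputs into one weighted-vote consensus
#'
#' For every read in the union of read ids, each tool casts its label
#' (absence from a tool's output counts as UNCLASSIFIED), votes are
#' projected to `target_rank` and tallied under the chosen strategy, and
#' the verdict with the highest aggregate weight is selected (see
#' [decide()] for tie and unknown rules). The result is deterministic and
#' independent of the order in which tool sets are supplied.
#'
#' @param sets list of `assignment_set`s with distinct tool names.
#' @param weights named weights covering every tool; `NULL` means equal
#'   weights of 1 — weights are meant to come from a config file or
#'   [fit_weights()], never guessed.
#' @param strategy see [strategies].
#' @param target_rank evaluation rank votes are projected to.
#' @param tree a `taxonomy_tree`.
#' @param project project votes to `target_rank` first (default TRUE).
#' @param require_unanimity optional stricter recall variant: a read is
#'   assigned only when all its classified votes agree on one taxon
#'   (off by default).
#' @param keep_tallies retain the per-read tally table (default TRUE).
#' @return object of class `consensus_result`: `consensus` (an
#'   `assignment_set` named "merge" or "merge_p"), `details` (data.frame
#'   read_id, verdict, winning_weight, tie_resolved), `tallies`
#'   (data.table read_id, label, weight; label -1 is UNKNOWN), plus the
#'   strategy and rank used.
#' @export
merge_all <- function(sets, weights = NULL, strategy = "recall",
                      target_rank = "species", tree, project = TRUE,
                      require_unanimity = FALSE, keep_tallies = TRUE) {
  strategy <- canon_strategy(strategy)
  if (!is.list(sets) || length(sets) == 0L)
    tv_config_error("merge_all needs at least one assignment set")
  if (inherits(sets, "assignment_set")) sets <- list(sets)
  tools <- vapply(sets, function(s) s$tool_name, "")
  if (anyDuplicated(tools)) tv_config_error("duplicate tool names in sets")
  if (is.null(weights)) weights <- setNames(rep(1, length(tools)), tools)
  weights <- weight_config(weights)
  miss <- setdiff(tools, names(weights))
  if (length(miss))
    tv_config_error(sprintf("no weight for tool(s): %s", paste(miss, collapse = ", ")))

  reads <- sort(unique(unlist(lapply(sets, function(s) names(s$assignments)))),
                method = "radix")
  n <- length(reads)
  if (n == 0L) tv_config_error("no reads in any assignment set")

  # long table of (read, projected label, weight), one row per tool x read
  pieces <- lapply(sets, function(s) {
    lab <- unname(s$assignments[reads])
    lab[is.na(lab)] <- UNCLASSIFIED          # missing read = unclassified vote
    if (project) lab <- project_taxids(tree, lab, target_rank)
    data.table::data.table(read = reads, label = as.integer(lab),
                           w = unname(weights[s$tool_name]))
  })
  dt <- data.table::rbindlist(pieces)
  dt <- dt[dt$w > 0, ]
  dt$label[dt$label < 0L] <- UNCLASSIFIED
  if (strategy == "recall") {
    dt <- dt[dt$label != UNCLASSIFIED, ]
  } else {
    dt$label[dt$label == UNCLASSIFIED] <- UNKNOWN   # abstentions vote UNKNOWN
  }

  label <- weight <- read <- NULL  # R CMD check appeasement for data.table NSE
  tal <- dt[, list(weight = sum(w)), by = list(read, label)]

  verdict <- rep(UNCLASSIFIED, n)
  winning <- rep(0, n)
  tie <- rep(FALSE, n)

  if (nrow(tal)) {
    data.table::setorder(tal, read, label)
    per <- tal[, {
      wmax <- max(weight)
      winners <- label[weight == wmax]
      taxa <- winners[winners > 0L]
      if (length(taxa) == 0L) {
        list(verdict = UNKNOWN, winning_weight = wmax, tie_resolved = FALSE)
      } else if (length(taxa) == 1L) {
        list(verdict = taxa, winning_weight = wmax, tie_resolved = FALSE)
      } else {
        list(verdict = NA_integer_, winning_weight = wmax, tie_resolved = TRUE)
      }
    }, by = read]
    idx <- match(per$read, reads)
    verdict[idx] <- per$verdict
    winning[idx] <- per$winning_weight
    tie[idx] <- per$tie_resolved
    # resolve taxid ties (rare) by LCA; root LCA -> UNCLASSIFIED
    if (anyNA(verdict)) {
      for (i in which(is.na(verdict))) {
        tr <- tal[tal$read == reads[i], ]
        taxa <- tr$label[tr$weight == max(tr$weight) & tr$label > 0L]
        anc <- lca(tree, taxa)
        verdict[i] <- if (anc == tree$root_taxid) UNCLASSIFIED else anc
      }
    }
    if (require_unanimity && strategy == "recall") {
      agree <- tal[tal$label > 0L,
                   list(nlab = length(unique(label))), by = read]
      disag <- agree$read[agree$nlab > 1L]
      j <- match(disag, reads)
      verdict[j] <- UNCLASSIFIED
      winning[j] <- 0
      tie[j] <- FALSE
    }
  }

  cons <- assignment_set(if (strategy == "recall") "merge" else "merge_p",
                         reads, verdict)
  structure(list(
    consensus = cons,
    details = data.frame(read_id = reads, verdict = verdict,
                         winning_weight = winning, tie_resolved = tie,
                         stringsAsFactors = FALSE),
    tallies = if (keep_tallies) {
      data.table::setnames(tal, c("read", "label", "weight"),
                           c("read_id", "label", "weight"))
      tal
    },
    strategy = strategy, target_rank = target_rank
  ), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  v <- x$details$verdict
  cat(sprintf("consensus_result (%s @ %s): %d reads | assigned %d, unclassified %d, unknown %d, ties %d\n",
              x$strategy, x$target_rank, length(v), sum(v > 0L),
              sum(v == UNCLASSIFIED), sum(v == UNKNOWN),
              sum(x$details$tie_resolved)))
  invisible(x)
}

#' Fit per-tool voting weights from a tuning truth set
#'
#' Each tool's weight is its accuracy at `target_rank` on the tuning reads
#' (correct-or-true-negative over total, per [confusion_at_rank()]),
#' normalised so the best tool gets 1. If every tool scores zero, equal
#' weights are returned with a warning. Weight fitting is optional tooling:
#' [merge_all()] never calls it implicitly.
#'
#' @param sets list of `assignment_set`s.
#' @param truth a `truth_set` covering the reads.
#' @param target_rank rank at which accuracy is measured.
#' @param tree a `taxonomy_tree`.
#' @return named weight vector (see [weight_config()]).
#' @export
fit_weights <- function(sets, truth, target_rank = "species", tree) {
  if (length(sets) == 0L) tv_config_error("fit_weights needs >= 1 assignment set")
  if (!inherits(truth, "truth_set") || nrow(truth) == 0L)
    tv_config_error("fit_weights needs a nonempty truth set")
  acc <- vapply(sets, function(s) {
    conf <- confusion_at_rank(s, truth, target_rank, tree)
    (conf$tp + conf$tn) / conf$n_total
  }, numeric(1))
  names(acc) <- vapply(sets, function(s) s$tool_name, "")
  if (all(acc == 0)) {
    warning("all tools scored zero accuracy on the tuning set; using equal weights")
    return(setNames(rep(1, length(acc)), names(acc)))
  }
  acc / max(acc)
}

#' Read / write a flat key-value merge configuration
#'
#' Two tab-separated columns, `key<TAB>value`. Reserved keys `strategy`
#' (merge / merge_p) and `target_rank`; every other key is a tool name with
#' a numeric weight.
#'
#' @param path config file path.
#' @return list with `weights`, `strategy`, `target_rank` (reserved keys
#'   may be NULL when absent).
#' @export
read_merge_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 2L))
    tv_config_error(sprintf("config line %d: expected key<TAB>value",
                            which(lengths(f) < 2L)[1L]))
  key <- vapply(f, `[[`, "", 1L)
  val <- vapply(f, `[[`, "", 2L)
  if (anyDuplicated(key)) tv_config_error("duplicate key in config")
  strategy <- if ("strategy" %in% key) canon_strategy(val[key == "strategy"])
  target_rank <- if ("target_rank" %in% key) val[key == "target_rank"]
  wk <- !key %in% c("strategy", "target_rank")
  weights <- NULL
  if (any(wk)) {
    wv <- suppressWarnings(as.numeric(val[wk]))
    if (anyNA(wv)) tv_config_error("non-numeric weight in config")
    weights <- weight_config(setNames(wv, key[wk]))
  }
  list(weights = weights, strategy = strategy, target_rank = target_rank)
}

#' @rdname read_merge_config
#' @param weights named weights to write.
#' @param strategy,target_rank reserved keys to include (optional).
#' @export
write_merge_config <- function(path, weights, strategy = NULL, target_rank = NULL) {
  lines <- character(0)
  if (!is.null(strategy)) lines <- c(lines, paste0("strategy\t", strategy))
  if (!is.null(target_rank)) lines <- c(lines, paste0("target_rank\t", target_rank))
  lines <- c(lines, sprintf("%s\t%s", names(weights),
                            formatC(weights, format = "g", digits = 12)))
  writeLines(lines, path)
  invisible(path)
}
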
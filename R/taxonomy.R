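#' Default taxonomic rank ladder
#'
#' Ordered from broadest to narrowest. Nodes whose rank is not on the ladder
#' (NCBI's "no rank" and friends) are transparent to projection: they are
#' skipped when walking towards the root and never returned by
#' [ancestor_at_rank()].
#'
#' @export
RANK_LADDER <- c("superkingdom", "phylum", "class", "order", "family",
                 "genus", "species", "subspecies")

#' Build a taxonomy tree from parallel vectors
#'
#' The NCBI dump convention is assumed: the root is the unique node that is
#' its own parent (conventionally taxid 1). Every other node's parent chain
#' must terminate at the root; cycles and dangling parents are structural
#' errors. Taxid 0 is reserved as the UNCLASSIFIED sentinel and may not
#' appear as a node.
#'
#' @param taxid integer vector of node ids (unique, positive).
#' @param parent integer vector of parent ids, parallel to `taxid`.
#' @param rank character vector of rank names ("no rank" for unranked).
#' @param name character vector of scientific names (optional, "" if absent).
#' @param ladder ordered rank ladder; default [RANK_LADDER].
#' @return an object of class `taxonomy_tree`.
#' @export
taxonomy_tree <- function(taxid, parent, rank, name = character(length(taxid)),
                          ladder = RANK_LADDER) {
  taxid <- as.integer(taxid)
  parent <- as.integer(parent)
  rank <- as.character(rank)
  name <- as.character(name)
  n <- length(taxid)
  if (length(parent) != n || length(rank) != n || length(name) != n)
    tv_structural_error("taxid, parent, rank, name must have equal length")
  if (n == 0L) tv_structural_error("taxonomy has no nodes")
  if (anyDuplicated(taxid))
    tv_structural_error(sprintf("duplicate taxid(s): %s",
                                paste(unique(taxid[duplicated(taxid)]), collapse = ", ")))
  if (any(taxid == 0L))
    tv_structural_error("taxid 0 is the UNCLASSIFIED sentinel and cannot be a node")
  if (any(is.na(taxid)) || any(is.na(parent)))
    tv_structural_error("NA taxid or parent")

  pidx <- match(parent, taxid)
  if (anyNA(pidx)) {
    bad <- taxid[is.na(pidx)]
    tv_structural_error(sprintf("node(s) reference absent parent: taxid %s",
                                paste(bad, collapse = ", ")))
  }
  roots <- which(parent == taxid)
  if (length(roots) != 1L)
    tv_structural_error(sprintf("expected exactly one self-parented root, found %d",
                                length(roots)))
  root_i <- roots

  # Reachability from the root detects cycles: an unreached node sits on a
  # parent chain that never meets the root.
  reached <- logical(n)
  reached[root_i] <- TRUE
  frontier <- root_i
  children <- split(seq_len(n), pidx)
  while (length(frontier)) {
    kids <- unlist(children[as.character(frontier)], use.names = FALSE)
    kids <- kids[!reached[kids]]
    reached[kids] <- TRUE
    frontier <- kids
  }
  if (!all(reached)) {
    bad <- taxid[!reached]
    tv_structural_error(sprintf("cycle detected: node(s) %s never reach the root",
                                paste(head(bad, 5L), collapse = ", ")))
  }

  structure(list(taxid = taxid, parent = parent, pidx = pidx,
                 rank = rank, name = name,
                 root_taxid = taxid[root_i], ladder = ladder),
            class = "taxonomy_tree")
}

#' Load a taxonomy from NCBI-dump-format nodes/names sources
#'
#' Consumes the pipe-delimited dump dialect: fields separated by `"\t|\t"`,
#' rows terminated by `"\t|"`. Only nodes.dmp columns 1-3 (taxid, parent,
#' rank) and names.dmp rows of class "scientific name" are used; everything
#' else is ignored. Names are optional — a node without one gets `""`.
#'
#' @param nodes_source path to (or character vector of lines of) a nodes.dmp.
#' @param names_source optional path/lines of a names.dmp.
#' @param ladder rank ladder to attach; default [RANK_LADDER].
#' @return a `taxonomy_tree`.
#' @export
load_taxonomy <- function(nodes_source, names_source = NULL, ladder = RANK_LADDER) {
  nodes <- parse_dump_rows(nodes_source, min_fields = 3L, what = "nodes.dmp")
  taxid <- suppressWarnings(as.integer(vapply(nodes, `[[`, "", 1L)))
  parent <- suppressWarnings(as.integer(vapply(nodes, `[[`, "", 2L)))
  rank <- trimws(vapply(nodes, `[[`, "", 3L))
  if (anyNA(taxid) || anyNA(parent))
    tv_parse_error("non-integer taxid or parent in nodes source")

  name <- character(length(taxid))
  if (!is.null(names_source)) {
    rows <- parse_dump_rows(names_source, min_fields = 4L, what = "names.dmp")
    ntax <- suppressWarnings(as.integer(vapply(rows, `[[`, "", 1L)))
    ntxt <- vapply(rows, `[[`, "", 2L)
    ncls <- trimws(vapply(rows, `[[`, "", 4L))
    keep <- !is.na(ntax) & ncls == "scientific name"
    idx <- match(ntax[keep], taxid)
    ok <- !is.na(idx)
    name[idx[ok]] <- trimws(ntxt[keep][ok])
  }
  taxonomy_tree(taxid, parent, rank, name, ladder = ladder)
}

# Split NCBI dump rows ("a\t|\tb\t|\t...\t|") into field lists.
parse_dump_rows <- function(source, min_fields, what) {
  lines <- if (length(source) == 1L && file.exists(source)) readLines(source) else source
  lines <- lines[nzchar(trimws(lines))]
  lines <- sub("\t\\|$", "", lines)
  fields <- strsplit(lines, "\t\\|\t")
  short <- which(lengths(fields) < min_fields)
  if (length(short))
    tv_parse_error(sprintf("%s line %d: expected >= %d pipe-delimited fields",
                           what, short[1L], min_fields))
  fields
}

tax_index <- function(tree, taxid) {
  i <- match(as.integer(taxid), tree$taxid)
  if (anyNA(i))
    tv_lookup_error(sprintf("unknown taxid(s): %s",
                            paste(taxid[is.na(i)], collapse = ", ")))
  i
}

#' Lineage of a node, from the node itself up to the root
#'
#' @param tree a `taxonomy_tree`.
#' @param taxid a single taxid present in the tree.
#' @return data.frame with columns `taxid`, `rank`, ordered node -> root.
#' @export
lineage <- function(tree, taxid) {
  i <- tax_index(tree, taxid)
  path <- integer(0)
  repeat {
    path <- c(path, i)
    if (tree$taxid[i] == tree$root_taxid) break
    i <- tree$pidx[i]
  }
  data.frame(taxid = tree$taxid[path], rank = tree$rank[path],
             stringsAsFactors = FALSE)
}

#' Ancestor of a node at a given ladder rank
#'
#' Walks from the node towards the root, skipping off-ladder ("no rank")
#' nodes, and returns the unique ancestor-or-self whose rank equals `rank`.
#' Returns `NA` when the node's own rank is already broader than the
#' requested rank, or when no ladder ancestor carries it.
#'
#' @param tree a `taxonomy_tree`.
#' @param taxid a single taxid present in the tree.
#' @param rank a rank name on the tree's ladder.
#' @return the ancestor taxid, or `NA_integer_`.
#' @export
ancestor_at_rank <- function(tree, taxid, rank) {
  target <- match(rank, tree$ladder)
  if (is.na(target))
    tv_config_error(sprintf("rank '%s' is not on the ladder", rank))
  i <- tax_index(tree, taxid)
  repeat {
    r <- tree$rank[i]
    if (identical(r, rank)) return(tree$taxid[i])
    d <- match(r, tree$ladder)
    if (!is.na(d) && d < target) return(NA_integer_)  # already broader
    if (tree$taxid[i] == tree$root_taxid) return(NA_integer_)
    i <- tree$pidx[i]
  }
}

# Vectorised projection used by the consensus/evaluation hot paths: projects
# the unique labels once, then maps. UNCLASSIFIED/UNKNOWN map to UNCLASSIFIED.
project_taxids <- function(tree, labels, rank) {
  labels <- as.integer(labels)
  u <- unique(labels)
  proj <- vapply(u, function(x) {
    if (x <= 0L) return(UNCLASSIFIED)
    p <- ancestor_at_rank(tree, x, rank)
    if (is.na(p)) UNCLASSIFIED else p
  }, integer(1))
  proj[match(labels, u)]
}

#' Lowest common ancestor of a set of taxids
#'
#' @param tree a `taxonomy_tree`.
#' @param taxids nonempty vector of taxids present in the tree.
#' @return the deepest taxid ancestral-or-equal to every input.
#' @export
lca <- function(tree, taxids) {
  taxids <- unique(as.integer(taxids))
  if (length(taxids) == 0L) tv_config_error("lca of an empty taxid set")
  paths <- lapply(taxids, function(t) rev(lineage(tree, t)$taxid))  # root -> node
  k <- min(lengths(paths))
  anc <- tree$root_taxid
  for (d in seq_len(k)) {
    level <- vapply(paths, `[[`, integer(1), d)
    if (length(unique(level)) != 1L) break
    anc <- level[1L]
  }
  anc
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("taxonomy_tree: %d nodes, root taxid %d\n",
              length(x$taxid), x$root_taxid))
  tab <- table(factor(x$rank, levels = c(x$ladder, "no rank")))
  cat("  ranks:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Serialize a taxonomy to NCBI-dump-dialect nodes/names text
#'
#' @param tree a `taxonomy_tree`.
#' @param nodes_path,names_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_taxonomy_dump <- function(tree, nodes_path, names_path) {
  nodes <- sprintf("%d\t|\t%d\t|\t%s\t|", tree$taxid, tree$parent, tree$rank)
  writeLines(nodes, nodes_path)
  has <- nzchar(tree$name)
  names_rows <- sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                        tree$taxid[has], tree$name[has])
  writeLines(names_rows, names_path)
  invisible(c(nodes_path, names_path))
}
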
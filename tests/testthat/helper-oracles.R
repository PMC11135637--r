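# Independent brute-force oracles. These deliberately avoid the package's
# ancestor_at_rank / lca / tally_votes implementations: they operate
# directly on the tree's parallel vectors so they can certify them.

# Fixed toy tree used across tests:
#   1 root (no rank)
#   +- 2 superkingdom
#      +- 11 phylum
#         +- 3 genus
#         |  +- 5 species -- 10 (no rank) -- 9 subspecies
#         |  +- 6 species
#         +- 4 genus
#            +- 7 species -- 12 subspecies
#            +- 8 species
toy_tree <- function() {
  taxonomy_tree(
    taxid  = c(1, 2, 11, 3, 4, 5, 6, 7, 8, 10, 9, 12),
    parent = c(1, 1, 2, 11, 11, 3, 3, 4, 4, 5, 10, 7),
    rank   = c("no rank", "superkingdom", "phylum", "genus", "genus",
               "species", "species", "species", "species", "no rank",
               "subspecies", "subspecies"),
    name   = c("root", "sk", "phy", "gA", "gB", "spA1", "spA2", "spB1",
               "spB2", "cladeA1", "strainA1", "strainB1")
  )
}

# node -> root ancestor chain straight off the parent vector
o_chain <- function(tree, t) {
  out <- integer(0)
  repeat {
    out <- c(out, t)
    if (t == tree$root_taxid) return(out)
    t <- tree$parent[match(t, tree$taxid)]
  }
}

o_project <- function(tree, t, rank, ladder = RANK_LADDER) {
  if (t <= 0L) return(0L)
  target <- match(rank, ladder)
  for (a in o_chain(tree, t)) {
    r <- tree$rank[match(a, tree$taxid)]
    if (identical(r, rank)) return(a)
    d <- match(r, ladder)
    if (!is.na(d) && d < target) return(0L)
  }
  0L
}

# pairwise-reduction LCA: first member of a's node->root chain that also
# appears in b's chain
o_lca2 <- function(tree, a, b) {
  cb <- o_chain(tree, b)
  for (x in o_chain(tree, a)) if (x %in% cb) return(x)
  tree$root_taxid
}
o_lca <- function(tree, set) Reduce(function(a, b) o_lca2(tree, a, b), set)

# one read's consensus by plain enumeration; votes is a named (by tool)
# integer vector, weights a named numeric vector
o_merge_read <- function(tree, votes, weights, strategy, rank) {
  acc <- list()
  for (tool in names(votes)) {
    w <- weights[[tool]]
    if (w <= 0) next
    lab <- o_project(tree, votes[[tool]], rank)
    key <- if (lab > 0L) as.character(lab) else "UNKNOWN"
    if (strategy %in% c("recall", "merge") && key == "UNKNOWN") next
    acc[[key]] <- (acc[[key]] %||% 0) + w
  }
  if (length(acc) == 0L) return(list(verdict = 0L, weight = 0))
  wts <- unlist(acc)
  wmax <- max(wts)
  winners <- names(wts)[wts == wmax]
  taxa <- as.integer(winners[winners != "UNKNOWN"])
  if (length(taxa) == 0L) return(list(verdict = -1L, weight = wmax))
  if (length(taxa) == 1L) return(list(verdict = taxa, weight = wmax))
  anc <- o_lca(tree, taxa)
  list(verdict = if (anc == tree$root_taxid) 0L else anc, weight = wmax)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random tree: node i attaches to a uniformly chosen earlier node; ranks
# are irrelevant for LCA so everything below the root is "no rank"
random_tree <- function(n, seed) {
  set.seed(seed)
  parent <- c(1L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  taxonomy_tree(seq_len(n), parent, c("no rank", rep("no rank", n - 1L)))
}

# random voting instance on the toy tree's species/strain labels
random_instance <- function(n_tools = 8L, candidates = c(5L, 6L, 7L, 8L, 9L, 12L)) {
  tools <- paste0("tool", seq_len(n_tools))
  votes <- sample(c(candidates, 0L), n_tools, replace = TRUE)
  weights <- stats::runif(n_tools, 0.1, 2)
  list(votes = stats::setNames(votes, tools),
       weights = stats::setNames(weights, tools))
}

make_sets <- function(instances) {
  # turn a list of per-read vote vectors into per-tool assignment_sets
  tools <- names(instances[[1L]])
  reads <- sprintf("r%04d", seq_along(instances))
  lapply(tools, function(tl)
    assignment_set(tl, reads, vapply(instances, `[[`, integer(1), tl)))
}
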
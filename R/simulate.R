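#' Simulation configuration
#'
#' The defaults restate the benchmark community the consensus was designed
#' for: 30 species spanning two superkingdoms (a bacteria-plus-fungi pool),
#' of which round(0.10 x 30) = 3 species are flagged out-of-reference —
#' deliberately absent from every simulated tool's reference database — and
#' 10,000 reads drawn uniformly across species. Branching factors are per
#' ladder rank down to species; species are spread evenly over the genera
#' the upper factors produce, and every species carries `n_strains`
#' subspecies children so over-specific calls are expressible.
#'
#' @param n_species number of species in the community.
#' @param out_of_reference_fraction fraction (in \[0,1)) of species flagged
#'   as absent from the reference databases.
#' @param n_reads number of simulated reads.
#' @param abundance "uniform" or "lognormal".
#' @param lognormal_sigma sd of the log-abundance draw when lognormal.
#' @param branching named integer vector of per-rank branching factors
#'   (superkingdom ... genus, all >= 1).
#' @param n_strains subspecies children per species (>= 1).
#' @param seed integer seed governing every random choice downstream.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 30L,
                              out_of_reference_fraction = 0.10,
                              n_reads = 10000L,
                              abundance = c("uniform", "lognormal"),
                              lognormal_sigma = 1,
                              branching = c(superkingdom = 2L, phylum = 1L,
                                            class = 1L, order = 1L,
                                            family = 1L, genus = 5L,
                                            species = 3L),
                              n_strains = 1L,
                              seed = 1L) {
  abundance <- match.arg(abundance)
  n_species <- as.integer(n_species)
  n_reads <- as.integer(n_reads)
  if (n_reads <= 0L) tv_config_error("n_reads must be > 0")
  if (n_species <= 0L) tv_config_error("n_species must be > 0")
  if (!is.finite(out_of_reference_fraction) ||
      out_of_reference_fraction < 0 || out_of_reference_fraction >= 1)
    tv_config_error("out_of_reference_fraction must be in [0, 1)")
  need <- c("superkingdom", "phylum", "class", "order", "family", "genus", "species")
  if (!all(need %in% names(branching)))
    tv_config_error(sprintf("branching must name ranks: %s", paste(need, collapse = ", ")))
  branching <- vapply(branching[need], as.integer, integer(1))
  if (any(branching < 1L)) tv_config_error("branching factors must be >= 1")
  if (prod(branching) < n_species)
    tv_config_error(sprintf("branching yields %d species < n_species = %d",
                            prod(branching), n_species))
  structure(list(n_species = n_species,
                 out_of_reference_fraction = out_of_reference_fraction,
                 n_oor_species = as.integer(round(out_of_reference_fraction * n_species)),
                 n_reads = n_reads, abundance = abundance,
                 lognormal_sigma = lognormal_sigma,
                 branching = branching, n_strains = as.integer(n_strains),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a ladder-complete toy taxonomy
#'
#' Root (taxid 1, "no rank"), then one tier per ladder rank down to genus
#' per the branching factors; exactly `n_species` species spread as evenly
#' as possible across the genera (round-robin), each with `n_strains`
#' subspecies children. Taxids are assigned sequentially, so the tree is a
#' pure function of the config.
#'
#' @param config a `simulation_config`.
#' @return a `taxonomy_tree`.
#' @export
simulate_taxonomy <- function(config) {
  b <- config$branching
  taxid <- 1L; parent <- 1L; rank <- "no rank"; name <- "root"
  nxt <- 2L
  tier <- 1L  # taxids of the current tier's parents
  upper <- c("superkingdom", "phylum", "class", "order", "family", "genus")
  for (r in upper) {
    ids <- integer(0)
    for (p in tier) {
      k <- b[[r]]
      new_ids <- seq.int(nxt, length.out = k)
      nxt <- nxt + k
      taxid <- c(taxid, new_ids)
      parent <- c(parent, rep(p, k))
      rank <- c(rank, rep(r, k))
      name <- c(name, sprintf("%s_%d", r, new_ids))
      ids <- c(ids, new_ids)
    }
    tier <- ids
  }
  genera <- tier
  # round-robin species allocation over genera
  gidx <- rep(seq_along(genera), length.out = config$n_species)
  gidx <- sort(gidx)
  sp_ids <- seq.int(nxt, length.out = config$n_species)
  nxt <- nxt + config$n_species
  taxid <- c(taxid, sp_ids)
  parent <- c(parent, genera[gidx])
  rank <- c(rank, rep("species", config$n_species))
  name <- c(name, sprintf("species_%d", sp_ids))
  for (s in sp_ids) {
    st <- seq.int(nxt, length.out = config$n_strains)
    nxt <- nxt + config$n_strains
    taxid <- c(taxid, st)
    parent <- c(parent, rep(s, config$n_strains))
    rank <- c(rank, rep("subspecies", config$n_strains))
    name <- c(name, sprintf("strain_%d", st))
  }
  taxonomy_tree(taxid, parent, rank, name)
}

species_taxids <- function(tree) tree$taxid[tree$rank == "species"]

#' Simulate ground truth reads over a toy taxonomy
#'
#' Draws `n_reads` reads from the tree's species under the configured
#' abundance model and flags `round(fraction x n_species)` species (chosen
#' at random under the config seed) as out-of-reference; every read from a
#' flagged species carries the flag.
#'
#' @param tree a `taxonomy_tree` from [simulate_taxonomy()].
#' @param config a `simulation_config`.
#' @return a `truth_set`.
#' @export
simulate_truth <- function(tree, config) {
  sp <- species_taxids(tree)
  if (length(sp) < config$n_species)
    tv_config_error("tree has fewer species than the config requires")
  sp <- sp[seq_len(config$n_species)]
  set.seed(config$seed)
  oor_species <- if (config$n_oor_species > 0L)
    sort(sample(sp, config$n_oor_species)) else integer(0)
  probs <- switch(config$abundance,
    uniform = rep(1 / length(sp), length(sp)),
    lognormal = {
      a <- exp(rnorm(length(sp), 0, config$lognormal_sigma))
      a / sum(a)
    })
  draws <- sample(sp, config$n_reads, replace = TRUE, prob = probs)
  ids <- sprintf("read%07d", seq_len(config$n_reads))
  truth_set(ids, draws, draws %in% oor_species)
}

#' Error profile of one simulated classifier
#'
#' For an in-reference read the tool's outcome category is drawn from five
#' probabilities that must sum to 1: correct species call; over-specific
#' call (a subspecies child of the true species — correct once projected
#' back to species); sibling miss (another species in the true genus);
#' distant miss (a species outside the true genus); abstention. For an
#' out-of-reference read the tool abstains with `oor_abstain_prob` and
#' otherwise asserts a uniformly random in-reference species, emulating a
#' database-bound classifier forced to pick something it knows.
#'
#' @param tool_name tool label.
#' @param p_correct,p_overspecific,p_sibling_miss,p_distant_miss,p_unclassified
#'   category probabilities (sum to 1 within 1e-9).
#' @param oor_abstain_prob abstention probability on out-of-reference reads.
#' @param seed_offset per-tool offset added to the master seed.
#' @return object of class `tool_profile`.
#' @export
tool_profile <- function(tool_name, p_correct, p_overspecific = 0,
                         p_sibling_miss = 0, p_distant_miss = 0,
                         p_unclassified = 0, oor_abstain_prob = 0.5,
                         seed_offset = 0L) {
  p <- c(correct = p_correct, overspecific = p_overspecific,
         sibling = p_sibling_miss, distant = p_distant_miss,
         unclassified = p_unclassified)
  if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-9)
    tv_config_error(sprintf("%s: category probabilities must lie in [0,1] and sum to 1",
                            tool_name))
  if (oor_abstain_prob < 0 || oor_abstain_prob > 1)
    tv_config_error("oor_abstain_prob must be in [0,1]")
  structure(list(tool_name = tool_name, p = p,
                 oor_abstain_prob = oor_abstain_prob,
                 seed_offset = as.integer(seed_offset)),
            class = "tool_profile")
}

#' Default panel of eight heterogeneous simulated classifiers
#'
#' Named after the eight merged real-world tools purely for readability; no
#' behavioural fidelity to any of them is claimed. Profiles vary accuracy,
#' over-specificity, sibling/distant confusion, abstention, and willingness
#' to assert a label on out-of-reference reads.
#'
#' @return named list of `tool_profile`s.
#' @export
default_tool_profiles <- function() {
  mk <- tool_profile
  list(
    kraken2    = mk("kraken2",    0.85, 0.05, 0.04, 0.02, 0.04, oor_abstain_prob = 0.50, seed_offset = 1L),
    krakenuniq = mk("krakenuniq", 0.83, 0.07, 0.04, 0.02, 0.04, oor_abstain_prob = 0.55, seed_offset = 2L),
    centrifuge = mk("centrifuge", 0.80, 0.04, 0.07, 0.04, 0.05, oor_abstain_prob = 0.35, seed_offset = 3L),
    clark      = mk("clark",      0.78, 0.02, 0.08, 0.04, 0.08, oor_abstain_prob = 0.45, seed_offset = 4L),
    clark_s    = mk("clark_s",    0.82, 0.03, 0.06, 0.03, 0.06, oor_abstain_prob = 0.40, seed_offset = 5L),
    k_slam     = mk("k_slam",     0.70, 0.02, 0.10, 0.08, 0.10, oor_abstain_prob = 0.30, seed_offset = 6L),
    megablast  = mk("megablast",  0.88, 0.02, 0.04, 0.02, 0.04, oor_abstain_prob = 0.60, seed_offset = 7L),
    kaiju      = mk("kaiju",      0.75, 0.03, 0.08, 0.06, 0.08, oor_abstain_prob = 0.25, seed_offset = 8L)
  )
}

#' Simulate per-tool classifier outputs for a truth set
#'
#' Each tool draws one outcome per read from its [tool_profile()]. The RNG
#' stream of tool `t` is seeded with `(master_seed + 100003 x seed_offset)
#' mod 2^31`, and reads are processed in truth order, so every output is a
#' pure function of (tree, truth, profile, master_seed).
#'
#' @param tree a `taxonomy_tree`.
#' @param truth a `truth_set` over that tree.
#' @param profiles list of `tool_profile`s (>= 1).
#' @param master_seed integer master seed.
#' @return named list of `assignment_set`s.
#' @export
simulate_tool_outputs <- function(tree, truth, profiles, master_seed = 1L) {
  if (length(profiles) == 0L) tv_config_error("need >= 1 tool profile")
  sp_all <- species_taxids(tree)
  inref_sp <- setdiff(sp_all, unique(truth$taxid[truth$oor]))
  sp_used <- sort(unique(truth$taxid))
  gidx <- tree$pidx[match(sp_all, tree$taxid)]
  genus_of <- setNames(tree$taxid[gidx], sp_all)
  strains_of <- split(tree$taxid[tree$rank == "subspecies"],
                      tree$parent[tree$rank == "subspecies"])
  siblings_of <- lapply(setNames(sp_all, sp_all), function(s) {
    sib <- sp_all[genus_of[as.character(sp_all)] == genus_of[as.character(s)]]
    setdiff(sib, s)
  })
  distant_of <- lapply(setNames(sp_all, sp_all), function(s)
    sp_all[genus_of[as.character(sp_all)] != genus_of[as.character(s)]])

  n <- nrow(truth)
  res <- lapply(profiles, function(pr) {
    set.seed((master_seed + 100003L * pr$seed_offset) %% 2147483647L)
    lab <- integer(n)
    oor <- truth$oor
    # out-of-reference reads: abstain or assert a random in-reference species
    if (any(oor)) {
      abst <- runif(sum(oor)) < pr$oor_abstain_prob
      pick <- sample(inref_sp, sum(oor), replace = TRUE)
      lab[oor] <- ifelse(abst, UNCLASSIFIED, pick)
    }
    ir <- which(!oor)
    if (length(ir)) {
      cat5 <- sample.int(5L, length(ir), replace = TRUE, prob = pr$p)
      sp <- truth$taxid[ir]
      out <- integer(length(ir))
      out[cat5 == 1L] <- sp[cat5 == 1L]
      w <- which(cat5 == 2L)  # overspecific: a strain child of the true species
      if (length(w)) {
        out[w] <- vapply(sp[w], function(s) {
          st <- strains_of[[as.character(s)]]
          if (length(st)) st[sample.int(length(st), 1L)] else s
        }, integer(1))
      }
      w <- which(cat5 == 3L)  # sibling miss, same genus (fallback: distant)
      if (length(w)) {
        out[w] <- vapply(sp[w], function(s) {
          sib <- siblings_of[[as.character(s)]]
          if (length(sib) == 0L) sib <- distant_of[[as.character(s)]]
          sib[sample.int(length(sib), 1L)]
        }, integer(1))
      }
      w <- which(cat5 == 4L)  # distant miss, outside the genus
      if (length(w)) {
        out[w] <- vapply(sp[w], function(s) {
          d <- distant_of[[as.character(s)]]
          d[sample.int(length(d), 1L)]
        }, integer(1))
      }
      out[cat5 == 5L] <- UNCLASSIFIED
      lab[ir] <- out
    }
    assignment_set(pr$tool_name, truth$read_id, lab)
  })
  setNames(res, vapply(profiles, function(p) p$tool_name, ""))
}

#' Emit a complete fixture directory
#'
#' Writes `taxonomy/nodes.dmp`, `taxonomy/names.dmp`, `truth.tsv` and one
#' file per tool under `tools/`, rotating through the five supported
#' dialects so every parser gets exercised. Everything re-parses into
#' structures equal to the in-memory originals.
#'
#' @param tree a `taxonomy_tree`.
#' @param truth a `truth_set`.
#' @param outputs named list of `assignment_set`s.
#' @param directory output directory (created if needed).
#' @return invisibly, a manifest data.frame (tool, dialect, path).
#' @export
emit_fixtures <- function(tree, truth, outputs, directory) {
  dir.create(file.path(directory, "taxonomy"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(directory, "tools"), recursive = TRUE, showWarnings = FALSE)
  write_taxonomy_dump(tree,
                      file.path(directory, "taxonomy", "nodes.dmp"),
                      file.path(directory, "taxonomy", "names.dmp"))
  write_truth(truth, file.path(directory, "truth.tsv"))
  ext <- c(kraken2 = "kraken2.tsv", centrifuge = "centrifuge.tsv",
           kaiju = "kaiju.tsv", clark = "clark.csv", generic_tsv = "tsv")
  dialects <- rep(CLASSIFIER_DIALECTS, length.out = length(outputs))
  paths <- character(length(outputs))
  for (i in seq_along(outputs)) {
    s <- outputs[[i]]
    paths[i] <- file.path(directory, "tools",
                          sprintf("%s.%s", s$tool_name, ext[[dialects[i]]]))
    write_assignment_file(s, paths[i], dialects[i])
  }
  manifest <- data.frame(tool = vapply(outputs, function(s) s$tool_name, ""),
                         dialect = dialects, path = paths,
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(directory, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Load a fixture directory back into memory
#'
#' @param directory a directory written by [emit_fixtures()].
#' @return list with `tree`, `truth`, `sets`, `manifest`.
#' @export
load_fixtures <- function(directory) {
  tree <- load_taxonomy(file.path(directory, "taxonomy", "nodes.dmp"),
                        file.path(directory, "taxonomy", "names.dmp"))
  truth <- parse_truth(file.path(directory, "truth.tsv"))
  manifest <- utils::read.delim(file.path(directory, "manifest.tsv"),
                                stringsAsFactors = FALSE)
  sets <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(directory, "tools", basename(p))
    parse_classifier_output(p, manifest$dialect[i], manifest$tool[i], tree = tree)
  })
  names(sets) <- manifest$tool
  list(tree = tree, truth = truth, sets = sets, manifest = manifest)
}
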
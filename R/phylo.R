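# motif gain/loss mapping on a phylogeny by small parsimony

# deterministic label for the branch above a node
node_branch_label <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  if (!is.null(tree$node.label)) {
    lab <- tree$node.label[node - ntip]
    if (!is.na(lab) && nzchar(lab)) return(lab)
  }
  paste0("node", node)
}

#' Minimum motif state changes on a tree (small parsimony)
#'
#' Fitch-style small parsimony over unordered states, generalized to
#' multifurcations (Hartigan's extension: at each internal node the
#' children's preferred state sets are tallied and the deficit from
#' unanimity is the change count).  Branch lengths are ignored; the tree is
#' used as rooted exactly as supplied.  The ancestral labeling is made
#' deterministic by preferring the parent's state where optimal, and
#' otherwise the first child's preferred state.
#'
#' @param tree An [ape::phylo] tree (rooted; multifurcations allowed).
#' @param states Named character vector: one state per tip label.  Any
#'   non-empty strings form the state alphabet.
#' @return List: `min_changes` (integer), `anc` (named character vector of
#'   states for every node, tips included; internal nodes named by their
#'   branch label), `changes` (data.frame `parent`, `child`, `branch`,
#'   `from`, `to` -- one row per branch where the optimal labeling changes
#'   state).
#' @export
fitch_minimum_changes <- function(tree, states) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss)) {
    stop("leaf (leaves) without state: ", paste(miss, collapse = ", "))
  }
  if (any(is.na(states) | !nzchar(states))) stop("empty state strings")
  # deterministic state order: first appearance over tips, tree tip order
  levels_ <- unique(unname(states[tree$tip.label]))

  nnode <- ntip + tree$Nnode
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  # children in parse (cladewise) order, so "first child" is well defined
  edge_clade <- ape::reorder.phylo(tree, "cladewise")$edge
  children <- split(edge_clade[, 2], edge_clade[, 1])
  up_sets <- vector("list", nnode)
  for (i in seq_len(ntip)) up_sets[[i]] <- unname(states[tree$tip.label[i]])
  min_changes <- 0L
  # postorder: parents appear after all their children
  for (parent in unique(edge[, 1])) {
    kids <- children[[as.character(parent)]]
    tal <- table(factor(unlist(up_sets[kids]), levels = levels_))
    K <- max(tal)
    up_sets[[parent]] <- levels_[tal == K]
    min_changes <- min_changes + (length(kids) - K)
  }
  # top-down optimal labeling
  final <- character(nnode)
  root <- ntip + 1L
  pick <- function(cands, prefer) {
    if (!is.null(prefer) && prefer %in% cands) return(prefer)
    cands[1]
  }
  root_cands <- up_sets[[root]]
  first_child <- children[[as.character(root)]][1]
  final[root] <- pick(root_cands,
                      intersect(up_sets[[first_child]], root_cands)[1])
  preorder <- rev(seq_len(nrow(edge)))
  for (i in preorder) {
    p <- edge[i, 1]; v <- edge[i, 2]
    final[v] <- pick(up_sets[[v]], final[p])
  }
  labels <- vapply(seq_len(nnode), function(v) node_branch_label(tree, v), "")
  chg <- which(final[edge[, 2]] != final[edge[, 1]])
  changes <- data.frame(
    parent = labels[edge[chg, 1]],
    child = labels[edge[chg, 2]],
    branch = labels[edge[chg, 2]],
    from = final[edge[chg, 1]],
    to = final[edge[chg, 2]],
    stringsAsFactors = FALSE)
  changes <- changes[order(changes$branch), , drop = FALSE]
  rownames(changes) <- NULL
  list(min_changes = as.integer(min_changes),
       anc = setNames(final, labels),
       changes = changes)
}

# tip-state vectors from an occupancy table, one per (pattern, anchor)
occupancy_states <- function(occupancy, mode = c("state", "binary")) {
  mode <- match.arg(mode)
  key <- paste0(occupancy$pattern_name, "@", occupancy$anchor_start_col,
                "-", occupancy$anchor_end_col)
  multi <- vapply(split(key, occupancy$pattern_name),
                  function(k) length(unique(k)) > 1L, TRUE)
  label <- ifelse(multi[occupancy$pattern_name], key, occupancy$pattern_name)
  st <- switch(mode,
    state = ifelse(occupancy$status == "variant",
                   paste0("variant:", occupancy$observed), occupancy$status),
    binary = ifelse(occupancy$status == "absent", "absent", "present"))
  lapply(split(seq_len(nrow(occupancy)), factor(label, levels = unique(label))),
         function(ix) setNames(st[ix], occupancy$seq_id[ix]))
}

#' Motif gain/loss event report
#'
#' Runs small parsimony per motif (per anchor locus, where a motif has
#' several) over the occupancy states of the tree's leaves.
#'
#' @param tree An [ape::phylo] tree whose tips match the occupancy
#'   `seq_id`s.
#' @param occupancy A [motif_occupancy_matrix()] data.frame.
#' @param mode `"state"` keeps canonical / each variant text / absent as
#'   distinct states; `"binary"` collapses to present / absent.
#' @return List of data.frames: `summary` (`motif`, `min_changes`,
#'   `root_state`, `n_change_branches`) and `events` (`motif`, `branch`,
#'   `from`, `to`).
#' @export
motif_event_report <- function(tree, occupancy, mode = "state") {
  tips <- tree$tip.label
  occ_ids <- unique(occupancy$seq_id)
  if (!setequal(tips, occ_ids)) {
    stop("leaf mismatch between tree and occupancy matrix: ",
         paste(c(setdiff(tips, occ_ids), setdiff(occ_ids, tips)),
               collapse = ", "))
  }
  sts <- occupancy_states(occupancy, mode)
  summ <- list(); ev <- list()
  for (motif in names(sts)) {
    fit <- fitch_minimum_changes(tree, sts[[motif]])
    root_lab <- node_branch_label(tree, length(tips) + 1L)
    summ[[motif]] <- data.frame(
      motif = motif, min_changes = fit$min_changes,
      root_state = unname(fit$anc[root_lab]),
      n_change_branches = nrow(fit$changes), stringsAsFactors = FALSE)
    if (nrow(fit$changes)) {
      ev[[motif]] <- cbind(motif = motif, fit$changes[c("branch", "from", "to")])
    }
  }
  events <- do.call(rbind, ev)
  if (is.null(events)) {
    events <- data.frame(motif = character(), branch = character(),
                         from = character(), to = character(),
                         stringsAsFactors = FALSE)
  }
  rownames(events) <- NULL
  list(summary = do.call(rbind, c(summ, list(make.row.names = FALSE))),
       events = events)
}

#' Is a leaf set a monophyletic, state-consistent clade?
#'
#' True iff every clade member carries the same state and the members'
#' most recent common ancestor has no other leaf descendants.
#'
#' @param tree An [ape::phylo] tree.
#' @param states Named character vector of leaf states.
#' @param clade Character vector of leaf labels.
#' @return Logical scalar.
#' @export
clade_consistency <- function(tree, states, clade) {
  unknown <- setdiff(clade, tree$tip.label)
  if (length(unknown)) stop("unknown leaf: ", paste(unknown, collapse = ", "))
  if (!length(clade)) stop("empty clade")
  if (length(unique(unname(states[clade]))) != 1L) return(FALSE)
  if (length(clade) == 1L) return(TRUE)
  mrca <- ape::getMRCA(tree, clade)
  desc <- ape::extract.clade(tree, mrca)$tip.label
  setequal(desc, clade)
}

#' Export tree annotation files
#'
#' Writes a per-leaf motif-state TSV (leaf, one column per motif, catalog
#' order) and a Newick copy of the tree, ready for a tree viewer.
#'
#' @param tree An [ape::phylo] tree.
#' @param occupancy A [motif_occupancy_matrix()] data.frame covering every
#'   leaf.
#' @param path Output TSV path; the Newick copy gets extension `.nwk`.
#' @return Named character vector of the two paths, invisibly.
#' @export
export_annotation <- function(tree, occupancy, path) {
  miss <- setdiff(tree$tip.label, occupancy$seq_id)
  if (length(miss)) {
    stop("leaf missing from occupancy matrix: ", paste(miss, collapse = ", "))
  }
  sts <- occupancy_states(occupancy, "state")
  tab <- data.frame(leaf = tree$tip.label, stringsAsFactors = FALSE)
  for (motif in names(sts)) tab[[motif]] <- unname(sts[[motif]][tab$leaf])
  write_result_tsv(tab, path, params = paste0("motifs=", length(sts)))
  nwk <- sub("\\.tsv$", ".nwk", path)
  if (identical(nwk, path)) nwk <- paste0(path, ".nwk")
  write_newick(tree, nwk)
  invisible(c(annotation = path, newick = nwk))
}
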
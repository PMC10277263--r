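# synthetic protein families with known evolutionary history: sequences
# evolved along a tree with implanted motifs, designed variant switches,
# and designed presence/absence across proteomes

#' Per-branch substitution probability for a target leaf-root identity
#'
#' Under the uniform 20-state substitution model used by the simulator,
#' the probability that a site is unchanged after `n_branches` branches is
#' `1/20 + (19/20) (1 - 20 p / 19)^n_branches`.  This inverts that
#' relation.
#'
#' @param identity Target expected leaf-root identity (fraction, e.g. 0.582).
#' @param n_branches Number of branches on the root-to-leaf path.
#' @return Per-branch, per-site substitution probability.
#' @export
subst_prob_for_identity <- function(identity, n_branches) {
  stopifnot(identity > 0.05, identity <= 1, n_branches >= 1)
  (19 / 20) * (1 - ((identity - 0.05) / 0.95)^(1 / n_branches))
}

#' Expected leaf-root identity under the simulator's substitution model
#'
#' @param p Per-branch, per-site substitution probability.
#' @param n_branches Number of branches on the root-to-leaf path.
#' @return Expected fraction of sites identical to the root.
#' @export
expected_identity <- function(p, n_branches) {
  0.05 + 0.95 * (1 - 20 * p / 19)^n_branches
}

#' Default motif implants
#'
#' One canonical instance of each catalogued motif, at non-overlapping
#' root positions echoing the loci where such a family carries them
#' (CC near the N-terminus; KDEL, CSSC and HxD in the first half; HxxHC
#' mid-sequence; a clathrin box towards the C-terminus).
#'
#' @return List of implant specs: `motif_name`, `text`, `position`,
#'   `protected`.
#' @export
default_implants <- function() {
  list(
    list(motif_name = "CC", text = "CC", position = 18L, protected = TRUE),
    list(motif_name = "starDEL", text = "KDEL", position = 130L, protected = TRUE),
    list(motif_name = "CSSC", text = "CSSC", position = 140L, protected = TRUE),
    list(motif_name = "HxD", text = "HMD", position = 150L, protected = TRUE),
    list(motif_name = "HxxHC", text = "HAAHC", position = 218L, protected = TRUE),
    list(motif_name = "clathrin_box", text = "SLVSVT", position = 446L,
         protected = TRUE))
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a deep protein family: ~480
#' residue proteins, leaf-root identity around 58% (five branches at the
#' matching per-branch substitution probability), a handful of short
#' conserved motif implants, and proteomes of the family sequence plus 20
#' composition-matched decoys.
#'
#' @param seed RNG seed; identical configs and seeds give byte-identical
#'   output.
#' @param n_leaves Number of leaves when `tree_mode = "random_yule"`.
#' @param tree_mode `"random_yule"` (pure-birth tree) or `"fixed_newick"`.
#' @param newick Newick string when `tree_mode = "fixed_newick"`.
#' @param root_length Root sequence length in residues.
#' @param subst_prob_per_branch Per-branch, per-site substitution
#'   probability (uniform replacement among the other 19 residues).
#' @param indel_rate Expected indel events per branch (Poisson).
#' @param mean_indel_length Mean indel length (geometric).
#' @param implants List of implant specs (see [default_implants()]).
#' @param switches List of designed variant switches: each a list
#'   `motif_name`, `branch` (label of the node below the branch), `new_text`.
#' @param absent_leaves Leaf labels whose proteomes lack the family.
#' @param decoys_per_proteome Decoy sequences per proteome.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_leaves = 16L,
                       tree_mode = c("random_yule", "fixed_newick"),
                       newick = NULL, root_length = 480L,
                       subst_prob_per_branch = subst_prob_for_identity(0.582, 5),
                       indel_rate = 0.5, mean_indel_length = 3,
                       implants = default_implants(),
                       switches = list(),
                       absent_leaves = character(),
                       decoys_per_proteome = 20L) {
  tree_mode <- match.arg(tree_mode)
  stopifnot(subst_prob_per_branch >= 0, subst_prob_per_branch < 1,
            indel_rate >= 0, mean_indel_length >= 1, root_length >= 1)
  # implant windows must fit and not overlap
  if (length(implants)) {
    iv <- do.call(rbind, lapply(implants, function(im) {
      c(start = im$position, end = im$position + nchar(im$text) - 1L)
    }))
    if (any(iv[, "end"] > root_length)) {
      stop("implant extends beyond root_length")
    }
    o <- order(iv[, "start"])
    if (nrow(iv) > 1L &&
        any(iv[o, "start"][-1] <= iv[o, "end"][-nrow(iv)])) {
      stop("overlapping implant windows")
    }
  }
  structure(list(seed = as.integer(seed), n_leaves = as.integer(n_leaves),
                 tree_mode = tree_mode, newick = newick,
                 root_length = as.integer(root_length),
                 subst_prob_per_branch = subst_prob_per_branch,
                 indel_rate = indel_rate,
                 mean_indel_length = mean_indel_length,
                 implants = implants, switches = switches,
                 absent_leaves = absent_leaves,
                 decoys_per_proteome = as.integer(decoys_per_proteome)),
            class = "sim_config")
}

# splice-aware state for one lineage: residues, per-site root origin
# (0 = novel), and motif window coordinates
apply_switch <- function(st, w_idx, new_text) {
  w <- st$windows[w_idx, ]
  new_chars <- strsplit(new_text, "")[[1]]
  d <- length(new_chars) - (w$end - w$start + 1L)
  pre <- seq_len(w$start - 1L)
  post <- if (w$end < length(st$chars)) (w$end + 1L):length(st$chars) else integer()
  st$chars <- c(st$chars[pre], new_chars, st$chars[post])
  st$origin <- c(st$origin[pre], rep(0L, length(new_chars)), st$origin[post])
  st$windows$end[w_idx] <- w$start + length(new_chars) - 1L
  shift <- st$windows$start > w$end
  st$windows$start[shift] <- st$windows$start[shift] + d
  st$windows$end[shift] <- st$windows$end[shift] + d
  st$windows$text[w_idx] <- new_text
  st$windows$switched[w_idx] <- TRUE
  st
}

protected_mask <- function(st) {
  mask <- rep(FALSE, length(st$chars))
  wp <- st$windows[st$windows$protected, , drop = FALSE]
  for (i in seq_len(nrow(wp))) mask[wp$start[i]:wp$end[i]] <- TRUE
  mask
}

apply_substitutions <- function(st, p) {
  if (p <= 0) return(st)
  elig <- which(!protected_mask(st))
  hit <- elig[stats::runif(length(elig)) < p]
  if (length(hit)) {
    # uniform replacement among the 19 other residues
    cur <- match(st$chars[hit], AA20)
    off <- sample.int(19L, length(hit), replace = TRUE)
    st$chars[hit] <- AA20[((cur - 1L + off) %% 20L) + 1L]
  }
  st
}

apply_indels <- function(st, rate, mean_len) {
  if (rate <= 0) return(st)
  n_ev <- rpois(1L, rate)
  for (ev in seq_len(n_ev)) {
    len <- rgeom(1L, 1 / mean_len) + 1L
    is_ins <- stats::runif(1) < 0.5
    n <- length(st$chars)
    wp <- st$windows[st$windows$protected, , drop = FALSE]
    placed <- FALSE
    for (try in 1:50) {
      if (is_ins) {
        # insert after position b (0..n); never inside a protected window
        b <- sample.int(n + 1L, 1L) - 1L
        if (nrow(wp) && any(b >= wp$start & b < wp$end)) next
        ins <- sample(AA20, len, replace = TRUE)
        pre <- seq_len(b)
        post <- if (b < n) (b + 1L):n else integer()
        st$chars <- c(st$chars[pre], ins, st$chars[post])
        st$origin <- c(st$origin[pre], rep(0L, len), st$origin[post])
        shift <- st$windows$start > b
        st$windows$start[shift] <- st$windows$start[shift] + len
        st$windows$end[shift] <- st$windows$end[shift] + len
      } else {
        if (len >= n) break
        s <- sample.int(n - len + 1L, 1L)
        e <- s + len - 1L
        if (nrow(wp) && any(s <= wp$end & e >= wp$start)) next
        keep <- setdiff(seq_len(n), s:e)
        st$chars <- st$chars[keep]
        st$origin <- st$origin[keep]
        shift <- st$windows$start > e
        st$windows$start[shift] <- st$windows$start[shift] - len
        st$windows$end[shift] <- st$windows$end[shift] - len
      }
      placed <- TRUE
      break
    }
  }
  st
}

#' Simulate a protein family along a tree
#'
#' Draws a random root sequence, implants the configured motifs, evolves
#' the sequence down the tree (per-site substitutions, Poisson indels of
#' geometric length outside protected windows, designed motif switches on
#' designated branches), and assembles one proteome per leaf (the family
#' sequence plus decoys; leaves listed in `absent_leaves` get decoys
#' only).
#'
#' @param config A [sim_config()].
#' @return List: `family` (leaf sequence data.frame), `tree`
#'   ([ape::phylo]), `proteomes` (named list of sequence data.frames),
#'   `taxonomy` (data.frame, lineages from the tree's subtree structure),
#'   `truth` (ground-truth list: `leaf_states`, `switch_events`,
#'   `presence`, `identity`, `root_sequence`), and `config`.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- switch(config$tree_mode,
    random_yule = ape::rphylo(config$n_leaves, birth = 1, death = 0),
    fixed_newick = {
      if (is.null(config$newick)) stop("fixed_newick needs a newick string")
      ape::read.tree(text = config$newick)
    })
  ntip <- length(tree$tip.label)
  labels <- vapply(seq_len(ntip + tree$Nnode),
                   function(v) node_branch_label(tree, v), "")
  # validate switches against branches and edit budget
  for (sw in config$switches) {
    if (!sw$branch %in% labels) stop("switch on unknown branch: ", sw$branch)
    im <- Filter(function(x) x$motif_name == sw$motif_name, config$implants)
    if (!length(im)) stop("switch for unimplanted motif: ", sw$motif_name)
  }

  root_chars <- sample(AA20, config$root_length, replace = TRUE)
  windows <- data.frame(motif = character(), start = integer(),
                        end = integer(), text = character(),
                        protected = logical(), switched = logical(),
                        stringsAsFactors = FALSE)
  for (im in config$implants) {
    txt <- strsplit(im$text, "")[[1]]
    root_chars[im$position + seq_along(txt) - 1L] <- txt
    windows <- rbind(windows, data.frame(
      motif = im$motif_name, start = im$position,
      end = im$position + length(txt) - 1L, text = im$text,
      protected = isTRUE(im$protected), switched = FALSE,
      stringsAsFactors = FALSE))
  }
  root_state <- list(chars = root_chars,
                     origin = seq_len(config$root_length),
                     windows = windows)

  # walk the tree root-to-leaves
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  preorder <- rev(seq_len(nrow(edge)))
  states <- vector("list", ntip + tree$Nnode)
  states[[ntip + 1L]] <- root_state
  for (i in preorder) {
    p <- edge[i, 1]; v <- edge[i, 2]
    st <- states[[p]]
    for (sw in config$switches) {
      if (sw$branch == labels[v]) {
        w_idx <- which(st$windows$motif == sw$motif_name)
        if (length(w_idx)) st <- apply_switch(st, w_idx[1], sw$new_text)
      }
    }
    st <- apply_substitutions(st, config$subst_prob_per_branch)
    st <- apply_indels(st, config$indel_rate, config$mean_indel_length)
    states[[v]] <- st
  }

  # collect leaves
  fam <- data.frame(id = tree$tip.label, description = "",
                    residues = vapply(seq_len(ntip), function(v) {
                      paste(states[[v]]$chars, collapse = "")
                    }, ""), stringsAsFactors = FALSE)
  leaf_states <- do.call(rbind, lapply(seq_len(ntip), function(v) {
    w <- states[[v]]$windows
    if (!nrow(w)) return(NULL)
    data.frame(leaf = tree$tip.label[v], motif = w$motif,
               start = w$start, end = w$end, text = w$text,
               switched = w$switched, stringsAsFactors = FALSE)
  }))
  identity <- data.frame(
    leaf = tree$tip.label,
    identity_to_root = vapply(seq_len(ntip), function(v) {
      st <- states[[v]]
      anc <- st$origin > 0L
      sum(anc & st$chars == root_chars[pmax(st$origin, 1L)]) /
        config$root_length
    }, 0))

  # proteomes: family sequence (unless designed absent) + decoys
  root_seq <- paste(root_chars, collapse = "")
  proteomes <- list()
  for (v in seq_len(ntip)) {
    leaf <- tree$tip.label[v]
    dec <- make_decoys(config$decoys_per_proteome,
                       lengths = pmax(50L, round(config$root_length *
                         stats::runif(config$decoys_per_proteome, 0.7, 1.3))),
                       query = root_seq, id_prefix = paste0(leaf, "_dec"))
    if (leaf %in% config$absent_leaves) {
      proteomes[[leaf]] <- dec
    } else {
      proteomes[[leaf]] <- rbind(
        data.frame(id = paste0(leaf, "_fam"), description = "",
                   residues = fam$residues[v], stringsAsFactors = FALSE),
        dec)
    }
  }

  # taxonomy: lineages from the chain of internal nodes above each leaf
  lineage <- vapply(seq_len(ntip), function(v) {
    chain <- character()
    node <- v
    while (node != ntip + 1L) {
      node <- edge[edge[, 2] == node, 1]
      chain <- c(labels[node], chain)
    }
    paste(c(chain, tree$tip.label[v]), collapse = ";")
  }, "")
  taxonomy <- data.frame(taxon_id = tree$tip.label, lineage = lineage,
                         stringsAsFactors = FALSE)
  taxonomy$ranks <- strsplit(taxonomy$lineage, ";", fixed = TRUE)

  truth <- list(
    leaf_states = leaf_states,
    switch_events = do.call(rbind, lapply(config$switches, function(sw) {
      data.frame(motif = sw$motif_name, branch = sw$branch,
                 new_text = sw$new_text, stringsAsFactors = FALSE)
    })),
    presence = data.frame(
      proteome_id = tree$tip.label,
      present = !(tree$tip.label %in% config$absent_leaves),
      stringsAsFactors = FALSE),
    identity = identity,
    root_sequence = root_seq)
  list(family = fam, tree = tree, proteomes = proteomes,
       taxonomy = taxonomy, truth = truth, config = config)
}

#' Generate decoy sequences guaranteed not to trigger the presence rule
#'
#' Random sequences, composition-matched to the query when one is given,
#' re-drawn (bounded retries) until they fail the homologue-detection
#' thresholds against the query.
#'
#' @param n Number of decoys.
#' @param lengths Integer vector of decoy lengths (recycled to `n`).
#' @param query Optional query string for composition matching and
#'   rejection screening.
#' @param thresholds,params Screening rule, as in [call_presence()].
#' @param seed Optional RNG seed (omit to use the current RNG stream).
#' @param id_prefix Prefix for decoy ids.
#' @param max_tries Retries per decoy before giving up.
#' @return Sequence data.frame with `n` rows.
#' @export
make_decoys <- function(n, lengths = 480L, query = NULL,
                        thresholds = presence_thresholds(),
                        params = align_params(), seed = NULL,
                        id_prefix = "decoy", max_tries = 20L) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) {
    return(data.frame(id = character(), description = character(),
                      residues = character(), stringsAsFactors = FALSE))
  }
  lengths <- rep_len(as.integer(lengths), n)
  comp <- if (!is.null(query)) {
    tab <- table(factor(strsplit(query, "")[[1]], levels = AA20))
    as.numeric(tab) / sum(tab)
  } else rep(1 / 20, 20)
  res <- character(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- paste(sample(AA20, lengths[i], replace = TRUE, prob = comp),
                    collapse = "")
      if (is.null(query)) { ok <- TRUE; res[i] <- cand; break }
      pa <- align_pair(query, cand, params)
      ic <- identity_and_coverage(pa, nchar(query))
      if (!(ic[["identity_pct"]] >= thresholds$identity &&
            ic[["coverage_pct"]] > thresholds$coverage)) {
        ok <- TRUE; res[i] <- cand; break
      }
    }
    if (!ok) stop("decoy rejection failed after ", max_tries, " tries")
  }
  data.frame(id = paste0(id_prefix, seq_len(n)), description = "",
             residues = res, stringsAsFactors = FALSE)
}

#' Write a simulation to disk
#'
#' @param sim Output of [simulate_family()].
#' @param dir Output directory (created if needed): `family.fasta`,
#'   `tree.nwk`, `taxonomy.tsv`, `proteomes/<id>.fasta`, and ground-truth
#'   TSVs.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(file.path(dir, "proteomes"), recursive = TRUE,
             showWarnings = FALSE)
  write_fasta(sim$family, file.path(dir, "family.fasta"))
  write_fasta(data.frame(id = "root", description = "ancestral sequence",
                         residues = sim$truth$root_sequence,
                         stringsAsFactors = FALSE),
              file.path(dir, "root.fasta"))
  write_newick(sim$tree, file.path(dir, "tree.nwk"))
  write_taxonomy(sim$taxonomy, file.path(dir, "taxonomy.tsv"))
  for (pid in names(sim$proteomes)) {
    write_fasta(sim$proteomes[[pid]],
                file.path(dir, "proteomes", paste0(pid, ".fasta")))
  }
  write_result_tsv(sim$truth$leaf_states,
                   file.path(dir, "truth_leaf_states.tsv"),
                   params = paste0("seed=", sim$config$seed))
  write_result_tsv(sim$truth$presence, file.path(dir, "truth_presence.tsv"),
                   params = paste0("seed=", sim$config$seed))
  invisible(dir)
}

#' Synthetic master alignment with designed conservation structure
#'
#' A stand-in (fully synthetic) for a deep-family master alignment: a
#' reference row plus diverged rows at a designed mean identity, an exact
#' designed number of invariant columns of which a designed number carry
#' histidine, and a fixed number of gap columns per row so every row has
#' the same ungapped length.
#'
#' @param n_rows Number of rows (reference included).
#' @param ref_length Ungapped row length.
#' @param n_invariant Number of invariant (gap-free, 100% identical)
#'   columns.
#' @param n_invariant_his How many of those carry H.
#' @param target_identity Designed mean row-to-reference identity
#'   (fraction), approximated columnwise.
#' @param gaps_per_row Gap columns per row.
#' @param seed RNG seed.
#' @return List: `aln` (an `aln_matrix`, reference row first), `truth`
#'   (designed `invariant_columns`, `his_columns`, `ref_id`).
#' @export
simulate_master_alignment <- function(n_rows = 129L, ref_length = 479L,
                                      n_invariant = 43L,
                                      n_invariant_his = 6L,
                                      target_identity = 0.582,
                                      gaps_per_row = 6L, seed = 1L) {
  stopifnot(n_invariant_his <= n_invariant, n_rows >= 2L)
  set.seed(seed)
  n_col <- ref_length + gaps_per_row
  inv <- sort(sample.int(n_col, n_invariant))
  his <- sort(sample(inv, n_invariant_his))
  other <- setdiff(seq_len(n_col), inv)
  ref <- sample(AA20, n_col, replace = TRUE)
  ref[his] <- "H"
  ref[setdiff(inv, his)] <- sample(setdiff(AA20, "H"),
                                   n_invariant - n_invariant_his,
                                   replace = TRUE)
  # columnwise substitution probability hitting the designed identity
  s <- (n_col * (1 - target_identity)) / length(other)
  s <- min(max(s, 0), 1)
  rows <- matrix(ref, nrow = n_rows, ncol = n_col, byrow = TRUE)
  for (r in 2:n_rows) {
    mut <- other[stats::runif(length(other)) < s]
    if (length(mut)) {
      cur <- match(rows[r, mut], AA20)
      off <- sample.int(19L, length(mut), replace = TRUE)
      rows[r, mut] <- AA20[((cur - 1L + off) %% 20L) + 1L]
    }
  }
  # every row (reference too) gets gaps in non-invariant columns
  for (r in seq_len(n_rows)) {
    rows[r, sample(other, gaps_per_row)] <- "-"
  }
  # enforce the design exactly: no accidental invariant columns
  for (j in other) {
    col <- rows[, j]
    if (all(col %in% AA20) && length(unique(col)) == 1L) {
      cur <- match(rows[2L, j], AA20)
      rows[2L, j] <- AA20[(cur %% 20L) + 1L]
    }
  }
  ids <- c("ref", sprintf("hom%03d", seq_len(n_rows - 1L)))
  aln <- aln_matrix(setNames(apply(rows, 1L, paste, collapse = ""), ids))
  list(aln = aln,
       truth = list(invariant_columns = inv, his_columns = his,
                    ref_id = "ref"))
}

#' End-to-end presence and switch-branch recovery experiment
#'
#' The pipeline's closed-loop validation: seeded replicate families are
#' simulated on a fixed six-leaf tree with one designed motif switch
#' (CSSC to CSSS on the branch into one cherry), one leaf whose proteome
#' lacks the family, no indels, and a substitution rate giving ~88%
#' expected leaf-root identity.  Each replicate then runs the real
#' pipeline: presence/absence profiling of every proteome against the root
#' sequence, motif occupancy over the (indel-free, hence trivially
#' aligned) family, and small parsimony -- and compares both results to the
#' generator's ground truth.  Because implant windows are protected, the
#' switch branch is homoplasy-free by construction in every replicate.
#'
#' @param n_reps Number of seeded replicates.
#' @param base_seed Seed of the first replicate (consecutive seeds follow).
#' @return Data.frame with one row per replicate: `seed`, `presence_ok`
#'   (designed presence/absence matrix recovered exactly), `switch_ok`
#'   (parsimony reports exactly one change, on the designed branch, to the
#'   designed variant state).
#' @export
presence_switch_recovery <- function(n_reps = 100L, base_seed = 1L) {
  nwk <- "((A,B)nAB,((C,D)nCD,(E,F)nEF)nCDEF)root;"
  implants <- list(
    list(motif_name = "CC", text = "CC", position = 18L, protected = TRUE),
    list(motif_name = "CSSC", text = "CSSC", position = 100L,
         protected = TRUE),
    list(motif_name = "starDEL", text = "KDEL", position = 200L,
         protected = TRUE))
  out <- lapply(seq_len(n_reps), function(i) {
    cfg <- sim_config(
      seed = base_seed + i - 1L, tree_mode = "fixed_newick", newick = nwk,
      root_length = 250L, decoys_per_proteome = 3L,
      subst_prob_per_branch = subst_prob_for_identity(0.88, 3),
      indel_rate = 0, implants = implants,
      switches = list(list(motif_name = "CSSC", branch = "nEF",
                           new_text = "CSSS")),
      absent_leaves = "C")
    sim <- simulate_family(cfg)
    prof <- build_profile(
      data.frame(id = "root", residues = sim$truth$root_sequence,
                 stringsAsFactors = FALSE),
      sim$proteomes)
    got <- prof$present[match(sim$truth$presence$proteome_id,
                              prof$proteome_id)]
    presence_ok <- identical(got, sim$truth$presence$present)
    aln <- aln_matrix(setNames(sim$family$residues, sim$family$id))
    occ <- motif_occupancy_matrix(aln, motif_catalog()["CSSC"])
    rep_ <- motif_event_report(sim$tree, occ)
    ev <- rep_$events[rep_$events$motif == "CSSC", , drop = FALSE]
    switch_ok <- rep_$summary$min_changes[rep_$summary$motif == "CSSC"] == 1L &&
      nrow(ev) == 1L && ev$branch == "nEF" && ev$to == "variant:CSSS"
    data.frame(seed = cfg$seed, presence_ok = presence_ok,
               switch_ok = switch_ok)
  })
  do.call(rbind, out)
}
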
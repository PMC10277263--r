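# independent brute-force oracles and small fixture builders

AA20_H <- c("A","C","D","E","F","G","H","I","K","L",
            "M","N","P","Q","R","S","T","V","W","Y")

random_protein <- function(n, alphabet = AA20_H) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# ---- motif scan oracle: test every window, one position at a time ----
oracle_scan <- function(seq, pattern, seq_id = "seq") {
  chars <- strsplit(seq, "")[[1]]
  L <- pattern$length
  sets <- lapply(pattern$specs, `[[`, "allowed")
  out <- list()
  if (length(chars) >= L) {
    for (s in 1:(length(chars) - L + 1L)) {
      ok <- TRUE
      for (k in 1:L) {
        if (!chars[s + k - 1L] %in% sets[[k]]) { ok <- FALSE; break }
      }
      if (ok) {
        out[[length(out) + 1L]] <- data.frame(
          pattern_name = pattern$name, seq_id = seq_id, start = s,
          end = s + L - 1L,
          matched_text = paste(chars[s:(s + L - 1L)], collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(pattern_name = character(), seq_id = character(),
                      start = integer(), end = integer(),
                      matched_text = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# ---- variant edit-distance oracle: enumerate every alignment path ----
oracle_edit_distance <- function(pattern, window) {
  sets <- lapply(pattern$specs, `[[`, "allowed")
  wc <- strsplit(window, "")[[1]]
  rec <- function(i, j) {
    if (i > length(wc) && j > length(sets)) return(0L)
    best <- Inf
    if (i <= length(wc) && j <= length(sets)) {
      best <- min(best, rec(i + 1L, j + 1L) + (!wc[i] %in% sets[[j]]))
    }
    if (i <= length(wc)) best <- min(best, rec(i + 1L, j) + 1L)
    if (j <= length(sets)) best <- min(best, rec(i, j + 1L) + 1L)
    best
  }
  as.integer(rec(1L, 1L))
}

# ---- local alignment oracle: enumerate all alignments ----
# every local alignment starts and ends with an aligned residue pair (gap
# columns at either end only cost); interior columns are enumerated
# exhaustively with affine gap costs (a gap of length L costs open + L*ext)
oracle_local_score <- function(q, t, mat, gap_open = 11, gap_extend = 1) {
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  m <- length(qc); n <- length(tc)
  best <- 0
  rec <- function(i, j, sc, last) {
    # (i, j) = next unconsumed positions; sc = score so far; alignment may
    # stop after any aligned pair
    if (last == "m" && sc > best) best <<- sc
    if (i <= m && j <= n) rec(i + 1L, j + 1L, sc + mat[qc[i], tc[j]], "m")
    if (i <= m) rec(i + 1L, j,
                    sc - gap_extend - if (last == "d") 0 else gap_open, "d")
    if (j <= n) rec(i, j + 1L,
                    sc - gap_extend - if (last == "i") 0 else gap_open, "i")
  }
  for (i in seq_len(m)) for (j in seq_len(n)) {
    rec(i + 1L, j + 1L, mat[qc[i], tc[j]], "m")
  }
  best
}

# ---- small parsimony oracle: enumerate all ancestral assignments ----
oracle_fitch <- function(tree, states) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  alpha <- unique(unname(states[tree$tip.label]))
  edge <- tree$edge
  node_state <- character(ntip + nint)
  node_state[seq_len(ntip)] <- unname(states[tree$tip.label])
  grid <- rep(list(alpha), nint)
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    node_state[(ntip + 1L):(ntip + nint)] <- unlist(combos[r, ])
    chg <- sum(node_state[edge[, 1]] != node_state[edge[, 2]])
    if (chg < best) best <- chg
  }
  as.integer(best)
}

# random rooted tree with optional multifurcations, tips A, B, C, ...
random_tree <- function(n_tips, binary = TRUE) {
  tr <- if (binary) ape::rtree(n_tips, rooted = TRUE, br = NULL)
        else ape::rtree(n_tips, rooted = TRUE, br = NULL)
  if (!binary && n_tips >= 4L) {
    # collapse random internal edges into multifurcations
    tr <- ape::di2multi(ape::rtree(n_tips, rooted = TRUE), tol = 0.4)
    tr$edge.length <- NULL
  }
  tr$tip.label <- LETTERS[seq_len(n_tips)]
  tr
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

tmp_file <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
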
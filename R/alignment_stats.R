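# column-level conservation analysis of a master alignment

# alignment as a residue character matrix (rows x columns)
aln_char_matrix <- function(aln) {
  stopifnot(inherits(aln, "aln_matrix"))
  m <- matrix(unlist(strsplit(aln$rows, ""), use.names = FALSE),
              nrow = aln$n_rows, ncol = aln$n_columns, byrow = TRUE)
  rownames(m) <- aln$ids
  m
}

#' Per-column conservation profiles and logo information content
#'
#' For each column, counts over the 20 canonical residues, Shannon entropy
#' `H = -sum f_a log2 f_a` with frequencies over non-gap residues, and the
#' sequence-logo information content `R = log2(20) - H - e_n` with the
#' Schneider-Stephens small-sample correction `e_n = 19 / (2 ln2 n)`,
#' clipped at 0.  Gaps are excluded from frequency denominators; unknown
#' residues (`X`) are treated as missing observations, like gaps.  Columns
#' with no observed residue get 0 bits.
#'
#' @param aln An `aln_matrix`.
#' @return A data.frame with one row per column: `column`, `n_nongap`,
#'   `gap_count`, `entropy_bits`, `info_bits`, plus a list column `counts`
#'   (named residue counts).
#' @export
column_profiles <- function(aln) {
  m <- aln_char_matrix(aln)
  nr <- nrow(m)
  prof <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    obs <- col[col %in% AA20]
    counts <- table(factor(obs, levels = AA20))
    counts <- counts[counts > 0L]
    n <- length(obs)
    if (n == 0L) {
      H <- 0; info <- 0
    } else {
      f <- as.numeric(counts) / n
      H <- -sum(f * log2(f))
      e_n <- 19 / (2 * log(2) * n)
      info <- max(0, log2(20) - H - e_n)
    }
    list(n_nongap = n, gap_count = nr - n, entropy_bits = H,
         info_bits = info, counts = as.list(counts))
  })
  out <- data.frame(
    column = seq_len(ncol(m)),
    n_nongap = vapply(prof, `[[`, 0L, "n_nongap"),
    gap_count = vapply(prof, `[[`, 0L, "gap_count"),
    entropy_bits = vapply(prof, `[[`, 0, "entropy_bits"),
    info_bits = vapply(prof, `[[`, 0, "info_bits"))
  out$counts <- lapply(prof, function(p) unlist(p$counts))
  out
}

#' Invariant alignment columns
#'
#' Columns in which every row carries the same canonical residue; a gap or
#' unknown residue anywhere disqualifies the column.
#'
#' @param aln An `aln_matrix`.
#' @return Ascending integer vector of 1-based column indices.
#' @export
invariant_columns <- function(aln) {
  m <- aln_char_matrix(aln)
  keep <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    all(col %in% AA20) && length(unique(col)) == 1L
  }, TRUE)
  which(keep)
}

#' Count invariant columns carrying a given residue
#'
#' Optionally restricted to a column subset (e.g. the positions resolvable
#' in a structural model).
#'
#' @param aln An `aln_matrix`.
#' @param residue One canonical amino acid letter.
#' @param columns Optional integer vector restricting the census to these
#'   columns.
#' @return Integer count.
#' @export
invariant_residue_census <- function(aln, residue, columns = NULL) {
  stopifnot(length(residue) == 1L, residue %in% AA20)
  inv <- invariant_columns(aln)
  if (!is.null(columns)) inv <- intersect(inv, columns)
  if (!length(inv)) return(0L)
  m <- aln_char_matrix(aln)
  sum(m[1L, inv] == residue)
}

# per-row coordinate maps between ungapped sequence positions and columns
row_coord_map <- function(aln, seq_id) {
  if (!seq_id %in% aln$ids) stop("unknown seq_id: ", seq_id)
  chars <- strsplit(aln$rows[[seq_id]], "")[[1]]
  nongap <- which(chars != "-")
  list(seq_to_col = nongap,                      # seq_pos -> column
       col_to_seq = {                            # column -> seq_pos or NA
         v <- rep(NA_integer_, length(chars))
         v[nongap] <- seq_along(nongap)
         v
       })
}

#' Map an ungapped sequence position to its alignment column
#'
#' @param aln An `aln_matrix`.
#' @param seq_id Row identifier.
#' @param seq_pos 1-based position in the ungapped row sequence.
#' @return 1-based column index.
#' @export
map_seq_to_column <- function(aln, seq_id, seq_pos) {
  map <- row_coord_map(aln, seq_id)
  if (any(seq_pos < 1L | seq_pos > length(map$seq_to_col))) {
    stop("seq_pos out of range for '", seq_id, "'")
  }
  map$seq_to_col[seq_pos]
}

#' Map an alignment column to an ungapped sequence position
#'
#' @param aln An `aln_matrix`.
#' @param seq_id Row identifier.
#' @param column 1-based column index.
#' @return 1-based ungapped position, or `NA` where the row has a gap.
#' @export
map_column_to_seq <- function(aln, seq_id, column) {
  map <- row_coord_map(aln, seq_id)
  if (any(column < 1L | column > length(map$col_to_seq))) {
    stop("column out of range for '", seq_id, "'")
  }
  map$col_to_seq[column]
}

#' Motif occupancy across an alignment
#'
#' The per-sequence, per-motif state table behind a motif-presence figure:
#' canonical motif matches are located in each degapped row and projected
#' to alignment columns; column intervals where at least
#' `anchor_min_frac` of rows carry a canonical match define the motif's
#' anchor windows; every row is then called at each anchor as `canonical`,
#' `variant` (with the observed text and edit distance) or `absent`.
#'
#' @param aln An `aln_matrix`.
#' @param catalog Named list of compiled patterns ([motif_catalog()]).
#' @param max_edits Edit budget for variant classification (defaults to the
#'   catalog's `max_edits` attribute, else 2).
#' @param anchor_min_frac Minimum fraction of rows with a canonical match
#'   required to declare an anchor window.
#' @return A data.frame with columns `seq_id`, `pattern_name`,
#'   `anchor_start_col`, `anchor_end_col`, `status` (canonical / variant /
#'   absent), `observed`, `variant_kind`, `distance`.
#' @export
motif_occupancy_matrix <- function(aln, catalog,
                                   max_edits = NULL,
                                   anchor_min_frac = 0.25) {
  stopifnot(inherits(aln, "aln_matrix"))
  if (!length(catalog)) stop("empty motif catalog")
  if (is.null(max_edits)) {
    max_edits <- attr(catalog, "max_edits")
    if (is.null(max_edits)) max_edits <- 2L
  }
  maps <- lapply(aln$ids, function(id) row_coord_map(aln, id))
  names(maps) <- aln$ids
  degapped <- gsub("-", "", aln$rows, fixed = TRUE)

  out <- list()
  for (pat in catalog) {
    # canonical matches per row, in alignment-column coordinates
    hits <- lapply(aln$ids, function(id) {
      h <- scan_sequence(degapped[[id]], pat, seq_id = id)
      if (nrow(h)) {
        h$col_start <- maps[[id]]$seq_to_col[h$start]
        h$col_end <- maps[[id]]$seq_to_col[h$end]
      }
      h
    })
    allhits <- do.call(rbind, hits)
    anchors <- anchor_windows(allhits, aln$n_rows, anchor_min_frac)
    if (is.null(anchors)) next
    for (a in seq_len(nrow(anchors))) {
      a0 <- anchors$start[a]; a1 <- anchors$end[a]
      for (id in aln$ids) {
        h <- hits[[which(aln$ids == id)]]
        can <- h[nrow(h) > 0 & h$col_start <= a1 & h$col_end >= a0, ,
                 drop = FALSE]
        if (nrow(can)) {
          out[[length(out) + 1L]] <- data.frame(
            seq_id = id, pattern_name = pat$name,
            anchor_start_col = a0, anchor_end_col = a1,
            status = "canonical", observed = can$matched_text[1],
            variant_kind = NA_character_, distance = 0L,
            stringsAsFactors = FALSE)
        } else {
          slice <- substr(aln$rows[[id]], a0, a1)
          window <- gsub("-", "", slice, fixed = TRUE)
          vc <- best_window_call(pat, window, max_edits)
          out[[length(out) + 1L]] <- data.frame(
            seq_id = id, pattern_name = pat$name,
            anchor_start_col = a0, anchor_end_col = a1,
            status = if (vc$status == "absent") "absent" else "variant",
            observed = vc$observed,
            variant_kind = if (vc$status %in% c("absent", "canonical"))
              NA_character_ else vc$status,
            distance = vc$distance, stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(seq_id = character(), pattern_name = character(),
                      anchor_start_col = integer(), anchor_end_col = integer(),
                      status = character(), observed = character(),
                      variant_kind = character(), distance = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

# merge overlapping canonical-match column intervals into candidate
# anchors; keep those supported by >= min_frac of rows.  Sorting by start
# makes the result invariant to row order.
anchor_windows <- function(hits, n_rows, min_frac) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  o <- order(hits$col_start, hits$col_end)
  hits <- hits[o, , drop = FALSE]
  grp <- integer(nrow(hits))
  g <- 1L; grp[1] <- 1L; cur_end <- hits$col_end[1]
  if (nrow(hits) > 1L) for (i in 2:nrow(hits)) {
    if (hits$col_start[i] <= cur_end) {
      grp[i] <- g
      cur_end <- max(cur_end, hits$col_end[i])
    } else {
      g <- g + 1L; grp[i] <- g; cur_end <- hits$col_end[i]
    }
  }
  res <- do.call(rbind, lapply(split(seq_len(nrow(hits)), grp), function(ix) {
    data.frame(start = min(hits$col_start[ix]), end = max(hits$col_end[ix]),
               support = length(unique(hits$seq_id[ix])))
  }))
  res <- res[res$support / n_rows >= min_frac, , drop = FALSE]
  if (!nrow(res)) return(NULL)
  res[order(res$start), , drop = FALSE]
}

# best variant call over all sub-windows of a (possibly wide) anchor slice
best_window_call <- function(pat, window, max_edits) {
  L <- pat$length
  m <- nchar(window)
  if (m == 0L) {
    return(list(status = "absent", observed = "", distance = L))
  }
  if (m <= L + max_edits) {
    return(classify_variant(pat, window, max_edits))
  }
  best <- NULL
  for (w in seq(max(1L, L - max_edits), L + max_edits)) {
    if (w > m) break
    for (s in 1:(m - w + 1L)) {
      vc <- classify_variant(pat, substr(window, s, s + w - 1L), max_edits)
      if (is.null(best) || vc$distance < best$distance) best <- vc
      if (best$distance == 0L) return(best)
    }
  }
  best
}

#' Per-column logo stack heights
#'
#' Residue stack heights `f_a * info_bits` for drawing a sequence logo.
#'
#' @param profiles Output of [column_profiles()].
#' @return Long data.frame: `column`, `residue`, `height`.
#' @export
logo_heights <- function(profiles) {
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    cts <- profiles$counts[[i]]
    if (!length(cts) || profiles$n_nongap[i] == 0L) return(NULL)
    f <- cts / profiles$n_nongap[i]
    data.frame(column = profiles$column[i], residue = names(cts),
               height = as.numeric(f) * profiles$info_bits[i],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
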
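#' Amino-acid property classes used by the motif grammar
#'
#' The clathrin-binding box is written `pL(phi)p(phi)p` where `phi` is a
#' bulky hydrophobic residue and `p` any polar residue.  These memberships
#' are this package's operational definition and can be overridden when
#' compiling a pattern; note that tyrosine deliberately belongs to both
#' classes.
#'
#' @return Named list of character vectors: `phi` (bulky hydrophobic) and
#'   `pol` (polar).
#' @export
motif_classes <- function() {
  list(phi = c("F", "I", "L", "M", "V", "W", "Y"),
       pol = c("C", "D", "E", "H", "K", "N", "Q", "R", "S", "T", "Y"))
}

#' Compile a degenerate motif pattern
#'
#' The pattern DSL has four token types: an uppercase letter is a literal
#' residue, `x` matches any of the 20 canonical residues, `[ABC]` an
#' enumerated residue class, and `{phi}` / `{pol}` the property classes of
#' [motif_classes()].  `X` (unknown residue) and `-` satisfy no position,
#' including `x`.
#'
#' @param name Pattern name.
#' @param dsl Pattern string, e.g. `"[GKRDN]DEL"` or `"{pol}L{phi}{pol}{phi}{pol}"`.
#' @param classes Property-class definitions (override to change `phi`/`pol`).
#' @return A `motif_pattern`: list with `name`, `specs` (one per position:
#'   `kind`, `allowed`, `token`), and `length`.
#' @examples
#' compile_pattern("starDEL", "[GKRDN]DEL")
#' @export
compile_pattern <- function(name, dsl, classes = motif_classes()) {
  if (!nzchar(dsl)) stop("empty pattern string for '", name, "'")
  chars <- strsplit(dsl, "")[[1]]
  specs <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "x") {
      specs[[length(specs) + 1L]] <-
        list(kind = "any", allowed = AA20, token = "x")
      i <- i + 1L
    } else if (ch %in% AA20) {
      specs[[length(specs) + 1L]] <-
        list(kind = "literal", allowed = ch, token = ch)
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      if (j > length(chars)) stop("unbalanced '[' at offset ", i, " in '", dsl, "'")
      memb <- chars[(i + 1L):(j - 1L)]
      if (!length(memb) || j == i + 1L) {
        stop("empty residue class at offset ", i, " in '", dsl, "'")
      }
      if (!all(memb %in% AA20)) {
        stop("invalid residue in class at offset ", i, " in '", dsl, "'")
      }
      specs[[length(specs) + 1L]] <-
        list(kind = "enum", allowed = unique(memb),
             token = paste0("[", paste(memb, collapse = ""), "]"))
      i <- j + 1L
    } else if (ch == "{") {
      j <- i + 1L
      while (j <= length(chars) && chars[j] != "}") j <- j + 1L
      if (j > length(chars)) stop("unbalanced '{' at offset ", i, " in '", dsl, "'")
      cls <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (!cls %in% names(classes)) {
        stop("unknown class '{", cls, "}' at offset ", i, " in '", dsl, "'")
      }
      specs[[length(specs) + 1L]] <-
        list(kind = "prop", allowed = classes[[cls]],
             token = paste0("{", cls, "}"))
      i <- j + 1L
    } else {
      stop("unexpected character '", ch, "' at offset ", i, " in '", dsl, "'")
    }
  }
  if (!length(specs)) stop("pattern '", name, "' compiled to zero positions")
  structure(list(name = name, specs = specs, length = length(specs)),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern> ", x$name, ": ",
      paste(vapply(x$specs, `[[`, "", "token"), collapse = ""),
      " (", x$length, " positions)\n", sep = "")
  invisible(x)
}

#' Built-in motif catalog
#'
#' The motifs tracked across the family: the selenium-binding CC pair, the
#' thioredoxin-like CxxC (canonically CSSC here), the ER-retention signal
#' `*DEL` with enumerated first position, the metal-binding HxD (and the
#' HxxD form), HxxHC, and the clathrin-binding box.
#'
#' @param max_edits Default edit budget attached to every pattern (used by
#'   variant classification).
#' @return Named list of compiled `motif_pattern`s with a `max_edits`
#'   attribute.
#' @export
motif_catalog <- function(max_edits = 2L) {
  dsl <- c(CC = "CC", CxxC = "CxxC", CSSC = "CSSC",
           starDEL = "[GKRDN]DEL", HxD = "HxD", HxxD = "HxxD",
           HxxHC = "HxxHC", clathrin_box = "{pol}L{phi}{pol}{phi}{pol}")
  cat_ <- lapply(names(dsl), function(nm) compile_pattern(nm, dsl[[nm]]))
  names(cat_) <- names(dsl)
  attr(cat_, "max_edits") <- as.integer(max_edits)
  cat_
}

#' Read a motif catalog from a TSV config file
#'
#' Columns: `name`, `dsl`, and optionally `max_edits` (first row's value is
#' used as the catalog-wide budget; default 2).
#'
#' @param path Path to the catalog TSV.
#' @return Named list of compiled patterns, as [motif_catalog()].
#' @export
read_catalog <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "#")
  if (!all(c("name", "dsl") %in% names(tab))) {
    stop("catalog file needs columns name, dsl; found: ",
         paste(names(tab), collapse = ", "))
  }
  cat_ <- lapply(seq_len(nrow(tab)),
                 function(i) compile_pattern(tab$name[i], tab$dsl[i]))
  names(cat_) <- tab$name
  attr(cat_, "max_edits") <-
    if ("max_edits" %in% names(tab)) as.integer(tab$max_edits[1]) else 2L
  cat_
}

# allowed-residue sets per position, as a list of character vectors
pattern_allowed <- function(pattern) lapply(pattern$specs, `[[`, "allowed")

#' Scan a sequence for motif occurrences
#'
#' Reports every window of pattern length whose residues all satisfy their
#' position specs, in ascending start order; overlapping and nested matches
#' are all reported.  `X` satisfies no position.
#'
#' @param seq Either a plain residue string, or a one-row sequence
#'   data.frame (columns `id`, `residues`) as returned by [read_fasta()].
#' @param pattern A compiled `motif_pattern`.
#' @param seq_id Identifier used in the output when `seq` is a plain string.
#' @return A data.frame with columns `pattern_name`, `seq_id`, `start`,
#'   `end`, `matched_text` (zero rows when there is no match); 1-based
#'   inclusive coordinates.
#' @export
scan_sequence <- function(seq, pattern, seq_id = "seq") {
  stopifnot(inherits(pattern, "motif_pattern"))
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1L)
    seq_id <- seq$id
    seq <- seq$residues
  }
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  L <- pattern$length
  empty <- data.frame(pattern_name = character(), seq_id = character(),
                      start = integer(), end = integer(),
                      matched_text = character(), stringsAsFactors = FALSE)
  if (n < L) return(empty)
  sets <- pattern_allowed(pattern)
  nw <- n - L + 1L
  hit <- chars[seq_len(nw) + 0L] %in% sets[[1]]
  if (L > 1L) for (k in 2L:L) {
    hit <- hit & (chars[seq_len(nw) + (k - 1L)] %in% sets[[k]])
  }
  starts <- which(hit)
  if (!length(starts)) return(empty)
  data.frame(pattern_name = pattern$name, seq_id = seq_id,
             start = starts, end = starts + L - 1L,
             matched_text = substring(seq, starts, starts + L - 1L),
             stringsAsFactors = FALSE)
}

#' Scan many sequences against a whole catalog
#'
#' @param seqs Sequence data.frame ([read_fasta()] output).
#' @param catalog Named list of compiled patterns ([motif_catalog()]).
#' @return Row-bound [scan_sequence()] results over all (sequence, pattern)
#'   pairs, catalog order within each sequence.
#' @export
scan_catalog <- function(seqs, catalog) {
  stopifnot(is.data.frame(seqs), length(catalog) >= 1L)
  out <- lapply(seq_len(nrow(seqs)), function(i) {
    do.call(rbind, lapply(catalog, function(p) scan_sequence(seqs[i, ], p)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify an observed window against a canonical motif
#'
#' Aligns the window to the pattern by minimum edit count, where a residue
#' satisfying its position spec costs 0, a violating residue costs 1
#' (substitution), and insertions/deletions cost 1 each; ties prefer
#' substitutions over indels, then the leftmost edit.  Status is
#' `canonical` at distance 0; otherwise `substitution`, `insertion` or
#' `deletion` by the window/pattern length relation; `absent` beyond
#' `max_edits`.
#'
#' @param pattern Compiled `motif_pattern`.
#' @param window Observed residue string.
#' @param max_edits Maximum edit count before the motif is called absent.
#' @return A list of class `variant_call`: `pattern_name`, `observed`,
#'   `status`, `edits` (data.frame: `pattern_pos`, `pattern_spec`,
#'   `observed`), `distance`.
#' @examples
#' classify_variant(compile_pattern("CxxC", "CxxC"), "CSSS")
#' @export
classify_variant <- function(pattern, window, max_edits = 2L) {
  stopifnot(inherits(pattern, "motif_pattern"))
  wchars <- strsplit(window, "")[[1]]
  if (length(wchars) && !all(wchars %in% AA_VALID)) {
    stop("window contains non-residue characters: ",
         paste(unique(wchars[!wchars %in% AA_VALID]), collapse = ""))
  }
  sets <- pattern_allowed(pattern)
  tokens <- vapply(pattern$specs, `[[`, "", "token")
  m <- length(wchars)
  L <- pattern$length
  # DP over (window prefix i, pattern prefix j); sub cost 0/1, indel 1
  D <- matrix(0L, m + 1L, L + 1L)
  D[, 1L] <- 0:m
  D[1L, ] <- 0:L
  if (m > 0L) for (i in 1:m) for (j in 1:L) {
    sub <- D[i, j] + (!wchars[i] %in% sets[[j]])
    D[i + 1L, j + 1L] <- min(sub, D[i, j + 1L] + 1L, D[i + 1L, j] + 1L)
  }
  dist <- D[m + 1L, L + 1L]
  # traceback, preferring diagonal (match/substitution) over indels so the
  # reported edit list is the substitution-rich, leftmost optimum
  edits <- data.frame(pattern_pos = integer(), pattern_spec = character(),
                      observed = character(), stringsAsFactors = FALSE)
  i <- m; j <- L
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        D[i + 1L, j + 1L] == D[i, j] + (!wchars[i] %in% sets[[j]])) {
      if (!wchars[i] %in% sets[[j]]) {
        edits <- rbind(data.frame(pattern_pos = j, pattern_spec = tokens[j],
                                  observed = wchars[i],
                                  stringsAsFactors = FALSE), edits)
      }
      i <- i - 1L; j <- j - 1L
    } else if (j > 0L && D[i + 1L, j + 1L] == D[i + 1L, j] + 1L) {
      edits <- rbind(data.frame(pattern_pos = j, pattern_spec = tokens[j],
                                observed = "-", stringsAsFactors = FALSE),
                     edits)
      j <- j - 1L
    } else {
      edits <- rbind(data.frame(pattern_pos = j, pattern_spec = "-",
                                observed = wchars[i],
                                stringsAsFactors = FALSE), edits)
      i <- i - 1L
    }
  }
  status <- if (dist == 0L) "canonical"
            else if (dist > max_edits) "absent"
            else if (m > L) "insertion"
            else if (m < L) "deletion"
            else "substitution"
  structure(list(pattern_name = pattern$name, observed = window,
                 status = status, edits = edits, distance = as.integer(dist)),
            class = "variant_call")
}

#' @export
print.variant_call <- function(x, ...) {
  cat("<variant_call> ", x$pattern_name, " ~ '", x$observed, "': ",
      x$status, " (distance ", x$distance, ")\n", sep = "")
  invisible(x)
}
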
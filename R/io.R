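#' Read protein sequences from a FASTA file
#'
#' Parses an ungapped protein FASTA file into a sequence table.  Sequences
#' must use the 20-letter amino-acid alphabet plus `X` (unknown residue);
#' gap characters are rejected -- use [read_alignment()] for gapped input.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `description`, `residues`, one
#'   row per record, in file order.
#' @seealso [write_fasta()], [read_alignment()]
#' @export
read_fasta <- function(path) {
  recs <- fasta_records(path)
  bad <- grepl("[-.]", recs$residues)
  if (any(bad)) {
    stop("gapped sequence for id '", recs$id[bad][1],
         "': use read_alignment() for aligned FASTA")
  }
  validate_residues(recs, path, allow_gap = FALSE)
  recs
}

#' Write sequences to a FASTA file
#'
#' @param seqs A sequence data.frame as returned by [read_fasta()] (columns
#'   `id`, `residues`, optionally `description`).
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  desc <- if ("description" %in% names(seqs)) seqs$description
          else rep("", nrow(seqs))
  hdr <- ifelse(nzchar(desc), paste(seqs$id, desc), seqs$id)
  x <- Biostrings::BStringSet(seqs$residues)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

# shared FASTA ingestion: Biostrings parses, we validate ids
fasta_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("no FASTA records in ", path)
  hdr <- names(x)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  }
  res <- toupper(as.character(x))
  if (any(!nzchar(res))) {
    stop("empty sequence for id '", id[!nzchar(res)][1], "'")
  }
  data.frame(id = id, description = desc, residues = unname(res),
             stringsAsFactors = FALSE)
}

# reject residues outside the amino-acid alphabet, reporting the file line
validate_residues <- function(recs, path, allow_gap) {
  ok_chars <- c(AA_VALID, if (allow_gap) "-")
  pat <- paste0("[^", paste(ok_chars, collapse = ""), "]")
  bad <- regexpr(pat, recs$residues)
  hit <- which(bad > 0L)
  if (!length(hit)) return(invisible(TRUE))
  i <- hit[1]
  ch <- substr(recs$residues[i], bad[i], bad[i])
  # locate the offending line for the error message
  lines <- readLines(path, warn = FALSE)
  ln <- grep(ch, lines, fixed = TRUE)
  ln <- ln[!startsWith(trimws(lines[ln]), ">")]
  stop("invalid residue '", ch, "' in sequence '", recs$id[i],
       "' (line ", if (length(ln)) ln[1] else "?", " of ", path, ")")
}

#' Read a multiple sequence alignment from aligned FASTA
#'
#' All rows must have equal length.  `.` gap characters are normalized to
#' `-`, the only internal gap character.
#'
#' @param path Path to an aligned FASTA file.
#' @return An `aln_matrix` object: list with `ids`, `rows` (named gapped
#'   strings), `n_rows`, `n_columns`.
#' @export
read_alignment <- function(path) {
  recs <- fasta_records(path)
  recs$residues <- gsub(".", "-", recs$residues, fixed = TRUE)
  validate_residues(recs, path, allow_gap = TRUE)
  w <- nchar(recs$residues)
  if (length(unique(w)) > 1L) {
    mode_w <- as.integer(names(which.max(table(w))))
    off <- recs$id[w != mode_w]
    stop("ragged alignment rows for id(s): ", paste(off, collapse = ", "))
  }
  aln_matrix(setNames(recs$residues, recs$id))
}

#' Construct an alignment matrix from gapped strings
#'
#' @param rows Named character vector of equal-length gapped sequences.
#' @return An `aln_matrix` object.
#' @export
aln_matrix <- function(rows) {
  stopifnot(is.character(rows), length(rows) >= 1L, !is.null(names(rows)))
  if (anyDuplicated(names(rows))) stop("duplicate row ids")
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("rows have unequal lengths")
  structure(list(ids = names(rows), rows = rows,
                 n_rows = length(rows), n_columns = w),
            class = "aln_matrix")
}

#' @export
print.aln_matrix <- function(x, ...) {
  cat("<aln_matrix> ", x$n_rows, " rows x ", x$n_columns, " columns\n",
      sep = "")
  invisible(x)
}

#' Write an alignment to aligned FASTA
#'
#' @param aln An `aln_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "aln_matrix"))
  write_fasta(data.frame(id = aln$ids, residues = unname(aln$rows),
                         stringsAsFactors = FALSE), path)
}

#' Read a rooted tree from a Newick file
#'
#' The tree is used as rooted exactly as parsed; multifurcations are
#' allowed, branch lengths and internal-node labels (e.g. posterior
#' supports) are preserved but ignored by the parsimony machinery.
#'
#' @param path Path to a Newick file containing a single tree.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in ", path,
                                          ": ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree, found ", length(tr))
    tr <- tr[[1]]
  }
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup)) stop("duplicate leaf label(s): ", paste(dup, collapse = ", "))
  tr
}

#' Write a tree to a Newick file
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a taxonomy table
#'
#' Tab-separated file with columns `taxon_id` and `lineage`, the latter a
#' semicolon-separated rank list ordered coarse to fine
#' (e.g. `Eukaryota;Fungi;Ascomycota`).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `taxon_id`, `lineage`, plus a list
#'   column `ranks` holding the split lineage.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
  need <- c("taxon_id", "lineage")
  if (!all(need %in% names(tab))) {
    stop("taxonomy file must have columns taxon_id, lineage; found: ",
         paste(names(tab), collapse = ", "))
  }
  if (any(is.na(tab$lineage) | !nzchar(trimws(tab$lineage)))) {
    stop("empty lineage for taxon_id: ",
         paste(tab$taxon_id[is.na(tab$lineage) | !nzchar(trimws(tab$lineage))],
               collapse = ", "))
  }
  dup <- unique(tab$taxon_id[duplicated(tab$taxon_id)])
  if (length(dup)) stop("duplicated taxon_id: ", paste(dup, collapse = ", "))
  tab$ranks <- lapply(strsplit(tab$lineage, ";", fixed = TRUE), trimws)
  tab[c("taxon_id", "lineage", "ranks")]
}

#' Write a taxonomy table
#'
#' @param taxonomy A data.frame with `taxon_id` and `lineage` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  write.table(taxonomy[c("taxon_id", "lineage")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

# commented provenance header used by all TSV outputs
write_result_tsv <- function(tab, path, params = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("motiphy"))
  writeLines(paste0("# motiphy ", ver,
                    if (length(params)) paste0(" | ", paste(params, collapse = " "))),
             con)
  suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}
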
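# homologue detection by local alignment under identity/coverage
# thresholds, and presence/absence phylogenetic profiling

#' Alignment scoring parameters
#'
#' Defaults mirror the common protein-search setup: BLOSUM62 with affine
#' gap costs of 11 to open and 1 to extend (a gap of length L costs
#' `11 + L`).
#'
#' @param matrix Substitution matrix name (a Biostrings data matrix, e.g.
#'   `"BLOSUM62"`, `"BLOSUM50"`, `"PAM250"`) or a numeric matrix.
#' @param gap_open,gap_extend Positive gap penalties.
#' @return A list of class `align_params`.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  if (gap_open <= 0 || gap_extend <= 0) {
    stop("gap penalties must be positive")
  }
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(matrix, envir = e)
  }
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend), class = "align_params")
}

#' Optimal local pairwise alignment
#'
#' Smith-Waterman-Gotoh local alignment with affine gaps (via Biostrings).
#' An empty alignment (score 0) is returned when no positive-scoring pair
#' of segments exists.
#'
#' @param query,target Residue strings, or one-row sequence data.frames
#'   (columns `id`, `residues`).
#' @param params An [align_params()] object.
#' @return A list of class `pairwise_alignment`: `query_id`, `target_id`,
#'   `aligned_query`, `aligned_target`, `score`, `n_columns`,
#'   `n_identities`, `query_span` (1-based ungapped query positions
#'   covered; `NA`s when the alignment is empty).
#' @export
align_pair <- function(query, target, params = align_params()) {
  stopifnot(inherits(params, "align_params"))
  qid <- "query"; tid <- "target"
  if (is.data.frame(query)) { qid <- query$id[1]; query <- query$residues[1] }
  if (is.data.frame(target)) { tid <- target$id[1]; target <- target$residues[1] }
  if (!nzchar(query) || !nzchar(target)) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query),
    subject = Biostrings::AAString(target),
    type = "local", substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  aq <- as.character(Biostrings::alignedPattern(pa))
  at <- as.character(Biostrings::alignedSubject(pa))
  ncol_ <- nchar(aq)
  nid <- if (ncol_ == 0L) 0L else {
    qc <- strsplit(aq, "")[[1]]; tc <- strsplit(at, "")[[1]]
    sum(qc == tc & qc != "-")
  }
  span <- if (ncol_ == 0L) c(NA_integer_, NA_integer_) else
    c(Biostrings::start(Biostrings::pattern(pa)),
      Biostrings::end(Biostrings::pattern(pa)))
  structure(list(query_id = qid, target_id = tid,
                 aligned_query = aq, aligned_target = at,
                 score = Biostrings::score(pa),
                 n_columns = ncol_, n_identities = as.integer(nid),
                 query_span = span),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> ", x$query_id, " vs ", x$target_id,
      ": score ", x$score, ", ", x$n_identities, "/", x$n_columns,
      " identities\n", sep = "")
  invisible(x)
}

#' Percent identity and query coverage of an alignment
#'
#' Identity uses all alignment columns in the denominator (gap columns
#' included); coverage is the query-span convention: the length of the
#' query segment between the first and last aligned query position,
#' divided by the full query length.
#'
#' @param pa A `pairwise_alignment`.
#' @param query_length Full (ungapped) query length.
#' @return Named numeric vector `c(identity_pct=, coverage_pct=)`.
#' @export
identity_and_coverage <- function(pa, query_length) {
  stopifnot(inherits(pa, "pairwise_alignment"))
  if (query_length <= 0) stop("query_length must be positive")
  if (pa$n_columns == 0L) {
    return(c(identity_pct = 0, coverage_pct = 0))
  }
  c(identity_pct = 100 * pa$n_identities / pa$n_columns,
    coverage_pct = 100 * (pa$query_span[2] - pa$query_span[1] + 1) /
      query_length)
}

#' Homologue presence thresholds
#'
#' The detection rule: identity at least `identity` percent (non-strict)
#' and query coverage strictly above `coverage` percent.
#'
#' @param identity Identity threshold in percent (default 70, `>=`).
#' @param coverage Coverage threshold in percent (default 80, `>`).
#' @return Named list.
#' @export
presence_thresholds <- function(identity = 70, coverage = 80) {
  list(identity = identity, coverage = coverage)
}

#' Call homologue presence in one proteome
#'
#' Aligns the query to every target, keeps the best-scoring target, and
#' thresholds its identity and coverage (single-best-hit rule).
#'
#' @param query Query sequence (string or one-row data.frame).
#' @param proteome Sequence data.frame of the proteome's proteins (may have
#'   zero rows).
#' @param thresholds A [presence_thresholds()] list.
#' @param params An [align_params()] object.
#' @param proteome_id Identifier recorded in the call.
#' @return One-row data.frame: `proteome_id`, `present`, `best_target_id`,
#'   `identity_pct`, `coverage_pct`, `target_length`, `score`.
#' @export
call_presence <- function(query, proteome,
                          thresholds = presence_thresholds(),
                          params = align_params(),
                          proteome_id = "proteome") {
  if (is.data.frame(query)) query <- query$residues[1]
  qlen <- nchar(query)
  if (is.null(proteome) || nrow(proteome) == 0L) {
    return(data.frame(proteome_id = proteome_id, present = FALSE,
                      best_target_id = NA_character_, identity_pct = 0,
                      coverage_pct = 0, target_length = NA_integer_,
                      score = NA_real_, stringsAsFactors = FALSE))
  }
  best <- NULL
  for (i in seq_len(nrow(proteome))) {
    pa <- align_pair(query, proteome[i, ], params)
    if (is.null(best) || pa$score > best$score) best <- pa
  }
  ic <- identity_and_coverage(best, qlen)
  present <- ic[["identity_pct"]] >= thresholds$identity &&
    ic[["coverage_pct"]] > thresholds$coverage
  data.frame(proteome_id = proteome_id, present = present,
             best_target_id = best$target_id,
             identity_pct = ic[["identity_pct"]],
             coverage_pct = ic[["coverage_pct"]],
             target_length = nchar(
               proteome$residues[proteome$id == best$target_id][1]),
             score = best$score, stringsAsFactors = FALSE)
}

#' Build a presence/absence phylogenetic profile
#'
#' One [call_presence()] per proteome, in input order.
#'
#' @param query Query sequence.
#' @param proteomes Named list of proteome sequence data.frames (one entry
#'   per proteome; names are proteome ids).
#' @param thresholds,params As in [call_presence()].
#' @return A data.frame with one row per proteome (the profile matrix);
#'   the query id is attached as attribute `query_id`.
#' @export
build_profile <- function(query, proteomes,
                          thresholds = presence_thresholds(),
                          params = align_params()) {
  stopifnot(length(proteomes) >= 1L, !is.null(names(proteomes)))
  if (anyDuplicated(names(proteomes))) {
    stop("duplicate proteome ids: ",
         paste(unique(names(proteomes)[duplicated(names(proteomes))]),
               collapse = ", "))
  }
  qid <- if (is.data.frame(query)) query$id[1] else "query"
  calls <- lapply(names(proteomes), function(pid) {
    call_presence(query, proteomes[[pid]], thresholds, params,
                  proteome_id = pid)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  attr(out, "query_id") <- qid
  out
}

#' Summarize a profile by taxonomic rank
#'
#' @param profile A [build_profile()] data.frame.
#' @param taxonomy A [read_taxonomy()] data.frame covering every proteome.
#' @param rank 1-based lineage depth to group by (1 = domain); lineages
#'   shorter than `rank` are grouped by their finest rank.
#' @return A data.frame: `group`, `n_present`, `n_absent`, sorted by
#'   `n_absent` descending, with a final `total` row.
#' @export
summarize_by_taxon <- function(profile, taxonomy, rank = 2L) {
  missing_ <- setdiff(profile$proteome_id, taxonomy$taxon_id)
  if (length(missing_)) {
    stop("proteome(s) without taxonomy: ", paste(missing_, collapse = ", "))
  }
  ranks <- taxonomy$ranks[match(profile$proteome_id, taxonomy$taxon_id)]
  grp <- vapply(ranks, function(r) r[[min(rank, length(r))]], "")
  agg <- do.call(rbind, lapply(split(seq_len(nrow(profile)), grp), function(ix) {
    data.frame(group = grp[ix[1]],
               n_present = sum(profile$present[ix]),
               n_absent = sum(!profile$present[ix]),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(-agg$n_absent, agg$group), , drop = FALSE]
  agg <- rbind(agg, data.frame(group = "total",
                               n_present = sum(profile$present),
                               n_absent = sum(!profile$present)))
  rownames(agg) <- NULL
  agg
}

#' Summary statistics of detected homologues
#'
#' @param profile A [build_profile()] data.frame.
#' @return Named numeric vector: `mean_identity_pct`, `mean_length` over
#'   present calls.
#' @export
distribution_stats <- function(profile) {
  hits <- profile[profile$present, , drop = FALSE]
  if (!nrow(hits)) stop("no present calls in profile")
  c(mean_identity_pct = mean(hits$identity_pct),
    mean_length = mean(hits$target_length))
}
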
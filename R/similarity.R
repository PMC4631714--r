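#' Manhattan dissimilarity between two descriptor vectors
#'
#' d(v1, v2) = sum_i |v1_i - v2_i| over all 5k components. No component or
#' vector normalization is applied — the moments keep their natural scales,
#' so the score responds to molecular size and spatial extent (scale
#' invariance is deliberately avoided).
#'
#' @param v1,v2 descriptor vectors ([fingerprint()] output or plain numeric
#'   of equal length). When both carry a scheme signature the signatures
#'   must agree.
#' @return non-negative dissimilarity score (unitless).
#' @export
manhattan <- function(v1, v2) {
  s1 <- attr(v1, "scheme_sig"); s2 <- attr(v2, "scheme_sig")
  if (!is.null(s1) && !is.null(s2) && !identical(s1, s2)) {
    stop("manhattan(): descriptor vectors come from different tier schemes")
  }
  if (length(v1) != length(v2)) {
    stop("manhattan(): descriptor vectors differ in length (",
         length(v1), " vs ", length(v2), ")")
  }
  sum(abs(as.numeric(v1) - as.numeric(v2)))
}

# Manhattan distances from each query row to each db row:
# returns length-nrow(db) vector of minima over query rows.
min_manhattan_to_db <- function(query_mat, db) {
  best <- rep(Inf, nrow(db))
  for (r in seq_len(nrow(query_mat))) {
    d <- rowSums(abs(db - matrix(query_mat[r, ], nrow(db), ncol(db),
                                 byrow = TRUE)))
    best <- pmin(best, d)
  }
  best
}

#' Ranked similarity search against a fingerprint collection
#'
#' Scores every database entry by its Manhattan dissimilarity to the query;
#' a multi-conformer query (several rows) scores each entry by the minimum
#' over conformers, so the combined ranking inspects the dissimilarity
#' minima. Results are sorted by ascending d, ties broken by hit id, and
#' truncated to `top_k`.
#'
#' @param query a descriptor vector, or a matrix whose rows are conformer
#'   fingerprints of one query.
#' @param db fingerprint matrix ([fingerprint_set()] /
#'   [read_fingerprints()]), rownames = ids.
#' @param top_k maximum number of hits returned (default 100).
#' @param exclude_ids ids omitted from the results (e.g. the query active
#'   in a screening benchmark); default none.
#' @param aggregate `"min"` (default) or `"mean"` over query conformers.
#' @return data.frame with columns `query_id`, `rank`, `hit_id`, `d`.
#' @export
fp_search <- function(query, db, top_k = 100L, exclude_ids = character(),
                      aggregate = c("min", "mean")) {
  aggregate <- match.arg(aggregate)
  qm <- if (is.matrix(query)) query else matrix(as.numeric(query), nrow = 1)
  sq <- attr(query, "scheme_sig"); sd_ <- attr(db, "scheme_sig")
  if (!is.null(sq) && !is.null(sd_) && !identical(sq, sd_)) {
    stop("fp_search(): query and db tier schemes differ")
  }
  if (ncol(qm) != ncol(db)) stop("fp_search(): descriptor length mismatch")
  query_id <- attr(query, "mol_id")
  if (is.null(query_id)) query_id <- rownames(qm)[1]
  if (is.null(query_id)) query_id <- "query"
  keep <- !(rownames(db) %in% exclude_ids)
  cand <- db[keep, , drop = FALSE]
  if (nrow(cand) == 0) {
    warning("fp_search(): no candidates left after exclusion")
    return(data.frame(query_id = character(), rank = integer(),
                      hit_id = character(), d = numeric(),
                      stringsAsFactors = FALSE))
  }
  d <- if (aggregate == "min") {
    min_manhattan_to_db(qm, cand)
  } else {
    tot <- rep(0, nrow(cand))
    for (r in seq_len(nrow(qm))) {
      tot <- tot + rowSums(abs(cand - matrix(qm[r, ], nrow(cand), ncol(cand),
                                             byrow = TRUE)))
    }
    tot / nrow(qm)
  }
  ord <- order(d, rownames(cand), method = "radix")
  ord <- ord[seq_len(min(top_k, length(ord)))]
  data.frame(query_id = query_id, rank = seq_along(ord),
             hit_id = rownames(cand)[ord], d = d[ord],
             stringsAsFactors = FALSE)
}

#' Reduced all-against-all dissimilarity matrix
#'
#' Runs every database entry as a query against the full collection and
#' keeps only the `top_k` best hits per row — the tractable substitute for
#' the full square matrix at library scale. Self-matches are retained by
#' default (a zero-d self hit flags repeated near-identical molecules in
#' the collection); set `include_self = FALSE` to drop each query's own
#' row.
#'
#' @param db fingerprint matrix, rownames = ids, at least 2 rows.
#' @param top_k per-query truncation (default 100).
#' @param include_self keep the query itself among its hits (default TRUE).
#' @return object of class `reduced_matrix`: named list of per-query
#'   results data.frames (see [fp_search()]), attribute `top_k`.
#' @export
reduced_matrix <- function(db, top_k = 100L, include_self = TRUE) {
  if (nrow(db) < 2) stop("reduced_matrix(): need at least 2 entries")
  ids <- rownames(db)
  out <- vector("list", nrow(db))
  names(out) <- ids
  for (i in seq_len(nrow(db))) {
    q <- db[i, , drop = TRUE]
    res <- fp_search(structure(q, mol_id = ids[i],
                               scheme_sig = attr(db, "scheme_sig")),
                     db, top_k = top_k,
                     exclude_ids = if (include_self) character() else ids[i])
    out[[i]] <- res
  }
  structure(out, class = "reduced_matrix", top_k = top_k)
}

#' @export
print.reduced_matrix <- function(x, ...) {
  cat(sprintf("<reduced_matrix> %d queries, top_k = %d\n", length(x),
              attr(x, "top_k")))
  invisible(x)
}

#' Write ranked search results as TSV
#'
#' Long format: query_id, rank, hit_id, d (6 decimals). A `.gz` suffix
#' triggers gzip compression.
#'
#' @param results a results data.frame from [fp_search()] or a
#'   [reduced_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, header_extra = character()) {
  if (inherits(results, "reduced_matrix")) {
    results <- do.call(rbind, c(results, list(make.row.names = FALSE)))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c("# topotier search results", header_extra,
               "query_id\trank\thit_id\td"), con)
  if (nrow(results)) {
    writeLines(sprintf("%s\t%d\t%s\t%.6f", results$query_id, results$rank,
                       results$hit_id, results$d), con)
  }
  invisible(path)
}

#' Full square dissimilarity matrix of a fingerprint collection
#'
#' Convenience for benchmark-scale sets (e.g. grouped pocket/ligand
#' classification): all pairwise Manhattan distances as a symmetric matrix
#' with zero diagonal.
#'
#' @param db fingerprint matrix, rownames = ids.
#' @return square numeric matrix with dimnames = ids.
#' @export
dissimilarity_matrix <- function(db) {
  m <- as.matrix(stats::dist(db, method = "manhattan"))
  dimnames(m) <- list(rownames(db), rownames(db))
  m
}
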
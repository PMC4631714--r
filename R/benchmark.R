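#' Screening set of actives and decoys
#'
#' @param actives named list: id -> fingerprint matrix (rows = conformers).
#' @param decoys named list with the same shape.
#' @return object of class `screen_set` with counts `A` and `D`.
#' @export
screen_set <- function(actives, decoys) {
  as_fp_list <- function(x) {
    lapply(x, function(f) if (is.matrix(f)) f else matrix(as.numeric(f),
                                                          nrow = 1))
  }
  if (length(actives) < 1 || length(decoys) < 1) {
    stop("screen_set(): need at least one active and one decoy")
  }
  ids <- c(names(actives), names(decoys))
  if (is.null(names(actives)) || is.null(names(decoys)) ||
      anyDuplicated(ids)) {
    stop("screen_set(): actives and decoys must carry unique ids")
  }
  structure(list(actives = as_fp_list(actives), decoys = as_fp_list(decoys),
                 A = length(actives), D = length(decoys)),
            class = "screen_set")
}

round_half_up <- function(x) floor(x + 0.5)

#' Enrichment factor of one ranked screen
#'
#' EF at the top x% fraction: the active/decoy count ratio in the top
#' segment of the ranked list, normalized by the dataset ratio A/D. The
#' segment holds the first `round(x/100 * length(ranked))` entries
#' (half-up rounding, minimum 1). When the segment contains no decoy the
#' EF is incalculable and `NA` is returned (the queries concerned are
#' counted, not averaged, by [screen_target()]).
#'
#' @param ranked ranked hit ids (character vector, best first) or a
#'   results data.frame from [fp_search()] (its `hit_id` column is used).
#'   The query active itself must not be present.
#' @param active_ids ids counted as actives.
#' @param x_pct top fraction in percent, in (0, 100].
#' @param A,D total unique actives and decoys in the dataset.
#' @return EF (non-negative) or `NA` when incalculable.
#' @export
enrichment_factor <- function(ranked, active_ids, x_pct, A, D) {
  if (is.data.frame(ranked)) ranked <- ranked$hit_id
  if (!(x_pct > 0 && x_pct <= 100)) stop("enrichment_factor(): x_pct must be in (0, 100]")
  if (A < 1 || D < 1) stop("enrichment_factor(): A and D must be >= 1")
  seg_n <- max(1L, round_half_up(x_pct / 100 * length(ranked)))
  seg_n <- min(seg_n, length(ranked))
  seg <- ranked[seq_len(seg_n)]
  a <- sum(seg %in% active_ids)
  d <- seg_n - a
  if (d == 0) return(NA_real_)
  (a / d) / (A / D)
}

#' Screen every active of a set as query and average the enrichment
#'
#' For each active the remaining actives plus all decoys are ranked by
#' minimum-over-conformer Manhattan dissimilarity (query active excluded
#' from its own results), and the EF computed at each fraction. Averages
#' are over calculable queries only; incalculable ones (no decoy in the
#' segment — perfect retrieval at that depth) are counted per fraction.
#'
#' @param set a [screen_set()].
#' @param fractions percent fractions (default `c(1.0, 0.25)`).
#' @param query_conformer index of the conformer used as query for each
#'   active (default 1; conformer selection, e.g. lowest energy, happens
#'   upstream).
#' @return object of class `enrichment_report`: list with `per_query`
#'   (data.frame: query_id, fraction, a plus EF or NA) and `summary`
#'   (data.frame: fraction, mean_ef, n_calculable, n_incalculable).
#' @export
screen_target <- function(set, fractions = c(1.0, 0.25),
                          query_conformer = 1L) {
  if (!inherits(set, "screen_set")) stop("screen_target(): set must be a screen_set")
  if (set$A < 2) stop("screen_target(): need A >= 2 to exclude the query and keep actives")
  db <- rbind(do.call(rbind, set$actives), do.call(rbind, set$decoys))
  # conformers of one id collapse to that id's best d: group rows by id
  row_id <- c(rep(names(set$actives), vapply(set$actives, nrow, integer(1))),
              rep(names(set$decoys), vapply(set$decoys, nrow, integer(1))))
  active_ids <- names(set$actives)
  per <- list()
  for (qid in active_ids) {
    qfp <- set$actives[[qid]]
    qr <- min(query_conformer, nrow(qfp))
    dvec <- min_manhattan_to_db(qfp[qr, , drop = FALSE], db)
    keep <- row_id != qid
    d_by_id <- tapply(dvec[keep], row_id[keep], min)
    ord <- order(d_by_id, names(d_by_id), method = "radix")
    ranked <- names(d_by_id)[ord]
    for (x in fractions) {
      per[[length(per) + 1L]] <- data.frame(
        query_id = qid, fraction = x,
        ef = enrichment_factor(ranked, active_ids, x, set$A, set$D),
        stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, per)
  summ <- do.call(rbind, lapply(fractions, function(x) {
    ef <- per$ef[per$fraction == x]
    data.frame(fraction = x,
               mean_ef = if (all(is.na(ef))) NA_real_ else mean(ef, na.rm = TRUE),
               n_calculable = sum(!is.na(ef)),
               n_incalculable = sum(is.na(ef)))
  }))
  structure(list(per_query = per, summary = summ),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("<enrichment_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Grouped dissimilarity matrix for classification benchmarks
#'
#' @param dissimilarity square symmetric matrix of pairwise dissimilarity
#'   scores (zero diagonal), dimnames = item ids.
#' @param groups named character/factor vector of group labels (names =
#'   item ids) or unnamed vector in matrix order.
#' @return object of class `grouped_matrix`.
#' @export
grouped_matrix <- function(dissimilarity, groups) {
  m <- as.matrix(dissimilarity)
  if (nrow(m) != ncol(m)) stop("grouped_matrix(): matrix must be square")
  if (max(abs(m - t(m))) > 1e-9) stop("grouped_matrix(): matrix must be symmetric within 1e-9")
  if (any(abs(diag(m)) > 1e-12)) stop("grouped_matrix(): diagonal must be zero")
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  if (!is.null(names(groups))) groups <- groups[ids]
  if (length(groups) != nrow(m) || anyNA(groups)) {
    stop("grouped_matrix(): need one group label per matrix row")
  }
  structure(list(ids = ids, d = m, groups = as.character(groups)),
            class = "grouped_matrix")
}

# Rank-sum (Mann-Whitney) AUC with tie correction: positives should have
# LOW dissimilarity, so rank by -d.
rank_sum_auc <- function(d, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(-d, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Per-query ROC AUC over ligand groups
#'
#' Each item in turn is the query; all other items are ranked by ascending
#' dissimilarity, positives being the query's own group. The AUC is the
#' tie-corrected rank-sum (Mann--Whitney) estimator; queries whose group has
#' no other member are skipped with a warning. The average is the mean over
#' scored queries.
#'
#' @param gm a [grouped_matrix()].
#' @return object of class `roc_report`: list with `per_query` (data.frame:
#'   query_id, group, auc), `average_auc`, `n_skipped`.
#' @export
roc_analysis <- function(gm) {
  if (!inherits(gm, "grouped_matrix")) stop("roc_analysis(): gm must be a grouped_matrix")
  if (length(unique(gm$groups)) < 2) stop("roc_analysis(): need at least 2 groups")
  n <- length(gm$ids)
  auc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    pos <- gm$groups[others] == gm$groups[i]
    if (!any(pos)) next
    auc[i] <- rank_sum_auc(gm$d[i, others], pos)
  }
  skipped <- is.na(auc)
  if (any(skipped)) {
    warning("roc_analysis(): skipped ", sum(skipped),
            " singleton-group query(ies)")
  }
  structure(list(per_query = data.frame(query_id = gm$ids,
                                        group = gm$groups, auc = auc,
                                        stringsAsFactors = FALSE),
                 average_auc = mean(auc, na.rm = TRUE),
                 n_skipped = sum(skipped)),
            class = "roc_report")
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf("<roc_report> %d queries, average AUC = %.4f",
              nrow(x$per_query), x$average_auc))
  if (x$n_skipped) cat(sprintf(" (%d skipped)", x$n_skipped))
  cat("\n")
  by_group <- tapply(x$per_query$auc, x$per_query$group, mean, na.rm = TRUE)
  print(round(by_group, 4))
  invisible(x)
}

#' Write a grouped dissimilarity matrix and its labels
#'
#' The matrix goes to `<path>` as TSV with an id header row and column;
#' labels go to `<path base>_groups.tsv` as two columns (id, group).
#'
#' @param gm a [grouped_matrix()].
#' @param path matrix output path (.tsv).
#' @return `path`, invisibly.
#' @export
write_grouped_matrix <- function(gm, path) {
  utils::write.table(data.frame(id = gm$ids, gm$d, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  gpath <- sub("\\.tsv$", "", path)
  utils::write.table(data.frame(id = gm$ids, group = gm$groups),
                     paste0(gpath, "_groups.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a grouped dissimilarity matrix written by [write_grouped_matrix()]
#' @param path matrix TSV path.
#' @return a [grouped_matrix()].
#' @export
read_grouped_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$id
  g <- utils::read.delim(paste0(sub("\\.tsv$", "", path), "_groups.tsv"),
                         stringsAsFactors = FALSE)
  grouped_matrix(m, stats::setNames(g$group, g$id))
}
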
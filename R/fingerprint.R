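#' Charge-tier scheme
#'
#' An ordered partition of the partial-charge axis into `k` disjoint
#' intervals covering the whole real line. Every atom falls in exactly one
#' tier; the fingerprint concatenates the moment block of each tier in
#' scheme order. The default tripartite scheme places the boundaries at
#' +/- 0.1 e with the central tier closed on both sides:
#' M = (-Inf, -0.1), N0 = [-0.1, +0.1], P = (+0.1, +Inf).
#'
#' @param boundaries numeric vector of interior cut points, strictly
#'   increasing (default `c(-0.1, 0.1)`).
#' @param closed character vector, one entry per cut point: `"upper"` if a
#'   charge exactly at the cut belongs to the tier above it, `"lower"` if to
#'   the tier below. The default `c("upper", "lower")` makes the central
#'   tier closed on both sides, so both boundary charges (+/- 0.1) land in
#'   N0.
#' @param labels optional tier labels; default `M`, `N0`, `P` for k = 3,
#'   otherwise `T1..Tk` (ordered most negative first).
#' @return object of class `tier_scheme` with fields `boundaries`, `closed`,
#'   `k`, `labels`.
#' @export
tier_scheme <- function(boundaries = c(-0.1, 0.1), closed = NULL,
                        labels = NULL) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 1 || is.unsorted(boundaries, strictly = TRUE)) {
    stop("tier_scheme(): boundaries must be strictly increasing")
  }
  k <- length(boundaries) + 1L
  if (is.null(closed)) {
    closed <- if (k == 3) c("upper", "lower") else rep("lower", k - 1L)
  }
  if (length(closed) != k - 1L || !all(closed %in% c("lower", "upper"))) {
    stop("tier_scheme(): closed must be ", k - 1L,
         " entries of 'lower'/'upper'")
  }
  if (is.null(labels)) {
    labels <- if (k == 3) c("M", "N0", "P") else paste0("T", seq_len(k))
  }
  if (length(labels) != k) stop("tier_scheme(): need ", k, " labels")
  structure(list(boundaries = boundaries, closed = closed, k = k,
                 labels = labels),
            class = "tier_scheme")
}

#' @export
print.tier_scheme <- function(x, ...) {
  lo <- c(-Inf, x$boundaries); hi <- c(x$boundaries, Inf)
  lob <- c("(", ifelse(x$closed == "upper", "[", "("))
  hib <- c(ifelse(x$closed == "lower", "]", ")"), ")")
  cat(sprintf("<tier_scheme> k = %d\n", x$k))
  for (t in seq_len(x$k)) {
    cat(sprintf("  %-4s %s%.4g, %.4g%s\n", x$labels[t], lob[t], lo[t],
                hi[t], hib[t]))
  }
  invisible(x)
}

# Tier index (1 = most negative) for each charge value.
tier_index <- function(q, scheme) {
  idx <- rep(1L, length(q))
  for (i in seq_along(scheme$boundaries)) {
    cut <- scheme$boundaries[i]
    above <- q > cut | (q == cut & scheme$closed[i] == "upper")
    idx <- idx + as.integer(above)
  }
  idx
}

scheme_signature <- function(scheme) {
  paste0("k", scheme$k, ":",
         paste(sprintf("%.17g", scheme$boundaries), collapse = ","),
         ":", paste(substr(scheme$closed, 1, 1), collapse = ""))
}

#' Partition atoms into charge tiers
#'
#' @param mol a charged [molecule()].
#' @param scheme a [tier_scheme()].
#' @return list of `k` integer vectors of atom indices (scheme order, most
#'   negative tier first); each atom index appears in exactly one tier.
#' @export
partition_by_charge <- function(mol, scheme = tier_scheme()) {
  q <- charges(mol)
  if (anyNA(q)) {
    stop("partition_by_charge(): uncharged atom(s); run ensure_charges() first")
  }
  idx <- tier_index(q, scheme)
  out <- lapply(seq_len(scheme$k), function(t) which(idx == t))
  names(out) <- scheme$labels
  out
}

#' Within-tier pairwise distance distribution
#'
#' The multiset of Euclidean distances over all ordered atom pairs (i, j),
#' i != j, within one tier — the diagonal is skipped, and each unordered
#' pair contributes twice, so the multiset has n^2 - n values for n tier
#' atoms.
#'
#' @param mol a [molecule()].
#' @param indices integer atom indices of the tier.
#' @return object of class `tier_distances`: list with `n_tier` and
#'   `values` (numeric, length n_tier^2 - n_tier; empty when n_tier <= 1).
#' @export
tier_distances <- function(mol, indices) {
  n <- length(indices)
  if (n <= 1) {
    return(structure(list(n_tier = n, values = numeric()),
                     class = "tier_distances"))
  }
  d <- as.numeric(stats::dist(coords(mol)[indices, , drop = FALSE]))
  structure(list(n_tier = n, values = rep(d, 2L)), class = "tier_distances")
}

#' Moments of a tier's distance distribution
#'
#' Five summaries of the off-diagonal pairwise-distance multiset of a tier
#' with n atoms (sums run over all n^2 - n ordered pairs):
#' \describe{
#'   \item{c1}{sum of distances / n^3 — spatial dispersion weighted down by
#'     the atom count.}
#'   \item{c2}{sample mean of the off-diagonal distances (sum / (n^2 - n)).}
#'   \item{c3}{(1/n^2) sum (x - c2)^2 — the dispersion term.}
#'   \item{c4}{standardized skewness: (1/n^2) sum (x - c2)^3 / c3^(3/2).}
#'   \item{c5}{Fisher kurtosis: (1/n^2) sum (x - c2)^4 / c3^2 - 3.}
#' }
#' Tiers with zero or one atom contribute five exact zeros; when c3 = 0
#' with n >= 2 (all distances equal) c4 and c5 are set to 0 by convention.
#' Note the deliberate normalization asymmetry — c2 averages over the
#' n^2 - n off-diagonal pairs while the central sums of c3--c5 are divided
#' by n^2 — kept as defined; see the methods vignette.
#'
#' @param dist a [tier_distances()] object.
#' @return named numeric vector `c(c1, c2, c3, c4, c5)`.
#' @export
compute_moments <- function(dist) {
  n <- as.numeric(dist$n_tier)   # n^3 overflows integer arithmetic
  out <- c(c1 = 0, c2 = 0, c3 = 0, c4 = 0, c5 = 0)
  if (n <= 1) return(out)
  x <- dist$values
  c2 <- mean(x)                      # n^2 - n terms
  dev <- x - c2
  n2 <- n * n
  c1 <- sum(x) / (n2 * n)
  c3 <- sum(dev^2) / n2
  if (c3 > 0) {
    c4 <- (sum(dev^3) / n2) / c3^1.5
    c5 <- (sum(dev^4) / n2) / c3^2 - 3
  } else {
    c4 <- 0; c5 <- 0
  }
  c(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5)
}

#' Charge-tiered shape-distribution fingerprint of a molecule
#'
#' Partitions the atoms by partial charge, computes each tier's
#' pairwise-distance moments and concatenates them in scheme order (most
#' negative tier first), giving a 5k-vector (15 for the default tripartite
#' scheme). The vector is invariant under rigid motion and atom reordering
#' but deliberately not under scaling.
#'
#' @param mol a charged [molecule()].
#' @param scheme a [tier_scheme()].
#' @return numeric vector of length `5 * scheme$k`, classed `topo_fp`, with
#'   attributes `scheme_sig`, `tier_counts`, `mol_id`; names are
#'   `<tier>.<moment>`.
#' @export
fingerprint <- function(mol, scheme = tier_scheme()) {
  tiers <- partition_by_charge(mol, scheme)
  blocks <- lapply(tiers, function(ix) compute_moments(tier_distances(mol, ix)))
  v <- unlist(blocks, use.names = FALSE)
  names(v) <- paste(rep(scheme$labels, each = 5L),
                    rep(c("c1", "c2", "c3", "c4", "c5"), scheme$k), sep = ".")
  structure(v,
            class = "topo_fp",
            scheme_sig = scheme_signature(scheme),
            tier_counts = lengths(tiers),
            mol_id = mol$mol_id)
}

#' @export
print.topo_fp <- function(x, ...) {
  cat(sprintf("<topo_fp> %s (tier counts: %s)\n", attr(x, "mol_id"),
              paste(attr(x, "tier_counts"), collapse = "/")))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Fingerprint a set of molecules into a collection matrix
#'
#' @param mols list of charged [molecule()] objects.
#' @param scheme a [tier_scheme()].
#' @return numeric matrix, one row per molecule (rownames = mol ids),
#'   5k columns; attribute `scheme_sig` records the scheme.
#' @export
fingerprint_set <- function(mols, scheme = tier_scheme()) {
  if (!length(mols)) {
    m <- matrix(numeric(), nrow = 0, ncol = 5L * scheme$k)
    attr(m, "scheme_sig") <- scheme_signature(scheme)
    return(m)
  }
  fps <- lapply(mols, fingerprint, scheme = scheme)
  m <- do.call(rbind, lapply(fps, as.numeric))
  rownames(m) <- vapply(fps, attr, character(1), "mol_id")
  colnames(m) <- names(fps[[1]])
  attr(m, "scheme_sig") <- scheme_signature(scheme)
  m
}

#' Write fingerprints to a TSV file
#'
#' One record per molecule: mol_id, k, tier counts and the 5k moments at 17
#' significant digits, so a write/read round trip is bit-exact. A `#` header
#' names the scheme and tier order. A `.gz` suffix triggers gzip
#' compression.
#'
#' @param fps fingerprint matrix from [fingerprint_set()] (needs attribute
#'   `scheme_sig` and per-row `tier_counts` are recomputed from columns when
#'   absent).
#' @param path output path (`.tsv` or `.tsv.gz`).
#' @param tier_counts optional integer matrix (rows matching `fps`) of
#'   per-tier atom counts.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fps, path, tier_counts = NULL,
                               header_extra = character()) {
  k <- ncol(fps) / 5L
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# topotier fingerprints; scheme=",
                      attr(fps, "scheme_sig"),
                      "; tier order most-negative first"),
               header_extra,
               paste(c("mol_id", "k", "tier_counts", colnames(fps)),
                     collapse = "\t")), con)
  tc <- if (is.null(tier_counts)) {
    matrix(NA_integer_, nrow(fps), k)
  } else tier_counts
  if (nrow(fps)) {
    rows <- vapply(seq_len(nrow(fps)), function(i) {
      paste(c(rownames(fps)[i], k,
              paste(tc[i, ], collapse = ","),
              sprintf("%.17g", fps[i, ])), collapse = "\t")
    }, character(1))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read fingerprints written by [write_fingerprints()]
#'
#' @param path TSV(.gz) path.
#' @return fingerprint matrix with `scheme_sig` attribute and, when present
#'   in the file, a `tier_counts` attribute.
#' @export
read_fingerprints <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  header <- lines[startsWith(lines, "#")][1]
  sig <- sub(".*scheme=([^;]+);.*", "\\1", header)
  body <- lines[!startsWith(lines, "#")]
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  body <- body[-1]
  vals <- strsplit(body, "\t", fixed = TRUE)
  m <- if (length(vals)) {
    do.call(rbind, lapply(vals, function(v) as.numeric(v[-(1:3)])))
  } else matrix(numeric(), 0, length(cols) - 3L)
  rownames(m) <- vapply(vals, `[`, character(1), 1L)
  colnames(m) <- cols[-(1:3)]
  attr(m, "scheme_sig") <- sig
  if (length(vals)) {
    attr(m, "tier_counts") <- do.call(rbind, lapply(vals, function(v) {
      suppressWarnings(as.integer(strsplit(v[3], ",", fixed = TRUE)[[1]]))
    }))
  }
  m
}
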
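test_that("enrichment factor reproduces the direct arithmetic case", {
  # 100-entry ranking, 10% segment with 5 actives and 5 decoys:
  # EF = (5/5) / (10/90) = 9
  actives <- paste0("act", 1:10)
  decoys <- paste0("dec", 1:90)
  ranked <- c(actives[1:5], decoys[1:5], actives[6:10], decoys[6:90])
  expect_equal(enrichment_factor(ranked, actives, 10, A = 10, D = 90), 9.0)
  # all-active top segment: incalculable
  perfect <- c(actives, decoys)
  expect_true(is.na(enrichment_factor(perfect, actives, 10, A = 10, D = 90)))
  # EF is invariant to permutations within the top segment
  shuffled <- c(sample(ranked[1:10]), ranked[-(1:10)])
  expect_equal(enrichment_factor(shuffled, actives, 10, A = 10, D = 90), 9.0)
  expect_error(enrichment_factor(ranked, actives, 0, 10, 90), "x_pct")
})

test_that("top segment size uses half-up rounding with a floor of one", {
  actives <- "a1"
  ranked <- c("a1", paste0("d", 1:199))           # 200 entries
  # 0.25% of 200 = 0.5 -> rounds half-up to 1
  expect_true(is.na(enrichment_factor(ranked, actives, 0.25, 2, 199)))
  ranked2 <- c("d0", "a1", paste0("d", 1:198))
  # segment of 1 holds a decoy: a=0 -> EF = 0
  expect_equal(enrichment_factor(ranked2, actives, 0.25, 2, 199), 0)
  # 1% of 150 = 1.5 -> 2 entries
  ranked3 <- c("a1", "d1", paste0("d", 2:149))
  ef <- enrichment_factor(ranked3, "a1", 1, A = 10, D = 140)
  expect_equal(ef, (1 / 1) / (10 / 140))
})

test_that("random rankings give mean EF near 1 (Monte-Carlo null)", {
  set.seed(17)
  A <- 20L; D <- 180L
  actives <- paste0("a", seq_len(A))
  pool <- c(actives, paste0("d", seq_len(D)))
  efs <- replicate(1000, {
    enrichment_factor(sample(pool), actives, 25, A = A, D = D)
  })
  efs <- efs[!is.na(efs)]
  se <- stats::sd(efs) / sqrt(length(efs))
  expect_lt(abs(mean(efs) - 1), 3 * se)
})

test_that("screen_target averages calculable EFs and counts the rest", {
  # 4 identical actives far from 20 decoys: every query retrieves the
  # other actives first, so the 1% segment (round(23*0.01)=0 -> 1 entry)
  # holds an active only -> incalculable for every query
  base <- fingerprint(random_mol(25, seed = 5))
  far <- fingerprint(random_mol(60, seed = 6))
  actives <- stats::setNames(lapply(1:4, function(i) {
    matrix(as.numeric(base), nrow = 1)
  }), paste0("act", 1:4))
  decoys <- stats::setNames(lapply(1:20, function(i) {
    matrix(as.numeric(far) + i, nrow = 1)
  }), paste0("dec", 1:20))
  rep_ <- screen_target(screen_set(actives, decoys),
                        fractions = c(1.0, 25))
  expect_equal(sort(unique(rep_$summary$fraction)), c(1.0, 25))
  row1 <- rep_$summary[rep_$summary$fraction == 1.0, ]
  expect_equal(row1$n_incalculable, 4L)
  expect_true(is.na(row1$mean_ef))
  # at 25% (segment of 6: 3 actives + 3 decoys) EF = (3/3)/(4/20) = 5
  row25 <- rep_$summary[rep_$summary$fraction == 25, ]
  expect_equal(row25$mean_ef, 5)
  expect_equal(row25$n_calculable, 4L)
})

test_that("a decoy pinned at rank 1 depresses small-fraction enrichment", {
  # actives sit on distant axes (pairwise d = 200); one decoy at the
  # origin is d = 100 from every active, so it always ranks first
  actives <- stats::setNames(lapply(1:5, function(i) {
    v <- rep(0, 15); v[i] <- 100
    matrix(v, nrow = 1)
  }), paste0("act", 1:5))
  decoys <- c(list(dec_close = matrix(rep(0, 15), nrow = 1)),
              stats::setNames(lapply(1:30, function(i) {
                matrix(rep(1000 + i, 15), nrow = 1)
              }), paste0("dec", 1:30)))
  rep_ <- screen_target(screen_set(actives, decoys), fractions = 3)
  # 3% of 35 ranked entries -> segment of 1, always the close decoy
  expect_true(all(rep_$per_query$ef == 0))
  expect_lt(rep_$summary$mean_ef, 1)
  expect_error(screen_target(screen_set(actives["act1"], decoys)),
               "A >= 2")
})

test_that("grouped matrices validate symmetry, diagonal and labels", {
  m <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  gm <- grouped_matrix(m, c(a = "g1", b = "g2"))
  expect_equal(gm$groups, c("g1", "g2"))
  bad <- m; bad[1, 2] <- 2
  expect_error(grouped_matrix(bad, c(a = "g1", b = "g2")), "symmetric")
  badd <- m; diag(badd) <- 0.5
  expect_error(grouped_matrix(badd, c(a = "g1", b = "g2")), "diagonal")
  expect_error(grouped_matrix(m, c(a = "g1")), "label")
})

test_that("perfect within-group separation yields AUC 1 for every query", {
  n <- 12
  groups <- rep(c("g1", "g2", "g3"), each = 4)
  d <- matrix(5, n, n) + stats::runif(n * n) # between-group: ~5-6
  d <- (d + t(d)) / 2
  same <- outer(groups, groups, "==")
  d[same] <- 0.5                              # within-group: 0.5
  diag(d) <- 0
  ids <- paste0("m", 1:n)
  dimnames(d) <- list(ids, ids)
  r <- roc_analysis(grouped_matrix(d, stats::setNames(groups, ids)))
  expect_true(all(r$per_query$auc == 1))
  expect_equal(r$average_auc, 1)
})

test_that("reversing the scores maps AUC to 1 - AUC", {
  set.seed(5)
  n <- 20
  groups <- rep(c("g1", "g2"), each = 10)
  d <- matrix(stats::runif(n * n, 1, 10), n)
  d <- (d + t(d)) / 2; diag(d) <- 0
  ids <- paste0("m", 1:n); dimnames(d) <- list(ids, ids)
  gm <- grouped_matrix(d, stats::setNames(groups, ids))
  r1 <- roc_analysis(gm)
  rev_d <- max(d) + 1 - d; diag(rev_d) <- 0
  r2 <- roc_analysis(grouped_matrix(rev_d, stats::setNames(groups, ids)))
  expect_equal(r2$per_query$auc, 1 - r1$per_query$auc, tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone transforms of d", {
  set.seed(6)
  n <- 16
  groups <- rep(c("g1", "g2", "g3", "g4"), each = 4)
  d <- matrix(stats::runif(n * n, 0.5, 4), n)
  d <- (d + t(d)) / 2; diag(d) <- 0
  ids <- paste0("m", 1:n); dimnames(d) <- list(ids, ids)
  gm1 <- grouped_matrix(d, stats::setNames(groups, ids))
  d2 <- d^3; diag(d2) <- 0
  gm2 <- grouped_matrix(d2, stats::setNames(groups, ids))
  expect_equal(roc_analysis(gm1)$per_query$auc,
               roc_analysis(gm2)$per_query$auc, tolerance = 1e-12)
})

test_that("rank-sum AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  n <- 30
  groups <- sample(rep(c("g1", "g2", "g3"), each = 10))
  d <- matrix(stats::runif(n * n, 0, 5), n)
  d <- (d + t(d)) / 2; diag(d) <- 0
  ids <- paste0("m", 1:n); dimnames(d) <- list(ids, ids)
  r <- roc_analysis(grouped_matrix(d, stats::setNames(groups, ids)))
  for (i in c(1, 7, 23)) {
    others <- setdiff(1:n, i)
    ref <- suppressMessages(pROC::auc(
      response = factor(groups[others] == groups[i],
                        levels = c(FALSE, TRUE)),
      predictor = -d[i, others], direction = "<"))
    expect_equal(r$per_query$auc[i], as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("permuted labels give mean AUC near 0.5 (Monte-Carlo null)", {
  set.seed(9)
  n <- 24
  d <- matrix(stats::runif(n * n, 1, 8), n)
  d <- (d + t(d)) / 2; diag(d) <- 0
  ids <- paste0("m", 1:n); dimnames(d) <- list(ids, ids)
  base_groups <- rep(c("g1", "g2", "g3"), each = 8)
  aucs <- replicate(500, {
    g <- sample(base_groups)
    roc_analysis(grouped_matrix(d, stats::setNames(g, ids)))$average_auc
  })
  se <- stats::sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se)
})

test_that("singleton groups are skipped with a warning", {
  n <- 5
  d <- matrix(1, n, n); diag(d) <- 0
  ids <- paste0("m", 1:n); dimnames(d) <- list(ids, ids)
  g <- c("a", "a", "b", "b", "lonely")
  expect_warning(r <- roc_analysis(grouped_matrix(d, stats::setNames(g, ids))),
                 "singleton")
  expect_equal(r$n_skipped, 1L)
})

test_that("grouped matrices round-trip through TSV", {
  n <- 6
  d <- matrix(stats::runif(n * n), n); d <- (d + t(d)) / 2; diag(d) <- 0
  ids <- paste0("m", 1:n); dimnames(d) <- list(ids, ids)
  gm <- grouped_matrix(d, stats::setNames(rep(c("x", "y"), 3), ids))
  path <- file.path(tempdir(), "gm_test.tsv")
  write_grouped_matrix(gm, path)
  back <- read_grouped_matrix(path)
  expect_equal(back$d, gm$d, tolerance = 1e-12)
  expect_equal(back$groups, gm$groups)
})
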
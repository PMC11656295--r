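# Preprocessing options: filtering, duplicate collapsing, transformation
# and gene-level scoring, each checked against direct computation or the
# corresponding base-R test as an independent oracle.

test_that("prefilter keeps the right genes and never invents new ones", {
  cnt <- toy_counts()
  expect_identical(prefilter(cnt, "none"), cnt)

  m <- matrix(c(0L, 0L, 4L, 5L, 5L, 5L), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  kept <- prefilter(m, "total_count", threshold = 10)
  expect_identical(rownames(kept), "c")  # row sums 0, 9, 10

  expect_identical(prefilter(cnt, "cpm_filter", cpm_cutoff = 0,
                             min_samples = 0), cnt)
  # property: output genes always a subset of input genes
  for (opt in c("none", "total_count", "cpm_filter")) {
    out <- prefilter(cnt, opt, threshold = 300, cpm_cutoff = 1,
                     min_samples = 2)
    expect_true(all(rownames(out) %in% rownames(cnt)))
    expect_identical(colnames(out), colnames(cnt))
  }
  expect_error(prefilter(m, "total_count", threshold = 1e6), "every gene")
})

test_that("deduplicate collapses many-to-one IDs by the chosen rule", {
  m <- matrix(c(5L, 5L, 7L, 7L, 1L, 1L), 3, 2, byrow = TRUE,
              dimnames = list(c("src1", "src2", "src3"), c("s1", "s2")))
  tbl <- data.frame(source = c("src1", "src2", "src3"),
                    target = c("T1", "T1", "T2"))

  first <- deduplicate(m, tbl, "keep_first")
  expect_identical(rownames(first), c("T1", "T2"))
  expect_identical(unname(first["T1", ]), c(5L, 5L))  # earlier row wins

  best <- deduplicate(m, tbl, "keep_highest_mean")
  expect_identical(unname(best["T1", ]), c(7L, 7L))  # mean 7 beats mean 5

  # bijective table: content unchanged, IDs relabeled
  bij <- data.frame(source = rownames(m), target = c("x", "y", "z"))
  out <- deduplicate(m, bij, "keep_first")
  expect_identical(unname(out), unname(m))
  expect_identical(rownames(out), c("x", "y", "z"))

  # unmapped source rows are dropped with a note, never an error
  expect_message(
    dropped <- deduplicate(m, tbl[1:2, ], "keep_first"),
    "dropped")
  expect_identical(rownames(dropped), "T1")

  # property: output IDs unique on simulated many-to-one tables
  cnt <- toy_counts(60, 6)
  t2 <- simulate_id_table(rownames(cnt), 0.3, seed = 4)
  for (opt in c("keep_first", "keep_highest_mean")) {
    expect_false(any(duplicated(rownames(deduplicate(cnt, t2, opt)))))
  }
})

test_that("transform options normalize as documented", {
  cnt <- toy_counts(20, 4)
  cpm <- transform_counts(cnt, "cpm")
  expect_equal(unname(colSums(cpm)), rep(1e6, 4))

  one <- cnt[, 1, drop = FALSE]
  expect_equal(sum(transform_counts(one, "cpm")), 1e6)

  # two identical columns: median-ratio size factors agree, columns match
  two <- cbind(s1 = cnt[, 1], s2 = cnt[, 1])
  rownames(two) <- rownames(cnt)
  mr <- transform_counts(two, "median_ratio_log")
  expect_equal(mr[, 1], mr[, 2])

  # hand-computed median-of-ratios: columns (10,10) and (20,20) have size
  # factors proportional to (1, 2), so normalized columns coincide
  toy <- matrix(c(10L, 20L, 10L, 20L), 2, 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("s1", "s2")))
  tr <- transform_counts(toy, "median_ratio_log")
  expect_equal(tr[, "s1"], tr[, "s2"])

  zero_col <- cbind(cnt[, 1], 0L)
  dimnames(zero_col) <- list(rownames(cnt), c("s1", "s2"))
  expect_error(transform_counts(zero_col, "cpm"), "all-zero")

  # fallback when no gene has all-nonzero counts
  sparse <- matrix(c(3L, 0L, 0L, 4L), 2, 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_message(transform_counts(sparse, "median_ratio_log"), "fall")

  # permutation equivariance in the gene dimension
  perm <- sample(nrow(cnt))
  for (opt in c("cpm", "log2_cpm", "median_ratio_log")) {
    expect_equal(transform_counts(cnt, opt)[perm, ],
                 transform_counts(cnt[perm, ], opt))
  }
})

test_that("welch_t matches t.test and behaves symmetrically", {
  x <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
  colnames(x) <- paste0("s", 1:6)
  la <- label_assignment(colnames(x), rep(c("A", "B"), each = 3))
  de <- de_score(x, la, "welch_t")
  expect_equal(de$statistic, -3.674, tolerance = 5e-4)

  # t.test as the independent oracle on random data
  set.seed(7)
  xm <- matrix(rnorm(40 * 10, sd = 2), 40, 10,
               dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:10)))
  lab <- label_assignment(colnames(xm), rep(c("A", "B"), each = 5))
  de2 <- de_score(xm, lab, "welch_t")
  for (i in c(1, 13, 40)) {
    tt <- t.test(xm[i, 1:5], xm[i, 6:10])
    expect_equal(de2$statistic[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(de2$p_value[i], tt$p.value, tolerance = 1e-10)
  }

  # no-effect gene
  flat <- rbind(g1 = rep(c(2, 3, 4), 2))
  colnames(flat) <- paste0("s", 1:6)
  la6 <- label_assignment(colnames(flat), rep(c("A", "B"), 3)[c(1, 3, 5, 2, 4, 6)])
  flat2 <- rbind(g1 = c(1, 1, 1, 1, 1, 1))
  colnames(flat2) <- paste0("s", 1:6)
  de0 <- de_score(flat2, la, "welch_t")
  expect_equal(de0$statistic, 0)
  expect_equal(de0$p_value, 1)

  # swapping the reference level negates every signed statistic
  swapped <- label_assignment(colnames(xm),
                              factor(rep(c("A", "B"), each = 5),
                                     levels = c("B", "A")))
  de3 <- de_score(xm, swapped, "welch_t")
  expect_equal(de3$statistic, -de2$statistic)
})

test_that("wilcoxon_z matches the normal-approximation rank-sum test", {
  set.seed(11)
  xm <- matrix(rnorm(25 * 12), 25, 12,
               dimnames = list(sprintf("g%02d", 1:25), sprintf("s%02d", 1:12)))
  xm[3, ] <- round(xm[3, ])  # force ties
  lab <- label_assignment(colnames(xm), rep(c("A", "B"), each = 6))
  de <- de_score(xm, lab, "wilcoxon_z")
  for (i in c(1, 3, 25)) {
    wt <- wilcox.test(xm[i, 1:6], xm[i, 7:12], exact = FALSE,
                      correct = FALSE)
    expect_equal(de$p_value[i], wt$p.value, tolerance = 1e-10)
  }
})

test_that("snr floors denominators and moderated_t shrinks variances", {
  # two genes with f-formula check: snr on a constant gene stays finite
  x <- rbind(const = rep(5, 8), var = c(1, 2, 3, 4, 8, 9, 10, 11))
  colnames(x) <- sprintf("s%d", 1:8)
  la <- label_assignment(colnames(x), rep(c("A", "B"), each = 4))
  de <- de_score(x, la, "snr")
  expect_true(all(is.finite(de$statistic)))
  expect_true(all(is.na(de$p_value)))  # snr is ranking-only
  # hand evaluation: means 2.5 / 9.5, raw sd 1.29; group B is floored at
  # 0.2 * |mean| = 1.9
  s <- sd(c(1, 2, 3, 4))
  expect_equal(de$statistic[2],
               (2.5 - 9.5) / (max(s, 0.5) + max(s, 1.9)), tolerance = 1e-10)
  # floored gene: sd 0 -> denominator 0.2 * |mean| on both sides
  expect_equal(de$statistic[1], 0)

  # moderated t equals the hand-computed shrunken statistic
  set.seed(3)
  xm <- matrix(rnorm(30 * 8, sd = rep(c(0.5, 3), each = 15)), 30, 8,
               dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:8)))
  lab <- label_assignment(colnames(xm), rep(c("A", "B"), each = 4))
  dm <- de_score(xm, lab, "moderated_t")
  v1 <- apply(xm[, 1:4], 1, var); v2 <- apply(xm[, 5:8], 1, var)
  s2 <- (3 * v1 + 3 * v2) / 6
  s2p <- (4 * mean(s2) + 6 * s2) / 10
  tm <- (rowMeans(xm[, 1:4]) - rowMeans(xm[, 5:8])) / sqrt(s2p * 0.5)
  expect_equal(dm$statistic, unname(tm), tolerance = 1e-10)
  expect_equal(dm$p_value, unname(2 * pt(-abs(tm), df = 10)),
               tolerance = 1e-10)
  # shrinkage pulls extreme variances toward the middle: high-variance
  # genes gain |t|, low-variance genes lose |t|
  tw <- de_score(xm, lab, "welch_t")$statistic
  hi <- s2 > mean(s2)
  expect_true(all(abs(dm$statistic[hi]) >= abs(tw[hi]) - 1e-9))
  expect_true(all(abs(dm$statistic[!hi]) <= abs(tw[!hi]) + 1e-9))
})

test_that("ranked lists sort decreasingly with deterministic ties", {
  de <- structure(data.frame(gene_id = c("gB", "gA", "gC"),
                             statistic = c(2, 5, 2),
                             log2fc = c(1, 2, 3),
                             p_value = c(0.5, 0.01, 0.5),
                             adj_p = c(0.5, 0.03, 0.5)),
                  class = c("de_result", "data.frame"))
  rk <- make_ranked_list(de, "statistic")
  expect_identical(rk$gene_id, c("gA", "gB", "gC"))  # tie: gB before gC
  expect_true(all(diff(rk$metric) <= 0))

  rk2 <- make_ranked_list(de, "signed_logp")
  expect_equal(rk2$metric[rk2$gene_id == "gA"], 2)  # -log10(0.01)

  de$statistic[2] <- NaN
  expect_error(make_ranked_list(de, "statistic"), "gA")
})

test_that("null welch p-values are approximately uniform", {
  sp <- simulation_spec(n_genes = 2000, seed = 42)
  cnt <- simulate_counts(sp)
  expr <- transform_counts(cnt, "log2_cpm", 0.5)
  fracs <- ks <- numeric(10)
  for (i in 1:10) {
    lab <- permute_labels(true_labels(sp), 1, seed = 50 + i)[[1]]
    de <- de_score(expr, lab, "welch_t")
    fracs[i] <- mean(abs(de$statistic) > qt(0.975, df = 18))
    ks[i] <- suppressWarnings(
      ks.test(de$p_value, "punif")$statistic)
  }
  expect_true(all(ks < 0.05))
  expect_gte(mean(fracs), 0.01)
  expect_lte(mean(fracs), 0.05)
})
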
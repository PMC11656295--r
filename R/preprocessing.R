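# Data-preprocessing options that a GSA practitioner chooses among:
# prefiltering of lowly expressed genes, removal of duplicated gene IDs
# after ID conversion, transformation/normalization, and gene-level
# differential expression scoring. Each step exposes a small set of named,
# swappable options so the optimizer can treat them uniformly.
#
# The differential expression options are deliberately self-contained
# scoring archetypes (Welch t, moderated t with a fixed shrinkage prior,
# Wilcoxon rank-sum z, signal-to-noise ratio). They stand in for the
# heavier model-based pipelines used in practice; the optimizer only needs
# interchangeable options with genuinely different behavior.

#' Prefilter lowly expressed genes
#'
#' @param counts integer count matrix (genes x samples, dimnames required).
#' @param option `"none"`, `"total_count"` (keep genes with row sum >=
#'   `threshold`) or `"cpm_filter"` (keep genes with counts-per-million
#'   above `cpm_cutoff` in at least `min_samples` samples).
#' @param threshold row-sum threshold for `total_count`.
#' @param cpm_cutoff,min_samples parameters of `cpm_filter`.
#' @return the filtered count matrix; samples unchanged. Removing every
#'   gene is an error (over-aggressive filter).
#' @export
prefilter <- function(counts, option = c("total_count", "none", "cpm_filter"),
                      threshold = 10, cpm_cutoff = 1, min_samples = 2) {
  check_count_matrix(counts)
  option <- match.arg(option)
  keep <- switch(option,
    none = rep(TRUE, nrow(counts)),
    total_count = {
      if (threshold < 0) stop_gv("threshold must be >= 0")
      rowSums(counts) >= threshold
    },
    cpm_filter = {
      if (min_samples > ncol(counts)) {
        stop_gv("min_samples exceeds the number of samples")
      }
      libs <- colSums(counts)
      if (any(libs == 0)) stop_gv("all-zero sample column")
      cpm <- sweep(counts, 2, libs, "/") * 1e6
      rowSums(cpm > cpm_cutoff) >= min_samples
    })
  if (!any(keep)) stop_gv("prefilter removed every gene")
  counts[keep, , drop = FALSE]
}

#' Collapse duplicated gene IDs after ID conversion
#'
#' Maps source gene IDs onto target IDs through a many-to-one conversion
#' table and resolves targets hit by several source rows.
#'
#' @param counts count matrix with source IDs as rownames.
#' @param table an `id_conversion_table` (columns `source`, `target`).
#' @param option `"keep_first"` retains the first-occurring source row per
#'   target; `"keep_highest_mean"` retains the source row with the largest
#'   mean count.
#' @return count matrix with unique target IDs as rownames. Source IDs
#'   absent from the table are dropped with a note, not an error.
#' @export
deduplicate <- function(counts, table,
                        option = c("keep_first", "keep_highest_mean")) {
  check_count_matrix(counts)
  option <- match.arg(option)
  if (!all(c("source", "target") %in% names(table))) {
    stop_gv("table must have columns 'source' and 'target'")
  }
  if (anyDuplicated(table$source) > 0) {
    stop_gv("each source ID may appear at most once in the table")
  }
  tgt <- table$target[match(rownames(counts), table$source)]
  unmapped <- is.na(tgt)
  if (any(unmapped)) {
    gv_note(sum(unmapped), " gene(s) absent from the ID table were dropped")
    counts <- counts[!unmapped, , drop = FALSE]
    tgt <- tgt[!unmapped]
  }
  if (!nrow(counts)) stop_gv("no gene maps through the ID table")
  keep <- switch(option,
    keep_first = !duplicated(tgt),
    keep_highest_mean = {
      mu <- rowMeans(counts)
      # stable: among rows of one target, keep the first with maximal mean
      ord <- order(tgt, -mu)
      sel <- ord[!duplicated(tgt[ord])]
      seq_len(nrow(counts)) %in% sel
    })
  out <- counts[keep, , drop = FALSE]
  rownames(out) <- tgt[keep]
  out
}

#' Transform and normalize a count matrix
#'
#' @param counts count matrix.
#' @param option `"cpm"` scales each sample to one million; `"log2_cpm"`
#'   applies `log2(CPM + pseudocount)`; `"median_ratio_log"` divides each
#'   sample by its median-of-ratios size factor (geometric-mean reference
#'   over genes with all-nonzero counts) and applies `log2(x + 1)`.
#' @param pseudocount pseudocount for `log2_cpm`.
#' @return real-valued expression matrix with the same dimnames.
#' @details If no gene has all-nonzero counts, `median_ratio_log` falls
#'   back to column-sum size factors (scaled to geometric mean 1) with a
#'   note. An all-zero sample is an error for every option.
#' @export
transform_counts <- function(counts,
                             option = c("log2_cpm", "cpm", "median_ratio_log"),
                             pseudocount = 0.5) {
  check_count_matrix(counts)
  option <- match.arg(option)
  libs <- colSums(counts)
  if (any(libs == 0)) stop_gv("all-zero sample column")
  if (option == "cpm") {
    return(sweep(counts, 2, libs, "/") * 1e6)
  }
  if (option == "log2_cpm") {
    if (pseudocount <= 0) stop_gv("pseudocount must be positive")
    return(log2(sweep(counts, 2, libs, "/") * 1e6 + pseudocount))
  }
  # median_ratio_log
  pos <- rowSums(counts == 0) == 0
  if (any(pos)) {
    ref <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
    sf <- apply(counts[pos, , drop = FALSE] / ref, 2, stats::median)
  } else {
    gv_note("no all-nonzero gene; median-ratio factors fall back to ",
            "column sums")
    sf <- libs / exp(mean(log(libs)))
  }
  log2(sweep(counts, 2, sf, "/") + 1)
}

# Vectorized two-group scoring cores. x: numeric matrix; ia/ib: column
# indices of the two groups. All return the signed statistic with positive
# values meaning higher expression in group A (the reference level).

welch_core <- function(x, ia, ib) {
  n1 <- length(ia); n2 <- length(ib)
  xa <- x[, ia, drop = FALSE]; xb <- x[, ib, drop = FALSE]
  m1 <- rowMeans(xa); m2 <- rowMeans(xb)
  v1 <- row_vars(xa); v2 <- row_vars(xb)
  se2 <- v1 / n1 + v2 / n2
  stat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))),
               n1 + n2 - 2)
  p <- 2 * stats::pt(-abs(stat), df = df)
  p[se2 == 0] <- 1
  list(statistic = stat, p = p, lfc = m1 - m2)
}

moderated_t_core <- function(x, ia, ib, prior_n = 4) {
  n1 <- length(ia); n2 <- length(ib)
  xa <- x[, ia, drop = FALSE]; xb <- x[, ib, drop = FALSE]
  m1 <- rowMeans(xa); m2 <- rowMeans(xb)
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * row_vars(xa) + (n2 - 1) * row_vars(xb)) / df
  # shrink per-gene variances toward their mean with a fixed prior weight
  # of `prior_n` pseudo-observations (documented stand-in for empirical
  # Bayes shrinkage)
  s2_post <- (prior_n * mean(s2) + df * s2) / (prior_n + df)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  stat <- ifelse(se > 0, (m1 - m2) / se, 0)
  p <- 2 * stats::pt(-abs(stat), df = df + prior_n)
  p[se == 0] <- 1
  list(statistic = stat, p = p, lfc = m1 - m2)
}

wilcoxon_z_core <- function(x, ia, ib) {
  n1 <- length(ia); n2 <- length(ib); n <- n1 + n2
  xs <- x[, c(ia, ib), drop = FALSE]
  r <- t(apply(xs, 1, rank))
  w <- rowSums(r[, seq_len(n1), drop = FALSE])
  mu <- n1 * (n + 1) / 2
  # tie-corrected variance of the rank sum
  tie_term <- apply(r, 1, function(rr) {
    tt <- table(rr)
    sum(tt^3 - tt)
  })
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- ifelse(sig2 > 0, (w - mu) / sqrt(sig2), 0)
  p <- 2 * stats::pnorm(-abs(z))
  p[sig2 == 0] <- 1
  list(statistic = z, p = p,
       lfc = rowMeans(x[, ia, drop = FALSE]) - rowMeans(x[, ib, drop = FALSE]))
}

snr_core <- function(x, ia, ib) {
  xa <- x[, ia, drop = FALSE]; xb <- x[, ib, drop = FALSE]
  m1 <- rowMeans(xa); m2 <- rowMeans(xb)
  s1 <- sqrt(row_vars(xa)); s2 <- sqrt(row_vars(xb))
  # denominator floor: SD no smaller than 0.2 * |group mean| and 1e-8
  s1 <- pmax(s1, 0.2 * abs(m1), 1e-8)
  s2 <- pmax(s2, 0.2 * abs(m2), 1e-8)
  list(statistic = (m1 - m2) / (s1 + s2), p = rep(NA_real_, nrow(x)),
       lfc = m1 - m2)
}

de_cores <- list(welch_t = welch_core, moderated_t = moderated_t_core,
                 wilcoxon_z = wilcoxon_z_core, snr = snr_core)

#' Score per-gene differential expression between two conditions
#'
#' @param x numeric expression matrix (typically log2 scale; the Wilcoxon
#'   option is invariant to monotone transforms).
#' @param labels a [label_assignment()]; the first factor level is the
#'   reference, and positive statistics mean higher expression in it.
#' @param option one of `"welch_t"`, `"moderated_t"`, `"wilcoxon_z"`,
#'   `"snr"`. The signal-to-noise ratio carries no p-value (its null
#'   distribution is not analytic); it is valid only as a ranking metric.
#' @return data.frame of class `de_result` with columns `gene_id`,
#'   `statistic`, `log2fc`, `p_value`, `adj_p` (Benjamini-Hochberg).
#' @export
de_score <- function(x, labels,
                     option = c("welch_t", "moderated_t", "wilcoxon_z",
                                "snr")) {
  option <- match.arg(option)
  stopifnot(inherits(labels, "label_assignment"))
  if (!all(labels$sample_ids %in% colnames(x))) {
    stop_gv("labels refer to samples absent from the matrix")
  }
  x <- x[, labels$sample_ids, drop = FALSE]
  ia <- which(labels$labels == levels(labels$labels)[1])
  ib <- which(labels$labels == levels(labels$labels)[2])
  if (length(ia) < 2 || length(ib) < 2) {
    stop_gv("each condition needs at least 2 samples")
  }
  core <- de_cores[[option]](x, ia, ib)
  out <- data.frame(gene_id = rownames(x),
                    statistic = unname(core$statistic),
                    log2fc = unname(core$lfc),
                    p_value = unname(core$p),
                    stringsAsFactors = FALSE)
  out$adj_p <- if (all(is.na(out$p_value))) NA_real_ else bh_adjust(out$p_value)
  attr(out, "de_method") <- option
  class(out) <- c("de_result", "data.frame")
  out
}

#' Build a ranked gene list from differential expression scores
#'
#' Sorts genes by a signed gene-level metric, decreasing; ties are broken
#' by gene ID in C-locale lexicographic order so the ranking is fully
#' deterministic.
#'
#' @param de a [de_score()] result.
#' @param metric `"statistic"`, `"log2fc"` or `"signed_logp"`
#'   (`sign(statistic) * -log10(p)`).
#' @return data.frame of class `ranked_list` with columns `gene_id`,
#'   `metric`. Missing metric values are an error naming the genes.
#' @export
make_ranked_list <- function(de, metric = c("statistic", "log2fc",
                                            "signed_logp")) {
  metric <- match.arg(metric)
  stopifnot(inherits(de, "de_result"))
  m <- switch(metric,
    statistic = de$statistic,
    log2fc = de$log2fc,
    signed_logp = {
      p <- pmax(de$p_value, 1e-300)  # guard log of exact zeros
      sign(de$statistic) * -log10(p)
    })
  bad <- !is.finite(m)
  if (any(bad)) {
    stop_gv("metric '", metric, "' undefined for gene(s): ",
            paste(utils::head(de$gene_id[bad], 5), collapse = ", "),
            if (sum(bad) > 5) " ..." else "")
  }
  ord <- order(-m, de$gene_id, method = "radix")
  out <- data.frame(gene_id = de$gene_id[ord], metric = m[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}
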
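# Internal implementations of the studied GSA method archetypes and their
# shared statistics. Four archetypes cover the ORA and FCS families:
#
#   ora              hypergeometric overrepresentation test of a DE list
#   gsea_sample_perm weighted-KS enrichment score, sample-permutation null
#   gsea_preranked   the same score on a fixed ranked list, gene-permutation
#                    null (the configuration known to inflate FDR when genes
#                    are correlated)
#   weighted_fcs     gene-frequency-weighted mean of |moderated t|,
#                    standardized against a sample-permutation null
#
# Permutation p-values use the pseudocount estimator (1 + b) / (1 + B) and
# FDR control is Benjamini-Hochberg on those p-values; the significance
# threshold (0.05 on BH-adjusted p, or the 0.25 "q" convention of the
# classic GSEA interface) travels with the MethodSpec.

#' Describe a GSA method archetype and its conventions
#'
#' @param archetype one of `"ora"`, `"gsea_sample_perm"`,
#'   `"gsea_preranked"`, `"weighted_fcs"`.
#' @param alpha significance threshold applied to the adjusted value;
#'   defaults to 0.05 except for the preranked archetype whose classic
#'   interface declares enrichment at q < 0.25.
#' @param threshold_on `"adjusted_p"` or `"q"`; metadata recording which
#'   convention `alpha` follows. Both are applied to the BH-adjusted
#'   permutation p-values here (no separate q-value estimator).
#' @param n_permutations permutation count for the FCS archetypes.
#' @param min_size,max_size set-size bounds after intersection with the
#'   analyzed genes; sets outside the bounds are skipped.
#' @param p_w weight exponent of the enrichment score, 0 (equal weights)
#'   or 1 (weight by |gene-level metric|).
#' @param label display name.
#' @param manual_only flag used by the experiment layer: methods that must
#'   be driven by hand (web interfaces) are excluded from the rank goal.
#' @return object of class `method_spec`.
#' @export
method_spec <- function(archetype = c("ora", "gsea_sample_perm",
                                      "gsea_preranked", "weighted_fcs"),
                        alpha = NULL, threshold_on = NULL,
                        n_permutations = 200, min_size = 5, max_size = 500,
                        p_w = 1, label = NULL, manual_only = FALSE) {
  archetype <- match.arg(archetype)
  if (is.null(alpha)) {
    alpha <- if (archetype == "gsea_preranked") 0.25 else 0.05
  }
  if (is.null(threshold_on)) {
    threshold_on <- if (archetype == "gsea_preranked") "q" else "adjusted_p"
  }
  threshold_on <- match.arg(threshold_on, c("adjusted_p", "q"))
  if (!p_w %in% c(0, 1)) stop_gv("p_w must be 0 or 1")
  if (alpha <= 0 || alpha >= 1) stop_gv("alpha must lie in (0, 1)")
  if (archetype != "ora" && n_permutations < 100) {
    stop_gv("FCS archetypes need n_permutations >= 100")
  }
  structure(list(archetype = archetype, alpha = alpha,
                 threshold_on = threshold_on,
                 n_permutations = as.integer(n_permutations),
                 min_size = as.integer(min_size),
                 max_size = as.integer(max_size),
                 p_w = p_w, label = label %||% archetype,
                 manual_only = isTRUE(manual_only)),
            class = "method_spec")
}

#' @export
print.method_spec <- function(x, ...) {
  cat("method_spec '", x$label, "' (", x$archetype, "), significant if ",
      x$threshold_on, " < ", x$alpha,
      if (x$manual_only) ", manual-only" else "", "\n", sep = "")
  invisible(x)
}

# Assemble the per-set result table shared by all archetypes.
gsa_result <- function(set, size, statistic, nes, p, spec, notes = character()) {
  adj <- bh_adjust(p)
  out <- data.frame(set = set, size = size, statistic = statistic,
                    nes = nes, p_value = p, adj_p = adj,
                    significant = adj < spec$alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "method") <- spec$archetype
  attr(out, "alpha") <- spec$alpha
  attr(out, "threshold_on") <- spec$threshold_on
  attr(out, "notes") <- notes
  class(out) <- c("gsa_result", "data.frame")
  out
}

# Intersect database sets with the analyzed genes and apply size bounds;
# strict_subset additionally drops sets covering every analyzed gene
# (required by the running-sum archetypes, whose miss step is undefined
# there).
filter_sets <- function(db, genes, spec, strict_subset = FALSE) {
  members <- lapply(db$sets, intersect, y = genes)
  sizes <- lengths(members)
  keep <- sizes >= spec$min_size & sizes <= spec$max_size
  if (strict_subset) keep <- keep & sizes < length(genes)
  skipped <- names(db$sets)[!keep]
  list(members = members[keep], sizes = sizes[keep], skipped = skipped)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (wraps [stats::p.adjust()]);
#' input order is preserved.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted values in `[0, 1]`, same order.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop_gv("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Resolve an ORA universe option
#'
#' @param option `"all_measured"` (every gene in the raw matrix after ID
#'   conversion), `"post_filter"` (genes surviving prefiltering, i.e. the
#'   analyzed genes) or `"all_annotated"` (union of the database's sets).
#' @param measured,analyzed character vectors of gene IDs.
#' @param db a [gene_set_db()].
#' @return character vector of universe gene IDs.
#' @export
resolve_universe <- function(option = c("all_measured", "post_filter",
                                        "all_annotated"),
                             measured, analyzed, db) {
  option <- match.arg(option)
  switch(option,
         all_measured = measured,
         post_filter = analyzed,
         all_annotated = unique(unlist(db$sets, use.names = FALSE)))
}

#' Hypergeometric overrepresentation test
#'
#' For each gene set, tests whether the differentially expressed gene list
#' contains more of the set's members than expected under random sampling
#' from the universe: the raw p-value is the upper-tail hypergeometric
#' probability of observing at least the attained overlap.
#'
#' @param de_genes character vector of DE gene IDs (intersected with the
#'   universe before testing).
#' @param universe character vector of background gene IDs.
#' @param db a [gene_set_db()].
#' @param spec a [method_spec()] with archetype `"ora"`; supplies the
#'   set-size bounds and significance convention.
#' @return a `gsa_result` data.frame (set, size, fold-enrichment statistic,
#'   raw and BH-adjusted p, significance flag). Sets with empty or
#'   out-of-bounds intersection with the universe are skipped with a note.
#' @export
ora_test <- function(de_genes, universe, db, spec = method_spec("ora")) {
  stopifnot(inherits(db, "gene_set_db"))
  universe <- unique(universe)
  if (!length(universe)) stop_gv("empty universe")
  de <- intersect(unique(de_genes), universe)
  N <- length(universe)
  n_de <- length(de)
  sets <- filter_sets(db, universe, spec)
  if (length(sets$skipped)) {
    gv_note(length(sets$skipped), " set(s) skipped (size bounds / no overlap ",
            "with the universe)")
  }
  if (!length(sets$members)) stop_gv("no testable set after size filtering")
  K <- sets$sizes
  k <- vapply(sets$members, function(m) length(intersect(m, de)), 1L)
  p <- stats::phyper(k - 1, K, N - K, n_de, lower.tail = FALSE)
  fe <- ifelse(n_de > 0, (k / n_de) / (K / N), 0)
  gsa_result(names(sets$members), K, fe, NA_real_, p, spec,
             notes = sets$skipped)
}

# Enrichment score from hit positions.
#   pos  sorted positions (1..N) of the set's members in the ranked list
#   w    |metric|^p_w at those positions
# The running sum increments by w/sum(w) at hits and decrements by
# 1/(N - nh) at misses; the extrema can only occur immediately after a hit
# (maximum candidates) or immediately before a hit / at the start (minimum
# candidates), so the score is computed in O(nh).
es_from_positions <- function(pos, w, N) {
  nh <- length(pos)
  m <- 1 / (N - nh)
  sw <- sum(w)
  cw <- if (sw > 0) cumsum(w) / sw else seq_len(nh) / nh
  drop_before <- (pos - seq_len(nh)) * m
  top <- cw - drop_before
  bottom <- c(0, cw[-nh]) - drop_before
  es_pos <- max(top)
  es_neg <- min(0, bottom)
  # ties in magnitude resolve to the positive extreme; the tolerance keeps
  # the choice stable under floating-point noise in the running sum
  if (es_pos >= abs(es_neg) - 1e-9) es_pos else es_neg
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks down the ranked gene list accumulating a running sum that rises by
#' `|metric|^p_w` (normalized over the set's members) at each set member and
#' falls by `1/(N - N_hit)` at each non-member; the enrichment score is the
#' signed maximum deviation from zero (ties between the positive and
#' negative extremes resolve to the positive one).
#'
#' @param ranked a [make_ranked_list()] result.
#' @param set_members character vector of gene IDs.
#' @param p_w weight exponent, 0 or 1.
#' @return a single numeric ES in `[-1, 1]`.
#' @export
enrichment_score <- function(ranked, set_members, p_w = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (!p_w %in% c(0, 1)) stop_gv("p_w must be 0 or 1")
  pos <- which(ranked$gene_id %in% set_members)
  N <- nrow(ranked)
  if (!length(pos)) stop_gv("set has no member in the ranked list")
  if (length(pos) == N) stop_gv("set covers the whole ranked list")
  es_from_positions(pos, abs(ranked$metric[pos])^p_w, N)
}

# Normalization + p-values shared by the permutation-based FCS archetypes.
# NES divides the observed ES by the mean null ES of the same sign; the raw
# p-value counts same-sign null scores at least as extreme, with the
# (1 + b) / (1 + B) pseudocount so p is never 0.
fcs_summarize <- function(set_names, sizes, es_obs, es_null, spec,
                          notes = character()) {
  B <- ncol(es_null)
  nes <- rep(NA_real_, length(es_obs))
  p <- rep(1, length(es_obs))
  for (s in seq_along(es_obs)) {
    same <- if (es_obs[s] >= 0) es_null[s, ] >= 0 else es_null[s, ] < 0
    if (!any(same)) {
      notes <- c(notes, paste0(set_names[s], ": no same-sign null ES; p = 1"))
      next
    }
    nes[s] <- es_obs[s] / mean(es_null[s, same])
    p[s] <- (1 + sum(same & abs(es_null[s, ]) >= abs(es_obs[s]))) / (1 + B)
  }
  gsa_result(set_names, sizes, es_obs, nes, p, spec, notes = notes)
}

# Positions of each set's members after reordering genes: rankpos[i] is the
# rank position of the gene stored at index i of `genes`.
positions_in_order <- function(ord, N) {
  rankpos <- integer(N)
  rankpos[ord] <- seq_len(N)
  rankpos
}

#' Preranked GSA with a gene-permutation null
#'
#' Computes the enrichment score of each set on a fixed, user-supplied
#' ranked list and assesses it against a null obtained by permuting gene
#' labels on that list (one shared permutation per iteration across all
#' sets). Because gene permutation destroys gene-gene correlation, this
#' null is miscalibrated on correlated data, which is exactly the behavior
#' the package exists to study.
#'
#' @param ranked a [make_ranked_list()] result.
#' @param db a [gene_set_db()].
#' @param spec a [method_spec()] (archetype `"gsea_preranked"` by
#'   convention); supplies `p_w`, permutation count, size bounds and the
#'   significance convention.
#' @param seed integer seed for the permutation stream.
#' @return a `gsa_result` with ES, NES, raw and BH-adjusted permutation
#'   p-values.
#' @export
gsea_preranked <- function(ranked, db, spec = method_spec("gsea_preranked"),
                           seed = 1L) {
  stopifnot(inherits(ranked, "ranked_list"), inherits(db, "gene_set_db"))
  genes <- ranked$gene_id
  N <- length(genes)
  sets <- filter_sets(db, genes, spec, strict_subset = TRUE)
  if (!length(sets$members)) stop_gv("set-size bounds exclude every set")
  idx <- lapply(sets$members, function(m) which(genes %in% m))
  wfull <- abs(ranked$metric)^spec$p_w
  es_obs <- vapply(idx, function(i) es_from_positions(i, wfull[i], N), 1)
  B <- spec$n_permutations
  es_null <- matrix(0, length(idx), B)
  with_seed(child_seed(seed, "gene_perm"), {
    for (b in seq_len(B)) {
      relocate <- sample.int(N)  # shared gene-label permutation
      for (s in seq_along(idx)) {
        pos <- sort(relocate[idx[[s]]])
        es_null[s, b] <- es_from_positions(pos, wfull[pos], N)
      }
    }
  })
  fcs_summarize(names(sets$members), sets$sizes, es_obs, es_null, spec,
                notes = sets$skipped)
}

#' GSA by enrichment score with a sample-permutation null
#'
#' Ranks genes by a two-group gene-level statistic computed from the
#' expression matrix, scores each set with the weighted KS enrichment
#' score, and builds the null by relabeling samples (preserving group
#' sizes) and recomputing the ranking each time — the calibrated
#' counterpart of [gsea_preranked()]. The p-value-calculation choice of the
#' analysis multiverse is exposed through `null`: with `"gene_perm"` the
#' observed ranking is kept and the null permutes gene labels instead.
#'
#' @param expr numeric expression matrix.
#' @param labels a [label_assignment()].
#' @param db a [gene_set_db()].
#' @param spec a [method_spec()].
#' @param seed integer seed.
#' @param de_option gene-level scoring method passed to [de_score()].
#' @param metric ranking metric passed to [make_ranked_list()].
#' @param null `"sample_perm"` (default) or `"gene_perm"`.
#' @return a `gsa_result`.
#' @export
gsea_sample_perm <- function(expr, labels, db,
                             spec = method_spec("gsea_sample_perm"),
                             seed = 1L, de_option = "welch_t",
                             metric = "statistic", null = c("sample_perm",
                                                            "gene_perm")) {
  null <- match.arg(null)
  stopifnot(inherits(labels, "label_assignment"), inherits(db, "gene_set_db"))
  de <- de_score(expr, labels, de_option)
  ranked <- make_ranked_list(de, metric)
  if (null == "gene_perm") {
    return(gsea_preranked(ranked, db, spec, seed = seed))
  }
  genes <- rownames(expr)
  N <- length(genes)
  sets <- filter_sets(db, genes, spec, strict_subset = TRUE)
  if (!length(sets$members)) stop_gv("set-size bounds exclude every set")
  member_idx <- lapply(sets$members, function(m) match(m, genes))

  rank_positions <- positions_in_order(match(ranked$gene_id, genes), N)
  wobs <- abs(ranked$metric)^spec$p_w
  es_obs <- vapply(seq_along(member_idx), function(s) {
    pos <- sort(rank_positions[member_idx[[s]]])
    es_from_positions(pos, wobs[pos], N)
  }, 1)

  x <- expr[, labels$sample_ids, drop = FALSE]
  lv <- labels$labels
  core <- de_cores[[de_option]]
  B <- spec$n_permutations
  es_null <- matrix(0, length(member_idx), B)
  with_seed(child_seed(seed, "sample_perm"), {
    for (b in seq_len(B)) {
      lp <- sample(lv)
      ia <- which(lp == levels(lv)[1]); ib <- which(lp == levels(lv)[2])
      cb <- core(x, ia, ib)
      m <- switch(metric,
                  statistic = cb$statistic,
                  log2fc = cb$lfc,
                  signed_logp = sign(cb$statistic) *
                    -log10(pmax(cb$p, 1e-300)))
      if (any(!is.finite(m))) {
        stop_gv("metric '", metric, "' undefined under permutation (de ",
                "method '", de_option, "')")
      }
      ord <- order(-m, genes, method = "radix")
      rp <- positions_in_order(ord, N)
      wb <- abs(m[ord])^spec$p_w
      for (s in seq_along(member_idx)) {
        pos <- sort(rp[member_idx[[s]]])
        es_null[s, b] <- es_from_positions(pos, wb[pos], N)
      }
    }
  })
  fcs_summarize(names(sets$members), sets$sizes, es_obs, es_null, spec,
                notes = sets$skipped)
}

#' Database-frequency weights for genes
#'
#' Gene `g` appearing in `f_g` of the database's sets (counted over the
#' analyzed genes) gets weight `1 + sqrt((f_max - f_g) / (f_max - f_min))`,
#' so genes private to few sets count up to twice as much as ubiquitous
#' ones; when every frequency is equal all weights are 1. Genes absent
#' from the database get the maximal weight 2 (their `f` is 0), but they
#' never enter a set score.
#'
#' @param db a [gene_set_db()].
#' @param genes character vector of analyzed gene IDs.
#' @return numeric weights aligned with `genes`.
#' @export
gene_frequency_weights <- function(db, genes) {
  freq <- table(unlist(lapply(db$sets, intersect, y = genes),
                       use.names = FALSE))
  f <- as.numeric(freq[genes])
  f[is.na(f)] <- 0
  fmax <- max(f[f > 0])
  fmin <- min(f[f > 0])
  if (fmax > fmin) 1 + sqrt((fmax - f) / (fmax - fmin)) else rep(1, length(f))
}

#' Gene-frequency-weighted functional class scoring
#'
#' Down-weights genes that appear in many sets of the database: gene `g`
#' with database frequency `f_g` gets weight
#' `1 + sqrt((f_max - f_g) / (f_max - f_min))` (all weights 1 when every
#' frequency is equal). Each set is scored by the weighted mean of
#' `|moderated t|` over its members and assessed against a
#' sample-permutation null; the reported `nes` column is the standardized
#' (z) score against that null.
#'
#' @param expr numeric expression matrix.
#' @param labels a [label_assignment()].
#' @param db a [gene_set_db()].
#' @param spec a [method_spec()].
#' @param seed integer seed.
#' @return a `gsa_result`.
#' @export
weighted_fcs <- function(expr, labels, db,
                         spec = method_spec("weighted_fcs"), seed = 1L) {
  stopifnot(inherits(labels, "label_assignment"), inherits(db, "gene_set_db"))
  genes <- rownames(expr)
  sets <- filter_sets(db, genes, spec)
  if (!length(sets$members)) stop_gv("set-size bounds exclude every set")
  member_idx <- lapply(sets$members, function(m) match(m, genes))

  w <- gene_frequency_weights(db, genes)

  x <- expr[, labels$sample_ids, drop = FALSE]
  lv <- labels$labels
  score_sets <- function(ia, ib) {
    mt <- abs(moderated_t_core(x, ia, ib)$statistic)
    vapply(member_idx, function(i) sum(w[i] * mt[i]) / sum(w[i]), 1)
  }
  ia0 <- which(lv == levels(lv)[1]); ib0 <- which(lv == levels(lv)[2])
  if (length(ia0) < 2 || length(ib0) < 2) {
    stop_gv("each condition needs at least 2 samples")
  }
  obs <- score_sets(ia0, ib0)
  B <- spec$n_permutations
  nullm <- matrix(0, length(member_idx), B)
  with_seed(child_seed(seed, "sample_perm"), {
    for (b in seq_len(B)) {
      lp <- sample(lv)
      nullm[, b] <- score_sets(which(lp == levels(lv)[1]),
                               which(lp == levels(lv)[2]))
    }
  })
  p <- (1 + rowSums(nullm >= obs)) / (1 + B)
  sds <- apply(nullm, 1, stats::sd)
  z <- ifelse(sds > 0, (obs - rowMeans(nullm)) / sds, 0)
  gsa_result(names(sets$members), sets$sizes, obs, z, p, spec,
             notes = sets$skipped)
}

#' Count differentially enriched gene sets
#'
#' @param result a `gsa_result`.
#' @return number of sets flagged significant under the result's threshold
#'   convention.
#' @export
count_degs <- function(result) {
  stopifnot(inherits(result, "gsa_result"))
  sum(result$significant)
}

#' Relative rank of a gene set
#'
#' Sets are densely ranked by ascending adjusted p-value (the smallest
#' adjusted p occupies rank 1; ties share one rank) and the target's rank
#' is divided by the maximum assigned rank. An adjusted p of 1 therefore
#' always yields a relative rank of exactly 1, and the value lies in
#' `(0, 1]` regardless of how many sets the result table contains.
#'
#' @param result a `gsa_result`.
#' @param target_set set name; an error names the set if absent.
#' @return relative rank in `(0, 1]`.
#' @export
relative_rank <- function(result, target_set) {
  stopifnot(inherits(result, "gsa_result"))
  i <- match(target_set, result$set)
  if (is.na(i)) stop_gv("target set '", target_set, "' absent from the result")
  levels_p <- sort(unique(result$adj_p))
  dense <- match(result$adj_p, levels_p)
  dense[i] / max(dense)
}
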
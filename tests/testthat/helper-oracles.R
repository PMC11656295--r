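# Independent oracles and fixture builders. Everything here is coded
# against the definitions directly (literal enumeration, literal running
# sums, the literal step-up formula) and never calls the implementation
# paths it is used to check.

# Upper-tail hypergeometric probability by summing binomial-coefficient
# counts over every possible overlap (exhaustive enumeration over draw
# classes): P(X >= k) for a universe of size N containing K set members,
# drawing n DE genes.
hyper_upper_oracle <- function(k, K, n, N) {
  ks <- seq(max(0, k), min(K, n))
  if (k > min(K, n)) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Literal enumeration of every n-subset of the universe (tiny N only).
hyper_combn_oracle <- function(k, set_idx, n, N) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) length(intersect(d, set_idx)) >= k))
}

# Brute-force weighted KS enrichment score: walk the ranked list one
# position at a time, tracking the full running sum.
es_brute <- function(ranked_ids, metric, set_members, p_w) {
  hit <- ranked_ids %in% set_members
  N <- length(ranked_ids)
  nh <- sum(hit)
  wr <- abs(metric)^p_w
  nr <- sum(wr[hit])
  running <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (hit[i]) {
      cur + (if (nr > 0) wr[i] / nr else 1 / nh)
    } else {
      cur - 1 / (N - nh)
    }
    running[i] <- cur
  }
  i_max <- which.max(running)
  i_min <- which.min(running)
  # magnitude ties resolve to the positive extreme (same convention and
  # float tolerance as the implementation under check)
  if (running[i_max] >= abs(running[i_min]) - 1e-9) {
    running[i_max]
  } else {
    running[i_min]
  }
}

# Literal Benjamini-Hochberg step-up: sort ascending, adjusted_i is the
# running minimum of m * p_j / j from the largest p down, clipped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- m * p[o] / seq_len(m)
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  adj_sorted <- pmin(adj_sorted, 1)
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Minimal ranked_list fixture.
toy_ranked <- function(ids, metric) {
  structure(data.frame(gene_id = ids, metric = metric,
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

# GSAResult fixture with prescribed adjusted p-values (for rank tests).
toy_gsa_result <- function(adj_p, alpha = 0.05) {
  structure(data.frame(set = sprintf("s%03d", seq_along(adj_p)),
                       size = 10L, statistic = 0, nes = NA_real_,
                       p_value = adj_p, adj_p = adj_p,
                       significant = adj_p < alpha,
                       stringsAsFactors = FALSE),
            class = c("gsa_result", "data.frame"))
}

# Small labelled count fixture: deterministic Poisson-ish counts.
toy_counts <- function(n_genes = 30, n_samples = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda = 50), n_genes, n_samples)
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%02d", seq_len(n_samples)))
  storage.mode(m) <- "integer"
  m
}

toy_labels <- function(n_samples = 8, origin = "true") {
  label_assignment(sprintf("s%02d", seq_len(n_samples)),
                   rep(c("A", "B"), each = n_samples / 2), origin = origin)
}

# Database whose sets are exactly the simulator's correlation blocks.
block_aligned_db <- function(genes, block_size = 40) {
  n <- length(genes)
  sets <- split(genes,
                rep(seq_len(ceiling(n / block_size)),
                    each = block_size)[seq_len(n)])
  names(sets) <- sprintf("set_%03d", seq_along(sets))
  gene_set_db(sets, "blocks")
}
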
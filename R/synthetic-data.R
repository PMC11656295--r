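# Synthetic RNA-seq data with the dependence structure the downstream
# analyses are sensitive to: negative-binomial counts, block-wise gene-gene
# correlation, library-size variation, optional enrichment signal in
# designated gene sets, many-to-one ID tables and label permutations.

#' Specify a synthetic RNA-seq simulation
#'
#' Describes a two-group negative-binomial count simulation. Gene-gene
#' dependence is induced block-wise through a Gaussian copula: within a
#' block all genes load on one shared latent factor with correlation `rho`,
#' across blocks genes are independent, and counts are obtained by mapping
#' the latent Gaussians through the negative-binomial quantile function so
#' the marginal count distribution is identical for every `rho`. This is a
#' stand-in generative model: real RNA-seq data is not block-exchangeable
#' and has gene-specific dispersion.
#'
#' @param n_genes number of genes.
#' @param samples_per_group integer vector of length 2; samples in each of
#'   the two conditions (first level is the reference).
#' @param nb_mean_log_range range (log2 scale) of per-gene baseline means,
#'   drawn uniformly.
#' @param nb_dispersion common negative-binomial dispersion (1/size);
#'   variance is `mu + dispersion * mu^2`.
#' @param correlation_block_size genes per correlation block.
#' @param within_block_correlation latent correlation `rho` in `[0, 1)`
#'   between genes of one block.
#' @param library_size_factor_range range of per-sample library size
#'   factors, drawn log-uniformly.
#' @param signal_sets named numeric vector (or list of name = effect) of
#'   log2 effect sizes for gene sets that carry true signal; set members are
#'   resolved against the database passed to [simulate_counts()]. A positive
#'   effect raises expression in the first (reference) condition.
#' @param seed integer seed; identical specs produce identical data.
#' @return an object of class `simulation_spec`.
#' @seealso [simulate_counts()], [simulate_database()], [permute_labels()]
#' @export
simulation_spec <- function(n_genes = 2000,
                            samples_per_group = c(10, 10),
                            nb_mean_log_range = c(3, 9),
                            nb_dispersion = 0.2,
                            correlation_block_size = 40,
                            within_block_correlation = 0,
                            library_size_factor_range = c(0.7, 1.3),
                            signal_sets = list(),
                            seed = 1L) {
  if (length(n_genes) != 1 || n_genes < 1) stop_gv("n_genes must be positive")
  if (length(samples_per_group) != 2 || any(samples_per_group < 2)) {
    stop_gv("samples_per_group must give two groups with >= 2 samples each")
  }
  rho <- within_block_correlation
  if (length(rho) != 1 || rho < 0 || rho >= 1) {
    stop_gv("within_block_correlation must lie in [0, 1)")
  }
  if (nb_dispersion <= 0) stop_gv("nb_dispersion must be positive")
  if (correlation_block_size < 1) stop_gv("correlation_block_size must be >= 1")
  if (any(library_size_factor_range <= 0) ||
      diff(library_size_factor_range) < 0) {
    stop_gv("library_size_factor_range must be positive and increasing")
  }
  effects <- unlist(signal_sets)
  if (length(effects) && (anyNA(effects) || any(!is.finite(effects)))) {
    stop_gv("signal effect sizes must be finite")
  }
  if (length(effects) && is.null(names(effects))) {
    stop_gv("signal_sets must be named by gene set")
  }
  structure(
    list(n_genes = as.integer(n_genes),
         samples_per_group = as.integer(samples_per_group),
         nb_mean_log_range = as.numeric(nb_mean_log_range),
         nb_dispersion = as.numeric(nb_dispersion),
         correlation_block_size = as.integer(correlation_block_size),
         within_block_correlation = as.numeric(rho),
         library_size_factor_range = as.numeric(library_size_factor_range),
         signal_sets = if (length(effects)) effects else numeric(0),
         seed = as.integer(seed)),
    class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("simulation_spec:", x$n_genes, "genes,",
      paste(x$samples_per_group, collapse = "+"), "samples, rho =",
      x$within_block_correlation, "\n")
  if (length(x$signal_sets)) {
    cat("  signal:", paste0(names(x$signal_sets), " (log2 effect ",
                            x$signal_sets, ")", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Simulate a gene-by-sample count matrix
#'
#' Draws negative-binomial counts under the model described in
#' [simulation_spec()]. Genes belonging to signal sets receive a group-wise
#' log2 mean difference equal to the stated effect size (higher in the first
#' condition for positive effects).
#'
#' @param spec a [simulation_spec()].
#' @param db a gene set database ([gene_set_db()]); required when
#'   `spec$signal_sets` is nonempty, ignored otherwise.
#' @return integer matrix (genes x samples) with gene IDs `g0001, ...` as
#'   rownames and sample IDs `s01, ...` as colnames.
#' @export
simulate_counts <- function(spec, db = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  G <- spec$n_genes
  n1 <- spec$samples_per_group[1]
  n2 <- spec$samples_per_group[2]
  n <- n1 + n2
  gene_ids <- sprintf("g%04d", seq_len(G))
  sample_ids <- sprintf("s%02d", seq_len(n))

  # per-gene log2 effect, resolved through the database
  effect <- numeric(G)
  names(effect) <- gene_ids
  if (length(spec$signal_sets)) {
    if (is.null(db)) stop_gv("signal_sets declared but no database supplied")
    stopifnot(inherits(db, "gene_set_db"))
    for (set_name in names(spec$signal_sets)) {
      members <- db$sets[[set_name]]
      if (is.null(members)) {
        stop_gv("signal set '", set_name, "' not found in database")
      }
      members <- intersect(members, gene_ids)
      effect[members] <- spec$signal_sets[[set_name]]
    }
  }

  with_seed(child_seed(spec$seed, "counts"), {
    base_log2 <- stats::runif(G, spec$nb_mean_log_range[1],
                              spec$nb_mean_log_range[2])
    lsr <- spec$library_size_factor_range
    sf <- exp(stats::runif(n, log(lsr[1]), log(lsr[2])))

    # latent Gaussian with block-constant correlation rho (Gaussian copula)
    rho <- spec$within_block_correlation
    block <- rep(seq_len(ceiling(G / spec$correlation_block_size)),
                 each = spec$correlation_block_size)[seq_len(G)]
    z <- matrix(stats::rnorm(G * n), G, n)
    if (rho > 0) {
      zb <- matrix(stats::rnorm(max(block) * n), max(block), n)
      z <- sqrt(rho) * zb[block, , drop = FALSE] + sqrt(1 - rho) * z
    }

    mu <- outer(2^base_log2, sf)
    if (any(effect != 0)) {
      mu[, seq_len(n1)] <- mu[, seq_len(n1)] * 2^effect
    }
    size <- 1 / spec$nb_dispersion
    counts <- matrix(stats::qnbinom(stats::pnorm(z), size = size, mu = mu),
                     G, n)
    dimnames(counts) <- list(gene_ids, sample_ids)
    storage.mode(counts) <- "integer"
    counts
  })
}

#' Construct the true condition labels for a simulation
#'
#' @param spec a [simulation_spec()].
#' @param levels two condition names; the first is the reference level.
#' @return a [label_assignment()].
#' @export
true_labels <- function(spec, levels = c("A", "B")) {
  stopifnot(inherits(spec, "simulation_spec"))
  n1 <- spec$samples_per_group[1]
  n2 <- spec$samples_per_group[2]
  label_assignment(sprintf("s%02d", seq_len(n1 + n2)),
                   rep(levels, c(n1, n2)), origin = "true")
}

#' Two-level condition assignment for a set of samples
#'
#' @param sample_ids character vector of sample IDs.
#' @param labels character vector of conditions, exactly two distinct
#'   values; the first value encountered is the reference level unless the
#'   vector is a factor.
#' @param origin `"true"` or a positive permutation index.
#' @return object of class `label_assignment` with fields `sample_ids`,
#'   `labels` (factor, 2 levels) and `origin`.
#' @export
label_assignment <- function(sample_ids, labels, origin = "true") {
  if (length(sample_ids) != length(labels)) {
    stop_gv("sample_ids and labels must have equal length")
  }
  if (anyDuplicated(sample_ids) > 0) stop_gv("sample IDs must be unique")
  f <- if (is.factor(labels)) labels else factor(labels, levels = unique(labels))
  if (nlevels(f) != 2) stop_gv("labels must have exactly two levels")
  if (!identical(origin, "true")) {
    origin <- as.integer(origin)
    if (is.na(origin) || origin < 1) {
      stop_gv("origin must be \"true\" or a positive permutation index")
    }
  }
  structure(list(sample_ids = as.character(sample_ids), labels = f,
                 origin = origin),
            class = "label_assignment")
}

#' @export
print.label_assignment <- function(x, ...) {
  cat("label_assignment (origin: ", format(x$origin), "): ",
      paste(levels(x$labels), table(x$labels), sep = "=", collapse = " / "),
      "\n", sep = "")
  invisible(x)
}

#' Randomly permute sample labels
#'
#' Generates uniformly random permutations of the condition vector across
#' samples. Permuting removes any true association between expression and
#' condition while preserving the per-level counts exactly, which is the
#' null model the overoptimism quantification is built on.
#'
#' @param truth a [label_assignment()] with the true labels.
#' @param n_permutations number of permutations (>= 1).
#' @param seed integer seed.
#' @return list of [label_assignment()] objects with origins
#'   `1..n_permutations`.
#' @export
permute_labels <- function(truth, n_permutations, seed = 1L) {
  stopifnot(inherits(truth, "label_assignment"))
  if (n_permutations < 1) stop_gv("n_permutations must be >= 1")
  with_seed(child_seed(seed, "labels"), {
    lapply(seq_len(n_permutations), function(i) {
      label_assignment(truth$sample_ids, sample(truth$labels), origin = i)
    })
  })
}

#' Gene set database
#'
#' @param sets named list of character vectors (gene IDs); names unique,
#'   every set nonempty, no duplicated IDs within one set.
#' @param name database name.
#' @return object of class `gene_set_db`.
#' @export
gene_set_db <- function(sets, name = "db") {
  if (!length(sets) || is.null(names(sets)) || anyDuplicated(names(sets)) > 0 ||
      any(!nzchar(names(sets)))) {
    stop_gv("sets must be a nonempty list with unique nonempty names")
  }
  sets <- lapply(sets, as.character)
  if (any(vapply(sets, length, 1L) == 0)) stop_gv("every set must be nonempty")
  if (any(vapply(sets, anyDuplicated, 1L) > 0)) {
    stop_gv("duplicate gene IDs within a set are forbidden")
  }
  structure(list(name = name, sets = sets), class = "gene_set_db")
}

#' @export
print.gene_set_db <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat("gene_set_db '", x$name, "': ", length(x$sets), " sets, sizes ",
      min(sizes), "-", max(sizes), "\n", sep = "")
  invisible(x)
}

#' Simulate a gene set database with controlled overlap
#'
#' Set sizes are uniform in `size_range`; a fixed fraction of each set's
#' members is shared with the previous set, so consecutive sets overlap by
#' exactly `round(overlap_fraction * size)` genes (non-consecutive sets may
#' overlap only by chance).
#'
#' @param n_sets number of sets.
#' @param size_range integer pair, inclusive set-size range.
#' @param universe character vector of candidate gene IDs.
#' @param overlap_fraction fraction in `[0, 1)` of a set shared with its
#'   predecessor.
#' @param seed integer seed.
#' @param name database name.
#' @return a [gene_set_db()].
#' @export
simulate_database <- function(n_sets, size_range, universe,
                              overlap_fraction = 0, seed = 1L,
                              name = "synthetic_db") {
  if (size_range[2] > length(universe)) {
    stop_gv("size_range exceeds the universe size")
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop_gv("overlap_fraction must lie in [0, 1)")
  }
  with_seed(child_seed(seed, "db", name), {
    size_pool <- seq.int(size_range[1], size_range[2])
    sizes <- size_pool[sample.int(length(size_pool), n_sets, replace = TRUE)]
    sets <- vector("list", n_sets)
    for (i in seq_len(n_sets)) {
      if (i == 1) {
        sets[[i]] <- sample(universe, sizes[i])
      } else {
        prev <- sets[[i - 1]]
        k <- round(overlap_fraction * sizes[i])
        k <- min(k, length(prev))
        shared <- if (k > 0) sample(prev, k) else character(0)
        pool <- setdiff(universe, prev)
        if (length(pool) < sizes[i] - k) {
          stop_gv("universe too small for the requested sizes and overlap")
        }
        sets[[i]] <- c(shared, sample(pool, sizes[i] - k))
      }
    }
    names(sets) <- sprintf("set_%03d", seq_len(n_sets))
    gene_set_db(sets, name = name)
  })
}

#' Simulate a many-to-one gene ID conversion table
#'
#' Emulates ID conversion (e.g. transcript to gene symbol) where several
#' source IDs can collapse onto one target ID. Duplicated targets receive
#' exactly two sources; the number of duplicated targets is chosen so that
#' approximately `duplicate_fraction` of all target IDs have >= 2 sources.
#'
#' @param gene_ids character vector of source IDs (each appears once).
#' @param duplicate_fraction fraction in `[0, 1)` of target IDs with
#'   multiple sources.
#' @param seed integer seed.
#' @return data.frame of class `id_conversion_table` with columns `source`
#'   and `target`, in the order of `gene_ids`.
#' @export
simulate_id_table <- function(gene_ids, duplicate_fraction = 0, seed = 1L) {
  if (duplicate_fraction < 0 || duplicate_fraction >= 1) {
    stop_gv("duplicate_fraction must lie in [0, 1)")
  }
  if (anyDuplicated(gene_ids) > 0) stop_gv("source gene IDs must be unique")
  n <- length(gene_ids)
  k <- round(duplicate_fraction * n / (1 + duplicate_fraction))
  if (duplicate_fraction > 0 && n >= 2) k <- max(k, 1L)
  m <- n - k
  with_seed(child_seed(seed, "idtable"), {
    shuffled <- sample(gene_ids)
    target_of <- character(n)
    names(target_of) <- shuffled
    targets <- sprintf("t%04d", seq_len(m))
    if (k > 0) {
      # first 2k shuffled sources pair onto the first k targets
      target_of[seq_len(2 * k)] <- rep(targets[seq_len(k)], each = 2)
    }
    if (m > k) target_of[(2 * k + 1):n] <- targets[(k + 1):m]
    out <- data.frame(source = gene_ids,
                      target = unname(target_of[gene_ids]),
                      stringsAsFactors = FALSE)
    class(out) <- c("id_conversion_table", "data.frame")
    out
  })
}
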
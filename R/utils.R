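# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that generators and
#' permutation machinery are reproducible without disturbing the caller's
#' random number stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible child seed
#'
#' One master seed per study; child seeds for individual artifacts (counts,
#' databases, permutations, settings) are derived deterministically so any
#' component can be regenerated in isolation. Strings are folded in with a
#' polynomial hash; everything stays below 2^31.
#'
#' @param master integer master seed.
#' @param ... integers and/or character scalars identifying the artifact.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(master, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (part in list(...)) {
    if (is.character(part)) {
      for (cp in utf8ToInt(paste(part, collapse = "/"))) {
        h <- (h * 31 + cp) %% m
      }
    } else {
      h <- (h * 7919 + as.numeric(part) %% m) %% m
    }
  }
  as.integer(h)
}

# Row-wise means/variances for a matrix split into two sample groups.
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) stop("need at least 2 columns to compute row variances")
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

# Condition message used for optional progress notes; suppressible via
# suppressMessages() or options(gsaverse.quiet = TRUE).
gv_note <- function(...) {
  if (!isTRUE(getOption("gsaverse.quiet", FALSE))) {
    message("gsaverse: ", ...)
  }
  invisible(NULL)
}

stop_gv <- function(..., call. = FALSE) stop(..., call. = call.)

is_count_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && !is.null(rownames(x)) &&
    !is.null(colnames(x)) && !anyNA(x) && all(x >= 0)
}

check_count_matrix <- function(x, what = "counts") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_gv(what, " must be a numeric matrix")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_gv(what, " must carry gene IDs as rownames and sample IDs as colnames")
  }
  if (anyDuplicated(rownames(x)) > 0) stop_gv(what, ": duplicated gene IDs")
  if (anyDuplicated(colnames(x)) > 0) stop_gv(what, ": duplicated sample IDs")
  if (anyNA(x) || any(x < 0)) stop_gv(what, ": entries must be nonnegative")
  invisible(x)
}
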
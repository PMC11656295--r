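# The analysis-choice space and the greedy stepwise optimization that
# emulates a well-intentioned researcher tweaking one choice at a time
# toward a goal. Steps are processed in a fixed, a-priori order; at each
# step every alternative option is evaluated with all other steps held at
# their current choices, the strictly best improving option is adopted
# (ties resolve to the earlier-declared alternative), and the incumbent is
# kept when nothing strictly improves. Every evaluation is recorded.

#' Declare one uncertain analysis step
#'
#' @param name step name (e.g. `"prefilter"`).
#' @param default single named list: the default option (name = option key,
#'   value = parameter list understood by [evaluate_config()]).
#' @param alternatives named list of alternative options, in the order used
#'   to break ties; must not contain the default key.
#' @param archetypes method archetypes the step applies to (`NULL` = all).
#' @param goals goal numbers (1 = maximize DEGS, 2 = minimize adjusted p,
#'   3 = minimize relative rank) the step applies to.
#' @return object of class `choice_step`.
#' @export
choice_step <- function(name, default, alternatives, archetypes = NULL,
                        goals = 1:3) {
  if (length(default) != 1 || is.null(names(default))) {
    stop_gv("default must be a single named option")
  }
  if (is.null(names(alternatives)) || anyDuplicated(names(alternatives)) > 0) {
    stop_gv("alternatives must be uniquely named")
  }
  if (names(default) %in% names(alternatives)) {
    stop_gv("the default option must not be among the alternatives")
  }
  structure(list(name = name, default = default,
                 alternatives = alternatives, archetypes = archetypes,
                 goals = goals),
            class = "choice_step")
}

# One concrete option taken from a step, carrying its key and parameters.
step_option <- function(step_name, key, params) {
  list(step = step_name, key = key, params = params)
}

#' Build the analysis choice space for a method and goal
#'
#' Declares the uncertain steps in their fixed a-priori order, roughly the
#' natural order of a GSA workflow with the DE method deliberately placed
#' before prefiltering (different DE pipelines prescribe different
#' prefilters, so a researcher settles the DE method first). Steps are
#' filtered by applicability: e.g. the gene set database is exploitable
#' only when maximizing the number of enriched sets, the universe exists
#' only for ORA, and the score weight only for the enrichment-score
#' methods.
#'
#' @param method a [method_spec()].
#' @param goal_number 1, 2 or 3.
#' @param db_names names of the available gene set databases; the first is
#'   the default. The database step enters the space only for goal 1 and
#'   only if more than one database is available.
#' @param has_id_table whether an ID conversion table is part of the
#'   context (otherwise the duplicate-removal step is dropped).
#' @return ordered list of [choice_step()]s, class `choice_space`.
#' @export
build_choice_space <- function(method, goal_number = 1, db_names = NULL,
                               has_id_table = TRUE) {
  stopifnot(inherits(method, "method_spec"))
  fcs_ranked <- c("gsea_preranked", "gsea_sample_perm")
  de_alts <- list(moderated_t = list(option = "moderated_t"),
                  wilcoxon_z = list(option = "wilcoxon_z"))
  if (method$archetype %in% fcs_ranked) {
    de_alts$snr <- list(option = "snr")  # ranking-only metric; no p-value
  }
  steps <- list(
    choice_step("dedup",
                default = list(keep_first = list(option = "keep_first")),
                alternatives = list(
                  keep_highest_mean = list(option = "keep_highest_mean"))),
    choice_step("de_method",
                default = list(welch_t = list(option = "welch_t")),
                alternatives = de_alts,
                archetypes = c("ora", fcs_ranked)),
    choice_step("prefilter",
                default = list(total_count_10 = list(option = "total_count",
                                                     threshold = 10)),
                alternatives = list(
                  none = list(option = "none"),
                  cpm_1_2 = list(option = "cpm_filter", cpm_cutoff = 1,
                                 min_samples = 2))),
    choice_step("transform",
                default = list(log2_cpm_0.5 = list(option = "log2_cpm",
                                                   pseudocount = 0.5)),
                alternatives = list(
                  median_ratio_log = list(option = "median_ratio_log"),
                  cpm = list(option = "cpm")),
                archetypes = c("gsea_sample_perm", "weighted_fcs")),
    if (!is.null(db_names) && length(db_names) > 1) {
      db_opts <- lapply(db_names, function(d) list(db = d))
      names(db_opts) <- db_names
      choice_step("geneset_db", default = db_opts[1],
                  alternatives = db_opts[-1], goals = 1)
    },
    choice_step("universe",
                default = list(all_measured = list(option = "all_measured")),
                alternatives = list(
                  post_filter = list(option = "post_filter"),
                  all_annotated = list(option = "all_annotated")),
                archetypes = "ora"),
    choice_step("gene_metric",
                default = list(statistic = list(metric = "statistic")),
                alternatives = list(
                  signed_logp = list(metric = "signed_logp"),
                  log2fc = list(metric = "log2fc")),
                archetypes = fcs_ranked),
    choice_step("pvalue_calc",
                default = list(sample_perm = list(null = "sample_perm")),
                alternatives = list(gene_perm = list(null = "gene_perm")),
                archetypes = "gsea_sample_perm"),
    choice_step("weight",
                default = list(weighted = list(p_w = 1)),
                alternatives = list(equal = list(p_w = 0)),
                archetypes = fcs_ranked)
  )
  steps <- Filter(Negate(is.null), steps)
  if (!has_id_table) steps <- Filter(function(s) s$name != "dedup", steps)
  keep <- vapply(steps, function(s) {
    (is.null(s$archetypes) || method$archetype %in% s$archetypes) &&
      goal_number %in% s$goals
  }, TRUE)
  structure(steps[keep], class = "choice_space")
}

#' @export
print.choice_space <- function(x, ...) {
  for (s in x) {
    cat(s$name, ": ", names(s$default), " | ",
        paste(names(s$alternatives), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Default analysis configuration of a choice space
#'
#' @param space a [build_choice_space()] result.
#' @return object of class `analysis_config`: one chosen option per step.
#' @export
default_config <- function(space) {
  stopifnot(inherits(space, "choice_space"))
  assignments <- lapply(space, function(s) {
    step_option(s$name, names(s$default), s$default[[1]])
  })
  names(assignments) <- vapply(space, `[[`, "", "name")
  structure(list(assignments = assignments), class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  keys <- vapply(x$assignments, `[[`, "", "key")
  cat(paste0(names(keys), " = ", keys, collapse = ", "), "\n")
  invisible(x)
}

#' Define an optimization goal
#'
#' @param kind `"max_degs"` (maximize the number of differentially
#'   enriched gene sets), `"min_adj_p"` (minimize a target set's adjusted
#'   p-value) or `"min_rank"` (minimize its relative rank).
#' @param target_set set name; required for the two targeted goals.
#' @return object of class `gsa_goal`.
#' @export
gsa_goal <- function(kind = c("max_degs", "min_adj_p", "min_rank"),
                     target_set = NULL) {
  kind <- match.arg(kind)
  if (kind != "max_degs" && is.null(target_set)) {
    stop_gv("goal '", kind, "' needs a target set")
  }
  structure(list(kind = kind, target_set = target_set), class = "gsa_goal")
}

goal_number <- function(goal) {
  switch(goal$kind, max_degs = 1L, min_adj_p = 2L, min_rank = 3L)
}

goal_from_number <- function(n, target_set = NULL) {
  gsa_goal(c("max_degs", "min_adj_p", "min_rank")[n], target_set)
}

#' Is a candidate objective a strict improvement?
#'
#' Equality is never an improvement; a failed evaluation (`NA`) never
#' improves.
#'
#' @param goal a [gsa_goal()].
#' @param candidate,incumbent objective values.
#' @return logical.
#' @export
is_improvement <- function(goal, candidate, incumbent) {
  if (is.na(candidate)) return(FALSE)
  if (goal$kind == "max_degs") candidate > incumbent else candidate < incumbent
}

#' Run one configured GSA pipeline and return the goal objective
#'
#' Executes duplicate removal, prefiltering, transformation, gene-level
#' scoring and the method archetype as dictated by the configuration, then
#' reduces the result table to the goal's scalar: the DEGS count, or the
#' target set's adjusted p-value / relative rank (defined as the worst
#' value 1 when the target was filtered out of the result).
#'
#' The ORA and preranked archetypes compute their DE input on a fixed
#' log2-CPM transform (their exploitable transform choice is absorbed by
#' the DE method choice); ORA's DE gene list is the genes with BH-adjusted
#' p below 0.05.
#'
#' @param config an `analysis_config`.
#' @param goal a [gsa_goal()].
#' @param context list with components `counts`, `labels`
#'   ([label_assignment()]), `databases` (named list of [gene_set_db()]),
#'   `method` ([method_spec()]), `seed`, and optionally `id_table` and
#'   `default_db`.
#' @return numeric objective; the full `gsa_result` is attached as
#'   attribute `"result"`. Identical (config, context, seed) give identical
#'   values. Errors name the failing step.
#' @export
evaluate_config <- function(config, goal, context) {
  stopifnot(inherits(config, "analysis_config"), inherits(goal, "gsa_goal"))
  method <- context$method
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_gv("step '", name, "': ", conditionMessage(e))
    })
  }
  opt <- function(step) config$assignments[[step]]

  counts <- context$counts
  if (!is.null(context$id_table) && !is.null(opt("dedup"))) {
    counts <- stage("dedup",
                    deduplicate(counts, context$id_table,
                                opt("dedup")$params$option))
  }
  measured <- rownames(counts)
  pf <- opt("prefilter")
  if (!is.null(pf)) {
    counts <- stage("prefilter", do.call(prefilter, c(list(counts),
                                                      pf$params)))
  }
  db_key <- if (!is.null(opt("geneset_db"))) opt("geneset_db")$params$db
            else context$default_db %||% names(context$databases)[1]
  db <- context$databases[[db_key]]
  if (is.null(db)) stop_gv("step 'geneset_db': unknown database '", db_key, "'")

  seed <- context$seed
  de_opt <- if (!is.null(opt("de_method"))) opt("de_method")$params$option
            else "welch_t"
  metric <- if (!is.null(opt("gene_metric"))) opt("gene_metric")$params$metric
            else "statistic"
  p_w <- if (!is.null(opt("weight"))) opt("weight")$params$p_w else method$p_w
  spec <- method
  spec$p_w <- p_w

  result <- switch(method$archetype,
    ora = {
      expr <- stage("transform", transform_counts(counts, "log2_cpm", 0.5))
      de <- stage("de_method", de_score(expr, context$labels, de_opt))
      if (all(is.na(de$adj_p))) {
        stop_gv("step 'de_method': '", de_opt, "' yields no p-values for ORA")
      }
      de_genes <- de$gene_id[de$adj_p < 0.05]
      uni_opt <- if (!is.null(opt("universe"))) opt("universe")$params$option
                 else "all_measured"
      universe <- resolve_universe(uni_opt, measured, rownames(counts), db)
      stage("ora", ora_test(de_genes, universe, db, spec))
    },
    gsea_preranked = {
      expr <- stage("transform", transform_counts(counts, "log2_cpm", 0.5))
      de <- stage("de_method", de_score(expr, context$labels, de_opt))
      ranked <- stage("gene_metric", make_ranked_list(de, metric))
      stage("gsea", gsea_preranked(ranked, db, spec, seed = seed))
    },
    gsea_sample_perm = {
      tr <- opt("transform")$params %||% list(option = "log2_cpm",
                                              pseudocount = 0.5)
      expr <- stage("transform", do.call(transform_counts,
                                         c(list(counts), tr)))
      null <- if (!is.null(opt("pvalue_calc"))) opt("pvalue_calc")$params$null
              else "sample_perm"
      stage("gsea", gsea_sample_perm(expr, context$labels, db, spec,
                                     seed = seed, de_option = de_opt,
                                     metric = metric, null = null))
    },
    weighted_fcs = {
      tr <- opt("transform")$params %||% list(option = "log2_cpm",
                                              pseudocount = 0.5)
      expr <- stage("transform", do.call(transform_counts,
                                         c(list(counts), tr)))
      stage("weighted_fcs", weighted_fcs(expr, context$labels, db, spec,
                                         seed = seed))
    })

  value <- switch(goal$kind,
    max_degs = as.numeric(count_degs(result)),
    min_adj_p = {
      i <- match(goal$target_set, result$set)
      if (is.na(i)) 1 else result$adj_p[i]  # filtered-out target: worst case
    },
    min_rank = {
      if (goal$target_set %in% result$set) {
        relative_rank(result, goal$target_set)
      } else 1
    })
  attr(value, "result") <- result
  value
}

#' Greedy stepwise optimization of an analysis configuration
#'
#' Starts from the all-default configuration, then sweeps the choice steps
#' once in their fixed order. At each step every alternative option is
#' evaluated with all other steps held at their current choices; the
#' strictly best improving alternative becomes the new choice (equal best
#' improvements resolve to the earlier-declared alternative; no strict
#' improvement keeps the incumbent). A failing option is treated as
#' non-improving, with the error recorded. One permutation seed
#' (`context$seed`) is shared by every evaluation of the trajectory, so
#' options are compared on identical permutation streams.
#'
#' @param space a [build_choice_space()] result.
#' @param goal a [gsa_goal()].
#' @param context evaluation context, see [evaluate_config()].
#' @param evaluator objective function with the signature of
#'   [evaluate_config()]; replaceable for testing.
#' @return object of class `optimization_trajectory`: `evaluations` (one
#'   row per objective evaluation: step, option, objective, incumbent at
#'   the time, whether chosen, permutation seed, note), `default_config`,
#'   `final_config`, `default_objective`, `optimized_objective`, `goal`.
#' @export
stepwise_optimize <- function(space, goal, context,
                              evaluator = evaluate_config) {
  stopifnot(inherits(space, "choice_space"), inherits(goal, "gsa_goal"))
  config <- default_config(space)
  seed <- context$seed %||% NA_integer_
  rows <- list()
  note_row <- function(step, option, objective, incumbent, chosen,
                       note = "") {
    rows[[length(rows) + 1]] <<- data.frame(
      step = step, option = option, objective = objective,
      incumbent = incumbent, chosen = chosen, perm_seed = seed, note = note,
      stringsAsFactors = FALSE)
  }

  incumbent <- as.numeric(evaluator(config, goal, context))
  default_objective <- incumbent
  note_row("(default)", "(default)", incumbent, NA_real_, TRUE)

  final <- config
  for (s in space) {
    best_key <- NULL
    best_obj <- incumbent
    for (key in names(s$alternatives)) {
      cfg <- final
      cfg$assignments[[s$name]] <- step_option(s$name, key,
                                               s$alternatives[[key]])
      obj <- tryCatch(as.numeric(evaluator(cfg, goal, context)),
                      error = function(e) {
                        structure(NA_real_,
                                  msg = conditionMessage(e))
                      })
      msg <- attr(obj, "msg") %||% ""
      obj <- as.numeric(obj)
      improving <- is_improvement(goal, obj, best_obj)
      note_row(s$name, key, obj, incumbent, FALSE, msg)
      if (improving) {  # strict: ties keep the earlier-declared option
        best_key <- key
        best_obj <- obj
      }
    }
    if (!is.null(best_key)) {
      final$assignments[[s$name]] <- step_option(s$name, best_key,
                                                 s$alternatives[[best_key]])
      incumbent <- best_obj
      idx <- length(rows) - length(s$alternatives) +
        match(best_key, names(s$alternatives))
      rows[[idx]]$chosen <- TRUE
    }
  }

  evaluations <- do.call(rbind, rows)
  traj <- structure(
    list(goal = goal, evaluations = evaluations, default_config = config,
         final_config = final, default_objective = default_objective,
         optimized_objective = incumbent, perm_seed = seed),
    class = "optimization_trajectory")
  # goal-directed monotonicity is structural; verify anyway
  stopifnot(!is_improvement(goal, traj$default_objective,
                            traj$optimized_objective))
  traj
}

#' @export
print.optimization_trajectory <- function(x, ...) {
  cat("optimization_trajectory (", x$goal$kind, "): ",
      format(x$default_objective), " -> ",
      format(x$optimized_objective), " over ",
      nrow(x$evaluations) - 1, " option evaluations\n", sep = "")
  invisible(x)
}

#' Overoptimism of an optimization trajectory
#'
#' Reduces a trajectory to the default-versus-optimized comparison: the
#' signed improvement (positive = result got better in the goal's
#' direction) and the steps whose chosen option departed from the default.
#'
#' @param trajectory an [stepwise_optimize()] result.
#' @return object of class `overoptimism_record` with fields
#'   `default_objective`, `optimized_objective`, `delta`, `changed_steps`,
#'   `goal_kind`.
#' @export
overoptimism <- function(trajectory) {
  stopifnot(inherits(trajectory, "optimization_trajectory"))
  d <- trajectory$default_objective
  o <- trajectory$optimized_objective
  delta <- if (trajectory$goal$kind == "max_degs") o - d else d - o
  def_keys <- vapply(trajectory$default_config$assignments, `[[`, "", "key")
  fin_keys <- vapply(trajectory$final_config$assignments, `[[`, "", "key")
  structure(list(default_objective = d, optimized_objective = o,
                 delta = delta,
                 changed_steps = names(fin_keys)[fin_keys != def_keys],
                 goal_kind = trajectory$goal$kind),
            class = "overoptimism_record")
}

#' @export
print.overoptimism_record <- function(x, ...) {
  cat("overoptimism (", x$goal_kind, "): ", format(x$default_objective),
      " -> ", format(x$optimized_objective), " (delta ", format(x$delta),
      ")\n", sep = "")
  if (length(x$changed_steps)) {
    cat("  changed:", paste(x$changed_steps, collapse = ", "), "\n")
  }
  invisible(x)
}
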
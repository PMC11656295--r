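# The study grid: every combination of goal, dataset, label assignment,
# method (and, for the targeted goals, target set) defines one optimization
# setting; each setting is one greedy optimization process. The experiment
# layer enumerates the grid, runs it reproducibly and resumably, and
# summarizes the optimized-versus-default gap.

#' The seven-method panel of the reference study design
#'
#' Three ORA-family methods (one driven through a web interface), one
#' gene-frequency-weighted FCS method, two enrichment-score methods with a
#' sample-permutation null (the web variant using the classic q < 0.25
#' convention) and one preranked enrichment-score method. The three
#' web-interface methods are flagged `manual_only`: optimizing them must be
#' done by hand, so the rank goal is skipped for them.
#'
#' @param n_permutations permutation count for the FCS archetypes.
#' @return named list of [method_spec()]s.
#' @export
default_method_panel <- function(n_permutations = 200) {
  list(
    ora_seq = method_spec("ora", label = "ora_seq"),
    ora_web = method_spec("ora", label = "ora_web", manual_only = TRUE),
    ora_pkg = method_spec("ora", label = "ora_pkg"),
    wfcs_pkg = method_spec("weighted_fcs", label = "wfcs_pkg",
                           n_permutations = n_permutations),
    gsea_pkg = method_spec("gsea_sample_perm", label = "gsea_pkg",
                           n_permutations = n_permutations),
    gsea_web = method_spec("gsea_sample_perm", alpha = 0.25,
                           threshold_on = "q", label = "gsea_web",
                           n_permutations = n_permutations,
                           manual_only = TRUE),
    gsea_preranked_web = method_spec("gsea_preranked",
                                     label = "gsea_preranked_web",
                                     n_permutations = n_permutations,
                                     manual_only = TRUE))
}

#' Describe a synthetic dataset for a study
#'
#' Bundles a count simulation with the database(s) and ID table simulated
#' alongside it. Counts are generated in a "source" ID space; the ID table
#' collapses them many-to-one onto target IDs, and the gene set databases
#' are defined over the target IDs, so the duplicate-removal analysis
#' choice is genuinely exercised.
#'
#' @param sim a [simulation_spec()].
#' @param n_databases number of gene set databases (>= 2 lets goal 1
#'   exploit the database choice).
#' @param n_sets,set_size_range,overlap_fraction database parameters, see
#'   [simulate_database()].
#' @param id_duplicate_fraction see [simulate_id_table()].
#' @return object of class `synthetic_dataset`.
#' @export
synthetic_dataset <- function(sim = simulation_spec(),
                              n_databases = 2, n_sets = 50,
                              set_size_range = c(10, 60),
                              overlap_fraction = 0.2,
                              id_duplicate_fraction = 0.1) {
  stopifnot(inherits(sim, "simulation_spec"))
  structure(list(sim = sim, n_databases = as.integer(n_databases),
                 n_sets = as.integer(n_sets),
                 set_size_range = set_size_range,
                 overlap_fraction = overlap_fraction,
                 id_duplicate_fraction = id_duplicate_fraction),
            class = "synthetic_dataset")
}

#' Define a study design
#'
#' @param goals subset of `1:3` (1 = maximize DEGS count, 2 = minimize the
#'   target set's adjusted p, 3 = minimize its relative rank).
#' @param datasets named list of [synthetic_dataset()] descriptors, or of
#'   pre-materialized contexts (lists with `counts`, `labels`, `databases`,
#'   optionally `id_table`).
#' @param n_label_permutations number of random sample-label permutations
#'   per dataset.
#' @param include_true_labels also run every setting on the true labels.
#' @param methods named list of [method_spec()]s.
#' @param target_sets two set names per dataset for the targeted goals:
#'   either a character vector of length 2 (used for every dataset) or a
#'   named list of such vectors.
#' @param master_seed master seed; every artifact and setting derives its
#'   own child seed from it.
#' @return object of class `study_design`.
#' @export
study_design <- function(goals = 1:3, datasets,
                         n_label_permutations = 10,
                         include_true_labels = TRUE,
                         methods = default_method_panel(),
                         target_sets = c("set_001", "set_002"),
                         master_seed = 1L) {
  if (!all(goals %in% 1:3)) stop_gv("goals must be a subset of 1:3")
  if (is.null(names(datasets)) || anyDuplicated(names(datasets)) > 0) {
    stop_gv("datasets must be uniquely named")
  }
  if (is.null(names(methods)) || anyDuplicated(names(methods)) > 0) {
    stop_gv("methods must be uniquely named")
  }
  if (n_label_permutations < 0) stop_gv("n_label_permutations must be >= 0")
  if (!is.list(target_sets)) {
    target_sets <- stats::setNames(rep(list(target_sets), length(datasets)),
                                   names(datasets))
  }
  if (any(c(2, 3) %in% goals)) {
    ok <- vapply(names(datasets),
                 function(d) length(target_sets[[d]]) == 2, TRUE)
    if (!all(ok)) stop_gv("each dataset needs exactly 2 target sets")
  }
  structure(list(goals = sort(unique(as.integer(goals))), datasets = datasets,
                 n_label_permutations = as.integer(n_label_permutations),
                 include_true_labels = isTRUE(include_true_labels),
                 methods = methods, target_sets = target_sets,
                 master_seed = as.integer(master_seed)),
            class = "study_design")
}

#' Enumerate all optimization settings of a study design
#'
#' One setting per combination of goal, dataset, label assignment and
#' method; the targeted goals additionally vary over the two target sets,
#' and the rank goal excludes `manual_only` methods.
#'
#' @param design a [study_design()].
#' @return data.frame with one row per setting: `setting_id`, `goal`,
#'   `dataset`, `label_origin` (`"true"` or the permutation index as a
#'   string), `method`, `target_set` (`NA` for goal 1) and the derived
#'   child `seed`.
#' @export
enumerate_settings <- function(design) {
  stopifnot(inherits(design, "study_design"))
  origins <- c(if (design$include_true_labels) "true",
               as.character(seq_len(design$n_label_permutations)))
  rows <- list()
  for (g in design$goals) {
    for (ds in names(design$datasets)) {
      targets <- if (g == 1) NA_character_ else design$target_sets[[ds]]
      for (origin in origins) {
        for (m in names(design$methods)) {
          if (g == 3 && design$methods[[m]]$manual_only) next
          for (tg in targets) {
            id <- paste0("g", g, "_", ds, "_", origin, "_", m,
                         if (!is.na(tg)) paste0("_", tg))
            rows[[length(rows) + 1]] <- data.frame(
              setting_id = id, goal = g, dataset = ds,
              label_origin = origin, method = m, target_set = tg,
              seed = child_seed(design$master_seed, "setting", id),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(setting_id = character(0), goal = integer(0),
                      dataset = character(0), label_origin = character(0),
                      method = character(0), target_set = character(0),
                      seed = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Materialize a dataset descriptor into an evaluation context skeleton.
materialize_dataset <- function(design, ds_name) {
  ds <- design$datasets[[ds_name]]
  if (!inherits(ds, "synthetic_dataset")) {
    # pre-materialized context
    stopifnot(is.list(ds), !is.null(ds$counts), !is.null(ds$labels),
              !is.null(ds$databases))
    truth <- ds$labels
    perms <- if (design$n_label_permutations > 0) {
      permute_labels(truth, design$n_label_permutations,
                     seed = child_seed(design$master_seed, "perm", ds_name))
    } else list()
    return(list(counts = ds$counts, truth = truth, perms = perms,
                databases = ds$databases, id_table = ds$id_table))
  }
  sim <- ds$sim
  sim$seed <- child_seed(design$master_seed, "data", ds_name)
  id_table <- simulate_id_table(
    sprintf("g%04d", seq_len(sim$n_genes)),
    duplicate_fraction = ds$id_duplicate_fraction,
    seed = child_seed(design$master_seed, "idtable", ds_name))
  target_universe <- unique(id_table$target)
  databases <- lapply(seq_len(ds$n_databases), function(i) {
    simulate_database(ds$n_sets, ds$set_size_range, target_universe,
                      overlap_fraction = ds$overlap_fraction,
                      seed = child_seed(design$master_seed, "db", ds_name, i),
                      name = paste0("db", i))
  })
  names(databases) <- paste0("db", seq_len(ds$n_databases))
  counts <- simulate_counts(sim)  # signal sets unsupported in source-ID space
  truth <- true_labels(sim)
  perms <- if (design$n_label_permutations > 0) {
    permute_labels(truth, design$n_label_permutations,
                   seed = child_seed(design$master_seed, "perm", ds_name))
  } else list()
  list(counts = counts, truth = truth, perms = perms, databases = databases,
       id_table = id_table)
}

#' Run every optimization setting of a study
#'
#' Materializes each dataset once, then runs one [stepwise_optimize()] per
#' setting. Records are appended to `records.tsv` in `outdir` as they
#' complete, the settings grid is written to `settings.tsv`, and each
#' trajectory is stored under `trajectories/`. A rerun skips settings that
#' already have a record, so an interrupted study resumes where it
#' stopped; per-setting failures are recorded with status `"failed"` and
#' never abort the study.
#'
#' @param design a [study_design()].
#' @param outdir output directory (created if needed).
#' @param verbose emit a progress note per setting.
#' @return invisibly, the records data.frame (one row per setting:
#'   objectives, delta, changed steps, status).
#' @export
run_study <- function(design, outdir, verbose = FALSE) {
  stopifnot(inherits(design, "study_design"))
  dir.create(file.path(outdir, "trajectories"), recursive = TRUE,
             showWarnings = FALSE)
  settings <- enumerate_settings(design)
  utils::write.table(settings, file.path(outdir, "settings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  records_path <- file.path(outdir, "records.tsv")
  done <- character(0)
  if (file.exists(records_path)) {
    done <- utils::read.delim(records_path, stringsAsFactors = FALSE)$setting_id
  }
  data_cache <- list()
  for (i in seq_len(nrow(settings))) {
    st <- settings[i, ]
    if (st$setting_id %in% done) next
    if (is.null(data_cache[[st$dataset]])) {
      data_cache[[st$dataset]] <- materialize_dataset(design, st$dataset)
    }
    dat <- data_cache[[st$dataset]]
    labels <- if (st$label_origin == "true") dat$truth
              else dat$perms[[as.integer(st$label_origin)]]
    method <- design$methods[[st$method]]
    context <- list(counts = dat$counts, labels = labels,
                    databases = dat$databases, id_table = dat$id_table,
                    method = method, seed = st$seed)
    goal <- goal_from_number(st$goal,
                             if (!is.na(st$target_set)) st$target_set)
    space <- build_choice_space(method, goal_number = st$goal,
                                db_names = names(dat$databases),
                                has_id_table = !is.null(dat$id_table))
    if (verbose) gv_note("running ", st$setting_id)
    rec <- tryCatch({
      traj <- stepwise_optimize(space, goal, context)
      utils::write.table(
        traj$evaluations,
        file.path(outdir, "trajectories", paste0(st$setting_id, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      oo <- overoptimism(traj)
      data.frame(setting_id = st$setting_id, goal = st$goal,
                 dataset = st$dataset, label_origin = st$label_origin,
                 method = st$method, target_set = st$target_set,
                 status = "ok",
                 default_objective = oo$default_objective,
                 optimized_objective = oo$optimized_objective,
                 delta = oo$delta,
                 changed_steps = paste(oo$changed_steps, collapse = ","),
                 n_evaluations = nrow(traj$evaluations),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(setting_id = st$setting_id, goal = st$goal,
                 dataset = st$dataset, label_origin = st$label_origin,
                 method = st$method, target_set = st$target_set,
                 status = paste0("failed: ", conditionMessage(e)),
                 default_objective = NA_real_,
                 optimized_objective = NA_real_, delta = NA_real_,
                 changed_steps = "", n_evaluations = NA_integer_,
                 stringsAsFactors = FALSE)
    })
    utils::write.table(rec, records_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = !file.exists(records_path),
                       append = file.exists(records_path))
  }
  invisible(utils::read.delim(records_path, stringsAsFactors = FALSE))
}

#' Summarize study records
#'
#' @param records the records data.frame from [run_study()] (or read back
#'   from `records.tsv`).
#' @return list of class `study_summary`: `objectives` — per (goal,
#'   method, label-origin class) the mean default and optimized objective,
#'   mean delta and the fraction of settings with any improvement;
#'   `step_changes` — how often each analysis step's choice departed from
#'   the default, per goal and method (the "trigger" tally).
#' @export
summarize_study <- function(records) {
  if (!nrow(records)) stop_gv("no records to summarize")
  ok <- records[records$status == "ok", , drop = FALSE]
  # records read back from disk carry empty change lists as NA
  ok$changed_steps <- as.character(ok$changed_steps)
  ok$changed_steps[is.na(ok$changed_steps)] <- ""
  ok$origin_class <- ifelse(ok$label_origin == "true", "true", "permutation")
  objectives <- do.call(rbind, lapply(
    split(ok, list(ok$goal, ok$method, ok$origin_class), drop = TRUE),
    function(d) data.frame(
      goal = d$goal[1], method = d$method[1],
      origin_class = d$origin_class[1], n = nrow(d),
      mean_default = mean(d$default_objective),
      mean_optimized = mean(d$optimized_objective),
      mean_delta = mean(d$delta),
      improved_fraction = mean(d$delta > 0),
      stringsAsFactors = FALSE)))
  rownames(objectives) <- NULL
  objectives <- objectives[order(objectives$goal, objectives$method,
                                 objectives$origin_class), ]

  changed <- lapply(seq_len(nrow(ok)), function(i) {
    steps <- strsplit(ok$changed_steps[i], ",", fixed = TRUE)[[1]]
    steps <- steps[nzchar(steps)]
    if (!length(steps)) return(NULL)
    data.frame(goal = ok$goal[i], method = ok$method[i], step = steps,
               stringsAsFactors = FALSE)
  })
  changed <- do.call(rbind, changed)
  step_changes <- if (is.null(changed)) {
    data.frame(goal = integer(0), method = character(0),
               step = character(0), n_changed = integer(0))
  } else {
    agg <- stats::aggregate(list(n_changed = rep(1L, nrow(changed))),
                            changed[c("goal", "method", "step")], sum)
    agg[order(agg$goal, agg$method, -agg$n_changed), ]
  }
  rownames(step_changes) <- NULL
  structure(list(objectives = objectives, step_changes = step_changes,
                 n_failed = sum(records$status != "ok")),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat("study summary (", sum(x$objectives$n), " settings",
      if (x$n_failed) paste0(", ", x$n_failed, " failed"), "):\n", sep = "")
  print(x$objectives, row.names = FALSE)
  invisible(x)
}
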
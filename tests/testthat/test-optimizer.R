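# Greedy stepwise optimization: contract checks with stub evaluators
# (known objective tables, exhaustive enumeration as the oracle) and with
# the real pipeline on small synthetic data.

# A choice space with numbered steps/options and a lookup-table evaluator.
stub_space <- function(option_counts) {
  steps <- lapply(seq_along(option_counts), function(i) {
    keys <- paste0("s", i, "_o", seq_len(option_counts[i]))
    opts <- lapply(keys, function(k) list(id = k))
    names(opts) <- keys
    choice_step(paste0("step", i), default = opts[1],
                alternatives = opts[-1])
  })
  structure(steps, class = "choice_space")
}

# evaluator reading a named objective table: key is the comma-joined
# option choice
table_evaluator <- function(tab) {
  function(config, goal, context) {
    key <- paste(vapply(config$assignments, `[[`, "", "key"),
                 collapse = ",")
    v <- tab[[key]]
    if (is.null(v)) stop("missing objective for ", key)
    v
  }
}

enumerate_configs <- function(space) {
  keysets <- lapply(space, function(s) c(names(s$default),
                                         names(s$alternatives)))
  grid <- expand.grid(keysets, stringsAsFactors = FALSE)
  apply(grid, 1, paste, collapse = ",")
}

test_that("improvement is strict and goal-directed", {
  expect_false(is_improvement(gsa_goal("max_degs"), 5, 5))
  expect_true(is_improvement(gsa_goal("max_degs"), 6, 5))
  expect_true(is_improvement(gsa_goal("min_adj_p", "t"), 0.058, 1))
  expect_false(is_improvement(gsa_goal("min_adj_p", "t"), 1, 0.058))
  expect_true(is_improvement(gsa_goal("min_rank", "t"), 0.07, 0.12))
  expect_false(is_improvement(gsa_goal("min_rank", "t"), NA, 0.5))
})

test_that("greedy optimization follows the known objective table", {
  space <- stub_space(c(2, 2))
  tab <- list("s1_o1,s2_o1" = 0, "s1_o2,s2_o1" = 3,
              "s1_o1,s2_o2" = 1, "s1_o2,s2_o2" = 7)
  tr <- stepwise_optimize(space, gsa_goal("max_degs"),
                          list(seed = 1), table_evaluator(tab))
  expect_equal(tr$default_objective, 0)
  expect_equal(tr$optimized_objective, 7)
  keys <- vapply(tr$final_config$assignments, `[[`, "", "key")
  expect_identical(unname(keys), c("s1_o2", "s2_o2"))
  # greedy equals global enumeration here by construction
  expect_equal(max(unlist(tab)), tr$optimized_objective)
  # audit completeness: default + one evaluation per alternative
  expect_equal(nrow(tr$evaluations), 1 + 2)
  oo <- overoptimism(tr)
  expect_equal(oo$delta, 7)
  expect_setequal(oo$changed_steps, c("step1", "step2"))
})

test_that("no-improvement spaces keep every default", {
  space <- stub_space(c(2, 3))
  cfgs <- enumerate_configs(space)
  tab <- as.list(setNames(rep(0, length(cfgs)), cfgs))
  tab[["s1_o1,s2_o1"]] <- 5  # the default is already the best
  tr <- stepwise_optimize(space, gsa_goal("max_degs"), list(seed = 1),
                          table_evaluator(tab))
  expect_equal(tr$optimized_objective, tr$default_objective)
  expect_identical(vapply(tr$final_config$assignments, `[[`, "", "key"),
                   vapply(tr$default_config$assignments, `[[`, "", "key"))
  expect_length(overoptimism(tr)$changed_steps, 0)
})

test_that("equal improvements resolve to the earlier-declared alternative", {
  space <- stub_space(c(3))
  tab <- list("s1_o1" = 0, "s1_o2" = 4, "s1_o3" = 4)
  tr <- stepwise_optimize(space, gsa_goal("max_degs"), list(seed = 1),
                          table_evaluator(tab))
  expect_identical(tr$final_config$assignments$step1$key, "s1_o2")
})

test_that("failing options are recorded and skipped, not fatal", {
  space <- stub_space(c(3))
  ev <- function(config, goal, context) {
    key <- config$assignments$step1$key
    if (key == "s1_o2") stop("this option crashes")
    c(s1_o1 = 1, s1_o3 = 2)[[key]]
  }
  tr <- stepwise_optimize(space, gsa_goal("max_degs"), list(seed = 1), ev)
  expect_equal(tr$optimized_objective, 2)
  bad <- tr$evaluations[tr$evaluations$option == "s1_o2", ]
  expect_true(is.na(bad$objective))
  expect_match(bad$note, "crashes")
})

test_that("greedy never beats, and with independent steps matches, the global optimum", {
  set.seed(17)
  for (r in 1:20) {
    counts <- sample(2:3, sample(2:4, 1), replace = TRUE)
    space <- stub_space(counts)
    cfgs <- enumerate_configs(space)
    # additive (independent) objective: greedy must equal global
    per_step <- lapply(counts, function(k) setNames(runif(k),
                                                    paste0("o", seq_len(k))))
    tab <- as.list(setNames(vapply(strsplit(cfgs, ","), function(ks) {
      sum(vapply(seq_along(ks), function(i) {
        per_step[[i]][[sub(".*_", "", ks[i])]]
      }, 1))
    }, 1), cfgs))
    tr <- stepwise_optimize(space, gsa_goal("max_degs"), list(seed = 1),
                            table_evaluator(tab))
    expect_equal(tr$optimized_objective, max(unlist(tab)), tolerance = 1e-12)

    # arbitrary (interacting) objective: greedy <= global, never worse
    # than the default
    tab2 <- as.list(setNames(runif(length(cfgs)), cfgs))
    tr2 <- stepwise_optimize(space, gsa_goal("max_degs"), list(seed = 1),
                             table_evaluator(tab2))
    expect_lte(tr2$optimized_objective, max(unlist(tab2)))
    expect_gte(tr2$optimized_objective, tr2$default_objective)
  }
})

test_that("the real pipeline evaluates deterministically with a shared seed", {
  sp <- simulation_spec(n_genes = 300, seed = 81)
  cnt <- simulate_counts(sp)
  idt <- simulate_id_table(rownames(cnt), 0.1, seed = 82)
  dbs <- list(db1 = simulate_database(12, c(8, 30), unique(idt$target),
                                      0.2, seed = 83),
              db2 = simulate_database(12, c(8, 30), unique(idt$target),
                                      0.2, seed = 84))
  for (arch in c("ora", "gsea_preranked", "weighted_fcs")) {
    m <- method_spec(arch, n_permutations = 100)
    ctx <- list(counts = cnt, labels = true_labels(sp), databases = dbs,
                id_table = idt, method = m, seed = 19)
    space <- build_choice_space(m, goal_number = 1, db_names = names(dbs))
    cfg <- default_config(space)
    v1 <- evaluate_config(cfg, gsa_goal("max_degs"), ctx)
    v2 <- evaluate_config(cfg, gsa_goal("max_degs"), ctx)
    expect_equal(as.numeric(v1), as.numeric(v2))

    tr <- suppressMessages(stepwise_optimize(space, gsa_goal("max_degs"),
                                             ctx))
    # goal-directed monotonicity + audit completeness
    expect_false(is_improvement(gsa_goal("max_degs"),
                                tr$default_objective,
                                tr$optimized_objective))
    expect_equal(nrow(tr$evaluations),
                 1 + sum(vapply(space, function(s)
                   length(s$alternatives), 1L)))
    # one shared permutation seed across all evaluations of the trajectory
    expect_true(all(tr$evaluations$perm_seed == 19))
  }
})

test_that("targets filtered out of the result take the worst objective", {
  sp <- simulation_spec(n_genes = 200, seed = 91)
  cnt <- simulate_counts(sp)
  genes <- rownames(cnt)
  dbs <- list(db1 = gene_set_db(list(tiny = genes[1:2],
                                     big = genes[3:40],
                                     other = genes[41:80])))
  m <- method_spec("ora")  # min_size 5 drops 'tiny'
  ctx <- list(counts = cnt, labels = true_labels(sp), databases = dbs,
              method = m, seed = 5)
  space <- build_choice_space(m, goal_number = 2, has_id_table = FALSE)
  cfg <- default_config(space)
  v <- suppressMessages(
    evaluate_config(cfg, gsa_goal("min_adj_p", "tiny"), ctx))
  expect_equal(as.numeric(v), 1)
  vr <- suppressMessages(
    evaluate_config(cfg, gsa_goal("min_rank", "tiny"), ctx))
  expect_equal(as.numeric(vr), 1)
})

test_that("choice-space applicability follows archetype and goal", {
  dbs <- c("db1", "db2")
  ora_space <- build_choice_space(method_spec("ora"), 1, dbs)
  expect_true("universe" %in% vapply(ora_space, `[[`, "", "name"))
  expect_false("weight" %in% vapply(ora_space, `[[`, "", "name"))
  expect_true("geneset_db" %in% vapply(ora_space, `[[`, "", "name"))

  # the database step is exploitable for goal 1 only
  ora_g2 <- build_choice_space(method_spec("ora"), 2, dbs)
  expect_false("geneset_db" %in% vapply(ora_g2, `[[`, "", "name"))

  gsea_space <- build_choice_space(method_spec("gsea_sample_perm"), 2)
  nm <- vapply(gsea_space, `[[`, "", "name")
  expect_true(all(c("transform", "gene_metric", "pvalue_calc", "weight")
                  %in% nm))
  expect_false("universe" %in% nm)

  wf <- build_choice_space(method_spec("weighted_fcs"), 3)
  expect_false("de_method" %in% vapply(wf, `[[`, "", "name"))
})
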
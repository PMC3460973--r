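test_that("colony objectives cycle through the five scores", {
  expect_equal(assign_stages(8),
               c("score3", "score2", "score1", "score5", "score0",
                 "score3", "score2", "score1"))
  expect_equal(assign_stages(1), "score3")
  toy <- make_toy(3, 2, seed = 1)
  cfg <- run_config("shmo", sequence = toy$target$sequence,
                    ss = toy$target$ss, libs = toy$libs, n_colonies = 2,
                    colony_stages = c("score0", "score0"),
                    n_decoys_colonies = 1, n_decoys_mc = 0)
  expect_equal(cfg$colony_stages, c("score0", "score0"))
  expect_error(run_config("shmo", sequence = toy$target$sequence,
                          ss = toy$target$ss, n_colonies = 3,
                          colony_stages = "score3"),
               "length")
})

test_that("channels preserve order and never redeliver", {
  ch <- new_channel()
  channel_push(ch, "a"); channel_push(ch, "b"); channel_push(ch, "c")
  expect_equal(unlist(channel_drain(ch)), c("a", "b", "c"))
  expect_equal(length(channel_drain(ch)), 0L)
})

test_that("shared-matrix batches commute on disjoint support", {
  # deposit-only batches (vanishing evaporation) on disjoint cells commute;
  # with evaporation interleaved the MMAS schedule is order-dependent by
  # design, which is the non-determinism the parallel scheme accepts
  inst <- small_instance(L = 10, n_cand = 3, seed = 26)
  b1 <- list(external_fragments = list(
    list(window = 0L, library = "F3", rank = 0L, quality = 0.4)),
    rho = 1e-12)
  b2 <- list(external_fragments = list(
    list(window = 5L, library = "F3", rank = 2L, quality = 0.7)),
    rho = 1e-12)
  pm_a <- new_pheromone_matrix(inst$libs$f3, tau_max = 10, tau_min = 1e-6)
  shared_tau_update(pm_a, b1); shared_tau_update(pm_a, b2)
  pm_b <- new_pheromone_matrix(inst$libs$f3, tau_max = 10, tau_min = 1e-6)
  shared_tau_update(pm_b, b2); shared_tau_update(pm_b, b1)
  expect_equal(pm_a$tau, pm_b$tau, tolerance = 1e-9)

  # two evaporation-only batches: cell multiplied by 0.9^2 = 0.81
  pm_c <- new_pheromone_matrix(inst$libs$f3, tau_max = 1, tau_min = 1e-6)
  shared_tau_update(pm_c, list(rho = 0.1))
  shared_tau_update(pm_c, list(rho = 0.1))
  expect_equal(pm_c$tau$F3[1, 1], 0.81)
})

test_that("single-colony shmo equals a bare colony run under one seed", {
  toy <- make_toy(4, 2, seed = 3)
  cfg <- run_config("shmo", sequence = toy$target$sequence,
                    ss = toy$target$ss, libs = toy$libs, n_colonies = 1,
                    n_decoys_colonies = 1, n_decoys_mc = 0, seed = 19,
                    colony_opts = list(n_ants = 2, max_iter = 4))
  res <- run(cfg)
  set.seed(19)
  pm <- new_pheromone_matrix(toy$libs$f3, toy$libs$f9)
  bare <- run_colony(toy$target, toy$libs,
                     colony_params(n_ants = 2, max_iter = 4), pm)
  expect_equal(res$decoys3$conformations[[1]]$phi, bare$decoy$phi)
  expect_equal(res$decoys3$entries$score3, bare$energy)
})

test_that("the default hybrid run instantiates 9 workers", {
  toy <- make_toy(3, 2, seed = 5)
  cfg <- run_config("mhmo", sequence = toy$target$sequence,
                    ss = toy$target$ss, libs = toy$libs,
                    n_decoys_colonies = 8, n_decoys_mc = 1, seed = 2,
                    colony_opts = list(n_ants = 1, max_iter = 1),
                    increase_cycles = 0.01)
  res <- run(cfg)
  expect_equal(cfg$n_colonies, 8L)
  expect_equal(res$n_workers, 9L)
})

test_that("scaled decoy quotas are met exactly and unions are consistent", {
  toy <- make_toy(3, 2, seed = 7)
  cfg <- run_config("mhmo", sequence = toy$target$sequence,
                    ss = toy$target$ss, libs = toy$libs, n_colonies = 2,
                    n_decoys_colonies = 6, n_decoys_mc = 2, seed = 4,
                    colony_opts = list(n_ants = 2, max_iter = 2),
                    increase_cycles = 0.02)
  res <- run(cfg)
  expect_equal(nrow(res$decoys1$entries), 6L)
  expect_equal(nrow(res$decoys2$entries), 2L)
  expect_equal(nrow(res$decoys12$entries), 6L)
  # decoys12 is a subset of the union, and exactly the lowest score3 values
  union_scores <- sort(c(res$decoys1$entries$score3,
                         res$decoys2$entries$score3))
  expect_equal(sort(res$decoys12$entries$score3), union_scores[1:6])
})

test_that("deterministic mode is bit-reproducible under the master seed", {
  toy <- make_toy(3, 2, seed = 9)
  cfg <- run_config("mhmo", sequence = toy$target$sequence,
                    ss = toy$target$ss, libs = toy$libs, n_colonies = 2,
                    n_decoys_colonies = 3, n_decoys_mc = 1, seed = 77,
                    colony_opts = list(n_ants = 2, max_iter = 2),
                    increase_cycles = 0.02)
  a <- run(cfg); b <- run(cfg)
  for (k in seq_along(a$decoys1$conformations)) {
    expect_identical(a$decoys1$conformations[[k]]$coords,
                     b$decoys1$conformations[[k]]$coords)
  }
  expect_identical(a$decoys2$conformations[[1]]$coords,
                   b$decoys2$conformations[[1]]$coords)
})

test_that("sequential mode emits decoys0 with no exchange machinery", {
  toy <- make_toy(3, 2, seed = 11)
  cfg <- run_config("sequential_mc", sequence = toy$target$sequence,
                    ss = toy$target$ss, libs = toy$libs,
                    n_decoys_mc = 3, seed = 5, increase_cycles = 0.02)
  res <- run(cfg)
  expect_equal(res$n_workers, 1L)
  expect_named(res, c("decoys0", "n_workers", "libs", "config"))
  expect_equal(nrow(res$decoys0$entries), 3L)
})

test_that("decoy sets write and re-read as PDB plus score table", {
  toy <- make_toy(4, 2, seed = 13)
  cfg <- run_config("shmo", sequence = toy$target$sequence,
                    ss = toy$target$ss, libs = toy$libs, n_colonies = 1,
                    n_decoys_colonies = 2, seed = 3,
                    colony_opts = list(n_ants = 1, max_iter = 1))
  res <- run(cfg)
  dir <- withr::local_tempdir()
  tab_path <- write_decoys(res$decoys3, dir)
  tab <- read_score_table(tab_path)
  expect_equal(nrow(tab), 2L)
  cf <- read_pdb(file.path(dir, paste0(tab$decoy_id[1], ".pdb")))
  expect_equal(n_residues(cf), 4L)
})

test_that("MC-accepted fragments raise their pheromone cells", {
  # paired-seed control: identical colonies, one fed deposits on a fixed
  # cell; after several iterations that cell's tau is strictly higher
  inst <- small_instance(L = 10, n_cand = 4, seed = 28, noise = 30)
  cell <- list(window = 2L, library = "F3", rank = 2L, quality = 1)
  tau_after <- function(deposit) {
    set.seed(91)
    st <- colony_new(inst$target, inst$libs,
                     colony_params(n_ants = 2, epsilon = 0, local_L = 0))
    for (it in 1:8)
      colony_iterate(st, if (deposit) list(cell) else list())
    st$pm$tau$F3[3, 3]
  }
  expect_gt(tau_after(TRUE), tau_after(FALSE))
})
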
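test_that("fragment selection follows the tau^alpha * eta^beta law", {
  expect_equal(select_fragment(2, 1, epsilon = 0), 0L)

  # exponent-zero symmetry: uniform over 4 candidates
  set.seed(41)
  draws <- replicate(1e4, select_fragment(c(5, 1, 3, 2), c(9, 1, 2, 4),
                                          alpha = 0, beta = 0, epsilon = 0))
  tab <- tabulate(draws + 1L, 4L)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)

  # tau (2, 1), eta (1, 1), alpha = beta = 1: P(rank 0) = 2/3
  draws <- replicate(1e4, select_fragment(c(2, 1), c(1, 1),
                                          alpha = 1, beta = 1, epsilon = 0))
  p_hat <- mean(draws == 0)
  se <- sqrt((2 / 3) * (1 / 3) / 1e4)
  expect_lt(abs(p_hat - 2 / 3), 3 * se)

  expect_error(select_fragment(numeric(0), numeric(0)), "empty")
  expect_error(select_fragment(c(1, -1), c(1, 1)), "non-positive")
})

test_that("selection concentrates on the max-tau candidate as alpha grows", {
  set.seed(43)
  draws <- replicate(2000, select_fragment(c(1.0, 0.5, 0.5), c(1, 1, 1),
                                           alpha = 40, beta = 0,
                                           epsilon = 0))
  expect_gt(mean(draws == 0), 0.99)
})

test_that("heuristic eta combines SS match and rank bias", {
  frag <- list(window_start = 0L, length = 3L, rank = 0L, library = "F3",
               phi = rep(-57, 3), psi = rep(-47, 3), omega = rep(180, 3),
               ss = c("H", "H", "H"))
  expect_equal(heuristic_eta(frag, "HHHLL"), 1.0)
  expect_equal(heuristic_eta(frag, "EEELL"), 0.5)
  etas <- vapply(0:5, function(r) {
    f <- frag; f$rank <- r; heuristic_eta(f, "HHHLL")
  }, numeric(1))
  expect_true(all(diff(etas) < 0))
  expect_true(all(etas > 0))
})

test_that("quality maps energies linearly onto [0, 1]", {
  expect_equal(quality(-5, -5, 10), 1)
  expect_equal(quality(10, -5, 10), 0)
  expect_equal(quality(2.5, -5, 10), 0.5)
  expect_equal(quality(99, -5, 10), 0)   # clipped
  expect_equal(quality(3, 7, 7), 1)      # degenerate interval
  expect_error(quality(0, 5, 1), "E_ref_worst")
})

test_that("pheromone updates evaporate, deposit and clamp", {
  inst <- small_instance(L = 10, n_cand = 4, seed = 3)
  pm <- new_pheromone_matrix(inst$libs$f3, inst$libs$f9, tau_max = 10,
                             tau_min = 1e-6)

  # evaporation + one deposit: 1.0 * 0.9 + 0.5 = 1.4 (tau_max far away)
  pm$tau$F3[] <- 1.0
  pheromone_update(pm, iteration_best = list(
    fragments = list(list(window = 2L, library = "F3", rank = 1L)),
    quality = 0.5), rho = 0.1)
  expect_equal(pm$tau$F3[3, 2], 1.4)
  expect_equal(pm$tau$F3[1, 1], 0.9)

  # vanishing evaporation with no deposits leaves tau unchanged
  before <- pm$tau$F3
  pheromone_update(pm, rho = 1e-12)
  expect_equal(pm$tau$F3, before, tolerance = 1e-9)

  # clamping at tau_max
  pm2 <- new_pheromone_matrix(inst$libs$f3, tau_max = 1)
  pheromone_update(pm2, iteration_best = list(
    fragments = list(list(window = 0L, library = "F3", rank = 0L)),
    quality = 1), rho = 0.01)
  expect_equal(pm2$tau$F3[1, 1], 1)

  expect_error(pheromone_update(pm, rho = 0), "rho")
})

test_that("tau bounds hold after arbitrary random update streams", {
  inst <- small_instance(L = 9, n_cand = 3, seed = 6)
  pm <- new_pheromone_matrix(inst$libs$f3, inst$libs$f9)
  set.seed(47)
  for (k in 1:60) {
    deps <- lapply(seq_len(sample(0:5, 1)), function(i) {
      lb <- sample(c("F3", "F9"), 1)
      nw <- nrow(pm$tau[[lb]])
      list(window = sample.int(nw, 1) - 1L,
           library = lb,
           rank = sample.int(3, 1) - 1L,
           quality = runif(1))
    })
    pheromone_update(pm, external_fragments = deps, rho = runif(1, 0.01, 1))
    for (lb in c("F3", "F9")) {
      v <- pm$tau[[lb]][!is.na(pm$tau[[lb]])]
      expect_true(all(v >= pm$tau_min - 1e-12 & v <= pm$tau_max + 1e-12))
    }
  }
  expect_equal(pm$version, 60L)
})

test_that("ant construction respects n_tries, pf and forced choices", {
  inst <- small_instance(L = 10, n_cand = 3, seed = 12)
  pm <- new_pheromone_matrix(inst$libs$f3, inst$libs$f9)
  eta <- list(F3 = acofold:::eta_matrix(inst$libs$f3, inst$target$ss),
              F9 = acofold:::eta_matrix(inst$libs$f9, inst$target$ss))

  # n_tries = 0: the extended chain comes back untouched
  p0 <- colony_params(n_tries = 0)
  out <- construct_conformation(inst$target, inst$libs, pm, eta, p0)
  expect_equal(out$conf$phi, rep(-120, 10))
  expect_equal(length(out$fragments), 0L)

  # pf = 1: every insertion comes from F9
  set.seed(51)
  p9 <- colony_params(pf = 1, n_tries = 20)
  out9 <- construct_conformation(inst$target, inst$libs, pm, eta, p9)
  expect_true(all(vapply(out9$fragments, function(f) f$library,
                         character(1)) == "F9"))

  # degenerate tau * eta forces candidate 1 on a single-window toy
  toy <- make_toy(3, 2, seed = 2)
  pmt <- new_pheromone_matrix(toy$libs$f3)
  pmt$tau$F3[1, ] <- c(pmt$tau_min, pmt$tau_max)
  etat <- list(F3 = matrix(c(1e-9, 1), 1, 2), F9 = NULL)
  pt <- colony_params(alpha = 6, beta = 6, epsilon = 0, n_tries = 4)
  set.seed(52)
  for (rep in 1:10) {
    outt <- construct_conformation(toy$target, toy$libs, pmt, etat, pt)
    expect_true(all(vapply(outt$fragments, function(f) f$rank,
                           integer(1)) == 1L))
  }
})

test_that("one-flip local search never worsens and finds tiny optima", {
  toy <- make_toy(3, 2, seed = 4, ss = "HHH")
  start <- build_backbone(insert_fragment(
    extended_conformation(toy$target$sequence, toy$target$ss),
    get_fragment(toy$libs$f3, 0L, which.max(toy$energies) - 1L)))
  out0 <- one_flip_local_search(start, toy$libs, "score3", 2.0, 0L)
  expect_equal(out0$conf$phi, start$phi)

  hits <- 0
  set.seed(53)
  for (s in 1:100) {
    out <- one_flip_local_search(start, toy$libs, "score3",
                                 local_T = 1e-9, local_L = 30L)
    expect_lte(out$energy, score(start, "score3") + 1e-9)
    if (abs(out$energy - toy$best_energy) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("loop refinement only moves loop residues and picks low energy", {
  # all-helix target: nothing to refine
  inst <- small_instance(L = 10, n_cand = 3, seed = 14)
  cf <- build_backbone(extended_conformation(inst$target$sequence,
                                             inst$target$ss))
  out <- refine_loops(cf, inst$libs$f1, "score3", 1e-9)
  expect_equal(out$conf$phi, cf$phi)

  # one loop residue, two 1-mer entries: T -> 0 picks the better one
  seqs <- "AAAAALAAAAA"; ssv <- "HHHHHLHHHHH"
  f3 <- generate_synthetic_library(seqs, ssv, 3L, 2L, 30, seed = 15L)
  f1 <- merge_to_f1(f3)
  cf2 <- build_backbone(extended_conformation(seqs, ssv))
  i <- 6L
  cands <- seq_len(n_candidates(f1, i - 1L)) - 1L
  energies <- vapply(cands, function(r) {
    score(build_backbone(insert_fragment(cf2, get_fragment(f1, i - 1L, r))),
          "score3")
  }, numeric(1))
  hits <- 0
  set.seed(55)
  for (s in 1:100) {
    out2 <- refine_loops(cf2, f1, "score3", 1e-9, n_props = 20L)
    if (abs(out2$energy - min(min(energies), score(cf2, "score3"))) < 1e-9)
      hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("termination criteria fire as configured", {
  inst <- small_instance(L = 9, n_cand = 2, seed = 16)
  st <- colony_new(inst$target, inst$libs,
                   colony_params(max_iter = 3, termination = "soft_time"))
  st$iter <- 2L
  expect_false(check_termination(st, st$params))
  st$iter <- 3L
  expect_true(check_termination(st, st$params))

  stc <- colony_new(inst$target, inst$libs,
                    colony_params(termination = "convergence"))
  stc$history <- rep(5.0, 9)
  expect_false(check_termination(stc, stc$params))
  stc$history <- rep(5.0, 10)
  expect_true(check_termination(stc, stc$params))
  stc$history <- c(rep(5, 8), 4.9, rep(4.9, 9))
  expect_true(check_termination(stc, stc$params))
})

test_that("a colony run emits decoys and a monotone best-so-far trace", {
  toy <- make_toy(4, 2, seed = 6)
  set.seed(57)
  res <- run_colony(toy$target, toy$libs,
                    colony_params(n_ants = 1, max_iter = 1))
  expect_s3_class(res$decoy, "conformation")
  expect_equal(length(res$history), 1L)

  set.seed(58)
  res2 <- run_colony(toy$target, toy$libs,
                     colony_params(n_ants = 3, max_iter = 12))
  expect_true(all(diff(res2$history) <= 0))
  expect_equal(res2$energy, min(res2$history))
})

test_that("colony search reaches the enumerated optimum on toys", {
  toy <- make_toy(3, 3, seed = 8, ss = "HHH")
  hits <- 0
  for (s in 1:100) {
    set.seed(600 + s)
    res <- run_colony(toy$target, toy$libs,
                      colony_params(n_ants = 3, max_iter = 6, epsilon = 0,
                                    local_T = 1e-9, local_L = 10))
    if (abs(res$energy - toy$best_energy) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("external deposits raise the selection frequency of a candidate", {
  inst <- small_instance(L = 10, n_cand = 4, seed = 18, noise = 30)
  target_cell <- list(window = 3L, library = "F3", rank = 3L, quality = 1)
  count_picks <- function(seed, deposit) {
    set.seed(seed)
    st <- colony_new(inst$target, inst$libs,
                     colony_params(n_ants = 4, epsilon = 0, local_L = 0))
    picks <- 0L
    for (it in 1:12) {
      ib <- colony_iterate(st, if (deposit) list(target_cell) else list())
      picks <- picks + sum(vapply(ib$fragments, function(f)
        f$library == "F3" && f$window == 3L && f$rank == 3L, logical(1)))
    }
    picks
  }
  with_dep <- sum(vapply(1:6, function(s) count_picks(700 + s, TRUE),
                         numeric(1)))
  without <- sum(vapply(1:6, function(s) count_picks(700 + s, FALSE),
                        numeric(1)))
  expect_gt(with_dep, without)
})
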
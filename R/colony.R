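## One MMAS ant colony.  Each ant assembles a conformation by repeated
## fragment insertion, choosing 9-mers over 3-mers with probability pf and
## candidates by the classic ACO selection law tau^alpha * eta^beta (with an
## epsilon chance of a uniform random pick).  The iteration best is polished
## by a one-flip Metropolis local search and loop refinement from F1, the
## shared pheromone matrix is updated (including deposits from externally
## supplied fragments), and the loop runs until a termination criterion
## fires.

#' Colony parameter set
#'
#' Defaults: 8 ants, alpha = 1, beta = 2, evaporation rho = 0.1, random-pick
#' probability epsilon = 0.05, 9-mer preference pf = 0.5, `n_tries = 2 * L`
#' fragment insertions per ant, 50 iterations, Metropolis temperature 2.0
#' and `local_L = L` one-flip tries (L = chain length; the two `NULL`
#' defaults are resolved when the colony is created).
#'
#' @param n_ants ants per iteration.
#' @param alpha,beta pheromone / heuristic exponents of the selection law.
#' @param rho evaporation factor in `(0, 1]`.
#' @param epsilon probability of a uniformly random fragment pick.
#' @param pf probability of proposing from F9 rather than F3.
#' @param n_tries fragment insertions per ant (`NULL` = `2 * L`).
#' @param max_iter iteration budget (the default termination criterion).
#' @param local_T Metropolis temperature of the local search.
#' @param local_L one-flip proposals per local search (`NULL` = `L`).
#' @param stage name of the composite score this colony minimises.
#' @param termination one of `"soft_time"` (iteration budget),
#'   `"hard_time"` (CPU seconds), `"convergence"` (no improvement over the
#'   last ten iterations), `"coverage"` (fraction of pheromone cells ever
#'   selected exceeds 0.5).
#' @param max_seconds CPU budget for `"hard_time"`.
#' @return list of class `"colony_params"`.
#' @export
colony_params <- function(n_ants = 8L, alpha = 1, beta = 2, rho = 0.1,
                          epsilon = 0.05, pf = 0.5, n_tries = NULL,
                          max_iter = 50L, local_T = 2.0, local_L = NULL,
                          stage = "score3", termination = "soft_time",
                          max_seconds = Inf) {
  stopifnot(n_ants >= 1, max_iter >= 1,
            epsilon >= 0, epsilon <= 1, pf >= 0, pf <= 1,
            rho > 0, rho <= 1, local_T > 0)
  structure(list(n_ants = as.integer(n_ants), alpha = alpha, beta = beta,
                 rho = rho, epsilon = epsilon, pf = pf, n_tries = n_tries,
                 max_iter = as.integer(max_iter), local_T = local_T,
                 local_L = local_L, stage = stage, termination = termination,
                 max_seconds = max_seconds),
            class = "colony_params")
}

#' Heuristic desirability of a fragment
#'
#' The a-priori bias of the selection law:
#' `0.5 * (fraction of fragment SS labels matching the predicted secondary
#' structure over the window) + 0.5 / (1 + rank)`.  Strictly positive, 1 at
#' a rank-0 fragment with a full SS match, strictly decreasing in rank.
#'
#' @param fragment a fragment (see [get_fragment()]).
#' @param ss_string predicted secondary structure of the whole target.
#' @return positive scalar.
#' @export
heuristic_eta <- function(fragment, ss_string) {
  if (length(ss_string) == 1L && nchar(ss_string[1]) > 1L)
    ss_string <- strsplit(ss_string, "")[[1]]
  idx <- fragment$window_start + seq_len(fragment$length)
  if (max(idx) > length(ss_string)) stop("fragment window outside target")
  match_frac <- mean(fragment$ss == ss_string[idx])
  0.5 * match_frac + 0.5 / (1 + fragment$rank)
}

## eta for every (window, rank) cell of a library, as a matrix parallel to
## the pheromone matrix
eta_matrix <- function(lib, ss_string) {
  if (length(ss_string) == 1L && nchar(ss_string[1]) > 1L)
    ss_string <- strsplit(ss_string, "")[[1]]
  nw <- n_windows(lib)
  ncand <- vapply(lib$windows, function(w) nrow(w$phi), 1L)
  m <- matrix(NA_real_, nw, max(ncand))
  for (w in seq_len(nw)) {
    idx <- (w - 1L) + seq_len(lib$frag_length)
    target_ss <- ss_string[idx]
    wd <- lib$windows[[w]]
    frac <- rowMeans(wd$ss == matrix(target_ss, nrow(wd$ss),
                                     lib$frag_length, byrow = TRUE))
    m[w, seq_len(ncand[w])] <- 0.5 * frac + 0.5 / (1 + seq_len(ncand[w]) - 1)
  }
  m
}

#' Probabilistic fragment selection (ACO selection law)
#'
#' With probability `epsilon` picks a candidate uniformly at random;
#' otherwise picks rank j with probability proportional to
#' `tau_j^alpha * eta_j^beta`.
#'
#' @param tau,eta positive numeric vectors over the window's candidates.
#' @param alpha,beta exponents.
#' @param epsilon random-pick probability.
#' @return 0-based rank of the selected candidate.
#' @export
select_fragment <- function(tau, eta, alpha = 1, beta = 2, epsilon = 0.05) {
  n <- length(tau)
  if (n == 0L || length(eta) != n) stop("empty or mismatched candidate set")
  if (any(tau <= 0) || any(eta <= 0)) stop("non-positive tau or eta")
  if (n == 1L) return(0L)
  if (epsilon > 0 && stats::runif(1) < epsilon)
    return(sample.int(n, 1L) - 1L)
  w <- tau^alpha * eta^beta
  sample.int(n, 1L, prob = w / sum(w)) - 1L
}

## pick a library for a proposal: F9 with probability pf when it exists
choose_library <- function(libs, pf) {
  if (!is.null(libs$f9) && n_windows(libs$f9) > 0 && stats::runif(1) < pf)
    "F9" else "F3"
}

#' Ant conformation construction
#'
#' Starting from the extended chain, performs `n_tries` fragment
#' insertions: choose F9 with probability `pf` (else F3), a window
#' uniformly at random, a candidate by [select_fragment()] against the
#' shared pheromone matrix, and splice it in.
#'
#' @param target list with `sequence` and `ss`.
#' @param libs list with fragment libraries `f3` and optionally `f9`.
#' @param pm shared pheromone matrix.
#' @param eta list of eta matrices (`F3`, `F9`) from [eta_matrix()].
#' @param params colony parameters.
#' @return list with `conf` (the finished conformation, coordinates built),
#'   `energy` (its stage score) and `fragments` (the insertion log of
#'   `(window, library, rank)` triples).
#' @export
construct_conformation <- function(target, libs, pm, eta, params) {
  conf <- extended_conformation(target$sequence, target$ss)
  n_tries <- params$n_tries %||% (2L * n_residues(conf))
  used <- vector("list", n_tries)
  if (n_tries > 0) {
    for (t in seq_len(n_tries)) {
      lb <- choose_library(libs, params$pf)
      lib <- if (lb == "F9") libs$f9 else libs$f3
      w <- sample.int(n_windows(lib), 1L) - 1L
      tv <- tau_levels(pm, lb, w)
      ev <- eta[[lb]][w + 1L, seq_along(tv)]
      r <- select_fragment(tv, ev, params$alpha, params$beta, params$epsilon)
      conf <- insert_fragment(conf, get_fragment(lib, w, r))
      used[[t]] <- list(window = w, library = lb, rank = r)
    }
  }
  conf <- ensure_coords(conf)
  list(conf = conf, energy = score(conf, params$stage), fragments = used)
}

#' One-flip Metropolis local search
#'
#' `local_L` single-fragment replacements (library by `pf`, window and
#' candidate uniformly at random), each accepted by the Metropolis
#' criterion at temperature `local_T`; returns the best conformation
#' visited, so the output energy never exceeds the input energy.
#'
#' @param conf starting conformation.
#' @param libs fragment libraries (`f3`, optional `f9`).
#' @param stage score name to minimise.
#' @param local_T Metropolis temperature.
#' @param local_L number of proposals (0 = return the input).
#' @param pf probability of proposing from F9.
#' @return list with `conf`, `energy` and `accepted` (log of accepted
#'   replacement triples).
#' @export
one_flip_local_search <- function(conf, libs, stage, local_T, local_L,
                                  pf = 0.5) {
  conf <- ensure_coords(conf)
  cur_e <- score(conf, stage)
  best <- conf; best_e <- cur_e
  accepted <- list()
  if (local_L > 0) {
    for (k in seq_len(local_L)) {
      lb <- choose_library(libs, pf)
      lib <- if (lb == "F9") libs$f9 else libs$f3
      w <- sample.int(n_windows(lib), 1L) - 1L
      r <- sample.int(n_candidates(lib, w), 1L) - 1L
      cand <- ensure_coords(insert_fragment(conf, get_fragment(lib, w, r)))
      cand_e <- score(cand, stage)
      if (metropolis_accept(cand_e - cur_e, local_T)) {
        conf <- cand; cur_e <- cand_e
        accepted[[length(accepted) + 1L]] <-
          list(window = w, library = lb, rank = r)
        if (cur_e < best_e) { best <- conf; best_e <- cur_e }
      }
    }
  }
  list(conf = best, energy = best_e, accepted = accepted)
}

#' Loop refinement from the 1-mer library
#'
#' One-flip Metropolis restricted to loop residues (label `"L"`), proposals
#' drawn from the residue's F1 entries; best-visited conformation returned.
#' Targets without loop residues are returned unchanged.
#'
#' @param conf starting conformation.
#' @param f1 the merged 1-mer library.
#' @param stage score name to minimise.
#' @param local_T Metropolis temperature.
#' @param n_props number of proposals; default twice the number of loop
#'   residues.
#' @return list with `conf` and `energy`.
#' @export
refine_loops <- function(conf, f1, stage, local_T, n_props = NULL) {
  conf <- ensure_coords(conf)
  cur_e <- score(conf, stage)
  loop_res <- which(conf$ss == "L")
  if (length(loop_res) == 0L || is.null(f1))
    return(list(conf = conf, energy = cur_e))
  if (is.null(n_props)) n_props <- 2L * length(loop_res)
  best <- conf; best_e <- cur_e
  for (k in seq_len(n_props)) {
    i <- loop_res[sample.int(length(loop_res), 1L)]
    nc <- n_candidates(f1, i - 1L)
    r <- sample.int(nc, 1L) - 1L
    cand <- ensure_coords(insert_fragment(conf, get_fragment(f1, i - 1L, r)))
    cand_e <- score(cand, stage)
    if (metropolis_accept(cand_e - cur_e, local_T)) {
      conf <- cand; cur_e <- cand_e
      if (cur_e < best_e) { best <- conf; best_e <- cur_e }
    }
  }
  list(conf = best, energy = best_e)
}

#' Check colony termination
#'
#' Implements the four criteria: `"soft_time"` -- the iteration budget has
#' been used (the default); `"hard_time"` -- a CPU-seconds budget;
#' `"convergence"` -- no best-energy improvement over the last ten
#' iterations; `"coverage"` -- more than half of the pheromone cells have
#' been selected at least once (approximated by the colony's own selection
#' bookkeeping).
#'
#' @param state colony state (from [colony_new()]).
#' @param params colony parameters.
#' @return logical.
#' @export
check_termination <- function(state, params) {
  switch(params$termination,
    soft_time = state$iter >= params$max_iter,
    hard_time = (proc.time()[["elapsed"]] - state$t0) >= params$max_seconds,
    convergence = {
      # no improvement of the best energy across the last ten iterations
      h <- state$history
      n <- length(h)
      n >= 10L && h[n] >= h[n - 9L]
    },
    coverage = state$cells_seen / max(1L, state$cells_total) > 0.5,
    stop("unknown termination criterion: ", params$termination)
  )
}

#' Create a colony worker
#'
#' @param target list with `sequence` and `ss`.
#' @param libs list with `f3`, optional `f9`, optional `f1`.
#' @param params colony parameters.
#' @param pm shared pheromone matrix (created over `libs` if `NULL`).
#' @return mutable colony state (environment).
#' @export
colony_new <- function(target, libs, params = colony_params(), pm = NULL) {
  if (is.null(pm)) pm <- new_pheromone_matrix(libs$f3, libs$f9)
  st <- new.env(parent = emptyenv())
  st$target <- target
  st$libs <- libs
  st$params <- params
  st$pm <- pm
  st$eta <- list(F3 = eta_matrix(libs$f3, target$ss),
                 F9 = if (!is.null(libs$f9)) eta_matrix(libs$f9, target$ss))
  st$best <- NULL; st$best_e <- Inf
  st$E_ref_best <- Inf; st$E_ref_worst <- -Inf
  st$history <- numeric(0)
  st$iter <- 0L
  st$t0 <- proc.time()[["elapsed"]]
  st$cells_total <- sum(vapply(Filter(Negate(is.null), pm$tau),
                               function(m) sum(!is.na(m)), 1L))
  st$seen <- character(0)
  st$cells_seen <- 0L
  class(st) <- "colony_state"
  st
}

#' Advance a colony by one iteration
#'
#' Constructs `n_ants` conformations, applies the one-flip local search and
#' loop refinement to the iteration best, updates the best-so-far, and
#' performs one pheromone update batch (iteration-best deposit plus any
#' externally supplied fragments).
#'
#' @param state colony state.
#' @param external_fragments fragments from the Monte-Carlo predictor,
#'   each `list(window, library, rank, quality)`.
#' @return the iteration-best result (list with `conf`, `energy`,
#'   `fragments`), invisibly; `state` is updated in place.
#' @export
colony_iterate <- function(state, external_fragments = list()) {
  p <- state$params
  ants <- vector("list", p$n_ants)
  for (a in seq_len(p$n_ants)) {
    ants[[a]] <- construct_conformation(state$target, state$libs,
                                        state$pm, state$eta, p)
  }
  energies <- vapply(ants, function(x) x$energy, numeric(1))
  ib <- ants[[which.min(energies)]]

  ls <- one_flip_local_search(ib$conf, state$libs, p$stage,
                              p$local_T, p$local_L %||%
                                n_residues(ib$conf), p$pf)
  rf <- refine_loops(ls$conf, state$libs$f1, p$stage, p$local_T)
  ib$conf <- rf$conf
  ib$energy <- rf$energy
  ib$fragments <- c(ib$fragments, ls$accepted)

  state$E_ref_best <- min(state$E_ref_best, min(energies), ib$energy)
  state$E_ref_worst <- max(state$E_ref_worst, max(energies), ib$energy)
  if (ib$energy < state$best_e) {
    state$best <- ib$conf
    state$best_e <- ib$energy
  }
  q <- quality(ib$energy, state$E_ref_best, state$E_ref_worst)
  # external (MC-predictor) fragments deposit with the same quality scaling,
  # computed from the MC conformation's stage energy when it is supplied
  external_fragments <- lapply(external_fragments, function(f) {
    if (is.null(f$quality)) {
      f$quality <- if (!is.null(f$energy) &&
                       is.finite(state$E_ref_best) &&
                       is.finite(state$E_ref_worst))
        quality(f$energy, state$E_ref_best, state$E_ref_worst) else 0.5
    }
    f
  })
  pheromone_update(state$pm,
                   iteration_best = list(fragments = ib$fragments,
                                         quality = q),
                   external_fragments = external_fragments,
                   rho = p$rho)
  keys <- vapply(ib$fragments, function(f)
    paste(f$library, f$window, f$rank), character(1))
  state$seen <- union(state$seen, keys)
  state$cells_seen <- length(state$seen)
  state$iter <- state$iter + 1L
  state$history <- c(state$history, state$best_e)
  invisible(ib)
}

#' Run a colony to termination
#'
#' Loops [colony_iterate()] until [check_termination()] fires and emits the
#' best-so-far conformation as the colony's decoy.  The best-so-far energy
#' trace is monotone non-increasing by construction.
#'
#' @inheritParams colony_new
#' @param inbox optional channel of external fragment messages (drained
#'   each iteration).
#' @param outbox optional channel; the iteration best is published to it.
#' @return list with `decoy` (conformation), `energy`, `history` and the
#'   final `state`.
#' @export
run_colony <- function(target, libs, params = colony_params(), pm = NULL,
                       inbox = NULL, outbox = NULL) {
  state <- colony_new(target, libs, params, pm)
  repeat {
    ext <- if (!is.null(inbox)) channel_drain_flat(inbox) else list()
    ib <- colony_iterate(state, ext)
    if (!is.null(outbox))
      channel_push(outbox, list(conf = ib$conf, energy = ib$energy))
    if (check_termination(state, params)) break
  }
  list(decoy = state$best, energy = state$best_e,
       history = state$history, state = state)
}
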
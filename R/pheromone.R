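## Shared MMAS pheromone matrix: one desirability level per
## (window, library, rank) fragment choice, clamped to [tau_min, tau_max]
## after every update batch.  The matrix is an environment so that several
## colonies (and the orchestrator) literally share one object, as the
## parallel scheme requires.

#' Create a shared MMAS pheromone matrix
#'
#' One level per (window, library, rank) cell over the F3 (and, when
#' present, F9) candidate sets.  Levels start at `tau_max` (the MMAS
#' convention) and every update clamps back into `[tau_min, tau_max]`.
#' The returned object is an environment: all colonies holding it see every
#' update -- the single shared matrix of the parallel design.
#'
#' @param f3 3-mer fragment library.
#' @param f9 optional 9-mer fragment library.
#' @param tau_max upper pheromone bound.
#' @param tau_min lower bound; default `tau_max / (2 * max candidate
#'   count)`.
#' @return environment of class `"pheromone_matrix"` with fields `tau`
#'   (list of window x rank matrices per library), `tau_min`, `tau_max`,
#'   `version`.
#' @export
new_pheromone_matrix <- function(f3, f9 = NULL, tau_max = 1,
                                 tau_min = NULL) {
  mk <- function(lib) {
    if (is.null(lib)) return(NULL)
    ncand <- vapply(lib$windows, function(w) nrow(w$phi), 1L)
    m <- matrix(NA_real_, n_windows(lib), max(ncand))
    for (w in seq_len(n_windows(lib))) m[w, seq_len(ncand[w])] <- tau_max
    m
  }
  tau <- list(F3 = mk(f3), F9 = mk(f9))
  maxcand <- max(vapply(Filter(Negate(is.null), tau), ncol, 1L))
  if (is.null(tau_min)) tau_min <- tau_max / (2 * maxcand)
  e <- new.env(parent = emptyenv())
  e$tau <- tau
  e$tau_min <- tau_min
  e$tau_max <- tau_max
  e$version <- 0L
  class(e) <- "pheromone_matrix"
  e
}

#' Pheromone levels for one window
#'
#' @param pm pheromone matrix.
#' @param library `"F3"` or `"F9"`.
#' @param window 0-based window start.
#' @return numeric vector of levels, one per candidate rank.
#' @export
tau_levels <- function(pm, library, window) {
  v <- pm$tau[[library]][window + 1L, ]
  v[!is.na(v)]
}

#' Solution quality for pheromone deposition
#'
#' Linearly rescales an energy into `[0, 1]` against reference best/worst
#' energies (1 at the best, 0 at the worst, clipped outside); this is the
#' amount of pheromone a solution deposits.  A degenerate reference
#' interval maps everything to 1.
#'
#' @param E energy of the solution.
#' @param E_ref_best,E_ref_worst reference energies with
#'   `E_ref_worst >= E_ref_best`.
#' @return value in `[0, 1]`.
#' @export
quality <- function(E, E_ref_best, E_ref_worst) {
  if (E_ref_worst < E_ref_best) stop("E_ref_worst < E_ref_best")
  if (E_ref_worst - E_ref_best <= 0) return(1)
  min(1, max(0, (E_ref_worst - E) / (E_ref_worst - E_ref_best)))
}

#' MMAS pheromone update with external deposits
#'
#' One update batch: every cell evaporates by `(1 - rho)`, the
#' iteration-best solution deposits its quality on every fragment cell it
#' used, externally supplied fragments (the Monte-Carlo predictor's
#' accepted fragments, treated as the choices of a "best-so-far ant")
#' deposit their own quality, and finally all cells are clamped to
#' `[tau_min, tau_max]`.  The version counter increments once per batch.
#'
#' @param pm pheromone matrix (modified in place; also returned).
#' @param iteration_best `NULL` or a list with `fragments` (list of
#'   `list(window, library, rank)`) and `quality` in `[0, 1]`.
#' @param external_fragments list of `list(window, library, rank, quality)`.
#' @param rho evaporation factor in `(0, 1]`.
#' @return the pheromone matrix, invisibly.
#' @export
pheromone_update <- function(pm, iteration_best = NULL,
                             external_fragments = list(), rho = 0.1) {
  if (!is.numeric(rho) || rho <= 0 || rho > 1) stop("rho must be in (0, 1]")
  for (lb in names(pm$tau)) {
    if (!is.null(pm$tau[[lb]])) pm$tau[[lb]] <- pm$tau[[lb]] * (1 - rho)
  }
  deposit <- function(frag, q) {
    lb <- frag$library
    m <- pm$tau[[lb]]
    if (is.null(m)) return()
    m[frag$window + 1L, frag$rank + 1L] <-
      m[frag$window + 1L, frag$rank + 1L] + q
    pm$tau[[lb]] <- m
  }
  if (!is.null(iteration_best)) {
    for (f in iteration_best$fragments) deposit(f, iteration_best$quality)
  }
  for (f in external_fragments) {
    q <- if (!is.null(f$quality)) f$quality else 0.5
    deposit(f, q)
  }
  for (lb in names(pm$tau)) {
    if (!is.null(pm$tau[[lb]]))
      pm$tau[[lb]] <- pmax(pmin(pm$tau[[lb]], pm$tau_max), pm$tau_min)
  }
  pm$version <- pm$version + 1L
  invisible(pm)
}

#' Apply one batch of pheromone operations to the shared matrix
#'
#' The shared-matrix contract: a batch (one evaporation plus its deposits)
#' applies as a unit with no interleaving; concurrent batches from
#' different workers may apply in any order, and in deterministic mode the
#' order is the round-robin worker order.
#'
#' @param pm pheromone matrix.
#' @param batch list with optional `iteration_best`, `external_fragments`,
#'   `rho` as in [pheromone_update()].
#' @return the pheromone matrix, invisibly.
#' @export
shared_tau_update <- function(pm, batch) {
  pheromone_update(pm,
                   iteration_best = batch$iteration_best,
                   external_fragments = batch$external_fragments %||% list(),
                   rho = batch$rho %||% 0.1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
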
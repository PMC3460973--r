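## Multi-stage Metropolis Monte-Carlo predictor.  Five stages minimise
## score0, score1, score2/score5 (alternating), score3 and score3 again:
## the first four propose fragment insertions (9-mers at stage 1, 3-mers
## after), the last proposes single-residue torsion perturbations.  At every
## stage boundary the working conformation is nudged toward the per-residue
## circular-mean torsions of the colonies' iteration-best solutions
## (the PerturbationSet), and every accepted fragment identity is streamed
## out so the colonies can convert it into pheromone.

#' Metropolis acceptance criterion
#'
#' Accept an energy change `deltaE` at temperature `T`: always when
#' `deltaE <= 0`, otherwise with probability `exp(-deltaE / T)`.
#'
#' @param deltaE proposed energy change.
#' @param T temperature, `> 0`.
#' @return logical.
#' @export
metropolis_accept <- function(deltaE, T) {
  if (!is.numeric(T) || T <= 0) stop("temperature must be positive")
  deltaE <= 0 || stats::runif(1) < exp(-deltaE / T)
}

#' Per-residue circular-mean torsions of a perturbation set
#'
#' The average is the circular mean (atan2 of averaged sines and cosines):
#' the arithmetic mean of 170 and -170 degrees is 0, the circular mean is
#' 180, which is why torsions must be averaged this way.
#'
#' @param confs non-empty list of conformations of equal length.
#' @return list with numeric vectors `phi` and `psi` (degrees).
#' @export
average_torsions <- function(confs) {
  if (length(confs) == 0L) stop("empty perturbation set")
  L <- n_residues(confs[[1]])
  phim <- vapply(confs, function(cf) cf$phi, numeric(L))
  psim <- vapply(confs, function(cf) cf$psi, numeric(L))
  phim <- matrix(phim, nrow = L); psim <- matrix(psim, nrow = L)
  list(phi = apply(phim, 1, circular_mean),
       psi = apply(psim, 1, circular_mean))
}

#' Blend a conformation toward the perturbation-set average
#'
#' Each phi and psi moves along the shortest circular arc toward the
#' average by fraction `lam`: `theta' = theta + lam * wrap(mean - theta)`.
#' `lam = 0` leaves the conformation unchanged, `lam = 1` sets the averages
#' exactly; omega is untouched.
#'
#' @param conf a conformation.
#' @param avg averages from [average_torsions()] (or a non-empty list of
#'   conformations, averaged on the fly).
#' @param lam blend fraction in `[0, 1]`.
#' @return the perturbed conformation (caches invalidated).
#' @export
apply_perturbation <- function(conf, avg, lam) {
  if (!is.numeric(lam) || lam < 0 || lam > 1) stop("lam must be in [0, 1]")
  if (lam == 0) return(conf)
  if (is.null(avg$phi)) avg <- average_torsions(avg)
  conf$phi <- wrap_angle(conf$phi + lam * angle_diff(avg$phi, conf$phi))
  conf$psi <- wrap_angle(conf$psi + lam * angle_diff(avg$psi, conf$psi))
  invalidate_caches(conf)
}

#' Stage schedule of the Monte-Carlo predictor
#'
#' The fixed stage order: score0 with 9-mer insertions, score1 with 3-mers,
#' score2/score5 alternating per 200-cycle block with 3-mers, score3 with
#' 3-mers, and a final score3 stage of single-residue torsion
#' perturbations.  Cycle counts are
#' `(2000, 2000, 2000, 4000, 4000) * increase_cycles / 4` and scale
#' linearly with `increase_cycles`.
#'
#' @param increase_cycles positive multiplier (4 reproduces the base
#'   counts).
#' @param base_cycles base cycle counts at `increase_cycles = 4`.
#' @return list of class `"stage_schedule"`; one element per stage with
#'   `name`, `move` (`"frag9"`, `"frag3"` or `"torsion"`), `cycles` and
#'   `alternate` (stage 3 only).
#' @export
stage_schedule <- function(increase_cycles = 4,
                           base_cycles = c(2000, 2000, 2000, 4000, 4000)) {
  stopifnot(increase_cycles > 0, length(base_cycles) == 5)
  cyc <- as.integer(round(base_cycles * increase_cycles / 4))
  structure(list(
    list(name = "score0", move = "frag9", cycles = cyc[1]),
    list(name = "score1", move = "frag3", cycles = cyc[2]),
    list(name = "score2", move = "frag3", cycles = cyc[3],
         alternate = "score5", block = 200L),
    list(name = "score3", move = "frag3", cycles = cyc[4]),
    list(name = "score3", move = "torsion", cycles = cyc[5])
  ), class = "stage_schedule")
}

#' Create a Monte-Carlo predictor worker
#'
#' @param target list with `sequence` and `ss`.
#' @param libs fragment libraries (`f3`, optional `f9`).
#' @param schedule a [stage_schedule()].
#' @param lambda perturbation blend fraction applied at stage boundaries.
#' @param temperature Metropolis temperature (fixed across stages).
#' @param sigma standard deviation (degrees) of the stage-5 torsion moves.
#' @param score_fn optional replacement scoring function
#'   `function(conformation, stage_name)`; the default is [score()].
#'   Useful for instrumenting or forcing the acceptance landscape.
#' @return mutable predictor state (environment).
#' @export
mc_new <- function(target, libs, schedule = stage_schedule(),
                   lambda = 0.3, temperature = 2.0, sigma = 10,
                   score_fn = NULL) {
  st <- new.env(parent = emptyenv())
  st$target <- target
  st$libs <- libs
  st$schedule <- schedule
  st$lambda <- lambda
  st$T <- temperature
  st$sigma <- sigma
  st$score_fn <- if (is.null(score_fn)) score else score_fn
  st$conf <- ensure_coords(extended_conformation(target$sequence, target$ss))
  st$stage_idx <- 0L
  st$frag_log <- list()
  st$n_proposals <- integer(length(schedule))
  st$done <- FALSE
  class(st) <- "mc_state"
  st
}

## one fragment-insertion or torsion proposal; returns updated (conf, e)
## plus acceptance bookkeeping through the enclosing environment
mc_run_stage <- function(st, stage, stage_no, perturbations) {
  conf <- st$conf
  if (length(perturbations) > 0 && st$lambda > 0) {
    conf <- apply_perturbation(conf, average_torsions(perturbations),
                               st$lambda)
  }
  conf <- ensure_coords(conf)
  torsion_stage <- identical(stage$move, "torsion")
  cur_name <- stage$name
  cur_e <- st$score_fn(conf, cur_name)
  best <- conf; best_e <- cur_e
  accepted <- list()
  L <- n_residues(conf)
  if (stage$cycles > 0) {
    for (cyc in seq_len(stage$cycles)) {
      if (!is.null(stage$alternate)) {
        blk <- ((cyc - 1L) %/% stage$block) %% 2L
        nm <- if (blk == 0L) stage$name else stage$alternate
        if (nm != cur_name) { cur_name <- nm; cur_e <- st$score_fn(conf, cur_name) }
      }
      if (torsion_stage) {
        i <- sample.int(L, 1L)
        cand <- conf
        cand$phi[i] <- wrap_angle(cand$phi[i] + stats::rnorm(1, 0, st$sigma))
        cand$psi[i] <- wrap_angle(cand$psi[i] + stats::rnorm(1, 0, st$sigma))
        cand <- ensure_coords(invalidate_caches(cand))
        cand_e <- st$score_fn(cand, cur_name)
        if (metropolis_accept(cand_e - cur_e, st$T)) {
          conf <- cand; cur_e <- cand_e
        }
      } else {
        lb <- if (stage$move == "frag9" && !is.null(st$libs$f9)) "F9" else "F3"
        lib <- if (lb == "F9") st$libs$f9 else st$libs$f3
        w <- sample.int(n_windows(lib), 1L) - 1L
        r <- sample.int(n_candidates(lib, w), 1L) - 1L
        cand <- ensure_coords(insert_fragment(conf, get_fragment(lib, w, r)))
        cand_e <- st$score_fn(cand, cur_name)
        acc <- metropolis_accept(cand_e - cur_e, st$T)
        st$frag_log[[length(st$frag_log) + 1L]] <- list(
          cycle = cyc, stage = stage_no, window = w, library = lb,
          rank = r, deltaE = cand_e - cur_e, accepted = acc)
        if (acc) {
          conf <- cand; cur_e <- cand_e
          accepted[[length(accepted) + 1L]] <-
            list(window = w, library = lb, rank = r)
        }
      }
      if (cur_e < best_e) { best <- conf; best_e <- cur_e }
      st$n_proposals[stage_no] <- st$n_proposals[stage_no] + 1L
    }
  }
  # the final (torsion) stage returns its best-visited conformation
  st$conf <- if (torsion_stage) best else conf
  accepted
}

#' Advance the Monte-Carlo predictor by one stage
#'
#' Drains the perturbation inbox, blends the working conformation toward
#' the perturbation-set average, runs the stage's proposal cycles, and
#' publishes the stage's accepted fragments (with a quality derived from
#' the stage energy) to the fragment outbox.
#'
#' @param st predictor state.
#' @param perturb_inbox optional channel carrying colony iteration-best
#'   conformations.
#' @param fragment_outbox optional channel; accepted fragments are pushed
#'   as one batch.
#' @return accepted fragments of the stage, invisibly.
#' @export
mc_step <- function(st, perturb_inbox = NULL, fragment_outbox = NULL) {
  if (st$done) stop("predictor already finished its schedule")
  st$stage_idx <- st$stage_idx + 1L
  stage <- st$schedule[[st$stage_idx]]
  perts <- if (!is.null(perturb_inbox)) {
    lapply(channel_drain(perturb_inbox), function(m) m$conf)
  } else list()
  accepted <- mc_run_stage(st, stage, st$stage_idx, perts)
  if (length(accepted) > 0) {
    e_final <- st$score_fn(ensure_coords(st$conf), stage$name)
    accepted <- lapply(accepted, function(f) { f$energy <- e_final; f })
  }
  if (!is.null(fragment_outbox) && length(accepted) > 0)
    channel_push(fragment_outbox, accepted)
  if (st$stage_idx >= length(st$schedule)) st$done <- TRUE
  invisible(accepted)
}

#' Run the full staged Monte-Carlo prediction
#'
#' Executes all five stages from the extended chain and returns the final
#' conformation as one decoy together with the accepted-fragment log.
#'
#' @inheritParams mc_new
#' @param perturb_inbox,fragment_outbox optional exchange channels (see
#'   [mc_step()]).
#' @return list with `decoy` (conformation), `score3`, `frag_log` (data
#'   frame: cycle, stage, window, library, rank, deltaE, accepted) and
#'   `n_proposals` per stage.
#' @export
run_stages <- function(target, libs, schedule = stage_schedule(),
                       lambda = 0.3, temperature = 2.0, sigma = 10,
                       perturb_inbox = NULL, fragment_outbox = NULL,
                       score_fn = NULL) {
  st <- mc_new(target, libs, schedule, lambda, temperature, sigma, score_fn)
  while (!st$done) mc_step(st, perturb_inbox, fragment_outbox)
  fl <- if (length(st$frag_log)) {
    do.call(rbind, lapply(st$frag_log, function(x)
      data.frame(cycle = x$cycle, stage = x$stage, window = x$window,
                 library = x$library, rank = x$rank, deltaE = x$deltaE,
                 accepted = x$accepted)))
  } else {
    data.frame(cycle = integer(0), stage = integer(0), window = integer(0),
               library = character(0), rank = integer(0),
               deltaE = numeric(0), accepted = logical(0))
  }
  decoy <- ensure_coords(st$conf)
  list(decoy = decoy, score3 = score(decoy, "score3"),
       frag_log = fl, n_proposals = st$n_proposals)
}
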
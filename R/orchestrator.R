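## Parallel-scheme driver.  Colony and Monte-Carlo workers advance
## round-robin against the single shared pheromone matrix: each colony takes
## one iteration, the MC predictor one stage, messages are exchanged at
## those boundaries (order-preserving, drained exactly once), and the whole
## run is a pure function of (config, seed).  Modes: sequential_mc
## (repeated MC runs -> decoys0), shmo (colonies sharing one matrix, no MC
## -> decoys3), mhmo (colonies + MC with bidirectional exchange ->
## decoys1, decoys2 and their score3-union decoys12).

## ---- exchange channels ----------------------------------------------------

#' Create an exchange channel
#'
#' A simple order-preserving message queue: pushes append, a drain returns
#' every pending message and empties the queue (messages are never
#' redelivered).
#'
#' @return an environment of class `"channel"`.
#' @export
new_channel <- function() {
  e <- new.env(parent = emptyenv())
  e$q <- list()
  class(e) <- "channel"
  e
}

#' @rdname new_channel
#' @param ch a channel.
#' @param msg any R object.
#' @export
channel_push <- function(ch, msg) {
  ch$q[[length(ch$q) + 1L]] <- msg
  invisible(ch)
}

#' @rdname new_channel
#' @export
channel_drain <- function(ch) {
  out <- ch$q
  ch$q <- list()
  out
}

## drain and flatten one level (for channels carrying batches)
channel_drain_flat <- function(ch) {
  out <- channel_drain(ch)
  if (length(out) == 0L) return(list())
  do.call(c, out)
}

## ---- configuration --------------------------------------------------------

#' Default colony objective assignment
#'
#' Colonies cycle through the composite scores
#' `score3, score2, score1, score5, score0` and repeat, so that the
#' population simultaneously minimises different objective functions.
#'
#' @param n_colonies number of colonies.
#' @return character vector of stage names, length `n_colonies`.
#' @export
assign_stages <- function(n_colonies) {
  stopifnot(n_colonies >= 1)
  rep(c("score3", "score2", "score1", "score5", "score0"),
      length.out = n_colonies)
}

#' Run configuration
#'
#' @param mode `"sequential_mc"`, `"shmo"` or `"mhmo"`.
#' @param sequence target amino-acid string.
#' @param ss predicted secondary-structure string (H/E/L).
#' @param libs list with fragment libraries `f3`, optional `f9`, optional
#'   `f1` (merged from f3/f9 when absent); `NULL` = generate synthetic
#'   libraries.
#' @param n_colonies number of ant colonies (default 8).
#' @param colony_stages stage name per colony (default [assign_stages()]).
#' @param n_decoys_colonies pooled colony decoy quota (decoys1/decoys3);
#'   the full-protocol value is 800.
#' @param n_decoys_mc MC decoy quota (decoys0/decoys2); full-protocol 100
#'   (800 for the sequential control).
#' @param seed master seed; every random draw of the run derives from it.
#' @param colony_opts named list of [colony_params()] overrides.
#' @param increase_cycles MC schedule multiplier (see [stage_schedule()]).
#' @param lambda perturbation blend fraction.
#' @param mc_sigma stage-5 torsion move s.d. (degrees).
#' @param n_per_window,noise_deg synthetic-library parameters used when
#'   `libs` is `NULL`.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(mode = c("mhmo", "shmo", "sequential_mc"),
                       sequence, ss, libs = NULL,
                       n_colonies = 8L, colony_stages = NULL,
                       n_decoys_colonies = 800L, n_decoys_mc = 100L,
                       seed = 1L, colony_opts = list(),
                       increase_cycles = 4, lambda = 0.3, mc_sigma = 10,
                       n_per_window = 200L, noise_deg = 10) {
  mode <- match.arg(mode)
  if (is.null(colony_stages)) colony_stages <- assign_stages(n_colonies)
  if (length(colony_stages) != n_colonies)
    stop("colony_stages length != n_colonies")
  if (nchar(sequence) != nchar(paste(ss, collapse = "")))
    stop("sequence and ss lengths differ")
  structure(list(mode = mode, sequence = sequence, ss = ss, libs = libs,
                 n_colonies = as.integer(n_colonies),
                 colony_stages = colony_stages,
                 n_decoys_colonies = as.integer(n_decoys_colonies),
                 n_decoys_mc = as.integer(n_decoys_mc),
                 seed = as.integer(seed), colony_opts = colony_opts,
                 increase_cycles = increase_cycles, lambda = lambda,
                 mc_sigma = mc_sigma, n_per_window = as.integer(n_per_window),
                 noise_deg = noise_deg),
            class = "run_config")
}

## build (or complete) the fragment libraries of a run
prepare_libraries <- function(config) {
  libs <- config$libs
  if (is.null(libs)) {
    L <- nchar(config$sequence)
    f3 <- generate_synthetic_library(config$sequence, config$ss, 3L,
                                     config$n_per_window, config$noise_deg,
                                     seed = config$seed)
    f9 <- if (L >= 9L)
      generate_synthetic_library(config$sequence, config$ss, 9L,
                                 config$n_per_window, config$noise_deg,
                                 seed = config$seed + 1L) else NULL
    libs <- list(f3 = f3, f9 = f9)
  }
  if (is.null(libs$f1)) libs$f1 <- merge_to_f1(libs$f3, libs$f9)
  libs
}

## ---- decoy sets ------------------------------------------------------------

#' Construct a decoy set
#'
#' @param label one of `"decoys0"`, `"decoys1"`, `"decoys2"`, `"decoys3"`,
#'   `"decoys12"`.
#' @param conformations list of decoy conformations.
#' @param score3 their final-ranking scores (computed when missing).
#' @param source character vector naming the emitting worker.
#' @return list of class `"decoy_set"` with an `entries` data frame
#'   (decoy_id, source, score3, ca_rmsd) and the conformations.
#' @export
decoy_set <- function(label, conformations, score3 = NULL, source = label) {
  n <- length(conformations)
  if (is.null(score3))
    score3 <- vapply(conformations, function(cf) score(ensure_coords(cf),
                                                       "score3"), numeric(1))
  entries <- data.frame(
    decoy_id = if (n) sprintf("%s_%04d", label, seq_len(n)) else character(0),
    source = rep_len(source, n),
    score3 = as.numeric(score3),
    ca_rmsd = rep(NA_real_, n),
    stringsAsFactors = FALSE)
  structure(list(label = label, entries = entries,
                 conformations = conformations),
            class = "decoy_set")
}

#' @export
print.decoy_set <- function(x, ...) {
  cat(sprintf("<decoy_set %s> %d decoys, score3 %s\n", x$label,
              nrow(x$entries),
              if (nrow(x$entries)) sprintf("[%.2f, %.2f]",
                                           min(x$entries$score3),
                                           max(x$entries$score3)) else "-"))
  invisible(x)
}

#' Attach native C-alpha RMSD values to a decoy set
#'
#' @param ds a decoy set.
#' @param native the native (or planted reference) conformation.
#' @return the decoy set with the `ca_rmsd` column filled.
#' @export
evaluate_decoys <- function(ds, native) {
  ds$entries$ca_rmsd <- vapply(ds$conformations,
                               function(cf) ca_rmsd(cf, native), numeric(1))
  ds
}

#' Write a decoy set as PDB files plus a score table
#'
#' @param ds a decoy set.
#' @param dir output directory (created if needed).
#' @return the score-table path, invisibly.
#' @export
write_decoys <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ds$conformations)) {
    write_pdb(ds$conformations[[i]],
              file.path(dir, paste0(ds$entries$decoy_id[i], ".pdb")))
  }
  tab <- file.path(dir, paste0(ds$label, "_scores.tsv"))
  utils::write.table(ds$entries, tab, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}

## ---- the driver ------------------------------------------------------------

#' Run the predictor in one of its three modes
#'
#' `sequential_mc` repeats the five-stage Monte-Carlo prediction with no
#' exchange and returns `decoys0`.  `shmo` runs the colonies against one
#' shared pheromone matrix with no MC worker and returns `decoys3`.
#' `mhmo` runs `n_colonies` colony workers plus one MC worker (9 workers at
#' the defaults) with bidirectional exchange and returns `decoys1`
#' (colonies), `decoys2` (MC) and `decoys12` (the `n_decoys_colonies`
#' lowest-score3 members of their union).  Workers advance round-robin;
#' a colony whose termination criterion fires emits its best-so-far as a
#' decoy and restarts with fresh ants (the shared matrix persists) until
#' the quota is met.  The whole run is reproducible bit-for-bit under
#' `config$seed`.
#'
#' @param config a [run_config()].
#' @return list with the mode's decoy sets plus `n_workers`, `libs` and
#'   `config`.
#' @export
run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  libs <- prepare_libraries(config)
  target <- list(sequence = config$sequence, ss = config$ss)
  schedule <- stage_schedule(config$increase_cycles)

  if (config$mode == "sequential_mc") {
    decoys <- vector("list", config$n_decoys_mc)
    for (k in seq_len(config$n_decoys_mc)) {
      decoys[[k]] <- run_stages(target, libs, schedule,
                                lambda = 0, sigma = config$mc_sigma)$decoy
    }
    return(list(decoys0 = decoy_set("decoys0", decoys, source = "mc"),
                n_workers = 1L, libs = libs, config = config))
  }

  pm <- new_pheromone_matrix(libs$f3, libs$f9)
  mk_params <- function(k) {
    do.call(colony_params,
            utils::modifyList(list(stage = config$colony_stages[k]),
                              config$colony_opts))
  }
  colonies <- lapply(seq_len(config$n_colonies), function(k)
    colony_new(target, libs, mk_params(k), pm))
  mc_enabled <- config$mode == "mhmo"
  n_workers <- config$n_colonies + as.integer(mc_enabled)

  frag_inbox <- new_channel()     # MC -> colonies (shared, drained once)
  perturb_inbox <- new_channel()  # colonies -> MC
  mc <- if (mc_enabled)
    mc_new(target, libs, schedule, config$lambda, sigma = config$mc_sigma)

  colony_decoys <- list(); colony_sources <- character(0)
  mc_decoys <- list()
  while (length(colony_decoys) < config$n_decoys_colonies ||
         (mc_enabled && length(mc_decoys) < config$n_decoys_mc)) {
    if (length(colony_decoys) < config$n_decoys_colonies) {
      for (k in seq_len(config$n_colonies)) {
        if (length(colony_decoys) >= config$n_decoys_colonies) break
        st <- colonies[[k]]
        ext <- channel_drain_flat(frag_inbox)
        ib <- colony_iterate(st, ext)
        if (mc_enabled)
          channel_push(perturb_inbox, list(conf = ib$conf, energy = ib$energy))
        if (check_termination(st, st$params)) {
          colony_decoys[[length(colony_decoys) + 1L]] <- st$best
          colony_sources <- c(colony_sources, sprintf("colony%02d", k))
          colonies[[k]] <- colony_new(target, libs, st$params, pm)
        }
      }
    }
    if (mc_enabled && length(mc_decoys) < config$n_decoys_mc) {
      mc_step(mc, perturb_inbox, frag_inbox)
      if (mc$done) {
        mc_decoys[[length(mc_decoys) + 1L]] <- ensure_coords(mc$conf)
        mc <- mc_new(target, libs, schedule, config$lambda,
                     sigma = config$mc_sigma)
      }
    }
  }

  if (config$mode == "shmo") {
    d3 <- decoy_set("decoys3", colony_decoys, source = colony_sources)
    return(list(decoys3 = d3, n_workers = n_workers, libs = libs,
                config = config))
  }
  d1 <- decoy_set("decoys1", colony_decoys, source = colony_sources)
  d2 <- decoy_set("decoys2", mc_decoys, source = "mc")
  d12 <- union_best(d1, d2,
                    min(config$n_decoys_colonies,
                        nrow(d1$entries) + nrow(d2$entries)))
  list(decoys1 = d1, decoys2 = d2, decoys12 = d12,
       n_workers = n_workers, libs = libs, config = config)
}
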
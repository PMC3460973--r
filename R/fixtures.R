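## Deterministic toy instances and benchmark-shaped synthetic targets.
## Toy instances are small enough that every conformation reachable by
## fragment insertion can be enumerated, giving an exact optimum to compare
## the stochastic search against.  Benchmark-like targets plant a
## near-native attraction basin (candidate 0 of every window is noise-free)
## so that search improvement is measurable without any deposited
## structure.

.TOY_AA <- c("A", "V", "L", "K", "E", "S", "G", "F")

#' Enumerate every conformation reachable by fragment insertion
#'
#' Breadth-first closure from the extended chain under the search's exact
#' move set: every (window, candidate) insertion from F3/F9 plus, where an
#' F1 library is supplied, every 1-mer insertion at loop-labelled residues
#' (the loop-refinement moves).  Because windows overlap, the reachable set
#' depends on insertion order and is NOT the product of per-window choices;
#' the closure is the exact search space of the assembly process.  The
#' pure-extended start is not an assembly and is excluded from the ranking
#' (no search move can return to it unless a fragment reproduces it).
#' Errors if the closure exceeds `max_states`.
#'
#' @param target list with `sequence` and `ss`.
#' @param libs fragment libraries (`f3`, optional `f9`, optional `f1`).
#' @param stage score name used to rank states.
#' @param max_states enumeration cap (default 1e4).
#' @return list with `n_states` (reachable assemblies), `best_energy`,
#'   `best_conf` and the full `energies` vector.
#' @export
enumerate_assemblies <- function(target, libs, stage = "score3",
                                 max_states = 1e4) {
  start <- extended_conformation(target$sequence, target$ss)
  moves <- list()
  for (lib in Filter(Negate(is.null), list(libs$f3, libs$f9))) {
    for (w in seq_len(n_windows(lib)) - 1L) {
      for (r in seq_len(n_candidates(lib, w)) - 1L) {
        moves[[length(moves) + 1L]] <- get_fragment(lib, w, r)
      }
    }
  }
  if (!is.null(libs$f1)) {
    loop_res <- which(start$ss == "L")
    for (i in loop_res) {
      for (r in seq_len(n_candidates(libs$f1, i - 1L)) - 1L) {
        moves[[length(moves) + 1L]] <- get_fragment(libs$f1, i - 1L, r)
      }
    }
  }
  key_of <- function(cf) paste(round(cf$phi, 4), round(cf$psi, 4),
                               round(cf$omega, 4), collapse = "|")
  seen <- new.env(parent = emptyenv())
  frontier <- list(start)
  assign(key_of(start), TRUE, envir = seen)
  states <- list()
  while (length(frontier) > 0) {
    nxt <- list()
    for (cf in frontier) {
      for (mv in moves) {
        cand <- insert_fragment(cf, mv)
        k <- key_of(cand)
        if (!exists(k, envir = seen, inherits = FALSE)) {
          assign(k, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- cand
          states[[length(states) + 1L]] <- cand
          if (length(states) > max_states)
            stop("assembly space exceeds ", max_states, " states")
        }
      }
    }
    frontier <- nxt
  }
  energies <- vapply(states, function(cf) score(ensure_coords(cf), stage),
                     numeric(1))
  best <- which.min(energies)
  list(n_states = length(states), best_energy = energies[best],
       best_conf = ensure_coords(states[[best]]), energies = energies)
}

#' Make a toy instance with an exhaustively enumerated optimum
#'
#' A 3-12 residue target with 1-3 fragment candidates per window, its tiny
#' F3 (and, for 9+ residues, F9) libraries, and the exact optimum of the
#' reachable assembly space under score3, computed on construction by
#' [enumerate_assemblies()].
#'
#' @param n_residues chain length in `[3, 12]`.
#' @param n_candidates candidates per window in `[1, 3]`.
#' @param seed RNG seed (the instance is bit-reproducible under it).
#' @param stage score used for the stored optimum.
#' @param ss optional secondary-structure string overriding the sampled
#'   labels (e.g. all-H toys have no loop-refinement moves).
#' @return list of class `"toy_instance"` with `target`, `libs`,
#'   `n_states`, `best_energy`, `best_conf`.
#' @export
make_toy <- function(n_residues, n_candidates, seed = 1L, stage = "score3",
                     ss = NULL) {
  if (n_residues < 3L || n_residues > 12L)
    stop("n_residues must be in [3, 12]")
  if (n_candidates < 1L || n_candidates > 3L)
    stop("n_candidates must be in [1, 3]")
  set.seed(seed)
  aa <- sample(.TOY_AA, n_residues, replace = TRUE)
  ss <- if (!is.null(ss)) strsplit(ss, "")[[1]] else
    sample(c("H", "E", "L"), n_residues, replace = TRUE,
           prob = c(0.5, 0.2, 0.3))
  if (length(ss) != n_residues) stop("ss length mismatch")
  sequence <- paste(aa, collapse = "")
  f3 <- generate_synthetic_library(sequence, ss, 3L,
                                   n_per_window = n_candidates,
                                   noise_deg = 25, seed = seed + 1L)
  f9 <- if (n_residues >= 9L)
    generate_synthetic_library(sequence, ss, 9L,
                               n_per_window = n_candidates,
                               noise_deg = 25, seed = seed + 2L) else NULL
  libs <- list(f3 = f3, f9 = f9, f1 = merge_to_f1(f3, f9))
  target <- list(sequence = sequence, ss = paste(ss, collapse = ""))
  enum <- enumerate_assemblies(target, libs, stage)
  structure(list(target = target, libs = libs, stage = stage,
                 n_states = enum$n_states, best_energy = enum$best_energy,
                 best_conf = enum$best_conf, energies = enum$energies),
            class = "toy_instance")
}

## optimise the torsions of the loop runs so that the reference fold is
## compact and clash-free: secondary-structure elements keep their ideal
## torsions and each maximal loop run's (phi, psi) are tuned by
## Nelder-Mead (three basin starts) to minimise score3 of a poly-alanine
## chain.  Without this the "native" would be a collection of straight
## elements with no tertiary packing, and no energy basin to find.
optimize_loop_torsions <- function(ss) {
  L <- length(ss)
  phi <- psi <- numeric(L)
  for (i in seq_len(L)) {
    tup <- .ideal_tuple(ss[i], 1L)
    phi[i] <- tup[1]; psi[i] <- tup[2]
  }
  runs <- rle(ss)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  loop_runs <- which(runs$values == "L" &
                     starts > 1L & ends < L)  # terminal loops stay ideal
  if (length(loop_runs) == 0L) return(list(phi = phi, psi = psi))
  aa0 <- paste(rep("A", L), collapse = "")
  ssv <- ss
  for (lr in loop_runs) {
    idx <- starts[lr]:ends[lr]
    k <- length(idx)
    objective <- function(p) {
      ph <- phi; ps <- psi
      ph[idx] <- wrap_angle(p[seq_len(k)])
      ps[idx] <- wrap_angle(p[k + seq_len(k)])
      cf <- build_backbone(new_conformation(aa0, ssv, ph, ps, rep(180, L)))
      score(cf, "score3")
    }
    basin_starts <- lapply(1:3, function(b)
      c(rep(.L_BASINS[b, 1], k), rep(.L_BASINS[b, 2], k)))
    best_val <- Inf; best_par <- basin_starts[[1]]
    for (s in basin_starts) {
      opt <- stats::optim(s, objective, method = "Nelder-Mead",
                          control = list(maxit = 250))
      if (opt$value < best_val) { best_val <- opt$value; best_par <- opt$par }
    }
    phi[idx] <- wrap_angle(best_par[seq_len(k)])
    psi[idx] <- wrap_angle(best_par[k + seq_len(k)])
  }
  list(phi = phi, psi = psi)
}

#' Make a benchmark-shaped synthetic target with a planted native
#'
#' Emulates the shape of a small-protein benchmark case (the real protocol
#' uses 49-88 residue targets).  The reference ("native") fold keeps ideal
#' torsions inside helices and strands while each interior loop's torsions
#' are optimised for a compact, clash-free arrangement, so that the native
#' sits in a genuine energy basin; the sequence places hydrophobic residues
#' at the fold's buried positions (which inside a helix reproduces the
#' ~3.6-residue amphipathic periodicity); and the synthetic F3/F9 libraries
#' are re-seeded so candidate 0 of every window carries the native torsion
#' window -- a known attraction basin that makes search improvement
#' measurable without any deposited structure.
#'
#' @param length chain length in `[20, 100]`.
#' @param ss_pattern secondary-structure string (H/E/L) of that length;
#'   strand blocks must be at least 3 residues (shorter is unbuildable).
#' @param seed RNG seed.
#' @param n_per_window candidates per window of the generated libraries.
#' @param noise_deg library torsion noise (degrees); the default is wide
#'   enough that random assemblies are clearly non-native.
#' @return list with `target`, `native` (conformation), `libs`.
#' @export
make_benchmark_like_target <- function(length, ss_pattern, seed = 1L,
                                       n_per_window = 200L, noise_deg = 25) {
  if (length < 20L || length > 100L) stop("length must be in [20, 100]")
  ss <- strsplit(ss_pattern, "")[[1]]
  if (base::length(ss) != length) stop("ss_pattern length mismatch")
  if (!all(ss %in% .SS_LABELS)) stop("bad ss labels")
  r <- rle(ss)
  if (any(r$values == "E" & r$lengths < 3L))
    stop("strand block shorter than 3 residues is unbuildable")
  set.seed(seed)
  tor <- optimize_loop_torsions(ss)
  ref <- build_backbone(new_conformation(paste(rep("A", length),
                                               collapse = ""),
                                         ss, tor$phi, tor$psi,
                                         rep(180, length)))
  # hydrophobic residues go to the buried positions of the reference fold
  ca <- ref$coords$CA
  D <- as.matrix(stats::dist(ca))
  nb <- rowSums(D < 10 & abs(outer(seq_len(length), seq_len(length), "-")) >= 2)
  buried <- nb >= stats::median(nb)
  hydro <- c("A", "V", "L", "I", "F", "M")
  polar <- c("S", "T", "N", "Q", "D", "E", "K", "R")
  aa <- character(length)
  for (i in seq_len(length)) {
    pool <- if (ss[i] != "L" && buried[i]) hydro else polar
    aa[i] <- sample(pool, 1L)
  }
  sequence <- paste(aa, collapse = "")
  # native = reference torsions + small noise; candidate 0 stays noise-free
  phi <- wrap_angle(tor$phi + stats::rnorm(length, 0, 2))
  psi <- wrap_angle(tor$psi + stats::rnorm(length, 0, 2))
  native <- build_backbone(new_conformation(sequence, ss, phi, psi,
                                            rep(180, length)))
  plant <- function(lib) {
    if (is.null(lib)) return(NULL)
    for (w in seq_len(n_windows(lib))) {
      idx <- (w - 1L) + seq_len(lib$frag_length)
      lib$windows[[w]]$phi[1, ] <- tor$phi[idx]
      lib$windows[[w]]$psi[1, ] <- tor$psi[idx]
      lib$windows[[w]]$omega[1, ] <- 180
    }
    lib
  }
  f3 <- plant(generate_synthetic_library(sequence, ss, 3L, n_per_window,
                                         noise_deg, seed = seed + 1L))
  f9 <- if (length >= 9L)
    plant(generate_synthetic_library(sequence, ss, 9L, n_per_window,
                                     noise_deg, seed = seed + 2L)) else NULL
  list(target = list(sequence = sequence, ss = ss_pattern),
       native = native,
       libs = list(f3 = f3, f9 = f9, f1 = merge_to_f1(f3, f9)))
}

#' Random fragment assembly baseline
#'
#' Builds decoys by inserting uniformly random fragments (same move set as
#' the ants, no pheromone, no heuristic, no energy): the null model against
#' which guided search is measured.
#'
#' @param target list with `sequence` and `ss`.
#' @param libs fragment libraries.
#' @param n number of decoys.
#' @param n_tries insertions per decoy (default `2 * L`, the ant default).
#' @param pf probability of drawing a 9-mer.
#' @return list of conformations.
#' @export
random_assembly <- function(target, libs, n, n_tries = NULL, pf = 0.5) {
  L <- nchar(target$sequence)
  if (is.null(n_tries)) n_tries <- 2L * L
  lapply(seq_len(n), function(k) {
    conf <- extended_conformation(target$sequence, target$ss)
    for (t in seq_len(n_tries)) {
      lb <- choose_library(libs, pf)
      lib <- if (lb == "F9") libs$f9 else libs$f3
      w <- sample.int(n_windows(lib), 1L) - 1L
      r <- sample.int(n_candidates(lib, w), 1L) - 1L
      conf <- insert_fragment(conf, get_fragment(lib, w, r))
    }
    ensure_coords(conf)
  })
}
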
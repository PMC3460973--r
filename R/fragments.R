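## Fragment libraries: the search space of the predictor.  F9 and F3 hold
## 200 rank-ordered 9-mer / 3-mer torsion runs per residue window (the shape
## of Robetta server output); F1, merged from both, holds the 1-mer torsion
## tuples used for loop refinement.  A fragment is identified everywhere by
## the triple (library, window_start, rank) -- the currency shared by the
## ant colonies, the Monte-Carlo predictor and the pheromone matrix.

## ideal torsion tuples per secondary-structure class; loop residues mix
## three allowed basins (poly-proline-like, alpha, left-handed)
.IDEAL_TORSIONS <- list(
  H = c(phi = -57, psi = -47),
  E = c(phi = -120, psi = 120)
)
.L_BASINS <- matrix(c(-75, 150,
                      -60, -30,
                       60,  30), nrow = 3, byrow = TRUE,
                    dimnames = list(NULL, c("phi", "psi")))

new_fragment_library <- function(kind, frag_length, target_length, windows) {
  structure(list(kind = kind, frag_length = frag_length,
                 target_length = target_length, windows = windows),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat(sprintf("<fragment_library %s> %d-mers, target %d aa, %d windows, %s candidates/window\n",
              x$kind, x$frag_length, x$target_length, length(x$windows),
              paste(range(vapply(x$windows, function(w) nrow(w$phi), 1L)),
                    collapse = "-")))
  invisible(x)
}

#' Number of windows of a fragment library
#' @param lib a fragment library.
#' @export
n_windows <- function(lib) length(lib$windows)

#' Number of candidate fragments at a window
#' @param lib a fragment library.
#' @param window 0-based window start.
#' @export
n_candidates <- function(lib, window) nrow(lib$windows[[window + 1L]]$phi)

#' Fetch one fragment from a library
#'
#' @param lib a fragment library.
#' @param window 0-based window start.
#' @param rank 0-based rank within the window's candidate set.
#' @return list with `window_start`, `length`, `rank`, `library` and torsion
#'   vectors `phi`, `psi`, `omega` plus `ss` labels.
#' @export
get_fragment <- function(lib, window, rank) {
  w <- lib$windows[[window + 1L]]
  if (is.null(w) || rank < 0L || rank >= nrow(w$phi))
    stop("no such fragment: window ", window, " rank ", rank)
  list(window_start = window, length = lib$frag_length, rank = rank,
       library = lib$kind,
       phi = w$phi[rank + 1L, ], psi = w$psi[rank + 1L, ],
       omega = w$omega[rank + 1L, ], ss = w$ss[rank + 1L, ])
}

#' Insert a fragment into a conformation
#'
#' Replaces the torsion tuples of the fragment's window; every other
#' residue's torsions are untouched.  Coordinate and score caches are
#' invalidated.
#'
#' @param conf a conformation.
#' @param fragment a fragment as returned by [get_fragment()].
#' @return the modified conformation.
#' @export
insert_fragment <- function(conf, fragment) {
  i0 <- fragment$window_start
  len <- fragment$length
  if (i0 < 0L || i0 + len > n_residues(conf))
    stop("fragment window [", i0, ", ", i0 + len - 1L, "] overflows the chain")
  idx <- seq.int(i0 + 1L, i0 + len)
  conf$phi[idx] <- wrap_angle(fragment$phi)
  conf$psi[idx] <- wrap_angle(fragment$psi)
  conf$omega[idx] <- wrap_angle(fragment$omega)
  invalidate_caches(conf)
}

#' Read a Rosetta-format fragment file
#'
#' Parses the Robetta/Rosetta fragment text format: blocks headed by
#' `position: <p> neighbors: <n>`, candidates separated by blank lines, one
#' line per fragment position carrying
#' `pdb-id chain resi aa ss phi psi omega ...`.  Ranks follow file order;
#' windows are re-indexed 0-based.
#'
#' @param path fragment file path.
#' @param frag_length declared fragment length (3 or 9); every candidate
#'   must have exactly this many lines.
#' @return a fragment library of kind `"F3"` or `"F9"`.
#' @export
read_rosetta_fragments <- function(path, frag_length) {
  lines <- readLines(path)
  hdr <- grep("^\\s*position:", lines)
  if (length(hdr) == 0L) stop("no 'position:' headers in ", path)
  windows <- list()
  for (h in seq_along(hdr)) {
    head_line <- lines[hdr[h]]
    m <- regmatches(head_line,
                    regexec("position:\\s*(\\d+)\\s+neighbors:\\s*(\\d+)", head_line))[[1]]
    if (length(m) != 3L) stop("malformed header: ", head_line)
    pos1 <- as.integer(m[2])          # 1-based in the file
    from <- hdr[h] + 1L
    to <- if (h < length(hdr)) hdr[h + 1L] - 1L else length(lines)
    body <- lines[from:to]
    # candidates are runs of non-blank lines
    blank <- grepl("^\\s*$", body)
    runs <- rle(blank)
    cand_lines <- split(body[!blank], cumsum(blank)[!blank])
    cands <- lapply(cand_lines, function(cl) {
      if (length(cl) != frag_length)
        stop("candidate with ", length(cl), " lines for a declared ",
             frag_length, "-mer at position ", pos1)
      fields <- strsplit(trimws(cl), "\\s+")
      t(vapply(fields, function(f) {
        if (length(f) < 8L) stop("short fragment line: ", paste(f, collapse = " "))
        tor <- suppressWarnings(as.numeric(f[6:8]))
        if (anyNA(tor)) stop("non-numeric torsion fields: ", paste(f, collapse = " "))
        c(tor, match(f[5], .SS_LABELS))
      }, numeric(4)))
    })
    nc <- length(cands)
    if (nc == 0L) stop("window at position ", pos1, " has no candidates")
    w <- list(
      phi = t(vapply(cands, function(m) m[, 1], numeric(frag_length))),
      psi = t(vapply(cands, function(m) m[, 2], numeric(frag_length))),
      omega = t(vapply(cands, function(m) m[, 3], numeric(frag_length))),
      ss = matrix(.SS_LABELS[t(vapply(cands, function(m) m[, 4],
                                      numeric(frag_length)))],
                  nrow = nc, byrow = FALSE)
    )
    if (frag_length == 1L) {
      w$phi <- matrix(w$phi, ncol = 1); w$psi <- matrix(w$psi, ncol = 1)
      w$omega <- matrix(w$omega, ncol = 1); w$ss <- matrix(w$ss, ncol = 1)
    }
    windows[[pos1]] <- w
  }
  if (any(vapply(windows, is.null, TRUE)))
    stop("missing windows in ", path)
  target_length <- length(windows) + frag_length - 1L
  new_fragment_library(if (frag_length == 9L) "F9" else "F3",
                       frag_length, target_length, windows)
}

## torsion tuple for one residue of a synthetic candidate; basin: index into
## .L_BASINS used for L residues (candidate 0 always uses basin 1)
.ideal_tuple <- function(ss, basin = 1L) {
  if (ss == "L") .L_BASINS[basin, ] else .IDEAL_TORSIONS[[ss]]
}

#' Generate a synthetic fragment library
#'
#' Emulates the shape of Robetta server output: for every residue window,
#' `n_per_window` rank-ordered candidates whose torsions are the ideal
#' values for the window's predicted secondary structure (helix -57/-47,
#' strand -120/120, loops a uniform mixture over three allowed basins) plus
#' wrapped Gaussian noise.  Candidate 0 is noise-free (loops use the first
#' basin), omega is trans (180) throughout, and SS labels are copied from
#' `ss`.  Bit-reproducible under `seed`.
#'
#' @param sequence target amino-acid string.
#' @param ss predicted secondary-structure string over H/E/L, same length.
#' @param frag_length 3 or 9 (or 1 for a direct 1-mer library).
#' @param n_per_window candidates per window (default 200, the Robetta
#'   count).
#' @param noise_deg standard deviation of the torsion noise in degrees.
#' @param seed RNG seed.
#' @return a fragment library.
#' @export
generate_synthetic_library <- function(sequence, ss, frag_length,
                                       n_per_window = 200L, noise_deg = 10,
                                       seed = 1L) {
  L <- nchar(sequence)
  if (length(ss) == 1L && nchar(ss[1]) > 1L) ss <- strsplit(ss, "")[[1]]
  if (length(ss) != L) stop("ss length != sequence length")
  if (!all(ss %in% .SS_LABELS)) stop("bad secondary-structure labels")
  if (frag_length > L) stop("fragment window longer than target")
  nw <- L - frag_length + 1L
  set.seed(seed)
  windows <- vector("list", nw)
  for (w in 1:nw) {
    res <- w:(w + frag_length - 1L)
    phi <- psi <- omega <- matrix(0, n_per_window, frag_length)
    for (k in seq_len(frag_length)) {
      lab <- ss[res[k]]
      basins <- if (lab == "L") {
        c(1L, sample.int(3L, n_per_window - 1L, replace = TRUE))
      } else rep(1L, n_per_window)
      base <- t(vapply(basins, function(b) .ideal_tuple(lab, b), numeric(2)))
      noise_phi <- c(0, stats::rnorm(n_per_window - 1L, 0, noise_deg))
      noise_psi <- c(0, stats::rnorm(n_per_window - 1L, 0, noise_deg))
      phi[, k] <- wrap_angle(base[, 1] + noise_phi)
      psi[, k] <- wrap_angle(base[, 2] + noise_psi)
      omega[, k] <- 180
    }
    windows[[w]] <- list(phi = phi, psi = psi, omega = omega,
                         ss = matrix(ss[res], n_per_window, frag_length,
                                     byrow = TRUE))
  }
  new_fragment_library(switch(as.character(frag_length),
                              "9" = "F9", "3" = "F3", "1" = "F1",
                              paste0("F", frag_length)),
                       frag_length, L, windows)
}

#' Merge 3-mer and 9-mer libraries into the 1-mer refinement library F1
#'
#' For every residue, collects the torsion tuple contributed at that residue
#' by every covering 3-mer and 9-mer candidate, deduplicated at 1e-6
#' degrees.  F1 drives loop refinement after the backbone has been roughly
#' assembled.
#'
#' @param f3,f9 fragment libraries over the same target (either may be
#'   `NULL`, but not both).
#' @return a fragment library of kind `"F1"` with window length 1.
#' @export
merge_to_f1 <- function(f3, f9 = NULL) {
  libs <- Filter(Negate(is.null), list(f3, f9))
  if (length(libs) == 0L || all(vapply(libs, n_windows, 1L) == 0L))
    stop("no fragment libraries to merge")
  tl <- unique(vapply(libs, function(l) l$target_length, 1L))
  if (length(tl) != 1L) stop("libraries have different target lengths")
  L <- tl
  windows <- vector("list", L)
  for (i in 1:L) {
    tup <- list()
    for (lib in libs) {
      fl <- lib$frag_length
      w_lo <- max(0L, i - fl); w_hi <- min(i - 1L, L - fl)
      if (w_lo > w_hi) next
      for (w0 in w_lo:w_hi) {          # 0-based windows covering residue i-1
        wd <- lib$windows[[w0 + 1L]]
        k <- i - w0                     # position within the fragment
        tup[[length(tup) + 1L]] <- cbind(wd$phi[, k], wd$psi[, k],
                                         wd$omega[, k],
                                         match(wd$ss[, k], .SS_LABELS))
      }
    }
    all_t <- do.call(rbind, tup)
    key <- paste(round(all_t[, 1] * 1e6), round(all_t[, 2] * 1e6),
                 round(all_t[, 3] * 1e6))
    keep <- !duplicated(key)
    all_t <- all_t[keep, , drop = FALSE]
    windows[[i]] <- list(phi = all_t[, 1, drop = FALSE],
                         psi = all_t[, 2, drop = FALSE],
                         omega = all_t[, 3, drop = FALSE],
                         ss = matrix(.SS_LABELS[all_t[, 4]], ncol = 1))
  }
  new_fragment_library("F1", 1L, L, windows)
}

#' Write a fragment library in the package's tab-separated format
#'
#' One row per fragment position: window (0-based), rank (0-based), pos,
#' aa, ss, phi, psi, omega.
#'
#' @param lib a fragment library.
#' @param path output path.
#' @param sequence optional target sequence used to fill the `aa` column
#'   (defaults to `"X"`).
#' @export
write_fragment_library <- function(lib, path, sequence = NULL) {
  aa <- if (is.null(sequence)) rep("X", lib$target_length)
        else strsplit(sequence, "")[[1]]
  rows <- list()
  for (w in seq_len(n_windows(lib))) {
    wd <- lib$windows[[w]]
    for (r in seq_len(nrow(wd$phi))) {
      for (k in seq_len(lib$frag_length)) {
        res <- w - 1L + k
        rows[[length(rows) + 1L]] <- data.frame(
          window = w - 1L, rank = r - 1L, pos = k - 1L,
          aa = aa[res], ss = wd$ss[r, k],
          phi = wd$phi[r, k], psi = wd$psi[r, k], omega = wd$omega[r, k])
      }
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a fragment library in the Rosetta fragment text format
#'
#' @param lib a fragment library.
#' @param path output path.
#' @export
write_rosetta_fragments <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (w in seq_len(n_windows(lib))) {
    wd <- lib$windows[[w]]
    writeLines(sprintf(" position: %12d neighbors: %12d", w, nrow(wd$phi)), con)
    writeLines("", con)
    for (r in seq_len(nrow(wd$phi))) {
      for (k in seq_len(lib$frag_length)) {
        writeLines(sprintf(" xxxx A %5d %s %s %9.3f %9.3f %9.3f",
                           w + k - 1L, "V", wd$ss[r, k],
                           wd$phi[r, k], wd$psi[r, k], wd$omega[r, k]), con)
      }
      writeLines("", con)
    }
  }
  invisible(path)
}
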
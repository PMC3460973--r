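## Centroid-level backbone model: one (phi, psi, omega) torsion tuple and one
## secondary-structure label (H, E or L) per residue; side chains are a single
## pseudo-atom (CEN).  Coordinates are a lazily built cache regenerated from
## the torsions.

.SS_LABELS <- c("H", "E", "L")

#' Construct a conformation from torsion tuples
#'
#' A conformation is the package's central container: an amino-acid sequence,
#' one secondary-structure label per residue, and per-residue backbone torsion
#' angles (phi, psi, omega) in degrees.  Cartesian coordinates of the four
#' centroid-model atoms (N, CA, C and the side-chain pseudo-atom CEN) are a
#' cache attached by [build_backbone()].
#'
#' @param sequence single string of 1-letter amino-acid codes.
#' @param ss secondary-structure labels, one of `"H"`, `"E"`, `"L"` per
#'   residue; either a single string or a character vector.
#' @param phi,psi,omega numeric vectors of torsion angles in degrees, one per
#'   residue.  Angles are wrapped to `[-180, 180)`.
#' @return an object of class `"conformation"`.
#' @export
new_conformation <- function(sequence, ss, phi, psi, omega) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  aa <- strsplit(sequence, "")[[1]]
  L <- length(aa)
  if (L < 1L) stop("empty sequence")
  if (length(ss) == 1L && nchar(ss[1]) > 1L) ss <- strsplit(ss, "")[[1]]
  if (length(ss) != L) stop("secondary-structure string length != sequence length")
  if (!all(ss %in% .SS_LABELS))
    stop("secondary-structure labels must be H, E or L")
  if (length(phi) != L || length(psi) != L || length(omega) != L)
    stop("torsion vectors must have one entry per residue")
  if (!all(is.finite(phi)) || !all(is.finite(psi)) || !all(is.finite(omega)))
    stop("non-finite torsion angle")
  structure(list(
    sequence = sequence,
    aa = aa,
    ss = ss,
    phi = wrap_angle(as.numeric(phi)),
    psi = wrap_angle(as.numeric(psi)),
    omega = wrap_angle(as.numeric(omega)),
    coords = NULL,
    score_cache = list()
  ), class = "conformation")
}

#' Number of residues in a conformation
#' @param conf a conformation.
#' @export
n_residues <- function(conf) length(conf$aa)

#' Torsion tuples of a conformation as a data frame
#'
#' @param conf a conformation.
#' @return data frame with columns `phi`, `psi`, `omega`, `ss`.
#' @export
torsions <- function(conf) {
  data.frame(phi = conf$phi, psi = conf$psi, omega = conf$omega,
             ss = conf$ss, stringsAsFactors = FALSE)
}

#' Fully extended starting conformation
#'
#' The search always starts from the extended chain
#' (phi = -120, psi = 120, omega = 180).
#'
#' @inheritParams new_conformation
#' @export
extended_conformation <- function(sequence, ss) {
  L <- nchar(sequence)
  new_conformation(sequence, ss,
                   phi = rep(-120, L), psi = rep(120, L), omega = rep(180, L))
}

## drop stale caches after any torsion edit
invalidate_caches <- function(conf) {
  conf$coords <- NULL
  conf$score_cache <- list()
  conf
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("<conformation> %d residues, ss: %s, coords: %s\n",
              n_residues(x), paste(rle(x$ss)$values, collapse = ""),
              if (is.null(x$coords)) "absent" else "cached"))
  invisible(x)
}
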
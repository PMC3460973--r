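## Torsion-space <-> Cartesian interconversion for the centroid backbone
## model, plus rigid superposition.  Bond lengths and angles are fixed at
## ideal values (Engh-Huber-like); only the torsions vary.

.GEOM <- list(
  b_n_ca    = 1.458,  # N-CA bond, Angstrom
  b_ca_c    = 1.525,  # CA-C
  b_c_n     = 1.329,  # C-N (peptide bond)
  b_ca_cen  = 1.53,   # CA-CEN pseudo-atom
  a_n_ca_c  = 111.2,  # backbone angles, degrees
  a_ca_c_n  = 116.2,
  a_c_n_ca  = 121.7,
  a_c_ca_cen = 110.1, # C-CA-CEN
  d_n_c_ca_cen = 122.6 # improper N-C-CA-CEN fixing the CEN direction
)

## sentinel for the dihedrals undefined at the chain termini
.SENTINEL_TORSION <- 180.0

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-10) stop("degenerate geometry: zero-length vector")
  a / n
}

## NeRF placement: position atom d bonded to c, with bond angle b-c-d and
## dihedral a-b-c-d (degrees).
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  ch <- torsion_deg * pi / 180
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ch), bond * sin(th) * sin(ch))
  bc <- vunit(c - b)
  n  <- vunit(vcross(b - a, bc))
  m  <- vcross(n, bc)
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

## dihedral angle p1-p2-p3-p4 in degrees in [-180, 180); errors on collinear
## input where the plane normals vanish
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-8 || vnorm(n2) < 1e-8)
    stop("dihedral undefined: collinear atoms")
  m1 <- vcross(n1, vunit(b2))
  # IUPAC sign convention (clockwise positive looking from p2 to p3)
  wrap_angle(-atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi)
}

#' Build Cartesian backbone coordinates from torsion angles
#'
#' Sequential chain extension (NeRF): residue 1 is placed in a canonical
#' frame (N at the origin, CA on +x, C in the xy-plane) and each further atom
#' is positioned from the previous three using ideal bond lengths and angles,
#' so the coordinates are a deterministic pure function of the torsions.
#' The side-chain pseudo-atom CEN is placed 1.53 A along the ideal C-beta
#' direction of every residue.
#'
#' @param torsions either a conformation or a data frame with columns
#'   `phi`, `psi`, `omega` (degrees) and `ss`.
#' @param sequence 1-letter amino-acid string; required when `torsions` is a
#'   data frame.
#' @return a conformation with the `coords` cache filled: a list of four
#'   `L x 3` matrices `N`, `CA`, `C`, `CEN` (Angstrom).
#' @export
build_backbone <- function(torsions, sequence = NULL) {
  if (inherits(torsions, "conformation")) {
    conf <- torsions
  } else {
    if (is.null(sequence)) stop("sequence required")
    if (nrow(torsions) < 1L) stop("empty torsion list")
    if (nrow(torsions) != nchar(sequence))
      stop("torsion list and sequence lengths differ")
    conf <- new_conformation(sequence, torsions$ss,
                             torsions$phi, torsions$psi, torsions$omega)
  }
  L <- n_residues(conf)
  N  <- matrix(0, L, 3); CA <- matrix(0, L, 3)
  Cc <- matrix(0, L, 3); CEN <- matrix(0, L, 3)
  g <- .GEOM
  N[1, ]  <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  a <- g$a_n_ca_c * pi / 180
  Cc[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(a), sin(a), 0)
  if (L > 1) {
    for (i in 2:L) {
      N[i, ]  <- place_atom(N[i - 1, ], CA[i - 1, ], Cc[i - 1, ],
                            g$b_c_n, g$a_ca_c_n, conf$psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], Cc[i - 1, ], N[i, ],
                            g$b_n_ca, g$a_c_n_ca, conf$omega[i - 1])
      Cc[i, ] <- place_atom(Cc[i - 1, ], N[i, ], CA[i, ],
                            g$b_ca_c, g$a_n_ca_c, conf$phi[i])
    }
  }
  for (i in 1:L) {
    CEN[i, ] <- place_atom(N[i, ], Cc[i, ], CA[i, ],
                           g$b_ca_cen, g$a_c_ca_cen, g$d_n_c_ca_cen)
  }
  conf$coords <- list(N = N, CA = CA, C = Cc, CEN = CEN)
  conf
}

## coordinates on demand; torsions are authoritative
ensure_coords <- function(conf) {
  if (is.null(conf$coords)) build_backbone(conf) else conf
}

#' Recover torsion angles from backbone coordinates
#'
#' Standard dihedral computation over the N, CA, C trace.  phi of the first
#' residue and psi/omega of the last are undefined and set to the sentinel
#' value 180.
#'
#' @param conf a conformation whose `coords` cache is present, or any list
#'   with `L x 3` matrices `N`, `CA`, `C` under `$coords`.
#' @return data frame of torsions as in [torsions()].
#' @export
extract_torsions <- function(conf) {
  if (is.null(conf$coords)) stop("coordinates absent")
  cs <- conf$coords
  L <- nrow(cs$CA)
  if (L < 2L) stop("need at least 2 residues to compute dihedrals")
  if (is.null(cs$N) || is.null(cs$C)) stop("missing backbone atoms")
  phi <- psi <- omega <- rep(.SENTINEL_TORSION, L)
  for (i in 1:L) {
    if (i > 1)
      phi[i] <- dihedral_deg(cs$C[i - 1, ], cs$N[i, ], cs$CA[i, ], cs$C[i, ])
    if (i < L) {
      psi[i]   <- dihedral_deg(cs$N[i, ], cs$CA[i, ], cs$C[i, ], cs$N[i + 1, ])
      omega[i] <- dihedral_deg(cs$CA[i, ], cs$C[i, ], cs$N[i + 1, ], cs$CA[i + 1, ])
    }
  }
  ss <- if (!is.null(conf$ss)) conf$ss else rep("L", L)
  phi <- wrap_angle(phi); psi <- wrap_angle(psi); omega <- wrap_angle(omega)
  # the sentinel is reported as +180 exactly, outside the wrap interval
  phi[1] <- .SENTINEL_TORSION
  psi[L] <- .SENTINEL_TORSION
  omega[L] <- .SENTINEL_TORSION
  data.frame(phi = phi, psi = psi, omega = omega, ss = ss,
             stringsAsFactors = FALSE)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of point set `A` onto `B` via SVD of the
#' covariance matrix, restricted to proper rotations (no reflection).
#'
#' @param A,B `n x 3` coordinate matrices, `n >= 3`, matched row-by-row.
#' @return list of class `"superposition"` with elements `rotation`
#'   (3x3, det +1), `translation` (length-3) such that
#'   `A %*% t(rotation) + translation` best fits `B`, and `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("point sets differ in size")
  if (nrow(A) < 3L) stop("need at least 3 points")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  H <- t(Ac) %*% Bc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- Ac %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Bc)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cb - R %*% ca),
                 rmsd = rmsd),
            class = "superposition")
}

#' C-alpha RMSD between two conformations
#'
#' Root-mean-square deviation of the alpha-carbon traces after optimal rigid
#' superposition, in Angstrom.
#'
#' @param pred,native conformations of equal length (coordinates are built
#'   from torsions if absent).
#' @return RMSD in Angstrom.
#' @export
ca_rmsd <- function(pred, native) {
  pred <- ensure_coords(pred); native <- ensure_coords(native)
  if (nrow(pred$coords$CA) != nrow(native$coords$CA))
    stop("conformations differ in length")
  kabsch_superpose(pred$coords$CA, native$coords$CA)$rmsd
}

#' Radius of gyration of the C-alpha trace
#'
#' Root-mean-square distance of the CA atoms from their centroid (Angstrom);
#' this is also the `rg` energy term.
#'
#' @param conf a conformation.
#' @export
radius_of_gyration <- function(conf) {
  conf <- ensure_coords(conf)
  ca <- conf$coords$CA
  sqrt(mean(rowSums(sweep(ca, 2, colMeans(ca))^2)))
}
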
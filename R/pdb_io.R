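## Minimal PDB dialect: ATOM records for N, CA, C and the CEN pseudo-atom,
## chain A, 1-based residue numbering.  Reading goes through bio3d so that
## standard all-atom files (e.g. deposited natives) parse too; atoms other
## than the four the model knows are ignored.

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")
.AA1 <- stats::setNames(names(.AA3), .AA3)

#' Write a conformation as a minimal PDB file
#'
#' Emits ATOM records for N, CA, C and CEN of every residue, chain A,
#' residues numbered from 1.  Coordinates are built from the torsions if the
#' cache is absent.
#'
#' @param conf a conformation.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(conf, path) {
  conf <- ensure_coords(conf)
  cs <- conf$coords
  L <- n_residues(conf)
  lines <- character(0)
  serial <- 0L
  for (i in 1:L) {
    res3 <- .AA3[conf$aa[i]]
    if (is.na(res3)) res3 <- "UNK"
    for (at in c("N", "CA", "C", "CEN")) {
      serial <- serial + 1L
      xyz <- cs[[at]][i, ]
      name <- if (at == "CEN") "CEN " else sprintf("%-3s", at)
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-4s%3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        serial, name, res3, i, xyz[1], xyz[2], xyz[3]))
    }
  }
  lines <- c(lines, "TER", "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a PDB file into a conformation
#'
#' Parses ATOM records (via \pkg{bio3d}) and keeps the N, CA, C and CEN/CB
#' coordinates of each residue; all other atoms are ignored, so standard
#' all-atom files work.  A residue without a CA is an error.  When the full
#' N/CA/C trace is present the torsions are recovered from the coordinates;
#' a missing CEN (or CB) is rebuilt at the ideal C-beta direction.
#' Secondary-structure labels are not stored in ATOM records and default to
#' `"L"` everywhere.
#'
#' @param path PDB file path.
#' @return a conformation with the `coords` cache filled.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  # first chain only
  at <- at[at$chain == at$chain[1] | is.na(at$chain), , drop = FALSE]
  resids <- unique(at$resno)
  L <- length(resids)
  if (L < 1L) stop("no residues parsed")
  pick <- function(rows, name) {
    hit <- rows[rows$elety == name, , drop = FALSE]
    if (nrow(hit) == 0L) return(NULL)
    as.numeric(hit[1, c("x", "y", "z")])
  }
  N <- CA <- Cc <- CEN <- matrix(NA_real_, L, 3)
  aa <- character(L)
  for (k in seq_along(resids)) {
    rows <- at[at$resno == resids[k], , drop = FALSE]
    ca <- pick(rows, "CA")
    if (is.null(ca))
      stop(sprintf("residue %d (%s) has no CA atom", resids[k], rows$resid[1]))
    CA[k, ] <- ca
    n <- pick(rows, "N");  if (!is.null(n))  N[k, ] <- n
    cc <- pick(rows, "C"); if (!is.null(cc)) Cc[k, ] <- cc
    cen <- pick(rows, "CEN"); if (is.null(cen)) cen <- pick(rows, "CB")
    if (!is.null(cen)) CEN[k, ] <- cen
    a1 <- .AA1[rows$resid[1]]
    aa[k] <- if (is.na(a1)) "X" else a1
  }
  full_trace <- !anyNA(N) && !anyNA(Cc)
  g <- .GEOM
  if (full_trace && anyNA(CEN)) {
    for (k in which(is.na(CEN[, 1])))
      CEN[k, ] <- place_atom(N[k, ], Cc[k, ], CA[k, ],
                             g$b_ca_cen, g$a_c_ca_cen, g$d_n_c_ca_cen)
  }
  ss <- rep("L", L)
  if (full_trace && L >= 2) {
    tt <- extract_torsions(list(coords = list(N = N, CA = CA, C = Cc), ss = ss))
    conf <- new_conformation(paste(aa, collapse = ""), ss,
                             tt$phi, tt$psi, tt$omega)
  } else {
    conf <- new_conformation(paste(aa, collapse = ""), ss,
                             rep(.SENTINEL_TORSION, L),
                             rep(.SENTINEL_TORSION, L),
                             rep(.SENTINEL_TORSION, L))
  }
  conf$coords <- list(N = N, CA = CA, C = Cc, CEN = CEN)
  conf
}

#' Read the first sequence from a FASTA file
#'
#' @param path FASTA file path.
#' @return single upper-case amino-acid string.
#' @export
read_fasta_sequence <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  if (length(seqs) < 1L) stop("no sequences in ", path)
  toupper(as.character(seqs[[1]]))
}
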
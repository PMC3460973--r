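# Shared builders for the test suite.  Everything is generated in code;
# no stored binary fixtures.

# ideal-geometry chain of one repeated torsion tuple
uniform_chain <- function(L, phi, psi, ss = "H", omega = 180, aa = "A") {
  build_backbone(new_conformation(
    paste(rep(aa, L), collapse = ""), paste(rep(ss, L), collapse = ""),
    rep(phi, L), rep(psi, L), rep(omega, L)))
}

ideal_helix <- function(L) uniform_chain(L, -57, -47, "H")
ideal_strand <- function(L) uniform_chain(L, -120, 120, "E")

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_res <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_res)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# a small target plus synthetic libraries, for colony/MC plumbing tests
small_instance <- function(L = 10, n_cand = 4, seed = 42, noise = 20) {
  ss <- paste(rep("H", L), collapse = "")
  sequence <- paste(rep(c("A", "L", "S", "K"), length.out = L), collapse = "")
  f3 <- generate_synthetic_library(sequence, ss, 3L, n_cand, noise, seed)
  f9 <- if (L >= 9) generate_synthetic_library(sequence, ss, 9L, n_cand,
                                               noise, seed + 1L) else NULL
  list(target = list(sequence = sequence, ss = ss),
       libs = list(f3 = f3, f9 = f9, f1 = merge_to_f1(f3, f9)))
}

# hand-written Rosetta-format 3-mer fragment file: 2 windows x 2 candidates
write_toy_rosetta_file <- function(path) {
  lines <- c(
    " position:            1 neighbors:            2",
    "",
    " 1ab1 A     7 A H   -57.000   -47.000   180.000",
    " 1ab1 A     8 L H   -58.000   -46.000   180.000",
    " 1ab1 A     9 K H   -59.000   -45.000   180.000",
    "",
    " 2cd2 B    11 V E  -120.000   120.000   180.000",
    " 2cd2 B    12 I E  -121.000   121.000   180.000",
    " 2cd2 B    13 T E  -122.000   122.000   180.000",
    "",
    " position:            2 neighbors:            2",
    "",
    " 3ef3 C    20 G L   -75.000   150.000   180.000",
    " 3ef3 C    21 S L   -60.000   -30.000   180.000",
    " 3ef3 C    22 N L    60.000    30.000   180.000",
    "",
    " 4gh4 D     2 A H   -57.000   -47.000   180.000",
    " 4gh4 D     3 A H   -57.000   -47.000   180.000",
    " 4gh4 D     4 A H   -57.000   -47.000   180.000",
    "")
  writeLines(lines, path)
  path
}
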
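test_that("the Rosetta fragment format parses into an indexed library", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_toy_rosetta_file(path)
  lib <- read_rosetta_fragments(path, 3L)
  expect_s3_class(lib, "fragment_library")
  expect_equal(lib$kind, "F3")
  expect_equal(n_windows(lib), 2L)
  expect_equal(n_candidates(lib, 0L), 2L)
  expect_equal(n_candidates(lib, 1L), 2L)
  expect_equal(lib$target_length, 4L)
  f <- get_fragment(lib, 0L, 0L)
  expect_equal(f$phi, c(-57, -58, -59))
  expect_equal(f$ss, c("H", "H", "H"))
  f2 <- get_fragment(lib, 1L, 0L)
  expect_equal(f2$psi, c(150, -30, 30))
  expect_equal(f2$ss, c("L", "L", "L"))
})

test_that("malformed fragment files are rejected", {
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_error(read_rosetta_fragments(empty, 3L), "position")

  wrong_len <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    " position:            1 neighbors:            1",
    "",
    " 1ab1 A     7 A H   -57.000   -47.000   180.000",
    " 1ab1 A     8 L H   -58.000   -46.000   180.000",
    " 1ab1 A     9 K H   -59.000   -45.000   180.000",
    " 1ab1 A    10 V H   -60.000   -44.000   180.000",
    ""), wrong_len)
  expect_error(read_rosetta_fragments(wrong_len, 3L), "4 lines")

  bad_num <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    " position:            1 neighbors:            1",
    "",
    " 1ab1 A     7 A H   -57.000       xxx   180.000",
    " 1ab1 A     8 L H   -58.000   -46.000   180.000",
    " 1ab1 A     9 K H   -59.000   -45.000   180.000",
    ""), bad_num)
  expect_error(read_rosetta_fragments(bad_num, 3L), "non-numeric")
})

test_that("synthetic libraries have the Robetta candidate count per window", {
  seq30 <- paste(rep(c("A", "L", "S"), 10), collapse = "")
  ss30 <- paste(rep("H", 30), collapse = "")
  lib <- generate_synthetic_library(seq30, ss30, 3L)
  expect_equal(n_windows(lib), 28L)
  for (w in seq_len(n_windows(lib)) - 1L)
    expect_equal(n_candidates(lib, w), 200L)
})

test_that("zero noise collapses every candidate onto the ideal tuple", {
  lib <- generate_synthetic_library("AAAAA", "HHHHH", 3L,
                                    n_per_window = 10L, noise_deg = 0)
  for (w in 0:2) {
    for (r in 0:9) {
      f <- get_fragment(lib, w, r)
      expect_equal(f$phi, rep(-57, 3))
      expect_equal(f$psi, rep(-47, 3))
      expect_equal(wrap_angle(f$omega), rep(wrap_angle(180), 3))
    }
  }
})

test_that("noisy candidates centre on the ideal torsions", {
  lib <- generate_synthetic_library(paste(rep("A", 10), collapse = ""),
                                    paste(rep("H", 10), collapse = ""),
                                    3L, n_per_window = 200L, noise_deg = 10,
                                    seed = 7L)
  se3 <- 3 * 10 / sqrt(200)
  for (w in c(0L, 4L, 7L)) {
    phis <- lib$windows[[w + 1L]]$phi[, 2]
    expect_lt(abs(circular_mean(phis) - (-57)), se3)
  }
})

test_that("library generation is bit-reproducible under a fixed seed", {
  a <- generate_synthetic_library("ALSKEF", "HHHLLL", 3L, 20L, 15, seed = 9L)
  b <- generate_synthetic_library("ALSKEF", "HHHLLL", 3L, 20L, 15, seed = 9L)
  expect_identical(a, b)
  c2 <- generate_synthetic_library("ALSKEF", "HHHLLL", 3L, 20L, 15, seed = 10L)
  expect_false(identical(a, c2))
})

test_that("F1 merge covers every residue and matches an enumeration oracle", {
  inst <- small_instance(L = 12, n_cand = 20, seed = 5)
  f1 <- inst$libs$f1
  expect_equal(f1$kind, "F1")
  expect_equal(n_windows(f1), 12L)
  for (i in seq_len(12) - 1L) expect_gte(n_candidates(f1, i), 1L)

  # independent enumeration at one interior residue: gather (phi, psi,
  # omega) from every covering 3-mer/9-mer candidate, dedup exactly
  res <- 6L  # 1-based
  gather <- function(lib) {
    out <- NULL
    for (w0 in 0:(n_windows(lib) - 1L)) {
      k <- res - w0
      if (k >= 1 && k <= lib$frag_length) {
        wd <- lib$windows[[w0 + 1L]]
        out <- rbind(out, cbind(wd$phi[, k], wd$psi[, k], wd$omega[, k]))
      }
    }
    out
  }
  all_t <- rbind(gather(inst$libs$f3), gather(inst$libs$f9))
  n_distinct <- nrow(unique(round(all_t, 6)))
  expect_equal(n_candidates(f1, res - 1L), n_distinct)
  expect_lte(n_candidates(f1, res - 1L), 3 * 20 + 9 * 20)
})

test_that("F1 merge is independent of input order", {
  inst <- small_instance(L = 10, n_cand = 5, seed = 2)
  a <- merge_to_f1(inst$libs$f3, inst$libs$f9)
  b <- merge_to_f1(inst$libs$f9, inst$libs$f3)
  for (i in 0:9) {
    ta <- cbind(a$windows[[i + 1]]$phi, a$windows[[i + 1]]$psi)
    tb <- cbind(b$windows[[i + 1]]$phi, b$windows[[i + 1]]$psi)
    expect_equal(ta[order(ta[, 1], ta[, 2]), ], tb[order(tb[, 1], tb[, 2]), ],
                 ignore_attr = TRUE)
  }
  expect_error(merge_to_f1(NULL, NULL), "no fragment")
})

test_that("fragment insertion is local, idempotent and last-writer-wins", {
  inst <- small_instance(L = 10, n_cand = 4, seed = 8)
  conf <- extended_conformation(inst$target$sequence, inst$target$ss)

  # idempotence: inserting the current torsions changes nothing
  same <- list(window_start = 0L, length = 3L, rank = 0L, library = "F3",
               phi = conf$phi[1:3], psi = conf$psi[1:3],
               omega = conf$omega[1:3], ss = conf$ss[1:3])
  expect_equal(insert_fragment(conf, same)$phi, conf$phi)

  # locality: a 3-mer at window 2 changes exactly residues 3..5
  f <- get_fragment(inst$libs$f3, 2L, 1L)
  out <- insert_fragment(conf, f)
  expect_equal(out$phi[-(3:5)], conf$phi[-(3:5)])
  expect_false(all(out$phi[3:5] == conf$phi[3:5]))
  expect_null(out$coords)

  # replay oracle: arbitrary insertion sequences resolve to the last writer
  set.seed(31)
  cur <- conf
  expected_phi <- conf$phi
  for (k in 1:25) {
    w <- sample(0:7, 1); r <- sample(0:3, 1)
    fr <- get_fragment(inst$libs$f3, w, r)
    cur <- insert_fragment(cur, fr)
    expected_phi[(w + 1):(w + 3)] <- wrap_angle(fr$phi)
  }
  expect_equal(cur$phi, expected_phi)

  # overflow
  bad <- get_fragment(inst$libs$f3, 0L, 0L); bad$window_start <- 8L
  expect_error(insert_fragment(conf, bad), "overflow")
})

test_that("library writers round-trip through the Rosetta reader", {
  lib <- generate_synthetic_library("ALSKEFG", "HHHLLHH", 3L, 3L, 12,
                                    seed = 4L)
  path <- withr::local_tempfile(fileext = ".txt")
  write_rosetta_fragments(lib, path)
  back <- read_rosetta_fragments(path, 3L)
  expect_equal(n_windows(back), n_windows(lib))
  for (w in 0:(n_windows(lib) - 1L)) {
    expect_equal(back$windows[[w + 1]]$phi, lib$windows[[w + 1]]$phi,
                 tolerance = 1e-3, ignore_attr = TRUE)
    expect_equal(back$windows[[w + 1]]$ss, lib$windows[[w + 1]]$ss,
                 ignore_attr = TRUE)
  }
})
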
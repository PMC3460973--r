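## Centroid-level energy terms and the staged composite scores.
##
## The five composite scores (score0, score1, score2, score5, score3) are
## fixed weighted sums of ten centroid energy terms; the weight table is
## reproduced exactly.  The individual terms are deliberately simple
## geometric surrogates that preserve each term's qualitative role
## (excluded volume, hydrophobic burial, chain compactness, strand pairing,
## ...) while staying cheap and fully testable; they are not Rosetta's
## statistical potentials.

.ENERGY_TERMS <- c("env", "pair", "cbeta", "vdw", "rg",
                   "cenpack", "hs_pair", "ss_pair", "rsigma", "sheet")

.STAGE_WEIGHTS <- local({
  w <- rbind(
    #        env pair cbeta  vdw rg cenpack hs_pair ss_pair rsigma sheet
    score0 = c(0,   0, 0,    0.10, 0, 0,    0,      0,      0,     0),
    score1 = c(1,   1, 0,    1,    0, 0,    1,      0.30,   0,     1),
    score2 = c(1,   1, 0.25, 1,    0, 0.50, 1,      1,      0,     1),
    score5 = c(1,   1, 0.25, 1,    0, 0.50, 1,      1,      0,     1),
    score3 = c(1,   1, 1,    1,    3, 1,    1,      1,      1,     1)
  )
  colnames(w) <- .ENERGY_TERMS
  w
})

## Kyte-Doolittle hydropathy, scaled to [-1, 1]
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
         G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
         P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2) / 4.5
.HYDROPHOBIC <- names(.KD)[.KD > 0]
.POS_CHARGED <- c("K", "R")
.NEG_CHARGED <- c("D", "E")

#' Stage weight presets
#'
#' Returns the weight vector combining the ten centroid energy terms into
#' one of the five composite scores used at the successive prediction
#' stages.  score0 is excluded volume only (weight 0.10), score3 -- the
#' final ranking score -- weights every term at 1 except the radius of
#' gyration at 3.
#'
#' @param name one of `"score0"`, `"score1"`, `"score2"`, `"score5"`,
#'   `"score3"`.
#' @param overrides optional named numeric vector of term -> coefficient
#'   replacements, enabling user-defined score variants.
#' @return list of class `"stage_weights"` with elements `name` and
#'   `weights` (named numeric over the ten terms).
#' @export
stage_weights <- function(name, overrides = NULL) {
  if (!name %in% rownames(.STAGE_WEIGHTS))
    stop("unknown stage: ", name)
  w <- .STAGE_WEIGHTS[name, ]
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), .ENERGY_TERMS)
    if (length(bad)) stop("unknown energy terms: ", paste(bad, collapse = ", "))
    w[names(overrides)] <- overrides
  }
  structure(list(name = name, weights = w), class = "stage_weights")
}

#' Names of the composite stage scores
#' @export
stage_names <- function() rownames(.STAGE_WEIGHTS)

## contiguous runs of one SS label; returns list of index vectors
ss_segments <- function(ss, label) {
  r <- rle(ss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == label
  mapply(function(s, e) s:e, starts[keep], ends[keep], SIMPLIFY = FALSE)
}

#' Compute the ten centroid energy terms of a conformation
#'
#' A deterministic pure function of the coordinates, sequence and
#' secondary-structure labels.  Terms (CA = alpha-carbon, CEN = side-chain
#' pseudo-atom, L = chain length, d = pairwise distance in Angstrom):
#' \describe{
#'   \item{vdw}{steric repulsion: sum over CA pairs `|i-j| >= 2` with
#'     `d < 4` of `(16 - d^2)^2 / 4`.}
#'   \item{rg}{radius of gyration of the CA trace.}
#'   \item{env}{hydrophobic burial: `-h(aa_i) * min(nb_i, 12)/12` summed
#'     over residues, `nb_i` = CA neighbours within 10 A excluding
#'     `i-1, i, i+1`, `h` = Kyte-Doolittle hydropathy scaled to [-1, 1].}
#'   \item{pair}{CEN contacts `|i-j| >= 3`, `d < 8`: -1 both hydrophobic,
#'     -0.5 opposite charges, +0.5 like charges.}
#'   \item{cbeta}{density regularity `sum((nb_i - 6)^2) / L`.}
#'   \item{cenpack}{minus the fraction of CEN pairs at 5-7 A.}
#'   \item{ss_pair}{minus the count of CA pairs from different strand
#'     segments at 4.2-5.5 A, per residue.}
#'   \item{hs_pair}{analogous helix-segment/strand-segment contacts at
#'     7-10 A, per residue.}
#'   \item{sheet}{minus the number of distinct paired strand-segment
#'     pairs.}
#'   \item{rsigma}{0.1 per paired strand pair whose segment direction
#'     vectors deviate more than 30 degrees from parallel or
#'     antiparallel.}
#' }
#'
#' @param conf a conformation (coordinates are built if absent).
#' @return named numeric vector over the ten terms.
#' @export
compute_terms <- function(conf) {
  conf <- ensure_coords(conf)
  ca <- conf$coords$CA
  cen <- conf$coords$CEN
  L <- nrow(ca)
  aa <- conf$aa
  ss <- conf$ss
  D <- as.matrix(stats::dist(ca))
  Dcen <- as.matrix(stats::dist(cen))
  sep <- abs(outer(seq_len(L), seq_len(L), "-"))
  upper <- upper.tri(D)

  # vdw
  sel <- upper & sep >= 2 & D < 4
  vdw <- if (any(sel)) sum(((16 - D[sel]^2)^2) / 4) else 0

  # rg
  rg <- sqrt(mean(rowSums(sweep(ca, 2, colMeans(ca))^2)))

  # neighbour counts (exclude self and sequence neighbours)
  nbmat <- D < 10 & sep >= 2
  nb <- rowSums(nbmat)

  h <- .KD[aa]; h[is.na(h)] <- 0
  env <- sum(-h * pmin(nb, 12) / 12)

  cbeta <- sum((nb - 6)^2) / L

  # pair: CEN contacts
  pair <- 0
  sel <- which(upper & sep >= 3 & Dcen < 8, arr.ind = TRUE)
  if (nrow(sel)) {
    ai <- aa[sel[, 1]]; aj <- aa[sel[, 2]]
    hyd <- ai %in% .HYDROPHOBIC & aj %in% .HYDROPHOBIC
    opp <- (ai %in% .POS_CHARGED & aj %in% .NEG_CHARGED) |
           (ai %in% .NEG_CHARGED & aj %in% .POS_CHARGED)
    like <- (ai %in% .POS_CHARGED & aj %in% .POS_CHARGED) |
            (ai %in% .NEG_CHARGED & aj %in% .NEG_CHARGED)
    pair <- sum(-1 * hyd) + sum(-0.5 * opp) + sum(0.5 * like)
  }

  # cenpack: fraction of CEN pairs in the packing shell
  npairs <- L * (L - 1) / 2
  cenpack <- if (npairs > 0)
    -sum(upper & Dcen >= 5 & Dcen <= 7) / npairs else 0

  # strand/helix segment terms
  esegs <- ss_segments(ss, "E")
  hsegs <- ss_segments(ss, "H")
  ss_pair <- 0; hs_pair <- 0; sheet <- 0; rsigma <- 0
  if (length(esegs) >= 2) {
    for (a in seq_len(length(esegs) - 1L)) {
      for (b in (a + 1L):length(esegs)) {
        sub <- D[esegs[[a]], esegs[[b]], drop = FALSE]
        cnt <- sum(sub >= 4.2 & sub <= 5.5)
        ss_pair <- ss_pair + cnt
        if (cnt > 0) {
          sheet <- sheet + 1
          da <- esegs[[a]]; db <- esegs[[b]]
          if (length(da) >= 2 && length(db) >= 2) {
            va <- vunit(ca[da[length(da)], ] - ca[da[1], ])
            vb <- vunit(ca[db[length(db)], ] - ca[db[1], ])
            ang <- acos(pmin(1, pmax(-1, sum(va * vb)))) * 180 / pi
            if (min(ang, 180 - ang) > 30) rsigma <- rsigma + 0.1
          }
        }
      }
    }
    ss_pair <- -ss_pair / L
    sheet <- -sheet
  }
  if (length(hsegs) >= 1 && length(esegs) >= 1) {
    for (a in seq_along(hsegs)) {
      for (b in seq_along(esegs)) {
        sub <- D[hsegs[[a]], esegs[[b]], drop = FALSE]
        hs_pair <- hs_pair + sum(sub >= 7 & sub <= 10)
      }
    }
    hs_pair <- -hs_pair / L
  }

  c(env = env, pair = pair, cbeta = cbeta, vdw = vdw, rg = rg,
    cenpack = cenpack, hs_pair = hs_pair, ss_pair = ss_pair,
    rsigma = rsigma, sheet = sheet)
}

#' Composite stage score of a conformation
#'
#' The weighted sum of the ten energy terms under a stage preset:
#' `sum(weight[stage, term] * term)`.
#'
#' @param conf a conformation.
#' @param stage stage name (see [stage_names()]) or a `stage_weights`
#'   object.
#' @param terms optional precomputed term vector (skips recomputation).
#' @return numeric score (lower is better).
#' @export
score <- function(conf, stage, terms = NULL) {
  sw <- if (inherits(stage, "stage_weights")) stage else stage_weights(stage)
  if (is.null(terms)) {
    cached <- conf$score_cache[[sw$name]]
    if (!is.null(cached)) return(cached)
    terms <- compute_terms(conf)
  }
  sum(sw$weights[.ENERGY_TERMS] * terms[.ENERGY_TERMS])
}

#' Attach a cached stage score to a conformation
#'
#' @inheritParams score
#' @return the conformation with `score_cache[[stage]]` filled.
#' @export
cache_score <- function(conf, stage) {
  sw <- if (inherits(stage, "stage_weights")) stage else stage_weights(stage)
  conf <- ensure_coords(conf)
  conf$score_cache[[sw$name]] <- score(conf, sw)
  conf
}
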
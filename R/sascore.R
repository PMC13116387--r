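# Synthetic-accessibility estimate on the conventional 1 (easy) to 10
# (hard) scale. The estimate combines structural-complexity penalties
# of the kind used in fragment-contribution SA scoring: molecule size,
# ring-fusion atoms, stereocenters, macrocycles, total ring count and
# unusual elements. Small rigid drug-like molecules land near 1-3,
# polycyclic stereo-rich structures near 6-9.

#' Synthetic-accessibility estimate (1 = easy, 10 = hard)
#'
#' A deterministic complexity-based estimate:
#' \deqn{SA = 1 + 0.035 max(0, heavy - 15) + 0.30 n_{fused}
#'   + 0.45 n_{stereo} + 1.5 [macrocycle] + 0.40 max(0, n_{rings} - 4)
#'   + 0.30 n_{unusual}}
#' clamped to \[1, 10\]. Feature definitions: \code{n_fused} is the
#' number of atoms shared by two or more rings, \code{n_stereo} the
#' number of stereocenters declared in the canonical isomeric SMILES,
#' \code{macrocycle} whether any ring has more than 8 members,
#' \code{n_unusual} the number of element types outside the common
#' organic set (C, H, N, O, F, S, Cl, Br, P, I).
#'
#' @param heavy heavy-atom count.
#' @param n_rings smallest-set ring count.
#' @param n_fused_atoms atoms belonging to >= 2 rings.
#' @param n_stereo declared stereocenters.
#' @param macrocycle logical, any ring larger than 8 atoms.
#' @param n_unusual element types outside the common organic set.
#' @return SA estimate in \[1, 10\].
#' @examples
#' saScore(heavy = 9, n_rings = 1, n_fused_atoms = 0, n_stereo = 0,
#'         macrocycle = FALSE, n_unusual = 0)
#' @export
saScore <- function(heavy, n_rings = 0, n_fused_atoms = 0, n_stereo = 0,
                    macrocycle = FALSE, n_unusual = 0) {
  raw <- 1 +
    0.035 * max(0, heavy - 15) +
    0.30 * n_fused_atoms +
    0.45 * n_stereo +
    1.5 * as.numeric(macrocycle) +
    0.40 * max(0, n_rings - 4) +
    0.30 * n_unusual
  min(max(raw, 1), 10)
}
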
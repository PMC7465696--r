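# Flory-Huggins machinery: chi from lattice contact energies, from
# dispersive (van der Waals) interactions, from the empirical
# temperature form, and from the nucleosome-clutch free-energy
# decomposition; plus the segregation product chi*N, regime
# classification against the order-disorder threshold, and the
# loop-extrusion mixing model.
#
# Unit convention for the clutch decomposition: all H terms are carried
# as energy divided by the Boltzmann constant (units of kelvin), the
# compaction entropy in units of k_B, so chi is dimensionless and the
# 1/T scaling is literal. Favourable binding contributions (the
# chromodomain-H3K9me3 and chromoshadow-dimerization terms) enter as
# positive magnitudes; the compaction and terminal-linker potentials
# oppose phase separation and are subtracted.

#' Flory-Huggins chi from lattice contact energies
#'
#' Mean-field incompressible-lattice form: the energy cost, in units of
#' thermal energy, of an A-B contact relative to the mean of the like
#' contacts, summed over the z nearest neighbours:
#' \deqn{\chi_{AB} = \frac{z}{k_B T}\left[\epsilon_{AB} -
#'   \tfrac{1}{2}(\epsilon_{AA} + \epsilon_{BB})\right]}
#'
#' @param z Coordination number of the lattice (>= 1).
#' @param kBT Thermal energy (> 0), same energy units as the epsilons.
#' @param epsAB,epsAA,epsBB Contact energies per repeat unit.
#' @return chi (dimensionless). Vectorized over all arguments.
#' @examples
#' chiLattice(z = 6, kBT = 1, epsAB = 0.5, epsAA = 0.2, epsBB = 0.2)
#' @export
chiLattice <- function(z, kBT, epsAB, epsAA, epsBB) {
    stopifnot(all(z >= 1), all(kBT > 0))
    (z / kBT) * (epsAB - (epsAA + epsBB) / 2)
}

#' Dispersive (van der Waals) contact energy of a segment pair
#'
#' London-dispersion contact energy between segments i and j with
#' polarizabilities alpha and first ionization potentials I at
#' separation r:
#' \deqn{\epsilon_{ij} = -\frac{3}{4}\,\frac{I_i I_j}{I_i + I_j}\,
#'   \frac{\alpha_i \alpha_j}{r^6}}
#' This is the energy of a single pair; summation over pairs is the
#' caller's responsibility.
#'
#' @param alphaI,alphaJ Segment polarizabilities (> 0, volume units).
#' @param ionI,ionJ First ionization potentials (> 0, energy units).
#' @param r Segment-segment separation (> 0).
#' @return Contact energy (negative; attractive). Vectorized.
#' @export
dispersiveContactEnergy <- function(alphaI, ionI, alphaJ, ionJ, r) {
    stopifnot(all(alphaI > 0), all(alphaJ > 0), all(ionI > 0),
              all(ionJ > 0))
    if (any(r <= 0)) stop("separation r must be > 0")
    -0.75 * (ionI * ionJ / (ionI + ionJ)) * alphaI * alphaJ / r^6
}

#' Dispersive chi for a pair of segment types
#'
#' Passing the pairwise dispersive contact energies through the lattice
#' form under the cubic-lattice assumptions (shared ionization potential
#' I, site volume V = r^3) gives
#' \deqn{\chi = \frac{3}{8}\,\frac{I}{k_B T}\,\frac{z}{V^2}\,
#'   (\alpha_A - \alpha_B)^2}
#' with I taken as the mean of the two ionization potentials. The
#' result is always >= 0: purely dispersive blocks always have some
#' tendency to phase separate. A warning is issued when the two
#' ionization potentials differ by more than 10\% of their mean, the
#' stated domain of the shared-I approximation.
#'
#' @param alphaA,alphaB Segment polarizabilities (> 0).
#' @param ionA,ionB First ionization potentials (> 0).
#' @param z Coordination number.
#' @param kBT Thermal energy (> 0).
#' @param V Lattice site volume (> 0).
#' @return chi >= 0 (dimensionless). Vectorized.
#' @examples
#' chiDispersive(alphaA = 2, alphaB = 1, ionA = 1, ionB = 1,
#'               z = 6, kBT = 1, V = 1)   # 2.25
#' @export
chiDispersive <- function(alphaA, alphaB, ionA, ionB, z, kBT, V) {
    stopifnot(all(alphaA > 0), all(alphaB > 0), all(ionA > 0),
              all(ionB > 0), all(z >= 1))
    if (any(kBT <= 0)) stop("kBT must be > 0")
    if (any(V <= 0)) stop("V must be > 0")
    I <- (ionA + ionB) / 2
    if (any(abs(ionA - ionB) / I > 0.10))
        warning("ionization potentials differ by more than 10%; the ",
                "shared-I approximation is questionable")
    (3 / 8) * (I / kBT) * (z / V^2) * (alphaA - alphaB)^2
}

#' Empirical temperature form of chi
#'
#' The general empirical parameterization
#' \deqn{\chi(T) = \alpha/T + \beta}
#' with an enthalpic coefficient alpha (temperature units) and an
#' excess-entropy coefficient beta (dimensionless), both determined
#' experimentally for a given composition.
#'
#' @param alphaEnthalpic Enthalpic coefficient (either sign).
#' @param betaEntropic Entropic coefficient (either sign).
#' @param T Absolute temperature (> 0, kelvin).
#' @return chi (dimensionless). Vectorized.
#' @export
chiEmpirical <- function(alphaEnthalpic, betaEntropic, T) {
    if (any(T <= 0)) stop("temperature must be > 0")
    alphaEnthalpic / T + betaEntropic
}

#' Clutch-level chi for bridged heterochromatin vs euchromatin
#'
#' The nucleosome-clutch decomposition of chi for a heterochromatin-like
#' clutch (H3K9me3-marked nucleosomes bridged by HP1 dimers) against a
#' euchromatic clutch:
#' \deqn{\chi_{HC} = \frac{H_{CD} + H_{CSD} - H_{COMP} - m\,H_{TL}}{T}
#'   + S_{COMP}}
#' where \eqn{H_{CD}} sums the chromodomain-H3K9me3 binding
#' contributions over the bridges in the clutch, \eqn{H_{CSD}} the
#' chromoshadow-domain dimerization contributions, \eqn{H_{COMP}} is the
#' compaction potential energy (linker elasticity plus steric
#' exclusion), \eqn{H_{TL}} the elastic energy of the terminal linker
#' joining the clutch to euchromatin, and \eqn{S_{COMP}} the excess
#' entropy given up on compaction. A domain/complex flanked by
#' euchromatin on both sides pays the terminal-linker penalty twice
#' (m = 2); a one-sided clutch pays it once (m = 1). With every term
#' zero (no HP1) the two clutches are thermodynamically equivalent and
#' chi = 0.
#'
#' H terms are energies divided by the Boltzmann constant (kelvin);
#' \code{S_COMP} is in units of the Boltzmann constant. The sign of
#' \code{S_COMP} is the caller's choice (entropy given up on compaction
#' argues for a negative value, but the decomposition does not fix it).
#'
#' @param H_CD Chromodomain-H3K9me3 binding contribution (kelvin),
#'   entered as a positive magnitude for favourable binding.
#' @param H_CSD Chromoshadow-domain dimerization contribution (kelvin),
#'   positive magnitude for favourable dimerization.
#' @param H_COMP Compaction potential energy (kelvin).
#' @param H_TL Terminal-linker elastic energy (kelvin).
#' @param S_COMP Excess compaction entropy (units of k_B).
#' @param T Absolute temperature (> 0, kelvin).
#' @param flankedBothSides Logical: euchromatin on both sides (counts
#'   the terminal-linker term twice)?
#' @return chi_HC (dimensionless). Vectorized.
#' @examples
#' chiClutch(H_CD = 600, H_CSD = 300, H_COMP = 200, H_TL = 100,
#'           T = 300)                            # 2
#' chiClutch(H_CD = 600, H_CSD = 300, H_COMP = 200, H_TL = 100,
#'           T = 300, flankedBothSides = TRUE)   # 5/3
#' @export
chiClutch <- function(H_CD, H_CSD, H_COMP, H_TL, S_COMP = 0, T = 310,
                      flankedBothSides = FALSE) {
    if (any(T <= 0)) stop("temperature must be > 0")
    m <- ifelse(flankedBothSides, 2, 1)
    (H_CD + H_CSD - H_COMP - m * H_TL) / T + S_COMP
}

#' Segregation product chi * N
#'
#' The degree of micro-phase separation of a block from its surroundings
#' is governed by the product of chi and the number of repeat units in
#' the block --- for chromatin, the number of clutches in the
#' domain/complex.
#'
#' @param chi Flory-Huggins parameter.
#' @param N Number of repeat units (>= 1).
#' @return chi * N. Vectorized.
#' @export
segregationProduct <- function(chi, N) {
    stopifnot(all(N >= 1))
    chi * N
}

#' Classify the segregation regime of a block
#'
#' Compares chi*N against the order-disorder threshold: below it the
#' system is disordered (mixed); close to or slightly above it the
#' interfaces are weak and wavy ("liquid-like"); far above it
#' (by default >= 5x the threshold, a configurable stand-in for
#' "much greater") the interfaces are discrete and sharp.
#'
#' @param chiN Segregation product(s).
#' @param chiN_ODT Order-disorder threshold (> 0). Defaults to the
#'   flexible-chain RPA spinodal at symmetric composition,
#'   \code{\link{chiNodtRPA}()}; chromatin's semi-flexible fibres have
#'   their own thresholds, so this is a parameter everywhere.
#' @param strongRatio Multiple of the threshold separating weak from
#'   strong segregation (default 5).
#' @return Factor with levels \code{disordered}, \code{weak_wavy},
#'   \code{strong_sharp}.
#' @examples
#' classifySegregation(c(5, 11, 100))
#' @export
classifySegregation <- function(chiN, chiN_ODT = chiNodtRPA(),
                                strongRatio = 5) {
    stopifnot(chiN_ODT > 0, strongRatio > 1)
    cls <- ifelse(chiN < chiN_ODT, "disordered",
           ifelse(chiN < strongRatio * chiN_ODT, "weak_wavy",
                  "strong_sharp"))
    factor(cls, levels = c("disordered", "weak_wavy", "strong_sharp"))
}

#' Loop-extrusion mixing of domains/complexes
#'
#' Models the mixing of heterochromatin-like domains/complexes with
#' euchromatin by cohesin-driven loop extrusion as an energy input E
#' subtracted from the segregation product: the effective product is
#' \code{chi*N - E}, and a call stays micro-phase separated iff the
#' effective product still reaches the order-disorder threshold. This
#' reproduces the three cohesin regimes: with extrusion absent
#' (cohesin loss) even small complexes reconstitute; at moderate
#' activity (wild type) only small-N complexes mix; at high activity
#' (extrusion unrestrained) even large-N domains mix. Smaller blocks
#' always mix first.
#'
#' @param chi Per-clutch chi of each call (vector).
#' @param N Clutch count of each call (vector, recycled with chi).
#' @param E Extrusion activity (>= 0), in the same dimensionless units
#'   as chi*N.
#' @param chiN_ODT Order-disorder threshold (default
#'   \code{\link{chiNodtRPA}()}).
#' @return A data.frame with columns \code{chi}, \code{N}, \code{chiN},
#'   \code{chiNeff} and \code{status} (factor \code{separated} /
#'   \code{mixed}).
#' @examples
#' extrusionMixing(chi = 0.5, N = c(100, 25), E = 5)
#' @export
extrusionMixing <- function(chi, N, E, chiN_ODT = chiNodtRPA()) {
    stopifnot(E >= 0, chiN_ODT > 0)
    chiN <- segregationProduct(chi, N)
    chiNeff <- chiN - E
    status <- factor(ifelse(chiNeff >= chiN_ODT, "separated", "mixed"),
                     levels = c("separated", "mixed"))
    data.frame(chi = chi, N = N, chiN = chiN, chiNeff = chiNeff,
               status = status)
}
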
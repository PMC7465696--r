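# Random-phase-approximation (Leibler) spinodal of a flexible diblock
# copolymer and lamellar composition profiles in the weak and strong
# segregation regimes. The spinodal at symmetric composition is the
# classical order-disorder threshold chi*N ~ 10.5.

#' Debye-type correlation function of a block
#'
#' The single-chain correlation function of a Gaussian block of
#' fraction f at dimensionless squared wavevector \eqn{x = q^2 R_g^2}:
#' \deqn{g(f, x) = \frac{2\,(f x + e^{-f x} - 1)}{x^2}}
#' with the continuous limit \eqn{g(f, 0) = f^2}. For \eqn{f x <
#' 10^{-4}} a series expansion is used to avoid the catastrophic
#' cancellation of \eqn{f x + e^{-f x} - 1} in floating point:
#' \deqn{g = f^2\left(1 - \tfrac{u}{3} + \tfrac{u^2}{12} -
#'   \tfrac{u^3}{60}\right), \quad u = f x.}
#'
#' @param f Block fraction, 0 < f <= 1.
#' @param x Dimensionless squared wavevector, >= 0.
#' @return g(f, x). Vectorized over x (and f of matching length).
#' @examples
#' debyeG(1, 0)        # 1
#' debyeG(0.5, 3.785)
#' @export
debyeG <- function(f, x) {
    stopifnot(all(f > 0), all(f <= 1), all(x >= 0))
    u <- f * x
    out <- numeric(length(u))
    small <- u < 1e-4
    us <- u[small]
    out[small] <- (f^2 + 0 * u)[small] *
        (1 - us / 3 + us^2 / 12 - us^3 / 60)
    xl <- x[!small]
    ul <- u[!small]
    out[!small] <- 2 * (ul + exp(-ul) - 1) / xl^2
    out
}

#' RPA correlation quotient of a diblock
#'
#' The Leibler structure-factor quotient whose minimum over x locates
#' the spinodal:
#' \deqn{F(x, f) = \frac{g(1, x)}{g(f, x)\,g(1-f, x) -
#'   \tfrac{1}{4}\left[g(1, x) - g(f, x) - g(1-f, x)\right]^2}}
#' F is symmetric in f and 1-f and diverges as x tends to 0 (the
#' homogeneous fluctuation is suppressed by chain connectivity).
#'
#' @param f Composition, 0 < f < 1.
#' @param x Dimensionless squared wavevector, > 0. Vectorized.
#' @return F(x, f).
#' @export
rpaF <- function(f, x) {
    stopifnot(all(f > 0), all(f < 1), all(x > 0))
    g1 <- debyeG(1, x)
    gf <- debyeG(f, x)
    gc <- debyeG(1 - f, x)
    den <- gf * gc - (g1 - gf - gc)^2 / 4
    if (any(den <= 0))
        stop("RPA denominator non-positive: outside the numerical domain")
    g1 / den
}

#' RPA spinodal of a diblock copolymer
#'
#' Locates the spinodal value of the segregation product,
#' \eqn{(\chi N)_s = \min_x F(x, f)/2}, by a log-spaced grid scan over
#' x followed by bracketed golden-section/parabolic refinement of the
#' best grid cell. At f = 1/2 this is the classical order-disorder
#' threshold, about 10.5.
#'
#' @param f Composition, 0 < f < 1.
#' @param xRange Search range for x (log-spaced grid), default
#'   \code{c(1e-3, 1e3)}.
#' @param tol Relative tolerance of the refinement on x.
#' @param gridN Number of grid points in the initial scan.
#' @return A list of class \code{"SpinodalResult"}: \code{f},
#'   \code{chiNs} (spinodal chi*N) and \code{xStar} (minimizing x).
#' @examples
#' spinodal(0.5)$chiNs   # ~10.495
#' @export
spinodal <- function(f, xRange = c(1e-3, 1e3), tol = 1e-8,
                     gridN = 512L) {
    stopifnot(f > 0, f < 1, length(xRange) == 2, xRange[1] > 0,
              xRange[2] > xRange[1])
    lx <- seq(log(xRange[1]), log(xRange[2]), length.out = gridN)
    vals <- rpaF(f, exp(lx)) / 2
    i <- which.min(vals)
    if (i == 1L || i == gridN)
        stop("spinodal minimum at the edge of the x grid; ",
             "widen xRange [grid min ", format(min(vals)), " at x = ",
             format(exp(lx[i])), "]")
    opt <- stats::optimize(function(l) rpaF(f, exp(l)) / 2,
                           interval = c(lx[i - 1L], lx[i + 1L]),
                           tol = tol)
    structure(list(f = f, chiNs = opt$objective,
                   xStar = exp(opt$minimum)),
              class = "SpinodalResult")
}

#' @export
print.SpinodalResult <- function(x, ...) {
    cat("RPA spinodal at f =", format(x$f), ": (chi N)_s =",
        format(x$chiNs, digits = 6), "at x* =",
        format(x$xStar, digits = 6), "\n")
    invisible(x)
}

#' Flexible-chain order-disorder threshold (memoized)
#'
#' The RPA spinodal at symmetric composition, \code{spinodal(0.5)$chiNs}
#' (about 10.495), computed once per session and cached. This is the
#' default threshold wherever one is needed; semi-flexible chromatin
#' fibres have their own thresholds and every consumer accepts one as a
#' parameter.
#'
#' @return Numeric scalar.
#' @export
chiNodtRPA <- local({
    cached <- NULL
    function() {
        if (is.null(cached))
            cached <<- spinodal(0.5)$chiNs
        cached
    }
})

#' Lamellar composition profile of an ordered diblock
#'
#' One-dimensional composition profile \eqn{\phi_A(r_\perp)} across the
#' lamellae of an ordered diblock, in the regime selected by
#' \code{\link{classifySegregation}}. In the weak (wavy) regime the
#' profile is a single harmonic about the mean composition,
#' \deqn{\phi_A(r) = f + A \cos(q^* r), \quad
#'   A = \min(f, 1-f)\,\sqrt{1 - (\chi N)_{ODT}/\chi N},}
#' a phenomenological amplitude law chosen for continuity at the
#' threshold (A = 0 there) and saturation well above it. In the strong
#' (sharp) regime the profile is a period-f square wave smoothed at each
#' edge by \eqn{\tfrac{1}{2}[1 + \tanh(2(r - r_{edge})/w)]} with the
#' standard strong-segregation (Helfand) interface width
#' \deqn{w = \frac{2 b}{\sqrt{6 \chi}}.}
#' The lamellar period is set by the spinodal wavevector,
#' \eqn{D = 2\pi R_g / \sqrt{x^*(f)}} with \eqn{R_g = b\sqrt{N/6}}.
#'
#' @param f Composition, 0 < f < 1.
#' @param N Repeat-unit (clutch) count, >= 1.
#' @param chi Flory-Huggins parameter.
#' @param chiN_ODT Order-disorder threshold (default
#'   \code{\link{chiNodtRPA}()}).
#' @param strongRatio Weak/strong boundary as a multiple of the
#'   threshold (default 5).
#' @param b Repeat-unit length (default 1; r is in units of b).
#' @param nPeriods Number of lamellar periods to tabulate.
#' @param nPoints Total number of sample positions (endpoint excluded,
#'   so the positions tile whole periods exactly).
#' @return A list of class \code{"CompositionProfile"}: \code{r},
#'   \code{phiA}, \code{regime}, \code{interfaceWidth} (NA in the weak
#'   regime), \code{period}, \code{f}, \code{chiN}.
#' @examples
#' p <- lamellarProfile(f = 0.5, N = 40, chi = 100 / 40)
#' mean(p$phiA)   # ~0.5
#' @export
lamellarProfile <- function(f, N, chi, chiN_ODT = chiNodtRPA(),
                            strongRatio = 5, b = 1, nPeriods = 2L,
                            nPoints = 1024L) {
    stopifnot(f > 0, f < 1, N >= 1, nPeriods >= 1, nPoints >= 16)
    chiN <- chi * N
    regime <- as.character(classifySegregation(chiN, chiN_ODT,
                                               strongRatio))
    if (regime == "disordered")
        stop("chi*N = ", format(chiN), " is below the order-disorder ",
             "threshold ", format(chiN_ODT),
             "; a disordered melt has no lamellar profile")
    sp <- spinodal(f)
    Rg <- b * sqrt(N / 6)
    D <- 2 * pi * Rg / sqrt(sp$xStar)
    r <- seq(0, nPeriods * D, length.out = nPoints + 1L)[-(nPoints + 1L)]
    if (regime == "weak_wavy") {
        A <- min(f, 1 - f) * sqrt(1 - chiN_ODT / chiN)
        phi <- f + A * cos(2 * pi * r / D)
        w <- NA_real_
    } else {
        w <- 2 * b / sqrt(6 * chi)
        rm_ <- r %% D
        # A-rich stripe of width f*D centred in each period; adjacent
        # period images included so the tanh tails wrap periodically
        r1 <- (1 - f) * D / 2
        r2 <- (1 + f) * D / 2
        bump <- function(rr) 0.5 * (tanh(2 * (rr - r1) / w) -
                                    tanh(2 * (rr - r2) / w))
        phi <- bump(rm_) + bump(rm_ - D) + bump(rm_ + D)
        phi <- pmin(pmax(phi, 0), 1)
    }
    structure(list(r = r, phiA = phi, regime = regime,
                   interfaceWidth = w, period = D, f = f, chiN = chiN),
              class = "CompositionProfile")
}

#' @export
print.CompositionProfile <- function(x, ...) {
    cat("Lamellar profile: regime", x$regime, "| chiN =",
        format(x$chiN, digits = 4), "| period =",
        format(x$period, digits = 4), "b | mean phi_A =",
        format(mean(x$phiA), digits = 4), "\n")
    invisible(x)
}
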
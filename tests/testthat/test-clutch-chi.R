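test_that("lattice chi: neutral case, worked value, label symmetry", {
    # eps_AB equal to the mean of like contacts is mixing-neutral
    expect_equal(chiLattice(6, 1, epsAB = 0.35, epsAA = 0.5,
                            epsBB = 0.2), 0)
    expect_equal(chiLattice(6, 1, epsAB = 0.5, epsAA = 0.2,
                            epsBB = 0.2), 1.8)
    # swapping A and B leaves chi unchanged
    expect_equal(chiLattice(6, 2, 0.4, 0.1, 0.3),
                 chiLattice(6, 2, 0.4, 0.3, 0.1))
    expect_error(chiLattice(6, 0, 1, 1, 1))
})

test_that("dispersive pair energy: value, symmetry, r^-6 scaling", {
    expect_equal(dispersiveContactEnergy(1, 2, 1, 2, 1), -0.75)
    expect_equal(dispersiveContactEnergy(1.3, 2.1, 0.7, 1.9, 1.1),
                 dispersiveContactEnergy(0.7, 1.9, 1.3, 2.1, 1.1))
    e1 <- dispersiveContactEnergy(1, 2, 1, 2, 1)
    e2 <- dispersiveContactEnergy(1, 2, 1, 2, 2)
    expect_equal(e1 / e2, 64)
    expect_error(dispersiveContactEnergy(1, 2, 1, 2, 0), "r must be > 0")
})

test_that("dispersive chi: zero at equal polarizability, symmetric, >= 0", {
    expect_equal(chiDispersive(1.5, 1.5, 1, 1, 6, 1, 1), 0)
    expect_equal(chiDispersive(2, 1, 1, 1, 6, 1, 1), 2.25)
    expect_equal(chiDispersive(2, 1, 1, 1, 6, 1, 1),
                 chiDispersive(1, 2, 1, 1, 6, 1, 1))
    set.seed(1)
    aA <- runif(50, 0.5, 3); aB <- runif(50, 0.5, 3)
    expect_true(all(chiDispersive(aA, aB, 1, 1, 6, 1, 1) >= 0))
    expect_warning(chiDispersive(2, 1, 1, 1.5, 6, 1, 1), "10%")
})

test_that("empirical chi is linear in 1/T", {
    expect_equal(chiEmpirical(30, -0.05, 300), 0.05)
    # alpha = 0 removes the temperature dependence
    expect_equal(chiEmpirical(0, 0.3, 200), chiEmpirical(0, 0.3, 500))
    # linearity: chi(T) - beta proportional to 1/T
    Ts <- c(250, 300, 350, 400)
    chis <- chiEmpirical(42, 0.1, Ts)
    expect_equal((chis - 0.1) * Ts, rep(42, 4))
    # monotone decreasing in T when alpha > 0
    expect_true(all(diff(chiEmpirical(42, 0.1, Ts)) < 0))
    expect_error(chiEmpirical(1, 0, 0))
})

test_that("clutch chi: zero baseline, worked cases, flanking rule", {
    # absent HP1 all terms vanish and the clutches are equivalent
    expect_equal(chiClutch(0, 0, 0, 0, 0, T = 300), 0)
    expect_equal(chiClutch(600, 300, 200, 100, 0, T = 300), 2)
    both <- chiClutch(600, 300, 200, 100, 0, T = 300,
                      flankedBothSides = TRUE)
    expect_equal(both, 5 / 3)
    # the terminal linker opposes phase separation: flanking on both
    # sides lowers chi
    expect_lt(both, chiClutch(600, 300, 200, 100, 0, T = 300))
    expect_error(chiClutch(1, 1, 1, 1, T = -5))
})

test_that("clutch chi is monotone in each free-energy term", {
    set.seed(7)
    n <- 300
    H_CD <- runif(n, 100, 1000); H_CSD <- runif(n, 100, 1000)
    H_COMP <- runif(n, 0, 300); H_TL <- runif(n, 0, 150)
    Tv <- runif(n, 280, 320)
    h <- 1e-4
    base <- chiClutch(H_CD, H_CSD, H_COMP, H_TL, 0, Tv)
    expect_true(all(chiClutch(H_CD + h, H_CSD, H_COMP, H_TL, 0, Tv)
                    > base))
    expect_true(all(chiClutch(H_CD, H_CSD + h, H_COMP, H_TL, 0, Tv)
                    > base))
    expect_true(all(chiClutch(H_CD, H_CSD, H_COMP + h, H_TL, 0, Tv)
                    < base))
    expect_true(all(chiClutch(H_CD, H_CSD, H_COMP, H_TL + h, 0, Tv)
                    < base))
    # decreasing in T while the net enthalpic numerator is positive
    pos <- (H_CD + H_CSD - H_COMP - H_TL) > 0
    withT <- chiClutch(H_CD, H_CSD, H_COMP, H_TL, 0, Tv + 1)
    expect_true(all((withT < base)[pos]))
    # severing the terminal linker never decreases chi
    cut <- chiClutch(H_CD, H_CSD, H_COMP, 0, 0, Tv)
    expect_true(all(cut >= base))
})

test_that("segregation product and regime classification", {
    expect_equal(segregationProduct(0.5, 30), 15)
    expect_true(all(segregationProduct(c(-1, 0, -0.2), 10) <= 0))
    expect_equal(segregationProduct(0.3, c(10, 20, 40)),
                 c(3, 6, 12))

    odt <- 10.495
    expect_equal(as.character(classifySegregation(5, odt)), "disordered")
    expect_equal(as.character(classifySegregation(11, odt)), "weak_wavy")
    expect_equal(as.character(classifySegregation(100, odt)),
                 "strong_sharp")
    # monotone in chiN: regime index never decreases
    grid <- seq(0.5, 200, by = 0.5)
    idx <- as.integer(classifySegregation(grid, odt))
    expect_true(all(diff(idx) >= 0))
})

test_that("extrusion mixing reproduces the three cohesin regimes", {
    odt <- 10.495
    # two calls: a large domain (N = 100) and a small complex (N = 25)
    # no extrusion (cohesin lost): both micro-phase separated
    e0 <- extrusionMixing(0.5, c(100, 25), E = 0, chiN_ODT = odt)
    expect_equal(as.character(e0$status), c("separated", "separated"))
    # moderate extrusion (wild type): only the small complex mixes
    e5 <- extrusionMixing(0.5, c(100, 25), E = 5, chiN_ODT = odt)
    expect_equal(as.character(e5$status), c("separated", "mixed"))
    expect_equal(e5$chiNeff, c(45, 7.5))
    # unrestrained extrusion: even the large domain mixes
    e45 <- extrusionMixing(0.5, c(100, 25), E = 45, chiN_ODT = odt)
    expect_equal(as.character(e45$status), c("mixed", "mixed"))
})

test_that("the mixed set grows with E and smaller blocks mix first", {
    set.seed(11)
    chi <- 0.4
    N <- sample(5:400, 60, replace = TRUE)
    prevMixed <- rep(FALSE, 60)
    for (E in c(0, 2, 10, 30, 80, 200)) {
        mixed <- extrusionMixing(chi, N, E)$status == "mixed"
        expect_true(all(mixed[prevMixed]))   # monotone in E
        prevMixed <- mixed
        # at fixed E and chi, no separated call is smaller than a mixed one
        if (any(mixed) && any(!mixed))
            expect_gt(min(N[!mixed]), max(N[mixed]))
    }
})
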
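test_that("PDB parsing resolves altlocs and separates chains and hetatms", {
    path <- withr::local_tempfile(fileext = ".pdb")
    atoms <- data.frame(name = "CA", resid = "ALA", chain = "A", resno = 1,
                        x = 1.5, y = -2.25, z = 3, b = 42.5, element = "C")
    writePdbFixture(path, atoms)
    mod <- parsePdb(path)
    expect_equal(nrow(mod$atoms), 1L)
    expect_equal(unlist(mod$atoms[1, c("x", "y", "z")]),
                 c(x = 1.5, y = -2.25, z = 3))
    expect_equal(mod$atoms$b, 42.5)

    ## altloc: higher occupancy wins
    alt <- rbind(
        data.frame(name = "CA", resid = "ALA", chain = "A", resno = 1,
                   x = 0, y = 0, z = 0, occ = 0.6, altloc = "A",
                   element = "C"),
        data.frame(name = "CA", resid = "ALA", chain = "A", resno = 1,
                   x = 9, y = 9, z = 9, occ = 0.4, altloc = "B",
                   element = "C"))
    writePdbFixture(path, alt)
    mod <- parsePdb(path)
    expect_equal(nrow(mod$atoms), 1L)
    expect_equal(mod$atoms$x, 0)

    ## chains and HETATM bookkeeping on the dimer fixture
    dimerFixture(path)
    mod <- parsePdb(path)
    expect_setequal(mod$chains, c("A", "B"))
    expect_equal(sum(mod$atoms$chain == "A"), 5L)
    expect_equal(unique(mod$hetatms$resid), "FAD")
    writeLines("REMARK nothing", path)
    expect_error(parsePdb(path), "no ATOM")
})

test_that("SASA of an isolated atom matches the closed-form sphere area", {
    for (r in c(1.52, 1.7, 1.8)) {
        at <- data.frame(chain = "A", resno = 1, resid = "GLY",
                         x = 0, y = 0, z = 0, element = "C")
        at$element <- "C"
        got <- sasaPerResidue(at, probe = 1.4, n_points = 240,
                              radii = c(C = r))
        expect_equal(got$sasa_abs, 4 * pi * (r + 1.4)^2, tolerance = 0.01)
    }
    expect_error(sasaPerResidue(data.frame(chain = "A", resno = 1,
                                           resid = "GLY", x = 0, y = 0,
                                           z = 0, element = "C"),
                                n_points = 8), ">= 16")
})

test_that("a fully enclosed atom has (near) zero SASA", {
    ## shell of 26 atoms on a 2.5 A grid cage around the centre
    g <- expand.grid(x = c(-2.5, 0, 2.5), y = c(-2.5, 0, 2.5),
                     z = c(-2.5, 0, 2.5))
    g <- g[!(g$x == 0 & g$y == 0 & g$z == 0), ]
    at <- rbind(data.frame(chain = "A", resno = 1, resid = "GLY",
                           x = 0, y = 0, z = 0, element = "C"),
                data.frame(chain = "A", resno = 2, resid = "GLY",
                           x = g$x, y = g$y, z = g$z, element = "C"))
    got <- sasaPerResidue(at, n_points = 240)
    expect_lt(got$sasa_abs[got$resno == 1] / (4 * pi * 3.1^2), 0.01)
})

test_that("two-atom SASA matches the analytic spherical-cap oracle", {
    probe <- 1.4
    r1 <- 1.7; r2 <- 1.55
    R1 <- r1 + probe; R2 <- r2 + probe
    for (d in c(2.2, 2.8, 3.4)) {
        at <- data.frame(chain = "A", resno = c(1, 2),
                         resid = "GLY", x = c(0, d), y = 0, z = 0,
                         element = c("C", "N"))
        got <- sasaPerResidue(at, probe = probe, n_points = 2000)
        ## buried cap height on sphere 1 from the plane of intersection
        x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
        a1_exact <- 4 * pi * R1^2 - 2 * pi * R1 * (R1 - x1)
        expect_equal(got$sasa_abs[1], a1_exact, tolerance = 0.01)
        x2 <- (d^2 + R2^2 - R1^2) / (2 * d)
        a2_exact <- 4 * pi * R2^2 - 2 * pi * R2 * (R2 - x2)
        expect_equal(got$sasa_abs[2], a2_exact, tolerance = 0.01)
    }
})

test_that("SASA is invariant under rigid-body motion and capped at 100", {
    set.seed(5)
    n <- 30
    at <- data.frame(chain = "A", resno = rep(1:6, each = 5),
                     resid = rep(c("ALA", "GLY", "SER", "VAL", "LEU",
                                   "THR"), each = 5),
                     x = rnorm(n, sd = 4), y = rnorm(n, sd = 4),
                     z = rnorm(n, sd = 4),
                     element = sample(c("C", "N", "O"), n, TRUE))
    base <- sasaPerResidue(at, n_points = 960)
    expect_true(all(base$sasa_rel >= 0 & base$sasa_rel <= 100))
    ## rotate about an arbitrary axis then translate
    th <- 0.83
    Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
    xyz <- as.matrix(at[, c("x", "y", "z")]) %*% Rz
    at2 <- at
    at2$x <- xyz[, 1] + 11.3; at2$y <- xyz[, 2] - 5; at2$z <- xyz[, 3] + 2
    moved <- sasaPerResidue(at2, n_points = 960)
    expect_equal(moved$sasa_abs, base$sasa_abs, tolerance = 0.005)
})

test_that("mean distance to a cofactor group is the plain arithmetic mean", {
    path <- withr::local_tempfile(fileext = ".pdb")
    atoms <- rbind(
        data.frame(name = "CA", resid = "GLY", chain = "A", resno = 1,
                   x = 0, y = 0, z = 0, element = "C", type = "ATOM"),
        data.frame(name = c("O1", "O2"), resid = "LIG", chain = "A",
                   resno = 90, x = c(3, 0), y = c(0, 4), z = 0,
                   element = "O", type = "HETATM"))
    writePdbFixture(path, atoms)
    mod <- parsePdb(path)
    got <- meanDistanceToGroup(mod, "LIG")
    expect_equal(got$d_mean, 3.5)  # mean of 3 and 4
    ## single-atom group degenerates to the plain distance
    got1 <- meanDistanceToGroup(mod, matrix(c(0, 0, 7), 1))
    expect_equal(got1$d_mean, 7)
    ## random group vs brute-force loop oracle
    set.seed(31)
    grp <- matrix(rnorm(30, sd = 5), ncol = 3)
    brute <- mean(apply(grp, 1, function(p) sqrt(sum(p^2))))
    expect_equal(meanDistanceToGroup(mod, grp)$d_mean, brute)
    expect_error(meanDistanceToGroup(mod, "FAD"), "no HETATM")
})

test_that("interface detection matches a brute-force all-pairs scan", {
    path <- withr::local_tempfile(fileext = ".pdb")
    dimerFixture(path, gap = 4.0)
    mod <- parsePdb(path)
    out <- interfaceResidues(mod, "A", "B", contact_cutoff = 5)
    ## brute force: every cross-chain atom pair within the cutoff
    A <- mod$atoms[mod$atoms$chain == "A", ]
    B <- mod$atoms[mod$atoms$chain == "B", ]
    brute <- list()
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
        d <- sqrt(sum((unlist(A[i, c("x", "y", "z")]) -
                           unlist(B[j, c("x", "y", "z")]))^2))
        if (d <= 5) {
            brute[[length(brute) + 1]] <- data.frame(
                chain = c(A$chain[i], B$chain[j]),
                resno = c(A$resno[i], B$resno[j]))
        }
    }
    brute <- unique(do.call(rbind, brute))
    got <- out$interface[order(out$interface$chain, out$interface$resno), ]
    want <- brute[order(brute$chain, brute$resno), ]
    expect_equal(got, want, ignore_attr = TRUE)
    ## gap 4: all residues touch across chains, so all d_interface = 0
    expect_true(all(out$distances$d_interface == 0))
    ## widen the gap: no contacts -> error
    dimerFixture(path, gap = 30)
    mod2 <- parsePdb(path)
    expect_error(interfaceResidues(mod2, "A", "B"), "no interface")
    ## single chain: undefined
    expect_error(interfaceResidues(mod, "A", "Z"), "both chains")
})

test_that("distance to interface is the distance to the closest interface CA", {
    ## chains touch only at residue 1 (others bent away in y)
    path <- withr::local_tempfile(fileext = ".pdb")
    resA <- data.frame(name = "CA", resid = "GLY", chain = "A",
                       resno = 1:3, x = c(0, 10, 20), y = 0, z = 0,
                       element = "C", type = "ATOM")
    resB <- data.frame(name = "CA", resid = "GLY", chain = "B",
                       resno = 1:3, x = c(0, 10, 20),
                       y = c(4, 40, 40), z = 0, element = "C",
                       type = "ATOM")
    writePdbFixture(path, rbind(resA, resB))
    out <- interfaceResidues(parsePdb(path), "A", "B", contact_cutoff = 5)
    expect_equal(nrow(out$interface), 2L)  # A:1 and B:1 only
    dA <- out$distances[out$distances$chain == "A", ]
    expect_equal(dA$d_interface, c(0, 10, 20))
})

test_that("active-site distances use explicit centres or ligand centroids", {
    path <- withr::local_tempfile(fileext = ".pdb")
    atoms <- rbind(
        data.frame(name = "CA", resid = "GLY", chain = "A", resno = 1:2,
                   x = c(0, 0), y = 0, z = c(0, 7.5), element = "C",
                   type = "ATOM"),
        data.frame(name = paste0("C", 1:4), resid = "DAL", chain = "A",
                   resno = 90, x = c(1, -1, 1, -1), y = c(1, 1, -1, -1),
                   z = 10, element = "C", type = "HETATM"))
    writePdbFixture(path, atoms)
    mod <- parsePdb(path)
    got <- distanceToActiveSite(mod, c(0, 0, 0))
    expect_equal(got$d_active, c(0, 7.5))
    ## centroid of the 4-atom ligand is (0,0,10); hand-computed distances
    gotc <- distanceToActiveSite(mod, "DAL")
    expect_equal(gotc$d_active, c(10, 2.5))
    expect_error(distanceToActiveSite(mod, "XXX"), "empty active-site")
})

test_that("residue scales look up verbatim and deltas are antisymmetric", {
    tab <- residueScaleTable()
    expect_equal(unname(residueScales("A")["hydrophobicity"]),
                 tab["A", "hydrophobicity"])
    expect_equal(unname(deltaScales("A", "A")), c(0, 0, 0))
    expect_equal(deltaScales("A", "V"), -deltaScales("V", "A"))
    expect_error(residueScales("Z"), "unknown amino acid")
    ## custom tables are honoured verbatim
    custom <- tab; custom["G", "polarity"] <- 77
    expect_equal(unname(residueScales("G", custom)["polarity"]), 77)
})

test_that("the assembled feature table carries B-factors and all distances", {
    path <- withr::local_tempfile(fileext = ".pdb")
    dimerFixture(path)
    mod <- parsePdb(path)
    feat <- residueFeatureTable(mod, chain = "A", fad_resid = "FAD",
                                interface_chains = c("A", "B"),
                                active_center = c(0, 0, 0),
                                cons = data.frame(resno = 1:5,
                                                  cons = c(100, 50, 100,
                                                           0, 25)),
                                n_points = 60)
    expect_equal(feat$position, 1:5)
    expect_equal(feat$bfactor, (1:5) * 10)  # written values, exactly
    expect_true(all(feat$sasa_rel >= 0 & feat$sasa_rel <= 100))
    expect_true(all(feat$d_fad >= 0))
    expect_equal(feat$cons, c(100, 50, 100, 0, 25))
    expect_equal(feat$d_active[1], 0)
    ## every chain-A residue touches chain B in this fixture
    expect_true(all(feat$d_interface == 0))
})
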
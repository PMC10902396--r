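## Per-residue structural features from a PDB file: Shrake-Rupley SASA,
## B-factors, mean distance to cofactor atoms, distance to the dimer
## interface, distance to the active site, and residue property scales.

#' Van der Waals radii used for SASA and contacts
#'
#' Element radii in Angstrom; unknown elements fall back to the carbon
#' radius with a warning. Hydrogens are excluded from SASA and contact
#' calculations (crystal structures of this era lack them).
#' @return named numeric vector.
#' @export
vdwRadii <- function() {
    c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
      FE = 1.80, ZN = 1.39, MG = 1.73, CA = 2.31, MN = 1.97, SE = 1.90)
}

#' Theoretical maximum accessible surface areas per residue
#'
#' Tripeptide-based theoretical maxima (Tien-style values, Angstrom^2)
#' used to normalize absolute SASA to the 0-100 relative scale. Shipped as
#' a replaceable table.
#' @return named numeric vector over the 20 amino acids (one-letter).
#' @export
maxAsaTable <- function() {
    c(A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225,
      G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
      P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174)
}

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Parse a PDB file into a structure model
#'
#' Thin wrapper over \code{bio3d::read.pdb} that resolves alternate
#' locations to the highest-occupancy conformer (ties: first encountered),
#' drops hydrogens, and splits protein (ATOM) from cofactor/ligand
#' (HETATM) records.
#'
#' @param path PDB file.
#' @return list of class \code{StructureModel}: \code{atoms} (protein
#'   heavy atoms with chain, resno, resid, elety, element, xyz, b,
#'   occupancy), \code{hetatms} (same for HETATM groups, keyed by resid),
#'   and \code{chains}.
#' @export
parsePdb <- function(path) {
    pdb <- bio3d::read.pdb(path)
    at <- pdb$atom
    if (nrow(at) == 0L) stop("no ATOM records in ", path)
    elem <- toupper(at$elesy)
    blank <- is.na(elem) | elem == ""
    elem[blank] <- toupper(substr(trimws(at$elety[blank]), 1L, 1L))
    at$element <- elem
    at <- at[at$element != "H", , drop = FALSE]
    ## altloc: keep the highest-occupancy conformer per atom site
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    if (anyDuplicated(key)) {
        occ <- ifelse(is.na(at$o), 1, at$o)
        ord <- order(-occ, seq_len(nrow(at)))
        at <- at[ord, ][!duplicated(key[ord]), ]
        at <- at[order(as.integer(rownames(at))), ]
    }
    if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)))
        stop("non-finite coordinates in ", path)
    prot <- at[at$type == "ATOM", , drop = FALSE]
    het <- at[at$type == "HETATM", , drop = FALSE]
    if (nrow(prot) == 0L) stop("no protein chain in ", path)
    structure(list(atoms = prot, hetatms = het,
                   chains = unique(prot$chain)),
              class = "StructureModel")
}

.xyz <- function(at) as.matrix(at[, c("x", "y", "z")])

## Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
.spherePoints <- function(n) {
    i <- seq_len(n) - 0.5
    z <- 1 - 2 * i / n
    r <- sqrt(pmax(0, 1 - z^2))
    phi <- i * pi * (3 - sqrt(5))
    cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Classic rolling-probe SASA: each heavy atom is inflated by the probe
#' radius and sampled with a deterministic Fibonacci sphere lattice; the
#' accessible fraction is the share of sample points not buried inside any
#' neighbouring inflated sphere. Per-residue absolute SASA is the sum over
#' the residue's atoms; relative SASA divides by the residue-type maximum
#' (\code{\link{maxAsaTable}}) and is capped at 100.
#'
#' @param model a \code{StructureModel} from \code{\link{parsePdb}}, or an
#'   atom data.frame with x, y, z, element (and chain/resno/resid for
#'   per-residue output).
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sphere sample points per atom (default 240; must be
#'   >= 16).
#' @param radii element radius table (default \code{\link{vdwRadii}}).
#' @param chain restrict to one chain (e.g. compute monomer exposure).
#' @return data.frame per residue: chain, resno, resid, aa, sasa_abs,
#'   sasa_rel. The per-atom areas are in attribute \code{atom_sasa}.
#' @export
sasaPerResidue <- function(model, probe = 1.4, n_points = 240L,
                           radii = vdwRadii(), chain = NULL) {
    if (n_points < 16L) stop("n_points must be >= 16")
    at <- if (inherits(model, "StructureModel")) model$atoms else model
    if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
    r <- radii[at$element]
    if (any(is.na(r))) {
        warning("unknown element(s): ",
                paste(unique(at$element[is.na(r)]), collapse = ", "),
                "; using carbon radius")
        r[is.na(r)] <- radii["C"]
    }
    xyz <- .xyz(at)
    R <- unname(r) + probe
    pts <- .spherePoints(n_points)
    n <- nrow(xyz)
    atom_sasa <- numeric(n)
    ## neighbour lists via cutoff on pairwise distances (blocked)
    maxR <- max(R)
    for (i in seq_len(n)) {
        d2 <- colSums((t(xyz) - xyz[i, ])^2)
        nb <- which(d2 < (R[i] + maxR)^2 & d2 > 1e-12)
        nb <- nb[sqrt(d2[nb]) < R[i] + R[nb]]
        if (length(nb) == 0L) {
            atom_sasa[i] <- 4 * pi * R[i]^2
            next
        }
        surf <- pts * R[i]
        surf <- sweep(surf, 2L, xyz[i, ], "+")
        free <- rep(TRUE, n_points)
        for (j in nb) {
            if (!any(free)) break
            dj <- colSums((t(surf[free, , drop = FALSE]) - xyz[j, ])^2)
            free[free] <- dj >= R[j]^2
        }
        atom_sasa[i] <- 4 * pi * R[i]^2 * sum(free) / n_points
    }
    key <- paste(at$chain, at$resno, sep = "|")
    idx <- !duplicated(key)
    res <- data.frame(chain = at$chain[idx], resno = at$resno[idx],
                      resid = at$resid[idx], stringsAsFactors = FALSE)
    res$aa <- unname(.AA3TO1[res$resid])
    res$sasa_abs <- as.numeric(tapply(atom_sasa, factor(key, unique(key)),
                                      sum))
    maxasa <- maxAsaTable()[res$aa]
    res$sasa_rel <- pmin(100, 100 * res$sasa_abs / maxasa)
    attr(res, "atom_sasa") <- atom_sasa
    res
}

.calpha <- function(model, chain = NULL) {
    at <- model$atoms
    ca <- at[trimws(at$elety) == "CA", , drop = FALSE]
    if (!is.null(chain)) ca <- ca[ca$chain %in% chain, , drop = FALSE]
    ca
}

#' Mean Calpha distance to a HETATM group
#'
#' For each residue, the arithmetic mean of the Euclidean distances from
#' its Calpha to every atom of the group (e.g. all FAD atoms).
#'
#' @param model a \code{StructureModel}.
#' @param group_resid HETATM residue name (e.g. "FAD"), or a coordinate
#'   matrix.
#' @param chain restrict residues to one chain.
#' @return data.frame: chain, resno, aa, d_mean. Residues lacking a Calpha
#'   are absent (flagged by omission).
#' @export
meanDistanceToGroup <- function(model, group_resid, chain = NULL) {
    if (is.matrix(group_resid)) {
        grp <- group_resid
    } else {
        het <- model$hetatms
        grp <- .xyz(het[het$resid == group_resid, , drop = FALSE])
        if (nrow(grp) == 0L)
            stop("no HETATM atoms with residue name ", group_resid)
    }
    ca <- .calpha(model, chain)
    xyz <- .xyz(ca)
    d <- vapply(seq_len(nrow(xyz)), function(i)
        mean(sqrt(colSums((t(grp) - xyz[i, ])^2))), numeric(1L))
    data.frame(chain = ca$chain, resno = ca$resno,
               aa = unname(.AA3TO1[ca$resid]), d_mean = d,
               stringsAsFactors = FALSE)
}

#' Dimer interface residues and distance to the interface
#'
#' Interface residues are those with any heavy-atom pair across the two
#' chains within \code{contact_cutoff} (a distance criterion standing in
#' for buried-surface detection). Each residue's \code{d_interface} is the
#' distance from its Calpha to the closest interface Calpha; interface
#' residues score 0.
#'
#' @param model a \code{StructureModel} with two chains.
#' @param chain_a,chain_b chain identifiers.
#' @param contact_cutoff heavy-atom contact distance, Angstrom (default 5).
#' @return list: \code{interface} (data.frame chain, resno of interface
#'   residues) and \code{distances} (data.frame chain, resno, aa,
#'   d_interface for every residue of both chains).
#' @export
interfaceResidues <- function(model, chain_a, chain_b,
                              contact_cutoff = 5.0) {
    at <- model$atoms
    A <- at[at$chain == chain_a, , drop = FALSE]
    B <- at[at$chain == chain_b, , drop = FALSE]
    if (nrow(A) == 0L || nrow(B) == 0L)
        stop("both chains must be present for interface features")
    xa <- .xyz(A); xb <- .xyz(B)
    cut2 <- contact_cutoff^2
    contact_a <- logical(nrow(A)); contact_b <- logical(nrow(B))
    for (i in seq_len(nrow(A))) {
        d2 <- colSums((t(xb) - xa[i, ])^2)
        hit <- d2 <= cut2
        if (any(hit)) {
            contact_a[i] <- TRUE
            contact_b[hit] <- TRUE
        }
    }
    iface <- unique(rbind(
        data.frame(chain = A$chain[contact_a], resno = A$resno[contact_a]),
        data.frame(chain = B$chain[contact_b], resno = B$resno[contact_b])))
    ca <- .calpha(model, c(chain_a, chain_b))
    ca_if <- merge(ca, iface, by = c("chain", "resno"))
    if (nrow(ca_if) == 0L)
        stop("no interface residues at cutoff ", contact_cutoff)
    xi <- .xyz(ca_if)
    xyz <- .xyz(ca)
    d <- vapply(seq_len(nrow(xyz)), function(i)
        min(sqrt(colSums((t(xi) - xyz[i, ])^2))), numeric(1L))
    is_if <- paste(ca$chain, ca$resno) %in% paste(iface$chain, iface$resno)
    d[is_if] <- 0
    list(interface = iface,
         distances = data.frame(chain = ca$chain, resno = ca$resno,
                                aa = unname(.AA3TO1[ca$resid]),
                                d_interface = d, stringsAsFactors = FALSE))
}

#' Distance from each residue to the active site
#'
#' The active-site centre is given explicitly: either a coordinate, or the
#' centroid of a named HETATM group (e.g. the bound substrate analogue).
#'
#' @param model a \code{StructureModel}.
#' @param center numeric length-3 coordinate, or a HETATM residue name
#'   whose atom centroid defines the centre.
#' @param chain restrict residues to one chain.
#' @return data.frame: chain, resno, aa, d_active.
#' @export
distanceToActiveSite <- function(model, center, chain = NULL) {
    if (is.character(center)) {
        het <- model$hetatms
        grp <- .xyz(het[het$resid == center, , drop = FALSE])
        if (nrow(grp) == 0L) stop("empty active-site selection: ", center)
        center <- colMeans(grp)
    }
    stopifnot(length(center) == 3L)
    ca <- .calpha(model, chain)
    xyz <- .xyz(ca)
    d <- sqrt(colSums((t(xyz) - center)^2))
    data.frame(chain = ca$chain, resno = ca$resno,
               aa = unname(.AA3TO1[ca$resid]), d_active = unname(d),
               stringsAsFactors = FALSE)
}

#' Default residue property scales
#'
#' Hydrophobicity (Kyte-Doolittle), bulkiness and polarity (Zimmerman)
#' per amino acid. These are defaults; any table with the same shape
#' (rownames = one-letter amino acids) can be supplied instead.
#' @return data.frame with columns hydrophobicity, bulkiness, polarity.
#' @export
residueScaleTable <- function() {
    aa <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")
    data.frame(row.names = aa,
        hydrophobicity = c(1.8, -4.5, -3.5, -3.5, 2.5, -3.5, -3.5, -0.4,
                           -3.2, 4.5, 3.8, -3.9, 1.9, 2.8, -1.6, -0.8,
                           -0.7, -0.9, -1.3, 4.2),
        bulkiness = c(11.50, 14.28, 12.82, 11.68, 13.46, 14.45, 13.57,
                      3.40, 13.69, 21.40, 21.40, 15.71, 16.25, 19.80,
                      17.43, 9.47, 15.77, 21.67, 18.03, 21.57),
        polarity = c(0.00, 52.00, 3.38, 49.70, 1.48, 3.53, 49.90, 0.00,
                     51.60, 0.13, 0.13, 49.50, 1.43, 0.35, 1.58, 1.67,
                     1.66, 2.10, 1.61, 0.13))
}

#' Residue property lookup and mutational deltas
#'
#' \code{residueScales} returns the configured property values of an amino
#' acid; \code{deltaScales} the mutant-minus-wild-type differences (the
#' direction is a convention: positive means the property increased upon
#' mutation).
#'
#' @param aa,wt_aa,mut_aa one-letter amino acids.
#' @param scale_table table shaped like \code{\link{residueScaleTable}}.
#' @return named numeric vector of the three properties (or their deltas).
#' @export
residueScales <- function(aa, scale_table = residueScaleTable()) {
    if (!aa %in% rownames(scale_table)) stop("unknown amino acid: ", aa)
    unlist(scale_table[aa, ])
}

#' @rdname residueScales
#' @export
deltaScales <- function(wt_aa, mut_aa, scale_table = residueScaleTable()) {
    residueScales(mut_aa, scale_table) - residueScales(wt_aa, scale_table)
}

#' Assemble the per-residue feature table
#'
#' Joins SASA, Calpha B-factor, FAD distance, interface distance and
#' active-site distance into one table keyed by PDB residue number, plus
#' wild-type property scales and (optionally) conservation.
#'
#' @param model a \code{StructureModel}.
#' @param chain chain to report features for.
#' @param fad_resid HETATM residue name of the cofactor (default "FAD");
#'   NULL to skip.
#' @param interface_chains length-2 chain ids for interface detection;
#'   NULL to skip.
#' @param active_center passed to \code{\link{distanceToActiveSite}};
#'   NULL to skip.
#' @param cons optional data.frame (resno, cons) of conservation scores
#'   0-100.
#' @param n_points SASA sphere sampling density.
#' @return data.frame: position (PDB resno), aa, sasa_rel, bfactor, and
#'   the requested distance/conservation/scale columns.
#' @export
residueFeatureTable <- function(model, chain, fad_resid = "FAD",
                                interface_chains = NULL,
                                active_center = NULL, cons = NULL,
                                n_points = 240L) {
    sasa <- sasaPerResidue(model, chain = chain, n_points = n_points)
    ca <- .calpha(model, chain)
    feat <- data.frame(position = ca$resno,
                       aa = unname(.AA3TO1[ca$resid]),
                       bfactor = ca$b, stringsAsFactors = FALSE)
    feat$sasa_rel <- sasa$sasa_rel[match(feat$position, sasa$resno)]
    if (!is.null(fad_resid)) {
        df <- meanDistanceToGroup(model, fad_resid, chain = chain)
        feat$d_fad <- df$d_mean[match(feat$position, df$resno)]
    }
    if (!is.null(interface_chains)) {
        di <- interfaceResidues(model, interface_chains[1L],
                                interface_chains[2L])$distances
        di <- di[di$chain == chain, ]
        feat$d_interface <- di$d_interface[match(feat$position, di$resno)]
    }
    if (!is.null(active_center)) {
        da <- distanceToActiveSite(model, active_center, chain = chain)
        feat$d_active <- da$d_active[match(feat$position, da$resno)]
    }
    if (!is.null(cons))
        feat$cons <- cons$cons[match(feat$position, cons$resno)]
    sc <- residueScaleTable()
    feat$wt_hydrophobicity <- sc[feat$aa, "hydrophobicity"]
    feat$wt_bulkiness <- sc[feat$aa, "bulkiness"]
    feat$wt_polarity <- sc[feat$aa, "polarity"]
    feat
}
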
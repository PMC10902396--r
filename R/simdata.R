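#' @importFrom stats quantile rnorm rpois rbinom runif median rmultinom setNames
#' @importFrom S4Vectors metadata
NULL

.BASES <- c("A", "C", "G", "T")

#' Gate specification for FACS bin placement
#'
#' Gate 1 is placed to capture a fixed fraction of a negative-control
#' (non-fluorescent) population; the remaining fluorescence range is split
#' into bins holding equal fractions of the expressing cells.
#'
#' @param neg_quantile fraction of negative-control cells captured by the
#'   first gate (default 0.99).
#' @param n_expressing_bins number of equal-occupancy bins above gate 1
#'   (default 3, for a 4-bin sort).
#' @return A list of class \code{GateSpec}.
#' @export
gateSpec <- function(neg_quantile = 0.99, n_expressing_bins = 3L) {
    stopifnot(neg_quantile > 0, neg_quantile < 1, n_expressing_bins >= 1)
    structure(list(neg_quantile = neg_quantile,
                   n_expressing_bins = as.integer(n_expressing_bins)),
              class = "GateSpec")
}

#' Configuration of a synthetic sort-seq experiment
#'
#' Parameters of the generative model: a site-saturation (NNK) library over
#' \code{wt_protein}, per-cell log2 fluorescence Normal(log2(mu_wt_fi) +
#' f_true, sigma_log2_fi), multinomial sorting into gated bins, and read
#' sampling at \code{read_depth_factor} reads per sorted cell.
#'
#' @param wt_protein wild-type amino-acid sequence (single-letter string).
#' @param n_positions number of mutagenized codons (from the N terminus);
#'   defaults to the full protein length.
#' @param barcodes_per_variant mean UMI count per variant (Poisson, min 1).
#' @param n_cells_total total cells sorted across the library.
#' @param read_depth_factor expected reads per sorted cell (default 25).
#' @param sigma_log2_fi per-cell log2-fluorescence SD (default 0.5; the
#'   assay's instrument noise is not published, so this is a free parameter).
#' @param mu_wt_fi wild-type geometric-mean fluorescence, arbitrary units.
#' @param mu_neg_fi geometric-mean fluorescence of non-displaying cells.
#' @param umi_error_rate per-base substitution probability on short reads.
#' @param conflict_rate fraction of UMIs deliberately linked to two variants
#'   in the pre-LUT records (for conflict-resolution testing).
#' @param f_missense_range range of the uniform distribution of true
#'   missense fitness (log2 scale).
#' @param f_nonsense true fitness of nonsense variants at non-C-terminal
#'   positions (default -0.7); C-terminal stops (late fraction of the
#'   sequence) are neutral.
#' @param nonsense_neutral_frac fraction of the sequence after which a stop
#'   codon no longer harms fitness (default 350/365).
#' @param seed integer RNG seed.
#' @param gates a \code{\link{gateSpec}}.
#' @param flank5,flank3 constant sequences bordering the UMI in short reads.
#' @return A list of class \code{SimConfig}.
#' @examples
#' cfg <- simConfig(wt_protein = "MKTAYIAK", n_cells_total = 1000, seed = 1)
#' @export
simConfig <- function(wt_protein,
                      n_positions = nchar(wt_protein),
                      barcodes_per_variant = 3,
                      n_cells_total = 1e5,
                      read_depth_factor = 25,
                      sigma_log2_fi = 0.5,
                      mu_wt_fi = 10000,
                      mu_neg_fi = 100,
                      umi_error_rate = 0,
                      conflict_rate = 0,
                      f_missense_range = c(-0.8, 0.3),
                      f_nonsense = -0.7,
                      nonsense_neutral_frac = 350 / 365,
                      seed = 1L,
                      gates = gateSpec(),
                      flank5 = "ACTGGCCGCT",
                      flank3 = "AGCGGTCAGT") {
    wt_protein <- toupper(wt_protein)
    if (nchar(wt_protein) < 2)
        stop("degenerate protein: length must be >= 2")
    if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", wt_protein))
        stop("wt_protein contains non-standard amino acids")
    stopifnot(n_positions >= 1, n_positions <= nchar(wt_protein),
              read_depth_factor > 0, mu_wt_fi > 0, mu_neg_fi > 0,
              umi_error_rate >= 0, umi_error_rate <= 1,
              conflict_rate >= 0, conflict_rate <= 1,
              sigma_log2_fi >= 0, inherits(gates, "GateSpec"))
    structure(list(wt_protein = wt_protein,
                   n_positions = as.integer(n_positions),
                   barcodes_per_variant = barcodes_per_variant,
                   n_cells_total = n_cells_total,
                   read_depth_factor = read_depth_factor,
                   sigma_log2_fi = sigma_log2_fi,
                   mu_wt_fi = mu_wt_fi, mu_neg_fi = mu_neg_fi,
                   umi_error_rate = umi_error_rate,
                   conflict_rate = conflict_rate,
                   f_missense_range = f_missense_range,
                   f_nonsense = f_nonsense,
                   nonsense_neutral_frac = nonsense_neutral_frac,
                   seed = as.integer(seed), gates = gates,
                   flank5 = flank5, flank3 = flank3),
              class = "SimConfig")
}

## NNK codons: N = A/C/G/T at positions 1-2, K = G/T at position 3.
.nnkCodons <- function() {
    grid <- expand.grid(b1 = .BASES, b2 = .BASES, b3 = c("G", "T"),
                        stringsAsFactors = FALSE)
    codons <- paste0(grid$b1, grid$b2, grid$b3)
    aa <- as.character(Biostrings::GENETIC_CODE[codons])
    setNames(aa, codons)
}

#' Enumerate NNK-realizable substitutions at one position
#'
#' For a wild-type amino acid, lists every amino-acid change reachable with
#' an NNK degenerate codon: up to 19 missense, one nonsense (the only NNK
#' stop is TAG), and a synonymous codon swap wherever some NNK codon other
#' than the gene's own codon encodes the same residue (every amino acid
#' except Met and Trp, whose single codons ATG/TGG are themselves NNK).
#' The wild-type codon defaults to the alphabetically first standard codon
#' of the residue, standing in for the actual gene sequence.
#'
#' @param wt_aa single-letter wild-type amino acid.
#' @param wt_codon the gene's codon at this position (optional).
#' @return data.frame with columns \code{mut_aa}, \code{mut_codon},
#'   \code{variant_class}.
#' @export
nnkSubstitutions <- function(wt_aa, wt_codon = NULL) {
    code <- .nnkCodons()
    if (is.null(wt_codon)) {
        all_codons <- Biostrings::GENETIC_CODE
        wt_codon <- sort(names(all_codons)[all_codons == wt_aa])[1L]
        if (length(wt_codon) == 0L) stop("no codon encodes ", wt_aa)
    } else if (Biostrings::GENETIC_CODE[[toupper(wt_codon)]] != wt_aa) {
        stop("wt_codon ", wt_codon, " does not encode ", wt_aa)
    }
    other <- code[names(code) != wt_codon]
    ## one representative codon per target amino acid (incl. stop and syn)
    keep <- !duplicated(other)
    df <- data.frame(mut_aa = unname(other[keep]),
                     mut_codon = names(other)[keep],
                     stringsAsFactors = FALSE)
    df$variant_class <- ifelse(df$mut_aa == "*", "nonsense",
                        ifelse(df$mut_aa == wt_aa, "synonymous", "missense"))
    df$wt_codon <- wt_codon
    df
}

.randomUmis <- function(n) {
    m <- matrix(sample(.BASES, 15L * n, replace = TRUE), nrow = n)
    apply(m, 1L, paste0, collapse = "")
}

#' Generate a barcoded NNK variant library with ground truth
#'
#' Builds the full set of NNK-realizable single-codon variants over the
#' mutagenized positions, assigns true expression/activity fitness values
#' (synonymous = 0; nonsense = \code{f_nonsense} except C-terminal stops;
#' missense uniform over \code{f_missense_range}), attaches random 15-nt
#' UMIs, and emits pre-LUT long-read records including a configurable
#' fraction of UMIs deliberately linked to two variants (as exact ties, so
#' the conflict-resolution rules must drop them).
#'
#' @param config a \code{\link{simConfig}}.
#' @param f_exp,f_act optional named vectors of true fitness per variant id,
#'   overriding the defaults.
#' @return list with \code{truth} (DataFrame: variant_id, position, wt_aa,
#'   mut_aa, variant_class, f_true_exp, f_true_act), \code{umi_map}
#'   (data.frame umi -> variant_id, with the conflicted flag), and
#'   \code{pre_lut} (data.frame of PreLutRecords).
#' @examples
#' lib <- generateLibrary(simConfig("MKTAYI", n_positions = 2, seed = 7))
#' head(as.data.frame(lib$truth))
#' @export
generateLibrary <- function(config, f_exp = NULL, f_act = NULL) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed)
    aas <- strsplit(config$wt_protein, "")[[1L]]
    rows <- lapply(seq_len(config$n_positions), function(pos) {
        sub <- nnkSubstitutions(aas[pos])
        sub$position <- pos
        sub$wt_aa <- aas[pos]
        sub
    })
    truth <- do.call(rbind, rows)
    truth$variant_id <- paste0(truth$wt_aa, truth$position, truth$mut_aa)
    ## default ground-truth fitness
    n <- nrow(truth)
    late <- truth$position > config$nonsense_neutral_frac * nchar(config$wt_protein)
    f <- runif(n, config$f_missense_range[1L], config$f_missense_range[2L])
    f[truth$variant_class == "synonymous"] <- 0
    f[truth$variant_class == "nonsense"] <- config$f_nonsense
    f[truth$variant_class == "nonsense" & late] <- 0
    truth$f_true_exp <- f
    truth$f_true_act <- f
    ## WT reference entry
    truth <- rbind(data.frame(mut_aa = aas[1L], mut_codon = NA_character_,
                              variant_class = "wt", wt_codon = NA_character_,
                              position = NA_integer_, wt_aa = aas[1L],
                              variant_id = "WT", f_true_exp = 0,
                              f_true_act = 0), truth)
    if (!is.null(f_exp))
        truth$f_true_exp[match(names(f_exp), truth$variant_id)] <- f_exp
    if (!is.null(f_act))
        truth$f_true_act[match(names(f_act), truth$variant_id)] <- f_act

    ## UMIs: Poisson(mean - 1) + 1 per variant, globally unique
    n_umi_per <- 1L + rpois(nrow(truth), max(config$barcodes_per_variant - 1, 0))
    total <- sum(n_umi_per)
    umis <- unique(.randomUmis(total + ceiling(0.01 * total) + 10L))
    while (length(umis) < total) umis <- unique(c(umis, .randomUmis(total)))
    umis <- umis[seq_len(total)]
    umi_map <- data.frame(umi = umis,
                          variant_id = rep(truth$variant_id, n_umi_per),
                          stringsAsFactors = FALSE)
    umi_map$conflicted <- runif(nrow(umi_map)) < config$conflict_rate

    pre_lut <- .emitPreLut(umi_map, truth$variant_id, config)
    list(truth = DataFrame(truth[, c("variant_id", "position", "wt_aa",
                                     "mut_aa", "wt_codon", "mut_codon",
                                     "variant_class", "f_true_exp",
                                     "f_true_act")]),
         umi_map = umi_map, pre_lut = pre_lut, config = config)
}

## Long-read records per UMI; conflicted UMIs get a tied second variant.
.emitPreLut <- function(umi_map, variant_ids, config) {
    n <- nrow(umi_map)
    support <- 1L + rpois(n, 2)
    mean_q <- round(pmax(rnorm(n, 32, 4), 5), 1)
    indels <- rpois(n, 0.2)
    rec <- data.frame(
        umi = rep(umi_map$umi, support),
        variant = rep(umi_map$variant_id, support),
        mean_q = rep(mean_q, support),
        n_indels = rep(indels, support),
        stringsAsFactors = FALSE)
    conf <- which(umi_map$conflicted)
    if (length(conf) > 0L) {
        alt <- vapply(umi_map$variant_id[conf], function(v)
            sample(setdiff(variant_ids, v), 1L), character(1L))
        extra <- data.frame(
            umi = rep(umi_map$umi[conf], support[conf]),
            variant = rep(alt, support[conf]),
            mean_q = rep(mean_q[conf], support[conf]),
            n_indels = rep(indels[conf], support[conf]),
            stringsAsFactors = FALSE)
        rec <- rbind(rec, extra)
    }
    rec$read_id <- sprintf("ccs/%06d", seq_len(nrow(rec)))
    rec[, c("read_id", "umi", "mean_q", "variant", "n_indels")]
}

#' Simulate per-cell fluorescence of a variant
#'
#' Per-cell log2 fluorescence is Normal(log2(mu_wt_fi) + f_true,
#' sigma_log2_fi), so the ratio of geometric means between a variant and the
#' wild type equals 2^f_true — the quantity the log2 fitness score inverts.
#'
#' @param f_true true log2 fitness.
#' @param n_cells number of cells (>= 1).
#' @param config a \code{\link{simConfig}}.
#' @return numeric vector of positive fluorescence values.
#' @export
simulateCellFluorescence <- function(f_true, n_cells, config) {
    stopifnot(n_cells >= 1)
    2 ^ rnorm(n_cells, log2(config$mu_wt_fi) + f_true, config$sigma_log2_fi)
}

#' Simulate a non-displaying negative-control population
#'
#' Cells with no display signal: log-normal noise around \code{mu_neg_fi},
#' emulating the secondary-antibody-only control used to set gate 1.
#'
#' @param n_cells number of cells.
#' @param config a \code{\link{simConfig}}.
#' @return numeric vector of fluorescence values.
#' @export
simulateNegativeControl <- function(n_cells, config) {
    2 ^ rnorm(n_cells, log2(config$mu_neg_fi), config$sigma_log2_fi)
}

#' Place FACS sorting gates
#'
#' Gate 1's upper threshold captures \code{neg_quantile} of the
#' negative-control population; expressing cells above it are split into
#' \code{n_expressing_bins} bins of equal occupancy (tertiles for three).
#'
#' @param negative_control_fi fluorescence of the negative-control cells.
#' @param expressing_fi fluorescence of the expressing (library) cells.
#' @param spec a \code{\link{gateSpec}}.
#' @return strictly increasing numeric thresholds (length
#'   \code{n_expressing_bins}); bin i is the interval between thresholds
#'   i-1 and i, bin 1 everything at or below threshold 1.
#' @export
placeGates <- function(negative_control_fi, expressing_fi, spec = gateSpec()) {
    stopifnot(length(negative_control_fi) > 0, length(expressing_fi) > 0)
    t1 <- unname(quantile(negative_control_fi, spec$neg_quantile))
    above <- expressing_fi[expressing_fi > t1]
    if (length(above) == 0L) stop("no expressing population above gate 1")
    k <- spec$n_expressing_bins
    th <- c(t1, unname(quantile(above, seq_len(k - 1L) / k)))
    if (any(diff(th) <= 0)) stop("gate thresholds not strictly increasing")
    th
}

#' Assign cells to sorting bins
#'
#' @param fi fluorescence values.
#' @param thresholds gate thresholds from \code{\link{placeGates}}.
#' @return integer bin index in 1..(length(thresholds) + 1); values at or
#'   below threshold 1 fall in bin 1.
#' @export
assignBins <- function(fi, thresholds) {
    findInterval(fi, thresholds, left.open = TRUE) + 1L
}

## corrupt aggregated UMI read tallies with per-base substitution errors
.corruptUmis <- function(tab, error_rate) {
    if (error_rate <= 0 || nrow(tab) == 0L) return(tab)
    p_read <- 1 - (1 - error_rate) ^ 15
    n_err <- rbinom(nrow(tab), tab$reads, p_read)
    tab$reads <- tab$reads - n_err
    idx <- rep(seq_len(nrow(tab)), n_err)
    if (length(idx) > 0L) {
        mut <- vapply(tab$umi[idx], function(u) {
            s <- strsplit(u, "")[[1L]]
            k <- max(1L, rbinom(1L, 15L, error_rate))
            pos <- sample(15L, min(k, 15L))
            s[pos] <- vapply(s[pos], function(b)
                sample(setdiff(.BASES, b), 1L), character(1L))
            paste0(s, collapse = "")
        }, character(1L))
        extra <- data.frame(umi = unname(mut), reads = 1L,
                            stringsAsFactors = FALSE)
        tab <- rbind(tab[tab$reads > 0L, ], extra)
        tab <- stats::aggregate(reads ~ umi, tab, sum)
    } else {
        tab <- tab[tab$reads > 0L, ]
    }
    tab
}

#' Sort a simulated library and sequence the bins
#'
#' Allocates cells to variants (equal shares by default), draws per-cell
#' fluorescence, sorts cells into the gated bins, and samples sequencing
#' reads: each bin receives Poisson(read_depth_factor * c_tot) reads spread
#' multinomially over its cells, each read reporting the UMI carried by its
#' cell (optionally corrupted at \code{umi_error_rate} per base).
#'
#' @param lib library from \code{\link{generateLibrary}}.
#' @param thresholds gate thresholds from \code{\link{placeGates}}.
#' @param config a \code{\link{simConfig}}.
#' @param cells_per_variant cells allocated to each variant: a scalar, or a
#'   vector along the truth table (so a wild-type reference can carry the
#'   higher abundance it has in a real library); default spreads
#'   \code{n_cells_total} equally.
#' @param replicate integer replicate index; offsets the RNG stream so two
#'   replicates are independent but jointly reproducible from
#'   \code{config$seed}.
#' @return list with \code{bins} (per-bin data.frame of umi, reads, mean_q),
#'   \code{meta} (bin_id, omega, c_tot, r_tot), and \code{cellTable}
#'   (variants x bins matrix of sorted-cell counts, the generator's own
#'   bookkeeping for oracle tests).
#' @export
simulateSortAndSequence <- function(lib, thresholds, config,
                                    cells_per_variant = NULL,
                                    replicate = 1L) {
    truth <- as.data.frame(lib$truth)
    set.seed(config$seed + 7919L * as.integer(replicate))
    nv <- nrow(truth)
    if (is.null(cells_per_variant))
        cells_per_variant <- max(1L, round(config$n_cells_total / nv))
    cells_per_variant <- rep_len(cells_per_variant, nv)
    n_bins <- length(thresholds) + 1L
    cellTable <- matrix(0L, nv, n_bins,
                        dimnames = list(truth$variant_id, NULL))
    umis_by_variant <- split(lib$umi_map$umi, lib$umi_map$variant_id)
    cell_bin <- vector("list", nv)
    cell_umi <- vector("list", nv)
    cell_fi <- vector("list", nv)
    for (i in seq_len(nv)) {
        fi <- simulateCellFluorescence(truth$f_true_exp[i],
                                       cells_per_variant[i], config)
        b <- assignBins(fi, thresholds)
        cellTable[i, ] <- tabulate(b, n_bins)
        v_umis <- umis_by_variant[[truth$variant_id[i]]]
        cell_umi[[i]] <- v_umis[sample.int(length(v_umis),
                                           cells_per_variant[i],
                                           replace = TRUE)]
        cell_bin[[i]] <- b
        cell_fi[[i]] <- fi
    }
    cell_bin <- unlist(cell_bin); cell_fi <- unlist(cell_fi)
    cell_umi <- unlist(cell_umi)
    bins <- vector("list", n_bins)
    meta <- data.frame(bin_id = seq_len(n_bins), omega = NA_real_,
                       c_tot = 0L, r_tot = 0L)
    for (b in seq_len(n_bins)) {
        in_bin <- which(cell_bin == b)
        meta$c_tot[b] <- length(in_bin)
        meta$omega[b] <- if (length(in_bin)) median(cell_fi[in_bin]) else NA
        if (length(in_bin) == 0L) {
            bins[[b]] <- data.frame(umi = character(0), reads = integer(0))
            next
        }
        r_tot <- rpois(1L, config$read_depth_factor * length(in_bin))
        reads_per_cell <- as.vector(rmultinom(1L, r_tot,
                                              rep(1, length(in_bin))))
        agg <- rowsum(reads_per_cell, cell_umi[in_bin])
        tab <- data.frame(umi = rownames(agg), reads = agg[, 1L],
                          stringsAsFactors = FALSE, row.names = NULL)
        tab <- tab[tab$reads > 0L, ]
        tab <- .corruptUmis(tab, config$umi_error_rate)
        bins[[b]] <- tab
        meta$r_tot[b] <- sum(tab$reads)
    }
    ## short-read mean quality: clean Q30 per base
    for (b in seq_len(n_bins))
        if (nrow(bins[[b]])) bins[[b]]$mean_q <- 30
    list(bins = bins, meta = meta, cellTable = cellTable)
}

#' Write a simulated experiment to disk
#'
#' Serializes the generator's outputs in the plain-text formats the pipeline
#' consumes: pre-LUT TSV, per-bin FASTQ (UMI between the configured constant
#' flanks, Phred-33 qualities), bin-metadata TSV and ground-truth TSV.
#'
#' @param lib library from \code{\link{generateLibrary}}.
#' @param sortrun result of \code{\link{simulateSortAndSequence}}.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix (default "sim").
#' @return invisibly, the named vector of paths written.
#' @export
writeSimulation <- function(lib, sortrun, dir, prefix = "sim") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cfg <- lib$config
    paths <- c(pre_lut = file.path(dir, paste0(prefix, "_pre_lut.tsv")),
               truth = file.path(dir, paste0(prefix, "_truth.tsv")),
               meta = file.path(dir, paste0(prefix, "_bins.tsv")))
    utils::write.table(lib$pre_lut, paths["pre_lut"], sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(as.data.frame(lib$truth), paths["truth"], sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(sortrun$meta, paths["meta"], sep = "\t",
                       row.names = FALSE, quote = FALSE)
    for (b in seq_along(sortrun$bins)) {
        tab <- sortrun$bins[[b]]
        fq <- file.path(dir, sprintf("%s_bin%d.fastq", prefix, b))
        paths[paste0("fastq_bin", b)] <- fq
        if (nrow(tab) == 0L) { file.create(fq); next }
        seqs <- rep(paste0(cfg$flank5, tab$umi, cfg$flank3), tab$reads)
        ids <- sprintf("read%07d", seq_along(seqs))
        qual <- vapply(nchar(seqs), function(w)
            strrep(rawToChar(as.raw(33L + 30L)), w), character(1L))
        writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), fq)
    }
    invisible(paths)
}
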
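#' Convert reads to sorted-cell numbers
#'
#' Reads are proportional evidence of cells: the cells of variant v in a
#' bin are c_v = r_v * c_tot / r_tot. The result is kept fractional;
#' rounding would bias low-count variants.
#'
#' @param r_v reads of the variant in the bin.
#' @param r_tot total assigned reads of the bin.
#' @param c_tot cells sorted into the bin.
#' @return fractional cell count(s); 0 with a warning when r_tot is 0.
#' @examples
#' readsToCells(10, 100, 50)  # 5
#' @export
readsToCells <- function(r_v, r_tot, c_tot) {
    stopifnot(c_tot >= 0, all(r_v >= 0))
    if (r_tot == 0) {
        warning("r_tot = 0: cell conversion undefined, returning 0")
        return(rep(0, length(r_v)))
    }
    r_v * c_tot / r_tot
}

#' Bin-median-weighted mean fluorescence (beta)
#'
#' The expected fluorescence of a variant across the sort: the weighted
#' mean of its per-bin cell numbers with each bin's median fluorescence
#' omega as the weight, beta = sum(omega_i c_vi) / sum(c_vi). Always lies
#' within [min(omega), max(omega)].
#'
#' @param c_v per-bin cell numbers of the variant.
#' @param omega per-bin median fluorescence (> 0).
#' @return beta, or NA if the variant has no cells (it is unobserved).
#' @examples
#' weightedMeanBeta(c(1, 1), c(100, 200))  # 150
#' @export
weightedMeanBeta <- function(c_v, omega) {
    stopifnot(length(c_v) == length(omega), all(omega > 0), all(c_v >= 0))
    tot <- sum(c_v)
    if (tot == 0) return(NA_real_)
    sum(omega * c_v) / tot
}

#' Log2 fitness score
#'
#' F = log2(beta_v / beta_wt): 0 for wild-type-like variants, -1 for a
#' halving of weighted mean fluorescence.
#'
#' @param beta_v variant's weighted mean fluorescence (> 0).
#' @param beta_wt wild-type's weighted mean fluorescence (> 0).
#' @return F, or NA (flagged) if either beta is not positive.
#' @export
fitnessScore <- function(beta_v, beta_wt) {
    out <- rep(NA_real_, length(beta_v))
    ok <- !is.na(beta_v) & beta_v > 0 & beta_wt > 0
    out[ok] <- log2(beta_v[ok] / beta_wt)
    out
}

#' Score every variant in a BinCounts object
#'
#' Runs the full per-replicate estimator: reads to cells per bin, beta per
#' variant, and F against the wild-type reference present in the same
#' table.
#'
#' @param bc a \linkS4class{BinCounts}.
#' @param wt variant id of the wild-type reference (default "WT").
#' @return \link[S4Vectors]{DataFrame} with variant_id, beta, F,
#'   cells_total; unobserved variants (no cells in any bin) are excluded.
#' @export
fitnessScores <- function(bc, wt = "WT") {
    meta <- binMeta(bc)
    reads <- readCounts(bc)
    if (!wt %in% rownames(reads))
        stop("wild-type reference '", wt, "' not present in counts")
    ## empty bins (no sorted cells) carry no information
    keep <- meta$c_tot > 0 & !is.na(meta$omega)
    meta <- meta[keep, , drop = FALSE]
    reads <- reads[, keep, drop = FALSE]
    cells <- reads
    for (b in seq_len(ncol(reads)))
        cells[, b] <- if (meta$r_tot[b] > 0)
            readsToCells(reads[, b], meta$r_tot[b], meta$c_tot[b])
        else 0
    beta <- apply(cells, 1L, weightedMeanBeta, omega = meta$omega)
    fit <- DataFrame(variant_id = rownames(reads), beta = unname(beta),
                     F = unname(fitnessScore(beta, beta[[wt]])),
                     cells_total = unname(rowSums(cells)))
    fit[!is.na(fit$beta), ]
}

#' Consensus fitness across replicates
#'
#' The final score is the cell-weighted mean of per-replicate scores,
#' F_fin = sum(F_vj c_vj) / sum(c_vj), where c_vj is the variant's total
#' reads-derived cell count in replicate j.
#'
#' @param reps list of per-replicate DataFrames from
#'   \code{\link{fitnessScores}}.
#' @return DataFrame with variant_id, F_fin, cells_total, n_reps, plus the
#'   per-replicate F and cell columns. Variants unobserved in every
#'   replicate are excluded.
#' @export
consensusScores <- function(reps) {
    stopifnot(length(reps) >= 1)
    ids <- sort(unique(unlist(lapply(reps, function(r) r$variant_id))))
    Fm <- Cm <- matrix(NA_real_, length(ids), length(reps),
                       dimnames = list(ids, paste0("rep", seq_along(reps))))
    for (j in seq_along(reps)) {
        r <- reps[[j]]
        Fm[r$variant_id, j] <- r$F
        Cm[r$variant_id, j] <- r$cells_total
    }
    w <- Cm
    w[is.na(Fm)] <- NA
    F_fin <- rowSums(Fm * w, na.rm = TRUE) / rowSums(w, na.rm = TRUE)
    out <- DataFrame(variant_id = ids, F_fin = unname(F_fin),
                     cells_total = unname(rowSums(Cm, na.rm = TRUE)),
                     n_reps = unname(rowSums(!is.na(Fm))))
    for (j in seq_along(reps)) {
        out[[paste0("F_rep", j)]] <- unname(Fm[, j])
        out[[paste0("cells_rep", j)]] <- unname(Cm[, j])
    }
    out[is.finite(out$F_fin), ]
}

#' Classify a codon substitution
#'
#' @param wt_codon,mut_codon standard-code DNA codons.
#' @return "synonymous", "nonsense" or "missense" (vectorized).
#' @examples
#' classifyVariant("GCT", "GCC")  # synonymous
#' classifyVariant("GCT", "TAG")  # nonsense
#' @export
classifyVariant <- function(wt_codon, mut_codon) {
    code <- Biostrings::GENETIC_CODE
    wt_aa <- code[toupper(wt_codon)]
    mut_aa <- code[toupper(mut_codon)]
    if (any(is.na(wt_aa)) || any(is.na(mut_aa)))
        stop("invalid codon")
    unname(ifelse(mut_aa == "*", "nonsense",
           ifelse(mut_aa == wt_aa, "synonymous", "missense")))
}

#' Neutral fitness range from synonymous variants
#'
#' Synonymous mutations leave the protein unchanged, so their fitness
#' distribution defines the assay's neutral range; variants within
#' mean +/- k*sd are indistinguishable from wild type.
#'
#' @param f_syn fitness scores of synonymous variants (>= 2).
#' @param k multiplier of the SD defining neutrality (default 1, matching
#'   the mean +/- SD convention).
#' @return list(mean, sd, lower, upper).
#' @export
neutralRange <- function(f_syn, k = 1) {
    f_syn <- f_syn[is.finite(f_syn)]
    if (length(f_syn) < 2) stop("need >= 2 synonymous scores")
    m <- mean(f_syn); s <- stats::sd(f_syn)
    list(mean = m, sd = s, lower = m - k * s, upper = m + k * s)
}

#' Single-clone expression score from gate summaries
#'
#' For clones assayed individually by flow cytometry: beta is the weighted
#' mean of per-gate cell percentages with the gate median fluorescence as
#' weight, and the score is the plain (not log2) ratio beta_v / beta_wt.
#'
#' @param omega_v,pct_v gate medians and percent of cells per gate for the
#'   variant.
#' @param omega_wt,pct_wt the same for the wild type.
#' @return list(beta_v, beta_wt, score).
#' @export
singleCloneExpression <- function(omega_v, pct_v, omega_wt, pct_wt) {
    b <- function(omega, pct) {
        stopifnot(length(omega) == length(pct), all(pct >= 0))
        if (sum(pct) <= 0) stop("gate percentages sum to zero")
        sum(omega * pct) / sum(pct)
    }
    bv <- b(omega_v, pct_v); bw <- b(omega_wt, pct_wt)
    list(beta_v = bv, beta_wt = bw, score = bv / bw)
}

#' Expression floor from nonsense statistics
#'
#' The floor below which variants are considered unexpressed: the mean plus
#' one SD of the nonsense (stop codon) expression fitness distribution,
#' computed from the data at hand.
#'
#' @param f_nonsense expression fitness of nonsense variants.
#' @return numeric floor.
#' @export
nonsenseExpressionFloor <- function(f_nonsense) {
    f <- f_nonsense[is.finite(f_nonsense)]
    if (length(f) < 2) stop("need >= 2 nonsense scores")
    mean(f) + stats::sd(f)
}

#' Normalized activity
#'
#' Deconvolutes catalytic activity from expression: na = 2^F_act / 2^F_exp,
#' the non-logarithmic activity fitness normalized by the non-logarithmic
#' expression fitness. Variants whose expression fitness does not clear the
#' floor (nonsense-derived by default) are excluded; na > 1 flags
#' expression-independent activity enhancement.
#'
#' @param F_act,F_exp log2 activity and expression fitness (vectors).
#' @param floor expression floor (e.g. from
#'   \code{\link{nonsenseExpressionFloor}}).
#' @return DataFrame with na and passes_expression_floor; rows with
#'   undefined fitness are excluded.
#' @examples
#' normalizedActivity(0, -1, floor = -2)$na  # 2
#' @export
normalizedActivity <- function(F_act, F_exp, floor) {
    ok <- is.finite(F_act) & is.finite(F_exp)
    F_act <- F_act[ok]; F_exp <- F_exp[ok]
    passes <- F_exp > floor
    DataFrame(na = ifelse(passes, 2 ^ (F_act - F_exp), NA_real_),
              passes_expression_floor = passes)
}

#' Filter variants by total cell support
#'
#' Retains variants represented by at least \code{min_cells} total cells
#' summed over replicates (default 10).
#'
#' @param records DataFrame with a \code{cells_total} column.
#' @param min_cells inclusive threshold (default 10).
#' @return filtered records.
#' @export
replicateSupportFilter <- function(records, min_cells = 10) {
    records[records$cells_total >= min_cells, , drop = FALSE]
}
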
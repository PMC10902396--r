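## Joint analysis of fitness and structural feature tables: per-position
## summaries, correlations, subgroup contrasts, conserved-site screens,
## heatmap export and activity-hotspot ranking.

#' Number of mutagenized positions
#'
#' Inclusive codon range of a site-saturation library (e.g. codons 2-365
#' give 364 positions).
#'
#' @param first_codon,last_codon inclusive codon bounds.
#' @return integer count.
#' @export
mutagenizedPositionCount <- function(first_codon, last_codon) {
    stopifnot(last_codon >= first_codon)
    as.integer(last_codon - first_codon + 1L)
}

#' Missense library coverage
#'
#' Percent of all possible single amino-acid substitutions observed:
#' 100 * n_observed / (n_positions * substitutions per position).
#'
#' @param n_observed missense variants observed.
#' @param n_positions mutagenized positions.
#' @param subs_per_position possible substitutions per position
#'   (default 19).
#' @return percentage.
#' @export
substitutionCoverage <- function(n_observed, n_positions,
                                 subs_per_position = 19L) {
    100 * n_observed / (n_positions * subs_per_position)
}

#' Join fitness with per-position features
#'
#' One row per variant, carrying its scores and its position's structural
#' features. Positions present in the fitness table but missing from the
#' feature table are kept and flagged, never silently dropped.
#'
#' @param fitness DataFrame/data.frame with variant_id, position,
#'   variant_class and fitness columns (e.g. F_exp, F_act, na).
#' @param features data.frame keyed by \code{position} (see
#'   \code{\link{residueFeatureTable}}).
#' @param position_map optional data.frame (library_position,
#'   structure_position) reconciling codon numbering with PDB numbering.
#' @return data.frame with a logical \code{has_features} column.
#' @export
joinFitnessFeatures <- function(fitness, features, position_map = NULL) {
    fit <- as.data.frame(fitness)
    pos <- fit$position
    if (!is.null(position_map))
        pos <- position_map$structure_position[
            match(pos, position_map$library_position)]
    idx <- match(pos, features$position)
    out <- cbind(fit, features[idx, setdiff(colnames(features),
                                            c("position", "aa")),
                               drop = FALSE])
    out$has_features <- !is.na(idx)
    rownames(out) <- NULL
    out
}

#' Per-position fitness summaries
#'
#' Arithmetic means over missense variants only (nonsense and synonymous
#' are excluded from position averages), with the variant count per
#' position.
#'
#' @param joined table from \code{\link{joinFitnessFeatures}} (or any
#'   data.frame with position, variant_class and score columns).
#' @param score_cols columns to average (those present are used).
#' @return data.frame: position, mean_<col> and n_<col> per score column.
#' @export
positionSummaries <- function(joined,
                              score_cols = c("F_exp", "F_act", "na")) {
    stopifnot(nrow(joined) > 0)
    mis <- joined[joined$variant_class == "missense", , drop = FALSE]
    score_cols <- intersect(score_cols, colnames(mis))
    positions <- sort(unique(mis$position))
    out <- data.frame(position = positions)
    for (col in score_cols) {
        v <- mis[[col]]
        ok <- is.finite(v)
        m <- tapply(v[ok], factor(mis$position[ok], positions), mean)
        n <- tapply(v[ok], factor(mis$position[ok], positions), length)
        out[[paste0("mean_", col)]] <- as.numeric(m)
        out[[paste0("n_", col)]] <- as.integer(ifelse(is.na(n), 0L, n))
    }
    out[rowSums(out[, grep("^n_", colnames(out)), drop = FALSE]) > 0L, ]
}

#' Correlation with two-sided p value
#'
#' Pearson or Spearman correlation with pairwise-complete deletion,
#' reporting coefficient, two-sided p and the n actually used.
#'
#' @param x,y numeric vectors.
#' @param method "pearson" or "spearman".
#' @return list(estimate, p_value, n, method).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
    method <- match.arg(method)
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L) stop("need >= 3 complete pairs")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(list(estimate = NA_real_, p_value = NA_real_,
                    n = length(x), method = method, degenerate = TRUE))
    ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                           alternative = "two.sided",
                                           exact = FALSE))
    list(estimate = unname(ct$estimate), p_value = ct$p.value,
         n = length(x), method = method)
}

#' Subgroup fitness contrast
#'
#' Mean score inside a feature-defined subgroup of single missense
#' variants versus the whole set, with the percent difference reported
#' against the absolute overall mean: 100 * (sub - all) / |all|.
#'
#' @param joined joined variant table.
#' @param mask logical vector (a feature predicate evaluated by the
#'   caller, e.g. \code{joined$d_fad < 4}).
#' @param score_col score column (default "F_act").
#' @param missense_only restrict to missense variants (default TRUE).
#' @return list(subgroup_mean, overall_mean, percent_difference,
#'   n_subgroup, n_overall).
#' @export
subgroupContrast <- function(joined, mask, score_col = "F_act",
                             missense_only = TRUE) {
    stopifnot(length(mask) == nrow(joined))
    keep <- is.finite(joined[[score_col]])
    if (missense_only) keep <- keep & joined$variant_class == "missense"
    v <- joined[[score_col]][keep]
    m <- mask[keep] & !is.na(mask[keep])
    if (!any(m)) stop("empty subgroup")
    sub <- mean(v[m]); all <- mean(v)
    list(subgroup_mean = sub, overall_mean = all,
         percent_difference = 100 * (sub - all) / abs(all),
         n_subgroup = sum(m), n_overall = length(v))
}

#' Conserved-site screen
#'
#' Selects positions at or above a conservation threshold, reports the
#' subset with mean expression score above a floor, and the correlation
#' between mean expression score and distance to the active site over the
#' conserved set.
#'
#' @param pos_summary per-position table with mean_F_exp, cons and
#'   (optionally) d_active columns.
#' @param cons_threshold conservation cutoff (default 100).
#' @param exp_floor expression-score floor (default 0).
#' @return list(conserved, positive, cor_exp_dactive).
#' @export
conservedSiteScreen <- function(pos_summary, cons_threshold = 100,
                                exp_floor = 0) {
    stopifnot("cons" %in% colnames(pos_summary))
    conserved <- pos_summary[!is.na(pos_summary$cons) &
                                 pos_summary$cons >= cons_threshold, ,
                             drop = FALSE]
    positive <- conserved[is.finite(conserved$mean_F_exp) &
                              conserved$mean_F_exp > exp_floor, ,
                          drop = FALSE]
    cc <- NULL
    if ("d_active" %in% colnames(conserved) && nrow(conserved) >= 3L)
        cc <- tryCatch(correlate(conserved$mean_F_exp, conserved$d_active),
                       error = function(e) NULL)
    list(conserved = conserved, positive = positive, cor_exp_dactive = cc)
}

#' Activity hotspot ranking
#'
#' Ranks variants by normalized activity (descending; ties broken by
#' variant id for determinism), takes the top \code{top_n}, counts
#' variants per position within that subset, and returns the \code{k} most
#' frequent positions.
#'
#' @param joined variant table with variant_id, position and na columns.
#' @param top_n subset size (default 1000); if fewer variants are
#'   eligible, all are used with a warning.
#' @param k number of hotspot positions to return (default 6).
#' @return data.frame: position, frequency, ranked by frequency (ties by
#'   position); attribute \code{top_variants} holds the subset.
#' @export
hotspotRanking <- function(joined, top_n = 1000L, k = 6L) {
    elig <- joined[is.finite(joined$na), , drop = FALSE]
    if (nrow(elig) == 0L) stop("no variants with normalized activity")
    if (nrow(elig) < top_n) {
        warning("only ", nrow(elig), " eligible variants; using all")
        top_n <- nrow(elig)
    }
    ord <- order(-elig$na, elig$variant_id)
    top <- elig[ord[seq_len(top_n)], , drop = FALSE]
    tab <- table(top$position)
    freq <- data.frame(position = as.integer(names(tab)),
                       frequency = as.integer(tab))
    freq <- freq[order(-freq$frequency, freq$position), , drop = FALSE]
    out <- utils::head(freq, k)
    rownames(out) <- NULL
    attr(out, "top_variants") <- top
    out
}

#' Position x amino-acid fitness matrix
#'
#' The landscape heatmap matrix: rows are the 20 amino acids plus stop
#' ("*"), columns the mutagenized positions; unobserved combinations are
#' NA, never 0. Synonymous variants fill the wild-type residue's cell.
#'
#' @param records variant table with position, mut_aa and a score column;
#'   must be consensus-scored (one row per position/mut_aa).
#' @param score_col score column (default "F_fin").
#' @return numeric matrix (21 x positions) with a \code{counts} attribute
#'   (variants per position).
#' @export
heatmapMatrix <- function(records, score_col = "F_fin") {
    rec <- as.data.frame(records)
    rec <- rec[!is.na(rec$position), , drop = FALSE]
    if (anyDuplicated(rec[, c("position", "mut_aa")]))
        stop("duplicate (position, mut_aa) rows: consensus-scored input required")
    aas <- c("A","C","D","E","F","G","H","I","K","L",
             "M","N","P","Q","R","S","T","V","W","Y","*")
    positions <- sort(unique(rec$position))
    m <- matrix(NA_real_, length(aas), length(positions),
                dimnames = list(aas, positions))
    m[cbind(match(rec$mut_aa, aas), match(rec$position, positions))] <-
        rec[[score_col]]
    attr(m, "counts") <- colSums(!is.na(m))
    m
}

#' Write / read a heatmap matrix as CSV
#'
#' @param m matrix from \code{\link{heatmapMatrix}}.
#' @param path CSV path.
#' @return \code{readHeatmap}: the matrix (losslessly round-tripped).
#' @export
writeHeatmap <- function(m, path) {
    utils::write.csv(as.data.frame(m, check.names = FALSE), path,
                     row.names = TRUE)
    invisible(path)
}

#' @rdname writeHeatmap
#' @export
readHeatmap <- function(path) {
    df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    as.matrix(df)
}
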
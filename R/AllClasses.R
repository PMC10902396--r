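#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
NULL

#' LookupTable: UMI to variant map
#'
#' The genotype/phenotype link of a barcoded sort-seq experiment: each 15-nt
#' unique molecular identifier (UMI) maps to exactly one variant call, with
#' provenance (number of supporting long reads, mean barcode quality) and a
#' flag marking calls outside the mutagenized region.
#'
#' @slot entries A \link[S4Vectors]{DataFrame} with columns \code{umi},
#'   \code{variant}, \code{support_reads}, \code{mean_q},
#'   \code{in_target_region}.
#'
#' @seealso \code{\link{resolveConflicts}} to build one from pre-LUT records,
#'   \code{\link{readLut}} / \code{\link{writeLut}} for TSV round-trips.
#' @export
setClass("LookupTable", slots = c(entries = "DataFrame"))

.LUT_COLS <- c("umi", "variant", "support_reads", "mean_q", "in_target_region")

setValidity("LookupTable", function(object) {
    e <- object@entries
    if (!all(.LUT_COLS %in% colnames(e)))
        return(paste("entries must have columns:",
                     paste(.LUT_COLS, collapse = ", ")))
    if (anyDuplicated(e$umi))
        return("duplicated UMIs in LookupTable")
    if (nrow(e) > 0L) {
        if (any(nchar(e$umi) != 15L))
            return("all UMIs must be exactly 15 nt")
        if (any(grepl("[^ACGT]", e$umi)))
            return("UMIs must be over {A,C,G,T} (no N)")
    }
    TRUE
})

#' Construct a LookupTable
#'
#' @param umi character vector of 15-nt barcodes.
#' @param variant character vector of variant identifiers (or
#'   \code{"OUT_OF_RANGE"}).
#' @param support_reads integer vector, long reads supporting each link.
#' @param mean_q numeric vector, mean Phred quality of the barcode.
#' @param in_target_region logical; \code{FALSE} for calls outside the
#'   mutagenized region (kept in the table, filtered at counting stage).
#' @return A \linkS4class{LookupTable}.
#' @examples
#' LookupTable(umi = strrep("A", 15), variant = "WT")
#' @export
LookupTable <- function(umi = character(), variant = character(),
                        support_reads = rep(1L, length(umi)),
                        mean_q = rep(NA_real_, length(umi)),
                        in_target_region = rep(TRUE, length(umi))) {
    new("LookupTable", entries = DataFrame(
        umi = as.character(umi), variant = as.character(variant),
        support_reads = as.integer(support_reads),
        mean_q = as.numeric(mean_q),
        in_target_region = as.logical(in_target_region)))
}

#' @describeIn LookupTable-class number of UMIs in the table
#' @param x a LookupTable
#' @export
setMethod("length", "LookupTable", function(x) nrow(x@entries))

setMethod("show", "LookupTable", function(object) {
    e <- object@entries
    cat("LookupTable with", nrow(e), "UMIs ->",
        length(unique(e$variant)), "variants\n")
    if (nrow(e) > 0L) {
        n_out <- sum(!e$in_target_region)
        if (n_out > 0L) cat("  ", n_out, "UMI(s) flagged out of target region\n")
        show(utils::head(as.data.frame(e), 4L))
    }
})

#' BinCounts: variants x FACS-bins read counts
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} whose \code{"reads"}
#' assay holds per-variant read counts in each sorting bin, and whose
#' \code{colData} carries the bin metadata needed by the fitness estimator:
#' \code{omega} (median fluorescence of the cells sorted into the bin),
#' \code{c_tot} (cells sorted) and \code{r_tot} (total assigned reads).
#'
#' @seealso \code{\link{binCountsFromReads}}, \code{\link{fitnessScores}}
#' @export
setClass("BinCounts", contains = "SummarizedExperiment")

setValidity("BinCounts", function(object) {
    cd <- SummarizedExperiment::colData(object)
    need <- c("omega", "c_tot", "r_tot")
    if (!all(need %in% colnames(cd)))
        return("colData must have omega, c_tot, r_tot")
    if (any(cd$omega <= 0, na.rm = TRUE)) return("omega must be > 0")
    if (any(is.na(cd$omega) & cd$c_tot > 0))
        return("omega missing for a non-empty bin")
    if (any(cd$c_tot < 0) || any(cd$r_tot < 0))
        return("c_tot and r_tot must be >= 0")
    if (!"reads" %in% SummarizedExperiment::assayNames(object))
        return("assay 'reads' missing")
    if (any(SummarizedExperiment::assay(object, "reads") < 0))
        return("read counts must be >= 0")
    TRUE
})

#' Construct a BinCounts object
#'
#' @param reads numeric matrix, variants in rows (rownames = variant ids),
#'   bins in columns.
#' @param binData data.frame or DataFrame with one row per bin and columns
#'   \code{omega}, \code{c_tot}, \code{r_tot}.
#' @return A \linkS4class{BinCounts}.
#' @examples
#' m <- matrix(c(5, 0, 2, 3), 2, 2, dimnames = list(c("WT", "A2G"), NULL))
#' bc <- BinCounts(m, data.frame(omega = c(100, 1000),
#'                               c_tot = c(10, 10), r_tot = c(5, 5)))
#' @export
BinCounts <- function(reads, binData) {
    binData <- as(binData, "DataFrame")
    if (is.null(binData$bin_id)) binData$bin_id <- seq_len(nrow(binData))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(reads = reads), colData = binData)
    colnames(se) <- paste0("bin", binData$bin_id)
    new("BinCounts", se)
}

#' @describeIn BinCounts-class the variants x bins read-count matrix
#' @param object a BinCounts
#' @export
setGeneric("readCounts", function(object) standardGeneric("readCounts"))

#' @rdname BinCounts-class
#' @export
setMethod("readCounts", "BinCounts",
    function(object) SummarizedExperiment::assay(object, "reads"))

#' @describeIn BinCounts-class per-bin metadata (omega, c_tot, r_tot)
#' @export
setGeneric("binMeta", function(object) standardGeneric("binMeta"))

#' @rdname BinCounts-class
#' @export
setMethod("binMeta", "BinCounts",
    function(object) SummarizedExperiment::colData(object))
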
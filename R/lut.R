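#' Read pre-LUT records
#'
#' Pre-LUT records are the digested long-read alignments linking each UMI to
#' a variant call: one row per read with the barcode sequence, its mean
#' Phred quality, the variant call (an identifier, \code{"WT"}, or
#' \code{"OUT_OF_RANGE"}) and the read's indel count.
#'
#' @param path TSV with columns read_id, umi, mean_q, variant, n_indels.
#' @return data.frame of records.
#' @export
readPreLut <- function(path) {
    rec <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("read_id", "umi", "mean_q", "variant", "n_indels")
    if (!all(need %in% colnames(rec)))
        stop("pre-LUT file must have columns: ", paste(need, collapse = ", "))
    rec
}

#' Filter pre-LUT records by barcode quality
#'
#' Retains records whose UMI mean Phred quality is at or above the
#' threshold (default Q20), preserving input order.
#'
#' @param records data.frame of pre-LUT records.
#' @param min_mean_q Phred threshold (default 20); the comparison is
#'   inclusive (\code{>=}).
#' @return filtered data.frame.
#' @export
filterRecords <- function(records, min_mean_q = 20) {
    stopifnot(min_mean_q >= 0)
    records[records$mean_q >= min_mean_q, , drop = FALSE]
}

#' Resolve barcode conflicts into a LookupTable
#'
#' Identical UMIs linked to different variant calls are adjudicated by, in
#' order: (1) strictly more supporting reads; (2) strictly higher maximum
#' mean barcode quality; (3) strictly fewer minimum indels in the
#' supporting reads. If no criterion separates the leading calls the UMI is
#' removed entirely. UMIs whose length is not 15 nt (or that contain N) are
#' dropped; calls of \code{"OUT_OF_RANGE"} are kept but flagged
#' \code{in_target_region = FALSE} for downstream filtering.
#'
#' @param records pre-filtered pre-LUT records (see
#'   \code{\link{filterRecords}}).
#' @return A \linkS4class{LookupTable}. Empty input gives an empty table.
#' @examples
#' rec <- data.frame(read_id = c("r1", "r2", "r3"),
#'                   umi = strrep("A", 15), mean_q = 30,
#'                   variant = c("A2G", "A2G", "A2T"), n_indels = 0)
#' resolveConflicts(rec)  # A2G wins on support
#' @export
resolveConflicts <- function(records) {
    if (nrow(records) == 0L) return(LookupTable())
    ok <- nchar(records$umi) == 15L & !grepl("[^ACGT]", records$umi)
    records <- records[ok, , drop = FALSE]
    if (nrow(records) == 0L) return(LookupTable())
    ## per (umi, variant): support, best quality, fewest indels
    key <- paste(records$umi, records$variant, sep = "\r")
    sp <- split(seq_len(nrow(records)), key)
    agg <- data.frame(
        umi = records$umi[vapply(sp, `[`, 1L, 1L)],
        variant = records$variant[vapply(sp, `[`, 1L, 1L)],
        support = lengths(sp),
        max_q = vapply(sp, function(i) max(records$mean_q[i]), numeric(1L)),
        min_indels = vapply(sp, function(i) min(records$n_indels[i]),
                            numeric(1L)),
        stringsAsFactors = FALSE)
    criteria <- list(function(a) a$support, function(a) a$max_q,
                     function(a) -a$min_indels)
    picked <- lapply(split(seq_len(nrow(agg)), agg$umi), function(i) {
        a <- agg[i, , drop = FALSE]
        for (crit_of in criteria) {
            if (length(i) == 1L) return(i)
            crit <- crit_of(a)
            top <- which(crit == max(crit))
            i <- i[top]; a <- a[top, , drop = FALSE]
        }
        if (length(i) == 1L) i else integer(0)  # full tie: drop the UMI
    })
    keep <- unlist(picked, use.names = FALSE)
    if (length(keep) == 0L) return(LookupTable())
    a <- agg[keep, ]
    a <- a[order(a$umi), ]
    LookupTable(umi = a$umi, variant = a$variant,
                support_reads = a$support, mean_q = a$max_q,
                in_target_region = a$variant != "OUT_OF_RANGE")
}

#' Build a LookupTable from pre-LUT records
#'
#' Convenience wrapper: quality filter then conflict resolution.
#'
#' @param records pre-LUT records (data.frame or TSV path).
#' @param min_mean_q Phred threshold (default 20).
#' @return A \linkS4class{LookupTable}.
#' @export
buildLut <- function(records, min_mean_q = 20) {
    if (is.character(records)) records <- readPreLut(records)
    resolveConflicts(filterRecords(records, min_mean_q))
}

#' Write / read a LookupTable as TSV
#'
#' The TSV round-trip is lossless; \code{readLut} re-validates the table
#' invariants (unique 15-nt UMIs over A/C/G/T) and reports the offending
#' line on malformed input.
#'
#' @param table a \linkS4class{LookupTable}.
#' @param path file path.
#' @return \code{writeLut}: invisibly, the path. \code{readLut}: a
#'   \linkS4class{LookupTable}.
#' @export
writeLut <- function(table, path) {
    stopifnot(is(table, "LookupTable"))
    utils::write.table(as.data.frame(table@entries), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeLut
#' @export
readLut <- function(path) {
    e <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(.LUT_COLS %in% colnames(e)))
        stop("malformed LUT header in ", path)
    bad <- which(nchar(e$umi) != 15L | grepl("[^ACGT]", e$umi))
    if (length(bad) > 0L)
        stop("malformed LUT row at line ", bad[1L] + 1L,
             ": UMI must be 15 nt over A/C/G/T")
    LookupTable(umi = e$umi, variant = e$variant,
                support_reads = e$support_reads, mean_q = e$mean_q,
                in_target_region = e$in_target_region)
}

#' Look up variants for a set of UMIs
#'
#' @param lut a \linkS4class{LookupTable}.
#' @param umi character vector.
#' @param in_target_only drop calls flagged outside the mutagenized region.
#' @return character vector of variant ids, NA where absent.
#' @export
lookupVariant <- function(lut, umi, in_target_only = FALSE) {
    e <- lut@entries
    if (in_target_only) e <- e[e$in_target_region, , drop = FALSE]
    e$variant[match(umi, e$umi)]
}
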
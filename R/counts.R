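#' UMI flank specification
#'
#' Short reads carry the 15-nt UMI between two constant sequences; the UMI
#' is located by anchored flank matching with a small mismatch budget
#' rather than by alignment.
#'
#' @param flank5,flank3 constant sequences 5' and 3' of the UMI.
#' @param max_mismatch allowed substitutions per flank (default 1).
#' @return list of class \code{FlankSpec}.
#' @export
flankSpec <- function(flank5, flank3, max_mismatch = 1L) {
    stopifnot(nchar(flank5) >= 4, nchar(flank3) >= 4, max_mismatch >= 0)
    structure(list(flank5 = flank5, flank3 = flank3,
                   max_mismatch = as.integer(max_mismatch)),
              class = "FlankSpec")
}

#' Extract the UMI from one read
#'
#' Scans for the 5' flank (allowing up to \code{max_mismatch}
#' substitutions), then for the 3' flank downstream of it, and returns the
#' intervening sub-sequence with its mean Phred quality. A missing flank is
#' signalled by NULL, not an error.
#'
#' @param seq read sequence (character).
#' @param qual Phred-33 quality string of the same length (or NULL).
#' @param spec a \code{\link{flankSpec}}.
#' @return list(umi, mean_q) or NULL if either flank is not found.
#' @export
extractUmi <- function(seq, qual = NULL, spec) {
    s <- Biostrings::DNAString(seq)
    m5 <- Biostrings::matchPattern(spec$flank5, s,
                                   max.mismatch = spec$max_mismatch)
    if (length(m5) == 0L) return(NULL)
    start5 <- Biostrings::end(m5)[1L] + 1L
    rest <- Biostrings::subseq(s, start5)
    m3 <- Biostrings::matchPattern(spec$flank3, rest,
                                   max.mismatch = spec$max_mismatch)
    if (length(m3) == 0L) return(NULL)
    end3 <- start5 + Biostrings::start(m3)[1L] - 2L
    if (end3 < start5) return(list(umi = "", mean_q = NA_real_))
    umi <- as.character(Biostrings::subseq(s, start5, end3))
    mean_q <- NA_real_
    if (!is.null(qual)) {
        q <- utf8ToInt(substr(qual, start5, end3)) - 33L
        mean_q <- mean(q)
    }
    list(umi = umi, mean_q = mean_q)
}

#' Extract UMIs from a per-bin FASTQ file
#'
#' @param path FASTQ (Phred-33) of one sorting bin.
#' @param spec a \code{\link{flankSpec}}.
#' @return data.frame(umi, mean_q), one row per read with both flanks
#'   found; reads missing a flank are dropped (counted in the
#'   \code{n_no_flank} attribute).
#' @export
extractUmisFromFastq <- function(path, spec) {
    ## the reader warns that it drops read-id metadata, which we never use
    fq <- withCallingHandlers(
        Biostrings::readQualityScaledDNAStringSet(path),
        warning = function(w) {
            if (grepl("metadata columns", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    seqs <- as.character(fq)
    dna <- Biostrings::DNAStringSet(seqs)
    ## vectorized anchored matching over the whole bin
    m5 <- Biostrings::vmatchPattern(spec$flank5, dna,
                                    max.mismatch = spec$max_mismatch)
    m3 <- Biostrings::vmatchPattern(spec$flank3, dna,
                                    max.mismatch = spec$max_mismatch)
    quals <- as.character(Biostrings::quality(fq))
    n <- length(fq)
    start <- end <- rep(NA_integer_, n)
    e5 <- lapply(m5, Biostrings::end)
    s3 <- lapply(m3, Biostrings::start)
    for (i in seq_len(n)) {
        if (length(e5[[i]]) == 0L) next
        a <- e5[[i]][1L] + 1L
        cand <- s3[[i]][s3[[i]] >= a]
        if (length(cand) == 0L) next
        start[i] <- a
        end[i] <- cand[1L] - 1L
    }
    ok <- !is.na(start) & end >= start
    out <- data.frame(umi = substr(seqs[ok], start[ok], end[ok]),
                      mean_q = vapply(which(ok), function(i)
                          mean(utf8ToInt(substr(quals[i], start[i],
                                                end[i])) - 33L),
                          numeric(1L)),
                      stringsAsFactors = FALSE)
    attr(out, "n_no_flank") <- sum(is.na(start))
    out
}

#' Tag UMIs against the look-up table
#'
#' Each read's UMI receives exactly one tag, with precedence size, then
#' quality, then lookup: 3 if the UMI is not 15 nt; else 2 if mean read
#' quality is below Q20 (or the UMI contains N); else 1 if present in the
#' look-up table; else 0.
#'
#' @param umi character vector of extracted UMIs.
#' @param mean_q numeric vector of mean Phred qualities.
#' @param lut a \linkS4class{LookupTable}.
#' @param min_q quality threshold (default 20).
#' @return integer vector of tags in \{0, 1, 2, 3\}.
#' @export
tagUmi <- function(umi, mean_q, lut, min_q = 20) {
    tag <- integer(length(umi))
    bad_size <- nchar(umi) != 15L
    bad_q <- !bad_size & (mean_q < min_q | grepl("[^ACGT]", umi))
    in_lut <- !bad_size & !bad_q & umi %in% lut@entries$umi
    tag[bad_size] <- 3L
    tag[bad_q] <- 2L
    tag[in_lut] <- 1L
    tag
}

#' Count tag-1 reads per variant in one bin
#'
#' Tag-1 UMIs are grouped by identity and mapped to variants through the
#' look-up table, summing reads over all UMIs of the same variant. Reads
#' whose LUT entry is flagged outside the target region are excluded.
#'
#' @param umi,tag parallel vectors from \code{\link{tagUmi}} (one element
#'   per read, or per aggregated UMI with \code{reads} weights).
#' @param lut a \linkS4class{LookupTable}.
#' @param reads per-row read multiplicities (default 1 each).
#' @return named numeric vector of read counts per variant; attribute
#'   \code{r_tot} holds their sum.
#' @export
countBin <- function(umi, tag, lut, reads = rep(1L, length(umi))) {
    keep <- tag == 1L
    if (!any(keep)) {
        warning("bin with zero tag-1 reads")
        out <- numeric(0)
        attr(out, "r_tot") <- 0
        return(out)
    }
    e <- lut@entries
    v <- e$variant[match(umi[keep], e$umi)]
    in_t <- e$in_target_region[match(umi[keep], e$umi)]
    w <- reads[keep][in_t]
    v <- v[in_t]
    out <- vapply(split(w, v), sum, numeric(1L))
    attr(out, "r_tot") <- sum(out)
    out
}

#' Assemble a BinCounts object from per-bin UMI tables
#'
#' Runs tagging and counting over every bin and combines the columns with
#' the bin metadata into the variants x bins container used by the fitness
#' estimator. \code{r_tot} is set to the total reads assigned to variants
#' in each bin.
#'
#' @param bin_tables list (one per bin) of data.frames with columns
#'   \code{umi}, \code{reads} (and optionally \code{mean_q}; Q30 is assumed
#'   where absent).
#' @param lut a \linkS4class{LookupTable}.
#' @param meta data.frame with one row per bin: \code{omega}, \code{c_tot}
#'   (and optionally \code{bin_id}).
#' @param min_q tagging quality threshold (default 20).
#' @return A \linkS4class{BinCounts}; a \code{tag_summary} matrix (tags x
#'   bins, in reads) is stored in its \code{metadata}.
#' @export
binCountsFromReads <- function(bin_tables, lut, meta, min_q = 20) {
    stopifnot(length(bin_tables) == nrow(meta))
    cols <- vector("list", length(bin_tables))
    tag_summary <- matrix(0, 4L, length(bin_tables),
                          dimnames = list(paste0("tag", 0:3), NULL))
    for (b in seq_along(bin_tables)) {
        tab <- bin_tables[[b]]
        if (nrow(tab) == 0L) { cols[[b]] <- numeric(0); next }
        if (is.null(tab$reads)) tab$reads <- 1L
        if (is.null(tab$mean_q)) tab$mean_q <- 30
        tags <- tagUmi(tab$umi, tab$mean_q, lut, min_q)
        for (t in 0:3)
            tag_summary[t + 1L, b] <- sum(tab$reads[tags == t])
        cols[[b]] <- suppressWarnings(countBin(tab$umi, tags, lut,
                                               tab$reads))
    }
    variants <- sort(unique(unlist(lapply(cols, names))))
    reads <- matrix(0, length(variants), length(cols),
                    dimnames = list(variants, NULL))
    for (b in seq_along(cols))
        if (length(cols[[b]])) reads[names(cols[[b]]), b] <- cols[[b]]
    meta$r_tot <- colSums(reads)
    bc <- BinCounts(reads, meta)
    S4Vectors::metadata(bc)$tag_summary <- tag_summary
    bc
}
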
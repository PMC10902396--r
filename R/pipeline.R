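## End-to-end orchestration: simulate -> build LUT -> count -> score ->
## consensus, with a manifest recording every parameter and the seed.

#' Run the simulated sort-seq pipeline end to end
#'
#' Generates a library, places gates from a simulated negative control,
#' sorts and sequences the requested number of replicates, builds the
#' look-up table from the pre-LUT records, counts tag-1 reads per bin,
#' scores fitness per replicate and computes the consensus. All
#' randomness flows from \code{config$seed}; rerunning with the same
#' config reproduces identical outputs.
#'
#' @param config a \code{\link{simConfig}}.
#' @param n_replicates number of independent sort replicates (default 2).
#' @param cells_per_variant cells per variant (default: equal split of
#'   \code{n_cells_total}).
#' @param n_negative negative-control population size (default 1e5).
#' @param out_dir if non-NULL, stage outputs (TSVs and a JSON manifest)
#'   are written there.
#' @return list: truth, lut, thresholds, replicates (per-replicate list
#'   with binCounts and fitness), consensus (DataFrame), manifest.
#' @export
runPipeline <- function(config, n_replicates = 2L,
                        cells_per_variant = NULL, n_negative = 1e5,
                        out_dir = NULL) {
    lib <- generateLibrary(config)
    lut <- buildLut(lib$pre_lut)
    neg <- simulateNegativeControl(n_negative, config)
    nv <- nrow(lib$truth)
    if (is.null(cells_per_variant))
        cells_per_variant <- max(1L, round(config$n_cells_total / nv))
    pool <- simulateCellFluorescence(0, 2000L, config)
    thresholds <- placeGates(neg, pool, config$gates)
    reps <- vector("list", n_replicates)
    for (j in seq_len(n_replicates)) {
        run <- simulateSortAndSequence(lib, thresholds, config,
                                       cells_per_variant, replicate = j)
        bc <- binCountsFromReads(run$bins, lut,
                                 run$meta[, c("bin_id", "omega", "c_tot")])
        reps[[j]] <- list(run = run, binCounts = bc,
                          fitness = fitnessScores(bc, wt = "WT"))
    }
    consensus <- consensusScores(lapply(reps, `[[`, "fitness"))
    truth_df <- as.data.frame(lib$truth)
    consensus$variant_class <-
        truth_df$variant_class[match(consensus$variant_id,
                                     truth_df$variant_id)]
    consensus$position <- truth_df$position[match(consensus$variant_id,
                                                  truth_df$variant_id)]
    manifest <- list(
        seed = config$seed,
        parameters = config[setdiff(names(config), "gates")],
        gates = unclass(config$gates),
        n_replicates = n_replicates,
        cells_per_variant = cells_per_variant,
        n_negative = n_negative,
        n_variants = nv,
        thresholds = thresholds,
        r_version = as.character(getRversion()))
    if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        writeLut(lut, file.path(out_dir, "lut.tsv"))
        utils::write.table(as.data.frame(consensus),
                           file.path(out_dir, "fitness.tsv"), sep = "\t",
                           row.names = FALSE, quote = FALSE)
        utils::write.table(truth_df, file.path(out_dir, "truth.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        jsonlite::write_json(manifest,
                             file.path(out_dir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    list(truth = lib$truth, lut = lut, thresholds = thresholds,
         replicates = reps, consensus = consensus, manifest = manifest)
}
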
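## shared toy joined table: 3 positions, mixed classes
toyJoined <- function() {
    data.frame(
        variant_id = c("A1C", "A1D", "A1E", "A1*", "G2V", "G2W", "G2G",
                       "S3A", "S3T"),
        position = c(1, 1, 1, 1, 2, 2, 2, 3, 3),
        variant_class = c("missense", "missense", "missense", "nonsense",
                          "missense", "missense", "synonymous",
                          "missense", "missense"),
        F_exp = c(-0.2, 0, 0.2, -0.7, -0.4, -0.6, 0.01, 0.1, 0.3),
        F_act = c(-0.3, -0.1, 0.1, -0.7, -0.5, -0.7, 0, 0.2, 0.4))
}

test_that("library arithmetic: positions and substitution coverage", {
    expect_identical(mutagenizedPositionCount(2, 365), 364L)
    expect_equal(substitutionCoverage(6434, 364), 6434 / (364 * 19) * 100)
    expect_equal(round(substitutionCoverage(6434, 364)), 93)
})

test_that("position summaries average missense variants only", {
    ps <- positionSummaries(toyJoined(), score_cols = c("F_exp", "F_act"))
    expect_equal(ps$position, c(1, 2, 3))
    ## position 1: nonsense excluded from the mean
    expect_equal(ps$mean_F_exp[1], mean(c(-0.2, 0, 0.2)))
    expect_equal(ps$n_F_exp[1], 3L)
    ## position 2: synonymous excluded
    expect_equal(ps$mean_F_exp[2], mean(c(-0.4, -0.6)))
    ## a position with only a nonsense variant vanishes from the summary
    only_stop <- data.frame(variant_id = "K9*", position = 9,
                            variant_class = "nonsense", F_exp = -0.7,
                            F_act = -0.7)
    ps2 <- positionSummaries(rbind(toyJoined(), only_stop))
    expect_false(9 %in% ps2$position)
})

test_that("position summaries recover simulated truth within CLT bounds", {
    set.seed(14)
    truth_mean <- c(-0.5, 0.1)
    rows <- do.call(rbind, lapply(1:2, function(p)
        data.frame(variant_id = paste0("v", p, "_", 1:40), position = p,
                   variant_class = "missense",
                   F_exp = rnorm(40, truth_mean[p], 0.1))))
    ps <- positionSummaries(rows, score_cols = "F_exp")
    se <- 0.1 / sqrt(40)
    expect_true(all(abs(ps$mean_F_exp - truth_mean) < 4 * se))
})

test_that("correlation matches the textbook formula and conventions", {
    x <- c(0.3, 1.2, 2.1, 2.9, 4.2, 5.1, 5.8, 7.2, 8.1, 9.0)
    y <- c(1.1, 0.4, 2.9, 2.1, 5.0, 4.3, 6.5, 6.9, 7.4, 9.5)
    got <- correlate(x, y)
    ## hand oracle: explicit product-moment formula + t transform
    r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    tval <- r * sqrt(8 / (1 - r^2))
    expect_equal(got$estimate, r, tolerance = 1e-12)
    expect_equal(got$p_value, 2 * pt(-abs(tval), 8), tolerance = 1e-12)
    expect_equal(got$n, 10L)
    ## perfect linearity
    expect_equal(correlate(x, 2 * x)$estimate, 1)
    ## monotone transform: spearman rho = -1 for y = -x^3
    g <- seq(-3, 3, by = 0.5)
    expect_equal(correlate(g, -g^3, method = "spearman")$estimate, -1)
    ## symmetric in argument order; pairwise-complete deletion
    xm <- c(x, NA); ym <- c(y, 5)
    expect_equal(correlate(xm, ym)$estimate, correlate(ym, xm)$estimate)
    expect_equal(correlate(xm, ym)$n, 10L)
    expect_true(isTRUE(correlate(rep(1, 5), 1:5)$degenerate))
    expect_error(correlate(1:2, 2:3), ">= 3")
})

test_that("subgroup contrasts report percent difference against |overall|", {
    j <- toyJoined()
    whole <- subgroupContrast(j, rep(TRUE, nrow(j)), "F_act")
    expect_equal(whole$percent_difference, 0)
    expect_equal(whole$n_subgroup, whole$n_overall)
    ## hand-built: subgroup mean -0.5 vs overall -0.25 -> -100%
    df <- data.frame(variant_id = letters[1:4], position = 1,
                     variant_class = "missense",
                     F_act = c(-0.5, -0.5, 0, 0))
    got <- subgroupContrast(df, c(TRUE, TRUE, FALSE, FALSE), "F_act")
    expect_equal(got$subgroup_mean, -0.5)
    expect_equal(got$overall_mean, -0.25)
    expect_equal(got$percent_difference, -100)
    expect_error(subgroupContrast(df, rep(FALSE, 4), "F_act"),
                 "empty subgroup")
})

test_that("subgroup and complement means recompose the overall mean", {
    set.seed(23)
    df <- data.frame(variant_id = paste0("v", 1:200), position = 1,
                     variant_class = "missense", F_act = rnorm(200))
    mask <- runif(200) < 0.3
    a <- subgroupContrast(df, mask, "F_act")
    b <- subgroupContrast(df, !mask, "F_act")
    recomposed <- (a$subgroup_mean * a$n_subgroup +
                       b$subgroup_mean * b$n_subgroup) / a$n_overall
    expect_equal(recomposed, a$overall_mean, tolerance = 1e-12)
})

test_that("conserved-site screen filters by conservation then expression", {
    ps <- data.frame(position = 1:6,
                     mean_F_exp = c(0.2, -0.1, 0.05, -0.3, 0.4, 0),
                     cons = c(100, 100, 100, 100, 100, 50),
                     d_active = c(20, 5, 15, 2, 30, 8))
    out <- conservedSiteScreen(ps)
    expect_equal(out$conserved$position, 1:5)
    expect_equal(out$positive$position, c(1, 3, 5))  # mean > 0 strictly
    expect_equal(out$cor_exp_dactive$n, 5L)
    ## planted positive trend between expression and active-site distance
    expect_gt(out$cor_exp_dactive$estimate, 0)
    ## nothing conserved -> empty
    ps$cons <- 10
    out2 <- conservedSiteScreen(ps)
    expect_equal(nrow(out2$conserved), 0L)
})

test_that("hotspot ranking counts positions in the top normalized scores", {
    ## one position holds the 19 highest na values
    set.seed(6)
    hot <- data.frame(variant_id = paste0("h", 1:19), position = 42,
                      na = runif(19, 5, 6))
    rest <- data.frame(variant_id = paste0("r", 1:81),
                       position = sample(1:20, 81, TRUE),
                       na = runif(81, 0, 1))
    j <- rbind(hot, rest)
    out <- hotspotRanking(j, top_n = 50, k = 3)
    expect_equal(out$position[1], 42)
    expect_equal(out$frequency[1], 19L)
    ## permutation invariance of input row order
    perm <- j[sample(nrow(j)), ]
    expect_equal(hotspotRanking(perm, top_n = 50, k = 3), out,
                 ignore_attr = TRUE)
    ## all-equal scores: deterministic tie-break by variant id
    eq <- data.frame(variant_id = paste0("v", sprintf("%02d", 1:30)),
                     position = rep(1:3, each = 10), na = 1)
    top <- attr(hotspotRanking(eq, top_n = 10, k = 3), "top_variants")
    expect_equal(top$variant_id, paste0("v", sprintf("%02d", 1:10)))
    expect_warning(hotspotRanking(eq, top_n = 100), "using all")
})

test_that("heatmap matrix encodes missing combinations as NA and round-trips", {
    rec <- data.frame(position = c(1, 1, 2), mut_aa = c("C", "*", "V"),
                      F_fin = c(0.1, -0.7, -0.2))
    m <- heatmapMatrix(rec, "F_fin")
    expect_equal(dim(m), c(21L, 2L))
    expect_equal(sum(!is.na(m)), 3L)
    expect_equal(m["C", "1"], 0.1)
    expect_equal(m["*", "1"], -0.7)
    expect_equal(unname(attr(m, "counts")), c(2L, 1L))
    ## a saturated position fills 20 cells plus the stop row
    sat <- data.frame(position = 7,
                      mut_aa = c("A","C","D","E","F","G","H","I","K","L",
                                 "M","N","P","Q","R","S","T","V","W","Y",
                                 "*"),
                      F_fin = rnorm(21))
    expect_equal(sum(!is.na(heatmapMatrix(sat, "F_fin"))), 21L)
    dup <- rbind(rec, rec[1, ])
    expect_error(heatmapMatrix(dup), "consensus-scored")
    path <- withr::local_tempfile(fileext = ".csv")
    writeHeatmap(m, path)
    back <- readHeatmap(path)
    expect_equal(back, m, ignore_attr = TRUE)
})

test_that("joined tables flag positions missing from the feature table", {
    fit <- data.frame(variant_id = c("A1C", "G2V", "K9R"),
                      position = c(1, 2, 9),
                      variant_class = "missense",
                      F_exp = c(-0.1, 0.2, 0))
    feat <- data.frame(position = 1:2, sasa_rel = c(30, 80),
                       d_fad = c(4, 12))
    j <- joinFitnessFeatures(fit, feat)
    expect_equal(nrow(j), 3L)  # nothing dropped
    expect_equal(j$has_features, c(TRUE, TRUE, FALSE))
    expect_equal(j$sasa_rel, c(30, 80, NA))
    ## a numbering map reconciles library and structure coordinates
    map <- data.frame(library_position = c(1, 2, 9),
                      structure_position = c(2, 1, 9))
    j2 <- joinFitnessFeatures(fit, feat, position_map = map)
    expect_equal(j2$sasa_rel, c(80, 30, NA))
})
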
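## Shared fixture builders: everything is generated in code at test time.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

randomProtein <- function(n, exclude = character()) {
    paste(sample(setdiff(AA20, exclude), n, replace = TRUE), collapse = "")
}

## minimal pre-LUT record set
preLutRecords <- function(umi, variant, mean_q = 30, n_indels = 0) {
    n <- max(length(umi), length(variant), length(mean_q),
             length(n_indels))
    data.frame(read_id = sprintf("r%03d", seq_len(n)),
               umi = rep_len(umi, n), mean_q = rep_len(mean_q, n),
               variant = rep_len(variant, n),
               n_indels = rep_len(n_indels, n),
               stringsAsFactors = FALSE)
}

## Write a PDB file from an atom table (name, resid, chain, resno, x, y, z,
## occ, b, element, altloc, type). Defaults build protein CA-only residues.
writePdbFixture <- function(path, atoms) {
    defaults <- list(name = "CA", resid = "ALA", chain = "A", occ = 1,
                     b = 0, element = NA, altloc = "", type = "ATOM")
    for (nm in names(defaults))
        if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
    atoms$element <- ifelse(is.na(atoms$element),
                            substr(atoms$name, 1L, 1L), atoms$element)
    lines <- vapply(seq_len(nrow(atoms)), function(i) {
        a <- atoms[i, ]
        sprintf("%-6s%5d  %-3s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                a$type, i, a$name, a$altloc, a$resid, a$chain, a$resno,
                a$x, a$y, a$z, a$occ, a$b, a$element)
    }, character(1L))
    writeLines(c(lines, "END"), path)
    path
}

## a compact two-chain dimer fixture with a known contact pair and a FAD-like
## HETATM group; CA-only residues on a line, chains offset in y
dimerFixture <- function(path, gap = 4.0) {
    resA <- data.frame(name = "CA", resid = "GLY", chain = "A",
                       resno = 1:5, x = (0:4) * 8, y = 0, z = 0,
                       b = (1:5) * 10, element = "C", type = "ATOM")
    resB <- data.frame(name = "CA", resid = "ALA", chain = "B",
                       resno = 1:5, x = (0:4) * 8, y = gap, z = 0,
                       b = 5, element = "C", type = "ATOM")
    fad <- data.frame(name = c("N1", "C2"), resid = "FAD", chain = "A",
                      resno = 500, x = c(0, 3), y = c(-6, -6), z = 0,
                      b = 0, element = c("N", "C"), type = "HETATM")
    writePdbFixture(path, rbind(resA, resB, fad))
}

## independent conflict-resolution oracle: plain restatement of the rules
## applied per UMI over (variant, support, max_q, min_indels) summaries
resolveOracle <- function(records) {
    records <- records[nchar(records$umi) == 15 &
                           !grepl("[^ACGT]", records$umi), , drop = FALSE]
    out <- list()
    for (u in unique(records$umi)) {
        r <- records[records$umi == u, ]
        s <- do.call(rbind, lapply(split(r, r$variant), function(g)
            data.frame(variant = g$variant[1], support = nrow(g),
                       max_q = max(g$mean_q), min_indels = min(g$n_indels))))
        cand <- s
        if (nrow(cand) > 1) {
            top <- cand[cand$support == max(cand$support), ]
            if (nrow(top) > 1) top <- top[top$max_q == max(top$max_q), ]
            if (nrow(top) > 1)
                top <- top[top$min_indels == min(top$min_indels), ]
            if (nrow(top) != 1) next
            cand <- top
        }
        out[[u]] <- cand$variant[1]
    }
    out
}
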
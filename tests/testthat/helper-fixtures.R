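## Fixture builders shared across test files. The depth fixture plants
## score-vetted guide cassettes on a PAM-free background, so the exact
## candidate set of every design region is known by construction and the
## expected outcome can be recomputed by the independent oracle pipeline.

.fixBases <- c("A", "C", "G", "T")

## random k-mer with no GG/CC dinucleotide (so it adds no PAM on either
## strand); optionally with an embedded Pol III terminator
fixKmer <- function(k, polyT = FALSE) {
    repeat {
        x <- sample(.fixBases, k, replace = TRUE)
        if (polyT && k >= 5) {
            at <- sample(seq_len(k - 4), 1)
            x[at:(at + 4)] <- "T"
        }
        s <- paste(x, collapse = "")
        if (!grepl("GG|CC", s) && (polyT || !grepl("TTTTT", s))) return(s)
    }
}

## a plant whose full 30-mer context has its only GG at positions 26-27
## and whose Rule Set 1 score (by the oracle scorer) clears `minScore`
fixGoodPlant <- function(at, minScore = 0.2, polyT = FALSE) {
    repeat {
        seq20 <- fixKmer(20, polyT = polyT)
        flank5 <- fixKmer(4)
        flank3 <- fixKmer(3)
        ctx <- paste0(flank5, seq20, "T", "GG", flank3)
        ch <- strsplit(ctx, "")[[1]]
        bad <- which(ch[-1] == ch[-30] & ch[-1] %in% c("G", "C")) + 1L
        if (!identical(bad, 27L)) next          # only the PAM GG allowed
        if (oracleRuleSet1(ctx) < minScore) next
        return(plantSpec(seq20 = seq20, at = at, flank5 = flank5,
                         flank3 = flank3, pamN = "T", polyT = polyT))
    }
}

## Build a genome where target i (width 200) has exactly sideSpec[[i]]
## planted candidates: list(up = <n>, down = <n>, polyTDown = TRUE/FALSE,
## strand = "+"/"-"). PAM-free background means the plants are the only
## protospacer sites genome-wide.
depthFixture <- function(sideSpec, seed) {
    set.seed(seed)
    nT <- length(sideSpec)
    L <- 4000L + nT * 3000L
    plants <- list()
    starts <- integer(nT); strands <- character(nT)
    for (i in seq_len(nT)) {
        sp <- sideSpec[[i]]
        s <- 2001L + (i - 1L) * 3000L
        e <- s + 199L
        strands[i] <- if (!is.null(sp$strand)) sp$strand else "+"
        starts[i] <- s
        ## genomic-left and -right windows; upstream is left for "+"
        leftAt <- function(j) s - 580L + 60L * (j - 1L)
        rightAt <- function(j) e + 120L + 60L * (j - 1L)
        upAt <- if (strands[i] == "+") leftAt else rightAt
        downAt <- if (strands[i] == "+") rightAt else leftAt
        for (j in seq_len(sp$up))
            plants[[length(plants) + 1L]] <- fixGoodPlant(upAt(j))
        pT <- isTRUE(sp$polyTDown)
        for (j in seq_len(sp$down))
            plants[[length(plants) + 1L]] <-
                fixGoodPlant(downAt(j), polyT = pT)
    }
    fx <- simGenome(L, seed = seed + 1000L, plants = plants,
                    pamFree = TRUE)
    targets <- GenomicRanges::GRanges("chrS",
                                      IRanges::IRanges(starts, width = 200L),
                                      strand = strands)
    names(targets) <- paste0("T", seq_len(nT))
    S4Vectors::mcols(targets)$score <- 0
    S4Vectors::mcols(targets)$autoNamed <- FALSE
    list(fx = fx, targets = targets,
         seqchar = as.character(fx$genome[[1]]))
}

## off-target table for a fixture genome, with an (empty) coding
## annotation so the exclusion pass runs silently
fixTable <- function(genome, coding = GenomicRanges::GRanges())
    buildOffTargetTable(genome, coding = coding)
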
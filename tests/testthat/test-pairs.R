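## hand-built candidate sets for the pairing layer
mkCands <- function(seqs, starts, scores, strand = "+",
                    tier = "neutral", side = "upstream") {
    gr <- GRanges("chr", IRanges(starts, width = 20),
                  strand = rep(strand, length.out = length(seqs)))
    mcols(gr) <- DataFrame(
        seq20 = seqs, context30 = strrep("A", 30),
        pamStart = starts + 20L, fpStart = starts, fpEnd = starts + 22L,
        cutBoundary = starts + 16L, side = side,
        maskTier = rep(tier, length.out = length(seqs)),
        score = scores, mm0 = 1L, mm1 = 0L, mm2 = 0L, mm3 = 0L, mm4 = 0L)
    gr
}
seqOf <- function(i) {
    ch <- c("A", "C", "G", "T")[1 + (i - 1) %% 4]
    paste0(strrep(ch, 19), c("A", "C", "G", "T")[1 + ((i - 1) %/% 4) %% 4])
}

test_that("pair enumeration is the Cartesian product of the two sides", {
    up <- mkCands(vapply(1:3, seqOf, ""), c(100, 200, 300), c(.5, .6, .7))
    down <- mkCands(vapply(4:7, seqOf, ""), c(2100, 2200, 2300, 2400),
                    c(.4, .5, .6, .7), side = "downstream")
    pairs <- enumeratePairs(up, down)
    expect_identical(nrow(pairs), 12L)
    expect_identical(nrow(enumeratePairs(up[0], down)), 0L)
    ## pair score and deletion size derive from the members
    expect_equal(pairs$pairScore, pairs$upScore + pairs$downScore)
    expect_equal(pairs$deletionSize, abs(pairs$downCut - pairs$upCut))
    prod <- enumeratePairs(up, down, scoreCombination = "product")
    expect_equal(prod$pairScore, prod$upScore * prod$downScore)
})

test_that("pair score filter is inclusive and ranking is tier-aware", {
    up <- mkCands(vapply(1:2, seqOf, ""), c(100, 200), c(0.2, 0.9),
                  tier = c("neutral", "disfavoured"))
    down <- mkCands(vapply(3:4, seqOf, ""), c(2100, 2200), c(0.2, 1.0),
                    side = "downstream")
    pairs <- enumeratePairs(up, down)
    expect_identical(nrow(filterPairScore(pairs, 0.4)), 4L)
    expect_identical(nrow(filterPairScore(pairs, 1.2)), 2L)
    expect_identical(nrow(filterPairScore(pairs, 2.0)), 0L)

    ranked <- rankPairs(pairs)
    ## neutral pairs precede disfavoured ones regardless of score
    expect_identical(ranked$maskTier, c("neutral", "neutral",
                                        "disfavoured", "disfavoured"))
    ## within a tier, scores are non-increasing
    expect_true(all(diff(ranked$pairScore[ranked$maskTier == "neutral"]) <= 0))
    ## a disfavoured 1.9 pair ranks after a neutral 0.4 pair
    expect_true(max(ranked$pairScore[ranked$maskTier == "disfavoured"]) >
                max(ranked$pairScore[ranked$maskTier == "neutral"]))

    ## distance mode: deletion sizes non-decreasing within tier
    rankedD <- rankPairs(pairs, method = "distance")
    neu <- rankedD[rankedD$maskTier == "neutral", ]
    expect_true(all(diff(neu$deletionSize) >= 0))
})

test_that("greedy diversity matches the hand-traced example", {
    ## P1=(A,B) 1.8, P2=(A,C) 1.7, P3=(A,D) 1.6, P4=(E,F) 1.5,
    ## v=0.5, n=4 => limit 2 => P3 skipped (A already used twice)
    A <- seqOf(1); B <- seqOf(2); C <- seqOf(3); D <- seqOf(4)
    E <- seqOf(5); F <- seqOf(6)
    pairs <- data.frame(upSeq = c(A, A, A, E), downSeq = c(B, C, D, F),
                        pairScore = c(1.8, 1.7, 1.6, 1.5),
                        stringsAsFactors = FALSE)
    sel <- applyDiversity(pairs, v = 0.5, n = 4)
    expect_identical(sel$downSeq, c(B, C, F))
    expect_identical(sel$rank, 1:3)
    ## v = 1: first n pairs unchanged
    expect_identical(applyDiversity(pairs, v = 1, n = 3)$downSeq, c(B, C, D))
    ## limit 1: no protospacer recurs
    sel1 <- applyDiversity(pairs, v = 0.1, n = 10)
    expect_identical(sel1$downSeq, c(B, F))
    expect_false(any(duplicated(c(sel1$upSeq, sel1$downSeq))))
})

test_that("greedy selection equals exhaustive rank-lexicographic choice", {
    usageOK <- function(idx, pairs, limit, n) {
        if (length(idx) > n) return(FALSE)
        u <- table(c(pairs$upSeq[idx], pairs$downSeq[idx]))
        all(u <= limit)
    }
    exhaustive <- function(pairs, v, n) {
        limit <- max(1, floor(v * n))
        m <- nrow(pairs)
        feasible <- list(integer(0))
        for (k in seq_len(min(n, m))) {
            cmb <- utils::combn(m, k)
            for (j in seq_len(ncol(cmb)))
                if (usageOK(cmb[, j], pairs, limit, n))
                    feasible[[length(feasible) + 1]] <- cmb[, j]
        }
        ## keep maximal sets: nothing addable within the caps and n
        isMax <- vapply(feasible, function(s) {
            if (length(s) >= n) return(TRUE)
            !any(vapply(setdiff(seq_len(m), s), function(e)
                usageOK(sort(c(s, e)), pairs, limit, n), logical(1)))
        }, logical(1))
        maxSets <- feasible[isMax]
        ## rank-lexicographic order: earlier (smaller) indices win
        best <- maxSets[[1]]
        for (s in maxSets[-1]) {
            l <- min(length(s), length(best))
            cmp <- which(s[seq_len(l)] != best[seq_len(l)])
            if (length(cmp) && s[cmp[1]] < best[cmp[1]]) best <- s
        }
        best
    }
    set.seed(17)
    for (rep in 1:12) {
        nu <- sample(2:4, 1); nd <- sample(2:4, 1)
        n <- sample(2:4, 1); v <- sample(c(0.3, 0.5, 1), 1)
        pairs <- expand.grid(u = seq_len(nu), d = seq_len(nd))
        pairs <- pairs[sample(nrow(pairs)), ]
        df <- data.frame(upSeq = vapply(pairs$u, seqOf, ""),
                         downSeq = vapply(pairs$d + 8, seqOf, ""),
                         stringsAsFactors = FALSE)
        rownames(df) <- NULL
        got <- applyDiversity(df, v = v, n = n)
        want <- exhaustive(df, v, n)
        expect_identical(paste(got$upSeq, got$downSeq),
                         paste(df$upSeq[sort(want)], df$downSeq[sort(want)]))
    }
    ## an 8x8-candidate instance at small n
    set.seed(18)
    big <- expand.grid(u = 1:8, d = 1:8)
    big <- big[sample(nrow(big)), ]
    df <- data.frame(upSeq = vapply(big$u, seqOf, ""),
                     downSeq = vapply(big$d + 8, seqOf, ""),
                     stringsAsFactors = FALSE)
    rownames(df) <- NULL
    got <- applyDiversity(df, v = 0.4, n = 3)
    want <- exhaustive(df, v = 0.4, n = 3)
    expect_identical(paste(got$upSeq, got$downSeq),
                     paste(df$upSeq[sort(want)], df$downSeq[sort(want)]))
})

test_that("DECKO ordering guarantees a leading G", {
    mk <- function(up, down) data.frame(upSeq = up, downSeq = down,
                                        sgRNA1 = NA, sgRNA2 = NA,
                                        stringsAsFactors = FALSE)
    ## only downstream starts with G: it goes first
    p <- deckoTransform(mk("ATGCATGCATGCATGCATGC", "GCCAGCCAGCCAGCCAGCCA"),
                        "DECKO")
    expect_identical(p$sgRNA1, "GCCAGCCAGCCAGCCAGCCA")
    expect_identical(p$sgRNA2, "ATGCATGCATGCATGCATGC")
    ## both start with G: upstream stays first
    p2 <- deckoTransform(mk("GTGCATGCATGCATGCATGC", "GCCAGCCAGCCAGCCAGCCA"),
                         "DECKO")
    expect_identical(p2$sgRNA1, "GTGCATGCATGCATGCATGC")
    ## neither: upstream first with a prepended G (21 nt)
    p3 <- deckoTransform(mk("ATGCATGCATGCATGCATGC", "CCGACCGACCGACCGACCGA"),
                         "DECKO")
    expect_identical(p3$sgRNA1, "GATGCATGCATGCATGCATGC")
    expect_identical(nchar(p3$sgRNA1), 21L)
    expect_identical(p3$sgRNA2, "CCGACCGACCGACCGACCGA")
    ## construct "none" passes members through in order
    p4 <- deckoTransform(mk("ATGCATGCATGCATGCATGC", "CCGACCGACCGACCGACCGA"))
    expect_identical(p4$sgRNA1, p4$upSeq)
})

test_that("designTarget labels depth as full/partial/failed correctly", {
    fx <- depthFixture(list(list(up = 4, down = 4),
                            list(up = 1, down = 3),
                            list(up = 2, down = 2, polyTDown = TRUE)),
                       seed = 101)
    tab <- fixTable(fx$fx$genome)
    cfg <- designConfig()
    r1 <- designTarget(fx$targets[1], fx$fx$genome, tab, cfg)
    expect_identical(r1$depth, "full")
    expect_identical(nrow(r1$pairs), 10L)
    r2 <- designTarget(fx$targets[2], fx$fx$genome, tab, cfg)
    expect_identical(r2$depth, "partial")
    expect_identical(nrow(r2$pairs), 3L)
    r3 <- designTarget(fx$targets[3], fx$fx$genome, tab, cfg)
    expect_identical(r3$depth, "failed")
    expect_identical(nrow(r3$pairs), 0L)
    ## returned pairs never exceed n and ranks are 1..k
    expect_identical(r1$pairs$rank, 1:10)
    ## determinism of the whole per-target pipeline
    r1b <- designTarget(fx$targets[1], fx$fx$genome, tab, cfg)
    expect_identical(r1$pairs, r1b$pairs)
})
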
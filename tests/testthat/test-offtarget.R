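P20 <- "ACGTACGTACGTACGTACGT"

test_that("PAM scanning finds constructed sites on both strands", {
    g <- DNAStringSet(c(chrT = paste0("AAAA", P20, "TGG", "AAA")))
    s <- scanProtospacers(g)
    expect_length(s, 1L)
    expect_identical(mcols(s)$seq20, P20)
    expect_identical(as.character(strand(s)), "+")
    expect_identical(start(s), 5L)

    g2 <- DNAStringSet(c(chrT = paste0("TTTCCA", oracleRevcomp(P20), "TTTT")))
    s2 <- scanProtospacers(g2)
    expect_length(s2, 1L)
    expect_identical(mcols(s2)$seq20, P20)
    expect_identical(as.character(strand(s2)), "-")

    ## N inside the 20-mer kills the site; N in the PAM's variable
    ## position does too
    gN <- DNAStringSet(c(chrT = paste0("AAAA", sub("T$", "N", P20),
                                       "TGG", "AAA")))
    expect_length(scanProtospacers(gN), 0L)
    gN2 <- DNAStringSet(c(chrT = paste0("AAAA", P20, "NGG", "AAA")))
    expect_length(scanProtospacers(gN2), 0L)

    ## a site needs 20 bases of upstream sequence on its strand
    gShort <- DNAStringSet(c(chrT = paste0(substr(P20, 1, 19), "TGG",
                                           "AAA")))
    expect_length(scanProtospacers(gShort), 0L)
})

test_that("scanning agrees with the position-by-position oracle", {
    set.seed(5)
    for (i in 1:5) {
        seq <- paste(sample(c("A", "C", "G", "T", "N"), 3000,
                            replace = TRUE,
                            prob = c(.29, .2, .2, .29, .02)),
                     collapse = "")
        got <- scanProtospacers(DNAStringSet(c(chr = seq)))
        want <- oracleScanSites(seq)
        o1 <- order(start(got), as.character(strand(got)))
        o2 <- order(want$start, want$strand)
        expect_identical(mcols(got)$seq20[o1], want$seq20[o2])
        expect_identical(start(got)[o1], want$start[o2])
        expect_identical(as.character(strand(got))[o1], want$strand[o2])
    }
})

test_that("off-target profiles match planted families and the oracle", {
    ## planted duplicate: profile (2,0,0,0,0)
    fx <- simGenome(5000, seed = 21,
                    plants = list(plantSpec(copies = c(2, 0, 0, 0, 0))))
    tab <- fixTable(fx$genome)
    expect_identical(unname(otProfiles(tab)[fx$plants$seq20[1], ]),
                     c(2L, 0L, 0L, 0L, 0L))

    ## planted 1-mismatch neighbour: profile (1,1,0,0,0)
    fx2 <- simGenome(5000, seed = 22,
                     plants = list(plantSpec(copies = c(1, 1, 0, 0, 0))))
    tab2 <- fixTable(fx2$genome)
    expect_identical(unname(otProfiles(tab2)[fx2$plants$seq20[1], ]),
                     c(1L, 1L, 0L, 0L, 0L))

    ## whole-table equality with the brute-force character oracle
    fx3 <- simGenome(4000, seed = 23, gc = 0.5)
    tab3 <- fixTable(fx3$genome)
    sites <- oracleScanSites(as.character(fx3$genome[[1]]))
    q <- sort(unique(sites$seq20))
    want <- oracleProfiles(q, sites$seq20)
    expect_identical(rownames(otProfiles(tab3)), q)
    expect_identical(unname(otProfiles(tab3)), unname(want))
    ## sum conservation: total counts = sites within Hamming <= 4
    expect_identical(unname(rowSums(otProfiles(tab3))),
                     unname(rowSums(want)))
})

test_that("packed and naive counting engines agree", {
    fx <- simGenome(30000, seed = 31)
    t1 <- fixTable(fx$genome)
    t2 <- buildOffTargetTable(fx$genome, coding = GRanges(),
                              engine = "naive")
    expect_identical(otProfiles(t1), otProfiles(t2))
})

test_that("profiles are invariant under reverse-complementing the genome", {
    fx <- simGenome(8000, seed = 41)
    g <- fx$genome
    grc <- DNAStringSet(setNames(as.character(reverseComplement(g[[1]])),
                                 names(g)))
    t1 <- fixTable(g)
    t2 <- fixTable(grc)
    expect_identical(otProfiles(t1), otProfiles(t2))
})

test_that("coding NAG/NGG exclusion removes <=2-mismatch neighbours only", {
    mutate <- function(seq, k) {
        ch <- strsplit(seq, "")[[1]]
        for (p in sample(20, k))
            ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
        paste(ch, collapse = "")
    }
    set.seed(6)
    for (d in 0:3) {
        guide <- plantSpec(name = "guide")
        fx <- simGenome(12000, seed = 100 + d, plants = list(guide))
        q <- fx$plants$seq20[1]
        neighbour <- mutate(q, d)
        fx2 <- simGenome(12000, seed = 200 + d,
                         plants = list(
                             plantSpec(seq20 = q, name = "guide"),
                             plantSpec(seq20 = neighbour, pam = "NAG",
                                       coding = TRUE, name = "codingNAG")))
        tab <- buildOffTargetTable(fx2$genome, coding = fx2$coding)
        if (d <= 2) expect_true(q %in% otExcluded(tab))
        else expect_false(q %in% otExcluded(tab))
        ## the exclusion set matches the brute-force coding-window scan
        seqchar <- as.character(fx2$genome[[1]])
        codingSeqs <- oracleCodingSeqs(seqchar, start(fx2$coding),
                                       end(fx2$coding))
        queries <- rownames(otProfiles(tab))
        wantExcluded <- queries[vapply(queries, function(qq)
            any(vapply(codingSeqs, function(cs)
                oracleHamming(qq, cs) <= 2, logical(1))), logical(1))]
        expect_setequal(otExcluded(tab), wantExcluded)
    }
})

test_that("coding exclusion interacts with filtering, not counting", {
    ## an excluded guide keeps its (clean) profile but is dropped by
    ## filterOffTarget even at permissive caps
    fx <- simGenome(12000, seed = 300,
                    plants = list(plantSpec(coding = TRUE, name = "cg")))
    tab <- buildOffTargetTable(fx$genome, coding = fx$coding)
    q <- fx$plants$seq20[1]
    expect_true(q %in% otExcluded(tab))
    expect_identical(unname(otProfiles(tab)[q, ]), c(1L, 0L, 0L, 0L, 0L))
})

test_that("threshold strings parse and compare as exact-bin caps", {
    th <- offTargetThreshold("1,0,0,x,x")
    expect_identical(thresholdCaps(th), c(1, 0, 0, Inf, Inf))
    expect_identical(thresholdString(th), "1,0,0,x,x")
    expect_identical(thresholdCaps(offTargetThreshold("1,1,5,x,x")),
                     c(1, 1, 5, Inf, Inf))
    expect_error(offTargetThreshold("1,0"), "exactly 5")
    expect_error(offTargetThreshold("1,0,0,x,y"), "invalid")

    expect_true(passesOffTarget(c(1, 0, 0, 7, 50), "1,0,0,x,x"))
    expect_false(passesOffTarget(c(2, 0, 0, 0, 0), "1,0,0,x,x"))
    expect_true(passesOffTarget(c(1, 0, 1, 0, 0), "1,0,1,x,x"))
    expect_false(passesOffTarget(c(1, 0, 1, 0, 0), "1,0,0,x,x"))
})

test_that("looser thresholds admit a superset of profiles", {
    set.seed(9)
    profiles <- matrix(rpois(200 * 5, 1), ncol = 5)
    profiles[, 1] <- profiles[, 1] + 1L
    for (i in 1:10) {
        tight <- c(sample(1:2, 1), sample(0:2, 2, TRUE), sample(0:5, 1), Inf)
        loose <- tight + c(sample(0:2, 4, TRUE), 0)
        pTight <- passesOffTarget(profiles, offTargetThreshold(tight))
        pLoose <- passesOffTarget(profiles, offTargetThreshold(loose))
        expect_true(all(pLoose[pTight]))
    }
})

test_that("the 6-field database round-trips byte-exactly", {
    fx <- simGenome(6000, seed = 51)
    tab <- fixTable(fx$genome)
    f1 <- withr::local_tempfile(fileext = ".csv")
    writeOffTargetDb(tab, f1)
    ## line format instantiation
    l1 <- readLines(f1)[1]
    expect_match(l1, "^[ACGT]{20},[0-9]+,[0-9]+,[0-9]+,[0-9]+,[0-9]+$")
    back <- readOffTargetDb(f1)
    expect_identical(otProfiles(back), otProfiles(tab))
    f2 <- withr::local_tempfile(fileext = ".csv")
    writeOffTargetDb(back, f2)
    expect_identical(readLines(f1), readLines(f2))

    ## empty table -> empty file -> empty table
    fe <- withr::local_tempfile()
    writeLines(character(0), fe)
    expect_identical(nrow(otProfiles(readOffTargetDb(fe))), 0L)

    ## malformed lines are reported with a line number
    writeLines(c(l1, "ACGT,1,2"), fe)
    expect_error(readOffTargetDb(fe), "line 2")

    ## coding-excluded 20-mers are removed on write
    fx2 <- simGenome(12000, seed = 52,
                     plants = list(plantSpec(coding = TRUE)))
    tab2 <- buildOffTargetTable(fx2$genome, coding = fx2$coding)
    writeOffTargetDb(tab2, f1)
    back2 <- readOffTargetDb(f1)
    expect_false(fx2$plants$seq20[1] %in% rownames(otProfiles(back2)))
    expect_true(fx2$plants$seq20[1] %in% rownames(otProfiles(tab2)))
})

test_that("building without a coding annotation warns and skips the pass", {
    fx <- simGenome(3000, seed = 61)
    expect_warning(tab <- buildOffTargetTable(fx$genome),
                   "exclusion pass skipped")
    expect_length(otExcluded(tab), 0L)
})
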
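## Synthetic genomes with planted protospacers, controlled off-target
## families, coding intervals and masks, for fully offline testing. The
## generator verifies every planted off-target profile post hoc with the
## naive exact-Hamming counter and re-rolls the background if the random
## sequence created an unintended neighbour.

.BASES <- c("A", "C", "G", "T")

.randomBases <- function(n, gc = 0.41) {
    sample(.BASES, n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

## background vector of single characters; pamFree forbids GG and CC
## dinucleotides anywhere, so the background contains no PAM on either
## strand and all protospacer sites are planted ones
.randomBackground <- function(n, gc = 0.41, pamFree = FALSE) {
    x <- .randomBases(n, gc)
    if (pamFree) {
        repeat {
            bad <- which(x[-1] == x[-n] & x[-1] %in% c("G", "C")) + 1L
            if (!length(bad)) break
            x[bad] <- .randomBases(length(bad), gc)
        }
    }
    x
}

.randomKmer <- function(k, gc = 0.41, pamFree = FALSE, polyT = FALSE) {
    repeat {
        x <- .randomBases(k, gc)
        if (polyT && k >= 5L) {
            at <- sample(seq_len(k - 4L), 1L)
            x[at:(at + 4L)] <- "T"
        }
        s <- paste(x, collapse = "")
        okPam <- !pamFree || !grepl("GG|CC", s)
        okT <- polyT || !grepl("TTTTT", s, fixed = TRUE)
        if (okPam && okT) return(s)
    }
}

.mutateKmer <- function(seq, k) {
    x <- strsplit(seq, "")[[1]]
    pos <- sample(seq_along(x), k)
    for (p in pos) x[p] <- sample(setdiff(.BASES, x[p]), 1L)
    paste(x, collapse = "")
}

#' Specify a planted protospacer
#'
#' Describes one protospacer family to plant into a synthetic genome: a
#' primary site plus optional extra copies at exact Hamming distances
#' 0-4, its PAM class, and whether it lies in a coding interval or a
#' mask. The generator turns each copy into a 30-bp cassette
#' (4-nt flank, 20-mer, N, GG/AG, 3-nt flank) inserted into background
#' sequence.
#'
#' @param seq20 the 20-mer to plant, or `"random"`.
#' @param copies integer vector of length 5: number of genomic sites
#'   requested at exact Hamming distance 0..4 from the primary 20-mer.
#'   The 0-distance bin counts the primary site itself, so it must be
#'   at least 1.
#' @param strand strand of the primary site.
#' @param pam `"NGG"` (a canonical site, counted in off-target profiles)
#'   or `"NAG"` (non-canonical; relevant only to the coding-region
#'   exclusion pass). Mismatch copies are always planted before NGG so
#'   they count as genomic sites.
#' @param coding plant the primary cassette inside an emitted coding
#'   interval.
#' @param positiveMask,negativeMask emit a positive-mask interval fully
#'   containing the primary site's 23-bp footprint / a negative-mask
#'   interval overlapping it by exactly 1 bp.
#' @param expected the off-target profile the generator should verify
#'   for this plant (length 5). Defaults to `copies`; override it when
#'   another explicitly planted 20-mer is a known neighbour, so the
#'   planted copies and the expected genome-wide counts differ.
#' @param polyT embed the Pol III terminator `TTTTT` in a random 20-mer.
#' @param at optional fixed 1-based genomic start for the primary
#'   20-mer footprint's leftmost base.
#' @param pamN the PAM's variable first base. Defaults to `"T"`; using a
#'   G here would create an overlapping shifted PAM and hence an
#'   unintended extra site.
#' @param flank5,flank3 optional fixed 4-nt / 3-nt context flanks
#'   (5'/3' on the plant's strand); random when `NULL`. Fixing them
#'   pins the 30-mer scoring context exactly.
#' @param name optional plant name.
#' @return a `PlantSpec` list, for [simGenome()].
#' @export
plantSpec <- function(seq20 = "random", copies = c(1, 0, 0, 0, 0),
                      strand = "+", pam = c("NGG", "NAG"), coding = FALSE,
                      positiveMask = FALSE, negativeMask = FALSE,
                      expected = NULL, polyT = FALSE, at = NA_integer_,
                      pamN = "T", flank5 = NULL, flank3 = NULL,
                      name = NULL) {
    pam <- match.arg(pam)
    stopifnot(length(copies) == 5L, all(copies >= 0), copies[1] >= 1,
              strand %in% c("+", "-"))
    if (is.null(expected)) expected <- copies
    stopifnot(length(expected) == 5L)
    if (!identical(seq20, "random")) {
        stopifnot(nchar(seq20) == 20L, !grepl("[^ACGT]", seq20))
    }
    structure(list(seq20 = seq20, copies = as.integer(copies),
                   expected = as.integer(expected),
                   strand = strand, pam = pam, coding = coding,
                   positiveMask = positiveMask, negativeMask = negativeMask,
                   polyT = polyT, at = as.integer(at), pamN = pamN,
                   flank5 = flank5, flank3 = flank3, name = name),
              class = "PlantSpec")
}

## assemble the 30-bp cassette and remember where the 20-mer sits in it
.makeCassette <- function(seq20, pamN, pam2, flank5, flank3, strand) {
    fwd <- paste0(flank5, seq20, pamN, pam2, flank3)
    if (strand == "+") list(seq = fwd, offset20 = 5L)
    else list(seq = .revcomp(fwd), offset20 = 7L)
}

#' Generate a synthetic genome with planted protospacers
#'
#' Builds a seeded random background of a given GC content, inserts the
#' requested plant cassettes at non-overlapping positions, and verifies
#' with the brute-force exact-Hamming counter that every planted NGG
#' 20-mer's off-target profile equals the requested copy numbers — i.e.
#' that the random background contributed no unintended neighbour within
#' 4 mismatches. On a violation the genome is re-rolled (fresh
#' background and positions) up to `maxTries` times before erroring.
#'
#' @param length background length in bp.
#' @param gc background GC fraction (default 0.41, human-like; PAM
#'   density grows with GC).
#' @param seed integer seed; the same seed always reproduces the same
#'   genome and annotations.
#' @param plants list of [plantSpec()] objects.
#' @param chrom chromosome name.
#' @param pamFree forbid GG/CC dinucleotides in the background (and at
#'   cassette junctions), so the planted cassettes are the only
#'   protospacer sites on either strand. Used to build fixtures with an
#'   exactly known candidate set.
#' @param maxTries re-roll budget.
#' @return a list: `genome` (named `DNAStringSet`), `plants` (data.frame
#'   truth table: name, seq20, context30, start of the 20-mer footprint
#'   (1-based, leftmost), strand, pam, flags, and the requested profile
#'   `c0`..`c4`), `coding`, `positiveMask`, `negativeMask` (`GRanges`).
#' @examples
#' fx <- simGenome(5000, seed = 1,
#'                 plants = list(plantSpec(copies = c(1, 2, 0, 0, 0))))
#' fx$plants
#' @export
simGenome <- function(length, gc = 0.41, seed = 1L, plants = list(),
                      chrom = "chrS", pamFree = FALSE, maxTries = 25L) {
    stopifnot(length >= 1000L)
    set.seed(seed)
    for (try in seq_len(maxTries)) {
        out <- .simGenomeOnce(length, gc, plants, chrom, pamFree)
        if (!is.null(out)) return(out)
    }
    stop("could not realise the requested plant layout in ", maxTries,
         " attempts; background keeps creating unintended neighbours")
}

.simGenomeOnce <- function(length, gc, plants, chrom, pamFree) {
    bg <- .randomBackground(length, gc, pamFree)
    occupied <- IRanges()
    cassettes <- list()
    truth <- list()
    place <- function(width, at = NA_integer_) {
        if (!is.na(at)) {
            s <- at
            if (s < 1L || s + width - 1L > length) stop("plant 'at' off genome")
            return(s)
        }
        for (k in 1:200) {
            s <- sample.int(length - width + 1L, 1L)
            cand <- IRanges(s - 10L, s + width + 9L)
            if (!length(findOverlaps(cand, occupied))) return(s)
        }
        NA_integer_
    }
    for (pi in seq_along(plants)) {
        sp <- plants[[pi]]
        nm <- if (!is.null(sp$name)) sp$name else sprintf("plant%d", pi)
        seq20 <- if (identical(sp$seq20, "random"))
            .randomKmer(20L, gc, pamFree, sp$polyT) else sp$seq20
        flank5 <- if (is.null(sp$flank5)) .randomKmer(4L, gc, pamFree)
                  else sp$flank5
        flank3 <- if (is.null(sp$flank3)) .randomKmer(3L, gc, pamFree)
                  else sp$flank3
        pam2 <- if (sp$pam == "NGG") "GG" else "AG"
        ## primary cassette (possibly at a fixed 20-mer position)
        cas <- .makeCassette(seq20, sp$pamN, pam2, flank5, flank3, sp$strand)
        at <- if (!is.na(sp$at)) sp$at - cas$offset20 + 1L else NA_integer_
        a <- place(30L, at)
        if (is.na(a)) return(NULL)
        occupied <- c(occupied, IRanges(a - 10L, a + 39L))
        cassettes[[base::length(cassettes) + 1L]] <- list(at = a, seq = cas$seq)
        start20 <- a + cas$offset20 - 1L
        truth[[base::length(truth) + 1L]] <- data.frame(
            name = nm, seq20 = seq20,
            context30 = paste0(flank5, seq20, sp$pamN, pam2, flank3),
            chrom = chrom, start = start20, strand = sp$strand, pam = sp$pam,
            coding = sp$coding, positiveMask = sp$positiveMask,
            negativeMask = sp$negativeMask, polyT = sp$polyT,
            c0 = sp$expected[1], c1 = sp$expected[2], c2 = sp$expected[3],
            c3 = sp$expected[4], c4 = sp$expected[5],
            cassetteStart = a, cassetteEnd = a + 29L,
            stringsAsFactors = FALSE)
        ## extra copies: exact duplicates and mismatched neighbours, all
        ## before NGG so that they are counted as genomic sites
        extra <- c(rep(0L, sp$copies[1] - 1L),
                   rep(1L, sp$copies[2]), rep(2L, sp$copies[3]),
                   rep(3L, sp$copies[4]), rep(4L, sp$copies[5]))
        for (k in extra) {
            cseq <- if (k == 0L) seq20 else .mutateKmer(seq20, k)
            ccas <- .makeCassette(cseq, sp$pamN, "GG",
                                  .randomKmer(4L, gc, pamFree),
                                  .randomKmer(3L, gc, pamFree),
                                  sample(c("+", "-"), 1L))
            ca <- place(30L)
            if (is.na(ca)) return(NULL)
            occupied <- c(occupied, IRanges(ca - 10L, ca + 39L))
            cassettes[[base::length(cassettes) + 1L]] <-
                list(at = ca, seq = ccas$seq)
        }
    }
    for (cs in cassettes) {
        idx <- cs$at:(cs$at + 29L)
        bg[idx] <- strsplit(cs$seq, "")[[1]]
    }
    if (pamFree) {
        ## repair any GG/CC formed at a cassette-background junction
        for (cs in cassettes) {
            for (j in c(cs$at - 1L, cs$at + 30L)) {
                if (j < 1L || j > length) next
                left <- if (j > 1L) bg[j - 1L] else ""
                right <- if (j < length) bg[j + 1L] else ""
                if ((bg[j] == "G" && (left == "G" || right == "G")) ||
                    (bg[j] == "C" && (left == "C" || right == "C")))
                    bg[j] <- "A"
            }
        }
    }
    genome <- DNAStringSet(setNames(paste(bg, collapse = ""), chrom))
    truth <- do.call(rbind, truth)
    ## post-hoc oracle check: requested == realised profiles
    if (!is.null(truth)) {
        sites <- scanProtospacers(genome)
        ngg <- truth[truth$pam == "NGG", , drop = FALSE]
        if (nrow(ngg)) {
            prof <- .mismatchProfilesNaive(ngg$seq20, mcols(sites)$seq20)
            want <- as.matrix(ngg[, c("c0", "c1", "c2", "c3", "c4")])
            if (!all(prof == want)) return(NULL)
        }
    }
    grOf <- function(flag) {
        if (is.null(truth)) return(GRanges())
        t2 <- truth[truth[[flag]], , drop = FALSE]
        if (!nrow(t2)) return(GRanges())
        if (flag == "negativeMask") {
            ## overlap the 23-bp footprint by exactly 1 bp
            fpEnd <- ifelse(t2$strand == "+", t2$start + 22L, t2$start + 19L)
            gr <- GRanges(chrom, IRanges(fpEnd,
                                         pmin(fpEnd + 6L, length)))
        } else {
            gr <- GRanges(chrom, IRanges(t2$cassetteStart, t2$cassetteEnd))
        }
        names(gr) <- t2$name
        gr
    }
    list(genome = genome,
         plants = if (is.null(truth)) truth else
             truth[, setdiff(names(truth), c("cassetteStart", "cassetteEnd"))],
         coding = grOf("coding"),
         positiveMask = grOf("positiveMask"),
         negativeMask = grOf("negativeMask"))
}

#' Generate non-overlapping target regions on a synthetic genome
#'
#' Places `count` disjoint targets, each far enough from the chromosome
#' ends and from each other that full design and exclude regions fit
#' without overlapping. Both strands are represented whenever
#' `count >= 2`.
#'
#' @param genome a named `DNAStringSet`.
#' @param count number of targets.
#' @param sizes target sizes to draw from (with replacement).
#' @param seed integer seed.
#' @param flank clearance in bp kept on both sides of every target
#'   (use at least `du + eu`).
#' @return a named `GRanges` (`T1`..`Tn`) with `score` and `autoNamed`
#'   metadata columns, as from [readTargets()].
#' @export
simTargets <- function(genome, count, sizes = c(200L, 1000L), seed = 1L,
                       flank = 650L) {
    stopifnot(count >= 1L)
    set.seed(seed)
    chrom <- names(genome)[1L]
    L <- width(genome)[1L]
    spans <- IRanges()
    starts <- integer(0); widths <- integer(0)
    for (i in seq_len(count)) {
        w <- sample(rep(sizes, 2L), 1L)
        placed <- FALSE
        for (k in 1:500) {
            s <- sample.int(L - w - 2L * flank, 1L) + flank
            cand <- IRanges(s - flank, s + w - 1L + flank)
            if (!length(findOverlaps(cand, spans))) {
                spans <- c(spans, cand)
                starts <- c(starts, s); widths <- c(widths, w)
                placed <- TRUE
                break
            }
        }
        if (!placed)
            stop("cannot place ", count, " targets of these sizes on a ",
                 L, " bp genome")
    }
    st <- sample(c("+", "-"), count, replace = TRUE)
    if (count >= 2L) { st[1L] <- "+"; st[2L] <- "-" }
    gr <- GRanges(chrom, IRanges(starts, width = widths), strand = st)
    names(gr) <- paste0("T", seq_len(count))
    mcols(gr)$score <- 0
    mcols(gr)$autoNamed <- FALSE
    gr
}
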
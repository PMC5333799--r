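## Candidate protospacer discovery within design regions, and the
## individual-guide filters: Pol III terminator, off-target caps with the
## coding exclusion, mask tiers, and the on-target score threshold.

## Candidate geometry, in 1-based genomic coordinates with the 20-mer
## footprint at [s, s+19]:
##   plus strand:  PAM [s+20, s+22], 30-mer context [s-4, s+25],
##                 blunt cut between positions s+16 | s+17
##   minus strand: PAM [s-3, s-1], context = revcomp of [s-6, s+23],
##                 cut between s+2 | s+3
## `cutBoundary` stores the 0-based boundary coordinate of the cut (the
## number of bases to its left), so deletion size is a plain difference.

#' Find candidate protospacers in a design region
#'
#' Scans both strands of a design region for NGG-adjacent 20-mers whose
#' 20-mer footprint lies entirely inside the region. The 30-mer scoring
#' context (`NNNN[20]NGGNNN`) is taken from the genome and may extend
#' past the region edge; candidates whose context would cross a
#' chromosome end are dropped.
#'
#' @param region a length-1 `GRanges` (a design region; zero width yields
#'   no candidates).
#' @param genome a named `DNAStringSet` or FASTA path.
#' @param side `"upstream"` or `"downstream"`, recorded on each candidate.
#' @return a `GRanges` over 20-mer footprints with metadata columns
#'   `seq20`, `context30`, `pamStart`, `fpStart`/`fpEnd` (the 23-bp
#'   protospacer+PAM footprint), `cutBoundary` (0-based genomic boundary
#'   of the predicted blunt cut, 3 bp 5' of the PAM), `side` and
#'   `maskTier` (initialised to `"neutral"`).
#' @export
findCandidates <- function(region, genome, side = c("upstream", "downstream")) {
    side <- match.arg(side)
    stopifnot(length(region) == 1L)
    genome <- .asGenome(genome)
    chrom <- as.character(seqnames(region))
    if (!chrom %in% names(genome))
        stop("unknown chromosome: ", chrom)
    chromSeq <- genome[[chrom]]
    chromLen <- nchar(chromSeq)
    emptyOut <- function() {
        gr <- GRanges()
        mcols(gr) <- DataFrame(seq20 = character(0), context30 = character(0),
                               pamStart = integer(0), fpStart = integer(0),
                               fpEnd = integer(0), cutBoundary = integer(0),
                               side = character(0), maskTier = character(0))
        gr
    }
    if (width(region) == 0L) return(emptyOut())
    ## scan a window padded enough to see PAMs of footprint-internal sites
    ws <- max(1L, start(region) - 25L)
    we <- min(chromLen, end(region) + 25L)
    df <- .scanChromSites(as.character(subseq(chromSeq, ws, we)))
    if (!nrow(df)) return(emptyOut())
    df$start <- df$start + ws - 1L
    df$pamStart <- df$pamStart + ws - 1L
    ## 20-mer footprint must lie inside the design region
    df <- df[df$start >= start(region) & df$start + 19L <= end(region), ,
             drop = FALSE]
    if (!nrow(df)) return(emptyOut())
    plus <- df$strand == "+"
    ctxStart <- ifelse(plus, df$start - 4L, df$start - 6L)
    ctxEnd <- ifelse(plus, df$start + 25L, df$start + 23L)
    inside <- ctxStart >= 1L & ctxEnd <= chromLen
    df <- df[inside, , drop = FALSE]
    if (!nrow(df)) return(emptyOut())
    plus <- df$strand == "+"
    ctxStart <- ctxStart[inside]; ctxEnd <- ctxEnd[inside]
    ctx <- vapply(seq_len(nrow(df)), function(i)
        as.character(subseq(chromSeq, ctxStart[i], ctxEnd[i])), character(1))
    ctx[!plus] <- .revcomp(ctx[!plus])
    gr <- GRanges(chrom, IRanges(df$start, width = 20L), strand = df$strand)
    mcols(gr) <- DataFrame(
        seq20 = df$seq20,
        context30 = ctx,
        pamStart = df$pamStart,
        fpStart = ifelse(plus, df$start, df$start - 3L),
        fpEnd = ifelse(plus, df$start + 22L, df$start + 19L),
        cutBoundary = ifelse(plus, df$start + 16L, df$start + 2L),
        side = side,
        maskTier = "neutral")
    gr
}

#' Remove protospacers containing the RNA Pol III terminator
#'
#' Drops every candidate whose 20-mer contains `TTTTT`, which would
#' terminate Pol III transcription of the sgRNA. Only the 20-mer is
#' examined, not the PAM or context flanks.
#'
#' @param cands candidate `GRanges` from [findCandidates()].
#' @return the filtered candidates.
#' @export
filterPolIII <- function(cands) {
    cands[!grepl("TTTTT", mcols(cands)$seq20, fixed = TRUE)]
}

#' Attach Rule Set 1 scores to candidates
#'
#' Candidates whose 30-mer context cannot be scored (non-ACGT characters,
#' e.g. assembly gaps in a flank) are dropped with a warning.
#'
#' @param cands candidate `GRanges`.
#' @return candidates with a numeric `score` metadata column.
#' @export
addGuideScores <- function(cands) {
    ctx <- mcols(cands)$context30
    ok <- nchar(ctx) == 30L & !grepl("[^ACGT]", ctx)
    if (any(!ok))
        warning(sum(!ok), " candidate(s) dropped: unscorable 30-mer context")
    cands <- cands[ok]
    mcols(cands)$score <- ruleSet1Score(mcols(cands)$context30)
    cands
}

#' Filter candidates on genome-wide off-target counts
#'
#' Keeps candidates whose off-target profile passes the per-bin caps and
#' that are not in the table's coding-excluded set. Candidates absent
#' from the table (a database/genome mismatch) are dropped with a
#' warning. The matched profile is attached as `mm0`..`mm4` columns.
#'
#' @param cands candidate `GRanges`.
#' @param table an [OffTargetTable-class].
#' @param threshold an [OffTargetThreshold-class] or its string form
#'   (default `"1,0,0,x,x"`).
#' @return the filtered candidates with profile columns attached.
#' @export
filterOffTarget <- function(cands, table, threshold = offTargetThreshold()) {
    stopifnot(is(table, "OffTargetTable"))
    threshold <- offTargetThreshold(threshold)
    if (!length(cands)) {
        for (k in 0:4) mcols(cands)[[paste0("mm", k)]] <- integer(0)
        return(cands)
    }
    seqs <- mcols(cands)$seq20
    idx <- match(seqs, rownames(otProfiles(table)))
    if (anyNA(idx)) {
        warning(sum(is.na(idx)), " candidate(s) absent from the off-target ",
                "database (database/genome mismatch); dropped")
        cands <- cands[!is.na(idx)]
        seqs <- mcols(cands)$seq20
        idx <- idx[!is.na(idx)]
    }
    prof <- otProfiles(table)[idx, , drop = FALSE]
    keep <- passesOffTarget(prof, threshold) & !seqs %in% otExcluded(table)
    cands <- cands[keep]
    prof <- prof[keep, , drop = FALSE]
    for (k in 1:5)
        mcols(cands)[[paste0("mm", k - 1L)]] <- unname(prof[, k])
    cands
}

#' Tag candidates against positive/negative masks
#'
#' The mask footprint is the 23-bp protospacer+PAM interval. With a
#' positive mask, any candidate not fully contained in the (merged)
#' favoured intervals is tagged `"disfavoured"`; with a negative mask,
#' any candidate overlapping a disfavoured interval by at least one base
#' pair is tagged `"disfavoured"`. Tags demote candidates in ranking but
#' never remove them; with no masks all candidates stay `"neutral"`.
#'
#' @param cands candidate `GRanges`.
#' @param positive,negative optional mask `GRanges` (or BED paths).
#' @return candidates with an updated `maskTier` column.
#' @export
tagMasks <- function(cands, positive = NULL, negative = NULL) {
    if (!length(cands) || (is.null(positive) && is.null(negative))) {
        return(cands)
    }
    fp <- GRanges(seqnames(cands),
                  IRanges(mcols(cands)$fpStart, mcols(cands)$fpEnd))
    tier <- mcols(cands)$maskTier
    if (!is.null(positive)) {
        if (is.character(positive)) positive <- readBed(positive)
        pos <- reduce(granges(positive), ignore.strand = TRUE)
        contained <- countOverlaps(fp, pos, type = "within",
                                   ignore.strand = TRUE) > 0
        tier[!contained] <- "disfavoured"
    }
    if (!is.null(negative)) {
        if (is.character(negative)) negative <- readBed(negative)
        hit <- countOverlaps(fp, granges(negative), minoverlap = 1L,
                             ignore.strand = TRUE) > 0
        tier[hit] <- "disfavoured"
    }
    mcols(cands)$maskTier <- tier
    cands
}

#' Filter candidates on individual on-target score
#'
#' Keeps candidates with `score >= si` (inclusive, so the default
#' `si = 0.2` keeps a guide scoring exactly 0.2). `si = 0` disables the
#' filter.
#'
#' @param cands candidate `GRanges` with a `score` column (see
#'   [addGuideScores()]).
#' @param si minimum individual score.
#' @return the filtered candidates.
#' @export
filterScore <- function(cands, si = 0.2) {
    if (!length(cands)) return(cands)
    cands[mcols(cands)$score >= si]
}
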
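## Pair assembly and prioritisation: Cartesian pairing of upstream and
## downstream candidates, pair-score filtering, tier-aware ranking, the
## greedy diversity cap, DECKO reordering, and the per-target driver.

.pairColumns <- function() {
    c("target", "chrom",
      "upStart", "upEnd", "upStrand", "upSeq", "upContext", "upScore",
      paste0("upMM", 0:4), "upFpStart", "upFpEnd", "upCut",
      "downStart", "downEnd", "downStrand", "downSeq", "downContext",
      "downScore", paste0("downMM", 0:4), "downFpStart", "downFpEnd",
      "downCut",
      "pairScore", "deletionSize", "maskTier", "rank", "sgRNA1", "sgRNA2")
}

.emptyPairFrame <- function() {
    cols <- .pairColumns()
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                         stringsAsFactors = FALSE)
    num <- c("upStart", "upEnd", "upScore", paste0("upMM", 0:4), "upFpStart",
             "upFpEnd", "upCut", "downStart", "downEnd", "downScore",
             paste0("downMM", 0:4), "downFpStart", "downFpEnd", "downCut",
             "pairScore", "deletionSize", "rank")
    for (cc in num) out[[cc]] <- numeric(0)
    out
}

.candFrame <- function(cands, prefix) {
    mc <- mcols(cands)
    df <- data.frame(Start = start(cands), End = end(cands),
                     Strand = as.character(strand(cands)),
                     Seq = mc$seq20, Context = mc$context30,
                     Score = mc$score,
                     MM0 = mc$mm0, MM1 = mc$mm1, MM2 = mc$mm2,
                     MM3 = mc$mm3, MM4 = mc$mm4,
                     FpStart = mc$fpStart, FpEnd = mc$fpEnd,
                     Cut = mc$cutBoundary, Tier = mc$maskTier,
                     stringsAsFactors = FALSE)
    names(df) <- paste0(prefix, names(df))
    df
}

#' Enumerate all upstream x downstream candidate pairs
#'
#' Forms the full Cartesian product of the two filtered candidate sets
#' (one member from each side; same-side pairs are never formed) and
#' computes the combined pair score, the deletion size (cut-site to
#' cut-site distance in bp), and the pair's mask tier (the worse of the
#' two members' tiers).
#'
#' @param upCands,downCands candidate `GRanges` (scored, filtered) for
#'   the upstream and downstream design regions.
#' @param scoreCombination `"sum"` or `"product"`.
#' @return a data.frame with one row per pair; empty when either side is
#'   empty.
#' @export
enumeratePairs <- function(upCands, downCands,
                           scoreCombination = c("sum", "product")) {
    scoreCombination <- match.arg(scoreCombination)
    if (!length(upCands) || !length(downCands)) return(.emptyPairFrame())
    idx <- expand.grid(u = seq_along(upCands), d = seq_along(downCands))
    up <- .candFrame(upCands, "up")[idx$u, , drop = FALSE]
    down <- .candFrame(downCands, "down")[idx$d, , drop = FALSE]
    out <- cbind(target = NA_character_,
                 chrom = as.character(seqnames(upCands))[idx$u],
                 up, down, stringsAsFactors = FALSE)
    out$pairScore <- pairScore(out$upScore, out$downScore,
                               method = scoreCombination)
    out$deletionSize <- abs(out$downCut - out$upCut)
    out$maskTier <- ifelse(out$upTier == "disfavoured" |
                           out$downTier == "disfavoured",
                           "disfavoured", "neutral")
    out$upTier <- NULL; out$downTier <- NULL
    out$rank <- NA_integer_
    out$sgRNA1 <- NA_character_
    out$sgRNA2 <- NA_character_
    rownames(out) <- NULL
    out
}

#' Filter pairs on combined score
#'
#' @param pairs pair data.frame from [enumeratePairs()].
#' @param sp minimum pair score (inclusive); on the sum scale by default.
#' @return the filtered pairs.
#' @export
filterPairScore <- function(pairs, sp = 0.4) {
    pairs[pairs$pairScore >= sp, , drop = FALSE]
}

#' Rank candidate pairs
#'
#' Orders pairs first by mask tier (neutral before disfavoured), then by
#' pair score descending (`method = "score"`) or deletion size ascending
#' (`method = "distance"`). Remaining ties resolve deterministically by
#' smaller deletion size, smaller upstream start, smaller downstream
#' start, then lexicographic protospacer sequences, so identical inputs
#' always give identical output order.
#'
#' @param pairs pair data.frame.
#' @param method `"score"` or `"distance"`.
#' @return the pairs, reordered.
#' @export
rankPairs <- function(pairs, method = c("score", "distance")) {
    method <- match.arg(method)
    if (!nrow(pairs)) return(pairs)
    tier <- as.integer(pairs$maskTier == "disfavoured")
    primary <- if (method == "score") -pairs$pairScore else pairs$deletionSize
    o <- order(tier, primary, pairs$deletionSize, pairs$upStart,
               pairs$downStart, pairs$upSeq, pairs$downSeq)
    out <- pairs[o, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Apply the diversity cap and select the returned pairs
#'
#' Walks the ranking greedily: a pair is accepted unless either member
#' protospacer already occurs in `max(1, floor(v * n))` accepted pairs;
#' selection stops after `n` acceptances. With `v = 1` this returns the
#' top `n` of the ranking unchanged; with `floor(v * n) <= 1` no
#' protospacer recurs at all.
#'
#' @param rankedPairs pair data.frame, already ranked.
#' @param v diversity fraction in (0, 1].
#' @param n maximum number of pairs to return.
#' @return the selected pairs with `rank` set to 1..k.
#' @export
applyDiversity <- function(rankedPairs, v = 0.5, n = 10L) {
    stopifnot(v > 0, v <= 1, n >= 1)
    limit <- max(1L, as.integer(floor(v * n)))
    if (!nrow(rankedPairs)) {
        rankedPairs$rank <- numeric(0)
        return(rankedPairs)
    }
    usage <- new.env(parent = emptyenv())
    used <- function(s) if (is.null(usage[[s]])) 0L else usage[[s]]
    take <- logical(nrow(rankedPairs))
    accepted <- 0L
    for (i in seq_len(nrow(rankedPairs))) {
        if (accepted >= n) break
        u <- rankedPairs$upSeq[i]; d <- rankedPairs$downSeq[i]
        if (used(u) >= limit || used(d) >= limit) next
        usage[[u]] <- used(u) + 1L
        usage[[d]] <- used(d) + 1L
        take[i] <- TRUE
        accepted <- accepted + 1L
    }
    out <- rankedPairs[take, , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
}

#' Order pair sequences for cloning (DECKO rule)
#'
#' Fills `sgRNA1`/`sgRNA2`. With `construct = "none"` these are simply
#' the upstream and downstream protospacers. Under `"DECKO"`, the first
#' expressed sgRNA is driven by a U6 promoter and must begin with G: if
#' exactly one member starts with G it is placed first; if both do, the
#' upstream member stays first; if neither does, the upstream member
#' stays first and receives a prepended G (21 nt).
#'
#' @param pairs pair data.frame.
#' @param construct `"none"` or `"DECKO"`.
#' @return the pairs with `sgRNA1`/`sgRNA2` filled.
#' @export
deckoTransform <- function(pairs, construct = c("none", "DECKO")) {
    construct <- match.arg(construct)
    if (!nrow(pairs)) return(pairs)
    up <- pairs$upSeq; down <- pairs$downSeq
    if (construct == "none") {
        pairs$sgRNA1 <- up
        pairs$sgRNA2 <- down
        return(pairs)
    }
    upG <- startsWith(up, "G"); downG <- startsWith(down, "G")
    first <- ifelse(upG, up,
             ifelse(downG, down, paste0("G", up)))
    second <- ifelse(upG, down,
              ifelse(downG, up, down))
    pairs$sgRNA1 <- first
    pairs$sgRNA2 <- second
    pairs
}

#' Design sgRNA pairs for one target
#'
#' Runs the whole per-target pipeline: design/exclude region
#' construction, candidate discovery on both strands, Pol III terminator
#' filter, scoring, off-target and coding-exclusion filter, mask
#' tagging, individual-score filter, pairing, pair-score filter,
#' ranking, the diversity cap, and (optionally) DECKO sequence ordering.
#' Problems degrade the single target (clipped or empty design regions,
#' empty candidate sides) rather than aborting a batch.
#'
#' @param target a length-1 named `GRanges`.
#' @param genome a named `DNAStringSet` or FASTA path.
#' @param table an [OffTargetTable-class].
#' @param config a [DesignConfig-class] (see [designConfig()]).
#' @param positiveMask,negativeMask optional mask `GRanges` or BED paths.
#' @return a list with elements `pairs` (data.frame of the returned,
#'   ranked pairs), `depth` (`"full"`, `"partial"` or `"failed"`), and
#'   `nUpCandidates`/`nDownCandidates` (surviving candidates per side).
#' @export
designTarget <- function(target, genome, table, config = designConfig(),
                         positiveMask = NULL, negativeMask = NULL) {
    stopifnot(length(target) == 1L, is(table, "OffTargetTable"))
    genome <- .asGenome(genome)
    tname <- if (!is.null(names(target))) names(target) else
        sprintf("%s_%d_%d", as.character(seqnames(target)),
                start(target) - 1L, end(target))
    regions <- suppressWarnings(
        makeDesignRegions(target, genome, du = config@du, dd = config@dd,
                          eu = config@eu, ed = config@ed))
    oneSide <- function(side) {
        cands <- findCandidates(regions[side], genome, side = side)
        cands <- filterPolIII(cands)
        cands <- addGuideScores(cands)
        cands <- filterOffTarget(cands, table, config@threshold)
        cands <- tagMasks(cands, positive = positiveMask,
                          negative = negativeMask)
        filterScore(cands, config@si)
    }
    up <- oneSide("upstream")
    down <- oneSide("downstream")
    pairs <- enumeratePairs(up, down,
                            scoreCombination = config@scoreCombination)
    pairs <- filterPairScore(pairs, config@sp)
    pairs <- rankPairs(pairs, method = config@ranking)
    pairs <- applyDiversity(pairs, v = config@v, n = config@n)
    pairs <- deckoTransform(pairs, construct = config@construct)
    if (nrow(pairs)) pairs$target <- tname
    depth <- if (nrow(pairs) == config@n) "full"
             else if (nrow(pairs) > 0) "partial"
             else "failed"
    list(pairs = pairs[, .pairColumns(), drop = FALSE], depth = depth,
         nUpCandidates = length(up), nDownCandidates = length(down))
}
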
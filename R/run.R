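## Batch driver and output writers: one design job over a BED of targets,
## emitting the pairs table, a protospacer BED track, per-target depths
## and summary statistics.

.fmtScore <- function(x) sprintf("%.6f", x)

.pairsOutFrame <- function(pairs) {
    ## on-disk representation: BED-convention 0-based half-open
    ## coordinates, fixed-precision scores, one row per returned pair
    data.frame(
        target = pairs$target,
        chrom = pairs$chrom,
        up_start = as.integer(pairs$upStart - 1L),
        up_end = as.integer(pairs$upEnd),
        up_strand = pairs$upStrand,
        up_seq = pairs$upSeq,
        up_context = pairs$upContext,
        up_score = .fmtScore(pairs$upScore),
        up_mm = paste(pairs$upMM0, pairs$upMM1, pairs$upMM2, pairs$upMM3,
                      pairs$upMM4, sep = ","),
        down_start = as.integer(pairs$downStart - 1L),
        down_end = as.integer(pairs$downEnd),
        down_strand = pairs$downStrand,
        down_seq = pairs$downSeq,
        down_context = pairs$downContext,
        down_score = .fmtScore(pairs$downScore),
        down_mm = paste(pairs$downMM0, pairs$downMM1, pairs$downMM2,
                        pairs$downMM3, pairs$downMM4, sep = ","),
        pair_score = .fmtScore(pairs$pairScore),
        deletion_size = as.integer(pairs$deletionSize),
        mask_tier = pairs$maskTier,
        rank = as.integer(pairs$rank),
        sgRNA_first = pairs$sgRNA1,
        sgRNA_second = pairs$sgRNA2,
        stringsAsFactors = FALSE)
}

.writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.protospacerBed <- function(pairs) {
    if (!nrow(pairs)) {
        gr <- GRanges()
        mcols(gr)$score <- numeric(0)
        return(gr)
    }
    df <- rbind(
        data.frame(chrom = pairs$chrom, start = pairs$upStart,
                   end = pairs$upEnd, seq = pairs$upSeq,
                   score = pairs$upScore, strand = pairs$upStrand),
        data.frame(chrom = pairs$chrom, start = pairs$downStart,
                   end = pairs$downEnd, seq = pairs$downSeq,
                   score = pairs$downScore, strand = pairs$downStrand))
    df <- unique(df)
    df <- df[order(df$chrom, df$start, df$strand), , drop = FALSE]
    gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
    names(gr) <- df$seq
    mcols(gr)$score <- round(df$score, 6)
    gr
}

.summaryStats <- function(perTarget, allPairs, n) {
    nT <- nrow(perTarget)
    nFull <- sum(perTarget$depth == "full")
    nPartial <- sum(perTarget$depth == "partial")
    nFailed <- sum(perTarget$depth == "failed")
    nDesigned <- nFull + nPartial
    totalPairs <- nrow(allPairs)
    memberScores <- c(allPairs$upScore, allPairs$downScore)
    c(n_targets = nT,
      n_designed = nDesigned,
      n_full = nFull, n_partial = nPartial, n_failed = nFailed,
      pct_full = 100 * nFull / nT,
      pct_partial = 100 * nPartial / nT,
      pct_failed = 100 * nFailed / nT,
      total_pairs = totalPairs,
      mean_pairs_per_designed_target =
          if (nDesigned) totalPairs / nDesigned else NaN,
      mean_protospacer_score =
          if (totalPairs) mean(memberScores) else NaN,
      mean_pair_score = if (totalPairs) mean(allPairs$pairScore) else NaN,
      mean_pair_distance =
          if (totalPairs) mean(allPairs$deletionSize) else NaN,
      n_requested_per_target = n)
}

#' Run a whole paired-guide design job
#'
#' Designs every target independently (one target's failure never aborts
#' the batch) and writes four files under `outPrefix`:
#' `<prefix>_pairs.tsv` (one row per returned pair, BED-convention
#' coordinates, sequences, scores, off-target profiles, deletion size,
#' rank and cloning-ordered sgRNA sequences), `<prefix>_protospacers.bed`
#' (BED6 of the distinct protospacer 20-mer footprints in returned
#' pairs; name = sequence, score = Rule Set 1 score),
#' `<prefix>_targets.tsv` (per-target depth) and `<prefix>_summary.tsv`
#' (aggregate statistics as metric/value rows). Outputs are
#' deterministic: identical inputs give byte-identical files.
#'
#' @param targets targets as a BED6 path or a named `GRanges` (see
#'   [readTargets()]). An empty target set is an error.
#' @param genome a FASTA path or named `DNAStringSet`.
#' @param db the off-target database: an [OffTargetTable-class], a path
#'   to a 6-field CSV database, or `NULL` to build the table from the
#'   genome on the fly (with `coding` used for the exclusion pass).
#' @param config a [DesignConfig-class].
#' @param positiveMask,negativeMask optional mask BED paths or `GRanges`.
#' @param coding optional coding-annotation BED path or `GRanges`; only
#'   used when `db` is `NULL`.
#' @param outPrefix output path prefix; defaults to the config's.
#' @return a [RunSummary-class], invisibly. The per-pair table is
#'   available via the written TSV.
#' @export
runBatch <- function(targets, genome, db = NULL, config = designConfig(),
                     positiveMask = NULL, negativeMask = NULL,
                     coding = NULL, outPrefix = NULL) {
    validObject(config)
    if (is.character(targets)) targets <- readTargets(targets)
    if (!length(targets)) stop("no targets")
    if (is.null(names(targets)))
        names(targets) <- sprintf("%s_%d_%d", as.character(seqnames(targets)),
                                  start(targets) - 1L, end(targets))
    genome <- .asGenome(genome)
    table <- if (is.null(db)) buildOffTargetTable(genome, coding = coding)
             else if (is.character(db)) readOffTargetDb(db)
             else db
    stopifnot(is(table, "OffTargetTable"))
    if (is.character(positiveMask)) positiveMask <- readBed(positiveMask)
    if (is.character(negativeMask)) negativeMask <- readBed(negativeMask)
    if (is.null(outPrefix)) outPrefix <- config@outPrefix

    res <- lapply(seq_along(targets), function(i)
        designTarget(targets[i], genome, table, config,
                     positiveMask = positiveMask,
                     negativeMask = negativeMask))
    perTarget <- data.frame(
        target = names(targets),
        depth = vapply(res, `[[`, character(1), "depth"),
        nPairs = vapply(res, function(r) nrow(r$pairs), integer(1)),
        nUpCandidates = vapply(res, `[[`, integer(1), "nUpCandidates"),
        nDownCandidates = vapply(res, `[[`, integer(1), "nDownCandidates"),
        stringsAsFactors = FALSE)
    allPairs <- do.call(rbind, lapply(res, `[[`, "pairs"))

    .writeTsv(.pairsOutFrame(allPairs), paste0(outPrefix, "_pairs.tsv"))
    writeBed(.protospacerBed(allPairs),
             paste0(outPrefix, "_protospacers.bed"))
    .writeTsv(perTarget, paste0(outPrefix, "_targets.tsv"))
    stats <- .summaryStats(perTarget, allPairs, config@n)
    .writeTsv(data.frame(metric = names(stats),
                         value = ifelse(is.na(stats), "NA",
                                        sprintf("%.6g", stats))),
              paste0(outPrefix, "_summary.tsv"))
    invisible(new("RunSummary", targets = perTarget, stats = stats))
}

#' Write cloning-ready oligonucleotide sequences
#'
#' Splices constant adapter sequence around each pair's cloning-ordered
#' sgRNA sequences. Under DECKO construction the first sgRNA may carry a
#' prepended G, so oligo lengths can differ by one nucleotide between
#' pairs.
#'
#' @param pairs the pair data.frame of [designTarget()] (or the
#'   concatenation over a batch).
#' @param template a single string containing the placeholders `{first}`
#'   and `{second}`, e.g. `"AAA{first}CCC{second}TTT"`. Missing either
#'   placeholder is an error.
#' @param path output path (TSV: target, rank, oligo).
#' @return `path`, invisibly.
#' @export
writeOligos <- function(pairs, template, path) {
    if (!grepl("{first}", template, fixed = TRUE) ||
        !grepl("{second}", template, fixed = TRUE))
        stop("oligo template must contain both {first} and {second} ",
             "placeholders")
    oligo <- vapply(seq_len(nrow(pairs)), function(i) {
        s <- sub("{first}", pairs$sgRNA1[i], template, fixed = TRUE)
        sub("{second}", pairs$sgRNA2[i], s, fixed = TRUE)
    }, character(1))
    out <- data.frame(target = pairs$target,
                      rank = if (nrow(pairs)) as.integer(pairs$rank)
                             else integer(0),
                      oligo = oligo, stringsAsFactors = FALSE)
    .writeTsv(out, path)
}
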
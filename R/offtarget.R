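## Genome-wide protospacer enumeration and exact-Hamming off-target
## profiling. Counting kernels live in src/hamming.cpp: the production
## route bit-packs 20-mers (2 bits/base) and uses XOR + popcount; a
## deliberately naive per-character route is kept as a brute-force oracle.

.revcomp <- function(x) {
    if (!length(x)) return(character(0))
    as.character(reverseComplement(DNAStringSet(x)))
}

## All NGG-adjacent 20-mer sites of one chromosome string, both strands.
## A site is reported only when the full 20-mer and the PAM lie within the
## chromosome and contain no non-ACGT character. Returned starts are
## 1-based leftmost genomic coordinates of the 20-mer footprint; the
## reported 20-mer reads 5'->3' on the site's strand.
.scanChromSites <- function(seqchar, pam2 = "GG") {
    n <- nchar(seqchar)
    empty <- data.frame(seq20 = character(0), start = integer(0),
                        strand = character(0), pamStart = integer(0))
    if (n < 23L) return(empty)
    ## plus strand: [20mer][N][p1 p2] with p1p2 matching pam2 (e.g. GG)
    pat <- sprintf("(?=[%s][%s])", substr(pam2, 1, 1), substr(pam2, 2, 2))
    hit <- function(s, p) {
        m <- gregexpr(p, s, perl = TRUE)[[1]]
        if (m[1] == -1L) integer(0) else as.integer(m)
    }
    p <- hit(seqchar, pat)                 # position of first PAM letter
    p <- p[p >= 22L]                       # room for N + 20-mer to the left
    plus <- empty
    if (length(p)) {
        seq20 <- substring(seqchar, p - 21L, p - 2L)
        pamN <- substring(seqchar, p - 1L, p - 1L)
        ok <- !grepl("[^ACGT]", seq20) & pamN %in% c("A", "C", "G", "T")
        plus <- data.frame(seq20 = seq20[ok], start = p[ok] - 21L,
                           strand = rep("+", sum(ok)),
                           pamStart = p[ok] - 1L)
    }
    ## minus strand: appears on the plus strand as [p2' p1'][N][20mer-rc],
    ## with primes denoting complements (CC N ... for an NGG PAM)
    comp <- chartr("ACGT", "TGCA", pam2)
    rpat <- sprintf("(?=[%s][%s])", substr(comp, 2, 2), substr(comp, 1, 1))
    q <- hit(seqchar, rpat)                # position of first complement letter
    q <- q[q + 22L <= n]
    minus <- empty
    if (length(q)) {
        fwd <- substring(seqchar, q + 3L, q + 22L)
        pamN <- substring(seqchar, q + 2L, q + 2L)
        ok <- !grepl("[^ACGT]", fwd) & pamN %in% c("A", "C", "G", "T")
        minus <- data.frame(seq20 = .revcomp(fwd[ok]), start = q[ok] + 3L,
                            strand = rep("-", sum(ok)), pamStart = q[ok])
    }
    rbind(plus, minus)
}

#' Scan a genome for canonical protospacer sites
#'
#' Enumerates every 20-mer lying immediately 5' of an NGG PAM, on both
#' strands of every chromosome. Sites whose 20-mer or PAM contains a
#' non-ACGT character, or that lack 20 bases of upstream sequence on
#' their strand, are skipped.
#'
#' @param genome a named `DNAStringSet` or FASTA path.
#' @return a `GRanges` over the 20-mer footprints (1-based, leftmost
#'   genomic coordinates) with metadata columns `seq20` (the protospacer,
#'   5'->3' on its strand) and `pamStart` (leftmost genomic coordinate of
#'   the 3-bp PAM).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chrT = "AAAAACGTACGTACGTACGTACGTTGGAAA"))
#' scanProtospacers(g)
#' @export
scanProtospacers <- function(genome) {
    genome <- .asGenome(genome)
    hits <- lapply(names(genome), function(chrom) {
        df <- .scanChromSites(as.character(genome[[chrom]]))
        if (nrow(df)) df$chrom <- chrom
        df
    })
    hits <- do.call(rbind, hits[vapply(hits, nrow, integer(1)) > 0])
    if (is.null(hits) || !nrow(hits)) {
        gr <- GRanges()
        mcols(gr)$seq20 <- character(0)
        mcols(gr)$pamStart <- integer(0)
        return(gr)
    }
    gr <- GRanges(hits$chrom, IRanges(hits$start, width = 20L),
                  strand = hits$strand)
    mcols(gr)$seq20 <- hits$seq20
    mcols(gr)$pamStart <- hits$pamStart
    gr
}

## 20-mers 5' of an NGG *or* NAG PAM whose full 23-bp site lies inside an
## annotated coding interval (both strands).
.codingProtospacers <- function(genome, coding) {
    genome <- .asGenome(genome)
    out <- character(0)
    for (i in seq_along(coding)) {
        chrom <- as.character(seqnames(coding))[i]
        if (!chrom %in% names(genome))
            stop("unknown chromosome in coding annotation: ", chrom)
        s <- max(1L, start(coding)[i])
        e <- min(nchar(genome[[chrom]]), end(coding)[i])
        if (e - s + 1L < 23L) next
        seg <- as.character(subseq(genome[[chrom]], s, e))
        for (pam in c("GG", "AG"))
            out <- c(out, .scanChromSites(seg, pam2 = pam)$seq20)
    }
    unique(out)
}

#' Build the genome-wide off-target count table
#'
#' For every unique protospacer 20-mer in the genome, counts the genomic
#' NGG-adjacent sites (both strands, with multiplicity) at exact Hamming
#' distance 0, 1, 2, 3 and 4 from it. The 0-bin therefore counts the
#' 20-mer's own occurrence(s). When a coding annotation is supplied, a
#' second pass flags every 20-mer within 2 mismatches of any 20-mer lying
#' 5' of an NGG or NAG PAM inside a coding interval; flagged 20-mers are
#' recorded as excluded (potential coding off-targets) and are treated as
#' unusable by [filterOffTarget()]. Without an annotation the pass is
#' skipped with a warning.
#'
#' @param genome a named `DNAStringSet` or FASTA path.
#' @param coding optional `GRanges` (or BED path) of protein-coding
#'   intervals for the NAG/NGG exclusion pass.
#' @param engine `"packed"` (bit-packed popcount kernel, the default) or
#'   `"naive"` (per-character brute force; identical results, kept as an
#'   independent oracle).
#' @return an [OffTargetTable-class].
#' @export
buildOffTargetTable <- function(genome, coding = NULL,
                                engine = c("packed", "naive")) {
    engine <- match.arg(engine)
    genome <- .asGenome(genome)
    sites <- scanProtospacers(genome)
    siteSeqs <- mcols(sites)$seq20
    queries <- sort(unique(siteSeqs))
    counter <- if (engine == "packed") .mismatchProfilesPacked
               else .mismatchProfilesNaive
    profiles <- if (length(queries)) counter(queries, siteSeqs)
                else matrix(integer(0), 0, 5)
    dimnames(profiles) <- list(queries, paste0("mm", 0:4))
    excluded <- character(0)
    if (is.null(coding)) {
        warning("no coding annotation supplied; ",
                "coding-region NAG/NGG exclusion pass skipped")
    } else {
        if (is.character(coding)) coding <- readBed(coding)
        codingSeqs <- .codingProtospacers(genome, coding)
        if (length(codingSeqs) && length(queries))
            excluded <- queries[.hasNeighborWithin(queries, codingSeqs, 2L)]
    }
    new("OffTargetTable", profiles = profiles, excluded = excluded)
}

#' Parse an off-target threshold string
#'
#' @param x either a string of five comma-separated tokens (integer or
#'   `"x"` for unlimited), e.g. the default `"1,0,0,x,x"`, or a numeric
#'   vector of length 5 (with `Inf` for unlimited).
#' @return an [OffTargetThreshold-class].
#' @examples
#' offTargetThreshold("1,0,0,x,x")
#' offTargetThreshold("1,1,5,x,x")
#' @export
offTargetThreshold <- function(x = "1,0,0,x,x") {
    if (is(x, "OffTargetThreshold")) return(x)
    if (is.numeric(x)) return(new("OffTargetThreshold", caps = as.numeric(x)))
    if (!is.character(x) || length(x) != 1L)
        stop("threshold must be a single string or a numeric vector")
    tok <- strsplit(trimws(x), ",", fixed = TRUE)[[1]]
    if (length(tok) != 5L)
        stop("off-target threshold must have exactly 5 comma-separated ",
             "tokens, got ", length(tok), ": '", x, "'")
    tok <- trimws(tok)
    bad <- !(tolower(tok) == "x" | grepl("^[0-9]+$", tok))
    if (any(bad))
        stop("invalid off-target threshold token(s): ",
             paste(tok[bad], collapse = ", "))
    caps <- ifelse(tolower(tok) == "x", Inf, suppressWarnings(as.numeric(tok)))
    new("OffTargetThreshold", caps = caps)
}

#' Test off-target profiles against a threshold
#'
#' A profile passes when its count in every capped bin is at most the
#' cap; `Inf` caps ("x") are ignored.
#'
#' @param profiles an integer matrix with 5 columns (bins 0-4), or a
#'   numeric vector of length 5.
#' @param threshold an [OffTargetThreshold-class] or its string form.
#' @return logical vector, one element per profile row.
#' @examples
#' passesOffTarget(c(1, 0, 0, 7, 50), "1,0,0,x,x")  # TRUE
#' passesOffTarget(c(2, 0, 0, 0, 0), "1,0,0,x,x")   # FALSE: duplicate site
#' @export
passesOffTarget <- function(profiles, threshold = offTargetThreshold()) {
    threshold <- offTargetThreshold(threshold)
    if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
    if (ncol(profiles) != 5L)
        stop("profiles must have 5 mismatch bins")
    caps <- thresholdCaps(threshold)
    apply(profiles, 1L, function(p) all(p <= caps))
}

#' Write / read the 6-field off-target database
#'
#' The flat-file database holds one line per unique usable 20-mer:
#' `SEQ,c0,c1,c2,c3,c4` — the protospacer sequence without the PAM,
#' followed by its off-target counts at 0-4 mismatches. Coding-excluded
#' 20-mers are *not* written (they are removed, matching how filtered
#' databases are distributed), so a table read from disk always has an
#' empty excluded set; for such tables write-read-write is byte-stable.
#' Lines are written sorted by sequence.
#'
#' @param table an [OffTargetTable-class].
#' @param path file path.
#' @return `writeOffTargetDb`: `path`, invisibly. `readOffTargetDb`: an
#'   `OffTargetTable`.
#' @export
writeOffTargetDb <- function(table, path) {
    stopifnot(is(table, "OffTargetTable"))
    p <- otProfiles(table)
    keep <- setdiff(rownames(p), otExcluded(table))
    p <- p[keep[order(keep)], , drop = FALSE]
    lines <- if (nrow(p))
        paste(rownames(p), p[, 1], p[, 2], p[, 3], p[, 4], p[, 5], sep = ",")
    else character(0)
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeOffTargetDb
#' @export
readOffTargetDb <- function(path) {
    if (!file.exists(path))
        stop("off-target database not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
        profiles <- matrix(integer(0), 0, 5,
                           dimnames = list(NULL, paste0("mm", 0:4)))
        return(new("OffTargetTable", profiles = profiles,
                   excluded = character(0)))
    }
    fields <- strsplit(lines, ",", fixed = TRUE)
    bad <- which(lengths(fields) != 6L)
    if (length(bad))
        stop("malformed off-target database line ", bad[1], " in ", path,
             ": expected 6 comma-separated fields")
    m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
    seqs <- m[, 1]
    badSeq <- which(nchar(seqs) != 20L | grepl("[^ACGT]", seqs))
    if (length(badSeq))
        stop("malformed 20-mer at line ", badSeq[1], " in ", path)
    counts <- suppressWarnings(matrix(as.integer(m[, -1]), ncol = 5L))
    badCnt <- which(apply(is.na(counts), 1L, any))
    if (length(badCnt))
        stop("non-integer off-target count at line ", badCnt[1], " in ", path)
    dimnames(counts) <- list(seqs, paste0("mm", 0:4))
    new("OffTargetTable", profiles = counts, excluded = character(0))
}
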
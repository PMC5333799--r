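## Genome and interval plumbing. All exported R-level coordinates are
## standard Bioconductor 1-based closed GRanges; BED files are read and
## written in the 0-based half-open BED convention.

#' Read a genome from FASTA
#'
#' Reads a (multi-)FASTA file into an uppercase [Biostrings::DNAStringSet].
#' Sequence names are truncated at the first whitespace, as genome
#' browsers do.
#'
#' @param path path to a FASTA file.
#' @return a named `DNAStringSet`.
#' @export
readGenome <- function(path) {
    if (!file.exists(path))
        stop("genome FASTA not found: ", path)
    g <- readDNAStringSet(path)
    DNAStringSet(setNames(toupper(as.character(g)),
                          sub("\\s.*$", "", names(g))))
}

.asGenome <- function(genome) {
    if (is.character(genome) && length(genome) == 1L)
        return(readGenome(genome))
    if (is(genome, "DNAStringSet")) {
        if (is.null(names(genome)))
            stop("genome DNAStringSet must be named by chromosome")
        return(genome)
    }
    stop("'genome' must be a FASTA path or a named DNAStringSet")
}

## Parse BED lines into a GRanges; shared by readTargets() and readBed().
.parseBed <- function(path, what = "BED") {
    if (!file.exists(path))
        stop(what, " file not found: ", path)
    lines <- readLines(path)
    keep <- !grepl("^\\s*(#|track\\b|browser\\b|$)", lines)
    lineNo <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) {
        gr <- GRanges()
        mcols(gr)$score <- numeric(0)
        mcols(gr)$autoNamed <- logical(0)
        return(gr)
    }
    fields <- strsplit(lines, "[ \t]+")
    nf <- lengths(fields)
    errs <- character(0)
    bad <- nf < 3L
    if (any(bad))
        errs <- c(errs, sprintf("line %d: fewer than 3 columns", lineNo[bad]))
    get <- function(i) vapply(fields, function(f)
        if (length(f) >= i) f[i] else NA_character_, character(1))
    chrom <- get(1L); s <- get(2L); e <- get(3L)
    start0 <- suppressWarnings(as.numeric(s))
    end0 <- suppressWarnings(as.numeric(e))
    badc <- !bad & (is.na(start0) | is.na(end0) |
                    start0 != floor(start0) | end0 != floor(end0) |
                    start0 < 0 | start0 >= end0)
    if (any(badc))
        errs <- c(errs, sprintf("line %d: malformed coordinates (%s, %s)",
                                lineNo[badc], s[badc], e[badc]))
    if (length(errs))
        stop(what, " parse errors in ", path, ":\n  ",
             paste(errs, collapse = "\n  "))
    nm <- get(4L)
    auto <- is.na(nm) | nm == "." | nm == ""
    nm[auto] <- sprintf("%s_%d_%d", chrom[auto],
                        as.integer(start0[auto]), as.integer(end0[auto]))
    sc <- suppressWarnings(as.numeric(get(5L)))
    sc[is.na(sc)] <- 0
    st <- get(6L)
    st[is.na(st) | !st %in% c("+", "-")] <- "+"
    gr <- GRanges(chrom, IRanges(start = as.integer(start0) + 1L,
                                 end = as.integer(end0)),
                  strand = st)
    names(gr) <- nm
    mcols(gr)$score <- sc
    mcols(gr)$autoNamed <- auto
    gr
}

#' Read target regions from a BED6 file
#'
#' Parses a BED file (>= 3 columns, tab- or space-separated) into target
#' regions. Unstranded records (`"."` or missing strand) are assigned to
#' the `+` strand; records without an identifier receive the
#' deterministic name `chrom_start_end` (BED coordinates), so repeated
#' runs are reproducible. Malformed coordinates are reported with their
#' line number. Duplicate names are made unique with a warning, since
#' target names key all downstream output.
#'
#' @param path path to a BED file.
#' @return a named [GenomicRanges::GRanges] with metadata columns `score`
#'   and `autoNamed` (whether the name was generated rather than
#'   user-supplied).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chrT\t100\t400\tT1\t0\t+", "chrT\t600\t900"), bed)
#' readTargets(bed)
#' @export
readTargets <- function(path) {
    gr <- .parseBed(path, what = "target BED")
    if (anyDuplicated(names(gr))) {
        warning("duplicated target names made unique")
        names(gr) <- make.unique(names(gr), sep = "_")
    }
    gr
}

#' Read a plain BED interval file (masks, coding annotation)
#'
#' @inheritParams readTargets
#' @return a [GenomicRanges::GRanges].
#' @export
readBed <- function(path) .parseBed(path, what = "BED")

#' Write intervals as BED6
#'
#' Writes a GRanges in the 0-based half-open BED6 convention
#' (tab-separated). Reading the result back with [readBed()] reproduces
#' coordinates, names, scores and strands exactly.
#'
#' @param gr a `GRanges`; names become the BED name column (`"."` when
#'   absent) and a numeric `score` metadata column the score column
#'   (0 when absent).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
    nm <- if (is.null(names(gr))) rep(".", length(gr)) else names(gr)
    sc <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else rep(0, length(gr))
    st <- as.character(strand(gr))
    st[st == "*"] <- "+"
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                     as.character(seqnames(gr)), start(gr) - 1L, end(gr), nm,
                     format(sc, trim = TRUE, scientific = FALSE,
                            drop0trailing = TRUE),
                     st)
    writeLines(lines, path)
    invisible(path)
}

#' Construct design regions flanking a target
#'
#' Builds the pair of protospacer search windows for one target: a design
#' region of `du` bp on the target's 5' side and `dd` bp on its 3' side,
#' each separated from the target by an exclude region of `eu` / `ed` bp.
#' Sides are interpreted relative to the target's own strand, so for a
#' minus-strand target the upstream design region lies genomically to the
#' right. Regions running off a chromosome end are clipped (possibly to
#' zero width) and flagged rather than failing the target.
#'
#' @param target a length-1 `GRanges` (strand `+`, `-`; `*` is treated
#'   as `+`).
#' @param genome a named `DNAStringSet` (used for chromosome bounds).
#' @param du,dd design-region lengths in bp (upstream/downstream of the
#'   target on its own strand).
#' @param eu,ed exclude-region lengths in bp.
#' @return a `GRanges` of length 2 named `upstream` and `downstream`,
#'   with metadata columns `side` and `clipped`. A fully off-chromosome
#'   side has zero width.
#' @examples
#' genome <- Biostrings::DNAStringSet(c(chrT = paste(rep("ACGT", 1000),
#'                                                   collapse = "")))
#' tgt <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1001, 2000),
#'                               strand = "+")
#' makeDesignRegions(tgt, genome)
#' @export
makeDesignRegions <- function(target, genome, du = 500L, dd = 500L,
                              eu = 100L, ed = 100L) {
    stopifnot(length(target) == 1L)
    if (du < 1L || dd < 1L) stop("'du' and 'dd' must be positive")
    if (eu < 0L || ed < 0L) stop("'eu' and 'ed' must be non-negative")
    genome <- .asGenome(genome)
    chrom <- as.character(seqnames(target))
    if (!chrom %in% names(genome))
        stop("unknown chromosome: ", chrom)
    chromLen <- nchar(genome[[chrom]])
    s <- start(target); e <- end(target)
    st <- as.character(strand(target))
    if (st == "*") st <- "+"
    ## sides follow the target's own strand: for "-" targets the
    ## upstream window (length du, gap eu) lies genomically to the right
    if (st == "+") {
        up <- c(s - eu - du, s - eu - 1L)
        down <- c(e + ed + 1L, e + ed + dd)
    } else {
        up <- c(e + eu + 1L, e + eu + du)
        down <- c(s - ed - dd, s - ed - 1L)
    }
    clip1 <- function(w) {
        s2 <- max(1L, w[1]); e2 <- min(chromLen, w[2])
        if (s2 > e2) { s2 <- min(max(1L, w[1]), chromLen + 1L); e2 <- s2 - 1L }
        list(start = s2, end = e2, clipped = s2 != w[1] || e2 != w[2])
    }
    cu <- clip1(up); cd <- clip1(down)
    out <- GRanges(chrom,
                   IRanges(start = c(cu$start, cd$start),
                           end = c(cu$end, cd$end)),
                   strand = st)
    names(out) <- c("upstream", "downstream")
    mcols(out)$side <- c("upstream", "downstream")
    mcols(out)$clipped <- c(cu$clipped, cd$clipped)
    if (any(mcols(out)$clipped))
        warning("design region(s) clipped at chromosome boundary for target ",
                if (!is.null(names(target))) names(target) else chrom)
    out
}

#' Extract plus-strand sequence for intervals
#'
#' Returns the forward-strand sequence of each interval, regardless of
#' the interval's strand (reverse-complementing is the caller's concern).
#' Out-of-bounds intervals and unknown chromosomes are errors.
#'
#' @param genome a named `DNAStringSet` or FASTA path.
#' @param gr a `GRanges` (zero-width ranges yield `""`).
#' @return character vector of sequences, one per range.
#' @export
extractSequence <- function(genome, gr) {
    genome <- .asGenome(genome)
    chrom <- as.character(seqnames(gr))
    unknown <- !chrom %in% names(genome)
    if (any(unknown))
        stop("unknown chromosome: ", paste(unique(chrom[unknown]),
                                           collapse = ", "))
    lens <- setNames(width(genome), names(genome))[chrom]
    if (any(start(gr) < 1L | end(gr) > lens))
        stop("interval out of chromosome bounds")
    vapply(seq_along(gr), function(i) {
        if (width(gr)[i] == 0L) return("")
        as.character(subseq(genome[[chrom[i]]], start(gr)[i], end(gr)[i]))
    }, character(1))
}

#' Pairwise overlap width of two intervals
#'
#' Number of bases shared by `a[i]` and `b[i]`; 0 when disjoint or on
#' different chromosomes. Strand is ignored.
#'
#' @param a,b `GRanges` of equal length (or either of length 1, which is
#'   recycled).
#' @return integer vector of overlap widths.
#' @export
overlapWidth <- function(a, b) {
    n <- max(length(a), length(b))
    ia <- rep_len(seq_along(a), n)
    ib <- rep_len(seq_along(b), n)
    w <- pmin(end(a)[ia], end(b)[ib]) - pmax(start(a)[ia], start(b)[ib]) + 1L
    w[as.character(seqnames(a))[ia] != as.character(seqnames(b))[ib]] <- 0L
    pmax(w, 0L)
}
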
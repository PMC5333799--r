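## Independent brute-force oracles, deliberately written with plain
## character operations and nested loops, sharing no code with the
## package's scanning/counting/selection paths.

.ORA_COMP <- c(A = "T", C = "G", G = "C", T = "A")

oracleRevcomp <- function(x) {
    vapply(x, function(s) {
        ch <- strsplit(s, "")[[1]]
        paste(rev(.ORA_COMP[ch]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

## every 20-mer immediately 5' of a [pam2] PAM (NGG by default), both
## strands, by direct position-by-position inspection
oracleScanSites <- function(seqchar, pam2 = "GG") {
    ch <- strsplit(seqchar, "")[[1]]
    n <- length(ch)
    p1 <- substr(pam2, 1, 1); p2 <- substr(pam2, 2, 2)
    c1 <- .ORA_COMP[[p1]]; c2 <- .ORA_COMP[[p2]]
    seq20 <- character(0); start <- integer(0); strand <- character(0)
    for (i in seq_len(max(0L, n - 1L))) {
        if (i >= 22L && ch[i] == p1 && ch[i + 1L] == p2) {
            s <- ch[(i - 21L):(i - 2L)]
            if (all(s %in% names(.ORA_COMP)) &&
                ch[i - 1L] %in% names(.ORA_COMP)) {
                seq20 <- c(seq20, paste(s, collapse = ""))
                start <- c(start, i - 21L)
                strand <- c(strand, "+")
            }
        }
        if (i + 22L <= n && ch[i] == c2 && ch[i + 1L] == c1) {
            s <- ch[(i + 3L):(i + 22L)]
            if (all(s %in% names(.ORA_COMP)) &&
                ch[i + 2L] %in% names(.ORA_COMP)) {
                seq20 <- c(seq20, paste(rev(.ORA_COMP[s]), collapse = ""))
                start <- c(start, i + 3L)
                strand <- c(strand, "-")
            }
        }
    }
    data.frame(seq20 = seq20, start = start, strand = strand,
               stringsAsFactors = FALSE)
}

oracleHamming <- function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

## all-pairs exact-Hamming binning, row per query, columns distance 0..4
oracleProfiles <- function(queries, sites) {
    sm <- do.call(rbind, strsplit(sites, ""))
    out <- matrix(0L, length(queries), 5L)
    for (i in seq_along(queries)) {
        q <- strsplit(queries[i], "")[[1]]
        d <- rowSums(sm != matrix(q, nrow(sm), 20L, byrow = TRUE))
        for (k in 0:4) out[i, k + 1L] <- sum(d == k)
    }
    out
}

## 20-mers before NGG or NAG fully inside the given intervals (1-based
## closed), both strands
oracleCodingSeqs <- function(seqchar, starts, ends) {
    out <- character(0)
    for (i in seq_along(starts)) {
        seg <- substr(seqchar, starts[i], ends[i])
        for (pam in c("GG", "AG"))
            out <- c(out, oracleScanSites(seg, pam)$seq20)
    }
    unique(out)
}

## per-sequence transcription of the published Rule Set 1 scoring script:
## intercept + GC deviation + matched position-specific features, then
## the logistic transform
oracleRuleSet1 <- function(seq30) {
    tab <- read.table(system.file("extdata", "ruleset1_coefficients.tsv",
                                  package = "crisprPairs"),
                      header = TRUE, sep = "\t", quote = "",
                      colClasses = c("character", "integer", "character",
                                     "numeric"))
    w <- function(f) tab$weight[tab$feature == f]
    score <- w("intercept")
    ch20 <- strsplit(substr(seq30, 5, 24), "")[[1]]
    gc <- sum(ch20 %in% c("G", "C"))
    if (gc < 10) score <- score + (10 - gc) * w("gc_low")
    if (gc > 10) score <- score + (gc - 10) * w("gc_high")
    feats <- tab[tab$feature %in% c("nt", "dint"), ]
    for (j in seq_len(nrow(feats))) {
        sub <- substr(seq30, feats$position[j],
                      feats$position[j] + nchar(feats$sequence[j]) - 1L)
        if (sub == feats$sequence[j]) score <- score + feats$weight[j]
    }
    1 / (1 + exp(-score))
}

## ---- independent end-to-end pipeline on a single target -------------
## Straight-line reimplementation of the whole per-target design under
## the standard defaults, built on the oracles above. Used to predict
## the exact pair sets and depth labels the pipeline must return.
oracleDesignTarget <- function(seqchar, tStart, tEnd, tStrand,
                               du = 500, dd = 500, eu = 100, ed = 100,
                               si = 0.2, sp = 0.4, v = 0.5, n = 10) {
    if (tStrand == "+") {
        up <- c(tStart - eu - du, tStart - eu - 1)
        down <- c(tEnd + ed + 1, tEnd + ed + dd)
    } else {
        up <- c(tEnd + eu + 1, tEnd + eu + du)
        down <- c(tStart - ed - dd, tStart - ed - 1)
    }
    sites <- oracleScanSites(seqchar)
    prof <- oracleProfiles(unique(sites$seq20), sites$seq20)
    rownames(prof) <- unique(sites$seq20)
    sideCands <- function(win) {
        k <- sites[sites$start >= win[1] & sites$start + 19 <= win[2], ,
                   drop = FALSE]
        if (!nrow(k)) return(k)
        ctx <- character(nrow(k)); cut <- numeric(nrow(k))
        keep <- logical(nrow(k))
        for (j in seq_len(nrow(k))) {
            s <- k$start[j]
            if (k$strand[j] == "+") {
                if (s - 4 < 1 || s + 25 > nchar(seqchar)) next
                ctx[j] <- substr(seqchar, s - 4, s + 25)
                cut[j] <- s + 16
            } else {
                if (s - 6 < 1 || s + 23 > nchar(seqchar)) next
                ctx[j] <- oracleRevcomp(substr(seqchar, s - 6, s + 23))
                cut[j] <- s + 2
            }
            keep[j] <- TRUE
        }
        k$context <- ctx; k$cut <- cut
        k <- k[keep, , drop = FALSE]
        k <- k[!grepl("TTTTT", k$seq20), , drop = FALSE]
        if (!nrow(k)) return(k)
        k$score <- vapply(k$context, oracleRuleSet1, numeric(1))
        k <- k[k$score >= si, , drop = FALSE]
        if (!nrow(k)) return(k)
        pr <- prof[k$seq20, , drop = FALSE]
        ok <- pr[, 1] <= 1 & pr[, 2] == 0 & pr[, 3] == 0  # caps 1,0,0,x,x
        k[ok, , drop = FALSE]
    }
    cu <- sideCands(up); cd <- sideCands(down)
    if (!nrow(cu) || !nrow(cd))
        return(list(depth = "failed",
                    pairs = data.frame(upSeq = character(0),
                                       downSeq = character(0))))
    pairs <- expand.grid(u = seq_len(nrow(cu)), d = seq_len(nrow(cd)))
    pairs$upSeq <- cu$seq20[pairs$u]; pairs$downSeq <- cd$seq20[pairs$d]
    pairs$score <- cu$score[pairs$u] + cd$score[pairs$d]
    pairs$del <- abs(cd$cut[pairs$d] - cu$cut[pairs$u])
    pairs$upStart <- cu$start[pairs$u]; pairs$downStart <- cd$start[pairs$d]
    pairs <- pairs[pairs$score >= sp, , drop = FALSE]
    pairs <- pairs[order(-pairs$score, pairs$del, pairs$upStart,
                         pairs$downStart, pairs$upSeq, pairs$downSeq), ,
                   drop = FALSE]
    limit <- max(1, floor(v * n))
    usage <- list()
    sel <- integer(0)
    for (i in seq_len(nrow(pairs))) {
        if (length(sel) >= n) break
        u <- pairs$upSeq[i]; d <- pairs$downSeq[i]
        cu2 <- if (is.null(usage[[u]])) 0 else usage[[u]]
        cd2 <- if (is.null(usage[[d]])) 0 else usage[[d]]
        if (cu2 >= limit || cd2 >= limit) next
        usage[[u]] <- cu2 + 1; usage[[d]] <- cd2 + 1
        sel <- c(sel, i)
    }
    out <- pairs[sel, c("upSeq", "downSeq"), drop = FALSE]
    rownames(out) <- NULL
    depth <- if (nrow(out) == n) "full" else if (nrow(out)) "partial"
             else "failed"
    list(depth = depth, pairs = out)
}
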
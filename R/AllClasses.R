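#' Off-target threshold
#'
#' Per-bin caps on the number of genomic sites allowed at exact Hamming
#' distance 0, 1, 2, 3 and 4 from a protospacer. The text form is five
#' comma-separated tokens, each a non-negative integer or `"x"` for
#' unlimited; the pipeline default `"1,0,0,x,x"` admits the site itself
#' (the 0-mismatch bin counts the candidate's own genomic occurrence) and
#' no other site within 2 mismatches.
#'
#' @slot caps numeric vector of length 5; `Inf` encodes "x" (no limit).
#'
#' @seealso [offTargetThreshold()], [passesOffTarget()]
#' @export
setClass("OffTargetThreshold", representation(caps = "numeric"))

setValidity("OffTargetThreshold", function(object) {
    caps <- object@caps
    if (length(caps) != 5L)
        return("'caps' must have length 5 (mismatch bins 0-4)")
    if (anyNA(caps) || any(caps < 0))
        return("'caps' must be non-negative (Inf for unlimited)")
    if (any(is.finite(caps) & caps != floor(caps)))
        return("finite caps must be whole numbers")
    TRUE
})

#' Genome-wide off-target count table
#'
#' For every unique 20-mer occurring immediately 5' of an NGG PAM in a
#' genome (either strand), the number of genomic protospacer sites at
#' exact Hamming distance 0..4 from it, counted with multiplicity. The
#' 0-mismatch bin includes the 20-mer's own occurrence(s), so it is always
#' at least 1. 20-mers failing the coding-region NAG/NGG exclusion are
#' kept in `excluded` and treated as unusable.
#'
#' @slot profiles integer matrix; rownames are uppercase ACGT 20-mers,
#'   columns `mm0`..`mm4`.
#' @slot excluded character vector of 20-mers rejected by the
#'   coding-region exclusion pass (each ≤2 mismatches from a 20-mer lying
#'   5' of an NGG or NAG inside an annotated coding interval).
#'
#' @seealso [buildOffTargetTable()], [readOffTargetDb()], [writeOffTargetDb()]
#' @export
setClass("OffTargetTable",
         representation(profiles = "matrix", excluded = "character"))

setValidity("OffTargetTable", function(object) {
    p <- object@profiles
    if (ncol(p) != 5L)
        return("'profiles' must have 5 columns (mismatch bins 0-4)")
    if (nrow(p) > 0) {
        rn <- rownames(p)
        if (is.null(rn))
            return("'profiles' must have 20-mer rownames")
        if (anyDuplicated(rn))
            return("duplicated 20-mers in 'profiles'")
        if (any(nchar(rn) != 20L) || any(grepl("[^ACGT]", rn)))
            return("rownames must be uppercase ACGT 20-mers")
        if (any(p < 0))
            return("negative off-target counts")
        if (any(p[, 1L] < 1L))
            return("the 0-mismatch bin must count the site itself (>= 1)")
    }
    if (any(!object@excluded %in% rownames(p)))
        return("'excluded' contains 20-mers absent from 'profiles'")
    TRUE
})

#' Design-run configuration
#'
#' All tunable parameters of a paired-guide design run, with the
#' pipeline's standard defaults: `n = 10` pairs per target, design regions
#' `du = dd = 500` bp separated from the target by exclude regions
#' `eu = ed = 100` bp, diversity fraction `v = 0.5`, minimum individual
#' score `si = 0.2`, minimum pair score `sp = 0.4` on the sum scale,
#' score combination `"sum"`, ranking `"score"`, construct method
#' `"none"`, and off-target caps `"1,0,0,x,x"`.
#'
#' @slot n integer, maximum number of pairs returned per target.
#' @slot du,dd integer, upstream/downstream design region lengths (bp),
#'   measured on the target's own strand.
#' @slot eu,ed integer, exclude-region lengths (bp) between target and
#'   design regions.
#' @slot v numeric in (0, 1], maximum fraction of returned pairs that may
#'   contain the same protospacer (usage cap `max(1, floor(v * n))`).
#' @slot si numeric, minimum Rule Set 1 score of an individual protospacer.
#' @slot sp numeric, minimum combined pair score.
#' @slot scoreCombination `"sum"` or `"product"`.
#' @slot ranking `"score"` (pair score, descending) or `"distance"`
#'   (deletion size, ascending).
#' @slot construct `"none"` or `"DECKO"` (first sgRNA must start with G).
#' @slot threshold an [OffTargetThreshold-class] object.
#' @slot outPrefix character, path/prefix for output files.
#'
#' @seealso [designConfig()]
#' @export
setClass("DesignConfig",
         representation(n = "integer", du = "integer", dd = "integer",
                        eu = "integer", ed = "integer",
                        v = "numeric", si = "numeric", sp = "numeric",
                        scoreCombination = "character",
                        ranking = "character", construct = "character",
                        threshold = "OffTargetThreshold",
                        outPrefix = "character"))

setValidity("DesignConfig", function(object) {
    msg <- character(0)
    if (object@n < 1L) msg <- c(msg, "'n' must be >= 1")
    if (object@du < 1L || object@dd < 1L)
        msg <- c(msg, "design region lengths 'du'/'dd' must be positive")
    if (object@eu < 0L || object@ed < 0L)
        msg <- c(msg, "exclude lengths 'eu'/'ed' must be >= 0")
    if (!(object@v > 0 && object@v <= 1))
        msg <- c(msg, "'v' must be in (0, 1]")
    if (object@si < 0) msg <- c(msg, "'si' must be >= 0")
    if (object@sp < 0) msg <- c(msg, "'sp' must be >= 0")
    if (!object@scoreCombination %in% c("sum", "product"))
        msg <- c(msg, "'scoreCombination' must be \"sum\" or \"product\"")
    if (!object@ranking %in% c("score", "distance"))
        msg <- c(msg, "'ranking' must be \"score\" or \"distance\"")
    if (!object@construct %in% c("none", "DECKO"))
        msg <- c(msg, "'construct' must be \"none\" or \"DECKO\"")
    if (length(msg)) msg else TRUE
})

#' Batch design summary
#'
#' Per-target design depth and aggregate statistics of a [runBatch()] job.
#' Depth labels follow the usual screen-design vocabulary: "full" when all
#' `n` requested pairs were returned, "partial" when between 1 and `n - 1`
#' were, "failed" when none were.
#'
#' @slot targets data.frame with one row per input target: `target`,
#'   `depth`, `nPairs`, `nUpCandidates`, `nDownCandidates`.
#' @slot stats named numeric vector of aggregate statistics (counts,
#'   percentages, mean scores and deletion distance).
#'
#' @seealso [runBatch()]
#' @export
setClass("RunSummary",
         representation(targets = "data.frame", stats = "numeric"))

setMethod("show", "OffTargetThreshold", function(object) {
    cat("OffTargetThreshold:", thresholdString(object), "\n")
})

setMethod("show", "OffTargetTable", function(object) {
    cat("OffTargetTable with", nrow(object@profiles), "unique 20-mers",
        sprintf("(%d coding-excluded)\n", length(object@excluded)))
    if (nrow(object@profiles)) {
        n <- min(3L, nrow(object@profiles))
        print(utils::head(object@profiles, n))
        if (nrow(object@profiles) > n) cat("...\n")
    }
})

setMethod("show", "DesignConfig", function(object) {
    cat("DesignConfig\n")
    cat(sprintf("  pairs per target (n): %d\n", object@n))
    cat(sprintf("  design regions (du/dd): %d/%d bp, excludes (eu/ed): %d/%d bp\n",
                object@du, object@dd, object@eu, object@ed))
    cat(sprintf("  off-target caps (t): %s\n", thresholdString(object@threshold)))
    cat(sprintf("  scores: si >= %g, sp >= %g (%s), ranking: %s\n",
                object@si, object@sp, object@scoreCombination, object@ranking))
    cat(sprintf("  diversity (v): %g, construct: %s, out prefix: %s\n",
                object@v, object@construct, object@outPrefix))
})

setMethod("show", "RunSummary", function(object) {
    s <- object@stats
    cat("RunSummary:", sprintf("%d targets", as.integer(s[["n_targets"]])), "\n")
    cat(sprintf("  depth: %.1f%% full, %.1f%% partial, %.1f%% failed\n",
                s[["pct_full"]], s[["pct_partial"]], s[["pct_failed"]]))
    cat(sprintf("  %d pairs over %d designed targets (mean %.2f pairs/target)\n",
                as.integer(s[["total_pairs"]]),
                as.integer(s[["n_designed"]]),
                s[["mean_pairs_per_designed_target"]]))
    if (is.finite(s[["mean_pair_score"]]))
        cat(sprintf("  mean protospacer score %.3f, mean pair score %.3f, mean distance %.0f bp\n",
                    s[["mean_protospacer_score"]], s[["mean_pair_score"]],
                    s[["mean_pair_distance"]]))
})

#' @describeIn RunSummary-class per-target depth table.
#' @param object a `RunSummary`.
#' @export
setGeneric("targetDepths", function(object) standardGeneric("targetDepths"))

#' @export
setMethod("targetDepths", "RunSummary", function(object) object@targets)

#' @describeIn RunSummary-class named vector of aggregate statistics.
#' @export
setGeneric("summaryStats", function(object) standardGeneric("summaryStats"))

#' @export
setMethod("summaryStats", "RunSummary", function(object) object@stats)

#' @describeIn OffTargetTable-class off-target count matrix (rows are
#'   20-mers, columns `mm0`..`mm4`).
#' @param object an `OffTargetTable`.
#' @export
setGeneric("otProfiles", function(object) standardGeneric("otProfiles"))

#' @export
setMethod("otProfiles", "OffTargetTable", function(object) object@profiles)

#' @describeIn OffTargetTable-class coding-excluded 20-mers.
#' @export
setGeneric("otExcluded", function(object) standardGeneric("otExcluded"))

#' @export
setMethod("otExcluded", "OffTargetTable", function(object) object@excluded)

#' @describeIn OffTargetThreshold-class numeric caps (length 5, `Inf`
#'   for unlimited).
#' @param object an `OffTargetThreshold`.
#' @export
setGeneric("thresholdCaps", function(object) standardGeneric("thresholdCaps"))

#' @export
setMethod("thresholdCaps", "OffTargetThreshold", function(object) object@caps)

#' @describeIn OffTargetThreshold-class canonical text form, e.g.
#'   `"1,0,0,x,x"`.
#' @export
setGeneric("thresholdString", function(object) standardGeneric("thresholdString"))

#' @export
setMethod("thresholdString", "OffTargetThreshold", function(object) {
    paste(ifelse(is.finite(object@caps),
                 format(object@caps, trim = TRUE, scientific = FALSE),
                 "x"),
          collapse = ",")
})
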
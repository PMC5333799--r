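## On-target efficiency scoring: the Doench 2014 "Rule Set 1" logistic
## regression over a 30-mer context NNNN[20-mer protospacer]NGGNNN.
## Coefficients ship as plain text in inst/extdata and are loaded once.

.rs1Cache <- new.env(parent = emptyenv())

#' Rule Set 1 model coefficients
#'
#' Loads the published Rule Set 1 parameterisation: an intercept, two
#' GC-content terms (penalties per base of deviation from 10 G/C in the
#' 20-mer, one slope below 10 and one above), and position-specific
#' nucleotide and dinucleotide weights over the 30-mer context (1-based
#' positions; the protospacer occupies positions 5-24 and the PAM "GG"
#' positions 26-27).
#'
#' @return a list with elements `intercept`, `gcLow`, `gcHigh`, and
#'   `features` (data.frame: `position`, `sequence`, `weight`).
#' @export
ruleSet1Weights <- function() {
    if (is.null(.rs1Cache$model)) {
        path <- system.file("extdata", "ruleset1_coefficients.tsv",
                            package = "crisprPairs", mustWork = TRUE)
        tab <- read.table(path, header = TRUE, sep = "\t", quote = "",
                          na.strings = "NA",
                          colClasses = c("character", "integer",
                                         "character", "numeric"))
        pull <- function(f) tab$weight[tab$feature == f]
        feats <- tab[tab$feature %in% c("nt", "dint"),
                     c("position", "sequence", "weight")]
        rownames(feats) <- NULL
        .rs1Cache$model <- list(intercept = pull("intercept"),
                                gcLow = pull("gc_low"),
                                gcHigh = pull("gc_high"),
                                features = feats)
    }
    .rs1Cache$model
}

#' Score 30-mer contexts with Rule Set 1
#'
#' Predicted cleavage efficiency in (0, 1) for each 30-mer context
#' `NNNN[20]NGGNNN`: the logistic transform of the intercept plus the
#' GC-deviation term plus the weights of all matching position-specific
#' nucleotide/dinucleotide features. The model is stateless; scoring a
#' batch equals scoring sequence by sequence.
#'
#' @param contexts character vector of 30-mers over ACGT with `GG` at
#'   positions 26-27 (the invariant part of the PAM). Anything else is an
#'   error; callers that tolerate unscorable candidates must drop them
#'   beforehand (see [addGuideScores()]).
#' @return numeric vector of scores in (0, 1).
#' @export
ruleSet1Score <- function(contexts) {
    if (!length(contexts)) return(numeric(0))
    if (any(nchar(contexts) != 30L))
        stop("Rule Set 1 requires 30-mer contexts")
    if (any(grepl("[^ACGT]", contexts)))
        stop("Rule Set 1 context contains non-ACGT characters")
    if (any(substr(contexts, 26L, 27L) != "GG"))
        stop("Rule Set 1 context must have 'GG' at positions 26-27")
    m <- ruleSet1Weights()
    score <- rep(m$intercept, length(contexts))
    gc <- nchar(gsub("[AT]", "", substr(contexts, 5L, 24L)))
    score <- score + ifelse(gc < 10L, (10L - gc) * m$gcLow,
                            ifelse(gc > 10L, (gc - 10L) * m$gcHigh, 0))
    f <- m$features
    for (i in seq_len(nrow(f))) {
        sub <- substr(contexts, f$position[i],
                      f$position[i] + nchar(f$sequence[i]) - 1L)
        score <- score + f$weight[i] * (sub == f$sequence[i])
    }
    1 / (1 + exp(-score))
}

#' Combine two individual guide scores into a pair score
#'
#' @param s1,s2 numeric vectors of individual scores in \[0, 1\].
#' @param method `"sum"` (pair score in \[0, 2\], the default scale on
#'   which the pair-score threshold `sp = 0.4` is defined) or
#'   `"product"` (in \[0, 1\]).
#' @return numeric vector of combined scores.
#' @examples
#' pairScore(0.6, 0.4)              # 1.0
#' pairScore(0.6, 0.4, "product")   # 0.24
#' @export
pairScore <- function(s1, s2, method = c("sum", "product")) {
    method <- match.arg(method)
    stopifnot(all(s1 >= 0 & s1 <= 1), all(s2 >= 0 & s2 <= 1))
    if (method == "sum") s1 + s2 else s1 * s2
}
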
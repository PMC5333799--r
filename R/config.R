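#' Create a design-run configuration
#'
#' Constructor for [DesignConfig-class] with the pipeline's standard
#' defaults. Argument names follow the tool's conventional short symbols.
#'
#' @param n maximum number of sgRNA pairs returned per target (default 10).
#' @param du,dd upstream/downstream design region lengths in bp
#'   (default 500), measured on the target's own strand.
#' @param eu,ed exclude-region lengths in bp between the target and each
#'   design region (default 100).
#' @param v diversity: maximum fraction of returned pairs containing the
#'   same protospacer (default 0.5; usage cap `max(1, floor(v * n))`).
#' @param si minimum individual Rule Set 1 score (default 0.2; 0 disables).
#' @param sp minimum combined pair score (default 0.4, on the scale set
#'   by `sc`). The default is defined on the sum scale and is applied
#'   unchanged when `sc = "product"`.
#' @param sc score combination, `"sum"` (default) or `"product"`.
#' @param r ranking method, `"score"` (default) or `"distance"`.
#' @param c construct method, `"none"` (default) or `"DECKO"`.
#' @param t off-target caps: an [OffTargetThreshold-class] or its string
#'   form (default `"1,0,0,x,x"`: the site itself, no other site within
#'   2 mismatches, bins 3-4 unlimited).
#' @param o output path prefix (default `"sgRNA_pairs"`).
#' @return a validated [DesignConfig-class].
#' @examples
#' designConfig()
#' designConfig(n = 5, t = "1,0,1,x,x", c = "DECKO")
#' @export
designConfig <- function(n = 10, du = 500, dd = 500, eu = 100, ed = 100,
                         v = 0.5, si = 0.2, sp = 0.4,
                         sc = "sum", r = "score", c = "none",
                         t = "1,0,0,x,x", o = "sgRNA_pairs") {
    ## the conventional parameter symbol `c` masks base::c here, so
    ## choice vectors are built with base::c explicitly
    sc <- match.arg(sc, base::c("sum", "product"))
    r <- match.arg(r, base::c("score", "distance"))
    c <- match.arg(c, base::c("none", "DECKO"))
    new("DesignConfig",
        n = as.integer(n), du = as.integer(du), dd = as.integer(dd),
        eu = as.integer(eu), ed = as.integer(ed),
        v = as.numeric(v), si = as.numeric(si), sp = as.numeric(sp),
        scoreCombination = sc, ranking = r, construct = c,
        threshold = offTargetThreshold(t), outPrefix = o)
}
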
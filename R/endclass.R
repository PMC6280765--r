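#' Merge per-replicate features into reproducible features
#'
#' Position-level support: a genomic position (per strand) is retained when
#' features from at least \code{minSupport} distinct replicates cover it;
#' maximal retained runs become merged features. Read and uuG counts are
#' re-aggregated by pooling all replicates' tracks over the merged
#' intervals, and each merged feature records how many replicates overlap
#' it.
#'
#' @param featureList List (length >= 2) of per-replicate feature
#'   \code{GRanges}.
#' @param minSupport Minimum number of supporting replicates (default 2).
#' @param tracks,uugTracks Optional lists of per-replicate
#'   \linkS4class{EndSignalTrack}s used to fill pooled \code{read_count} /
#'   \code{uuG_count}.
#' @return A \code{GRanges} with metadata \code{support}, \code{read_count},
#'   \code{uuG_count}, \code{cap_class}.
#' @export
mergeReplicable <- function(featureList, minSupport = 2L,
                            tracks = NULL, uugTracks = NULL) {
    if (length(featureList) < 2L)
        stop("feature merging requires at least 2 replicates")
    allf <- .concatGRanges(unname(featureList))
    out <- GenomicRanges::GRanges()
    if (length(allf)) {
        lens <- tapply(GenomicRanges::end(allf),
                       as.character(GenomicRanges::seqnames(allf)), max)
        for (s in unique(as.character(BiocGenerics::strand(allf)))) {
            for (ch in names(lens)) {
                total <- NULL
                for (gr in featureList) {
                    sub <- gr[as.character(BiocGenerics::strand(gr)) == s &
                              as.character(GenomicRanges::seqnames(gr)) == ch]
                    cv <- IRanges::coverage(
                        IRanges::reduce(GenomicRanges::ranges(sub)),
                        width = lens[[ch]])
                    total <- if (is.null(total)) cv else total + cv
                }
                sl <- IRanges::slice(total, lower = minSupport, rangesOnly = TRUE)
                if (length(sl))
                    out <- .concatGRanges(list(out,
                        GenomicRanges::GRanges(ch, sl, strand = s)))
            }
        }
    }
    out <- BiocGenerics::sort(out)
    support <- integer(length(out))
    for (gr in featureList)
        support <- support + as.integer(IRanges::overlapsAny(out, gr,
                                                             ignore.strand = FALSE))
    mcols(out)$support <- support
    rc <- rep(NA_real_, length(out)); uc <- rep(NA_real_, length(out))
    if (!is.null(tracks)) {
        rc <- Reduce(`+`, lapply(tracks, massInFeatures, features = out))
    }
    if (!is.null(uugTracks)) {
        uc <- Reduce(`+`, lapply(uugTracks, massInFeatures, features = out))
    }
    mcols(out)$read_count <- rc
    mcols(out)$uuG_count <- uc
    mcols(out)$cap_class <- rep("unclassified", length(out))
    out
}

#' Classify features as capped or noncapped by uuG fraction
#'
#' A feature is capped when at least \code{threshold} (default 10%,
#' boundary inclusive) of all pooled reads mapping within it carry an
#' upstream untemplated guanosine; otherwise noncapped. Features with zero
#' reads remain unclassified. Pooling is across all replicates of the
#' sample type: the pooled fraction is sum(uuG)/sum(reads), not the mean of
#' per-replicate fractions.
#'
#' @param features \code{GRanges} with \code{read_count} and \code{uuG_count}.
#' @param threshold Minimum uuG fraction for a cap call (default 0.10).
#' @return The \code{GRanges} with \code{cap_class} filled.
#' @export
classifyCap <- function(features, threshold = 0.10) {
    rc <- mcols(features)$read_count
    uc <- mcols(features)$uuG_count
    cls <- rep("unclassified", length(features))
    pos <- !is.na(rc) & rc > 0
    cls[pos] <- ifelse(uc[pos] / rc[pos] >= threshold, "capped", "noncapped")
    mcols(features)$cap_class <- cls
    features
}

#' Merge replicates and classify cap status in one step
#'
#' @inheritParams mergeReplicable
#' @inheritParams classifyCap
#' @return Merged, classified feature \code{GRanges}.
#' @export
endClass <- function(featureList, tracks, uugTracks,
                     minSupport = 2L, threshold = 0.10) {
    merged <- mergeReplicable(featureList, minSupport, tracks, uugTracks)
    classifyCap(merged, threshold)
}
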
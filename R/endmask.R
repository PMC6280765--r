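#' Dominant isoform of a gene
#'
#' The isoform whose exons contain the greatest weighted BODY read mass
#' (BODY coverage measures transcript abundance; 5P signal is concentrated
#' at termini). Ties are broken deterministically by greater exonic length,
#' then lexicographic transcript id.
#'
#' @param txset A \linkS4class{TranscriptSet}.
#' @param geneID Gene identifier.
#' @param bodyTrack BODY \linkS4class{EndSignalTrack}.
#' @return The dominant transcript id.
#' @export
dominantIsoform <- function(txset, geneID, bodyTrack) {
    info <- txInfo(txset)
    ids <- info$transcript_id[info$gene_id == geneID]
    if (!length(ids)) stop("no isoforms for gene ", geneID)
    if (length(ids) == 1L) return(ids)
    mass <- vapply(ids, function(id)
        sum(massInFeatures(bodyTrack, txExons(txset, id))), numeric(1))
    len <- info$length[match(ids, info$transcript_id)]
    ids[order(-mass, -len, ids)][1L]
}

#' Remove 5P signal inside capped features ("cap-masking")
#'
#' All signal at positions contained in replicable capped features is
#' discarded so that downstream cleavage statistics see only noncapped
#' (5'-monophosphate) ends.
#'
#' @param track A 5P \linkS4class{EndSignalTrack}.
#' @param cappedFeatures \code{GRanges} of capped features (same strand
#'   matching applies).
#' @return List: \code{track} (masked) and \code{maskedMass} (weight
#'   removed).
#' @export
capMask <- function(track, cappedFeatures) {
    res <- .trackErase(track, cappedFeatures)
    list(track = res$track, maskedMass = res$removed)
}

#' Project genomic 5P signal into spliced transcript coordinates
#'
#' Positions inside the transcript's exons (matching strand) map to offsets
#' from the transcript's 5' start, exon-spliced; minus-strand transcripts
#' reverse the offset axis. Intronic and intergenic signal is dropped.
#'
#' @param track A stranded \linkS4class{EndSignalTrack}.
#' @param txset A \linkS4class{TranscriptSet}.
#' @param id Transcript identifier.
#' @param maskedMass Cap-masked mass to record on the result (default 0).
#' @return A \linkS4class{TranscriptTrack}.
#' @export
projectToTranscript <- function(track, txset, id, maskedMass = 0) {
    ex <- txExons(txset, id)
    chrom <- as.character(GenomicRanges::seqnames(ex))[1L]
    strand <- as.character(BiocGenerics::strand(ex))[1L]
    L <- txLength(txset, id)
    p <- trackData(track)
    p <- p[p$chrom == chrom & p$strand == strand, , drop = FALSE]
    offs <- integer(); vals <- numeric()
    if (nrow(p)) {
        st0 <- GenomicRanges::start(ex) - 1L
        en0 <- GenomicRanges::end(ex)          # 0-based half-open
        cum <- c(0L, cumsum(en0 - st0))
        for (j in seq_along(st0)) {
            ii <- which(p$pos >= st0[j] & p$pos < en0[j])
            if (!length(ii)) next
            o <- cum[j] + (p$pos[ii] - st0[j])
            if (strand == "-") o <- L - 1L - o
            offs <- c(offs, o)
            vals <- c(vals, p$weight[ii])
        }
    }
    ord <- order(offs)
    new("TranscriptTrack", transcriptID = id, length = as.integer(L),
        offsets = as.integer(offs[ord]), values = vals[ord],
        maskedMass = as.numeric(maskedMass))
}

#' @rdname TranscriptTrack-class
#' @export
setMethod("maskedMass", "TranscriptTrack", function(x) x@maskedMass)

#' @rdname TranscriptTrack-class
#' @export
setMethod("totalMass", "TranscriptTrack", function(x) sum(x@values))

setMethod("show", "TranscriptTrack", function(object) {
    cat(sprintf("TranscriptTrack %s: L = %d nt, %d position(s), mass %g (masked %g)\n",
                object@transcriptID, object@length, length(object@offsets),
                sum(object@values), object@maskedMass))
})

#' Proportion of cleaved to total (cleaved + full-length) signal
#'
#' @param cleaved Signal at the cleavage site.
#' @param capped Capped (full-length) signal of the gene.
#' @return cleaved / (cleaved + capped); NA when both are zero.
#' @export
cleavageProportion <- function(cleaved, capped) {
    stopifnot(all(cleaved >= 0, na.rm = TRUE), all(capped >= 0, na.rm = TRUE))
    out <- cleaved / (cleaved + capped)
    out[cleaved == 0 & capped == 0] <- NA_real_
    out
}

#' Cap-masked transcript-coordinate 5P tracks for all genes
#'
#' Discards 5P signal inside replicable capped features, selects each
#' gene's dominant isoform from BODY coverage, and projects the remaining
#' signal into that isoform's spliced coordinates.
#'
#' @param track 5P \linkS4class{EndSignalTrack}.
#' @param cappedFeatures \code{GRanges} of capped features.
#' @param txset A \linkS4class{TranscriptSet}.
#' @param bodyTrack BODY \linkS4class{EndSignalTrack}.
#' @return List: \code{tracks} (named list of
#'   \linkS4class{TranscriptTrack}s, one per gene, named by dominant
#'   transcript id), \code{summary} (per-gene data.frame with capped,
#'   noncapped and masked mass), \code{maskedMass} (total).
#' @export
endMask <- function(track, cappedFeatures, txset, bodyTrack) {
    mk <- capMask(track, cappedFeatures)
    info <- txInfo(txset)
    genes <- unique(info$gene_id)
    tracks <- list()
    summ <- vector("list", length(genes))
    for (gi in seq_along(genes)) {
        g <- genes[gi]
        dom <- dominantIsoform(txset, g, bodyTrack)
        ex <- txExons(txset, dom)
        cappedMass <- sum(massInFeatures(track,
            IRanges::subsetByOverlaps(cappedFeatures, ex, ignore.strand = FALSE)))
        tt <- projectToTranscript(mk$track, txset, dom, maskedMass = cappedMass)
        tracks[[dom]] <- tt
        summ[[gi]] <- data.frame(gene_id = g, transcript_id = dom,
                                 capped_mass = cappedMass,
                                 noncapped_mass = sum(tt@values),
                                 stringsAsFactors = FALSE)
    }
    list(tracks = tracks, summary = do.call(rbind, summ),
         maskedMass = mk$maskedMass)
}
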
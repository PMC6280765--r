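#' Construct a TranscriptSet from exon ranges
#'
#' @param exons A \code{GRangesList} of exons per transcript (1-based closed
#'   coordinates, the GenomicRanges convention), named by transcript.
#' @param gene_id Character vector of gene ids, parallel to \code{exons}.
#' @param biotype Optional biotype vector (defaults to NA).
#' @param tpm Optional abundance vector in transcripts per million.
#' @return A \linkS4class{TranscriptSet}.
#' @export
TranscriptSet <- function(exons, gene_id, biotype = NA_character_, tpm = NA_real_) {
    exons <- GenomicRanges::GRangesList(lapply(exons, function(g) BiocGenerics::sort(g)))
    info <- data.frame(
        transcript_id = names(exons),
        gene_id = gene_id,
        chrom = vapply(exons, function(g)
            as.character(GenomicRanges::seqnames(g))[1L], character(1)),
        strand = vapply(exons, function(g)
            as.character(BiocGenerics::strand(g))[1L], character(1)),
        length = vapply(exons, function(g)
            sum(GenomicRanges::width(g)), integer(1)),
        tpm = rep_len(tpm, length(exons)),
        biotype = rep_len(biotype, length(exons)),
        stringsAsFactors = FALSE
    )
    rownames(info) <- NULL
    new("TranscriptSet", exons = exons, info = info)
}

#' Load a transcript annotation from GTF/GFF3
#'
#' Exon records are grouped by transcript; 1-based inclusive GTF coordinates
#' become the package's internal ranges. When a genome is supplied, every
#' transcript chromosome is checked against it.
#'
#' @param path GTF or GFF3 file.
#' @param genome Optional \linkS4class{GenomeIndex} for chromosome validation.
#' @return A \linkS4class{TranscriptSet}.
#' @export
loadAnnotation <- function(path, genome = NULL) {
    gr <- rtracklayer::import(path)
    gr <- gr[tolower(as.character(gr$type)) == "exon"]
    if (length(gr) == 0L)
        stop("no exon records found in ", path)
    tid <- gr$transcript_id
    if (is.null(tid) && !is.null(gr$Parent))
        tid <- vapply(as.list(gr$Parent), function(p)
            sub("^transcript:", "", p[1L]), character(1))
    if (is.null(tid) || anyNA(tid))
        stop("exon records must carry transcript_id (or Parent)")
    gid <- gr$gene_id
    if (is.null(gid)) gid <- tid
    bt <- gr$gene_biotype
    if (is.null(bt)) bt <- gr$transcript_biotype
    if (is.null(bt)) bt <- rep(NA_character_, length(gr))

    strands <- as.character(BiocGenerics::strand(gr))
    if (any(strands == "*"))
        stop("exon records must be stranded")
    byTx <- split(seq_along(gr), tid)
    for (ii in byTx) {
        if (length(unique(strands[ii])) != 1L)
            stop("transcript ", tid[ii[1L]], " has exons on multiple strands")
        if (length(unique(as.character(GenomicRanges::seqnames(gr)[ii]))) != 1L)
            stop("transcript ", tid[ii[1L]], " has exons on multiple chromosomes")
    }
    exl <- GenomicRanges::GRangesList(lapply(byTx, function(ii) gr[ii]))
    ts <- TranscriptSet(
        exl,
        gene_id = vapply(byTx, function(ii) gid[ii[1L]], character(1)),
        biotype = vapply(byTx, function(ii) as.character(bt[ii[1L]]), character(1))
    )
    if (!is.null(genome)) {
        bad <- setdiff(unique(ts@info$chrom), chromNames(genome))
        if (length(bad))
            stop("annotation references absent chromosome(s): ",
                 paste(bad, collapse = ", "))
    }
    ts
}

#' @rdname TranscriptSet-class
#' @export
setMethod("txInfo", "TranscriptSet", function(x) x@info)

#' @rdname TranscriptSet-class
#' @param id Transcript identifier.
#' @export
setMethod("txExons", "TranscriptSet", function(x, id) x@exons[[id]])

#' @rdname TranscriptSet-class
#' @export
setMethod("txLength", "TranscriptSet", function(x, id) {
    x@info$length[match(id, x@info$transcript_id)]
})

#' @rdname TranscriptSet-class
#' @export
setMethod("txTPM", "TranscriptSet", function(x, id) {
    x@info$tpm[match(id, x@info$transcript_id)]
})

setMethod("show", "TranscriptSet", function(object) {
    cat("TranscriptSet with", nrow(object@info), "transcript(s) in",
        length(unique(object@info$gene_id)), "gene(s)\n")
})

#' Estimate transcript abundance (TPM) from BODY exonic coverage
#'
#' Reads per exonic base, normalised so that abundances sum to one million.
#' BODY signal is nonstranded, so every track position falling inside a
#' transcript's exons contributes regardless of strand.
#'
#' @param txset A \linkS4class{TranscriptSet}.
#' @param bodyTrack An \linkS4class{EndSignalTrack} of BODY fragment starts.
#' @return The TranscriptSet with its \code{tpm} column filled.
#' @export
computeTPM <- function(txset, bodyTrack) {
    p <- trackData(bodyTrack)
    info <- txset@info
    mass <- numeric(nrow(info))
    if (nrow(p)) {
        pg <- GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$pos + 1L, p$pos + 1L))
        ex <- unlist(txset@exons, use.names = FALSE)
        txidx <- rep(seq_len(nrow(info)), lengths(txset@exons))
        hits <- GenomicRanges::findOverlaps(pg, ex, ignore.strand = TRUE)
        if (length(hits)) {
            w <- p$weight[S4Vectors::queryHits(hits)]
            tx <- txidx[S4Vectors::subjectHits(hits)]
            agg <- rowsum(w, tx)
            mass[as.integer(rownames(agg))] <- agg[, 1L]
        }
    }
    dens <- mass / info$length
    tot <- sum(dens)
    info$tpm <- if (tot > 0) dens / tot * 1e6 else rep(0, length(dens))
    txset@info <- info
    txset
}

#' Spliced transcript sequence in cDNA sense
#'
#' @param txset A \linkS4class{TranscriptSet}.
#' @param genome A \linkS4class{GenomeIndex}.
#' @param id Transcript identifier.
#' @return A character scalar of length \code{txLength(txset, id)}.
#' @export
transcriptSequence <- function(txset, genome, id) {
    ex <- txExons(txset, id)
    chrom <- as.character(GenomicRanges::seqnames(ex))[1L]
    pieces <- .seqViews(genome, chrom,
                        GenomicRanges::start(ex) - 1L, GenomicRanges::end(ex))
    s <- paste(pieces, collapse = "")
    if (as.character(BiocGenerics::strand(ex))[1L] == "-")
        s <- .revcomp(s)
    s
}
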
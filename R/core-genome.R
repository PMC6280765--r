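#' Build or read a GenomeIndex
#'
#' `readGenome()` loads a FASTA file; `GenomeIndex()` wraps in-memory
#' sequences. Sequence is stored uppercase so the accessor always returns
#' A/C/G/T/N.
#'
#' @param sequences A named character vector or \code{DNAStringSet}.
#' @return A \linkS4class{GenomeIndex}.
#' @examples
#' g <- GenomeIndex(c(chr1 = "ACGTACGTAC"))
#' getSeqRegion(g, "chr1", 0, 4)            # "ACGT"
#' getSeqRegion(g, "chr1", 0, 4, "-")       # "ACGT" reverse-complemented
#' @export
GenomeIndex <- function(sequences) {
    if (is.character(sequences))
        sequences <- Biostrings::DNAStringSet(toupper(sequences))
    else
        sequences <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
    new("GenomeIndex", sequences = sequences)
}

#' @rdname GenomeIndex
#' @param path Path to a FASTA file.
#' @export
readGenome <- function(path) {
    seqs <- Biostrings::readDNAStringSet(path)
    # keep only the first whitespace-delimited token of each FASTA header
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    GenomeIndex(seqs)
}

#' @rdname GenomeIndex-class
#' @export
setMethod("chromNames", "GenomeIndex", function(x) names(x@sequences))

#' @rdname GenomeIndex-class
#' @export
setMethod("chromLengths", "GenomeIndex", function(x) {
    stats::setNames(Biostrings::width(x@sequences), names(x@sequences))
})

setMethod("show", "GenomeIndex", function(object) {
    cat("GenomeIndex with", length(object@sequences), "chromosome(s),",
        sum(as.numeric(Biostrings::width(object@sequences))), "nt total\n")
})

#' Extract genome sequence for a region
#'
#' Coordinates are 0-based half-open. For \code{strand == "-"} the reverse
#' complement is returned, i.e. sequence in cDNA sense for a minus-strand
#' read.
#'
#' @param genome A \linkS4class{GenomeIndex}.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand "+" or "-".
#' @return A character scalar.
#' @export
getSeqRegion <- function(genome, chrom, start, end, strand = "+") {
    stopifnot(is(genome, "GenomeIndex"))
    if (!chrom %in% names(genome@sequences))
        stop("unknown chromosome: ", chrom)
    len <- length(genome@sequences[[chrom]])
    if (start < 0 || end > len || start >= end)
        stop(sprintf("region [%d,%d) out of bounds for %s (length %d)",
                     start, end, chrom, len))
    s <- Biostrings::subseq(genome@sequences[[chrom]], start + 1L, end)
    if (strand == "-")
        s <- Biostrings::reverseComplement(s)
    as.character(s)
}

## Vectorised region extraction used by masking / bias code: returns one
## string per (start,end) pair on a single chromosome, plus-strand sense.
.seqViews <- function(genome, chrom, start0, end0) {
    subj <- genome@sequences[[chrom]]
    as.character(Biostrings::extractAt(
        subj, IRanges::IRanges(start0 + 1L, end0)))
}

## concatenate GRanges with possibly disjoint seqlevels (the seqinfo-merge
## warning is expected and meaningless here)
.concatGRanges <- function(grl) {
    grl <- grl[vapply(grl, length, integer(1)) > 0L]
    if (!length(grl)) return(GenomicRanges::GRanges())
    suppressWarnings(do.call(c, unname(grl)))
}

.revcomp <- function(x) {
    out <- character(length(x))
    nz <- nchar(x) > 0L
    if (any(nz))
        out[nz] <- as.character(
            Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz])))
    out
}
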
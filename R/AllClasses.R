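#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRangesList
NULL

#' GenomeIndex: an indexed genome with a strand-aware region accessor
#'
#' Thin wrapper around a \link[Biostrings]{DNAStringSet} holding one entry per
#' chromosome. All region accessors take 0-based half-open coordinates;
#' minus-strand access returns the reverse complement, so sequence is always
#' delivered in cDNA (read) sense.
#'
#' @slot sequences A \code{DNAStringSet}, one element per chromosome.
#' @export
setClass("GenomeIndex", slots = c(sequences = "DNAStringSet"))

setValidity("GenomeIndex", function(object) {
    if (length(object@sequences) == 0L)
        return("genome must contain at least one chromosome")
    if (is.null(names(object@sequences)) || anyDuplicated(names(object@sequences)))
        return("chromosome names must be present and unique")
    if (any(Biostrings::width(object@sequences) <= 0L))
        return("chromosome lengths must be > 0")
    TRUE
})

#' TranscriptSet: exon models plus per-transcript metadata
#'
#' Exon intervals are held as a \code{GRangesList} named by transcript
#' (1-based, closed, the GenomicRanges convention); the \code{info} table
#' carries transcript_id, gene_id, chrom, strand, spliced length, abundance
#' (TPM, possibly NA until computed from a BODY library) and biotype.
#'
#' @slot exons \code{GRangesList} of exons per transcript, sorted 5' to 3'
#'   in genomic coordinates.
#' @slot info \code{data.frame} with one row per transcript.
#' @export
setClass("TranscriptSet", slots = c(exons = "GRangesList", info = "data.frame"))

setValidity("TranscriptSet", function(object) {
    info <- object@info
    need <- c("transcript_id", "gene_id", "chrom", "strand", "length", "tpm", "biotype")
    if (!all(need %in% names(info)))
        return(paste("info must contain columns:", paste(need, collapse = ", ")))
    if (length(object@exons) != nrow(info))
        return("exons and info must describe the same transcripts")
    if (!identical(names(object@exons), info$transcript_id))
        return("exons must be named by transcript_id in info order")
    if (!all(info$strand %in% c("+", "-")))
        return("strand must be '+' or '-'")
    ok <- vapply(seq_along(object@exons), function(i) {
        ex <- object@exons[[i]]
        if (length(ex) == 0L) return(FALSE)
        if (length(unique(as.character(GenomicRanges::seqnames(ex)))) != 1L) return(FALSE)
        st <- GenomicRanges::start(ex)
        en <- GenomicRanges::end(ex)
        if (is.unsorted(st, strictly = TRUE) && length(ex) > 1L) return(FALSE)
        if (length(ex) > 1L && any(st[-1L] <= en[-length(en)])) return(FALSE)
        sum(en - st + 1L) == info$length[i]
    }, logical(1))
    if (!all(ok))
        return("each transcript needs sorted non-overlapping exons on one chromosome whose widths sum to its length")
    if (any(!is.na(info$tpm) & info$tpm < 0))
        return("TPM values must be >= 0")
    TRUE
})

#' EndSignalTrack: sparse per-position weighted 5'-end counts
#'
#' One row per (chrom, strand, position) with a strictly positive weight.
#' Positions are 0-based. Strand is "+", "-" or "*" ("*" marks nonstranded
#' BODY signal, which stranded consumers apply to both strands).
#'
#' @slot positions \code{data.frame} with columns \code{chrom}, \code{strand},
#'   \code{pos} (integer, 0-based) and \code{weight} (numeric > 0).
#' @export
setClass("EndSignalTrack", slots = c(positions = "data.frame"))

setValidity("EndSignalTrack", function(object) {
    p <- object@positions
    if (!all(c("chrom", "strand", "pos", "weight") %in% names(p)))
        return("positions needs columns chrom, strand, pos, weight")
    if (nrow(p) == 0L) return(TRUE)
    if (!all(p$strand %in% c("+", "-", "*")))
        return("strand must be one of '+', '-', '*'")
    if (any(p$weight <= 0))
        return("all stored weights must be > 0")
    if (any(p$pos < 0L))
        return("positions must be >= 0")
    if (anyDuplicated(paste(p$chrom, p$strand, p$pos)))
        return("one row per (chrom, strand, pos) is required")
    TRUE
})

#' LibraryStats: per-sample normalisation quantities
#'
#' Holds the mean BODY fragment length F, total mapped BODY reads R_B, total
#' mapped 5P reads R_E and the derived 5P/BODY scaling factor S.
#'
#' @slot fragLength mean BODY fragment length in nt (F > 0).
#' @slot bodyReads total mapped BODY reads (R_B > 0).
#' @slot endReads total mapped 5P reads (R_E > 0).
#' @slot scale scaling factor S (> 0, or NA before estimation).
#' @export
setClass("LibraryStats", slots = c(fragLength = "numeric", bodyReads = "numeric",
                                   endReads = "numeric", scale = "numeric"))

setValidity("LibraryStats", function(object) {
    if (object@fragLength <= 0) return("fragment length F must be > 0")
    if (object@bodyReads <= 0 || object@endReads <= 0)
        return("read totals R_B and R_E must be > 0")
    if (!is.na(object@scale) && object@scale <= 0)
        return("scaling factor S must be > 0")
    TRUE
})

#' KdeConfig: kernel density settings for subtractive feature calling
#'
#' A truncated Laplace kernel evaluated on the integer genomic grid. The
#' truncation radius must be at least four bandwidths, where the kernel has
#' decayed below exp(-4) of its peak.
#'
#' @slot bandwidth Laplace bandwidth b in nt (default 15).
#' @slot radius truncation radius in nt (default 4 * b).
#' @export
setClass("KdeConfig", slots = c(bandwidth = "numeric", radius = "numeric"))

setValidity("KdeConfig", function(object) {
    if (object@bandwidth <= 0) return("bandwidth must be > 0")
    if (object@radius < 4 * object@bandwidth)
        return("truncation radius must be >= 4 * bandwidth")
    TRUE
})

#' KmerBiasModel: sequence-context reweighting for 5'-end counts
#'
#' Observed k-mer frequencies at read 5' ends (depth clipped to one read per
#' position) against background frequencies over annotated exon space; the
#' per-read weight is background/observed for the read's start context,
#' clipped to \code{cap}.
#'
#' @slot k k-mer size.
#' @slot window integer offsets (relative to the 5' end, cDNA sense) spanned
#'   by the context; length-2 c(from, to) with to - from + 1 == k.
#' @slot observed named numeric, observed context frequencies (sums to 1).
#' @slot background named numeric, background context frequencies (sums to 1).
#' @slot cap length-2 numeric, lower/upper bound on weights.
#' @export
setClass("KmerBiasModel", slots = c(k = "integer", window = "integer",
                                    observed = "numeric", background = "numeric",
                                    cap = "numeric"))

setValidity("KmerBiasModel", function(object) {
    if (length(object@window) != 2L ||
        object@window[2L] - object@window[1L] + 1L != object@k)
        return("window must span exactly k offsets")
    for (nm in c("observed", "background")) {
        f <- slot(object, nm)
        if (length(f) && abs(sum(f) - 1) > 1e-9)
            return(sprintf("%s frequencies must sum to 1", nm))
    }
    if (length(object@cap) != 2L || object@cap[1L] <= 0 ||
        object@cap[1L] > object@cap[2L])
        return("cap must be c(lower, upper) with 0 < lower <= upper")
    TRUE
})

#' TranscriptTrack: 5'-end signal in spliced transcript coordinates
#'
#' Weighted 5P counts at offsets from the start of the dominant isoform
#' (0-based, exon-spliced), together with the mass removed by cap-masking.
#'
#' @slot transcriptID transcript identifier.
#' @slot length spliced transcript length L in nt.
#' @slot offsets integer offsets in [0, L).
#' @slot values weights (>= 0), parallel to offsets.
#' @slot maskedMass weight removed from this transcript's span by cap-masking.
#' @export
setClass("TranscriptTrack", slots = c(transcriptID = "character", length = "integer",
                                      offsets = "integer", values = "numeric",
                                      maskedMass = "numeric"))

setValidity("TranscriptTrack", function(object) {
    if (length(object@offsets) != length(object@values))
        return("offsets and values must be parallel")
    if (length(object@offsets) &&
        (min(object@offsets) < 0L || max(object@offsets) >= object@length))
        return("offsets must lie in [0, length)")
    if (any(object@values < 0)) return("values must be >= 0")
    if (anyDuplicated(object@offsets)) return("offsets must be unique")
    TRUE
})
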
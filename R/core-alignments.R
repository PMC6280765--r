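## reference-consumed width per CIGAR (M/D/N/=/X ops); computed once per
## distinct CIGAR string since alignments repeat few distinct forms
.cigarRefWidth <- function(cigar) {
    u <- unique(cigar)
    w <- vapply(regmatches(u, gregexpr("[0-9]+[MIDNSHP=X]", u)), function(ops) {
        n <- as.integer(sub(".$", "", ops))
        op <- substr(ops, nchar(ops), nchar(ops))
        sum(n[op %in% c("M", "D", "N", "=", "X")])
    }, integer(1))
    w[match(cigar, u)]
}

#' Read alignments and reduce them to 5'-end records
#'
#' Each SAM/BAM record is reduced to the genomic coordinate of the read's
#' 5'-most aligned base in read orientation (the alignment end for
#' reverse-strand reads), its strand, the nucleotides soft-clipped from the
#' read's 5' end reported in cDNA sense (the base adjacent to the
#' genome-matching sequence is the last character), and the read's mapping
#' multiplicity. BODY records carry the leftmost (fragment start) coordinate
#' and are flagged nonstranded (\code{"*"}).
#'
#' Multiplicity is by default the number of reported best-score alignments
#' per read name (matching upstream aligners that emit all best-score hits as
#' primary records); \code{multiplicityTag} switches to an integer tag such
#' as \code{"NH"} instead.
#'
#' @param path SAM or BAM file (SAM is converted on the fly).
#' @param libraryType "5P" (stranded 5'-end library) or "BODY" (nonstranded).
#' @param genome Optional \linkS4class{GenomeIndex}; reference names are then
#'   validated against it.
#' @param multiplicityTag Optional BAM tag holding the hit count.
#' @return A \code{data.frame} with columns \code{read_id}, \code{chrom},
#'   \code{strand}, \code{pos} (0-based 5'-end), \code{uuN},
#'   \code{multiplicity}. One row per reported alignment.
#' @export
readEndAlignments <- function(path, libraryType = c("5P", "BODY"),
                              genome = NULL, multiplicityTag = NULL) {
    libraryType <- match.arg(libraryType)
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        path <- Rsamtools::asBam(path, destination = dest,
                                 overwrite = TRUE, indexDestination = FALSE)
    }
    what <- c("qname", "flag", "rname", "pos", "cigar", "seq")
    param <- Rsamtools::ScanBamParam(
        what = what,
        tag = if (is.null(multiplicityTag)) character() else multiplicityTag)
    b <- Rsamtools::scanBam(path, param = param)[[1L]]

    mapped <- !bitwAnd(b$flag, 4L)
    n_nocigar <- sum(mapped & (is.na(b$cigar) | b$cigar == "*"))
    if (n_nocigar > 0L)
        warning(n_nocigar, " mapped record(s) without CIGAR were rejected")
    keep <- mapped & !is.na(b$cigar) & b$cigar != "*" & !is.na(b$pos)
    if (!any(keep))
        return(data.frame(read_id = character(), chrom = character(),
                          strand = character(), pos = integer(),
                          uuN = character(), multiplicity = integer()))
    qname <- b$qname[keep]
    flag <- b$flag[keep]
    chrom <- as.character(b$rname[keep])
    pos1 <- b$pos[keep]
    cigar <- b$cigar[keep]
    seqs <- as.character(b$seq[keep])

    if (!is.null(genome)) {
        bad <- setdiff(unique(chrom), chromNames(genome))
        if (length(bad))
            stop("alignment references unknown chromosome(s): ",
                 paste(bad, collapse = ", "))
    }

    rev <- bitwAnd(flag, 16L) > 0L
    refw <- .cigarRefWidth(cigar)
    lead <- suppressWarnings(as.integer(sub("^(?:[0-9]+H)?([0-9]+)S.*$", "\\1", cigar,
                                            perl = TRUE)))
    lead[!grepl("^(?:[0-9]+H)?[0-9]+S", cigar, perl = TRUE)] <- 0L
    trail <- suppressWarnings(as.integer(sub("^.*?([0-9]+)S(?:[0-9]+H)?$", "\\1", cigar,
                                             perl = TRUE)))
    trail[!grepl("[0-9]+S(?:[0-9]+H)?$", cigar, perl = TRUE)] <- 0L

    if (libraryType == "BODY") {
        pos0 <- pos1 - 1L
        strand <- rep("*", length(pos0))
        uuN <- rep("", length(pos0))
    } else {
        pos0 <- ifelse(rev, pos1 - 1L + refw - 1L, pos1 - 1L)
        strand <- ifelse(rev, "-", "+")
        uuN <- character(length(pos0))
        fwd_clip <- !rev & lead > 0L
        uuN[fwd_clip] <- substr(seqs[fwd_clip], 1L, lead[fwd_clip])
        rev_clip <- rev & trail > 0L
        if (any(rev_clip)) {
            nc <- nchar(seqs[rev_clip])
            tailseq <- substr(seqs[rev_clip], nc - trail[rev_clip] + 1L, nc)
            uuN[rev_clip] <- .revcomp(tailseq)
        }
    }

    if (!is.null(multiplicityTag) && length(b$tag[[multiplicityTag]])) {
        mult <- as.integer(b$tag[[multiplicityTag]][keep])
    } else {
        cnt <- table(qname)
        mult <- as.integer(cnt[qname])
    }

    data.frame(read_id = qname, chrom = chrom, strand = strand,
               pos = as.integer(pos0), uuN = uuN, multiplicity = mult,
               stringsAsFactors = FALSE)
}
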
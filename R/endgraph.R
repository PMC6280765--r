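#' Kernel density configuration
#'
#' @param bandwidth Laplace bandwidth b in nt (default 15).
#' @param radius Kernel truncation radius (default 4 * bandwidth, where the
#'   kernel has fallen below exp(-4) of its peak).
#' @return A \linkS4class{KdeConfig}.
#' @export
kdeConfig <- function(bandwidth = 15, radius = 4 * bandwidth) {
    new("KdeConfig", bandwidth = as.numeric(bandwidth), radius = as.numeric(radius))
}

#' Library statistics container
#'
#' @param fragLength Mean BODY fragment length F (nt).
#' @param bodyReads Total mapped BODY reads R_B.
#' @param endReads Total mapped 5P reads R_E.
#' @param scale Scaling factor S (NA until estimated).
#' @return A \linkS4class{LibraryStats}.
#' @export
libraryStats <- function(fragLength, bodyReads, endReads, scale = NA_real_) {
    new("LibraryStats", fragLength = as.numeric(fragLength),
        bodyReads = as.numeric(bodyReads), endReads = as.numeric(endReads),
        scale = as.numeric(scale))
}

#' @rdname LibraryStats-class
#' @export
setMethod("scaleFactor", "LibraryStats", function(x) x@scale)

setMethod("show", "LibraryStats", function(object) {
    cat(sprintf("LibraryStats: F = %g nt, R_B = %g, R_E = %g, S = %g\n",
                object@fragLength, object@bodyReads, object@endReads,
                object@scale))
})

#' Mask template-switch strand-invasion artifacts
#'
#' Track positions whose immediately upstream genomic 4-mer (in cDNA sense)
#' matches the last four bases of the template-switching oligo with at most
#' one mismatch are removed: such 5' ends can arise from the oligo invading
#' the template rather than from a genuine RNA 5' end. Positions too close
#' to a chromosome edge to have four upstream bases are kept.
#'
#' @param track A stranded \linkS4class{EndSignalTrack}.
#' @param genome A \linkS4class{GenomeIndex}.
#' @param tso Template-switching oligo sequence (>= 4 nt; default the
#'   Smart-seq2 TSO).
#' @param maxMismatch Mismatch tolerance (default 1).
#' @return The masked \linkS4class{EndSignalTrack}; removed mass is the
#'   difference in \code{totalMass()}.
#' @export
maskStrandInvasion <- function(track, genome,
                               tso = "AAGCAGTGGTATCAACGCAGAGTACATGGG",
                               maxMismatch = 1L) {
    tso <- toupper(tso)
    if (nchar(tso) < 4L) stop("TSO sequence must be at least 4 nt")
    last4 <- substr(tso, nchar(tso) - 3L, nchar(tso))
    p <- trackData(track)
    if (!nrow(p)) return(track)
    drop <- logical(nrow(p))
    lens <- chromLengths(genome)
    for (ch in unique(p$chrom)) {
        len <- lens[[ch]]
        for (s in c("+", "-")) {
            ii <- which(p$chrom == ch & p$strand == s)
            if (!length(ii)) next
            if (s == "+") {
                st <- p$pos[ii] - 4L
                ok <- st >= 0L
                up <- rep(NA_character_, length(ii))
                if (any(ok)) up[ok] <- .seqViews(genome, ch, st[ok], st[ok] + 4L)
            } else {
                st <- p$pos[ii] + 1L
                ok <- st + 4L <= len
                up <- rep(NA_character_, length(ii))
                if (any(ok)) up[ok] <- .revcomp(.seqViews(genome, ch, st[ok], st[ok] + 4L))
            }
            mm <- rep(NA_integer_, length(ii))
            has <- !is.na(up)
            if (any(has)) {
                m <- matrix(0L, nrow = sum(has), ncol = 4L)
                for (j in 1:4)
                    m[, j] <- substr(up[has], j, j) != substr(last4, j, j)
                mm[has] <- rowSums(m)
            }
            drop[ii] <- !is.na(mm) & mm <= maxMismatch
        }
    }
    p <- p[!drop, , drop = FALSE]
    rownames(p) <- NULL
    new("EndSignalTrack", positions = p)
}

#' 5P/BODY scaling factor
#'
#' S = (2 F x 10^6 / sum_i TPM_i L_i) x (R_B / R_E): the expected ratio of
#' 5'-end-containing cDNA fragments to gene-body fragments under the
#' assumption that all RNA is full length. Multiplying 5P counts by S puts
#' them on the BODY library's per-position scale.
#'
#' @param stats A \linkS4class{LibraryStats} carrying F, R_B and R_E.
#' @param txset A \linkS4class{TranscriptSet} with TPM filled (see
#'   \code{\link{computeTPM}}).
#' @return The \linkS4class{LibraryStats} with its \code{scale} slot set.
#' @examples
#' ts <- TranscriptSet(GenomicRanges::GRangesList(
#'     t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000), "+")),
#'     gene_id = "g1", tpm = 1e6)
#' scaleFactor(scalingFactor(libraryStats(500, 1e6, 1e6), ts))  # 1
#' @export
scalingFactor <- function(stats, txset) {
    info <- txInfo(txset)
    if (anyNA(info$tpm))
        stop("transcript TPM values are not set; run computeTPM() first")
    denom <- sum(info$tpm * info$length)
    if (denom <= 0) stop("sum of TPM_i * L_i is zero")
    S <- (2 * stats@fragLength * 1e6 / denom) * (stats@bodyReads / stats@endReads)
    stats@scale <- S
    stats
}

#' Subtractive Laplace kernel density
#'
#' Fits a truncated Laplace kernel (bandwidth b) over the signed point set
#' (ER x S) - BR: scaled 5'-end counts contribute positive mass, BODY counts
#' negative mass. The density is evaluated at every integer position within
#' the truncation radius of any data point; outside that it is exactly zero.
#' Nonstranded ("*") BODY counts subtract from both strands.
#'
#' @param er Stranded 5P \linkS4class{EndSignalTrack} (after strand-invasion
#'   masking).
#' @param br BODY \linkS4class{EndSignalTrack}.
#' @param S Scaling factor from \code{\link{scalingFactor}}.
#' @param cfg A \linkS4class{KdeConfig}.
#' @return A list of segments, each \code{list(chrom, strand, start, dens)}
#'   with \code{start} the 0-based position of \code{dens[1]}.
#' @export
subtractiveDensity <- function(er, br, S, cfg = kdeConfig()) {
    b <- cfg@bandwidth
    R <- as.integer(round(cfg@radius))
    ep <- trackData(er)
    bp <- trackData(br)
    segs <- list()
    strands <- unique(ep$strand)
    strands <- strands[strands %in% c("+", "-")]
    for (ch in unique(ep$chrom)) {
        for (s in strands) {
            e <- ep[ep$chrom == ch & ep$strand == s, , drop = FALSE]
            if (!nrow(e)) next
            bsel <- bp$chrom == ch & (bp$strand == s | bp$strand == "*")
            bpt <- bp[bsel, , drop = FALSE]
            agg <- rowsum(c(S * e$weight, -bpt$weight), c(e$pos, bpt$pos))
            pts <- as.integer(rownames(agg))
            wts <- agg[, 1L]
            lo <- min(pts) - R
            hi <- max(pts) + R
            dens <- numeric(hi - lo + 1L)
            idx <- pts - lo + 1L
            for (d in -R:R) {
                kv <- exp(-abs(d) / b) / (2 * b)
                tgt <- idx + d
                dens[tgt] <- dens[tgt] + wts * kv
            }
            segs[[length(segs) + 1L]] <- list(chrom = ch, strand = s,
                                              start = lo, dens = dens)
        }
    }
    segs
}

#' Extract discrete features from a subtractive density
#'
#' Maximal runs of consecutive integer positions with strictly positive
#' density become features. Weighted 5P read counts and uuG counts are
#' aggregated per feature from the supplied (unmasked) tracks.
#'
#' @param density Output of \code{\link{subtractiveDensity}}.
#' @param track,uugTrack Optional \linkS4class{EndSignalTrack}s used to fill
#'   \code{read_count} / \code{uuG_count}.
#' @param minWidth Minimum feature width in nt (default 1).
#' @return A \code{GRanges} (1-based closed coordinates) with metadata
#'   columns \code{read_count}, \code{uuG_count}, \code{cap_class}.
#' @export
extractFeatures <- function(density, track = NULL, uugTrack = NULL, minWidth = 1L) {
    grl <- lapply(density, function(seg) {
        r <- rle(seg$dens > 0)
        if (!any(r$values)) return(GenomicRanges::GRanges())
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        keep <- r$values & r$lengths >= minWidth
        if (!any(keep)) return(GenomicRanges::GRanges())
        st0 <- seg$start + starts[keep] - 1L
        en0 <- seg$start + ends[keep]          # 0-based half-open end
        GenomicRanges::GRanges(seg$chrom, IRanges::IRanges(st0 + 1L, en0),
                               strand = seg$strand)
    })
    gr <- .concatGRanges(grl)
    gr <- BiocGenerics::sort(gr)
    mcols(gr)$read_count <- if (!is.null(track)) massInFeatures(track, gr)
                            else rep(NA_real_, length(gr))
    mcols(gr)$uuG_count <- if (!is.null(uugTrack)) massInFeatures(uugTrack, gr)
                           else rep(NA_real_, length(gr))
    mcols(gr)$cap_class <- rep("unclassified", length(gr))
    gr
}

#' Per-replicate 5'-end feature calling
#'
#' The full subtractive pipeline for one replicate: strand-invasion masking
#' of the 5P track, TPM estimation from the BODY track, scaling-factor
#' computation, subtractive Laplace density, and feature extraction. Feature
#' read/uuG counts are aggregated from the unmasked tracks.
#'
#' @param er,uug,br 5P signal, 5P uuG and BODY \linkS4class{EndSignalTrack}s.
#' @param genome A \linkS4class{GenomeIndex}.
#' @param txset A \linkS4class{TranscriptSet}.
#' @param tso Template-switching oligo (see \code{\link{maskStrandInvasion}}).
#' @param fragLength Mean BODY fragment length F in nt (default 500).
#' @param cfg A \linkS4class{KdeConfig}.
#' @return List: \code{features} (GRanges), \code{stats}
#'   (\linkS4class{LibraryStats}), \code{maskedMass} (signal removed as
#'   strand invasion).
#' @export
endGraph <- function(er, uug, br, genome, txset,
                     tso = "AAGCAGTGGTATCAACGCAGAGTACATGGG",
                     fragLength = 500, cfg = kdeConfig()) {
    txset <- computeTPM(txset, br)
    stats <- libraryStats(fragLength, totalMass(br), totalMass(er))
    stats <- scalingFactor(stats, txset)
    masked <- maskStrandInvasion(er, genome, tso)
    dens <- subtractiveDensity(masked, br, scaleFactor(stats), cfg)
    feats <- extractFeatures(dens, track = er, uugTrack = uug)
    list(features = feats, stats = stats,
         maskedMass = totalMass(er) - totalMass(masked))
}
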
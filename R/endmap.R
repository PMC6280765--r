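#' Per-nucleotide sequence complexity
#'
#' Distinct-substring-growth complexity: at each position i the number of new
#' distinct substrings ending there is i - l_i, where l_i is the longest
#' suffix of the first i bases that already occurred earlier in the read
#' (overlaps allowed). The score is sum(log2(i - l_i)) divided by read
#' length. Homopolymers and short tandem repeats score near zero; random
#' sequence scores well above typical thresholds.
#'
#' @param seqs Character vector of A/C/G/T/N reads.
#' @return Numeric vector of per-nucleotide complexity scores.
#' @export
iComplexity <- function(seqs) {
    if (any(!nzchar(seqs))) stop("empty read sequence")
    icomplexity_cpp(toupper(seqs))
}

#' Low-complexity read filter
#'
#' @param seqs Character vector of read sequences.
#' @param threshold Minimum per-nucleotide complexity (default 0.15); reads
#'   scoring below it are discarded.
#' @return Logical vector: TRUE = keep.
#' @examples
#' complexityFilter(c(strrep("A", 20), "ACGTTGCAGGTCCATAGCTA"))
#' @export
complexityFilter <- function(seqs, threshold = 0.15) {
    iComplexity(seqs) >= threshold
}

#' Does an alignment carry an upstream untemplated guanosine?
#'
#' TRUE iff the soft-clipped base immediately adjacent to the aligned 5' end
#' (the last character of the cDNA-sense uuN string) is G. Additional
#' clipped bases further upstream (template-switch oligo remnants) are
#' ignored.
#'
#' @param x Either the uuN character vector or an alignment \code{data.frame}
#'   from \code{\link{readEndAlignments}}.
#' @return Logical vector.
#' @export
extractUuG <- function(x) {
    uuN <- if (is.data.frame(x)) x$uuN else as.character(x)
    uuN[is.na(uuN)] <- ""
    nchar(uuN) > 0L & substr(uuN, nchar(uuN), nchar(uuN)) == "G"
}

## k-mer context at each 5' end, cDNA sense; NA when out of bounds or
## containing non-ACGT. aln: data.frame with chrom/strand/pos.
.startContexts <- function(aln, genome, window) {
    ctx <- rep(NA_character_, nrow(aln))
    k <- window[2L] - window[1L] + 1L
    for (ch in unique(aln$chrom)) {
        len <- chromLengths(genome)[[ch]]
        for (s in c("+", "-")) {
            ii <- which(aln$chrom == ch & aln$strand == s)
            if (!length(ii)) next
            if (s == "+") {
                st <- aln$pos[ii] + window[1L]
                en <- st + k
                ok <- st >= 0L & en <= len
                if (any(ok))
                    ctx[ii[ok]] <- .seqViews(genome, ch, st[ok], en[ok])
            } else {
                en <- aln$pos[ii] - window[1L] + 1L
                st <- en - k
                ok <- st >= 0L & en <= len
                if (any(ok))
                    ctx[ii[ok]] <- .revcomp(.seqViews(genome, ch, st[ok], en[ok]))
            }
        }
    }
    ctx[!is.na(ctx) & grepl("[^ACGT]", ctx)] <- NA_character_
    ctx
}

#' Fit a k-mer bias model from exonic read 5' ends
#'
#' Observed context frequencies are computed from the 5' ends of reads
#' falling inside annotated exons (same strand as the transcript), with the
#' read depth at every position clipped to one before counting so that
#' expression differences do not masquerade as sequence bias. Background
#' frequencies are taken over all annotated exonic positions. The stored
#' per-context weight is background/observed, clipped to \code{cap}.
#'
#' @param aln Alignment \code{data.frame} from \code{\link{readEndAlignments}}.
#' @param txset A \linkS4class{TranscriptSet}.
#' @param genome A \linkS4class{GenomeIndex}.
#' @param k Context size in nt (default 6).
#' @param window Length-2 integer: offsets of the context relative to the 5'
#'   end in cDNA sense (default c(-3, 2), i.e. three bases upstream through
#'   two downstream of the first aligned base).
#' @param cap Length-2 numeric bounds on the weights (default c(0.1, 10)).
#' @return A \linkS4class{KmerBiasModel}.
#' @export
fitBiasModel <- function(aln, txset, genome, k = 6L,
                         window = c(-3L, k - 4L), cap = c(0.1, 10)) {
    window <- as.integer(window)
    stopifnot(window[2L] - window[1L] + 1L == k)
    ex <- unlist(txset@exons, use.names = FALSE)
    pg <- GenomicRanges::GRanges(aln$chrom,
                                 IRanges::IRanges(aln$pos + 1L, aln$pos + 1L),
                                 strand = aln$strand)
    exonic <- IRanges::overlapsAny(pg, ex, ignore.strand = FALSE)
    aln <- aln[exonic, , drop = FALSE]
    if (!nrow(aln))
        stop("no exonic reads available to fit the bias model")
    # depth clip: one observation per distinct 5'-end position
    aln <- aln[!duplicated(paste(aln$chrom, aln$strand, aln$pos)), , drop = FALSE]
    obs_ctx <- .startContexts(aln, genome, window)
    obs_ctx <- obs_ctx[!is.na(obs_ctx)]
    if (!length(obs_ctx))
        stop("no usable start contexts for the bias model")
    obs <- table(obs_ctx)
    observed <- as.numeric(obs) / sum(obs)
    names(observed) <- names(obs)

    # background: every exonic position, transcript strand
    bgdf <- do.call(rbind, lapply(seq_along(txset@exons), function(i) {
        exi <- txset@exons[[i]]
        pos <- unlist(lapply(seq_along(exi), function(j)
            seq.int(GenomicRanges::start(exi)[j] - 1L,
                    GenomicRanges::end(exi)[j] - 1L)), use.names = FALSE)
        data.frame(chrom = as.character(GenomicRanges::seqnames(exi))[1L],
                   strand = as.character(BiocGenerics::strand(exi))[1L],
                   pos = pos, stringsAsFactors = FALSE)
    }))
    bgdf <- bgdf[!duplicated(paste(bgdf$chrom, bgdf$strand, bgdf$pos)), , drop = FALSE]
    bg_ctx <- .startContexts(bgdf, genome, window)
    bg_ctx <- bg_ctx[!is.na(bg_ctx)]
    bg <- table(bg_ctx)
    background <- as.numeric(bg) / sum(bg)
    names(background) <- names(bg)

    new("KmerBiasModel", k = as.integer(k), window = window,
        observed = observed, background = background, cap = as.numeric(cap))
}

#' Bias weights for a set of alignments
#'
#' background/observed frequency ratio of each read's 5'-end context,
#' clipped to the model's cap bounds. Contexts never seen among the exonic
#' training reads (no evidence of bias) get weight 1.
#'
#' @param model A \linkS4class{KmerBiasModel}.
#' @param aln Alignment \code{data.frame}.
#' @param genome A \linkS4class{GenomeIndex}.
#' @return Numeric weights, one per alignment row.
#' @export
biasWeights <- function(model, aln, genome) {
    ctx <- .startContexts(aln, genome, model@window)
    w <- rep(1, nrow(aln))
    known <- !is.na(ctx) & ctx %in% names(model@observed)
    if (any(known)) {
        o <- model@observed[ctx[known]]
        b <- model@background[ctx[known]]
        b[is.na(b)] <- 0
        w[known] <- pmin(model@cap[2L], pmax(model@cap[1L], b / o))
    }
    w
}

#' Proportional ("rich-get-richer") rescue of multimapping reads
#'
#' Uniquely mapping reads seed a per-position coverage map. Multimappers are
#' then processed in multiplicity bins 2, 3, ..., 100; within a bin, reads
#' are ordered from lowest possible genomic position to highest (ties broken
#' by read id). A read whose candidate locations carry any existing coverage
#' is assigned proportionally, P_i = C_i / sum_j C_j, and its weights update
#' the coverage map immediately; the bin is re-swept until a full pass
#' assigns nothing, after which the remaining reads get equal weights
#' P_i = 1/n. Reads with multiplicity above 100 are discarded.
#'
#' @param aln Alignment \code{data.frame} with one row per candidate
#'   location (columns read_id, chrom, strand, pos, multiplicity).
#' @return The same \code{data.frame} with a \code{weight} column; each
#'   read's weights sum to 1. Discarded rows are removed (with a warning).
#' @export
rescueMultimappers <- function(aln) {
    n <- nrow(aln)
    aln$weight <- rep(NA_real_, n)
    over <- aln$multiplicity > 100L
    if (any(over)) {
        warning(length(unique(aln$read_id[over])),
                " read(s) with multiplicity > 100 discarded")
        aln <- aln[!over, , drop = FALSE]
    }
    uniq <- aln$multiplicity == 1L
    aln$weight[uniq] <- 1
    if (any(!uniq)) {
        cov <- new.env(hash = TRUE, parent = emptyenv())
        key <- paste(aln$chrom, aln$strand, aln$pos, sep = "\r")
        ucov <- rowsum(rep(1, sum(uniq)), key[uniq])
        for (j in seq_len(nrow(ucov))) cov[[rownames(ucov)[j]]] <- ucov[j, 1L]
        idxByRead <- split(which(!uniq), aln$read_id[!uniq])
        mult <- vapply(idxByRead, function(ii) aln$multiplicity[ii[1L]], integer(1))
        minChrom <- vapply(idxByRead, function(ii) min(aln$chrom[ii]), character(1))
        minPos <- vapply(idxByRead, function(ii)
            as.numeric(min(aln$pos[ii][aln$chrom[ii] == min(aln$chrom[ii])])),
            numeric(1))
        for (m in sort(unique(mult))) {
            sel <- which(mult == m)
            sel <- sel[order(minChrom[sel], minPos[sel], names(idxByRead)[sel])]
            pending <- sel
            repeat {
                assigned_any <- FALSE
                still <- integer()
                for (r in pending) {
                    ii <- idxByRead[[r]]
                    kk <- key[ii]
                    C <- vapply(kk, function(k)
                        if (is.null(cov[[k]])) 0 else cov[[k]], numeric(1))
                    if (sum(C) > 0) {
                        w <- C / sum(C)
                        aln$weight[ii] <- w
                        for (j in seq_along(kk))
                            cov[[kk[j]]] <- (if (is.null(cov[[kk[j]]])) 0
                                             else cov[[kk[j]]]) + w[j]
                        assigned_any <- TRUE
                    } else {
                        still <- c(still, r)
                    }
                }
                pending <- still
                if (!assigned_any || !length(pending)) break
            }
            for (r in pending) {
                ii <- idxByRead[[r]]
                w <- rep(1 / length(ii), length(ii))
                aln$weight[ii] <- w
                kk <- key[ii]
                for (j in seq_along(kk))
                    cov[[kk[j]]] <- (if (is.null(cov[[kk[j]]])) 0
                                     else cov[[kk[j]]]) + w[j]
            }
        }
    }
    aln
}

#' Accumulate weighted 5'-end signal tracks
#'
#' track[pos] = sum over reads of read weight x bias weight. A second track
#' accumulates only reads carrying an upstream untemplated guanosine.
#'
#' @param aln Alignment \code{data.frame}; a \code{weight} column (e.g. from
#'   \code{\link{rescueMultimappers}}) is used if present, else weight 1.
#' @param biasModel Optional \linkS4class{KmerBiasModel}.
#' @param genome Required when \code{biasModel} is given.
#' @return List with elements \code{signal} and \code{uug}, both
#'   \linkS4class{EndSignalTrack}s.
#' @export
buildTracks <- function(aln, biasModel = NULL, genome = NULL) {
    w <- if ("weight" %in% names(aln)) aln$weight else rep(1, nrow(aln))
    if (!is.null(biasModel)) {
        if (is.null(genome)) stop("genome required for bias correction")
        w <- w * biasWeights(biasModel, aln, genome)
    }
    keep <- !is.na(w)
    uug <- extractUuG(aln)
    list(signal = EndSignalTrack(aln$chrom[keep], aln$strand[keep],
                                 aln$pos[keep], w[keep]),
         uug = EndSignalTrack(aln$chrom[keep & uug], aln$strand[keep & uug],
                              aln$pos[keep & uug], w[keep & uug]))
}

#' End-to-end 5'-end track construction from an alignment file
#'
#' Reads alignments, resolves multimappers, optionally applies k-mer bias
#' correction, and returns the weighted signal and uuG tracks plus simple
#' run statistics.
#'
#' @param path SAM/BAM file.
#' @param libraryType "5P" or "BODY".
#' @param genome A \linkS4class{GenomeIndex} (required for bias correction).
#' @param txset A \linkS4class{TranscriptSet} (required for bias correction).
#' @param bias Apply k-mer bias correction (default FALSE).
#' @param ... Passed to \code{\link{fitBiasModel}}.
#' @return List: \code{signal}, \code{uug}, \code{stats} (reads in/kept,
#'   multiplicity histogram).
#' @export
endMap <- function(path, libraryType = c("5P", "BODY"), genome = NULL,
                   txset = NULL, bias = FALSE, ...) {
    libraryType <- match.arg(libraryType)
    aln <- readEndAlignments(path, libraryType, genome = genome)
    aln <- rescueMultimappers(aln)
    model <- NULL
    if (bias) {
        if (is.null(genome) || is.null(txset))
            stop("bias correction needs both genome and annotation")
        model <- fitBiasModel(aln, txset, genome, ...)
    }
    tracks <- buildTracks(aln, model, genome)
    nreads <- length(unique(aln$read_id))
    list(signal = tracks$signal, uug = tracks$uug,
         stats = list(alignments = nrow(aln), reads = nreads,
                      multiplicity = table(aln$multiplicity[!duplicated(aln$read_id)])))
}
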
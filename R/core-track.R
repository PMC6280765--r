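#' Construct an EndSignalTrack
#'
#' Duplicate (chrom, strand, pos) entries are summed; zero-weight entries are
#' dropped, so the sparse map only ever stores positive weights.
#'
#' @param chrom,strand,pos,weight Parallel vectors (pos is 0-based).
#' @return An \linkS4class{EndSignalTrack}.
#' @examples
#' t <- EndSignalTrack("chr1", "+", c(5L, 6L, 6L), c(2, 1, 1))
#' totalMass(t)  # 4
#' @export
EndSignalTrack <- function(chrom = character(), strand = character(),
                           pos = integer(), weight = numeric()) {
    n <- max(length(chrom), length(strand), length(pos), length(weight))
    if (n > 0L) {
        d <- data.table::data.table(
            chrom = rep_len(as.character(chrom), n),
            strand = rep_len(as.character(strand), n),
            pos = rep_len(as.integer(pos), n),
            weight = rep_len(as.numeric(weight), n))
        d <- d[, list(weight = sum(weight)), by = c("chrom", "strand", "pos")]
        d <- d[d$weight > 0]
        data.table::setorderv(d, c("chrom", "strand", "pos"))
        p <- as.data.frame(d)
    } else {
        p <- data.frame(chrom = character(), strand = character(),
                        pos = integer(), weight = numeric())
    }
    new("EndSignalTrack", positions = p)
}

#' @rdname EndSignalTrack-class
#' @export
setMethod("trackData", "EndSignalTrack", function(x) x@positions)

#' @rdname EndSignalTrack-class
#' @export
setMethod("totalMass", "EndSignalTrack", function(x) sum(x@positions$weight))

setMethod("show", "EndSignalTrack", function(object) {
    p <- object@positions
    cat("EndSignalTrack:", nrow(p), "position(s),",
        format(sum(p$weight)), "total mass",
        if (nrow(p)) sprintf("(%s)", paste(unique(p$strand), collapse = "/")) else "",
        "\n")
})

## positions as width-1 GRanges ("*" rows stay "*")
.trackGRanges <- function(track) {
    p <- trackData(track)
    GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$pos + 1L, p$pos + 1L),
                           strand = p$strand, weight = p$weight)
}

#' Total track mass falling inside a set of features
#'
#' Strand-aware: a "*" (nonstranded) track row matches features on either
#' strand, and "*" features match track rows on either strand.
#'
#' @param track An \linkS4class{EndSignalTrack}.
#' @param features A \code{GRanges}.
#' @return Numeric vector of masses, parallel to \code{features}.
#' @export
massInFeatures <- function(track, features) {
    out <- numeric(length(features))
    p <- trackData(track)
    if (!nrow(p) || !length(features)) return(out)
    pg <- .trackGRanges(track)
    hits <- GenomicRanges::findOverlaps(pg, features, ignore.strand = FALSE)
    if (length(hits)) {
        agg <- rowsum(p$weight[S4Vectors::queryHits(hits)],
                      S4Vectors::subjectHits(hits))
        out[as.integer(rownames(agg))] <- agg[, 1L]
    }
    out
}

## drop all track rows whose position falls inside `features` (strand-aware)
.trackErase <- function(track, features) {
    p <- trackData(track)
    if (!nrow(p) || !length(features))
        return(list(track = track, removed = 0))
    pg <- .trackGRanges(track)
    hit <- IRanges::overlapsAny(pg, features, ignore.strand = FALSE)
    removed <- sum(p$weight[hit])
    p <- p[!hit, , drop = FALSE]
    rownames(p) <- NULL
    tr <- new("EndSignalTrack", positions = p)
    list(track = tr, removed = removed)
}

#' Write / read per-strand bedGraph files
#'
#' `writeBedGraph()` writes one 0-based half-open bedGraph file per strand
#' present in the track (suffixes \code{.plus.bedgraph} / \code{.minus.bedgraph};
#' a nonstranded track is written to \code{<prefix>.bedgraph}). Runs of
#' adjacent positions with equal weight are merged into one interval. Values
#' are printed with 17 significant digits so that read(write(t)) reproduces
#' the track exactly.
#'
#' @param track An \linkS4class{EndSignalTrack}.
#' @param prefix Output path prefix.
#' @return `writeBedGraph()` returns the written paths invisibly;
#'   `readBedGraph()` returns an \linkS4class{EndSignalTrack}.
#' @export
writeBedGraph <- function(track, prefix) {
    p <- trackData(track)
    strands <- c("+", "-", "*")
    suffix <- c(`+` = ".plus.bedgraph", `-` = ".minus.bedgraph", `*` = ".bedgraph")
    written <- character()
    present <- unique(p$strand)
    if (length(present) == 0L) present <- "*"
    for (s in strands) {
        if (!s %in% present) next
        path <- paste0(prefix, suffix[[s]])
        ps <- p[p$strand == s, , drop = FALSE]
        if (nrow(ps)) {
            ps <- ps[order(ps$chrom, ps$pos), , drop = FALSE]
            run <- cumsum(!(c(FALSE, ps$chrom[-1L] == ps$chrom[-nrow(ps)] &
                                       ps$pos[-1L] == ps$pos[-nrow(ps)] + 1L &
                                       ps$weight[-1L] == ps$weight[-nrow(ps)])))
            starts <- ps$pos[!duplicated(run)]
            ends <- ps$pos[rev(!duplicated(rev(run)))] + 1L
            lines <- sprintf("%s\t%d\t%d\t%.17g",
                             ps$chrom[!duplicated(run)], starts, ends,
                             ps$weight[!duplicated(run)])
        } else {
            lines <- character()
        }
        writeLines(lines, path)
        written <- c(written, path)
    }
    invisible(written)
}

#' @rdname writeBedGraph
#' @export
readBedGraph <- function(prefix) {
    suffix <- c(`+` = ".plus.bedgraph", `-` = ".minus.bedgraph", `*` = ".bedgraph")
    chrom <- character(); strand <- character(); pos <- integer(); weight <- numeric()
    found <- FALSE
    for (s in names(suffix)) {
        path <- paste0(prefix, suffix[[s]])
        if (!file.exists(path)) next
        found <- TRUE
        if (file.size(path) == 0L) next
        gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                       error = function(e)
                           stop("malformed bedGraph in ", path, ": ",
                                conditionMessage(e)))
        if (!length(gr)) next
        w <- GenomicRanges::width(gr)
        chrom <- c(chrom, rep(as.character(GenomicRanges::seqnames(gr)), w))
        strand <- c(strand, rep(s, sum(w)))
        pos <- c(pos, unlist(lapply(seq_along(gr), function(i)
            seq.int(GenomicRanges::start(gr)[i] - 1L, GenomicRanges::end(gr)[i] - 1L)),
            use.names = FALSE))
        weight <- c(weight, rep(gr$score, w))
    }
    if (!found)
        stop("no bedGraph files found for prefix ", prefix)
    EndSignalTrack(chrom, strand, pos, weight)
}
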
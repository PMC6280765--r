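## shared fixtures and independent oracles for the test suite

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

write_sam <- function(path, chromLens, records) {
    hdr <- c("@HD\tVN:1.6",
             sprintf("@SQ\tSN:%s\tLN:%d", names(chromLens), chromLens))
    writeLines(c(hdr, records), path)
    path
}

sam_record <- function(qname, flag, chrom, pos1, cigar, seq) {
    paste(qname, flag, chrom, pos1, 255L, cigar, "*", 0L, 0L, seq, "*",
          sep = "\t")
}

gtf_lines <- function(chrom, start1, end1, strand, gene, tx) {
    sprintf('%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            chrom, start1, end1, strand, gene, tx)
}

single_exon_txset <- function(chrom = "chr1", start1 = 1, end1 = 1000,
                              strand = "+", tpm = NA_real_,
                              id = "t1", gene = "g1") {
    TranscriptSet(GenomicRanges::GRangesList(stats::setNames(list(
        GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, end1), strand)),
        id)), gene_id = gene, tpm = tpm)
}

## direct O(N*M) truncated-Laplace convolution, independent of the
## package's sparse evaluation
kde_oracle <- function(grid, pts, wts, b = 15, R = 60) {
    K <- outer(grid, pts, function(x, p) {
        d <- abs(x - p)
        ifelse(d <= R, exp(-d / b) / (2 * b), 0)
    })
    as.vector(K %*% wts)
}

## density lookup across segments (0 outside any segment)
dens_at <- function(segs, chrom, strand, pos) {
    for (seg in segs) {
        if (seg$chrom == chrom && seg$strand == strand) {
            i <- pos - seg$start + 1L
            inside <- i >= 1L & i <= length(seg$dens)
            out <- numeric(length(pos))
            out[inside] <- seg$dens[i[inside]]
            return(out)
        }
    }
    numeric(length(pos))
}

## ungapped antisense window scan in plain R: minimum position-weighted
## penalty over all window starts (oracle for the C++ scanner)
ungapped_scan_oracle <- function(srna, target) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    s <- strsplit(chartr("U", "T", toupper(srna)), "")[[1L]]
    w <- strsplit(toupper(target), "")[[1L]]
    n <- length(s); L <- length(w)
    pen1 <- function(a, b) {
        if (comp[[a]] == b) return(0)
        if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(0.5)
        1
    }
    best <- Inf; best_t <- NA
    for (t in 0:(L - n)) {
        sc <- 0
        for (i in 1:n) {
            m <- if (i >= 2 && i <= 13) 2 else 1
            sc <- sc + m * pen1(s[i], w[t + n - i + 1L])
        }
        if (sc < best) { best <- sc; best_t <- t }
    }
    list(score = best, start = best_t)
}
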
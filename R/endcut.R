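## base coding shared with the C++ scan: A=0, C=1, G=2, T/U=3, other -1
.baseCodes <- function(seq) {
    v <- strsplit(chartr("Uu", "Tt", toupper(seq)), "")[[1L]]
    codes <- unname(c(A = 0L, C = 1L, G = 2L, T = 3L)[v])
    codes[is.na(codes)] <- -1L
    codes
}

#' Composition-preserving shuffles of a small RNA
#'
#' @param seq sRNA sequence (>= 15 nt; RNA or DNA alphabet).
#' @param n Number of shuffles (default 1000).
#' @param seed RNG seed; cohorts are reproducible per seed.
#' @return Character vector of \code{n} shuffled sequences.
#' @export
shuffleSrna <- function(seq, n = 1000L, seed = 1L) {
    if (nchar(seq) < 15L)
        stop("sRNA sequence shorter than 15 nt")
    ch <- strsplit(seq, "")[[1L]]
    withr::with_seed(seed, {
        vapply(seq_len(n), function(i)
            paste(sample(ch), collapse = ""), character(1))
    })
}

#' Position-weighted duplex penalty (Allen) score
#'
#' Sum of penalties over the sRNA-target duplex: mismatch 1.0, G:U wobble
#' 0.5, bulged nucleotide 1.0, each doubled at sRNA positions 2-13
#' (5'->3'). Lower means better complementarity.
#'
#' @param states Character vector of pairing states per sRNA position
#'   5'->3', each one of "match", "GU", "mismatch", "bulge".
#' @param positions Optional integer positions (default
#'   \code{seq_along(states)}), used when a bulge inserts an extra state.
#' @return Numeric score >= 0.
#' @examples
#' allenScore(rep("match", 21))                         # 0
#' allenScore(replace(rep("match", 21), 5, "GU"))        # 1.0
#' allenScore(replace(rep("match", 21), 20, "mismatch")) # 1.0
#' @export
allenScore <- function(states, positions = seq_along(states)) {
    pen <- c(match = 0, GU = 0.5, mismatch = 1, bulge = 1)
    if (!all(states %in% names(pen)))
        stop("unknown pairing state: ",
             paste(setdiff(states, names(pen)), collapse = ", "))
    mult <- ifelse(positions >= 2 & positions <= 13, 2, 1)
    sum(pen[states] * mult)
}

#' Predict sRNA target sites on a set of transcripts
#'
#' Scans every transcript for antisense duplexes of the sRNA allowing
#' Watson-Crick matches, G:U pairs, mismatches and single-nucleotide bulges
#' on either strand, scored with the position-weighted penalty table of
#' \code{\link{allenScore}}. Sites scoring at most \code{maxScore} are
#' reported; when several window variants produce the same cleavage
#' coordinate on a transcript, the best-scoring one is kept. The cleavage
#' coordinate is the transcript base paired to sRNA position 10 (0-based):
#' the 5'-most nucleotide of the 3' cleavage fragment, with the scissile
#' bond between the tenth and eleventh duplex nucleotides.
#'
#' @param srna sRNA sequence (character scalar).
#' @param transcripts Named character vector (or \code{DNAStringSet}) of
#'   transcript sequences in cDNA sense.
#' @param maxScore Maximum reported score (default 10).
#' @return \code{data.frame}: transcript_id, start (0-based window start),
#'   allen_score, cleavage_offset.
#' @export
predictTargets <- function(srna, transcripts, maxScore = 10) {
    if (!is.character(transcripts))
        transcripts <- stats::setNames(as.character(transcripts),
                                       names(transcripts))
    if (is.null(names(transcripts)))
        stop("transcripts must be named")
    sc <- .baseCodes(srna)
    res <- lapply(names(transcripts), function(id) {
        tc <- .baseCodes(transcripts[[id]])
        d <- scan_targets_cpp(tc, sc, maxScore)
        if (!nrow(d)) return(NULL)
        d <- d[order(d$cleavage, d$score), , drop = FALSE]
        d <- d[!duplicated(d$cleavage), , drop = FALSE]
        data.frame(transcript_id = id, start = d$start,
                   allen_score = d$score, cleavage_offset = d$cleavage,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    if (is.null(out))
        out <- data.frame(transcript_id = character(), start = integer(),
                          allen_score = numeric(), cleavage_offset = integer(),
                          stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Local fold change at predicted cleavage sites
#'
#' FC = (reads at the cleavage offset + 1) / (maximum reads at any single
#' offset within +/- window nt + 1). Offsets within 1 nt of the site are
#' excluded from the flank so slightly offset sRNA isoforms are not
#' penalised; the window is clipped at transcript bounds.
#'
#' @param ttrack A \linkS4class{TranscriptTrack} (cap-masked, sense strand).
#' @param offsets Integer vector of cleavage offsets (0-based).
#' @param window Flank half-width in nt: 20 or 50 (default 50).
#' @return \code{data.frame}: site_reads, flank_max, fc.
#' @export
siteFoldChange <- function(ttrack, offsets, window = 50L) {
    dense <- numeric(ttrack@length)
    if (length(ttrack@offsets))
        dense[ttrack@offsets + 1L] <- ttrack@values
    site <- ifelse(offsets >= 0L & offsets < ttrack@length,
                   dense[pmax(1L, offsets + 1L)], 0)
    site[offsets < 0L | offsets >= ttrack@length] <- 0
    fmax <- flank_max_cpp(dense, as.integer(offsets), as.integer(window))
    data.frame(site_reads = site, flank_max = fmax,
               fc = (site + 1) / (fmax + 1))
}

#' Empirical one-sided p-values against a shuffled-sRNA null
#'
#' p_fc tests whether the observed fold change exceeds the null fold-change
#' distribution; p_as whether the observed score is lower than the null
#' score distribution. Both use an add-one correction so p > 0 always (a
#' requirement of the downstream Fisher combination):
#' p_fc = (1 + #\{null FC >= obs\}) / (1 + N), and analogously with <= for
#' scores.
#'
#' @param fc,score Observed fold change(s) and Allen score(s).
#' @param nullFc,nullScore Pooled null fold changes / scores from the
#'   shuffled cohort, processed identically to the observed sRNA.
#' @return \code{data.frame}: p_fc, p_as.
#' @export
empiricalPvalues <- function(fc, score, nullFc, nullScore) {
    if (length(nullFc) == 0L || length(nullScore) == 0L)
        stop("empty null distribution")
    n1 <- length(nullFc); n2 <- length(nullScore)
    p_fc <- vapply(fc, function(x) (1 + sum(nullFc >= x)) / (1 + n1), numeric(1))
    p_as <- vapply(score, function(x) (1 + sum(nullScore <= x)) / (1 + n2), numeric(1))
    data.frame(p_fc = p_fc, p_as = p_as)
}

#' Combine p-values and adjust across the library
#'
#' Fisher's combination X = -2(ln p_fc + ln p_as) referred to chi-square
#' with 4 df, Benjamini-Hochberg adjustment across all sites tested in the
#' library, and the significance gate: adjusted p < 0.05, fold change > 1,
#' and at least one read per ten million transcriptome-mapping reads
#' (RPTM >= 1).
#'
#' @param calls \code{data.frame} with columns p_fc, p_as, fc, rptm.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return The \code{data.frame} with p_combined, p_adjusted, significant.
#' @export
combineAndAdjust <- function(calls, alpha = 0.05) {
    X <- -2 * (log(calls$p_fc) + log(calls$p_as))
    calls$p_combined <- stats::pchisq(X, df = 4, lower.tail = FALSE)
    calls$p_adjusted <- stats::p.adjust(calls$p_combined, method = "BH")
    calls$significant <- calls$p_adjusted < alpha & calls$fc > 1.0 &
        calls$rptm >= 1
    calls
}

#' Reads per ten million transcriptome-mapping reads
#'
#' @param siteReads Weighted reads at the site.
#' @param totalReads Total transcriptome-mapping reads (> 0).
#' @return siteReads * 1e7 / totalReads.
#' @export
rptm <- function(siteReads, totalReads) {
    if (any(totalReads <= 0)) stop("total transcriptome reads must be > 0")
    siteReads * 1e7 / totalReads
}

#' Detect sRNA-guided cleavage sites with an empirical null
#'
#' For each sRNA: predict target sites on the transcriptome, quantify the
#' local 5'-end fold change at each site on the cap-masked transcript
#' tracks, build the null from a cohort of composition-preserving shuffles
#' of the same sRNA processed identically, and compute one-sided empirical
#' p-values for fold change and duplex score. P-values are
#' Fisher-combined, BH-adjusted across all sites of all sRNAs in the
#' library, and gated on FC > 1 and RPTM >= 1.
#'
#' @param srnas Named character vector of sRNA sequences.
#' @param transcripts Named character vector (or \code{DNAStringSet}) of
#'   transcript sequences.
#' @param ttracks Named list of \linkS4class{TranscriptTrack}s (cap-masked),
#'   names matching \code{transcripts}.
#' @param nShuffles Cohort size per sRNA (default 1000).
#' @param seed RNG seed for the shuffles.
#' @param window Fold-change flank gating significance: 50 (default) or 20;
#'   both FC20 and FC50 are reported.
#' @param maxScore Maximum duplex penalty score for candidate sites.
#' @param totalReads Total transcriptome-mapping reads (default: summed
#'   track mass).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return \code{data.frame}, one row per tested site: srna, transcript_id,
#'   cleavage_offset, allen_score, site_reads, fc20, fc50, fc, p_fc, p_as,
#'   p_combined, p_adjusted, rptm, significant. sRNAs whose shuffled
#'   cohorts yield no null sites are skipped with a warning.
#' @export
endCut <- function(srnas, transcripts, ttracks, nShuffles = 1000L, seed = 1L,
                   window = 50L, maxScore = 10, totalReads = NULL,
                   alpha = 0.05) {
    if (!is.character(transcripts))
        transcripts <- stats::setNames(as.character(transcripts),
                                       names(transcripts))
    if (is.null(totalReads))
        totalReads <- sum(vapply(ttracks, function(t) sum(t@values), numeric(1)))
    ## transcript codes and dense value vectors, computed once for the
    ## cohort scans (nulls are processed identically to observed sites)
    txCodes <- lapply(transcripts, .baseCodes)
    txDense <- lapply(names(transcripts), function(id) {
        tt <- ttracks[[id]]
        dense <- numeric(tt@length)
        if (length(tt@offsets)) dense[tt@offsets + 1L] <- tt@values
        dense
    })
    quantify <- function(sites, w) {
        if (!nrow(sites))
            return(cbind(sites, site_reads = numeric(0), flank_max = numeric(0),
                         fc = numeric(0)))
        parts <- lapply(split(seq_len(nrow(sites)), sites$transcript_id),
                        function(ii) {
            tid <- sites$transcript_id[ii[1L]]
            cbind(sites[ii, , drop = FALSE],
                  siteFoldChange(ttracks[[tid]], sites$cleavage_offset[ii], w))
        })
        out <- do.call(rbind, parts)
        rownames(out) <- NULL
        out
    }
    all_calls <- list()
    for (nm in names(srnas)) {
        obs <- predictTargets(srnas[[nm]], transcripts, maxScore)
        if (!nrow(obs)) next
        q50 <- quantify(obs, 50L)
        q20 <- quantify(obs, 20L)
        ord <- order(q50$transcript_id, q50$cleavage_offset)
        q50 <- q50[ord, , drop = FALSE]
        q20 <- q20[order(q20$transcript_id, q20$cleavage_offset), , drop = FALSE]
        cohort <- shuffleSrna(srnas[[nm]], nShuffles, seed)
        null <- null_site_stats_cpp(txCodes, txDense, lapply(cohort, .baseCodes),
                                    maxScore, as.integer(window))
        nullFc <- null$fc; nullAs <- null$score
        if (!length(nullFc)) {
            warning("no null sites for sRNA ", nm, "; skipped")
            next
        }
        gating_fc <- if (as.integer(window) == 50L) q50$fc else q20$fc
        pv <- empiricalPvalues(gating_fc, q50$allen_score, nullFc, nullAs)
        all_calls[[nm]] <- data.frame(
            srna = nm, transcript_id = q50$transcript_id,
            cleavage_offset = q50$cleavage_offset,
            allen_score = q50$allen_score, site_reads = q50$site_reads,
            fc20 = q20$fc, fc50 = q50$fc, fc = gating_fc,
            p_fc = pv$p_fc, p_as = pv$p_as,
            rptm = rptm(q50$site_reads, totalReads),
            stringsAsFactors = FALSE)
    }
    if (!length(all_calls))
        return(data.frame())
    calls <- do.call(rbind, all_calls)
    rownames(calls) <- NULL
    calls <- combineAndAdjust(calls, alpha)
    calls[order(calls$srna, calls$transcript_id, calls$cleavage_offset), ]
}
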
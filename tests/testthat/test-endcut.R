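revcomp1 <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))

test_that("sRNA shuffles preserve length and composition, reproducibly", {
    expect_error(shuffleSrna("ACGUACGUACGU"), "15")
    expect_equal(unique(shuffleSrna(strrep("A", 16), n = 20)), strrep("A", 16))
    sq <- "ACGUUAGGCAUCGAUGCAAUG"
    sh <- shuffleSrna(sq, n = 50, seed = 3)
    expect_equal(length(sh), 50L)
    cnt0 <- sort(table(strsplit(sq, "")[[1]]))
    for (s in sh[1:10])
        expect_equal(sort(table(strsplit(s, "")[[1]])), cnt0)
    expect_identical(sh, shuffleSrna(sq, n = 50, seed = 3))
    expect_false(identical(sh, shuffleSrna(sq, n = 50, seed = 4)))
})

test_that("duplex scoring applies the position-weighted penalty table", {
    expect_equal(allenScore(rep("match", 21)), 0)
    # G:U at position 5: 0.5 doubled inside the 2-13 core
    expect_equal(allenScore(replace(rep("match", 21), 5, "GU")), 1)
    # mismatch at position 20: outside the core, not doubled
    expect_equal(allenScore(replace(rep("match", 21), 20, "mismatch")), 1)
    # mismatch at position 1: not doubled either
    expect_equal(allenScore(replace(rep("match", 21), 1, "mismatch")), 1)
    expect_equal(allenScore(replace(rep("match", 21), 13, "bulge")), 2)
    expect_error(allenScore(c("match", "wobble")), "unknown")
})

test_that("target prediction finds planted complements at the right coordinate", {
    set.seed(14)
    sr <- "TTGGATTGAAGGGAGCTCTAC"   # 21 nt
    ws <- 37L
    tx <- rand_dna(200)
    substr(tx, ws + 1L, ws + 21L) <- revcomp1(sr)
    hits <- predictTargets(sr, c(t1 = tx), maxScore = 3)
    perfect <- hits[hits$allen_score == 0, ]
    expect_equal(nrow(perfect), 1L)
    expect_equal(perfect$start, ws)
    # cleavage opposite sRNA positions 10/11: ws + n - 10
    expect_equal(perfect$cleavage_offset, ws + 21L - 10L)
    # no qualifying window -> empty
    none <- predictTargets(strrep("G", 21), c(t1 = strrep("G", 100)),
                           maxScore = 5)
    expect_equal(nrow(none), 0L)
})

test_that("scan scores agree with an ungapped oracle and find seed mismatches", {
    set.seed(15)
    sr <- "ACGGATGCATTTGCCTCAGGA"
    tx <- rand_dna(300)
    site <- revcomp1(sr)
    # one mismatch opposite sRNA position 5 (core, doubled): force the
    # target base paired to position 5 (window index n - 5) to mismatch
    s5 <- substr(sr, 5, 5)
    bad <- setdiff(c("A", "C", "G", "T"),
                   c(revcomp1(s5), ifelse(s5 %in% c("G", "T"),
                                          chartr("GT", "TG", s5), "")))
    substr(site, 21L - 5L + 1L, 21L - 5L + 1L) <- bad[1]
    substr(tx, 101L, 121L) <- site
    hits <- predictTargets(sr, c(t1 = tx), maxScore = 4)
    best <- hits[which.min(hits$allen_score), ]
    expect_equal(best$allen_score, 2)
    expect_equal(best$start, 100L)
    # oracle agreement at the planted window
    orc <- ungapped_scan_oracle(sr, tx)
    expect_equal(orc$score, 2)
    expect_equal(orc$start, 100L)
})

test_that("fold change uses add-one smoothing and a 1-nt exclusion zone", {
    tt <- function(off, val, L = 500L)
        new("TranscriptTrack", transcriptID = "t", length = L,
            offsets = as.integer(off), values = as.numeric(val),
            maskedMass = 0)
    # 9 reads at the site, flank max 4 -> (9+1)/(4+1) = 2
    r <- siteFoldChange(tt(c(100L, 120L), c(9, 4)), 100L, 50L)
    expect_equal(r$fc, 2)
    # empty track -> (0+1)/(0+1) = 1
    r0 <- siteFoldChange(tt(integer(), numeric()), 100L, 50L)
    expect_equal(r0$fc, 1)
    # 50 reads at site+1 are excluded; flank max elsewhere 0 -> FC = 6
    r1 <- siteFoldChange(tt(c(100L, 101L), c(5, 50)), 100L, 50L)
    expect_equal(r1$fc, 6)
    # window is clipped at transcript bounds
    r2 <- siteFoldChange(tt(c(3L, 30L), c(2, 7), L = 40L), 3L, 50L)
    expect_equal(r2$flank_max, 7)
    # the 20-nt window sees a narrower flank than the 50-nt window
    tr <- tt(c(100L, 130L), c(4, 9))
    expect_equal(siteFoldChange(tr, 100L, 20L)$fc, 5)
    expect_equal(siteFoldChange(tr, 100L, 50L)$fc, 0.5)
})

test_that("empirical p-values count null exceedances with add-one correction", {
    # observed above every null, N = 999 -> 1/1000
    p <- empiricalPvalues(10, 0, rep(1, 999), rep(8, 999))
    expect_equal(p$p_fc, 1 / 1000)
    expect_equal(p$p_as, 1 / 1000)
    # observed at the null median -> ~0.5
    nulls <- seq(0.5, 1.5, length.out = 999)
    expect_equal(empiricalPvalues(1, 5, nulls, nulls * 5)$p_fc, 0.5,
                 tolerance = 0.01)
    # counting example: nulls {1,1,2,3}, observed 2 -> (1+2)/5
    expect_equal(empiricalPvalues(2, 99, c(1, 1, 2, 3), c(99, 99))$p_fc, 0.6)
    expect_error(empiricalPvalues(1, 1, numeric(), numeric()), "empty")
})

test_that("Fisher combination and BH adjustment behave as defined", {
    base <- data.frame(p_fc = 1, p_as = 1, fc = 2, rptm = 10)
    expect_equal(combineAndAdjust(base)$p_combined, 1)
    # p_fc = p_as = 0.05: X = -4 ln 0.05, survival = exp(-X/2)(1 + X/2)
    b2 <- data.frame(p_fc = 0.05, p_as = 0.05, fc = 2, rptm = 10)
    X <- -2 * (log(0.05) + log(0.05))
    expect_equal(combineAndAdjust(b2)$p_combined, exp(-X / 2) * (1 + X / 2))
    expect_equal(combineAndAdjust(b2)$p_combined, 0.0175, tolerance = 1e-2)
    # BH with uniform p-values is the identity
    m <- data.frame(p_fc = rep(0.1, 8), p_as = rep(0.1, 8), fc = 2, rptm = 10)
    out <- combineAndAdjust(m)
    expect_equal(out$p_adjusted, rep(out$p_combined[1], 8))
    # significance gate: all three conditions required
    g <- data.frame(p_fc = c(0.001, 0.001, 0.001), p_as = c(0.001, 0.001, 0.001),
                    fc = c(2, 0.9, 2), rptm = c(10, 10, 0.5))
    expect_equal(combineAndAdjust(g)$significant, c(TRUE, FALSE, FALSE))
})

test_that("RPTM is reads per ten million transcriptome-mapping reads", {
    expect_equal(rptm(1, 1e7), 1)
    expect_equal(rptm(5, 5e7), 1)
    expect_equal(rptm(3, 1e6), 30)
    expect_error(rptm(1, 0), "> 0")
})

test_that("cleavage calls are invariant to transcript order", {
    set.seed(31)
    srnas <- c(mA = "TTGGATTGAAGGGAGCTCTAC", mB = "ACGGATGCATTTGCCTCAGGA")
    pl <- data.frame(srna = c("mA", "mB"), transcript = c("tx01", "tx03"),
                     offset = c(150L, 222L))
    sim <- simulateCleavageAssay(srnas, n_tx = 4, tx_len = 400, planted = pl,
                                 seed = 5)
    calls1 <- endCut(srnas, sim$transcripts, sim$tracks, nShuffles = 100,
                     seed = 9)
    ord <- rev(names(sim$transcripts))
    calls2 <- endCut(srnas, sim$transcripts[ord], sim$tracks[ord],
                     nShuffles = 100, seed = 9)
    rownames(calls1) <- rownames(calls2) <- NULL
    expect_equal(calls1, calls2)
    # both planted sites called significant
    sig <- calls1[calls1$significant, ]
    expect_true(all(paste(pl$srna, pl$transcript, pl$offset) %in%
                    paste(sig$srna, sig$transcript_id, sig$cleavage_offset)))
})
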
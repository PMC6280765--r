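test_that("strand-invasion masking removes TSO-complementary upstream contexts", {
    # genome: positions chosen so the 4-mer upstream of each track point is
    # controlled; TSO ends in TGGG
    g <- GenomeIndex(c(chr1 = paste0("AAAA", "TGGG", "CCCC", "TGCG", "ACGT",
                                     "AAAA")))
    tso <- "AAGCAGTGGTATCAACGCAGAGTACATGGG"
    # + strand: upstream 4-mer of pos 8 is [4,8) = TGGG (exact -> masked),
    # pos 16 is [12,16) = TGCG (1 mismatch -> masked),
    # pos 20 is [16,20) = ACGT (3 mismatches -> kept)
    tr <- EndSignalTrack(rep("chr1", 3), rep("+", 3), c(8L, 16L, 20L),
                         c(1, 1, 1))
    out <- maskStrandInvasion(tr, g, tso)
    expect_equal(trackData(out)$pos, 20L)
    expect_equal(totalMass(tr) - totalMass(out), 2)
    # minus strand: upstream of pos 11 (cDNA sense) is revcomp([12,16)) =
    # CGCA (>=2 mismatches -> kept); fabricate an exact match: upstream of
    # minus pos 3 is revcomp([4,8)) = CCCA -> 2 mismatches -> kept
    tr2 <- EndSignalTrack(rep("chr1", 2), rep("-", 2), c(11L, 3L), c(1, 1))
    expect_equal(nrow(trackData(maskStrandInvasion(tr2, g, tso))), 2L)
    # a minus-strand position whose downstream revcomp matches exactly:
    # genome CCCA at [8,12) -> revcomp = TGGG
    g2 <- GenomeIndex(c(chr1 = paste0(strrep("A", 8), "CCCA", strrep("A", 8))))
    tr3 <- EndSignalTrack("chr1", "-", 7L, 1)
    expect_equal(nrow(trackData(maskStrandInvasion(tr3, g2, tso))), 0L)
    expect_error(maskStrandInvasion(tr, g, "TGG"), "4 nt")
})

test_that("scaling factor follows its closed form", {
    # identity case: one transcript, TPM 1e6, L 1000, F 500, R_B = R_E
    ts <- single_exon_txset(end1 = 1000, tpm = 1e6)
    expect_identical(scaleFactor(scalingFactor(libraryStats(500, 1e6, 1e6), ts)),
                     1)
    # linear in R_B, inverse in R_E
    s0 <- scaleFactor(scalingFactor(libraryStats(300, 2e6, 1e6), ts))
    expect_equal(scaleFactor(scalingFactor(libraryStats(300, 4e6, 1e6), ts)),
                 2 * s0)
    expect_equal(scaleFactor(scalingFactor(libraryStats(300, 2e6, 2e6), ts)),
                 s0 / 2)
    # three-transcript case against an independent hand evaluation
    ex <- GenomicRanges::GRangesList(
        t1 = GenomicRanges::GRanges("c", IRanges::IRanges(1, 1000), "+"),
        t2 = GenomicRanges::GRanges("c", IRanges::IRanges(2001, 4000), "+"),
        t3 = GenomicRanges::GRanges("c", IRanges::IRanges(5001, 5500), "+"))
    ts3 <- TranscriptSet(ex, gene_id = c("g1", "g2", "g3"),
                         tpm = c(5e5, 3e5, 2e5))
    hand <- (2 * 450 * 1e6 / (5e5 * 1000 + 3e5 * 2000 + 2e5 * 500)) *
        (2e6 / 1e6)
    expect_equal(scaleFactor(scalingFactor(libraryStats(450, 2e6, 1e6), ts3)),
                 hand)
    ts0 <- single_exon_txset(end1 = 1000, tpm = 0)
    expect_error(scalingFactor(libraryStats(500, 1e6, 1e6), ts0), "zero")
})

test_that("subtractive density equals a direct convolution oracle", {
    set.seed(11)
    cfg <- kdeConfig(15)
    for (i in 1:10) {
        er <- EndSignalTrack("c", "+", sample(0:9999, 120), runif(120, 0.2, 5))
        br <- EndSignalTrack("c", "*", sample(0:9999, 150), runif(150, 0.2, 5))
        S <- runif(1, 0.5, 3)
        seg <- subtractiveDensity(er, br, S, cfg)[[1]]
        ed <- trackData(er); bd <- trackData(br)
        grid <- seg$start:(seg$start + length(seg$dens) - 1L)
        oracle <- kde_oracle(grid, c(ed$pos, bd$pos),
                             c(S * ed$weight, -bd$weight))
        expect_lt(max(abs(oracle - seg$dens)), 1e-9)
    }
    # empty input: no density, no features
    expect_equal(length(subtractiveDensity(EndSignalTrack(), EndSignalTrack(),
                                           1, cfg)), 0L)
    expect_equal(length(extractFeatures(list())), 0L)
})

test_that("a single 5P spike yields one feature spanning the kernel support", {
    cfg <- kdeConfig(15)
    er <- EndSignalTrack("c", "+", 5000L, 1)
    seg <- subtractiveDensity(er, EndSignalTrack(), 1, cfg)
    f <- extractFeatures(seg, track = er)
    expect_equal(length(f), 1L)
    # positive exactly over the truncation window [4940, 5060]
    expect_equal(GenomicRanges::start(f), 4941L)
    expect_equal(GenomicRanges::end(f), 5061L)
    expect_equal(f$read_count, 1)
    # two positive runs separated by a non-positive gap -> two features
    er2 <- EndSignalTrack(c("c", "c"), c("+", "+"), c(1000L, 2000L), c(1, 1))
    f2 <- extractFeatures(subtractiveDensity(er2, EndSignalTrack(), 1, cfg))
    expect_equal(length(f2), 2L)
})

test_that("self-subtraction, scaling monotonicity and linearity hold", {
    set.seed(21)
    cfg <- kdeConfig(15)
    pos <- sample(0:3000, 80); w <- runif(80, 0.5, 4)
    br <- EndSignalTrack("c", "*", pos, w)
    er_same <- EndSignalTrack("c", "+", pos, w)
    # ER = BR with S = 1: non-positive everywhere, no features
    expect_equal(length(extractFeatures(
        subtractiveDensity(er_same, br, 1, cfg))), 0L)
    # growing S never shrinks features (positive sets are nested)
    er <- EndSignalTrack("c", "+", sample(0:3000, 40), runif(40, 0.5, 4))
    d1 <- subtractiveDensity(er, br, 1, cfg)[[1]]
    d2 <- subtractiveDensity(er, br, 2.5, cfg)[[1]]
    pos1 <- d1$start + which(d1$dens > 0) - 1L
    pos2 <- d2$start + which(d2$dens > 0) - 1L
    expect_true(all(pos1 %in% pos2))
    # density is linear in the 5P signal (shared BR = 0)
    er1 <- EndSignalTrack("c", "+", sample(0:2000, 30), runif(30))
    er2 <- EndSignalTrack("c", "+", sample(0:2000, 30), runif(30))
    both <- EndSignalTrack(c(trackData(er1)$chrom, trackData(er2)$chrom),
                           "+", c(trackData(er1)$pos, trackData(er2)$pos),
                           c(trackData(er1)$weight, trackData(er2)$weight))
    dA <- subtractiveDensity(er1, EndSignalTrack(), 1, cfg)
    dB <- subtractiveDensity(er2, EndSignalTrack(), 1, cfg)
    dAB <- subtractiveDensity(both, EndSignalTrack(), 1, cfg)
    probe <- sample(0:2100, 200)
    expect_lt(max(abs(dens_at(dAB, "c", "+", probe) -
                      dens_at(dA, "c", "+", probe) -
                      dens_at(dB, "c", "+", probe))), 1e-9)
})
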
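test_that("low-complexity reads are discarded and random reads kept", {
    expect_false(complexityFilter(strrep("A", 20)))
    expect_false(complexityFilter(strrep("A", 50)))
    # periodic repeats score between homopolymers and random sequence
    expect_lt(iComplexity(strrep("AT", 25)), 1.5)
    expect_error(iComplexity(""), "empty")
    # default threshold keeps ordinary sequence
    expect_true(complexityFilter("ACGTTGCAGGTCCATAGCTAGCATGGATC"))
    # uniform-random 50-mers score far above the cutoff
    set.seed(42)
    reads <- vapply(seq_len(5000), function(i) rand_dna(50), character(1))
    scores <- iComplexity(reads)
    expect_gte(mean(scores >= 0.15), 0.99)
    expect_gt(min(scores), 0.15)
})

test_that("uuG calls use only the base adjacent to the genome match", {
    expect_false(extractUuG(""))
    expect_true(extractUuG("G"))
    expect_true(extractUuG("TG"))    # G adjacent to the aligned 5' end
    expect_false(extractUuG("GT"))
    expect_equal(extractUuG(c("", "G", "TG", "GT")),
                 c(FALSE, TRUE, TRUE, FALSE))
})

test_that("bias model recovers planted start-context enrichment", {
    set.seed(4)
    g <- GenomeIndex(c(chr1 = rand_dna(20000)))
    ts <- single_exon_txset(end1 = 20000)
    ctx2 <- substring(getSeqRegion(g, "chr1", 0, 20000), 1:19999, 2:20000)
    acpos <- which(ctx2 == "AC") - 1L
    other <- which(ctx2 != "AC") - 1L
    # distinct start positions, AC contexts 4x enriched over their share
    starts <- c(sample(acpos, 1000), sample(other, 3000))
    aln <- data.frame(read_id = sprintf("r%04d", seq_along(starts)),
                      chrom = "chr1", strand = "+", pos = starts,
                      uuN = "", multiplicity = 1L)
    bm <- fitBiasModel(aln, ts, g, k = 2L, window = c(0L, 1L))
    w_ac <- biasWeights(bm, aln[1, , drop = FALSE], g)
    expect_equal(w_ac, 0.25, tolerance = 0.1)
    # reads matching the background distribution get weights near 1
    aln2 <- data.frame(read_id = sprintf("q%04d", 1:4000), chrom = "chr1",
                       strand = "+", pos = sample(0:19998, 4000), uuN = "",
                       multiplicity = 1L)
    bm2 <- fitBiasModel(aln2, ts, g, k = 2L, window = c(0L, 1L))
    expect_equal(unname(biasWeights(bm2, aln2[1:100, ], g)), rep(1, 100),
                 tolerance = 0.15)
    expect_error(fitBiasModel(aln[0, ], ts, g, k = 2L, window = c(0L, 1L)),
                 "exonic")
})

test_that("stacked reads contribute depth 1 to the observed k-mer matrix", {
    set.seed(9)
    g <- GenomeIndex(c(chr1 = rand_dna(2000)))
    ts <- single_exon_txset(end1 = 2000)
    # 100 reads stacked at one position + 1 read elsewhere: both contexts
    # must be observed with equal frequency
    aln <- data.frame(read_id = sprintf("r%03d", 1:101), chrom = "chr1",
                      strand = "+", pos = c(rep(500L, 100), 900L), uuN = "",
                      multiplicity = 1L)
    bm <- fitBiasModel(aln, ts, g, k = 2L, window = c(0L, 1L))
    obs <- bm@observed
    expect_equal(sum(obs), 1)
    expect_true(all(obs %in% c(0.5, 1)))   # two contexts (or one if equal)
})

test_that("proportional rescue follows the published assignment rules", {
    base <- function(id, pos, mult)
        data.frame(read_id = id, chrom = "chr1", strand = "+", pos = pos,
                   multiplicity = mult)
    # coverage 3 vs 1 -> weights 0.75 / 0.25
    aln <- rbind(base(c("u1", "u2", "u3"), 100L, 1L), base("u4", 200L, 1L),
                 base(c("m1", "m1"), c(100L, 200L), 2L))
    r <- rescueMultimappers(aln)
    expect_equal(r$weight[r$read_id == "m1"], c(0.75, 0.25))
    # zero coverage everywhere -> equal weights 1/n
    aln2 <- base(c("m1", "m1", "m1"), c(10L, 20L, 30L), 3L)
    r2 <- rescueMultimappers(aln2)
    expect_equal(r2$weight, rep(1 / 3, 3))
    # cascade: m1 resolved by unique coverage, its assignment then
    # resolves m2
    aln3 <- rbind(base("u1", 100L, 1L),
                  base(c("m1", "m1"), c(100L, 300L), 2L),
                  base(c("m2", "m2"), c(300L, 500L), 2L))
    r3 <- rescueMultimappers(aln3)
    expect_equal(r3$weight[r3$read_id == "m1"], c(1, 0))
    # m2 sees coverage 0 at 300 (m1 put nothing there) -> 1/n fallback
    expect_equal(r3$weight[r3$read_id == "m2"], c(0.5, 0.5))
    # multiplicity > 100 discarded with a warning
    aln4 <- base(rep("m9", 101), seq(0L, by = 10L, length.out = 101), 101L)
    expect_warning(r4 <- rescueMultimappers(aln4), "discarded")
    expect_equal(nrow(r4), 0L)
})

test_that("rescue matches the step-by-step replay oracle on random instances", {
    set.seed(13)
    for (i in 1:30) {
        fx <- makeMultimapFixture(sample(2:20, 1), sample(2:5, 1), seed = i)
        r <- rescueMultimappers(fx$alignments)
        m <- merge(r, fx$expected, by = c("read_id", "chrom", "strand", "pos"))
        expect_equal(nrow(m), nrow(r))
        expect_lt(max(abs(m$weight.x - m$weight.y)), 1e-9)
    }
    # determinism: repeated runs are identical
    fx <- makeMultimapFixture(12, 4, seed = 99)
    expect_identical(rescueMultimappers(fx$alignments),
                     rescueMultimappers(fx$alignments))
})

test_that("track building conserves read mass and applies weights", {
    aln <- data.frame(read_id = c("a", "b", "c"), chrom = "chr1",
                      strand = "+", pos = c(5L, 5L, 9L), uuN = c("", "G", ""),
                      multiplicity = 1L)
    tr <- buildTracks(aln)
    expect_equal(trackData(tr$signal)$weight, c(2, 1))
    expect_equal(totalMass(tr$signal), 3)
    expect_equal(totalMass(tr$uug), 1)
    # weighted reads multiply through
    aln$weight <- c(0.75, 0.5, 1)
    tr2 <- buildTracks(aln)
    expect_equal(totalMass(tr2$signal), 2.25)
    # conservation on a larger random fixture
    set.seed(3)
    n <- 100
    aln3 <- data.frame(read_id = sprintf("r%03d", 1:n), chrom = "chr1",
                       strand = sample(c("+", "-"), n, TRUE),
                       pos = sample.int(50L, n, TRUE), uuN = "",
                       multiplicity = 1L, weight = runif(n))
    expect_equal(totalMass(buildTracks(aln3)$signal), sum(aln3$weight))
})
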
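test_that("config validation rejects out-of-range rates and depths", {
    expect_error(simConfig(capped_uug_rate = 1.5), "rates")
    expect_error(simConfig(xrn1_removal = -0.1), "rates")
    expect_error(simConfig(depth_5p = 0), "depths")
})

test_that("simulated outputs parse with the package readers and match truth", {
    cfg <- simConfig(rng_seed = 5, n_genes = 20, n_chroms = 2,
                     depth_5p = 10000, depth_body = 10000)
    sim <- simulateDataset(cfg, dir = withr::local_tempdir())
    genome <- readGenome(sim$paths$genome)
    txset <- loadAnnotation(sim$paths$annotation, genome)
    expect_equal(nrow(txInfo(txset)), 20L)
    aln <- readEndAlignments(sim$paths$sam_5p[1], "5P", genome = genome)
    # depth is exact (multinomial allocation), minus rare boundary drops
    expect_equal(nrow(aln), nrow(sim$truth$labels))
    expect_gte(nrow(aln), 0.98 * cfg$depth_5p)
    # per-read truth agreement: label table join by read id
    lab <- sim$truth$labels
    m <- merge(aln, lab, by = "read_id")
    expect_equal(nrow(m), nrow(aln))
    # uuG flags in the SAM reproduce the truth labels
    expect_equal(extractUuG(m$uuN), m$uug)
    # capped reads sit within jitter of the annotated TSS
    tss <- sim$truth$tss
    mc <- m[m$label == "capped", ]
    d <- abs(mc$pos - tss$tss0[match(mc$gene_id, tss$gene_id)])
    expect_equal(unname(stats::quantile(d, 0.99)), 6, tolerance = 3)
    # read strands match gene strands
    expect_equal(mc$strand, tss$strand[match(mc$gene_id, tss$gene_id)])
    # genome sequence at capped forward 5' ends matches the read core
    b <- readEndAlignments(sim$paths$sam_body[1], "BODY", genome = genome)
    expect_equal(nrow(b), cfg$depth_body)
    expect_true(all(b$strand == "*"))
})

test_that("simulated uuG fraction converges to the configured rates", {
    cfg <- simConfig(rng_seed = 2, n_genes = 20, n_chroms = 2,
                     depth_5p = 10000, depth_body = 1000)
    sim <- simulateDataset(cfg, dir = withr::local_tempdir())
    lab <- sim$truth$labels
    capped <- lab[lab$label == "capped", ]
    expect_equal(mean(capped$uug), 0.15, tolerance = 0.02 / 0.15)
    noncap <- lab[lab$label != "capped", ]
    expect_equal(mean(noncap$uug), 0.02, tolerance = 0.5)
})

test_that("5P depth is stable across seeds", {
    tot <- vapply(1:3, function(s) {
        cfg <- simConfig(rng_seed = s, n_genes = 10, n_chroms = 1,
                         depth_5p = 5000, depth_body = 1000)
        nrow(simulateDataset(cfg, dir = withr::local_tempdir())$truth$labels)
    }, numeric(1))
    expect_true(all(abs(tot - 5000) / 5000 <= 0.02))
})

test_that("exonuclease mode removes the configured fraction of noncapped reads", {
    base <- list(rng_seed = 7, n_genes = 10, n_chroms = 1, depth_5p = 8000,
                 depth_body = 1000)
    ctrl <- simulateDataset(do.call(simConfig, base),
                            dir = withr::local_tempdir())
    full <- simulateDataset(do.call(simConfig, c(base, xrn1_mode = TRUE,
                                                 xrn1_removal = 1.0)),
                            dir = withr::local_tempdir())
    # removal fraction 1.0 -> no noncapped-label reads remain
    expect_equal(sum(full$truth$labels$label != "capped"), 0L)
    # capped reads are identical to the control run (same seed)
    expect_equal(full$truth$labels$label,
                 ctrl$truth$labels$label[ctrl$truth$labels$label == "capped"])
    part <- simulateDataset(do.call(simConfig, c(base, xrn1_mode = TRUE)),
                            dir = withr::local_tempdir())
    nc0 <- sum(ctrl$truth$labels$label != "capped")
    nc1 <- sum(part$truth$labels$label != "capped")
    expect_equal(nc1 / nc0, 0.1, tolerance = 0.2)
})

test_that("planted cleavage sites appear in the genome and the read stream", {
    sr <- "TTGGATTGAAGGGAGCTCTAC"
    pl <- data.frame(gene = "g003", srna = sr, offset = 300L,
                     efficiency = 0.3)
    cfg <- simConfig(rng_seed = 4, n_genes = 10, n_chroms = 1,
                     depth_5p = 5000, depth_body = 1000, cleavage_sites = pl)
    sim <- simulateDataset(cfg, dir = withr::local_tempdir())
    lab <- sim$truth$labels
    cl <- lab[lab$label == "cleavage", ]
    expect_true(all(cl$gene_id == "g003"))
    expect_true(all(cl$offset == 300L))
    expect_gt(nrow(cl), 0)
    # the planted antisense site is present in the transcript sequence
    genome <- readGenome(sim$paths$genome)
    txset <- loadAnnotation(sim$paths$annotation, genome)
    txs <- transcriptSequence(txset, genome, "g003.1")
    hits <- predictTargets(sr, c(tx = txs), maxScore = 0)
    expect_true(300L %in% hits$cleavage_offset)
    # a site outside the transcript is an error
    bad <- data.frame(gene = "g003", srna = sr, offset = 5L, efficiency = 0.3)
    expect_error(simulateDataset(simConfig(rng_seed = 4, n_genes = 10,
                                           n_chroms = 1, depth_5p = 100,
                                           depth_body = 100,
                                           cleavage_sites = bad),
                                 dir = withr::local_tempdir()),
                 "outside")
})

test_that("multimapper fixtures reproduce hand-computable cases", {
    # single read, two loci, no unique coverage -> 0.5/0.5
    aln <- data.frame(read_id = "m1", chrom = "chr1", strand = "+",
                      pos = c(10L, 20L), multiplicity = 2L)
    expect_equal(rescueMultimappers(aln)$weight, c(0.5, 0.5))
    # fixtures are reproducible and their oracle weights sum to 1 per read
    fx <- makeMultimapFixture(10, 4, seed = 7)
    fx2 <- makeMultimapFixture(10, 4, seed = 7)
    expect_identical(fx, fx2)
    sums <- tapply(fx$expected$weight, fx$expected$read_id, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("cleavage assay tracks respect the background stack cap", {
    srnas <- c(m1 = "TTGGATTGAAGGGAGCTCTAC")
    pl <- data.frame(srna = "m1", transcript = "tx01", offset = 100L)
    sim <- simulateCleavageAssay(srnas, n_tx = 3, tx_len = 300, planted = pl,
                                 site_reads = 12, max_stack = 2, seed = 3)
    for (id in names(sim$tracks)) {
        v <- sim$tracks[[id]]@values
        off <- sim$tracks[[id]]@offsets
        planted_here <- pl$offset[pl$transcript == id]
        expect_true(all(v[!off %in% planted_here] <= 2))
    }
    expect_gte(sim$tracks[["tx01"]]@values[
        sim$tracks[["tx01"]]@offsets == 100L], 12)
    # planted target site is present in the transcript
    hits <- predictTargets(srnas[[1]], sim$transcripts["tx01"], maxScore = 0)
    expect_true(100L %in% hits$cleavage_offset)
})
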
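#' Configuration for the synthetic paired-library generator
#'
#' The defaults emulate the data regime the pipeline targets: a few hundred
#' expressed genes, log-normally distributed abundances, capped 5' ends
#' piling at the TSS with ~15% upstream-untemplated-G, noncapped
#' degradation 5' ends biased toward 3' gene regions with ~2% uuG, optional
#' planted sRNA cleavage products, a nonstranded BODY library tiling
#' transcripts, and an optional in-vitro 5'->3' exonuclease treatment mode
#' that depletes noncapped ends.
#'
#' @param rng_seed Integer seed; all outputs are reproducible per seed.
#' @param n_genes Number of genes (one single-exon transcript each).
#' @param n_chroms Number of chromosomes genes are distributed over.
#' @param gene_length Length-2 range of transcript lengths (nt).
#' @param intergenic Length-2 range of intergenic gaps (nt).
#' @param tpm_meanlog,tpm_sdlog Log-normal expression model; abundances are
#'   normalised to sum to one million (TPM).
#' @param capped_uug_rate uuG probability for capped reads (default 0.15).
#' @param noncapped_uug_rate uuG probability for noncapped reads (default 0.02).
#' @param tss_jitter_sd Positional jitter of capped 5' ends around the TSS (nt).
#' @param degradation_fraction Fraction of a gene's 5P reads that are
#'   degradation products.
#' @param n_hotspots Number of discrete degradation focal positions per gene;
#'   their locations are drawn with linearly increasing density toward the
#'   3' end.
#' @param hotspot_jitter_sd Jitter of degradation ends around their focal
#'   position (nt).
#' @param cleavage_sites Optional \code{data.frame(gene, srna, offset,
#'   efficiency)}: plant the sRNA's perfect target site so that the cleavage
#'   coordinate (transcript base paired to sRNA position 10) equals
#'   \code{offset}, and direct \code{efficiency} of the gene's 5P reads to it.
#' @param depth_5p,depth_body Total read counts per library.
#' @param fragment_length Mean BODY fragment length F (nt), used for scaling.
#' @param read_length Aligned read length written to the SAM files.
#' @param xrn1_mode Deplete noncapped-label reads (degradation + cleavage),
#'   emulating exonucleolytic digestion of 5'-monophosphorylated RNA.
#' @param xrn1_removal Fraction of noncapped-label reads removed (default 0.9).
#' @return A validated config list of class \code{endkit_sim_config}.
#' @export
simConfig <- function(rng_seed = 1L, n_genes = 200L, n_chroms = 5L,
                      gene_length = c(1000L, 2000L), intergenic = c(400L, 1200L),
                      tpm_meanlog = 0, tpm_sdlog = 1,
                      capped_uug_rate = 0.15, noncapped_uug_rate = 0.02,
                      tss_jitter_sd = 2, degradation_fraction = 0.25,
                      n_hotspots = 3L, hotspot_jitter_sd = 3,
                      cleavage_sites = NULL,
                      depth_5p = 200000L, depth_body = 200000L,
                      fragment_length = 500, read_length = 50L,
                      xrn1_mode = FALSE, xrn1_removal = 0.9) {
    cfg <- list(rng_seed = as.integer(rng_seed), n_genes = as.integer(n_genes),
                n_chroms = as.integer(n_chroms), gene_length = gene_length,
                intergenic = intergenic, tpm_meanlog = tpm_meanlog,
                tpm_sdlog = tpm_sdlog, capped_uug_rate = capped_uug_rate,
                noncapped_uug_rate = noncapped_uug_rate,
                tss_jitter_sd = tss_jitter_sd,
                degradation_fraction = degradation_fraction,
                n_hotspots = as.integer(n_hotspots),
                hotspot_jitter_sd = hotspot_jitter_sd,
                cleavage_sites = cleavage_sites,
                depth_5p = as.integer(depth_5p),
                depth_body = as.integer(depth_body),
                fragment_length = fragment_length,
                read_length = as.integer(read_length),
                xrn1_mode = isTRUE(xrn1_mode), xrn1_removal = xrn1_removal)
    rates <- c(cfg$capped_uug_rate, cfg$noncapped_uug_rate,
               cfg$degradation_fraction, cfg$xrn1_removal)
    if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
    if (cfg$depth_5p <= 0L || cfg$depth_body <= 0L) stop("depths must be > 0")
    class(cfg) <- "endkit_sim_config"
    cfg
}

.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

.writeSAM <- function(path, chromLens, qname, flag, chrom, pos1, cigar, seq) {
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(chromLens), chromLens))
    body <- paste(qname, flag, chrom, pos1, 255L, cigar, "*", 0L, 0L, seq, "*",
                  sep = "\t")
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Generate a synthetic genome, annotation and paired 5P/BODY alignments
#'
#' Writes a FASTA genome, a GTF annotation, one SAM file per library and
#' plain-text truth tables (true TSS per gene, planted cleavage offsets,
#' per-read labels) to \code{dir}. All randomness comes from one seeded
#' generator, so outputs are reproducible per seed. Every read carries
#' exactly one label: capped, degradation or cleavage.
#'
#' @param cfg A config from \code{\link{simConfig}}.
#' @param dir Output directory (created if needed).
#' @param replicates Number of biological replicates: the genome, gene
#'   layout and expression levels are shared (seeded by \code{rng_seed});
#'   read sampling is independent per replicate.
#' @return List: file \code{paths} (\code{sam_5p} and \code{sam_body} are
#'   vectors with one file per replicate), \code{truth} tables (tss,
#'   cleavage, labels), the gene table, and the config.
#' @export
simulateDataset <- function(cfg = simConfig(), dir = tempfile("endkitsim"),
                            replicates = 1L) {
    stopifnot(inherits(cfg, "endkit_sim_config"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(cfg$rng_seed)
    rl <- cfg$read_length

    ## gene layout: round-robin over chromosomes, sequential placement
    genes <- data.frame(
        gene_id = sprintf("g%03d", seq_len(cfg$n_genes)),
        transcript_id = sprintf("g%03d.1", seq_len(cfg$n_genes)),
        chrom = sprintf("chr%d", rep_len(seq_len(cfg$n_chroms), cfg$n_genes)),
        strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
        length = sample(cfg$gene_length[1L]:cfg$gene_length[2L], cfg$n_genes,
                        replace = TRUE),
        stringsAsFactors = FALSE)
    x <- stats::rlnorm(cfg$n_genes, cfg$tpm_meanlog, cfg$tpm_sdlog)
    genes$tpm <- x / sum(x) * 1e6

    ## transcript sequences (planting happens in transcript space)
    txseq <- vapply(genes$length, .randSeq, character(1))
    plant <- cfg$cleavage_sites
    if (!is.null(plant)) {
        for (r in seq_len(nrow(plant))) {
            gi <- match(plant$gene[r], genes$gene_id)
            if (is.na(gi)) stop("planted site references unknown gene ",
                                plant$gene[r])
            sr <- chartr("Uu", "Tt", toupper(plant$srna[r]))
            n <- nchar(sr)
            ws <- plant$offset[r] - (n - 10L)
            if (ws < 0L || ws + n > genes$length[gi])
                stop("planted site outside transcript for gene ", plant$gene[r])
            site <- .revcomp(sr)
            substr(txseq[gi], ws + 1L, ws + n) <- site
        }
    }

    ## chromosome assembly
    chromSeq <- character(cfg$n_chroms)
    names(chromSeq) <- sprintf("chr%d", seq_len(cfg$n_chroms))
    genes$start0 <- NA_integer_
    for (ci in seq_len(cfg$n_chroms)) {
        idx <- which(genes$chrom == names(chromSeq)[ci])
        cursor <- 0L
        parts <- character()
        for (gi in idx) {
            gap <- sample(cfg$intergenic[1L]:cfg$intergenic[2L], 1L)
            parts <- c(parts, .randSeq(gap))
            cursor <- cursor + gap
            genes$start0[gi] <- cursor
            gs <- if (genes$strand[gi] == "+") txseq[gi] else .revcomp(txseq[gi])
            parts <- c(parts, gs)
            cursor <- cursor + genes$length[gi]
        }
        parts <- c(parts, .randSeq(600L))
        chromSeq[ci] <- paste(parts, collapse = "")
    }
    chromLens <- nchar(chromSeq)
    genes$end0 <- genes$start0 + genes$length      # half-open
    genes$tss0 <- ifelse(genes$strand == "+", genes$start0, genes$end0 - 1L)

    ## --- reads, per replicate ----------------------------------------------
    sam5_paths <- character(replicates)
    samb_paths <- character(replicates)
    labs_all <- vector("list", replicates)
    for (rep_i in seq_len(replicates)) {
    set.seed(cfg$rng_seed * 1000L + rep_i)
    cnt <- as.vector(stats::rmultinom(1L, cfg$depth_5p, prob = genes$tpm))
    gene_idx <- integer(); offs <- integer(); labels <- character()
    for (gi in seq_len(cfg$n_genes)) {
        n_tot <- cnt[gi]
        if (n_tot == 0L) next
        L <- genes$length[gi]
        n_cl <- 0L; cl_off <- integer(0)
        if (!is.null(plant)) {
            pr <- plant[plant$gene == genes$gene_id[gi], , drop = FALSE]
            if (nrow(pr)) {
                per <- pmin(n_tot, round(pr$efficiency * n_tot))
                n_cl <- as.integer(sum(per))
                cl_off <- rep(as.integer(pr$offset), per)
            }
        }
        n_deg <- as.integer(round(cfg$degradation_fraction * (n_tot - n_cl)))
        n_cap <- n_tot - n_cl - n_deg
        hs <- pmin(L - 1L, as.integer(floor(L * sqrt(stats::runif(cfg$n_hotspots)))))
        o_cap <- as.integer(round(stats::rnorm(n_cap, 0, cfg$tss_jitter_sd)))
        o_cap <- pmax(-200L, pmin(L - 1L, o_cap))
        o_deg <- hs[sample.int(cfg$n_hotspots, n_deg, replace = TRUE)] +
            as.integer(round(stats::rnorm(n_deg, 0, cfg$hotspot_jitter_sd)))
        o_deg <- pmax(0L, pmin(L - 1L, o_deg))
        gene_idx <- c(gene_idx, rep(gi, n_tot))
        offs <- c(offs, o_cap, o_deg, cl_off)
        labels <- c(labels, rep("capped", n_cap), rep("degradation", n_deg),
                    rep("cleavage", n_cl))
    }
    uug_rate <- ifelse(labels == "capped", cfg$capped_uug_rate,
                       cfg$noncapped_uug_rate)
    uug <- stats::runif(length(labels)) < uug_rate
    if (cfg$xrn1_mode) {
        drop <- labels != "capped" & stats::runif(length(labels)) < cfg$xrn1_removal
        gene_idx <- gene_idx[!drop]; offs <- offs[!drop]
        labels <- labels[!drop]; uug <- uug[!drop]
    }
    strand <- genes$strand[gene_idx]
    chrom <- genes$chrom[gene_idx]
    pos5 <- ifelse(strand == "+", genes$start0[gene_idx] + offs,
                   genes$end0[gene_idx] - 1L - offs)
    ## drop the rare read whose alignment would leave the chromosome
    fits <- ifelse(strand == "+",
                   pos5 >= 0L & pos5 + rl <= chromLens[chrom],
                   pos5 - rl + 1L >= 0L & pos5 < chromLens[chrom])
    gene_idx <- gene_idx[fits]; offs <- offs[fits]; labels <- labels[fits]
    uug <- uug[fits]; strand <- strand[fits]; chrom <- chrom[fits]
    pos5 <- pos5[fits]
    n5 <- length(pos5)
    qname <- sprintf("r%d.p%07d", rep_i, seq_len(n5))

    seqs <- character(n5); cig <- character(n5); pos1 <- integer(n5)
    for (ch in unique(chrom)) {
        subj <- Biostrings::DNAString(chromSeq[[ch]])
        fw <- which(chrom == ch & strand == "+")
        if (length(fw)) {
            core <- as.character(Biostrings::extractAt(
                subj, IRanges::IRanges(pos5[fw] + 1L, pos5[fw] + rl)))
            seqs[fw] <- ifelse(uug[fw], paste0("G", core), core)
            cig[fw] <- ifelse(uug[fw], sprintf("1S%dM", rl), sprintf("%dM", rl))
            pos1[fw] <- pos5[fw] + 1L
        }
        rv <- which(chrom == ch & strand == "-")
        if (length(rv)) {
            core <- as.character(Biostrings::extractAt(
                subj, IRanges::IRanges(pos5[rv] - rl + 2L, pos5[rv] + 1L)))
            # minus-strand SAM SEQ is reference-forward; the read's 5'
            # soft-clipped G appears as a trailing C
            seqs[rv] <- ifelse(uug[rv], paste0(core, "C"), core)
            cig[rv] <- ifelse(uug[rv], sprintf("%dM1S", rl), sprintf("%dM", rl))
            pos1[rv] <- pos5[rv] - rl + 2L
        }
    }
    flag <- ifelse(strand == "+", 0L, 16L)
    sam5 <- file.path(dir, sprintf("reads_5p_rep%d.sam", rep_i))
    .writeSAM(sam5, chromLens, qname, flag, chrom, pos1, cig, seqs)
    sam5_paths[rep_i] <- sam5

    ## --- BODY reads ---------------------------------------------------------
    bidx <- sample.int(cfg$n_genes, cfg$depth_body, replace = TRUE,
                       prob = genes$tpm * genes$length)
    boff <- as.integer(floor(stats::runif(cfg$depth_body) *
                             (genes$length[bidx] - rl + 1L)))
    bleft <- ifelse(genes$strand[bidx] == "+", genes$start0[bidx] + boff,
                    genes$end0[bidx] - boff - rl)
    bchrom <- genes$chrom[bidx]
    bseq <- character(cfg$depth_body)
    for (ch in unique(bchrom)) {
        subj <- Biostrings::DNAString(chromSeq[[ch]])
        ii <- which(bchrom == ch)
        bseq[ii] <- as.character(Biostrings::extractAt(
            subj, IRanges::IRanges(bleft[ii] + 1L, bleft[ii] + rl)))
    }
    bflag <- sample(c(0L, 16L), cfg$depth_body, replace = TRUE)
    samb <- file.path(dir, sprintf("reads_body_rep%d.sam", rep_i))
    .writeSAM(samb, chromLens,
              sprintf("r%d.b%07d", rep_i, seq_len(cfg$depth_body)),
              bflag, bchrom, bleft + 1L, sprintf("%dM", rl), bseq)
    samb_paths[rep_i] <- samb
    labs_all[[rep_i]] <- data.frame(read_id = qname, replicate = rep_i,
                                    gene_id = genes$gene_id[gene_idx],
                                    label = labels, uug = uug, offset = offs,
                                    stringsAsFactors = FALSE)
    }

    ## --- genome, annotation, truth ------------------------------------------
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(chromSeq), fa)
    gtf <- file.path(dir, "annotation.gtf")
    writeLines(sprintf(
        '%s\tendkit_sim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
        genes$chrom, genes$start0 + 1L, genes$end0, genes$strand,
        genes$gene_id, genes$transcript_id), gtf)

    tss <- genes[, c("gene_id", "transcript_id", "chrom", "strand", "tss0",
                     "tpm", "length")]
    labs <- do.call(rbind, labs_all)
    cl_truth <- if (is.null(plant)) {
        data.frame(gene = character(), srna = character(), offset = integer(),
                   efficiency = numeric())
    } else plant
    utils::write.table(tss, file.path(dir, "tss_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cl_truth, file.path(dir, "cleavage_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(labs, file.path(dir, "read_labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    list(paths = list(genome = fa, annotation = gtf, sam_5p = sam5_paths,
                      sam_body = samb_paths),
         truth = list(tss = tss, cleavage = cl_truth, labels = labs),
         genes = genes, config = cfg)
}

## Literal replay of the published multimapper-rescue loop, kept deliberately
## naive (plain vectors and loops) so it can serve as an independent oracle
## for rescueMultimappers().
.replayRescue <- function(aln) {
    aln$weight <- NA_real_
    aln <- aln[aln$multiplicity <= 100L, , drop = FALSE]
    cov <- numeric(0)
    keyof <- function(i) paste(aln$chrom[i], aln$strand[i], aln$pos[i])
    getcov <- function(k) if (k %in% names(cov)) cov[[k]] else 0
    addcov <- function(k, w) {
        if (k %in% names(cov)) cov[[k]] <<- cov[[k]] + w
        else cov[c(names(cov), k)] <<- c(unname(cov), w)
    }
    for (i in which(aln$multiplicity == 1L)) {
        aln$weight[i] <- 1
        addcov(keyof(i), 1)
    }
    mm_ids <- unique(aln$read_id[aln$multiplicity > 1L])
    if (length(mm_ids)) {
        mults <- vapply(mm_ids, function(id)
            aln$multiplicity[aln$read_id == id][1L], integer(1))
        for (m in 2:100) {
            ids <- mm_ids[mults == m]
            if (!length(ids)) next
            lowchrom <- vapply(ids, function(id)
                min(aln$chrom[aln$read_id == id]), character(1))
            lowpos <- vapply(ids, function(id) {
                rows <- which(aln$read_id == id)
                rows <- rows[aln$chrom[rows] == min(aln$chrom[rows])]
                as.numeric(min(aln$pos[rows]))
            }, numeric(1))
            ids <- ids[order(lowchrom, lowpos, ids)]
            pending <- ids
            repeat {
                progressed <- FALSE
                remaining <- character(0)
                for (id in pending) {
                    rows <- which(aln$read_id == id)
                    C <- vapply(rows, function(i) getcov(keyof(i)), numeric(1))
                    if (sum(C) > 0) {
                        w <- C / sum(C)
                        aln$weight[rows] <- w
                        for (j in seq_along(rows)) addcov(keyof(rows[j]), w[j])
                        progressed <- TRUE
                    } else remaining <- c(remaining, id)
                }
                pending <- remaining
                if (!progressed || !length(pending)) break
            }
            for (id in pending) {
                rows <- which(aln$read_id == id)
                w <- rep(1 / length(rows), length(rows))
                aln$weight[rows] <- w
                for (j in seq_along(rows)) addcov(keyof(rows[j]), w[j])
            }
        }
    }
    aln
}

#' Random multimapper-rescue instance with oracle weights
#'
#' Builds a small alignment instance (unique reads seeding coverage plus
#' multimapping reads over a shared position pool) together with the
#' expected assignment weights computed by a literal, step-by-step replay
#' of the proportional-rescue loop.
#'
#' @param n_reads Number of multimapping reads (<= 20).
#' @param n_loci Maximum candidate locations per read (<= 5 is typical).
#' @param seed RNG seed.
#' @return List: \code{alignments} (data.frame, one row per candidate
#'   location, unique reads included) and \code{expected} (same rows with
#'   oracle weights).
#' @export
makeMultimapFixture <- function(n_reads = 10L, n_loci = 4L, seed = 1L) {
    stopifnot(n_reads <= 20L)
    withr::with_seed(seed, {
        chroms <- c("chrA", "chrB")
        pool <- expand.grid(chrom = chroms, pos = seq(10L, 10L + 3L * n_reads, 3L),
                            stringsAsFactors = FALSE)
        n_uni <- max(1L, stats::rpois(1L, n_reads / 2))
        rows <- list()
        for (u in seq_len(n_uni)) {
            p <- pool[sample.int(nrow(pool), 1L), ]
            rows[[length(rows) + 1L]] <- data.frame(
                read_id = sprintf("u%02d", u), chrom = p$chrom, strand = "+",
                pos = p$pos, multiplicity = 1L, stringsAsFactors = FALSE)
        }
        for (r in seq_len(n_reads)) {
            m <- sample(2:max(2L, min(n_loci, nrow(pool))), 1L)
            p <- pool[sample.int(nrow(pool), m), ]
            rows[[length(rows) + 1L]] <- data.frame(
                read_id = sprintf("m%02d", r), chrom = p$chrom, strand = "+",
                pos = p$pos, multiplicity = m, stringsAsFactors = FALSE)
        }
        aln <- do.call(rbind, rows)
        rownames(aln) <- NULL
        list(alignments = aln, expected = .replayRescue(aln))
    })
}

#' Transcript-level cleavage assay simulator
#'
#' Generates random transcript sequences and sparse noncapped 5'-end tracks,
#' optionally planting perfect sRNA target sites: the sRNA's reverse
#' complement is written into the transcript and \code{site_reads} 5' ends
#' are placed exactly at the cleavage coordinate (the base paired to sRNA
#' position 10). Background degradation ends are scattered uniformly with a
#' per-position stack cap so planted sites face quiet flanks.
#'
#' @param srnas Named character vector of sRNA sequences.
#' @param n_tx Number of transcripts.
#' @param tx_len Transcript length (nt).
#' @param planted Optional \code{data.frame(srna, transcript, offset)} of
#'   sites to plant (offset = cleavage coordinate, 0-based).
#' @param site_reads Reads placed at each planted cleavage site.
#' @param background_per_tx Background 5'-end reads per transcript.
#' @param max_stack Per-position cap on background reads (default 2).
#' @param seed RNG seed.
#' @return List: \code{transcripts} (named character), \code{tracks} (named
#'   list of \linkS4class{TranscriptTrack}s), \code{truth} (planted sites).
#' @export
simulateCleavageAssay <- function(srnas, n_tx = 6L, tx_len = 500L,
                                  planted = NULL, site_reads = 12L,
                                  background_per_tx = 30L, max_stack = 2L,
                                  seed = 1L) {
    withr::with_seed(seed, {
        tx <- vapply(rep(tx_len, n_tx), .randSeq, character(1))
        names(tx) <- sprintf("tx%02d", seq_len(n_tx))
        if (!is.null(planted)) {
            for (r in seq_len(nrow(planted))) {
                sr <- chartr("Uu", "Tt", toupper(srnas[[planted$srna[r]]]))
                n <- nchar(sr)
                ws <- planted$offset[r] - (n - 10L)
                if (ws < 0L || ws + n > tx_len)
                    stop("planted site outside transcript")
                substr(tx[[planted$transcript[r]]], ws + 1L, ws + n) <- .revcomp(sr)
            }
        }
        tracks <- list()
        for (id in names(tx)) {
            bg <- sample.int(tx_len, background_per_tx, replace = TRUE) - 1L
            tab <- table(bg)
            off <- as.integer(names(tab))
            val <- pmin(as.integer(tab), max_stack)
            if (!is.null(planted)) {
                pr <- planted[planted$transcript == id, , drop = FALSE]
                for (r in seq_len(nrow(pr))) {
                    hit <- which(off == pr$offset[r])
                    if (length(hit)) val[hit] <- val[hit] + site_reads
                    else { off <- c(off, pr$offset[r]); val <- c(val, site_reads) }
                }
            }
            ord <- order(off)
            tracks[[id]] <- new("TranscriptTrack", transcriptID = id,
                                length = as.integer(tx_len),
                                offsets = off[ord], values = as.numeric(val[ord]),
                                maskedMass = 0)
        }
        list(transcripts = tx, tracks = tracks,
             truth = if (is.null(planted))
                 data.frame(srna = character(), transcript = character(),
                            offset = integer())
             else planted)
    })
}
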
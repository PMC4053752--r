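vcf_lines <- function(records) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=LABEL,Number=1,Type=String,Description=\"label\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"maf\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    records)
}

test_that("read_vcf keeps pure indels, derives kind and net length, and
           skips SNVs with a count", {
  f <- withr::local_tempfile(lines = vcf_lines(c(
    "chr1\t100\td1\tATCG\tA\t.\tPASS\tLABEL=disease",
    "chr1\t200\ti1\tA\tATTT\t.\tPASS\tLABEL=neutral;AF=0.12",
    "chr1\t300\ts1\tA\tT\t.\tPASS\t.")))
  expect_message(ind <- read_vcf(f), "skipped 1")
  expect_equal(nrow(ind), 2L)
  expect_equal(ind$kind, c("deletion", "insertion"))
  expect_equal(ind$net_len, c(3L, 3L))
  expect_equal(ind$label, c("disease", "neutral"))
  expect_equal(ind$maf, c(NA, 0.12))
  expect_equal(attr(ind, "n_skipped"), 1L)
})

test_that("read_vcf splits multi-allelic records and flags odd anchors", {
  f <- withr::local_tempfile(lines = vcf_lines(
    "chr1\t100\tm1\tAT\tA,ATTTT\t.\tPASS\t."))
  ind <- read_vcf(f)
  expect_equal(nrow(ind), 2L)
  expect_equal(ind$kind, c("deletion", "insertion"))

  f2 <- withr::local_tempfile(lines = vcf_lines(
    "chr1\t100\tx1\tCAT\tG\t.\tPASS\t."))
  expect_warning(read_vcf(f2), "anchor")
})

test_that("read_transcripts builds models from GTF + FASTA and hand
           translation matches", {
  # 2-exon transcript, CDS length 300 (stop included) -> 99-residue protein
  aa <- paste(rep(c("M", "K", "T"), 33), collapse = "")
  codons <- paste(nfsindel:::CODON_OF[strsplit(aa, "")[[1]]], collapse = "")
  cds <- paste0(codons, "TAA")  # 300 nt
  expect_equal(nchar(cds), 300L)
  gtf <- c(
    paste("chrT\ttoy\texon\t1001\t1150\t.\t+\t.",
          "transcript_id \"t1\"; protein_id \"p1\";", sep = "\t"),
    paste("chrT\ttoy\tCDS\t1001\t1150\t.\t+\t0",
          "transcript_id \"t1\"; protein_id \"p1\";", sep = "\t"),
    paste("chrT\ttoy\texon\t1201\t1350\t.\t+\t.",
          "transcript_id \"t1\"; protein_id \"p1\";", sep = "\t"),
    paste("chrT\ttoy\tCDS\t1201\t1350\t.\t+\t0",
          "transcript_id \"t1\"; protein_id \"p1\";", sep = "\t"))
  gf <- withr::local_tempfile(lines = gtf, fileext = ".gtf")
  ff <- withr::local_tempfile(lines = c(">p1", aa), fileext = ".fa")
  tx <- read_transcripts(gf, ff)
  expect_equal(nrow(tx), 1L)
  expect_equal(tx$protein_len, 99L)
  expect_equal(nrow(tx$exons[[1]]), 2L)
})

test_that("transcripts violating model invariants are dropped with reasons", {
  aa <- paste(rep("M", 99), collapse = "")
  mk <- function(cds_end) c(
    paste0("chrT\ttoy\texon\t1001\t", cds_end,
           "\t.\t+\t.\ttranscript_id \"t1\"; protein_id \"p1\";"),
    paste0("chrT\ttoy\tCDS\t1001\t", cds_end,
           "\t.\t+\t0\ttranscript_id \"t1\"; protein_id \"p1\";"))
  ff <- withr::local_tempfile(lines = c(">p1", aa), fileext = ".fa")

  # CDS length 301: not divisible by 3
  g1 <- withr::local_tempfile(lines = mk(1301), fileext = ".gtf")
  expect_message(t1 <- read_transcripts(g1, ff), "not divisible by 3")
  expect_equal(nrow(t1), 0L)

  # CDS length 303 but protein length mismatch handled too
  g2 <- withr::local_tempfile(lines = mk(1306), fileext = ".gtf")
  expect_message(t2 <- read_transcripts(g2, ff), "inconsistent")
  expect_equal(nrow(t2), 0L)

  # overlapping exons
  g3 <- withr::local_tempfile(lines = c(
    "chrT\ttoy\texon\t1001\t1150\t.\t+\t.\ttranscript_id \"t1\"; protein_id \"p1\";",
    "chrT\ttoy\texon\t1100\t1250\t.\t+\t.\ttranscript_id \"t1\"; protein_id \"p1\";",
    "chrT\ttoy\tCDS\t1001\t1150\t.\t+\t0\ttranscript_id \"t1\"; protein_id \"p1\";"),
    fileext = ".gtf")
  expect_message(t3 <- read_transcripts(g3, ff), "overlapping")
  expect_equal(nrow(t3), 0L)
})

test_that("classify_indels partitions indels and honours stop precedence", {
  tx <- toy_transcript(100, "+")
  # 3-base deletion wholly inside CDS
  d3 <- toy_deletion(tx, 28, 30)
  # 4-base deletion -> frameshift
  d4 <- toy_deletion(tx, 28, 31)
  got <- classify_indels(dplyr::bind_rows(d3, d4), tx)
  expect_equal(got$category, c("NFS_coding", "FS_coding"))

  # deletion overlapping the stop codon (CDS indices 301..303 for len 100)
  cdsp <- nfsindel:::cds_positions(tx)
  dstop <- toy_deletion(tx, 299, 301, id = "dstop")
  expect_equal(classify_indels(dstop, tx)$category, "stop_overlap")

  # intronic deletion: pick bases strictly between the two exons
  exons <- tx$exons[[1]]
  ipos <- exons$end[1] + 10L
  g <- strsplit(tx$genome_seq, "")[[1]]
  dintron <- tibble::tibble(id = "din", chrom = tx$chrom, pos = ipos,
                            ref = paste(g[ipos:(ipos + 3)], collapse = ""),
                            alt = g[ipos], kind = "deletion", net_len = 3L,
                            label = "unknown", maf = NA_real_,
                            transcript_id = tx$transcript_id)
  expect_equal(classify_indels(dintron, tx)$category, "intronic")
})

test_that("every fuzzed indel gets exactly one category and NFS implies
           net length divisible by 3", {
  set.seed(31)
  cats <- c("NFS_coding", "FS_coding", "intronic", "stop_overlap",
            "noncoding")
  for (i in 1:60) {
    tx <- toy_transcript(sample(60:120, 1), sample(c("+", "-"), 1),
                         seed = 1000 + i)
    pos <- sample(nchar(tx$genome_seq) - 10, 1)
    net <- sample(1:6, 1)
    g <- strsplit(tx$genome_seq, "")[[1]]
    ind <- tibble::tibble(id = "z", chrom = tx$chrom, pos = pos,
                          ref = paste(g[pos:(pos + net)], collapse = ""),
                          alt = g[pos], kind = "deletion",
                          net_len = net, label = "unknown", maf = NA_real_,
                          transcript_id = tx$transcript_id)
    got <- classify_indels(ind, tx)$category
    expect_length(got, 1)
    expect_true(got %in% cats)
    if (got == "NFS_coding") expect_equal(net %% 3, 0)
  }
})

test_that("map_to_protein handles in-phase, out-of-phase and insertions", {
  tx <- toy_transcript(100, "+")
  # codon-aligned deletion of codon 10 (CDS 28..30)
  p1 <- map_to_protein(toy_deletion(tx, 28, 30), tx)
  expect_equal(p1$first_res, 10L)
  expect_equal(p1$last_res, 10L)
  expect_equal(p1$n_del, 1L)
  # out-of-phase: CDS 29..31 touches codons 10 and 11
  p2 <- map_to_protein(toy_deletion(tx, 29, 31), tx)
  expect_equal(c(p2$first_res, p2$last_res), c(10L, 11L))
  expect_equal(p2$n_del, 1L)
  # insertion between codons 10 and 11
  p3 <- map_to_protein(toy_insertion(tx, 10, "W"), tx)
  expect_equal(c(p3$first_res, p3$last_res), c(10L, 11L))
  expect_equal(p3$inserted_aa, "W")
  expect_equal(p3$dN, 9L)
  expect_equal(p3$dC, 90L)
})

test_that("reconstructed mutant protein length differs by exactly n_del", {
  set.seed(32)
  for (i in 1:30) {
    strand <- sample(c("+", "-"), 1)
    tx <- toy_transcript(sample(60:120, 1), strand, seed = 2000 + i)
    L <- tx$protein_len
    k <- sample(1:3, 1)
    if (runif(1) < 0.5) {
      r <- sample(seq(5, L - k - 5), 1)
      ind <- toy_deletion(tx, 3 * (r - 1) + 1, 3 * (r + k - 1))
      if (classify_indels(ind, tx)$category != "NFS_coding") next
      mut <- nfsindel::mutant_protein(ind, tx)
      expect_equal(nchar(mut), L - k)
      pi_ <- map_to_protein(ind, tx)
      expect_equal(pi_$n_del, k)
    } else {
      r <- sample(seq(5, L - 5), 1)
      ind <- tryCatch(toy_insertion(tx, r, random_aa_seq(k)),
                      error = function(e) NULL)
      if (is.null(ind)) next  # insertion point at the intron
      if (classify_indels(ind, tx)$category != "NFS_coding") next
      mut <- nfsindel::mutant_protein(ind, tx)
      expect_equal(nchar(mut), L + k)
    }
  }
})

test_that("splice distances match the worked exon example and the
           brute-force scan, on both strands", {
  # exon 101-200 (+), deletion of bases 151-153 -> d5 = 50, d3 = 47
  tx <- tibble::tibble(
    transcript_id = "t", chrom = "c", strand = "+", protein_id = "p",
    protein_seq = "", protein_len = 0L,
    exons = list(tibble::tibble(start = 101L, end = 200L)),
    cds = list(tibble::tibble(start = 101L, end = 200L)))
  ind <- tibble::tibble(id = "d", chrom = "c", pos = 150L, ref = "NNNN",
                        alt = "N", kind = "deletion", net_len = 3L,
                        transcript_id = "t")
  got <- splice_distances(ind, tx)
  expect_equal(c(got$d5, got$d3), c(50L, 47L))
  # first exon base -> d5 = 0
  ind0 <- dplyr::mutate(ind, pos = 100L)
  expect_equal(splice_distances(ind0, tx)$d5, 0L)
  # minus strand mirrors the boundary roles
  txm <- dplyr::mutate(tx, strand = "-")
  gotm <- splice_distances(ind, txm)
  expect_equal(c(gotm$d5, gotm$d3), c(47L, 50L))

  set.seed(33)
  for (i in 1:1000) {
    strand <- sample(c("+", "-"), 1)
    start <- sample(1:500, 1)
    len <- sample(20:200, 1)
    exon <- c(start, start + len - 1)
    t2 <- tibble::tibble(
      transcript_id = "t", chrom = "c", strand = strand, protein_id = "p",
      protein_seq = "", protein_len = 0L,
      exons = list(tibble::tibble(start = exon[1], end = exon[2])),
      cds = list(tibble::tibble(start = exon[1], end = exon[2])))
    net <- sample(1:6, 1)
    anchor <- sample(seq(exon[1] - 1, exon[2] - net), 1)
    if (anchor + 1 < exon[1]) next
    i2 <- tibble::tibble(id = "d", chrom = "c", pos = anchor,
                         ref = strrep("N", net + 1), alt = "N",
                         kind = "deletion", net_len = net,
                         transcript_id = "t")
    got <- splice_distances(i2, t2)
    want <- brute_splice(t2, seq(anchor + 1, anchor + net))
    expect_equal(c(got$d5, got$d3), unname(want))
  }
})

test_that("splice distances refuse junction-spanning indels", {
  tx <- toy_transcript(100, "+")
  exons <- tx$exons[[1]]
  ind <- tibble::tibble(id = "j", chrom = tx$chrom,
                        pos = exons$end[1] - 1L, ref = "NNNN", alt = "N",
                        kind = "deletion", net_len = 3L,
                        transcript_id = tx$transcript_id)
  expect_error(splice_distances(ind, tx), "host exon")
})

test_that("insertion/deletion site overlap follows the flank rule", {
  mk <- function(kind, first, last, pid = "p1") {
    tibble::tibble(protein_id = pid, kind = kind, first_res = first,
                   last_res = last)
  }
  expect_true(sites_overlap(mk("insertion", 10, 11), mk("deletion", 11, 13)))
  expect_false(sites_overlap(mk("insertion", 10, 11), mk("deletion", 12, 13)))
  expect_false(sites_overlap(mk("insertion", 10, 11),
                             mk("deletion", 200, 201)))
  expect_false(sites_overlap(mk("insertion", 10, 11),
                             mk("deletion", 10, 12, pid = "p2")))
})
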
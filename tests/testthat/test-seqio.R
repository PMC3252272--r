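# FASTA/miRBase/GFF3 input-output and spliced transcript models.

test_that("FASTA reading normalizes DNA to RNA and preserves order", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGT", ">y desc text", "ggtacc"), f)
  seqs <- read_fasta(f)
  expect_identical(seqs, c(x = "ACGU", y = "GGUACC"))
})

test_that("an empty FASTA yields an empty set and bad input errors name the problem", {
  f <- withr::local_tempfile(fileext = ".fa")
  file.create(f)
  expect_length(read_fasta(f), 0)
  writeLines(c(">a", "ACGU", ">a", "ACGU"), f)
  expect_error(read_fasta(f), "duplicate record id")
  writeLines(c(">a", "ACXU"), f)
  expect_error(read_fasta(f), "non-ACGU")
  expect_error(read_fasta(file.path(tempdir(), "no-such.fa")), "no such file")
})

test_that("write/read round trip is identity on generated sequences", {
  set.seed(5)
  seqs <- setNames(vapply(1:3, function(i) rand_rna(sample(30:80, 1)), ""),
                   c("tx1", "tx2", "tx3"))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)
  # a second round trip is byte-stable
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(read_fasta(f), f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("miRBase ids parse into species and family", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">ath-miR396a MIMAT dummy", "UUCCACAGCUUUCUUGAACUG",
               ">osa-miR396e", "UUCCACAGGCUUUCUUGAACUG",
               ">osa-miR396f-5p", "UUCCACAGGCUUUCUUGAACUG"), f)
  m <- read_mirbase_mature(f)
  expect_identical(m$species, c("ath", "osa", "osa"))
  expect_identical(unique(m$family), "miR396")
})

test_that("family partition sizes follow the id grammar", {
  f <- withr::local_tempfile(fileext = ".fa")
  ids <- c("ath-miR159a", "ath-miR159b", "ath-miR159c", "osa-miR159a.1",
           "ath-miR319a", "ath-miR319b-3p")
  writeLines(as.vector(rbind(paste0(">", ids),
                             rep(paste0(strrep("ACGU", 5), "A"), length(ids)))),
             f)
  m <- read_mirbase_mature(f)
  expect_identical(sort(as.vector(table(m$family)), decreasing = TRUE),
                   c(4L, 2L))
})

test_that("records without a miR token are skipped with a warning", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">ath-miR396a", "UUCCACAGCUUUCUUGAACUG",
               ">spikein-control", "ACGUACGUACGUACGUACGUA"), f)
  expect_warning(m <- read_mirbase_mature(f), "skipped")
  expect_equal(nrow(m), 1)
  expect_equal(attr(m, "n_skipped"), 1)
})

test_that("transcript models record junctions at cumulative exon boundaries", {
  tx <- build_transcript(c("AAA", "CCC"), id = "t")
  expect_equal(tx$seq, "AAACCC")
  expect_equal(tx$junctions, 3)
  single <- build_transcript("ACGUACG")
  expect_length(single$junctions, 0)
  expect_error(build_transcript(c("AAA", "")), "empty exon")
  # invariants over random exon structures
  set.seed(9)
  for (rep in 1:10) {
    k <- sample(1:5, 1)
    exons <- vapply(seq_len(k), function(i) rand_rna(sample(3:20, 1)), "")
    tx <- build_transcript(exons)
    expect_equal(sum(tx$exon_lengths), nchar(tx$seq))
    expect_length(tx$junctions, k - 1)
    if (k > 1) expect_lt(max(tx$junctions), nchar(tx$seq))
  }
})

test_that("GFF3 exons splice to the hand-built plus-strand transcript", {
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  #          1234567890123456789012
  writeLines(c(">chr1", "AAACCCGGGUUUACGUACGUAC"), fa)
  writeLines(c("##gff-version 3",
               "chr1\ttoy\texon\t1\t6\t.\t+\t.\tParent=tx1",
               "chr1\ttoy\texon\t13\t18\t.\t+\t.\tParent=tx1"), gff)
  tx <- read_gff3_exons(gff, fa)
  expect_equal(tx$tx1$seq, paste0("AAACCC", "ACGUAC"))
  expect_equal(tx$tx1$junctions, 6)
})

test_that("minus-strand exons are reverse-complemented into transcription order", {
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(">chr1", "AAACCCGGGUUUACGUACGUAC"), fa)
  writeLines(c("##gff-version 3",
               "chr1\ttoy\texon\t1\t6\t.\t-\t.\tParent=tx1",
               "chr1\ttoy\texon\t13\t18\t.\t-\t.\tParent=tx1"), gff)
  tx <- read_gff3_exons(gff, fa)
  # transcription order: downstream exon first, both reverse-complemented
  expect_equal(tx$tx1$seq, paste0("GUACGU", "GGGUUU"))
})

test_that("exon coordinates beyond the contig and mixed strands error", {
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(">chr1", "AAACCCGGG"), fa)
  writeLines(c("##gff-version 3",
               "chr1\ttoy\texon\t1\t20\t.\t+\t.\tParent=tx1"), gff)
  expect_error(read_gff3_exons(gff, fa), "outside sequence bounds")
  writeLines(c("##gff-version 3",
               "chr1\ttoy\texon\t1\t3\t.\t+\t.\tParent=tx1",
               "chr1\ttoy\texon\t5\t7\t.\t-\t.\tParent=tx1"), gff)
  expect_error(read_gff3_exons(gff, fa), "mixed strands")
})

test_that("a generated genome+GFF3 reproduces the generator's spliced sequences", {
  sq <- mir396_sequences()
  sim <- gen_transcriptome(sq[["ath-miR396a"]], n_transcripts = 3,
                           site_specs = list(site_spec(junction_after = 10),
                                             site_spec(junction_after = 5)),
                           length = 150, seed = 101)
  for (strand in c("+", "-")) {
    fa <- withr::local_tempfile(fileext = ".fa")
    gff <- withr::local_tempfile(fileext = ".gff3")
    write_genome_gff(sim$transcripts, fa, gff, strand = strand, seed = 7)
    back <- read_gff3_exons(gff, fa)
    for (id in names(sim$transcripts)) {
      expect_equal(back[[id]]$seq, sim$transcripts[[id]]$seq,
                   info = paste(strand, id))
      expect_equal(back[[id]]$junctions, sim$transcripts[[id]]$junctions)
    }
  }
})

test_that("expression TSV round trips and rejects non-positive values", {
  m <- matrix(c(1.5, 0.8, 1.31, 1.02, 2.0, 0.99), 2,
              dimnames = list(c("g1", "g2"), c("hyl1", "se", "dcl1")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(m, f)
  expect_equal(read_expression_tsv(f), m)
  m2 <- m; m2[1, 1] <- -1
  write_expression_tsv(m2, f)
  expect_error(read_expression_tsv(f), "positive")
})
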
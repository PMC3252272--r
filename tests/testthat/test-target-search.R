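# Target-site scanning, overlap merging, junction flags, cleavage mapping.

mir396a <- mir396_sequences()[["ath-miR396a"]]

test_that("a planted perfect site is found once with score 0 and exact coordinates", {
  set.seed(13)
  sim <- gen_transcriptome(mir396a, n_transcripts = 1,
                           site_specs = list(site_spec()), length = 200,
                           seed = 13)
  sites <- search_targets(mir396a, sim$transcripts)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$score, 0)
  expect_equal(sites$start, sim$truth$start)
  expect_equal(sites$end, sim$truth$end)
  expect_false(sites$spans_junction)
})

test_that("planted sites across the score range are recovered and decoys excluded", {
  specs <- c(
    lapply(0:5, function(mm) site_spec(mismatches = mm)),
    lapply(1:4, function(wb) site_spec(wobbles = wb)),
    list(site_spec(bulge = "target"), site_spec(bulge = "mirna"),
         site_spec(mismatches = 2, wobbles = 2),
         site_spec(mismatches = 3, bulge = "target")),
    lapply(1:4, function(i) site_spec(decoy = TRUE))
  )
  sim <- gen_transcriptome(mir396a, n_transcripts = length(specs),
                           site_specs = specs, length = 150, seed = 29)
  sites <- search_targets(mir396a, sim$transcripts)
  truth <- sim$truth[!sim$truth$decoy, ]
  # recall and precision 1.0 against the planted truth
  expect_equal(nrow(sites), nrow(truth))
  key <- function(df) paste(df$transcript_id, df$start, df$end)
  expect_setequal(key(sites), key(truth))
  m <- match(key(sites), key(truth))
  expect_equal(sites$score, truth$score[m])
})

test_that("junction-spanning sites are flagged, single-exon sites are not", {
  sim <- gen_transcriptome(mir396a, n_transcripts = 4,
                           site_specs = list(site_spec(junction_after = 11),
                                             site_spec(junction_after = 3),
                                             site_spec(), site_spec()),
                           length = 150, seed = 31)
  sites <- search_targets(mir396a, sim$transcripts)
  m <- match(paste(sites$transcript_id, sites$start),
             paste(sim$truth$transcript_id, sim$truth$start))
  expect_equal(sites$spans_junction, !is.na(sim$truth$junction[m]))
})

test_that("searching exon pieces spliced together equals searching the flat sequence", {
  sim <- gen_transcriptome(mir396a, n_transcripts = 1,
                           site_specs = list(site_spec(junction_after = 10)),
                           length = 160, seed = 37)
  tx <- sim$transcripts[[1]]
  flat <- setNames(tx$seq, tx$id)
  s_model <- search_targets(mir396a, tx)
  s_flat <- search_targets(mir396a, flat)
  expect_equal(s_model$start, s_flat$start)
  expect_equal(s_model$end, s_flat$end)
  expect_equal(s_model$score, s_flat$score)
  # only the junction flag differs: the flat sequence has no exon model
  expect_true(s_model$spans_junction)
  expect_false(s_flat$spans_junction)
})

test_that("raising the score cap never removes a reported site", {
  sim <- gen_transcriptome(mir396a, n_transcripts = 3,
                           site_specs = list(site_spec(mismatches = 2),
                                             site_spec(mismatches = 4),
                                             site_spec(wobbles = 2)),
                           length = 150, seed = 41)
  lo <- search_targets(mir396a, sim$transcripts,
                       scoring_params(max_score = 5))
  hi <- search_targets(mir396a, sim$transcripts,
                       scoring_params(max_score = 10))
  key <- function(df) paste(df$transcript_id, df$start, df$end)
  expect_true(all(key(lo) %in% key(hi)))
})

test_that("cleavage maps opposite miRNA position 10 in a gap-free duplex", {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  window <- paste(rev(comp[strsplit(mir396a, "")[[1]]]), collapse = "")
  set.seed(43)
  tx <- setNames(paste0(rand_rna(100), window, rand_rna(80)), "t1")
  sites <- search_targets(mir396a, tx)
  expect_equal(sites$start, 101)
  expect_equal(sites$end, 121)
  expect_equal(sites$cleavage_coord, 112) # base opposite miRNA position 10
  expect_equal(map_cleavage_site(sites[1, ]), 112)
})

test_that("a target bulge 5' of the cleavage base shifts the coordinate by one", {
  sq <- mir396_sequences()
  set.seed(47)
  flank5 <- rand_rna(100); flank3 <- rand_rna(80)
  tx_bulged <- setNames(paste0(flank5, sq[["GRF2_site"]], flank3), "t1")
  bulged <- search_targets(mir396a, tx_bulged)
  # gap-free reference: the same window bound by the monocot variant
  flush <- search_targets(sq[["miR396_7-8insG"]], tx_bulged)
  expect_equal(bulged$cleavage_coord, flush$cleavage_coord - 1)
  expect_equal(bulged$end - bulged$cleavage_coord, 10)
})

test_that("a miRNA-side bulge leaves the cleavage coordinate unchanged", {
  # bHLH74-style site: perfectly complementary to the 21-nt miRNA, so the
  # 22-nt insG variant binds it with one bulged miRNA base
  sq <- mir396_sequences()
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  window <- paste(rev(comp[strsplit(mir396a, "")[[1]]]), collapse = "")
  set.seed(53)
  tx <- setNames(paste0(rand_rna(60), window, rand_rna(60)), "t1")
  flat <- search_targets(mir396a, tx)
  mbulge <- search_targets(sq[["miR396_7-8insG"]], tx)
  aln <- mbulge$alignment[[1]]
  expect_equal(sum(aln$columns$state == "BULGE_MIRNA"), 1)
  expect_equal(mbulge$cleavage_coord, flat$cleavage_coord)
})

test_that("sites failing the 10-11 anchor report no cleavage coordinate", {
  # relax the anchor so a site mismatched at position 10 is reported
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  wchars <- rev(comp[strsplit(mir396a, "")[[1]]])
  # window position opposite miRNA 10 is index length-10+1 from the 5' end
  k <- length(wchars) - 10 + 1
  wchars[k] <- c(A = "C", C = "A", G = "A", U = "C")[wchars[k]]
  set.seed(59)
  tx <- setNames(paste0(rand_rna(50), paste(wchars, collapse = ""),
                        rand_rna(50)), "t1")
  sites <- search_targets(mir396a, tx,
                          scoring_params(require_paired_10_11 = FALSE))
  expect_equal(nrow(sites), 1)
  expect_true(is.na(sites$cleavage_coord))
  expect_error(map_cleavage_site(sites[1, ]), "not cleavable")
  # with the anchor required, the mismatched-at-10 alignment is excluded;
  # anything still reported must pair 10-11 (at a worse score) and carry a
  # cleavage coordinate
  strict <- search_targets(mir396a, tx, scoring_params())
  if (nrow(strict) > 0) {
    expect_true(all(!is.na(strict$cleavage_coord)))
    expect_true(all(strict$score > sites$score))
  }
})

test_that("an empty result is a valid, well-formed table", {
  set.seed(61)
  tx <- setNames(rand_rna(150), "t1")
  sites <- search_targets(mir396a, tx)
  expect_s3_class(sites, "target_sites")
  expect_equal(nrow(sites), 0)
})

test_that("sites TSV round trips through write and read", {
  sim <- gen_transcriptome(mir396a, n_transcripts = 1,
                           site_specs = list(site_spec(bulge = "target")),
                           length = 150, seed = 67)
  sites <- search_targets(mir396a, sim$transcripts)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sites_tsv(sites, f)
  back <- read_sites_tsv(f)
  expect_equal(back$start, sites$start)
  expect_equal(back$score, sites$score)
  expect_equal(back$cleavage_coord, sites$cleavage_coord)
  expect_match(back$duplex_render, "/")
})
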
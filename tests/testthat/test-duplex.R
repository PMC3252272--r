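# Duplex alignment: optimality, constraints, scoring arithmetic.

test_that("a perfect reverse complement aligns with score 0, all Watson-Crick", {
  mir <- "UUCCACAG"
  window <- "CUGUGGAA" # reverse complement
  aln <- align_duplex(mir, window)
  expect_equal(aln$score, 0)
  expect_true(all(aln$columns$state == "WATSON_CRICK"))
  expect_equal(nrow(aln$columns), 8)
})

test_that("miR396a:GRF2 has exactly one target bulge between positions 7 and 8", {
  sq <- mir396_sequences()
  aln <- align_duplex(sq[["ath-miR396a"]], sq[["GRF2_site"]],
                      mirna_id = "ath-miR396a")
  gaps <- which(aln$columns$state %in% c("BULGE_MIRNA", "BULGE_TARGET"))
  expect_length(gaps, 1)
  expect_equal(aln$columns$state[gaps], "BULGE_TARGET")
  # the bulged column sits between the columns pairing miRNA positions 7 and 8
  expect_equal(aln$columns$mirna_pos[gaps - 1], 7)
  expect_equal(aln$columns$mirna_pos[gaps + 1], 8)
  expect_equal(sum(aln$columns$state == "MISMATCH"), 0)
  # score equals an independent census of its columns
  expect_equal(aln$score, score_alignment(aln))
  expect_equal(aln$score, 1)
})

test_that("score_alignment implements the weighted column census", {
  cols <- data.frame(
    state = c("WATSON_CRICK", "MISMATCH", "GU_WOBBLE", "MISMATCH",
              "BULGE_TARGET", "WATSON_CRICK"),
    mirna_pos = c(1L, 2L, 3L, 4L, NA, 5L),
    target_pos = c(1L, 2L, 3L, 4L, 5L, 6L),
    mirna_base = c("A", "A", "G", "C", NA, "G"),
    target_base = c("U", "C", "U", "A", "G", "C"),
    stringsAsFactors = FALSE
  )
  aln <- structure(list(mirna_id = "m", mirna = "AAGCG", window = "GCGUAGU",
                        columns = cols, score = NA, delta_g = NA,
                        feasible = TRUE),
                   class = "duplex_alignment")
  expect_equal(score_alignment(aln), 2 * 1 + 1 * 0.5 + 1 * 1) # 3.5
  expect_equal(score_alignment(aln, scoring_params(wobble = 1)), 4)
  # all-WC alignment scores 0
  wc <- aln
  wc$columns <- cols[cols$state == "WATSON_CRICK", ]
  expect_equal(score_alignment(wc), 0)
})

test_that("score is monotone in column degradation", {
  sq <- mir396_sequences()
  aln <- align_duplex(sq[["ath-miR396a"]], sq[["GRF2_site"]])
  worse <- aln
  k <- which(worse$columns$state == "WATSON_CRICK")[3]
  worse$columns$state[k] <- "MISMATCH"
  expect_gt(score_alignment(worse), score_alignment(aln))
  wobbled <- aln
  wobbled$columns$state[k] <- "GU_WOBBLE"
  expect_gte(score_alignment(wobbled), score_alignment(aln))
})

test_that("window lengths outside the band are rejected", {
  expect_error(align_duplex("UUCCACAG", "CUGU"), "outside")
  expect_error(align_duplex("UUCCACAG", strrep("A", 13)), "outside")
})

test_that("an impossible 10-11 anchor yields the sentinel no-site result", {
  # twelve A's against twelve A's: every column would be a mismatch,
  # which the anchor constraint forbids at positions 10 and 11
  aln <- align_duplex(strrep("A", 12), strrep("A", 12))
  expect_false(aln$feasible)
  expect_identical(aln$score, Inf)
  expect_equal(nrow(aln$columns), 0)
  # without the constraint the alignment exists
  relaxed <- align_duplex(strrep("A", 12), strrep("A", 12),
                          scoring_params(require_paired_10_11 = FALSE))
  expect_true(relaxed$feasible)
  expect_equal(relaxed$score, 12)
})

test_that("the 10-11 anchor keeps positions 10 and 11 contiguously paired", {
  set.seed(42)
  n_checked <- 0
  for (rep in 1:60) {
    mir <- rand_rna(sample(11:22, 1))
    win <- rand_rna(nchar(mir) + sample(-2:2, 1))
    aln <- align_duplex(mir, win, scoring_params(max_score = 99))
    if (!aln$feasible) next
    k10 <- which(!is.na(aln$columns$mirna_pos) & aln$columns$mirna_pos == 10)
    k11 <- which(!is.na(aln$columns$mirna_pos) & aln$columns$mirna_pos == 11)
    expect_true(aln$columns$state[k10] %in% c("WATSON_CRICK", "GU_WOBBLE"))
    expect_true(aln$columns$state[k11] %in% c("WATSON_CRICK", "GU_WOBBLE"))
    expect_equal(k11, k10 + 1L)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 30)
})

test_that("DP score equals exhaustive enumeration on tiny duplexes", {
  set.seed(7)
  for (rep in 1:40) {
    L <- sample(4:6, 1)
    mir <- rand_rna(L)
    win <- rand_rna(L + sample(-2:2, 1))
    params <- scoring_params(require_paired_10_11 = FALSE)
    aln <- align_duplex(mir, win, params)
    expect_equal(aln$score, enum_score(mir, win, params),
                 info = paste(mir, win))
    expect_equal(aln$score, score_alignment(aln, params))
  }
})

test_that("DP energy equals exhaustive pair-chain enumeration on tiny duplexes", {
  set.seed(8)
  ep <- energy_params()
  for (rep in 1:40) {
    L <- sample(4:6, 1)
    mir <- rand_rna(L)
    win <- rand_rna(L + sample(-2:2, 1))
    params <- scoring_params(require_paired_10_11 = FALSE)
    aln <- align_duplex(mir, win, params, objective = "energy")
    brute <- enum_energy(mir, win, ep, params)
    if (!aln$feasible) {
      expect_identical(brute, Inf)
    } else {
      expect_equal(duplex_delta_g(aln, ep), brute, info = paste(mir, win))
    }
  }
})

test_that("alignment output is deterministic and the band is honored", {
  set.seed(11)
  for (rep in 1:20) {
    cs <- rand_duplex_case()
    a1 <- align_duplex(cs$mirna, cs$window,
                       scoring_params(require_paired_10_11 = FALSE))
    a2 <- align_duplex(cs$mirna, cs$window,
                       scoring_params(require_paired_10_11 = FALSE))
    expect_identical(a1$columns, a2$columns)
    # every miRNA base consumed exactly once, in order
    got <- a1$columns$mirna_pos[!is.na(a1$columns$mirna_pos)]
    expect_identical(as.integer(got), seq_len(nchar(cs$mirna)))
    got_t <- a1$columns$target_pos[!is.na(a1$columns$target_pos)]
    expect_identical(as.integer(got_t), seq_len(nchar(cs$window)))
  }
})

test_that("duplex rendering shows strands and gaps in display orientation", {
  sq <- mir396_sequences()
  aln <- align_duplex(sq[["ath-miR396a"]], sq[["GRF2_site"]],
                      mirna_id = "ath-miR396a")
  lines <- render_duplex(aln)
  expect_length(lines, 3)
  expect_match(lines[1], "^5' CAGUUCAAGAAAGCCUGUGGAA 3'")
  expect_match(lines[3], "-")       # the bulge shows as a gap on the miRNA line
  expect_match(lines[3], "ath-miR396a")
})
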
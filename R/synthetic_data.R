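# Synthetic-data generators: transcriptomes with planted target sites,
# mutant fold-change matrices, small RNA libraries -- each with recorded
# ground truth so recovery can be verified without re-generation.

.wc_partner <- c(A = "U", C = "G", G = "C", U = "A")
.wobble_partner <- c(A = NA, C = NA, G = "U", U = "G")

#' Specification of one planted target site
#'
#' Describes the architecture of a site to plant into a synthetic transcript:
#' the number of mismatches and G:U wobbles, an optional bulge (on the target
#' or the miRNA side, of a given length, between miRNA positions `bulge_after`
#' and `bulge_after + 1`), an optional exon junction inside the site, and
#' whether the site is a decoy (mutated to score exactly one penalty unit
#' above the reporting cap, so it sits just outside the threshold).  The
#' resulting penalty score is known in closed form:
#' `mismatches + 0.5 * wobbles + bulge_len` under default weights.
#'
#' @param mismatches Number of planted mismatches.
#' @param wobbles Number of planted G:U wobbles.
#' @param bulge `"none"`, `"target"` or `"mirna"`.
#' @param bulge_len Bulge length in nt (1 to 3).
#' @param bulge_after miRNA position 5' of the bulge (default 7: a bulge
#'   between positions 7 and 8, the conserved miR396:GRF architecture).
#' @param junction_after Place an exon boundary after this many site bases
#'   (1 to site length - 1), or `NULL` for an unspliced site.
#' @param decoy Plant a just-above-threshold decoy instead.
#' @param transcript Index of the transcript to plant into (default: next
#'   free one).
#' @param at Spliced start coordinate for the site (default: random).
#' @return An object of class `site_spec`.
#' @examples
#' site_spec(bulge = "target")  # GRF2-style architecture
#' site_spec(junction_after = 10)  # bHLH74-style junction site
#' @export
site_spec <- function(mismatches = 0L, wobbles = 0L,
                      bulge = c("none", "target", "mirna"), bulge_len = 1L,
                      bulge_after = 7L, junction_after = NULL, decoy = FALSE,
                      transcript = NULL, at = NULL) {
  bulge <- match.arg(bulge)
  stopifnot(mismatches >= 0L, wobbles >= 0L, bulge_len >= 1L, bulge_len <= 3L,
            bulge_after >= 2L)
  structure(
    list(mismatches = as.integer(mismatches), wobbles = as.integer(wobbles),
         bulge = bulge, bulge_len = as.integer(bulge_len),
         bulge_after = as.integer(bulge_after),
         junction_after = junction_after, decoy = isTRUE(decoy),
         transcript = transcript, at = at),
    class = "site_spec"
  )
}

# choose mutation positions: away from the ends, the 10-11 cleavage anchor
# and the bulge, and pairwise separated so planted penalties do not interact
.pick_positions <- function(n, L, bulge, bulge_after, taken = integer(0)) {
  pool <- setdiff(3:(L - 2L), 9:12)
  if (bulge != "none") {
    pool <- setdiff(pool, (bulge_after - 1L):(bulge_after + 2L))
  }
  pool <- setdiff(pool, unlist(lapply(taken, function(p) (p - 1L):(p + 1L))))
  picked <- integer(0)
  while (length(picked) < n) {
    if (length(pool) == 0L) {
      stop("cannot place ", n, " spaced mutations in a ", L, "-nt site",
           call. = FALSE)
    }
    p <- if (length(pool) == 1L) pool else sample(pool, 1L)
    picked <- c(picked, p)
    pool <- setdiff(pool, (p - 1L):(p + 1L))
  }
  sort(picked)
}

# build one planted site; returns the 5'->3' window and its closed-form score
.plant_site <- function(mirna, spec, params) {
  mchars <- strsplit(mirna, "", fixed = TRUE)[[1L]]
  L <- length(mchars)
  rt <- unname(.wc_partner[mchars])  # target 3'->5', aligned to miRNA 1..L
  n_mm <- if (spec$decoy) as.integer(floor(params$max_score / params$mismatch) + 1L)
          else spec$mismatches
  wob_pos <- integer(0)
  if (spec$wobbles > 0L && !spec$decoy) {
    eligible <- setdiff(intersect(which(mchars %in% c("G", "U")), 3:(L - 2L)),
                        9:12)
    if (spec$bulge != "none") {
      eligible <- setdiff(eligible,
                          (spec$bulge_after - 1L):(spec$bulge_after + 2L))
    }
    if (length(eligible) < spec$wobbles) {
      stop("not enough G/U miRNA positions for ", spec$wobbles, " wobbles",
           call. = FALSE)
    }
    wob_pos <- sort(sample(eligible, spec$wobbles))
    rt[wob_pos] <- unname(.wobble_partner[mchars[wob_pos]])
  }
  mm_pos <- if (n_mm > 0L) {
    .pick_positions(n_mm, L, spec$bulge, spec$bulge_after, taken = wob_pos)
  } else integer(0)
  for (p in mm_pos) {
    forbidden <- c(.wc_partner[mchars[p]], .wobble_partner[mchars[p]], rt[p])
    choices <- setdiff(.rna_bases, forbidden[!is.na(forbidden)])
    rt[p] <- if (length(choices) == 1L) choices else sample(choices, 1L)
  }
  bulged_nt <- 0L
  if (spec$bulge == "target") {
    ba <- spec$bulge_after
    if (ba >= L) stop("bulge_after beyond the miRNA 3' end", call. = FALSE)
    # inserted bases should pair neither flanking miRNA base
    forbidden <- c(.wc_partner[mchars[c(ba, ba + 1L)]],
                   .wobble_partner[mchars[c(ba, ba + 1L)]])
    choices <- setdiff(.rna_bases, forbidden[!is.na(forbidden)])
    if (length(choices) == 0L) choices <- "C"
    ins <- sample(choices, spec$bulge_len, replace = TRUE)
    rt <- append(rt, ins, after = ba)
    bulged_nt <- spec$bulge_len
  } else if (spec$bulge == "mirna") {
    ba <- spec$bulge_after
    if (ba + spec$bulge_len > L) stop("miRNA bulge beyond the 3' end",
                                      call. = FALSE)
    rt <- rt[-((ba + 1L):(ba + spec$bulge_len))]
    bulged_nt <- spec$bulge_len
  }
  window <- paste(rev(rt), collapse = "")  # back to 5'->3'
  score <- n_mm * params$mismatch + length(wob_pos) * params$wobble +
    bulged_nt * params$bulge_per_nt
  list(window = window, score = score, n_mismatch = n_mm,
       n_wobble = length(wob_pos))
}

# every reportable window overlapping [at, at + w - 1] on a transcript, as
# the target scan would see it
.overlapping_windows <- function(mirna_int, tx_int, at, w, params) {
  L <- length(mirna_int)
  n <- length(tx_int)
  out <- list()
  for (w2 in seq(max(L - params$max_bulge, 2L), L + params$max_bulge)) {
    o_range <- max(1L, at - w2 + 1L):min(n - w2 + 1L, at + w - 1L)
    for (o in o_range) {
      res <- .dp_score_align(mirna_int, rev(tx_int[o:(o + w2 - 1L)]),
                             params$mismatch, params$wobble,
                             params$bulge_per_nt, params$max_bulge,
                             params$require_paired_10_11)
      if (res$feasible && res$score <= params$max_score) {
        out[[length(out) + 1L]] <- c(start = o, end = o + w2 - 1L,
                                     score = res$score)
      }
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

# a planted site is accepted only if the scan over its neighbourhood
# reproduces exactly the intended record: for decoys, no reportable window at
# all; otherwise the merged best window is the planted interval at the
# closed-form score (random mutations occasionally interact through register
# shifts; such draws are rejected and redrawn)
.planted_site_valid <- function(mirna_int, tx_int, at, w, planned_score,
                                decoy, params) {
  cand <- .overlapping_windows(mirna_int, tx_int, at, w, params)
  if (decoy) return(is.null(cand))
  if (is.null(cand)) return(FALSE)
  cand <- cand[order(cand[, "score"], cand[, "start"],
                     cand[, "end"] - cand[, "start"]), , drop = FALSE]
  cand[1L, "score"] == planned_score && cand[1L, "start"] == at &&
    cand[1L, "end"] == at + w - 1L
}

#' Generate a synthetic transcriptome with planted target sites
#'
#' Transcripts are uniform-random background sequence of the requested base
#' composition; each [site_spec()] plants one target site built by mutating
#' the reverse complement of the miRNA, so the optimal alignment score of the
#' planted window is known in closed form.  Sites with `junction_after` get a
#' two-exon transcript model whose boundary falls inside the site.  Each
#' planted site is verified against a scan of its neighbourhood and redrawn
#' when the random mutations happen to interact (through register shifts or
#' the flanking sequence), so the truth table is exact by construction:
#' decoys admit no reportable window, and every true site's best overlapping
#' window is the planted interval at the closed-form score.  The truth table
#' records every planted coordinate, architecture and score; recovery tests
#' consume only outputs plus truth.
#'
#' @param mirna Mature miRNA sequence.
#' @param n_transcripts Number of transcripts to generate.
#' @param site_specs List of [site_spec()] objects.
#' @param length Transcript length in nt.
#' @param seed Integer seed (required; generators never touch global RNG
#'   state).
#' @param params [scoring_params()] used for closed-form site scores.
#' @param base_freq Background base frequencies for A, C, G, U.
#' @return A list with `transcripts` (named list of `transcript_model`),
#'   `truth` (data frame), `mirna` and `seed`.
#' @examples
#' sim <- gen_transcriptome(mir396_sequences()[["ath-miR396a"]],
#'                          n_transcripts = 2,
#'                          site_specs = list(site_spec(bulge = "target")),
#'                          length = 200, seed = 1)
#' sim$truth
#' @export
gen_transcriptome <- function(mirna, n_transcripts, site_specs = list(),
                              length = 500L, seed,
                              params = scoring_params(),
                              base_freq = rep(0.25, 4)) {
  stopifnot(n_transcripts >= 1L, length >= nchar(mirna) + 10L,
            all(vapply(site_specs, inherits, logical(1), "site_spec")))
  mirna <- .normalize_rna(c(mirna = mirna), "miRNA")[[1L]]
  withr::with_seed(as.integer(seed), {
    seqs <- vapply(seq_len(n_transcripts), function(i) {
      paste(sample(.rna_bases, length, replace = TRUE, prob = base_freq),
            collapse = "")
    }, character(1))
    names(seqs) <- sprintf("tx%03d", seq_len(n_transcripts))
    used <- list()
    truth <- list()
    next_tx <- 0L
    transcripts <- list()
    for (k in seq_along(site_specs)) {
      spec <- site_specs[[k]]
      ti <- if (!is.null(spec$transcript)) as.integer(spec$transcript)
            else (next_tx <- next_tx + 1L)
      if (ti > n_transcripts) {
        stop("site spec ", k, " assigned to transcript ", ti,
             " but only ", n_transcripts, " transcripts generated",
             call. = FALSE)
      }
      mirna_int <- .seq_ints(mirna)
      ok <- FALSE
      for (attempt in 1:50) {
        planted <- .plant_site(mirna, spec, params)
        w <- nchar(planted$window)
        margin <- 5L
        at <- if (!is.null(spec$at)) as.integer(spec$at)
              else sample((margin + 1L):(length - w - margin), 1L)
        if (at < 1L || at + w - 1L > length) {
          stop("site spec ", k, " does not fit in the transcript",
               call. = FALSE)
        }
        iv <- c(at, at + w - 1L)
        overlaps <- any(vapply(used[[as.character(ti)]] %||% list(),
                               function(u) iv[1L] <= u[2L] && u[1L] <= iv[2L],
                               logical(1)))
        if (overlaps) {
          if (!is.null(spec$at)) {
            stop("overlapping planted sites on transcript ", ti,
                 call. = FALSE)
          }
          next
        }
        s <- seqs[[ti]]
        substr(s, at, at + w - 1L) <- planted$window
        if (.planted_site_valid(mirna_int, .seq_ints(s), at, w,
                                planted$score, spec$decoy, params)) {
          seqs[[ti]] <- s
          used[[as.character(ti)]] <- c(used[[as.character(ti)]] %||% list(),
                                        list(iv))
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not realize site spec ", k,
             " (mutations kept interacting with the local context)",
             call. = FALSE)
      }
      junction <- NA_integer_
      if (!is.null(spec$junction_after)) {
        ja <- as.integer(spec$junction_after)
        if (ja < 1L || ja >= w) {
          stop("junction_after must fall strictly inside the site",
               call. = FALSE)
        }
        junction <- at + ja - 1L
      }
      truth[[k]] <- data.frame(
        transcript_id = names(seqs)[ti], start = at, end = at + w - 1L,
        score = planted$score, n_mismatch = planted$n_mismatch,
        n_wobble = planted$n_wobble, bulge = spec$bulge,
        bulge_len = if (spec$bulge == "none") 0L else spec$bulge_len,
        bulge_after = if (spec$bulge == "none") NA_integer_ else spec$bulge_after,
        junction = junction, decoy = spec$decoy,
        site_seq = planted$window, stringsAsFactors = FALSE
      )
    }
    truth <- if (base::length(truth)) do.call(rbind, truth) else
      data.frame(transcript_id = character(0), start = integer(0),
                 end = integer(0), score = numeric(0), n_mismatch = integer(0),
                 n_wobble = integer(0), bulge = character(0),
                 bulge_len = integer(0), bulge_after = integer(0),
                 junction = integer(0), decoy = logical(0),
                 site_seq = character(0), stringsAsFactors = FALSE)
    for (id in names(seqs)) {
      jx <- truth$junction[truth$transcript_id == id & !is.na(truth$junction)]
      transcripts[[id]] <- if (base::length(jx) > 0L) {
        bounds <- sort(unique(jx))
        starts <- c(1L, bounds + 1L)
        ends <- c(bounds, nchar(seqs[[id]]))
        build_transcript(substring(seqs[[id]], starts, ends), id = id)
      } else {
        build_transcript(seqs[[id]], id = id)
      }
    }
    list(transcripts = transcripts, truth = truth, mirna = mirna,
         seed = as.integer(seed))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic transcriptome as a toy genome FASTA plus GFF3
#'
#' Each transcript becomes one contig: its exons separated by random intron
#' sequence, with exon features (1-based inclusive) pointing at the
#' transcript via `Parent`.  With `strand = "-"` the contig is
#' reverse-complemented and coordinates are remapped, exercising
#' minus-strand splicing in [read_gff3_exons()].
#'
#' @param transcripts Named list of `transcript_model` objects.
#' @param fasta_path,gff_path Output paths.
#' @param intron_length Length of the random introns.
#' @param strand `"+"` or `"-"` (applied to all transcripts).
#' @param seed Integer seed for the intron sequence.
#' @return Invisibly, `list(fasta = fasta_path, gff = gff_path)`.
#' @export
write_genome_gff <- function(transcripts, fasta_path, gff_path,
                             intron_length = 60L, strand = "+", seed) {
  stopifnot(strand %in% c("+", "-"))
  withr::with_seed(as.integer(seed), {
    contigs <- character(0)
    rows <- list()
    for (tx in transcripts) {
      lens <- tx$exon_lengths
      starts_sp <- c(1L, cumsum(lens[-length(lens)]) + 1L)
      ends_sp <- cumsum(lens)
      pieces <- substring(tx$seq, starts_sp, ends_sp)
      contig <- ""
      gstart <- integer(0); gend <- integer(0)
      for (i in seq_along(pieces)) {
        s <- nchar(contig) + 1L
        contig <- paste0(contig, pieces[i])
        gstart <- c(gstart, s); gend <- c(gend, nchar(contig))
        if (i < length(pieces)) {
          contig <- paste0(contig, paste(sample(.rna_bases, intron_length,
                                                replace = TRUE),
                                         collapse = ""))
        }
      }
      if (strand == "-") {
        n <- nchar(contig)
        contig <- .revcomp_rna(contig)
        tmp <- n - gend + 1L
        gend <- n - gstart + 1L
        gstart <- tmp
      }
      cname <- paste0(tx$id, "_locus")
      contigs[cname] <- contig
      rows[[tx$id]] <- data.frame(
        seqid = cname, source = "mirduplex", type = "exon",
        start = sort(gstart), end = sort(gend), score = ".", strand = strand,
        phase = ".", attributes = paste0("Parent=", tx$id),
        stringsAsFactors = FALSE
      )
    }
    write_fasta(contigs, fasta_path)
    gff <- do.call(rbind, rows)
    con <- file(gff_path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    write.table(gff, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  })
  invisible(list(fasta = fasta_path, gff = gff_path))
}

#' Generate a mutant-vs-wild-type fold-change matrix
#'
#' True targets receive a per-gene fold drawn uniformly from `fold_range`,
#' multiplied by per-genotype lognormal noise `exp(N(0, noise_sd^2))`; all
#' other genes are pure lognormal noise around 1.  The drawn folds are
#' recorded in the `truth` attribute.
#'
#' @param genes Character vector of gene ids.
#' @param true_targets Subset of `genes` planted as up-regulated.
#' @param fold_range Uniform range of true fold changes (must lie above 1).
#' @param noise_sd Standard deviation of log-scale noise (>= 0).
#' @param genotypes Genotype column labels.
#' @param seed Integer seed.
#' @return Numeric matrix (genes x genotypes) with attribute `truth`.
#' @examples
#' m <- gen_expression(paste0("g", 1:5), "g1", seed = 1)
#' attr(m, "truth")
#' @export
gen_expression <- function(genes, true_targets, fold_range = c(1.3, 2.0),
                           noise_sd = 0.05,
                           genotypes = c("hyl1", "se", "dcl1"), seed) {
  stopifnot(all(true_targets %in% genes), !anyDuplicated(genes),
            length(fold_range) == 2L, all(fold_range > 1),
            fold_range[1L] <= fold_range[2L])
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    fold <- setNames(rep(1, length(genes)), genes)
    fold[true_targets] <- runif(length(true_targets), fold_range[1L],
                                fold_range[2L])
    noise <- matrix(rlnorm(length(genes) * length(genotypes), 0, noise_sd),
                    length(genes), length(genotypes))
    m <- fold * noise
    dimnames(m) <- list(genes, genotypes)
    attr(m, "truth") <- data.frame(gene = genes,
                                   is_true = genes %in% true_targets,
                                   fold = unname(fold),
                                   stringsAsFactors = FALSE)
    m
  })
}

#' Generate a small RNA read library from variant proportions
#'
#' Read identities are drawn multinomially from `proportions`; each read then
#' receives a 3'-end length offset drawn from `trim_profile` (negative:
#' truncation; positive: extension with random bases), emulating the 3'
#' heterogeneity of real miRNA sequencing reads.  The multinomial draw is
#' recorded in `truth`.
#'
#' @param variants Named character vector of variant sequences.
#' @param proportions Variant proportions (non-negative, summing to 1).
#' @param depth Number of reads.
#' @param trim_profile Named numeric vector of probabilities over 3' length
#'   offsets (names are integer offsets).  Default: 80% exact length, 8%/2%
#'   one/two nt short, 8%/2% one/two nt extended.
#' @param seed Integer seed.
#' @return A list with `reads` (named character vector) and `truth` (data
#'   frame of drawn per-variant read counts).
#' @examples
#' sq <- mir396_sequences()[1:2]
#' lib <- gen_library(sq, c(0.7, 0.3), depth = 100, seed = 1)
#' lib$truth
#' @export
gen_library <- function(variants, proportions, depth,
                        trim_profile = c("-2" = 0.02, "-1" = 0.08, "0" = 0.80,
                                         "1" = 0.08, "2" = 0.02), seed) {
  stopifnot(is.character(variants), !is.null(names(variants)), depth >= 1L,
            length(proportions) == length(variants))
  if (any(proportions < 0)) stop("negative proportion", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-8) {
    stop("proportions must sum to 1", call. = FALSE)
  }
  stopifnot(!is.null(names(trim_profile)), all(trim_profile >= 0),
            abs(sum(trim_profile) - 1) < 1e-8)
  variants <- .normalize_rna(variants, "variants")
  offsets <- as.integer(names(trim_profile))
  withr::with_seed(as.integer(seed), {
    counts <- as.vector(rmultinom(1L, depth, proportions))
    idx <- rep(seq_along(variants), counts)
    idx <- sample(idx)  # shuffle library order
    deltas <- sample(offsets, depth, replace = TRUE, prob = trim_profile)
    reads <- vapply(seq_len(depth), function(r) {
      v <- variants[[idx[r]]]
      d <- deltas[r]
      if (d < 0L) {
        substr(v, 1L, nchar(v) + d)
      } else if (d > 0L) {
        paste0(v, paste(sample(.rna_bases, d, replace = TRUE), collapse = ""))
      } else v
    }, character(1))
    names(reads) <- sprintf("read%05d", seq_len(depth))
    list(reads = reads,
         truth = data.frame(variant_id = names(variants), count = counts,
                            proportion = proportions,
                            stringsAsFactors = FALSE),
         seed = as.integer(seed))
  })
}
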
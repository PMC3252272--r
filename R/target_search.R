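# Scanning spliced transcripts for miRNA target sites, junction flags and
# predicted cleavage coordinates.

.as_transcript_list <- function(transcripts) {
  if (inherits(transcripts, "transcript_model")) {
    transcripts <- setNames(list(transcripts), transcripts$id)
  } else if (is.character(transcripts)) {
    stopifnot(!is.null(names(transcripts)))
    transcripts <- setNames(
      lapply(names(transcripts),
             function(id) build_transcript(transcripts[[id]], id = id)),
      names(transcripts))
  } else if (is.list(transcripts)) {
    stopifnot(all(vapply(transcripts, inherits, logical(1), "transcript_model")))
    names(transcripts) <- vapply(transcripts, `[[`, character(1), "id")
  } else {
    stop("transcripts must be a named character vector or transcript models",
         call. = FALSE)
  }
  transcripts
}

#' Scan transcripts for miRNA target sites
#'
#' Every window of length `|mirna| - max_bulge` to `|mirna| + max_bulge` at
#' every offset of each spliced transcript is aligned with [align_duplex()];
#' windows whose optimal penalty is at most `params$max_score` are candidate
#' sites.  Overlapping candidate windows for the same miRNA are merged to the
#' best-scoring one (ties: leftmost, then shortest), so one biological site
#' yields one record.  Each reported site carries its alignment, free energy,
#' an exon-junction flag and the predicted cleavage coordinate opposite
#' miRNA positions 10-11.
#'
#' @param mirna Mature miRNA sequence or single-row `mature_mirna` data frame.
#' @param transcripts Named character vector of spliced sequences, a
#'   `transcript_model`, or a list of `transcript_model` objects.
#' @param params [scoring_params()].
#' @param energy [energy_params()].
#' @param mirna_id Optional miRNA identifier for reporting.
#' @return A data frame of class `target_sites` with columns
#'   `transcript_id`, `start`, `end` (1-based inclusive spliced coordinates),
#'   `score`, `delta_g`, `spans_junction`, `cleavage_coord` and a list column
#'   `alignment`; sorted by transcript, start and score.
#' @examples
#' sq <- mir396_sequences()
#' tx <- c(t1 = paste0("ACGUACGUAC", sq[["GRF2_site"]], "GGAUCCAAGG"))
#' search_targets(sq[["ath-miR396a"]], tx)
#' @export
search_targets <- function(mirna, transcripts, params = scoring_params(),
                           energy = energy_params(), mirna_id = NULL) {
  if (is.data.frame(mirna)) {
    stopifnot(nrow(mirna) == 1L)
    if (is.null(mirna_id)) mirna_id <- mirna$id
    mirna <- mirna$seq
  }
  if (is.null(mirna_id)) mirna_id <- "miRNA"
  mirna <- .normalize_rna(c(mirna = mirna), "miRNA")[[1L]]
  transcripts <- .as_transcript_list(transcripts)
  stopifnot(length(transcripts) > 0L)
  L <- nchar(mirna)
  mi <- .seq_ints(mirna)
  widths <- seq(max(L - params$max_bulge, 2L), L + params$max_bulge)

  hits <- list()
  for (tx in transcripts) {
    n <- nchar(tx$seq)
    tx_int <- .seq_ints(tx$seq)
    cand <- list()
    for (w in widths) {
      if (w > n) next
      for (o in seq_len(n - w + 1L)) {
        res <- .dp_score_align(mi, rev(tx_int[o:(o + w - 1L)]),
                               params$mismatch, params$wobble,
                               params$bulge_per_nt, params$max_bulge,
                               params$require_paired_10_11)
        if (res$feasible && res$score <= params$max_score) {
          cand[[length(cand) + 1L]] <-
            data.frame(start = o, end = o + w - 1L, score = res$score)
        }
      }
    }
    if (length(cand) == 0L) next
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$start, cand$end), , drop = FALSE]
    # merge chains of mutually overlapping windows to the best-scoring one
    cluster <- integer(nrow(cand))
    cur <- 1L; cur_end <- cand$end[1L]; cluster[1L] <- 1L
    if (nrow(cand) > 1L) {
      for (k in 2L:nrow(cand)) {
        if (cand$start[k] <= cur_end) {
          cluster[k] <- cur
          cur_end <- max(cur_end, cand$end[k])
        } else {
          cur <- cur + 1L; cluster[k] <- cur; cur_end <- cand$end[k]
        }
      }
    }
    for (cl in unique(cluster)) {
      cc <- cand[cluster == cl, , drop = FALSE]
      cc <- cc[order(cc$score, cc$start, cc$end - cc$start), , drop = FALSE]
      best <- cc[1L, ]
      window <- substr(tx$seq, best$start, best$end)
      aln <- align_duplex(mirna, window, params = params, energy = energy,
                          mirna_id = mirna_id)
      cleav <- tryCatch(
        best$end - .cleavage_offset(aln) + 1L,
        error = function(e) NA_integer_
      )
      hits[[length(hits) + 1L]] <- data.frame(
        transcript_id = tx$id, start = best$start, end = best$end,
        score = aln$score, delta_g = aln$delta_g,
        spans_junction = any(tx$junctions >= best$start &
                               tx$junctions < best$end),
        cleavage_coord = cleav, stringsAsFactors = FALSE
      )
      attr(hits[[length(hits)]], "aln") <- aln
    }
  }
  if (length(hits) == 0L) {
    out <- data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      delta_g = numeric(0), spans_junction = logical(0),
                      cleavage_coord = integer(0), stringsAsFactors = FALSE)
    out$alignment <- list()
    class(out) <- c("target_sites", "data.frame")
    return(out)
  }
  alns <- lapply(hits, attr, "aln")
  out <- do.call(rbind, hits)
  out$alignment <- alns
  ord <- order(out$transcript_id, out$start, out$score)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("target_sites", "data.frame")
  out
}

# target-strand offset (1 = window 3' end) opposite miRNA position 10 in the
# cognate register: bulged target bases 5' of the cleavage base shift it,
# bulged miRNA bases do not
.cleavage_offset <- function(aln) {
  cols <- aln$columns
  k10 <- which(!is.na(cols$mirna_pos) & cols$mirna_pos == 10L &
                 cols$state %in% c("WATSON_CRICK", "GU_WOBBLE"))
  k11 <- which(!is.na(cols$mirna_pos) & cols$mirna_pos == 11L &
                 cols$state %in% c("WATSON_CRICK", "GU_WOBBLE"))
  if (length(k10) != 1L || length(k11) != 1L || k11 != k10 + 1L) {
    stop("miRNA positions 10-11 are not contiguously paired; ",
         "site is not cleavable under the canonical model", call. = FALSE)
  }
  10L + sum(cols$state[seq_len(k10 - 1L)] == "BULGE_TARGET")
}

#' Predicted cleavage coordinate of a target site
#'
#' miRNA-guided cleavage occurs between the target bases opposite miRNA
#' positions 10 and 11 (counted from the miRNA 5' end).  The reported
#' coordinate is the spliced position of the base opposite position 10 in
#' the cognate register: bulged target bases 5' of it shift the coordinate by
#' their length, bulged miRNA bases do not.
#'
#' @param site One row of a [search_targets()] result, or a
#'   `duplex_alignment` together with `end`.
#' @param end Spliced coordinate of the window 3' end (only when `site` is a
#'   `duplex_alignment`).
#' @return 1-based spliced cleavage coordinate.
#' @examples
#' sq <- mir396_sequences()
#' tx <- c(t1 = paste0(strrep("AC", 50), sq[["GRF2_site"]], strrep("GU", 50)))
#' sites <- search_targets(sq[["ath-miR396a"]], tx)
#' map_cleavage_site(sites[1, ])
#' @export
map_cleavage_site <- function(site, end = NULL) {
  if (inherits(site, "duplex_alignment")) {
    stopifnot(!is.null(end))
    return(as.integer(end) - .cleavage_offset(site) + 1L)
  }
  stopifnot(is.data.frame(site), nrow(site) == 1L, "alignment" %in% names(site))
  site$end - .cleavage_offset(site$alignment[[1L]]) + 1L
}

#' Write target sites as TSV
#'
#' Tab-separated with header; the duplex is rendered as a single field with
#' the three display lines joined by `/`; missing values are written as `.`.
#'
#' @param sites A `target_sites` data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  df <- as.data.frame(sites)
  df$duplex_render <- vapply(sites$alignment, function(a) {
    paste(render_duplex(a), collapse = "/")
  }, character(1))
  df$alignment <- NULL
  df$cleavage_coord <- ifelse(is.na(df$cleavage_coord), ".",
                              as.character(df$cleavage_coord))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a target-sites TSV written by [write_sites_tsv()]
#'
#' @param path Path to the TSV.
#' @return A data frame (without alignment objects).
#' @export
read_sites_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$cleavage_coord <- suppressWarnings(as.integer(df$cleavage_coord))
  df
}
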
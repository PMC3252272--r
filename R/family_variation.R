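# Per-position sequence variation within miRNA families: consensus,
# deviation counts, equal-contribution normalization.

.members_of <- function(x) {
  # accept a mature_mirna data frame or a plain character vector of sequences
  if (is.data.frame(x)) return(setNames(x$seq, x$id))
  stopifnot(is.character(x))
  x
}

.family_groups <- function(x) {
  # named list family -> character vector of member sequences
  if (is.data.frame(x)) {
    stopifnot(all(c("family", "seq") %in% names(x)))
    return(split(setNames(x$seq, x$id), x$family))
  }
  stopifnot(is.list(x), !is.null(names(x)))
  lapply(x, .members_of)
}

# 5'-anchored character matrix (members x positions), NA beyond each 3' end
.family_matrix <- function(seqs) {
  P <- max(nchar(seqs))
  t(vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    c(ch, rep(NA_character_, P - length(ch)))
  }, character(P)))
}

# per-position consensus symbol over {A,C,G,U, NA=absent}; base ties are
# broken lexicographically (A < C < G < U) and bases win ties against absence
.consensus_symbols <- function(mat) {
  apply(mat, 2L, function(col) {
    tab <- table(factor(col, levels = .rna_bases))
    n_absent <- sum(is.na(col))
    if (n_absent > max(tab)) return(NA_character_)
    .rna_bases[which.max(tab)]
  })
}

#' Consensus sequence of a miRNA family
#'
#' Members are anchored at their 5' ends (position 1 = 5' end) and padded at
#' the 3' end; the consensus base at each position is the most frequent one,
#' with ties broken lexicographically (A < C < G < U).  Trailing positions
#' where fewer than half of the members have a base are trimmed.  A
#' single-member family returns the member itself with a warning, since no
#' variation is measurable.
#'
#' @param members Character vector of member sequences (5'->3'), or a
#'   `mature_mirna` data frame.
#' @return Consensus sequence string.
#' @examples
#' family_consensus(c("AAAA", "AAAU", "AAAU"))  # "AAAU"
#' @export
family_consensus <- function(members) {
  seqs <- .normalize_rna(.members_of(members), "family members")
  if (length(seqs) < 1L) stop("empty family", call. = FALSE)
  if (length(seqs) == 1L) {
    warning("single-member family: consensus is the member itself; ",
            "no variation measurable", call. = FALSE)
    return(unname(seqs))
  }
  cons <- .consensus_symbols(.family_matrix(seqs))
  paste(cons[!is.na(cons)], collapse = "")
}

# deviation flags over the consensus frame for one member whose length
# differs from the consensus, allowing a single gap: an insertion or
# deletion is attributed to its 5'-most equivalent position and the
# remainder is re-aligned
.gapped_deviation_flags <- function(row, cons, max_gap = 3L) {
  P <- length(cons)
  mem <- row[!is.na(row)]
  cs <- cons[!is.na(cons)]
  Lm <- length(mem); Pc <- length(cs)
  naive <- (is.na(row) != is.na(cons)) |
    (!is.na(row) & !is.na(cons) & row != cons)
  g <- Lm - Pc
  if (g == 0L || abs(g) > max_gap) return(naive)
  # choose the placement with the fewest deviation events (the indel counts
  # as one event plus one per residual mismatch); ties go to the 5'-most k
  best <- NULL; best_events <- Inf
  if (g > 0L) { # insertion in the member
    for (k in seq_len(Pc + 1L)) {
      flags <- rep(FALSE, P)
      pre <- seq_len(k - 1L)
      flags[pre] <- mem[pre] != cs[pre]
      events <- 1L + sum(flags[pre])
      flags[min(k, P)] <- TRUE # the inserted base(s), charged once here
      post <- seq_len(Pc - k + 1L)
      if (length(post) > 0L) {
        mismatched <- mem[k + g + post - 1L] != cs[k + post - 1L]
        events <- events + sum(mismatched)
        flags[k + post - 1L] <- flags[k + post - 1L] | mismatched
      }
      if (events < best_events) { best <- flags; best_events <- events }
    }
  } else { # deletion in the member
    g <- -g
    for (k in seq_len(Lm + 1L)) {
      flags <- rep(FALSE, P)
      pre <- seq_len(k - 1L)
      flags[pre] <- mem[pre] != cs[pre]
      events <- 1L + sum(flags[pre])
      flags[k:(k + g - 1L)] <- TRUE # the deleted consensus base(s)
      post <- seq_len(Lm - k + 1L)
      if (length(post) > 0L) {
        mismatched <- mem[k + post - 1L] != cs[k + g + post - 1L]
        events <- events + sum(mismatched)
        flags[k + g + post - 1L] <- flags[k + g + post - 1L] | mismatched
      }
      if (events < best_events) { best <- flags; best_events <- events }
    }
  }
  if (sum(naive) < best_events) naive else best
}

# per-position deviation counts of a family against its own consensus;
# a base missing where the consensus has one (or vice versa) deviates
.family_deviations <- function(seqs, count = "position", gapped = FALSE) {
  mat <- .family_matrix(seqs)
  cons <- .consensus_symbols(mat)
  dev <- t(apply(mat, 1L, function(row) {
    if (gapped) {
      .gapped_deviation_flags(row, cons)
    } else {
      (is.na(row) != is.na(cons)) | (!is.na(row) & !is.na(cons) & row != cons)
    }
  }))
  if (length(seqs) == 1L) dev <- matrix(FALSE, 1L, ncol(mat))
  if (count == "sequence") {
    # each deviating member contributes once, at its 5'-most deviating position
    dev <- t(apply(dev, 1L, function(row) {
      out <- rep(FALSE, length(row))
      if (any(row)) out[which(row)[1L]] <- TRUE
      out
    }))
  }
  list(consensus = cons, d = colSums(dev), n = length(seqs))
}

#' Per-position variation profile across miRNA families
#'
#' For each family, the per-position deviation count `d_p` is the number of
#' members whose base at position `p` (5'-anchored) differs from the family
#' consensus; a base missing due to length differences counts as a deviation.
#' Counts are normalized to the family size (`v_p = d_p / n`), so each family
#' contributes at most 1 per position, and the summary `V_p` is the sum of
#' the normalized contributions over families.
#'
#' @param x A `mature_mirna` data frame (grouped by its `family` column) or a
#'   named list of member sequence vectors, one element per family.
#' @param count `"position"` (default): a member deviating at several
#'   positions is counted at each; `"sequence"`: each deviating member is
#'   counted once, at its 5'-most deviating position.
#' @param merge Optional merge specification passed to [merge_families()]
#'   before profiling (e.g. `"miR159:miR319"`).
#' @param gapped With `FALSE` (default) members are compared to the
#'   consensus strictly by position; with `TRUE` a member whose length
#'   differs from the consensus is re-aligned with a single-gap allowance,
#'   so an insertion such as the monocot miR396 7-8insG is charged once, at
#'   its 5'-most equivalent position (position 8), instead of shifting every
#'   downstream position.
#' @return A list of class `variation_summary`: `positions`, `V` (per-position
#'   totals), `v` (positions x families matrix of normalized deviations) and
#'   `families` (per-family profiles with `n_members`, `consensus`,
#'   `deviations`, `normalized`).
#' @examples
#' fams <- list(f1 = c("AAAAAAAA", "AAAAAAAA", "AAAAAAAA", "AAAAAAAU"),
#'              f2 = c("GGGGGGGG", "GGGGGGGU"))
#' variation_profile(fams)$V[8]  # 1/4 + 1/2 = 0.75
#' @export
variation_profile <- function(x, count = c("position", "sequence"),
                              merge = NULL, gapped = FALSE) {
  count <- match.arg(count)
  groups <- .family_groups(x)
  if (!is.null(merge)) groups <- merge_families(groups, merge)
  groups <- lapply(groups, .normalize_rna, context = "family members")
  P <- max(vapply(groups, function(g) max(nchar(g)), integer(1)))
  fams <- names(groups)
  v <- matrix(0, P, length(fams), dimnames = list(NULL, fams))
  profiles <- list()
  for (f in fams) {
    res <- .family_deviations(groups[[f]], count = count, gapped = gapped)
    v[seq_along(res$d), f] <- res$d / res$n
    profiles[[f]] <- list(
      family_id = f, n_members = res$n,
      consensus = paste(res$consensus[!is.na(res$consensus)], collapse = ""),
      deviations = res$d, normalized = res$d / res$n)
  }
  structure(
    list(positions = seq_len(P), V = rowSums(v), v = v, families = profiles),
    class = "variation_summary"
  )
}

#' @export
print.variation_summary <- function(x, ...) {
  cat("variation_summary over", length(x$families), "family(ies),",
      length(x$positions), "positions\n")
  print(data.frame(position = x$positions, V = round(x$V, 4)))
  invisible(x)
}

#' Merge miRNA families before profiling
#'
#' Pools the members of the named families under a merged id; downstream
#' consensus and deviation counts are then recomputed on the pooled members
#' (never averaged).  Families whose modal member lengths differ are merged
#' with a warning under 5' anchoring.
#'
#' @param x A named list of family member vectors or a `mature_mirna` data
#'   frame.
#' @param merge_spec Either a string like `"miR159:miR319"` (merge those
#'   families into one named `"miR159/miR319"`) or a named character vector
#'   mapping old family ids to merged ids.
#' @return The same type as `x`, with families merged.
#' @examples
#' fams <- list(miR159 = c("AAAA"), miR319 = c("AAAU"))
#' names(merge_families(fams, "miR159:miR319"))
#' @export
merge_families <- function(x, merge_spec) {
  if (is.character(merge_spec) && is.null(names(merge_spec))) {
    parts <- strsplit(merge_spec, ":", fixed = TRUE)
    merge_spec <- unlist(lapply(parts, function(p) {
      setNames(rep(paste(p, collapse = "/"), length(p)), p)
    }))
  }
  stopifnot(is.character(merge_spec), !is.null(names(merge_spec)))
  recode <- function(f) ifelse(f %in% names(merge_spec), merge_spec[f], f)
  if (is.data.frame(x)) {
    x$family <- unname(recode(x$family))
    return(x)
  }
  groups <- .family_groups(x)
  new_names <- unname(recode(names(groups)))
  out <- lapply(unique(new_names), function(nf) {
    pooled <- unlist(groups[new_names == nf], use.names = FALSE)
    src <- names(groups)[new_names == nf]
    if (length(src) > 1L) {
      modal_len <- vapply(groups[src], function(g) {
        as.integer(names(sort(table(nchar(g)), decreasing = TRUE))[1L])
      }, integer(1))
      if (length(unique(modal_len)) > 1L) {
        warning("merging families with different canonical lengths (",
                paste(src, modal_len, sep = "=", collapse = ", "),
                "); proceeding with 5' anchoring", call. = FALSE)
      }
    }
    pooled
  })
  names(out) <- unique(new_names)
  out
}

#' Shared positions between two family consensus sequences
#'
#' Compares the 5'-anchored consensus of two families, allowing at most one
#' gap in either consensus (subfamilies such as miR159 and miR319 are offset
#' by one nucleotide at the 5' end).  Among candidate placements the one
#' maximizing the number of identical columns wins (ties: no gap, then the
#' 5'-most gap, gap in the second sequence before the first).
#'
#' @param members_a,members_b Member sequences (character vectors or
#'   `mature_mirna` data frames) of the two families.
#' @param max_gap Maximum gap length to consider (0 disables gapping).
#' @return A list with `shared` (number of identical aligned columns),
#'   `length` (the longer consensus length), `gap` (description of the
#'   placement) and the two consensus strings.
#' @examples
#' ath <- ath_mir159_mir319()
#' consensus_shared_positions(ath[ath$family == "miR159", ],
#'                            ath[ath$family == "miR319", ])
#' @export
consensus_shared_positions <- function(members_a, members_b, max_gap = 1L) {
  cons_a <- suppressWarnings(family_consensus(members_a))
  cons_b <- suppressWarnings(family_consensus(members_b))
  a <- strsplit(cons_a, "", fixed = TRUE)[[1L]]
  b <- strsplit(cons_b, "", fixed = TRUE)[[1L]]
  count_matches <- function(x, y) {
    n <- min(length(x), length(y))
    sum(x[seq_len(n)] == y[seq_len(n)], na.rm = TRUE)
  }
  gap_into <- function(x, at, len) {
    append(x, rep(NA_character_, len), after = at)
  }
  best <- list(shared = count_matches(a, b), gap = "none")
  if (max_gap >= 1L) {
    for (len in seq_len(max_gap)) {
      for (at in 0:length(b)) {
        sh <- count_matches(a, gap_into(b, at, len))
        if (sh > best$shared) {
          best <- list(shared = sh,
                       gap = sprintf("%d-nt gap in b after position %d", len, at))
        }
      }
      for (at in 0:length(a)) {
        sh <- count_matches(gap_into(a, at, len), b)
        if (sh > best$shared) {
          best <- list(shared = sh,
                       gap = sprintf("%d-nt gap in a after position %d", len, at))
        }
      }
    }
  }
  list(shared = best$shared, length = max(length(a), length(b)),
       gap = best$gap, consensus_a = cons_a, consensus_b = cons_b)
}

#' Write a variation profile as TSV
#'
#' Columns: position, the summary `V`, then one normalized column per family.
#'
#' @param summary A `variation_summary`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_profile_tsv <- function(summary, path) {
  df <- data.frame(position = summary$positions, V = summary$V,
                   summary$v, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
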
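# Bulge-aware miRNA:target duplex alignment, complementarity scoring and
# nearest-neighbor free-energy evaluation.

.rna_bases <- c("A", "C", "G", "U")
.pair_rev <- c(CG = "GC", GC = "CG", GU = "UG", UG = "GU",
               AU = "UA", UA = "AU")

.seq_ints <- function(x) match(strsplit(x, "", fixed = TRUE)[[1L]], .rna_bases) - 1L

.revstr <- function(x) {
  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}

# pair code ("CG", "GU", ...) for a miRNA base over a target base, or NA
.pair_code <- function(m, t) {
  code <- paste0(m, t)
  ifelse(code %in% names(.pair_rev), code, NA_character_)
}

.pair_state <- function(m, t) {
  code <- .pair_code(m, t)
  ifelse(is.na(code), "MISMATCH",
         ifelse(code %in% c("GU", "UG"), "GU_WOBBLE", "WATSON_CRICK"))
}

.empty_columns <- function() {
  data.frame(state = character(0), mirna_pos = integer(0),
             target_pos = integer(0), mirna_base = character(0),
             target_base = character(0), stringsAsFactors = FALSE)
}

# columns for an unpaired stretch of `a` miRNA and `b` target bases starting
# after consumed counts (i0, j0): mismatches first (5'-side), then the
# excess as a bulge run -- the canonical decomposition used throughout
.run_columns <- function(i0, j0, a, b, mi, tg) {
  if (a == 0L && b == 0L) return(.empty_columns())
  m <- min(a, b)
  st <- ip <- jp <- c()
  if (m > 0L) {
    st <- rep("MISMATCH", m)
    ip <- i0 + seq_len(m)
    jp <- j0 + seq_len(m)
  }
  if (a > b) {
    st <- c(st, rep("BULGE_MIRNA", a - b))
    ip <- c(ip, i0 + m + seq_len(a - b))
    jp <- c(jp, rep(NA_integer_, a - b))
  } else if (b > a) {
    st <- c(st, rep("BULGE_TARGET", b - a))
    ip <- c(ip, rep(NA_integer_, b - a))
    jp <- c(jp, j0 + m + seq_len(b - a))
  }
  data.frame(state = st, mirna_pos = as.integer(ip), target_pos = as.integer(jp),
             mirna_base = ifelse(is.na(ip), NA_character_, mi[ip]),
             target_base = ifelse(is.na(jp), NA_character_, tg[jp]),
             stringsAsFactors = FALSE)
}

.new_alignment <- function(mirna_id, mirna, window, columns, score, feasible) {
  structure(
    list(mirna_id = mirna_id, mirna = mirna, window = window,
         columns = columns, score = score, delta_g = NA_real_,
         feasible = feasible),
    class = "duplex_alignment"
  )
}

#' Align a miRNA against one target window
#'
#' Global alignment of the full miRNA (5'->3') against the full target window
#' (read 3'->5', antiparallel) by dynamic programming over three column
#' types: a column consuming one base of each strand (Watson-Crick pair, G:U
#' wobble or mismatch), a bulged miRNA base, or a bulged target base.  With
#' `objective = "score"` the alignment minimizes the empirical
#' complementarity penalty of [scoring_params()]; ties are broken toward
#' fewer gap columns and then toward gaps nearest the miRNA 3' end.  With
#' `objective = "energy"` it minimizes the nearest-neighbor free energy of
#' [duplex_delta_g()] instead.  When pairing at miRNA positions 10-11 is
#' required but impossible, a sentinel "no site" alignment with infinite
#' score and `feasible = FALSE` is returned.
#'
#' @param mirna Mature miRNA sequence (5'->3'; DNA accepted and normalized),
#'   or a single-row `mature_mirna` data frame.
#' @param window Target window sequence (5'->3', sense mRNA orientation).
#'   Its length must be within `params$max_bulge` of the miRNA length.
#' @param params [scoring_params()].
#' @param objective Optimize the complementarity `"score"` (default) or the
#'   nearest-neighbor `"energy"`.
#' @param energy [energy_params()] used for `delta_g` and the energy
#'   objective.
#' @param mirna_id Optional identifier for reporting.
#' @return A `duplex_alignment`: list with `mirna`, `window`, `columns` (a
#'   data frame of column states with 1-based miRNA positions and 3'->5'
#'   target offsets), `score`, `delta_g` and `feasible`.
#' @examples
#' sq <- mir396_sequences()
#' aln <- align_duplex(sq[["ath-miR396a"]], sq[["GRF2_site"]],
#'                     mirna_id = "ath-miR396a")
#' aln
#' @export
align_duplex <- function(mirna, window, params = scoring_params(),
                         objective = c("score", "energy"),
                         energy = energy_params(), mirna_id = NULL) {
  objective <- match.arg(objective)
  if (is.data.frame(mirna)) {
    stopifnot(nrow(mirna) == 1L)
    if (is.null(mirna_id)) mirna_id <- mirna$id
    mirna <- mirna$seq
  }
  stopifnot(inherits(params, "scoring_params"), inherits(energy, "energy_params"))
  mirna <- .normalize_rna(c(mirna = mirna), "miRNA")[[1L]]
  window <- .normalize_rna(c(window = window), "target window")[[1L]]
  if (is.null(mirna_id)) mirna_id <- "miRNA"
  L <- nchar(mirna); W <- nchar(window)
  if (abs(W - L) > params$max_bulge) {
    stop("window length ", W, " outside the +/-", params$max_bulge,
         " nt band around the miRNA length ", L, call. = FALSE)
  }
  mi <- .seq_ints(mirna)
  tg <- .seq_ints(.revstr(window))          # target consumed 3'->5'
  mchars <- strsplit(mirna, "", fixed = TRUE)[[1L]]
  tchars <- strsplit(.revstr(window), "", fixed = TRUE)[[1L]]

  if (objective == "score") {
    res <- .dp_score_align(mi, tg, params$mismatch, params$wobble,
                           params$bulge_per_nt, params$max_bulge,
                           params$require_paired_10_11)
    if (!res$feasible) {
      return(.new_alignment(mirna_id, mirna, window, .empty_columns(),
                            Inf, FALSE))
    }
    i <- j <- 0L
    cols <- lapply(res$moves, function(mv) {
      if (mv == 0L) {
        i <<- i + 1L; j <<- j + 1L
        data.frame(state = .pair_state(mchars[i], tchars[j]),
                   mirna_pos = i, target_pos = j, mirna_base = mchars[i],
                   target_base = tchars[j], stringsAsFactors = FALSE)
      } else if (mv == 1L) {
        i <<- i + 1L
        data.frame(state = "BULGE_MIRNA", mirna_pos = i,
                   target_pos = NA_integer_, mirna_base = mchars[i],
                   target_base = NA_character_, stringsAsFactors = FALSE)
      } else {
        j <<- j + 1L
        data.frame(state = "BULGE_TARGET", mirna_pos = NA_integer_,
                   target_pos = j, mirna_base = NA_character_,
                   target_base = tchars[j], stringsAsFactors = FALSE)
      }
    })
    columns <- do.call(rbind, cols)
    aln <- .new_alignment(mirna_id, mirna, window, columns, res$score, TRUE)
  } else {
    res <- .dp_energy_align(mi, tg, energy$stack, energy$bulge,
                            energy$internal, energy$terminal_au,
                            energy$initiation, energy$lxc,
                            params$max_bulge, params$require_paired_10_11)
    if (!res$feasible) {
      return(.new_alignment(mirna_id, mirna, window, .empty_columns(),
                            Inf, FALSE))
    }
    pi <- res$pair_i; pj <- res$pair_j
    cols <- list(.run_columns(0L, 0L, pi[1L] - 1L, pj[1L] - 1L, mchars, tchars))
    for (k in seq_along(pi)) {
      cols[[length(cols) + 1L]] <- data.frame(
        state = .pair_state(mchars[pi[k]], tchars[pj[k]]),
        mirna_pos = pi[k], target_pos = pj[k], mirna_base = mchars[pi[k]],
        target_base = tchars[pj[k]], stringsAsFactors = FALSE)
      if (k < length(pi)) {
        cols[[length(cols) + 1L]] <- .run_columns(
          pi[k], pj[k], pi[k + 1L] - pi[k] - 1L, pj[k + 1L] - pj[k] - 1L,
          mchars, tchars)
      }
    }
    cols[[length(cols) + 1L]] <- .run_columns(pi[length(pi)], pj[length(pj)],
                                              L - pi[length(pi)],
                                              W - pj[length(pj)],
                                              mchars, tchars)
    columns <- do.call(rbind, cols)
    aln <- .new_alignment(mirna_id, mirna, window, columns, NA_real_, TRUE)
    aln$score <- score_alignment(aln, params)
  }
  if (any(aln$columns$state %in% c("WATSON_CRICK", "GU_WOBBLE"))) {
    aln$delta_g <- duplex_delta_g(aln, energy)
  }
  aln
}

#' Complementarity penalty of a duplex alignment
#'
#' `mismatch_penalty * #mismatches + wobble_penalty * #wobbles +
#' bulge_penalty_per_nt * #bulged nucleotides`, recomputed from the
#' alignment columns.
#'
#' @param aln A `duplex_alignment`.
#' @param params [scoring_params()].
#' @return Non-negative penalty score.
#' @examples
#' sq <- mir396_sequences()
#' aln <- align_duplex(sq[["ath-miR396a"]], sq[["GRF2_site"]])
#' score_alignment(aln) # 1: the single bulged target nucleotide
#' @export
score_alignment <- function(aln, params = scoring_params()) {
  stopifnot(inherits(aln, "duplex_alignment"))
  if (!aln$feasible) return(Inf)
  st <- aln$columns$state
  sum(st == "MISMATCH") * params$mismatch +
    sum(st == "GU_WOBBLE") * params$wobble +
    sum(st %in% c("BULGE_MIRNA", "BULGE_TARGET")) * params$bulge_per_nt
}

.loop_energy <- function(n, tab, lxc) {
  if (n <= length(tab)) tab[n]
  else tab[length(tab)] + lxc * log(n / length(tab))
}

.terminal_au <- function(code, ep) {
  if (code %in% c("CG", "GC")) 0 else ep$terminal_au
}

#' Nearest-neighbor hybridization free energy of a duplex alignment
#'
#' Additive Turner-style evaluation of an alignment: duplex initiation, plus
#' one stacking term for each pair of adjacent paired columns (Watson-Crick
#' or G:U; the stack is retained across a single-nucleotide bulge), plus a
#' length-dependent bulge or internal-loop penalty for each maximal internal
#' run of unpaired columns, plus a terminal AU/GU penalty at each end of the
#' duplex.  Unpaired columns outside the outermost pairs are free ends and
#' contribute nothing.  The result is order-independent given the alignment.
#'
#' @param aln A `duplex_alignment`.
#' @param ep [energy_params()].
#' @return Free energy in kcal/mol (more negative = stronger binding).
#' @examples
#' sq <- mir396_sequences()
#' a <- align_duplex(sq[["ath-miR396a"]], sq[["GRF2_site"]])
#' duplex_delta_g(a)
#' @export
duplex_delta_g <- function(aln, ep = energy_params()) {
  stopifnot(inherits(aln, "duplex_alignment"), inherits(ep, "energy_params"))
  cols <- aln$columns
  paired <- which(cols$state %in% c("WATSON_CRICK", "GU_WOBBLE"))
  if (length(paired) == 0L) {
    stop("alignment has no paired columns; free energy undefined",
         call. = FALSE)
  }
  codes <- .pair_code(cols$mirna_base[paired], cols$target_base[paired])
  e <- ep$initiation + .terminal_au(codes[1L], ep) +
    .terminal_au(codes[length(codes)], ep)
  if (length(paired) > 1L) {
    for (k in seq_len(length(paired) - 1L)) {
      i1 <- paired[k]; i2 <- paired[k + 1L]
      a <- cols$mirna_pos[i2] - cols$mirna_pos[i1] - 1L   # unpaired miRNA nt
      b <- cols$target_pos[i2] - cols$target_pos[i1] - 1L # unpaired target nt
      stk <- ep$stack[codes[k], .pair_rev[codes[k + 1L]]]
      if (a == 0L && b == 0L) {
        e <- e + stk
      } else if (a + b == 1L) {
        e <- e + stk + .loop_energy(1L, ep$bulge, ep$lxc)
      } else if (b == 0L) {
        e <- e + .loop_energy(a, ep$bulge, ep$lxc)
      } else if (a == 0L) {
        e <- e + .loop_energy(b, ep$bulge, ep$lxc)
      } else {
        e <- e + .loop_energy(a + b, ep$internal, ep$lxc)
      }
    }
  }
  e
}

#' Free-energy difference between two alignments on the same window
#'
#' `delta_delta_g = delta_g(aln_b) - delta_g(aln_a)`; negative values mean
#' `aln_b` binds the shared target window more strongly than `aln_a`.
#'
#' @param aln_a,aln_b `duplex_alignment` objects sharing the same target
#'   window.
#' @param ep [energy_params()].
#' @return Free-energy difference in kcal/mol.
#' @examples
#' sq <- mir396_sequences()
#' bulged <- align_duplex(sq[["ath-miR396a"]], sq[["GRF2_site"]])
#' flush  <- align_duplex(sq[["miR396_7-8insG"]], sq[["GRF2_site"]])
#' delta_delta_g(bulged, flush) # about -7 kcal/mol: bulge removal
#' @export
delta_delta_g <- function(aln_a, aln_b, ep = energy_params()) {
  stopifnot(inherits(aln_a, "duplex_alignment"),
            inherits(aln_b, "duplex_alignment"))
  if (!identical(aln_a$window, aln_b$window)) {
    stop("alignments are on different target windows", call. = FALSE)
  }
  duplex_delta_g(aln_b, ep) - duplex_delta_g(aln_a, ep)
}

#' Render a duplex in the three-line miRBase style
#'
#' Target 5'->3' on top, pair symbols in the middle (`|` Watson-Crick,
#' `:` G:U wobble, space for mismatches), miRNA 3'->5' at the bottom;
#' bulged positions show a `-` on the opposite strand.
#'
#' @param aln A `duplex_alignment`.
#' @return Character vector of three lines.
#' @export
render_duplex <- function(aln) {
  stopifnot(inherits(aln, "duplex_alignment"))
  if (!aln$feasible) return(c("5' (no feasible duplex) 3'", "", ""))
  cols <- aln$columns[rev(seq_len(nrow(aln$columns))), ] # target 5'->3'
  sym <- c(WATSON_CRICK = "|", GU_WOBBLE = ":", MISMATCH = " ",
           BULGE_MIRNA = " ", BULGE_TARGET = " ")
  top <- ifelse(is.na(cols$target_base), "-", cols$target_base)
  bot <- ifelse(is.na(cols$mirna_base), "-", cols$mirna_base)
  c(paste0("5' ", paste(top, collapse = ""), " 3' target"),
    paste0("   ", paste(sym[cols$state], collapse = "")),
    paste0("3' ", paste(bot, collapse = ""), " 5' ", aln$mirna_id))
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(render_duplex(x), sep = "\n")
  cat(sprintf("score = %s, delta G = %s kcal/mol\n",
              format(x$score), format(round(x$delta_g, 2))))
  invisible(x)
}

#' Tabulate duplex alignments
#'
#' One row per alignment: miRNA id, window, score, free energy and the
#' miRNA-position intervals flanking each bulge.
#'
#' @param alns A `duplex_alignment` or list of them.
#' @return A data frame.
#' @export
duplex_table <- function(alns) {
  if (inherits(alns, "duplex_alignment")) alns <- list(alns)
  do.call(rbind, lapply(alns, function(a) {
    bulges <- which(a$columns$state %in% c("BULGE_MIRNA", "BULGE_TARGET"))
    bpos <- if (length(bulges) == 0L) "." else {
      paste(vapply(bulges, function(k) {
        prev <- a$columns$mirna_pos[seq_len(k - 1L)]
        lo <- if (any(!is.na(prev))) max(prev, na.rm = TRUE) else 0L
        side <- if (a$columns$state[k] == "BULGE_MIRNA") "m" else "t"
        paste0(side, lo, "-", lo + 1L)
      }, character(1)), collapse = ",")
    }
    data.frame(mirna_id = a$mirna_id, window = a$window, score = a$score,
               delta_g = a$delta_g, bulges = bpos, stringsAsFactors = FALSE)
  }))
}
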
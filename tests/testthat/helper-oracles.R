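# Independent plain-R oracles for the duplex alignment model, plus literal
# enumerators used to cross-check the oracles themselves at tiny sizes.

RNA <- c("A", "C", "G", "U")
ORACLE_PAIRS <- c("CG", "GC", "GU", "UG", "AU", "UA")
ORACLE_WC <- c("CG", "GC", "AU", "UA")
ORACLE_REV <- c(CG = "GC", GC = "CG", GU = "UG", UG = "GU",
                AU = "UA", UA = "AU")

rand_rna <- function(n) paste(sample(RNA, n, replace = TRUE), collapse = "")

# column cost of pairing miRNA base m over target base t
oracle_col_cost <- function(m, t, params) {
  code <- paste0(m, t)
  if (code %in% ORACLE_WC) 0
  else if (code %in% ORACLE_PAIRS) params$wobble
  else params$mismatch
}

# minimum complementarity penalty over all monotone global alignments,
# bounded bulge runs, optional 10-11 pairing constraint; bottom-up over
# (miRNA consumed, target consumed, last-move run state)
oracle_score <- function(mirna, window, params = scoring_params()) {
  m <- strsplit(mirna, "")[[1]]
  t <- rev(strsplit(window, "")[[1]])
  L <- length(m); W <- length(t); mb <- params$max_bulge
  req <- params$require_paired_10_11 && L >= 11
  # states: 1 = pair/start, 2..(mb+1) = miRNA-bulge run, rest = target-bulge
  S <- 2 * mb + 1
  D <- array(Inf, dim = c(L + 1, W + 1, S))
  D[1, 1, 1] <- 0
  for (i in 0:L) for (j in 0:W) for (s in 1:S) {
    d <- D[i + 1, j + 1, s]
    if (!is.finite(d)) next
    if (i < L && j < W) {
      cost <- oracle_col_cost(m[i + 1], t[j + 1], params)
      mm <- !paste0(m[i + 1], t[j + 1]) %in% ORACLE_PAIRS
      if (!(req && mm && (i + 1) %in% c(10, 11))) {
        D[i + 2, j + 2, 1] <- min(D[i + 2, j + 2, 1], d + cost)
      }
    }
    if (i < L && !(req && (i + 1) %in% c(10, 11))) {
      run <- if (s >= 2 && s <= mb + 1) s - 1 else 0
      if (run < mb) {
        D[i + 2, j + 1, run + 2] <- min(D[i + 2, j + 1, run + 2],
                                        d + params$bulge_per_nt)
      }
    }
    if (j < W && !(req && i == 10)) {
      run <- if (s > mb + 1) s - mb - 1 else 0
      if (run < mb) {
        D[i + 1, j + 2, mb + run + 2] <- min(D[i + 1, j + 2, mb + run + 2],
                                             d + params$bulge_per_nt)
      }
    }
  }
  min(D[L + 1, W + 1, ])
}

# minimum nearest-neighbor free energy over all pair chains of the duplex
# model (pairs are WC or G:U; loop side-difference bounded by max_bulge;
# free single-stranded ends; optional contiguous pairing at 10-11)
oracle_energy <- function(mirna, window, ep = energy_params(),
                          params = scoring_params()) {
  m <- strsplit(mirna, "")[[1]]
  t <- rev(strsplit(window, "")[[1]])
  L <- length(m); W <- length(t); mb <- params$max_bulge
  req <- params$require_paired_10_11 && L >= 11
  code <- outer(m, t, paste0)
  pairable <- matrix(code %in% ORACLE_PAIRS, L, W)
  loopE <- function(n, tab) {
    if (n <= length(tab)) tab[n]
    else tab[length(tab)] + ep$lxc * log(n / length(tab))
  }
  tau <- function(cd) if (cd %in% c("CG", "GC")) 0 else ep$terminal_au
  E <- matrix(Inf, L, W)
  for (i in 1:L) for (j in 1:W) {
    if (!pairable[i, j]) next
    best <- Inf
    if (abs(i - j) <= mb && !(req && i > 10)) {
      best <- ep$initiation + tau(code[i, j])
    }
    if (i > 1 && j > 1) {
      for (pi in 1:(i - 1)) {
        if (req && pi <= 9 && i >= 11) next
        for (pj in 1:(j - 1)) {
          if (!is.finite(E[pi, pj])) next
          a <- i - pi - 1; b <- j - pj - 1
          if (abs(a - b) > mb) next
          if (req && pi == 10 && !(i == 11 && a == 0 && b == 0)) next
          stk <- ep$stack[code[pi, pj], ORACLE_REV[code[i, j]]]
          cost <- if (a == 0 && b == 0) stk
            else if (a + b == 1) stk + loopE(1, ep$bulge)
            else if (b == 0) loopE(a, ep$bulge)
            else if (a == 0) loopE(b, ep$bulge)
            else loopE(a + b, ep$internal)
          best <- min(best, E[pi, pj] + cost)
        }
      }
    }
    E[i, j] <- best
  }
  best <- Inf
  for (i in 1:L) for (j in 1:W) {
    if (!is.finite(E[i, j])) next
    if (req && i < 11) next
    if (abs((L - i) - (W - j)) > mb) next
    best <- min(best, E[i, j] + tau(code[i, j]))
  }
  best
}

# literal exhaustive enumeration of every monotone move sequence (tiny sizes
# only): cross-checks oracle_score without any recurrence sharing
enum_score <- function(mirna, window, params = scoring_params()) {
  m <- strsplit(mirna, "")[[1]]
  t <- rev(strsplit(window, "")[[1]])
  L <- length(m); W <- length(t); mb <- params$max_bulge
  req <- params$require_paired_10_11 && L >= 11
  rec <- function(i, j, mrun, trun) {
    if (i == L && j == W) return(0)
    best <- Inf
    if (i < L && j < W) {
      mm <- !paste0(m[i + 1], t[j + 1]) %in% ORACLE_PAIRS
      if (!(req && mm && (i + 1) %in% c(10, 11))) {
        best <- min(best, oracle_col_cost(m[i + 1], t[j + 1], params) +
                      rec(i + 1, j + 1, 0, 0))
      }
    }
    if (i < L && mrun < mb && !(req && (i + 1) %in% c(10, 11))) {
      best <- min(best, params$bulge_per_nt + rec(i + 1, j, mrun + 1, 0))
    }
    if (j < W && trun < mb && !(req && i == 10)) {
      best <- min(best, params$bulge_per_nt + rec(i, j + 1, 0, trun + 1))
    }
    best
  }
  rec(0, 0, 0, 0)
}

# literal exhaustive enumeration of every pair chain (tiny sizes only):
# cross-checks oracle_energy
enum_energy <- function(mirna, window, ep = energy_params(),
                        params = scoring_params()) {
  m <- strsplit(mirna, "")[[1]]
  t <- rev(strsplit(window, "")[[1]])
  L <- length(m); W <- length(t); mb <- params$max_bulge
  req <- params$require_paired_10_11 && L >= 11
  code <- outer(m, t, paste0)
  loopE <- function(n, tab) {
    if (n <= length(tab)) tab[n]
    else tab[length(tab)] + ep$lxc * log(n / length(tab))
  }
  tau <- function(cd) if (cd %in% c("CG", "GC")) 0 else ep$terminal_au
  best <- Inf
  extend <- function(i, j, acc) {
    # option: close the duplex here
    if ((!req || i >= 11) && abs((L - i) - (W - j)) <= mb) {
      best <<- min(best, acc + tau(code[i, j]))
    }
    if (i >= L || j >= W) return(invisible())
    for (ni in (i + 1):L) {
      if (req && i <= 9 && ni >= 11) next
      for (nj in (j + 1):W) {
        if (!code[ni, nj] %in% ORACLE_PAIRS) next
        a <- ni - i - 1; b <- nj - j - 1
        if (abs(a - b) > mb) next
        if (req && i == 10 && !(ni == 11 && a == 0 && b == 0)) next
        stk <- ep$stack[code[i, j], ORACLE_REV[code[ni, nj]]]
        cost <- if (a == 0 && b == 0) stk
          else if (a + b == 1) stk + loopE(1, ep$bulge)
          else if (b == 0) loopE(a, ep$bulge)
          else if (a == 0) loopE(b, ep$bulge)
          else loopE(a + b, ep$internal)
        extend(ni, nj, acc + cost)
      }
    }
  }
  for (i in 1:L) for (j in 1:W) {
    if (!code[i, j] %in% ORACLE_PAIRS) next
    if (abs(i - j) > mb) next
    if (req && i > 10) next
    extend(i, j, ep$initiation + tau(code[i, j]))
  }
  best
}

# random (miRNA, window) pair with the window length inside the DP band
rand_duplex_case <- function(max_mirna = 10, max_delta = 3) {
  L <- sample(4:max_mirna, 1)
  d <- sample(-min(max_delta, L - 2):max_delta, 1)
  list(mirna = rand_rna(L), window = rand_rna(L + d))
}
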
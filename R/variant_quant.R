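# Quantification of miRNA sequence-variant abundance in small RNA libraries.

# multiplicity from the collapsed-read FASTA dialect "id_xN"
.read_multiplicity <- function(ids) {
  m <- regmatches(ids, regexpr("_x([0-9]+)$", ids))
  n <- rep(1L, length(ids))
  has <- nzchar(m)
  n[has] <- as.integer(sub("_x", "", m[has], fixed = TRUE))
  n
}

# a read matches a variant iff their 5' ends coincide, the overlapping
# prefix is identical, and the 3' length difference is at most trim_tol
.match_matrix <- function(reads, variants, trim_tol) {
  rl <- nchar(reads)
  out <- matrix(FALSE, length(reads), length(variants),
                dimnames = list(NULL, names(variants)))
  for (k in seq_along(variants)) {
    v <- variants[[k]]
    lv <- nchar(v)
    ok <- abs(rl - lv) <= trim_tol
    n <- pmin(rl, lv)
    out[, k] <- ok & substring(reads, 1L, n) == substring(v, 1L, n)
  }
  out
}

#' Count reads supporting each miRNA sequence variant
#'
#' A read supports a variant when it equals the variant exactly, or equals it
#' truncated or extended by at most `trim_tol` nucleotides at the 3' end with
#' all overlapping bases identical (the 5' end, which defines targeting, must
#' match exactly).  Reads consistent with more than one variant are split
#' fractionally between them (`ambiguous = "split"`, the default) or
#' discarded (`"strict"`); unmatched reads are counted and reported, never
#' silently assigned.  Collapsed-FASTA multiplicities (`id_xN`) are honored.
#'
#' @param reads Named character vector of read sequences (e.g. from
#'   [read_fasta()] with `format = "fastq"` for FASTQ input; qualities are
#'   ignored).
#' @param variants Named character vector of variant sequences, or a
#'   `mature_mirna` data frame.  Variants must remain distinguishable under
#'   the matching rule.
#' @param trim_tol 3'-end length tolerance in nt. Default 2.
#' @param ambiguous `"split"` or `"strict"`.
#' @param library_id Library label for the output.
#' @return Data frame of class `variant_counts`: `variant_id`, `library_id`,
#'   `count`, `abundance`; attributes `n_reads`, `n_unmatched`, `n_ambiguous`.
#' @examples
#' reads <- setNames(rep("ACGUACGUACGUACGUACGUA", 3), paste0("r", 1:3))
#' count_variant_reads(reads, c(v1 = "ACGUACGUACGUACGUACGUA"))
#' @export
count_variant_reads <- function(reads, variants, trim_tol = 2L,
                                ambiguous = c("split", "strict"),
                                library_id = "library") {
  ambiguous <- match.arg(ambiguous)
  if (is.data.frame(variants)) variants <- setNames(variants$seq, variants$id)
  stopifnot(is.character(variants), !is.null(names(variants)),
            trim_tol >= 0L)
  variants <- .normalize_rna(variants, "variants")
  # indistinguishable variants make counting ill-defined: refuse upfront
  if (length(variants) > 1L) {
    vm <- .match_matrix(variants, variants, trim_tol)
    vm[lower.tri(vm, diag = TRUE)] <- FALSE
    if (any(vm)) {
      idx <- which(vm, arr.ind = TRUE)[1L, ]
      stop("variants identical under the matching rule (trim_tol = ",
           trim_tol, "): ", names(variants)[idx[1L]], " vs ",
           names(variants)[idx[2L]], call. = FALSE)
    }
  }
  counts <- setNames(numeric(length(variants)), names(variants))
  n_unmatched <- 0
  n_ambiguous <- 0
  n_reads <- 0
  if (length(reads) > 0L) {
    reads <- .normalize_rna(reads, "reads")
    mult <- .read_multiplicity(names(reads))
    n_reads <- sum(mult)
    mm <- .match_matrix(unname(reads), variants, trim_tol)
    nmatch <- rowSums(mm)
    n_unmatched <- sum(mult[nmatch == 0L])
    n_ambiguous <- sum(mult[nmatch > 1L])
    for (k in seq_along(variants)) {
      uniq <- mm[, k] & nmatch == 1L
      counts[k] <- sum(mult[uniq])
      if (ambiguous == "split") {
        amb <- mm[, k] & nmatch > 1L
        counts[k] <- counts[k] + sum(mult[amb] / nmatch[amb])
      }
    }
  }
  out <- data.frame(variant_id = names(variants), library_id = library_id,
                    count = unname(counts), stringsAsFactors = FALSE)
  out$abundance <- if (sum(out$count) > 0) out$count / sum(out$count) else 0
  class(out) <- c("variant_counts", "data.frame")
  attr(out, "n_reads") <- n_reads
  attr(out, "n_unmatched") <- n_unmatched
  attr(out, "n_ambiguous") <- n_ambiguous
  out
}

#' Relative abundance of variant counts within one library
#'
#' @param counts A `variant_counts` data frame (or any data frame with
#'   `variant_id`, `library_id`, `count`) from a single library.
#' @return The input with `abundance = count / sum(count)`; an all-zero
#'   library yields zero abundances with a warning.
#' @examples
#' x <- data.frame(variant_id = c("a", "b"), library_id = "l", count = c(3, 1))
#' relative_abundance(x)$abundance  # 0.75 0.25
#' @export
relative_abundance <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("variant_id", "library_id", "count") %in% names(counts)))
  if (length(unique(counts$library_id)) > 1L) {
    stop("counts mix several libraries: ",
         paste(unique(counts$library_id), collapse = ", "), call. = FALSE)
  }
  if (any(counts$count < 0)) stop("negative counts", call. = FALSE)
  total <- sum(counts$count)
  if (total == 0) {
    warning("library has zero matching reads; abundances set to 0",
            call. = FALSE)
    counts$abundance <- 0
  } else {
    counts$abundance <- counts$count / total
  }
  counts
}

#' Write variant abundances as TSV
#'
#' @param counts A `variant_counts` data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_abundance_tsv <- function(counts, path) {
  write.table(as.data.frame(counts), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
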
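# Sequence and annotation input/output: FASTA/FASTQ, miRBase mature FASTA,
# GFF3 exon structures, spliced transcript models, expression tables.

.rna_complement <- c(A = "U", C = "G", G = "C", U = "A")

# normalize a nucleotide string to the RNA alphabet (uppercase, T->U)
.normalize_rna <- function(x, context = "sequence") {
  x <- chartr("t", "u", toupper(x))
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop("non-ACGU characters in ", context, ": ",
         paste(head(names(x)[bad], 3L), collapse = ", "), call. = FALSE)
  }
  x
}

.revcomp_rna <- function(x) {
  vapply(x, function(s) {
    paste(rev(.rna_complement[strsplit(s, "", fixed = TRUE)[[1]]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Read sequences from a FASTA or FASTQ file
#'
#' Reads records with [Biostrings::readBStringSet()], normalizes them to the
#' RNA alphabet (uppercase, T replaced by U, so DNA input is accepted
#' anywhere RNA is expected) and returns them as a named character vector in
#' file order.  Record ids are the first whitespace-delimited token of each
#' header and must be unique.
#'
#' @param path Path to a FASTA (or, with `format = "fastq"`, FASTQ) file.
#' @param format `"fasta"` (default) or `"fastq"`.
#' @return Named character vector of 5'->3' RNA sequences.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "ACGT"), f)
#' read_fasta(f) # T is normalized to U
#' @export
read_fasta <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) {
      stop("malformed ", toupper(format), " in ", path, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (length(set) == 0L) return(setNames(character(0), character(0)))
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  seqs <- as.character(set)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence record(s): ", paste(ids[empty], collapse = ", "),
         call. = FALSE)
  }
  names(seqs) <- ids
  .normalize_rna(seqs, context = path)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Read mature miRNAs in the miRBase FASTA dialect
#'
#' miRBase mature headers look like `>ath-miR396a MIMAT0000944 ...`: the id
#' starts with a species prefix, then the miRNA name.  The family is the
#' `miR<number>` token with any lettered paralog suffix and `-3p`/`-5p` arm
#' suffix stripped, so `osa-miR396e` and `osa-miR396f-5p` both belong to
#' family `miR396`.  Records whose id carries no miR/MIR token are skipped
#' with a warning.
#'
#' @param path Path to a mature-miRNA FASTA file.
#' @return A data frame of class `mature_mirna` with columns `id`, `species`,
#'   `family`, `seq`; the number of skipped records is stored in attribute
#'   `n_skipped`.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">ath-miR396a", "UUCCACAGCUUUCUUGAACUG"), f)
#' read_mirbase_mature(f)
#' @export
read_mirbase_mature <- function(path) {
  seqs <- read_fasta(path)
  ids <- names(seqs)
  fam <- regmatches(ids, regexpr("(?i)mir-?[0-9]+", ids, perl = TRUE))
  has_fam <- grepl("(?i)mir-?[0-9]+", ids, perl = TRUE)
  if (any(!has_fam)) {
    warning(sum(!has_fam), " record(s) without a miR family token skipped: ",
            paste(head(ids[!has_fam], 3L), collapse = ", "), call. = FALSE)
  }
  ids_keep <- ids[has_fam]
  seqs <- seqs[has_fam]
  family <- paste0("miR", gsub("[^0-9]", "", fam))
  species <- ifelse(grepl("-", ids_keep, fixed = TRUE),
                    sub("-.*$", "", ids_keep), NA_character_)
  out <- data.frame(id = ids_keep, species = species, family = family,
                    seq = unname(seqs), stringsAsFactors = FALSE)
  short <- nchar(out$seq) < 19L | nchar(out$seq) > 24L
  if (any(short)) {
    warning("mature sequence length outside 19-24 nt: ",
            paste(out$id[short], collapse = ", "), call. = FALSE)
  }
  class(out) <- c("mature_mirna", "data.frame")
  attr(out, "n_skipped") <- sum(!has_fam)
  out
}

#' Build a spliced transcript model from exon sequences
#'
#' Concatenates exon sequences in transcription order and records the
#' spliced coordinates of the exon junctions: junction `j` means an exon
#' boundary falls between spliced positions `j` and `j + 1`.
#'
#' @param exon_seqs Character vector of exon sequences, 5'->3' in
#'   transcription order.
#' @param id Transcript identifier.
#' @return An object of class `transcript_model` with fields `id`, `seq`,
#'   `exon_lengths` and `junctions`.
#' @examples
#' tx <- build_transcript(c("AAA", "CCC"), id = "tx1")
#' tx$junctions # 3
#' @export
build_transcript <- function(exon_seqs, id = "transcript") {
  stopifnot(length(exon_seqs) >= 1L)
  if (any(!nzchar(exon_seqs))) stop("empty exon sequence", call. = FALSE)
  exon_seqs <- .normalize_rna(setNames(exon_seqs, seq_along(exon_seqs)),
                              context = paste0("exons of ", id))
  lens <- unname(nchar(exon_seqs))
  structure(
    list(id = id, seq = paste(exon_seqs, collapse = ""),
         exon_lengths = lens,
         junctions = if (length(lens) > 1L) cumsum(lens[-length(lens)])
                     else integer(0)),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("transcript_model ", x$id, ": ", nchar(x$seq), " nt, ",
      length(x$exon_lengths), " exon(s)",
      if (length(x$junctions)) paste0(", junctions at ",
                                      paste(x$junctions, collapse = ",")),
      "\n", sep = "")
  invisible(x)
}

#' Build spliced transcript models from a GFF3 file and a genome FASTA
#'
#' Exon features (1-based, inclusive, per the GFF3 specification) are grouped
#' by their `Parent` transcript, sorted in transcription order (reverse
#' order and reverse-complemented for minus-strand transcripts) and spliced
#' with [build_transcript()].
#'
#' @param gff_path GFF3 file with exon features carrying `Parent` ids.
#' @param fasta_path Genome FASTA with the seqids referenced by the GFF3.
#' @return Named list of `transcript_model` objects.
#' @export
read_gff3_exons <- function(gff_path, fasta_path) {
  genome <- read_fasta(fasta_path)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", gff_path, call. = FALSE)
  parents <- S4Vectors::mcols(gr)$Parent
  parent_id <- vapply(seq_along(gr), function(i) {
    p <- parents[[i]]
    if (length(p) == 0L) stop("exon without Parent attribute in ", gff_path,
                              call. = FALSE)
    as.character(p[[1L]])
  }, character(1))
  out <- list()
  for (tx in unique(parent_id)) {
    ex <- gr[parent_id == tx]
    chrom <- unique(as.character(GenomicRanges::seqnames(ex)))
    if (length(chrom) != 1L) {
      stop("exons of ", tx, " on multiple sequences", call. = FALSE)
    }
    strand <- unique(as.character(GenomicRanges::strand(ex)))
    if (length(strand) != 1L) {
      stop("mixed strands within transcript ", tx, call. = FALSE)
    }
    if (!chrom %in% names(genome)) {
      stop("GFF3 seqid ", chrom, " not found in ", fasta_path, call. = FALSE)
    }
    contig <- genome[[chrom]]
    st <- GenomicRanges::start(ex)
    en <- GenomicRanges::end(ex)
    if (any(st < 1L) || any(en > nchar(contig))) {
      stop("exon outside sequence bounds for transcript ", tx, call. = FALSE)
    }
    ord <- order(st)
    pieces <- substring(contig, st[ord], en[ord])
    if (strand == "-") pieces <- rev(.revcomp_rna(pieces))
    out[[tx]] <- build_transcript(pieces, id = tx)
  }
  out
}

#' Read a gene-by-genotype fold-change table
#'
#' Tab-separated file with a header row: column 1 holds gene ids, remaining
#' columns linear-scale mutant/wild-type fold changes, one column per
#' genotype.  All values must be positive and all row/column labels unique.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix (genes x genotypes).
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs a gene column and at least ",
                          "one genotype column", call. = FALSE)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(df)[-1L])) {
    stop("duplicate genotype labels", call. = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("fold changes must be positive finite numbers", call. = FALSE)
  }
  rownames(m) <- genes
  m
}

#' Write a fold-change matrix as TSV
#'
#' @param fc Numeric matrix (genes x genotypes) with dimnames.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression_tsv <- function(fc, path) {
  stopifnot(is.matrix(fc), !is.null(rownames(fc)), !is.null(colnames(fc)))
  df <- data.frame(gene = rownames(fc), fc, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
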
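# Evidence funnel: intersect predicted target sites with expression
# up-regulation across miRNA-pathway mutant genotypes.

#' Filter predicted targets by mutant up-regulation
#'
#' One record per gene with a predicted site: the gene passes when its
#' mutant/wild-type fold change reaches `min_fold` in every required genotype
#' (`mode = "all"`, the default three-mutant concordance rule over hyl1, se
#' and dcl1) or in at least one (`mode = "any"`).  The threshold is closed:
#' 30% up-regulation means fold change >= 1.30 exactly.  Genes with sites but
#' absent from the matrix are reported with `NA` fold changes and
#' `passes = NA` (and a warning), never silently dropped.
#'
#' @param sites A [search_targets()] result or any data frame with a
#'   `transcript_id` column; transcript ids are taken as gene ids.
#' @param expr Numeric fold-change matrix (genes x genotypes), linear scale,
#'   e.g. from [read_expression_tsv()] or [gen_expression()].
#' @param genotypes Genotype columns required; all must exist in `expr`.
#' @param min_fold Closed fold-change threshold. Default 1.30.
#' @param mode `"all"` (concordant up-regulation, default) or `"any"`.
#' @return Data frame of class `prioritized_targets`: `gene_id`, one
#'   `fc_<genotype>` column per genotype, `min_fc`, `n_sites`, `passes`,
#'   `evidence_summary`; sorted by `min_fc` descending.
#' @examples
#' expr <- matrix(c(1.5, 1.41, 1.35), 1, dimnames = list("g1", c("hyl1", "se", "dcl1")))
#' sites <- data.frame(transcript_id = "g1")
#' filter_by_expression(sites, expr)
#' @export
filter_by_expression <- function(sites, expr,
                                 genotypes = c("hyl1", "se", "dcl1"),
                                 min_fold = 1.30, mode = c("all", "any")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)),
            is.data.frame(sites), "transcript_id" %in% names(sites),
            length(genotypes) >= 1L, min_fold > 0)
  missing_gt <- setdiff(genotypes, colnames(expr))
  if (length(missing_gt) > 0L) {
    stop("genotype(s) absent from expression matrix: ",
         paste(missing_gt, collapse = ", "), call. = FALSE)
  }
  genes <- unique(sites$transcript_id)
  n_sites <- vapply(genes, function(g) sum(sites$transcript_id == g),
                    integer(1))
  absent <- !genes %in% rownames(expr)
  if (any(absent)) {
    warning(sum(absent), " gene(s) with sites missing from the expression ",
            "matrix: ", paste(head(genes[absent], 5L), collapse = ", "),
            call. = FALSE)
  }
  fc <- matrix(NA_real_, length(genes), length(genotypes),
               dimnames = list(genes, genotypes))
  fc[genes[!absent], ] <- expr[genes[!absent], genotypes, drop = FALSE]
  hit <- fc >= min_fold
  passes <- if (mode == "all") apply(hit, 1L, function(x) all(x))
            else apply(hit, 1L, function(x) any(x))
  min_fc <- apply(fc, 1L, function(x) if (all(is.na(x))) NA_real_ else min(x))
  summary_txt <- vapply(seq_along(genes), function(k) {
    if (absent[k]) return("not measured")
    paste0(sum(hit[k, ]), "/", length(genotypes), " genotypes >= ", min_fold)
  }, character(1))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (g in genotypes) out[[paste0("fc_", g)]] <- fc[, g]
  out$min_fc <- min_fc
  out$n_sites <- n_sites
  out$passes <- passes
  out$evidence_summary <- summary_txt
  out <- out[order(-ifelse(is.na(out$min_fc), -Inf, out$min_fc),
                   out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("prioritized_targets", "data.frame")
  out
}

#' Write prioritized targets as TSV
#'
#' @param targets A `prioritized_targets` data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_prioritized_tsv <- function(targets, path) {
  df <- as.data.frame(targets)
  for (cn in names(df)) {
    if (is.numeric(df[[cn]])) df[[cn]][is.na(df[[cn]])] <- NA
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}
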
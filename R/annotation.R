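#' Classify gene biotypes into mRNA and lncRNA classes
#'
#' Maps each gene to either `mRNA` (GENCODE `protein_coding`) or one of the
#' four long non-coding classes used throughout the pipeline: `antisense`,
#' `lincRNA`, `sense_intronic`, `sense_overlapping`. Genes of any other
#' biotype (miRNA, pseudogene, ...) are excluded and counted.
#'
#' @param src a GTF file path (GENCODE-style, gene records carrying a
#'   `gene_type` or `gene_biotype` attribute), a TSV file path with columns
#'   `gene_id`, `biotype` and optionally `symbol`, or a data.frame with those
#'   columns.
#' @param strip_version drop the trailing `.N` version from Ensembl-style
#'   gene ids (default `TRUE`); ids are the join key across all tables.
#' @return a data.frame with columns `gene_id`, `symbol`, `biotype_class`,
#'   one row per retained gene, with attribute `n_excluded` giving the number
#'   of genes dropped for having an out-of-scope biotype.
#' @export
classify_biotypes <- function(src, strip_version = TRUE) {
  if (is.character(src) && length(src) == 1) {
    if (grepl("\\.gtf(\\.gz)?$|\\.gff3?(\\.gz)?$", src, ignore.case = TRUE)) {
      gr <- rtracklayer::import(src)
      md <- as.data.frame(gr)
      if ("type" %in% names(md)) md <- md[md$type == "gene", , drop = FALSE]
      bt_col <- intersect(c("gene_type", "gene_biotype"), names(md))[1]
      if (is.na(bt_col)) stop("GTF records carry no gene_type/gene_biotype attribute")
      df <- data.frame(gene_id = md$gene_id,
                       symbol = if ("gene_name" %in% names(md)) md$gene_name else md$gene_id,
                       biotype = md[[bt_col]],
                       stringsAsFactors = FALSE)
    } else {
      df <- utils::read.delim(src, sep = "\t", comment.char = "#",
                              stringsAsFactors = FALSE)
    }
  } else if (is.data.frame(src)) {
    df <- src
  } else stop("'src' must be a file path or a data.frame")

  if (!all(c("gene_id", "biotype") %in% names(df)))
    stop("annotation needs columns gene_id and biotype")
  if (!"symbol" %in% names(df)) df$symbol <- df$gene_id

  miss <- is.na(df$biotype) | df$biotype == ""
  if (any(miss)) {
    warning(sum(miss), " gene(s) without a biotype attribute excluded")
    df <- df[!miss, , drop = FALSE]
  }

  class_map <- c(protein_coding = "mRNA",
                 antisense = "antisense",
                 antisense_RNA = "antisense",
                 lincRNA = "lincRNA",
                 sense_intronic = "sense_intronic",
                 sense_overlapping = "sense_overlapping")
  keep <- df$biotype %in% names(class_map)
  out <- data.frame(gene_id = as.character(df$gene_id[keep]),
                    symbol = as.character(df$symbol[keep]),
                    biotype_class = unname(class_map[df$biotype[keep]]),
                    stringsAsFactors = FALSE)
  if (strip_version) out$gene_id <- sub("\\.\\d+$", "", out$gene_id)
  if (anyDuplicated(out$gene_id)) {
    warning("duplicate gene ids after version stripping; keeping first occurrence")
    out <- out[!duplicated(out$gene_id), , drop = FALSE]
  }
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Is a biotype class long non-coding?
#'
#' @param biotype_class character vector of classes from [classify_biotypes()].
#' @return logical vector, `TRUE` for the four lncRNA classes.
#' @export
is_lncRNA_class <- function(biotype_class) {
  biotype_class %in% c("antisense", "lincRNA", "sense_intronic", "sense_overlapping")
}

#' Read a miRNA-to-target prediction table
#'
#' Reads a miRcode-style TSV with columns `miRNA_id` and `gene_id` (extra
#' columns are ignored), deduplicates, and builds both the forward
#' (miRNA to target genes) and reverse (gene to targeting miRNAs) indices.
#'
#' @param path TSV file path.
#' @param strip_version drop trailing `.N` versions from gene ids.
#' @return an object of class `TargetMap`: a list with elements `forward`
#'   (named list miRNA_id -> character vector of gene ids) and `reverse`
#'   (named list gene_id -> character vector of miRNA ids). Empty target sets
#'   are not stored.
#' @export
read_target_map <- function(path, strip_version = TRUE) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("miRNA_id", "gene_id")
  if (!all(need %in% names(df)))
    stop("target table must have columns: ", paste(need, collapse = ", "))
  target_map(df[, need], strip_version = strip_version)
}

#' @rdname read_target_map
#' @param edges data.frame with columns `miRNA_id`, `gene_id`.
#' @export
target_map <- function(edges, strip_version = TRUE) {
  mi <- as.character(edges$miRNA_id)
  g <- as.character(edges$gene_id)
  if (strip_version) g <- sub("\\.\\d+$", "", g)
  keep <- !duplicated(paste0(mi, "\r", g)) & !is.na(mi) & !is.na(g) & mi != "" & g != ""
  mi <- mi[keep]; g <- g[keep]
  structure(list(forward = split(g, mi), reverse = split(mi, g)),
            class = "TargetMap")
}

#' @export
print.TargetMap <- function(x, ...) {
  cat(sprintf("TargetMap: %d miRNAs -> %d genes (%d edges)\n",
              length(x$forward), length(x$reverse),
              sum(lengths(x$forward))))
  invisible(x)
}
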
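#' Read gene models from a GFF3 file
#'
#' Parses a version-3 GFF file and returns one gene model per `gene`
#' feature. GFF3 coordinates (1-based, inclusive) are converted to the
#' package-internal 0-based half-open convention on ingest, so that all
#' downstream interval arithmetic uses a single convention.
#'
#' The transcription start site (TSS) is derived per strand: `start` for
#' `+` genes and `end - 1` for `-` genes (0-based positions). Features
#' with unknown strand (`.`/`*`) are treated as `+` and reported via a
#' message. Sub-features (exons, UTRs, introns) are retained in the
#' `features` attribute but are not required by the location classifier,
#' which bins against the gene body as a whole.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame of class `gene_models` with columns `gene_id`,
#'   `chrom`, `start`, `end` (0-based half-open), `strand`, `tss`, `tes`;
#'   sub-features, when present, in `attr(, "features")`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  fasta_at <- match("##FASTA", lines)
  if (!is.na(fasta_at)) body[fasta_at:length(body)] <- FALSE
  nfields <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfields != 9L)) {
    bad <- which(body)[which(nfields != 9L)[1L]]
    stop("malformed GFF3 line ", bad, " in ", path,
         ": expected 9 tab-separated fields, found ", nfields[nfields != 9L][1L])
  }
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[as.character(gr$type) == "gene"]
  if (length(genes) == 0L) stop("no gene features in ", path)
  ids <- genes$ID
  if (is.null(ids)) ids <- genes$Name
  if (is.null(ids) || anyNA(ids)) stop("gene features lack ID attributes in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate gene id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  strand <- as.character(BiocGenerics::strand(genes))
  if (any(strand == "*")) {
    message(sum(strand == "*"), " gene(s) with unknown strand treated as '+'")
    strand[strand == "*"] <- "+"
  }
  start0 <- BiocGenerics::start(genes) - 1L
  end0 <- BiocGenerics::end(genes)
  models <- data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = start0,
    end = end0,
    strand = strand,
    tss = ifelse(strand == "+", start0, end0 - 1L),
    tes = ifelse(strand == "+", end0 - 1L, start0),
    stringsAsFactors = FALSE
  )
  rownames(models) <- NULL
  feat_types <- c("five_prime_UTR", "exon", "intron", "three_prime_UTR")
  sub <- gr[as.character(gr$type) %in% feat_types]
  if (length(sub) > 0L) {
    parent <- vapply(as.list(sub$Parent), function(p)
      if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))
    attr(models, "features") <- data.frame(
      gene_id = parent,
      chrom = as.character(GenomicRanges::seqnames(sub)),
      start = BiocGenerics::start(sub) - 1L,
      end = BiocGenerics::end(sub),
      type = as.character(sub$type),
      stringsAsFactors = FALSE
    )
  }
  class(models) <- c("gene_models", "data.frame")
  validate_gene_models(models)
  models
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff3()]: internal 0-based half-open coordinates are
#' converted back to the 1-based inclusive GFF3 convention, so a
#' write-then-read round trip is the identity on the model table.
#'
#' @param models A `gene_models` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  validate_gene_models(models)
  gr <- GenomicRanges::GRanges(
    seqnames = models$chrom,
    ranges = IRanges::IRanges(start = models$start + 1L, end = models$end),
    strand = models$strand
  )
  gr$type <- "gene"
  gr$ID <- models$gene_id
  gr$source <- "stmgrn"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

validate_gene_models <- function(models) {
  stopifnot(is.data.frame(models),
            all(c("gene_id", "chrom", "start", "end", "strand", "tss") %in%
                  names(models)))
  if (anyDuplicated(models$gene_id)) stop("duplicate gene ids")
  if (any(models$start < 0L)) stop("negative gene start")
  if (any(models$end <= models$start)) stop("gene end must exceed start")
  if (!all(models$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  tss_exp <- ifelse(models$strand == "+", models$start, models$end - 1L)
  if (!all(models$tss == tss_exp)) stop("tss inconsistent with strand")
  invisible(models)
}

#' Construct a gene-model table from vectors
#'
#' Convenience constructor used by the synthetic-genome generator and in
#' tests; coordinates are 0-based half-open.
#'
#' @param gene_id,chrom,start,end,strand Per-gene vectors.
#' @return A `gene_models` data.frame (see [read_gff3()]).
#' @export
gene_models <- function(gene_id, chrom, start, end, strand) {
  models <- data.frame(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  models$tss <- ifelse(models$strand == "+", models$start, models$end - 1L)
  models$tes <- ifelse(models$strand == "+", models$end - 1L, models$start)
  class(models) <- c("gene_models", "data.frame")
  validate_gene_models(models)
}
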
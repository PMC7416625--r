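#' @importFrom GenomicRanges GRanges mcols mcols<- start end width seqnames
#'   strand sort
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
#' @importFrom utils read.delim write.table
NULL

## Internal coordinate convention: genes and features live in GRanges,
## i.e. 1-based inclusive coordinates, the native Bioconductor convention
## shared by GFF3.  BED I/O (0-based half-open) converts at the boundary,
## as does intervalSpan(), which speaks the half-open dialect used in
## printed "start to end = length" genome coordinates.

#' Length of a half-open genomic interval
#'
#' Arithmetic helper for BED-style half-open coordinates, where the span
#' of an interval is simply \code{end - start}.  Printed genome
#' coordinates of the form "located at 33,306,010 to 33,306,151 bp,
#' 141 bp long" follow this convention.
#'
#' @param start,end integer positions, \code{start < end}.
#' @return integer span \code{end - start} in bp.
#' @examples
#' intervalSpan(33306010, 33306151)  # 141
#' @export
intervalSpan <- function(start, end) {
  if (any(!is.finite(start)) || any(!is.finite(end)))
    stop("start/end must be finite")
  if (any(start >= end))
    stop("intervalSpan() requires start < end (half-open convention)")
  end - start
}

#' Read gene loci from a GFF3 file
#'
#' Imports features of type \code{gene} from a GFF3 file into a
#' \link[GenomicRanges]{GRanges} sorted by (chromosome, start), with
#' metadata columns \code{gene_id} and \code{confidence_class}
#' (\code{HCC}/\code{LCC}/\code{unknown}, from the \code{confidence}
#' attribute when present).
#'
#' @param path path to a GFF3 file.
#' @return a sorted \code{GRanges} of gene loci.
#' @export
readGffGenes <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop("GFF3 parse error in '", path, "': ",
                        conditionMessage(e)))
  if (length(gr) == 0)
    return(GRanges(gene_id = character(0),
                   confidence_class = character(0)))
  gr <- gr[tolower(as.character(gr$type)) == "gene"]
  id <- gr$ID
  if (is.null(id) || anyNA(id))
    stop("GFF3 gene features must carry an ID attribute")
  conf <- gr$confidence
  if (is.null(conf)) conf <- rep("unknown", length(gr))
  conf[is.na(conf) | !conf %in% c("HCC", "LCC")] <- "unknown"
  out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                 strand = strand(gr))
  mcols(out) <- DataFrame(gene_id = as.character(id),
                          confidence_class = conf)
  sort(out, ignore.strand = TRUE)
}

#' Write gene loci to a GFF3 file
#'
#' Inverse of \code{\link{readGffGenes}}: coordinates and strand
#' round-trip exactly.
#'
#' @param genes a \code{GRanges} with a \code{gene_id} metadata column.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGffGenes <- function(genes, path) {
  stopifnot(is(genes, "GRanges"), !is.null(genes$gene_id))
  gr <- genes
  gr$type <- "gene"
  gr$source <- "genomescapes"
  gr$ID <- genes$gene_id
  gr$gene_id <- NULL
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a genetic map from TSV
#'
#' Expects tab-separated columns \code{marker}, \code{chromosome},
#' \code{bp}, \code{cM}.  Markers are returned sorted by (chromosome, bp)
#' with ties broken by marker id; cM values are not required to be
#' monotone (cleaning happens in \code{\link{mareyMap}}).
#'
#' @param path path to the TSV file.
#' @return data.frame with columns \code{marker}, \code{chromosome},
#'   \code{bp}, \code{cM}.
#' @export
readGeneticMap <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("marker", "chromosome", "bp", "cM")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("genetic map is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(d) == 0)
    return(d[, need])
  d$bp <- suppressWarnings(as.numeric(d$bp))
  d$cM <- suppressWarnings(as.numeric(d$cM))
  if (anyNA(d$bp) || anyNA(d$cM))
    stop("non-numeric bp or cM value in genetic map")
  if (any(d$bp < 0))
    stop("negative bp position in genetic map")
  if (anyDuplicated(d$marker))
    warning("duplicated marker ids in genetic map; all rows kept")
  d <- d[order(d$chromosome, d$bp, d$marker), need]
  rownames(d) <- NULL
  d
}

#' Write a genetic map to TSV
#' @param map data.frame as returned by \code{\link{readGeneticMap}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGeneticMap <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transposable-element table from TSV
#'
#' Columns: \code{family}, \code{chromosome}, \code{position},
#' \code{dist_to_centromere}, \code{ltr_length}, \code{mismatches}.
#' Mismatch counts must satisfy \code{0 <= mismatches <= ltr_length}.
#'
#' @param path path to the TSV file.
#' @return data.frame of elements.
#' @export
readTeTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("family", "chromosome", "position", "dist_to_centromere",
            "ltr_length", "mismatches")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("TE table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(d$ltr_length <= 0)) stop("ltr_length must be positive")
  if (any(d$mismatches < 0 | d$mismatches > d$ltr_length))
    stop("mismatches must lie in [0, ltr_length]")
  d[, need]
}

#' Read an ordered best-hit ortholog table from TSV
#'
#' Columns: \code{query_gene_id}, \code{query_chrom}, \code{query_start},
#' \code{subject_gene_id}, \code{subject_chrom}, \code{subject_start},
#' \code{hit_present} (logical or 0/1).  Rows must be ordered by
#' (query_chrom, query_start).
#'
#' @param path path to the TSV file.
#' @return data.frame ordered by query position.
#' @export
readOrthologTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("query_gene_id", "query_chrom", "query_start",
            "subject_gene_id", "subject_chrom", "subject_start",
            "hit_present")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("ortholog table is missing column(s): ",
         paste(miss, collapse = ", "))
  d$hit_present <- as.logical(d$hit_present)
  o <- order(d$query_chrom, d$query_start)
  if (is.unsorted(o)) d <- d[o, ]
  rownames(d) <- NULL
  d[, need]
}

#' Read genome sequences from a FASTA file
#'
#' Thin wrapper over \link[Biostrings]{readDNAStringSet} that truncates
#' names at the first whitespace, the convention of chromosome-keyed
#' analyses in this package.
#'
#' @param path path to an (uncompressed or gzipped) FASTA file.
#' @return a \code{DNAStringSet} named by sequence id.
#' @export
readFastaSequences <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write genome sequences to a FASTA file
#'
#' @param seqs a \code{DNAStringSet}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeFastaSequences <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read features from a BED file
#'
#' @param path path to a BED file (0-based half-open on disk).
#' @return a \code{GRanges} (1-based inclusive) with a \code{label}
#'   metadata column taken from the BED name field.
#' @export
readBedFeatures <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  lbl <- gr$name
  if (is.null(lbl)) lbl <- rep(NA_character_, length(gr))
  mcols(gr) <- DataFrame(label = lbl)
  gr
}

#' Write features to a BED file
#'
#' @param features a \code{GRanges}; an optional \code{label} metadata
#'   column becomes the BED name field.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeBedFeatures <- function(features, path) {
  gr <- features
  if (!is.null(gr$label)) {
    gr$name <- gr$label
    gr$label <- NULL
  }
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
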
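#' Read a BED file into an annotation GRanges
#'
#' BED coordinates are 0-based half-open; internally annotations are held as
#' 1-based closed `GRanges`, so an input line `start end` becomes
#' `[start + 1, end]`. Genome-browser style 1-based inclusive coordinates
#' (e.g. "chr20:48,900,221-48,901,229") can be ingested with
#' `one_based = TRUE`, which shifts the start by one before conversion.
#'
#' @param path Path to a tab-separated BED3/BED6(+) file. Lines starting with
#'   `track`, `browser` or `#` are ignored.
#' @param class_col Optional 1-based column index holding the element class
#'   (one of `r paste(enhmeth:::.element_classes, collapse = ", ")`); values
#'   outside that vocabulary are mapped to `"other"`.
#' @param one_based If `TRUE`, interpret the coordinate columns as 1-based
#'   inclusive (genome-browser convention) instead of BED.
#' @return A `GRanges` with metadata columns `name` and `element_class`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chrS\t100\t300\tenh1", bed)
#' read_bed(bed)
#' @export
read_bed <- function(path, class_col = NULL, one_based = FALSE) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(GenomicRanges::GRanges(name = character(0),
                                  element_class = character(0)))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", idx[which(nf < 3L)[1L]],
         ": fewer than 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad)) {
    stop("malformed BED line ", idx[bad[1L]], ": non-numeric coordinates")
  }
  if (one_based) start0 <- start0 - 1
  bad <- which(start0 < 0 | start0 >= end0)
  if (length(bad)) {
    stop("invalid interval on line ", idx[bad[1L]],
         ": require 0 <= start < end (half-open)")
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))],
                                  ""), "")
  strand <- rep(".", length(idx))
  has6 <- nf >= 6L
  strand[has6] <- vapply(fields[has6], `[[`, "", 6L)
  strand[!strand %in% c("+", "-")] <- "*"
  cls <- rep("other", length(idx))
  if (!is.null(class_col)) {
    if (any(nf < class_col)) {
      stop("class_col = ", class_col, " exceeds column count on line ",
           idx[which(nf < class_col)[1L]])
    }
    cls <- vapply(fields, `[[`, "", class_col)
    cls[!cls %in% .element_classes] <- "other"
  }
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start0 + 1, end = end0),
                         strand = strand, name = name, element_class = cls)
}

#' Write an annotation GRanges as BED
#'
#' The inverse of [read_bed()]: 1-based closed ranges are emitted as 0-based
#' half-open BED6 rows, so a read/write cycle round-trips coordinates exactly.
#'
#' @param gr A `GRanges`; metadata columns `name` and `element_class` are
#'   used when present.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  name <- if ("name" %in% names(S4Vectors::mcols(gr))) gr$name else "."
  score <- 0
  strd <- as.character(GenomicRanges::strand(gr))
  strd[strd == "*"] <- "."
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = name, score = score, strand = strd)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Total overlap between two interval sets
#'
#' Each set is first merged into non-overlapping unions per chromosome so
#' duplicated annotations do not double count; the returned value is the
#' total number of base pairs in the intersection of the two merged sets.
#' Symmetric in its arguments; chromosomes absent from one set contribute 0.
#'
#' @param a,b `GRanges` interval sets (strand is ignored).
#' @return Integer total overlap in bp.
#' @export
overlap_length <- function(a, b) {
  am <- GenomicRanges::reduce(a, ignore.strand = TRUE)
  bm <- GenomicRanges::reduce(b, ignore.strand = TRUE)
  ov <- suppressWarnings(GenomicRanges::intersect(am, bm,
                                                  ignore.strand = TRUE))
  sum(as.numeric(GenomicRanges::width(ov)))
}

#' Merged total length of an interval set
#'
#' @param a A `GRanges`.
#' @return Total bp covered by the merged (non-overlapping) union of `a`.
#' @export
total_length <- function(a) {
  sum(as.numeric(GenomicRanges::width(
    GenomicRanges::reduce(a, ignore.strand = TRUE))))
}

#' Assign each region the gene with the nearest TSS
#'
#' Distance is measured from the region midpoint to the TSS, strand-agnostic.
#' Ties are broken toward the TSS at the lower coordinate, which makes the
#' assignment deterministic and independent of input order. Regions on a
#' chromosome with no TSS get `NA`.
#'
#' @param regions A `GRanges` of query regions.
#' @param tss A data.frame with columns `gene`, `chrom`, `pos` (TSS
#'   coordinate, same 1-based frame as the `GRanges`).
#' @return Character vector of gene names, one per region.
#' @export
nearest_gene <- function(regions, tss) {
  stopifnot(is.data.frame(tss), all(c("gene", "chrom", "pos") %in% names(tss)))
  if (nrow(tss) == 0L) stop("tss list is empty")
  mid <- (GenomicRanges::start(regions) + GenomicRanges::end(regions)) / 2
  chr <- as.character(GenomicRanges::seqnames(regions))
  # order TSS by coordinate so which.min's first-match rule realises the
  # lower-coordinate tie-break
  tss <- tss[order(tss$chrom, tss$pos), , drop = FALSE]
  vapply(seq_along(regions), function(i) {
    cand <- tss[tss$chrom == chr[i], , drop = FALSE]
    if (nrow(cand) == 0L) return(NA_character_)
    as.character(cand$gene[which.min(abs(cand$pos - mid[i]))])
  }, "")
}
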
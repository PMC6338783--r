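#' Enrichment of DMRs in annotated functional elements
#'
#' For each element class i the score is (Lm_i / Lm) / (L_i / L), where
#' Lm_i is the total length of DMRs overlapping class-i elements, Lm the
#' total DMR length, L_i the total class-i element length and L the total
#' length of all annotated elements combined. A score of 1 means the class
#' captures exactly its length share of DMR bases; scores above 1 indicate
#' enrichment. All lengths are computed on merged interval unions so
#' duplicated annotations do not double count, and each class is scored
#' against the full DMR set independently (a DMR base overlapping elements
#' of several classes counts toward each).
#'
#' @param dmrs `GRanges` of differentially methylated regions.
#' @param annotation `GRanges` with an `element_class` metadata column.
#' @param total_annotated Optional override for L in bp; default is the
#'   merged union length of the whole annotation.
#' @param classes Element classes to score; default all classes present in
#'   the annotation. A requested class absent from the annotation has
#'   L_i = 0 and gets the undefined-score sentinel `NA` (not zero).
#' @return Data.frame with one row per class: `element_class`, `Lm_i`,
#'   `Lm`, `L_i`, `L`, `score`. `score` is `NA` for a class with L_i = 0.
#' @examples
#' anno <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(1, 101), c(100, 1000)),
#'   element_class = c("enhancer", "intergenic"))
#' dmrs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(81, 130))
#' enrichment(dmrs, anno)
#' @export
enrichment <- function(dmrs, annotation, total_annotated = NULL,
                       classes = NULL) {
  if (!"element_class" %in% names(S4Vectors::mcols(annotation))) {
    stop("annotation must carry an 'element_class' metadata column")
  }
  Lm <- total_length(dmrs)
  if (Lm == 0) stop("no DMRs: total DMR length is zero")
  L <- if (is.null(total_annotated)) total_length(annotation) else
    as.numeric(total_annotated)
  if (L <= 0) stop("total annotated length L must be positive")
  if (is.null(classes)) classes <- sort(unique(annotation$element_class))
  rows <- lapply(classes, function(cl) {
    el <- annotation[annotation$element_class == cl]
    L_i <- total_length(el)
    Lm_i <- overlap_length(dmrs, el)
    score <- if (L_i > 0) (Lm_i / Lm) / (L_i / L) else NA_real_
    data.frame(element_class = cl, Lm_i = Lm_i, Lm = Lm, L_i = L_i, L = L,
               score = score, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
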
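# PSSM-based search for polyadenylation signals (PAS, 6-mers) upstream and
# GU-rich downstream sequence elements (DSE, 7-mers) downstream of annotated
# cleavage sites, plus the insertion-effect call on polyadenylation-site
# usage.
#
# Offset convention: the cleavage site is position 0 (last transcribed base);
# -1 is the base immediately upstream, +1 the first base after cleavage.

BASES <- c("A", "C", "G", "T")

#' Construct a per-position nucleotide frequency matrix
#'
#' @param mat Numeric matrix, one row per motif position, columns A, C, G, T;
#'   each row sums to 1.
#' @return An object of class `frequency_matrix`.
#' @export
frequency_matrix <- function(mat) {
  mat <- as.matrix(mat)
  if (is.null(colnames(mat))) colnames(mat) <- BASES
  mat <- mat[, BASES, drop = FALSE]
  if (any(mat < 0)) stop("validation error: negative frequencies")
  if (any(abs(rowSums(mat) - 1) > 1e-9))
    stop("validation error: position frequencies must sum to 1")
  structure(mat, class = c("frequency_matrix", "matrix"))
}

#' Read a frequency matrix from TSV (rows = positions, columns = A,C,G,T)
#' @param path File path.
#' @return A [frequency_matrix()].
#' @export
read_frequency_matrix <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  frequency_matrix(as.matrix(tab[, BASES]))
}

#' Write a frequency matrix to TSV
#' @param fm A [frequency_matrix()].
#' @param path File path.
#' @export
write_frequency_matrix <- function(fm, path) {
  write.table(as.data.frame(unclass(fm)), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Default PAS frequency matrix (6-mer)
#'
#' AATAAA-dominant hexamer model allowing the main canonical variant ATTAAA
#' (and residual mass on the other bases). This is a documented default, not
#' a reprint of any published matrix; supply your own via
#' [read_frequency_matrix()] to reproduce a specific empirical model.
#'
#' @return A [frequency_matrix()] with 6 rows.
#' @export
default_pas_matrix <- function() {
  f <- rbind(
    c(A = 0.94, C = 0.02, G = 0.02, T = 0.02),
    c(A = 0.80, C = 0.02, G = 0.02, T = 0.16),
    c(A = 0.06, C = 0.02, G = 0.02, T = 0.90),
    c(A = 0.94, C = 0.02, G = 0.02, T = 0.02),
    c(A = 0.94, C = 0.02, G = 0.02, T = 0.02),
    c(A = 0.94, C = 0.02, G = 0.02, T = 0.02))
  frequency_matrix(f)
}

#' Default DSE frequency matrix (7-mer)
#'
#' Generic GU/U-rich downstream element model (documented default; see
#' [default_pas_matrix()]).
#'
#' @return A [frequency_matrix()] with 7 rows.
#' @export
default_dse_matrix <- function() {
  row <- c(A = 0.05, C = 0.05, G = 0.33, T = 0.57)
  frequency_matrix(matrix(rep(row, 7), nrow = 7, byrow = TRUE,
                          dimnames = list(NULL, BASES)))
}

#' Build a log-likelihood PSSM from a frequency matrix
#'
#' Scores are `log2((f + pseudocount) / (background + pseudocount))` against
#' an equiprobable background (0.25 per base). With `pseudocount = 0`, cells
#' with zero frequency score `-Inf` and the result carries an
#' `has_minus_inf` attribute. The log base only rescales scores (rank order
#' of windows is unchanged); bits (base 2) is the default.
#'
#' @param fm A [frequency_matrix()].
#' @param pseudocount Non-negative pseudocount (default 0.01).
#' @param base Logarithm base (default 2).
#' @return An object of class `pssm` (matrix positions x A,C,G,T, in bits).
#' @export
build_pssm <- function(fm, pseudocount = 0.01, base = 2) {
  fm <- frequency_matrix(unclass(fm))
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  scores <- log((unclass(fm) + pseudocount) / (0.25 + pseudocount), base = base)
  structure(scores, class = c("pssm", "matrix"),
            has_minus_inf = any(is.infinite(scores)))
}

#' Motif length of a PSSM or frequency matrix
#' @param x A `pssm` or `frequency_matrix`.
#' @return Integer length.
#' @export
motif_length <- function(x) nrow(x)

#' Score a window against a PSSM
#'
#' Sum of the per-position scores. `N` (or any non-ACGT character)
#' contributes 0.
#'
#' @param pssm A [build_pssm()] result.
#' @param window Character string of length `motif_length(pssm)`.
#' @return Score in bits.
#' @export
score_window <- function(pssm, window) {
  window <- toupper(window)
  L <- nrow(pssm)
  if (nchar(window) != L)
    stop("usage error: window length ", nchar(window), " != motif length ", L)
  idx <- match(strsplit(window, "")[[1]], BASES)
  ok <- which(!is.na(idx))
  sum(unclass(pssm)[cbind(ok, idx[ok])])
}

#' Scan the 50-bp region on one side of a cleavage site
#'
#' Slides a window of the motif length along the region (sense strand),
#' returning one hit per start position. Upstream: region offsets -50..-1;
#' downstream: +1..+50. Window start offsets are relative to the cleavage
#' site (position 0 = last transcribed base). Regions truncated by the
#' sequence end return fewer hits and a `truncated` attribute.
#'
#' @param pssm A [build_pssm()] result.
#' @param sequence Sense-strand nucleotide string.
#' @param cs Cleavage-site position (1-based) within `sequence`.
#' @param side `"upstream"` or `"downstream"`.
#' @param region_width Region width in bp (default 50).
#' @return `data.frame(offset, sequence, score)`, attribute `truncated`.
#' @export
scan_region <- function(pssm, sequence, cs, side = c("upstream", "downstream"),
                        region_width = 50L) {
  side <- match.arg(side)
  sequence <- toupper(as.character(sequence))
  len <- nchar(sequence)
  cs <- as.integer(cs)
  if (cs < 1L || cs > len) stop("bounds error: cs outside sequence")
  L <- nrow(pssm)
  if (side == "upstream") {
    lo <- max(1L, cs - as.integer(region_width))
    hi <- cs - 1L
  } else {
    lo <- cs + 1L
    hi <- min(len, cs + as.integer(region_width))
  }
  truncated <- (hi - lo + 1L) < region_width
  starts <- if (hi - lo + 1L >= L) seq.int(lo, hi - L + 1L) else integer(0)
  windows <- vapply(starts, function(s) substr(sequence, s, s + L - 1L),
                    character(1))
  hits <- data.frame(
    offset = as.integer(starts - cs),
    sequence = windows,
    score = vapply(windows, function(w) score_window(pssm, w), numeric(1),
                   USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  attr(hits, "truncated") <- truncated
  hits
}

# Best hit whose whole window lies inside [region[1], region[2]] (offsets).
# containment = "start" relaxes to start-in-region. Ties: window center
# closest to the region center, then most upstream.
best_hit_in_region <- function(hits, motif_len, region,
                               containment = c("whole", "start")) {
  containment <- match.arg(containment)
  if (!nrow(hits)) return(NULL)
  last_start <- if (containment == "whole") region[2] - motif_len + 1L else region[2]
  keep <- hits$offset >= region[1] & hits$offset <= last_start
  if (!any(keep)) return(NULL)
  cand <- hits[keep, , drop = FALSE]
  top <- cand[cand$score == max(cand$score), , drop = FALSE]
  if (nrow(top) > 1L) {
    center <- mean(region)
    d <- abs((top$offset + (motif_len - 1) / 2) - center)
    top <- top[d == min(d), , drop = FALSE]
    top <- top[which.min(top$offset), , drop = FALSE]
  }
  list(offset = top$offset[1], sequence = top$sequence[1], score = top$score[1])
}

#' Annotate a cleavage site with its best PAS and DSE motifs
#'
#' Scans 50 bp on each side of the cleavage site on the sense strand of the
#' gene, then keeps the highest-scoring hexamer whose whole window lies in
#' the expected PAS region (offsets -26..-12) and the highest-scoring 7-mer
#' within the DSE region (+1..+25). Minus-strand genes are reverse-
#' complemented before scanning; reported hit offsets are always in
#' transcript sense.
#'
#' @param sequence Reference nucleotide string.
#' @param cs Cleavage-site position on the reference (1-based).
#' @param pas_pssm,dse_pssm PSSMs from [build_pssm()].
#' @param strand Strand of the gene owning the cleavage site.
#' @param pas_region,dse_region Offset windows (defaults c(-26,-12), c(1,25)).
#' @param score_threshold Hits scoring at or below this are labelled
#'   `"none"` (default 0 bits, i.e. no better than background).
#' @param containment `"whole"` (default) requires the entire motif inside
#'   the region; `"start"` only its first base.
#' @return An object of class `cs_annotation`: list with `cs`, `strand`,
#'   `pas`, `dse` (each `NULL` or list(offset, sequence, score)), and
#'   `strength_label` in weak/strong/none (strong only after
#'   [compare_pas_strength()]).
#' @export
annotate_cleavage_site <- function(sequence, cs, pas_pssm, dse_pssm,
                                   strand = "+",
                                   pas_region = c(-26L, -12L),
                                   dse_region = c(1L, 25L),
                                   score_threshold = 0,
                                   containment = c("whole", "start")) {
  containment <- match.arg(containment)
  sequence <- toupper(as.character(sequence))
  cs <- as.integer(cs)
  cs_ref <- cs
  if (strand == "-") {
    sequence <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
    cs <- nchar(sequence) - cs + 1L
  }
  pas_hits <- scan_region(pas_pssm, sequence, cs, "upstream")
  dse_hits <- scan_region(dse_pssm, sequence, cs, "downstream")
  pas <- best_hit_in_region(pas_hits, nrow(pas_pssm), pas_region, containment)
  dse <- best_hit_in_region(dse_hits, nrow(dse_pssm), dse_region, containment)
  label <- if (is.null(pas) || pas$score <= score_threshold) "none" else "weak"
  structure(list(cs = cs_ref, strand = strand, pas = pas, dse = dse,
                 strength_label = label,
                 pas_hits = pas_hits, dse_hits = dse_hits),
            class = "cs_annotation")
}

#' @export
print.cs_annotation <- function(x, ...) {
  cat("cleavage site ", x$cs, " (", x$strand, " strand), PAS: ",
      if (is.null(x$pas)) "none" else
        sprintf("%s @ %d (%.2f bits)", x$pas$sequence, x$pas$offset, x$pas$score),
      ", DSE: ",
      if (is.null(x$dse)) "none" else
        sprintf("%s @ +%d (%.2f bits)", x$dse$sequence, x$dse$offset, x$dse$score),
      ", label: ", x$strength_label, "\n", sep = "")
  invisible(x)
}

#' Order two cleavage sites by PAS strength
#'
#' Labels the annotation with the higher-scoring PAS `"strong"` and the other
#' `"weak"`; exact ties give both `"equal"`.
#'
#' @param annot_proximal,annot_distal `cs_annotation` objects.
#' @return List with relabelled `proximal` and `distal` annotations and an
#'   `ordering` string (`"distal_stronger"`, `"proximal_stronger"`,
#'   `"equal"`, or `"undefined"` when a PAS hit is missing).
#' @export
compare_pas_strength <- function(annot_proximal, annot_distal) {
  if (is.null(annot_proximal[["pas"]]) || is.null(annot_distal[["pas"]])) {
    return(list(proximal = annot_proximal, distal = annot_distal,
                ordering = "undefined"))
  }
  sp <- annot_proximal[["pas"]]$score
  sd_ <- annot_distal[["pas"]]$score
  if (sp == sd_) {
    annot_proximal$strength_label <- annot_distal$strength_label <- "equal"
    ordering <- "equal"
  } else if (sd_ > sp) {
    annot_distal$strength_label <- "strong"
    annot_proximal$strength_label <- "weak"
    ordering <- "distal_stronger"
  } else {
    annot_proximal$strength_label <- "strong"
    annot_distal$strength_label <- "weak"
    ordering <- "proximal_stronger"
  }
  list(proximal = annot_proximal, distal = annot_distal, ordering = ordering)
}

#' Predict whether a cleavage site remains usable after a TE insertion
#'
#' Two loss rules, reported separately and never collapsed:
#' `insertion_separates_pas_cs` when the element falls between the PAS 3' end
#' and the cleavage site and stretches the PAS-to-CS distance beyond
#' `max_pas_cs_span`; `insertion_disrupts_dse` when the insertion point lies
#' within the DSE region (+1..+25) downstream of the cleavage site.
#' Coordinates of annotation and insertion must share the reference
#' (without-TE) frame, in transcript-sense orientation.
#'
#' @param annot A `cs_annotation` with a PAS hit.
#' @param ins A [te_insertion()].
#' @param max_pas_cs_span Maximum functional PAS-to-CS span in bp (default 40).
#' @param dse_region DSE offset window (default c(1, 25)).
#' @return List (`pas_usage_call`): `cs`, `usable`, `reason` in
#'   intact/insertion_separates_pas_cs/insertion_disrupts_dse, plus the
#'   effective `pas_cs_distance` after insertion.
#' @export
predict_insertion_effect <- function(annot, ins, max_pas_cs_span = 40L,
                                     dse_region = c(1L, 25L)) {
  if (is.null(annot[["pas"]])) stop("annotation lacks a PAS hit")
  L <- nchar(annot$pas$sequence)
  cs <- as.integer(annot$cs)
  pas_end <- cs + annot$pas$offset + L - 1L  # transcript-sense frame
  dist0 <- cs - pas_end
  between <- ins$after_base >= pas_end && ins$after_base < cs
  dist <- as.integer(dist0 + if (between) insertion_shift(ins) else 0L)
  in_dse <- ins$after_base >= cs + dse_region[1] - 1L &&
    ins$after_base <= cs + dse_region[2] - 1L
  if (between && dist > max_pas_cs_span) {
    call <- list(usable = FALSE, reason = "insertion_separates_pas_cs")
  } else if (in_dse) {
    call <- list(usable = FALSE, reason = "insertion_disrupts_dse")
  } else {
    call <- list(usable = TRUE, reason = "intact")
  }
  structure(c(list(cs = cs), call, list(pas_cs_distance = dist)),
            class = "pas_usage_call")
}

#' Write motif hits as BED
#'
#' Emits one BED6 line per hit (0-based half-open genomic span of the motif
#' window) with the PSSM score in the score column.
#'
#' @param hits Data frame from [scan_region()] (offsets in transcript sense).
#' @param cs Cleavage-site position on the reference (1-based).
#' @param chrom Reference sequence name.
#' @param strand Strand of the gene owning the cleavage site.
#' @param path Output path.
#' @export
write_hits_bed <- function(hits, cs, chrom, strand = "+", path) {
  L <- nchar(hits$sequence[1])
  start1 <- if (strand == "+") cs + hits$offset
  else cs - hits$offset - (L - 1L)  # transcript-sense offset on minus strand
  bed <- data.frame(chrom = chrom, start = start1 - 1L, end = start1 + L - 1L,
                    name = hits$sequence, score = hits$score, strand = strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write motif hits as TSV
#' @param hits Data frame from [scan_region()].
#' @param cs Cleavage site the offsets are relative to.
#' @param region Offset window used for the in-region flag.
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, cs, region, path) {
  L <- nchar(hits$sequence[1])
  out <- data.frame(cs = cs, offset = hits$offset, window = hits$sequence,
                    score = hits$score,
                    in_region = hits$offset >= region[1] &
                      hits$offset <= region[2] - L + 1L)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
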
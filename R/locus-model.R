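#' @importFrom stats lm coef pf pt pchisq qnorm qt rbinom rexp rnorm runif sd setNames var
#' @importFrom utils read.delim write.table
NULL

# Coordinates are 1-based, inclusive, GFF3-style throughout. A cleavage site
# (CS) is stored as the position of the LAST transcribed base; cleavage occurs
# immediately 3' of it.

#' Construct a transcript isoform record
#'
#' A transcript isoform on a single reference sequence, carrying the two
#' 3'-end landmarks this pipeline needs: the last base of the stop codon and
#' the cleavage site (last transcribed base).
#'
#' @param gene_id,isoform_id Identifiers.
#' @param chrom Reference sequence name.
#' @param start,end 1-based inclusive span of the mature transcript on the
#'   reference.
#' @param strand `"+"` or `"-"`.
#' @param stop_codon_last_base Position of the last base of the stop codon.
#' @param cleavage_site Position of the last transcribed base. On the `+`
#'   strand this must equal `end`; on the `-` strand it must equal `start`.
#' @return An object of class `transcript_isoform`.
#' @export
transcript_isoform <- function(gene_id, isoform_id, chrom, start, end, strand,
                               stop_codon_last_base, cleavage_site) {
  stopifnot(is.character(strand), strand %in% c("+", "-"))
  start <- as.integer(start); end <- as.integer(end)
  stop_codon_last_base <- as.integer(stop_codon_last_base)
  cleavage_site <- as.integer(cleavage_site)
  if (start < 1L || end < start)
    stop("invalid interval: need 1 <= start <= end, got [", start, ", ", end, "]")
  if (cleavage_site < start || cleavage_site > end)
    stop("cleavage_site ", cleavage_site, " outside span [", start, ", ", end, "]")
  expected_cs <- if (strand == "+") end else start
  if (cleavage_site != expected_cs)
    stop("cleavage_site must be the ", if (strand == "+") "end" else "start",
         " of the span on the ", strand, " strand")
  structure(
    list(gene_id = gene_id, isoform_id = isoform_id, chrom = chrom,
         start = start, end = end, strand = strand,
         stop_codon_last_base = stop_codon_last_base,
         cleavage_site = cleavage_site),
    class = "transcript_isoform"
  )
}

#' Construct a TE insertion record
#'
#' The element is inserted between `after_base` and `after_base + 1` on the
#' reference frame. `tsd_length` bases immediately 5' of the insertion point
#' are duplicated on the 3' side of the element (target-site duplication), so
#' coordinates downstream of the insertion shift by `length + tsd_length`.
#'
#' @param after_base 1-based reference position the element is inserted after.
#' @param length Element length in bp (> 0).
#' @param tsd_length Target-site duplication length in bp (>= 0).
#' @param te_id Optional identifier.
#' @param chrom Optional reference sequence name.
#' @return An object of class `te_insertion`.
#' @export
te_insertion <- function(after_base, length, tsd_length = 0L, te_id = NA_character_,
                         chrom = NA_character_) {
  after_base <- as.integer(after_base); length <- as.integer(length)
  tsd_length <- as.integer(tsd_length)
  if (length <= 0L) stop("TE length must be > 0")
  if (tsd_length < 0L) stop("tsd_length must be >= 0")
  structure(list(chrom = chrom, after_base = after_base, length = length,
                 tsd_length = tsd_length, te_id = te_id),
            class = "te_insertion")
}

#' Total coordinate shift caused by an insertion
#' @param ins A [te_insertion()].
#' @return Shift in bp (`length + tsd_length`).
#' @export
insertion_shift <- function(ins) ins$length + ins$tsd_length

#' Construct a locus architecture
#'
#' One genotype of the locus: a reference sequence, its genes (each a list
#' with `gene_id`, `strand`, and a list of [transcript_isoform()]s), and any
#' TE insertions annotated on that sequence.
#'
#' @param genotype_label `"with_TE"` or `"without_TE"`.
#' @param sequence Nucleotide string (single reference sequence).
#' @param genes Named list of gene records.
#' @param insertions List of [te_insertion()] records.
#' @param chrom Reference sequence name.
#' @return An object of class `locus_architecture`.
#' @export
locus_architecture <- function(genotype_label, sequence, genes,
                               insertions = list(), chrom = "locus") {
  stopifnot(genotype_label %in% c("with_TE", "without_TE"))
  sequence <- toupper(as.character(sequence))
  len <- nchar(sequence)
  for (g in genes) {
    for (iso in g$isoforms) {
      if (iso$start < 1L || iso$end > len)
        stop("isoform ", iso$isoform_id, " span [", iso$start, ", ", iso$end,
             "] outside sequence [1, ", len, "]")
    }
  }
  strands <- vapply(genes, function(g) g$strand, character(1))
  if (length(genes) == 2L && length(unique(strands)) != 2L)
    warning("antisense locus expected genes on opposite strands")
  structure(list(genotype_label = genotype_label, chrom = chrom,
                 sequence = sequence, genes = genes, insertions = insertions),
            class = "locus_architecture")
}

#' @export
print.locus_architecture <- function(x, ...) {
  cat("locus_architecture [", x$genotype_label, "], ", nchar(x$sequence),
      " bp, ", length(x$genes), " gene(s), ",
      sum(vapply(x$genes, function(g) length(g$isoforms), integer(1))),
      " isoform(s), ", length(x$insertions), " insertion(s)\n", sep = "")
  invisible(x)
}

#' All isoforms of a locus as a flat list
#' @param locus A [locus_architecture()].
#' @return Named list of `transcript_isoform` objects keyed by `isoform_id`.
#' @export
locus_isoforms <- function(locus) {
  isos <- unlist(lapply(locus$genes, function(g) g$isoforms), recursive = FALSE)
  names(isos) <- vapply(isos, function(i) i$isoform_id, character(1))
  isos
}

#' Load a locus from FASTA + GFF3 + insertions TSV
#'
#' The GFF3 must contain `gene` features and `mRNA` features carrying
#' `stop_codon_last_base` and `cleavage_site` attributes; the insertions TSV
#' has columns `chrom`, `after_base` (1-based), `length`, `tsd_length`,
#' `te_id`.
#'
#' @param fasta_path,gff3_path Paths to the sequence and annotation.
#' @param insertions_path Optional path to the insertions TSV.
#' @param genotype_label Genotype carried by these files; if `NULL`, taken
#'   from a `genotype` attribute on the GFF3 region/gene lines when present,
#'   else `"without_TE"`.
#' @return A [locus_architecture()].
#' @export
load_locus <- function(fasta_path, gff3_path, insertions_path = NULL,
                       genotype_label = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) stop("expected a single-sequence FASTA")
  chrom <- sub("\\s.*$", "", names(seqs)[1])
  sequence <- as.character(seqs[[1]])

  gff <- rtracklayer::import(gff3_path)
  if (!all(as.character(GenomicRanges::seqnames(gff)) == chrom))
    stop("GFF3 features do not reference FASTA sequence '", chrom, "'")
  md <- S4Vectors::mcols(gff)
  types <- as.character(md$type)

  if (is.null(genotype_label)) {
    genotype_label <- if (!is.null(md$genotype) && any(!is.na(md$genotype)))
      as.character(md$genotype[!is.na(md$genotype)][1]) else "without_TE"
  }

  tx_idx <- which(types %in% c("mRNA", "transcript"))
  if (!length(tx_idx)) stop("annotation error: no mRNA/transcript features")
  genes <- list()
  for (i in tx_idx) {
    gid <- as.character(unlist(md$Parent[i]))[1]
    if (is.na(gid) || !length(gid)) gid <- as.character(md$gene_id[i])
    iid <- as.character(md$ID[i])
    scb <- if (is.null(md$stop_codon_last_base)) NA_integer_ else
      suppressWarnings(as.integer(md$stop_codon_last_base[i]))
    cs <- if (is.null(md$cleavage_site)) NA_integer_ else
      suppressWarnings(as.integer(md$cleavage_site[i]))
    if (is.na(scb) || is.na(cs))
      stop("annotation error: isoform ", iid,
           " lacks stop_codon_last_base/cleavage_site attributes")
    iso <- transcript_isoform(
      gene_id = gid, isoform_id = iid, chrom = chrom,
      start = GenomicRanges::start(gff)[i], end = GenomicRanges::end(gff)[i],
      strand = as.character(GenomicRanges::strand(gff))[i],
      stop_codon_last_base = scb, cleavage_site = cs)
    if (is.null(genes[[gid]]))
      genes[[gid]] <- list(gene_id = gid, strand = iso$strand, isoforms = list())
    genes[[gid]]$isoforms[[iid]] <- iso
  }

  insertions <- list()
  if (!is.null(insertions_path)) {
    tab <- read.delim(insertions_path, comment.char = "#",
                      stringsAsFactors = FALSE)
    insertions <- lapply(seq_len(nrow(tab)), function(r)
      te_insertion(after_base = tab$after_base[r], length = tab$length[r],
                   tsd_length = tab$tsd_length[r], te_id = tab$te_id[r],
                   chrom = tab$chrom[r]))
  }

  locus_architecture(genotype_label, sequence, genes, insertions, chrom = chrom)
}

#' Write a locus to FASTA + GFF3 + insertions TSV
#'
#' @param locus A [locus_architecture()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of file paths (fasta, gff3, insertions).
#' @export
write_locus <- function(locus, dir, prefix = locus$genotype_label) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(prefix, ".fa"))
  gff3 <- file.path(dir, paste0(prefix, ".gff3"))
  ins <- file.path(dir, paste0(prefix, "_insertions.tsv"))

  dna <- Biostrings::DNAStringSet(locus$sequence)
  names(dna) <- locus$chrom
  Biostrings::writeXStringSet(dna, fasta, width = 60L)

  rows <- list()
  for (g in locus$genes) {
    spans <- vapply(g$isoforms, function(i) c(i$start, i$end), integer(2))
    rows[[length(rows) + 1L]] <- data.frame(
      start = min(spans[1, ]), end = max(spans[2, ]), strand = g$strand,
      type = "gene", ID = g$gene_id, Parent = NA_character_,
      stop_codon_last_base = NA_character_, cleavage_site = NA_character_,
      genotype = locus$genotype_label, stringsAsFactors = FALSE)
    for (i in g$isoforms) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = i$start, end = i$end, strand = i$strand, type = "mRNA",
        ID = i$isoform_id, Parent = g$gene_id,
        stop_codon_last_base = as.character(i$stop_codon_last_base),
        cleavage_site = as.character(i$cleavage_site),
        genotype = NA_character_, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = locus$chrom,
    ranges = IRanges::IRanges(tab$start, tab$end),
    strand = tab$strand)
  S4Vectors::mcols(gr)$type <- tab$type
  S4Vectors::mcols(gr)$ID <- tab$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(tab$Parent), "", tab$Parent)
  S4Vectors::mcols(gr)$stop_codon_last_base <- tab$stop_codon_last_base
  S4Vectors::mcols(gr)$cleavage_site <- tab$cleavage_site
  S4Vectors::mcols(gr)$genotype <- tab$genotype
  rtracklayer::export(gr, gff3, format = "gff3")

  itab <- if (length(locus$insertions)) {
    do.call(rbind, lapply(locus$insertions, function(x) data.frame(
      chrom = ifelse(is.na(x$chrom), locus$chrom, x$chrom),
      after_base = x$after_base, length = x$length,
      tsd_length = x$tsd_length, te_id = x$te_id, stringsAsFactors = FALSE)))
  } else {
    data.frame(chrom = character(), after_base = integer(), length = integer(),
               tsd_length = integer(), te_id = character())
  }
  con <- file(ins, "w")
  writeLines("# after_base is 1-based: element inserted between after_base and after_base+1", con)
  write.table(itab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  c(fasta = fasta, gff3 = gff3, insertions = ins)
}

#' 3' UTR length of an isoform
#'
#' Counts the bases strictly 3' of the stop codon through the cleavage site
#' inclusive, in the sense strand of the gene.
#'
#' @param isoform A [transcript_isoform()].
#' @return Length in bp.
#' @export
utr3_length <- function(isoform) {
  n <- if (isoform$strand == "+")
    isoform$cleavage_site - isoform$stop_codon_last_base
  else
    isoform$stop_codon_last_base - isoform$cleavage_site
  if (n < 0)
    stop("geometry error: stop codon lies 3' of the cleavage site for isoform ",
         isoform$isoform_id)
  n
}

#' Mature transcript length of an isoform
#' @param isoform A [transcript_isoform()].
#' @return `end - start + 1` in bp.
#' @export
transcript_length <- function(isoform) isoform$end - isoform$start + 1L

#' Overlap between two antisense transcripts
#'
#' Size of the inclusive intersection of the two spans; 0 when disjoint.
#' The isoforms must lie on opposite strands of the same reference.
#'
#' @param isoA,isoB [transcript_isoform()] objects.
#' @return Overlap in bp.
#' @export
antisense_overlap <- function(isoA, isoB) {
  if (!identical(isoA$chrom, isoB$chrom))
    stop("usage error: isoforms on different reference sequences")
  if (isoA$strand == isoB$strand)
    stop("usage error: antisense overlap requires opposite strands")
  max(0L, min(isoA$end, isoB$end) - max(isoA$start, isoB$start) + 1L)
}

shift_coord <- function(pos, after_base, shift) {
  ifelse(pos > after_base, pos + shift, pos)
}

#' Insert a TE into a locus, lifting all coordinates
#'
#' Every coordinate strictly greater than `ins$after_base` is shifted by
#' `length + tsd_length`; the sequence gains the element followed by a copy
#' of the `tsd_length` bases immediately 5' of the insertion point. The
#' genotype label flips to `"with_TE"`.
#'
#' @param locus A `without_TE` [locus_architecture()].
#' @param ins A [te_insertion()] with `after_base` inside the sequence.
#' @param te_sequence Nucleotide string of length `ins$length`.
#' @return A new [locus_architecture()].
#' @export
apply_insertion <- function(locus, ins, te_sequence) {
  te_sequence <- toupper(as.character(te_sequence))
  if (nchar(te_sequence) != ins$length)
    stop("te_sequence length ", nchar(te_sequence), " != ins$length ", ins$length)
  len <- nchar(locus$sequence)
  if (ins$after_base < ins$tsd_length || ins$after_base > len)
    stop("after_base outside sequence")
  hit_cds <- Filter(function(iso) {
    cds_lo <- if (iso$strand == "+") iso$start else iso$stop_codon_last_base
    cds_hi <- if (iso$strand == "+") iso$stop_codon_last_base else iso$end
    ins$after_base >= cds_lo && ins$after_base < cds_hi
  }, locus_isoforms(locus))
  if (length(hit_cds))
    warning("insertion point ", ins$after_base, " falls inside the CDS of ",
            paste(names(hit_cds), collapse = ", "))
  shift <- insertion_shift(ins)
  tsd <- if (ins$tsd_length > 0L)
    substr(locus$sequence, ins$after_base - ins$tsd_length + 1L, ins$after_base)
  else ""
  new_seq <- paste0(substr(locus$sequence, 1L, ins$after_base),
                    te_sequence, tsd,
                    substr(locus$sequence, ins$after_base + 1L, len))
  new_genes <- lapply(locus$genes, function(g) {
    g$isoforms <- lapply(g$isoforms, function(i) {
      i$start <- shift_coord(i$start, ins$after_base, shift)
      i$end <- shift_coord(i$end, ins$after_base, shift)
      i$stop_codon_last_base <- shift_coord(i$stop_codon_last_base,
                                            ins$after_base, shift)
      i$cleavage_site <- shift_coord(i$cleavage_site, ins$after_base, shift)
      i
    })
    g
  })
  locus_architecture("with_TE", new_seq, new_genes,
                     insertions = c(locus$insertions, list(ins)),
                     chrom = locus$chrom)
}

#' Remove a TE from a locus (inverse coordinate lift)
#'
#' Inverse of [apply_insertion()]: drops the element and its duplicated TSD
#' from the sequence and shifts downstream coordinates back.
#'
#' @param locus A `with_TE` [locus_architecture()] produced by
#'   [apply_insertion()].
#' @param ins The same [te_insertion()] that was applied.
#' @return A `without_TE` [locus_architecture()].
#' @export
delete_insertion <- function(locus, ins) {
  shift <- insertion_shift(ins)
  len <- nchar(locus$sequence)
  new_seq <- paste0(substr(locus$sequence, 1L, ins$after_base),
                    substr(locus$sequence, ins$after_base + shift + 1L, len))
  new_genes <- lapply(locus$genes, function(g) {
    g$isoforms <- lapply(g$isoforms, function(i) {
      i$start <- shift_coord(i$start, ins$after_base, -shift)
      i$end <- shift_coord(i$end, ins$after_base, -shift)
      i$stop_codon_last_base <- shift_coord(i$stop_codon_last_base,
                                            ins$after_base, -shift)
      i$cleavage_site <- shift_coord(i$cleavage_site, ins$after_base, -shift)
      i
    })
    g
  })
  keep <- Filter(function(x) !identical(x$after_base, ins$after_base),
                 locus$insertions)
  locus_architecture("without_TE", new_seq, new_genes, insertions = keep,
                     chrom = locus$chrom)
}

#' Distances from a TE insertion to the flanking PAS and cleavage site
#'
#' All positions are in transcript-sense coordinates of the gene owning the
#' cleavage site, on the reference (without-TE) frame. `bp_pas_to_te` counts
#' the bases strictly after the PAS 3' end up to the insertion point;
#' `bp_te_to_cs` is the distance from the insertion point to the cleavage
#' site, which on the with-TE frame equals the gap between the element's 3'
#' end (including the duplicated target site) and the shifted cleavage site.
#'
#' @param ins A [te_insertion()].
#' @param pas_end Position of the PAS 3'-most base.
#' @param cs Cleavage site (last transcribed base).
#' @return A list with `between` (logical), `bp_pas_to_te`, `bp_te_to_cs`,
#'   and `flag` (`"ok"` or `"not_between"`).
#' @export
insertion_context <- function(ins, pas_end, cs) {
  if (!(ins$after_base >= pas_end && ins$after_base < cs))
    return(list(between = FALSE, bp_pas_to_te = NA_integer_,
                bp_te_to_cs = NA_integer_, flag = "not_between"))
  list(between = TRUE,
       bp_pas_to_te = as.integer(ins$after_base - pas_end),
       bp_te_to_cs = as.integer(cs - ins$after_base),
       flag = "ok")
}

#' Paths to the packaged two-gene locus fixture
#'
#' A small synthetic reconstruction of the CG11699/Kmn1 antisense locus with
#' the coordinates that reproduce the published structural quantities (3'UTR
#' lengths 110/221/73 bp, antisense overlaps 140/28 bp, transcript-length
#' difference 188 bp, PAS-TE and TE-CS distances 7 and 12 bp). Each genotype
#' is annotated with its own declared coordinates.
#'
#' @param genotype `"without_TE"` or `"with_TE"`.
#' @return Named character vector of paths (fasta, gff3, insertions).
#' @export
locus_fixture_path <- function(genotype = c("without_TE", "with_TE")) {
  genotype <- match.arg(genotype)
  dir <- system.file("extdata", package = "apaTE")
  c(fasta = file.path(dir, paste0(genotype, ".fa")),
    gff3 = file.path(dir, paste0(genotype, ".gff3")),
    insertions = file.path(dir, paste0(genotype, "_insertions.tsv")))
}

#' Load the packaged locus fixture
#' @inheritParams locus_fixture_path
#' @return A [locus_architecture()].
#' @export
locus_fixture <- function(genotype = c("without_TE", "with_TE")) {
  genotype <- match.arg(genotype)
  p <- locus_fixture_path(genotype)
  load_locus(p["fasta"], p["gff3"], p["insertions"], genotype_label = genotype)
}
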
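test_that("a uniform frequency matrix maps to the all-zero PSSM", {
  fm <- frequency_matrix(matrix(0.25, nrow = 6, ncol = 4,
                                dimnames = list(NULL, c("A", "C", "G", "T"))))
  p <- build_pssm(fm)
  expect_true(all(p == 0))
  expect_equal(score_window(p, "AATAAA"), 0)
})

test_that("PSSM cells follow the pseudocount log-likelihood closed form", {
  fm <- toy_matrix("A", f = 1)  # single position, f(A) = 1
  p <- build_pssm(fm, pseudocount = 0.01)
  expect_equal(unname(p[1, "A"]), 1.9577718, tolerance = 1e-6)  # log2(1.01/0.26)
  expect_equal(unname(p[1, "C"]), log2(0.01 / 0.26), tolerance = 1e-12)
})

test_that("zero pseudocount permits and flags -Inf scores", {
  p <- build_pssm(toy_matrix("A", f = 1), pseudocount = 0)
  expect_true(attr(p, "has_minus_inf"))
  expect_identical(unname(p[1, "C"]), -Inf)
})

test_that("negative frequencies are rejected", {
  m <- matrix(c(1.25, -0.25, 0, 0), nrow = 1,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  expect_error(frequency_matrix(m), "negative")
})

test_that("consensus window score matches the hand-computed sum", {
  p <- build_pssm(toy_matrix("AATAAA", f = 0.85), pseudocount = 0)
  expect_equal(score_window(p, "AATAAA"), 10.59321, tolerance = 1e-4)
  expect_error(score_window(p, "AATAA"), "usage error")
  # N contributes zero
  expect_equal(score_window(p, "NATAAA"),
               score_window(p, "AATAAA") - unname(p[1, "A"]))
})

test_that("every non-consensus hexamer scores strictly below the consensus", {
  p <- build_pssm(toy_matrix("AATAAA", f = 0.85), pseudocount = 0)
  kmers <- all_kmers(6)
  scores <- vapply(kmers, function(k) score_window(p, k), numeric(1))
  expect_identical(names(which.max(scores)), "AATAAA")
  expect_true(all(scores[names(scores) != "AATAAA"] < max(scores)))
})

test_that("scan_region yields region_length - motif_length + 1 hits", {
  set.seed(21)
  seqn <- random_dna_str(200)
  pas <- build_pssm(default_pas_matrix())
  dse <- build_pssm(default_dse_matrix())
  up <- scan_region(pas, seqn, cs = 100, side = "upstream")
  down <- scan_region(dse, seqn, cs = 100, side = "downstream")
  expect_identical(nrow(up), 45L)
  expect_identical(nrow(down), 44L)
  expect_false(attr(up, "truncated"))
  expect_identical(range(up$offset), c(-50L, -6L))
  expect_identical(range(down$offset), c(1L, 44L))
})

test_that("truncated and empty regions are flagged", {
  set.seed(22)
  seqn <- random_dna_str(60)
  pas <- build_pssm(default_pas_matrix())
  tr <- scan_region(pas, seqn, cs = 20, side = "upstream")
  expect_true(attr(tr, "truncated"))
  expect_identical(nrow(tr), 19L - 6L + 1L)
  short <- scan_region(pas, seqn, cs = 3, side = "upstream")
  expect_identical(nrow(short), 0L)
  expect_true(attr(short, "truncated"))
  expect_error(scan_region(pas, seqn, cs = 100, side = "upstream"),
               "bounds error")
})

test_that("best-hit selection equals exhaustive enumeration", {
  pas <- build_pssm(default_pas_matrix())
  dse <- build_pssm(default_dse_matrix())
  set.seed(23)
  for (i in 1:25) {
    seqn <- random_dna_str(200)
    ann <- annotate_cleavage_site(seqn, 100, pas, dse)
    # oracle: enumerate all windows fully inside the region by hand
    brute_best <- function(pssm, lo, hi) {
      L <- nrow(pssm)
      offs <- lo:(hi - L + 1L)
      sc <- vapply(offs, function(o)
        score_window(pssm, substr(seqn, 100 + o, 100 + o + L - 1L)),
        numeric(1))
      max(sc)
    }
    expect_equal(ann$pas$score, brute_best(pas, -26L, -12L))
    expect_equal(ann$dse$score, brute_best(dse, 1L, 25L))
  }
})

test_that("PSSM rank order is invariant under change of log base", {
  fm <- default_pas_matrix()
  p2 <- build_pssm(fm, base = 2)
  pe <- build_pssm(fm, base = exp(1))
  set.seed(24)
  kmers <- replicate(100, random_dna_str(6))
  s2 <- vapply(kmers, function(k) score_window(p2, k), numeric(1))
  se <- vapply(kmers, function(k) score_window(pe, k), numeric(1))
  # natural-log scores are the bit scores scaled by ln 2, so every pairwise
  # ordering (hence every best-hit choice) is preserved
  expect_equal(se, s2 * log(2), tolerance = 1e-12)
  expect_identical(which.max(s2), which.max(se))
})

test_that("planted consensus PAS is recovered in at least 95% of loci", {
  pas <- build_pssm(default_pas_matrix())
  dse <- build_pssm(default_dse_matrix())
  set.seed(25)
  hits <- vapply(1:150, function(i) {
    seqn <- random_dna_str(160)
    cs <- 110L
    off <- sample(seq(-26L, -17L), 1)
    at <- cs + off
    seqn <- paste0(substr(seqn, 1, at - 1), "AATAAA",
                   substr(seqn, at + 6, nchar(seqn)))
    ann <- annotate_cleavage_site(seqn, cs, pas, dse)
    identical(ann$pas$offset, off)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("annotation of a motif-free sequence returns a none label", {
  pas <- build_pssm(default_pas_matrix())
  dse <- build_pssm(default_dse_matrix())
  seqn <- paste(rep("C", 200), collapse = "")
  ann <- annotate_cleavage_site(seqn, 100, pas, dse)
  expect_lte(ann$pas$score, 0)
  expect_identical(ann$strength_label, "none")
})

test_that("fixture distal PAS lies at offset -24 within the expected region", {
  wo <- locus_fixture("without_TE")
  pas <- build_pssm(default_pas_matrix())
  dse <- build_pssm(default_dse_matrix())
  ann <- annotate_cleavage_site(wo$sequence, 1721, pas, dse)
  expect_identical(ann$pas$offset, -24L)
  expect_identical(ann$pas$sequence, "AATAAA")
  expect_gte(ann$pas$offset, -26L)
  expect_lte(ann$pas$offset + 5L, -12L)
})

test_that("minus-strand cleavage sites are scanned in transcript sense", {
  wo <- locus_fixture("without_TE")
  pas <- build_pssm(default_pas_matrix())
  dse <- build_pssm(default_dse_matrix())
  ann <- annotate_cleavage_site(wo$sequence, 1582, pas, dse, strand = "-")
  expect_identical(ann$pas$sequence, "AATAAA")  # planted as TTTATT on plus
  expect_identical(ann$pas$offset, -21L)
})

test_that("compare_pas_strength orders the fixture sites and is antisymmetric", {
  wo <- locus_fixture("without_TE")
  pas <- build_pssm(default_pas_matrix())
  dse <- build_pssm(default_dse_matrix())
  prox <- annotate_cleavage_site(wo$sequence, 1610, pas, dse)
  dist <- annotate_cleavage_site(wo$sequence, 1721, pas, dse)
  cmp <- compare_pas_strength(prox, dist)
  expect_identical(cmp$ordering, "distal_stronger")
  expect_identical(cmp$distal$strength_label, "strong")
  expect_identical(cmp$proximal$strength_label, "weak")
  swapped <- compare_pas_strength(dist, prox)
  expect_identical(swapped$ordering, "proximal_stronger")
  expect_identical(swapped$proximal$strength_label, "strong")
  # exact ties
  tie <- compare_pas_strength(dist, dist)
  expect_identical(tie$ordering, "equal")
  expect_identical(tie$proximal$strength_label, "equal")
  # missing hit
  none <- prox; none$pas <- NULL
  expect_identical(compare_pas_strength(none, dist)$ordering, "undefined")
})

test_that("insertion-effect prediction applies both loss rules separately", {
  wo <- locus_fixture("without_TE")
  pas <- build_pssm(default_pas_matrix())
  dse <- build_pssm(default_dse_matrix())
  dist <- annotate_cleavage_site(wo$sequence, 1721, pas, dse)
  # intact geometry: PAS-to-CS span 19 bp without the element
  far <- te_insertion(2500, 186, 2)
  call0 <- predict_insertion_effect(dist, far)
  expect_true(call0$usable)
  expect_identical(call0$reason, "intact")
  expect_identical(call0$pas_cs_distance, 19L)
  # the fixture element stretches the span to 207 bp
  call1 <- predict_insertion_effect(dist, wo$insertions[[1]])
  expect_false(call1$usable)
  expect_identical(call1$reason, "insertion_separates_pas_cs")
  expect_identical(call1$pas_cs_distance, 207L)
  # insertion inside the DSE region downstream of the CS
  call2 <- predict_insertion_effect(dist, te_insertion(1721 + 10, 186, 2))
  expect_false(call2$usable)
  expect_identical(call2$reason, "insertion_disrupts_dse")
})

test_that("hit writers emit TSV flags and 0-based BED spans", {
  wo <- locus_fixture("without_TE")
  pas <- build_pssm(default_pas_matrix())
  hits <- scan_region(pas, wo$sequence, 1721, "upstream")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(hits, cs = 1721, region = c(-26L, -12L), tsv)
  tab <- read.delim(tsv)
  expect_identical(nrow(tab), nrow(hits))
  expect_identical(sum(tab$in_region), 10L)  # starts -26..-17
  bed <- withr::local_tempfile(fileext = ".bed")
  write_hits_bed(hits, cs = 1721, chrom = wo$chrom, strand = "+", path = bed)
  bt <- read.delim(bed, header = FALSE)
  planted <- bt[bt$V4 == "AATAAA" & bt$V5 == max(bt$V5), ]
  expect_identical(planted$V2, 1696L)  # 0-based start of the 1697-1702 hexamer
  expect_identical(planted$V3, 1702L)
})

test_that("frequency matrices round-trip through TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  fm <- default_pas_matrix()
  write_frequency_matrix(fm, path)
  rd <- read_frequency_matrix(path)
  expect_equal(unclass(rd), unclass(fm), ignore_attr = TRUE)
})
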
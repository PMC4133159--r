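test_that("packaged fixture loads with the expected structure", {
  wo <- locus_fixture("without_TE")
  expect_s3_class(wo, "locus_architecture")
  expect_length(wo$genes, 2L)
  expect_length(locus_isoforms(wo), 4L)
  expect_length(wo$insertions, 1L)
  expect_setequal(vapply(wo$genes, function(g) g$strand, character(1)),
                  c("+", "-"))
})

test_that("load_locus rejects annotations outside the sequence", {
  wo_paths <- locus_fixture_path("without_TE")
  bad_gff <- withr::local_tempfile(fileext = ".gff3")
  lines <- readLines(wo_paths["gff3"])
  writeLines(gsub("\t2600\t", "\t5000\t", lines, fixed = TRUE), bad_gff)
  expect_error(load_locus(wo_paths["fasta"], bad_gff), "outside sequence")
})

test_that("load_locus requires cleavage-site attributes", {
  wo_paths <- locus_fixture_path("without_TE")
  bad_gff <- withr::local_tempfile(fileext = ".gff3")
  lines <- readLines(wo_paths["gff3"])
  writeLines(gsub("cleavage_site=[0-9]+;?", "", lines), bad_gff)
  expect_error(load_locus(wo_paths["fasta"], bad_gff), "annotation error")
})

test_that("3'UTR lengths reproduce the published isoform geometry", {
  iso <- locus_isoforms(locus_fixture("without_TE"))
  expect_identical(utr3_length(iso[["CG11699-short"]]), 110L)
  expect_identical(utr3_length(iso[["CG11699-long"]]), 221L)
  expect_identical(utr3_length(iso[["Kmn1-shortUTR"]]), 73L)
  # the short-UTR antisense isoform is unchanged by the insertion
  isow <- locus_isoforms(locus_fixture("with_TE"))
  expect_identical(utr3_length(isow[["Kmn1-shortUTR"]]), 73L)
})

test_that("utr3_length errors when the stop codon lies 3' of the cleavage site", {
  iso <- transcript_isoform("g", "g-1", "chr", 1, 100, "+",
                            stop_codon_last_base = 100, cleavage_site = 100)
  iso$stop_codon_last_base <- 150L  # force inconsistent geometry
  expect_error(utr3_length(iso), "geometry error")
})

test_that("transcript lengths differ by the TE plus target-site duplication", {
  wo <- locus_isoforms(locus_fixture("without_TE"))
  wi <- locus_isoforms(locus_fixture("with_TE"))
  expect_identical(transcript_length(wo[["Kmn1-main"]]), 1019L)
  expect_identical(transcript_length(wi[["Kmn1-main"]]), 1207L)
  expect_identical(transcript_length(wi[["Kmn1-main"]]) -
                     transcript_length(wo[["Kmn1-main"]]), 188L)
})

test_that("antisense overlap matches the published genotype difference", {
  wo <- locus_isoforms(locus_fixture("without_TE"))
  wi <- locus_isoforms(locus_fixture("with_TE"))
  expect_identical(antisense_overlap(wo[["CG11699-long"]], wo[["Kmn1-main"]]),
                   140L)
  expect_identical(antisense_overlap(wi[["CG11699-short"]], wi[["Kmn1-main"]]),
                   28L)
})

test_that("antisense overlap handles disjoint spans and rejects same strand", {
  a <- transcript_isoform("gA", "a", "chr", 1, 10, "+", 1, 10)
  b <- transcript_isoform("gB", "b", "chr", 100, 110, "-", 110, 100)
  expect_identical(antisense_overlap(a, b), 0L)
  b_plus <- transcript_isoform("gB", "b", "chr", 100, 110, "+", 100, 110)
  expect_error(antisense_overlap(a, b_plus), "usage error")
})

test_that("antisense overlap is symmetric, bounded, and equals per-base counting", {
  set.seed(42)
  for (i in 1:50) {
    p <- random_antisense_pair()
    ov <- antisense_overlap(p$a, p$b)
    expect_identical(ov, antisense_overlap(p$b, p$a))
    expect_lte(ov, min(transcript_length(p$a), transcript_length(p$b)))
    expect_identical(ov, brute_force_overlap(p$a, p$b))
  }
})

test_that("apply_insertion lifts coordinates by length plus TSD", {
  ins <- te_insertion(after_base = 1709, length = 186, tsd_length = 2)
  shift <- apaTE:::shift_coord
  expect_identical(shift(100L, ins$after_base, insertion_shift(ins)), 100L)
  expect_identical(shift(1721L, ins$after_base, insertion_shift(ins)), 1909L)
})

test_that("apply then delete restores the original architecture", {
  wo <- locus_fixture("without_TE")
  ins <- wo$insertions[[1]]
  set.seed(7)
  te_seq <- random_dna_str(ins$length)
  wi <- apply_insertion(wo, ins, te_seq)
  expect_identical(wi$genotype_label, "with_TE")
  expect_identical(nchar(wi$sequence), nchar(wo$sequence) + 188L)
  back <- delete_insertion(wi, ins)
  expect_identical(back$sequence, wo$sequence)
  expect_equal(locus_isoforms(back), locus_isoforms(wo))
})

test_that("insertion preserves distances on one side and stretches across", {
  wo <- locus_fixture("without_TE")
  ins <- wo$insertions[[1]]
  set.seed(8)
  wi <- apply_insertion(wo, ins, random_dna_str(ins$length))
  iso_wo <- locus_isoforms(wo)
  iso_wi <- locus_isoforms(wi)
  # both CG11699 cleavage sites upstream vs downstream of the insertion point
  cs_up <- iso_wo[["CG11699-short"]]$cleavage_site    # 1610 < 1709
  cs_down <- iso_wo[["CG11699-long"]]$cleavage_site   # 1721 > 1709
  expect_identical(iso_wi[["CG11699-short"]]$cleavage_site, cs_up)
  expect_identical(iso_wi[["CG11699-long"]]$cleavage_site - cs_up,
                   (cs_down - cs_up) + insertion_shift(ins))
  # same-side pair: antisense gene stop vs its downstream end
  expect_identical(
    iso_wi[["Kmn1-main"]]$end - iso_wi[["Kmn1-main"]]$stop_codon_last_base,
    iso_wo[["Kmn1-main"]]$end - iso_wo[["Kmn1-main"]]$stop_codon_last_base)
})

test_that("insertion inside a CDS warns but does not error", {
  wo <- locus_fixture("without_TE")
  ins <- te_insertion(after_base = 1200, length = 10, tsd_length = 0)
  set.seed(9)
  expect_warning(apply_insertion(wo, ins, random_dna_str(10)), "CDS")
})

test_that("insertion_context reproduces the PAS/TE/CS geometry", {
  ins <- te_insertion(1709, 186, 2)
  ctx <- insertion_context(ins, pas_end = 1702, cs = 1721)
  expect_true(ctx$between)
  expect_identical(ctx$bp_pas_to_te, 7L)
  expect_identical(ctx$bp_te_to_cs, 12L)
  # adjacency: immediately after the PAS end
  adj <- insertion_context(te_insertion(1702, 186, 2), 1702, 1721)
  expect_identical(adj$bp_pas_to_te, 0L)
  # downstream of the cleavage site: flagged, distances unset
  out <- insertion_context(te_insertion(1800, 186, 2), 1702, 1721)
  expect_false(out$between)
  expect_identical(out$flag, "not_between")
  expect_true(is.na(out$bp_pas_to_te))
})

test_that("UTR length difference equals the inter-CS distance for shared stops", {
  set.seed(11)
  for (i in 1:20) {
    stop_base <- sample(200:400, 1)
    cs1 <- stop_base + sample(30:100, 1)
    cs2 <- cs1 + sample(1:150, 1)
    short <- transcript_isoform("g", "s", "chr", 100, cs1, "+", stop_base, cs1)
    long <- transcript_isoform("g", "l", "chr", 100, cs2, "+", stop_base, cs2)
    expect_identical(utr3_length(long) - utr3_length(short), cs2 - cs1)
  }
})

test_that("written loci read back identically", {
  dir <- withr::local_tempdir()
  sim <- simulate_locus(dir, seed = 123)
  rd <- load_locus(sim$without["fasta"], sim$without["gff3"],
                   sim$without["insertions"], genotype_label = "without_TE")
  expect_identical(rd$sequence, sim$loci$without_TE$sequence)
  expect_equal(locus_isoforms(rd), locus_isoforms(sim$loci$without_TE))
  rd2 <- load_locus(sim$with["fasta"], sim$with["gff3"],
                    sim$with["insertions"], genotype_label = "with_TE")
  expect_identical(rd2$sequence, sim$loci$with_TE$sequence)
  expect_equal(locus_isoforms(rd2), locus_isoforms(sim$loci$with_TE))
})
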
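test_that("gene_model validates structure and derives introns", {
  ex <- data.frame(start = c(11, 61, 121), end = c(40, 90, 150))
  g <- gene_model("g1", "chr1", "+", ex)
  expect_equal(g$n_exons, 3)
  intr <- introns(g)
  expect_equal(nrow(intr), g$n_exons - 1)
  expect_equal(intr$start, c(41, 91))
  expect_equal(intr$end, c(60, 120))

  # 17 exons yield 16 introns
  ex17 <- data.frame(start = seq(1, by = 200, length.out = 17))
  ex17$end <- ex17$start + 98  # 99 bp each, 17 * 99 divisible by 3
  g17 <- gene_model("g17", "chr1", "+", ex17)
  expect_equal(g17$n_exons, 17)
  expect_equal(nrow(introns(g17)), 16)

  expect_error(gene_model("bad", "chr1", "+",
                          data.frame(start = c(1, 50), end = c(60, 80))),
               "overlap")
  expect_error(gene_model("bad", "chr1", "+",
                          data.frame(start = 1, end = 10)),
               "multiple of 3")
})

test_that("VCF reading skips non-SNPs and errors on missing samples", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "mini.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"d\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "WT", "mutant", "F2_bulk", sep = "\t"),
    "chr1\t100\t.\tC\tT\t.\tPASS\t.\tGT:AD\t0/0:9,0\t1/1:0,9\t1/1:2,18",
    "chr1\t200\t.\tG\tTA\t.\tPASS\t.\tGT:AD\t0/0:9,0\t1/1:0,9\t0/1:5,5",
    "chr1\t300\t.\tA\tC,G\t.\tPASS\t.\tGT:AD\t0/0:9,0,0\t1/1:0,9,0\t0/1:5,5,0",
    "chr1\t400\t.\tT\tC\t.\tPASS\t.\tGT:AD\t0/1:5,4\t1/1:0,9\t0/0:20,0"),
    vcf)
  expect_message(rec <- read_variants(vcf, "WT", "mutant", "F2_bulk"),
                 "skipped 2")
  expect_equal(nrow(rec), 2)  # the indel and the multiallelic are gone
  expect_equal(attr(rec, "skipped"), c(indel = 1L, multiallelic = 1L))
  expect_equal(rec$pos, c(100, 400))
  expect_equal(rec$bulk_ref, c(2L, 20L))
  expect_equal(rec$bulk_alt, c(18L, 0L))
  expect_equal(rec$wt_call, c("hom_ref", "het"))

  expect_error(read_variants(vcf, "WT", "mutant", "no_such_bulk"),
               "no_such_bulk")
  expect_error(read_variants(file.path(dir, "absent.vcf"), "a", "b", "c"),
               "no such file")
})

test_that("the allele-count TSV dialect is read equivalently", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "counts.tsv")
  d <- data.frame(chrom = "chr1", pos = c(10, 20), ref = c("C", "G"),
                  alt = c("T", "A"), wt_gt = c("0/0", "hom_ref"),
                  mut_gt = c("1/1", "het"), bulk_ref = c(0, 7),
                  bulk_alt = c(21, 8))
  write.table(d, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- read_variants_tsv(tsv)
  expect_equal(rec$wt_call, c("hom_ref", "hom_ref"))
  expect_equal(rec$mut_call, c("hom_alt", "het"))
  expect_equal(rec$bulk_alt, c(21L, 8L))
  expect_error(read_variants_tsv(file.path(dir, "nope.tsv")), "no such file")
  bad <- file.path(dir, "bad.tsv")
  write.table(d[, -3], bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_variants_tsv(bad), "missing column")
})

test_that("homozygous_differences keeps exactly mutant hom-alt / wt hom-ref", {
  rec <- data.frame(
    chrom = "chr1", pos = 1:5, ref = "C", alt = "T",
    wt_call = c("hom_ref", "hom_ref", "het", "hom_alt", "hom_ref"),
    mut_call = c("hom_alt", "het", "hom_alt", "hom_alt", "missing"))
  out <- homozygous_differences(rec)
  expect_equal(out$pos, 1)
  expect_equal(attr(out, "n_dropped"), 4)

  # on error-free simulated data the retained set is the simulator's truth
  sim <- shared_sim()
  hom <- homozygous_differences(sim$variants)
  expect_equal(hom[, c("chrom", "pos", "ref", "alt")],
               sim$mutations[, c("chrom", "pos", "ref", "alt")])
})

test_that("genomic-to-CDS mapping matches a per-base exhaustive scan", {
  ex <- data.frame(start = c(101, 161, 301), end = c(130, 220, 330))
  for (strand in c("+", "-")) {
    g <- gene_model("g", "chr1", strand, ex)
    # oracle: walk every exonic base in transcription order
    plus_order <- unlist(mapply(seq, ex$start, ex$end, SIMPLIFY = FALSE))
    walk <- if (strand == "+") plus_order else rev(plus_order)
    for (pos in seq(95, 340, by = 1)) {
      m <- map_genomic_to_cds(g, pos)
      if (pos %in% plus_order) {
        expect_equal(m$status, "coding")
        expect_equal(m$cds_offset, which(walk == pos))
        expect_equal(map_cds_to_genomic(g, m$cds_offset), pos)
      } else if (pos < 101 || pos > 330) {
        expect_equal(m$status, "intergenic")
      } else {
        expect_equal(m$status, "intronic")
      }
    }
  }
})

test_that("intronic positions report distance to the nearest exon boundary", {
  g <- gene_model("g", "chr1", "+",
                  data.frame(start = c(1, 101), end = c(60, 160)))
  expect_equal(map_genomic_to_cds(g, 61)$boundary_dist, 1)   # donor + 1
  expect_equal(map_genomic_to_cds(g, 100)$boundary_dist, 1)  # acceptor - 1
  expect_equal(map_genomic_to_cds(g, 80)$boundary_dist, 20)
  expect_equal(map_genomic_to_cds(g, 1)$cds_offset, 1)       # first CDS base
})

test_that("CDS offsets convert to residue and codon position", {
  expect_equal(cds_offset_to_residue(1), data.frame(residue = 1,
                                                    codon_pos = 1))
  expect_equal(cds_offset_to_residue(3), data.frame(residue = 1,
                                                    codon_pos = 3))
  # offset 2297 is codon position 2 of residue 766
  expect_equal(cds_offset_to_residue(2297),
               data.frame(residue = 766, codon_pos = 2))
  expect_error(cds_offset_to_residue(0), ">= 1")
})

test_that("effect annotation classifies coding, splice and intergenic SNPs", {
  tl <- toy_locus()
  rec <- data.frame(
    chrom = "chrT",
    pos = c(9, 13, 15, 22, 18, 2),
    ref = c("C", "T", "T", "A", "G", "A"),
    alt = c("T", "C", "G", "T", "C", "G"))
  ann <- annotate_effect(rec, list(tl$model), tl$sequences)
  # C>T at codon position 2 of TCT (Ser) -> TTT: the S-to-F change
  expect_equal(ann$effect[1], "nonsynonymous")
  expect_equal(ann$aa_ref[1], "S")
  expect_equal(ann$aa_alt[1], "F")
  expect_equal(ann$aa_pos[1], 2)
  # T>C at codon position 3 of GCT (Ala) -> GCC: synonymous
  expect_equal(ann$effect[2], "synonymous")
  # intronic SNPs within 2 bp of a donor/acceptor are splicing
  expect_equal(ann$effect[3], "splicing")
  expect_equal(ann$effect[4], "splicing")
  expect_equal(ann$effect[5], "intronic")
  expect_equal(ann$effect[6], "intergenic")
  expect_true(is.na(ann$aa_pos[3]))

  # stop gain: GGA -> TGA at codon 4 position 1 (genomic 24)
  stop_rec <- data.frame(chrom = "chrT", pos = 24, ref = "G", alt = "T")
  expect_equal(annotate_effect(stop_rec, list(tl$model),
                               tl$sequences)$effect, "stop_gain")
  # stop loss: TAA -> CAA at codon 5 position 1 (genomic 27)
  sl <- data.frame(chrom = "chrT", pos = 27, ref = "T", alt = "C")
  expect_equal(annotate_effect(sl, list(tl$model), tl$sequences)$effect,
               "stop_loss")

  # reference mismatch is a data-consistency error
  bad <- data.frame(chrom = "chrT", pos = 9, ref = "G", alt = "A")
  expect_error(annotate_effect(bad, list(tl$model), tl$sequences),
               "reference mismatch")
})

test_that("annotation is strand-consistent under reverse complement", {
  tl <- toy_locus()
  rec <- data.frame(chrom = "chrT",
                    pos = c(9, 13, 15, 24),
                    ref = c("C", "T", "T", "G"),
                    alt = c("T", "C", "G", "T"))
  ann_plus <- annotate_effect(rec, list(tl$model), tl$sequences)
  mir <- mirror_locus(tl$sequences, tl$model, rec)
  ann_minus <- annotate_effect(mir$records, list(mir$model), mir$sequences)
  expect_equal(ann_minus$effect, ann_plus$effect)
  expect_equal(ann_minus$aa_ref, ann_plus$aa_ref)
  expect_equal(ann_minus$aa_pos, ann_plus$aa_pos)
  expect_equal(ann_minus$aa_alt, ann_plus$aa_alt)
})

test_that("translate_cds follows the standard code and stop conventions", {
  expect_equal(translate_cds("ATGTAA"), "M")
  expect_equal(translate_cds("ATGTCTGCTGGATAA"), "MSAG")
  expect_error(translate_cds("ATGTA"), "multiple of 3")
  expect_error(translate_cds("ATGTAAGGG"), "internal stop")
  expect_equal(translate_cds("ATGTAAGGG", truncate_at_stop = TRUE), "M")
  expect_error(translate_cds("ATGNNNTAA"), "invalid codon")

  # a 2,715 bp CDS with a terminal stop encodes 904 residues
  set.seed(42)
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  cds <- paste(c(sample(sense, 904, replace = TRUE), "TAA"), collapse = "")
  expect_equal(nchar(cds), 2715)
  expect_equal(nchar(translate_cds(cds)), 904)

  # random 300-codon CDS agrees with an independent translation oracle
  cds300 <- paste(c(sample(sense, 299, replace = TRUE), "TGA"),
                  collapse = "")
  oracle <- as.character(Biostrings::translate(Biostrings::DNAString(cds300)))
  oracle <- sub("\\*$", "", oracle)
  expect_equal(translate_cds(cds300), oracle)
})

test_that("EMS typicality is exactly the G>A / C>T rule", {
  expect_true(ems_typical("C", "T"))
  expect_true(ems_typical("G", "A"))
  expect_false(ems_typical("A", "C"))
  expect_false(ems_typical("G", "T"))
  expect_false(ems_typical("T", "C"))
  # a six-variant candidate list with one G>T transversion flags five
  ref <- c("G", "G", "C", "C", "C", "G")
  alt <- c("A", "T", "T", "T", "T", "A")
  expect_equal(sum(ems_typical(ref, alt)), 5)
})
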
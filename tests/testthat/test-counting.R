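test_that("VCF import keeps biallelic SNPs and tallies the rest", {
  dir <- withr::local_tempdir()
  vcf <- write_fixture_vcf(dir)
  snps <- read_snp_variants(vcf)
  expect_equal(length(snps), 6)               # indel + multiallelic dropped
  expect_equal(attr(snps, "n_skipped"), 2)
  expect_true(all(S4Vectors::mcols(snps)$ref %in% c("A", "C", "G", "T")))
  expect_true(all(S4Vectors::mcols(snps)$ref != S4Vectors::mcols(snps)$alt))
})

test_that("reference masking replaces exactly the SNP bases with N", {
  dir <- withr::local_tempdir()
  fa <- write_fixture_fasta(dir)
  out <- file.path(dir, "masked.fa")

  ## empty variant list: output sequence identical to input
  empty <- GenomicRanges::GRanges()
  mask_reference(fa, empty, out)
  expect_identical(as.character(Biostrings::readDNAStringSet(out)),
                   as.character(Biostrings::readDNAStringSet(fa)))

  ## one SNP at position 5 of a 10 bp contig: one N at 0-based offset 4
  mini <- file.path(dir, "mini.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(ctg = "ACGTACGTAC")), mini)
  v <- GenomicRanges::GRanges("ctg", IRanges::IRanges(5, 5))
  mask_reference(mini, v, out)
  masked <- as.character(Biostrings::readDNAStringSet(out))
  expect_equal(masked, c(ctg = "ACGTNCGTAC"))

  ## k SNPs introduce exactly k Ns, all other bases byte-identical
  vcf <- write_fixture_vcf(dir)
  snps <- read_snp_variants(vcf)
  mask_reference(fa, snps, out)
  orig <- as.character(Biostrings::readDNAStringSet(fa))
  got <- as.character(Biostrings::readDNAStringSet(out))
  n_added <- sum(vapply(strsplit(got, ""), function(x) sum(x == "N"), 0)) -
    sum(vapply(strsplit(orig, ""), function(x) sum(x == "N"), 0))
  expect_equal(n_added, length(snps))
  same <- mapply(function(a, b) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    all(av[bv != "N"] == bv[bv != "N"])
  }, orig, got)
  expect_true(all(same))

  ## out-of-bounds variant names the offender
  bad <- GenomicRanges::GRanges("ctg", IRanges::IRanges(99, 99))
  expect_error(mask_reference(mini, bad, out), "ctg:99")
})

test_that("allele counting follows the pseudo-replication rules", {
  dir <- withr::local_tempdir()
  genome <- fixture_genome()
  snp_tab <- fixture_snps(genome)
  vcf <- write_fixture_vcf(dir, snp_tab)
  rs <- fixture_reads(genome, snp_tab)
  bam <- write_fixture_bam(dir, rs)
  variants <- read_snp_variants(vcf)
  got <- count_snp_alleles(bam, variants)

  ## align rows with the fixture SNP table
  key <- paste(got$chrom, got$pos)
  got <- got[match(paste(snp_tab$chrom, snp_tab$pos), key), ]

  ## the multi-SNP read counted once, at its leftmost SNP (s1, ref)
  ## fixture bookkeeping: s1 gets 6 bulk ref + the multi-SNP read
  expect_equal(got$ref_count[snp_tab$id == "s1"], 7)
  ## the phred-19 base at s1 was skipped; that read counted at s2 instead
  expect_equal(got$alt_count[snp_tab$id == "s2"], 1)
  ## a read whose only SNP base is low-quality contributes nothing
  expect_equal(got$n_lowqual[snp_tab$id == "s3"], 1)
  ## overlapping mates contribute a single observation at s4
  expect_equal(got$ref_count[snp_tab$id == "s4"], 2 + 1)
  ## multimapper and non-allelic base at s6 are excluded from allele counts
  expect_equal(got$ref_count[snp_tab$id == "s6"], 4)
  expect_equal(got$alt_count[snp_tab$id == "s6"], 3)
  expect_equal(got$n_other[snp_tab$id == "s6"], 1)

  ## full brute-force re-scan oracle over every fixture read
  oracle <- oracle_snp_counts(rs$reads, snp_tab)
  expect_equal(got$ref_count, oracle$ref_count)
  expect_equal(got$alt_count, oracle$alt_count)

  ## pseudo-replication guard: no fragment counted twice
  n_frags <- length(unique(vapply(rs$reads, `[[`, "", "qname")))
  expect_lte(sum(got$ref_count + got$alt_count), n_frags)

  ## disabling the unique filter admits the NH=2 read
  got_all <- count_snp_alleles(bam, variants, unique_only = FALSE)
  expect_equal(sum(got_all$ref_count + got_all$alt_count),
               sum(got$ref_count + got$alt_count) + 1)

  ## contig mismatch is reported
  odd <- GenomicRanges::GRanges("chrX", IRanges::IRanges(5, 5))
  S4Vectors::mcols(odd)$ref <- "A"; S4Vectors::mcols(odd)$alt <- "C"
  expect_error(count_snp_alleles(bam, odd), "chrX")
  expect_error(count_snp_alleles(file.path(dir, "absent.bam"), variants),
               "not found")
})

test_that("gene aggregation sums SNPs, maps parents and drops orphans", {
  dir <- withr::local_tempdir()
  gff <- write_fixture_gff(dir)
  genes <- read_gene_models(gff)
  expect_setequal(names(genes), c("geneA", "geneB", "geneC"))

  snp_counts <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    pos = c(21L, 101L, 150L, 70L, 50L),
    ref = "A", alt = "C",
    ref_count = c(10L, 4L, 3L, 7L, 6L),
    alt_count = c(5L, 1L, 5L, 2L, 2L),
    n_lowqual = 0L, n_other = 0L
  )
  class(snp_counts) <- c("snp_allele_counts", "data.frame")

  ## mother carries the reference allele: additivity over a gene's SNPs
  byref <- aggregate_gene_counts(snp_counts, genes, mother_allele = "ref")
  expect_equal(byref$maternal[byref$gene_id == "geneA"], 14)  # 10 + 4
  expect_equal(byref$paternal[byref$gene_id == "geneA"], 6)   # 5 + 1
  expect_equal(byref$maternal[byref$gene_id == "geneB"], 3)
  ## the intronic SNP at chr1:70 lands in no exon: dropped and tallied
  expect_equal(attr(byref, "n_intergenic"), 1)
  ## its 9 reads appear in no gene
  expect_equal(sum(byref$maternal) + sum(byref$paternal),
               sum(snp_counts$ref_count + snp_counts$alt_count) - 9)

  ## reciprocal cross: swapping the parental map swaps the columns exactly
  byalt <- aggregate_gene_counts(snp_counts, genes, mother_allele = "alt")
  expect_equal(byalt$maternal, byref$paternal)
  expect_equal(byalt$paternal, byref$maternal)

  ## combining two reciprocal crosses into one table
  tab <- combine_crosses(list(byref, byalt))
  expect_equal(n_crosses(tab), 2L)
  expect_equal(unname(maternal_counts(tab)[, 1]),
               unname(paternal_counts(tab)[, 2]))
})

test_that("the full counting pipeline runs end to end on the fixture", {
  dir <- withr::local_tempdir()
  genome <- fixture_genome()
  snp_tab <- fixture_snps(genome)
  vcf <- write_fixture_vcf(dir, snp_tab)
  gff <- write_fixture_gff(dir)
  bam <- write_fixture_bam(dir, fixture_reads(genome, snp_tab))
  per_gene <- count_cross(bam, vcf, gff, mother_allele = "ref")
  expect_setequal(per_gene$gene_id, c("geneA", "geneB", "geneC"))
  ## geneA: s1 (7 ref, 2 alt) + s2 (1 ref, 1 alt) + s3 (3 ref, 4 alt)
  expect_equal(per_gene$maternal[per_gene$gene_id == "geneA"], 11)
  expect_equal(per_gene$paternal[per_gene$gene_id == "geneA"], 7)
})
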
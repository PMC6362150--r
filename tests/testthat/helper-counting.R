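## In-code fixture for the counting stage: a 2-contig genome, biallelic
## SNPs (plus an indel and a multiallelic record that must be skipped),
## two genes on chr1 and one on chr2, and a small set of reads with known
## alleles written as SAM and converted to indexed BAM.

fixture_genome <- function() {
  set.seed(4242)
  seqs <- c(
    chr1 = paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                 collapse = ""),
    chr2 = paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                 collapse = "")
  )
  Biostrings::DNAStringSet(seqs)
}

## SNP table: positions are 1-based; alt is a base different from ref
fixture_snps <- function(genome = fixture_genome()) {
  pos <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    pos = c(21L, 41L, 101L, 150L, 70L, 50L),
    id = c("s1", "s2", "s3", "s4", "s5_intron", "s6"),
    stringsAsFactors = FALSE
  )
  pos$ref <- vapply(seq_len(nrow(pos)), function(i) {
    as.character(Biostrings::subseq(genome[[pos$chrom[i]]],
                                    pos$pos[i], pos$pos[i]))
  }, character(1))
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  pos$alt <- unname(rot[pos$ref])
  pos
}

write_fixture_fasta <- function(dir, genome = fixture_genome()) {
  path <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(genome, path)
  path
}

write_fixture_vcf <- function(dir, snps = fixture_snps(),
                              extra_records = TRUE) {
  path <- file.path(dir, "snps.vcf")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=200>",
    "##contig=<ID=chr2,length=100>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t%s\t%s\t%s\t50\tPASS\t.",
            snps$chrom, snps$pos, snps$id, snps$ref, snps$alt)
  )
  if (extra_records) {
    lines <- c(lines,
               "chr1\t30\tindel1\tAC\tA\t50\tPASS\t.",
               "chr1\t160\tmulti1\tA\tC,G\t50\tPASS\t.")
  }
  writeLines(lines, path)
  path
}

write_fixture_gff <- function(dir) {
  path <- file.path(dir, "genes.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t11\t130\t.\t+\t.\tID=geneA",
    "chr1\ttest\texon\t11\t60\t.\t+\t.\tParent=geneA;gene_id=geneA",
    "chr1\ttest\texon\t81\t130\t.\t+\t.\tParent=geneA;gene_id=geneA",
    "chr1\ttest\tgene\t141\t190\t.\t-\t.\tID=geneB",
    "chr1\ttest\texon\t141\t190\t.\t-\t.\tParent=geneB;gene_id=geneB",
    "chr2\ttest\tgene\t11\t90\t.\t+\t.\tID=geneC",
    "chr2\ttest\texon\t11\t90\t.\t+\t.\tParent=geneC;gene_id=geneC"
  ), path)
  path
}

## read sequence copied from the genome with chosen alleles substituted
fixture_read_seq <- function(genome, chrom, start, len, subst = list()) {
  s <- as.character(Biostrings::subseq(genome[[chrom]], start,
                                       start + len - 1L))
  for (sub in subst) {
    at <- sub$pos - start + 1L
    substr(s, at, at) <- sub$base
  }
  s
}

## Build the read set. Returns list(sam_lines, reads) where `reads` keeps
## the per-read metadata the brute-force oracle needs.
fixture_reads <- function(genome = fixture_genome(),
                          snps = fixture_snps()) {
  snp_at <- function(id) snps[snps$id == id, ]
  q_hi <- function(len) strrep("I", len)          # phred 40
  reads <- list()
  add <- function(qname, chrom, pos, cigar, seq, qual, flag = 0L,
                  mapq = 60L, nh = 1L, rnext = "*", pnext = 0L) {
    reads[[length(reads) + 1L]] <<- list(
      qname = qname, flag = flag, chrom = chrom, pos = pos, mapq = mapq,
      cigar = cigar, seq = seq, qual = qual, nh = nh,
      rnext = rnext, pnext = pnext)
  }

  ## multi-SNP read: covers s1 (21) and s2 (41), both high quality, carries
  ## ref at s1 and alt at s2 -> must count once, at s1 (leftmost)
  s1 <- snp_at("s1"); s2 <- snp_at("s2")
  seq <- fixture_read_seq(genome, "chr1", 10L, 40L,
                          list(list(pos = s1$pos, base = s1$ref),
                               list(pos = s2$pos, base = s2$alt)))
  add("multi_snp", "chr1", 10L, "40M", seq, q_hi(40))

  ## low-quality base at s1 (phred 19), high at s2 -> counts at s2 (alt)
  seq <- fixture_read_seq(genome, "chr1", 15L, 40L,
                          list(list(pos = s1$pos, base = s1$alt),
                               list(pos = s2$pos, base = s2$alt)))
  qual <- q_hi(40)
  substr(qual, s1$pos - 15L + 1L, s1$pos - 15L + 1L) <- "4"  # phred 19
  add("lowqual_s1", "chr1", 15L, "40M", seq, qual)

  ## read whose only SNP base is phred 19 -> contributes nothing
  s3 <- snp_at("s3")
  seq <- fixture_read_seq(genome, "chr1", 90L, 40L,
                          list(list(pos = s3$pos, base = s3$ref)))
  qual <- q_hi(40)
  substr(qual, s3$pos - 90L + 1L, s3$pos - 90L + 1L) <- "4"
  add("lowqual_only", "chr1", 90L, "40M", seq, qual)

  ## multimapper (NH = 2) over s6 -> excluded under unique_only
  s6 <- snp_at("s6")
  seq <- fixture_read_seq(genome, "chr2", 40L, 40L,
                          list(list(pos = s6$pos, base = s6$alt)))
  add("multimap", "chr2", 40L, "40M", seq, q_hi(40), mapq = 1L, nh = 2L)

  ## base matching neither allele at s6 -> tallied as "other"
  other <- setdiff(c("A", "C", "G", "T"), c(s6$ref, s6$alt))[1]
  seq <- fixture_read_seq(genome, "chr2", 35L, 40L,
                          list(list(pos = s6$pos, base = other)))
  add("other_base", "chr2", 35L, "40M", seq, q_hi(40))

  ## proper pair whose mates both cover s4 -> one observation (ref)
  s4 <- snp_at("s4")
  seq1 <- fixture_read_seq(genome, "chr1", 130L, 40L,
                           list(list(pos = s4$pos, base = s4$ref)))
  seq2 <- fixture_read_seq(genome, "chr1", 140L, 40L,
                           list(list(pos = s4$pos, base = s4$ref)))
  add("pair1", "chr1", 130L, "40M", seq1, q_hi(40), flag = 99L,
      rnext = "=", pnext = 140L)
  add("pair1", "chr1", 140L, "40M", seq2, q_hi(40), flag = 147L,
      rnext = "=", pnext = 130L)

  ## spliced read: 10M40N10M starting at 35 covers s2 (41) in its first
  ## block and spans the s5 intron position inside the N gap
  seq <- fixture_read_seq(genome, "chr1", 35L, 10L,
                          list(list(pos = s2$pos, base = s2$ref)))
  seq <- paste0(seq, fixture_read_seq(genome, "chr1", 85L, 10L))
  add("spliced", "chr1", 35L, "10M40N10M", seq, q_hi(20))

  ## bulk reads with known alleles for the aggregation totals
  set.seed(99)
  bulk <- list(
    list(id = "s1", n_ref = 6L, n_alt = 2L, start = 5L),
    list(id = "s3", n_ref = 3L, n_alt = 4L, start = 95L),
    list(id = "s4", n_ref = 2L, n_alt = 5L, start = 145L),
    list(id = "s5_intron", n_ref = 3L, n_alt = 1L, start = 55L),
    list(id = "s6", n_ref = 4L, n_alt = 3L, start = 30L)
  )
  for (b in bulk) {
    sn <- snp_at(b$id)
    for (i in seq_len(b$n_ref + b$n_alt)) {
      allele <- if (i <= b$n_ref) sn$ref else sn$alt
      start <- b$start + (i %% 3L)  # wiggle starts, keep the SNP covered
      seq <- fixture_read_seq(genome, sn$chrom, start, 40L,
                              list(list(pos = sn$pos, base = allele)))
      add(sprintf("bulk_%s_%02d", b$id, i), sn$chrom, start, "40M",
          seq, q_hi(40))
    }
  }

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              "@SQ\tSN:chr1\tLN:200",
              "@SQ\tSN:chr2\tLN:100")
  body <- vapply(reads, function(r) {
    paste(r$qname, r$flag, r$chrom, r$pos, r$mapq, r$cigar,
          r$rnext, r$pnext, 0L, r$seq, r$qual,
          paste0("NH:i:", r$nh), sep = "\t")
  }, character(1))
  list(sam = c(header, body), reads = reads)
}

write_fixture_bam <- function(dir, rs = fixture_reads()) {
  sam_path <- file.path(dir, "reads.sam")
  writeLines(rs$sam, sam_path)
  bam <- Rsamtools::asBam(sam_path, file.path(dir, "reads"),
                          overwrite = TRUE, indexDestination = TRUE)
  bam
}

## Independent brute-force re-scan of the fixture reads: same counting
## rules, implemented directly on the read list with a tiny CIGAR walker.
oracle_snp_counts <- function(reads, snps, min_baseq = 20,
                              unique_only = TRUE) {
  covered_base <- function(r, pos) {
    ## returns c(base, phred) when pos is inside an M block, else NULL
    ops <- regmatches(r$cigar, gregexpr("\\d+[MIDNSHP=X]", r$cigar))[[1]]
    ref <- r$pos; query <- 1L
    for (op in ops) {
      n <- as.integer(sub("[A-Z=]$", "", op))
      type <- sub("^\\d+", "", op)
      if (type %in% c("M", "=", "X")) {
        if (pos >= ref && pos < ref + n) {
          at <- query + (pos - ref)
          return(c(substr(r$seq, at, at),
                   utf8ToInt(substr(r$qual, at, at)) - 33L))
        }
        ref <- ref + n; query <- query + n
      } else if (type %in% c("D", "N")) {
        ref <- ref + n
      } else if (type %in% c("I", "S")) {
        query <- query + n
      }
    }
    NULL
  }
  ref_count <- alt_count <- setNames(integer(nrow(snps)), snps$id)
  frags <- split(reads, vapply(reads, `[[`, "", "qname"))
  for (frag in frags) {
    if (unique_only && any(vapply(frag, `[[`, 0L, "nh") > 1L)) next
    obs <- list()
    for (r in frag) {
      for (i in seq_len(nrow(snps))) {
        if (snps$chrom[i] != r$chrom) next
        bq <- covered_base(r, snps$pos[i])
        if (is.null(bq)) next
        base <- bq[1]; q <- as.integer(bq[2])
        if (q < min_baseq) next
        if (base != snps$ref[i] && base != snps$alt[i]) next
        obs[[length(obs) + 1L]] <- list(snp = i, pos = snps$pos[i],
                                        base = base)
      }
    }
    if (length(obs) == 0) next
    pos <- vapply(obs, `[[`, 0L, "pos")
    pick <- obs[[which.min(pos)]]
    if (pick$base == snps$ref[pick$snp])
      ref_count[pick$snp] <- ref_count[pick$snp] + 1L
    else
      alt_count[pick$snp] <- alt_count[pick$snp] + 1L
  }
  data.frame(id = snps$id, ref_count = unname(ref_count),
             alt_count = unname(alt_count), stringsAsFactors = FALSE)
}
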
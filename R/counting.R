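## Allelic read counting at parental SNPs.
##
## Coordinate conventions: VCF and GFF3 are 1-based on disk and are read
## with Bioconductor importers that keep 1-based closed intervals
## (GRanges); all arithmetic below stays in that representation.

#' Read biallelic SNPs from a VCF
#'
#' Keeps biallelic single-nucleotide records with REF and ALT in
#' {A, C, G, T}; indels and multiallelic records are skipped and tallied.
#'
#' @param vcf_path VCF file (plain or bgzipped).
#' @return GRanges with metadata columns `ref` and `alt` (single bases) and
#'   attribute `n_skipped` (number of non-biallelic-SNP records dropped).
#' @export
read_snp_variants <- function(vcf_path) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  vcf <- VariantAnnotation::readVcf(vcf_path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(altl)
  alt <- rep(NA_character_, length(rr))
  alt[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  ok <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt) & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  out <- GenomicRanges::granges(rr)[ok]
  S4Vectors::mcols(out)$ref <- ref[ok]
  S4Vectors::mcols(out)$alt <- alt[ok]
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Mask SNP positions in a reference genome
#'
#' Writes a copy of the genome FASTA in which the base at every SNP
#' position is replaced by `N`, so reads carrying either parental allele
#' map without reference bias. All other bases are untouched.
#'
#' @param genome_path input FASTA.
#' @param variants GRanges of SNPs (from [read_snp_variants()]).
#' @param out_path output FASTA path.
#' @return `out_path`, invisibly.
#' @export
mask_reference <- function(genome_path, variants, out_path) {
  genome <- Biostrings::readDNAStringSet(genome_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chrom <- as.character(GenomicRanges::seqnames(variants))
  pos <- GenomicRanges::start(variants)
  missing_chr <- setdiff(unique(chrom), names(genome))
  if (length(missing_chr) > 0)
    stop("variant chromosome(s) absent from the genome: ",
         paste(missing_chr, collapse = ", "))
  oob <- pos > Biostrings::width(genome)[match(chrom, names(genome))] | pos < 1
  if (any(oob)) {
    i <- which(oob)[1]
    stop("variant out of chromosome bounds: ", chrom[i], ":", pos[i])
  }
  for (ch in unique(chrom)) {
    at <- pos[chrom == ch]
    genome[[ch]] <- Biostrings::replaceLetterAt(
      genome[[ch]], at, rep("N", length(at)))
  }
  Biostrings::writeXStringSet(genome, out_path)
  invisible(out_path)
}

#' Count allelic reads at SNP positions
#'
#' Tallies, for every SNP, the reads supporting the reference and the
#' alternate allele, under the counting rules that prevent
#' pseudo-replication and low-quality calls: only uniquely mapped reads
#' are used (NH tag == 1 when present, otherwise MAPQ >= `min_mapq`);
#' bases with phred quality below `min_base_quality` at the SNP are
#' ignored (tallied as `n_lowqual`); bases matching neither allele are
#' tallied as `n_other`; and each read -- or read pair, so that
#' overlapping mates cannot double-count -- contributes at most one allele
#' observation, at its leftmost SNP with a usable base.
#'
#' @param bam_path coordinate-sorted, indexed BAM.
#' @param variants GRanges of biallelic SNPs with `ref`/`alt` metadata.
#' @param min_base_quality minimum phred base quality at the SNP
#'   (default 20; a phred-19 base is excluded).
#' @param min_mapq MAPQ threshold used when the NH tag is absent.
#' @param unique_only drop multi-mapping reads (default TRUE).
#' @param dedup drop reads flagged as PCR/optical duplicates
#'   (default FALSE).
#' @return data.frame (`snp_allele_counts`) with one row per SNP: `chrom`,
#'   `pos`, `ref`, `alt`, `ref_count`, `alt_count`, `n_lowqual`,
#'   `n_other`.
#' @export
count_snp_alleles <- function(bam_path, variants, min_base_quality = 20,
                              min_mapq = 20, unique_only = TRUE,
                              dedup = FALSE) {
  if (!file.exists(bam_path)) stop("BAM not found: ", bam_path)
  if (!file.exists(paste0(bam_path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam_path)))
    stop("BAM index (.bai) not found for: ", bam_path)
  bam_chroms <- names(Rsamtools::scanBamHeader(bam_path)[[1]]$targets)
  snp_chroms <- unique(as.character(GenomicRanges::seqnames(variants)))
  missing_chr <- setdiff(snp_chroms, bam_chroms)
  if (length(missing_chr) > 0)
    stop("contig name mismatch between BAM and variants: ",
         paste(missing_chr, collapse = ", "))

  param <- Rsamtools::ScanBamParam(
    what = c("qname", "mapq", "seq", "qual"),
    tag = "NH",
    which = GenomicRanges::reduce(variants),
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE,
      isDuplicate = if (dedup) FALSE else NA
    )
  )
  aln <- GenomicAlignments::readGAlignments(bam_path, param = param,
                                            use.names = FALSE)
  ## the 'which' windows can return a read more than once; deduplicate by
  ## (qname, position) so each alignment is considered exactly once
  md <- S4Vectors::mcols(aln)
  key <- paste(md$qname, GenomicRanges::seqnames(aln),
               GenomicRanges::start(aln), GenomicAlignments::cigar(aln))
  aln <- aln[!duplicated(key)]
  md <- S4Vectors::mcols(aln)

  if (unique_only && length(aln) > 0) {
    nh <- md$NH
    uniq <- ifelse(!is.na(nh), nh == 1L, md$mapq >= min_mapq)
    aln <- aln[uniq]
    md <- S4Vectors::mcols(aln)
  }

  n_snp <- length(variants)
  ref_count <- alt_count <- n_lowqual <- n_other <- integer(n_snp)
  if (length(aln) > 0) {
    ov <- GenomicRanges::findOverlaps(variants, aln)
    if (length(ov) > 0) {
      snp_i <- S4Vectors::queryHits(ov)
      read_i <- S4Vectors::subjectHits(ov)
      ## lay read sequence and qualities onto reference coordinates
      laid_seq <- GenomicAlignments::sequenceLayer(
        md$seq, GenomicAlignments::cigar(aln))
      laid_qual <- GenomicAlignments::sequenceLayer(
        Biostrings::BStringSet(md$qual), GenomicAlignments::cigar(aln))
      offs <- GenomicRanges::start(variants)[snp_i] -
        GenomicRanges::start(aln)[read_i] + 1L
      base <- substr(as.character(laid_seq[read_i]), offs, offs)
      qual <- utf8ToInt(paste(substr(as.character(laid_qual[read_i]),
                                     offs, offs), collapse = "")) - 33L
      ref <- S4Vectors::mcols(variants)$ref[snp_i]
      alt <- S4Vectors::mcols(variants)$alt[snp_i]
      usable <- qual >= min_base_quality & (base == ref | base == alt)
      low <- qual < min_base_quality
      other <- !low & !usable

      ## one observation per fragment: among usable (read, SNP) pairs of a
      ## fragment, keep the leftmost SNP; overlapping mates at that SNP
      ## count once (first by coordinate)
      frag <- md$qname[read_i]
      cand <- which(usable)
      ord <- cand[order(frag[cand],
                        GenomicRanges::start(variants)[snp_i[cand]],
                        read_i[cand])]
      chosen <- ord[!duplicated(frag[ord])]
      is_ref <- base[chosen] == ref[chosen]
      ref_tab <- table(factor(snp_i[chosen][is_ref], levels = seq_len(n_snp)))
      alt_tab <- table(factor(snp_i[chosen][!is_ref], levels = seq_len(n_snp)))
      ref_count <- as.integer(ref_tab)
      alt_count <- as.integer(alt_tab)
      n_lowqual <- as.integer(table(factor(snp_i[low], levels = seq_len(n_snp))))
      n_other <- as.integer(table(factor(snp_i[other], levels = seq_len(n_snp))))
    }
  }
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(variants)),
    pos = GenomicRanges::start(variants),
    ref = S4Vectors::mcols(variants)$ref,
    alt = S4Vectors::mcols(variants)$alt,
    ref_count = ref_count, alt_count = alt_count,
    n_lowqual = n_lowqual, n_other = n_other,
    stringsAsFactors = FALSE
  )
  class(out) <- c("snp_allele_counts", "data.frame")
  out
}

#' Read gene models from a GFF3 file
#'
#' Exon intervals are grouped per gene (via the exons' `gene_id`
#' attribute, or by following `Parent` through mRNA records) and merged;
#' genes without exon records fall back to their full gene range.
#'
#' @param gff_path GFF3 file.
#' @return named GRangesList of merged exon ranges per gene.
#' @export
read_gene_models <- function(gff_path) {
  if (!file.exists(gff_path)) stop("GFF not found: ", gff_path)
  gff <- rtracklayer::import(gff_path)
  type <- as.character(gff$type)
  exons <- gff[type == "exon"]
  gene_of <- function(x) {
    gid <- S4Vectors::mcols(x)$gene_id
    if (!is.null(gid) && !all(is.na(gid))) return(as.character(gid))
    parent <- as.character(unlist(S4Vectors::mcols(x)$Parent))
    tx <- gff[type %in% c("mRNA", "transcript")]
    tx_gene <- as.character(unlist(S4Vectors::mcols(tx)$Parent))
    names(tx_gene) <- S4Vectors::mcols(tx)$ID
    ifelse(parent %in% names(tx_gene), tx_gene[parent], parent)
  }
  if (length(exons) > 0) {
    by_gene <- GenomicRanges::split(GenomicRanges::granges(exons),
                                    gene_of(exons))
  } else {
    genes <- gff[type == "gene"]
    if (length(genes) == 0) stop("no exon or gene records in ", gff_path)
    by_gene <- GenomicRanges::split(GenomicRanges::granges(genes),
                                    as.character(S4Vectors::mcols(genes)$ID))
  }
  GenomicRanges::reduce(by_gene)
}

#' Aggregate SNP allele counts into per-gene parental counts
#'
#' Sums SNP-level allele counts within each gene's exons and converts
#' ref/alt to maternal/paternal according to which parent carries the
#' reference allele in the given cross. SNPs overlapping no gene, or more
#' than one gene, are dropped and tallied.
#'
#' @param snp_counts a `snp_allele_counts` data.frame.
#' @param gene_models GRangesList from [read_gene_models()].
#' @param mother_allele `"ref"` if the maternal parent of this cross
#'   carries the reference allele, `"alt"` otherwise. Swapping this value
#'   (the reciprocal cross) swaps the maternal/paternal columns exactly.
#' @return data.frame with `gene_id`, `maternal`, `paternal`; attributes
#'   `n_intergenic` and `n_ambiguous` count dropped SNPs.
#' @export
aggregate_gene_counts <- function(snp_counts, gene_models,
                                  mother_allele = c("ref", "alt")) {
  mother_allele <- match.arg(mother_allele)
  stopifnot(inherits(snp_counts, "snp_allele_counts"))
  snp_gr <- GenomicRanges::GRanges(
    snp_counts$chrom,
    IRanges::IRanges(snp_counts$pos, width = 1L))
  ov <- GenomicRanges::findOverlaps(snp_gr, gene_models)
  hits_per_snp <- tabulate(S4Vectors::queryHits(ov), nbins = length(snp_gr))
  ambiguous <- hits_per_snp > 1L
  intergenic <- hits_per_snp == 0L
  use <- S4Vectors::queryHits(ov)[!ambiguous[S4Vectors::queryHits(ov)]]
  gene <- names(gene_models)[S4Vectors::subjectHits(ov)][
    !ambiguous[S4Vectors::queryHits(ov)]]
  ref_sum <- tapply(snp_counts$ref_count[use], gene, sum)
  alt_sum <- tapply(snp_counts$alt_count[use], gene, sum)
  gid <- sort(unique(gene))
  maternal <- if (mother_allele == "ref") ref_sum[gid] else alt_sum[gid]
  paternal <- if (mother_allele == "ref") alt_sum[gid] else ref_sum[gid]
  out <- data.frame(gene_id = gid,
                    maternal = as.integer(maternal),
                    paternal = as.integer(paternal),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_intergenic") <- sum(intergenic)
  attr(out, "n_ambiguous") <- sum(ambiguous)
  out
}

#' Combine per-cross gene counts into an allelic count table
#'
#' @param cross_counts named list of data.frames from
#'   [aggregate_gene_counts()], one per reciprocal cross, in cross order.
#'   Genes absent from a cross get zero counts.
#' @return an [allelic_counts()] table.
#' @export
combine_crosses <- function(cross_counts) {
  stopifnot(length(cross_counts) >= 1)
  genes <- sort(unique(unlist(lapply(cross_counts, `[[`, "gene_id"))))
  k <- length(cross_counts)
  m <- p <- matrix(0L, length(genes), k)
  for (c in seq_len(k)) {
    i <- match(cross_counts[[c]]$gene_id, genes)
    m[i, c] <- cross_counts[[c]]$maternal
    p[i, c] <- cross_counts[[c]]$paternal
  }
  allelic_counts(m, p, gene_id = genes)
}

#' Count allelic reads per gene for one cross
#'
#' Convenience wrapper: [read_snp_variants()] + [count_snp_alleles()] +
#' [read_gene_models()] + [aggregate_gene_counts()].
#'
#' @inheritParams count_snp_alleles
#' @param vcf_path biallelic SNP VCF.
#' @param gff_path gene models (GFF3).
#' @param mother_allele see [aggregate_gene_counts()].
#' @return per-gene data.frame as from [aggregate_gene_counts()].
#' @export
count_cross <- function(bam_path, vcf_path, gff_path,
                        mother_allele = c("ref", "alt"),
                        min_base_quality = 20, min_mapq = 20,
                        unique_only = TRUE, dedup = FALSE) {
  variants <- read_snp_variants(vcf_path)
  snp_counts <- count_snp_alleles(bam_path, variants,
                                  min_base_quality = min_base_quality,
                                  min_mapq = min_mapq,
                                  unique_only = unique_only, dedup = dedup)
  genes <- read_gene_models(gff_path)
  aggregate_gene_counts(snp_counts, genes, mother_allele = mother_allele)
}
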
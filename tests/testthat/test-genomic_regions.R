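write_fasta <- function(seqs, path) {
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n),
                                                      seqs[[n]]))), path)
  path
}

gff3_lines <- function(rows) {
  c("##gff-version 3", rows)
}

test_that("load_genome normalizes GFF3 coordinates to 0-based half-open", {
  fa <- tempfile(fileext = ".fasta")
  gff <- tempfile(fileext = ".gff3")
  write_fasta(list(chr1 = random_dna(100, seed = 1)), fa)
  writeLines(gff3_lines(
    "chr1\ttest\tgene\t1\t100\t.\t+\t.\tID=g1"), gff)
  g <- load_genome(fa, gff)
  ft <- g$annotation$features
  expect_equal(ft$start[ft$type == "gene"], 0)
  expect_equal(ft$end[ft$type == "gene"], 100)
})

test_that("annotation errors name the offending record", {
  fa <- tempfile(fileext = ".fasta")
  gff <- tempfile(fileext = ".gff3")
  write_fasta(list(chr1 = random_dna(100, seed = 2)), fa)
  writeLines(gff3_lines(
    "chrZ\ttest\tgene\t1\t50\t.\t+\t.\tID=g1"), gff)
  expect_error(load_genome(fa, gff), "chrZ")

  writeLines(gff3_lines(c(
    "chr1\ttest\tgene\t10\t50\t.\t+\t.\tID=g1",
    "chr1\ttest\texon\t5\t20\t.\t+\t.\tID=g1.e1;Parent=g1")), gff)
  expect_error(load_genome(fa, gff), "outside its parent gene")

  writeLines(gff3_lines(c(
    "chr1\ttest\tgene\t10\t50\t.\t+\t.\tID=g1",
    "chr1\ttest\texon\t12\t20\t.\t+\t.\tID=x.e1;Parent=gX")), gff)
  expect_error(load_genome(fa, gff), "parent gene")
})

test_that("exon Parent chains through mRNA records resolve to the gene", {
  fa <- tempfile(fileext = ".fasta")
  gff <- tempfile(fileext = ".gff3")
  write_fasta(list(chr1 = random_dna(200, seed = 3)), fa)
  writeLines(gff3_lines(c(
    "chr1\ttest\tgene\t11\t150\t.\t-\t.\tID=g1",
    "chr1\ttest\tmRNA\t11\t150\t.\t-\t.\tID=t1;Parent=g1",
    "chr1\ttest\texon\t11\t60\t.\t-\t.\tID=t1.e1;Parent=t1",
    "chr1\ttest\texon\t101\t150\t.\t-\t.\tID=t1.e2;Parent=t1",
    "chr1\ttest\tCDS\t21\t60\t.\t-\t.\tID=t1.c1;Parent=t1")), gff)
  g <- load_genome(fa, gff)
  ft <- g$annotation$features
  expect_true(all(ft$gene_id == "g1"))
  expect_equal(sum(ft$type == "exon"), 2)
  regs <- derive_regions(g)
  expect_equal(regs$intronic$intervals$start, 60)
  expect_equal(regs$intronic$intervals$end, 100)
})

test_that("the minimal GenBank feature-table reader agrees with GFF3", {
  fa <- tempfile(fileext = ".fasta")
  write_fasta(list(plasmid1 = random_dna(300, seed = 4)), fa)
  gb <- tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       plasmid1       300 bp    DNA     linear",
    "FEATURES             Location/Qualifiers",
    "     gene            11..200",
    "                     /gene=\"abcA\"",
    "     CDS             join(11..60,101..200)",
    "                     /gene=\"abcA\"",
    "     exon            11..60",
    "                     /gene=\"abcA\"",
    "     exon            101..200",
    "                     /gene=\"abcA\"",
    "     gene            complement(221..280)",
    "                     /locus_tag=\"orf2\"",
    "     exon            complement(221..280)",
    "                     /locus_tag=\"orf2\"",
    "ORIGIN",
    "//"), gb)
  g <- load_genome(fa, gb)
  ft <- g$annotation$features
  expect_equal(sum(ft$type == "gene"), 2)
  expect_equal(ft$start[ft$type == "gene"], c(10, 220))
  expect_equal(ft$strand[ft$type == "gene"], c("+", "-"))
  ## the joined CDS spans its enclosing range
  expect_equal(ft[ft$type == "CDS", c("start", "end")],
               data.frame(start = 10, end = 200), ignore_attr = TRUE)
  regs <- derive_regions(g)
  expect_equal(regs$intronic$intervals$start, 60)
})

test_that("derive_regions handles degenerate covers", {
  ## one gene covering the whole chromosome with one exon covering the gene
  ann <- genome_annotation(
    data.frame(id = "c", length = 100L),
    data.frame(chrom = "c", start = c(0, 0), end = c(100, 100),
               strand = "+", type = c("gene", "exon"), gene_id = "g1"))
  regs <- derive_regions(ann)
  comp <- region_composition(regs, 100)
  expect_equal(comp$percent[comp$region == "intergenic"], 0)
  expect_equal(comp$percent[comp$region == "intronic"], 0)
  expect_equal(comp$percent[comp$region == "exonic"], 100)

  ## chromosome with no genes at all
  ann2 <- genome_annotation(
    data.frame(id = "c", length = 100L),
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), type = character(0),
               gene_id = character(0)))
  comp2 <- region_composition(derive_regions(ann2), 100)
  expect_equal(comp2$percent[comp2$region == "intergenic"], 100)
  expect_equal(sum(comp2$percent[comp2$region != "intergenic"]), 0)
})

test_that("region labels equal a brute-force per-base oracle", {
  for (seed in c(1, 2, 3)) {
    ann <- random_annotation(chrom_len = 10000L, n_genes = 20L, seed = seed)
    regs <- derive_regions(ann)
    oracle <- oracle_region_masks(ann$chromosomes, ann$features)
    for (cls in c("genic", "exonic", "CDS", "intronic", "intergenic")) {
      got <- region_set_to_mask(regs[[cls]], ann$chromosomes)
      expect_equal(got$chr1, oracle$chr1[[cls]],
                   info = sprintf("class %s seed %d", cls, seed))
    }
    comp <- region_composition(regs, 10000)
    expect_equal(comp$bp[comp$region == "genic"], sum(oracle$chr1$genic))
    expect_equal(comp$percent[comp$region == "genic"] +
                   comp$percent[comp$region == "intergenic"], 100,
                 tolerance = 1e-9)
  }
})

test_that("region_composition validates genome length", {
  ann <- random_annotation(seed = 5)
  expect_error(region_composition(derive_regions(ann), 0), "positive")
  ## gene covering half of a 1000 bp chromosome
  ann2 <- genome_annotation(
    data.frame(id = "c", length = 1000L),
    data.frame(chrom = "c", start = 0L, end = 500L, strand = "+",
               type = "gene", gene_id = "g1"))
  comp <- region_composition(derive_regions(ann2), 1000)
  expect_equal(comp$percent[comp$region == "genic"], 50)
  expect_equal(comp$percent[comp$region == "intergenic"], 50)
})

test_that("extract_sequences follows the orientation policy", {
  seqs <- Biostrings::DNAStringSet(c(c1 = "ACGTAAAA"))
  rs_plus <- strdecomp:::region_set("exonic", data.frame(
    chrom = "c1", start = 0L, end = 4L, strand = "+"))
  expect_equal(as.character(extract_sequences(rs_plus, seqs))[[1]], "ACGT")
  rs_minus <- strdecomp:::region_set("CDS", data.frame(
    chrom = "c1", start = 0L, end = 4L, strand = "-"))
  ## palindromic check: revcomp("ACGT") == "ACGT"
  expect_equal(as.character(extract_sequences(rs_minus, seqs))[[1]], "ACGT")
  seqs2 <- Biostrings::DNAStringSet(c(c1 = "AACTAAAA"))
  rs_minus3 <- strdecomp:::region_set("CDS", data.frame(
    chrom = "c1", start = 0L, end = 3L, strand = "-"))
  expect_equal(as.character(extract_sequences(rs_minus3, seqs2))[[1]], "GTT")
  ## forward policy overrides gene orientation
  expect_equal(as.character(
    extract_sequences(rs_minus3, seqs2, orientation = "forward"))[[1]], "AAC")
  ## intronic regions always come from the forward strand
  rs_intr <- strdecomp:::region_set("intronic", data.frame(
    chrom = "c1", start = 0L, end = 3L, strand = "-"))
  expect_equal(as.character(extract_sequences(rs_intr, seqs2))[[1]], "AAC")
})

test_that("derived regions survive a GFF3 re-emission round trip", {
  cfg <- synthetic_genome_config(chromosomes = c(chrA = 60000L, chrB = 40000L),
                                 gene_density = 150, seed = 9)
  g <- generate_genome(cfg)
  regs <- derive_regions(g)
  gff <- tempfile(fileext = ".gff3")
  fa <- tempfile(fileext = ".fasta")
  annotation_to_gff3(g, gff)
  Biostrings::writeXStringSet(g$sequences, fa)
  g2 <- load_genome(fa, gff)
  regs2 <- derive_regions(g2)
  for (cls in names(regs))
    expect_equal(regs[[cls]]$intervals[, c("chrom", "start", "end")],
                 regs2[[cls]]$intervals[, c("chrom", "start", "end")],
                 info = cls)
})

test_that("regions export to BED as 0-based half-open", {
  ann <- genome_annotation(
    data.frame(id = "c", length = 1000L),
    data.frame(chrom = "c", start = 100L, end = 300L, strand = "-",
               type = "gene", gene_id = "g1"))
  regs <- derive_regions(ann)
  bed <- tempfile(fileext = ".bed")
  regions_to_bed(regs$intergenic, bed)
  df <- read.table(bed, sep = "\t")
  expect_equal(df$V2, c(0, 300))
  expect_equal(df$V3, c(100, 1000))
})
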
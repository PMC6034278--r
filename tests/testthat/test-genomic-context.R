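# Genomic environment of LTRs: intragenic status, orientation, introns,
# directional distances and gene density.

simple_genes <- function() {
  data.frame(gene_id = c("G1", "G2"),
             chrom = "chr1",
             start = c(10000L, 100000L), end = c(30000L, 120000L),
             strand = c("+", "-"), stringsAsFactors = FALSE)
}

test_that("an intronic antisense LTR is classified as such", {
  genes <- simple_genes()
  exons <- data.frame(gene_id = c("G1", "G1"),
                      chrom = "chr1",
                      start = c(10000L, 28000L), end = c(12000L, 30000L),
                      strand = "+", stringsAsFactors = FALSE)
  ltrs <- data.frame(ltr_id = "L1", chrom = "chr1",
                     start = 15000L, end = 15600L, strand = "-",
                     stringsAsFactors = FALSE)
  ctx <- classify_context(ltrs, list(genes = genes, exons = exons))
  expect_equal(ctx$status, "intragenic")
  expect_equal(ctx$orientation_vs_gene, "antisense")
  expect_true(ctx$intron_overlap)
  expect_equal(ctx$host_gene, "G1")
  # overlapping an exon negates the intron call
  ltrs2 <- data.frame(ltr_id = "L2", chrom = "chr1",
                      start = 11500L, end = 12100L, strand = "+",
                      stringsAsFactors = FALSE)
  ctx2 <- classify_context(ltrs2, list(genes = genes, exons = exons))
  expect_false(ctx2$intron_overlap)
  expect_equal(ctx2$orientation_vs_gene, "sense")
  # malformed model: exon outside its gene
  exons_bad <- exons
  exons_bad$end[2] <- 40000L
  expect_error(classify_context(ltrs, list(genes = genes,
                                           exons = exons_bad)),
               "malformed")
})

test_that("an intergenic LTR reports gap distances to flanking genes", {
  genes <- simple_genes()
  ltrs <- data.frame(ltr_id = "L1", chrom = "chr1",
                     start = 80000L, end = 80600L, strand = "+",
                     stringsAsFactors = FALSE)
  ctx <- classify_context(ltrs, list(genes = genes, exons = NULL))
  expect_equal(ctx$status, "intergenic")
  expect_true(is.na(ctx$orientation_vs_gene))
  # upstream (+ LTR: left) sense gene G1 ends at 30000 -> gap 50000
  expect_equal(ctx$dist_upstream_sense, 50000)
  expect_equal(ctx$dist_upstream_antisense, Inf)
  # downstream antisense gene G2 starts at 100000 -> gap 19400
  expect_equal(ctx$dist_downstream_antisense, 100000 - 80600)
  expect_equal(ctx$dist_downstream_sense, Inf)
})

test_that("context calls equal the brute-force oracle on a random fixture", {
  fx <- random_context_fixture(60, 40, seed = 16)
  ctx <- classify_context(fx$ltrs, list(genes = fx$genes, exons = NULL))
  oracle <- context_oracle(fx$ltrs, fx$genes)
  expect_identical(ctx$status, oracle$status)
  expect_identical(ctx$orientation_vs_gene, oracle$orientation_vs_gene)
  for (col in c("dist_upstream_sense", "dist_upstream_antisense",
                "dist_downstream_sense", "dist_downstream_antisense")) {
    expect_equal(ctx[[col]], oracle[[col]], label = col)
  }
})

test_that("flipping gene strands swaps the sense and antisense distances", {
  fx <- random_context_fixture(40, 30, seed = 17)
  ctx <- classify_context(fx$ltrs, list(genes = fx$genes, exons = NULL))
  flipped <- fx$genes
  flipped$strand <- chartr("+-", "-+", flipped$strand)
  ctx2 <- classify_context(fx$ltrs, list(genes = flipped, exons = NULL))
  expect_equal(ctx2$dist_upstream_sense, ctx$dist_upstream_antisense)
  expect_equal(ctx2$dist_upstream_antisense, ctx$dist_upstream_sense)
  expect_equal(ctx2$dist_downstream_sense, ctx$dist_downstream_antisense)
  expect_equal(ctx2$dist_downstream_antisense, ctx$dist_downstream_sense)
  intra <- ctx$status == "intragenic"
  expect_identical(ctx2$orientation_vs_gene[intra] == "sense",
                   ctx$orientation_vs_gene[intra] == "antisense")
})

test_that("gene-density ratio reflects planted neighbourhood density", {
  profiles <- data.frame(
    ltr_id = sprintf("L%02d", 1:20),
    category = rep(c("Pr", "Silent"), each = 10),
    excluded = FALSE, n_functions = 1L, pr_pa_switch = FALSE,
    stringsAsFactors = FALSE)
  # identical placement: ratio exactly 1
  ltrs <- data.frame(ltr_id = profiles$ltr_id, chrom = "chr1",
                     start = rep(50000L, 20), end = rep(50600L, 20),
                     strand = "+", stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = sprintf("G%d", 1:4), chrom = "chr1",
                      start = c(20000L, 40000L, 60000L, 80000L),
                      end = c(25000L, 45000L, 65000L, 85000L),
                      strand = "+", stringsAsFactors = FALSE)
  dr <- density_ratio(ltrs, profiles, genes)
  expect_equal(dr$ratio, 1)
  # promoter windows planted twice as dense
  ltrs2 <- ltrs
  ltrs2$start[11:20] <- 500000L
  ltrs2$end[11:20] <- 500600L
  genes2 <- rbind(genes,
                  data.frame(gene_id = c("G5", "G6"), chrom = "chr1",
                             start = c(490000L, 510000L),
                             end = c(495000L, 515000L), strand = "+"))
  # promoter LTRs keep 4 genes in the window, silent LTRs see 2
  dr2 <- density_ratio(ltrs2, profiles, genes2)
  expect_equal(dr2$ratio, 2)
  # gene order permutation changes nothing
  dr3 <- density_ratio(ltrs2, profiles, genes2[sample.int(6), ])
  expect_equal(dr3$ratio, dr2$ratio)
  # both classes must be present
  expect_error(
    density_ratio(ltrs, profiles[profiles$category == "Pr", ], genes),
    "silent")
})

test_that("BED and GFF3 gene annotation round-trips through the reader", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t2000\tGENE1\t0\t+",
               "chr2\t4999\t9000\tGENE2\t0\t-"), bed)
  ga <- read_gene_annotation(bed)
  expect_equal(ga$genes$start, c(999L, 4999L))
  expect_equal(ga$genes$end, c(2000L, 9000L))
  expect_equal(ga$genes$gene_id, c("GENE1", "GENE2"))
  expect_null(ga$exons)

  gen <- generate_annotation(sim_params(
    n_loci = c(HERV_prototypes = 0L, HERV_Dfam = 0L, MaLR_Dfam = 0L,
               gene = 5L), seed = 20L))
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models_gff3(gen$truth$gene_models, gff)
  ga2 <- read_gene_annotation(gff)
  expect_equal(nrow(ga2$genes), 5L)
  expect_equal(nrow(ga2$exons), 15L)
  expect_equal(ga2$genes$start, gen$truth$gene_models$genes$start)
  expect_equal(ga2$genes$end, gen$truth$gene_models$genes$end)
  expect_setequal(unique(ga2$exons$gene_id), ga2$genes$gene_id)
})
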
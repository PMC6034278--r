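# Pathway-exclusive gene selection, co-expression edges, bipartite network
# and gene proximity.

test_that("exclusive genes belong to exactly one significant pathway", {
  tab <- data.frame(
    gene_symbol = c("A", "B", "B", "C", "D"),
    pathway_id = c("P1", "P1", "P2", "P3", "P_NS"),
    pathway_significant = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  excl <- select_exclusive_genes(tab)
  expect_setequal(excl$gene_symbol, c("A", "C"))   # B in two, D only non-sig
  expect_equal(excl$pathway_id[excl$gene_symbol == "A"], "P1")
  dup <- rbind(tab, tab[1, ])
  expect_error(validate_pathway_table(dup), "duplicated")
})

net_fixture <- function(n_samples = 45, seed = 12) {
  set.seed(seed)
  samples <- sprintf("S%02d", seq_len(n_samples))
  ann <- data.frame(
    probeset_id = c("H1_a", "H1_b", "H2_a", "G1_pb", "G2_pb"),
    locus_id = c("H1", "H1", "H2", "G1", "G2"),
    repertoire = c(rep("HERV_Dfam", 3), "gene", "gene"),
    group = c(rep("HERV_Dfam", 3), "", ""),
    region = c(rep("internal", 3), "gene_body", "gene_body"),
    ltr_role = "none", chrom = "chr1",
    start = c(100L, 200L, 60000L, 1000L, 300000L),
    end = c(150L, 250L, 60050L, 21000L, 320000L),
    strand = "+", stringsAsFactors = FALSE)
  g1 <- stats::rnorm(n_samples)
  m <- rbind(H1_a = g1 + stats::rnorm(n_samples, 0, 0.05),
             H1_b = stats::rnorm(n_samples),
             H2_a = -g1,
             G1_pb = g1,
             G2_pb = stats::rnorm(n_samples))
  colnames(m) <- samples
  list(ann = ann, matrix = m)
}

test_that("edges require near-identical profiles and collapse per locus", {
  fx <- net_fixture()
  e <- correlate_herv_genes(fx$matrix, c("H1_a", "H1_b", "H2_a"),
                            c("G1_pb", "G2_pb"), fx$ann)
  # H1 correlates with G1 through H1_a only; the negated profile H2 never
  expect_equal(nrow(e), 1L)
  expect_equal(e$herv_locus_id, "H1")
  expect_equal(e$gene_symbol, "G1")
  expect_gt(e$correlation, 0.99)
  # a perfectly identical profile gives r = 1
  m2 <- fx$matrix
  m2["H1_a", ] <- m2["G1_pb", ]
  e2 <- correlate_herv_genes(m2, "H1_a", "G1_pb", fx$ann)
  expect_equal(e2$correlation, 1)
  # constant profiles are skipped with a warning
  m2["H1_a", ] <- 5
  expect_warning(
    e3 <- correlate_herv_genes(m2, "H1_a", "G1_pb", fx$ann),
    "constant")
  expect_equal(nrow(e3), 0L)
})

test_that("raising the correlation threshold never adds edges", {
  set.seed(13)
  n <- 40
  ids <- sprintf("X%02d", seq_len(n))
  ann <- data.frame(probeset_id = ids, locus_id = ids,
                    repertoire = c(rep("HERV_Dfam", n / 2),
                                   rep("gene", n / 2)),
                    group = "", region = c(rep("internal", n / 2),
                                           rep("gene_body", n / 2)),
                    ltr_role = "none", chrom = "chr1",
                    start = seq_len(n) * 1000L,
                    end = seq_len(n) * 1000L + 100L, strand = "+",
                    stringsAsFactors = FALSE)
  ann$group[ann$repertoire == "HERV_Dfam"] <- "HERV_Dfam"
  base <- stats::rnorm(30)
  m <- t(vapply(seq_len(n), function(i)
    base * stats::runif(1, 0, 1.5) + stats::rnorm(30, 0, 1),
    numeric(30)))
  dimnames(m) <- list(ids, sprintf("S%02d", 1:30))
  hv <- ids[1:(n / 2)]; gv <- ids[(n / 2 + 1):n]
  prev <- correlate_herv_genes(m, hv, gv, ann, r_min = 0.2)
  for (r in c(0.4, 0.6, 0.8, 0.95)) {
    cur <- correlate_herv_genes(m, hv, gv, ann, r_min = r)
    expect_true(all(paste(cur$herv_locus_id, cur$gene_symbol) %in%
                      paste(prev$herv_locus_id, prev$gene_symbol)))
    prev <- cur
  }
})

test_that("network splits loci into exclusive and shared", {
  edges <- data.frame(
    herv_locus_id = c("H1", "H2", "H2", "H2", "H3"),
    gene_symbol = c("A", "A", "B", "C", "D"),
    correlation = 0.9, n_probesets = 1L, stringsAsFactors = FALSE)
  excl <- data.frame(gene_symbol = c("A", "B", "C", "D"),
                     pathway_id = c("P1", "P2", "P3", "P1"),
                     stringsAsFactors = FALSE)
  net <- build_network(edges, excl)
  expect_equal(net$n_exclusive, 2L)   # H1 (P1), H3 (P1)
  expect_equal(net$n_shared, 1L)      # H2 spans P1/P2/P3
  memb <- net$membership
  expect_equal(memb$n_pathways[memb$herv_locus_id == "H2"], 3L)
  expect_true(igraph::is_bipartite(net$graph))
  expect_equal(igraph::vcount(net$graph), 3L + 3L)
  # unknown gene rejected
  edges$gene_symbol[1] <- "ZZ"
  expect_error(build_network(edges, excl), "ZZ")
})

test_that("node and edge counts are invariant under input permutation", {
  fx <- net_fixture(seed = 14)
  edges <- data.frame(
    herv_locus_id = c("H1", "H2", "H1"),
    gene_symbol = c("G1", "G1", "G2"),
    correlation = c(0.9, 0.85, 0.95), n_probesets = 1L,
    stringsAsFactors = FALSE)
  excl <- data.frame(gene_symbol = c("G1", "G2"),
                     pathway_id = c("P1", "P2"), stringsAsFactors = FALSE)
  n1 <- build_network(edges, excl)
  n2 <- build_network(edges[c(3, 1, 2), ], excl[2:1, ])
  expect_equal(n2$membership, n1$membership)
  expect_equal(igraph::ecount(n2$graph), igraph::ecount(n1$graph))
})

test_that("gene proximity uses inclusive 40 kb gap distances", {
  ann <- data.frame(
    probeset_id = c("H1_a", "H2_a", "H3_a"),
    locus_id = c("H1", "H2", "H3"),
    repertoire = "HERV_Dfam", group = "HERV_Dfam", region = "internal",
    ltr_role = "none", chrom = c("chr1", "chr1", "chr2"),
    start = c(100000L, 400000L, 5000L), end = c(100600L, 400600L, 5600L),
    strand = "+", stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("GA", "GB"), chrom = "chr1",
                      start = c(140599L, 440601L), end = c(150000L, 450000L),
                      strand = "+", stringsAsFactors = FALSE)
  edges <- data.frame(herv_locus_id = c("H1", "H2", "H3"),
                      stringsAsFactors = FALSE)
  out <- proximity_annotate(edges, ann, genes, max_dist = 40000L)
  expect_equal(out$distance_bp, c(39999, 40001, Inf))
  expect_identical(out$near_gene, c(TRUE, FALSE, FALSE))
  # overlap means distance zero
  genes2 <- data.frame(gene_id = "GC", chrom = "chr1",
                       start = 100300L, end = 100900L, strand = "+",
                       stringsAsFactors = FALSE)
  out2 <- proximity_annotate(edges[1, , drop = FALSE], ann, genes2)
  expect_equal(out2$distance_bp, 0)
  expect_true(out2$near_gene)
})

test_that("indexed proximity equals the brute-force gap on a fixture", {
  set.seed(15)
  n <- 20
  ann <- data.frame(
    probeset_id = sprintf("H%02d_a", 1:n),
    locus_id = sprintf("H%02d", 1:n),
    repertoire = "HERV_Dfam", group = "HERV_Dfam", region = "internal",
    ltr_role = "none",
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = sample.int(900000L, n), stringsAsFactors = FALSE)
  ann$end <- ann$start + 600L
  ann$strand <- "+"
  genes <- data.frame(
    gene_id = sprintf("G%02d", 1:15),
    chrom = sample(c("chr1", "chr2"), 15, replace = TRUE),
    start = sample.int(900000L, 15), strand = "+",
    stringsAsFactors = FALSE)
  genes$end <- genes$start + sample(1000:20000, 15)
  edges <- data.frame(herv_locus_id = ann$locus_id,
                      stringsAsFactors = FALSE)
  out <- proximity_annotate(edges, ann, genes)
  oracle <- mapply(gap_oracle, ann$chrom, ann$start, ann$end,
                   MoreArgs = list(genes = genes))
  expect_equal(out$distance_bp, unname(oracle))
})
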
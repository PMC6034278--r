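# Moderated t, BH adjustment, DE calling, locus aggregation, phenotypes,
# clustering and ddCt.

make_two_group <- function(n = 50, nA = 6, nB = 6, seed = 1,
                           effect_rows = integer(), effect = 2) {
  set.seed(seed)
  sheet <- data.frame(
    sample_id = sprintf("S%02d", seq_len(nA + nB)),
    donor = sprintf("D%d", rep(seq_len(max(nA, nB)), 2)[seq_len(nA + nB)]),
    condition = rep(c("LPS", "NS"), c(nA, nB)),
    replicate = 1L, stringsAsFactors = FALSE)
  sheet$replicate <- stats::ave(seq_len(nrow(sheet)),
                                paste(sheet$donor, sheet$condition),
                                FUN = seq_along)
  sds <- sqrt(1 / stats::rgamma(n, shape = 3, rate = 0.3))
  m <- matrix(stats::rnorm(n * (nA + nB), 8, rep(sds, nA + nB)), nrow = n,
              dimnames = list(sprintf("P%03d", seq_len(n)),
                              sheet$sample_id))
  m[effect_rows, seq_len(nA)] <- m[effect_rows, seq_len(nA)] + effect
  list(matrix = m, sheet = sheet)
}

test_that("identical groups give zero fold change and p = 1", {
  sheet <- tiny_sheet()
  m <- matrix(5, nrow = 3, ncol = nrow(sheet),
              dimnames = list(c("a", "b", "c"), sheet$sample_id))
  r <- moderated_t(m, sheet, c("LPS", "NS"))
  expect_equal(r$log2fc, rep(0, 3))
  expect_equal(r$t_mod, rep(0, 3))
  expect_equal(r$p, rep(1, 3))
  expect_false(any(r$significant))
})

test_that("prior-df limits recover the ordinary t and the z-like test", {
  tg <- make_two_group(n = 80, nA = 8, nB = 8, seed = 2)
  # d0 = 0: ordinary equal-variance two-sample t
  r0 <- moderated_t(tg$matrix, tg$sheet, c("LPS", "NS"), prior_df = 0)
  p_oracle <- apply(tg$matrix, 1L, function(x)
    stats::t.test(x[1:8], x[9:16], var.equal = TRUE)$p.value)
  expect_equal(r0$p, unname(p_oracle), tolerance = 1e-12)
  # d0 = Inf with fixed prior variance: z-like test on that variance
  s02 <- 1.3
  rI <- moderated_t(tg$matrix, tg$sheet, c("LPS", "NS"),
                    prior_df = Inf, prior_var = s02)
  z <- rI$log2fc / sqrt(s02 * (1 / 8 + 1 / 8))
  expect_equal(rI$p, 2 * stats::pnorm(-abs(z)), tolerance = 1e-12)
})

test_that("the empirical-Bayes fit matches the reference implementation", {
  tg <- make_two_group(n = 400, nA = 8, nB = 8, seed = 3,
                       effect_rows = 1:40)
  r <- moderated_t(tg$matrix, tg$sheet, c("LPS", "NS"))
  design <- stats::model.matrix(~ 0 + factor(tg$sheet$condition,
                                             levels = c("NS", "LPS")))
  colnames(design) <- c("NS", "LPS")
  fit <- limma::lmFit(tg$matrix, design)
  fit <- limma::contrasts.fit(
    fit, limma::makeContrasts(LPS - NS, levels = design))
  fit <- limma::eBayes(fit)
  expect_equal(attr(r, "df_prior"), fit$df.prior, tolerance = 1e-8)
  expect_equal(attr(r, "var_prior"), fit$s2.prior, tolerance = 1e-8)
  expect_equal(r$t_mod, unname(fit$t[, 1]), tolerance = 1e-8)
  expect_equal(r$p, unname(fit$p.value[, 1]), tolerance = 1e-8)
})

test_that("zero-variance-everywhere input is squeezed, not crashed", {
  sq <- squeeze_var(rep(0, 10), df = 4)
  expect_identical(sq$df_prior, Inf)
  expect_equal(sq$var_post, rep(0, 10))
  # homogeneous variances: no positive trigamma solution, df_prior = Inf
  sq2 <- squeeze_var(rep(2, 50), df = 10)
  expect_identical(sq2$df_prior, Inf)
  expect_equal(sq2$var_prior, 2)
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:25) {
    p <- stats::runif(sample(1:400, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
})

test_that("DE calling uses strict boundaries", {
  res <- data.frame(probeset_id = c("a", "b", "c", "d"),
                    log2fc = c(2, 1.0, -2, 1.5),
                    adj_p = c(0.05, 0.01, 0.04, 0.049))
  cd <- call_de(res, de_config())
  expect_setequal(cd$results$probeset_id, c("c", "d"))  # a: p, b: lfc
  expect_equal(cd$n_up, 1L)
  expect_equal(cd$n_down, 1L)
})

test_that("significant probesets collapse to distinct loci", {
  ann <- tiny_annotation()
  res <- data.frame(
    probeset_id = c("L1_U3", "L1_R", "L1_U5", "D1_int", "G1_pb1"),
    log2fc = 2, adj_p = 0.001, significant = TRUE)
  agg <- aggregate_loci(res, ann)
  expect_equal(agg$n_total, 3L)            # L1, D1, G1
  expect_equal(agg$loci$n_probesets_sig[agg$loci$locus_id == "L1"], 3L)
  expect_equal(sum(agg$per_repertoire$n_loci), agg$n_total)
  expect_equal(sum(agg$per_chrom$n_loci), agg$n_total)
  bad <- rbind(res, data.frame(probeset_id = "GHOST", log2fc = 2,
                               adj_p = 0.001, significant = TRUE))
  expect_error(aggregate_loci(bad, ann), "GHOST")
})

test_that("phenotype classes are disjoint and exhaustive over patterns", {
  lv <- c(up = 1, down = -1, ns = 0)
  pat <- expand.grid(a = names(lv), b = names(lv),
                     stringsAsFactors = FALSE)
  mk <- function(dir) data.frame(
    probeset_id = sprintf("P%d", seq_len(nrow(pat))),
    log2fc = 2 * lv[dir],
    adj_p = ifelse(dir == "ns", 0.9, 0.001))
  ph <- classify_phenotype(mk(pat$a), mk(pat$b))
  expected <- ifelse(pat$a == "up" & pat$b == "down", "tolerisable",
              ifelse(pat$a == "up", "non_tolerisable",
              ifelse(pat$a == "down", "down_modulated", "unclassified")))
  expect_identical(ph$probesets$class, expected)
  expect_error(classify_phenotype(mk(pat$a), mk(pat$b)[1:3, ]),
               "different probesets")
})

test_that("clustering recovers planted condition blocks", {
  sheet <- generate_design(3L, c("NS", "LPS", "ET"), 2L)
  set.seed(9)
  base <- matrix(stats::rnorm(60 * nrow(sheet), 6, 0.1), nrow = 60)
  shift <- rbind(outer(rep(1, 20), 4 * (sheet$condition == "NS")),
                 outer(rep(1, 20), 4 * (sheet$condition == "LPS")),
                 outer(rep(1, 20), 4 * (sheet$condition == "ET")))
  m <- base + shift
  dimnames(m) <- list(sprintf("P%03d", 1:60), sheet$sample_id)
  cl <- top_variance_cluster(m, de_config(top_variance_fraction = 0.67))
  groups <- stats::cutree(cl$hclust, k = 3)
  expect_equal(length(unique(tapply(groups, sheet$condition,
                                    function(x) unique(x)))), 3L)
  # each condition maps to exactly one cluster
  expect_true(all(tapply(groups, sheet$condition,
                         function(x) length(unique(x))) == 1L))
})

test_that("duplicated samples sit at zero distance and merge first", {
  sheet <- tiny_sheet()
  set.seed(10)
  m <- matrix(stats::rnorm(40 * nrow(sheet)), nrow = 40,
              dimnames = list(sprintf("P%02d", 1:40), sheet$sample_id))
  m[, 2] <- m[, 1]
  cl <- top_variance_cluster(m, de_config(top_variance_fraction = 1))
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)
  expect_setequal(-cl$hclust$merge[1, ], c(1L, 2L))
  # probeset order permutation does not change the dendrogram
  set.seed(11)
  perm <- sample.int(nrow(m))
  cl2 <- top_variance_cluster(m[perm, ], de_config(top_variance_fraction = 1))
  expect_equal(cl2$hclust$merge, cl$hclust$merge)
  expect_equal(cl2$hclust$height, cl$hclust$height)
})

test_that("ddCt reproduces hand-computed fold changes", {
  # ddCt = 0 -> FC 1; ddCt = -1 -> FC 2
  r <- ddct(ct_target = c(24, 23), ct_refs = c(20, 20),
            condition = c("NS", "LPS"), calibrator = "NS")
  expect_equal(r$fold_change, c(1, 2))
  # target 24 against a single reference at 20 gives dCt 4; with the
  # calibrator at dCt 5 the fold change is 2^(5-4) = 2
  r2 <- ddct(ct_target = c(25, 24), ct_refs = c(20, 20),
             condition = c("NS", "LPS"))
  expect_equal(r2$fold_change[2], 2)
  # two references enter via their arithmetic mean
  r3 <- ddct(ct_target = c(24, 24), ct_refs = cbind(c(19, 19), c(21, 21)),
             condition = c("NS", "LPS"))
  expect_equal(r3$fold_change, c(1, 1))
  expect_error(ddct(24, 20, "LPS", calibrator = "NS"), "calibrator")
})
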
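# Independent oracles and fixture builders shared across the test files.
# Oracles are deliberately written as naive brute-force implementations,
# structurally different from the package code paths they check.

# Benjamini-Hochberg step-up, computed from the textbook definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# The four positive predicates of the LTR decision rule, evaluated
# independently (scalar, no ordering/overwriting logic).
function_predicates <- function(u3, u5, th = 4.5, fc = 3) {
  f <- log2(fc)
  c(Silent = u3 <= th && u5 <= th,
    pA = u3 > th && (u3 - u5) >= f,
    Pr = u5 > th && (u5 - u3) >= f,
    RdT = u3 > th && u5 > th && abs(u3 - u5) < f)
}

function_oracle <- function(u3, u5, th = 4.5, fc = 3) {
  hits <- function_predicates(u3, u5, th, fc)
  if (sum(hits) > 1L) return("CONFLICT")
  if (sum(hits) == 0L) return("Undetermined")
  names(hits)[hits]
}

# O(n*m) genomic-context oracle on 0-based half-open intervals.
context_oracle <- function(ltrs, genes) {
  out <- vector("list", nrow(ltrs))
  for (i in seq_len(nrow(ltrs))) {
    l <- ltrs[i, ]
    same <- genes[genes$chrom == l$chrom, , drop = FALSE]
    ov <- pmin(same$end, l$end) - pmax(same$start, l$start)
    inside <- which(ov > 0)
    host <- if (length(inside)) inside[which.max(ov[inside])] else NA
    gap_left <- function(strand) {
      g <- same[same$strand == strand & same$end <= l$start, , drop = FALSE]
      if (nrow(g) == 0L) Inf else min(l$start - g$end)
    }
    gap_right <- function(strand) {
      g <- same[same$strand == strand & same$start >= l$end, , drop = FALSE]
      if (nrow(g) == 0L) Inf else min(g$start - l$end)
    }
    up <- if (l$strand == "+") gap_left else gap_right
    dn <- if (l$strand == "+") gap_right else gap_left
    anti <- if (l$strand == "+") "-" else "+"
    out[[i]] <- data.frame(
      ltr_id = l$ltr_id,
      status = if (is.na(host)) "intergenic" else "intragenic",
      orientation_vs_gene = if (is.na(host)) NA_character_ else
        if (same$strand[host] == l$strand) "sense" else "antisense",
      dist_upstream_sense = up(l$strand),
      dist_upstream_antisense = up(anti),
      dist_downstream_sense = dn(l$strand),
      dist_downstream_antisense = dn(anti),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Brute-force minimal gap between a locus interval and every gene.
gap_oracle <- function(chrom, start, end, genes) {
  same <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(same) == 0L) return(Inf)
  min(pmax(pmax(same$start - end, start - same$end), 0))
}

# Random LTR/gene interval fixture for context oracle comparisons.
random_context_fixture <- function(n_ltr, n_gene, seed) {
  set.seed(seed)
  ltrs <- data.frame(
    ltr_id = sprintf("L%04d", seq_len(n_ltr)),
    chrom = sample(c("chr1", "chr2", "chr3"), n_ltr, replace = TRUE),
    start = sample.int(2000000L, n_ltr), strand = sample(c("+", "-"),
                                                         n_ltr, TRUE),
    stringsAsFactors = FALSE)
  ltrs$end <- ltrs$start + 600L
  genes <- data.frame(
    gene_id = sprintf("G%04d", seq_len(n_gene)),
    chrom = sample(c("chr1", "chr2", "chr3"), n_gene, replace = TRUE),
    start = sample.int(2000000L, n_gene),
    strand = sample(c("+", "-"), n_gene, TRUE), stringsAsFactors = FALSE)
  genes$end <- genes$start + sample(500:30000, n_gene, replace = TRUE)
  list(ltrs = ltrs, genes = genes)
}

# Minimal hand-built annotation: two attributable solo LTRs (one per
# locus), one provirus lacking U5 on its 3' LTR, a Dfam locus and a gene.
tiny_annotation <- function() {
  data.frame(
    probeset_id = c("L1_U3", "L1_R", "L1_U5",
                    "L2_U3", "L2_U5",
                    "P1_5_U3", "P1_5_U5", "P1_3_part", "P1_gag",
                    "D1_lp", "D1_int",
                    "G1_pb1"),
    locus_id = c(rep("L1", 3), rep("L2", 2), rep("P1", 4),
                 rep("D1", 2), "G1"),
    repertoire = c(rep("HERV_prototypes", 9),
                   rep("MaLR_Dfam", 2), "gene"),
    group = c(rep("HERV-H", 9), rep("MaLR_Dfam", 2), ""),
    region = c("U3", "R", "U5", "U3", "U5", "U3", "U5", "LTR_part", "gag",
               "LTR_part", "internal", "gene_body"),
    ltr_role = c(rep("solo", 5), "five_prime", "five_prime", "three_prime",
                 "none", "solo", "none", "none"),
    chrom = "chr1",
    start = seq(0L, 1100L, by = 100L),
    end = seq(50L, 1150L, by = 100L),
    strand = "+",
    stringsAsFactors = FALSE
  )
}

# Small factorial design sheet.
tiny_sheet <- function(n_donors = 2L, conditions = c("NS", "LPS"),
                       n_reps = 2L) {
  generate_design(n_donors, conditions, n_reps)
}

# Matrix with given dimnames filled from a function of (row, col).
grid_matrix <- function(probesets, samples, fill) {
  m <- outer(seq_along(probesets), seq_along(samples), fill)
  dimnames(m) <- list(probesets, samples)
  m
}
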
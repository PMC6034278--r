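# Moderated-t differential expression between stimulation conditions,
# Benjamini-Hochberg adjustment, DE calling, locus-level aggregation,
# tolerisability phenotypes, top-variance clustering and a 2^-ddCt utility.
#
# The moderated t follows the standard empirical-Bayes variance squeeze:
# per-probeset pooled residual variance s^2 with d residual df; prior
# hyperparameters (d0, s0^2) fitted by moment matching on log s^2 (the
# method-of-moments identities E[log s^2] and Var[log s^2] of a scaled F
# variate, solved by trigamma inversion); posterior variance
# s_post^2 = (d0 s0^2 + d s^2)/(d0 + d); t = log2FC / (s_post * c) with
# c^2 = 1/nA + 1/nB and d + d0 degrees of freedom.

#' Configuration for differential-expression calling
#'
#' @param alpha adjusted-p significance level (default 0.05, strict `<`).
#' @param lfc_min absolute log2 fold-change cutoff (default 1, strict `>`).
#' @param top_variance_fraction fraction of most variable probesets used by
#'   [top_variance_cluster()] (default 0.01).
#' @param linkage agglomeration method for sample clustering: `"complete"`
#'   (default) or `"average"`.
#' @param paired if `TRUE`, the condition contrast is computed on
#'   within-donor differences (donor as a blocking factor). Off by default:
#'   the reference analysis compares condition groups directly.
#' @return list of class `de_config`.
#' @export
de_config <- function(alpha = 0.05, lfc_min = 1,
                      top_variance_fraction = 0.01,
                      linkage = c("complete", "average"),
                      paired = FALSE) {
  stopifnot(alpha > 0, alpha < 1, lfc_min >= 0,
            top_variance_fraction > 0, top_variance_fraction <= 1)
  structure(list(alpha = alpha, lfc_min = lfc_min,
                 top_variance_fraction = top_variance_fraction,
                 linkage = match.arg(linkage), paired = isTRUE(paired)),
            class = "de_config")
}

# Solve trigamma(x) = y by Newton iteration (monotone decreasing trigamma).
trigamma_inverse <- function(y) {
  out <- y
  big <- y > 1e7
  out[big] <- 1 / sqrt(y[big])
  small <- y < 1e-6
  out[small] <- 1 / y[small]
  mid <- which(!big & !small)
  if (length(mid) > 0L) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (max(-dif / x) < 1e-8) break
    }
    out[mid] <- x
  }
  out
}

#' Empirical-Bayes squeeze of sample variances
#'
#' Fits the prior degrees of freedom `df_prior` and prior variance
#' `var_prior` by moment matching on `log(s2)` and returns the posterior
#' (squeezed) variances. With homogeneous observed variances the trigamma
#' equation has no positive solution and `df_prior = Inf` (all posteriors
#' equal the prior mean).
#'
#' @param s2 per-probeset sample variances.
#' @param df residual degrees of freedom of each `s2` (scalar).
#' @return list `df_prior, var_prior, var_post`.
#' @export
squeeze_var <- function(s2, df) {
  stopifnot(df >= 1)
  n <- length(s2)
  if (n == 0L) stop("empty variance vector", call. = FALSE)
  x <- pmax(s2, 0)
  m <- stats::median(x)
  if (m == 0) {
    # all (or most) variances zero: degenerate but legal input
    return(list(df_prior = Inf, var_prior = mean(x), var_post = rep(mean(x), n)))
  }
  x <- pmax(x, 1e-5 * m)
  z <- log(x)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    df_prior <- Inf
    var_prior <- mean(x)
  } else {
    df_prior <- 2 * trigamma_inverse(evar)
    var_prior <- exp(mean(e) + digamma(df_prior / 2) - log(df_prior / 2))
  }
  var_post <- if (is.infinite(df_prior)) rep(var_prior, n) else
    (df_prior * var_prior + df * s2) / (df_prior + df)
  list(df_prior = df_prior, var_prior = var_prior, var_post = var_post)
}

#' Moderated t-test between two conditions
#'
#' Computes, per probeset, the log2 fold change between the two condition
#' groups of the contrast, the pooled residual variance, its empirical-Bayes
#' squeeze (see [squeeze_var()]), the moderated t statistic, two-sided
#' p-values on `df + df_prior` degrees of freedom, Benjamini-Hochberg
#' adjusted p-values, and the significance call (`adj_p < alpha` and
#' `|log2FC| > lfc_min`, both strict).
#'
#' @param matrix log2 intensity matrix.
#' @param sheet sample sheet covering the matrix columns.
#' @param contrast length-2 character vector `(A, B)`: log2FC is
#'   `mean(A) - mean(B)` (e.g. `c("LPS", "NS")`).
#' @param config a [de_config()].
#' @param prior_df,prior_var optional fixed hyperparameters overriding the
#'   empirical-Bayes fit (`prior_df = 0` gives the ordinary two-sample t;
#'   `prior_df = Inf` with `prior_var` gives a z-like test).
#' @return data.frame `probeset_id, log2fc, s2, s2_post, t_mod, df_total,
#'   p, adj_p, significant, direction`.
#' @export
moderated_t <- function(matrix, sheet, contrast, config = de_config(),
                        prior_df = NULL, prior_var = NULL) {
  sheet <- validate_sample_sheet(sheet)
  stopifnot(length(contrast) == 2L)
  idx <- match(colnames(matrix), sheet$sample_id)
  if (anyNA(idx)) stop("matrix samples missing from sheet", call. = FALSE)
  cond <- sheet$condition[idx]
  a_cols <- which(cond == contrast[1L])
  b_cols <- which(cond == contrast[2L])
  if (length(a_cols) < 2L || length(b_cols) < 2L) {
    stop("each contrast condition needs >= 2 samples (got ",
         length(a_cols), " and ", length(b_cols), ")", call. = FALSE)
  }

  if (config$paired) {
    # within-donor differences of per-donor condition means
    donor <- sheet$donor[idx]
    shared <- intersect(unique(donor[a_cols]), unique(donor[b_cols]))
    if (length(shared) < 2L) stop("paired fit needs >= 2 shared donors",
                                  call. = FALSE)
    diffs <- vapply(shared, function(d) {
      rowMeans(matrix[, a_cols[donor[a_cols] == d], drop = FALSE]) -
        rowMeans(matrix[, b_cols[donor[b_cols] == d], drop = FALSE])
    }, numeric(nrow(matrix)))
    lfc <- rowMeans(diffs)
    d <- length(shared) - 1L
    s2 <- rowSums((diffs - lfc)^2) / d
    cfac <- 1 / length(shared)
  } else {
    a <- matrix[, a_cols, drop = FALSE]
    b <- matrix[, b_cols, drop = FALSE]
    ma <- rowMeans(a); mb <- rowMeans(b)
    lfc <- ma - mb
    d <- length(a_cols) + length(b_cols) - 2L
    s2 <- (rowSums((a - ma)^2) + rowSums((b - mb)^2)) / d
    cfac <- 1 / length(a_cols) + 1 / length(b_cols)
  }

  if (is.null(prior_df)) {
    sq <- squeeze_var(s2, d)
  } else if (is.infinite(prior_df)) {
    if (is.null(prior_var)) stop("prior_var required when prior_df = Inf",
                                 call. = FALSE)
    sq <- list(df_prior = Inf, var_prior = prior_var,
               var_post = rep(prior_var, length(s2)))
  } else if (prior_df == 0) {
    sq <- list(df_prior = 0, var_prior = NA_real_, var_post = s2)
  } else {
    if (is.null(prior_var)) stop("prior_var required with fixed prior_df",
                                 call. = FALSE)
    sq <- list(df_prior = prior_df, var_prior = prior_var,
               var_post = (prior_df * prior_var + d * s2) / (prior_df + d))
  }

  se <- sqrt(sq$var_post * cfac)
  t_mod <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  df_total <- d + sq$df_prior
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p[is.infinite(t_mod)] <- 0
  adj <- bh_adjust(p)
  res <- data.frame(
    probeset_id = rownames(matrix),
    log2fc = lfc, s2 = s2, s2_post = sq$var_post, t_mod = t_mod,
    df_total = df_total, p = p, adj_p = adj,
    stringsAsFactors = FALSE, row.names = NULL)
  res$significant <- res$adj_p < config$alpha & abs(res$log2fc) > config$lfc_min
  res$direction <- ifelse(!res$significant, "ns",
                          ifelse(res$log2fc > 0, "up", "down"))
  attr(res, "df_prior") <- sq$df_prior
  attr(res, "var_prior") <- sq$var_prior
  attr(res, "contrast") <- contrast
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (monotone in rank, capped at 1, input order
#' preserved). Thin validated wrapper over the standard step-up procedure.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Call differentially expressed probesets
#'
#' Strict cutoffs: `adj_p < alpha` and `|log2FC| > lfc_min`; boundary values
#' are not significant.
#'
#' @param results data.frame from [moderated_t()].
#' @param config a [de_config()].
#' @return list `results` (significant rows with direction), `n_up`,
#'   `n_down`.
#' @export
call_de <- function(results, config = de_config()) {
  sig <- results$adj_p < config$alpha & abs(results$log2fc) > config$lfc_min
  out <- results[sig, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  list(results = out,
       n_up = sum(out$direction == "up"),
       n_down = sum(out$direction == "down"))
}

#' Aggregate differentially expressed probesets to loci
#'
#' Collapses significant probesets to distinct differentially expressed loci
#' (DELs for retroelements, DEGs for genes) and tallies them per repertoire,
#' per structure (solo LTR versus provirus) and per chromosome. Per-
#' repertoire counts sum to the total by construction.
#'
#' @param de_results data.frame from [moderated_t()] (its significant rows
#'   are used), or the `results` element of [call_de()].
#' @param annotation validated probeset annotation covering the probesets.
#' @return list `loci` (per-locus table), `per_repertoire`, `per_structure`,
#'   `per_chrom`, `n_total`.
#' @export
aggregate_loci <- function(de_results, annotation) {
  if (is.list(de_results) && !is.data.frame(de_results) &&
      !is.null(de_results$results)) {
    de_results <- de_results$results
  }
  ann <- validate_annotation(annotation)
  sig <- if ("significant" %in% names(de_results))
    de_results[de_results$significant, , drop = FALSE] else de_results
  m <- match(sig$probeset_id, ann$probeset_id)
  if (anyNA(m)) {
    stop("significant probeset(s) without annotation: ",
         paste(utils::head(sig$probeset_id[is.na(m)], 3L), collapse = ", "),
         call. = FALSE)
  }
  loc <- ann$locus_id[m]
  # locus structure: provirus if the locus has proviral LTRs or internal
  # genes on the chip, solo LTR otherwise (genes stay "gene")
  roles <- split(ann$ltr_role, ann$locus_id)
  reps <- split(ann$repertoire, ann$locus_id)
  structure_of <- function(l) {
    if (reps[[l]][1L] == "gene") return("gene")
    if (any(roles[[l]] %in% c("five_prime", "three_prime"))) return("provirus")
    "solo_LTR"
  }
  ids <- sort(unique(loc))
  if (length(ids) == 0L) {
    return(list(loci = data.frame(), per_repertoire = data.frame(),
                per_structure = data.frame(), per_chrom = data.frame(),
                n_total = 0L))
  }
  first <- match(ids, ann$locus_id)
  loci <- data.frame(
    locus_id = ids,
    repertoire = ann$repertoire[first],
    chrom = ann$chrom[first],
    structure = vapply(ids, structure_of, character(1L)),
    n_probesets_sig = as.integer(table(loc)[ids]),
    stringsAsFactors = FALSE, row.names = NULL)
  count_by <- function(f) {
    t <- as.data.frame(table(f), stringsAsFactors = FALSE)
    names(t) <- c(names(t)[1L], "n_loci")
    t
  }
  pr <- count_by(loci$repertoire); names(pr)[1L] <- "repertoire"
  ps <- count_by(loci$structure); names(ps)[1L] <- "structure"
  pc <- count_by(loci$chrom); names(pc)[1L] <- "chrom"
  list(loci = loci, per_repertoire = pr, per_structure = ps, per_chrom = pc,
       n_total = nrow(loci))
}

#' Classify tolerisability phenotypes
#'
#' From the LPS-vs-NS and ET-vs-LPS contrasts (computed on the same
#' probesets):
#' tolerisable = induced by LPS and significantly reduced after tolerance
#' (up in LPSvsNS, down in ETvsLPS); non-tolerisable = induced by LPS and
#' not reduced; down-modulated = repressed by LPS; otherwise unclassified.
#' The four classes are disjoint and exhaustive.
#'
#' @param de_lps_ns,de_et_lps data.frames from [moderated_t()] for the
#'   LPS-vs-NS and ET-vs-LPS contrasts.
#' @param config a [de_config()] (cutoffs re-applied for consistency).
#' @param annotation optional; when given, phenotypes are also aggregated
#'   per locus by majority vote over its classified probesets (ties or no
#'   classified probeset give `unclassified`).
#' @return list `probesets` (data.frame `probeset_id, class`) and `loci`
#'   (or `NULL` without annotation).
#' @export
classify_phenotype <- function(de_lps_ns, de_et_lps, config = de_config(),
                               annotation = NULL) {
  if (!setequal(de_lps_ns$probeset_id, de_et_lps$probeset_id) ||
      nrow(de_lps_ns) != nrow(de_et_lps)) {
    stop("the two contrasts cover different probesets", call. = FALSE)
  }
  b <- de_et_lps[match(de_lps_ns$probeset_id, de_et_lps$probeset_id), ,
                 drop = FALSE]
  a <- de_lps_ns
  sig_a <- a$adj_p < config$alpha & abs(a$log2fc) > config$lfc_min
  sig_b <- b$adj_p < config$alpha & abs(b$log2fc) > config$lfc_min
  up_a <- sig_a & a$log2fc > 0
  down_a <- sig_a & a$log2fc < 0
  down_b <- sig_b & b$log2fc < 0
  class <- rep("unclassified", nrow(a))
  class[up_a & down_b] <- "tolerisable"
  class[up_a & !down_b] <- "non_tolerisable"
  class[down_a] <- "down_modulated"
  probesets <- data.frame(probeset_id = a$probeset_id, class = class,
                          stringsAsFactors = FALSE)
  loci <- NULL
  if (!is.null(annotation)) {
    ann <- validate_annotation(annotation)
    m <- match(probesets$probeset_id, ann$probeset_id)
    if (anyNA(m)) stop("probeset(s) without annotation", call. = FALSE)
    cls_by_locus <- split(probesets$class, ann$locus_id[m])
    vote <- vapply(cls_by_locus, function(cl) {
      cl <- cl[cl != "unclassified"]
      if (length(cl) == 0L) return("unclassified")
      t <- sort(table(cl), decreasing = TRUE)
      if (length(t) > 1L && t[1L] == t[2L]) return("unclassified")
      names(t)[1L]
    }, character(1L))
    loci <- data.frame(locus_id = names(vote), class = as.vector(vote),
                       stringsAsFactors = FALSE, row.names = NULL)
  }
  list(probesets = probesets, loci = loci)
}

#' Cluster samples on the most variable probesets
#'
#' Ranks probesets by variance across samples, keeps the top fraction,
#' computes the sample-sample correlation distance (1 - Pearson r) and
#' clusters agglomeratively with the configured linkage. Constant probesets
#' among the selection (undefined correlation) are dropped with a warning.
#'
#' @param matrix log2 intensity matrix (>= 3 samples).
#' @param config a [de_config()].
#' @return list `hclust` (stats::hclust object), `order` (sample labels in
#'   dendrogram order), `heatmap` (selected probesets x reordered samples),
#'   `probesets` (selected ids), `n_dropped`.
#' @export
top_variance_cluster <- function(matrix, config = de_config()) {
  if (ncol(matrix) < 3L) stop("need >= 3 samples to cluster", call. = FALSE)
  v <- rowSums((matrix - rowMeans(matrix))^2) / (ncol(matrix) - 1L)
  n_top <- max(2L, ceiling(config$top_variance_fraction * nrow(matrix)))
  sel <- order(v, decreasing = TRUE)[seq_len(min(n_top, nrow(matrix)))]
  sub <- matrix[sel, , drop = FALSE]
  const <- apply(sub, 1L, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warning(sum(const), " constant probeset(s) dropped from clustering")
    sub <- sub[!const, , drop = FALSE]
  }
  if (nrow(sub) < 2L) stop("fewer than 2 variable probesets", call. = FALSE)
  d <- stats::as.dist(1 - stats::cor(sub))
  hc <- stats::hclust(d, method = config$linkage)
  list(hclust = hc, order = colnames(sub)[hc$order],
       heatmap = sub[, hc$order, drop = FALSE],
       probesets = rownames(sub), n_dropped = sum(const))
}

#' Relative quantification by the 2^-ddCt method
#'
#' `dCt = Ct_target - mean(Ct_refs)` per sample (arithmetic mean of the
#' housekeeping Cts, i.e. geometric-mean normalisation of expression);
#' `ddCt` is taken against the mean dCt of the calibrator condition and the
#' fold change is `2^-ddCt`, so the calibrator condition averages 1.
#'
#' @param ct_target numeric vector of target-assay Ct values per sample.
#' @param ct_refs numeric vector (one reference assay) or matrix/data.frame
#'   (samples x reference assays) of housekeeping Ct values.
#' @param condition character vector of sample conditions.
#' @param calibrator the calibrator condition (default `"NS"`).
#' @return data.frame `condition, dct, ddct, fold_change`.
#' @export
ddct <- function(ct_target, ct_refs, condition, calibrator = "NS") {
  refs <- as.matrix(ct_refs)
  if (nrow(refs) != length(ct_target) ||
      length(condition) != length(ct_target)) {
    stop("ct_target, ct_refs and condition must have matching lengths",
         call. = FALSE)
  }
  if (any(!is.finite(ct_target)) || any(!is.finite(refs))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  if (!calibrator %in% condition) {
    stop("calibrator condition '", calibrator, "' absent", call. = FALSE)
  }
  dct <- ct_target - rowMeans(refs)
  ddct <- dct - mean(dct[condition == calibrator])
  data.frame(condition = condition, dct = dct, ddct = ddct,
             fold_change = 2^(-ddct), stringsAsFactors = FALSE)
}
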
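# Expression calling: CV-calibrated intensity threshold, active-probeset
# calls and transcriptome summaries per repertoire / class / group.

#' Configuration for expression calling
#'
#' @param activity_threshold_log2 log2 intensity a probeset must exceed to
#'   count as positive in a sample (default 5.5, i.e. 2^5.5 linear).
#' @param min_samples minimum number of positive samples for an active call
#'   (default 14).
#' @param n_samples reference design width (default 45); informational,
#'   calls are made over whatever samples the matrix contains.
#' @param cv_limit calibration accepts an intensity level once the
#'   `cv_percentile`-th percentile of the replicate CV above it is below
#'   this limit (default 0.10).
#' @param cv_percentile percentile of the CV distribution used by the
#'   calibration (default 75).
#' @param bin_width_log2 width of the mean-intensity bins scanned by the
#'   calibration (default 0.25).
#' @return list of class `call_config`.
#' @export
call_config <- function(activity_threshold_log2 = 5.5, min_samples = 14L,
                        n_samples = 45L, cv_limit = 0.10,
                        cv_percentile = 75, bin_width_log2 = 0.25) {
  stopifnot(min_samples > 0L, min_samples <= n_samples,
            cv_percentile > 0, cv_percentile < 100,
            cv_limit > 0, bin_width_log2 > 0)
  structure(list(activity_threshold_log2 = activity_threshold_log2,
                 min_samples = as.integer(min_samples),
                 n_samples = as.integer(n_samples),
                 cv_limit = cv_limit, cv_percentile = cv_percentile,
                 bin_width_log2 = bin_width_log2),
            class = "call_config")
}

# Per-probeset replicate CV: linear-scale sd/mean within each donor x
# condition replicate group, averaged over groups (groups with < 2
# replicates are skipped).
replicate_cv <- function(matrix, sheet) {
  sheet <- validate_sample_sheet(sheet)
  idx <- match(colnames(matrix), sheet$sample_id)
  if (anyNA(idx)) {
    stop("matrix samples missing from sample sheet: ",
         paste(colnames(matrix)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  grp <- paste(sheet$donor[idx], sheet$condition[idx], sep = ".")
  lin <- 2^matrix
  cvs <- NULL
  ngrp <- 0L
  for (g in unique(grp)) {
    cols <- which(grp == g)
    if (length(cols) < 2L) next
    sub <- lin[, cols, drop = FALSE]
    m <- rowMeans(sub)
    s <- sqrt(rowSums((sub - m)^2) / (length(cols) - 1L))
    cv <- s / m
    cvs <- if (is.null(cvs)) cv else cvs + cv
    ngrp <- ngrp + 1L
  }
  if (ngrp == 0L) {
    stop("no replicate group with >= 2 samples; cannot compute CV",
         call. = FALSE)
  }
  cvs / ngrp
}

#' Calibrate the positive-intensity threshold
#'
#' Finds the minimal log2 intensity level shared by all repertoires at which
#' signal variability becomes acceptable: probesets are binned by their mean
#' log2 intensity, and the returned threshold is the smallest bin lower edge
#' `t` such that, for every repertoire separately, the `cv_percentile`-th
#' percentile of the replicate CV over probesets with mean `>= t` is below
#' `cv_limit`. The replicate CV of a probeset is the linear-scale sd/mean
#' within each donor x condition replicate group, averaged over groups.
#'
#' @param matrix log2 intensity matrix (probesets x samples).
#' @param annotation validated probeset annotation (for the repertoire of
#'   each probeset).
#' @param sheet sample sheet defining the replicate groups.
#' @param config a [call_config()].
#' @return the calibrated log2 threshold (a bin lower edge).
#' @export
calibrate_threshold <- function(matrix, annotation, sheet,
                                config = call_config()) {
  ann <- validate_annotation(annotation)
  rep_of <- ann$repertoire[match(rownames(matrix), ann$probeset_id)]
  if (anyNA(rep_of)) {
    stop("matrix contains probesets absent from the annotation",
         call. = FALSE)
  }
  cv <- replicate_cv(matrix, sheet)
  means <- rowMeans(matrix)
  w <- config$bin_width_log2
  edges <- seq(floor(min(means) / w) * w, max(means), by = w)
  reps <- unique(rep_of)
  pr <- config$cv_percentile / 100
  for (t in edges) {
    keep <- means >= t
    if (!any(keep)) break
    ok <- TRUE
    for (r in reps) {
      sel <- keep & rep_of == r
      if (!any(sel)) { ok <- FALSE; break }  # repertoire not represented
      if (stats::quantile(cv[sel], pr, names = FALSE) >= config$cv_limit) {
        ok <- FALSE; break
      }
    }
    if (ok) return(t)
  }
  stop("no intensity bin satisfies the CV criterion for all repertoires; ",
       "widen the intensity range of the data or relax cv_limit",
       call. = FALSE)
}

#' Call transcriptionally active probesets
#'
#' A probeset is active when its intensity is strictly over the threshold in
#' at least `min_samples` samples, pooling samples of all conditions.
#'
#' @param matrix log2 intensity matrix.
#' @param config a [call_config()].
#' @return data.frame `probeset_id, n_over, active`.
#' @export
call_active <- function(matrix, config = call_config()) {
  stopifnot(config$min_samples <= ncol(matrix))
  n_over <- rowSums(matrix > config$activity_threshold_log2)
  data.frame(probeset_id = rownames(matrix),
             n_over = as.integer(n_over),
             active = n_over >= config$min_samples,
             stringsAsFactors = FALSE)
}

#' Summarize the transcriptome per repertoire / class / group
#'
#' Counts and percentages of active probesets within each group, each
#' retrovirus class (sum of its member groups, when a class map is given)
#' and each repertoire, plus an overall row. Groups partition the probesets,
#' so class and repertoire rows are exact sums of their members.
#'
#' @param calls output of [call_active()].
#' @param annotation validated probeset annotation covering every called
#'   probeset.
#' @param class_map optional data.frame `group, class` mapping groups to
#'   retrovirus classes (e.g. gamma/beta/spuma for the prototype groups).
#' @return data.frame `level, repertoire, class, group, n_total, n_active,
#'   pct_active`.
#' @export
summarize_transcriptome <- function(calls, annotation, class_map = NULL) {
  ann <- validate_annotation(annotation)
  m <- match(calls$probeset_id, ann$probeset_id)
  if (anyNA(m)) {
    stop("probeset(s) without annotation: ",
         paste(utils::head(calls$probeset_id[is.na(m)], 3L), collapse = ", "),
         call. = FALSE)
  }
  rep_of <- ann$repertoire[m]
  grp_of <- ann$group[m]
  active <- calls$active

  row_for <- function(level, repertoire, class, group, sel) {
    data.frame(level = level, repertoire = repertoire, class = class,
               group = group, n_total = sum(sel),
               n_active = sum(active[sel]),
               pct_active = if (sum(sel) > 0) 100 * sum(active[sel]) / sum(sel)
                            else NA_real_,
               stringsAsFactors = FALSE)
  }

  out <- list(row_for("all", "", "", "", rep(TRUE, length(active))))
  for (r in unique(rep_of)) {
    out[[length(out) + 1L]] <- row_for("repertoire", r, "", "", rep_of == r)
    for (g in unique(grp_of[rep_of == r])) {
      cls <- if (!is.null(class_map) && g %in% class_map$group)
        class_map$class[match(g, class_map$group)] else ""
      out[[length(out) + 1L]] <-
        row_for("group", r, cls, g, rep_of == r & grp_of == g)
    }
  }
  if (!is.null(class_map)) {
    cls_of <- class_map$class[match(grp_of, class_map$group)]
    for (cl in unique(stats::na.omit(cls_of))) {
      sel <- !is.na(cls_of) & cls_of == cl
      out[[length(out) + 1L]] <- row_for("class",
                                         unique(rep_of[sel])[1L], cl, "", sel)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Structural distribution of the chip versus the transcriptome
#'
#' For the precisely annotated prototype repertoire, compares the share of
#' solo LTR, 5' LTR, 3' LTR and internal proviral-gene probesets on the chip
#' with their share among active probesets. Both vectors sum to 1.
#'
#' @param calls output of [call_active()].
#' @param annotation validated probeset annotation.
#' @return data.frame `category, chip_share, transcriptome_share`.
#' @export
structure_distribution <- function(calls, annotation) {
  ann <- validate_annotation(annotation)
  ann <- ann[ann$repertoire == "HERV_prototypes", , drop = FALSE]
  if (nrow(ann) == 0L) stop("no prototype probesets in annotation",
                            call. = FALSE)
  cat_of <- ifelse(ann$region %in% c("gag", "pol", "env", "internal"),
                   "proviral_genes",
                   c(solo = "solo_LTR", five_prime = "five_prime_LTR",
                     three_prime = "three_prime_LTR")[ann$ltr_role])
  active <- calls$active[match(ann$probeset_id, calls$probeset_id)]
  cats <- c("solo_LTR", "five_prime_LTR", "three_prime_LTR",
            "proviral_genes")
  chip <- as.vector(table(factor(cat_of, levels = cats)))
  tx <- as.vector(table(factor(cat_of[active %in% TRUE], levels = cats)))
  out <- data.frame(category = cats,
                    chip_share = chip / sum(chip),
                    transcriptome_share = if (sum(tx) > 0) tx / sum(tx)
                                          else NA_real_,
                    stringsAsFactors = FALSE)
  if (sum(tx) == 0) {
    warning("no active prototype probesets; transcriptome share undefined")
  }
  out
}
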
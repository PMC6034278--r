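# Per-sample functional assignment of attributable LTRs from their U3 and
# U5 probeset signals, and cross-sample combination profiling.
#
# Decision rule (all on the log2 scale, theta = function threshold,
# f = log2 fold change):
#   Pr     <=>  u5 > theta  and  u5 - u3 >= f
#   pA     <=>  u3 > theta  and  u3 - u5 >= f
#   RdT    <=>  u3 > theta  and  u5 > theta  and  |u3 - u5| < f
#   Silent <=>  u3 <= theta and  u5 <= theta
#   Undetermined otherwise.
# The five cases partition the (u3, u5) plane; "at least 3 times higher" is
# read inclusively, so a fold change of exactly 3 is Pr/pA, not RdT.

#' Configuration for LTR function assignment
#'
#' @param function_threshold_log2 positive-signal cutoff used for function
#'   attribution (default 4.5 log2; deliberately lower than the 5.5
#'   expression-calling threshold to retain sensitivity).
#' @param fold_change required U3/U5 linear fold change (default 3).
#' @return list of class `function_config`.
#' @export
function_config <- function(function_threshold_log2 = 4.5, fold_change = 3) {
  stopifnot(fold_change >= 1)
  structure(list(function_threshold_log2 = function_threshold_log2,
                 fold_change = fold_change),
            class = "function_config")
}

#' Assign an LTR function from U3 and U5 signals
#'
#' Vectorised over `u3_log2`/`u5_log2`; see the decision rule in the module
#' header. Exactly one label fires for any pair of finite inputs.
#'
#' @param u3_log2,u5_log2 log2 signals of the U3 and U5 subdomains.
#' @param config a [function_config()].
#' @return factor with levels `Silent, pA, Pr, RdT, Undetermined`.
#' @export
assign_function <- function(u3_log2, u5_log2, config = function_config()) {
  if (any(!is.finite(u3_log2)) || any(!is.finite(u5_log2))) {
    stop("u3_log2 and u5_log2 must be finite", call. = FALSE)
  }
  th <- config$function_threshold_log2
  f <- log2(config$fold_change)
  out <- rep("Undetermined", length(u3_log2))
  out[u3_log2 <= th & u5_log2 <= th] <- "Silent"
  out[u3_log2 > th & u5_log2 > th & abs(u3_log2 - u5_log2) < f] <- "RdT"
  out[u3_log2 > th & (u3_log2 - u5_log2) >= f] <- "pA"
  out[u5_log2 > th & (u5_log2 - u3_log2) >= f] <- "Pr"
  factor(out, levels = FUNCTIONS)
}

# U3 and U5 signal matrices (attributable LTRs x samples): median across
# each LTR's U3 probesets and across its U5 probesets. Median aggregation
# is robust to a single failing probe.
ltr_signal_matrices <- function(matrix, annotation) {
  ann <- validate_annotation(annotation)
  ltrs <- attributable_ltrs(ann)
  if (nrow(ltrs) == 0L) stop("no attributable LTR in annotation",
                             call. = FALSE)
  ann <- ann[ann$region %in% c("U3", "U5") & ann$ltr_role != "none", ,
             drop = FALSE]
  ann <- ann[make_ltr_id(ann$locus_id, ann$ltr_role) %in% ltrs$ltr_id, ,
             drop = FALSE]
  miss <- setdiff(ann$probeset_id, rownames(matrix))
  if (length(miss) > 0L) {
    stop("intensity matrix lacks probeset(s): ",
         paste(utils::head(miss, 3L), collapse = ", "), call. = FALSE)
  }
  one <- function(region) {
    sub <- ann[ann$region == region, , drop = FALSE]
    id <- make_ltr_id(sub$locus_id, sub$ltr_role)
    counts <- table(id)
    m <- matrix(NA_real_, nrow = nrow(ltrs), ncol = ncol(matrix),
                dimnames = list(ltrs$ltr_id, colnames(matrix)))
    single <- names(counts)[counts == 1L]
    if (length(single) > 0L) {
      rows <- sub$probeset_id[match(single, id)]
      m[single, ] <- matrix[rows, , drop = FALSE]
    }
    multi <- names(counts)[counts > 1L]
    for (l in multi) {
      m[l, ] <- apply(matrix[sub$probeset_id[id == l], , drop = FALSE],
                      2L, stats::median)
    }
    m
  }
  list(ltrs = ltrs, u3 = one("U3"), u5 = one("U5"))
}

#' Per-LTR U3/U5 signal summary for one sample
#'
#' Aggregates an attributable LTR's U3 probesets and U5 probesets to one
#' signal each (median across probesets) for the given sample.
#'
#' @param matrix log2 intensity matrix.
#' @param annotation validated probeset annotation.
#' @param sample_id one sample present in the matrix.
#' @param config unused; kept for interface symmetry.
#' @return data.frame `ltr_id, locus_id, ltr_role, u3_log2, u5_log2`.
#' @export
summarize_ltr <- function(matrix, annotation, sample_id,
                          config = function_config()) {
  if (!sample_id %in% colnames(matrix)) {
    stop("sample not in matrix: ", sample_id, call. = FALSE)
  }
  sm <- ltr_signal_matrices(matrix, annotation)
  data.frame(sm$ltrs,
             u3_log2 = sm$u3[, sample_id],
             u5_log2 = sm$u5[, sample_id],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call LTR functions for every attributable LTR in every sample
#'
#' @param matrix log2 intensity matrix.
#' @param annotation validated probeset annotation.
#' @param sheet sample sheet (samples must cover the matrix columns).
#' @param config a [function_config()].
#' @return list with `calls` (long data.frame `ltr_id, sample_id, func,
#'   u3_log2, u5_log2`; one row per attributable LTR per sample) and
#'   `tally` (per-sample counts and percentages of each function).
#' @export
call_all_functions <- function(matrix, annotation, sheet,
                               config = function_config()) {
  sheet <- validate_sample_sheet(sheet)
  miss <- setdiff(colnames(matrix), sheet$sample_id)
  if (length(miss) > 0L) {
    stop("matrix sample(s) absent from sheet: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  sm <- ltr_signal_matrices(matrix, annotation)
  nl <- nrow(sm$ltrs)
  ns <- ncol(matrix)
  u3 <- as.vector(sm$u3)
  u5 <- as.vector(sm$u5)
  func <- assign_function(u3, u5, config)
  calls <- data.frame(
    ltr_id = rep(sm$ltrs$ltr_id, times = ns),
    sample_id = rep(colnames(matrix), each = nl),
    func = func,
    u3_log2 = u3, u5_log2 = u5,
    stringsAsFactors = FALSE)
  tal <- as.data.frame(table(sample_id = calls$sample_id, func = calls$func),
                       stringsAsFactors = FALSE)
  names(tal)[names(tal) == "Freq"] <- "n"
  tal$pct <- 100 * tal$n / nl
  list(calls = calls, tally = tal)
}

# canonical combination label: functions joined in fixed order
combination_category <- function(has_silent, has_pa, has_pr, has_rdt) {
  parts <- cbind(ifelse(has_silent, "Silent", NA),
                 ifelse(has_pa, "pA", NA),
                 ifelse(has_pr, "Pr", NA),
                 ifelse(has_rdt, "RdT", NA))
  apply(parts, 1L, function(x) paste(stats::na.omit(x), collapse = "/"))
}

#' Profile cross-sample function combinations per LTR
#'
#' LTRs called Undetermined in at least one sample are excluded (and
#' counted); the rest are categorised by the set of functions observed
#' across samples, joined in the fixed order Silent/pA/Pr/RdT (e.g.
#' `"Silent"`, `"Silent/Pr"`, `"Silent/pA/Pr"`).
#'
#' @param calls the `calls` data.frame (or the list) from
#'   [call_all_functions()]. Every LTR must be called in every sample.
#' @return list with `profiles` (data.frame `ltr_id, category, excluded,
#'   n_functions, pr_pa_switch`), `combination_counts` (category counts over
#'   non-excluded LTRs) and `n_excluded`.
#' @export
profile_functions <- function(calls) {
  if (is.list(calls) && !is.data.frame(calls) && !is.null(calls$calls)) {
    calls <- calls$calls
  }
  tab <- table(calls$ltr_id, factor(calls$func, levels = FUNCTIONS))
  cover <- rowSums(tab)
  if (length(unique(cover)) > 1L) {
    stop("incomplete sample coverage: LTRs are called in differing numbers ",
         "of samples", call. = FALSE)
  }
  excluded <- tab[, "Undetermined"] > 0L
  has <- tab[, c("Silent", "pA", "Pr", "RdT"), drop = FALSE] > 0L
  category <- combination_category(has[, "Silent"], has[, "pA"],
                                   has[, "Pr"], has[, "RdT"])
  n_fun <- rowSums(has)
  profiles <- data.frame(
    ltr_id = rownames(tab),
    category = ifelse(excluded, "Undetermined", category),
    excluded = as.vector(excluded),
    n_functions = as.integer(n_fun),
    pr_pa_switch = as.vector(has[, "Pr"] & has[, "pA"]),
    stringsAsFactors = FALSE, row.names = NULL)
  kept <- profiles[!profiles$excluded, , drop = FALSE]
  cc <- as.data.frame(table(category = kept$category),
                      stringsAsFactors = FALSE)
  names(cc)[names(cc) == "Freq"] <- "n"
  cc <- cc[order(-cc$n), , drop = FALSE]
  rownames(cc) <- NULL
  list(profiles = profiles, combination_counts = cc,
       n_excluded = sum(excluded))
}

#' Summarise operational determinism of LTR functions
#'
#' Over non-excluded LTRs: the fraction showing a single function across all
#' samples (constitutive), the fraction shifting between two or more
#' functions, and the fraction whose observed set contains both promoter and
#' polyA (the rare Pr/pA switch).
#'
#' @param profiles output of [profile_functions()] (list or its `profiles`
#'   data.frame).
#' @return list `constitutive_fraction, shifting_fraction,
#'   pr_pa_switch_fraction, n_ltrs, n_excluded, counts` (per-category
#'   counts).
#' @export
determinism_summary <- function(profiles) {
  if (is.list(profiles) && !is.data.frame(profiles) &&
      !is.null(profiles$profiles)) {
    profiles <- profiles$profiles
  }
  kept <- profiles[!profiles$excluded, , drop = FALSE]
  if (nrow(kept) == 0L) {
    stop("no non-excluded LTR profile to summarise", call. = FALSE)
  }
  counts <- as.data.frame(table(category = kept$category),
                          stringsAsFactors = FALSE)
  names(counts)[names(counts) == "Freq"] <- "n"
  list(
    constitutive_fraction = mean(kept$n_functions == 1L),
    shifting_fraction = mean(kept$n_functions >= 2L),
    pr_pa_switch_fraction = mean(kept$pr_pa_switch),
    n_ltrs = nrow(kept),
    n_excluded = sum(profiles$excluded),
    counts = counts
  )
}
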
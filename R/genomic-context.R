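# Genomic environment of functional versus silent LTRs: intragenic /
# intergenic status, orientation relative to the host gene, intron overlap,
# strand-resolved nearest-gene distances and gene-density ratios.
# All internal coordinates are 0-based half-open.

#' Read gene annotation from BED6 or GFF3
#'
#' BED6 provides gene intervals only; GFF3 may additionally provide exon
#' rows (`Parent` linking exons to genes), enabling intron-overlap calls.
#' Coordinates are converted to the internal 0-based half-open convention.
#'
#' @param path a `.bed` or `.gff`/`.gff3` file.
#' @return list with `genes` (data.frame `gene_id, chrom, start, end,
#'   strand`) and `exons` (same shape plus `gene_id` of the parent, or
#'   `NULL` for BED input).
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("gene annotation not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    genes <- data.frame(
      gene_id = if (!is.null(gr$name)) gr$name else
        as.character(seq_along(gr)),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
    return(list(genes = genes, exons = NULL))
  }
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "GFF3")
    as_df <- function(sub, id) {
      data.frame(gene_id = id,
                 chrom = as.character(GenomicRanges::seqnames(sub)),
                 start = GenomicRanges::start(sub) - 1L,
                 end = GenomicRanges::end(sub),
                 strand = as.character(GenomicRanges::strand(sub)),
                 stringsAsFactors = FALSE)
    }
    g <- gr[gr$type == "gene"]
    e <- gr[gr$type == "exon"]
    genes <- as_df(g, if (!is.null(g$ID)) g$ID else
      as.character(seq_along(g)))
    exons <- if (length(e) > 0L) {
      parent <- vapply(as.list(e$Parent), function(x)
        if (length(x)) x[[1L]] else NA_character_, character(1L))
      as_df(e, parent)
    } else NULL
    return(list(genes = genes, exons = exons))
  }
  stop("unsupported gene annotation format: ", ext, call. = FALSE)
}

check_gene_models <- function(genes, exons) {
  if (is.null(exons)) return(invisible(NULL))
  m <- match(exons$gene_id, genes$gene_id)
  if (anyNA(m)) stop("exon with unknown parent gene", call. = FALSE)
  bad <- exons$chrom != genes$chrom[m] |
    exons$start < genes$start[m] | exons$end > genes$end[m]
  if (any(bad)) {
    stop("malformed gene model: exon outside its gene (",
         paste(utils::head(unique(exons$gene_id[bad]), 3L), collapse = ", "),
         ")", call. = FALSE)
  }
  invisible(NULL)
}

df_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end),
                         strand = x$strand)
}

# Nearest gap to genes entirely left / right of each interval, per strand
# class; Inf when no such gene exists on the chromosome.
directional_gaps <- function(iv, genes) {
  n <- nrow(iv)
  out <- list("left+" = rep(Inf, n), "left-" = rep(Inf, n),
              "right+" = rep(Inf, n), "right-" = rep(Inf, n))
  for (ch in unique(iv$chrom)) {
    q <- which(iv$chrom == ch)
    for (s in c("+", "-")) {
      g <- genes[genes$chrom == ch & genes$strand == s, , drop = FALSE]
      if (nrow(g) == 0L) next
      ends <- sort(g$end)
      starts <- sort(g$start)
      cnt <- findInterval(iv$start[q], ends)
      has <- cnt >= 1L
      out[[paste0("left", s)]][q[has]] <-
        iv$start[q][has] - ends[cnt[has]]
      cnt2 <- findInterval(iv$end[q] - 1L, starts) + 1L
      has2 <- cnt2 <= length(starts)
      out[[paste0("right", s)]][q[has2]] <-
        starts[cnt2[has2]] - iv$end[q][has2]
    }
  }
  out
}

#' Characterise the genomic context of LTRs
#'
#' For each LTR interval: intragenic status (>= 1 bp intersection with a
#' gene, either strand), orientation relative to the host gene (the gene
#' with the largest overlap when several apply), intron overlap (overlaps a
#' gene but no exon; `NA` when the annotation has no exon models), and the
#' four nearest gap distances upstream/downstream x sense/antisense.
#' Upstream/downstream are relative to the LTR's strand; sense means the
#' gene lies on the same strand as the LTR.
#'
#' @param ltrs data.frame of LTR intervals (`ltr_id, chrom, start, end,
#'   strand`), e.g. from [ltr_intervals()].
#' @param gene_annotation list from [read_gene_annotation()], or a
#'   data.frame of gene intervals.
#' @return data.frame `ltr_id, status, orientation_vs_gene, intron_overlap,
#'   dist_upstream_sense, dist_upstream_antisense, dist_downstream_sense,
#'   dist_downstream_antisense, host_gene`.
#' @export
classify_context <- function(ltrs, gene_annotation) {
  if (is.data.frame(gene_annotation)) {
    gene_annotation <- list(genes = gene_annotation, exons = NULL)
  }
  genes <- gene_annotation$genes
  exons <- gene_annotation$exons
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(genes)))
  if (!"gene_id" %in% names(genes)) {
    genes$gene_id <- as.character(seq_len(nrow(genes)))
  }
  check_gene_models(genes, exons)

  lgr <- df_granges(ltrs)
  ggr <- df_granges(genes)
  hits <- GenomicRanges::findOverlaps(lgr, ggr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ow <- GenomicRanges::width(IRanges::pintersect(
    IRanges::ranges(lgr)[qh], IRanges::ranges(ggr)[sh]))
  # host gene = largest overlap
  host <- rep(NA_integer_, nrow(ltrs))
  if (length(qh) > 0L) {
    ord <- order(qh, -ow)
    first <- !duplicated(qh[ord])
    host[qh[ord][first]] <- sh[ord][first]
  }
  intragenic <- !is.na(host)
  orientation <- ifelse(
    intragenic,
    ifelse(genes$strand[host] == ltrs$strand, "sense", "antisense"),
    NA_character_)

  intron <- rep(NA, nrow(ltrs))
  if (!is.null(exons)) {
    egr <- df_granges(exons)
    in_exon <- GenomicRanges::countOverlaps(lgr, egr,
                                            ignore.strand = TRUE) > 0L
    intron <- intragenic & !in_exon
  }

  # upstream on a '+' LTR is genomic left, on a '-' LTR genomic right;
  # sense = gene on the same strand as the LTR
  gaps <- directional_gaps(ltrs, genes)
  plus <- ltrs$strand == "+"
  d_up_s <- ifelse(plus, gaps[["left+"]], gaps[["right-"]])
  d_up_a <- ifelse(plus, gaps[["left-"]], gaps[["right+"]])
  d_dn_s <- ifelse(plus, gaps[["right+"]], gaps[["left-"]])
  d_dn_a <- ifelse(plus, gaps[["right-"]], gaps[["left+"]])

  data.frame(
    ltr_id = ltrs$ltr_id,
    status = ifelse(intragenic, "intragenic", "intergenic"),
    orientation_vs_gene = orientation,
    intron_overlap = intron,
    dist_upstream_sense = d_up_s,
    dist_upstream_antisense = d_up_a,
    dist_downstream_sense = d_dn_s,
    dist_downstream_antisense = d_dn_a,
    host_gene = ifelse(intragenic, genes$gene_id[host], NA_character_),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Gene-density ratio around promoter versus silent LTRs
#'
#' Counts the distinct genes overlapping a window centred on each LTR
#' midpoint and returns the ratio of the mean count over constitutive
#' promoter LTRs to the mean over constitutive silent LTRs.
#'
#' @param ltrs data.frame of LTR intervals (`ltr_id, chrom, start, end`).
#' @param profiles `profiles` data.frame (or list) from
#'   [profile_functions()].
#' @param gene_annotation list from [read_gene_annotation()] or a gene
#'   data.frame.
#' @param window_bp window width in bp (default 100000).
#' @return list `ratio, mean_promoter, mean_silent, n_promoter, n_silent`.
#' @export
density_ratio <- function(ltrs, profiles, gene_annotation,
                          window_bp = 100000L) {
  if (is.list(profiles) && !is.data.frame(profiles) &&
      !is.null(profiles$profiles)) {
    profiles <- profiles$profiles
  }
  if (is.data.frame(gene_annotation)) {
    gene_annotation <- list(genes = gene_annotation)
  }
  genes <- gene_annotation$genes
  cat_of <- profiles$category[match(ltrs$ltr_id, profiles$ltr_id)]
  pr <- which(cat_of == "Pr")
  sil <- which(cat_of == "Silent")
  if (length(pr) == 0L || length(sil) == 0L) {
    stop("need at least one constitutive promoter and one silent LTR",
         call. = FALSE)
  }
  mid <- (ltrs$start + ltrs$end) %/% 2L
  half <- as.integer(window_bp) %/% 2L
  win <- GenomicRanges::GRanges(
    ltrs$chrom,
    IRanges::IRanges(pmax(mid - half, 0L) + 1L, mid + half))
  counts <- GenomicRanges::countOverlaps(win, df_granges(genes),
                                         ignore.strand = TRUE)
  list(ratio = mean(counts[pr]) / mean(counts[sil]),
       mean_promoter = mean(counts[pr]),
       mean_silent = mean(counts[sil]),
       n_promoter = length(pr), n_silent = length(sil))
}
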
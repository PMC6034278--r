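# Integration of HERV/MaLR loci into gene pathways by co-expression with
# pathway-exclusive genes, and the bipartite locus-pathway network.

#' Read a pathway-membership table
#'
#' TSV with columns `gene_symbol, pathway_id, pathway_significant`
#' (logical) and optional `z_score`; (gene, pathway) pairs must be unique.
#' Pathway activation calls are consumed as input, not computed.
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
read_pathway_table <- function(path) {
  if (!file.exists(path)) stop("pathway table not found: ", path,
                               call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  validate_pathway_table(tab)
}

#' @rdname read_pathway_table
#' @param table data.frame to validate.
#' @export
validate_pathway_table <- function(table) {
  req <- c("gene_symbol", "pathway_id", "pathway_significant")
  missing <- setdiff(req, names(table))
  if (length(missing) > 0L) {
    stop("pathway table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  table$pathway_significant <- as.logical(table$pathway_significant)
  if (anyNA(table$pathway_significant)) {
    stop("pathway_significant must be logical", call. = FALSE)
  }
  if (anyDuplicated(table[, c("gene_symbol", "pathway_id")])) {
    stop("duplicated (gene, pathway) pair in pathway table", call. = FALSE)
  }
  invisible(table)
}

#' Select genes exclusive to one significant pathway
#'
#' @param pathway_table validated pathway table.
#' @return data.frame `gene_symbol, pathway_id`: genes appearing in exactly
#'   one significant pathway.
#' @export
select_exclusive_genes <- function(pathway_table) {
  tab <- validate_pathway_table(pathway_table)
  sig <- tab[tab$pathway_significant, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(data.frame(gene_symbol = character(), pathway_id = character(),
                      stringsAsFactors = FALSE))
  }
  cnt <- table(sig$gene_symbol)
  keep <- names(cnt)[cnt == 1L]
  out <- sig[sig$gene_symbol %in% keep, c("gene_symbol", "pathway_id"),
             drop = FALSE]
  out <- out[order(out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlate retroelement probesets with pathway-exclusive genes
#'
#' Pearson correlation on log2 intensities across all samples between each
#' HERV/MaLR probeset and each gene probeset; probeset-level hits are
#' collapsed to locus level by the maximum correlation across the locus's
#' probesets. The threshold is inclusive (`>= r_min`).
#'
#' @param matrix log2 intensity matrix.
#' @param herv_probesets character vector of retroelement probesets to test
#'   (typically the expressed ones).
#' @param gene_probesets character vector of gene probesets (typically those
#'   of the exclusive genes).
#' @param annotation validated probeset annotation (maps probesets to loci
#'   and gene symbols).
#' @param r_min correlation threshold (default 0.8).
#' @return data.frame `herv_locus_id, gene_symbol, correlation,
#'   n_probesets` (probesets of the locus passing the threshold for that
#'   gene).
#' @export
correlate_herv_genes <- function(matrix, herv_probesets, gene_probesets,
                                 annotation, r_min = 0.8) {
  ann <- validate_annotation(annotation)
  herv_probesets <- intersect(herv_probesets, rownames(matrix))
  gene_probesets <- intersect(gene_probesets, rownames(matrix))
  if (length(herv_probesets) == 0L || length(gene_probesets) == 0L) {
    return(data.frame(herv_locus_id = character(), gene_symbol = character(),
                      correlation = numeric(), n_probesets = integer(),
                      stringsAsFactors = FALSE))
  }
  h <- matrix[herv_probesets, , drop = FALSE]
  g <- matrix[gene_probesets, , drop = FALSE]
  const_h <- apply(h, 1L, function(x) stats::sd(x) == 0)
  const_g <- apply(g, 1L, function(x) stats::sd(x) == 0)
  if (any(const_h) || any(const_g)) {
    warning(sum(const_h) + sum(const_g),
            " constant profile(s) skipped (undefined correlation)")
    h <- h[!const_h, , drop = FALSE]
    g <- g[!const_g, , drop = FALSE]
  }
  if (nrow(h) == 0L || nrow(g) == 0L) {
    return(data.frame(herv_locus_id = character(), gene_symbol = character(),
                      correlation = numeric(), n_probesets = integer(),
                      stringsAsFactors = FALSE))
  }
  cc <- stats::cor(t(h), t(g))
  hit <- which(cc >= r_min, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    return(data.frame(herv_locus_id = character(), gene_symbol = character(),
                      correlation = numeric(), n_probesets = integer(),
                      stringsAsFactors = FALSE))
  }
  locus <- ann$locus_id[match(rownames(h)[hit[, 1L]], ann$probeset_id)]
  gene <- ann$locus_id[match(rownames(g)[hit[, 2L]], ann$probeset_id)]
  r <- cc[hit]
  key <- paste(locus, gene, sep = "\r")
  ord <- order(key, -r)
  first <- !duplicated(key[ord])
  out <- data.frame(
    herv_locus_id = locus[ord][first],
    gene_symbol = gene[ord][first],
    correlation = r[ord][first],
    n_probesets = as.integer(table(key)[key[ord][first]]),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$herv_locus_id, out$gene_symbol), , drop = FALSE]
}

#' Build the bipartite locus-pathway network
#'
#' Loci inherit the pathways of the exclusive genes they correlate with;
#' the bipartite graph connects loci to pathways (edge weight = number of
#' supporting genes). Loci in exactly one pathway are "exclusive", loci in
#' two or more are "shared"; per-repertoire totals sum to the overall locus
#' count.
#'
#' @param edges data.frame from [correlate_herv_genes()].
#' @param exclusive_genes data.frame from [select_exclusive_genes()].
#' @param annotation optional validated annotation for per-repertoire
#'   totals.
#' @return list `graph` (igraph bipartite graph), `membership` (per-locus
#'   pathway count and list), `n_exclusive`, `n_shared`, `per_repertoire`.
#' @export
build_network <- function(edges, exclusive_genes, annotation = NULL) {
  m <- match(edges$gene_symbol, exclusive_genes$gene_symbol)
  if (anyNA(m)) {
    stop("edge gene(s) not in the exclusive-gene set: ",
         paste(utils::head(unique(edges$gene_symbol[is.na(m)]), 3L),
               collapse = ", "), call. = FALSE)
  }
  ep <- data.frame(locus = edges$herv_locus_id,
                   pathway = exclusive_genes$pathway_id[m],
                   stringsAsFactors = FALSE)
  ep <- ep[!duplicated(ep), , drop = FALSE]
  loci <- sort(unique(ep$locus))
  n_path <- vapply(split(ep$pathway, ep$locus), length, integer(1L))[loci]
  membership <- data.frame(
    herv_locus_id = loci,
    n_pathways = as.integer(n_path),
    pathways = vapply(split(ep$pathway, ep$locus),
                      function(x) paste(sort(x), collapse = ","),
                      character(1L))[loci],
    stringsAsFactors = FALSE, row.names = NULL)
  paths <- sort(unique(ep$pathway))
  weight <- as.integer(table(paste(edges$herv_locus_id,
                                   exclusive_genes$pathway_id[m]))[
                         paste(ep$locus, ep$pathway)])
  graph <- igraph::graph_from_data_frame(
    cbind(ep, weight = weight), directed = FALSE,
    vertices = data.frame(name = c(loci, paths),
                          type = rep(c(FALSE, TRUE),
                                     c(length(loci), length(paths)))))
  per_rep <- NULL
  if (!is.null(annotation)) {
    ann <- validate_annotation(annotation)
    rep_of <- ann$repertoire[match(loci, ann$locus_id)]
    per_rep <- as.data.frame(table(repertoire = rep_of),
                             stringsAsFactors = FALSE)
    names(per_rep)[names(per_rep) == "Freq"] <- "n_loci"
  }
  list(graph = graph, membership = membership,
       n_exclusive = sum(membership$n_pathways == 1L),
       n_shared = sum(membership$n_pathways >= 2L),
       per_repertoire = per_rep)
}

#' Flag network loci in the vicinity of genes
#'
#' The distance between a locus and a gene is the minimal gap between their
#' intervals (0 when overlapping); loci on a chromosome without genes get
#' infinite distance. The flag is inclusive (`distance <= max_dist`).
#'
#' @param edges data.frame with a `herv_locus_id` column (e.g. from
#'   [correlate_herv_genes()] or the membership table).
#' @param annotation validated probeset annotation (locus coordinates).
#' @param gene_annotation data.frame or GRanges of gene intervals; a
#'   data.frame needs columns `chrom, start, end` (0-based half-open) and
#'   optionally `gene_id`.
#' @param max_dist distance cutoff in bp (default 40000).
#' @return `edges` with columns `distance_bp, near_gene, nearest_gene`
#'   appended (one row per distinct locus in the membership case).
#' @export
proximity_annotate <- function(edges, annotation, gene_annotation,
                               max_dist = 40000L) {
  ann <- validate_annotation(annotation)
  genes <- as_gene_granges(gene_annotation)
  loci <- unique(edges$herv_locus_id)
  iv <- locus_intervals(ann)
  iv <- iv[match(loci, iv$locus_id), , drop = FALSE]
  if (anyNA(iv$locus_id)) {
    stop("locus coordinates missing from annotation", call. = FALSE)
  }
  lg <- GenomicRanges::GRanges(
    iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end))
  nd <- GenomicRanges::distanceToNearest(lg, genes, ignore.strand = TRUE)
  dist <- rep(Inf, length(lg))
  nearest <- rep(NA_character_, length(lg))
  qh <- S4Vectors::queryHits(nd)
  dist[qh] <- S4Vectors::mcols(nd)$distance
  gene_ids <- if (!is.null(genes$gene_id)) genes$gene_id else
    as.character(seq_along(genes))
  nearest[qh] <- gene_ids[S4Vectors::subjectHits(nd)]
  i <- match(edges$herv_locus_id, loci)
  edges$distance_bp <- dist[i]
  edges$near_gene <- dist[i] <= max_dist
  edges$nearest_gene <- nearest[i]
  edges
}

# Coerce a gene annotation (data.frame with 0-based half-open coords, list
# from read_gene_annotation, or GRanges) to GRanges.
as_gene_granges <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  if (is.list(x) && !is.data.frame(x) && !is.null(x$genes)) x <- x$genes
  if (methods::is(x, "GRanges")) return(x)
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  gr <- GenomicRanges::GRanges(
    x$chrom, IRanges::IRanges(x$start + 1L, x$end),
    strand = if ("strand" %in% names(x)) x$strand else "*")
  gr$gene_id <- if ("gene_id" %in% names(x)) x$gene_id else
    as.character(seq_len(nrow(x)))
  gr
}
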
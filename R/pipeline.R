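# End-to-end orchestration: simulate (or load) -> expression calling ->
# LTR function profiling -> differential expression -> phenotypes ->
# clustering -> pathway network -> genomic context, with a machine-readable
# JSON report and an md5 manifest of every output.

#' Pipeline configuration
#'
#' In demo mode the synthetic generator provides all inputs; otherwise the
#' annotation/matrix/sheet (and optionally gene annotation and pathway
#' table) are read from the given paths, which must exist.
#'
#' @param outdir output directory (created if needed).
#' @param seed integer seed; in demo mode it overrides the generator seed.
#' @param demo generate inputs with [simulate_chip()] (default `TRUE`).
#' @param sim a [sim_params()] for demo mode.
#' @param annotation_path,matrix_path,sheet_path input TSVs (non-demo).
#' @param gene_annotation_path optional BED6/GFF3 for the context stage.
#' @param pathway_table_path optional pathway TSV for the network stage.
#' @param call,func,de stage configurations ([call_config()],
#'   [function_config()], [de_config()]).
#' @param r_min correlation threshold of the network stage.
#' @param max_dist gene-proximity cutoff in bp.
#' @param use_calibrated use the calibrated threshold instead of the
#'   configured `activity_threshold_log2` for expression calls (default
#'   `FALSE`: the calibrated value is reported, the configured one applied).
#' @return list of class `run_config`.
#' @export
run_config <- function(outdir, seed = 1L, demo = TRUE,
                       sim = NULL,
                       annotation_path = NULL, matrix_path = NULL,
                       sheet_path = NULL, gene_annotation_path = NULL,
                       pathway_table_path = NULL,
                       call = call_config(), func = function_config(),
                       de = de_config(), r_min = 0.8, max_dist = 40000L,
                       use_calibrated = FALSE) {
  if (demo) {
    if (is.null(sim)) sim <- sim_params(seed = seed)
    sim$seed <- as.integer(seed)
  } else {
    if (is.null(annotation_path) || is.null(matrix_path) ||
        is.null(sheet_path)) {
      stop("non-demo mode requires annotation_path, matrix_path and ",
           "sheet_path", call. = FALSE)
    }
    for (p in c(annotation_path, matrix_path, sheet_path)) {
      if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
    }
    for (p in c(gene_annotation_path, pathway_table_path)) {
      if (!is.null(p) && !file.exists(p)) {
        stop("input file not found: ", p, call. = FALSE)
      }
    }
  }
  structure(list(outdir = outdir, seed = as.integer(seed), demo = demo,
                 sim = sim, annotation_path = annotation_path,
                 matrix_path = matrix_path, sheet_path = sheet_path,
                 gene_annotation_path = gene_annotation_path,
                 pathway_table_path = pathway_table_path,
                 call = call, func = func, de = de, r_min = r_min,
                 max_dist = as.integer(max_dist),
                 use_calibrated = use_calibrated),
            class = "run_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes the stages in order (simulate -> call -> ltr-function -> de ->
#' phenotype -> cluster -> network -> context), writing one TSV (or Newick /
#' GraphML) per output plus a JSON report embedding the configuration, the
#' per-stage summaries and an md5 manifest. Fully reproducible from
#' (config, seed). A stage failure halts the run with the stage name.
#'
#' @param config a [run_config()].
#' @return the report list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, demo = config$demo, stages = list())
  t_all <- proc.time()[["elapsed"]]
  outputs <- character()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    message(sprintf("[retrotome] stage %-12s ...", name))
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s (partial outputs in %s)",
                   name, conditionMessage(e), config$outdir), call. = FALSE)
    })
    message(sprintf("[retrotome] stage %-12s done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  emit <- function(x, file) {
    path <- file.path(config$outdir, file)
    write_tsv(x, path)
    outputs <<- c(outputs, path)
    path
  }

  ## inputs ---------------------------------------------------------------
  dat <- stage("inputs", {
    if (config$demo) {
      d <- simulate_chip(config$sim)
      emit(d$annotation, "annotation.tsv")
      emit(d$sheet, "samples.tsv")
      path <- file.path(config$outdir, "matrix.tsv")
      write_matrix(d$matrix, path)
      outputs <- c(outputs, path)
      emit(d$truth$loci, "truth_loci.tsv")
      if (!is.null(d$truth$ltrs)) emit(d$truth$ltrs, "truth_ltrs.tsv")
      emit(d$truth$probesets, "truth_probesets.tsv")
      d
    } else {
      sheet <- read_sample_sheet(config$sheet_path)
      list(annotation = read_annotation(config$annotation_path),
           sheet = sheet,
           matrix = read_matrix(config$matrix_path, sheet),
           truth = NULL)
    }
  })

  ## expression calling ---------------------------------------------------
  calls <- stage("call", {
    thr <- tryCatch(
      calibrate_threshold(dat$matrix, dat$annotation, dat$sheet,
                          config$call),
      error = function(e) NA_real_)
    cfg <- config$call
    if (config$use_calibrated && is.finite(thr)) {
      cfg$activity_threshold_log2 <- thr
    }
    ac <- call_active(dat$matrix, cfg)
    emit(ac, "activity_calls.tsv")
    summ <- summarize_transcriptome(ac, dat$annotation,
                                    class_map = PROTO_GROUPS)
    emit(summ, "transcriptome_summary.tsv")
    sd <- structure_distribution(ac, dat$annotation)
    emit(sd, "structure_distribution.tsv")
    report$stages$call <- list(
      calibrated_threshold_log2 = thr,
      applied_threshold_log2 = cfg$activity_threshold_log2,
      n_active = sum(ac$active),
      pct_active = 100 * mean(ac$active))
    list(calls = ac, threshold = thr)
  })

  ## LTR function ---------------------------------------------------------
  fun <- stage("ltr-function", {
    cf <- call_all_functions(dat$matrix, dat$annotation, dat$sheet,
                             config$func)
    emit(cf$tally, "ltr_function_tally.tsv")
    prof <- profile_functions(cf)
    emit(prof$profiles, "ltr_profiles.tsv")
    emit(prof$combination_counts, "ltr_combination_counts.tsv")
    det <- determinism_summary(prof)
    emit(data.frame(metric = c("constitutive_fraction", "shifting_fraction",
                               "pr_pa_switch_fraction", "n_ltrs",
                               "n_excluded"),
                    value = c(det$constitutive_fraction,
                              det$shifting_fraction,
                              det$pr_pa_switch_fraction,
                              det$n_ltrs, det$n_excluded)),
         "ltr_determinism.tsv")
    report$stages$ltr_function <- det[c("constitutive_fraction",
                                         "shifting_fraction",
                                         "pr_pa_switch_fraction",
                                         "n_ltrs", "n_excluded")]
    list(calls = cf, profiles = prof)
  })

  ## differential expression ----------------------------------------------
  de <- stage("de", {
    res <- list()
    for (ct in list(c("LPS", "NS"), c("ET", "LPS"))) {
      nm <- paste(ct, collapse = "_vs_")
      r <- moderated_t(dat$matrix, dat$sheet, ct, config$de)
      emit(r, sprintf("de_%s.tsv", nm))
      cd <- call_de(r, config$de)
      agg <- aggregate_loci(r, dat$annotation)
      if (agg$n_total > 0L) {
        emit(agg$loci, sprintf("del_%s.tsv", nm))
      }
      report$stages$de[[nm]] <- list(n_up = cd$n_up, n_down = cd$n_down,
                                      n_del = agg$n_total)
      res[[nm]] <- r
    }
    res
  })

  ## phenotype ------------------------------------------------------------
  stage("phenotype", {
    ph <- classify_phenotype(de$LPS_vs_NS, de$ET_vs_LPS, config$de,
                             annotation = dat$annotation)
    emit(ph$probesets, "phenotype_probesets.tsv")
    emit(ph$loci, "phenotype_loci.tsv")
    report$stages$phenotype <- as.list(table(ph$loci$class))
    ph
  })

  ## clustering -----------------------------------------------------------
  stage("cluster", {
    cl <- top_variance_cluster(dat$matrix, config$de)
    nwk <- file.path(config$outdir, "sample_dendrogram.nwk")
    ape::write.tree(ape::as.phylo(cl$hclust), file = nwk)
    outputs <- c(outputs, nwk)
    hm <- data.frame(probeset_id = rownames(cl$heatmap), cl$heatmap,
                     check.names = FALSE)
    emit(hm, "heatmap_matrix.tsv")
    report$stages$cluster <- list(n_probesets = length(cl$probesets))
    NULL
  })

  ## pathway network ------------------------------------------------------
  stage("network", {
    ptab <- if (config$demo) {
      generate_pathway_table(dat$truth)
    } else if (!is.null(config$pathway_table_path)) {
      read_pathway_table(config$pathway_table_path)
    } else NULL
    if (is.null(ptab) || nrow(ptab) == 0L) {
      report$stages$network <- list(skipped = "no pathway table")
      return(NULL)
    }
    excl <- select_exclusive_genes(ptab)
    ann <- dat$annotation
    active_ids <- calls$calls$probeset_id[calls$calls$active]
    herv_pb <- intersect(
      active_ids, ann$probeset_id[ann$repertoire != "gene"])
    gene_pb <- ann$probeset_id[ann$locus_id %in% excl$gene_symbol]
    edges <- correlate_herv_genes(dat$matrix, herv_pb, gene_pb, ann,
                                  r_min = config$r_min)
    emit(edges, "network_edges.tsv")
    if (nrow(edges) > 0L) {
      net <- build_network(edges, excl, annotation = ann)
      gml <- file.path(config$outdir, "network.graphml")
      igraph::write_graph(net$graph, gml, format = "graphml")
      outputs <- c(outputs, gml)
      memb <- net$membership
      gene_ann <- if (config$demo) dat$truth$gene_models$genes else
        if (!is.null(config$gene_annotation_path))
          read_gene_annotation(config$gene_annotation_path)$genes else NULL
      if (!is.null(gene_ann)) {
        memb <- proximity_annotate(memb, ann, gene_ann, config$max_dist)
      }
      emit(memb, "network_membership.tsv")
      report$stages$network <- list(
        n_edges = nrow(edges), n_loci = nrow(net$membership),
        n_exclusive = net$n_exclusive, n_shared = net$n_shared)
    } else {
      report$stages$network <- list(n_edges = 0L, n_loci = 0L)
    }
    NULL
  })

  ## genomic context ------------------------------------------------------
  stage("context", {
    gmod <- if (config$demo) {
      gm <- dat$truth$gene_models
      if (is.null(gm$genes)) NULL else gm
    } else if (!is.null(config$gene_annotation_path)) {
      read_gene_annotation(config$gene_annotation_path)
    } else NULL
    if (is.null(gmod)) {
      report$stages$context <- list(skipped = "no gene annotation")
      return(NULL)
    }
    iv <- ltr_intervals(dat$annotation)
    at <- attributable_ltrs(dat$annotation)
    iv <- iv[iv$ltr_id %in% at$ltr_id, , drop = FALSE]
    ctx <- classify_context(iv, gmod)
    emit(ctx, "genomic_context.tsv")
    dr <- tryCatch(
      density_ratio(iv, fun$profiles, gmod),
      error = function(e) NULL)
    report$stages$context <- list(
      n_intragenic = sum(ctx$status == "intragenic"),
      n_intergenic = sum(ctx$status == "intergenic"),
      pct_antisense = 100 * mean(
        ctx$orientation_vs_gene[ctx$status == "intragenic"] == "antisense"),
      density_ratio = if (is.null(dr)) NA_real_ else dr$ratio)
    NULL
  })

  ## report ---------------------------------------------------------------
  report$elapsed_s <- round(proc.time()[["elapsed"]] - t_all, 2L)
  manifest <- data.frame(
    file = basename(outputs),
    md5 = unname(tools::md5sum(outputs)),
    stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  report$manifest <- manifest
  report$config <- serializable_config(config)
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(report)
}

serializable_config <- function(config) {
  cfg <- unclass(config)
  cfg$sim <- if (!is.null(cfg$sim)) unclass(cfg$sim) else NULL
  cfg$call <- unclass(cfg$call)
  cfg$func <- unclass(cfg$func)
  cfg$de <- unclass(cfg$de)
  cfg
}
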
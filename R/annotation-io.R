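# Data model and readers/writers for chip annotation, intensity matrices,
# sample sheets. All genomic coordinates are 0-based half-open (BED
# convention); intensities are stored and exchanged on the log2 scale.

#' Controlled vocabularies of the chip data model
#'
#' Enumerations used throughout the package: probeset repertoires, structural
#' regions, LTR roles and stimulation conditions.
#'
#' @name vocabularies
#' @keywords internal
NULL

REPERTOIRES <- c("HERV_prototypes", "HERV_Dfam", "MaLR_Dfam", "gene")
REGIONS     <- c("U3", "R", "U5", "gag", "pol", "env", "LTR_part",
                 "internal", "gene_body")
LTR_REGIONS <- c("U3", "R", "U5", "LTR_part")
LTR_ROLES   <- c("solo", "five_prime", "three_prime", "none")
CONDITIONS  <- c("NS", "LPS", "ET", "ET_IFNG")
FUNCTIONS   <- c("Silent", "pA", "Pr", "RdT", "Undetermined")

ANNOTATION_COLS <- c("probeset_id", "locus_id", "repertoire", "group",
                     "region", "ltr_role", "chrom", "start", "end", "strand")

#' Build the identifier of an LTR entity
#'
#' An LTR is keyed by the pair (locus, role) so that a provirus contributes
#' two LTRs (5' and 3') and a solo element exactly one.
#'
#' @param locus_id character vector of locus identifiers.
#' @param ltr_role character vector, one of `"solo"`, `"five_prime"`,
#'   `"three_prime"`.
#' @return character vector of LTR identifiers.
#' @export
make_ltr_id <- function(locus_id, ltr_role) {
  paste(locus_id, ltr_role, sep = ":")
}

#' Validate a probeset annotation table
#'
#' Checks column presence, enumeration membership, coordinate sanity
#' (`end > start`), probeset uniqueness and the structural coherence rule:
#' for retroelement repertoires a probeset lies in an LTR subdomain
#' (U3/R/U5/LTR_part) if and only if it carries an LTR role.
#'
#' @param annotation data.frame with the columns listed in
#'   [read_annotation()].
#' @return the validated annotation, invisibly, with enum columns normalised
#'   to character and coordinates to integer.
#' @export
validate_annotation <- function(annotation) {
  missing <- setdiff(ANNOTATION_COLS, names(annotation))
  if (length(missing) > 0L) {
    stop("annotation is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ann <- annotation
  for (col in c("probeset_id", "locus_id", "repertoire", "group", "region",
                "ltr_role", "chrom", "strand")) {
    ann[[col]] <- as.character(ann[[col]])
  }
  ann$start <- as.integer(ann$start)
  ann$end   <- as.integer(ann$end)

  check_enum <- function(col, allowed) {
    bad <- !ann[[col]] %in% allowed
    if (any(bad)) {
      stop(sprintf("annotation column '%s' has unknown value(s): %s (line %s)",
                   col, paste(unique(ann[[col]][bad]), collapse = ", "),
                   paste(utils::head(which(bad), 3L), collapse = ", ")),
           call. = FALSE)
    }
  }
  check_enum("repertoire", REPERTOIRES)
  check_enum("region", REGIONS)
  check_enum("ltr_role", LTR_ROLES)
  check_enum("strand", c("+", "-"))

  if (anyNA(ann$start) || anyNA(ann$end) ||
      any(ann$start < 0L) || any(ann$end < 0L)) {
    stop("annotation coordinates must be non-negative integers", call. = FALSE)
  }
  bad <- ann$end <= ann$start
  if (any(bad)) {
    stop(sprintf("annotation has end <= start at line(s) %s",
                 paste(utils::head(which(bad), 5L), collapse = ", ")),
         call. = FALSE)
  }
  dup <- duplicated(ann$probeset_id)
  if (any(dup)) {
    stop("duplicated probeset_id: ",
         paste(utils::head(unique(ann$probeset_id[dup]), 5L), collapse = ", "),
         call. = FALSE)
  }
  retro <- ann$repertoire != "gene"
  is_ltr <- ann$region %in% LTR_REGIONS
  has_role <- ann$ltr_role != "none"
  bad <- retro & (is_ltr != has_role)
  if (any(bad)) {
    stop(sprintf(paste0("LTR subdomain regions must carry an LTR role (and ",
                        "vice versa) for retroelement repertoires; violated ",
                        "at line(s) %s"),
                 paste(utils::head(which(bad), 5L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(ann)
}

#' Read a probeset annotation table
#'
#' Reads a tab-separated annotation file with header
#' `probeset_id locus_id repertoire group region ltr_role chrom start end strand`
#' and validates it (see [validate_annotation()]). Coordinates are 0-based
#' half-open.
#'
#' @param path path to a TSV file.
#' @return data.frame, one row per probeset.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  validate_annotation(ann)
}

#' Write a probeset annotation table
#'
#' @param annotation validated annotation data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  ann <- validate_annotation(annotation)
  utils::write.table(ann[, ANNOTATION_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a sample sheet
#'
#' A sample sheet has columns `sample_id`, `donor`, `condition`, `replicate`;
#' (donor, condition, replicate) must be unique and conditions must belong to
#' the NS/LPS/ET(/ET_IFNG) vocabulary.
#'
#' @param sheet data.frame.
#' @return the validated sheet, invisibly.
#' @export
validate_sample_sheet <- function(sheet) {
  req <- c("sample_id", "donor", "condition", "replicate")
  missing <- setdiff(req, names(sheet))
  if (length(missing) > 0L) {
    stop("sample sheet is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$donor     <- as.character(sheet$donor)
  sheet$condition <- as.character(sheet$condition)
  sheet$replicate <- as.integer(sheet$replicate)
  bad <- !sheet$condition %in% CONDITIONS
  if (any(bad)) {
    stop("unknown condition(s): ",
         paste(unique(sheet$condition[bad]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicated sample_id in sample sheet", call. = FALSE)
  }
  key <- paste(sheet$donor, sheet$condition, sheet$replicate)
  if (anyDuplicated(key)) {
    stop("duplicated (donor, condition, replicate) in sample sheet",
         call. = FALSE)
  }
  invisible(sheet)
}

#' Read a sample sheet
#' @param path TSV file with columns `sample_id donor condition replicate`.
#' @return validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path, call. = FALSE)
  sheet <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
}

#' Write a sample sheet
#' @param sheet validated sample sheet.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  sheet <- validate_sample_sheet(sheet)
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a log2 intensity matrix
#'
#' Reads a TSV whose first column is `probeset_id` and remaining columns are
#' samples. All sample columns must appear in the sample sheet; cells must be
#' finite (no NA). Columns are reordered to follow the sheet's sample order.
#'
#' @param path TSV file.
#' @param sheet validated sample sheet.
#' @return numeric matrix (probesets x samples) with dimnames.
#' @export
read_matrix <- function(path, sheet) {
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  sheet <- validate_sample_sheet(sheet)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1L] != "probeset_id") {
    stop("first column of an intensity matrix must be 'probeset_id'",
         call. = FALSE)
  }
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("duplicated probeset_id in matrix", call. = FALSE)
  samples <- names(tab)[-1L]
  unknown <- setdiff(samples, sheet$sample_id)
  if (length(unknown) > 0L) {
    stop("matrix sample(s) absent from sample sheet: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat) || any(!is.finite(mat))) {
    stop("intensity matrix contains NA or non-finite values", call. = FALSE)
  }
  rownames(mat) <- ids
  mat[, intersect(sheet$sample_id, samples), drop = FALSE]
}

#' Write a log2 intensity matrix
#'
#' Values are written at 6 decimal places, which the reader round-trips.
#'
#' @param matrix numeric matrix with probeset rownames and sample colnames.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            !is.null(colnames(matrix)))
  tab <- data.frame(probeset_id = rownames(matrix),
                    round(matrix, 6L),
                    check.names = FALSE, row.names = NULL)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Identify attributable LTRs
#'
#' An LTR is attributable when the chip carries at least one U3 probeset and
#' at least one U5 probeset for it, so promoter and polyA usage can be
#' discriminated from the two subdomain signals.
#'
#' @param annotation validated probeset annotation.
#' @return data.frame with columns `ltr_id`, `locus_id`, `ltr_role`, one row
#'   per attributable LTR, ordered by `ltr_id`.
#' @export
attributable_ltrs <- function(annotation) {
  ann <- validate_annotation(annotation)
  ann <- ann[ann$ltr_role != "none" & ann$region %in% c("U3", "U5"), ,
             drop = FALSE]
  if (nrow(ann) == 0L) {
    return(data.frame(ltr_id = character(), locus_id = character(),
                      ltr_role = character(), stringsAsFactors = FALSE))
  }
  id <- make_ltr_id(ann$locus_id, ann$ltr_role)
  has_u3 <- unique(id[ann$region == "U3"])
  has_u5 <- unique(id[ann$region == "U5"])
  keep <- sort(intersect(has_u3, has_u5))
  first <- match(keep, id)
  data.frame(ltr_id = keep,
             locus_id = ann$locus_id[first],
             ltr_role = ann$ltr_role[first],
             stringsAsFactors = FALSE)
}

#' Genomic intervals of LTR entities
#'
#' Collapses the LTR-subdomain probesets (U3/R/U5/LTR_part) of each LTR to a
#' single interval (the range of its probesets) for genomic-context analyses.
#'
#' @param annotation validated probeset annotation.
#' @return data.frame `ltr_id, locus_id, ltr_role, chrom, start, end, strand`.
#' @export
ltr_intervals <- function(annotation) {
  ann <- validate_annotation(annotation)
  ann <- ann[ann$ltr_role != "none" & ann$region %in% LTR_REGIONS, ,
             drop = FALSE]
  if (nrow(ann) == 0L) {
    return(data.frame(ltr_id = character(), locus_id = character(),
                      ltr_role = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  id <- make_ltr_id(ann$locus_id, ann$ltr_role)
  o <- order(id)
  ann <- ann[o, , drop = FALSE]
  id <- id[o]
  first <- !duplicated(id)
  data.frame(
    ltr_id = id[first],
    locus_id = ann$locus_id[first],
    ltr_role = ann$ltr_role[first],
    chrom = ann$chrom[first],
    start = as.integer(tapply(ann$start, id, min)[id[first]]),
    end = as.integer(tapply(ann$end, id, max)[id[first]]),
    strand = ann$strand[first],
    stringsAsFactors = FALSE
  )
}

#' Genomic intervals of loci
#'
#' Collapses all probesets of each locus to a single interval.
#'
#' @param annotation validated probeset annotation.
#' @return data.frame `locus_id, repertoire, chrom, start, end, strand`.
#' @export
locus_intervals <- function(annotation) {
  ann <- validate_annotation(annotation)
  o <- order(ann$locus_id)
  ann <- ann[o, , drop = FALSE]
  first <- !duplicated(ann$locus_id)
  id <- ann$locus_id
  data.frame(
    locus_id = id[first],
    repertoire = ann$repertoire[first],
    chrom = ann$chrom[first],
    start = as.integer(tapply(ann$start, id, min)[id[first]]),
    end = as.integer(tapply(ann$end, id, max)[id[first]]),
    strand = ann$strand[first],
    stringsAsFactors = FALSE
  )
}
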
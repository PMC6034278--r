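# Synthetic chip-data generator. Emits probeset annotation, a full-factorial
# stimulation design, log2 intensity matrices and the planted ground truth
# (locus activity, LTR function, condition program) that downstream stages
# are tested against.
#
# Intensity model (linear scale):
#   Y = 2^(sig + donor + delta) + 2^(bg + gamma)
# where `sig` is the planted log2 signal mean for the probeset under the
# sample's condition (absent for unexpressed probesets), `bg` a per-probeset
# background affinity, donor ~ N(0, donor_sd_log2) a donor random effect on
# the signal term, and delta/gamma independent Gaussian log2 noise. The
# additive background term makes the replicate coefficient of variation fall
# with intensity (high near the noise floor, ~noise_cv for bright probesets),
# which is what the threshold-calibration stage exploits.
#
# Noise calibration: a log2-normal term 2^delta with sd_log2 = log2(1 + cv)
# has linear-scale CV sqrt(exp((sd_log2*ln2)^2) - 1) = 0.0583 for a target
# cv of 0.06 (about 3% under target); the exact inversion would be
# sd_log2 = sqrt(log1p(cv^2))/log(2). The approximation is the documented
# convention.

PROTO_GROUPS <- data.frame(
  group = c("HERV-H", "HERV-W", "HERV-E", "PRIMA-41",
            "HML-2", "HML-8", "HERV-L", "HERV-T"),
  class = c("gamma", "gamma", "gamma", "gamma",
            "beta", "beta", "spuma", "gamma"),
  stringsAsFactors = FALSE
)

PROGRAMS <- c("tolerisable", "non_tolerisable", "down_modulated",
              "constitutive")

#' Simulation parameters for the synthetic chip generator
#'
#' @param n_loci named integer vector: loci per repertoire
#'   (`HERV_prototypes`, `HERV_Dfam`, `MaLR_Dfam`, `gene`).
#' @param fraction_active probability that a locus is transcriptionally
#'   active (default 0.056, the share of the targeted HERV/MaLR repertoire
#'   expressed in PBMCs).
#' @param function_mix probabilities over `Silent`, `Pr`, `pA`, `RdT` for
#'   attributable LTRs (defaults 0.705/0.152/0.118/0.025).
#' @param shift_mix probabilities that an attributable LTR carries a
#'   condition-dependent program (`Silent_Pr`: silent unstimulated, promoter
#'   under LPS/ET; `Silent_pA` symmetric). Defaults 0 (all constitutive).
#' @param program_mix probabilities over condition programs for active loci.
#' @param attributable_fraction fraction of prototype LTRs carrying both U3
#'   and U5 probesets (planted exactly by count).
#' @param solo_fraction fraction of prototype loci that are solo LTRs (the
#'   rest are proviruses with two LTRs and gag/pol/env probesets).
#' @param intragenic_fraction fraction of solo prototype LTRs relocated
#'   inside gene loci (one per host gene, antisense with probability 2/3,
#'   intronic in 80% of cases), so the genomic-context stage sees both
#'   intragenic and intergenic LTRs (default 0.3).
#' @param noise_floor_log2 log2 background level (default 3.0).
#' @param floor_spread_log2 per-probeset background-affinity spread: the
#'   background of unexpressed bulk probesets is drawn uniformly from
#'   `[floor, floor + spread]`, emulating probe-affinity variation.
#' @param active_mean_log2,active_sd_log2 log2 mean and spread of active
#'   signal levels (defaults 8.0 and 1.0).
#' @param effect_log2 condition effect size on programmed loci (default 2.0).
#' @param donor_sd_log2 donor random-effect sd (default 0.3).
#' @param noise_cv target linear-scale replicate CV of the signal term
#'   (default 0.06).
#' @param bg_cv linear-scale CV of the background term (default 0.25).
#' @param margin_log2 separation margin between planted class means and the
#'   downstream decision boundaries (default 0.5); makes recovery a designed
#'   property rather than luck.
#' @param activity_threshold_log2,function_threshold_log2,fold_change the
#'   downstream decision boundaries the margins are measured against.
#' @param seed integer seed; the generator derives per-stage sub-seeds
#'   (annotation: `seed`, intensities: `seed + 1`, pathway table: `seed + 2`).
#' @return validated list of class `sim_params`.
#' @export
sim_params <- function(n_loci = c(HERV_prototypes = 400L, HERV_Dfam = 300L,
                                  MaLR_Dfam = 300L, gene = 120L),
                       fraction_active = 0.056,
                       function_mix = c(Silent = 0.705, Pr = 0.152,
                                        pA = 0.118, RdT = 0.025),
                       shift_mix = c(Silent_Pr = 0, Silent_pA = 0),
                       program_mix = c(tolerisable = 0.25,
                                       non_tolerisable = 0.25,
                                       down_modulated = 0.25,
                                       constitutive = 0.25),
                       attributable_fraction = 1.0,
                       solo_fraction = 0.6,
                       intragenic_fraction = 0.3,
                       noise_floor_log2 = 3.0,
                       floor_spread_log2 = 2.0,
                       active_mean_log2 = 8.0,
                       active_sd_log2 = 1.0,
                       effect_log2 = 2.0,
                       donor_sd_log2 = 0.3,
                       noise_cv = 0.06,
                       bg_cv = 0.25,
                       margin_log2 = 0.5,
                       activity_threshold_log2 = 5.5,
                       function_threshold_log2 = 4.5,
                       fold_change = 3,
                       seed = 1L) {
  p <- list(n_loci = n_loci, fraction_active = fraction_active,
            function_mix = function_mix, shift_mix = shift_mix,
            program_mix = program_mix,
            attributable_fraction = attributable_fraction,
            solo_fraction = solo_fraction,
            intragenic_fraction = intragenic_fraction,
            noise_floor_log2 = noise_floor_log2,
            floor_spread_log2 = floor_spread_log2,
            active_mean_log2 = active_mean_log2,
            active_sd_log2 = active_sd_log2,
            effect_log2 = effect_log2,
            donor_sd_log2 = donor_sd_log2,
            noise_cv = noise_cv, bg_cv = bg_cv,
            margin_log2 = margin_log2,
            activity_threshold_log2 = activity_threshold_log2,
            function_threshold_log2 = function_threshold_log2,
            fold_change = fold_change,
            seed = as.integer(seed))
  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  stopifnot(all(c("HERV_prototypes", "HERV_Dfam", "MaLR_Dfam", "gene") %in%
                  names(p$n_loci)))
  if (any(p$n_loci < 0)) stop("n_loci must be non-negative", call. = FALSE)
  chk_prob <- function(x, nm) {
    if (abs(sum(x) - 1) > 1e-9) {
      stop(nm, " must sum to 1 (got ", sum(x), ")", call. = FALSE)
    }
    if (any(x < 0)) stop(nm, " must be non-negative", call. = FALSE)
  }
  chk_prob(p$function_mix[c("Silent", "Pr", "pA", "RdT")], "function_mix")
  chk_prob(p$program_mix[PROGRAMS], "program_mix")
  if (sum(p$shift_mix) > 1 || any(p$shift_mix < 0)) {
    stop("shift_mix fractions must be in [0,1] with sum <= 1", call. = FALSE)
  }
  for (f in c("fraction_active", "attributable_fraction", "solo_fraction",
              "intragenic_fraction")) {
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must be in [0,1]", call. = FALSE)
  }
  for (f in c("donor_sd_log2", "noise_cv", "bg_cv", "active_sd_log2",
              "floor_spread_log2", "margin_log2")) {
    if (p[[f]] < 0) stop(f, " must be >= 0", call. = FALSE)
  }
  if (is.na(p$seed)) stop("seed is required", call. = FALSE)
  class(p) <- "sim_params"
  p
}

#' Generate a full-factorial stimulation design
#'
#' @param n_donors number of donors (reference design: 5).
#' @param conditions character vector of stimulation conditions (reference
#'   design: NS, LPS, ET).
#' @param n_reps replicates per donor x condition (reference design: 3,
#'   giving the 45-sample sheet).
#' @return validated sample sheet data.frame.
#' @export
generate_design <- function(n_donors = 5L, conditions = c("NS", "LPS", "ET"),
                            n_reps = 3L) {
  if (length(conditions) == 0L) stop("conditions must be non-empty",
                                     call. = FALSE)
  stopifnot(n_donors >= 1L, n_reps >= 1L)
  grid <- expand.grid(replicate = seq_len(n_reps),
                      condition = conditions,
                      donor = sprintf("D%02d", seq_len(n_donors)),
                      stringsAsFactors = FALSE)
  sheet <- data.frame(
    sample_id = sprintf("%s_%s_R%d", grid$donor, grid$condition,
                        grid$replicate),
    donor = grid$donor,
    condition = as.character(grid$condition),
    replicate = as.integer(grid$replicate),
    stringsAsFactors = FALSE
  )
  validate_sample_sheet(sheet)
}

#' Generate synthetic chip annotation with planted ground truth
#'
#' Prototype loci are solo LTRs (U3/R/U5 probesets when attributable, a
#' single LTR_part probeset otherwise) or proviruses (two LTRs plus
#' gag/pol/env probesets); Dfam loci carry LTR_part and internal probesets;
#' gene loci carry gene_body probesets and a three-exon gene model.
#' Coordinates are non-overlapping per chromosome (0-based half-open). The
#' ground truth records per-locus activity and condition program, per-LTR
#' planted function, and per-probeset expected log2 means under NS/LPS/ET.
#'
#' @param params a [sim_params()] object.
#' @return list with elements `annotation` (validated data.frame) and
#'   `truth` (list: `params`, `loci`, `ltrs`, `probesets`, `gene_models`,
#'   `class_map`).
#' @export
generate_annotation <- function(params) {
  p <- validate_sim_params(params)
  set.seed(p$seed)
  chroms <- sprintf("chr%d", 1:22)

  ## ---- locus table -----------------------------------------------------
  blocks <- list()
  n_proto <- p$n_loci[["HERV_prototypes"]]
  if (n_proto > 0L) {
    grp <- PROTO_GROUPS$group[sample.int(nrow(PROTO_GROUPS), n_proto,
                                         replace = TRUE)]
    is_solo <- rep(FALSE, n_proto)
    n_solo <- round(p$solo_fraction * n_proto)
    if (n_solo > 0L) is_solo[sample.int(n_proto, n_solo)] <- TRUE
    blocks$proto <- data.frame(
      locus_id = sprintf("HP%05d", seq_len(n_proto)),
      repertoire = "HERV_prototypes", group = grp,
      structure = ifelse(is_solo, "solo_LTR", "provirus"),
      len = ifelse(is_solo, 600L, 7000L), stringsAsFactors = FALSE)
  }
  for (rep_nm in c("HERV_Dfam", "MaLR_Dfam")) {
    n <- p$n_loci[[rep_nm]]
    if (n == 0L) next
    pref <- if (rep_nm == "HERV_Dfam") "HD" else "MD"
    blocks[[rep_nm]] <- data.frame(
      locus_id = sprintf("%s%05d", pref, seq_len(n)),
      repertoire = rep_nm, group = rep_nm, structure = "solo_LTR",
      len = 2000L, stringsAsFactors = FALSE)
  }
  n_gene <- p$n_loci[["gene"]]
  if (n_gene > 0L) {
    blocks$gene <- data.frame(
      locus_id = sprintf("GENE%04d", seq_len(n_gene)),
      repertoire = "gene", group = "", structure = "gene",
      len = sample(5000:30000, n_gene, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  loci <- do.call(rbind, blocks)
  rownames(loci) <- NULL
  n_loc <- nrow(loci)
  if (n_loc == 0L) stop("no loci requested", call. = FALSE)

  loci$chrom <- chroms[(seq_len(n_loc) - 1L) %% length(chroms) + 1L]
  loci$strand <- sample(c("+", "-"), n_loc, replace = TRUE)
  gap <- sample(5000:50000, n_loc, replace = TRUE)
  loci$start <- loci$end <- 0L
  for (ch in unique(loci$chrom)) {
    idx <- which(loci$chrom == ch)
    e <- 10000L + cumsum(gap[idx] + loci$len[idx])
    loci$end[idx] <- as.integer(e)
    loci$start[idx] <- as.integer(e - loci$len[idx])
  }

  ## ---- intragenic relocation -------------------------------------------
  # move a fraction of solo prototype LTRs inside gene loci (one per host
  # gene; antisense to the host with probability 2/3; 80% land in the
  # first intron, 20% overlap the first exon). Retroelement loci remain
  # non-overlapping among themselves.
  solo_idx <- which(loci$repertoire == "HERV_prototypes" &
                      loci$structure == "solo_LTR")
  gene_idx <- which(loci$repertoire == "gene")
  n_rel <- min(round(p$intragenic_fraction * length(solo_idx)),
               length(gene_idx))
  if (n_rel > 0L) {
    rel <- sort(sample(solo_idx, n_rel))
    hosts <- sample(gene_idx, n_rel)
    in_exon <- stats::runif(n_rel) < 0.2
    off <- ifelse(in_exon, 300L, 700L)
    loci$chrom[rel] <- loci$chrom[hosts]
    loci$start[rel] <- loci$start[hosts] + off
    loci$end[rel] <- loci$start[rel] + 600L
    anti <- stats::runif(n_rel) < 2 / 3
    host_strand <- loci$strand[hosts]
    loci$strand[rel] <- ifelse(anti, chartr("+-", "-+", host_strand),
                               host_strand)
  }

  ## ---- LTR table -------------------------------------------------------
  proto <- loci[loci$repertoire == "HERV_prototypes", , drop = FALSE]
  solo <- proto[proto$structure == "solo_LTR", , drop = FALSE]
  prov <- proto[proto$structure == "provirus", , drop = FALSE]
  ltr_tab <- rbind(
    if (nrow(solo)) data.frame(locus_id = solo$locus_id, ltr_role = "solo",
                               ltr_start = solo$start,
                               chrom = solo$chrom, strand = solo$strand,
                               group = solo$group, stringsAsFactors = FALSE),
    if (nrow(prov)) data.frame(locus_id = prov$locus_id,
                               ltr_role = "five_prime",
                               ltr_start = prov$start,
                               chrom = prov$chrom, strand = prov$strand,
                               group = prov$group, stringsAsFactors = FALSE),
    if (nrow(prov)) data.frame(locus_id = prov$locus_id,
                               ltr_role = "three_prime",
                               ltr_start = prov$start + 6400L,
                               chrom = prov$chrom, strand = prov$strand,
                               group = prov$group, stringsAsFactors = FALSE)
  )
  n_ltr <- if (is.null(ltr_tab)) 0L else nrow(ltr_tab)
  if (n_ltr > 0L) {
    ltr_tab$attributable <- FALSE
    n_attr <- round(p$attributable_fraction * n_ltr)
    if (n_attr > 0L) ltr_tab$attributable[sample.int(n_ltr, n_attr)] <- TRUE
    ltr_tab$ltr_id <- make_ltr_id(ltr_tab$locus_id, ltr_tab$ltr_role)
  }

  ## ---- probesets -------------------------------------------------------
  pbs <- list()
  role_tag <- c(solo = "sL", five_prime = "5L", three_prime = "3L")
  if (n_ltr > 0L) {
    at <- ltr_tab[ltr_tab$attributable, , drop = FALSE]
    if (nrow(at)) {
      k <- rep(seq_len(nrow(at)), each = 3L)
      off_s <- rep(c(0L, 220L, 320L), nrow(at))
      off_e <- rep(c(220L, 320L, 600L), nrow(at))
      pbs$u <- data.frame(
        probeset_id = sprintf("%s_%s_%s", at$locus_id[k],
                              role_tag[at$ltr_role[k]],
                              rep(c("U3", "R", "U5"), nrow(at))),
        locus_id = at$locus_id[k], repertoire = "HERV_prototypes",
        group = at$group[k], region = rep(c("U3", "R", "U5"), nrow(at)),
        ltr_role = at$ltr_role[k], chrom = at$chrom[k],
        start = at$ltr_start[k] + off_s, end = at$ltr_start[k] + off_e,
        strand = at$strand[k], stringsAsFactors = FALSE)
    }
    na <- ltr_tab[!ltr_tab$attributable, , drop = FALSE]
    if (nrow(na)) {
      pbs$part <- data.frame(
        probeset_id = sprintf("%s_%s_part", na$locus_id,
                              role_tag[na$ltr_role]),
        locus_id = na$locus_id, repertoire = "HERV_prototypes",
        group = na$group, region = "LTR_part", ltr_role = na$ltr_role,
        chrom = na$chrom, start = na$ltr_start, end = na$ltr_start + 600L,
        strand = na$strand, stringsAsFactors = FALSE)
    }
  }
  if (nrow(prov)) {
    k <- rep(seq_len(nrow(prov)), each = 3L)
    reg <- rep(c("gag", "pol", "env"), nrow(prov))
    pbs$internal_proto <- data.frame(
      probeset_id = sprintf("%s_%s", prov$locus_id[k], reg),
      locus_id = prov$locus_id[k], repertoire = "HERV_prototypes",
      group = prov$group[k], region = reg, ltr_role = "none",
      chrom = prov$chrom[k],
      start = prov$start[k] + rep(c(1000L, 2500L, 4500L), nrow(prov)),
      end = prov$start[k] + rep(c(2500L, 4500L, 6000L), nrow(prov)),
      strand = prov$strand[k], stringsAsFactors = FALSE)
  }
  dfam <- loci[loci$repertoire %in% c("HERV_Dfam", "MaLR_Dfam"), ,
               drop = FALSE]
  if (nrow(dfam)) {
    k <- rep(seq_len(nrow(dfam)), each = 3L)
    pbs$dfam <- data.frame(
      probeset_id = sprintf("%s_%s", dfam$locus_id[k],
                            rep(c("lp1", "lp2", "int"), nrow(dfam))),
      locus_id = dfam$locus_id[k], repertoire = dfam$repertoire[k],
      group = dfam$group[k],
      region = rep(c("LTR_part", "LTR_part", "internal"), nrow(dfam)),
      ltr_role = rep(c("solo", "solo", "none"), nrow(dfam)),
      chrom = dfam$chrom[k],
      start = dfam$start[k] + rep(c(0L, 1700L, 800L), nrow(dfam)),
      end = dfam$start[k] + rep(c(300L, 2000L, 1200L), nrow(dfam)),
      strand = dfam$strand[k], stringsAsFactors = FALSE)
  }
  gn <- loci[loci$repertoire == "gene", , drop = FALSE]
  if (nrow(gn)) {
    k <- rep(seq_len(nrow(gn)), each = 2L)
    first <- rep(c(TRUE, FALSE), nrow(gn))
    pbs$gene <- data.frame(
      probeset_id = sprintf("%s_pb%d", gn$locus_id[k],
                            rep(1:2, nrow(gn))),
      locus_id = gn$locus_id[k], repertoire = "gene", group = "",
      region = "gene_body", ltr_role = "none", chrom = gn$chrom[k],
      start = ifelse(first, gn$start[k] + 100L, gn$end[k] - 700L),
      end = ifelse(first, gn$start[k] + 400L, gn$end[k] - 100L),
      strand = gn$strand[k], stringsAsFactors = FALSE)
  }
  annotation <- do.call(rbind, pbs)
  rownames(annotation) <- NULL
  annotation <- validate_annotation(annotation)

  ## ---- gene models -----------------------------------------------------
  gene_models <- list(genes = NULL, exons = NULL)
  if (nrow(gn)) {
    gene_models$genes <- data.frame(
      gene_id = gn$locus_id, chrom = gn$chrom, start = gn$start,
      end = gn$end, strand = gn$strand, stringsAsFactors = FALSE)
    mid <- gn$start + as.integer(gn$len / 2)
    k <- rep(seq_len(nrow(gn)), each = 3L)
    gene_models$exons <- data.frame(
      gene_id = gn$locus_id[k], chrom = gn$chrom[k],
      start = as.integer(rbind(gn$start, mid, gn$end - 600L))[
        seq_len(3L * nrow(gn))],
      end = as.integer(rbind(gn$start + 400L, mid + 500L, gn$end))[
        seq_len(3L * nrow(gn))],
      strand = gn$strand[k], stringsAsFactors = FALSE)
  }

  ## ---- planted labels --------------------------------------------------
  loci$active <- stats::runif(n_loc) < p$fraction_active
  loci$program <- "none"
  n_act <- sum(loci$active)
  if (n_act > 0L) {
    loci$program[loci$active] <- sample(PROGRAMS, n_act, replace = TRUE,
                                        prob = p$program_mix[PROGRAMS])
  }

  if (n_ltr > 0L) {
    ltr_tab$func <- "Silent"
    ltr_tab$shift <- "none"
    attr_idx <- which(ltr_tab$attributable)
    if (length(attr_idx) > 0L) {
      p_shift <- sum(p$shift_mix)
      shifted <- stats::runif(length(attr_idx)) < p_shift
      if (any(shifted)) {
        ltr_tab$shift[attr_idx[shifted]] <- sample(
          names(p$shift_mix), sum(shifted), replace = TRUE,
          prob = p$shift_mix / p_shift)
      }
      const <- attr_idx[!shifted]
      if (length(const) > 0L) {
        ltr_tab$func[const] <- sample(
          c("Silent", "Pr", "pA", "RdT"), length(const), replace = TRUE,
          prob = p$function_mix[c("Silent", "Pr", "pA", "RdT")])
      }
    }
  }

  ## ---- per-probeset planted signal -------------------------------------
  n_pb <- nrow(annotation)
  base_sig <- rep(NA_real_, n_pb)
  program <- rep("none", n_pb)
  bg <- rep(p$noise_floor_log2, n_pb)
  loc_of <- match(annotation$locus_id, loci$locus_id)
  is_u3u5r <- annotation$region %in% c("U3", "R", "U5")

  # bulk probesets (gag/pol/env, internal, LTR_part, gene_body)
  bulk <- which(!is_u3u5r)
  bulk_active <- loci$active[loc_of[bulk]]
  off <- bulk[!bulk_active]
  bg[off] <- stats::runif(length(off), p$noise_floor_log2,
                          p$noise_floor_log2 + p$floor_spread_log2)
  on <- bulk[bulk_active]
  if (length(on) > 0L) {
    act_loc <- unique(annotation$locus_id[on])
    mu_loc <- pmax(stats::rnorm(length(act_loc), p$active_mean_log2,
                                p$active_sd_log2),
                   p$activity_threshold_log2 + p$margin_log2)
    names(mu_loc) <- act_loc
    base_sig[on] <- pmax(mu_loc[annotation$locus_id[on]] +
                           stats::rnorm(length(on), 0, 0.2),
                         p$activity_threshold_log2 + p$margin_log2)
    program[on] <- loci$program[loc_of[on]]
  }

  # attributable-LTR U3/R/U5 probesets: planted function with margins
  if (n_ltr > 0L && any(ltr_tab$attributable)) {
    at_idx <- which(ltr_tab$attributable)
    ann_ltr_id <- make_ltr_id(annotation$locus_id, annotation$ltr_role)
    row_of <- function(region) {
      idx <- which(annotation$region == region)
      idx[match(ltr_tab$ltr_id[at_idx], ann_ltr_id[idx])]
    }
    u3_row <- row_of("U3"); r_row <- row_of("R"); u5_row <- row_of("U5")
    lo <- max(p$function_threshold_log2 + p$margin_log2,
              p$noise_floor_log2 + log2(p$fold_change) + p$margin_log2)
    h <- pmax(stats::rnorm(length(at_idx), p$active_mean_log2,
                           p$active_sd_log2), lo)
    fn <- ltr_tab$func[at_idx]
    sh <- ltr_tab$shift[at_idx]
    loc_i <- match(ltr_tab$locus_id[at_idx], loci$locus_id)
    loc_prog <- ifelse(loci$active[loc_i], loci$program[loc_i], "none")

    hot_u5 <- sh == "Silent_Pr" | (sh == "none" & fn %in% c("Pr", "RdT"))
    hot_u3 <- sh == "Silent_pA" | (sh == "none" & fn %in% c("pA", "RdT"))
    hot_r <- hot_u5 | hot_u3
    prog_lab <- ifelse(sh != "none", paste0("shift_", sh), loc_prog)

    base_sig[u5_row[hot_u5]] <- h[hot_u5]
    base_sig[u3_row[hot_u3]] <- h[hot_u3]
    base_sig[r_row[hot_r]] <- h[hot_r]
    program[u5_row[hot_u5]] <- prog_lab[hot_u5]
    program[u3_row[hot_u3]] <- prog_lab[hot_u3]
    program[r_row[hot_r]] <- prog_lab[hot_r]
  }

  # a locus with no expressed probeset (a solo LTR whose LTR drew Silent)
  # has nothing to carry a program: its planted activity is retracted so
  # the truth stays observable
  has_sig <- tapply(!is.na(base_sig), annotation$locus_id, any)
  dead <- loci$locus_id %in% names(has_sig)[!has_sig] & loci$active
  loci$active[dead] <- FALSE
  loci$program[dead] <- "none"

  cond_means <- planted_condition_means(base_sig, program, bg, p)
  probesets <- data.frame(
    probeset_id = annotation$probeset_id,
    locus_id = annotation$locus_id,
    bg_log2 = bg,
    base_sig_log2 = base_sig,
    program = program,
    mean_NS = cond_means$NS,
    mean_LPS = cond_means$LPS,
    mean_ET = cond_means$ET,
    stringsAsFactors = FALSE
  )

  truth <- list(
    params = p,
    loci = loci[, c("locus_id", "repertoire", "group", "structure", "chrom",
                    "start", "end", "strand", "active", "program")],
    ltrs = if (n_ltr > 0L)
      ltr_tab[, c("ltr_id", "locus_id", "ltr_role", "group", "attributable",
                  "func", "shift")]
    else NULL,
    probesets = probesets,
    gene_models = gene_models,
    class_map = PROTO_GROUPS
  )
  list(annotation = annotation, truth = truth)
}

# Planted log2 signal under one condition, applying the condition program:
# tolerisable +effect in LPS only, non_tolerisable +effect in LPS and ET,
# down_modulated -effect in LPS and ET, shift_* expressed in LPS/ET only.
# The optional ET_IFNG arm behaves like LPS (IFN-gamma reverses tolerance).
condition_signal <- function(base_sig, program, condition, effect) {
  sig <- base_sig
  if (condition == "NS") {
    sig[program %in% c("shift_Silent_Pr", "shift_Silent_pA")] <- NA_real_
    return(sig)
  }
  lps_like <- condition %in% c("LPS", "ET_IFNG")
  up_lps <- program == "tolerisable" & lps_like
  up_both <- program == "non_tolerisable"
  down <- program == "down_modulated"
  sig[up_lps] <- sig[up_lps] + effect
  sig[up_both] <- sig[up_both] + effect
  sig[down] <- sig[down] - effect
  sig
}

planted_condition_means <- function(base_sig, program, bg, p) {
  out <- list()
  for (cond in c("NS", "LPS", "ET")) {
    sig <- condition_signal(base_sig, program, cond, p$effect_log2)
    lin <- 2^bg + ifelse(is.na(sig), 0, 2^sig)
    out[[cond]] <- log2(lin)
  }
  out
}

#' Generate a log2 intensity matrix from planted truth
#'
#' See the model documented at the top of this file. Reproducible from the
#' parameter seed: the stage uses `seed + 1`.
#'
#' @param annotation annotation from [generate_annotation()].
#' @param truth matching ground-truth list.
#' @param sheet sample sheet from [generate_design()].
#' @param params the same [sim_params()] used for annotation.
#' @return numeric log2 matrix (probesets x samples).
#' @export
generate_intensities <- function(annotation, truth, sheet, params) {
  p <- validate_sim_params(params)
  sheet <- validate_sample_sheet(sheet)
  if (!identical(annotation$probeset_id, truth$probesets$probeset_id)) {
    stop("annotation and truth come from different generation runs",
         call. = FALSE)
  }
  n <- nrow(annotation)
  ns <- nrow(sheet)
  set.seed(p$seed + 1L)

  donors <- unique(sheet$donor)
  donor_fx <- matrix(stats::rnorm(n * length(donors), 0, p$donor_sd_log2),
                     nrow = n, dimnames = list(NULL, donors))
  sd_sig <- log2(1 + p$noise_cv)
  sd_bg <- log2(1 + p$bg_cv)
  delta <- matrix(stats::rnorm(n * ns, 0, sd_sig), nrow = n)
  gamma <- matrix(stats::rnorm(n * ns, 0, sd_bg), nrow = n)

  sig_by_cond <- lapply(
    stats::setNames(nm = unique(sheet$condition)),
    function(cond) condition_signal(truth$probesets$base_sig_log2,
                                    truth$probesets$program, cond,
                                    p$effect_log2))
  bg <- truth$probesets$bg_log2
  out <- matrix(NA_real_, nrow = n, ncol = ns,
                dimnames = list(annotation$probeset_id, sheet$sample_id))
  for (j in seq_len(ns)) {
    sig <- sig_by_cond[[sheet$condition[j]]] + donor_fx[, sheet$donor[j]]
    lin <- 2^(bg + gamma[, j]) + ifelse(is.na(sig), 0, 2^(sig + delta[, j]))
    out[, j] <- log2(lin)
  }
  out
}

#' One-call synthetic dataset
#'
#' @param params a [sim_params()] object.
#' @param n_donors,conditions,n_reps design passed to [generate_design()].
#' @return list with `annotation`, `truth`, `sheet`, `matrix`.
#' @export
simulate_chip <- function(params, n_donors = 5L,
                          conditions = c("NS", "LPS", "ET"), n_reps = 3L) {
  gen <- generate_annotation(params)
  sheet <- generate_design(n_donors, conditions, n_reps)
  mat <- generate_intensities(gen$annotation, gen$truth, sheet, params)
  list(annotation = gen$annotation, truth = gen$truth, sheet = sheet,
       matrix = mat)
}

#' Generate a pathway-membership table from planted truth
#'
#' Emulates the output of an upstream pathway-activation analysis: programmed
#' (condition-responsive) active genes are assigned to significant pathways
#' (most to exactly one, some to two), and a few inactive genes to a
#' non-significant pathway.
#'
#' @param truth ground truth from [generate_annotation()].
#' @param n_pathways number of significant pathways.
#' @param seed integer; defaults to the generator seed + 2.
#' @return data.frame `gene_symbol, pathway_id, pathway_significant, z_score`.
#' @export
generate_pathway_table <- function(truth, n_pathways = 6L, seed = NULL) {
  if (is.null(seed)) seed <- truth$params$seed + 2L
  set.seed(seed)
  genes <- truth$loci[truth$loci$repertoire == "gene", , drop = FALSE]
  prog <- genes[genes$active & genes$program != "constitutive", , drop = FALSE]
  paths <- sprintf("PW%02d", seq_len(n_pathways))
  rows <- list()
  if (nrow(prog) > 0L) {
    for (i in seq_len(nrow(prog))) {
      k <- if (stats::runif(1) < 0.3) 2L else 1L
      for (pw in sample(paths, min(k, length(paths)))) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_symbol = prog$locus_id[i], pathway_id = pw,
          pathway_significant = TRUE,
          z_score = round(sample(c(-1, 1), 1L) * stats::runif(1, 2, 3), 3L),
          stringsAsFactors = FALSE)
      }
    }
  }
  quiet <- genes[!genes$active, , drop = FALSE]
  if (nrow(quiet) > 0L) {
    for (g in utils::head(quiet$locus_id, 3L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_symbol = g, pathway_id = "PW_NS", pathway_significant = FALSE,
        z_score = round(stats::runif(1, -1, 1), 3L),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_symbol = character(), pathway_id = character(),
                      pathway_significant = logical(), z_score = numeric(),
                      stringsAsFactors = FALSE))
  }
  tab <- do.call(rbind, rows)
  tab[!duplicated(tab[, c("gene_symbol", "pathway_id")]), , drop = FALSE]
}

#' Write generator gene models as GFF3
#'
#' @param gene_models the `gene_models` element of the ground truth.
#' @param path output path (.gff3). Coordinates are converted from the
#'   internal 0-based half-open convention to 1-based inclusive GFF.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(gene_models, path) {
  g <- gene_models$genes
  e <- gene_models$exons
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!is.null(g)) {
    writeLines(sprintf("%s\tretrotome\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$start + 1L, g$end, g$strand, g$gene_id),
               con)
  }
  if (!is.null(e)) {
    writeLines(sprintf(
      "%s\tretrotome\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
      e$chrom, e$start + 1L, e$end, e$strand, e$gene_id,
      as.integer(stats::ave(seq_len(nrow(e)), e$gene_id, FUN = seq_along)),
      e$gene_id),
      con)
  }
  invisible(path)
}
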
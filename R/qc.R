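# Variant-, sample- and cell-level quality control.

RNA_ARTEFACT_SITES <- data.frame(
  position = c(2617L, 2129L, 295L, 5746L, 13710L, 5985L),
  ref = c("A", "G", "C", "G", "A", "G"),
  alt = c("G", "A", "T", "A", "G", "T")
)

in_low_complexity <- function(position, low_complexity = MT_LOW_COMPLEXITY) {
  out <- rep(FALSE, length(position))
  for (i in seq_len(nrow(low_complexity))) {
    out <- out | (position >= low_complexity$start[i] &
                    position <= low_complexity$end[i])
  }
  out
}

#' Filter a variant call table
#'
#' Applies, in fixed order: single-nucleotide alleles only; allele fraction
#' >= `min_af` (default 2%); depth >= `min_depth` (default 200x); at least
#' `min_strand_reads` (default 2) minor-allele reads on each strand;
#' low-complexity region exclusion (66-71, 300-316, 513-525, 3106-3107,
#' 12418-12425, 16182-16194); and, for `mode = "rna_bulk"`, removal of the
#' six known RNA artefact sites (2617A>G, 2129G>A, 295C>T, 5746G>A,
#' 13710A>G, 5985G>T).
#'
#' @param calls VariantCall data frame (`sample_id`, `position`, `ref`,
#'   `alt`, `allele_fraction`, `depth`, `alt_forward`, `alt_reverse`).
#' @param ref a `MitoReference` (supplies the low-complexity mask).
#' @param mode `"wgs_bulk"`, `"rna_bulk"` or `"scrna"`.
#' @param min_af,min_depth,min_strand_reads filter thresholds.
#' @return List with `calls` (retained rows) and `report` (a `FilterReport`
#'   data frame of per-rule removal counts; removals + retained = input).
#' @export
filter_variant_calls <- function(calls, ref = NULL,
                                 mode = c("wgs_bulk", "rna_bulk", "scrna"),
                                 min_af = 0.02, min_depth = 200,
                                 min_strand_reads = 2) {
  mode <- match.arg(mode)
  need <- c("sample_id", "position", "ref", "alt", "allele_fraction",
            "depth", "alt_forward", "alt_reverse")
  miss <- setdiff(need, names(calls))
  if (length(miss)) stop("calls missing columns: ", paste(miss, collapse = ", "))
  bad_allele <- !(calls$ref %in% BASES) | !(calls$alt %in% BASES) |
    is.na(calls$ref) | is.na(calls$alt)
  malformed <- bad_allele & (nchar(calls$ref) != 1 | nchar(calls$alt) != 1 |
                               grepl("[^ACGTN-]", paste0(calls$ref, calls$alt)))
  low_complexity <- if (is.null(ref)) MT_LOW_COMPLEXITY else ref$low_complexity
  n0 <- nrow(calls)
  rules <- c("not_snv", "af_below_min", "depth_below_min",
             "strand_support", "low_complexity", "rna_artefact")
  removed <- stats::setNames(integer(length(rules)), rules)
  keep <- calls
  drop_rule <- function(keep, bad, rule) {
    removed[rule] <<- sum(bad)
    keep[!bad, , drop = FALSE]
  }
  is_snv <- keep$ref %in% BASES & keep$alt %in% BASES & keep$ref != keep$alt
  keep <- drop_rule(keep, !is_snv, "not_snv")
  keep <- drop_rule(keep, keep$allele_fraction < min_af, "af_below_min")
  keep <- drop_rule(keep, keep$depth < min_depth, "depth_below_min")
  keep <- drop_rule(keep, keep$alt_forward < min_strand_reads |
                      keep$alt_reverse < min_strand_reads, "strand_support")
  keep <- drop_rule(keep, in_low_complexity(keep$position, low_complexity),
                    "low_complexity")
  if (mode == "rna_bulk") {
    key <- paste(keep$position, keep$ref, keep$alt)
    bad <- key %in% paste(RNA_ARTEFACT_SITES$position, RNA_ARTEFACT_SITES$ref,
                          RNA_ARTEFACT_SITES$alt)
    keep <- drop_rule(keep, bad, "rna_artefact")
  }
  report <- data.frame(rule = names(removed), removed = as.integer(removed),
                       stringsAsFactors = FALSE)
  report <- rbind(report, data.frame(rule = "retained", removed = nrow(keep)))
  stopifnot(sum(report$removed) == n0)
  list(calls = keep, report = report)
}

#' Heteroplasmy state from an allele fraction
#'
#' Bulk: `< 2%` absent, `2-98%` heteroplasmic, `> 98%` homoplasmic.
#' Single-cell RNA-seq: the homoplasmy threshold drops to 95%. Boundary
#' values are heteroplasmic.
#'
#' @param allele_fraction numeric vector in `[0, 1]`.
#' @param mode `"wgs_bulk"`, `"rna_bulk"` (bulk thresholds) or `"scrna"`.
#' @return Character vector in `{"absent", "heteroplasmic", "homoplasmic"}`.
#' @export
call_heteroplasmy_state <- function(allele_fraction,
                                    mode = c("wgs_bulk", "rna_bulk", "scrna")) {
  mode <- match.arg(mode)
  stopifnot(all(allele_fraction >= 0 & allele_fraction <= 1))
  hi <- if (mode == "scrna") 0.95 else 0.98
  ifelse(allele_fraction < 0.02, "absent",
         ifelse(allele_fraction <= hi, "heteroplasmic", "homoplasmic"))
}

#' Sample-level quality control
#'
#' Fails samples whose mean mtDNA depth is below `min_mean_depth` (400x);
#' fails both members of any sample pair sharing more than
#' `max_shared_variants` (10) heteroplasmic variants with similar HFs
#' (|dHF| <= `hf_tolerance`, default 0.05; likely cross-contamination); and
#' fails iPSC samples without a matched fibroblast that itself passes.
#'
#' @param samples SampleMeta data frame (needs `line_id`, `tissue`,
#'   `mean_mtdna_depth`; `fibroblast_line` for iPSC rows if pairing is to be
#'   checked).
#' @param calls filtered VariantCall table (heteroplasmic calls are used for
#'   the contamination check).
#' @param min_mean_depth,max_shared_variants,hf_tolerance rule parameters.
#' @return Data frame `line_id`, `pass`, `reason`.
#' @export
sample_qc <- function(samples, calls, min_mean_depth = 400,
                      max_shared_variants = 10, hf_tolerance = 0.05) {
  pass <- rep(TRUE, nrow(samples))
  reason <- rep("", nrow(samples))
  flag <- function(i, why) {
    pass[i] <<- FALSE
    reason[i] <<- ifelse(nzchar(reason[i]), paste(reason[i], why, sep = ";"),
                         why)
  }
  low <- samples$mean_mtdna_depth < min_mean_depth
  if (any(low)) flag(which(low), "depth")
  het <- calls[call_heteroplasmy_state(calls$allele_fraction) ==
                 "heteroplasmic", , drop = FALSE]
  ids <- samples$line_id
  by_sample <- split(het[, c("position", "ref", "alt", "allele_fraction")],
                     factor(het$sample_id, levels = ids))
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      a <- by_sample[[i]]; b <- by_sample[[j]]
      if (is.null(a) || is.null(b) || !nrow(a) || !nrow(b)) next
      m <- merge(a, b, by = c("position", "ref", "alt"))
      n_sim <- sum(abs(m$allele_fraction.x - m$allele_fraction.y) <=
                     hf_tolerance)
      if (n_sim > max_shared_variants) {
        flag(i, "contamination"); flag(j, "contamination")
      }
    }
  }
  if ("fibroblast_line" %in% names(samples)) {
    is_ipsc <- samples$tissue == "iPSC"
    fib_ok <- samples$line_id[samples$tissue == "fibroblast" & pass]
    orphan <- is_ipsc & !(samples$fibroblast_line %in% fib_ok)
    if (any(orphan)) flag(which(orphan), "no_matched_fibroblast")
  }
  data.frame(line_id = samples$line_id, pass = pass, reason = reason,
             stringsAsFactors = FALSE)
}

#' Single-cell quality control
#'
#' Applies the five single-cell rules: (1) retain cells with mean mtDNA depth
#' above 200x; (2) exclude stage-specific variants detected in only a single
#' cell of a line (likely sequencing error; variants also present in the
#' matched fibroblast bulk are protected); (3) call heteroplasmy with the
#' single-cell bands (2-95%); (4) exclude cells with more than 20
#' heteroplasmic variants; (5) retain only mtDNA positions whose mean depth
#' across cells is above 200x (the testable base mask).
#'
#' @param cell_calls VariantCall table with `sample_id` = cell id plus a
#'   `line_id` column.
#' @param cell_depths data frame `cell_id`, `mean_depth`.
#' @param site_depths data frame `position`, `mean_depth` (positions absent
#'   from the table count as below threshold).
#' @param fibro_variants optional data frame `position`, `ref`, `alt` of
#'   matched fibroblast bulk variants protected from the singleton rule.
#' @param min_depth depth threshold for rules 1 and 5.
#' @param max_heteroplasmies cell-level variant-count cap (rule 4).
#' @return List: `calls` (retained), `cells` (retained cell ids),
#'   `region_mask` (retained positions), `report` (per-rule removals).
#' @export
cell_qc <- function(cell_calls, cell_depths, site_depths,
                    fibro_variants = NULL, min_depth = 200,
                    max_heteroplasmies = 20) {
  report <- list()
  # (1) cell depth
  ok_cells <- cell_depths$cell_id[cell_depths$mean_depth > min_depth]
  drop1 <- setdiff(unique(cell_calls$sample_id), ok_cells)
  calls <- cell_calls[cell_calls$sample_id %in% ok_cells, , drop = FALSE]
  report$low_depth_cells <- length(drop1)
  # (5) region mask (applied before variant counting so rule 4 sees testable
  # sites only)
  mask <- sort(site_depths$position[site_depths$mean_depth > min_depth])
  n_pre <- nrow(calls)
  calls <- calls[calls$position %in% mask, , drop = FALSE]
  report$masked_region_calls <- n_pre - nrow(calls)
  # (3) heteroplasmy bands
  state <- call_heteroplasmy_state(calls$allele_fraction, mode = "scrna")
  report$absent_calls <- sum(state == "absent")
  calls <- calls[state != "absent", , drop = FALSE]
  state <- state[state != "absent"]
  # (2) singleton stage-specific variants
  key <- paste(calls$line_id, calls$position, calls$ref, calls$alt)
  n_cells_with <- stats::ave(seq_along(key), key, FUN = length)
  protected <- if (!is.null(fibro_variants)) {
    paste(calls$position, calls$ref, calls$alt) %in%
      paste(fibro_variants$position, fibro_variants$ref, fibro_variants$alt)
  } else rep(FALSE, nrow(calls))
  singleton <- n_cells_with == 1L & !protected & state == "heteroplasmic"
  report$singleton_variants <- sum(singleton)
  calls <- calls[!singleton, , drop = FALSE]
  # (4) cells with too many heteroplasmies
  state <- call_heteroplasmy_state(calls$allele_fraction, mode = "scrna")
  nhet <- table(calls$sample_id[state == "heteroplasmic"])
  bad_cells <- names(nhet)[nhet > max_heteroplasmies]
  report$high_burden_cells <- length(bad_cells)
  calls <- calls[!(calls$sample_id %in% bad_cells), , drop = FALSE]
  cells <- setdiff(ok_cells, bad_cells)
  list(calls = calls, cells = cells, region_mask = mask,
       report = data.frame(rule = names(report),
                           count = as.integer(unlist(report)),
                           stringsAsFactors = FALSE))
}
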
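# Readers/writers for variant tables, run configuration and the end-to-end
# pipeline driver.

VARIANT_COLUMNS <- c("sample_id", "position", "ref", "alt", "allele_fraction",
                     "depth", "alt_forward", "alt_reverse")

#' Read a variant call table (TSV or VCF)
#'
#' TSV requires the columns `sample_id`, `position`, `ref`, `alt`,
#' `allele_fraction`, `depth`, `alt_forward`, `alt_reverse` (extra columns
#' are preserved). VCF (as written by [write_variant_table()] or an external
#' caller) must carry per-sample FORMAT fields `AF`, `DP`, `ADF`, `ADR`;
#' indel records are excluded and counted in the attached report.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"vcf"` (guessed from the extension by
#'   default).
#' @return VariantCall data frame with attribute `excluded_indels`.
#' @export
read_variant_table <- function(path, dialect = c("auto", "tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (dialect == "tsv") {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    miss <- setdiff(VARIANT_COLUMNS, names(d))
    if (length(miss))
      stop("variant table missing columns: ", paste(miss, collapse = ", "))
    n0 <- nrow(d)
    snv <- nchar(d$ref) == 1 & nchar(d$alt) == 1 & d$ref %in% BASES &
      d$alt %in% BASES
    d <- d[snv, , drop = FALSE]
    attr(d, "excluded_indels") <- n0 - nrow(d)
    rownames(d) <- NULL
    return(d)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  snv <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 & fix$REF %in% BASES &
    fix$ALT %in% BASES
  excluded <- sum(!snv)
  get_num <- function(el) {
    m <- vcfR::extract.gt(v, element = el, as.numeric = TRUE)
    m[snv, , drop = FALSE]
  }
  af <- get_num("AF"); dp <- get_num("DP")
  adf <- get_num("ADF"); adr <- get_num("ADR")
  pos <- as.integer(fix$POS[snv])
  out <- do.call(rbind, lapply(colnames(af), function(s) {
    present <- !is.na(af[, s])
    data.frame(sample_id = s, position = pos[present],
               ref = fix$REF[snv][present], alt = fix$ALT[snv][present],
               allele_fraction = af[present, s],
               depth = as.integer(dp[present, s]),
               alt_forward = as.integer(adf[present, s]),
               alt_reverse = as.integer(adr[present, s]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "excluded_indels") <- excluded
  out
}

#' Write a variant call table (TSV or VCF)
#'
#' The VCF dialect stores one genotype column per sample with FORMAT
#' `GT:AF:DP:ADF:ADR`; samples without a call at a site get `./.`.
#'
#' @param calls VariantCall data frame.
#' @param path output path.
#' @param dialect `"tsv"` or `"vcf"` (guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(calls, path,
                                dialect = c("auto", "tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.vcf$", path)) "vcf" else "tsv"
  }
  if (dialect == "tsv") {
    utils::write.table(calls, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  samples <- sort(unique(calls$sample_id))
  key <- paste(calls$position, calls$ref, calls$alt)
  sites <- !duplicated(key)
  site <- calls[sites, c("position", "ref", "alt")]
  ord <- order(site$position, site$alt)
  site <- site[ord, , drop = FALSE]
  skey <- paste(site$position, site$ref, site$alt)
  gt <- matrix("./.", nrow(site), length(samples),
               dimnames = list(NULL, samples))
  idx <- cbind(match(key, skey), match(calls$sample_id, samples))
  gt[idx] <- sprintf("0/1:%.8g:%d:%d:%d", calls$allele_fraction, calls$depth,
                     calls$alt_forward, calls$alt_reverse)
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chrM,length=16569>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=ADF,Number=1,Type=Integer,Description=\"Alt reads forward strand\">",
           "##FORMAT=<ID=ADR,Number=1,Type=Integer,Description=\"Alt reads reverse strand\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(
    "chrM", site$position, ".", site$ref, site$alt, ".", "PASS", ".",
    "GT:AF:DP:ADF:ADR",
    apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Default run configuration
#'
#' @param ... named overrides (input paths, thresholds, seed, output
#'   directory).
#' @return A `RunConfig` list with every threshold at its default.
#' @export
run_config <- function(...) {
  cfg <- list(
    fibro_calls = NULL, ipsc_calls = NULL, samples = NULL,
    fibro_calls_unfiltered = NULL,
    mode = "wgs_bulk",
    min_af = 0.02, min_depth = 200, min_strand_reads = 2,
    hf_homoplasmy_bulk = 0.98, hf_homoplasmy_sc = 0.95,
    min_sample_depth = 400, contamination_shared = 10,
    contamination_hf_tolerance = 0.05,
    seed = 1L, out_dir = NULL,
    version = as.character(utils::packageVersion("mitodyn"))
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "RunConfig"
  cfg
}

#' Write / read a run configuration as YAML
#'
#' @param cfg a [run_config()] list.
#' @param path YAML path.
#' @return The config (read) or the path (write, invisibly).
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the bulk pipeline end-to-end
#'
#' Filter, pair, classify, shift, direction-test, rate-estimate and build
#' spectra from file inputs or in-memory tables, writing all result tables
#' and a JSON summary when `out_dir` is set.
#'
#' @param config a [run_config()]; `fibro_calls`, `ipsc_calls` and `samples`
#'   may be paths or data frames.
#' @param ref a `MitoReference` (default [mito_reference()]).
#' @return List of result tables: `filter_reports`, `qc`, `pairs`,
#'   `classified`, `shifts`, `direction`, `rate`, `spectra`, `summary`.
#' @export
run_pipeline <- function(config, ref = mito_reference()) {
  get_tab <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) read_variant_table(x) else x
  }
  stage <- "inputs"
  result <- tryCatch({
    fib <- get_tab(config$fibro_calls)
    ips <- get_tab(config$ipsc_calls)
    samples <- if (is.character(config$samples))
      utils::read.delim(config$samples, stringsAsFactors = FALSE) else
        config$samples
    if (is.null(fib) || is.null(ips) || is.null(samples))
      stop("fibro_calls, ipsc_calls and samples are required")
    stage <- "filter"
    ff <- filter_variant_calls(fib, ref, mode = config$mode,
                               min_af = config$min_af,
                               min_depth = config$min_depth,
                               min_strand_reads = config$min_strand_reads)
    fi <- filter_variant_calls(ips, ref, mode = config$mode,
                               min_af = config$min_af,
                               min_depth = config$min_depth,
                               min_strand_reads = config$min_strand_reads)
    stage <- "sample_qc"
    qc <- sample_qc(samples, rbind(ff$calls, fi$calls),
                    min_mean_depth = config$min_sample_depth,
                    max_shared_variants = config$contamination_shared,
                    hf_tolerance = config$contamination_hf_tolerance)
    ok <- qc$line_id[qc$pass]
    samples_ok <- samples[samples$line_id %in% ok, , drop = FALSE]
    stage <- "classify"
    pairs <- pair_lines(samples_ok)
    classified <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      classify_pair(pairs[i, ],
                    ff$calls[ff$calls$sample_id == pairs$fibroblast_line[i], ],
                    fi$calls[fi$calls$sample_id == pairs$ipsc_line[i], ],
                    ref)
    }))
    stage <- "shift"
    shifts <- shift_records(classified, samples_ok)
    n_inc <- sum(shifts$hs > 0)
    direction <- direction_binomial(n_inc, nrow(shifts))
    stage <- "rate"
    rate <- specific_mutation_rate(classified, nrow(pairs),
                                   get_tab(config$fibro_calls_unfiltered))
    stage <- "signatures"
    spectra <- list(
      fibroblast = build_spectrum96(
        ff$calls[call_heteroplasmy_state(ff$calls$allele_fraction) ==
                   "heteroplasmic", ], ref),
      ipsc = build_spectrum96(
        fi$calls[call_heteroplasmy_state(fi$calls$allele_fraction) ==
                   "heteroplasmic", ], ref)
    )
    summary <- summarise_results(classified, shifts, direction, rate)
    list(filter_reports = list(fibroblast = ff$report, ipsc = fi$report),
         qc = qc, pairs = pairs, classified = classified, shifts = shifts,
         direction = direction, rate = rate, spectra = spectra,
         summary = summary, seed = config$seed)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(config$out_dir)) write_summary(result, config$out_dir)
  result
}

summarise_results <- function(classified, shifts, direction, rate) {
  fib_het <- classified$category %in% c("shared", "lost")
  ipsc_set <- classified$category %in% c("shared", "ipsc_specific")
  n_shared <- sum(classified$category == "shared")
  n_lost <- sum(classified$category == "lost")
  n_spec <- sum(classified$category == "ipsc_specific")
  frac <- function(a, b) if (b > 0) a / b else NULL
  list(
    n_shared = n_shared, n_lost = n_lost, n_ipsc_specific = n_spec,
    shared_fraction = frac(n_shared, sum(fib_het)),
    lost_fraction = frac(n_lost, sum(fib_het)),
    specific_fraction = frac(n_spec, sum(ipsc_set)),
    n_increase = sum(shifts$hs > 0), n_shifts = nrow(shifts),
    direction_estimate = direction$estimate,
    direction_ci = c(direction$ci_low, direction$ci_high),
    direction_p = direction$p_value,
    rate_per_bp_per_genome = rate$rate_per_bp_per_genome,
    rate_ci = c(rate$ci_low, rate$ci_high),
    nsss = if ("region" %in% names(classified))
      nsss_ratio(classified[classified$category == "ipsc_specific", ]) else NULL
  )
}

#' Write the result bundle to disk
#'
#' Writes classification/shift TSVs and a machine-readable JSON summary
#' (headline statistics; empty classifications give `null` fractions, not
#' zero).
#'
#' @param results list from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_summary <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(results$classified,
                     file.path(out_dir, "classified_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(results$shifts, file.path(out_dir, "shifts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(results$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
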
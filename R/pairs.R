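# Fibroblast -> iPSC pair classification, heteroplasmic shifts, mutation
# rates, region enrichment and the cohort regression models.

#' Pair each iPSC line with its founder fibroblast line
#'
#' One pair per iPSC line; two iPSCs derived from the same fibroblast form
#' two separate pairs. iPSC lines without a matched fibroblast are excluded
#' with a warning.
#'
#' @param samples SampleMeta data frame with `line_id`, `tissue` and, for
#'   iPSC rows, `fibroblast_line` (falls back to donor matching when absent).
#' @return Data frame `fibroblast_line`, `ipsc_line`, `donor_id`.
#' @export
pair_lines <- function(samples) {
  ipsc <- samples[samples$tissue == "iPSC", , drop = FALSE]
  fib <- samples[samples$tissue == "fibroblast", , drop = FALSE]
  if (!nrow(ipsc)) {
    return(data.frame(fibroblast_line = character(), ipsc_line = character(),
                      donor_id = character(), stringsAsFactors = FALSE))
  }
  if (!"fibroblast_line" %in% names(ipsc)) {
    ipsc$fibroblast_line <- fib$line_id[match(ipsc$donor_id, fib$donor_id)]
  }
  ok <- ipsc$fibroblast_line %in% fib$line_id
  if (any(!ok)) {
    warning(sum(!ok), " iPSC line(s) without a matched fibroblast excluded")
  }
  data.frame(fibroblast_line = ipsc$fibroblast_line[ok],
             ipsc_line = ipsc$line_id[ok],
             donor_id = ipsc$donor_id[ok], stringsAsFactors = FALSE)
}

merge_pair_calls <- function(fibro_calls, ipsc_calls) {
  f <- fibro_calls[, c("position", "ref", "alt", "allele_fraction")]
  i <- ipsc_calls[, c("position", "ref", "alt", "allele_fraction")]
  names(f)[4] <- "hf_fibro"
  names(i)[4] <- "hf_ipsc"
  m <- merge(f, i, by = c("position", "ref", "alt"), all = TRUE)
  m$hf_fibro[is.na(m$hf_fibro)] <- 0
  m$hf_ipsc[is.na(m$hf_ipsc)] <- 0
  m
}

#' Classify variants across one fibroblast/iPSC pair
#'
#' Using the 2% detection threshold and heteroplasmy bands: `shared` when the
#' variant is present (>= 2%) in both members and heteroplasmic in at least
#' one; `lost` when heteroplasmic in the fibroblast and below 2% in the iPSC;
#' `ipsc_specific` when heteroplasmic in the iPSC and below 2% in the
#' fibroblast. Variants homoplasmic in both members (inherited haplogroup
#' variants) are not classified.
#'
#' @param pair one-row data frame (or list) with `fibroblast_line`,
#'   `ipsc_line`, `donor_id`.
#' @param fibro_calls,ipsc_calls filtered VariantCall tables for the two
#'   lines.
#' @param ref optional `MitoReference`; when supplied, region class and
#'   pathogenic flags are annotated.
#' @return ClassifiedVariant data frame.
#' @export
classify_pair <- function(pair, fibro_calls, ipsc_calls, ref = NULL) {
  m <- merge_pair_calls(fibro_calls, ipsc_calls)
  sf <- call_heteroplasmy_state(m$hf_fibro)
  si <- call_heteroplasmy_state(m$hf_ipsc)
  cat_ <- rep(NA_character_, nrow(m))
  some_het <- sf == "heteroplasmic" | si == "heteroplasmic"
  cat_[sf != "absent" & si != "absent" & some_het] <- "shared"
  cat_[sf == "heteroplasmic" & si == "absent"] <- "lost"
  cat_[si == "heteroplasmic" & sf == "absent"] <- "ipsc_specific"
  out <- data.frame(
    donor = pair$donor_id, fibroblast_line = pair$fibroblast_line,
    ipsc_line = pair$ipsc_line,
    position = m$position, ref = m$ref, alt = m$alt,
    hf_fibro = m$hf_fibro, hf_ipsc = m$hf_ipsc, category = cat_,
    stringsAsFactors = FALSE
  )
  out <- out[!is.na(out$category), , drop = FALSE]
  if (!is.null(ref) && nrow(out)) {
    out$region <- classify_variant_region(ref, out$position, out$ref, out$alt)
    out$pathogenic <- paste(out$position, out$alt) %in%
      paste(ref$pathogenic_sites$position, ref$pathogenic_sites$alt)
  }
  rownames(out) <- NULL
  out
}

#' Classify variants across a fibroblast with two derived iPSC lines
#'
#' Fibroblast heteroplasmies partition into `shared_both`, `shared_one` and
#' `lost_both`; iPSC variants absent from the fibroblast partition into
#' `ipsc_specific_both` and `ipsc_specific_one`.
#'
#' @param fibro_calls,ipsc_calls_1,ipsc_calls_2 filtered VariantCall tables.
#' @param ref optional `MitoReference` for annotation.
#' @return Data frame with `duo_subcategory` per unique variant.
#' @export
classify_duo <- function(fibro_calls, ipsc_calls_1, ipsc_calls_2, ref = NULL) {
  m1 <- merge_pair_calls(fibro_calls, ipsc_calls_1)
  names(m1)[names(m1) == "hf_ipsc"] <- "hf_ipsc_1"
  i2 <- ipsc_calls_2[, c("position", "ref", "alt", "allele_fraction")]
  names(i2)[4] <- "hf_ipsc_2"
  m1 <- merge(m1, i2, by = c("position", "ref", "alt"), all = TRUE)
  m1$hf_fibro[is.na(m1$hf_fibro)] <- 0
  m1$hf_ipsc_1[is.na(m1$hf_ipsc_1)] <- 0
  m1$hf_ipsc_2[is.na(m1$hf_ipsc_2)] <- 0
  sf <- call_heteroplasmy_state(m1$hf_fibro)
  s1 <- call_heteroplasmy_state(m1$hf_ipsc_1)
  s2 <- call_heteroplasmy_state(m1$hf_ipsc_2)
  in1 <- s1 != "absent"; in2 <- s2 != "absent"
  sub <- rep(NA_character_, nrow(m1))
  # fibroblast heteroplasmies partition into the three fibroblast categories
  sub[sf == "heteroplasmic" & in1 & in2] <- "shared_both"
  sub[sf == "heteroplasmic" & xor(in1, in2)] <- "shared_one"
  sub[sf == "heteroplasmic" & !in1 & !in2] <- "lost_both"
  # iPSC variants not detected in the fibroblast
  ipsc_het <- sf == "absent" & (s1 == "heteroplasmic" | s2 == "heteroplasmic")
  sub[ipsc_het & in1 & in2] <- "ipsc_specific_both"
  sub[ipsc_het & xor(in1, in2)] <- "ipsc_specific_one"
  out <- data.frame(position = m1$position, ref = m1$ref, alt = m1$alt,
                    hf_fibro = m1$hf_fibro, hf_ipsc_1 = m1$hf_ipsc_1,
                    hf_ipsc_2 = m1$hf_ipsc_2, duo_subcategory = sub,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$duo_subcategory), , drop = FALSE]
  if (!is.null(ref) && nrow(out)) {
    out$region <- classify_variant_region(ref, out$position, out$ref, out$alt)
  }
  rownames(out) <- NULL
  out
}

#' Heteroplasmic shift (HS)
#'
#' `hs = log2(hf_ipsc / hf_fibro)`: the fold change in heteroplasmy fraction
#' during reprogramming, defined for shared variants (both HFs > 0).
#'
#' @param hf_fibro,hf_ipsc heteroplasmy fractions in `(0, 1]`.
#' @return Numeric vector of shifts.
#' @export
heteroplasmic_shift <- function(hf_fibro, hf_ipsc) {
  if (any(hf_fibro <= 0 | hf_ipsc <= 0))
    stop("heteroplasmic shift is undefined for zero HFs; restrict to shared ",
         "variants or supply an explicit floor")
  log2(hf_ipsc / hf_fibro)
}

#' Build shift records for shared variants
#'
#' @param classified ClassifiedVariant table from [classify_pair()] (rows of
#'   all categories; only `shared` rows yield shifts).
#' @param samples optional SampleMeta to attach age/haplogroup covariates.
#' @param extreme_threshold shift value above which a shift is flagged
#'   extreme (default 6).
#' @return ShiftRecord data frame with `hs`, `direction`, `extreme` and
#'   covariates.
#' @export
shift_records <- function(classified, samples = NULL, extreme_threshold = 6) {
  sh <- classified[classified$category == "shared", , drop = FALSE]
  sh <- sh[sh$hf_fibro > 0 & sh$hf_ipsc > 0, , drop = FALSE]
  hs <- heteroplasmic_shift(sh$hf_fibro, sh$hf_ipsc)
  out <- data.frame(
    donor = sh$donor, fibroblast_line = sh$fibroblast_line,
    ipsc_line = sh$ipsc_line, position = sh$position, ref = sh$ref,
    alt = sh$alt, hf_fibro = sh$hf_fibro, hf_ipsc = sh$hf_ipsc, hs = hs,
    direction = ifelse(hs > 0, "increase", "decrease"),
    extreme = hs > extreme_threshold, stringsAsFactors = FALSE
  )
  if ("region" %in% names(sh)) out$region <- sh$region
  if (!is.null(samples)) {
    i <- match(out$ipsc_line, samples$line_id)
    out$age <- samples$age[i]
    out$macro_haplogroup <- samples$macro_haplogroup[i]
  }
  rownames(out) <- NULL
  out
}

#' Exact binomial test of shift direction
#'
#' Two-sided exact binomial test of the increase proportion against 0.5 with
#' a Clopper-Pearson 95% confidence interval.
#'
#' @param n_increase,n_total counts of increasing and total shared shifts.
#' @param conf_level confidence level (default 0.95).
#' @return List `estimate`, `p_value`, `ci_low`, `ci_high`.
#' @export
direction_binomial <- function(n_increase, n_total, conf_level = 0.95) {
  if (n_total == 0) stop("n_total must be positive")
  bt <- stats::binom.test(n_increase, n_total, p = 0.5,
                          conf.level = conf_level)
  list(estimate = n_increase / n_total, p_value = bt$p.value,
       ci_low = bt$conf.int[1], ci_high = bt$conf.int[2])
}

#' iPSC-specific mutation rate
#'
#' Counts iPSC-specific variants, rescuing as pre-existing any whose
#' fibroblast allele fraction is above zero in the unfiltered fibroblast
#' calls, and estimates `rate = events / (16,569 x n_lines)` per base pair
#' per genome per reprogramming with an exact Poisson 95% CI. An optional
#' copies-per-cell normaliser yields the per-molecule rate.
#'
#' @param classified ClassifiedVariant table (all pairs combined; needs
#'   `ipsc_line`, `position`, `ref`, `alt`, `category`, optionally
#'   `fibroblast_line` and `pathogenic`).
#' @param n_lines number of iPSC lines in the denominator.
#' @param fibro_calls_unfiltered unfiltered fibroblast VariantCall table
#'   (`sample_id`, `position`, `ref`, `alt`, `allele_fraction`), or `NULL`
#'   to skip the rescue (flagged in the output).
#' @param pathogenic_only restrict events to flagged pathogenic variants.
#' @param copies_per_cell optional normaliser for the per-molecule rate.
#' @return RateEstimate list: `n_events`, `n_rescued`, `n_lines`,
#'   `rate_per_bp_per_genome`, `ci_low`, `ci_high`,
#'   `rate_per_bp_per_molecule` (NA unless `copies_per_cell` given),
#'   `rescued_applied`.
#' @export
specific_mutation_rate <- function(classified, n_lines,
                                   fibro_calls_unfiltered = NULL,
                                   pathogenic_only = FALSE,
                                   copies_per_cell = NULL) {
  ev <- classified[classified$category == "ipsc_specific", , drop = FALSE]
  if (pathogenic_only) {
    if (!"pathogenic" %in% names(ev))
      stop("pathogenic flags missing; classify with a reference that ",
           "carries a pathogenic site list")
    ev <- ev[ev$pathogenic, , drop = FALSE]
  }
  n_rescued <- 0L
  rescued <- FALSE
  if (!is.null(fibro_calls_unfiltered) && nrow(ev)) {
    uf <- fibro_calls_unfiltered
    uf <- uf[uf$allele_fraction > 0, , drop = FALSE]
    if ("fibroblast_line" %in% names(ev)) {
      key_ev <- paste(ev$fibroblast_line, ev$position, ev$ref, ev$alt)
      key_uf <- paste(uf$sample_id, uf$position, uf$ref, uf$alt)
    } else {
      key_ev <- paste(ev$position, ev$ref, ev$alt)
      key_uf <- paste(uf$position, uf$ref, uf$alt)
    }
    pre <- key_ev %in% key_uf
    n_rescued <- sum(pre)
    ev <- ev[!pre, , drop = FALSE]
    rescued <- TRUE
  }
  n_events <- nrow(ev)
  denom <- MT_GENOME_LENGTH * n_lines
  pt <- stats::poisson.test(n_events)
  out <- list(
    n_events = n_events, n_rescued = n_rescued, n_lines = n_lines,
    rate_per_bp_per_genome = n_events / denom,
    ci_low = pt$conf.int[1] / denom, ci_high = pt$conf.int[2] / denom,
    rate_per_bp_per_molecule = if (is.null(copies_per_cell)) NA_real_ else
      n_events / denom / copies_per_cell,
    rescue_applied = rescued
  )
  class(out) <- "RateEstimate"
  out
}

#' @export
print.RateEstimate <- function(x, ...) {
  cat(sprintf("RateEstimate: %d events / %d lines -> %.3g per bp per genome (95%% CI %.3g-%.3g)%s\n",
              x$n_events, x$n_lines, x$rate_per_bp_per_genome, x$ci_low,
              x$ci_high,
              if (!x$rescue_applied) " [no sub-threshold rescue applied]" else ""))
  invisible(x)
}

#' Mutation-rate sensitivity to the iPSC detection threshold
#'
#' Recomputes the iPSC-specific rate over a descending grid of iPSC
#' detection thresholds (default 2% down to 0.5% in 0.5% steps), holding the
#' fibroblast rescue rule fixed (fibroblast AF > 0 means pre-existing). The
#' resulting rate is monotone non-decreasing as the threshold falls.
#'
#' @param pairs pair table from [pair_lines()].
#' @param ipsc_calls_unfiltered unfiltered iPSC VariantCall table.
#' @param fibro_calls_unfiltered unfiltered fibroblast VariantCall table.
#' @param thresholds descending numeric grid of detection thresholds.
#' @return Data frame `threshold`, `n_events`, `rate`.
#' @export
threshold_sensitivity <- function(pairs, ipsc_calls_unfiltered,
                                  fibro_calls_unfiltered,
                                  thresholds = c(0.02, 0.015, 0.01, 0.005)) {
  uf <- fibro_calls_unfiltered[fibro_calls_unfiltered$allele_fraction > 0, ,
                               drop = FALSE]
  key_uf <- paste(uf$sample_id, uf$position, uf$ref, uf$alt)
  n_lines <- nrow(pairs)
  ic <- ipsc_calls_unfiltered[
    ipsc_calls_unfiltered$sample_id %in% pairs$ipsc_line, , drop = FALSE]
  fib_of <- pairs$fibroblast_line[match(ic$sample_id, pairs$ipsc_line)]
  key_fib <- paste(fib_of, ic$position, ic$ref, ic$alt)
  pre <- key_fib %in% key_uf
  out <- lapply(thresholds, function(t) {
    n_ev <- sum(ic$allele_fraction >= t & ic$allele_fraction <= 0.98 & !pre)
    data.frame(threshold = t, n_events = n_ev,
               rate = n_ev / (MT_GENOME_LENGTH * n_lines))
  })
  do.call(rbind, out)
}

#' Nonsynonymous/synonymous ratio of coding-region heteroplasmies
#'
#' @param variants data frame with a `region` column.
#' @return `count(nonsynonymous) / count(synonymous)`; `NA` when no
#'   synonymous variants are present (unless the NS count is 0, which gives
#'   0).
#' @export
nsss_ratio <- function(variants) {
  ns <- sum(variants$region == "nonsynonymous")
  ss <- sum(variants$region == "synonymous")
  if (ss == 0) {
    if (ns == 0) return(0)
    return(NA_real_)
  }
  ns / ss
}

#' Region mutation frequencies with Fisher enrichment tests
#'
#' Per region class, `frequency = variant count / (region length x n_lines)`
#' per base pair. Two-sided Fisher exact tests compare each region's count
#' against (a) the rest of the genome and (b) the genome-wide expectation,
#' using opportunity counts `length x n_lines`. Raw and Benjamini-Hochberg
#' adjusted p-values are reported.
#'
#' @param variants data frame with `position` and `region`.
#' @param ref a `MitoReference`.
#' @param n_lines number of lines the variants were called in.
#' @return Data frame per region: `n`, `length_bp`, `frequency`,
#'   `p_vs_rest`, `or_vs_rest`, `p_vs_expected`, `or_vs_expected`, `q_vs_rest`.
#' @export
region_mutation_frequency <- function(variants, ref, n_lines) {
  rl <- region_lengths(ref)
  # coding region counts split into NS/SS at the variant level; frequency
  # denominators use the coding span for both
  reg_of <- function(r) ifelse(r %in% c("nonsynonymous", "synonymous"),
                               "coding", r)
  span <- rl[c("dloop", "coding", "rRNA", "tRNA", "noncoding_other")]
  counts <- table(factor(reg_of(variants$region), levels = names(span)))
  total <- sum(counts)
  total_len <- sum(span)
  res <- lapply(names(span), function(r) {
    a <- as.integer(counts[r]); la <- as.integer(span[r])
    b <- total - a; lb <- total_len - la
    f_rest <- stats::fisher.test(matrix(c(a, la * n_lines - a,
                                          b, lb * n_lines - b), 2))
    f_exp <- stats::fisher.test(matrix(c(a, la * n_lines - a,
                                         total, total_len * n_lines - total), 2))
    data.frame(region = r, n = a, length_bp = la,
               frequency = a / (la * n_lines),
               p_vs_rest = f_rest$p.value, or_vs_rest = unname(f_rest$estimate),
               p_vs_expected = f_exp$p.value,
               or_vs_expected = unname(f_exp$estimate),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q_vs_rest <- stats::p.adjust(res$p_vs_rest, "BH")
  res
}

#' Relative mtDNA copy number per diploid cell
#'
#' `CNmt = 2 x DPmt / DPautosome`.
#'
#' @param mean_mtdna_depth,mean_autosomal_depth mean fold coverages.
#' @return Copies per diploid cell.
#' @export
relative_copy_number <- function(mean_mtdna_depth, mean_autosomal_depth) {
  if (any(mean_autosomal_depth <= 0)) stop("autosomal depth must be positive")
  2 * mean_mtdna_depth / mean_autosomal_depth
}

tidy_fit <- function(fit, model) {
  s <- summary(fit)$coefficients
  data.frame(model = model, term = rownames(s), estimate = s[, 1],
             se = s[, 2], p_value = s[, ncol(s)], row.names = NULL,
             stringsAsFactors = FALSE)
}

drop_single_level <- function(df, vars) {
  keep <- vars[vapply(vars, function(v)
    length(unique(df[[v]][!is.na(df[[v]])])) > 1, logical(1))]
  dropped <- setdiff(vars, keep)
  if (length(dropped))
    warning("dropping single-level covariate(s): ",
            paste(dropped, collapse = ", "))
  keep
}

#' Linear models of heteroplasmy burden and mean HF on donor age
#'
#' Fits ordinary least squares of the per-line heteroplasmic variant count
#' (fibroblast and iPSC) and of the logit-transformed mean heteroplasmy
#' fraction on donor age, sex and macro-haplogroup (four models). Lines with
#' no heteroplasmies contribute burden 0 and are excluded from the mean-HF
#' models.
#'
#' @param samples SampleMeta (needs `line_id`, `tissue`, `age`, `sex`,
#'   `macro_haplogroup`).
#' @param calls filtered VariantCall table; heteroplasmic calls define burden
#'   and mean HF.
#' @return Coefficient table (model, term, estimate, se, p_value).
#' @export
fit_age_models <- function(samples, calls) {
  het <- calls[call_heteroplasmy_state(calls$allele_fraction) ==
                 "heteroplasmic", , drop = FALSE]
  burden <- table(factor(het$sample_id, levels = samples$line_id))
  mean_hf <- tapply(het$allele_fraction,
                    factor(het$sample_id, levels = samples$line_id), mean)
  d <- samples
  d$burden <- as.integer(burden[d$line_id])
  d$mean_hf <- as.numeric(mean_hf[d$line_id])
  d$logit_hf <- stats::qlogis(pmin(pmax(d$mean_hf, 1e-6), 1 - 1e-6))
  out <- list()
  for (tis in c("fibroblast", "iPSC")) {
    di <- d[d$tissue == tis, , drop = FALSE]
    if (nrow(di) < 10) next
    covs <- drop_single_level(di, c("sex", "macro_haplogroup"))
    rhs <- paste(c("age", covs), collapse = " + ")
    mlab <- if (tis == "fibroblast") c("burden_fibro", "hf_fibro") else
      c("burden_ipsc", "hf_ipsc")
    out[[mlab[1]]] <- tidy_fit(
      stats::lm(stats::as.formula(paste("burden ~", rhs)), data = di), mlab[1])
    dh <- di[!is.na(di$logit_hf), , drop = FALSE]
    if (nrow(dh) >= 10) {
      covs2 <- drop_single_level(dh, c("sex", "macro_haplogroup"))
      rhs2 <- paste(c("age", covs2), collapse = " + ")
      out[[mlab[2]]] <- tidy_fit(
        stats::lm(stats::as.formula(paste("logit_hf ~", rhs2)), data = dh),
        mlab[2])
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Logistic model of heteroplasmic-shift direction
#'
#' Fits `increase ~ logit(hf_fibro) + region + haplogroup + age` by logistic
#' regression, with the D-loop as the region reference level. Complete
#' separation is flagged (`separation` attribute) when fitted probabilities
#' collapse to 0/1 or coefficients diverge.
#'
#' @param shifts ShiftRecord table from [shift_records()] (needs `hs`,
#'   `hf_fibro`, `region`; uses `macro_haplogroup` and `age` when present).
#' @return Coefficient table with attribute `separation`.
#' @export
fit_shift_direction_model <- function(shifts) {
  d <- shifts
  d$increase <- as.integer(d$hs > 0)
  if (length(unique(d$increase)) < 2) {
    out <- data.frame(model = character(0), term = character(0),
                      estimate = numeric(0), se = numeric(0),
                      p_value = numeric(0))
    attr(out, "separation") <- TRUE
    warning("all shifts in one direction: model degenerate, separation flagged")
    return(out)
  }
  d$logit_hf_fibro <- stats::qlogis(pmin(pmax(d$hf_fibro, 1e-6), 1 - 1e-6))
  d$region <- stats::relevel(factor(d$region), ref = "dloop")
  covs <- c("logit_hf_fibro", "region")
  if ("macro_haplogroup" %in% names(d)) covs <- c(covs, "macro_haplogroup")
  if ("age" %in% names(d)) covs <- c(covs, "age")
  covs <- drop_single_level(d, covs)
  fit <- suppressWarnings(
    stats::glm(stats::as.formula(paste("increase ~",
                                       paste(covs, collapse = " + "))),
               family = stats::binomial(), data = d))
  out <- tidy_fit(fit, "shift_direction")
  p <- stats::fitted(fit)
  attr(out, "separation") <- any(abs(stats::coef(fit)) > 15, na.rm = TRUE) ||
    all(p > 0.999 | p < 0.001)
  out
}
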
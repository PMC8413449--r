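# Strand-resolved 6- and 96-class mutational spectra on the circular
# mitochondrial genome.
#
# Substitution classes follow the pyrimidine convention: every substitution
# is expressed with a pyrimidine reference base (C>A, C>G, C>T, T>A, T>C,
# T>G) and the strand records which strand carried that pyrimidine. The
# loaded FASTA is treated as the L strand by default; set `fasta_strand =
# "H"` to flip the convention.

SUB_CLASSES6 <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

context96_labels <- function() {
  out <- character(0)
  for (cls in SUB_CLASSES6) {
    rb <- substr(cls, 1, 1)
    for (p5 in BASES) for (p3 in BASES) {
      out <- c(out, paste0(p5, "[", cls, "]", p3))
    }
  }
  out
}

#' Assign the pyrimidine substitution class and strand of a substitution
#'
#' When the reference-strand base is a pyrimidine the class is `ref>alt` on
#' the reference strand; otherwise both alleles and the trinucleotide
#' context are complemented and the substitution is assigned to the opposite
#' strand.
#'
#' @param ref_base,alt_base reference and alternate bases (vectors).
#' @param ref a `MitoReference` (for the trinucleotide context).
#' @param position 1-based positions.
#' @param fasta_strand which strand the loaded FASTA represents (`"L"`
#'   default, or `"H"`).
#' @return Data frame `class6`, `strand`, `context` (5' base + pyrimidine
#'   ref + 3' base), `class96` (e.g. `A[C>T]G`).
#' @export
assign_substitution_class <- function(ref_base, alt_base, ref, position,
                                      fasta_strand = c("L", "H")) {
  fasta_strand <- match.arg(fasta_strand)
  if (any(ref_base == alt_base)) stop("ref and alt alleles must differ")
  other <- setdiff(c("L", "H"), fasta_strand)
  pyr <- ref_base %in% c("C", "T")
  cls <- ifelse(pyr, paste0(ref_base, ">", alt_base),
                paste0(comp_base(ref_base), ">", comp_base(alt_base)))
  strand <- ifelse(pyr, fasta_strand, other)
  ctx <- trinucleotide_context(ref, position)
  ctx <- ifelse(pyr, ctx, revcomp(ctx))
  data.frame(class6 = cls, strand = strand, context = ctx,
             class96 = paste0(substr(ctx, 1, 1), "[", cls, "]",
                              substr(ctx, 3, 3)),
             stringsAsFactors = FALSE)
}

#' Strand-resolved 96-class mutational spectrum
#'
#' Counts variants per 96 substitution classes and strand and normalises
#' each count by the frequency of its trinucleotide context on that strand
#' of the reference, giving context-normalised substitution rates.
#'
#' @param variants data frame with `position`, `ref`, `alt`.
#' @param ref a `MitoReference`.
#' @param fasta_strand strand convention, see [assign_substitution_class()].
#' @return A `SignatureSpectrum` list: `counts` and `rates` (96 x 2 matrices,
#'   columns `L`/`H`), `total_variants`, `labels`.
#' @export
build_spectrum96 <- function(variants, ref, fasta_strand = "L") {
  labels <- context96_labels()
  counts <- matrix(0L, length(labels), 2,
                   dimnames = list(labels, c("L", "H")))
  if (nrow(variants)) {
    cl <- assign_substitution_class(variants$ref, variants$alt, ref,
                                    variants$position, fasta_strand)
    tab <- table(factor(cl$class96, levels = labels),
                 factor(cl$strand, levels = c("L", "H")))
    counts <- counts + unclass(tab)
  }
  freqL <- context_frequencies(ref, "L")
  freqH <- context_frequencies(ref, "H")
  ctx_of <- paste0(substr(labels, 1, 1), substr(labels, 3, 3),
                   substr(labels, 7, 7))
  denom <- cbind(L = freqL[ctx_of], H = freqH[ctx_of])
  rates <- counts / denom
  rates[denom == 0] <- 0
  structure(list(counts = counts, rates = rates,
                 total_variants = sum(counts), labels = labels,
                 scheme = "96", fasta_strand = fasta_strand),
            class = "SignatureSpectrum")
}

#' @export
print.SignatureSpectrum <- function(x, ...) {
  cat("SignatureSpectrum:", x$scheme, "classes x 2 strands,",
      x$total_variants, "variants\n")
  invisible(x)
}

#' Collapse a 96-class spectrum to 6 classes
#'
#' @param spectrum a 96-class `SignatureSpectrum`.
#' @return A 6-class `SignatureSpectrum` (counts summed over contexts; rates
#'   re-normalised by total context frequency per pyrimidine base).
#' @export
collapse_spectrum6 <- function(spectrum) {
  stopifnot(spectrum$scheme == "96")
  cls <- substr(spectrum$labels, 3, 5)
  counts <- rowsum(spectrum$counts, cls)[SUB_CLASSES6, , drop = FALSE]
  # 6-class output reports relative frequencies (regional display
  # convention), not context-normalised rates
  freq <- if (sum(counts) > 0) counts / sum(counts) else counts
  structure(list(counts = counts, rates = freq,
                 total_variants = sum(counts), labels = SUB_CLASSES6,
                 scheme = "6", fasta_strand = spectrum$fasta_strand),
            class = "SignatureSpectrum")
}

#' Six-class spectra by mtDNA region
#'
#' Per region class, the relative frequency of the six pyrimidine
#' substitution classes on each strand (frequencies sum to 1 within a
#' nonempty region).
#'
#' @param variants data frame with `position`, `ref`, `alt` and a `region`
#'   column (from [classify_variant_region()]).
#' @param ref a `MitoReference`.
#' @param fasta_strand strand convention.
#' @return Data frame `region`, `class6`, `strand`, `count`, `frequency`.
#' @export
spectrum6_by_region <- function(variants, ref, fasta_strand = "L") {
  stopifnot("region" %in% names(variants))
  if (!nrow(variants)) {
    return(data.frame(region = character(), class6 = character(),
                      strand = character(), count = integer(),
                      frequency = numeric()))
  }
  cl <- assign_substitution_class(variants$ref, variants$alt, ref,
                                  variants$position, fasta_strand)
  d <- data.frame(region = variants$region, class6 = cl$class6,
                  strand = cl$strand)
  tab <- as.data.frame(table(region = d$region,
                             class6 = factor(d$class6, levels = SUB_CLASSES6),
                             strand = factor(d$strand, levels = c("L", "H"))),
                       stringsAsFactors = FALSE)
  names(tab)[4] <- "count"
  tot <- stats::ave(tab$count, tab$region, FUN = sum)
  tab$frequency <- ifelse(tot > 0, tab$count / tot, 0)
  tab
}

#' Stouffer combination of p-values
#'
#' Combines k p-values as `Z = sum(z_i) / sqrt(k)`. One-sided inputs use
#' `z_i = qnorm(1 - p_i)`; two-sided inputs (the default for Fisher tests)
#' use the magnitude transform `z_i = qnorm(1 - p_i / 2)`, under which a
#' vector of p = 1 gives Z = 0 and a combined p of 0.5. The combined p is
#' the upper tail of Z.
#'
#' @param p vector of p-values.
#' @param sided `"two"` or `"one"`.
#' @return List `z`, `p_value`.
#' @export
stouffer_combine <- function(p, sided = c("two", "one")) {
  sided <- match.arg(sided)
  p <- p[!is.na(p)]
  if (!length(p)) stop("no p-values to combine")
  z <- if (sided == "two") stats::qnorm(1 - p / 2) else stats::qnorm(1 - p)
  Z <- sum(z) / sqrt(length(z))
  list(z = Z, p_value = stats::pnorm(Z, lower.tail = FALSE))
}

#' Compare two spectra class-by-class with a combined Stouffer p
#'
#' Per class (and strand, when resolved), a two-sided Fisher exact test of
#' the class count against the remainder between the two cohorts; the
#' per-class p-values are combined by Stouffer's method. Classes with an
#' all-zero margin are skipped and listed.
#'
#' @param spectrum_a,spectrum_b `SignatureSpectrum` objects of the same
#'   scheme.
#' @return List `per_class` (data frame with odds ratios, CIs, p),
#'   `combined_z`, `combined_p`, `skipped`.
#' @export
compare_spectra_stouffer <- function(spectrum_a, spectrum_b) {
  stopifnot(spectrum_a$scheme == spectrum_b$scheme)
  ca <- as.vector(spectrum_a$counts)
  cb <- as.vector(spectrum_b$counts)
  lab <- as.vector(outer(rownames(spectrum_a$counts),
                         colnames(spectrum_a$counts), paste, sep = "/"))
  ta <- sum(ca); tb <- sum(cb)
  res <- lapply(seq_along(ca), function(i) {
    m <- matrix(c(ca[i], ta - ca[i], cb[i], tb - cb[i]), 2)
    if (ca[i] + cb[i] == 0) {
      return(data.frame(class = lab[i], count_a = ca[i], count_b = cb[i],
                        odds_ratio = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_,
                        skipped = TRUE, stringsAsFactors = FALSE))
    }
    ft <- stats::fisher.test(m)
    data.frame(class = lab[i], count_a = ca[i], count_b = cb[i],
               odds_ratio = unname(ft$estimate), ci_low = ft$conf.int[1],
               ci_high = ft$conf.int[2], p_value = ft$p.value,
               skipped = FALSE, stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, res)
  comb <- stouffer_combine(per_class$p_value[!per_class$skipped], "two")
  list(per_class = per_class, combined_z = comb$z, combined_p = comb$p_value,
       skipped = per_class$class[per_class$skipped])
}

#' Correlate a 96-class spectrum with external signatures
#'
#' Pearson correlation of the strand-summed context-normalised rate vector
#' against each column of an external 96-row signature matrix (e.g. cancer
#' signatures). The external matrix must carry a `context` column in
#' `A[C>A]A` notation matching the spectrum ordering; a mismatch is an
#' error.
#'
#' @param spectrum a 96-class `SignatureSpectrum`.
#' @param external data frame with `context` plus one numeric column per
#'   named signature.
#' @return Data frame `signature`, `r_squared`, `p_value`.
#' @export
correlate_signatures <- function(spectrum, external) {
  stopifnot(spectrum$scheme == "96")
  if (!"context" %in% names(external))
    stop("external signature matrix needs a 'context' column")
  if (!setequal(external$context, spectrum$labels) ||
      anyDuplicated(external$context))
    stop("external signature contexts do not match the 96-class ordering")
  ext <- external[match(spectrum$labels, external$context), , drop = FALSE]
  x <- rowSums(spectrum$rates)
  sig_cols <- setdiff(names(ext), "context")
  res <- lapply(sig_cols, function(s) {
    ct <- stats::cor.test(x, ext[[s]])
    data.frame(signature = s, r_squared = unname(ct$estimate)^2,
               p_value = ct$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
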
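# mtDNA genome length (rCRS numbering)
MT_GENOME_LENGTH <- 16569L

# low-complexity intervals excluded from variant calling (1-based, closed)
MT_LOW_COMPLEXITY <- data.frame(
  start = c(66L, 300L, 513L, 3106L, 12418L, 16182L),
  end   = c(71L, 316L, 525L, 3107L, 12425L, 16194L)
)

REGION_CLASSES <- c("dloop", "nonsynonymous", "synonymous", "rRNA", "tRNA",
                    "noncoding_other")

BASES <- c("A", "C", "G", "T")

comp_base <- function(x) chartr("ACGT", "TGCA", x)

revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# vertebrate mitochondrial codon table (named character vector codon -> AA),
# built lazily from Biostrings
.mito_env <- new.env(parent = emptyenv())

mito_codon_table <- function() {
  if (is.null(.mito_env$codon_table)) {
    gc2 <- Biostrings::getGeneticCode("2")  # vertebrate mitochondrial
    .mito_env$codon_table <- gc2
  }
  .mito_env$codon_table
}

#' Deterministic synthetic mtDNA-like reference sequence
#'
#' Generates a synthetic 16,569-base circular sequence with rCRS-like base
#' composition, homopolymer/repeat tracts at the canonical low-complexity
#' intervals, and fixed reference alleles at well-known hotspot and pathogenic
#' positions so that the bundled site lists are consistent with the sequence.
#' The real rCRS is not distributed with the package; any single-record FASTA
#' of length 16,569 can be supplied to [load_reference()] instead.
#'
#' @return A single character string of length-16,569 bases (A/C/G/T).
#' @export
synthetic_mtdna_sequence <- function() {
  if (!is.null(.mito_env$synthetic_seq)) return(.mito_env$synthetic_seq)
  bases <- withr::with_seed(165690, {
    # approximate rCRS composition: A 30.9%, C 31.3%, G 13.1%, T 24.7%
    sample(BASES, MT_GENOME_LENGTH, replace = TRUE,
           prob = c(0.309, 0.313, 0.131, 0.247))
  })
  set_run <- function(from, to, b) {
    bases[from:to] <<- strsplit(b, "")[[1]]
  }
  # low-complexity tracts
  set_run(66, 71, "CCCCCC")
  set_run(300, 316, "CCCCCCCCCCTCCCCCC")  # poly-C tract interrupted at 310
  set_run(513, 525, "CACACACACACAC")
  set_run(3106, 3107, "CC")
  set_run(12418, 12425, "AAAAAAAA")
  set_run(16182, 16194, "CCCCCCCCCCCCC")
  # anchor reference alleles at recurrent / pathogenic sites
  anchors <- c(
    "310" = "T", "414" = "T", "1392" = "T", "2623" = "A", "13327" = "A",
    "13369" = "T",
    "1494" = "C", "1555" = "A", "3243" = "A", "3256" = "C", "3271" = "T",
    "3460" = "G", "3697" = "G", "3733" = "G", "4171" = "C", "5703" = "G",
    "7445" = "A", "8344" = "A", "8356" = "T", "8363" = "G", "8993" = "T",
    "9176" = "T", "9185" = "T", "10158" = "T", "10191" = "T", "10197" = "G",
    "11777" = "C", "11778" = "G", "13513" = "G", "13514" = "A",
    "14459" = "G", "14484" = "T", "14487" = "T"
  )
  bases[as.integer(names(anchors))] <- unname(anchors)
  out <- paste(bases, collapse = "")
  .mito_env$synthetic_seq <- out
  out
}

#' Path to a bundled annotation file
#'
#' @param file one of `"mtdna_annotation.tsv"`, `"dloop_subregions.tsv"`,
#'   `"pathogenic_sites.tsv"`.
#' @return Path to the installed file.
#' @export
mito_extdata <- function(file) {
  p <- system.file("extdata", file, package = "mitodyn")
  if (!nzchar(p)) stop("bundled file not found: ", file)
  p
}

in_feature <- function(position, start, end) {
  # closed 1-based interval, wrapping the origin when start > end
  if (start <= end) position >= start & position <= end
  else position >= start | position <= end
}

feature_length <- function(start, end) {
  if (start <= end) end - start + 1L
  else (MT_GENOME_LENGTH - start + 1L) + end
}

#' Load a circular mtDNA reference with annotation
#'
#' Reads a single-record FASTA of exactly 16,569 bases plus a tab-separated
#' gene/region annotation (columns `name`, `start`, `end`, `strand`, `kind`),
#' the D-loop subregion coordinate table and a pathogenic-site list, and
#' returns a `MitoReference` object used by all downstream operations.
#'
#' The annotation `strand` records the reading orientation of each feature
#' relative to the FASTA as supplied: `"H"` features are read in FASTA
#' orientation, `"L"` features on the reverse complement. Coordinates are
#' 1-based inclusive; the D-loop interval wraps the origin (16024-576).
#'
#' @param fasta_path single-record FASTA path; `NULL` uses the synthetic
#'   bundled sequence from [synthetic_mtdna_sequence()].
#' @param annotation_path gene annotation TSV; default bundled table.
#' @param dloop_path D-loop subregion TSV (`name`, `start`, `end`).
#' @param pathogenic_path pathogenic site TSV (`position`, `ref`, `alt`,
#'   `label`); `NULL` for none.
#' @return An object of class `MitoReference`.
#' @export
load_reference <- function(fasta_path = NULL,
                           annotation_path = mito_extdata("mtdna_annotation.tsv"),
                           dloop_path = mito_extdata("dloop_subregions.tsv"),
                           pathogenic_path = mito_extdata("pathogenic_sites.tsv")) {
  if (is.null(fasta_path)) {
    seq <- synthetic_mtdna_sequence()
  } else {
    ss <- Biostrings::readDNAStringSet(fasta_path)
    if (length(ss) != 1L)
      stop("reference FASTA must contain exactly one sequence, found ",
           length(ss))
    seq <- as.character(ss[[1]])
  }
  if (nchar(seq) != MT_GENOME_LENGTH)
    stop("reference sequence length is ", nchar(seq), ", expected ",
         MT_GENOME_LENGTH)
  genes <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  need <- c("name", "start", "end", "strand", "kind")
  if (!all(need %in% names(genes)))
    stop("annotation is missing columns: ",
         paste(setdiff(need, names(genes)), collapse = ", "))
  if (!any(genes$kind == "dloop"))
    stop("annotation must contain a D-loop feature (kind = 'dloop')")
  bad <- genes$start < 1 | genes$end < 1 |
    genes$start > MT_GENOME_LENGTH | genes$end > MT_GENOME_LENGTH
  if (any(bad))
    stop("annotation intervals outside [1, 16569]: ",
         paste(genes$name[bad], collapse = ", "))
  dup <- duplicated(genes[, c("kind", "start", "end")])
  if (any(dup))
    stop("duplicate identical-kind features: ",
         paste(genes$name[dup], collapse = ", "))
  dloop <- utils::read.delim(dloop_path, stringsAsFactors = FALSE)
  pathogenic <- if (is.null(pathogenic_path)) {
    data.frame(position = integer(), ref = character(), alt = character(),
               label = character())
  } else {
    utils::read.delim(pathogenic_path, stringsAsFactors = FALSE)
  }
  ref <- structure(
    list(
      sequence = seq,
      bases = strsplit(seq, "")[[1]],
      genes = genes,
      low_complexity = MT_LOW_COMPLEXITY,
      dloop_subregions = dloop,
      pathogenic_sites = pathogenic,
      cache = new.env(parent = emptyenv())
    ),
    class = "MitoReference"
  )
  ref
}

#' Default reference built from the synthetic sequence and bundled annotation
#'
#' @return A `MitoReference`.
#' @export
mito_reference <- function() load_reference(NULL)

#' @export
print.MitoReference <- function(x, ...) {
  cat("MitoReference: circular mtDNA,", nchar(x$sequence), "bp,",
      nrow(x$genes), "annotated features,",
      nrow(x$pathogenic_sites), "pathogenic sites\n")
  invisible(x)
}

wrap_position <- function(position) {
  ((position - 1L) %% MT_GENOME_LENGTH) + 1L
}

#' Trinucleotide context around a position (circular)
#'
#' Returns the bases at positions (p-1, p, p+1) with wrap-around at the
#' origin, as a 3-character string. Vectorised over `position`.
#'
#' @param ref a `MitoReference`.
#' @param position 1-based position(s) in `[1, 16569]`.
#' @return Character vector of 3-base contexts.
#' @export
trinucleotide_context <- function(ref, position) {
  if (any(position < 1 | position > MT_GENOME_LENGTH))
    stop("position out of range [1, 16569]")
  b <- ref$bases
  paste0(b[wrap_position(position - 1L)], b[position],
         b[wrap_position(position + 1L)])
}

# integer map position -> row index in ref$genes; features with the earlier
# genomic start take precedence where features overlap (ATP8 over ATP6,
# ND4L over ND4). 0 = unannotated (noncoding_other).
feature_map <- function(ref) {
  if (!is.null(ref$cache$feature_map)) return(ref$cache$feature_map)
  genes <- ref$genes
  map <- integer(MT_GENOME_LENGTH)
  ord <- order(genes$start, decreasing = TRUE)
  for (i in ord) {
    s <- genes$start[i]; e <- genes$end[i]
    pos <- if (s <= e) s:e else c(s:MT_GENOME_LENGTH, 1:e)
    map[pos] <- i
  }
  ref$cache$feature_map <- map
  map
}

#' Region class of a substitution
#'
#' Classifies each (position, ref, alt) substitution into one of the region
#' classes `dloop`, `nonsynonymous`, `synonymous`, `rRNA`, `tRNA` or
#' `noncoding_other`. Protein-coding positions are translated with the
#' vertebrate mitochondrial genetic code in the annotated reading frame and
#' orientation; a terminal partial codon (incomplete stop completed by
#' polyadenylation) is padded with `A`. Where protein genes overlap, the gene
#' first in genomic order decides the class ([classify_variant_region_detail()]
#' reports the alternative consequence).
#'
#' @param ref a `MitoReference`.
#' @param position,ref_allele,alt_allele vectors describing substitutions.
#' @return Character vector of region classes.
#' @export
classify_variant_region <- function(ref, position, ref_allele, alt_allele) {
  n <- length(position)
  stopifnot(length(ref_allele) == n, length(alt_allele) == n)
  obs <- ref$bases[position]
  bad <- obs != ref_allele
  if (any(bad))
    stop("ref allele mismatch at position(s): ",
         paste(position[bad], collapse = ", "))
  map <- feature_map(ref)
  fi <- map[position]
  kind <- ifelse(fi == 0L, "noncoding_other", ref$genes$kind[pmax(fi, 1L)])
  out <- character(n)
  out[kind == "dloop"] <- "dloop"
  out[kind == "rrna"] <- "rRNA"
  out[kind == "trna"] <- "tRNA"
  out[kind == "noncoding" | kind == "noncoding_other"] <- "noncoding_other"
  is_prot <- kind == "protein"
  if (any(is_prot)) {
    out[is_prot] <- protein_consequence(ref, position[is_prot],
                                        alt_allele[is_prot], fi[is_prot])
  }
  out
}

# consequence ('synonymous'/'nonsynonymous') for protein-gene substitutions,
# vectorised; fi = feature row indices
protein_consequence <- function(ref, position, alt_allele, fi) {
  genes <- ref$genes
  ct <- mito_codon_table()
  b <- ref$bases
  s <- genes$start[fi]; e <- genes$end[fi]; strand <- genes$strand[fi]
  get_base <- function(pos, past_end) ifelse(past_end, "A", b[wrap_position(pos)])
  n <- length(position)
  ref_cod <- alt_cod <- character(n)
  isH <- strand == "H"
  if (any(isH)) {
    i <- which(isH)
    off <- position[i] - s[i]                 # 0-based offset into gene
    ci <- off %/% 3L                          # codon index
    cp <- off %% 3L                           # 0-based position within codon
    p1 <- s[i] + ci * 3L
    cod_pos <- cbind(p1, p1 + 1L, p1 + 2L)
    past <- cod_pos > e[i]                    # partial terminal codon
    cb <- matrix(get_base(cod_pos, past), ncol = 3)
    ref_cod[i] <- paste0(cb[, 1], cb[, 2], cb[, 3])
    ab <- cb
    ab[cbind(seq_along(i), cp + 1L)] <- alt_allele[i]
    alt_cod[i] <- paste0(ab[, 1], ab[, 2], ab[, 3])
  }
  if (any(!isH)) {
    i <- which(!isH)
    off <- e[i] - position[i]                 # 0-based offset on reverse strand
    ci <- off %/% 3L
    cp <- off %% 3L
    p1 <- e[i] - ci * 3L                      # genomic positions of codon, 5'->3' on L
    cod_pos <- cbind(p1, p1 - 1L, p1 - 2L)
    past <- cod_pos < s[i]
    cb <- matrix(comp_base(get_base(cod_pos, past)), ncol = 3)
    cb[past] <- "A"                           # pad in mRNA sense
    ref_cod[i] <- paste0(cb[, 1], cb[, 2], cb[, 3])
    ab <- cb
    ab[cbind(seq_along(i), cp + 1L)] <- comp_base(alt_allele[i])
    alt_cod[i] <- paste0(ab[, 1], ab[, 2], ab[, 3])
  }
  ifelse(unname(ct[ref_cod]) == unname(ct[alt_cod]),
         "synonymous", "nonsynonymous")
}

#' Detailed region classification including overlapping-gene diagnostics
#'
#' @inheritParams classify_variant_region
#' @return Data frame with `position`, `ref`, `alt`, `region`, `gene`, and,
#'   where a second feature overlaps the position, `alt_gene` and
#'   `alt_region`.
#' @export
classify_variant_region_detail <- function(ref, position, ref_allele,
                                           alt_allele) {
  region <- classify_variant_region(ref, position, ref_allele, alt_allele)
  map <- feature_map(ref)
  fi <- map[position]
  gene <- ifelse(fi == 0L, NA_character_, ref$genes$name[pmax(fi, 1L)])
  # find a second overlapping feature, if any
  genes <- ref$genes
  alt_gene <- alt_region <- rep(NA_character_, length(position))
  for (k in seq_along(position)) {
    hits <- which(vapply(seq_len(nrow(genes)), function(i)
      in_feature(position[k], genes$start[i], genes$end[i]), logical(1)))
    hits <- setdiff(hits, fi[k])
    if (length(hits)) {
      j <- hits[1]
      alt_gene[k] <- genes$name[j]
      alt_region[k] <- if (genes$kind[j] == "protein") {
        protein_consequence(ref, position[k], alt_allele[k], j)
      } else {
        switch(genes$kind[j], dloop = "dloop", rrna = "rRNA", trna = "tRNA",
               "noncoding_other")
      }
    }
  }
  data.frame(position = position, ref = ref_allele, alt = alt_allele,
             region = region, gene = gene, alt_gene = alt_gene,
             alt_region = alt_region, stringsAsFactors = FALSE)
}

#' D-loop subregion containing a position
#'
#' Looks a position up in the bundled (user-editable) D-loop subregion table;
#' when subregions overlap, the smallest containing interval is returned.
#'
#' @param ref a `MitoReference`.
#' @param position 1-based position(s).
#' @return Character vector of subregion labels, `NA` outside all subregions.
#' @export
dloop_subregion <- function(ref, position) {
  d <- ref$dloop_subregions
  len <- mapply(feature_length, d$start, d$end)
  vapply(position, function(p) {
    hit <- which(mapply(function(s, e) in_feature(p, s, e), d$start, d$end))
    if (!length(hit)) return(NA_character_)
    d$name[hit[which.min(len[hit])]]
  }, character(1))
}

#' Trinucleotide context frequencies of the reference
#'
#' Counts all 16,569 circular positions by their trinucleotide context. The
#' H-strand counts are the reverse-complement relabelling of the L-strand
#' counts (the loaded FASTA is treated as the L strand by convention;
#' see [assign_substitution_class()]).
#'
#' @param ref a `MitoReference`.
#' @param strand `"L"` (FASTA as loaded) or `"H"` (reverse complement).
#' @return Named integer vector over the 64 trinucleotides.
#' @export
context_frequencies <- function(ref, strand = c("L", "H")) {
  strand <- match.arg(strand)
  key <- paste0("ctxfreq_", strand)
  if (!is.null(ref$cache[[key]])) return(ref$cache[[key]])
  ctx <- trinucleotide_context(ref, seq_len(MT_GENOME_LENGTH))
  if (strand == "H") ctx <- revcomp(ctx)
  all64 <- apply(expand.grid(BASES, BASES, BASES)[, 3:1], 1, paste,
                 collapse = "")
  tab <- table(factor(ctx, levels = sort(all64)))
  out <- as.integer(tab)
  names(out) <- names(tab)
  ref$cache[[key]] <- out
  out
}

#' Enumerate and classify all possible substitutions
#'
#' Classifies all 16,569 x 3 single-base substitutions; cached on the
#' reference object. Used for region-weighted placement in the simulator and
#' for mutational-opportunity calculations.
#'
#' @param ref a `MitoReference`.
#' @return Data frame with `position`, `ref`, `alt`, `region`.
#' @export
classify_all_substitutions <- function(ref) {
  if (!is.null(ref$cache$all_subs)) return(ref$cache$all_subs)
  pos <- rep(seq_len(MT_GENOME_LENGTH), each = 3L)
  rb <- ref$bases[pos]
  alt <- unlist(lapply(ref$bases, function(b) setdiff(BASES, b)),
                use.names = FALSE)
  region <- classify_variant_region(ref, pos, rb, alt)
  out <- data.frame(position = pos, ref = rb, alt = alt, region = region,
                    stringsAsFactors = FALSE)
  ref$cache$all_subs <- out
  out
}

#' Region lengths in base pairs
#'
#' Base-pair span of each region class, assigning every position the class of
#' its containing feature (protein positions count as coding). Used as the
#' denominator of region mutation frequencies; the D-loop spans 1122 bp.
#'
#' @param ref a `MitoReference`.
#' @param collapse_coding count protein-gene positions as one `"coding"`
#'   region (`TRUE`) or leave them out (`FALSE`, default returns per-kind
#'   spans: dloop, coding, rRNA, tRNA, noncoding_other).
#' @return Named integer vector of base-pair spans.
#' @export
region_lengths <- function(ref, collapse_coding = TRUE) {
  map <- feature_map(ref)
  kind <- ifelse(map == 0L, "noncoding_other", ref$genes$kind[pmax(map, 1L)])
  kind[kind == "rrna"] <- "rRNA"
  kind[kind == "trna"] <- "tRNA"
  kind[kind == "protein"] <- "coding"
  tab <- table(kind)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
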
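# shared fixtures built in code

the_ref <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) ref <<- mito_reference()
    ref
  }
})

# a minimal VariantCall row builder with sensible read-level defaults
make_calls <- function(sample_id, position, ref_allele, alt, af,
                       depth = 1000L, source = "wgs_bulk") {
  n <- max(length(sample_id), length(position), length(af))
  af <- rep_len(af, n)
  depth <- rep_len(depth, n)
  alt_reads <- round(af * depth)
  fwd <- floor(alt_reads / 2)
  data.frame(
    sample_id = rep_len(sample_id, n), position = rep_len(position, n),
    ref = rep_len(ref_allele, n), alt = rep_len(alt, n),
    allele_fraction = af, depth = depth, alt_forward = fwd,
    alt_reverse = alt_reads - fwd, source = source,
    stringsAsFactors = FALSE
  )
}

# calls for a position taking ref/alt from the reference itself
ref_calls <- function(ref, sample_id, position, af, depth = 1000L) {
  rb <- strsplit(ref$sequence, "")[[1]][position]
  alt <- vapply(rb, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                character(1))
  make_calls(sample_id, position, rb, alt, af, depth)
}
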
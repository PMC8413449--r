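test_that("substitution classes follow the pyrimidine-strand convention", {
  ref <- the_ref()
  b <- strsplit(ref$sequence, "")[[1]]
  posC <- which(b == "C")[10]
  posG <- which(b == "G")[10]
  clC <- assign_substitution_class("C", "T", ref, posC)
  expect_equal(clC$class6, "C>T")
  expect_equal(clC$strand, "L")
  clG <- assign_substitution_class("G", "A", ref, posG)
  expect_equal(clG$class6, "C>T")
  expect_equal(clG$strand, "H")
  # complemented context for purine references, circular at the origin
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  expect_equal(clG$context, rc(trinucleotide_context(ref, posG)))
  posG1 <- which(b == "G")
  posG1 <- posG1[posG1 %in% c(1, 16569)][1]
  if (!is.na(posG1)) {
    cl1 <- assign_substitution_class("G", "A", ref, posG1)
    expect_equal(cl1$context, rc(trinucleotide_context(ref, posG1)))
  }
  # flipping the FASTA-strand convention swaps the strand labels
  clC2 <- assign_substitution_class("C", "T", ref, posC, fasta_strand = "H")
  expect_equal(clC2$strand, "H")
  expect_error(assign_substitution_class("C", "C", ref, posC), "differ")
})

test_that("96-class spectrum counts, rates and collapse behave", {
  ref <- the_ref()
  empty <- build_spectrum96(data.frame(position = integer(),
                                       ref = character(),
                                       alt = character()), ref)
  expect_equal(sum(empty$counts), 0)
  # a single C>T lands in exactly one cell, with rate = 1/context frequency
  b <- strsplit(ref$sequence, "")[[1]]
  posC <- which(b == "C")[100]
  one <- build_spectrum96(data.frame(position = posC, ref = "C", alt = "T"),
                          ref)
  expect_equal(sum(one$counts), 1)
  expect_equal(sum(one$counts > 0), 1)
  ctx <- trinucleotide_context(ref, posC)
  lab <- paste0(substr(ctx, 1, 1), "[C>T]", substr(ctx, 3, 3))
  expect_equal(one$counts[lab, "L"], 1)
  expect_equal(one$rates[lab, "L"],
               1 / context_frequencies(ref, "L")[[ctx]])
  # random variant set: rates equal counts / context frequencies everywhere
  withr::with_seed(12, {
    pos <- sample.int(16569, 500)
  })
  rb <- b[pos]
  alt <- vapply(rb, function(x) setdiff(c("A", "C", "G", "T"), x)[1],
                character(1))
  sp <- build_spectrum96(data.frame(position = pos, ref = rb, alt = alt), ref)
  expect_equal(sum(sp$counts), 500)
  fl <- context_frequencies(ref, "L")
  fh <- context_frequencies(ref, "H")
  ctx_of <- paste0(substr(sp$labels, 1, 1), substr(sp$labels, 3, 3),
                   substr(sp$labels, 7, 7))
  expect_equal(unname(sp$rates[, "L"]), unname(sp$counts[, "L"] / fl[ctx_of]))
  expect_equal(unname(sp$rates[, "H"]), unname(sp$counts[, "H"] / fh[ctx_of]))
  # 96 -> 6 collapse identity
  s6 <- collapse_spectrum6(sp)
  cls <- substr(sp$labels, 3, 5)
  for (cl in rownames(s6$counts)) {
    expect_equal(unname(s6$counts[cl, ]),
                 unname(colSums(sp$counts[cls == cl, ])))
  }
})

test_that("strand counts swap under a reverse-complemented reference", {
  ref <- the_ref()
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", ref$sequence), "")[[1]]),
              collapse = "")
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">rc", rc), fa)
  ref_rc <- load_reference(fa)
  b <- strsplit(ref$sequence, "")[[1]]
  withr::with_seed(13, {
    pos <- sample.int(16569, 200)
  })
  rb <- b[pos]
  alt <- vapply(rb, function(x) setdiff(c("A", "C", "G", "T"), x)[2],
                character(1))
  sp <- build_spectrum96(data.frame(position = pos, ref = rb, alt = alt), ref)
  # same substitutions expressed in reverse-complement coordinates
  pos_rc <- 16569 - pos + 1
  sp_rc <- build_spectrum96(data.frame(position = pos_rc,
                                       ref = chartr("ACGT", "TGCA", rb),
                                       alt = chartr("ACGT", "TGCA", alt)),
                            ref_rc)
  expect_equal(unname(sp$counts[, "L"]), unname(sp_rc$counts[, "H"]))
  expect_equal(unname(sp$counts[, "H"]), unname(sp_rc$counts[, "L"]))
})

test_that("regional 6-class frequencies sum to one and conserve counts", {
  ref <- the_ref()
  b <- strsplit(ref$sequence, "")[[1]]
  withr::with_seed(14, {
    pos <- sample.int(16569, 300)
  })
  rb <- b[pos]
  alt <- vapply(rb, function(x) setdiff(c("A", "C", "G", "T"), x)[1],
                character(1))
  v <- data.frame(position = pos, ref = rb, alt = alt,
                  region = classify_variant_region(ref, pos, rb, alt))
  tab <- spectrum6_by_region(v, ref)
  expect_equal(sum(tab$count), 300)  # region split conserves totals
  for (r in unique(v$region)) {
    expect_equal(sum(tab$frequency[tab$region == r]), 1)
  }
  # all-C>T input concentrates on one class
  vC <- v[v$ref == "C", ]
  vC$alt <- "T"
  vC$region <- classify_variant_region(ref, vC$position, vC$ref, vC$alt)
  tc <- spectrum6_by_region(vC, ref)
  agg <- tapply(tc$count, tc$class6, sum)
  expect_equal(unname(agg[["C>T"]]), nrow(vC))
})

test_that("simulated signature weights are recovered in the spectrum", {
  ref <- the_ref()
  w <- c("C>A" = 0.12, "C>G" = 0.08, "C>T" = 0.35, "T>A" = 0.05,
         "T>C" = 0.30, "T>G" = 0.10)
  n_lines <- 1L
  empty_truth <- data.frame(line_id = character(), position = integer(),
                            ref = character(), alt = character(),
                            true_hf = numeric(), origin = character())
  samples <- data.frame(line_id = "F1", donor_id = "D1",
                        tissue = "fibroblast", age = 50, sex = "F",
                        macro_haplogroup = "H", passage = 3,
                        mean_mtdna_depth = 1000, mean_autosomal_depth = 44)
  # 1000 de novo events in one line via an inflated rate
  p <- sim_params(de_novo_rate = 1000 / 16569, signature_weights = w)
  rep_ <- simulate_reprogramming(empty_truth, samples, ref, p, seed = 17)
  sp <- build_spectrum96(rep_$truth, ref)
  s6 <- collapse_spectrum6(sp)
  n <- sum(s6$counts)
  freq <- rowSums(s6$counts) / n
  for (cl in names(w)) {
    se <- sqrt(w[cl] * (1 - w[cl]) / n)
    expect_lt(abs(freq[cl] - w[cl]), 3 * se)
  }
})

test_that("Stouffer combination matches its closed forms", {
  # identical spectra: per-class p = 1, combined p ~ 0.5
  ref <- the_ref()
  b <- strsplit(ref$sequence, "")[[1]]
  withr::with_seed(15, {
    pos <- sample.int(16569, 100)
  })
  rb <- b[pos]
  alt <- vapply(rb, function(x) setdiff(c("A", "C", "G", "T"), x)[1],
                character(1))
  v <- data.frame(position = pos, ref = rb, alt = alt)
  sp <- collapse_spectrum6(build_spectrum96(v, ref))
  cmp <- compare_spectra_stouffer(sp, sp)
  expect_true(all(abs(cmp$per_class$p_value[!cmp$per_class$skipped] - 1) <
                    1e-9))
  expect_equal(cmp$combined_p, 0.5, tolerance = 1e-6)
  # one-sided closed form: two p = 0.05 inputs give Z = 2.326, p ~ 0.010
  sc <- stouffer_combine(c(0.05, 0.05), sided = "one")
  expect_equal(sc$z, 2 * qnorm(0.95) / sqrt(2), tolerance = 1e-6)
  expect_equal(sc$z, 2.326, tolerance = 1e-3)
  expect_equal(sc$p_value, 0.0100, tolerance = 1e-3)
  # per-class Fisher equals the hypergeometric enumeration oracle
  sp2 <- sp
  sp2$counts[1, 1] <- sp2$counts[1, 1] + 20L
  cmp2 <- compare_spectra_stouffer(sp, sp2)
  i <- 1
  a <- cmp2$per_class$count_a[i]; bb <- cmp2$per_class$count_b[i]
  ta <- sum(sp$counts); tb <- sum(sp2$counts)
  ft <- fisher.test(matrix(c(a, ta - a, bb, tb - bb), 2))
  expect_equal(cmp2$per_class$p_value[i], ft$p.value, tolerance = 1e-12)
})

test_that("signature correlation is exact for self and drops for permutations", {
  ref <- the_ref()
  b <- strsplit(ref$sequence, "")[[1]]
  withr::with_seed(16, {
    pos <- sample.int(16569, 400)
  })
  rb <- b[pos]
  alt <- vapply(rb, function(x) setdiff(c("A", "C", "G", "T"), x)[1],
                character(1))
  sp <- build_spectrum96(data.frame(position = pos, ref = rb, alt = alt), ref)
  x <- rowSums(sp$rates)
  ext <- data.frame(context = sp$labels, self = x,
                    permuted = withr::with_seed(17, sample(x)),
                    noise = withr::with_seed(18, runif(96)))
  res <- correlate_signatures(sp, ext)
  expect_equal(res$r_squared[res$signature == "self"], 1, tolerance = 1e-12)
  expect_lt(res$r_squared[res$signature == "permuted"], 1)
  # brute-force R^2 oracle
  r2 <- (cov(x, ext$noise) / sqrt(var(x) * var(ext$noise)))^2
  expect_equal(res$r_squared[res$signature == "noise"], r2, tolerance = 1e-12)
  # mismatched ordering is an error
  bad <- ext
  bad$context[1] <- "Z[C>A]A"
  expect_error(correlate_signatures(sp, bad), "match")
})
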
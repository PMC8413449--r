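test_that("pairing yields one pair per iPSC line and excludes orphans", {
  samples <- data.frame(
    line_id = c("F1", "F2", "I1", "I2", "I3", "I4"),
    donor_id = c("D1", "D2", "D1", "D1", "D2", "D9"),
    tissue = c("fibroblast", "fibroblast", rep("iPSC", 4)),
    fibroblast_line = c(NA, NA, "F1", "F1", "F2", "F9"),
    stringsAsFactors = FALSE
  )
  expect_warning(pairs <- pair_lines(samples), "matched fibroblast")
  expect_equal(nrow(pairs), 3)
  expect_equal(sum(pairs$fibroblast_line == "F1"), 2)  # duo shares one fibroblast
  empty <- pair_lines(samples[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("pair classification implements the shared/lost/specific rules", {
  ref <- the_ref()
  pair <- data.frame(fibroblast_line = "F1", ipsc_line = "I1",
                     donor_id = "D1")
  fib <- ref_calls(ref, "F1", c(1000, 2000, 3000, 4000), c(0.10, 0.10, 0.99, 0.995))
  ips <- ref_calls(ref, "I1", c(1000, 3000, 4000, 5000), c(0.30, 0.20, 0.999, 0.25))
  cl <- classify_pair(pair, fib, ips, ref)
  cat_of <- function(p) cl$category[cl$position == p]
  expect_equal(cat_of(1000), "shared")         # het in both
  expect_equal(cat_of(2000), "lost")           # het in fibro, absent in iPSC
  expect_equal(cat_of(3000), "shared")         # homoplasmic fibro, het iPSC
  expect_equal(cat_of(5000), "ipsc_specific")  # het iPSC, absent fibro
  expect_false(4000 %in% cl$position)          # homoplasmic in both: unclassified
  expect_true(all(c("region", "pathogenic") %in% names(cl)))
  # partition law: every fibroblast heteroplasmy is shared or lost, and lost
  # variants are fibroblast heteroplasmies
  fib_het <- fib$position[call_heteroplasmy_state(fib$allele_fraction) ==
                            "heteroplasmic"]
  expect_true(all(fib_het %in%
                    cl$position[cl$category %in% c("shared", "lost")]))
  expect_true(all(cl$position[cl$category == "lost"] %in% fib_het))
})

test_that("duo subcategories partition fibroblast and iPSC variant sets", {
  ref <- the_ref()
  fib <- ref_calls(ref, "F1", c(1000, 2000, 3000), 0.10)
  i1 <- ref_calls(ref, "I1", c(1000, 2000, 4000, 5000), c(0.2, 0.2, 0.2, 0.2))
  i2 <- ref_calls(ref, "I2", c(1000, 4000), c(0.3, 0.3))
  duo <- classify_duo(fib, i1, i2, ref)
  sub_of <- function(p) duo$duo_subcategory[duo$position == p]
  expect_equal(sub_of(1000), "shared_both")
  expect_equal(sub_of(2000), "shared_one")
  expect_equal(sub_of(3000), "lost_both")
  expect_equal(sub_of(4000), "ipsc_specific_both")
  expect_equal(sub_of(5000), "ipsc_specific_one")
  # partitions are complete
  expect_setequal(
    duo$position[duo$duo_subcategory %in% c("shared_both", "shared_one",
                                            "lost_both")], fib$position)
  expect_setequal(
    duo$position[duo$duo_subcategory %in% c("ipsc_specific_both",
                                            "ipsc_specific_one")],
    c(4000, 5000))
})

test_that("heteroplasmic shift is the log2 HF ratio with its symmetries", {
  expect_equal(heteroplasmic_shift(0.02, 0.04), 1)
  expect_equal(heteroplasmic_shift(0.10, 0.80), 3)
  x <- c(0.05, 0.2, 0.7)
  expect_equal(heteroplasmic_shift(x, x), rep(0, 3))
  # antisymmetry and scale invariance
  expect_equal(heteroplasmic_shift(0.1, 0.4), -heteroplasmic_shift(0.4, 0.1))
  expect_equal(heteroplasmic_shift(0.1, 0.4),
               heteroplasmic_shift(0.05, 0.2))
  expect_error(heteroplasmic_shift(0, 0.1), "undefined")
})

test_that("direction test reproduces Clopper-Pearson intervals", {
  d <- direction_binomial(138, 161)
  expect_equal(d$ci_low, 0.793, tolerance = 5e-4)
  expect_equal(d$ci_high, 0.907, tolerance = 5e-4)
  expect_lt(d$p_value, 2.2e-16)
  # boundary cases against the beta-quantile closed form
  expect_equal(direction_binomial(0, 10)$ci_low, 0)
  expect_equal(direction_binomial(8, 8)$ci_low, 0.025^(1 / 8),
               tolerance = 1e-9)
  # brute-force beta-quantile oracle across a grid
  for (k in c(3, 7, 12)) {
    d <- direction_binomial(k, 20)
    expect_equal(d$ci_low, qbeta(0.025, k, 20 - k + 1), tolerance = 1e-9)
    expect_equal(d$ci_high, qbeta(0.975, k + 1, 20 - k), tolerance = 1e-9)
  }
  expect_error(direction_binomial(0, 0), "positive")
})

test_that("specific mutation rate counts, rescues and bounds correctly", {
  ref <- the_ref()
  cl <- data.frame(
    fibroblast_line = "F1", ipsc_line = "I1",
    position = c(1000, 2000, 3000), ref = "A", alt = "G",
    category = "ipsc_specific", pathogenic = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  # toy arithmetic: 3 events, 2 lines
  r <- specific_mutation_rate(cl, 2)
  expect_equal(r$rate_per_bp_per_genome, 3 / (16569 * 2))
  expect_equal(r$rate_per_bp_per_genome, 9.05e-5, tolerance = 0.005)
  expect_false(r$rescue_applied)
  # sub-threshold rescue removes pre-existing variants
  uf <- data.frame(sample_id = "F1", position = 1000, ref = "A", alt = "G",
                   allele_fraction = 0.01)
  r2 <- specific_mutation_rate(cl, 2, uf)
  expect_equal(r2$n_events, 2)
  expect_equal(r2$n_rescued, 1)
  # zero events: exact Poisson upper bound
  r0 <- specific_mutation_rate(cl[0, ], 10)
  expect_equal(r0$rate_per_bp_per_genome, 0)
  expect_equal(r0$ci_high, 3.688879 / (16569 * 10), tolerance = 1e-6)
  # rate scales inversely with lines and ignores line order
  expect_equal(specific_mutation_rate(cl, 4)$rate_per_bp_per_genome,
               r$rate_per_bp_per_genome / 2)
  expect_equal(specific_mutation_rate(cl[c(3, 1, 2), ], 2)$rate_per_bp_per_genome,
               r$rate_per_bp_per_genome)
})

test_that("rate recovery on synthetic cohorts respects the Poisson interval", {
  ref <- the_ref()
  rate_true <- 8.6e-5
  n_lines <- 141L
  samples <- data.frame(line_id = sprintf("F%03d", 1:n_lines),
                        donor_id = sprintf("D%03d", 1:n_lines),
                        tissue = "fibroblast", age = 50, sex = "F",
                        macro_haplogroup = "H", passage = 3,
                        mean_mtdna_depth = 1000, mean_autosomal_depth = 44)
  empty_truth <- data.frame(line_id = character(), position = integer(),
                            ref = character(), alt = character(),
                            true_hf = numeric(), origin = character())
  p <- sim_params(de_novo_rate = rate_true)
  covered <- 0L
  for (r in 1:50) {
    rep_ <- simulate_reprogramming(empty_truth, samples, ref, p,
                                   seed = 1000 + r)
    cl <- data.frame(fibroblast_line = "x", ipsc_line = rep_$truth$line_id,
                     position = rep_$truth$position, ref = rep_$truth$ref,
                     alt = rep_$truth$alt, category = "ipsc_specific",
                     stringsAsFactors = FALSE)
    est <- specific_mutation_rate(cl, n_lines)
    if (est$ci_low <= rate_true && rate_true <= est$ci_high)
      covered <- covered + 1L
  }
  expect_gte(covered, 45L)  # >= 90% of 50 replicates
})

test_that("threshold sensitivity is monotone and matches the uniform oracle", {
  ref <- the_ref()
  pairs <- data.frame(fibroblast_line = "F1", ipsc_line = "I1",
                      donor_id = "D1")
  # uniform founding HFs on (0, 0.04]: halving the threshold doubles events
  withr::with_seed(71, {
    af <- runif(4000, 0, 0.04)
  })
  ips <- ref_calls(ref, "I1", sample(16569, 4000), af)
  fib_uf <- ips[0, ]
  ts <- threshold_sensitivity(pairs, ips, fib_uf,
                              thresholds = c(0.02, 0.015, 0.01, 0.005))
  expect_equal(nrow(ts), 4)
  expect_true(all(diff(ts$rate) >= 0))  # non-decreasing as threshold falls
  expect_equal(ts$rate[3] / ts$rate[1], 1.5, tolerance = 0.1)  # U(0,.04): 1% keeps 3/4 vs 1/2
  expect_equal(ts$rate[4] / ts$rate[1], 1.75, tolerance = 0.1)
})

test_that("NS/SS ratio and region frequencies follow their formulas", {
  ref <- the_ref()
  v <- data.frame(region = c(rep("nonsynonymous", 4), "synonymous"))
  expect_equal(nsss_ratio(v), 4)
  expect_equal(nsss_ratio(data.frame(region = "synonymous")), 0)
  expect_true(is.na(nsss_ratio(data.frame(region = "nonsynonymous"))))
  expect_equal(nsss_ratio(data.frame(region = character(0))), 0)
  # region frequency arithmetic: 10 D-loop variants, 10 lines, span 1122
  v2 <- data.frame(position = rep(300, 10), region = rep("dloop", 10))
  rf <- region_mutation_frequency(v2, ref, 10)
  expect_equal(rf$length_bp[rf$region == "dloop"], 1122)
  expect_equal(rf$frequency[rf$region == "dloop"], 10 / (1122 * 10))
  expect_equal(rf$frequency[rf$region == "dloop"], 8.91e-4, tolerance = 0.001)
  # Fisher on small counts equals the hypergeometric enumeration oracle
  a <- 8; la <- 30; b <- 3; lb <- 40
  ft <- fisher.test(matrix(c(a, la - a, b, lb - b), 2))
  m <- a + b
  dens <- dhyper(0:m, la, lb, m)
  p_oracle <- sum(dens[dens <= dens[a + 1] * (1 + 1e-7)])
  expect_equal(ft$p.value, p_oracle, tolerance = 1e-9)
})

test_that("uniform placement produces no spurious region enrichment", {
  ref <- the_ref()
  withr::with_seed(55, {
    pos <- sample.int(16569, 300, replace = TRUE)
  })
  rb <- strsplit(ref$sequence, "")[[1]][pos]
  alt <- vapply(rb, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                character(1))
  v <- data.frame(position = pos,
                  region = classify_variant_region(ref, pos, rb, alt))
  rf <- region_mutation_frequency(v, ref, 20)
  expect_true(all(rf$q_vs_rest > 0.05))
})

test_that("copy number is the depth ratio in a diploid cell", {
  expect_equal(relative_copy_number(44, 44), 2)
  expect_equal(relative_copy_number(1824, 44), 82.9, tolerance = 0.001)
  expect_equal(relative_copy_number(0, 44), 0)
  expect_error(relative_copy_number(100, 0), "positive")
})

test_that("age models recover simulated slopes and pass the shuffle null", {
  ref <- the_ref()
  p <- sim_params()
  hits <- 0L
  for (r in 1:20) {
    sim <- simulate_fibroblast_cohort(ref, p, seed = 300 + r)
    calls <- simulate_read_counts(sim$truth, ref, p, seed = 300 + r)
    fit <- fit_age_models(sim$samples, calls)
    est <- fit[fit$model == "burden_fibro" & fit$term == "age", ]
    if (abs(est$estimate - 0.10) <= 2 * est$se) hits <- hits + 1L
  }
  expect_gte(hits, 17L)
  # age-shuffled data: slope CI covers zero
  sim <- simulate_fibroblast_cohort(ref, p, seed = 777)
  calls <- simulate_read_counts(sim$truth, ref, p, seed = 777)
  sim$samples$age <- withr::with_seed(778, sample(sim$samples$age))
  fit0 <- fit_age_models(sim$samples, calls)
  est0 <- fit0[fit0$model == "burden_fibro" & fit0$term == "age", ]
  expect_lt(abs(est0$estimate), 3 * est0$se)
})

test_that("shift-direction model recovers a simulated region effect", {
  withr::with_seed(91, {
    n <- 1500
    region <- sample(c("dloop", "nonsynonymous", "tRNA", "synonymous"), n,
                     replace = TRUE)
    hf <- rbeta(n, 1.3, 12.8)
    eta <- 0.3 + 0.78 * (region == "nonsynonymous") +
      0.89 * (region == "tRNA")
    inc <- rbinom(n, 1, plogis(eta))
    shifts <- data.frame(hs = ifelse(inc == 1, 1, -1), hf_fibro = hf,
                         region = region)
  })
  fit <- fit_shift_direction_model(shifts)
  est <- fit[fit$term == "regionnonsynonymous", ]
  expect_lt(abs(est$estimate - 0.78), 2 * est$se)
  expect_false(attr(fit, "separation"))
  # balanced covariate-free data: intercept near zero
  withr::with_seed(92, {
    s2 <- data.frame(hs = rep(c(1, -1), 400), hf_fibro = rbeta(800, 2, 10),
                     region = "dloop")
  })
  fit2 <- suppressWarnings(fit_shift_direction_model(s2))
  i2 <- fit2[fit2$term == "(Intercept)", ]
  expect_lt(abs(i2$estimate), 2 * i2$se + 0.2)
  # all increases: degenerate, separation flagged
  s3 <- data.frame(hs = rep(1, 50), hf_fibro = 0.1, region = "dloop")
  expect_warning(fit3 <- fit_shift_direction_model(s3), "separation|direction")
  expect_true(attr(fit3, "separation"))
})
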
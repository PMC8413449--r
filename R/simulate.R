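# Synthetic fibroblast -> iPSC cohort generator.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: an age-dependent heteroplasmy burden in fibroblasts, beta-distributed
# heteroplasmy fractions of clonally expanded somatic variants, region-weighted
# mutation placement with recurrent hotspots, a binomial segregating-unit
# bottleneck at reprogramming plus signature-driven de novo mutations,
# binomial read sampling at gamma-distributed depth, and single cells with
# latent clone structure and variant-linked expression effects.

#' Simulation parameters
#'
#' Returns the default parameter set for the synthetic cohort, overridable by
#' name. Defaults reflect the study conditions the analysis is designed for:
#' 146 fibroblast donors aged 27-77, burden slope 0.10 heteroplasmies/year,
#' an m.414 hotspot carried by 19.2% of lines, a de novo rate of 8.62e-5 per
#' base pair per genome per reprogramming, and read depth with mean 1824x.
#'
#' @param ... named overrides of any default.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(...) {
  p <- list(
    n_donors = 146L,
    age_range = c(27, 77),
    burden_slope = 0.10,          # heteroplasmies per year of donor age
    burden_intercept = 2.8,       # burden at age 0 (Poisson mean offset)
    hf_shape = c(1.3, 12.8),      # beta HF model for somatic heteroplasmies
    hf_min = 0.02,                # detection-capable floor for simulated HFs
    n_inherited = 3L,             # homoplasmic (haplogroup) variants per donor
    region_weights = c(dloop = 2.2, nonsynonymous = 1, synonymous = 1,
                       rRNA = 1.6, tRNA = 1, noncoding_other = 1),
    hotspot_sites = data.frame(
      position = c(414L, 2623L, 13369L),
      alt = c("G", "G", "C"),
      prob = c(0.192, 0.123, 0.123)
    ),
    bottleneck_size = 5L,         # effective segregating units N
    de_novo_rate = 8.62e-5,       # new mutations / bp / genome / reprogramming
    de_novo_hf_shape = c(1, 30),  # founding HF beta, truncated at hf_min
    signature_weights = c("C>A" = 0.12, "C>G" = 0.08, "C>T" = 0.35,
                          "T>A" = 0.05, "T>C" = 0.30, "T>G" = 0.10),
    strand_prob_L = 0.5,          # probability the pyrimidine strand is L
    depth_mean = 1824,
    depth_sd = 2249,
    error_sites_per_sample = 0,   # spurious low-AF sites to exercise filters
    error_af = 0.005,
    # single-cell parameters
    clone_freqs = c(0.5, 0.5),
    sc_noise_sd = 0.01,
    sc_singleton_rate = 0,        # per-cell rate of private artefact variants
    n_genes = 100L,
    expr_base_log2 = 3,
    expr_effect = 0,              # log2 shift at HF = 1 for affected genes
    n_affected_genes = 0L,
    sc_stage_sd = 0,              # per-gene stage random effect (log2)
    sc_batch_sd = 0,
    n_batches = 1L,
    nb_size = 2,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown sim_params: ", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  stopifnot(p$bottleneck_size >= 1, p$de_novo_rate >= 0,
            all(p$hotspot_sites$prob >= 0 & p$hotspot_sites$prob <= 1))
  if (diff(range(p$age_range)) <= 0) stop("degenerate age_range")
  class(p) <- "sim_params"
  p
}

maybe_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

draw_hf <- function(n, shape, floor) {
  # beta truncated below at `floor` by inverse-CDF sampling
  lo <- stats::pbeta(floor, shape[1], shape[2])
  u <- stats::runif(n, lo, 1)
  stats::qbeta(u, shape[1], shape[2])
}

MACRO_HAPLOGROUPS <- c("H", "U", "J", "T", "K", "I", "V", "W")
HAPLOGROUP_FREQS <- c(0.44, 0.13, 0.11, 0.10, 0.09, 0.05, 0.04, 0.04)

#' Simulate a fibroblast cohort with age-dependent heteroplasmy burden
#'
#' Per donor, the heteroplasmic variant count is Poisson with mean
#' `burden_intercept + burden_slope * age`; heteroplasmy fractions follow the
#' truncated beta model (implicit clonal expansion); substitutions are placed
#' genome-wide with region-class weights, plus recurrent hotspot variants
#' carried with fixed per-line probabilities, plus `n_inherited` homoplasmic
#' haplogroup variants per donor.
#'
#' @param ref a `MitoReference`.
#' @param params a [sim_params()] list.
#' @param seed integer seed for reproducibility; `NULL` uses the current RNG
#'   state.
#' @return List with `samples` (sample metadata) and `truth` (true variant
#'   table: `line_id`, `position`, `ref`, `alt`, `true_hf`, `origin`).
#' @export
simulate_fibroblast_cohort <- function(ref, params = sim_params(),
                                       seed = params$seed) {
  maybe_seed(seed, {
    n <- params$n_donors
    donors <- sprintf("D%03d", seq_len(n))
    lines <- sprintf("F%03d", seq_len(n))
    ages <- round(stats::runif(n, params$age_range[1], params$age_range[2]))
    samples <- data.frame(
      line_id = lines, donor_id = donors, tissue = "fibroblast",
      age = ages,
      sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.58, 0.42)),
      macro_haplogroup = sample(MACRO_HAPLOGROUPS, n, replace = TRUE,
                                prob = HAPLOGROUP_FREQS),
      passage = sample(2:6, n, replace = TRUE),
      mean_mtdna_depth = pmax(401, round(stats::rnorm(n, params$depth_mean,
                                                      params$depth_sd / 4))),
      mean_autosomal_depth = round(stats::rnorm(n, 44, 9)),
      stringsAsFactors = FALSE
    )
    subs <- classify_all_substitutions(ref)
    w <- params$region_weights[subs$region]
    lam <- pmax(0, params$burden_intercept + params$burden_slope * ages)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      k <- stats::rpois(1, lam[i])
      idx <- sample.int(nrow(subs), k, prob = w)
      som <- subs[idx, c("position", "ref", "alt")]
      som$true_hf <- draw_hf(k, params$hf_shape, params$hf_min)
      som$origin <- rep("somatic_fibroblast", k)
      hs <- params$hotspot_sites
      carry <- stats::runif(nrow(hs)) < hs$prob
      if (any(carry)) {
        hot <- data.frame(position = hs$position[carry],
                          ref = ref$bases[hs$position[carry]],
                          alt = hs$alt[carry],
                          true_hf = draw_hf(sum(carry), params$hf_shape,
                                            params$hf_min),
                          origin = "somatic_fibroblast",
                          stringsAsFactors = FALSE)
        som <- som[!(som$position %in% hot$position), ]
        som <- rbind(som, hot)
      }
      if (params$n_inherited > 0) {
        # inherited homoplasmies: uniform placement, HF 1
        ii <- sample.int(nrow(subs), params$n_inherited)
        inh <- subs[ii, c("position", "ref", "alt")]
        inh <- inh[!(inh$position %in% som$position), , drop = FALSE]
        if (nrow(inh)) {
          inh$true_hf <- 1
          inh$origin <- "inherited"
          som <- rbind(som, inh)
        }
      }
      som$line_id <- rep(lines[i], nrow(som))
      truth[[i]] <- som
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    truth <- truth[, c("line_id", "position", "ref", "alt", "true_hf", "origin")]
    list(samples = samples, truth = truth)
  })
}

# map every possible substitution to its pyrimidine 6-class and strand
substitution_class_table <- function(ref) {
  if (!is.null(ref$cache$sub_class)) return(ref$cache$sub_class)
  subs <- classify_all_substitutions(ref)
  pyr <- subs$ref %in% c("C", "T")
  cls <- ifelse(pyr, paste0(subs$ref, ">", subs$alt),
                paste0(comp_base(subs$ref), ">", comp_base(subs$alt)))
  out <- cbind(subs, data.frame(class6 = cls,
                                strand = ifelse(pyr, "L", "H"),
                                stringsAsFactors = FALSE))
  ref$cache$sub_class <- out
  out
}

#' Pass a fibroblast cohort through a reprogramming bottleneck
#'
#' Each fibroblast heteroplasmy fraction p becomes p' = B/N with
#' B ~ Binomial(N, p) independently for each derived iPSC line
#' (`N = bottleneck_size` segregating units). De novo mutations are added per
#' line as Poisson(`de_novo_rate` x 16,569) events, with substitution types
#' drawn from the 6-class signature weights and strand, and founding HFs from
#' the truncated `de_novo_hf_shape` beta.
#'
#' @param truth fibroblast truth table from [simulate_fibroblast_cohort()].
#' @param samples fibroblast sample metadata (for donor ages/haplogroups).
#' @param ref a `MitoReference`.
#' @param params a [sim_params()] list.
#' @param n_ipsc_per_donor integer (recycled over donors): iPSC lines derived
#'   from each fibroblast line.
#' @param seed integer seed; `NULL` uses current RNG state.
#' @return List with `samples` (iPSC metadata incl. `fibroblast_line`) and
#'   `truth` (iPSC truth table).
#' @export
simulate_reprogramming <- function(truth, samples, ref, params = sim_params(),
                                   n_ipsc_per_donor = 1L, seed = params$seed) {
  maybe_seed(seed, {
    N <- params$bottleneck_size
    sub_cls <- substitution_class_table(ref)
    # de novo placement: draw the pyrimidine class from the signature
    # weights and the strand from strand_prob_L, then a site uniformly
    # among that class's opportunities
    cls_key <- paste(sub_cls$class6, sub_cls$strand)
    cls_index <- split(seq_len(nrow(sub_cls)), cls_key)
    draw_de_novo <- function(k) {
      cls <- sample(names(params$signature_weights), k, replace = TRUE,
                    prob = params$signature_weights)
      strand <- ifelse(stats::runif(k) < params$strand_prob_L, "L", "H")
      idx <- vapply(paste(cls, strand), function(key) {
        pool <- cls_index[[key]]
        pool[sample.int(length(pool), 1)]
      }, integer(1), USE.NAMES = FALSE)
      idx
    }
    nfib <- nrow(samples)
    nip <- rep_len(n_ipsc_per_donor, nfib)
    out_truth <- list()
    out_samples <- list()
    ctr <- 0L
    for (i in seq_len(nfib)) {
      fl <- samples$line_id[i]
      ft <- truth[truth$line_id == fl, , drop = FALSE]
      for (j in seq_len(nip[i])) {
        ctr <- ctr + 1L
        il <- sprintf("I%03d_%d", i, j)
        it <- ft
        if (nrow(it)) {
          it$true_hf <- stats::rbinom(nrow(it), N, it$true_hf) / N
          it <- it[it$true_hf > 0, , drop = FALSE]
        }
        k <- stats::rpois(1, params$de_novo_rate * MT_GENOME_LENGTH)
        if (k > 0) {
          idx <- draw_de_novo(k)
          dn <- sub_cls[idx, c("position", "ref", "alt")]
          dn$true_hf <- draw_hf(k, params$de_novo_hf_shape, params$hf_min)
          dn$origin <- "de_novo_reprogramming"
          dn$line_id <- il
          dn <- dn[, c("line_id", "position", "ref", "alt", "true_hf", "origin")]
          if (nrow(it)) {
            it$line_id <- il
            dn <- dn[!(dn$position %in% it$position), , drop = FALSE]
            it <- rbind(it, dn)
          } else it <- dn
        } else if (nrow(it)) it$line_id <- il
        out_truth[[ctr]] <- it
        out_samples[[ctr]] <- data.frame(
          line_id = il, donor_id = samples$donor_id[i], tissue = "iPSC",
          age = samples$age[i], sex = samples$sex[i],
          macro_haplogroup = samples$macro_haplogroup[i],
          passage = sample(8:43, 1),
          mean_mtdna_depth = pmax(401, round(stats::rnorm(1, params$depth_mean,
                                                          params$depth_sd / 4))),
          mean_autosomal_depth = round(stats::rnorm(1, 44, 9)),
          fibroblast_line = fl, stringsAsFactors = FALSE
        )
      }
    }
    truth_i <- do.call(rbind, out_truth)
    rownames(truth_i) <- NULL
    list(samples = do.call(rbind, out_samples), truth = truth_i)
  })
}

#' Simulate read-level variant calls from a truth table
#'
#' Per variant, the read depth is gamma-distributed with the configured
#' mean/sd, alternate reads are Binomial(depth, true HF) and are split
#' binomially between strands. Optional per-sample error sites at low allele
#' fraction exercise the downstream filters. Sites whose sampled alternate
#' count is zero are retained with allele fraction 0 (an unfiltered call
#' table; thresholding is the job of [filter_variant_calls()]).
#'
#' @param truth truth table (`line_id`, `position`, `ref`, `alt`, `true_hf`).
#' @param ref a `MitoReference`.
#' @param params a [sim_params()] list.
#' @param source data source label for the calls.
#' @param seed integer seed; `NULL` uses current RNG state.
#' @return A `VariantCall` data frame: `sample_id`, `position`, `ref`, `alt`,
#'   `allele_fraction`, `depth`, `alt_forward`, `alt_reverse`, `source`.
#' @export
simulate_read_counts <- function(truth, ref, params = sim_params(),
                                 source = "wgs_bulk", seed = params$seed) {
  maybe_seed(seed, {
    n <- nrow(truth)
    shape <- (params$depth_mean / params$depth_sd)^2
    depth <- pmax(1L, round(stats::rgamma(n, shape = shape,
                                          scale = params$depth_sd^2 /
                                            params$depth_mean)))
    alt <- stats::rbinom(n, depth, truth$true_hf)
    fwd <- stats::rbinom(n, alt, 0.5)
    calls <- data.frame(
      sample_id = truth$line_id, position = truth$position, ref = truth$ref,
      alt = truth$alt, allele_fraction = alt / depth, depth = depth,
      alt_forward = fwd, alt_reverse = alt - fwd, source = source,
      stringsAsFactors = FALSE
    )
    if (params$error_sites_per_sample > 0) {
      ids <- unique(truth$line_id)
      err <- lapply(ids, function(id) {
        k <- stats::rpois(1, params$error_sites_per_sample)
        if (k == 0) return(NULL)
        pos <- sample.int(MT_GENOME_LENGTH, k)
        rb <- ref$bases[pos]
        ab <- vapply(rb, function(b) sample(setdiff(BASES, b), 1), character(1))
        d <- pmax(1L, round(stats::rgamma(k, shape = shape,
                                          scale = params$depth_sd^2 /
                                            params$depth_mean)))
        a <- stats::rbinom(k, d, params$error_af)
        f <- stats::rbinom(k, a, 0.5)
        data.frame(sample_id = id, position = pos, ref = rb, alt = ab,
                   allele_fraction = a / d, depth = d, alt_forward = f,
                   alt_reverse = a - f, source = source,
                   stringsAsFactors = FALSE)
      })
      calls <- rbind(calls, do.call(rbind, err))
    }
    rownames(calls) <- NULL
    calls
  })
}

#' Simulate single cells with clone structure and expression effects
#'
#' Cells are assigned to latent clones with the configured frequencies. Each
#' sub-homoplasmic truth variant is carried by one clone at HF
#' `min(1, true_hf / clone_freq)` so pseudo-bulk averages recover the bulk
#' truth; near-homoplasmic variants (HF >= 0.95) are ancestral and present in
#' every clone. Per-cell HFs add Gaussian noise (sd `sc_noise_sd`) where the
#' clone carries the variant and are exactly 0 elsewhere. Expression counts
#' are negative binomial with log2 mean shifted by `expr_effect` x HF of the
#' first clone-defining variant for the first `n_affected_genes` genes, plus
#' optional stage and batch random effects. Collection day and pseudotime are
#' drawn per requested stage to exercise the stage-assignment thresholds.
#'
#' @param line_truth truth table for one line.
#' @param n_cells number of cells.
#' @param stages character vector of true stages to draw cells from (any of
#'   `"iPSC"`, `"mesendo"`, `"defendo"`, `"undefined"`), recycled over cells.
#' @param ref a `MitoReference`.
#' @param params a [sim_params()] list.
#' @param seed integer seed; `NULL` uses current RNG state.
#' @return List with `hf` (cells x variants matrix), `expr` (cells x genes
#'   counts), `meta` (cell metadata with `collection_day`, `pseudotime`,
#'   `true_stage`, `clone`), and `variants` (variant identities with clone
#'   assignment).
#' @export
simulate_single_cells <- function(line_truth, n_cells, stages = "iPSC",
                                  ref = NULL, params = sim_params(),
                                  seed = params$seed) {
  stopifnot(n_cells >= 1)
  maybe_seed(seed, {
    cf <- params$clone_freqs / sum(params$clone_freqs)
    K <- length(cf)
    clone <- sample.int(K, n_cells, replace = TRUE, prob = cf)
    v <- line_truth[, c("position", "ref", "alt", "true_hf")]
    nv <- nrow(v)
    ancestral <- v$true_hf >= 0.95
    v$clone <- NA_integer_
    if (any(!ancestral))
      v$clone[!ancestral] <- sample.int(K, sum(!ancestral), replace = TRUE,
                                        prob = cf)
    v$clone_hf <- ifelse(ancestral, v$true_hf,
                         pmin(1, v$true_hf / cf[ifelse(is.na(v$clone), 1,
                                                       v$clone)]))
    hf <- matrix(0, n_cells, nv)
    for (j in seq_len(nv)) {
      carrier <- if (ancestral[j]) rep(TRUE, n_cells) else clone == v$clone[j]
      if (any(carrier)) {
        x <- v$clone_hf[j] + stats::rnorm(sum(carrier), 0, params$sc_noise_sd)
        hf[carrier, j] <- pmin(1, pmax(0.001, x))
      }
    }
    vid <- paste0(v$position, v$ref, ">", v$alt)
    dimnames(hf) <- list(sprintf("cell%04d", seq_len(n_cells)), vid)
    stage <- rep_len(stages, n_cells)
    day <- ifelse(stage == "iPSC", 0L,
                  ifelse(stage == "mesendo", sample(1:2, n_cells, TRUE),
                         ifelse(stage == "defendo", sample(2:3, n_cells, TRUE),
                                2L)))
    pt <- numeric(n_cells)
    pt[stage == "iPSC"] <- stats::runif(sum(stage == "iPSC"), 0, 0.1)
    pt[stage == "mesendo"] <- stats::runif(sum(stage == "mesendo"), 0.15, 0.499)
    pt[stage == "defendo"] <- stats::runif(sum(stage == "defendo"), 0.701, 1)
    pt[stage == "undefined"] <- stats::runif(sum(stage == "undefined"), 0.5, 0.7)
    meta <- data.frame(
      cell_id = rownames(hf),
      line_id = if (nrow(line_truth)) line_truth$line_id[1] else "line1",
      collection_day = day, pseudotime = pt, true_stage = stage,
      clone = clone, stringsAsFactors = FALSE
    )
    # expression: NB counts, optionally shifted by the HF of a marker variant
    G <- params$n_genes
    logmu <- matrix(params$expr_base_log2, n_cells, G)
    if (params$n_affected_genes > 0 && nv > 0) {
      marker <- hf[, 1]
      gidx <- seq_len(min(params$n_affected_genes, G))
      logmu[, gidx] <- logmu[, gidx] + params$expr_effect * marker
    }
    if (params$sc_stage_sd > 0) {
      st <- factor(stage)
      eff <- matrix(stats::rnorm(nlevels(st) * G, 0, params$sc_stage_sd),
                    nlevels(st), G)
      logmu <- logmu + eff[as.integer(st), , drop = FALSE]
    }
    batch <- sample.int(params$n_batches, n_cells, replace = TRUE)
    if (params$sc_batch_sd > 0) {
      eff <- matrix(stats::rnorm(params$n_batches * G, 0, params$sc_batch_sd),
                    params$n_batches, G)
      logmu <- logmu + eff[batch, , drop = FALSE]
    }
    meta$batch <- batch
    expr <- matrix(stats::rnbinom(n_cells * G, mu = 2^logmu,
                                  size = params$nb_size), n_cells, G)
    dimnames(expr) <- list(rownames(hf), sprintf("gene%03d", seq_len(G)))
    list(hf = hf, expr = expr, meta = meta, variants = v)
  })
}
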
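# Single-cell heteroplasmy: stage assignment, pseudo-bulk, carrier
# statistics, cross-stage concordance and mtDNA-based lineage clustering.

#' Assign differentiation stages from collection day and pseudotime
#'
#' `iPSC`: collected at day 0. `mesendo`: day 1 or 2 with pseudotime in
#' `[0.15, 0.5)`. `defendo`: day 2 or 3 with pseudotime above 0.7.
#' Everything else (including boundary pseudotime values 0.5 and 0.7, and
#' cells with missing pseudotime, with a warning) is `undefined`.
#'
#' @param meta CellMeta data frame with `collection_day` and `pseudotime`.
#' @return `meta` with a `stage` column filled; every cell receives exactly
#'   one stage.
#' @export
assign_stage <- function(meta) {
  day <- meta$collection_day
  pt <- meta$pseudotime
  if (any(is.na(pt))) {
    warning(sum(is.na(pt)), " cell(s) with missing pseudotime set undefined")
  }
  stage <- rep("undefined", nrow(meta))
  stage[!is.na(day) & day == 0] <- "iPSC"
  ok <- !is.na(pt) & !is.na(day)
  stage[ok & day %in% c(1, 2) & pt >= 0.15 & pt < 0.5] <- "mesendo"
  stage[ok & day %in% c(2, 3) & pt > 0.7] <- "defendo"
  meta$stage <- stage
  meta
}

#' Pseudo-bulk heteroplasmy fractions
#'
#' Per variant, the mean per-cell HF over all cells of the group, zeros
#' included — the single-cell emulation of a bulk measurement.
#'
#' @param matrix cells x variants HF matrix.
#' @param group cell ids (rownames) or logical/integer row index; default
#'   all cells.
#' @return Named numeric vector of pseudo-bulk HFs per variant.
#' @export
pseudo_bulk_hf <- function(matrix, group = NULL) {
  m <- if (is.null(group)) matrix else matrix[group, , drop = FALSE]
  if (!nrow(m)) stop("empty cell group")
  colMeans(m)
}

#' Carrier proportion and mean carrier HF per variant
#'
#' A carrier is a cell with HF at or above the detection threshold (2%).
#' When non-carrier HFs are exactly zero,
#' `pseudo_bulk = proportion x mean_carrier_hf`.
#'
#' @param matrix cells x variants HF matrix.
#' @param group optional cell subset as in [pseudo_bulk_hf()].
#' @param threshold carrier HF threshold.
#' @return Data frame `variant`, `n_cells`, `n_carriers`, `proportion`,
#'   `mean_carrier_hf` (NA when no carriers).
#' @export
carrier_statistics <- function(matrix, group = NULL, threshold = 0.02) {
  m <- if (is.null(group)) matrix else matrix[group, , drop = FALSE]
  if (!nrow(m)) stop("empty cell group")
  carrier <- m >= threshold
  n_car <- colSums(carrier)
  mean_hf <- ifelse(n_car > 0, colSums(m * carrier) / n_car, NA_real_)
  data.frame(variant = colnames(m), n_cells = nrow(m), n_carriers = n_car,
             proportion = n_car / nrow(m), mean_carrier_hf = mean_hf,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mutation frequency binned by carrier proportion
#'
#' Variants are binned by the proportion of cells carrying them; the per-bin
#' rate is the variant count divided by (number of cells x 16,569 bp).
#'
#' @param matrix cells x variants HF matrix (one line).
#' @param breaks bin edges partitioning (0, 1]; default deciles.
#' @param threshold carrier HF threshold.
#' @return Data frame `bin`, `n_variants`, `rate`.
#' @export
binned_mutation_frequency <- function(matrix, breaks = seq(0, 1, 0.1),
                                      threshold = 0.02) {
  cs <- carrier_statistics(matrix, threshold = threshold)
  cs <- cs[cs$n_carriers > 0, , drop = FALSE]
  bins <- cut(cs$proportion, breaks, include.lowest = FALSE)
  tab <- table(bins)
  n_cells <- nrow(matrix)
  data.frame(bin = names(tab), n_variants = as.integer(tab),
             rate = as.integer(tab) / (n_cells * MT_GENOME_LENGTH),
             stringsAsFactors = FALSE)
}

#' Cross-stage concordance of per-variant statistics
#'
#' For each line with at least `min_cells` cells in every stage, Pearson
#' R-squared between stages of the log2 carrier proportions and of the mean
#' carrier HFs, over variants carried in both stages.
#'
#' @param matrix cells x variants HF matrix.
#' @param meta CellMeta with `cell_id`, `line_id`, `stage`.
#' @param stages stages to compare pairwise.
#' @param min_cells per-stage inclusion rule (default 20).
#' @return Data frame `line_id`, `stage_a`, `stage_b`, `n_variants`,
#'   `r2_proportion`, `p_proportion`, `r2_mean_hf`, `p_mean_hf`; attribute
#'   `excluded_lines` lists lines failing the cell rule.
#' @export
stage_concordance <- function(matrix, meta,
                              stages = c("iPSC", "mesendo", "defendo"),
                              min_cells = 20) {
  res <- list()
  excluded <- character(0)
  for (line in unique(meta$line_id)) {
    lm_ <- meta[meta$line_id == line & meta$stage %in% stages, , drop = FALSE]
    ncs <- table(factor(lm_$stage, levels = stages))
    if (any(ncs < min_cells)) {
      excluded <- c(excluded, line)
      next
    }
    for (a in seq_along(stages)) for (b in seq_len(a - 1L)) {
      sa <- stages[a]; sb <- stages[b]
      ca <- carrier_statistics(matrix, lm_$cell_id[lm_$stage == sa])
      cb <- carrier_statistics(matrix, lm_$cell_id[lm_$stage == sb])
      both <- ca$n_carriers > 0 & cb$n_carriers > 0
      if (sum(both) < 2) {
        res[[length(res) + 1L]] <- data.frame(
          line_id = line, stage_a = sb, stage_b = sa,
          n_variants = sum(both), r2_proportion = NA_real_,
          p_proportion = NA_real_, r2_mean_hf = NA_real_,
          p_mean_hf = NA_real_, stringsAsFactors = FALSE)
        next
      }
      tp <- stats::cor.test(log2(ca$proportion[both]),
                            log2(cb$proportion[both]))
      th <- stats::cor.test(ca$mean_carrier_hf[both],
                            cb$mean_carrier_hf[both])
      res[[length(res) + 1L]] <- data.frame(
        line_id = line, stage_a = sb, stage_b = sa, n_variants = sum(both),
        r2_proportion = unname(tp$estimate)^2, p_proportion = tp$p.value,
        r2_mean_hf = unname(th$estimate)^2, p_mean_hf = th$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(line_id = character(), stage_a = character(),
               stage_b = character(), n_variants = integer(),
               r2_proportion = numeric(), p_proportion = numeric(),
               r2_mean_hf = numeric(), p_mean_hf = numeric())
  attr(out, "excluded_lines") <- excluded
  out
}

#' mtDNA-based lineage clustering of single cells
#'
#' Filters variant columns to those carried by more than
#' `min_carrier_fraction` of cells, embeds cells in 2-D from the HF matrix
#' (deterministic principal components by default; `method = "umap"` uses
#' uwot when installed, with the seed recorded in the output), and cuts an
#' average-linkage hierarchical clustering of the Euclidean HF distances at
#' an absolute height (`cut_height`, default 0.5 — roughly the separation
#' produced by a single homoplasmic marker). Marker variants per cluster are
#' those with the largest difference between the cluster mean HF and the
#' overall mean.
#'
#' @param matrix cells x variants HF matrix.
#' @param meta CellMeta (carried through to the output).
#' @param min_carrier_fraction variant inclusion rule (default 0.01).
#' @param method `"pca"` or `"umap"`.
#' @param cut_height dendrogram cut height on Euclidean HF distance.
#' @param n_markers marker variants reported per cluster.
#' @param seed seed recorded and used for the stochastic embedding.
#' @return A `LineageResult` list: `embedding` (cells x 2), `cluster`
#'   (integer per cell), `markers` (per-cluster data frame), `n_clusters`,
#'   `variants_used`, `method`, `seed`, `note`.
#' @export
lineage_clusters <- function(matrix, meta = NULL, min_carrier_fraction = 0.01,
                             method = c("pca", "umap"), cut_height = 0.5,
                             n_markers = 5, seed = 1L) {
  method <- match.arg(method)
  cs <- carrier_statistics(matrix)
  keep <- cs$proportion > min_carrier_fraction
  note <- NULL
  if (!any(keep)) {
    return(structure(list(
      embedding = matrix(0, nrow(matrix), 2,
                         dimnames = list(rownames(matrix), c("dim1", "dim2"))),
      cluster = rep(1L, nrow(matrix)), markers = NULL, n_clusters = 1L,
      variants_used = character(0), method = method, seed = seed,
      note = "no variants passed the carrier-fraction filter"),
      class = "LineageResult"))
  }
  m <- matrix[, keep, drop = FALSE]
  emb <- if (method == "umap" && requireNamespace("uwot", quietly = TRUE)) {
    withr::with_seed(seed, uwot::umap(m, n_neighbors = min(15, nrow(m) - 1)))
  } else {
    if (method == "umap") {
      note <- "uwot not installed; fell back to PCA"
      method <- "pca"
    }
    p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    k <- min(2L, ncol(p$x))
    cbind(p$x[, seq_len(k)], matrix(0, nrow(m), 2 - k))
  }
  dimnames(emb) <- list(rownames(matrix), c("dim1", "dim2"))
  hc <- stats::hclust(stats::dist(m), method = "average")
  cluster <- if (max(hc$height) <= cut_height) rep(1L, nrow(m)) else
    stats::cutree(hc, h = cut_height)
  overall <- colMeans(m)
  markers <- do.call(rbind, lapply(sort(unique(cluster)), function(k) {
    mu <- colMeans(m[cluster == k, , drop = FALSE])
    d <- abs(mu - overall)
    top <- order(d, decreasing = TRUE)[seq_len(min(n_markers, length(d)))]
    data.frame(cluster = k, variant = colnames(m)[top], mean_hf = mu[top],
               delta = d[top], row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(embedding = emb, cluster = cluster, markers = markers,
                 n_clusters = length(unique(cluster)),
                 variants_used = colnames(m), method = method, seed = seed,
                 note = note),
            class = "LineageResult")
}

#' @export
print.LineageResult <- function(x, ...) {
  cat("LineageResult:", length(x$cluster), "cells,", x$n_clusters,
      "cluster(s),", length(x$variants_used), "variants,", x$method,
      "embedding\n")
  invisible(x)
}

#' Label single-cell variants by fibroblast sharing
#'
#' Variants also present in the matched fibroblast bulk calls are
#' `fibroblast_shared`, the rest `stage_specific`. The summary reports the
#' fraction of fibroblast-shared variants carried by more than 95% and more
#' than 50% of cells.
#'
#' @param matrix cells x variants HF matrix (variant columns named
#'   `<position><ref>><alt>` as produced by the simulator) — or any naming,
#'   provided `variant_positions` etc. are supplied via `variants`.
#' @param fibro_calls matched fibroblast bulk VariantCall table, or `NULL`
#'   (all variants stage-specific, with a warning).
#' @param variants optional data frame `variant`, `position`, `ref`, `alt`
#'   mapping column names to substitutions; defaults to parsing the column
#'   names.
#' @return List `labels` (per-variant data frame with `label`, `proportion`)
#'   and `summary` (`n_shared`, `frac_above_95`, `frac_above_50`).
#' @export
fibroblast_sharing <- function(matrix, fibro_calls, variants = NULL) {
  cs <- carrier_statistics(matrix)
  if (is.null(variants)) {
    pm <- regmatches(cs$variant,
                     regexec("^([0-9]+)([ACGT])>([ACGT])$", cs$variant))
    variants <- data.frame(
      variant = cs$variant,
      position = vapply(pm, function(x) as.integer(x[2]), integer(1)),
      ref = vapply(pm, function(x) x[3], character(1)),
      alt = vapply(pm, function(x) x[4], character(1)),
      stringsAsFactors = FALSE)
  }
  if (is.null(fibro_calls) || !nrow(fibro_calls)) {
    warning("no matched fibroblast calls: all variants labelled stage_specific")
    shared <- rep(FALSE, nrow(cs))
  } else {
    shared <- paste(variants$position, variants$ref, variants$alt) %in%
      paste(fibro_calls$position, fibro_calls$ref, fibro_calls$alt)
  }
  labels <- data.frame(variant = cs$variant,
                       label = ifelse(shared, "fibroblast_shared",
                                      "stage_specific"),
                       proportion = cs$proportion, stringsAsFactors = FALSE)
  sh <- labels[labels$label == "fibroblast_shared", , drop = FALSE]
  summary <- list(
    n_shared = nrow(sh),
    frac_above_95 = if (nrow(sh)) mean(sh$proportion > 0.95) else NA_real_,
    frac_above_50 = if (nrow(sh)) mean(sh$proportion > 0.50) else NA_real_
  )
  list(labels = labels, summary = summary)
}
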
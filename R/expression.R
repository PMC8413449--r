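# Heteroplasmy-expression association: variable-gene selection, variance
# partitioning and differential expression between mtDNA-defined sub-clones.

lognorm <- function(counts) {
  # library-size normalised log2 expression
  sf <- rowSums(counts)
  sf[sf == 0] <- 1
  log2(counts / sf * mean(sf) + 1)
}

#' Select the most variable genes
#'
#' Ranks genes by the significance of their deviation above a mean-variance
#' trend (loess of log variance on log mean of the log-normalised
#' expression), and returns the top `n`. Deterministic.
#'
#' @param expr cells x genes count (or log-normalised) matrix.
#' @param n number of genes (default 4000); when fewer genes are available
#'   all are returned with a warning.
#' @param normalised set `TRUE` when `expr` is already log-normalised.
#' @return Character vector of selected gene names, most significant first.
#' @export
select_variable_genes <- function(expr, n = 4000, normalised = FALSE) {
  le <- if (normalised) expr else lognorm(expr)
  mu <- colMeans(le)
  v <- apply(le, 2, stats::var)
  ok <- v > 0 & mu > 0
  if (n >= ncol(expr)) {
    warning("fewer genes than requested: returning all")
    return(colnames(expr)[order(-v)])
  }
  fit <- stats::loess(log(v[ok]) ~ log(mu[ok]), span = 0.75,
                      family = "symmetric")
  resid <- rep(-Inf, ncol(le))
  resid[ok] <- log(v[ok]) - stats::fitted(fit)
  # standardised deviation above the trend; larger = more overdispersed
  z <- (resid - stats::median(resid[ok])) / stats::mad(resid[ok])
  colnames(expr)[order(-z)][seq_len(n)]
}

#' Variance-component decomposition of gene expression
#'
#' Per gene, partitions expression variance into cell stage, experiment
#' batch, cell line identity (random effects via a linear mixed model) and
#' the per-cell mean heteroplasmy fraction of nonsynonymous mtDNA variants
#' (fixed effect; its share is the variance of the fitted HF component),
#' plus residual. With a single line (within-line analysis), the mean
#' nonsynonymous HF is the sole structured component and the model reduces
#' to ordinary least squares.
#'
#' @param expr cells x genes matrix (counts are log-normalised internally).
#' @param meta data frame with per-cell `stage`, `batch`, `line_id` (any
#'   single-level factor is dropped with a warning).
#' @param mean_nonsyn_hf numeric per-cell covariate, or `NULL`.
#' @param normalised set `TRUE` when `expr` is already log-normalised.
#' @return A `VarianceDecomposition` data frame: per gene, fractions for
#'   `stage`, `batch`, `line`, `hf`, `residual` (each in `[0, 1]`, summing
#'   to 1 up to rounding).
#' @export
variance_components <- function(expr, meta, mean_nonsyn_hf = NULL,
                                normalised = FALSE) {
  le <- if (normalised) expr else lognorm(expr)
  rand <- c(stage = "stage", batch = "batch", line = "line_id")
  rand <- rand[names(rand)[vapply(rand, function(v)
    v %in% names(meta) && length(unique(meta[[v]])) > 1, logical(1))]]
  dropped <- setdiff(c("stage", "batch", "line"), names(rand))
  if (length(dropped))
    warning("single-level or missing factor(s) dropped: ",
            paste(dropped, collapse = ", "))
  use_hf <- !is.null(mean_nonsyn_hf) && stats::var(mean_nonsyn_hf) > 0
  out <- matrix(0, ncol(le), 5,
                dimnames = list(colnames(le),
                                c("stage", "batch", "line", "hf", "residual")))
  for (g in seq_len(ncol(le))) {
    y <- le[, g]
    if (stats::var(y) == 0) {
      out[g, "residual"] <- 1
      next
    }
    if (length(rand)) {
      d <- data.frame(y = y, meta[, rand, drop = FALSE])
      names(d)[-1] <- names(rand)
      if (use_hf) d$hf <- mean_nonsyn_hf
      rhs <- paste(sprintf("(1 | %s)", names(rand)), collapse = " + ")
      if (use_hf) rhs <- paste("hf +", rhs)
      fit <- suppressWarnings(suppressMessages(
        lme4::lmer(stats::as.formula(paste("y ~", rhs)), data = d,
                   REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular =
                                                 "ignore"))))
      vc <- as.data.frame(lme4::VarCorr(fit))
      vrand <- stats::setNames(vc$vcov[match(names(rand), vc$grp)],
                               names(rand))
      vres <- vc$vcov[vc$grp == "Residual"]
      vhf <- if (use_hf) stats::var(lme4::fixef(fit)[["hf"]] * d$hf) else 0
      tot <- sum(vrand, vres, vhf)
      out[g, names(rand)] <- vrand / tot
      out[g, "hf"] <- vhf / tot
      out[g, "residual"] <- vres / tot
    } else if (use_hf) {
      fit <- stats::lm(y ~ mean_nonsyn_hf)
      vhf <- stats::var(stats::fitted(fit))
      vres <- stats::var(stats::residuals(fit))
      out[g, "hf"] <- vhf / (vhf + vres)
      out[g, "residual"] <- vres / (vhf + vres)
    } else {
      out[g, "residual"] <- 1
    }
  }
  out <- as.data.frame(out)
  out$gene <- colnames(le)
  class(out) <- c("VarianceDecomposition", class(out))
  out[, c("gene", "stage", "batch", "line", "hf", "residual")]
}

#' Differential expression between mtDNA genotype groups
#'
#' Dichotomises cells into carriers (HF at or above `carrier_threshold`) and
#' non-carriers of one mtDNA variant (or at HF 50% when carriers are
#' near-homoplasmic), then fits a per-gene linear model on log-normalised
#' expression with cell stage as a covariate (moderated statistics via
#' limma), with Benjamini-Hochberg adjustment. mtDNA-encoded and ribosomal
#' genes should be excluded via `exclude_genes`.
#'
#' @param expr cells x genes count matrix.
#' @param meta data frame with per-cell `stage`.
#' @param genotype_hf numeric per-cell HF of the grouping variant.
#' @param variant_id label of the grouping variant.
#' @param min_cells_per_group minimum cells per genotype group (default 15).
#' @param carrier_threshold HF threshold defining carriers.
#' @param exclude_genes gene names to drop before testing.
#' @param fdr significance threshold on adjusted p-values.
#' @param normalised set `TRUE` when `expr` is already log-normalised.
#' @return A `DEResult` data frame: per gene `effect` (log2 fold change),
#'   `p_value`, `q_value`, `significant`; attributes `variant`, `split_rule`,
#'   `n_carrier`, `n_noncarrier`.
#' @export
de_by_mtdna_genotype <- function(expr, meta, genotype_hf, variant_id = "variant",
                                 min_cells_per_group = 15,
                                 carrier_threshold = 0.02,
                                 exclude_genes = character(0), fdr = 0.1,
                                 normalised = FALSE) {
  keep <- setdiff(colnames(expr), exclude_genes)
  le <- if (normalised) expr[, keep, drop = FALSE] else
    lognorm(expr)[, keep, drop = FALSE]
  carrier <- genotype_hf >= carrier_threshold
  split_rule <- "carrier_2pct"
  # near-homoplasmic carriers (or a degenerate all-carrier split under the
  # 2% rule) switch to the 50% HF split
  if ((any(carrier) && stats::median(genotype_hf[carrier]) > 0.95) ||
      all(carrier)) {
    carrier <- genotype_hf >= 0.5
    split_rule <- "hf_50pct"
  }
  n1 <- sum(carrier); n0 <- sum(!carrier)
  if (n1 == 0 || n0 == 0)
    stop("single genotype group for variant ", variant_id)
  if (min(n1, n0) < min_cells_per_group)
    warning("fewer than ", min_cells_per_group, " cells in a genotype group")
  design_df <- data.frame(genotype = as.integer(carrier))
  if ("stage" %in% names(meta) && length(unique(meta$stage)) > 1)
    design_df$stage <- factor(meta$stage)
  design <- stats::model.matrix(~ ., design_df)
  fit <- limma::eBayes(limma::lmFit(t(le), design))
  tt <- limma::topTable(fit, coef = "genotype", number = Inf, sort.by = "none")
  out <- data.frame(gene = rownames(tt), effect = tt$logFC,
                    p_value = tt$P.Value, q_value = tt$adj.P.Val,
                    significant = tt$adj.P.Val < fdr, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "variant") <- variant_id
  attr(out, "split_rule") <- split_rule
  attr(out, "n_carrier") <- n1
  attr(out, "n_noncarrier") <- n0
  class(out) <- c("DEResult", class(out))
  out
}
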
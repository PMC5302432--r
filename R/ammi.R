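#' Fit the AMMI model to a genotype x environment mean table
#'
#' Additive Main effects and Multiplicative Interaction: the grand mean and
#' additive genotype and environment effects are removed by two-way ANOVA
#' on the cell means, and the double-centred residual matrix
#' `Z_ij = Y_ij - rowmean_i - colmean_j + grandmean` is decomposed by SVD.
#' Scores use symmetric scaling (both sides multiplied by sqrt(lambda_k)),
#' so that `mu + g_i + e_j + sum_k gscore_ik * escore_jk` reconstructs the
#' input exactly. The variance explained by axis k is
#' `lambda_k^2 / sum(lambda^2) * 100`, i.e. a share of the interaction sum
#' of squares, not of the total.
#'
#' Each axis is oriented so that the environment with the largest absolute
#' score is positive; the SVD sign is otherwise arbitrary.
#'
#' When plot-level data are supplied, the classical two-way ANOVA with
#' replication is run and F tests for genotype, environment and G x E
#' against the pooled error are reported.
#'
#' @param means a `trait_matrix` from [cell_means()] or a plain complete
#'   numeric matrix (genotypes in rows) with at least 2 rows and columns.
#' @param data optional [met_dataset()] with replicates, for the F tests.
#' @param trait trait selector for the ANOVA when `data` is given;
#'   defaults to the trait of `means` when available.
#' @return Object of class `ammi_fit`: `grand_mean`, `genotype_effects`,
#'   `environment_effects`, `lambdas`, `genotype_scores`,
#'   `environment_scores` (columns PC1..PCk, k = min(G,E) - 1),
#'   `var_explained` (percent), and `anova` (or NULL).
#' @export
#' @examples
#' M <- outer(1:4, 1:3, "+") + 10   # purely additive: zero interaction
#' fit <- fit_ammi(M)
#' max(abs(fit$lambdas))
fit_ammi <- function(means, data = NULL, trait = NULL) {
  if (inherits(means, "trait_matrix")) {
    if (is.null(trait)) trait <- means$trait
    M <- means$values
  } else {
    M <- as.matrix(means)
  }
  if (nrow(M) < 2 || ncol(M) < 2)
    stop("AMMI needs at least a 2 x 2 genotype x environment table")
  if (anyNA(M)) stop("AMMI requires a complete matrix (no missing cells)")
  if (is.null(rownames(M))) rownames(M) <- sprintf("G%02d", seq_len(nrow(M)))
  if (is.null(colnames(M))) colnames(M) <- sprintf("E%d", seq_len(ncol(M)))

  mu <- mean(M)
  g <- rowMeans(M) - mu
  e <- colMeans(M) - mu
  Z <- M - outer(rowMeans(M), rep(1, ncol(M))) -
    outer(rep(1, nrow(M)), colMeans(M)) + mu

  K <- min(dim(M)) - 1
  s <- svd(Z)
  lam <- s$d[seq_len(K)]
  gsc <- s$u[, seq_len(K), drop = FALSE] %*% diag(sqrt(lam), K, K)
  esc <- s$v[, seq_len(K), drop = FALSE] %*% diag(sqrt(lam), K, K)
  for (k in seq_len(K)) {           # fixed orientation rule
    j <- which.max(abs(esc[, k]))
    if (esc[j, k] < 0) {
      esc[, k] <- -esc[, k]
      gsc[, k] <- -gsc[, k]
    }
  }
  dimnames(gsc) <- list(rownames(M), paste0("PC", seq_len(K)))
  dimnames(esc) <- list(colnames(M), paste0("PC", seq_len(K)))
  tot <- sum(lam^2)
  ve <- if (tot > 0) 100 * lam^2 / tot else rep(NA_real_, K)

  an <- NULL
  if (!is.null(data)) {
    stopifnot(inherits(data, "met_dataset"))
    col <- resolve_trait(data, if (is.null(trait)) "yield" else trait)
    rec <- data$records
    rec$genotype <- factor(rec$genotype, levels = data$genotypes)
    rec$environment <- factor(rec$environment, levels = data$environments)
    fml <- stats::as.formula(paste0("`", col, "` ~ genotype * environment"))
    an <- quiet_anova(stats::lm(fml, data = rec))
    rownames(an) <- c("genotype", "environment", "ge", "residual")
  }

  structure(
    list(grand_mean = mu, genotype_effects = g, environment_effects = e,
         lambdas = lam, genotype_scores = gsc, environment_scores = esc,
         var_explained = ve, anova = an, trait = trait),
    class = "ammi_fit")
}

#' @export
print.ammi_fit <- function(x, ...) {
  cat("AMMI fit", if (!is.null(x$trait)) paste0("for '", x$trait, "'"),
      "\n  grand mean:", format(x$grand_mean), "\n")
  cat("  interaction axes:", length(x$lambdas),
      "| variance explained (%):",
      paste(format(round(x$var_explained, 1)), collapse = ", "), "\n")
  invisible(x)
}

# Ordering key that zaps numerical noise in scores: the stability ranking
# must treat an exactly additive table (scores ~ 1e-14) as all-tied.
zap_score <- function(x) round(x, 8)

#' Stability ranking from an AMMI fit
#'
#' Genotypes are split at the grand mean of the performance values
#' (above/below average, the biplot's vertical-axis convention); within the
#' above-average class genotypes are ranked by |PC1| ascending (closer to
#' zero = more stable), the below-average class follows, ranked the same
#' way. Ties on |PC1| break by performance descending, then by genotype
#' name. When every PC1 score is zero the ranking falls back to performance
#' descending, then name.
#'
#' @param fit an `ammi_fit`.
#' @param performance optional named per-genotype performance means;
#'   defaults to the fit's genotype means (grand mean + effects).
#' @return data.frame `genotype`, `performance`, `PC1`, `class`
#'   ("above"/"below" average), `rank`, ordered by rank. The environment
#'   scores are attached as attribute `"environment_scores"`.
#' @export
stability_ranking <- function(fit, performance = NULL) {
  stopifnot(inherits(fit, "ammi_fit"))
  genotypes <- rownames(fit$genotype_scores)
  if (is.null(performance))
    performance <- fit$grand_mean + fit$genotype_effects
  performance <- performance[genotypes]
  pc1 <- fit$genotype_scores[, 1]
  split_at <- mean(performance)
  cls <- ifelse(performance >= split_at, "above", "below")
  key_cls <- ifelse(cls == "above", 0L, 1L)
  o <- order(key_cls, zap_score(abs(pc1)), -performance, genotypes)
  out <- data.frame(genotype = genotypes[o],
                    performance = unname(performance[o]),
                    PC1 = unname(pc1[o]), class = cls[o],
                    rank = seq_along(o), stringsAsFactors = FALSE)
  attr(out, "environment_scores") <- fit$environment_scores[, 1]
  out
}

#' Biplot data export
#'
#' One row per genotype and per environment with the trait mean and the
#' first (and second, when available) interaction axis scores, for plotting
#' performance against PC1 externally.
#'
#' @param fit an `ammi_fit`.
#' @param performance optional named per-genotype means (defaults to the
#'   fit's genotype means); environment means are the fit's column means.
#' @return data.frame `label`, `type` ("genotype"/"environment"), `mean`,
#'   `PC1`, `PC2` (NA when only one axis exists).
#' @export
biplot_data <- function(fit, performance = NULL) {
  stopifnot(inherits(fit, "ammi_fit"))
  genotypes <- rownames(fit$genotype_scores)
  environments <- rownames(fit$environment_scores)
  if (is.null(performance))
    performance <- fit$grand_mean + fit$genotype_effects
  K <- ncol(fit$genotype_scores)
  pc2g <- if (K >= 2) fit$genotype_scores[, 2] else rep(NA_real_, length(genotypes))
  pc2e <- if (K >= 2) fit$environment_scores[, 2] else rep(NA_real_, length(environments))
  rbind(
    data.frame(label = genotypes, type = "genotype",
               mean = unname(performance[genotypes]),
               PC1 = unname(fit$genotype_scores[, 1]), PC2 = unname(pc2g),
               stringsAsFactors = FALSE),
    data.frame(label = environments, type = "environment",
               mean = unname(fit$grand_mean + fit$environment_effects),
               PC1 = unname(fit$environment_scores[, 1]), PC2 = unname(pc2e),
               stringsAsFactors = FALSE))
}
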
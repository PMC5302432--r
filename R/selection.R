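#' Elston's multiplicative selection index
#'
#' For each genotype, the product over traits of `(x_it - LAL_t)`, where
#' the lowest acceptable limit LAL is a per-trait culling threshold. A
#' genotype whose value for any trait does not strictly exceed its LAL
#' receives a score of 0 and a threshold-failure flag; flagged genotypes
#' rank after all positive-score genotypes. Values minus thresholds are
#' used as-is: shifting a trait changes scores unless its LAL shifts
#' equally. The score is invariant to trait ordering and strictly
#' increasing in each trait above its LAL.
#'
#' @param trait_means numeric matrix or data.frame of per-genotype trait
#'   means, genotypes in rows (rownames), traits in columns.
#' @param lal named numeric vector of lowest acceptable limits covering
#'   every trait column.
#' @return data.frame `genotype`, `EMI`, `below_lal` (flag), `rank`,
#'   ordered by score descending (ties by name).
#' @export
#' @examples
#' x <- rbind(Svale = c(Fe = 54, Zn = 48, Cu = 75, Mg = 53),
#'            Starke = c(Fe = 42, Zn = 52, Cu = 74, Mg = 56))
#' elston_index(x, c(Fe = 28, Zn = 40, Cu = 50, Mg = 25))
elston_index <- function(trait_means, lal) {
  X <- as.matrix(trait_means)
  if (is.null(rownames(X))) stop("trait_means needs genotype rownames")
  miss <- setdiff(colnames(X), names(lal))
  if (length(miss) > 0)
    stop("no LAL for trait(s): ", paste(miss, collapse = ", "))
  if (anyNA(X)) stop("missing trait value(s) in trait_means")
  D <- sweep(X, 2, lal[colnames(X)])
  pass <- apply(D > 0, 1, all)
  score <- ifelse(pass, apply(D, 1, prod), 0)
  o <- order(-score, rownames(X))
  data.frame(genotype = rownames(X)[o], EMI = unname(score[o]),
             below_lal = unname(!pass[o]), rank = seq_len(nrow(X)),
             stringsAsFactors = FALSE)
}

#' Genotypic covariance matrix across traits
#'
#' Estimates the trait x trait genotypic covariance as the covariance,
#' across genotypes, of the BLUP genotype main effects of each trait
#' (shrunken values are stable for small trials). Prerequisite of the
#' desired-gains index.
#'
#' @param data a [met_dataset()] (complete).
#' @param traits character vector of >= 1 trait selectors.
#' @param method variance-component method passed to [fit_varcomp()].
#' @return symmetric trait x trait covariance matrix.
#' @export
genotypic_covariance <- function(data, traits,
                                 method = c("auto", "anova", "em_reml")) {
  stopifnot(inherits(data, "met_dataset"))
  if (length(data$genotypes) < 3)
    stop("genotypic covariance unreliable with fewer than 3 genotypes")
  B <- sapply(traits, function(tr) {
    vc <- fit_varcomp(data, tr, method = method)
    gv <- predict_genotypic_values(vc, data, tr)
    gv$genotype_blup
  })
  colnames(B) <- traits
  stats::cov(B)
}

#' Pesek-Baker desired-gains selection index
#'
#' Index coefficients solve `G b = d`, where G is the genotypic covariance
#' matrix and d the vector of desired gains, so the predicted response to
#' selection is proportional to the desired gains (a zero desired gain
#' asks the index to hold that trait constant, generally with a nonzero
#' coefficient). Scores are `sum_t b_t x_it`; genotypes are ranked by
#' score descending.
#'
#' @param trait_means per-genotype trait means, genotypes in rows.
#' @param G trait x trait genotypic covariance matrix, e.g. from
#'   [genotypic_covariance()].
#' @param gains named numeric vector of desired gains, same traits.
#' @param ridge nonnegative ridge added to diag(G) when G is
#'   ill-conditioned (default 0).
#' @return data.frame `genotype`, `BDGI`, `rank`; the coefficients `b` and
#'   expected gain direction `G %*% b` are attached as attributes
#'   `"coefficients"` and `"expected_gain"`.
#' @export
baker_index <- function(trait_means, G, gains, ridge = 0) {
  X <- as.matrix(trait_means)
  traits <- colnames(X)
  if (!all(traits %in% names(gains)))
    stop("desired gains must cover every trait column")
  G <- as.matrix(G)
  if (is.null(dimnames(G))) dimnames(G) <- list(traits, traits)
  G <- G[traits, traits]
  d <- gains[traits]
  Gr <- G + diag(ridge, nrow(G))
  if (kappa(Gr) > 1e10)
    stop("genotypic covariance matrix is singular or ill-conditioned; ",
         "consider a ridge > 0")
  b <- solve(Gr, d)
  score <- drop(X %*% b)
  o <- order(-score, rownames(X))
  out <- data.frame(genotype = rownames(X)[o], BDGI = unname(score[o]),
                    rank = seq_len(nrow(X)), stringsAsFactors = FALSE)
  attr(out, "coefficients") <- stats::setNames(drop(b), traits)
  attr(out, "expected_gain") <- stats::setNames(drop(G %*% b), traits)
  out
}

#' Combined "balanced genotype" ranking
#'
#' Aggregates per-method, per-trait rank vectors into a single ranking by
#' the mean rank across components; ties break by genotype name. Every
#' component must rank the same genotype set.
#'
#' @param ranks named list of rank components; each either a data.frame
#'   with `genotype` and `rank` columns or a named numeric rank vector.
#' @return data.frame with `genotype`, one column per component, the
#'   `mean_rank`, and the final `rank`.
#' @export
balanced_ranking <- function(ranks) {
  stopifnot(is.list(ranks), length(ranks) >= 1, !is.null(names(ranks)))
  as_vec <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$rank, x$genotype)
    else x
  }
  vecs <- lapply(ranks, as_vec)
  genotypes <- sort(names(vecs[[1]]))
  for (nm in names(vecs))
    if (!setequal(names(vecs[[nm]]), genotypes))
      stop("component '", nm, "' ranks a different genotype set")
  M <- sapply(vecs, function(v) v[genotypes])
  mean_rank <- rowMeans(M)
  o <- order(mean_rank, genotypes)
  out <- data.frame(genotype = genotypes[o], M[o, , drop = FALSE],
                    mean_rank = unname(mean_rank[o]),
                    rank = seq_along(genotypes),
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}
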
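# Mixed model for one trait of a MET: y_ijr = mu + E_j + g_i + ge_ij + eps,
# with environments fixed and genotype and interaction effects random.

met_model_frame <- function(data, trait) {
  col <- resolve_trait(data, trait)
  rec <- data$records
  list(y = rec[[col]],
       geno = factor(rec$genotype, levels = data$genotypes),
       env = factor(rec$environment, levels = data$environments),
       col = col)
}

met_design <- function(mf) {
  X <- stats::model.matrix(~ 0 + env, data = mf)
  Zg <- stats::model.matrix(~ 0 + geno, data = mf)
  ge <- interaction(mf$geno, mf$env, sep = ":", lex.order = TRUE)
  Zge <- stats::model.matrix(~ 0 + ge, data = list(ge = ge))
  list(X = X, Zg = Zg, Zge = Zge, ge_levels = levels(ge))
}

reml_loglik <- function(y, X, V) {
  cv <- chol(V)
  Vi_y <- backsolve(cv, forwardsolve(t(cv), y))
  Vi_X <- backsolve(cv, forwardsolve(t(cv), X))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(Vi_X, y))
  Py <- Vi_y - Vi_X %*% beta
  -0.5 * (2 * sum(log(diag(cv))) + determinant(XtViX)$modulus[1] +
            sum(y * Py))
}

#' Estimate variance components for a random-genotype MET model
#'
#' Fits `y = mu + E_j + g_i + (ge)_ij + eps` with environments fixed and
#' genotype and interaction random. For balanced data (equal replicate
#' counts in every cell, at least 2) the ANOVA closed forms are used:
#' `sigma2_eps = MS_err`, `sigma2_ge = (MS_GE - MS_err) / r`,
#' `sigma2_g = (MS_G - MS_GE) / (r e)`, negatives truncated to zero. For
#' unbalanced data (or on request) EM-REML is iterated from the
#' method-of-moments start until the relative change in the REML
#' log-likelihood falls below `tol`.
#'
#' @param data a [met_dataset()] with >= 2 genotypes and environments.
#' @param trait trait selector.
#' @param method `"auto"` (closed forms when balanced, EM-REML otherwise),
#'   `"anova"`, or `"em_reml"`.
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter maximum EM iterations (default 10000).
#' @return Object of class `met_varcomp`: `sigma2_g`, `sigma2_ge`,
#'   `sigma2_eps`, `method`, `converged`, `n_iterations`, `trait`.
#' @export
fit_varcomp <- function(data, trait, method = c("auto", "anova", "em_reml"),
                        tol = 1e-8, max_iter = 10000) {
  stopifnot(inherits(data, "met_dataset"))
  method <- match.arg(method)
  if (length(data$genotypes) < 2 || length(data$environments) < 2)
    stop("need at least 2 genotypes and 2 environments")
  mf <- met_model_frame(data, trait)
  counts <- table(mf$geno, mf$env)
  if (any(counts == 0)) stop("incomplete G x E layout")
  balanced <- length(unique(as.vector(counts))) == 1
  r <- as.vector(counts)[1]
  if (method == "auto") method <- if (balanced && r >= 2) "anova" else "em_reml"

  if (method == "anova") {
    if (!balanced) stop("ANOVA closed forms require balanced data")
    if (r < 2) stop("ANOVA closed forms require >= 2 replicates per cell")
    est <- varcomp_anova(mf, r)
    return(structure(
      list(sigma2_g = unname(est["g"]), sigma2_ge = unname(est["ge"]),
           sigma2_eps = unname(est["eps"]), method = "anova_closed_form",
           converged = TRUE, n_iterations = 0L, trait = mf$col),
      class = "met_varcomp"))
  }

  varcomp_em(mf, tol = tol, max_iter = max_iter)
}

# Closed-form ANOVA estimators for the balanced layout.
varcomp_anova <- function(mf, r) {
  g <- nlevels(mf$geno); e <- nlevels(mf$env)
  cellm <- tapply(mf$y, list(mf$geno, mf$env), mean)
  gm <- rowMeans(cellm); em <- colMeans(cellm); grand <- mean(cellm)
  ss_err <- sum((mf$y - cellm[cbind(as.integer(mf$geno),
                                    as.integer(mf$env))])^2)
  ms_err <- ss_err / (g * e * (r - 1))
  resid_int <- cellm - outer(gm, rep(1, e)) - outer(rep(1, g), em) + grand
  ms_ge <- r * sum(resid_int^2) / ((g - 1) * (e - 1))
  ms_g <- r * e * sum((gm - grand)^2) / (g - 1)
  c(g = max((ms_g - ms_ge) / (r * e), 0),
    ge = max((ms_ge - ms_err) / r, 0),
    eps = ms_err)
}

# EM-REML for the two random components plus residual (Searle, Casella &
# McCulloch form): sigma2_k <- sigma2_k + sigma2_k^2/q_k *
# (y'P Zk Zk' P y - tr(Zk' P Zk)), with Z0 = I for the residual. Updates
# stay nonnegative; components collapsing below a numerical floor are
# pinned at zero.
varcomp_em <- function(mf, tol = 1e-8, max_iter = 10000) {
  d <- met_design(mf)
  y <- mf$y; X <- d$X
  n <- length(y)
  GgGt <- tcrossprod(d$Zg)     # n x n incidence cross-products
  GeGt <- tcrossprod(d$Zge)
  qg <- ncol(d$Zg); qge <- ncol(d$Zge)

  counts <- table(mf$geno, mf$env)
  r <- max(mean(counts), 1)
  start <- if (all(counts == counts[1]) && counts[1] >= 2)
    varcomp_anova(mf, counts[1]) else NULL
  vy <- stats::var(y)
  floor_v <- 1e-10 * max(vy, 1e-12)
  s2 <- c(g = NA, ge = NA, eps = NA)
  if (is.null(start)) {
    s2[] <- c(vy / 4, vy / 4, vy / 2)
  } else {
    s2[] <- pmax(start, vy / 100)   # strictly positive deterministic start
  }

  ll_old <- -Inf; converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    V <- s2["g"] * GgGt + s2["ge"] * GeGt + diag(s2["eps"], n)
    cv <- chol(V)
    Vi <- chol2inv(cv)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    P <- Vi - ViX %*% solve(XtViX, t(ViX))
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(cv))) + determinant(XtViX)$modulus[1] +
                    sum(y * Py))

    new <- s2
    if (s2["g"] > 0) {
      PZZ <- P %*% GgGt
      new["g"] <- s2["g"] + s2["g"]^2 / qg *
        (sum(Py * (GgGt %*% Py)) - sum(diag(PZZ)))
    }
    if (s2["ge"] > 0) {
      PZZ <- P %*% GeGt
      new["ge"] <- s2["ge"] + s2["ge"]^2 / qge *
        (sum(Py * (GeGt %*% Py)) - sum(diag(PZZ)))
    }
    new["eps"] <- s2["eps"] + s2["eps"]^2 / n *
      (sum(Py * Py) - sum(diag(P)))
    new[new < floor_v] <- 0
    rel_ll <- abs(ll - ll_old) / (abs(ll) + 1)
    delta <- max(abs(new - s2) / (abs(s2) + floor_v + 1e-300))
    s2 <- new
    if (is.finite(rel_ll) && rel_ll < tol && delta < sqrt(tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged)
    stop("EM-REML did not converge in ", max_iter, " iterations ",
         "(last relative log-likelihood change ",
         format(abs(ll - ll_old) / (abs(ll) + 1)), ")")
  structure(
    list(sigma2_g = unname(s2["g"]), sigma2_ge = unname(s2["ge"]),
         sigma2_eps = unname(s2["eps"]), method = "em_reml",
         converged = converged, n_iterations = it, trait = mf$col),
    class = "met_varcomp")
}

#' @export
print.met_varcomp <- function(x, ...) {
  cat("Variance components (", x$method, ") for '", x$trait, "'\n", sep = "")
  cat("  sigma2_g   =", format(x$sigma2_g), "\n")
  cat("  sigma2_ge  =", format(x$sigma2_ge), "\n")
  cat("  sigma2_eps =", format(x$sigma2_eps), "\n")
  if (x$method == "em_reml")
    cat("  converged in", x$n_iterations, "iterations\n")
  invisible(x)
}

#' Predict genotypic values per environment by BLUP
#'
#' Solves Henderson's mixed model equations at the estimated variance
#' components and returns `GV_ij = mu_hat_j + BLUP(g_i) + BLUP(ge_ij)`,
#' the predicted genotypic value of genotype i in environment j (trait
#' units). A variance component of zero drops its random term (full
#' shrinkage); as `sigma2_g` grows the genotype BLUPs approach the raw
#' genotype-mean deviations (no shrinkage).
#'
#' @param vc a `met_varcomp` from [fit_varcomp()].
#' @param data the [met_dataset()] the components were estimated from.
#' @param trait trait selector; defaults to the component fit's trait.
#' @return Object of class `gv_table`: `gv` (genotype x environment
#'   matrix), `env_means` (observed environment means of cell means, the
#'   RPGV denominators), `genotype_blup`, `mu_hat`, `vc`,
#'   `nonpositive` (genotypes with any GV <= 0, for which harmonic
#'   statistics are undefined).
#' @export
predict_genotypic_values <- function(vc, data, trait = NULL) {
  stopifnot(inherits(vc, "met_varcomp"), inherits(data, "met_dataset"))
  if (is.null(trait)) trait <- vc$trait
  mf <- met_model_frame(data, trait)
  d <- met_design(mf)
  y <- mf$y
  G <- nlevels(mf$geno); E <- nlevels(mf$env)

  # A residual component of exactly zero would remove the MME ridge and
  # make the equations singular; floor it at a negligible positive value.
  s2e <- max(vc$sigma2_eps, 1e-10 * max(stats::var(y), 1e-12))
  Zs <- list(); lam <- numeric(0)
  if (vc$sigma2_g > 0) { Zs$g <- d$Zg; lam <- c(lam, s2e / vc$sigma2_g) }
  if (vc$sigma2_ge > 0) { Zs$ge <- d$Zge; lam <- c(lam, s2e / vc$sigma2_ge) }

  X <- d$X
  if (length(Zs) == 0) {
    beta <- solve(crossprod(X), crossprod(X, y))
    u_g <- rep(0, G); u_ge <- matrix(0, G, E)
  } else {
    Z <- do.call(cbind, Zs)
    ridge <- rep(lam, vapply(Zs, ncol, integer(1)))
    C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
               cbind(crossprod(Z, X), crossprod(Z) + diag(ridge)))
    rhs <- c(crossprod(X, y), crossprod(Z, y))
    sol <- solve(C, rhs)
    beta <- sol[seq_len(E)]
    u <- sol[-seq_len(E)]
    off <- 0
    if (vc$sigma2_g > 0) {
      u_g <- u[seq_len(G)]; off <- G
    } else u_g <- rep(0, G)
    if (vc$sigma2_ge > 0) {
      # ge levels are genotype-major (environment varies fastest)
      u_ge <- t(matrix(u[off + seq_len(G * E)], E, G))
    } else u_ge <- matrix(0, G, E)
  }

  gv <- outer(rep(1, G), as.vector(beta)) + outer(u_g, rep(1, E)) + u_ge
  dimnames(gv) <- list(levels(mf$geno), levels(mf$env))
  cellm <- tapply(y, list(mf$geno, mf$env), mean)
  env_means <- colMeans(cellm)
  nonpos <- rownames(gv)[apply(gv <= 0, 1, any)]
  if (length(nonpos) > 0)
    warning("nonpositive genotypic values for: ",
            paste(nonpos, collapse = ", "),
            "; harmonic statistics undefined for these genotypes")
  structure(
    list(gv = gv, env_means = env_means,
         genotype_blup = stats::setNames(u_g, levels(mf$geno)),
         mu_hat = mean(beta), vc = vc, trait = mf$col,
         nonpositive = nonpos),
    class = "gv_table")
}

#' @export
print.gv_table <- function(x, ...) {
  cat("BLUP genotypic values for '", x$trait, "': ", nrow(x$gv),
      " genotypes x ", ncol(x$gv), " environments\n", sep = "")
  invisible(x)
}

#' Harmonic-mean genotypic-value stability statistics
#'
#' From the predicted genotypic values `GV_ij` (all > 0) computes, per
#' genotype over the `e` environments:
#' HMGV = e / sum_j (1 / GV_ij), the harmonic mean of genotypic values
#' (performance plus stability, trait units);
#' RPGV = (1/e) sum_j (GV_ij / mu_j), the relative performance of
#' genotypic values (adaptability, dimensionless); and
#' HMRPGV = e / sum_j (mu_j / GV_ij), the harmonic mean of the relative
#' performances (yield, stability and adaptability simultaneously). The
#' environment references `mu_j` are the observed environment means.
#' Genotypes are ranked by HMRPGV descending, ties by name.
#'
#' @param gv a `gv_table` from [predict_genotypic_values()].
#' @return data.frame `genotype`, `HMGV`, `RPGV`, `HMRPGV`, `rank`,
#'   ordered by rank.
#' @export
hmgv_rpgv_hmrpgv <- function(gv) {
  stopifnot(inherits(gv, "gv_table"))
  if (length(gv$nonpositive) > 0)
    stop("harmonic statistics undefined (nonpositive genotypic values) ",
         "for: ", paste(gv$nonpositive, collapse = ", "))
  V <- gv$gv
  e <- ncol(V)
  mu_j <- gv$env_means
  hmgv <- e / rowSums(1 / V)
  rel <- sweep(V, 2, mu_j, "/")
  rpgv <- rowMeans(rel)
  hmrpgv <- e / rowSums(1 / rel)
  o <- order(-hmrpgv, rownames(V))
  data.frame(genotype = rownames(V)[o], HMGV = unname(hmgv[o]),
             RPGV = unname(rpgv[o]), HMRPGV = unname(hmrpgv[o]),
             rank = seq_len(nrow(V)), stringsAsFactors = FALSE)
}

#' One-call BLUP stability analysis
#'
#' Convenience wrapper: [fit_varcomp()], [predict_genotypic_values()] and
#' [hmgv_rpgv_hmrpgv()] in sequence.
#'
#' @inheritParams fit_varcomp
#' @return list with `varcomp`, `gv`, and the `stats` ranking table.
#' @export
blup_stability <- function(data, trait, method = c("auto", "anova", "em_reml")) {
  vc <- fit_varcomp(data, trait, method = method)
  gv <- predict_genotypic_values(vc, data, trait)
  list(varcomp = vc, gv = gv, stats = hmgv_rpgv_hmrpgv(gv))
}
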
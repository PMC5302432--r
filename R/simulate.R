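#' Simulation configuration for balanced MET datasets
#'
#' Defines the generative model of [generate_met()]:
#' yield_ijr = mu + g_i + e_j + Z_ij + eps_ijr with centred genotype and
#' environment effects, an exactly low-rank interaction Z built from
#' orthonormal score vectors scaled by the given singular values, and iid
#' Gaussian plot error. Mineral concentrations follow a dilution law,
#' conc = base * (mu / E[yield_ij])^dilution_exponent * (1 + eta) with
#' multiplicative noise of coefficient of variation `conc_cv`, floored at 0.
#'
#' Defaults emulate the published Ekhaga trial design: 19 genotypes x 3
#' year-environments x 2 replicates, overall yield near 3960 kg ha-1 with
#' genotype, environment and plot dispersions of 700, 600 and 450 kg ha-1,
#' a single interaction axis of 900 kg ha-1, population concentrations near
#' 43 (Fe), 36 (Zn), 5.3 (Cu) and 1200 (Mg) mg kg-1, and 4 of 19 genotypes
#' hulled (spelt/primitive).
#'
#' @param n_genotypes,n_environments,n_replicates positive integers.
#' @param mu_yield overall mean yield, kg ha-1.
#' @param sigma_g,sigma_env,sigma_eps genotype, environment and plot-error
#'   standard deviations, kg ha-1 (each >= 0).
#' @param interaction_lambdas nonnegative singular values of the interaction
#'   (kg ha-1); at most `min(n_genotypes, n_environments) - 1` of them.
#' @param minerals named list; each element a list with `base_conc`
#'   (mg kg-1), `dilution_exponent` (>= 0) and `conc_cv` (>= 0).
#' @param hulled_fraction fraction of genotypes flagged as hulled (grouped
#'   "Spelt"), in [0, 1].
#' @param seed integer RNG seed; the dataset is a pure function of the
#'   configuration including the seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genotypes = 19, n_environments = 3,
                       n_replicates = 2, mu_yield = 3960,
                       sigma_g = 700, sigma_env = 600, sigma_eps = 450,
                       interaction_lambdas = c(900),
                       minerals = list(
                         Fe = list(base_conc = 43, dilution_exponent = 0.5, conc_cv = 0.12),
                         Zn = list(base_conc = 36, dilution_exponent = 0.5, conc_cv = 0.12),
                         Cu = list(base_conc = 5.3, dilution_exponent = 0.5, conc_cv = 0.12),
                         Mg = list(base_conc = 1200, dilution_exponent = 0.3, conc_cv = 0.08)),
                       hulled_fraction = 4 / 19, seed = 1L) {
  stopifnot(n_genotypes >= 2, n_environments >= 2, n_replicates >= 1,
            sigma_g >= 0, sigma_env >= 0, sigma_eps >= 0,
            hulled_fraction >= 0, hulled_fraction <= 1)
  if (any(interaction_lambdas < 0))
    stop("interaction_lambdas must be nonnegative")
  if (length(interaction_lambdas) > min(n_genotypes, n_environments) - 1)
    stop("at most min(G, E) - 1 interaction singular values are allowed")
  if (length(minerals) == 0 || is.null(names(minerals)))
    stop("`minerals` must be a named list")
  for (m in names(minerals)) {
    spec <- minerals[[m]]
    if (spec$base_conc < 0 || spec$dilution_exponent < 0 || spec$conc_cv < 0)
      stop("invalid mineral spec for ", m)
  }
  structure(
    list(n_genotypes = n_genotypes, n_environments = n_environments,
         n_replicates = n_replicates, mu_yield = mu_yield,
         sigma_g = sigma_g, sigma_env = sigma_env, sigma_eps = sigma_eps,
         interaction_lambdas = interaction_lambdas, minerals = minerals,
         hulled_fraction = hulled_fraction, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Orthonormal n x k score matrix orthogonal to the ones vector: centred
# Gaussian draws followed by QR. Guarantees exactly zero row/column sums of
# the interaction and exact singular-value truth for oracle tests.
orthonormal_scores <- function(n, k) {
  A <- matrix(stats::rnorm(n * k), n, k)
  A <- sweep(A, 2, colMeans(A))
  qr.Q(qr(A))
}

#' Generate a balanced MET dataset with known ground truth
#'
#' Draws a dataset under the model described in [sim_config()] and returns
#' it together with the generating truth (effects, interaction scores,
#' expected cell means and concentrations), so downstream estimators can be
#' tested against known values.
#'
#' @param config a [sim_config()].
#' @return list with elements `data` (a [met_dataset()]) and `truth`
#'   (class `met_truth`: `genotype_effects`, `environment_effects`,
#'   `interaction` matrix, `lambdas`, `alpha`, `gamma`, `cell_means`,
#'   `expected_conc` per mineral, `seed`).
#' @export
#' @examples
#' sim <- generate_met(sim_config(seed = 42))
#' sim$data
generate_met <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  G <- config$n_genotypes; E <- config$n_environments; R <- config$n_replicates
  set.seed(config$seed)

  g <- stats::rnorm(G, 0, config$sigma_g); g <- g - mean(g)
  e <- stats::rnorm(E, 0, config$sigma_env); e <- e - mean(e)
  K <- length(config$interaction_lambdas)
  if (K > 0) {
    alpha <- orthonormal_scores(G, K)
    gamma <- orthonormal_scores(E, K)
    Z <- alpha %*% diag(config$interaction_lambdas, K, K) %*% t(gamma)
  } else {
    alpha <- matrix(0, G, 0); gamma <- matrix(0, E, 0)
    Z <- matrix(0, G, E)
  }
  cellmu <- config$mu_yield + outer(g, rep(1, E)) + outer(rep(1, G), e) + Z

  genotypes <- sprintf("G%02d", seq_len(G))
  environments <- sprintf("E%d", seq_len(E))
  n_hulled <- ceiling(config$hulled_fraction * G)
  groups <- c(rep("Spelt", n_hulled), rep("Old cultivar", G - n_hulled))

  idx <- expand.grid(replicate = seq_len(R), environment = seq_len(E),
                     genotype = seq_len(G))
  idx <- idx[order(idx$genotype, idx$environment, idx$replicate), ]
  n <- nrow(idx)
  ymu <- cellmu[cbind(idx$genotype, idx$environment)]
  yield <- pmax(ymu + stats::rnorm(n, 0, config$sigma_eps), 0)

  rec <- data.frame(genotype = genotypes[idx$genotype],
                    group = groups[idx$genotype],
                    environment = environments[idx$environment],
                    replicate = idx$replicate,
                    yield_kg_ha = yield,
                    stringsAsFactors = FALSE)

  expected_conc <- list()
  safe_mu <- pmax(cellmu, 1e-6)
  for (m in names(config$minerals)) {
    spec <- config$minerals[[m]]
    cmu <- spec$base_conc * (config$mu_yield / safe_mu)^spec$dilution_exponent
    expected_conc[[m]] <- cmu
    base_cell <- cmu[cbind(idx$genotype, idx$environment)]
    rec[[paste0("conc_", m, "_mg_kg")]] <-
      pmax(base_cell * (1 + stats::rnorm(n, 0, spec$conc_cv)), 0)
  }

  truth <- structure(
    list(genotype_effects = stats::setNames(g, genotypes),
         environment_effects = stats::setNames(e, environments),
         interaction = Z, lambdas = config$interaction_lambdas,
         alpha = alpha, gamma = gamma, cell_means = cellmu,
         expected_conc = expected_conc, seed = config$seed),
    class = "met_truth")
  list(data = met_dataset(rec, minerals = names(config$minerals)),
       truth = truth)
}
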
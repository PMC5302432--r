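#' Dehulling correction for hulled wheats
#'
#' Spelt and primitive wheats (einkorn, emmer) are harvested with hulls on;
#' their naked-grain yield is estimated as a fixed fraction (default 75%)
#' of the hulled yield. Non-hulled genotypes pass through unchanged.
#'
#' @param yield_raw recorded yield, kg ha-1 (>= 0).
#' @param is_hulled logical; apply the correction?
#' @param factor fraction of grain mass remaining after dehulling, (0, 1].
#' @return Corrected yield, kg ha-1. Vectorised over all arguments.
#' @export
#' @examples
#' dehull_adjust(4000, TRUE, 0.75)   # 3000
#' dehull_adjust(4000, FALSE, 0.75)  # 4000
dehull_adjust <- function(yield_raw, is_hulled, factor = 0.75) {
  if (any(factor <= 0 | factor > 1)) stop("`factor` must be in (0, 1]")
  if (any(yield_raw < 0)) stop("`yield_raw` must be >= 0")
  ifelse(is_hulled, factor * yield_raw, yield_raw)
}

#' Nutritional yield of a mineral
#'
#' The number of adults whose full daily recommended intake (DRI) of a
#' mineral can be met for a year from one hectare's harvest:
#' NY = yield * conc / (dri * year_days), with yield in kg ha-1 (dehulled
#' basis), concentration in mg kg-1 and DRI in mg day-1. The mg ha-1
#' produced divided by the mg adult-1 year-1 required.
#'
#' @param yield_adj dehull-corrected yield, kg ha-1 (>= 0).
#' @param conc mineral concentration, mg kg-1 wholemeal (>= 0).
#' @param dri daily recommended intake, mg day-1 (> 0).
#' @param year_days days per year (default 365).
#' @return Nutritional yield, adults ha-1 year-1. Vectorised.
#' @export
#' @examples
#' nutritional_yield(6920, 38.0, 12)   # 60.04 adults ha-1 year-1
nutritional_yield <- function(yield_adj, conc, dri, year_days = 365) {
  if (any(dri <= 0)) stop("`dri` must be > 0")
  if (any(yield_adj < 0) || any(conc < 0))
    stop("yield and concentration must be >= 0")
  yield_adj * conc / (dri * year_days)
}

#' Grams of wholemeal needed daily to reach 100% of a DRI
#'
#' Nutrient density expressed as the daily amount to consume:
#' 1000 * dri / conc grams.
#'
#' @param conc mineral concentration, mg kg-1 (> 0).
#' @param dri daily recommended intake, mg day-1.
#' @return grams day-1. Vectorised.
#' @export
#' @examples
#' amount_for_dri(49.0, 12)  # 244.9 g of Svale wholemeal for Fe
amount_for_dri <- function(conc, dri) {
  if (any(conc <= 0))
    stop("undefined nutrient density: concentration must be > 0")
  1000 * dri / conc
}

#' Append plot-level nutritional-yield columns to a dataset
#'
#' Applies the dehulling correction to each plot's yield (by genotype-group
#' membership in `config$hulled_groups`), then computes `ny_<mineral>` for
#' every mineral in `config$dri` present in the data. A `yield_adj_kg_ha`
#' column is added as well.
#'
#' @param data a [met_dataset()].
#' @param config an [analysis_config()].
#' @return The dataset with added columns.
#' @export
add_nutritional_yield <- function(data, config = analysis_config()) {
  stopifnot(inherits(data, "met_dataset"))
  missing_min <- setdiff(names(config$dri), data$minerals)
  if (length(missing_min) > 0)
    stop("configured mineral(s) not present in data: ",
         paste(missing_min, collapse = ", "))
  rec <- data$records
  hulled <- rec$group %in% config$hulled_groups
  rec$yield_adj_kg_ha <- dehull_adjust(rec$yield_kg_ha, hulled,
                                       config$dehulling_factor)
  for (m in names(config$dri)) {
    conc <- rec[[paste0("conc_", m, "_mg_kg")]]
    rec[[paste0("ny_", m)]] <- nutritional_yield(
      rec$yield_adj_kg_ha, conc, config$dri[[m]], config$year_days)
  }
  data$records <- rec
  data
}

#' Per-genotype trait means and standard deviations
#'
#' Averages plot-level values per genotype (over all environments and
#' replicates, the published Table-2 convention: the genotype mean
#' nutritional yield is the mean of per-plot nutritional yields, not the
#' formula applied to mean yield and mean concentration). SD is the sample
#' standard deviation (denominator N - 1).
#'
#' @param data a [met_dataset()], typically after
#'   [add_nutritional_yield()].
#' @param traits character vector of trait selectors (see [cell_means()]).
#' @return data.frame with `genotype`, `group`, `n`, and `mean_`/`sd_`
#'   columns per trait.
#' @export
genotype_summary <- function(data, traits) {
  stopifnot(inherits(data, "met_dataset"))
  rec <- data$records
  gf <- factor(rec$genotype, levels = data$genotypes)
  out <- data.frame(genotype = data$genotypes,
                    group = rec$group[match(data$genotypes, rec$genotype)],
                    n = as.integer(table(gf)),
                    stringsAsFactors = FALSE)
  for (tr in traits) {
    col <- resolve_trait(data, tr)
    out[[paste0("mean_", tr)]] <- as.numeric(tapply(rec[[col]], gf, mean))
    out[[paste0("sd_", tr)]] <- as.numeric(tapply(rec[[col]], gf, stats::sd))
  }
  out
}

#' Population means over genotype means
#'
#' The population summary of a trait is the unweighted mean of the
#' per-genotype means (each genotype counts once regardless of plot
#' counts).
#'
#' @param gs a genotype summary from [genotype_summary()].
#' @return named numeric vector, one entry per `mean_` column.
#' @export
population_summary <- function(gs) {
  cols <- grep("^mean_", names(gs), value = TRUE)
  stats::setNames(vapply(cols, function(cl) mean(gs[[cl]]), numeric(1)),
                  sub("^mean_", "", cols))
}

#' Pearson correlations among traits
#'
#' Correlations are computed on genotype x environment cell means (one
#' observation per cell), pairing traits cell-wise. Two-sided p-values come
#' from the t test of [stats::cor.test()]. A trait with zero variance
#' yields `NA` correlations, flagged by a warning.
#'
#' @param data a [met_dataset()].
#' @param traits character vector of at least two trait selectors.
#' @return list of class `trait_correlations` with matrices `r`, `p`, and
#'   the number of paired observations `n`.
#' @export
trait_correlations <- function(data, traits) {
  stopifnot(inherits(data, "met_dataset"), length(traits) >= 2)
  vals <- sapply(traits, function(tr) as.vector(cell_means(data, tr)$values))
  n <- nrow(vals)
  if (n < 3) stop("need at least 3 paired observations")
  k <- length(traits)
  r <- diag(1, k); p <- matrix(NA_real_, k, k); diag(p) <- 0
  dimnames(r) <- dimnames(p) <- list(traits, traits)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (stats::sd(vals[, i]) == 0 || stats::sd(vals[, j]) == 0) {
      warning("zero variance in trait pair (", traits[i], ", ", traits[j],
              "); correlation undefined")
      r[i, j] <- r[j, i] <- NA_real_
      next
    }
    ct <- stats::cor.test(vals[, i], vals[, j])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  structure(list(r = r, p = p, n = n), class = "trait_correlations")
}

#' @export
print.trait_correlations <- function(x, ...) {
  cat("Pearson correlations on", x$n, "genotype x environment cells\n")
  stars <- ifelse(!is.na(x$p) & x$p < 0.005, "***", "")
  m <- matrix(paste0(format(round(x$r, 2)), stars),
              nrow(x$r), dimnames = dimnames(x$r))
  print(m, quote = FALSE)
  cat("*** significant at p < 0.005\n")
  invisible(x)
}

# ANOVA table without the "essentially perfect fit" warning: only the sums
# of squares are consumed, which are exact for noise-free inputs.
quiet_anova <- function(fit) {
  withCallingHandlers(stats::anova(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' Genotype / environment / interaction variance attribution
#'
#' Two-way fixed-effects ANOVA sum-of-squares decomposition of a trait at
#' plot level, reported as proportions of the total SS for genotype,
#' environment, their interaction and residual. With a single replicate per
#' cell the interaction and residual are confounded: the additive model is
#' fitted and the remainder is reported as `ge_plus_residual` with a
#' warning.
#'
#' @param data a [met_dataset()], complete for the trait.
#' @param trait trait selector.
#' @return list of class `variance_partition` with `ss` (named sums of
#'   squares), `proportions` (summing to 1 when defined), `df`, and an
#'   `anova` table.
#' @export
variance_partition <- function(data, trait) {
  stopifnot(inherits(data, "met_dataset"))
  col <- resolve_trait(data, trait)
  rec <- data$records
  rec$genotype <- factor(rec$genotype, levels = data$genotypes)
  rec$environment <- factor(rec$environment, levels = data$environments)
  y <- rec[[col]]
  replicated <- nrow(rec) >
    length(data$genotypes) * length(data$environments)
  if (replicated) {
    fit <- stats::lm(y ~ genotype * environment, data = rec)
    an <- quiet_anova(fit)
    ss <- stats::setNames(an$`Sum Sq`,
                          c("genotype", "environment", "ge", "residual"))
  } else {
    warning("no replication: G x E and residual are confounded")
    fit <- stats::lm(y ~ genotype + environment, data = rec)
    an <- quiet_anova(fit)
    ss <- stats::setNames(an$`Sum Sq`,
                          c("genotype", "environment", "ge_plus_residual"))
  }
  total <- sum(ss)
  # relative floor: an all-constant trait gives SS at rounding-noise level
  tss_floor <- 1e-10 * length(y) * (mean(y)^2 + 1)
  props <- if (total > tss_floor) ss / total else {
    warning("total sum of squares is zero; proportions undefined")
    ss * NA_real_
  }
  structure(list(ss = ss, proportions = props,
                 df = stats::setNames(an$Df, names(ss)), anova = an),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("Variance attribution (proportion of total SS):\n")
  print(round(x$proportions, 3))
  invisible(x)
}
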
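#' Multi-environment trial dataset
#'
#' Validates and wraps a plot-level trial table: one row per genotype x
#' environment x replicate, with grain yield (kg ha-1 at 13% moisture) and
#' one concentration column per mineral (mg kg-1 wholemeal), named
#' `conc_<mineral>_mg_kg`.
#'
#' @param records data.frame with columns `genotype`, `group`,
#'   `environment`, `replicate`, `yield_kg_ha` and the concentration
#'   columns.
#' @param minerals optional character vector fixing the mineral order;
#'   inferred from the concentration columns when `NULL`.
#' @return An object of class `met_dataset`: the validated records plus the
#'   ordered mineral, genotype and environment lists and a `complete` flag
#'   (TRUE iff every genotype x environment cell has at least one record).
#' @export
#' @examples
#' df <- data.frame(genotype = c("A", "A", "B", "B"), group = "Cultivar",
#'                  environment = "2012", replicate = c(1, 2, 1, 2),
#'                  yield_kg_ha = c(4000, 4200, 3800, 3900),
#'                  conc_Fe_mg_kg = c(40, 41, 45, 44))
#' met_dataset(df)
met_dataset <- function(records, minerals = NULL) {
  records <- as.data.frame(records)
  required <- c("genotype", "group", "environment", "replicate", "yield_kg_ha")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  conc_cols <- grep("^conc_.+_mg_kg$", names(records), value = TRUE)
  inferred <- sub("^conc_", "", sub("_mg_kg$", "", conc_cols))
  if (is.null(minerals)) {
    minerals <- inferred
  } else {
    miss <- setdiff(minerals, inferred)
    if (length(miss) > 0)
      stop("no concentration column for mineral(s): ",
           paste(miss, collapse = ", "))
  }
  if (length(minerals) == 0)
    stop("dataset must contain at least one conc_<mineral>_mg_kg column")

  records$genotype <- as.character(records$genotype)
  records$group <- as.character(records$group)
  records$environment <- as.character(records$environment)
  records$replicate <- as.integer(records$replicate)
  records$yield_kg_ha <- as.double(records$yield_kg_ha)
  for (cc in conc_cols) records[[cc]] <- as.double(records[[cc]])
  if (any(is.na(records$replicate)) || any(records$replicate < 1))
    stop("`replicate` must be a positive integer")

  bad <- which(records$yield_kg_ha < 0)
  if (length(bad) > 0)
    stop("negative yield_kg_ha in row(s): ", paste(bad, collapse = ", "))
  for (m in minerals) {
    col <- paste0("conc_", m, "_mg_kg")
    bad <- which(records[[col]] < 0)
    if (length(bad) > 0)
      stop("negative ", col, " in row(s): ", paste(bad, collapse = ", "))
  }

  key <- paste(records$genotype, records$environment, records$replicate,
               sep = "\r")
  if (anyDuplicated(key) > 0) {
    d <- records[duplicated(key), , drop = FALSE]
    stop("duplicate (genotype, environment, replicate): ",
         paste(unique(paste(d$genotype, d$environment, d$replicate)),
               collapse = "; "))
  }

  # canonical byte-order sort: downstream matrices are then invariant to
  # the ordering of the input rows
  genotypes <- sort(unique(records$genotype), method = "radix")
  environments <- sort(unique(records$environment), method = "radix")
  n_cells <- nrow(unique(records[c("genotype", "environment")]))
  complete <- n_cells == length(genotypes) * length(environments)
  if (!complete)
    warning("incomplete genotype x environment layout: ", n_cells, " of ",
            length(genotypes) * length(environments), " cells observed")

  structure(
    list(records = records, minerals = minerals, genotypes = genotypes,
         environments = environments, complete = complete),
    class = "met_dataset"
  )
}

#' Read a plot-level trial table from CSV
#'
#' Comma-separated, header line, decimal point, UTF-8. Columns as in
#' [met_dataset()].
#'
#' @param path path to the CSV file.
#' @param minerals optional mineral subset/order, see [met_dataset()].
#' @param quiet suppress the record-count message.
#' @return A `met_dataset`.
#' @export
read_met <- function(path, minerals = NULL, quiet = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  data <- met_dataset(df, minerals = minerals)
  if (!quiet)
    message("read ", nrow(data$records), " plot records: ",
            length(data$genotypes), " genotypes x ",
            length(data$environments), " environments, minerals ",
            paste(data$minerals, collapse = "/"))
  data
}

#' Write a trial dataset to CSV at full precision
#'
#' Numeric columns are written with 17 significant digits so that a write
#' followed by [read_met()] reproduces every value exactly.
#'
#' @param data a `met_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_met <- function(data, path) {
  stopifnot(inherits(data, "met_dataset"))
  out <- data$records
  for (col in names(out))
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.met_dataset <- function(x, ...) {
  cat("MET dataset: ", nrow(x$records), " plots, ",
      length(x$genotypes), " genotypes x ", length(x$environments),
      " environments\n", sep = "")
  cat("  minerals: ", paste(x$minerals, collapse = ", "), "\n", sep = "")
  cat("  complete layout: ", x$complete, "\n", sep = "")
  invisible(x)
}

# Map a trait selector to a column of the records. Accepts a column name,
# "yield" (alias for yield_kg_ha), a mineral name (its concentration), or a
# mineral nutritional-yield column ny_<mineral> if present.
resolve_trait <- function(data, trait) {
  cols <- names(data$records)
  if (trait %in% cols) return(trait)
  if (trait == "yield") return("yield_kg_ha")
  if (trait %in% data$minerals) return(paste0("conc_", trait, "_mg_kg"))
  ny <- paste0("ny_", trait)
  if (ny %in% cols) return(ny)
  stop("trait '", trait, "' not found in dataset; have: ",
       paste(cols, collapse = ", "))
}

#' Genotype-by-environment cell means for one trait
#'
#' Each cell is the arithmetic mean over replicates; the replicate counts
#' are recorded alongside. Invariant to the ordering of the input rows.
#'
#' @param data a `met_dataset`.
#' @param trait trait selector: a record column name, `"yield"`, a mineral
#'   name (concentration), or a mineral with a computed `ny_` column.
#' @return An object of class `trait_matrix`: list with `values` and
#'   `rep_counts` (genotype x environment matrices) and `trait`.
#' @export
cell_means <- function(data, trait) {
  stopifnot(inherits(data, "met_dataset"))
  col <- resolve_trait(data, trait)
  rec <- data$records
  gf <- factor(rec$genotype, levels = data$genotypes)
  ef <- factor(rec$environment, levels = data$environments)
  counts <- table(gf, ef)
  if (any(counts == 0)) {
    idx <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop("empty cell: genotype '", data$genotypes[idx[1]],
         "' in environment '", data$environments[idx[2]], "'")
  }
  vals <- tapply(rec[[col]], list(gf, ef), mean)
  vals <- matrix(as.vector(vals), nrow(vals),
                 dimnames = list(data$genotypes, data$environments))
  cnt <- matrix(as.integer(counts), nrow(counts),
                dimnames = dimnames(vals))
  structure(list(values = vals, rep_counts = cnt, trait = col),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("Trait matrix for '", x$trait, "': ", nrow(x$values), " genotypes x ",
      ncol(x$values), " environments\n", sep = "")
  print(round(x$values, 2))
  invisible(x)
}
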
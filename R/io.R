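RESULT_COLUMNS <- c("scenario", "method", "beta", "mean_F", "median", "IQR",
                    "coverage_pct", "power_pct", "n_reps_used",
                    "mc_se_median", "mc_se_coverage")

#' Write a simulated dataset as CSV
#'
#' Columns are `id, g1..gJ, x, y`; the latent confounder `u` (and covariate
#' `v`, when present) are withheld unless `oracle = TRUE`, since they are
#' unobservable in a real study.
#'
#' @param dataset a `sim_dataset` (or compatible list).
#' @param path output path.
#' @param oracle include the latent `u` (and `v`) columns.
#' @return the path, invisibly.
#' @export
write_dataset_csv <- function(dataset, path, oracle = FALSE) {
  G <- dataset$genotypes
  df <- data.frame(id = seq_len(nrow(G)), G, x = dataset$x, y = dataset$y,
                   check.names = FALSE)
  if (oracle) {
    df$u <- dataset$u
    if (!is.null(dataset$v)) df$v <- dataset$v
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genotype-phenotype dataset from CSV
#'
#' Expects a header row with columns `id` (optional), genotype columns, `x`
#' and `y` (optionally `u`, `v`). Genotype columns are either declared via
#' `genotype_cols` or taken to be every column named `g<number>`. Genotype
#' entries must be dosages in \{0, 1, 2\} unless `dosage = TRUE`, which
#' admits continuous dosages in [0, 2] (e.g. imputed genotypes).
#'
#' @param path CSV path (comma-separated, `.` decimal, UTF-8).
#' @param genotype_cols optional character vector naming genotype columns.
#' @param dosage allow fractional dosages in [0, 2].
#' @return a list of class `sim_dataset` with `genotypes`, `x`, `y` and any
#'   latent columns present (`truth` is `NULL` for user data).
#' @export
read_dataset_csv <- function(path, genotype_cols = NULL, dosage = FALSE) {
  if (!file.exists(path)) stop("dataset file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (is.null(genotype_cols))
    genotype_cols <- grep("^g[0-9]+$", names(df), value = TRUE)
  missing_cols <- setdiff(c(genotype_cols, "x", "y"), names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  if (length(genotype_cols) == 0L)
    stop("no genotype columns found (expected g1, g2, ... or genotype_cols)",
         call. = FALSE)
  G <- as.matrix(df[genotype_cols])
  for (cn in c(genotype_cols, "x", "y"))
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))[1]
      stop(sprintf("non-numeric cell in column '%s' (row %d)", cn,
                   if (is.na(bad)) 1L else bad), call. = FALSE)
    }
  bad <- if (dosage) which(G < 0 | G > 2) else which(!(G %in% c(0, 1, 2)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(G))
    stop(sprintf("invalid genotype value %s at row %d, column '%s'%s",
                 format(G[bad[1]]), rc[1], genotype_cols[rc[2]],
                 if (dosage) " (must be in [0, 2])" else " (must be 0, 1 or 2)"),
         call. = FALSE)
  }
  structure(list(genotypes = G, x = df$x, y = df$y,
                 u = df[["u"]], v = df[["v"]], truth = NULL),
            class = "sim_dataset")
}

#' Write study results as CSV
#'
#' Writes a [run_table()]/[run_cell()] result with exactly the declared
#' column set, in order:
#' `scenario,method,beta,mean_F,median,IQR,coverage_pct,power_pct,n_reps_used,mc_se_median,mc_se_coverage`.
#'
#' @param table a results data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_results_csv <- function(table, path) {
  missing_cols <- setdiff(RESULT_COLUMNS, names(table))
  if (length(missing_cols))
    stop("results table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  utils::write.csv(table[RESULT_COLUMNS], path, row.names = FALSE)
  invisible(path)
}
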
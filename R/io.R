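# Readers and writers for the plain-text interchange formats.

#' Read a genetic map
#'
#' Tab-separated file with columns `marker`, `chr`, `pos` (cM).
#' @param path File path.
#' @return Data frame sorted by chromosome and position.
#' @export
read_genetic_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("marker", "chr", "pos") %in% names(map)))
  if (anyDuplicated(map$marker)) stop("duplicate marker ids in map")
  map[order(map$chr, map$pos), , drop = FALSE]
}

#' Read a genotype score matrix
#'
#' CSV with individuals in rows (first column = id) and markers in columns;
#' values 0/1/2 or empty for missing.
#' @param path File path.
#' @return Integer matrix with row names.
#' @export
read_genotypes <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(d)
}

#' Read a cross-design table
#'
#' CSV mapping each genotype to its cross and parents: columns `genotype`,
#' `cross`, `recurrent`, `donor`, optional `subpopulation`.
#' @param path File path.
#' @return Data frame.
#' @export
read_crosses <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("genotype", "cross", "recurrent", "donor") %in% names(d)))
  if (anyDuplicated(d$genotype)) stop("a genotype maps to several crosses")
  d
}

#' Read plot-level phenotypes
#'
#' Long-format CSV: `genotype`, `environment`, `value` plus optional
#' `cross`, `replicate`, `block`, `row`, `col`, `trait`.
#' @param path File path.
#' @return Data frame.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("genotype", "environment", "value") %in% names(d)))
  d
}

#' Read daily environmental covariate series
#'
#' CSV with columns `environment`, `day`, `ec`, `value`.
#' @param path File path.
#' @return Data frame.
#' @export
read_ec_daily <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("environment", "day", "ec", "value") %in% names(d)))
  d
}

#' Read a projection grid
#'
#' CSV with a `point` id, optional `lat`/`lon`, and one column per EC.
#' @param path File path.
#' @return Data frame.
#' @export
read_projection_grid <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a simulated BCNAM experiment to plain-text files
#'
#' Writes `genotypes.csv`, `map.tsv`, `crosses.csv`, `phenotypes.csv`,
#' `ec_daily.csv` and `truth.json` into a directory.
#'
#' @param sim A `bcnam_sim`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "bcnam_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("genotypes.csv", "map.tsv", "crosses.csv",
                            "phenotypes.csv", "ec_daily.csv", "truth.json"))
  utils::write.csv(data.frame(id = rownames(sim$genotypes), sim$genotypes,
                              check.names = FALSE),
                   paths[1], row.names = FALSE)
  utils::write.table(sim$map, paths[2], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.csv(sim$crosses, paths[3], row.names = FALSE)
  utils::write.csv(sim$phenotypes, paths[4], row.names = FALSE)
  utils::write.csv(sim$ec_daily, paths[5], row.names = FALSE)
  truth <- list(
    seed = sim$config$seed,
    vcov = sim$config$vcov,
    ec_values = sim$ec_values,
    qtl = lapply(sim$truth, function(q) {
      q$effect_by_env <- as.data.frame(q$effect_by_env)
      q
    }))
  jsonlite::write_json(truth, paths[6], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
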
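#' Validate a long-format phenotype table
#'
#' Checks and annotates the long-format table at the heart of the package:
#' one record per (population, genotype, plant, row, col, time, value), with
#' value possibly missing (`NA`). Verifies the three-level nesting (each
#' genotype belongs to exactly one population, each plant to exactly one
#' genotype), that each plant occupies a single (row, col) cell with no two
#' plants sharing a cell, and that no plant has two records at the same time.
#' Times are collected into the common measurement grid.
#'
#' Identifiers are treated as opaque strings; deterministic integer codes are
#' assigned in first-appearance order and stored as attributes together with
#' the dimension summary (`k`, `L`, `M`, `n`, `r`, `c`).
#'
#' @param table a data frame with columns `population`, `genotype`, `plant`,
#'   `row`, `col`, `time`, `value`, plus optional design-factor columns.
#' @param factors optional named character vector tagging extra columns with
#'   roles: `"condition"`, `"average"` or `"random"` (e.g.
#'   `c(lot = "average")`).
#' @return the table as a tibble of class `pheno_table`, with a `pheno_dims`
#'   attribute; retrieve it with [pheno_dims()].
#' @examples
#' tab <- tibble::tibble(
#'   population = "P1", genotype = rep(c("g1", "g2"), each = 4),
#'   plant = rep(sprintf("pl%d", 1:4), each = 2),
#'   row = rep(1:2, each = 4), col = rep(rep(1:2, each = 2), 2),
#'   time = rep(c(1, 2), 4), value = rnorm(8))
#' tab <- validate_pheno(tab)
#' pheno_dims(tab)
#' @export
validate_pheno <- function(table, factors = NULL) {
  needed <- c("population", "genotype", "plant", "row", "col", "time", "value")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  tab <- tibble::as_tibble(table)
  tab$population <- as.character(tab$population)
  tab$genotype <- as.character(tab$genotype)
  tab$plant <- as.character(tab$plant)
  if (!is.numeric(tab$row) || !is.numeric(tab$col)) {
    stop("row and col must be integer coordinates")
  }
  if (any(tab$row < 1 | tab$col < 1 | tab$row != round(tab$row) |
          tab$col != round(tab$col))) {
    stop("row and col must be positive integers (1-based grid coordinates)")
  }
  if (!is.numeric(tab$time) || any(!is.finite(tab$time))) {
    stop("time must be finite numeric")
  }

  # nesting: genotype -> exactly one population; plant -> exactly one genotype
  gp <- dplyr::distinct(tab, .data$genotype, .data$population)
  bad <- gp$genotype[duplicated(gp$genotype)]
  if (length(bad)) {
    stop("nesting violation: genotype(s) ", paste(unique(bad), collapse = ", "),
         " appear in more than one population")
  }
  pg <- dplyr::distinct(tab, .data$plant, .data$genotype)
  bad <- pg$plant[duplicated(pg$plant)]
  if (length(bad)) {
    stop("nesting violation: plant(s) ", paste(unique(bad), collapse = ", "),
         " appear in more than one genotype")
  }
  # each plant one cell; each cell at most one plant
  pc <- dplyr::distinct(tab, .data$plant, .data$row, .data$col)
  bad <- pc$plant[duplicated(pc$plant)]
  if (length(bad)) {
    stop("grid violation: plant(s) ", paste(unique(bad), collapse = ", "),
         " occupy more than one (row, col) cell")
  }
  cell <- paste(pc$row, pc$col, sep = ":")
  if (anyDuplicated(cell)) {
    stop("grid violation: two plants share cell(s) ",
         paste(unique(cell[duplicated(cell)]), collapse = ", "))
  }
  # at most one record per (plant, time)
  if (anyDuplicated(tab[c("plant", "time")])) {
    stop("duplicate (plant, time) record(s) found")
  }

  if (!is.null(factors)) {
    if (is.null(names(factors)) ||
        !all(factors %in% c("condition", "average", "random"))) {
      stop("factors must be a named vector with roles condition/average/random")
    }
    miss <- setdiff(names(factors), names(tab))
    if (length(miss)) stop("factor column(s) not in table: ",
                           paste(miss, collapse = ", "))
  }

  times <- sort(unique(tab$time))
  plants <- unique(tab$plant)
  genos <- unique(tab$genotype)
  pops <- unique(tab$population)
  dims <- list(
    k = length(pops), L = length(genos), M = length(plants),
    n = length(times), r = max(tab$row), c = max(tab$col),
    times = times, populations = pops, genotypes = genos, plants = plants,
    n_slots = length(plants) * length(times),
    factors = factors
  )
  attr(tab, "pheno_dims") <- dims
  class(tab) <- unique(c("pheno_table", class(tab)))
  tab
}

#' Dimension summary of a validated phenotype table
#'
#' @param table a table returned by [validate_pheno()].
#' @return list with `k` (populations), `L` (genotypes), `M` (plants),
#'   `n` (times), `r`, `c` (grid), the id vectors, and `n_slots = M * n`
#'   (the plant-by-time array size including missing slots).
#' @export
pheno_dims <- function(table) {
  d <- attr(table, "pheno_dims")
  if (is.null(d)) stop("not a validated pheno_table; run validate_pheno() first")
  d
}

#' Complete a phenotype table over the plant-by-time grid
#'
#' Expands the table so every (plant, time) slot is present, with `NA` value
#' and a `missing` flag where no record was observed. Plant-level metadata
#' (population, genotype, coordinates, design factors) is filled in.
#'
#' @param table a validated `pheno_table`.
#' @return tibble with one row per (plant, time) slot.
#' @export
complete_slots <- function(table) {
  d <- pheno_dims(table)
  meta_cols <- setdiff(names(table), c("time", "value"))
  meta <- dplyr::distinct(table[meta_cols])
  grid <- tidyr::expand_grid(plant = d$plants, time = d$times)
  out <- dplyr::left_join(grid, meta, by = "plant")
  out <- dplyr::left_join(out, table[c("plant", "time", "value")],
                          by = c("plant", "time"))
  out$missing <- is.na(out$value)
  attr(out, "pheno_dims") <- d
  class(out) <- unique(c("pheno_table", class(out)))
  out
}

#' Read a phenotype table from CSV
#'
#' Long format with header `population,genotype,plant,row,col,time,value`
#' plus optional design-factor columns. Empty fields or `NA` encode missing
#' values.
#'
#' @param path CSV file path.
#' @inheritParams validate_pheno
#' @export
read_pheno_csv <- function(path, factors = NULL) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_pheno(tab, factors = factors)
}
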
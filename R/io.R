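#' Read a pedigree file
#'
#' Reads a three-column table of trio records (individual, sire, dam).
#' Unknown parents may be coded `"0"`, `"NA"` or an empty string. The
#' pedigree is validated: ids must be unique, every named parent must
#' itself appear as an individual, and the parent-offspring graph must be
#' acyclic (so a topological order with parents before offspring exists).
#'
#' @param path Path to a CSV (or whitespace-delimited) file with columns
#'   id, sire, dam. A header line is expected for CSV input.
#' @return A `pedigree` object: a data.frame with character columns
#'   `id`, `sire`, `dam`, where `NA` marks an unknown parent.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                        strip.white = TRUE)
  if (ncol(df) < 3L) {
    stop("pedigree file must have three columns: id, sire, dam", call. = FALSE)
  }
  as_pedigree(df[, 1:3])
}

#' Construct and validate a pedigree
#'
#' @param df A data.frame whose first three columns are individual id,
#'   sire id and dam id (characters; `"0"`, `""`, `"NA"` or `NA` mean
#'   unknown).
#' @return A validated `pedigree` data.frame.
#' @export
as_pedigree <- function(df) {
  ped <- data.frame(
    id   = as.character(df[[1]]),
    sire = normalize_parent(df[[2]]),
    dam  = normalize_parent(df[[3]]),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ped$id)) {
    stop("duplicate individual id(s): ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "),
         call. = FALSE)
  }
  parents <- stats::na.omit(c(ped$sire, ped$dam))
  missing_par <- setdiff(parents, ped$id)
  if (length(missing_par)) {
    stop("parent id(s) not present as individuals: ",
         paste(utils::head(missing_par, 5), collapse = ", "), call. = FALSE)
  }
  # topological sort doubles as the cycle (incl. self-ancestry) check
  attr(ped, "topo_order") <- pedigree_order(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x %in% c("0", "", "NA")] <- NA_character_
  x
}

# Kahn's algorithm; returns row indices with parents before offspring,
# errors on any cycle (a self-ancestor is a 1-cycle).
pedigree_order <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  sire_i <- unname(idx[ped$sire])
  dam_i <- unname(idx[ped$dam])
  indeg <- (!is.na(sire_i)) + (!is.na(dam_i))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sire_i[i], dam_i[i])) {
      if (!is.na(p)) {
        if (p == i) stop("individual '", ped$id[i], "' is its own ancestor",
                         call. = FALSE)
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    i <- queue[[1]]; queue <- queue[-1]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != n) {
    stop("pedigree contains a cycle (an individual is its own ancestor)",
         call. = FALSE)
  }
  out
}

#' Write a pedigree to CSV
#'
#' Unknown parents are written as `"0"`.
#' @param ped A `pedigree`.
#' @param path Output file path.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(id = ped$id,
                    sire = ifelse(is.na(ped$sire), "0", ped$sire),
                    dam = ifelse(is.na(ped$dam), "0", ped$dam))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genotype matrix of allele counts
#'
#' Canonical dialect: CSV with a header of marker names, first column the
#' individual id, remaining entries allele counts in \{0, 1, 2\} or `NA`.
#' PLINK `.raw` additive coding is accepted by stripping its leading
#' metadata columns (FID/IID/PAT/MAT/SEX/PHENOTYPE).
#'
#' @param path Path to the genotype file.
#' @return A `genotype_table`: list with `ids`, integer matrix `counts`
#'   (individuals x markers, `NA` for missing) and `allele_freqs`, the
#'   per-marker reference-allele frequency computed from non-missing
#'   entries.
#' @export
read_genotypes <- function(path) {
  first <- readLines(path, n = 1L)
  plink <- grepl("^FID[ \t]", first)
  if (plink) {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    meta <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                      colnames(df))
    ids <- as.character(df[["IID"]])
    df <- df[, setdiff(colnames(df), meta), drop = FALSE]
  } else {
    df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  counts <- as.matrix(df)
  storage.mode(counts) <- "integer"
  rownames(counts) <- ids
  as_genotype_table(counts)
}

#' Construct a genotype table from a count matrix
#'
#' @param counts Integer matrix, individuals x markers, entries in
#'   \{0, 1, 2\} or `NA`; rownames are individual ids.
#' @return A `genotype_table` with allele frequencies recomputed from the
#'   non-missing entries.
#' @export
as_genotype_table <- function(counts) {
  if (is.null(rownames(counts))) {
    stop("genotype matrix must carry individual ids as rownames", call. = FALSE)
  }
  bad <- !(counts %in% c(0L, 1L, 2L, NA))
  if (any(bad)) {
    stop("genotype entries must be 0, 1, 2 or NA; found: ",
         paste(utils::head(unique(counts[bad]), 3), collapse = ", "),
         call. = FALSE)
  }
  n_obs <- colSums(!is.na(counts))
  if (any(n_obs == 0L)) {
    stop("marker(s) with all genotypes missing (allele frequency undefined): ",
         paste(utils::head(colnames(counts)[n_obs == 0L], 5), collapse = ", "),
         call. = FALSE)
  }
  p <- colMeans(counts, na.rm = TRUE) / 2
  g <- list(ids = rownames(counts), counts = counts, allele_freqs = p)
  class(g) <- "genotype_table"
  g
}

#' Write a genotype table to CSV
#' @param g A `genotype_table`.
#' @param path Output file path.
#' @export
write_genotypes <- function(g, path) {
  df <- data.frame(id = g$ids, g$counts, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Impute missing genotypes from marginal allele frequencies
#'
#' Each missing cell is replaced by the sum of two independent
#' Bernoulli(p_j) draws, p_j being the observed frequency of the marker's
#' reference allele — allele-level sampling consistent with the
#' Hardy-Weinberg assumption behind the genomic relationship matrix.
#' Allele frequencies are recomputed after imputation.
#'
#' @param g A `genotype_table`.
#' @param seed Integer seed; the result is reproducible given the seed.
#' @return A complete `genotype_table`.
#' @export
impute_missing <- function(g, seed) {
  miss <- which(is.na(g$counts))
  if (!length(miss)) return(g)
  counts <- g$counts
  p_cell <- g$allele_freqs[((miss - 1L) %/% nrow(counts)) + 1L]
  counts[miss] <- with_seed(seed, {
    stats::rbinom(length(miss), size = 2L, prob = p_cell)
  })
  as_genotype_table(counts)
}

#' Filter markers on minor allele frequency
#'
#' Removes markers whose minor allele frequency, `min(p, 1 - p)` on the
#' reference-allele frequency, is strictly below `threshold`. Marker
#' order is preserved. Impute before filtering: missing entries are not
#' allowed here.
#'
#' @param g A complete `genotype_table`.
#' @param threshold MAF threshold (default 0.05).
#' @return The filtered `genotype_table`.
#' @export
filter_maf <- function(g, threshold = 0.05) {
  if (anyNA(g$counts)) {
    stop("genotypes contain missing values; run impute_missing() first",
         call. = FALSE)
  }
  maf <- pmin(g$allele_freqs, 1 - g$allele_freqs)
  keep <- maf >= threshold
  if (!any(keep)) stop("all markers removed by the MAF filter", call. = FALSE)
  as_genotype_table(g$counts[, keep, drop = FALSE])
}

#' Read a management-unit assignment file
#'
#' @param path CSV with columns id, unit.
#' @return A `unit_assignment` data.frame with character columns `id`
#'   and `unit`.
#' @export
read_units <- function(path) {
  df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                        strip.white = TRUE)
  as_unit_assignment(df)
}

#' Construct and validate a management-unit assignment
#'
#' @param df Data.frame whose first two columns are individual id and
#'   unit label.
#' @return A validated `unit_assignment`.
#' @export
as_unit_assignment <- function(df) {
  ua <- data.frame(id = as.character(df[[1]]), unit = as.character(df[[2]]),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(ua$id)) {
    stop("individual(s) assigned to more than one unit: ",
         paste(unique(ua$id[duplicated(ua$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(ua$unit) | ua$unit == "")) {
    stop("empty unit label", call. = FALSE)
  }
  class(ua) <- c("unit_assignment", "data.frame")
  ua
}

#' Write a unit assignment to CSV
#' @param units A `unit_assignment`.
#' @param path Output file path.
#' @export
write_units <- function(units, path) {
  utils::write.csv(as.data.frame(units)[, c("id", "unit")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
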
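#' Construct a genotype matrix
#'
#' The central data structure of the package: a sample-by-locus matrix of
#' biallelic dosages (counts of the alternate allele, 0/1/2, `NA` for a
#' missing call) carrying per-locus scaffold and 1-based position
#' annotations.
#'
#' @param dosage integer matrix, samples in rows (rownames = sample ids),
#'   loci in columns (colnames = locus ids); values in `{0, 1, 2, NA}`.
#' @param scaffold character vector, one scaffold id per locus.
#' @param position integer vector, 1-based base-pair coordinate per locus.
#' @return An object of class `genotype_matrix`: the dosage matrix with
#'   `scaffold` and `position` attributes.
#' @export
genotype_matrix <- function(dosage, scaffold, position) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("dosage matrix must have sample rownames and locus colnames")
  if (anyDuplicated(rownames(dosage)))
    stop("duplicate sample ids")
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  if (length(scaffold) != ncol(dosage) || length(position) != ncol(dosage))
    stop("scaffold/position length must equal the number of loci")
  position <- as.integer(position)
  if (any(position < 1L)) stop("positions must be positive (1-based)")
  if (anyDuplicated(paste(scaffold, position)))
    stop("(scaffold, position) pairs must be unique")
  structure(dosage,
            scaffold = as.character(scaffold),
            position = position,
            class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci on %d scaffold(s); %.2f%% missing\n",
              nrow(x), ncol(x), length(unique(attr(x, "scaffold"))),
              100 * mean(is.na(x))))
  invisible(x)
}

#' Subset a genotype matrix, keeping locus annotations in step
#' @param x a `genotype_matrix`.
#' @param i,j sample and locus indices.
#' @param ... ignored.
#' @param drop ignored; dimensions are always kept.
#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  scaf <- attr(x, "scaffold"); pos <- attr(x, "position")
  m <- unclass(x)
  attr(m, "scaffold") <- NULL; attr(m, "position") <- NULL
  if (missing(i)) i <- seq_len(nrow(m))
  if (missing(j)) j <- seq_len(ncol(m))
  out <- m[i, j, drop = FALSE]
  if (is.character(j)) j <- match(j, colnames(m))
  if (is.logical(j)) j <- which(j)
  structure(out, scaffold = scaf[j], position = pos[j],
            class = c("genotype_matrix", "matrix", "array"))
}

loci_info <- function(g) {
  data.frame(locus = colnames(g),
             scaffold = attr(g, "scaffold"),
             position = attr(g, "position"),
             stringsAsFactors = FALSE)
}

#' Validate a population map against a genotype matrix
#'
#' A population map assigns every sample to a population, every population
#' to a region (lineage), and carries per-sample coordinates in decimal
#' degrees.
#'
#' @param map data.frame with columns `sample`, `population`, `region`,
#'   `lat`, `lon`.
#' @param g optional `genotype_matrix`; if given, every genotyped sample
#'   must be present in the map.
#' @return the map, invisibly, after validation.
#' @export
validate_popmap <- function(map, g = NULL) {
  need <- c("sample", "population", "region", "lat", "lon")
  if (!all(need %in% names(map)))
    stop("population map must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(map$sample)) stop("duplicate samples in population map")
  p2r <- unique(map[, c("population", "region")])
  if (anyDuplicated(p2r$population))
    stop("each population must belong to exactly one region")
  if (!is.null(g)) {
    missing_samples <- setdiff(rownames(g), map$sample)
    if (length(missing_samples))
      stop("samples absent from population map: ",
           paste(utils::head(missing_samples, 5), collapse = ", "))
  }
  invisible(map)
}

# map aligned to the rows of g (drops map rows without genotypes)
align_map <- function(g, map) {
  validate_popmap(map, g)
  map[match(rownames(g), map$sample), , drop = FALSE]
}
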
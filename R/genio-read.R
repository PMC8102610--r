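#' Read a genotype matrix from VCF or a dosage CSV
#'
#' VCF input (via vcfR) keeps biallelic SNP records only; multi-allelic
#' records are dropped with a message. Dosage is the count of alternate
#' alleles in the GT field; `./.` (or `.`) is missing. Matrix input is a
#' CSV with sample rows, locus columns and values 0/1/2/NA, optionally
#' accompanied by `<path>.loci.csv` (locus, scaffold, position); without
#' it, loci are placed on a single synthetic scaffold 10 kb apart.
#'
#' @param path file path.
#' @param format `"vcf"` or `"matrix"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    biallelic <- vcfR::is.biallelic(v) & nchar(fix[, "REF"]) == 1 &
      nchar(fix[, "ALT"]) == 1 & !is.na(fix[, "ALT"])
    n_drop <- sum(!biallelic)
    if (n_drop > 0)
      message(n_drop, " non-biallelic-SNP record(s) dropped")
    v <- v[biallelic, ]
    fix <- vcfR::getFIX(v)
    gt <- vcfR::extract.gt(v, element = "GT")
    first <- substr(gt, 1, 1)
    third <- substr(gt, 3, 3)
    dos <- (first == "1") + (third == "1")
    dos[first == "." | third == "." | is.na(gt)] <- NA_integer_
    ids <- fix[, "ID"]
    ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
    dosage <- t(dos)
    colnames(dosage) <- ids
    genotype_matrix(dosage, fix[, "CHROM"], as.integer(fix[, "POS"]))
  } else {
    m <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(m)
    loci_path <- paste0(path, ".loci.csv")
    if (file.exists(loci_path)) {
      li <- utils::read.csv(loci_path, stringsAsFactors = FALSE)
      li <- li[match(colnames(m), li$locus), ]
      genotype_matrix(m, li$scaffold, li$position)
    } else {
      genotype_matrix(m, rep("scaffold_1", ncol(m)),
                      seq_len(ncol(m)) * 10000L)
    }
  }
}

#' Write a genotype matrix
#'
#' `write_genotypes()` writes either a minimal VCF v4.2 (GT field only,
#' `./.` for missing, REF=A/ALT=T placeholders) or a dosage CSV plus a
#' `.loci.csv` sidecar, such that [read_genotypes()] round-trips the
#' dosages exactly.
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @param format `"vcf"` or `"matrix"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("vcf", "matrix")) {
  format <- match.arg(format)
  if (format == "vcf") {
    li <- loci_info(g)
    gt <- t(unclass(g))
    gtc <- matrix("./.", nrow(gt), ncol(gt))
    gtc[gt == 0L] <- "0/0"; gtc[gt == 1L] <- "0/1"; gtc[gt == 2L] <- "1/1"
    body <- paste(li$scaffold, li$position, li$locus, "A", "T", ".", "PASS",
                  ".", "GT",
                  apply(gtc, 1, paste, collapse = "\t"), sep = "\t")
    header <- c("##fileformat=VCFv4.2",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", rownames(g)), collapse = "\t"))
    writeLines(c(header, body), path)
  } else {
    utils::write.csv(as.data.frame(unclass(g)), path, row.names = TRUE)
    utils::write.csv(loci_info(g), paste0(path, ".loci.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read and write the population map and environment tables
#'
#' Plain CSVs: the population map has columns sample, population, region,
#' lat, lon; the environment table has a sample column followed by five
#' continuous variables.
#'
#' @param path file path.
#' @return a data.frame.
#' @export
read_popmap <- function(path) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_popmap(map)
  map
}

#' @rdname read_popmap
#' @export
read_env <- function(path) {
  env <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample" %in% names(env)) stop("environment table needs a sample column")
  vars <- setdiff(names(env), "sample")
  if (any(!vapply(env[vars], is.numeric, logical(1))))
    stop("environmental variables must be numeric")
  if (any(!is.finite(as.matrix(env[vars]))))
    stop("environmental variables must be finite and non-missing")
  env
}
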
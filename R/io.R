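# Delimited-text readers and writers for maps, genotypes and phenotypes.
# All writers emit a provenance header (package version, date, and any
# key = value pairs such as seeds) as '#' comment lines; readers skip them.

provenance_header <- function(...) {
  extra <- list(...)
  lines <- c(paste0("# mtmim ", as.character(utils::packageVersion("mtmim"))),
             paste0("# written ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  if (length(extra))
    lines <- c(lines, paste0("# ", names(extra), " = ",
                             vapply(extra, as.character, character(1))))
  lines
}

write_with_header <- function(df, path, ...) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(...), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
}

#' Write / read a linkage map
#'
#' CSV with columns `marker`, `chromosome`, `position_cM` and a provenance
#' header in `#` comment lines.
#'
#' @param map a [linkage_map()].
#' @param path file path.
#' @param ... extra `key = value` pairs for the provenance header.
#' @export
write_linkage_map <- function(map, path, ...) {
  write_with_header(data.frame(marker = map$marker, chromosome = map$chr,
                               position_cM = map$pos), path, ...)
}

#' @rdname write_linkage_map
#' @export
read_linkage_map <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("marker", "chromosome", "position_cM")
  if (!all(need %in% names(df)))
    stop("map file must have columns ", paste(need, collapse = ", "))
  linkage_map(df$marker, df$chromosome, df$position_cM)
}

#' Write / read backcross genotypes
#'
#' CSV with one row per subject and one column per marker; values
#' 0 (heterozygote Qq), 1 (homozygote QQ) or NA.
#'
#' @param geno a [bc_genotypes()] matrix.
#' @param path file path.
#' @param ... provenance header pairs.
#' @export
write_genotypes <- function(geno, path, ...) {
  write_with_header(as.data.frame(unclass(geno)), path, ...)
}

#' @rdname write_genotypes
#' @param map the [linkage_map()] the genotypes belong to.
#' @export
read_genotypes <- function(path, map) {
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  x <- as.matrix(df)
  bad <- which(!(x %in% c(0, 1)) & !is.na(x), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("invalid genotype value at row ", bad[1, 1], ", column '",
         colnames(x)[bad[1, 2]], "' (expected 0, 1 or NA)")
  bc_genotypes(x, map)
}

#' Write / read phenotypes
#'
#' CSV with one row per subject and one column per trait; missing cells are
#' rejected on read (the model requires complete phenotypes).
#'
#' @param Y `n x T` phenotype matrix.
#' @param path file path.
#' @param ... provenance header pairs.
#' @export
write_phenotypes <- function(Y, path, ...) {
  write_with_header(as.data.frame(Y), path, ...)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  Y <- as.matrix(df)
  if (anyNA(Y)) {
    idx <- which(is.na(Y), arr.ind = TRUE)
    stop("missing phenotype at subject ", idx[1, 1], ", trait '",
         colnames(Y)[idx[1, 2]], "': the model requires complete phenotypes")
  }
  storage.mode(Y) <- "double"
  Y
}

#' Read and cross-validate a full dataset
#'
#' @param map_path,geno_path,pheno_path file paths written by the
#'   corresponding writers.
#' @param quiet suppress the summary message.
#' @return list with `map`, `geno`, `pheno`.
#' @export
read_dataset <- function(map_path, geno_path, pheno_path, quiet = FALSE) {
  map <- read_linkage_map(map_path)
  geno <- read_genotypes(geno_path, map)
  pheno <- read_phenotypes(pheno_path)
  if (nrow(geno) != nrow(pheno))
    stop("subject-count mismatch: ", nrow(geno), " genotyped vs ",
         nrow(pheno), " phenotyped")
  if (!quiet)
    message(sprintf(
      "dataset: n = %d subjects, %d traits, %d markers on %d chromosomes, %.1f%% missing genotypes",
      nrow(geno), ncol(pheno), nrow(map), length(unique(map$chr)),
      100 * mean(is.na(geno))))
  list(map = map, geno = geno, pheno = pheno)
}
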
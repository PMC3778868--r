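#' Backcross marker genotypes
#'
#' Observed marker genotypes for a backcross population: 1 = homozygote QQ,
#' 0 = heterozygote Qq, NA = missing. Columns follow the marker order of the
#' attached linkage map.
#'
#' @param x integer/numeric matrix, subjects in rows, markers in columns;
#'   entries in \{0, 1, NA\}. Column names, when present, must match the map's
#'   marker names.
#' @param map a [linkage_map()].
#' @return a matrix of class `"bc_genotypes"` with the map attached as an
#'   attribute.
#' @export
bc_genotypes <- function(x, map) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(map))
    stop("genotype matrix has ", ncol(x), " columns but the map has ",
         nrow(map), " markers")
  bad <- !(x %in% c(0, 1)) & !is.na(x)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("invalid genotype code at subject ", idx[1], ", marker ", idx[2],
         " (expected 0 = Qq, 1 = QQ, or NA)")
  }
  if (!is.null(colnames(x)) && !identical(colnames(x), map$marker)) {
    if (!setequal(colnames(x), map$marker))
      stop("genotype column names do not match the map's marker names")
    x <- x[, map$marker, drop = FALSE]
  }
  storage.mode(x) <- "integer"
  colnames(x) <- map$marker
  structure(x, map = map, class = c("bc_genotypes", class(unclass(x))))
}

#' Cockerham genotype coding for a backcross
#'
#' Codes latent QTL genotypes as +1/2 (homozygote QQ) and -1/2 (heterozygote
#' Qq), the orthogonal scaling under which a backcross locus has genotypic
#' variance 1/4.
#'
#' @param genotype character (`"QQ"`/`"Qq"`) or the 1/0 coding used by
#'   [bc_genotypes()].
#' @return numeric vector of codes in \{+0.5, -0.5\}.
#' @export
cockerham_code <- function(genotype) {
  if (is.character(genotype)) {
    if (!all(genotype %in% c("QQ", "Qq")))
      stop("genotype must be 'QQ' or 'Qq'")
    g <- as.integer(genotype == "QQ")
  } else {
    if (any(is.na(genotype)))
      stop("cannot code a missing genotype: coding applies to latent QTL genotypes")
    if (!all(genotype %in% c(0, 1))) stop("genotype codes must be 0 or 1")
    g <- as.integer(genotype)
  }
  ifelse(g == 1L, 0.5, -0.5)
}
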
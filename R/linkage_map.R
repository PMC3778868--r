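#' Linkage map
#'
#' A genetic linkage map: ordered markers with chromosome assignments and
#' positions in centiMorgans on the Haldane scale, 0-based from the first
#' marker of each chromosome.
#'
#' @param marker character vector of genome-wide unique marker names.
#' @param chr chromosome identifiers (coerced to character; order of first
#'   appearance is kept).
#' @param pos positions in cM, strictly increasing within each chromosome.
#' @return a `data.frame` of class `"linkage_map"` with columns
#'   `marker`, `chr`, `pos`.
#' @export
linkage_map <- function(marker, chr, pos) {
  chr <- as.character(chr)
  marker <- as.character(marker)
  pos <- as.numeric(pos)
  if (length(marker) != length(chr) || length(chr) != length(pos))
    stop("marker, chr and pos must have equal length")
  if (anyDuplicated(marker)) stop("marker names must be unique genome-wide")
  if (any(pos < 0)) stop("marker positions must be non-negative")
  chr_levels <- unique(chr)
  ord <- order(match(chr, chr_levels), pos)
  out <- data.frame(marker = marker[ord], chr = chr[ord], pos = pos[ord],
                    stringsAsFactors = FALSE)
  for (cc in chr_levels) {
    p <- out$pos[out$chr == cc]
    if (any(diff(p) <= 0))
      stop("marker positions must be strictly increasing within chromosome ", cc)
  }
  class(out) <- c("linkage_map", "data.frame")
  out
}

#' @export
print.linkage_map <- function(x, ...) {
  cat("Linkage map:", length(unique(x$chr)), "chromosomes,",
      nrow(x), "markers\n")
  spans <- tapply(x$pos, x$chr, function(p) diff(range(p)))
  cat("  spans (cM):", paste(names(spans), format(spans), sep = ":",
                             collapse = ", "), "\n")
  invisible(x)
}

map_chromosomes <- function(map) unique(map$chr)

#' Genome evaluation grid
#'
#' Builds the ordered set of genome positions at which putative QTL are
#' evaluated: a regular grid (default 1 cM) within the marker span of each
#' chromosome, always including the marker positions themselves.
#'
#' @param map a [linkage_map()].
#' @param step grid step in cM (default 1).
#' @return a `data.frame` of class `"genome_grid"` with columns `chr`, `pos`,
#'   `is_marker` and `interval` (index of the marker interval the point falls
#'   in; points at markers carry the index of the interval they close).
#' @export
genome_grid <- function(map, step = 1) {
  if (step <= 0) stop("grid step must be positive")
  pieces <- lapply(unique(map$chr), function(cc) {
    mp <- map$pos[map$chr == cc]
    p <- sort(unique(c(seq(mp[1], mp[length(mp)], by = step), mp)))
    data.frame(chr = cc, pos = p,
               is_marker = p %in% mp,
               interval = findInterval(p, mp, rightmost.closed = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "step") <- step
  class(out) <- c("genome_grid", "data.frame")
  out
}

# index of the grid row for a (chr, pos) pair; error when absent
grid_index <- function(grid, chr, pos, tol = 1e-8) {
  i <- which(grid$chr == as.character(chr) & abs(grid$pos - pos) < tol)
  if (length(i) != 1)
    stop("position ", chr, ":", pos, " is not a grid point")
  i
}

# marker-interval id of an arbitrary chromosome position (not necessarily a
# grid point); positions exactly at a marker get the closing interval index,
# with is_marker flag returned alongside
position_interval <- function(map, chr, pos) {
  mp <- map$pos[map$chr == as.character(chr)]
  if (length(mp) == 0) stop("unknown chromosome ", chr)
  if (pos < mp[1] || pos > mp[length(mp)])
    stop("position ", pos, " outside the marker span of chromosome ", chr)
  list(interval = findInterval(pos, mp, rightmost.closed = TRUE),
       at_marker = any(abs(mp - pos) < 1e-8))
}

# TRUE when two positions on one chromosome lie strictly inside the same
# marker interval (where the product-form mixing probabilities break down)
same_open_interval <- function(map, chr1, pos1, chr2, pos2) {
  if (as.character(chr1) != as.character(chr2)) return(FALSE)
  a <- position_interval(map, chr1, pos1)
  b <- position_interval(map, chr2, pos2)
  !a$at_marker && !b$at_marker && a$interval == b$interval
}
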
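#' Genome layout: autosome lengths and a linkage map
#'
#' A `genome_layout` holds the ordered autosome names, their physical lengths
#' in bp, and a per-chromosome linkage map given as anchors of
#' (physical position bp, cumulative cM). The summed autosome length is the
#' denominator of every F_ROH estimate, and the map anchors are the single
#' source of truth for physical <-> genetic coordinate conversion used by
#' both the tract simulator and the ROH age dating.
#'
#' @param chrom character vector of chromosome names (ordered).
#' @param length numeric vector of chromosome lengths in bp (> 0).
#' @param map data.frame with columns `chrom`, `pos` (bp) and `cM`
#'   (cumulative genetic position). Each chromosome needs at least two
#'   anchors, strictly increasing in `pos` and non-decreasing in `cM`.
#'   If `NULL`, a uniform map is built with [uniform_map()] at
#'   `cM_per_mb` cM/Mb.
#' @param cM_per_mb recombination rate for the default uniform map.
#' @return an object of class `genome_layout` with elements `chrom`
#'   (data.frame `chrom`, `length`) and `map`.
#' @examples
#' gl <- genome_layout(c("chr1", "chr2"), c(50e6, 40e6))
#' genetic_pos(gl, "chr1", 10e6)
#' @export
genome_layout <- function(chrom, length, map = NULL, cM_per_mb = 1) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != base::length(length))
    stop("'chrom' and 'length' must have equal length")
  if (anyDuplicated(chrom)) stop("duplicated chromosome names")
  if (any(!is.finite(length)) || any(length <= 0))
    stop("chromosome lengths must be positive and finite")
  obj <- structure(
    list(chrom = data.frame(chrom = chrom, length = length,
                            stringsAsFactors = FALSE),
         map = NULL),
    class = "genome_layout")
  if (is.null(map)) {
    obj <- uniform_map(obj, cM_per_mb)
  } else {
    obj$map <- validate_map(map, obj$chrom)
  }
  obj
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosomes, %.1f Mb total, %.1f cM map\n",
              nrow(x$chrom), sum(x$chrom$length) / 1e6,
              sum(vapply(split(x$map$cM, x$map$chrom),
                         function(z) max(z) - min(z), 0))))
  invisible(x)
}

#' Attach a uniform linkage map to a layout
#'
#' Places two anchors per chromosome, at position 0 and the chromosome end,
#' giving a constant recombination rate.
#'
#' @param layout a `genome_layout`.
#' @param cM_per_mb recombination rate in cM per Mb.
#' @return the layout with `map` replaced.
#' @export
uniform_map <- function(layout, cM_per_mb = 1) {
  stopifnot(inherits(layout, "genome_layout"), cM_per_mb >= 0)
  ch <- layout$chrom
  layout$map <- data.frame(
    chrom = rep(ch$chrom, each = 2),
    pos = as.numeric(rbind(0, ch$length)),
    cM = as.numeric(rbind(0, ch$length * cM_per_mb / 1e6)),
    stringsAsFactors = FALSE)
  layout
}

validate_map <- function(map, chrom_tab) {
  need <- c("chrom", "pos", "cM")
  if (!all(need %in% names(map)))
    stop("map must have columns chrom, pos, cM")
  map <- map[order(match(map$chrom, chrom_tab$chrom), map$pos), need]
  map$chrom <- as.character(map$chrom)
  if (!all(map$chrom %in% chrom_tab$chrom))
    stop("map references unknown chromosomes: ",
         paste(setdiff(map$chrom, chrom_tab$chrom), collapse = ", "))
  for (cc in unique(map$chrom)) {
    sub <- map[map$chrom == cc, ]
    if (nrow(sub) < 2)
      stop("chromosome ", cc, " has fewer than 2 map anchors")
    if (any(diff(sub$pos) <= 0))
      stop("map positions not strictly increasing on ", cc,
           " near pos ", sub$pos[which(diff(sub$pos) <= 0)[1] + 1])
    if (any(diff(sub$cM) < 0))
      stop("decreasing cM on ", cc,
           " at pos ", sub$pos[which(diff(sub$cM) < 0)[1] + 1])
  }
  rownames(map) <- NULL
  map
}

#' Read a linkage map from TSV
#'
#' Expects a tab-separated file with header columns `chrom`, `pos`
#' (physical bp) and `cM` (cumulative genetic position). Rows are sorted on
#' load; a chromosome whose sorted cM values decrease is rejected with an
#' error naming the offending position.
#'
#' @param path file path.
#' @param layout optional `genome_layout`; when supplied the map is attached
#'   and the layout returned, otherwise the validated anchor data.frame is
#'   returned.
#' @export
read_linkage_map <- function(path, layout = NULL) {
  map <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (is.null(layout)) {
    tab <- data.frame(chrom = unique(as.character(map$chrom)))
    tab$length <- vapply(tab$chrom,
                         function(cc) max(map$pos[map$chrom == cc]), 0)
    validate_map(map, tab)
  } else {
    layout$map <- validate_map(map, layout$chrom)
    layout
  }
}

#' Write a linkage map to TSV
#' @param layout a `genome_layout`.
#' @param path output file path.
#' @export
write_linkage_map <- function(layout, path) {
  utils::write.table(layout$map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

map_anchors <- function(layout, chrom) {
  sub <- layout$map[layout$map$chrom == chrom, ]
  if (nrow(sub) == 0) stop("no map anchors for chromosome ", chrom)
  sub
}

#' Physical to genetic position
#'
#' Piecewise-linear interpolation of the map anchors. Positions outside the
#' anchored range are clamped to the terminal anchor cM values; the number of
#' clamped queries is returned in attribute `n_clamped`.
#'
#' @param layout a `genome_layout`.
#' @param chrom single chromosome name.
#' @param pos numeric vector of physical positions (bp).
#' @return numeric vector of cumulative cM, with attribute `n_clamped`.
#' @export
genetic_pos <- function(layout, chrom, pos) {
  a <- map_anchors(layout, chrom)
  out <- stats::approx(a$pos, a$cM, xout = pos, rule = 2, ties = "ordered")$y
  attr(out, "n_clamped") <- sum(pos < min(a$pos) | pos > max(a$pos))
  out
}

#' Genetic to physical position
#'
#' Inverse interpolation of the map anchors (first matching physical
#' position on zero-recombination plateaus). Values outside the map range
#' are clamped to the chromosome's terminal anchors.
#'
#' @inheritParams genetic_pos
#' @param cM numeric vector of cumulative genetic positions.
#' @export
physical_pos <- function(layout, chrom, cM) {
  a <- map_anchors(layout, chrom)
  keep <- !duplicated(a$cM)  # plateau -> earliest bp
  stats::approx(a$cM[keep], a$pos[keep], xout = cM, rule = 2,
                ties = "ordered")$y
}

chrom_length <- function(layout, chrom) {
  layout$chrom$length[match(chrom, layout$chrom$chrom)]
}

#' Total genome length of a layout
#' @param layout a `genome_layout`.
#' @return total bp across chromosomes.
#' @export
genome_size <- function(layout) sum(layout$chrom$length)
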
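#' Merge intervals (0-based half-open)
#'
#' Sorts and unions overlapping or adjacent intervals per chromosome.
#' @param bed data.frame `chrom`, `start`, `end` (0-based half-open).
#' @export
merge_intervals <- function(bed) {
  if (is.null(bed) || nrow(bed) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  bed <- bed[order(bed$chrom, bed$start, bed$end), c("chrom", "start", "end")]
  out <- NULL
  for (cc in unique(bed$chrom)) {
    b <- bed[bed$chrom == cc, ]
    s <- b$start[1]; e <- b$end[1]
    for (i in seq_len(nrow(b))[-1]) {
      if (b$start[i] <= e) e <- max(e, b$end[i])
      else { out <- rbind(out, data.frame(chrom = cc, start = s, end = e))
             s <- b$start[i]; e <- b$end[i] }
    }
    out <- rbind(out, data.frame(chrom = cc, start = s, end = e))
  }
  rownames(out) <- NULL
  out
}

#' Expand intervals by a flank and clip to chromosome bounds
#' @param bed data.frame `chrom`, `start`, `end` (0-based half-open).
#' @param flank bp added on both sides.
#' @param layout a `genome_layout` for clipping.
#' @export
flank_intervals <- function(bed, flank, layout) {
  if (is.null(bed) || nrow(bed) == 0) return(bed)
  L <- chrom_length(layout, bed$chrom)
  data.frame(chrom = bed$chrom, start = pmax(0, bed$start - flank),
             end = pmin(L, bed$end + flank), stringsAsFactors = FALSE)
}

#' Greedy capture-target tiling with exclusion masks
#'
#' Places fixed-length targets left to right on each chromosome: the next
#' target starts at the earliest position at least `min_gap` after the end
#' of the previous target (end-to-start gap) that does not intersect the
#' merged exclusion mask. The mask is the union of `exclusions` and
#' `exons` expanded by `exon_flank` bp on both sides. Deterministic and
#' idempotent; fully masked chromosomes yield zero targets and are counted.
#'
#' @param layout a `genome_layout` (chromosome sizes).
#' @param target_len target length in bp.
#' @param min_gap minimum end-to-start spacing between targets in bp
#'   (default 19,700).
#' @param exclusions,exons optional BED data.frames (0-based half-open),
#'   e.g. repeat masks and exon annotations.
#' @param exon_flank bp excluded around each exon (default 100,000).
#' @return data.frame of class `target_set`: `chrom`, `start`, `end`
#'   (0-based half-open), `target_id`; attribute `n_masked_chroms`.
#' @export
select_targets <- function(layout, target_len = 500, min_gap = 19700,
                           exclusions = NULL, exons = NULL,
                           exon_flank = 1e5) {
  stopifnot(target_len > 0, min_gap >= 0)
  mask <- merge_intervals(rbind(
    if (!is.null(exclusions)) exclusions[, c("chrom", "start", "end")],
    if (!is.null(exons))
      flank_intervals(exons[, c("chrom", "start", "end")], exon_flank,
                      layout)[, c("chrom", "start", "end")]))
  out <- NULL
  n_masked <- 0L
  for (i in seq_len(nrow(layout$chrom))) {
    cc <- layout$chrom$chrom[i]
    L <- layout$chrom$length[i]
    mk <- mask[mask$chrom == cc, , drop = FALSE]
    cursor <- 0
    starts <- numeric(0)
    while (cursor + target_len <= L) {
      s <- cursor
      repeat {
        hit <- which(mk$start < s + target_len & mk$end > s)
        if (length(hit) == 0) break
        s <- max(mk$end[hit])
        if (s + target_len > L) { s <- NA; break }
      }
      if (is.na(s)) break
      starts <- c(starts, s)
      cursor <- s + target_len + min_gap
    }
    if (length(starts) == 0) n_masked <- n_masked + 1L
    else out <- rbind(out, data.frame(chrom = cc, start = starts,
                                      end = starts + target_len,
                                      stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  out$target_id <- if (nrow(out)) sprintf("t%06d", seq_len(nrow(out)))
                   else character(0)
  structure(out, class = c("target_set", "data.frame"),
            n_masked_chroms = n_masked)
}

#' Prune targets with excessive pilot coverage
#'
#' Removes every target whose mean coverage is at least three times the
#' mean on-target coverage, where that mean is computed over targets with
#' coverage above 0 only (zero-coverage targets — typically under-sequenced
#' rather than repetitive — are excluded from the mean and never pruned).
#' High-coverage targets usually collect reads from multiple paralogs and
#' inflate apparent heterozygosity.
#'
#' @param targets a `target_set` (or plain BED data.frame).
#' @param coverage numeric vector of per-target mean coverage, aligned with
#'   `targets` rows (or a `coverage` column on `targets`).
#' @param fold pruning threshold as a multiple of the mean (default 3).
#' @return the pruned target set; attribute `threshold` records the cutoff
#'   used (`NA` with a warning when every target has zero coverage).
#' @export
prune_high_coverage <- function(targets, coverage = targets$coverage,
                                fold = 3) {
  if (nrow(targets) == 0) return(targets)
  if (is.null(coverage) || length(coverage) != nrow(targets))
    stop("coverage must be supplied for every target")
  pos <- coverage > 0
  if (!any(pos)) {
    warning("all targets have zero coverage; mean undefined, nothing pruned")
    attr(targets, "threshold") <- NA_real_
    return(targets)
  }
  thr <- fold * mean(coverage[pos])
  keep <- !(pos & coverage >= thr)
  out <- targets[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  attr(out, "n_masked_chroms") <- attr(targets, "n_masked_chroms")
  class(out) <- class(targets)
  out
}
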
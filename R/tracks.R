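#' Per-residue validation-track comparison
#'
#' Experimental RSCC and B-factor tracks and predicted (scaled) pLDDT
#' tracks are aligned on a common residue numbering (the predicted model's
#' sequence numbering), correlated, and scanned for residues where the two
#' sources of confidence disagree.
#'
#' @name tracks
NULL

#' Align per-residue tracks on common numbering
#'
#' Each track's residue numbers are shifted by its offset (author numbering
#' to reference numbering), then the intersection of residue sets is taken.
#' Offsets are constant per chain (identical sequences), so no alignment
#' search is needed.
#'
#' @param track_list named list of [per_residue_track()]s (>= 2).
#' @param offsets numeric vector of per-track numbering offsets (added to
#'   each track's residue numbers), recycled if length 1.
#' @return list with `residues` (sorted common numbering) and `series`
#'   (named list of aligned numeric vectors).
#' @export
align_tracks <- function(track_list, offsets = 0) {
  if (length(track_list) < 2) stop("need at least 2 tracks")
  offsets <- rep_len(offsets, length(track_list))
  keyed <- mapply(function(tr, off) {
    v <- tr$values
    names(v) <- as.integer(names(v)) + off
    v
  }, track_list, offsets, SIMPLIFY = FALSE)
  common <- Reduce(intersect, lapply(keyed, names))
  if (length(common) == 0) stop("no common residues after applying offsets")
  common <- as.character(sort(as.integer(common)))
  series <- lapply(keyed, function(v) unname(v[common]))
  if (is.null(names(series)) || any(names(series) == ""))
    names(series) <- vapply(track_list, function(tr) tr$metric_name,
                            character(1))
  list(residues = as.integer(common), series = series)
}

#' Pearson correlation between two aligned series
#'
#' @param paired result of [align_tracks()].
#' @param a,b names of the series to correlate.
#' @return Pearson r in [-1, 1].
#' @export
track_correlation <- function(paired, a, b) {
  va <- paired$series[[a]]
  vb <- paired$series[[b]]
  if (is.null(va) || is.null(vb)) stop("series not found: ", a, " / ", b)
  if (length(va) < 3) stop("need at least 3 common residues")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(va, vb)
}

#' Flag residues where experimental and predicted confidence disagree
#'
#' Kind A: the experiment is confident but the prediction is not
#' (RSCC > `high_thr`, pLDDT < `low_thr`); kind B: the prediction is
#' confident but the experimental fit is poor (pLDDT > `high_thr`,
#' RSCC < `low_thr`). The two sets are disjoint whenever
#' `high_thr > low_thr`.
#'
#' @param paired result of [align_tracks()] containing `RSCC` and `pLDDT`
#'   series.
#' @param high_thr,low_thr thresholds on the common [0, 1] scale.
#' @return data.frame with `residue` and `kind` (`"A"` or `"B"`); zero rows
#'   when nothing is discrepant.
#' @export
flag_discrepancies <- function(paired, high_thr = 0.9, low_thr = 0.7) {
  rscc <- paired$series[["RSCC"]]
  plddt <- paired$series[["pLDDT"]]
  if (is.null(rscc) || is.null(plddt))
    stop("paired tracks must contain RSCC and pLDDT series")
  a <- rscc > high_thr & plddt < low_thr
  b <- plddt > high_thr & rscc < low_thr
  data.frame(residue = c(paired$residues[a], paired$residues[b]),
             kind = c(rep("A", sum(a)), rep("B", sum(b))),
             stringsAsFactors = FALSE)
}
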
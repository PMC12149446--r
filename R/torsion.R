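#' Backbone torsions and torsional comparison metrics
#'
#' phi(i) is the C(i-1)-N(i)-CA(i)-C(i) torsion, psi(i) the
#' N(i)-CA(i)-C(i)-N(i+1) torsion, both in degrees in [-180, 180). Chain
#' breaks (consecutive CA-CA distance > 4.5 A) make the flanking angles
#' undefined, as do chain termini. Agreement between an experimental chain
#' and its prediction is quantified with four metrics per angle: circular
#' RMSD and MAE on the wrapped difference, Pearson correlation on the raw
#' paired angles, and the 1-D Wasserstein distance between the marginal
#' angle distributions.
#'
#' @name torsion
NULL

#' Backbone phi/psi torsions of a chain
#'
#' @param chain a [chain_model()].
#' @return data.frame with `auth_seq`, `res_name`, `phi`, `psi` (degrees,
#'   `NA` where undefined) and `residue_class` (`general`, `glycine`,
#'   `proline`, `pre-proline`, `ile-val`).
#' @export
backbone_torsions <- function(chain) {
  fr <- backbone_frames(chain)
  n <- fr$n
  if (n < 2) stop("need at least 2 backbone-complete consecutive residues")
  phi <- psi <- rep(NA_real_, n)
  seq_adjacent <- function(i) !fr$brk[i + 1]   # i and i+1 connected
  for (i in seq_len(n)) {
    if (i > 1 && !fr$brk[i])
      phi[i] <- torsion4(fr$C[i - 1, ], fr$N[i, ], fr$CA[i, ], fr$C[i, ])
    if (i < n && !fr$brk[i + 1])
      psi[i] <- torsion4(fr$N[i, ], fr$CA[i, ], fr$C[i, ], fr$N[i + 1, ])
  }
  if (all(is.na(phi)) && all(is.na(psi)))
    stop("no computable torsion angles (all residues isolated)")
  # map 180 -> -180 so angles live in [-180, 180)
  phi[!is.na(phi) & phi >= 180] <- -180
  psi[!is.na(psi) & psi >= 180] <- -180
  nxt <- c(fr$res_name[-1], NA)
  nxt[c(fr$brk[-1], TRUE)] <- NA
  cls <- ifelse(fr$res_name == "GLY", "glycine",
         ifelse(fr$res_name == "PRO", "proline",
         ifelse(!is.na(nxt) & nxt == "PRO", "pre-proline",
         ifelse(fr$res_name %in% c("ILE", "VAL"), "ile-val", "general"))))
  data.frame(auth_seq = fr$auth_seq, res_name = fr$res_name,
             phi = phi, psi = psi, residue_class = cls,
             stringsAsFactors = FALSE)
}

#' Wrapped angular difference
#'
#' `((a - b + 180) mod 360) - 180`, mapping any difference into
#' (-180, 180]; 179 vs -179 gives 2, not 358.
#'
#' @param a,b angles in degrees.
#' @return wrapped difference in degrees.
#' @export
wrapped_diff <- function(a, b) wrap180(a - b)

#' First-order Wasserstein distance between two angle samples
#'
#' Earth-mover's distance between the empirical distributions on the linear
#' scale \[-180, 180). Computed exactly from the merged empirical CDFs
#' (handles unequal sample sizes).
#'
#' @param sample_a,sample_b numeric vectors (degrees), nonempty.
#' @return distance in degrees.
#' @export
wasserstein_1d <- function(sample_a, sample_b) {
  a <- sort(sample_a[!is.na(sample_a)])
  b <- sort(sample_b[!is.na(sample_b)])
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  grid <- sort(unique(c(a, b)))
  if (length(grid) == 1) return(0)
  Fa <- stats::ecdf(a)(grid)
  Fb <- stats::ecdf(b)(grid)
  k <- length(grid)
  sum(abs(Fa[-k] - Fb[-k]) * diff(grid))
}

#' Torsional comparison of an experimental/predicted chain pair
#'
#' Residues are paired by author number (both chains on the predicted
#' model's numbering). Per angle the circular RMSD and MAE use the wrapped
#' difference; Pearson correlation is computed on the raw paired angles
#' (with a circular-correlation option); the Wasserstein distance compares
#' the two marginal samples.
#'
#' @param exp_torsions,pred_torsions data.frames from [backbone_torsions()].
#' @param circular_correlation if `TRUE`, use the Fisher-Lee circular
#'   correlation coefficient instead of plain Pearson.
#' @return list with per-angle `rmsd`, `mae`, `wasserstein`, `pearson`, and
#'   `n_paired`.
#' @export
torsion_comparison <- function(exp_torsions, pred_torsions,
                               circular_correlation = FALSE) {
  m <- merge(exp_torsions, pred_torsions, by = "auth_seq",
             suffixes = c("_exp", "_pred"))
  out <- list()
  for (ang in c("phi", "psi")) {
    e <- m[[paste0(ang, "_exp")]]
    p <- m[[paste0(ang, "_pred")]]
    ok <- !is.na(e) & !is.na(p)
    if (sum(ok) < 10)
      stop("fewer than 10 paired residues with defined ", ang)
    d <- wrapped_diff(e[ok], p[ok])
    corr <- if (circular_correlation) circular_cor(e[ok], p[ok])
            else stats::cor(e[ok], p[ok])
    out[[ang]] <- list(rmsd = sqrt(mean(d^2)), mae = mean(abs(d)),
                       wasserstein = wasserstein_1d(e[ok], p[ok]),
                       pearson = corr, n_paired = sum(ok))
  }
  out$n_paired <- min(out$phi$n_paired, out$psi$n_paired)
  out
}

# Fisher-Lee circular correlation coefficient
circular_cor <- function(a, b) {
  a <- deg2rad(a); b <- deg2rad(b)
  abar <- atan2(mean(sin(a)), mean(cos(a)))
  bbar <- atan2(mean(sin(b)), mean(cos(b)))
  num <- sum(sin(a - abar) * sin(b - bbar))
  den <- sqrt(sum(sin(a - abar)^2) * sum(sin(b - bbar)^2))
  num / den
}
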
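#' Model quality scores: Sr, C-score, estimated and true TM-score
#'
#' The folding confidence score combines the alignment depth, the model's
#' weighted satisfaction of the top-L long-range predicted contacts (Sr),
#' and the convergence density of the decoy cluster (Dc):
#' `C-score = 0.2 * ln(Nf) + ln(Sr * Dc)`. A linear calibration maps the
#' C-score to an expected TM-score,
#' `TM = 0.0659 * C-score + 0.477` (residual RMSD 0.084).
#'
#' @name quality_score
NULL

TM_SLOPE <- 0.0659
TM_INTERCEPT <- 0.477
TM_UNCERTAINTY <- 0.084

#' Weighted satisfaction rate of top-L long-range contacts
#'
#' Over the top-L contacts (L = chain length) with sequence separation
#' > 24, `Sr = (1/n_L) * sum(delta_i * w_i^2)` where `delta_i` indicates a
#' Cb-Cb distance at or below 8 A in the model and `w_i` is the contact's
#' consensus confidence `U_ij` (already in (0, 1]).
#'
#' @param model a `ChainConformation`.
#' @param cs a `ConsensusContactSet`.
#' @param sat_dist satisfaction threshold in A (default 8).
#' @return Sr in `[0, 1]`; 0 with a warning when there are no long-range
#'   contacts.
#' @export
satisfaction_rate <- function(model, cs, sat_dist = 8) {
  stopifnot(inherits(model, "ChainConformation"),
            inherits(cs, "ConsensusContactSet"))
  lr <- long_range_subset(cs, top = model$n_res)
  ct <- lr$contacts
  if (nrow(ct) == 0L) {
    cf_warn("cf_no_long_range_warning",
            "no long-range contacts available for Sr; returning 0")
    return(0)
  }
  if (max(ct$j) > model$n_res) {
    cf_abort("cf_index_range_error", "contact index exceeds model length")
  }
  dv <- model$cb[ct$i, , drop = FALSE] - model$cb[ct$j, , drop = FALSE]
  d <- sqrt(rowSums(dv * dv))
  delta <- as.numeric(d <= sat_dist)
  mean(delta * ct$u^2)
}

#' Folding confidence score (C-score)
#'
#' `0.2 * ln(nf) + ln(sr * dc)`. Zero `sr` or `dc` are floored at 1e-6
#' (with a warning) so failed runs stay finite.
#'
#' @param nf effective sequence count (> 0).
#' @param sr contact satisfaction rate.
#' @param dc convergence density.
#' @return C-score (scalar).
#' @export
c_score <- function(nf, sr, dc) {
  if (!is.finite(nf) || nf <= 0) {
    cf_abort("cf_domain_error", "nf must be > 0")
  }
  if (sr < 1e-6 || dc < 1e-6) {
    cf_warn("cf_floored_score_warning",
            "Sr or Dc floored at 1e-6 in C-score")
  }
  0.2 * log(nf) + log(max(sr, 1e-6) * max(dc, 1e-6))
}

#' Estimated TM-score from the C-score calibration
#'
#' Linear calibration `0.0659 * c + 0.477`, clamped to `[0, 1]`; the
#' reported uncertainty is the calibration's residual RMSD, 0.084.
#'
#' @param c C-score value(s).
#' @return list with `tm_estimate` and `uncertainty`.
#' @export
estimate_tm <- function(c) {
  list(tm_estimate = clamp(TM_SLOPE * c + TM_INTERCEPT, 0, 1),
       uncertainty = TM_UNCERTAINTY)
}

#' TM-score between two equal-length conformations
#'
#' Length-normalized structural similarity in (0, 1]:
#' `TM = max (1/L) sum 1 / (1 + (d_i/d0)^2)` over superpositions, with
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8` (floored at 0.5). The maximization
#' seeds Kabsch superpositions from sliding windows of several lengths and
#' iteratively refines each on the residue subset within distance cutoffs,
#' keeping the best score.
#'
#' @param model,reference `ChainConformation`s of equal length.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(model, reference) {
  xa <- reference$ca; xb <- model$ca
  if (nrow(xa) != nrow(xb)) {
    cf_abort("cf_length_mismatch_error", "conformations differ in length")
  }
  n <- nrow(xa)
  d0 <- max(0.5, 1.24 * (max(n - 15, 1))^(1 / 3) - 1.8)
  score_of <- function(fitted) {
    d2 <- rowSums((xa - fitted)^2)
    mean(1 / (1 + d2 / d0^2))
  }
  best <- 0
  win_lens <- unique(c(4, 8, pmax(4, floor(n / c(1, 2, 4)))))
  for (wl in win_lens) {
    starts <- unique(round(seq(1, n - wl + 1,
                               length.out = min(32, n - wl + 1))))
    for (st in starts) {
      sub <- st:(st + wl - 1)
      for (iter in 1:10) {
        fit <- superposed_sq_dev(xa, xb, sub = sub)
        sc <- score_of(fit$fitted)
        if (sc > best) best <- sc
        d <- sqrt(rowSums((xa - fit$fitted)^2))
        cutoff <- max(d0 + 1, 4.5)
        new_sub <- which(d <= cutoff)
        if (length(new_sub) < 4 || identical(new_sub, sub)) break
        sub <- new_sub
      }
    }
  }
  best
}

#' Check a C-score / TM-score calibration
#'
#' @param pairs data.frame (or list of length-2 vectors) with columns
#'   `c_score` and `tm` of observed (C-score, true TM-score) pairs.
#' @return list with `pearson` (correlation) and `rmsd_of_fit` (residual
#'   RMSD against the linear calibration).
#' @export
calibration_check <- function(pairs) {
  df <- as.data.frame(pairs)
  if (ncol(df) == 2 && !all(c("c_score", "tm") %in% names(df))) {
    names(df) <- c("c_score", "tm")
  }
  if (nrow(df) < 3) {
    cf_abort("cf_domain_error", "need at least 3 calibration pairs")
  }
  if (stats::sd(df$c_score) < 1e-12 || stats::sd(df$tm) < 1e-12) {
    cf_abort("cf_degenerate_variance_error",
             "degenerate variance in calibration pairs")
  }
  pred <- TM_SLOPE * df$c_score + TM_INTERCEPT
  list(pearson = stats::cor(df$c_score, df$tm),
       rmsd_of_fit = sqrt(mean((df$tm - pred)^2)))
}

#' Assemble a confidence report
#'
#' @param nf effective sequence count.
#' @param sr contact satisfaction rate.
#' @param dc convergence density.
#' @return a `ConfidenceReport`: list with `nf`, `sr`, `dc`, `c_score`,
#'   `tm_estimate`, `tm_uncertainty`.
#' @export
confidence_report <- function(nf, sr, dc) {
  cs <- c_score(nf, sr, dc)
  est <- estimate_tm(cs)
  structure(list(nf = nf, sr = sr, dc = dc, c_score = cs,
                 tm_estimate = est$tm_estimate,
                 tm_uncertainty = est$uncertainty),
            class = "ConfidenceReport")
}

#' @export
print.ConfidenceReport <- function(x, ...) {
  cat(sprintf(
    "ConfidenceReport: Nf = %.1f, Sr = %.3f, Dc = %.3f, C-score = %.3f, est. TM = %.3f +/- %.3f\n",
    x$nf, x$sr, x$dc, x$c_score, x$tm_estimate, x$tm_uncertainty))
  invisible(x)
}
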
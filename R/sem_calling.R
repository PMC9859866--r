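#' Per-probe reference thresholds for stochastic epigenetic mutation calling
#'
#' For every probe, computes the first and third quartiles of the beta values
#' across a designated reference sample set, the interquartile range
#' IQR = Q3 - Q1, and the extreme-outlier bounds `lower = Q1 - 3*IQR`,
#' `upper = Q3 + 3*IQR`. A subject's beta value strictly below `lower` is a
#' hypo-methylated stochastic epigenetic mutation (SEM); strictly above
#' `upper`, a hyper-methylated SEM.
#'
#' Quartiles use linear interpolation between order statistics at position
#' `1 + (n - 1) * q` (the default convention of [stats::quantile()], type 7).
#' Bounds are deliberately not clamped to \[0, 1\]: a probe whose lower bound
#' is negative simply cannot yield hypo calls.
#'
#' Probes with any missing reference value, or with `IQR < iqr_floor`, are
#' flagged unusable and never called.
#'
#' @param beta A `beta_matrix` (probes x samples).
#' @param reference_ids Character vector of sample ids forming the reference
#'   set; must contain at least 4 samples.
#' @param iqr_floor Minimum IQR for a probe to be usable. Default `1e-6`
#'   excludes only numerically constant probes.
#' @return data.frame of class `probe_thresholds` with columns `probe_id`,
#'   `q1`, `q3`, `iqr`, `lower`, `upper`, `usable`.
#' @export
compute_reference_thresholds <- function(beta, reference_ids, iqr_floor = 1e-6) {
  if (!all(reference_ids %in% colnames(beta)))
    stop("reference ids absent from beta matrix: ",
         paste(setdiff(reference_ids, colnames(beta)), collapse = ", "))
  if (length(reference_ids) < 4L)
    stop("at least 4 reference samples are required for stable quartiles")
  ref <- beta[, reference_ids, drop = FALSE]
  n <- ncol(ref)
  has_na <- rowSums(is.na(ref)) > 0L
  # type-7 quartiles, vectorised across probes: sort each row once and
  # interpolate at positions 1 + (n-1)*q
  srt <- t(apply(ref, 1L, sort, na.last = TRUE))
  qpos <- function(q) {
    h <- 1 + (n - 1) * q
    lo <- floor(h); hi <- ceiling(h)
    srt[, lo] * (1 - (h - lo)) + srt[, hi] * (h - lo)
  }
  q1 <- qpos(0.25)
  q3 <- qpos(0.75)
  q1[has_na] <- NA_real_
  q3[has_na] <- NA_real_
  iqr <- q3 - q1
  out <- data.frame(probe_id = rownames(beta),
                    q1 = q1, q3 = q3, iqr = iqr,
                    lower = q1 - 3 * iqr, upper = q3 + 3 * iqr,
                    usable = !has_na & !is.na(iqr) & iqr >= iqr_floor,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("probe_thresholds", "data.frame")
  out
}

#' Call stochastic epigenetic mutations against precomputed thresholds
#'
#' A call is made when a target sample's beta value falls strictly outside
#' the probe's reference bounds: `beta < lower` (hypo) or `beta > upper`
#' (hyper). Unusable probes and missing values are never called.
#'
#' @param beta A `beta_matrix`.
#' @param thresholds `probe_thresholds` from [compute_reference_thresholds()];
#'   must cover exactly the probes of `beta`, in order.
#' @param target_ids Sample ids to evaluate. Default: all samples. A sample
#'   present in both the reference and target sets is evaluated against
#'   thresholds computed with itself included (no leave-one-out correction).
#' @return data.frame of class `sem_calls` with columns `sample_id`,
#'   `probe_id`, `direction` ("hypo"/"hyper"), `beta`, `threshold`.
#' @export
call_sems <- function(beta, thresholds, target_ids = colnames(beta)) {
  if (!identical(thresholds$probe_id, rownames(beta)))
    stop("probe mismatch between beta matrix and thresholds")
  if (!all(target_ids %in% colnames(beta)))
    stop("target ids absent from beta matrix: ",
         paste(setdiff(target_ids, colnames(beta)), collapse = ", "))
  tgt <- beta[, target_ids, drop = FALSE]
  usable <- thresholds$usable
  hypo <- !is.na(tgt) & usable & tgt < thresholds$lower
  hyper <- !is.na(tgt) & usable & tgt > thresholds$upper
  hy <- which(hypo, arr.ind = TRUE)
  hr <- which(hyper, arr.ind = TRUE)
  out <- data.frame(
    sample_id = c(target_ids[hy[, 2L]], target_ids[hr[, 2L]]),
    probe_id = c(thresholds$probe_id[hy[, 1L]], thresholds$probe_id[hr[, 1L]]),
    direction = c(rep("hypo", nrow(hy)), rep("hyper", nrow(hr))),
    beta = c(tgt[hypo], tgt[hyper]),
    threshold = c(thresholds$lower[hy[, 1L]], thresholds$upper[hr[, 1L]]),
    stringsAsFactors = FALSE)
  ord <- order(match(out$sample_id, target_ids), match(out$probe_id, thresholds$probe_id))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sem_calls", "data.frame")
  out
}

#' @export
print.sem_calls <- function(x, ...) {
  cat(sprintf("sem_calls: %d calls (%d hypo, %d hyper) in %d sample(s)\n",
              nrow(x), sum(x$direction == "hypo"), sum(x$direction == "hyper"),
              length(unique(x$sample_id))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Per-sample SEM burdens
#'
#' Counts hypo- and hyper-methylated SEM calls per sample and attaches the
#' natural log of each positive count (`NA` when the count is zero, since
#' ln(0) is undefined; such samples are excluded from downstream log-scale
#' models).
#'
#' @param calls `sem_calls` from [call_sems()].
#' @param target_ids Samples to report (zero-count samples included).
#'   Default: the samples present in `calls`.
#' @return data.frame of class `sem_burden` with columns `sample_id`,
#'   `n_hypo`, `n_hyper`, `ln_hypo`, `ln_hyper`.
#' @export
sem_burden <- function(calls, target_ids = unique(calls$sample_id)) {
  nh <- table(factor(calls$sample_id[calls$direction == "hypo"], levels = target_ids))
  nr <- table(factor(calls$sample_id[calls$direction == "hyper"], levels = target_ids))
  out <- data.frame(sample_id = target_ids,
                    n_hypo = as.integer(nh), n_hyper = as.integer(nr),
                    stringsAsFactors = FALSE)
  out$ln_hypo <- ifelse(out$n_hypo > 0L, log(out$n_hypo), NA_real_)
  out$ln_hyper <- ifelse(out$n_hyper > 0L, log(out$n_hyper), NA_real_)
  rownames(out) <- NULL
  class(out) <- c("sem_burden", "data.frame")
  out
}
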
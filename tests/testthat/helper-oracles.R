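# Independent brute-force oracles and small fixture builders.

# random valid beta matrix
make_beta <- function(n_probes, n_samples, seed = 1, missing = 0) {
  set.seed(seed)
  m <- matrix(runif(n_probes * n_samples), nrow = n_probes,
              dimnames = list(sprintf("p%04d", seq_len(n_probes)),
                              sprintf("s%02d", seq_len(n_samples))))
  if (missing > 0) m[sample(length(m), missing)] <- NA
  as_beta_matrix(m)
}

make_sheet <- function(n_pairs, zygosity = "DZ", groups = c("case", "control")) {
  as_sample_sheet(data.frame(
    sample_id = paste0("s", rep(seq_len(n_pairs), each = 2), c("A", "B")),
    family_id = paste0("F", rep(seq_len(n_pairs), each = 2)),
    pair_id = paste0("P", rep(seq_len(n_pairs), each = 2)),
    zygosity = rep(zygosity, length.out = 2 * n_pairs),
    group = rep(groups, n_pairs),
    sex = "F", batch = "b1", stringsAsFactors = FALSE))
}

# scalar per-probe threshold oracle: plain quantile() calls, one probe at a time
naive_thresholds <- function(beta, reference_ids, iqr_floor = 1e-6) {
  out <- NULL
  for (i in seq_len(nrow(beta))) {
    x <- beta[i, reference_ids]
    if (anyNA(x)) {
      row <- data.frame(probe_id = rownames(beta)[i], q1 = NA_real_,
                        q3 = NA_real_, iqr = NA_real_, lower = NA_real_,
                        upper = NA_real_, usable = FALSE)
    } else {
      q <- unname(quantile(x, c(0.25, 0.75), type = 7))
      iqr <- q[2] - q[1]
      row <- data.frame(probe_id = rownames(beta)[i], q1 = q[1], q3 = q[2],
                        iqr = iqr, lower = q[1] - 3 * iqr,
                        upper = q[2] + 3 * iqr, usable = iqr >= iqr_floor)
    }
    out <- rbind(out, row)
  }
  out
}

# double-loop SEM caller
naive_calls <- function(beta, thr, target_ids = colnames(beta)) {
  rows <- list()
  for (j in target_ids) {
    for (i in seq_len(nrow(beta))) {
      v <- beta[i, j]
      if (is.na(v) || !thr$usable[i]) next
      if (v < thr$lower[i]) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = j, probe_id = rownames(beta)[i], direction = "hypo",
          beta = v, threshold = thr$lower[i], stringsAsFactors = FALSE)
      } else if (v > thr$upper[i]) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = j, probe_id = rownames(beta)[i], direction = "hyper",
          beta = v, threshold = thr$upper[i], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(sample_id = character(0), probe_id = character(0),
                      direction = character(0), beta = numeric(0),
                      threshold = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# exhaustive window-scan oracle for one sample x direction scan
naive_region_scan <- function(calls, manifest, window_probes, min_sems, q_max) {
  res <- list()
  for (sid in unique(calls$sample_id)) {
    for (dir in c("hypo", "hyper")) {
      hits <- calls$probe_id[calls$sample_id == sid & calls$direction == dir]
      if (!length(hits)) next
      r_s <- length(hits) / nrow(manifest)
      wins <- NULL
      for (chr in unique(manifest$chromosome)) {
        mi <- which(manifest$chromosome == chr)
        if (length(mi) < window_probes) next
        for (s in seq_len(length(mi) - window_probes + 1L)) {
          ii <- mi[s:(s + window_probes - 1L)]
          k <- sum(manifest$probe_id[ii] %in% hits)
          p <- sum(dbinom(k:window_probes, window_probes, r_s))
          wins <- rbind(wins, data.frame(chr = chr, i1 = ii[1], i2 = ii[window_probes],
                                         k = k, p = p))
        }
      }
      if (is.null(wins)) next
      wins$q <- p.adjust(wins$p, "BH")
      sig <- wins[wins$q <= q_max & wins$k >= min_sems, , drop = FALSE]
      if (!nrow(sig)) next
      # iterative pairwise merge of strictly overlapping intervals
      iv <- sig
      repeat {
        merged_any <- FALSE
        i <- 1L
        while (i < nrow(iv)) {
          j <- i + 1L
          while (j <= nrow(iv)) {
            if (iv$chr[i] == iv$chr[j] &&
                iv$i1[j] <= iv$i2[i] && iv$i2[j] >= iv$i1[i]) {
              iv$i1[i] <- min(iv$i1[i], iv$i1[j])
              iv$i2[i] <- max(iv$i2[i], iv$i2[j])
              iv$p[i] <- min(iv$p[i], iv$p[j])
              iv$q[i] <- min(iv$q[i], iv$q[j])
              iv <- iv[-j, , drop = FALSE]
              merged_any <- TRUE
            } else j <- j + 1L
          }
          i <- i + 1L
        }
        if (!merged_any) break
      }
      for (i in seq_len(nrow(iv))) {
        ii <- iv$i1[i]:iv$i2[i]
        res[[length(res) + 1L]] <- data.frame(
          sample_id = sid, direction = dir, chromosome = iv$chr[i],
          start_bp = manifest$position[iv$i1[i]],
          end_bp = manifest$position[iv$i2[i]],
          n_sems = sum(manifest$probe_id[ii] %in% hits),
          p_enrich = iv$p[i], q = iv$q[i], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res))
    return(data.frame(sample_id = character(0), direction = character(0),
                      chromosome = character(0), start_bp = integer(0),
                      end_bp = integer(0), n_sems = integer(0),
                      p_enrich = numeric(0), q = numeric(0)))
  out <- do.call(rbind, res)
  out[order(out$sample_id, out$direction, out$chromosome, out$start_bp), ,
      drop = FALSE]
}

# helper: calls table built directly (bypassing thresholds)
fake_calls <- function(sample_id, probe_id, direction) {
  df <- data.frame(sample_id = sample_id, probe_id = probe_id,
                   direction = direction,
                   beta = rep(NA_real_, length(probe_id)),
                   threshold = rep(NA_real_, length(probe_id)),
                   stringsAsFactors = FALSE)
  class(df) <- c("sem_calls", "data.frame")
  df
}
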
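#' Convert beta values to M-values
#'
#' M = log2(beta / (1 - beta)) with beta clamped to
#' \[epsilon, 1 - epsilon\] so that boundary values stay finite.
#'
#' @param beta Numeric matrix (or vector) of beta values in \[0, 1\].
#' @param epsilon Clamp width. Default `1e-3`.
#' @return M-values of the same shape.
#' @export
beta_to_m <- function(beta, epsilon = 1e-3) {
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

# Discordant complete pairs: matrix of sample-id pairs (case, control).
discordant_pairs <- function(samples) {
  out <- list()
  for (p in unique(samples$pair_id)) {
    s <- samples[samples$pair_id == p, , drop = FALSE]
    if (nrow(s) == 2L && setequal(s$group, c("case", "control"))) {
      out[[length(out) + 1L]] <- c(case = s$sample_id[s$group == "case"],
                                   control = s$sample_id[s$group == "control"])
    }
  }
  if (length(out) == 0L)
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("case", "control"))))
  do.call(rbind, out)
}

#' Paired site-level differential methylation test
#'
#' For each probe, computes the within-pair M-value difference
#' (case minus control) over the complete discordant twin pairs and applies
#' a one-sample t-test against zero, with Benjamini-Hochberg correction
#' across probes. Pairs with a missing member at a probe are dropped for
#' that probe; probes retaining fewer than 3 pairs get no statistic. Probes
#' with zero variance and zero mean difference receive p = 1.
#'
#' @param beta `beta_matrix`.
#' @param samples `sample_sheet`; only complete discordant case/control
#'   pairs enter the analysis.
#' @param epsilon Clamp for the M-value transform.
#' @return data.frame of class `site_stats`: `probe_id`, `n_pairs`,
#'   `mean_beta_diff`, `mean_m_diff`, `t`, `p`, `q`.
#' @export
paired_site_test <- function(beta, samples, epsilon = 1e-3) {
  prs <- discordant_pairs(samples)
  if (nrow(prs) < 3L) stop("need at least 3 complete discordant pairs")
  m <- beta_to_m(beta, epsilon)
  dm <- m[, prs[, "case"], drop = FALSE] - m[, prs[, "control"], drop = FALSE]
  db <- beta[, prs[, "case"], drop = FALSE] - beta[, prs[, "control"], drop = FALSE]
  stats_from_diffs(rownames(beta), dm, db, id_col = "probe_id")
}

# Shared paired-t machinery for site- and region-level differences.
stats_from_diffs <- function(ids, dm, db, id_col) {
  n <- rowSums(!is.na(dm))
  mu <- rowMeans(dm, na.rm = TRUE)
  sdv <- apply(dm, 1L, stats::sd, na.rm = TRUE)
  tt <- mu / (sdv / sqrt(n))
  p <- 2 * stats::pt(-abs(tt), df = n - 1L)
  degen <- !is.na(sdv) & sdv == 0
  p[degen & abs(mu) < .Machine$double.eps] <- 1
  p[degen & abs(mu) >= .Machine$double.eps] <- 0
  tt[degen] <- ifelse(abs(mu[degen]) < .Machine$double.eps, 0, Inf * sign(mu[degen]))
  invalid <- n < 3L
  tt[invalid] <- NA_real_; p[invalid] <- NA_real_
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  out <- data.frame(id = ids, n_pairs = n,
                    mean_beta_diff = rowMeans(db, na.rm = TRUE),
                    mean_m_diff = mu, t = tt, p = p, q = q,
                    stringsAsFactors = FALSE)
  names(out)[1L] <- id_col
  rownames(out) <- NULL
  class(out) <- c("site_stats", "data.frame")
  out
}

#' Build region definitions from a manifest
#'
#' Region classes: `gene` (all probes annotated to a symbol), `promoter`
#' (probes within `promoter_bp` upstream of the first probe of each gene),
#' `island` (maximal runs of probes with manifest `region_class` "island"),
#' `tiling` (fixed genomic windows of `tiling_bp`).
#'
#' @param manifest `cpg_manifest`.
#' @param class Region class.
#' @param promoter_bp Upstream window for promoters. Default 1500.
#' @param tiling_bp Tiling window width. Default 5000.
#' @return Named list mapping region id to a character vector of probe ids.
#' @export
manifest_regions <- function(manifest, class = c("gene", "promoter", "island", "tiling"),
                             promoter_bp = 1500L, tiling_bp = 5000L) {
  class <- match.arg(class)
  if (class == "gene") {
    gl <- split_gene_symbols(manifest$gene_symbols)
    ng <- lengths(gl)
    f <- data.frame(gene = unlist(gl, use.names = FALSE),
                    probe = rep(manifest$probe_id, ng),
                    stringsAsFactors = FALSE)
    return(split(f$probe, f$gene))
  }
  if (class == "promoter") {
    gl <- split_gene_symbols(manifest$gene_symbols)
    ng <- lengths(gl)
    f <- data.frame(gene = unlist(gl, use.names = FALSE),
                    pos = rep(manifest$position, ng),
                    chr = rep(manifest$chromosome, ng),
                    stringsAsFactors = FALSE)
    out <- list()
    for (g in unique(f$gene)) {
      fg <- f[f$gene == g, , drop = FALSE]
      chr <- fg$chr[which.min(fg$pos)]
      tss <- min(fg$pos[fg$chr == chr])
      sel <- manifest$chromosome == chr &
        manifest$position >= tss - promoter_bp & manifest$position < tss
      if (any(sel)) out[[paste0("prom:", g)]] <- manifest$probe_id[sel]
    }
    return(out)
  }
  if (class == "island") {
    if (is.null(manifest$region_class)) return(list())
    isl <- !is.na(manifest$region_class) & manifest$region_class == "island"
    # maximal runs of island probes within a chromosome
    r <- rle(paste0(manifest$chromosome, ":", isl))
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    out <- list()
    for (i in seq_along(r$values)) {
      if (!endsWith(r$values[i], ":TRUE")) next
      ii <- idx_start[i]:idx_end[i]
      id <- sprintf("island:%s:%d-%d", manifest$chromosome[ii[1L]],
                    manifest$position[ii[1L]], manifest$position[ii[length(ii)]])
      out[[id]] <- manifest$probe_id[ii]
    }
    return(out)
  }
  # tiling
  win <- paste0(manifest$chromosome, ":",
                (manifest$position - 1L) %/% tiling_bp)
  sp <- split(manifest$probe_id, win)
  names(sp) <- paste0("tile:", names(sp))
  sp
}

#' Paired region-level differential methylation test
#'
#' Averages member-probe M-values per region and sample, then applies the
#' paired within-pair t-test of [paired_site_test()] at region level, with
#' BH correction within the region class.
#'
#' @param beta `beta_matrix`.
#' @param samples `sample_sheet`.
#' @param manifest `cpg_manifest`.
#' @param class Region class: gene, promoter, island or tiling.
#' @param epsilon Clamp for the M transform.
#' @param promoter_bp,tiling_bp Region-definition parameters (see
#'   [manifest_regions()]).
#' @return data.frame of class `site_stats` with `region_id` plus
#'   `region_class` and `n_probes` columns.
#' @export
region_test <- function(beta, samples, manifest,
                        class = c("gene", "promoter", "island", "tiling"),
                        epsilon = 1e-3, promoter_bp = 1500L, tiling_bp = 5000L) {
  class <- match.arg(class)
  regions <- manifest_regions(manifest, class, promoter_bp, tiling_bp)
  regions <- lapply(regions, intersect, rownames(beta))
  keep <- lengths(regions) > 0L
  if (!all(keep))
    message(sum(!keep), " region(s) without usable probes skipped")
  regions <- regions[keep]
  if (length(regions) == 0L) stop("no regions with usable probes for class '", class, "'")
  m <- beta_to_m(beta, epsilon)
  rm_mat <- t(vapply(regions, function(pr) colMeans(m[pr, , drop = FALSE], na.rm = TRUE),
                     numeric(ncol(beta))))
  rb_mat <- t(vapply(regions, function(pr) colMeans(beta[pr, , drop = FALSE], na.rm = TRUE),
                     numeric(ncol(beta))))
  colnames(rm_mat) <- colnames(beta); colnames(rb_mat) <- colnames(beta)
  prs <- discordant_pairs(samples)
  if (nrow(prs) < 3L) stop("need at least 3 complete discordant pairs")
  dm <- rm_mat[, prs[, "case"], drop = FALSE] - rm_mat[, prs[, "control"], drop = FALSE]
  db <- rb_mat[, prs[, "case"], drop = FALSE] - rb_mat[, prs[, "control"], drop = FALSE]
  dm[is.nan(dm)] <- NA_real_; db[is.nan(db)] <- NA_real_
  out <- stats_from_diffs(names(regions), dm, db, id_col = "region_id")
  out$region_class <- class
  out$n_probes <- lengths(regions)
  out
}

#' Volcano table for differential-methylation results
#'
#' @param stats A `site_stats` table.
#' @return data.frame with `id`, `difference` (mean beta difference) and
#'   `neg_log10_p` for plotting.
#' @export
volcano_table <- function(stats) {
  data.frame(id = stats[[1L]],
             difference = stats$mean_beta_diff,
             neg_log10_p = -log10(stats$p),
             stringsAsFactors = FALSE)
}
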
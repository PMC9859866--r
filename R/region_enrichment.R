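#' Scan for genomic regions enriched in same-direction SEMs
#'
#' For each sample and direction, slides a window of `window_probes`
#' consecutive usable probes along each chromosome (step one probe). The SEM
#' count k in a window of m probes is tested against the upper tail of
#' Binomial(m, r_s), where r_s is that sample's genome-wide SEM rate for the
#' direction (calls / usable probes). Benjamini-Hochberg correction is
#' applied across all windows of a sample-direction scan; windows with
#' q <= `q_max` and k >= `min_sems` are merged when they overlap. A merged
#' region keeps the minimum window q and the number of distinct SEM probes
#' it covers.
#'
#' @param calls `sem_calls` from [call_sems()].
#' @param manifest `cpg_manifest` covering the probe universe of the calls.
#' @param thresholds Optional `probe_thresholds`; when supplied, only usable
#'   probes present in the manifest form the scan backbone. Default: all
#'   manifest probes are treated as usable.
#' @param window_probes Window width in probes. Default 10.
#' @param min_sems Minimum SEM count for a window to be reported. Default 3.
#' @param q_max BH-adjusted significance ceiling. Default 0.05.
#' @return data.frame of class `enriched_regions`: `sample_id`, `direction`,
#'   `chromosome`, `start_bp`, `end_bp`, `n_sems` (k), `n_probes` (m),
#'   `p_enrich`, `q`, `gene_symbols` (semicolon-joined genes of the SEM
#'   probes in the region).
#' @export
scan_enriched_regions <- function(calls, manifest, thresholds = NULL,
                                  window_probes = 10L, min_sems = 3L,
                                  q_max = 0.05) {
  if (window_probes < min_sems)
    stop("window_probes must be >= min_sems")
  unknown <- setdiff(unique(calls$probe_id), manifest$probe_id)
  if (length(unknown))
    stop("calls on probes absent from manifest: ",
         paste(utils::head(unknown, 3L), collapse = ", "))
  usable_ids <- manifest$probe_id
  if (!is.null(thresholds))
    usable_ids <- intersect(usable_ids, thresholds$probe_id[thresholds$usable])
  bb <- manifest[manifest$probe_id %in% usable_ids, , drop = FALSE]  # sorted
  n_usable <- nrow(bb)
  if (n_usable == 0L || nrow(calls) == 0L)
    return(empty_regions())
  res <- list()
  for (sid in unique(calls$sample_id)) {
    for (dir in c("hypo", "hyper")) {
      hit_ids <- calls$probe_id[calls$sample_id == sid & calls$direction == dir]
      if (length(hit_ids) == 0L) next
      r_s <- length(intersect(hit_ids, bb$probe_id)) / n_usable
      if (r_s == 0) next
      hit <- bb$probe_id %in% hit_ids
      wins <- windows_one_scan(bb, hit, window_probes, r_s)
      if (is.null(wins)) next
      wins$q <- stats::p.adjust(wins$p, method = "BH")
      keep <- wins$q <= q_max & wins$k >= min_sems
      if (!any(keep)) next
      merged <- merge_windows(wins[keep, , drop = FALSE], bb, hit)
      merged$sample_id <- sid
      merged$direction <- dir
      res[[length(res) + 1L]] <- merged
    }
  }
  if (length(res) == 0L) return(empty_regions())
  out <- do.call(rbind, res)
  out <- out[, c("sample_id", "direction", "chromosome", "start_bp", "end_bp",
                 "n_sems", "n_probes", "p_enrich", "q", "gene_symbols")]
  rownames(out) <- NULL
  class(out) <- c("enriched_regions", "data.frame")
  out
}

empty_regions <- function() {
  out <- data.frame(sample_id = character(0), direction = character(0),
                    chromosome = character(0), start_bp = integer(0),
                    end_bp = integer(0), n_sems = integer(0),
                    n_probes = integer(0), p_enrich = numeric(0),
                    q = numeric(0), gene_symbols = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("enriched_regions", "data.frame")
  out
}

# All sliding windows of w usable probes for one sample x direction.
# Returns NULL when no chromosome holds w usable probes.
windows_one_scan <- function(bb, hit, w, r_s) {
  out <- list()
  for (chr in unique(bb$chromosome)) {
    ci <- which(bb$chromosome == chr)
    if (length(ci) < w) next
    h <- hit[ci]
    # rolling sum of w consecutive probes
    cs <- cumsum(c(0L, as.integer(h)))
    k <- cs[(w + 1L):length(cs)] - cs[1L:(length(cs) - w)]
    start <- seq_len(length(ci) - w + 1L)
    out[[chr]] <- data.frame(chromosome = chr,
                             i_start = ci[start], i_end = ci[start + w - 1L],
                             k = k,
                             p = stats::pbinom(k - 1L, w, r_s, lower.tail = FALSE),
                             stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

# Merge overlapping significant windows (indices into the usable backbone bb).
merge_windows <- function(wins, bb, hit) {
  wins <- wins[order(wins$chromosome, wins$i_start), , drop = FALSE]
  res <- list()
  cur <- NULL
  flush <- function(cur) {
    ii <- cur$i_start:cur$i_end
    sem_ii <- ii[hit[ii]]
    genes <- unique(unlist(split_gene_symbols(bb$gene_symbols[sem_ii])))
    data.frame(chromosome = cur$chromosome,
               start_bp = bb$position[cur$i_start],
               end_bp = bb$position[cur$i_end],
               n_sems = length(sem_ii),
               n_probes = cur$i_end - cur$i_start + 1L,
               p_enrich = cur$p_min, q = cur$q_min,
               gene_symbols = paste(genes, collapse = ";"),
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(wins))) {
    wi <- wins[i, ]
    if (is.null(cur)) {
      cur <- list(chromosome = wi$chromosome, i_start = wi$i_start,
                  i_end = wi$i_end, p_min = wi$p, q_min = wi$q)
    } else if (wi$chromosome == cur$chromosome && wi$i_start <= cur$i_end) {
      cur$i_end <- max(cur$i_end, wi$i_end)
      cur$p_min <- min(cur$p_min, wi$p)
      cur$q_min <- min(cur$q_min, wi$q)
    } else {
      res[[length(res) + 1L]] <- flush(cur)
      cur <- list(chromosome = wi$chromosome, i_start = wi$i_start,
                  i_end = wi$i_end, p_min = wi$p, q_min = wi$q)
    }
  }
  res[[length(res) + 1L]] <- flush(cur)
  do.call(rbind, res)
}

#' Compare region-level gene sets across three populations
#'
#' Collects the genes named in per-sample enriched regions of each
#' population and direction, and returns the genes unique to cases, unique
#' to controls, and shared, retaining the supporting sample ids.
#'
#' @param case_regions,control_regions,reference_regions `enriched_regions`
#'   tables (may be empty).
#' @return list with per direction ("hypo"/"hyper"): `cases_only`,
#'   `controls_only`, `shared` (character vectors of gene symbols) and
#'   `support` (named list mapping gene -> sample ids).
#' @export
compare_region_genes <- function(case_regions, control_regions,
                                 reference_regions = empty_regions()) {
  genes_of <- function(regions, dir) {
    r <- regions[regions$direction == dir & nzchar(regions$gene_symbols), ,
                 drop = FALSE]
    gl <- split_gene_symbols(r$gene_symbols)
    support <- list()
    for (i in seq_along(gl)) {
      for (g in gl[[i]])
        support[[g]] <- unique(c(support[[g]], r$sample_id[i]))
    }
    support
  }
  out <- list()
  for (dir in c("hypo", "hyper")) {
    ca <- genes_of(case_regions, dir)
    co <- genes_of(control_regions, dir)
    rf <- genes_of(reference_regions, dir)
    cases_only <- setdiff(names(ca), union(names(co), names(rf)))
    controls_only <- setdiff(names(co), union(names(ca), names(rf)))
    shared <- intersect(names(ca), names(co))
    out[[dir]] <- list(cases_only = sort(cases_only),
                       controls_only = sort(controls_only),
                       shared = sort(shared),
                       support = c(ca[cases_only], co[controls_only]))
  }
  out
}
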
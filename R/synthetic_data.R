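#' Design parameters for a synthetic twin methylation cohort
#'
#' Captures the study conditions the generator emulates: a twin cohort with
#' monozygotic (MZ) and dizygotic (DZ) pairs, mostly discordant for case
#' status, probed on an array-like bimodal beta scale, with rare single-probe
#' stochastic epimutations spiked at group-differential rates in the hypo
#' direction and optional contiguous epimutation clusters.
#'
#' @param n_pairs_mz,n_pairs_dz Numbers of MZ and DZ twin pairs. Defaults 10
#'   and 10 (a 20-pair desk-scale cohort).
#' @param concordant_fraction Fraction of pairs concordant for case status
#'   (both twins cases); the rest are discordant (one case, one control).
#'   Default 0.2, mirroring a mostly-discordant twin design.
#' @param n_probes Number of CpG probes. Default 20000.
#' @param n_chromosomes Chromosomes the probes are spread over. Default 2.
#' @param probes_per_gene Consecutive probes sharing a synthetic gene symbol.
#'   Default 10.
#' @param sem_rate_control Expected spiked epimutations per control sample
#'   (Poisson mean, hypo and hyper together). Default 50.
#' @param sem_rate_case_multiplier Multiplier (>= 1) applied to the hypo
#'   spike rate in cases; hyper rates are identical across groups, matching
#'   the direction of the group effect the cohort emulates. Default 2.
#' @param hypo_fraction Share of spiked SEMs that are hypo-methylated.
#'   Default 0.5.
#' @param cluster_spikes List of cluster specifications, each a list with
#'   `sample` (a sample id or a role string "case#k" / "control#k"),
#'   `chromosome` (index), `span` (>= 2 probes), `direction`
#'   ("hypo"/"hyper") and optional `displacement` (default 0.2).
#' @param family_effect_sd Beta-scale SD of the per-pair shared shift; MZ
#'   pairs receive a second shared shift of the same SD. Default 0.02.
#' @param noise_sd Beta-scale SD of i.i.d. measurement noise. Default 0.03.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return List of class `cohort_design`.
#' @export
cohort_design <- function(n_pairs_mz = 10L, n_pairs_dz = 10L,
                          concordant_fraction = 0.2,
                          n_probes = 20000L, n_chromosomes = 2L,
                          probes_per_gene = 10L,
                          sem_rate_control = 50,
                          sem_rate_case_multiplier = 2,
                          hypo_fraction = 0.5,
                          cluster_spikes = list(),
                          family_effect_sd = 0.02, noise_sd = 0.03,
                          seed = 1L) {
  stopifnot(n_pairs_mz >= 0, n_pairs_dz >= 0, n_pairs_mz + n_pairs_dz >= 1,
            concordant_fraction >= 0, concordant_fraction <= 1,
            n_probes >= 1, sem_rate_control >= 0,
            sem_rate_case_multiplier >= 1,
            hypo_fraction >= 0, hypo_fraction <= 1,
            family_effect_sd >= 0, noise_sd >= 0)
  for (cl in cluster_spikes)
    if (is.null(cl$span) || cl$span < 2L) stop("cluster span must be >= 2 probes")
  structure(list(n_pairs_mz = n_pairs_mz, n_pairs_dz = n_pairs_dz,
                 concordant_fraction = concordant_fraction,
                 n_probes = n_probes, n_chromosomes = n_chromosomes,
                 probes_per_gene = probes_per_gene,
                 sem_rate_control = sem_rate_control,
                 sem_rate_case_multiplier = sem_rate_case_multiplier,
                 hypo_fraction = hypo_fraction,
                 cluster_spikes = cluster_spikes,
                 family_effect_sd = family_effect_sd, noise_sd = noise_sd,
                 seed = seed),
            class = "cohort_design")
}

#' Generate a synthetic CpG manifest
#'
#' Probes are spread evenly over chromosomes at increasing positions with
#' inter-probe gaps drawn uniformly from \[200, 2000\] bp. Consecutive
#' blocks of `probes_per_gene` probes share a synthetic gene symbol; every
#' fourth gene block is labelled a CpG island in `region_class`.
#'
#' @param n_probes Total probes (>= 1).
#' @param n_chromosomes Number of chromosomes.
#' @param probes_per_gene Block size sharing one gene symbol.
#' @param seed Integer seed.
#' @return A `cpg_manifest`.
#' @export
generate_manifest <- function(n_probes, n_chromosomes = 2L,
                              probes_per_gene = 10L, seed = 1L) {
  if (n_probes < 1L) stop("n_probes must be positive")
  set.seed(seed)
  per_chr <- diff(round(seq(0, n_probes, length.out = n_chromosomes + 1L)))
  rows <- list()
  k <- 0L
  for (ci in seq_len(n_chromosomes)) {
    np <- per_chr[ci]
    if (np == 0L) next
    gaps <- sample(200:2000, np, replace = TRUE)
    pos <- cumsum(gaps)
    gene_block <- (seq_len(np) - 1L) %/% probes_per_gene
    rows[[ci]] <- data.frame(
      probe_id = sprintf("cg%07d", k + seq_len(np)),
      chromosome = sprintf("chr%02d", ci),
      position = pos,
      gene_symbols = sprintf("G%02d_%04d", ci, gene_block + 1L),
      region_class = ifelse(gene_block %% 4L == 3L, "island", "other"),
      stringsAsFactors = FALSE)
    k <- k + np
  }
  as_cpg_manifest(do.call(rbind, rows))
}

resolve_sample_role <- function(role, sheet) {
  if (role %in% sheet$sample_id) return(role)
  m <- regmatches(role, regexec("^(case|control)#([0-9]+)$", role))[[1L]]
  if (length(m) == 3L) {
    ids <- sheet$sample_id[sheet$group == m[2L]]
    k <- as.integer(m[3L])
    if (k >= 1L && k <= length(ids)) return(ids[k])
  }
  stop("cannot resolve cluster sample role '", role, "'")
}

#' Generate a twin-structured beta matrix with known spiked epimutations
#'
#' Per-probe baseline means follow a bimodal mixture (modes near 0.1 and
#' 0.85 with minor intermediate mass) mimicking array beta distributions.
#' Co-twins share a per-pair random shift (SD `family_effect_sd`); MZ pairs
#' share an additional shift of the same SD, so MZ within-pair correlation
#' exceeds DZ. I.i.d. Gaussian noise (SD `noise_sd`) is added and values
#' truncated to \[0, 1\].
#'
#' Single-probe spikes: per sample, a Poisson number of probes (group- and
#' direction-specific rates, see [cohort_design()]) is displaced strictly
#' beyond the cohort's pre-spike outlier bound (Q1 - 3 IQR for hypo,
#' Q3 + 3 IQR for hyper) by at least 0.15 beta units, then clamped to
#' \[0.001, 0.999\]; only probes where the full displacement fits inside the
#' clamp are eligible, so every recorded spike is guaranteed callable.
#' Cluster spikes displace every probe in a contiguous span the same way
#' (individual cluster probes may be uncallable where the local bound leaves
#' no room below 0.001 / above 0.999).
#'
#' @param design A `cohort_design`.
#' @param manifest A `cpg_manifest` with `nrow(manifest) == design$n_probes`.
#'   Default: generated from the design.
#' @return List with `beta` (`beta_matrix`), `samples` (`sample_sheet`) and
#'   `truth` (list `sems`: data.frame sample_id/probe_id/direction/value/
#'   ref_lower/ref_upper; `clusters`: data.frame sample_id/chromosome/
#'   start_index/end_index/start_bp/end_bp/direction/span).
#' @export
generate_cohort <- function(design, manifest = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  if (is.null(manifest))
    manifest <- generate_manifest(design$n_probes, design$n_chromosomes,
                                  design$probes_per_gene, design$seed)
  if (nrow(manifest) != design$n_probes)
    stop("manifest size does not match design$n_probes")
  set.seed(design$seed + 1L)
  np <- design$n_probes
  n_pairs <- design$n_pairs_mz + design$n_pairs_dz
  zyg <- rep(c("MZ", "DZ"), c(design$n_pairs_mz, design$n_pairs_dz))
  n_conc <- round(design$concordant_fraction * n_pairs)
  # spread concordant pairs over both zygosities deterministically
  conc <- rep(FALSE, n_pairs)
  if (n_conc > 0L)
    conc[round(seq(1L, n_pairs, length.out = n_conc))] <- TRUE
  pair_id <- sprintf("P%02d", seq_len(n_pairs))
  sex_pair <- sample(c("M", "F"), n_pairs, replace = TRUE)
  sheet <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
    sexes <- if (zyg[i] == "MZ") rep(sex_pair[i], 2L)
             else c(sex_pair[i], sample(c("M", "F"), 1L))
    data.frame(sample_id = paste0(zyg[i], sprintf("%02d", i), c("A", "B")),
               family_id = sprintf("F%02d", i), pair_id = pair_id[i],
               zygosity = zyg[i],
               group = if (conc[i]) c("case", "case") else c("case", "control"),
               sex = sexes, batch = "b1", stringsAsFactors = FALSE)
  }))
  sheet <- as_sample_sheet(sheet)
  n_s <- nrow(sheet)

  # baseline bimodal probe means
  comp <- sample(1:3, np, replace = TRUE, prob = c(0.45, 0.45, 0.10))
  mu <- numeric(np)
  mu[comp == 1L] <- stats::runif(sum(comp == 1L), 0.05, 0.15)
  mu[comp == 2L] <- stats::runif(sum(comp == 2L), 0.80, 0.90)
  mu[comp == 3L] <- stats::runif(sum(comp == 3L), 0.30, 0.70)

  pair_idx <- match(sheet$pair_id, pair_id)
  fam_shift <- matrix(stats::rnorm(np * n_pairs, 0, design$family_effect_sd),
                      nrow = np)
  mz_shift <- matrix(stats::rnorm(np * n_pairs, 0, design$family_effect_sd),
                     nrow = np)
  mz_shift[, zyg != "MZ"] <- 0
  beta <- mu + fam_shift[, pair_idx, drop = FALSE] +
    mz_shift[, pair_idx, drop = FALSE] +
    matrix(stats::rnorm(np * n_s, 0, design$noise_sd), nrow = np)
  beta <- pmin(pmax(beta, 0), 1)
  rownames(beta) <- manifest$probe_id
  colnames(beta) <- sheet$sample_id

  # pre-spike outlier bounds over the full cohort
  thr <- compute_reference_thresholds(as_beta_matrix(beta), sheet$sample_id)
  elig_hypo <- which(thr$usable & thr$lower - 0.20 >= 0.001)
  elig_hyper <- which(thr$usable & thr$upper + 0.20 <= 0.999)

  sems <- list()
  rate_hypo <- design$sem_rate_control * design$hypo_fraction
  rate_hyper <- design$sem_rate_control * (1 - design$hypo_fraction)
  for (j in seq_len(n_s)) {
    is_case <- sheet$group[j] == "case"
    lam_h <- rate_hypo * if (is_case) design$sem_rate_case_multiplier else 1
    n_h <- min(stats::rpois(1L, lam_h), length(elig_hypo))
    n_r <- min(stats::rpois(1L, rate_hyper), length(elig_hyper))
    ph <- if (n_h > 0L) elig_hypo[sample.int(length(elig_hypo), n_h)] else integer(0)
    # a mid-range probe can be eligible in both directions; never spike the
    # same cell twice
    elig_r <- setdiff(elig_hyper, ph)
    n_r <- min(n_r, length(elig_r))
    pr <- if (n_r > 0L) elig_r[sample.int(length(elig_r), n_r)] else integer(0)
    if (n_h > 0L) {
      disp <- 0.15 + stats::runif(n_h, 0, 0.05)
      beta[cbind(ph, j)] <- pmax(thr$lower[ph] - disp, 0.001)
    }
    if (n_r > 0L) {
      disp <- 0.15 + stats::runif(n_r, 0, 0.05)
      beta[cbind(pr, j)] <- pmin(thr$upper[pr] + disp, 0.999)
    }
    if (n_h + n_r > 0L)
      sems[[length(sems) + 1L]] <- data.frame(
        sample_id = sheet$sample_id[j],
        probe_id = thr$probe_id[c(ph, pr)],
        direction = rep(c("hypo", "hyper"), c(n_h, n_r)),
        value = beta[cbind(c(ph, pr), j)],
        ref_lower = thr$lower[c(ph, pr)],
        ref_upper = thr$upper[c(ph, pr)],
        stringsAsFactors = FALSE)
  }
  truth_sems <- if (length(sems)) do.call(rbind, sems) else
    data.frame(sample_id = character(0), probe_id = character(0),
               direction = character(0), value = numeric(0),
               ref_lower = numeric(0), ref_upper = numeric(0),
               stringsAsFactors = FALSE)

  clusters <- list()
  for (cl in design$cluster_spikes) {
    sid <- resolve_sample_role(cl$sample, sheet)
    j <- match(sid, sheet$sample_id)
    chr <- sprintf("chr%02d", cl$chromosome)
    ci <- which(manifest$chromosome == chr)
    if (length(ci) < cl$span)
      stop("cluster span exceeds probe count on ", chr)
    disp0 <- if (is.null(cl$displacement)) 0.2 else cl$displacement
    # spikes must be callable after clamping: place the span where the
    # displacement fits inside [0.001, 0.999] for (nearly) all member probes
    callable <- if (cl$direction == "hypo") {
      thr$usable[ci] & thr$lower[ci] - disp0 >= 0.001
    } else {
      thr$usable[ci] & thr$upper[ci] + disp0 <= 0.999
    }
    roll <- cumsum(c(0L, as.integer(callable)))
    n_call <- roll[(cl$span + 1L):length(roll)] -
      roll[1L:(length(roll) - cl$span)]
    good <- which(n_call >= ceiling(0.8 * cl$span))
    start <- if (length(good)) good[sample.int(length(good), 1L)]
             else which.max(n_call)
    ii <- ci[start:(start + cl$span - 1L)]
    disp <- disp0
    if (cl$direction == "hypo") {
      beta[cbind(ii, j)] <- pmin(pmax(thr$lower[ii] - disp, 0.001), 0.999)
    } else {
      beta[cbind(ii, j)] <- pmin(pmax(thr$upper[ii] + disp, 0.001), 0.999)
    }
    clusters[[length(clusters) + 1L]] <- data.frame(
      sample_id = sid, chromosome = chr,
      start_index = ii[1L], end_index = ii[length(ii)],
      start_bp = manifest$position[ii[1L]],
      end_bp = manifest$position[ii[length(ii)]],
      direction = cl$direction, span = cl$span, stringsAsFactors = FALSE)
  }
  truth_clusters <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(sample_id = character(0), chromosome = character(0),
               start_index = integer(0), end_index = integer(0),
               start_bp = integer(0), end_bp = integer(0),
               direction = character(0), span = integer(0),
               stringsAsFactors = FALSE)

  list(beta = as_beta_matrix(beta), samples = sheet,
       truth = list(sems = truth_sems, clusters = truth_clusters))
}
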
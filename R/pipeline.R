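#' Run the full SEM analysis pipeline on a configuration
#'
#' Orchestrates simulate (optional) -> threshold/call -> burden summaries and
#' group test -> region scan -> gene-set annotation -> differential
#' methylation, writing every stage artifact plus a JSON manifest with MD5
#' checksums, the seed and per-stage row counts. All randomness flows from
#' the single `seed` entry (the generator consumes it directly; no other
#' stage is stochastic), so identical configurations give bit-identical
#' artifacts.
#'
#' @param config A named list, or the path to a YAML file holding one.
#'   Recognised blocks: `seed` (integer), `out_dir`, `beta`, `samples`,
#'   `manifest` (input paths, unless `simulate` is given), `simulate`
#'   (arguments for [cohort_design()]), `call` (`iqr_floor`), `regions`
#'   (`window_probes`, `min_sems`, `q_max`), `burden` (`covariates`),
#'   `genes` (`candidates`), `diffmeth` (`classes`). Unknown keys are
#'   rejected.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Invisibly, the artifact manifest (named list of files with MD5
#'   checksums).
#' @export
run_sem_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "out_dir", "beta", "samples", "manifest", "simulate",
             "call", "regions", "burden", "genes", "diffmeth")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  log_stage <- function(stage, ...) message(sprintf("[%s] ", stage), ...)
  artifacts <- character(0)
  emit <- function(name) artifacts <<- c(artifacts, file.path(out_dir, name))

  stage <- "input"
  tryCatch({
    if (!is.null(config$simulate)) {
      stage <- "simulate"
      des <- do.call(cohort_design, c(config$simulate, list(seed = seed)))
      manifest <- generate_manifest(des$n_probes, des$n_chromosomes,
                                    des$probes_per_gene, seed)
      cohort <- generate_cohort(des, manifest)
      beta <- cohort$beta; samples <- cohort$samples
      write_beta_matrix(beta, file.path(out_dir, "beta.tsv")); emit("beta.tsv")
      write_sample_sheet(samples, file.path(out_dir, "samples.csv")); emit("samples.csv")
      write_manifest(manifest, file.path(out_dir, "manifest.tsv")); emit("manifest.tsv")
      utils::write.table(cohort$truth$sems, file.path(out_dir, "truth_sems.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit("truth_sems.tsv")
      utils::write.table(cohort$truth$clusters, file.path(out_dir, "truth_clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit("truth_clusters.tsv")
      log_stage(stage, sprintf("seed=%d, %d probes x %d samples, %d spiked SEMs, %d clusters",
                               seed, nrow(beta), ncol(beta),
                               nrow(cohort$truth$sems), nrow(cohort$truth$clusters)))
    } else {
      for (key in c("beta", "samples", "manifest"))
        if (is.null(config[[key]]))
          stop("config lacks both a 'simulate' block and a '", key, "' path")
      beta <- read_beta_matrix(config$beta)
      samples <- read_sample_sheet(config$samples)
      manifest <- read_manifest(config$manifest)
      log_stage(stage, sprintf("%d probes x %d samples read", nrow(beta), ncol(beta)))
    }

    stage <- "call"
    iqr_floor <- if (is.null(config$call$iqr_floor)) 1e-6 else config$call$iqr_floor
    cohort_ids <- samples$sample_id[samples$group %in% c("case", "control")]
    thr <- compute_reference_thresholds(beta, cohort_ids, iqr_floor)
    calls <- call_sems(beta, thr, cohort_ids)
    utils::write.table(as.data.frame(calls), file.path(out_dir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("calls.tsv")
    burden <- sem_burden(calls, cohort_ids)
    utils::write.table(as.data.frame(burden), file.path(out_dir, "burden.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("burden.tsv")
    log_stage(stage, sprintf("%d calls, %d usable probes", nrow(calls), sum(thr$usable)))

    stage <- "burden-test"
    covs <- if (is.null(config$burden$covariates)) "sex" else config$burden$covariates
    tests <- list()
    for (dir in c("hypo", "hyper")) {
      summ <- summarize_burden(burden, samples, dir)
      fit <- tryCatch(compare_burden_mixed(burden, samples, dir, covs),
                      error = function(e) NULL)
      tests[[dir]] <- data.frame(
        direction = dir,
        case_median = summ$median[summ$group == "case"],
        control_median = summ$median[summ$group == "control"],
        estimate = if (is.null(fit)) NA_real_ else fit$estimate,
        p_value = if (is.null(fit)) NA_real_ else fit$p_value,
        method = if (is.null(fit)) NA_character_ else fit$method,
        stringsAsFactors = FALSE)
    }
    bt <- do.call(rbind, tests)
    utils::write.table(bt, file.path(out_dir, "burden_test.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("burden_test.tsv")
    log_stage(stage, sprintf("hypo p=%.3g, hyper p=%.3g", bt$p_value[1L], bt$p_value[2L]))

    stage <- "regions"
    rp <- config$regions
    regions <- scan_enriched_regions(
      calls, manifest, thr,
      window_probes = if (is.null(rp$window_probes)) 10L else rp$window_probes,
      min_sems = if (is.null(rp$min_sems)) 3L else rp$min_sems,
      q_max = if (is.null(rp$q_max)) 0.05 else rp$q_max)
    utils::write.table(as.data.frame(regions), file.path(out_dir, "regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("regions.tsv")
    write_regions_bed(regions, file.path(out_dir, "regions.bed")); emit("regions.bed")
    log_stage(stage, sprintf("%d enriched regions", nrow(regions)))

    stage <- "genes"
    sets <- annotate_sem_genes(calls, manifest, samples)
    venn <- venn_univocal(sets)
    utils::write.table(data.frame(set = names(venn$counts), n = venn$counts),
                       file.path(out_dir, "venn_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("venn_counts.tsv")
    cands <- if (is.null(config$genes$candidates)) default_candidate_genes()
             else config$genes$candidates
    hits <- candidate_gene_screen(venn, cands, sets)
    utils::write.table(hits, file.path(out_dir, "candidate_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("candidate_hits.tsv")
    log_stage(stage, sprintf("univocal case genes: %d hypo / %d hyper; %d candidate hits",
                             venn$counts["univocal_cases_hypo"],
                             venn$counts["univocal_cases_hyper"], nrow(hits)))

    stage <- "diffmeth"
    site <- paired_site_test(beta, samples)
    utils::write.table(as.data.frame(site), file.path(out_dir, "diffmeth_site.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("diffmeth_site.tsv")
    utils::write.table(volcano_table(site), file.path(out_dir, "volcano_site.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("volcano_site.tsv")
    classes <- if (is.null(config$diffmeth$classes)) "gene" else config$diffmeth$classes
    for (cls in classes) {
      rt <- suppressMessages(region_test(beta, samples, manifest, cls))
      fn <- sprintf("diffmeth_%s.tsv", cls)
      utils::write.table(as.data.frame(rt), file.path(out_dir, fn),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit(fn)
    }
    log_stage(stage, sprintf("%d sites tested, min q = %.3g",
                             sum(!is.na(site$p)), suppressWarnings(min(site$q, na.rm = TRUE))))
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  manifest_out <- list(seed = seed,
                       files = lapply(stats::setNames(artifacts, basename(artifacts)),
                                      function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest_out, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest_out)
}
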
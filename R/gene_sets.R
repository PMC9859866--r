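#' Default candidate-gene list for the congenital-hypothyroidism screen
#'
#' Dyshormonogenesis and thyroid-development genes plus the imprinted loci
#' recurrently implicated in twin-discordance methylation studies.
#'
#' @return Character vector of gene symbols.
#' @export
default_candidate_genes <- function() {
  c("DUOX2", "DUOXA2", "TPO", "PAX8", "NKX2-1", "NKX2-5", "GLIS3",
    "SLC26A4", "FOXI1", "TSHB", "BICC1", "FAM50B", "MEG8")
}

#' Annotate single-probe SEM calls to genes, by population and direction
#'
#' A gene enters a population-direction set iff at least one SEM of that
#' direction, in at least one sample of that population, falls on a probe
#' annotated to the gene. Probes without gene annotation contribute nothing;
#' probes annotated to several genes contribute to each.
#'
#' @param calls `sem_calls`.
#' @param manifest `cpg_manifest` (must cover all called probes).
#' @param samples `sample_sheet` giving each sample's population via its
#'   `group` column (case/control/reference).
#' @return Object of class `population_gene_sets`: nested list
#'   `[[population]][[direction]]` of data.frames with `gene`, `n_evidence`
#'   (supporting sample-probe pairs) and `samples` (semicolon-joined ids).
#' @export
annotate_sem_genes <- function(calls, manifest, samples) {
  unknown <- setdiff(unique(calls$probe_id), manifest$probe_id)
  if (length(unknown))
    stop("called probe(s) missing from manifest: ",
         paste(utils::head(unknown, 3L), collapse = ", "))
  pop <- samples$group[match(calls$sample_id, samples$sample_id)]
  if (anyNA(pop)) stop("calls contain samples absent from the sample sheet")
  gmap <- split_gene_symbols(
    manifest$gene_symbols[match(calls$probe_id, manifest$probe_id)])
  ng <- lengths(gmap)
  flat <- data.frame(population = rep(pop, ng),
                     direction = rep(calls$direction, ng),
                     sample_id = rep(calls$sample_id, ng),
                     gene = unlist(gmap, use.names = FALSE),
                     stringsAsFactors = FALSE)
  out <- list()
  for (p in c("case", "control", "reference")) {
    out[[p]] <- list()
    for (dir in c("hypo", "hyper")) {
      f <- flat[flat$population == p & flat$direction == dir, , drop = FALSE]
      if (nrow(f) == 0L) {
        out[[p]][[dir]] <- data.frame(gene = character(0),
                                      n_evidence = integer(0),
                                      samples = character(0),
                                      stringsAsFactors = FALSE)
        next
      }
      sp <- split(f$sample_id, f$gene)
      out[[p]][[dir]] <- data.frame(
        gene = names(sp),
        n_evidence = lengths(sp),
        samples = vapply(sp, function(s) paste(sort(unique(s)), collapse = ";"), ""),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  class(out) <- "population_gene_sets"
  out
}

#' @export
print.population_gene_sets <- function(x, ...) {
  cat("population_gene_sets:\n")
  for (p in names(x))
    cat(sprintf("  %-9s hypo: %5d genes   hyper: %5d genes\n",
                p, nrow(x[[p]]$hypo), nrow(x[[p]]$hyper)))
  invisible(x)
}

#' Three-population Venn analysis of SEM-annotated genes
#'
#' A gene is "univocal" for a population when it appears in that population's
#' set for a direction and in neither of the other two populations' sets for
#' the same direction. Also reports the cross-direction intersections
#' (genes hyper-methylated univocally in one group and hypo-methylated
#' univocally in the other) and the genes carrying both hyper- and
#' hypo-methylation in cases — in two variants: restricted to case-univocal
#' genes in both directions, and unrestricted (any case gene in both
#' directions).
#'
#' @param sets `population_gene_sets` from [annotate_sem_genes()].
#' @return Object of class `sem_venn`: lists `univocal_cases`,
#'   `univocal_controls` (each with `hypo`/`hyper` character vectors),
#'   `cross` (`controls_hyper_cases_hypo`, `cases_hyper_controls_hypo`),
#'   `cases_both_directions` (`univocal` and `all` variants) and `counts`.
#' @export
venn_univocal <- function(sets) {
  g <- function(p, dir) sets[[p]][[dir]]$gene
  uni <- function(dir) {
    list(cases = setdiff(g("case", dir), union(g("control", dir), g("reference", dir))),
         controls = setdiff(g("control", dir), union(g("case", dir), g("reference", dir))))
  }
  uh <- uni("hypo"); ur <- uni("hyper")
  res <- list(
    univocal_cases = list(hypo = sort(uh$cases), hyper = sort(ur$cases)),
    univocal_controls = list(hypo = sort(uh$controls), hyper = sort(ur$controls)),
    cross = list(
      controls_hyper_cases_hypo = sort(intersect(ur$controls, uh$cases)),
      cases_hyper_controls_hypo = sort(intersect(ur$cases, uh$controls))),
    cases_both_directions = list(
      univocal = sort(intersect(uh$cases, ur$cases)),
      all = sort(intersect(g("case", "hypo"), g("case", "hyper")))))
  res$counts <- c(
    univocal_cases_hypo = length(res$univocal_cases$hypo),
    univocal_controls_hypo = length(res$univocal_controls$hypo),
    univocal_cases_hyper = length(res$univocal_cases$hyper),
    univocal_controls_hyper = length(res$univocal_controls$hyper),
    controls_hyper_cases_hypo = length(res$cross$controls_hyper_cases_hypo),
    cases_hyper_controls_hypo = length(res$cross$cases_hyper_controls_hypo),
    cases_both_directions_univocal = length(res$cases_both_directions$univocal),
    cases_both_directions_all = length(res$cases_both_directions$all))
  class(res) <- "sem_venn"
  res
}

#' @export
print.sem_venn <- function(x, ...) {
  cat("sem_venn univocal gene counts:\n")
  print(x$counts)
  invisible(x)
}

#' Screen univocal gene sets against a candidate list
#'
#' Transparent membership screen: for each candidate gene, reports whether
#' it occurs in the univocal case or control set of each direction, with
#' the supporting samples when population sets are supplied.
#'
#' @param venn `sem_venn` from [venn_univocal()].
#' @param candidates Character vector of gene symbols (case-sensitive exact
#'   match). Default [default_candidate_genes()].
#' @param sets Optional `population_gene_sets`, used to recover supporting
#'   sample ids.
#' @return data.frame with one row per candidate found in at least one
#'   univocal set: `gene`, `set` ("cases"/"controls"), `direction`,
#'   `samples`.
#' @export
candidate_gene_screen <- function(venn, candidates = default_candidate_genes(),
                                  sets = NULL) {
  if (length(candidates) == 0L) stop("candidate list is empty")
  rows <- list()
  for (side in c("cases", "controls")) {
    uv <- venn[[paste0("univocal_", side)]]
    for (dir in c("hypo", "hyper")) {
      hit <- intersect(candidates, uv[[dir]])
      for (gene in hit) {
        supp <- ""
        if (!is.null(sets)) {
          tab <- sets[[if (side == "cases") "case" else "control"]][[dir]]
          supp <- tab$samples[match(gene, tab$gene)]
        }
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, set = side, direction = dir, samples = supp,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(gene = character(0), set = character(0),
                      direction = character(0), samples = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
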
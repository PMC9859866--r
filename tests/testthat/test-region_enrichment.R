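test_that("no calls yield an empty region list; bad window params error", {
  m <- generate_manifest(100, 1, 10, seed = 1)
  empty <- fake_calls(character(0), character(0), character(0))
  expect_equal(nrow(scan_enriched_regions(empty, m)), 0L)
  calls <- fake_calls("s1", m$probe_id[1], "hypo")
  expect_error(scan_enriched_regions(calls, m, window_probes = 2L, min_sems = 3L),
               "window_probes")
  expect_error(scan_enriched_regions(fake_calls("s1", "nope", "hypo"), m),
               "absent from manifest")
})

test_that("window p-value equals the closed-form binomial upper tail", {
  # 10,000-probe genome, 8 SEMs packed in one 10-probe window, 2 elsewhere
  m <- generate_manifest(10000, 1, 10, seed = 2)
  hit_probes <- c(m$probe_id[101:108], m$probe_id[c(4000, 8000)])
  calls <- fake_calls(rep("s1", 10), hit_probes, "hypo")
  r_s <- 10 / 10000
  regs <- scan_enriched_regions(calls, m, window_probes = 10L)
  expect_gte(nrow(regs), 1L)
  top <- regs[which.min(regs$p_enrich), ]
  expect_equal(top$n_sems, 8L)
  p_hand <- sum(choose(10, 8:10) * r_s^(8:10) * (1 - r_s)^(10 - (8:10)))
  expect_equal(top$p_enrich, p_hand, tolerance = 1e-12)
  expect_true(all(regs$q >= 0 & regs$q <= 1))
})

test_that("scan equals exhaustive window enumeration on small instances", {
  for (seed in c(3, 9, 27)) {
    set.seed(seed)
    m <- generate_manifest(400, 2, 10, seed = seed)
    # two samples with clumped + scattered calls in both directions
    mk <- function(sid, dir, clump_at, clump_n, scatter_n) {
      idx <- c(clump_at:(clump_at + clump_n - 1L),
               sample(nrow(m), scatter_n))
      fake_calls(rep(sid, length(idx)), m$probe_id[unique(idx)][seq_along(unique(idx))],
                 dir)
    }
    calls <- do.call(rbind, list(mk("sA", "hypo", 20, 6, 8),
                                 mk("sA", "hyper", 250, 4, 5),
                                 mk("sB", "hypo", 120, 5, 10)))
    class(calls) <- c("sem_calls", "data.frame")
    got <- scan_enriched_regions(calls, m, window_probes = 8L,
                                 min_sems = 3L, q_max = 0.1)
    ora <- naive_region_scan(calls, m, window_probes = 8L,
                             min_sems = 3L, q_max = 0.1)
    got <- got[order(got$sample_id, got$direction, got$chromosome, got$start_bp),
               c("sample_id", "direction", "chromosome", "start_bp", "end_bp",
                 "n_sems", "p_enrich", "q")]
    rownames(got) <- rownames(ora) <- NULL
    expect_equal(got, ora, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("merging merged regions is idempotent", {
  m <- generate_manifest(300, 1, 10, seed = 4)
  calls <- fake_calls(rep("s1", 12), m$probe_id[c(50:57, 60:63)], "hypo")
  regs <- scan_enriched_regions(calls, m, window_probes = 10L)
  # regions are maximal: no two share a chromosome and overlap
  if (nrow(regs) > 1L) {
    for (i in 1:(nrow(regs) - 1L)) {
      same <- regs$chromosome == regs$chromosome[i] & seq_len(nrow(regs)) > i
      expect_true(all(regs$start_bp[same] > regs$end_bp[i] |
                        regs$end_bp[same] < regs$start_bp[i]))
    }
  }
  expect_gte(nrow(regs), 1L)
})

test_that("a spiked cluster is recovered and annotated to its gene", {
  des <- cohort_design(n_probes = 3000, n_pairs_mz = 5, n_pairs_dz = 5,
                       sem_rate_control = 10, seed = 19,
                       cluster_spikes = list(list(sample = "case#3",
                                                  chromosome = 1, span = 9,
                                                  direction = "hypo")))
  ch <- generate_cohort(des)
  man <- generate_manifest(des$n_probes, des$n_chromosomes,
                           des$probes_per_gene, des$seed)
  thr <- compute_reference_thresholds(ch$beta, ch$samples$sample_id)
  calls <- call_sems(ch$beta, thr)
  regs <- scan_enriched_regions(calls, man, thr)
  cl <- ch$truth$clusters
  hit <- regs$sample_id == cl$sample_id & regs$direction == "hypo" &
    regs$chromosome == cl$chromosome &
    regs$start_bp <= cl$end_bp & regs$end_bp >= cl$start_bp
  expect_true(any(hit))
  cluster_genes <- unique(unlist(split_gene_symbols(
    man$gene_symbols[cl$start_index:cl$end_index])))
  found_genes <- unique(unlist(split_gene_symbols(regs$gene_symbols[hit])))
  expect_true(any(cluster_genes %in% found_genes))
})

test_that("three-population region gene comparison isolates population-unique genes", {
  mk_reg <- function(sid, dir, genes) {
    data.frame(sample_id = sid, direction = dir, chromosome = "chr01",
               start_bp = 1L, end_bp = 2L, n_sems = 3L, n_probes = 10L,
               p_enrich = 1e-5, q = 1e-3, gene_symbols = genes,
               stringsAsFactors = FALSE)
  }
  cases <- rbind(mk_reg("c1", "hypo", "G1;G2"), mk_reg("c2", "hypo", "G2"))
  ctrls <- mk_reg("k1", "hypo", "G2")
  out <- compare_region_genes(cases, ctrls)
  expect_equal(out$hypo$cases_only, "G1")
  expect_equal(out$hypo$controls_only, character(0))
  expect_equal(out$hypo$shared, "G2")
  expect_equal(out$hypo$support$G1, "c1")

  # identical inputs -> nothing unique
  same <- compare_region_genes(cases, cases)
  expect_equal(same$hypo$cases_only, character(0))
  expect_equal(same$hypo$controls_only, character(0))
})
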
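man3 <- as_cpg_manifest(data.frame(
  probe_id = c("p1", "p2", "p3", "p4"),
  chromosome = "chr01",
  position = c(100L, 300L, 500L, 700L),
  gene_symbols = c("G1;G2", "G3", "", "G4"),
  stringsAsFactors = FALSE))

sheet3 <- as_sample_sheet(data.frame(
  sample_id = c("ca1", "co1", "re1"),
  family_id = c("F1", "F1", "F2"), pair_id = c("P1", "P1", "P2"),
  zygosity = "DZ", group = c("case", "control", "reference"),
  sex = "F", batch = "b1", stringsAsFactors = FALSE))

test_that("SEM gene annotation honours multi-gene probes and populations", {
  calls <- fake_calls("ca1", "p1", "hypo")
  sets <- annotate_sem_genes(calls, man3, sheet3)
  expect_setequal(sets$case$hypo$gene, c("G1", "G2"))
  expect_equal(nrow(sets$case$hyper), 0L)
  expect_equal(nrow(sets$control$hypo), 0L)

  # unannotated probes contribute nothing; missing probes error
  none <- annotate_sem_genes(fake_calls("ca1", "p3", "hypo"), man3, sheet3)
  expect_equal(nrow(none$case$hypo), 0L)
  expect_error(annotate_sem_genes(fake_calls("ca1", "px", "hypo"), man3, sheet3),
               "missing from manifest.*px")

  empty <- annotate_sem_genes(fake_calls(character(0), character(0), character(0)),
                              man3, sheet3)
  expect_true(all(vapply(c("case", "control", "reference"),
                         function(p) nrow(empty[[p]]$hypo) == 0L, logical(1))))
})

test_that("spiked sample-specific SEM genes are recovered exactly", {
  des <- cohort_design(n_probes = 2000, n_pairs_mz = 4, n_pairs_dz = 4,
                       sem_rate_control = 15, seed = 23)
  ch <- generate_cohort(des)
  man <- generate_manifest(des$n_probes, des$n_chromosomes,
                           des$probes_per_gene, des$seed)
  thr <- compute_reference_thresholds(ch$beta, ch$samples$sample_id)
  calls <- call_sems(ch$beta, thr)
  sets <- annotate_sem_genes(calls, man, ch$samples)
  tr <- ch$truth$sems
  tr_case <- tr[tr$direction == "hypo" &
                  ch$samples$group[match(tr$sample_id, ch$samples$sample_id)] == "case", ]
  truth_genes <- unique(unlist(split_gene_symbols(
    man$gene_symbols[match(tr_case$probe_id, man$probe_id)])))
  expect_true(all(truth_genes %in% sets$case$hypo$gene))
})

test_that("univocal sets follow three-way set difference", {
  mk_sets <- function(case_h, ctrl_h, ref_h) {
    s <- list(case = list(hypo = data.frame(gene = case_h),
                          hyper = data.frame(gene = character(0))),
              control = list(hypo = data.frame(gene = ctrl_h),
                             hyper = data.frame(gene = character(0))),
              reference = list(hypo = data.frame(gene = ref_h),
                               hyper = data.frame(gene = character(0))))
    class(s) <- "population_gene_sets"
    s
  }
  v <- venn_univocal(mk_sets(c("A", "B", "C"), c("B", "D"), "C"))
  expect_equal(v$univocal_cases$hypo, "A")
  expect_equal(v$univocal_controls$hypo, "D")
  expect_equal(unname(v$counts["univocal_cases_hypo"]), 1L)

  eq <- venn_univocal(mk_sets(c("A", "B"), c("A", "B"), c("A", "B")))
  expect_equal(eq$univocal_cases$hypo, character(0))
  expect_equal(eq$univocal_controls$hypo, character(0))
})

test_that("partition identity and monotonicity hold on random set triples", {
  pool <- sprintf("G%03d", 1:60)
  set.seed(99)
  for (i in 1:50) {
    mk <- function() sample(pool, rpois(1, 15))
    case_h <- mk(); ctrl_h <- mk(); ref_h <- mk()
    s <- list(case = list(hypo = data.frame(gene = case_h),
                          hyper = data.frame(gene = mk())),
              control = list(hypo = data.frame(gene = ctrl_h),
                             hyper = data.frame(gene = mk())),
              reference = list(hypo = data.frame(gene = ref_h),
                               hyper = data.frame(gene = mk())))
    class(s) <- "population_gene_sets"
    v <- venn_univocal(s)
    # |univocal cases| + |cases covered by the other populations| = |cases|
    expect_equal(length(v$univocal_cases$hypo) +
                   length(intersect(case_h, union(ctrl_h, ref_h))),
                 length(unique(case_h)))
    # univocal sets are disjoint from both other populations
    expect_equal(intersect(v$univocal_cases$hypo, union(ctrl_h, ref_h)),
                 character(0))
    # growing the reference can only shrink univocal sets
    s2 <- s
    s2$reference$hypo <- data.frame(gene = union(ref_h, sample(pool, 5)))
    v2 <- venn_univocal(s2)
    expect_true(all(v2$univocal_cases$hypo %in% v$univocal_cases$hypo))
  }
})

test_that("candidate screen equals a naive membership filter", {
  calls <- rbind(fake_calls("ca1", c("p1", "p4"), "hypo"),
                 fake_calls("co1", "p2", "hyper"))
  class(calls) <- c("sem_calls", "data.frame")
  sets <- annotate_sem_genes(calls, man3, sheet3)
  venn <- venn_univocal(sets)
  cands <- c("G1", "G3", "G9")
  hits <- candidate_gene_screen(venn, cands, sets)
  # naive filter
  naive <- NULL
  for (side in c("cases", "controls")) for (dir in c("hypo", "hyper")) {
    uv <- venn[[paste0("univocal_", side)]][[dir]]
    for (g in cands) if (g %in% uv)
      naive <- rbind(naive, data.frame(gene = g, set = side, direction = dir))
  }
  expect_equal(hits[, c("gene", "set", "direction")], naive)
  expect_equal(hits$samples[hits$gene == "G1"], "ca1")

  # empty venn -> empty hits; empty candidate list errors
  empty_sets <- annotate_sem_genes(fake_calls(character(0), character(0),
                                              character(0)), man3, sheet3)
  expect_equal(nrow(candidate_gene_screen(venn_univocal(empty_sets))), 0L)
  expect_error(candidate_gene_screen(venn, character(0)), "empty")
})

test_that("default candidate list covers the dyshormonogenesis and imprinted loci", {
  cands <- default_candidate_genes()
  expect_true(all(c("SLC26A4", "FOXI1", "NKX2-5", "TSHB", "FAM50B", "MEG8")
                  %in% cands))
  expect_equal(anyDuplicated(cands), 0L)
})
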
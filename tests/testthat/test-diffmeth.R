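test_that("beta-to-M transform hits known values and clamps at the boundary", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  eps <- 1e-3
  expect_equal(beta_to_m(0), log2(eps / (1 - eps)))
  expect_equal(beta_to_m(1), log2((1 - eps) / eps))
})

test_that("identical twins give all-zero differences and p = 1", {
  sheet <- make_sheet(4)
  b <- make_beta(30, 8, seed = 3)
  colnames(b) <- sheet$sample_id
  for (p in unique(sheet$pair_id)) {
    ids <- sheet$sample_id[sheet$pair_id == p]
    b[, ids[2]] <- b[, ids[1]]
  }
  st <- paired_site_test(b, sheet)
  expect_true(all(st$mean_m_diff == 0))
  expect_true(all(st$p == 1))
})

test_that("t statistic matches the closed form on a hand-built example", {
  sheet <- make_sheet(4)
  d <- c(0.5, 0.6, 0.4, 0.5)  # target within-pair M differences
  base_beta <- 0.5            # M = 0 for controls
  case_beta <- 2^d / (1 + 2^d)  # logit2 inverse of d
  m <- matrix(base_beta, 1, 8,
              dimnames = list("p1", sheet$sample_id))
  m[1, sheet$sample_id[sheet$group == "case"]] <- case_beta
  st <- paired_site_test(as_beta_matrix(m), sheet)
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(st$t, t_hand, tolerance = 1e-10)
  expect_equal(st$n_pairs, 4L)
  expect_equal(st$p, 2 * pt(-abs(t_hand), df = 3), tolerance = 1e-12)
})

test_that("pairs with missing members are dropped per probe; q is BH-monotone", {
  sheet <- make_sheet(5)
  b <- make_beta(50, 10, seed = 8)
  colnames(b) <- sheet$sample_id
  b[1, sheet$sample_id[1]] <- NA
  st <- paired_site_test(b, sheet)
  expect_equal(st$n_pairs[1], 4L)
  expect_true(all(st$n_pairs[-1] == 5L))
  ok <- !is.na(st$p)
  expect_equal(st$q[ok], p.adjust(st$p[ok], "BH"))
  # sign consistency: the M transform is monotone, so each within-pair
  # difference agrees in sign with its beta-scale counterpart beyond the
  # clamp width (mean differences can disagree because the logit is convex
  # near the boundaries)
  prs <- sheet$sample_id
  cases <- prs[seq(1, 10, 2)]; ctrls <- prs[seq(2, 10, 2)]
  db <- b[, cases] - b[, ctrls]
  dm <- beta_to_m(b[, cases]) - beta_to_m(b[, ctrls])
  big <- !is.na(db) & abs(db) > 2e-3
  expect_true(all(sign(db[big]) == sign(dm[big])))
})

test_that("region averaging: single-probe regions equal site stats, balanced probes cancel", {
  man <- as_cpg_manifest(data.frame(
    probe_id = c("p1", "p2", "p3"), chromosome = "chr01",
    position = c(100L, 200L, 2100L),
    gene_symbols = c("GA", "GB", "GB"), stringsAsFactors = FALSE))
  sheet <- make_sheet(4)
  set.seed(5)
  b <- matrix(runif(12, 0.3, 0.7), 3, 8,
              dimnames = list(c("p1", "p2", "p3"), sheet$sample_id))
  # GB probes: +d and -d on the M scale in every pair -> mean difference 0
  cases <- sheet$sample_id[sheet$group == "case"]
  ctrls <- sheet$sample_id[sheet$group == "control"]
  b["p2", ] <- 0.5; b["p3", ] <- 0.5
  b["p2", cases] <- 2^0.4 / (1 + 2^0.4)
  b["p3", cases] <- 2^-0.4 / (1 + 2^-0.4)
  b <- as_beta_matrix(b)
  rt <- region_test(b, sheet, man, "gene")
  st <- paired_site_test(b, sheet)
  expect_equal(rt$t[rt$region_id == "GA"], st$t[st$probe_id == "p1"])
  expect_equal(rt$mean_m_diff[rt$region_id == "GB"], 0, tolerance = 1e-12)
  expect_gt(rt$p[rt$region_id == "GB"], 0.99)
})

test_that("promoter, island and tiling regions derive from the manifest", {
  man <- generate_manifest(200, 1, 10, seed = 6)
  gene <- manifest_regions(man, "gene")
  expect_equal(length(gene), 20L)
  expect_true(all(lengths(gene) == 10L))
  prom <- manifest_regions(man, "promoter")
  expect_true(all(grepl("^prom:", names(prom))))
  isl <- manifest_regions(man, "island")
  expect_equal(length(isl), 5L)  # every 4th of 20 gene blocks
  til <- manifest_regions(man, "tiling", tiling_bp = 5000L)
  pos_by_tile <- split(man$position, paste0("tile:", man$chromosome, ":",
                                            (man$position - 1L) %/% 5000L))
  expect_true(all(vapply(pos_by_tile, function(p) diff(range(p)) < 5000L,
                         logical(1))))
  expect_equal(sum(lengths(til)), 200L)
})

test_that("a spiked group-level shift in one gene ranks first among regions", {
  hits <- vapply(1:20, function(s) {
    des <- cohort_design(seed = s, n_probes = 1000, n_pairs_mz = 5,
                         n_pairs_dz = 5, sem_rate_control = 0)
    ch <- generate_cohort(des)
    man <- generate_manifest(des$n_probes, des$n_chromosomes,
                             des$probes_per_gene, des$seed)
    target <- man$gene_symbols[1]
    probes <- man$probe_id[man$gene_symbols == target]
    cases <- ch$samples$sample_id[ch$samples$group == "case"]
    b <- unclass(ch$beta)
    b[probes, cases] <- pmin(b[probes, cases] + 0.1, 1)
    rt <- region_test(as_beta_matrix(b), ch$samples, man, "gene")
    rt$region_id[which.min(rt$p)] == target
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("null within-pair differences keep the nominal false-positive rate", {
  des <- cohort_design(seed = 31, n_probes = 20000, sem_rate_control = 0)
  ch <- generate_cohort(des)
  st <- paired_site_test(ch$beta, ch$samples)
  frac <- mean(st$p < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})
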
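test_that("generated scenarios realize their exclusive targets exactly", {
  targets <- c(D = 5L, S = 5L, DS = 0L)
  sc <- deg_scenario_config(targets, n_genes_universe = 50,
                            tissues = "leaf", seed = 1)
  dc <- generate_deg_scenario(sc)
  it <- exclusive_intersections(dc, "leaf")
  expect_equal(it$entries$n_members[it$entries$key == "D"], 5L)
  expect_equal(it$entries$n_members[it$entries$key == "S"], 5L)
  expect_equal(it$entries$n_members[it$entries$key == "DS"], 0L)
})

test_that("random feasible configs are realized exactly (property)", {
  set.seed(10)
  for (rep in 1:15) {
    n_stresses <- sample(2:4, 1)
    stresses <- names(multistress::stress_codes())[seq_len(n_stresses)]
    keys <- multistress:::all_keys(stresses)
    targets <- stats::setNames(sample(0:6, length(keys), replace = TRUE),
                               keys)
    sc <- deg_scenario_config(targets, n_genes_universe = 200,
                              tissues = "leaf", seed = 100 + rep)
    dc <- generate_deg_scenario(sc)
    it <- exclusive_intersections(dc, "leaf")
    for (k in keys) {
      expect_equal(it$entries$n_members[it$entries$key == k],
                   unname(targets[k]), label = paste("key", k, "rep", rep))
    }
  }
})

test_that("scenario generation is deterministic under seed and varies
           across seeds with fixed category sizes", {
  targets <- c(D = 8L, S = 8L, DS = 4L)
  d1 <- generate_deg_scenario(deg_scenario_config(targets, 100,
                                                  tissues = "leaf", seed = 5))
  d2 <- generate_deg_scenario(deg_scenario_config(targets, 100,
                                                  tissues = "leaf", seed = 5))
  expect_identical(d1$records, d2$records)
  d3 <- generate_deg_scenario(deg_scenario_config(targets, 100,
                                                  tissues = "leaf", seed = 6))
  expect_false(identical(sort(d1$records$gene_id), sort(d3$records$gene_id)))
  i1 <- exclusive_intersections(d1, "leaf")
  i3 <- exclusive_intersections(d3, "leaf")
  expect_equal(i1$entries$n_members, i3$entries$n_members)
})

test_that("infeasible configurations are rejected", {
  expect_error(deg_scenario_config(c(D = 80, S = 40), n_genes_universe = 100,
                                   tissues = "leaf", seed = 1),
               "universe")
  expect_error(deg_scenario_config(c(D = 10), n_genes_universe = 100,
                                   universe_sizes = c(dry_down = 5),
                                   tissues = "leaf", seed = 1),
               "universe size")
  expect_error(deg_scenario_config(c(D = 5), 100, tissues = "leaf", seed = 1,
                                   direction_probs = list(D = c(0.4, 0.3, 0.3))),
               "p_mixed")
})

test_that("direction probabilities are honoured within binomial error", {
  targets <- c(DS = 400L)
  sc <- deg_scenario_config(
    targets, n_genes_universe = 1000, tissues = "leaf", seed = 9,
    direction_probs = list(DS = c(0.25, 0.25, 0.5))
  )
  dc <- generate_deg_scenario(sc)
  it <- classify_directionality(dc, exclusive_intersections(dc, "leaf"))
  row <- it$entries[it$entries$key == "DS", ]
  expect_equal(row$n_up + row$n_down + row$n_mixed, 400L)
  se <- sqrt(0.5 * 0.5 / 400)
  expect_lt(abs(row$n_mixed / 400 - 0.5), 4 * se)
})

test_that("DEG fdr values sit below the threshold and universes contain
           the DEGs plus fill to the configured size", {
  sc <- deg_scenario_config(c(D = 10L, S = 5L), n_genes_universe = 100,
                            universe_sizes = c(dry_down = 60, salt = 40),
                            tissues = "root", seed = 12)
  dc <- generate_deg_scenario(sc)
  expect_true(all(dc$records$fdr <= 0.05))
  expect_true(all(dc$records$log2fc != 0))
  expect_length(dc$universes[["root.dry_down"]], 60L)
  expect_length(dc$universes[["root.salt"]], 40L)
  expect_true(all(deg_genes <- dc$records$gene_id[dc$records$stress == "salt"]
                  %in% dc$universes[["root.salt"]]))
})

test_that("two-tissue scenarios carry independent structure per tissue", {
  sc <- deg_scenario_config(list(leaf = c(D = 6L, N = 3L),
                                 root = c(D = 2L, N = 8L, DN = 1L)),
                            n_genes_universe = 100, seed = 3)
  dc <- generate_deg_scenario(sc)
  il <- exclusive_intersections(dc, "leaf")
  ir <- exclusive_intersections(dc, "root")
  expect_equal(il$entries$n_members[il$entries$key == "D"], 6L)
  expect_equal(ir$entries$n_members[ir$entries$key == "DN"], 1L)
})

test_that("module scenarios respect sizes and injections", {
  genes <- sprintf("g%04d", 1:500)
  part <- generate_module_scenario(c(a = 300L, b = 150L, grey = 50L),
                                   genes, seed = 2)
  expect_equal(sort(unname(part$module_sizes)), c(50L, 150L, 300L))

  dset <- genes[1:40]
  inj <- generate_module_scenario(
    c(a = 300L, b = 150L, grey = 50L), genes,
    injections = list(list(genes = dset, module = "b", n_forced = 35L)),
    seed = 2
  )
  expect_gte(sum(inj$assignment[dset] == "b"), 35L)
  expect_equal(unname(inj$module_sizes["b"]), 150L)

  expect_error(
    generate_module_scenario(
      c(a = 10L), genes[1:10],
      injections = list(list(genes = genes[1:5], module = "zz",
                             n_forced = 2L)),
      seed = 1),
    "unknown module"
  )
  expect_error(
    generate_module_scenario(
      c(a = 5L, b = 5L), genes[1:10],
      injections = list(list(genes = genes[1:2], module = "a",
                             n_forced = 4L)),
      seed = 1),
    "available"
  )
})

test_that("phenotype tables satisfy design invariants", {
  tab <- generate_phenotype_table(n_per_treatment = 6, seed = 8)
  expect_equal(nrow(tab), 30L)
  expect_setequal(unique(tab$treatment),
                  c("control", "dry_down", "peg", "salt", "nutrient"))
  expect_setequal(unique(tab$block), c(1L, 2L))
  expect_equal(ncol(tab) - 3L, 21L)  # 21 trait columns
  expect_equal(tab$LMF + tab$SMF + tab$RMF, rep(1, 30), tolerance = 1e-9)
  expect_true(all(tab$total_biomass > 0))
})

test_that("missing-rate masking hits the expected number of cells", {
  rate <- 11 / 630
  n_miss <- vapply(1:40, function(s) {
    tab <- generate_phenotype_table(n_per_treatment = 6, seed = s,
                                    missing_rate = rate)
    sum(is.na(tab[, -(1:3)]))
  }, numeric(1))
  # 630 trait cells per table; expected ~11 missing
  expect_equal(mean(n_miss), 11, tolerance = 0.2)
  expect_error(generate_phenotype_table(6, missing_rate = 2, seed = 1),
               "missing_rate")
})

test_that("phenotype tables round-trip through CSV with missing cells", {
  tab <- generate_phenotype_table(n_per_treatment = 5, seed = 9,
                                  missing_rate = 0.05)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_phenotype_table(tab, tf)
  back <- read_phenotype_table(tf)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
})

test_that("null effects produce no significant traits at tiny noise", {
  tab <- generate_phenotype_table(n_per_treatment = 8, seed = 13)
  # with no treatment effects the KW test should rarely reject; check a few
  # traits are all quiet at a strict threshold
  ps <- vapply(c("RWC", "d13C", "chlorophyll", "stem_height"),
               function(tr) treatment_tests(tab, tr)$kw_p, numeric(1))
  expect_true(all(ps > 0.01))
})
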
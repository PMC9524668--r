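test_that("read_deg_table applies the FDR threshold and keeps the universe", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "gene_id\ttissue\tstress\tlog2fc\tfdr",
    "g1\tleaf\tsalt\t1.5\t0.01",
    "g2\tleaf\tsalt\t-0.7\t0.049",
    "g3\tleaf\tsalt\t0.2\t0.2"
  ), tf)
  dc <- read_deg_table(tf, fdr_threshold = 0.05)
  expect_equal(nrow(dc$records), 2L)
  expect_setequal(dc$records$gene_id, c("g1", "g2"))
  expect_length(dc$universes[["leaf.salt"]], 3L)
})

test_that("an empty DEG table yields an empty collection without error", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene_id\ttissue\tstress\tlog2fc\tfdr", tf)
  dc <- read_deg_table(tf)
  expect_s3_class(dc, "deg_collection")
  expect_equal(nrow(dc$records), 0L)
})

test_that("malformed tables are rejected with informative errors", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ttissue\tstress\tlog2fc",
               "g1\tleaf\tsalt\t1.0"), tf)
  expect_error(read_deg_table(tf), "fdr")

  dup <- data.frame(gene_id = c("g1", "g1"), tissue = "leaf", stress = "salt",
                    log2fc = c(1, 2), fdr = 0.01)
  expect_error(deg_collection(dup), "duplicate")

  bad_tissue <- data.frame(gene_id = "g1", tissue = "shoot", stress = "salt",
                           log2fc = 1, fdr = 0.01)
  expect_error(deg_collection(bad_tissue), "tissue")

  bad_stress <- data.frame(gene_id = "g1", tissue = "leaf", stress = "heat",
                           log2fc = 1, fdr = 0.01)
  expect_error(deg_collection(bad_stress), "stress")

  deg_out <- data.frame(gene_id = "g9", tissue = "leaf", stress = "salt",
                        log2fc = 1, fdr = 0.01)
  expect_error(deg_collection(deg_out, universes = list(leaf.salt = "g1")),
               "universe")
})

test_that("exclusive intersections match the worked three-set example", {
  dc <- make_collection(list(dry_down = c("g1", "g2", "g3"),
                             salt = c("g2", "g3", "g4"),
                             peg = "g3"))
  it <- exclusive_intersections(dc, "leaf")
  get <- function(k) sort(it$entries$members[[which(it$entries$key == k)]])
  expect_equal(get("D"), "g1")
  expect_equal(get("S"), "g4")
  expect_equal(get("DS"), "g2")
  expect_equal(get("DSP"), "g3")
  other <- setdiff(it$entries$key, c("D", "S", "DS", "DSP"))
  expect_true(all(it$entries$n_members[it$entries$key %in% other] == 0L))
})

test_that("degenerate intersection structures behave", {
  one <- make_collection(list(salt = c("g1", "g2")))
  it1 <- exclusive_intersections(one, "leaf")
  expect_equal(it1$entries$n_members[it1$entries$key == "S"], 2L)

  same <- make_collection(list(dry_down = c("g1", "g2"), salt = c("g1", "g2"),
                               peg = c("g1", "g2"), nutrient = c("g1", "g2")))
  it4 <- exclusive_intersections(same, "leaf")
  expect_equal(it4$entries$n_members[it4$entries$key == "DSPN"], 2L)
  expect_true(all(it4$entries$n_members[it4$entries$key != "DSPN"] == 0L))

  empty <- make_collection(list(salt = "g1"))
  expect_warning(er <- exclusive_intersections(empty, "root"), "no DEG")
  expect_equal(nrow(er$entries), 0L)
})

test_that("exclusive intersections agree with brute-force enumeration and
           partition the DEG union", {
  set.seed(42)
  for (rep in 1:60) {
    sets <- rand_stress_sets(sample(2:4, 1L), sample(5:50, 1L))
    dc <- make_collection(sets)
    it <- exclusive_intersections(dc, "leaf")
    oracle <- oracle_exclusive(sets)
    for (i in seq_len(nrow(it$entries))) {
      key <- it$entries$key[i]
      expected <- if (key %in% names(oracle)) sort(oracle[[key]]) else
        character(0)
      expect_equal(sort(it$entries$members[[i]]), expected)
    }
    # partition property: disjoint and covering
    all_members <- unlist(it$entries$members)
    expect_false(anyDuplicated(all_members) > 0L)
    expect_setequal(all_members, unique(unlist(sets)))
    # per-stress totals reconstruct the input set sizes
    for (s in names(sets)) {
      in_keys <- vapply(it$entries$key, function(k) {
        grepl(multistress::stress_codes()[[s]], k, fixed = TRUE)
      }, logical(1))
      expect_equal(sum(it$entries$n_members[in_keys]),
                   length(unique(sets[[s]])))
    }
  }
})

test_that("unique_fraction reproduces published-table arithmetic", {
  expect_equal(unique_fraction(152, 1384), 10.98)
  expect_equal(unique_fraction(3201, 8624), 37.12)
  expect_equal(unique_fraction(0, 100), 0)
  expect_error(unique_fraction(1, 0), "positive")
  expect_error(unique_fraction(5, 3), "n_unique")
})

test_that("directionality splits category members into up/down/mixed", {
  lfc <- list(dry_down = c(g1 = 1.2, g2 = -0.5, g3 = 2.0),
              salt = c(g1 = -0.4, g2 = -1.1, g3 = 0.7))
  dc <- make_collection(list(dry_down = c("g1", "g2", "g3"),
                             salt = c("g1", "g2", "g3")),
                        log2fc = lfc)
  it <- classify_directionality(dc, exclusive_intersections(dc, "leaf"))
  row <- it$entries[it$entries$key == "DS", ]
  expect_equal(row$n_up, 1L)    # g3: positive in both stresses
  expect_equal(row$n_down, 1L)  # g2: negative in both
  expect_equal(row$n_mixed, 1L) # g1: up in dry-down, down in salt
  expect_equal(row$pct_mixed, 33.33)
  expect_equal(row$n_up + row$n_down + row$n_mixed, row$n_members)
})

test_that("percentage of differentially regulated DEGs matches counts", {
  # pct_mixed is a pure function of the three counts
  pct <- function(up, down, mixed) {
    multistress::unique_fraction(mixed, up + down + mixed)
  }
  expect_equal(pct(390, 272, 4), 0.60)
  expect_equal(pct(253, 167, 144), 25.53)
})

test_that("a zero log2 fold change for a DEG is rejected", {
  dc <- make_collection(list(salt = "g1"), log2fc = list(salt = c(g1 = 0)))
  expect_error(classify_directionality(dc, exclusive_intersections(dc, "leaf")),
               "log2fc")
})

test_that("tissue DEG-count chi-square matches the closed form", {
  res <- leaf_root_count_test(9317, 7412)
  expect_equal(res$chi2, (9317 - 7412)^2 / (9317 + 7412), tolerance = 1e-12)
  expect_lt(res$p, 0.001)

  expect_equal(leaf_root_count_test(10, 10)$chi2, 0)
  expect_equal(leaf_root_count_test(10, 10)$p, 1)
  expect_equal(leaf_root_count_test(0, 20)$chi2, 20)
  expect_error(leaf_root_count_test(0, 0), "zero")
})

test_that("intersection tables round-trip through TSV", {
  set.seed(11)
  sets <- list(dry_down = sprintf("g%02d", 1:8),
               salt = sprintf("g%02d", 5:12),
               peg = sprintf("g%02d", c(1, 6, 7, 13)),
               nutrient = sprintf("g%02d", c(2, 6, 12, 14)))
  dc <- make_collection(sets)
  it <- classify_directionality(dc, exclusive_intersections(dc, "leaf"))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_intersection_table(it, tf)
  back <- read_intersection_table(tf)
  expect_equal(back$tissue, it$tissue)
  expect_equal(back$entries$key, it$entries$key)
  expect_equal(back$entries$n_members, it$entries$n_members)
  expect_equal(back$entries$pct_mixed, it$entries$pct_mixed)
  expect_equal(lapply(back$entries$members, sort),
               lapply(it$entries$members, sort))
  expect_equal(back$per_stress, it$per_stress)
})

test_that("a four-stress table with full sharing fills all 15 categories", {
  shared <- sprintf("s%02d", 1:5)
  sets <- lapply(1:4, function(i) c(shared, sprintf("u%d_%d", i, 1:3)))
  names(sets) <- names(multistress::stress_codes())
  # add pairwise-only genes so every multi-stress key is non-empty
  pairs <- utils::combn(names(sets), 2L)
  for (k in seq_len(ncol(pairs))) {
    g <- sprintf("p%02d", k)
    sets[[pairs[1, k]]] <- c(sets[[pairs[1, k]]], g)
    sets[[pairs[2, k]]] <- c(sets[[pairs[2, k]]], g)
  }
  triples <- utils::combn(names(sets), 3L)
  for (k in seq_len(ncol(triples))) {
    g <- sprintf("t%02d", k)
    for (s in triples[, k]) sets[[s]] <- c(sets[[s]], g)
  }
  dc <- make_collection(sets)
  it <- exclusive_intersections(dc, "leaf")
  expect_equal(nrow(it$entries), 15L)
  expect_true(all(it$entries$n_members > 0L))
  expect_equal(sum(nchar(it$entries$key) > 1L), 11L)
})

test_that("DEG collections round-trip through write/read", {
  set.seed(5)
  sets <- rand_stress_sets(3L, 20L)
  dc <- make_collection(sets, universe = sprintf("g%02d", 1:25))
  td <- withr::local_tempdir()
  paths <- write_deg_table(dc, file.path(td, "degs.tsv"))
  back <- read_deg_table(file.path(td, "degs.tsv"),
                         universe_path = paths[2])
  ord <- function(r) r[order(r$gene_id, r$stress), ]
  expect_equal(ord(back$records), ord(dc$records), ignore_attr = TRUE)
  expect_equal(lapply(back$universes[sort(names(back$universes))], sort),
               lapply(dc$universes[sort(names(dc$universes))], sort))
})
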
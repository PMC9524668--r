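# Shared fixtures and independent oracles built in code.

# Build a deg_collection from a named list of per-stress DEG gene vectors
# for one tissue; log2fc defaults to +1 unless given per (stress, gene).
make_collection <- function(sets, tissue = "leaf", universe = NULL,
                            log2fc = NULL) {
  recs <- do.call(rbind, lapply(names(sets), function(s) {
    genes <- sets[[s]]
    if (length(genes) == 0L) return(NULL)
    fc <- if (!is.null(log2fc) && s %in% names(log2fc)) {
      log2fc[[s]][genes]
    } else rep(1, length(genes))
    data.frame(gene_id = genes, tissue = tissue, stress = s,
               log2fc = unname(fc), fdr = 0.01, stringsAsFactors = FALSE)
  }))
  universes <- NULL
  if (!is.null(universe)) {
    universes <- stats::setNames(
      rep(list(universe), length(sets)),
      vapply(names(sets), function(s) paste(tissue, s, sep = "."), "")
    )
  }
  deg_collection(recs, universes = universes)
}

# Independent oracle for exclusive intersections: per-gene enumeration of
# calling subsets with naive set operations, no bit tricks.
oracle_exclusive <- function(sets) {
  genes <- sort(unique(unlist(sets)))
  codes <- multistress::stress_codes()
  keys <- vapply(genes, function(g) {
    calling <- names(sets)[vapply(sets, function(ss) g %in% ss, logical(1))]
    ord <- names(codes)
    paste(codes[ord[ord %in% calling]], collapse = "")
  }, character(1))
  split(genes, keys)
}

# Independent step-up BH oracle: sort, cummin from the largest rank.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

rand_stress_sets <- function(n_stresses, n_genes) {
  stresses <- names(multistress::stress_codes())[seq_len(n_stresses)]
  genes <- sprintf("g%02d", seq_len(n_genes))
  sets <- lapply(stresses, function(s) {
    k <- sample.int(n_genes, 1L)
    sample(genes, k)
  })
  names(sets) <- stresses
  sets[vapply(sets, length, integer(1)) > 0L]
}
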
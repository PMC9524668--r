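#' Gene-to-module partition
#'
#' A co-expression module assignment: every gene carries exactly one module
#' label. The special unassigned label (WGCNA's "grey") is a valid block of
#' the partition — it occupies genes and participates in simulation — but it
#' is not a biological module, and downstream results for it are flagged.
#'
#' @param assignment Named character vector (names = gene ids, values =
#'   module labels), or a data frame with columns `gene_id` and
#'   `module_label`.
#' @param unassigned_label Label of the unassigned pseudo-module
#'   (default `"grey"`).
#' @return Object of class `module_partition` with elements `assignment`,
#'   `module_sizes` (named, decreasing), and `unassigned_label`.
#' @export
module_partition <- function(assignment, unassigned_label = "grey") {
  if (is.data.frame(assignment)) {
    req <- c("gene_id", "module_label")
    miss <- setdiff(req, names(assignment))
    if (length(miss) > 0L) {
      stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
    }
    assignment <- stats::setNames(as.character(assignment$module_label),
                                  as.character(assignment$gene_id))
  }
  if (is.null(names(assignment)) || any(!nzchar(names(assignment)))) {
    stop("assignment must be named by gene id", call. = FALSE)
  }
  if (anyDuplicated(names(assignment))) {
    stop("gene(s) assigned more than once: ",
         paste(utils::head(unique(names(assignment)[
           duplicated(names(assignment))]), 5L), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(assignment) || any(!nzchar(assignment))) {
    stop("every gene needs a non-empty module label", call. = FALSE)
  }
  sizes <- table(assignment)
  sizes <- sort(stats::setNames(as.integer(sizes), names(sizes)),
                decreasing = TRUE)
  structure(list(assignment = assignment, module_sizes = sizes,
                 unassigned_label = unassigned_label),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("Module partition: ", length(x$assignment), " genes in ",
      length(x$module_sizes), " modules (sizes ",
      paste(range(x$module_sizes), collapse = "-"), ")\n", sep = "")
  if (x$unassigned_label %in% names(x$module_sizes)) {
    cat("  unassigned ('", x$unassigned_label, "'): ",
        x$module_sizes[[x$unassigned_label]], " genes\n", sep = "")
  }
  invisible(x)
}

#' Read a gene-to-module partition from TSV
#'
#' @param path TSV with header columns `gene_id`, `module_label`.
#' @param unassigned_label Unassigned pseudo-module label (default "grey").
#' @return A [module_partition].
#' @export
read_module_partition <- function(path, unassigned_label = "grey") {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  module_partition(tab, unassigned_label = unassigned_label)
}

#' Write a module partition as TSV
#'
#' @param x A [module_partition].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_module_partition <- function(x, path) {
  stopifnot(inherits(x, "module_partition"))
  utils::write.table(
    data.frame(gene_id = names(x$assignment),
               module_label = unname(x$assignment)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Simulate a random module partition with fixed module sizes
#'
#' Draws a uniform random gene-to-module partition with exactly the given
#' module sizes — the building block of the simulated-network null, in which
#' random networks preserve the observed module size spectrum while
#' destroying any association between module membership and differential
#' expression.
#'
#' @param module_sizes Named integer vector of module sizes; must sum to the
#'   number of genes.
#' @param gene_ids Character vector of gene ids to partition.
#' @param seed Integer RNG seed.
#' @param unassigned_label Passed through to [module_partition()].
#' @return A [module_partition].
#' @export
simulate_module_assignment <- function(module_sizes, gene_ids, seed,
                                       unassigned_label = "grey") {
  gene_ids <- as.character(gene_ids)
  if (sum(module_sizes) != length(gene_ids)) {
    stop("module sizes sum to ", sum(module_sizes), " but there are ",
         length(gene_ids), " genes", call. = FALSE)
  }
  if (any(module_sizes < 1L)) stop("module sizes must be >= 1", call. = FALSE)
  labels <- rep(names(module_sizes), times = module_sizes)
  perm <- with_seed(seed, sample.int(length(gene_ids)))
  module_partition(stats::setNames(labels, gene_ids[perm]),
                   unassigned_label = unassigned_label)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector (monotone,
#' capped at 1, stable under input order). Thin validated front-end to
#' [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03))
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Module-membership enrichment against a simulated-network null
#'
#' For each DEG set and each module, compares the observed number of set
#' members in the module with its distribution across `n_sims` random
#' partitions preserving the observed module sizes
#' ([simulate_module_assignment()]). One random partition is drawn per
#' replicate and reused for every DEG set in that replicate, mirroring the
#' simulation of whole networks. P-values use the same two-tailed percentile
#' procedure as the overlap null ([two_tailed_percentile_p()]) and are
#' Benjamini-Hochberg-adjusted across all (set, module) pairs in the call;
#' direction is called at the adjusted alpha. Pairs involving the unassigned
#' pseudo-module are computed but flagged `is_grey = TRUE` and should not be
#' interpreted biologically.
#'
#' @param deg_sets Named list of character vectors: DEG set id (e.g.
#'   `"leaf:DSPN"`) to member gene ids.
#' @param partition Observed [module_partition].
#' @param n_sims Number of simulated partitions (default 1000).
#' @param seed Integer RNG seed.
#' @param alpha Significance level applied to adjusted p-values
#'   (default 0.05).
#' @param keep_samples Keep per-pair null counts as an attribute.
#' @return Object of class `module_enrichment`: data frame with columns
#'   `deg_set_id`, `module`, `observed`, `null_mean`, `p_two_tailed`,
#'   `p_adjusted`, `direction`, `is_grey`.
#' @export
module_membership_enrichment <- function(deg_sets, partition,
                                         n_sims = 1000L, seed,
                                         alpha = 0.05,
                                         keep_samples = FALSE) {
  stopifnot(inherits(partition, "module_partition"),
            is.list(deg_sets), length(deg_sets) > 0L,
            !is.null(names(deg_sets)))
  if (missing(seed)) stop("an explicit `seed` is required", call. = FALSE)
  n_sims <- as.integer(n_sims)
  stopifnot(n_sims >= 1L)

  genes <- names(partition$assignment)
  offenders <- lapply(deg_sets, setdiff, y = genes)
  n_off <- vapply(offenders, length, integer(1))
  if (any(n_off > 0L)) {
    i <- which(n_off > 0L)[1L]
    stop("DEG set '", names(deg_sets)[i], "' has gene(s) absent from the ",
         "partition: ", paste(utils::head(offenders[[i]], 5L), collapse = ", "),
         call. = FALSE)
  }

  modules <- names(partition$module_sizes)
  n_mod <- length(modules)
  mod_idx <- match(partition$assignment, modules)   # per gene, observed
  set_idx <- lapply(deg_sets, match, table = genes)

  observed <- vapply(set_idx, function(ix) {
    tabulate(mod_idx[ix], nbins = n_mod)
  }, integer(n_mod))                                # n_mod x n_sets

  # one random partition per replicate, reused across DEG sets
  sim_labels <- rep.int(seq_len(n_mod), times = partition$module_sizes)
  null_counts <- with_seed(seed, {
    arr <- array(0L, dim = c(n_sims, n_mod, length(deg_sets)))
    for (r in seq_len(n_sims)) {
      sim_mod <- integer(length(genes))
      sim_mod[sample.int(length(genes))] <- sim_labels
      for (s in seq_along(set_idx)) {
        arr[r, , s] <- tabulate(sim_mod[set_idx[[s]]], nbins = n_mod)
      }
    }
    arr
  })

  grid <- expand.grid(module = seq_len(n_mod), set = seq_along(deg_sets))
  p <- vapply(seq_len(nrow(grid)), function(i) {
    m <- grid$module[i]; s <- grid$set[i]
    two_tailed_percentile_p(observed[m, s], null_counts[, m, s])
  }, numeric(1))
  p_adj <- benjamini_hochberg(p)
  direction <- vapply(seq_len(nrow(grid)), function(i) {
    m <- grid$module[i]; s <- grid$set[i]
    call_direction(observed[m, s], null_counts[, m, s], p_adj[i], alpha)
  }, character(1))

  res <- data.frame(
    deg_set_id = names(deg_sets)[grid$set],
    module = modules[grid$module],
    observed = observed[cbind(grid$module, grid$set)],
    null_mean = vapply(seq_len(nrow(grid)), function(i) {
      mean(null_counts[, grid$module[i], grid$set[i]])
    }, numeric(1)),
    p_two_tailed = p,
    p_adjusted = p_adj,
    direction = direction,
    is_grey = modules[grid$module] == partition$unassigned_label,
    stringsAsFactors = FALSE
  )
  attr(res, "n_sims") <- n_sims
  attr(res, "seed") <- as.integer(seed)
  attr(res, "alpha") <- alpha
  if (keep_samples) attr(res, "samples") <- null_counts
  class(res) <- c("module_enrichment", "data.frame")
  res
}

#' @export
print.module_enrichment <- function(x, ...) {
  cat("Module-membership enrichment (", attr(x, "n_sims"),
      " simulated partitions, seed ", attr(x, "seed"), ")\n", sep = "")
  sig <- x[x$direction != "ns" & !x$is_grey, , drop = FALSE]
  cat("  ", nrow(sig), " of ", sum(!x$is_grey),
      " (set, module) pairs significant after BH at alpha ",
      attr(x, "alpha"), "\n", sep = "")
  if (nrow(sig) > 0L) {
    df <- as.data.frame(sig)
    df$null_mean <- round(df$null_mean, 2)
    df$p_two_tailed <- signif(df$p_two_tailed, 3)
    df$p_adjusted <- signif(df$p_adjusted, 3)
    print(df[order(df$p_adjusted), ], row.names = FALSE)
  }
  invisible(x)
}

#' Write a module enrichment result as TSV
#'
#' @param x A `module_enrichment`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_module_enrichment <- function(x, path) {
  stopifnot(inherits(x, "module_enrichment"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
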
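#' Two-tailed Monte-Carlo percentile p-value
#'
#' Percentile p-value of an observed count within a Monte-Carlo null sample,
#' doubled for a two-tailed test and capped at 1. The add-one ("plus-one")
#' convention is used in both tails: with `N` null samples,
#' `p_upper = (1 + #\{samples >= observed\})/(N + 1)` and symmetrically for
#' the lower tail; ties count toward both tails. This avoids a reported p of
#' exactly zero and gives a minimum attainable p of `2/(N + 1)` (0.002 at
#' 1000 replicates).
#'
#' @param observed Observed count.
#' @param samples Numeric vector of null counts (one per replicate).
#' @return Two-tailed p-value in `(0, 1]`.
#' @export
#' @examples
#' two_tailed_percentile_p(9, 1:10) # 6/11
two_tailed_percentile_p <- function(observed, samples) {
  if (length(samples) == 0L) {
    stop("null sample vector is empty", call. = FALSE)
  }
  stopifnot(length(observed) == 1L, is.finite(observed))
  n <- length(samples)
  p_upper <- (1 + sum(samples >= observed)) / (n + 1)
  p_lower <- (1 + sum(samples <= observed)) / (n + 1)
  min(1, 2 * min(p_upper, p_lower))
}

#' Configuration for the overlap null
#'
#' @param n_reps Number of Monte-Carlo replicates (default 1000).
#' @param seed Integer RNG seed; required, so every run is reproducible.
#' @param alpha Significance level for direction calls (default 0.05).
#' @param universe_mode `"per_stress"` (each pseudo-DEG set is drawn from its
#'   own stress's expressed-gene universe, the default) or `"shared"` (all
#'   sets drawn from the union of the universes in the tissue).
#' @return A list of class `overlap_config`.
#' @export
overlap_config <- function(n_reps = 1000L, seed, alpha = 0.05,
                           universe_mode = c("per_stress", "shared")) {
  universe_mode <- match.arg(universe_mode)
  stopifnot(n_reps >= 1L, alpha > 0, alpha < 1)
  if (missing(seed)) stop("an explicit `seed` is required", call. = FALSE)
  structure(list(n_reps = as.integer(n_reps), seed = as.integer(seed),
                 alpha = alpha, universe_mode = universe_mode),
            class = "overlap_config")
}

#' Size-matched null distributions for intersection sizes
#'
#' For each Monte-Carlo replicate, draws for every stress a uniform
#' without-replacement sample from that stress's expressed-gene universe,
#' matched in size to the observed DEG set, and recomputes the exclusive
#' intersections. The resulting per-category count vectors are the null
#' distributions against which observed intersection sizes are tested.
#'
#' @param x A [deg_collection].
#' @param tissue `"leaf"` or `"root"`.
#' @param config An [overlap_config()].
#' @return List with `keys` (category keys), `samples` (matrix, `n_reps` rows
#'   by one column per key), `observed` (named observed exclusive sizes) and
#'   `stresses`.
#' @export
sample_null_intersections <- function(x, tissue, config) {
  stopifnot(inherits(x, "deg_collection"), inherits(config, "overlap_config"))
  check_tissue(tissue)
  stresses <- stresses_present(x, tissue)
  if (length(stresses) == 0L) {
    stop("no DEG records for tissue '", tissue, "'", call. = FALSE)
  }

  sets <- lapply(stresses, function(s) deg_genes(x, tissue, s))
  names(sets) <- stresses
  sizes <- vapply(sets, length, integer(1))

  universes <- lapply(stresses, function(s) {
    u <- x$universes[[universe_id(tissue, s)]]
    if (is.null(u)) stop("no universe for ", universe_id(tissue, s),
                         call. = FALSE)
    u
  })
  names(universes) <- stresses
  if (config$universe_mode == "shared") {
    shared <- unique(unlist(universes, use.names = FALSE))
    universes <- lapply(stresses, function(s) shared)
    names(universes) <- stresses
  }

  too_big <- sizes > vapply(universes, length, integer(1))
  if (any(too_big)) {
    stop("DEG count exceeds universe size for stress(es): ",
         paste(stresses[too_big], collapse = ", "), call. = FALSE)
  }

  genes <- unique(unlist(universes, use.names = FALSE))
  uni_idx <- lapply(universes, match, genes)
  n_genes <- length(genes)

  keys <- all_keys(stresses)
  key_code <- vapply(keys, function(k) {
    sum(2L^(match(key_stresses(k), stresses) - 1L))
  }, numeric(1))
  n_codes <- 2L^length(stresses) - 1L

  samples <- with_seed(config$seed, {
    out <- matrix(0L, nrow = config$n_reps, ncol = length(keys),
                  dimnames = list(NULL, keys))
    code <- integer(n_genes)
    for (r in seq_len(config$n_reps)) {
      code[] <- 0L
      for (j in seq_along(stresses)) {
        drawn <- uni_idx[[j]][sample.int(length(uni_idx[[j]]), sizes[j])]
        code[drawn] <- code[drawn] + 2L^(j - 1L)
      }
      counts <- tabulate(code, nbins = n_codes)
      out[r, ] <- counts[key_code]
    }
    out
  })

  obs_table <- exclusive_intersections(x, tissue)
  observed <- stats::setNames(obs_table$entries$n_members,
                              obs_table$entries$key)[keys]

  list(keys = keys, samples = samples, observed = observed,
       stresses = stresses)
}

# Direction call shared by the overlap and module nulls: "more"/"fewer"
# only when p clears alpha AND the observation lies on the corresponding
# side of the null median.
call_direction <- function(observed, samples, p, alpha) {
  med <- stats::median(samples)
  if (p < alpha && observed > med) "more"
  else if (p < alpha && observed < med) "fewer"
  else "ns"
}

#' Monte-Carlo enrichment test for DEG set intersections
#'
#' Tests every exclusive intersection category against its size-matched
#' Monte-Carlo null ([sample_null_intersections()]): categories holding more
#' genes than expected by chance are called `more`, fewer than expected
#' `fewer`, at the two-tailed percentile p-value. Raw p-values are the
#' primary result (one test per category, as in the original procedure); a
#' Benjamini-Hochberg column is included for convenience.
#'
#' @param x A [deg_collection].
#' @param tissue `"leaf"` or `"root"`.
#' @param config An [overlap_config()].
#' @param keep_samples Keep the per-category null sample matrix as an
#'   attribute for audit (default TRUE).
#' @return Object of class `overlap_test`: a data frame with columns `key`,
#'   `observed`, `null_mean`, `null_sd`, `p_two_tailed`, `p_adj`,
#'   `direction`, with the config stored as an attribute.
#' @export
overlap_enrichment_test <- function(x, tissue, config, keep_samples = TRUE) {
  nulls <- sample_null_intersections(x, tissue, config)
  p <- vapply(seq_along(nulls$keys), function(i) {
    two_tailed_percentile_p(nulls$observed[i], nulls$samples[, i])
  }, numeric(1))
  direction <- vapply(seq_along(nulls$keys), function(i) {
    call_direction(nulls$observed[i], nulls$samples[, i], p[i], config$alpha)
  }, character(1))

  res <- data.frame(
    key = nulls$keys,
    observed = as.integer(nulls$observed),
    null_mean = colMeans(nulls$samples),
    null_sd = apply(nulls$samples, 2L, stats::sd),
    p_two_tailed = p,
    p_adj = benjamini_hochberg(p),
    direction = direction,
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "tissue") <- tissue
  attr(res, "config") <- config
  if (keep_samples) attr(res, "samples") <- nulls$samples
  class(res) <- c("overlap_test", "data.frame")
  res
}

#' @export
print.overlap_test <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("Monte-Carlo intersection-size test (", attr(x, "tissue"),
      " tissue; ", cfg$n_reps, " replicates, seed ", cfg$seed,
      ", universes ", cfg$universe_mode, ")\n", sep = "")
  df <- as.data.frame(x)
  df$null_mean <- round(df$null_mean, 2)
  df$null_sd <- round(df$null_sd, 2)
  df$p_two_tailed <- signif(df$p_two_tailed, 3)
  df$p_adj <- signif(df$p_adj, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an overlap test result as TSV
#'
#' @param x An `overlap_test`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_overlap_test <- function(x, path) {
  stopifnot(inherits(x, "overlap_test"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
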
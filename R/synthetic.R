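#' Configuration for a synthetic DEG scenario
#'
#' Describes a multi-stress DEG experiment to be constructed exactly: the
#' expressed-gene universe, per-stress universe sizes, the exclusive
#' intersection structure (how many genes are called by exactly each subset
#' of stresses), and per-category directionality probabilities. The default
#' universe of 39,042 genes matches the scale of a typical well-annotated
#' plant genome expression screen across five treatments and two tissues.
#'
#' @param target_exclusive_sizes Named integer vector: canonical intersection
#'   key (e.g. `"DSPN"`, `"SN"`, `"D"`) to the number of genes whose calling
#'   set is exactly that subset. Alternatively a named list with one such
#'   vector per tissue.
#' @param n_genes_universe Total genes in the scenario (default 39042).
#' @param tissues Tissues to generate (default `c("leaf", "root")`).
#' @param universe_sizes Named per-stress universe sizes (default: every
#'   stress universe is the full gene set).
#' @param direction_probs Named list: key to `c(p_up, p_down, p_mixed)`
#'   summing to 1; `p_mixed` must be 0 for singleton keys. Default: 0.45 /
#'   0.45 / 0.10 for multi-stress keys, 0.5 / 0.5 / 0 for singletons.
#' @param fdr_threshold DEG threshold emulated (default 0.05).
#' @param seed Integer RNG seed.
#' @return List of class `deg_scenario_config`.
#' @export
deg_scenario_config <- function(target_exclusive_sizes,
                                n_genes_universe = 39042L,
                                tissues = c("leaf", "root"),
                                universe_sizes = NULL,
                                direction_probs = NULL,
                                fdr_threshold = 0.05,
                                seed) {
  if (missing(seed)) stop("an explicit `seed` is required", call. = FALSE)
  stopifnot(n_genes_universe >= 1L)
  bad_t <- setdiff(tissues, .tissue_levels)
  if (length(bad_t) > 0L) {
    stop("unknown tissue(s): ", paste(bad_t, collapse = ", "), call. = FALSE)
  }
  per_tissue <- is.list(target_exclusive_sizes) &&
    !is.null(names(target_exclusive_sizes)) &&
    all(names(target_exclusive_sizes) %in% .tissue_levels)
  targets <- if (per_tissue) target_exclusive_sizes else
    stats::setNames(rep(list(target_exclusive_sizes), length(tissues)),
                    tissues)
  targets <- targets[tissues]

  for (tis in tissues) {
    tg <- targets[[tis]]
    if (is.null(names(tg)) || any(!nzchar(names(tg)))) {
      stop("target sizes must be named by intersection key", call. = FALSE)
    }
    lapply(names(tg), key_stresses)  # validates keys
    if (any(tg < 0)) stop("target sizes must be >= 0", call. = FALSE)
    if (sum(tg) > n_genes_universe) {
      stop("targets for ", tis, " need ", sum(tg),
           " genes but universe has ", n_genes_universe, call. = FALSE)
    }
    stresses <- unique(unlist(lapply(names(tg), key_stresses)))
    usz <- universe_sizes
    if (is.null(usz)) {
      usz <- stats::setNames(rep(n_genes_universe, length(stresses)), stresses)
    }
    for (s in stresses) {
      implied <- sum(tg[vapply(names(tg),
                               function(k) s %in% key_stresses(k),
                               logical(1))])
      cap <- if (s %in% names(usz)) usz[[s]] else n_genes_universe
      if (implied > cap) {
        stop("implied DEG total for ", s, " in ", tis, " (", implied,
             ") exceeds its universe size (", cap, ")", call. = FALSE)
      }
    }
  }

  dp <- direction_probs
  if (!is.null(dp)) {
    for (k in names(dp)) {
      pr <- dp[[k]]
      if (length(pr) != 3L || abs(sum(pr) - 1) > 1e-9 || any(pr < 0)) {
        stop("direction probs for ", k,
             " must be 3 non-negative values summing to 1", call. = FALSE)
      }
      if (length(key_stresses(k)) == 1L && pr[3L] > 0) {
        stop("p_mixed must be 0 for singleton key ", k, call. = FALSE)
      }
    }
  }

  structure(list(targets = targets, n_genes_universe = as.integer(n_genes_universe),
                 tissues = tissues, universe_sizes = universe_sizes,
                 direction_probs = dp, fdr_threshold = fdr_threshold,
                 seed = as.integer(seed)),
            class = "deg_scenario_config")
}

# Direction probabilities for a key, falling back to defaults.
.key_direction_probs <- function(config, key) {
  if (!is.null(config$direction_probs) &&
      key %in% names(config$direction_probs)) {
    return(config$direction_probs[[key]])
  }
  if (length(key_stresses(key)) == 1L) c(0.5, 0.5, 0) else c(0.45, 0.45, 0.10)
}

#' Generate a DEG collection with exact intersection structure
#'
#' Constructive allocation: genes are assigned to intersection categories so
#' that the realized exclusive intersections equal the configured targets
#' exactly (no sampling error at the set level); randomness enters only
#' through which genes land in which category, the per-gene fold-change
#' signs and magnitudes, and the FDR values. DEG FDRs are drawn uniformly in
#' (0, threshold\]; log2 fold-change magnitudes are log-normal; "mixed"
#' genes receive at least one positive and one negative sign among their
#' member stresses. Per-stress universes contain all of that stress's DEGs
#' plus a random fill up to the configured universe size.
#'
#' @param config A [deg_scenario_config()].
#' @return A [deg_collection] spanning the configured tissues.
#' @export
generate_deg_scenario <- function(config) {
  stopifnot(inherits(config, "deg_scenario_config"))
  n <- config$n_genes_universe
  genes <- sprintf("gene%06d", seq_len(n))

  with_seed(config$seed, {
    rec_list <- list()
    universes <- list()

    for (tis in config$tissues) {
      tg <- config$targets[[tis]]
      tg <- tg[order(match(names(tg), all_keys(names(.stress_codes))))]
      perm <- sample.int(n)
      cursor <- 0L
      stress_genes <- list()

      for (key in names(tg)) {
        size <- tg[[key]]
        if (size == 0L) next
        idx <- perm[(cursor + 1L):(cursor + size)]
        cursor <- cursor + size
        members <- genes[idx]
        stresses <- key_stresses(key)
        k_s <- length(stresses)
        pr <- .key_direction_probs(config, key)
        cat3 <- sample.int(3L, size, replace = TRUE, prob = pr)

        # sign matrix (genes x member stresses): consistent up, consistent
        # down, or mixed with both signs guaranteed present
        signs <- matrix(sample(c(-1, 1), size * k_s, replace = TRUE),
                        nrow = size, ncol = k_s)
        signs[cat3 == 1L, ] <- 1
        signs[cat3 == 2L, ] <- -1
        mixed <- which(cat3 == 3L)
        for (gi in mixed) {
          if (all(signs[gi, ] == 1)) signs[gi, sample.int(k_s, 1L)] <- -1
          if (all(signs[gi, ] == -1)) signs[gi, sample.int(k_s, 1L)] <- 1
        }

        mag <- matrix(stats::rlnorm(size * k_s, meanlog = 0, sdlog = 0.5),
                      nrow = size, ncol = k_s)
        rec_list[[length(rec_list) + 1L]] <- data.frame(
          gene_id = rep(members, times = k_s),
          tissue = tis,
          stress = rep(stresses, each = size),
          log2fc = as.vector(signs * mag),
          fdr = stats::runif(size * k_s, 0, config$fdr_threshold),
          stringsAsFactors = FALSE
        )
        for (s in stresses) {
          stress_genes[[s]] <- c(stress_genes[[s]], members)
        }
      }

      stresses_all <- unique(unlist(lapply(names(tg), key_stresses)))
      for (s in stresses_all) {
        dg <- stress_genes[[s]]
        if (is.null(dg)) dg <- character(0)
        cap <- if (!is.null(config$universe_sizes) &&
                   s %in% names(config$universe_sizes)) {
          config$universe_sizes[[s]]
        } else n
        fill <- setdiff(genes, dg)
        extra <- cap - length(dg)
        uni <- c(dg, if (extra > 0L) sample(fill, extra) else character(0))
        universes[[universe_id(tis, s)]] <- uni
      }
    }

    records <- do.call(rbind, rec_list)
    deg_collection(records, universes = universes,
                   fdr_threshold = config$fdr_threshold)
  })
}

#' Generate a module partition with injected DEG enrichment
#'
#' Builds a gene-to-module partition with exactly the given module sizes.
#' Optional injections force a chosen number of genes from a named DEG set
#' into a named module before the remaining genes are assigned uniformly at
#' random — a constructed enrichment signal for power/recovery testing.
#'
#' @param module_sizes Named integer vector of module sizes; must sum to the
#'   number of genes.
#' @param gene_ids Character vector of gene ids to partition (for a
#'   [deg_collection], use the union of its universes).
#' @param injections List of injections, each a list with elements `genes`
#'   (character vector: the DEG set) and `module` (target label) and
#'   `n_forced` (how many set genes to place in the module).
#' @param seed Integer RNG seed.
#' @param unassigned_label Passed to [module_partition()].
#' @return A [module_partition].
#' @export
generate_module_scenario <- function(module_sizes, gene_ids,
                                     injections = list(), seed,
                                     unassigned_label = "grey") {
  if (missing(seed)) stop("an explicit `seed` is required", call. = FALSE)
  gene_ids <- as.character(gene_ids)
  if (sum(module_sizes) != length(gene_ids)) {
    stop("module sizes sum to ", sum(module_sizes), " but there are ",
         length(gene_ids), " genes", call. = FALSE)
  }
  with_seed(seed, {
    assignment <- stats::setNames(rep(NA_character_, length(gene_ids)),
                                  gene_ids)
    capacity <- module_sizes
    for (inj in injections) {
      stopifnot(all(c("genes", "module", "n_forced") %in% names(inj)))
      if (!inj$module %in% names(capacity)) {
        stop("injection targets unknown module '", inj$module, "'",
             call. = FALSE)
      }
      pool <- intersect(as.character(inj$genes),
                        gene_ids[is.na(assignment)])
      if (length(pool) < inj$n_forced) {
        stop("injection into '", inj$module, "' needs ", inj$n_forced,
             " unassigned set genes but only ", length(pool),
             " are available", call. = FALSE)
      }
      if (capacity[[inj$module]] < inj$n_forced) {
        stop("module '", inj$module, "' has capacity ",
             capacity[[inj$module]], " < n_forced ", inj$n_forced,
             call. = FALSE)
      }
      chosen <- if (length(pool) == 1L) pool else sample(pool, inj$n_forced)
      assignment[chosen] <- inj$module
      capacity[[inj$module]] <- capacity[[inj$module]] - inj$n_forced
    }
    free <- names(assignment)[is.na(assignment)]
    labels <- rep(names(capacity), times = capacity)
    assignment[free[sample.int(length(free))]] <- labels
    module_partition(assignment, unassigned_label = unassigned_label)
  })
}

# Baseline trait means and noise SDs for a sunflower-scale seedling
# harvested ~20 days after germination; generic desk values, documented in
# the methods vignette.
.pheno_traits <- function() {
  data.frame(
    trait = c("total_biomass", "LMF", "SMF", "RMF", "LMA", "chlorophyll",
              "RWC", "d13C", "d15N", "pct_C", "pct_N", "stem_height",
              "stem_diameter", "rooting_depth", "n_root_tips",
              "n_tips_hypocotyl", "n_tips_taproot", "n_adventitious",
              "n_basal", "hypocotyl_diameter", "taproot_diameter"),
    stringsAsFactors = FALSE
  )
}

.pheno_baselines <- c(
  leaf_mass = 0.25, stem_mass = 0.10, root_mass = 0.08,
  LMA = 0.003, chlorophyll = 300, RWC = 0.92, d13C = -30, d15N = 3,
  pct_C = 40, pct_N = 4, stem_height = 80, stem_diameter = 2.5,
  rooting_depth = 150, n_root_tips = 50, n_tips_hypocotyl = 10,
  n_tips_taproot = 30, n_adventitious = 5, n_basal = 3,
  hypocotyl_diameter = 2, taproot_diameter = 1.5
)

.pheno_noise_sd <- c(
  leaf_mass = 0.04, stem_mass = 0.02, root_mass = 0.015,
  LMA = 0.0004, chlorophyll = 25, RWC = 0.03, d13C = 0.8, d15N = 0.6,
  pct_C = 1.5, pct_N = 0.4, stem_height = 8, stem_diameter = 0.25,
  rooting_depth = 15, n_root_tips = 8, n_tips_hypocotyl = 2.5,
  n_tips_taproot = 5, n_adventitious = 1.5, n_basal = 1,
  hypocotyl_diameter = 0.2, taproot_diameter = 0.15
)

#' Generate a synthetic phenotype table
#'
#' Emulates a randomized-block stress experiment: five treatments (control
#' plus four stresses), two blocks, `n_per_treatment` individuals per
#' treatment, and 21 trait columns. Organ masses (leaf, stem, root) are
#' generated first — Gaussian around baselines plus any configured treatment
#' shift, truncated at a small positive floor — so total biomass and the
#' mass fractions satisfy their sum-to-one invariant by construction. All
#' other traits are Gaussian around their baselines plus shifts. Missing
#' cells are masked completely at random at `missing_rate` over the trait
#' cells only.
#'
#' @param n_per_treatment Individuals per treatment (default 11).
#' @param effects Named list: treatment to a named numeric vector of
#'   additive shifts on generator traits (the organ masses `leaf_mass`,
#'   `stem_mass`, `root_mass` and any directly generated trait such as
#'   `RWC`, `d15N`, ...). Default: no effects.
#' @param noise_sd Named numeric vector overriding per-trait noise SDs.
#' @param missing_rate Probability a trait cell is masked (default 0).
#' @param seed Integer RNG seed.
#' @return Data frame of class `phenotype_table` with columns
#'   `individual_id`, `block`, `treatment` and the 21 traits.
#' @export
generate_phenotype_table <- function(n_per_treatment = 11L,
                                     effects = list(),
                                     noise_sd = NULL,
                                     missing_rate = 0,
                                     seed) {
  if (missing(seed)) stop("an explicit `seed` is required", call. = FALSE)
  stopifnot(n_per_treatment >= 2L)
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  treatments <- c("control", "dry_down", "peg", "salt", "nutrient")
  bad <- setdiff(names(effects), treatments)
  if (length(bad) > 0L) {
    stop("unknown treatment(s) in effects: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sds <- .pheno_noise_sd
  if (!is.null(noise_sd)) sds[names(noise_sd)] <- noise_sd

  with_seed(seed, {
    n <- n_per_treatment * length(treatments)
    treatment <- rep(treatments, each = n_per_treatment)
    block <- rep(rep_len(c(1L, 2L), n_per_treatment), length(treatments))

    gen <- function(name, tr) {
      shift <- if (!is.null(effects[[tr]]) && name %in% names(effects[[tr]])) {
        effects[[tr]][[name]]
      } else 0
      stats::rnorm(n_per_treatment, .pheno_baselines[[name]] + shift,
                   sds[[name]])
    }

    rows <- lapply(treatments, function(tr) {
      lm <- pmax(gen("leaf_mass", tr), 1e-4)
      sm <- pmax(gen("stem_mass", tr), 1e-4)
      rm_ <- pmax(gen("root_mass", tr), 1e-4)
      fr <- mass_fractions(lm, sm, rm_)
      data.frame(
        treatment = tr,
        total_biomass = fr$total, LMF = fr$LMF, SMF = fr$SMF, RMF = fr$RMF,
        LMA = pmax(gen("LMA", tr), 1e-6),
        chlorophyll = gen("chlorophyll", tr),
        RWC = gen("RWC", tr),
        d13C = gen("d13C", tr), d15N = gen("d15N", tr),
        pct_C = gen("pct_C", tr), pct_N = pmax(gen("pct_N", tr), 0.01),
        stem_height = pmax(gen("stem_height", tr), 1),
        stem_diameter = pmax(gen("stem_diameter", tr), 0.1),
        rooting_depth = pmax(gen("rooting_depth", tr), 1),
        n_root_tips = pmax(round(gen("n_root_tips", tr)), 0),
        n_tips_hypocotyl = pmax(round(gen("n_tips_hypocotyl", tr)), 0),
        n_tips_taproot = pmax(round(gen("n_tips_taproot", tr)), 0),
        n_adventitious = pmax(round(gen("n_adventitious", tr)), 0),
        n_basal = pmax(round(gen("n_basal", tr)), 0),
        hypocotyl_diameter = pmax(gen("hypocotyl_diameter", tr), 0.05),
        taproot_diameter = pmax(gen("taproot_diameter", tr), 0.05),
        stringsAsFactors = FALSE
      )
    })
    tab <- do.call(rbind, rows)
    tab <- cbind(
      individual_id = sprintf("ind%03d", seq_len(n)),
      block = block,
      tab
    )

    if (missing_rate > 0) {
      trait_cols <- setdiff(names(tab), c("individual_id", "block",
                                          "treatment"))
      for (cl in trait_cols) {
        mask <- stats::runif(n) < missing_rate
        tab[[cl]][mask] <- NA
      }
    }
    class(tab) <- c("phenotype_table", "data.frame")
    tab
  })
}

#' Write a phenotype table as CSV (missing cells empty)
#'
#' @param x Phenotype data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phenotype_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a phenotype CSV
#'
#' @param path CSV with header `individual_id`, `block`, `treatment` and
#'   trait columns; empty cells are missing.
#' @return Data frame of class `phenotype_table`.
#' @export
read_phenotype_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  req <- c("treatment")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0L) {
    stop("phenotype table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  class(tab) <- c("phenotype_table", "data.frame")
  tab
}
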
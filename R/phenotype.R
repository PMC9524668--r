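#' Leaf relative water content
#'
#' RWC = (FM - DM)/(HM - DM), where FM is fresh mass at collection, HM the
#' mass after full rehydration, and DM the oven-dry mass. An indicator of
#' plant water status; nominally a fraction in \[0, 1\], but measurement
#' noise can push it slightly outside that range, in which case a warning is
#' raised and the value returned unclipped.
#'
#' @param fresh_mass,hydrated_mass,dry_mass Masses (g), vectorised.
#' @return RWC fraction(s).
#' @export
#' @examples
#' relative_water_content(2, 3, 1) # 0.5
relative_water_content <- function(fresh_mass, hydrated_mass, dry_mass) {
  if (any(dry_mass < 0, na.rm = TRUE)) {
    stop("dry mass must be non-negative", call. = FALSE)
  }
  if (any(hydrated_mass <= dry_mass, na.rm = TRUE)) {
    stop("hydrated mass must exceed dry mass (RWC undefined)", call. = FALSE)
  }
  rwc <- (fresh_mass - dry_mass) / (hydrated_mass - dry_mass)
  if (any(rwc < 0 | rwc > 1, na.rm = TRUE)) {
    warning("RWC outside [0, 1] (measurement noise); not clipped",
            call. = FALSE)
  }
  rwc
}

#' Organ mass fractions
#'
#' Total biomass and the leaf/stem/root mass fractions (LMF, SMF, RMF), each
#' organ's dry mass as a proportion of total dry biomass. Fractions sum to 1
#' by construction.
#'
#' @param leaf_mass,stem_mass,root_mass Organ dry masses (g), vectorised.
#' @return List with `total`, `LMF`, `SMF`, `RMF`.
#' @export
#' @examples
#' mass_fractions(0.12, 0.03, 0.05)
mass_fractions <- function(leaf_mass, stem_mass, root_mass) {
  if (any(c(leaf_mass, stem_mass, root_mass) < 0, na.rm = TRUE)) {
    stop("masses must be non-negative", call. = FALSE)
  }
  total <- leaf_mass + stem_mass + root_mass
  if (any(total == 0, na.rm = TRUE)) {
    stop("total biomass is zero; fractions undefined", call. = FALSE)
  }
  list(total = total, LMF = leaf_mass / total, SMF = stem_mass / total,
       RMF = root_mass / total)
}

#' Leaf mass per area
#'
#' @param dry_mass Leaf dry mass (g), vectorised.
#' @param area Leaf area (cm^2), vectorised.
#' @return LMA in g/cm^2.
#' @export
leaf_mass_per_area <- function(dry_mass, area) {
  if (any(area <= 0, na.rm = TRUE)) {
    stop("leaf area must be positive", call. = FALSE)
  }
  if (any(dry_mass < 0, na.rm = TRUE)) {
    stop("dry mass must be non-negative", call. = FALSE)
  }
  dry_mass / area
}

# Compact letter display by insert-and-absorb: start from one letter
# covering all groups; for every significantly different pair sharing a
# letter, split that letter column; absorb columns that became subsets.
# Alphabetical (input-order) tie-breaking.
compact_letter_display <- function(groups, pairwise_p, alpha) {
  cols <- list(groups)
  pairs <- which(upper.tri(pairwise_p), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    i <- groups[pairs[k, "row"]]
    j <- groups[pairs[k, "col"]]
    p <- pairwise_p[pairs[k, "row"], pairs[k, "col"]]
    if (is.na(p) || p >= alpha) next
    hit <- vapply(cols, function(cc) i %in% cc && j %in% cc, logical(1))
    for (h in which(hit)) {
      cols <- c(cols, list(setdiff(cols[[h]], j)))
      cols[[h]] <- setdiff(cols[[h]], i)
    }
    # absorb: drop any column that is a subset of another
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) {
      for (b in seq_along(cols)) {
        if (a != b && keep[a] && keep[b] &&
            all(cols[[a]] %in% cols[[b]]) &&
            !(all(cols[[b]] %in% cols[[a]]) && a < b)) {
          keep[a] <- FALSE
        }
      }
    }
    cols <- cols[keep]
  }
  # order columns by first member's position for stable letter assignment
  first_pos <- vapply(cols, function(cc) min(match(cc, groups)), numeric(1))
  cols <- cols[order(first_pos)]
  letters_out <- stats::setNames(rep("", length(groups)), groups)
  for (ci in seq_along(cols)) {
    l <- letters[ci]
    for (g in cols[[ci]]) {
      letters_out[g] <- paste0(letters_out[g], l)
    }
  }
  letters_out
}

#' Nonparametric treatment tests for one trait
#'
#' Kruskal-Wallis rank-sum test (with tie correction) for an overall
#' treatment effect, followed — only when the overall test is significant at
#' `alpha` — by pairwise two-sided Wilcoxon rank-sum tests with
#' Benjamini-Hochberg adjustment and a compact letter display summarising
#' which treatment pairs are not distinguishable. Pairwise tests use exact
#' enumeration when both groups have fewer than 8 observations and no ties,
#' and the normal approximation with tie correction otherwise. A
#' block-stratified Kruskal-Wallis p-value per block is also reported so
#' block-dependent significance can be flagged.
#'
#' @param table Data frame with columns `treatment`, optionally `block`, and
#'   the trait column.
#' @param trait Name of the trait column to test.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `trait_test`: list with `trait`, `kw_statistic`,
#'   `kw_p`, `pairwise` (symmetric matrix of adjusted p, `NULL` if the
#'   overall test was not run or not significant), `letters` (named by
#'   treatment), and `block_kw_p` (named per-block p-values, if `block`
#'   present).
#' @export
treatment_tests <- function(table, trait, alpha = 0.05) {
  if (!trait %in% names(table)) {
    stop("trait '", trait, "' not found", call. = FALSE)
  }
  if (!"treatment" %in% names(table)) {
    stop("column 'treatment' required", call. = FALSE)
  }
  values <- table[[trait]]
  treat <- as.character(table$treatment)
  ok <- !is.na(values) & !is.na(treat)
  values <- values[ok]
  treat <- treat[ok]
  groups <- unique(treat)
  if (length(groups) < 2L || any(table(treat) < 2L)) {
    stop("need >= 2 treatments with >= 2 observations each", call. = FALSE)
  }

  constant <- stats::var(values) == 0
  if (constant) {
    kw_stat <- 0
    kw_p <- 1
  } else {
    kw <- stats::kruskal.test(values, factor(treat))
    kw_stat <- unname(kw$statistic)
    kw_p <- unname(kw$p.value)
  }

  pairwise <- NULL
  if (!constant && kw_p < alpha) {
    m <- matrix(NA_real_, length(groups), length(groups),
                dimnames = list(groups, groups))
    raw <- c()
    idx <- utils::combn(length(groups), 2L)
    for (k in seq_len(ncol(idx))) {
      x <- values[treat == groups[idx[1L, k]]]
      y <- values[treat == groups[idx[2L, k]]]
      exact <- length(x) < 8L && length(y) < 8L
      wt <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = "two.sided", exact = exact)
      )
      raw[k] <- wt$p.value
    }
    adj <- benjamini_hochberg(raw)
    for (k in seq_len(ncol(idx))) {
      m[idx[1L, k], idx[2L, k]] <- adj[k]
      m[idx[2L, k], idx[1L, k]] <- adj[k]
    }
    pairwise <- m
  }

  letters_out <- if (is.null(pairwise)) {
    stats::setNames(rep("a", length(groups)), groups)
  } else {
    compact_letter_display(groups, pairwise, alpha)
  }

  block_kw_p <- NULL
  if ("block" %in% names(table) && !constant) {
    blk <- as.character(table$block)[ok]
    block_kw_p <- vapply(unique(blk), function(b) {
      vb <- values[blk == b]
      tb <- treat[blk == b]
      if (length(unique(tb)) < 2L || stats::var(vb) == 0) return(NA_real_)
      unname(stats::kruskal.test(vb, factor(tb))$p.value)
    }, numeric(1))
  }

  structure(list(trait = trait, kw_statistic = kw_stat, kw_p = kw_p,
                 pairwise = pairwise, letters = letters_out,
                 block_kw_p = block_kw_p, alpha = alpha),
            class = "trait_test")
}

#' @export
print.trait_test <- function(x, ...) {
  cat("Trait '", x$trait, "': Kruskal-Wallis H = ",
      format(round(x$kw_statistic, 3)), ", p = ", format(signif(x$kw_p, 3)),
      "\n", sep = "")
  cat("  groups: ",
      paste(names(x$letters), x$letters, sep = "=", collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

# Iterative low-rank (SVD) imputation on a standardized matrix; the
# probabilistic-PCA-style default. Converges on the missing entries.
impute_iterative_svd <- function(z, rank, tol = 1e-6, max_iter = 200L) {
  miss <- is.na(z)
  z[miss] <- 0
  for (it in seq_len(max_iter)) {
    sv <- svd(z, nu = rank, nv = rank)
    recon <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
    delta <- max(abs(recon[miss] - z[miss]), 0)
    z[miss] <- recon[miss]
    if (delta < tol) break
  }
  z
}

#' PCA of phenotype traits with missing-value imputation
#'
#' Centers and unit-scales each trait, imputes missing cells, and runs a
#' principal component analysis. Traits with zero variance (among observed
#' values) are excluded with a warning. The default imputation is iterative
#' low-rank SVD reconstruction on the standardized matrix (a
#' probabilistic-PCA-style EM scheme); `method = "mean"` falls back to
#' column-mean imputation (which, on the standardized scale, is zero).
#'
#' @param table Data frame holding the trait columns.
#' @param traits Character vector of trait column names to include.
#' @param method Imputation method, `"iterative_svd"` (default) or `"mean"`.
#' @param rank Rank of the SVD reconstruction used for imputation (default
#'   `min(3, n_traits - 1)`).
#' @return Object of class `trait_pca`: list with `scores` (individuals x
#'   components), `loadings` (traits x components), `pct_variance`
#'   (percentage of variance per component, summing to 100), and
#'   `traits_used`.
#' @export
trait_pca <- function(table, traits, method = c("iterative_svd", "mean"),
                      rank = NULL) {
  method <- match.arg(method)
  miss_cols <- setdiff(traits, names(table))
  if (length(miss_cols) > 0L) {
    stop("trait(s) not found: ", paste(miss_cols, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(table[traits])
  storage.mode(m) <- "double"
  if (length(traits) < 2L || nrow(m) < 3L) {
    stop("need >= 2 traits and >= 3 individuals", call. = FALSE)
  }

  sds <- apply(m, 2L, stats::sd, na.rm = TRUE)
  zero_var <- !is.finite(sds) | sds == 0
  if (any(zero_var)) {
    warning("excluding zero-variance trait(s): ",
            paste(traits[zero_var], collapse = ", "), call. = FALSE)
    m <- m[, !zero_var, drop = FALSE]
    traits <- traits[!zero_var]
    if (ncol(m) < 2L) stop("fewer than 2 usable traits", call. = FALSE)
  }

  z <- scale(m)
  if (anyNA(z)) {
    if (method == "mean") {
      z[is.na(z)] <- 0
    } else {
      if (is.null(rank)) rank <- min(3L, ncol(z) - 1L)
      z <- impute_iterative_svd(z, rank = max(1L, rank))
    }
  }

  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 pct_variance = pct, traits_used = traits),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("Trait PCA: ", length(x$traits_used), " traits, ",
      nrow(x$scores), " individuals\n", sep = "")
  k <- min(4L, length(x$pct_variance))
  cat("  variance explained: ",
      paste0("PC", seq_len(k), " ", round(x$pct_variance[seq_len(k)], 1), "%",
             collapse = ", "), "\n", sep = "")
  invisible(x)
}
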
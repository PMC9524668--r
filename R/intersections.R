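#' Exclusive (UpSet-style) intersections of DEG sets
#'
#' Assigns every DEG in a tissue to exactly one intersection category: the
#' exact set of stresses that call it differentially expressed. Categories
#' are therefore mutually disjoint and partition the union of the per-stress
#' DEG sets; singleton categories hold the genes unique to one stress.
#'
#' @param x A [deg_collection].
#' @param tissue `"leaf"` or `"root"`.
#' @return An object of class `intersection_table`: a list with `tissue`;
#'   `entries`, a data frame with one row per non-empty subset of the
#'   stresses present (columns `key`, `n_members`, `n_up`, `n_down`,
#'   `n_mixed`, `pct_mixed`; direction columns are `NA` until
#'   [classify_directionality()] is applied) and a list-column `members`;
#'   and `per_stress`, the per-stress totals (DEG count, up/down counts,
#'   unique count and percentage).
#' @seealso [classify_directionality()], [unique_fraction()]
#' @export
#' @examples
#' recs <- data.frame(
#'   gene_id = c("g1", "g2", "g3", "g2", "g3", "g4", "g3"),
#'   tissue = "leaf",
#'   stress = c("dry_down", "dry_down", "dry_down", "salt", "salt", "salt",
#'              "peg"),
#'   log2fc = 1, fdr = 0.01
#' )
#' it <- exclusive_intersections(deg_collection(recs), "leaf")
#' it$entries[it$entries$n_members > 0, c("key", "n_members")]
exclusive_intersections <- function(x, tissue) {
  stopifnot(inherits(x, "deg_collection"))
  check_tissue(tissue)
  stresses <- stresses_present(x, tissue)
  if (length(stresses) == 0L) {
    warning("no DEG records for tissue '", tissue, "'; returning empty table",
            call. = FALSE)
    entries <- data.frame(key = character(0), n_members = integer(0),
                          n_up = integer(0), n_down = integer(0),
                          n_mixed = integer(0), pct_mixed = numeric(0))
    entries$members <- list()
    return(structure(list(tissue = tissue, entries = entries,
                          per_stress = data.frame()),
                     class = "intersection_table"))
  }

  sets <- lapply(stresses, function(s) deg_genes(x, tissue, s))
  names(sets) <- stresses
  genes <- unique(unlist(sets, use.names = FALSE))

  # bit-code each gene by the subset of stresses calling it
  code <- integer(length(genes))
  for (j in seq_along(stresses)) {
    idx <- match(sets[[j]], genes)
    code[idx] <- code[idx] + 2L^(j - 1L)
  }

  keys <- all_keys(stresses)
  key_code <- vapply(keys, function(k) {
    sum(2L^(match(key_stresses(k), stresses) - 1L))
  }, numeric(1))

  members <- unname(lapply(key_code, function(cd) genes[code == cd]))
  entries <- data.frame(
    key = keys,
    n_members = vapply(members, length, integer(1)),
    n_up = NA_integer_, n_down = NA_integer_, n_mixed = NA_integer_,
    pct_mixed = NA_real_,
    stringsAsFactors = FALSE
  )
  entries$members <- members
  rownames(entries) <- NULL

  r <- x$records
  r <- r[r$tissue == tissue, , drop = FALSE]
  per_stress <- do.call(rbind, lapply(stresses, function(s) {
    rs <- r[r$stress == s, , drop = FALSE]
    n_unique <- entries$n_members[entries$key == stress_key(s)]
    data.frame(
      stress = s,
      n_degs = nrow(rs),
      n_up = sum(rs$log2fc > 0),
      n_down = sum(rs$log2fc < 0),
      n_unique = n_unique,
      pct_unique = unique_fraction(n_unique, nrow(rs)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(per_stress) <- NULL

  structure(list(tissue = tissue, entries = entries, per_stress = per_stress),
            class = "intersection_table")
}

#' @export
print.intersection_table <- function(x, ...) {
  cat("Exclusive DEG intersections (", x$tissue, " tissue)\n", sep = "")
  e <- x$entries[x$entries$n_members > 0L, setdiff(names(x$entries), "members"),
                 drop = FALSE]
  if (nrow(e) == 0L) {
    cat("  (empty)\n")
  } else {
    print(e, row.names = FALSE)
  }
  if (NROW(x$per_stress) > 0L) {
    cat("Per-stress totals:\n")
    print(x$per_stress, row.names = FALSE)
  }
  invisible(x)
}

#' Percentage of DEGs unique to a stress
#'
#' The fraction of a stress's DEGs found in no other stress, as a percentage
#' rounded half-away-from-zero to two decimals (the convention of summary
#' tables such as "152 (10.98%)").
#'
#' @param n_unique Number of DEGs unique to the stress.
#' @param n_total Total DEGs for the stress.
#' @return Percentage, two decimals.
#' @export
#' @examples
#' unique_fraction(152, 1384) # 10.98
unique_fraction <- function(n_unique, n_total) {
  if (any(n_total <= 0)) {
    stop("n_total must be positive", call. = FALSE)
  }
  if (any(n_unique < 0) || any(n_unique > n_total)) {
    stop("n_unique must lie in [0, n_total]", call. = FALSE)
  }
  round_half_up(100 * n_unique / n_total, 2L)
}

#' Classify directionality of shared DEGs
#'
#' For each intersection category, splits member genes into consistently
#' upregulated (log2 fold change > 0 in every member stress), consistently
#' downregulated (< 0 in every member stress), and differentially regulated
#' ("mixed": upregulated in at least one member stress and downregulated in
#' at least one other). A DEG with a log2 fold change of exactly zero is
#' rejected: a significant call with no estimated effect indicates an
#' upstream inconsistency, and silently assigning it a sign would corrupt
#' the counts.
#'
#' @param x The [deg_collection] the table was computed from.
#' @param table An `intersection_table` from [exclusive_intersections()].
#' @return The table with `n_up`, `n_down`, `n_mixed` and `pct_mixed`
#'   (percentage of mixed genes among category members, two decimals) filled
#'   in.
#' @export
classify_directionality <- function(x, table) {
  stopifnot(inherits(x, "deg_collection"), inherits(table, "intersection_table"))
  tissue <- table$tissue
  r <- x$records[x$records$tissue == tissue, , drop = FALSE]
  if (any(r$log2fc == 0)) {
    bad <- r$gene_id[r$log2fc == 0][1L]
    stop("log2fc is exactly 0 for DEG ", bad, " (", tissue,
         "); sign undefined", call. = FALSE)
  }
  lookup <- split(r$log2fc, paste(r$gene_id, r$stress, sep = "\r"))

  for (i in seq_len(nrow(table$entries))) {
    key <- table$entries$key[i]
    genes <- table$entries$members[[i]]
    stresses <- key_stresses(key)
    if (length(genes) == 0L) {
      table$entries$n_up[i] <- 0L
      table$entries$n_down[i] <- 0L
      table$entries$n_mixed[i] <- 0L
      table$entries$pct_mixed[i] <- NA_real_
      next
    }
    signs <- vapply(genes, function(g) {
      fc <- vapply(stresses, function(s) {
        v <- lookup[[paste(g, s, sep = "\r")]]
        if (is.null(v)) {
          stop("gene ", g, " lacks a log2fc for member stress ", s,
               call. = FALSE)
        }
        v[1L]
      }, numeric(1))
      if (all(fc > 0)) 1L else if (all(fc < 0)) -1L else 0L
    }, integer(1))
    n_up <- sum(signs == 1L)
    n_down <- sum(signs == -1L)
    n_mixed <- sum(signs == 0L)
    table$entries$n_up[i] <- n_up
    table$entries$n_down[i] <- n_down
    table$entries$n_mixed[i] <- n_mixed
    table$entries$pct_mixed[i] <-
      round_half_up(100 * n_mixed / (n_up + n_down + n_mixed), 2L)
  }
  table
}

#' Chi-square comparison of DEG counts between tissues
#'
#' One-degree-of-freedom goodness-of-fit chi-square test of two DEG counts
#' against equal expected proportions (0.5/0.5), without continuity
#' correction — the test used to ask whether one tissue yields more DEGs
#' than the other.
#'
#' @param n_leaf,n_root DEG counts for the two tissues.
#' @return List with `chi2` and `p`.
#' @export
#' @examples
#' leaf_root_count_test(9317, 7412)
leaf_root_count_test <- function(n_leaf, n_root) {
  stopifnot(length(n_leaf) == 1L, length(n_root) == 1L,
            n_leaf >= 0, n_root >= 0)
  if (n_leaf + n_root == 0) {
    stop("both counts are zero; test undefined", call. = FALSE)
  }
  ht <- stats::chisq.test(c(n_leaf, n_root), p = c(0.5, 0.5), correct = FALSE)
  list(chi2 = unname(ht$statistic), p = unname(ht$p.value))
}

#' Write an intersection table
#'
#' Writes the category table as a TSV (columns `key`, `n_members`, `n_up`,
#' `n_down`, `n_mixed`, `pct_mixed`, plus a comma-separated `members`
#' column so the table round-trips through [read_intersection_table()]) and
#' the per-stress totals as a second TSV.
#'
#' @param table An `intersection_table`.
#' @param path Output path for the category TSV.
#' @param per_stress_path Output path for the totals TSV (default: `path`
#'   with a `_per_stress.tsv` suffix).
#' @return Invisibly, the paths written.
#' @export
write_intersection_table <- function(table, path, per_stress_path = NULL) {
  stopifnot(inherits(table, "intersection_table"))
  if (is.null(per_stress_path)) {
    per_stress_path <- paste0(sub("\\.tsv$", "", path), "_per_stress.tsv")
  }
  e <- table$entries
  flat <- data.frame(
    tissue = rep(table$tissue, nrow(e)),
    key = e$key, n_members = e$n_members, n_up = e$n_up, n_down = e$n_down,
    n_mixed = e$n_mixed, pct_mixed = e$pct_mixed,
    members = vapply(e$members, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ps <- table$per_stress
  if (NROW(ps) == 0L) {
    ps <- data.frame(tissue = character(0), stress = character(0),
                     n_degs = integer(0), n_up = integer(0),
                     n_down = integer(0), n_unique = integer(0),
                     pct_unique = numeric(0))
  } else {
    ps <- cbind(tissue = table$tissue, ps)
  }
  utils::write.table(ps, per_stress_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, per_stress_path))
}

#' Read an intersection table written by [write_intersection_table()]
#'
#' @param path Path to the category TSV.
#' @param per_stress_path Path to the totals TSV (default derived from
#'   `path` as in [write_intersection_table()]).
#' @return An `intersection_table`.
#' @export
read_intersection_table <- function(path, per_stress_path = NULL) {
  if (is.null(per_stress_path)) {
    per_stress_path <- paste0(sub("\\.tsv$", "", path), "_per_stress.tsv")
  }
  flat <- utils::read.delim(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  ps <- utils::read.delim(per_stress_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  tissue <- if (nrow(flat) > 0L) flat$tissue[1L] else
    if (nrow(ps) > 0L) ps$tissue[1L] else NA_character_
  entries <- data.frame(
    key = as.character(flat$key), n_members = flat$n_members,
    n_up = flat$n_up, n_down = flat$n_down, n_mixed = flat$n_mixed,
    pct_mixed = flat$pct_mixed, stringsAsFactors = FALSE
  )
  entries$members <- lapply(flat$members, function(m) {
    if (is.na(m) || !nzchar(m)) character(0) else strsplit(m, ",")[[1]]
  })
  ps$tissue <- NULL
  structure(list(tissue = tissue, entries = entries, per_stress = ps),
            class = "intersection_table")
}
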
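#' DEG collection
#'
#' Container for differential-expression results across stress treatments and
#' tissues: the significant gene calls (DEGs at an FDR threshold) together
#' with the per-(tissue, stress) expressed-gene universes that form the
#' sampling frame for the Monte-Carlo overlap null. The expression filter
#' itself (e.g. 1 count-per-million in two or more libraries within a
#' tissue/treatment group) is applied upstream by the DE caller; this object
#' stores its result.
#'
#' @param records Data frame with columns `gene_id`, `tissue`, `stress`,
#'   `log2fc`, `fdr`. Rows with `fdr` above `fdr_threshold` are kept only as
#'   universe members, not as DEGs.
#' @param universes Named list mapping `"<tissue>.<stress>"` to a character
#'   vector of gene ids passing the expression filter for that group. If
#'   `NULL`, universes are taken to be all genes present in `records` for
#'   each (tissue, stress).
#' @param fdr_threshold FDR significance cutoff for calling a DEG
#'   (default 0.05).
#'
#' @return An object of class `deg_collection`: a list with elements
#'   `records` (DEG rows only), `universes`, and `fdr_threshold`.
#' @export
#' @examples
#' recs <- data.frame(
#'   gene_id = c("g1", "g2", "g3"),
#'   tissue = "leaf", stress = "salt",
#'   log2fc = c(1.2, -0.8, 0.1), fdr = c(0.01, 0.049, 0.2)
#' )
#' dc <- deg_collection(recs)
#' n_degs(dc)
deg_collection <- function(records, universes = NULL, fdr_threshold = 0.05) {
  req <- c("gene_id", "tissue", "stress", "log2fc", "fdr")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- as.data.frame(records)[req]
  records$gene_id <- as.character(records$gene_id)
  records$tissue <- as.character(records$tissue)
  records$stress <- as.character(records$stress)

  if (any(!nzchar(records$gene_id)) || anyNA(records$gene_id)) {
    stop("gene_id must be non-empty", call. = FALSE)
  }
  bad_t <- setdiff(unique(records$tissue), .tissue_levels)
  if (length(bad_t) > 0L) {
    stop("unknown tissue label(s): ", paste(bad_t, collapse = ", "),
         call. = FALSE)
  }
  bad_s <- setdiff(unique(records$stress), names(.stress_codes))
  if (length(bad_s) > 0L) {
    stop("unknown stress label(s): ", paste(bad_s, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(records$fdr) || any(records$fdr < 0 | records$fdr > 1)) {
    stop("fdr must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(records$log2fc))) {
    stop("log2fc must be finite", call. = FALSE)
  }
  key <- paste(records$gene_id, records$tissue, records$stress, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate (gene_id, tissue, stress) row: ", dup$gene_id, "/",
         dup$tissue, "/", dup$stress, call. = FALSE)
  }
  if (!is.numeric(fdr_threshold) || length(fdr_threshold) != 1L ||
      fdr_threshold < 0 || fdr_threshold > 1) {
    stop("fdr_threshold must be a single value in [0, 1]", call. = FALSE)
  }

  if (is.null(universes)) {
    grp <- universe_id(records$tissue, records$stress)
    universes <- lapply(split(records$gene_id, grp), unique)
  } else {
    if (is.null(names(universes)) || any(!nzchar(names(universes)))) {
      stop("universes must be a named list keyed '<tissue>.<stress>'",
           call. = FALSE)
    }
    universes <- lapply(universes, as.character)
  }

  degs <- records[records$fdr <= fdr_threshold, , drop = FALSE]
  rownames(degs) <- NULL

  # every DEG must be a member of its group's universe
  if (nrow(degs) > 0L) {
    grp <- universe_id(degs$tissue, degs$stress)
    for (g in unique(grp)) {
      uni <- universes[[g]]
      if (is.null(uni)) {
        stop("no universe for group ", g, call. = FALSE)
      }
      out <- setdiff(degs$gene_id[grp == g], uni)
      if (length(out) > 0L) {
        stop("DEG gene(s) absent from universe ", g, ": ",
             paste(utils::head(out, 5L), collapse = ", "), call. = FALSE)
      }
    }
  }

  structure(
    list(records = degs, universes = universes, fdr_threshold = fdr_threshold),
    class = "deg_collection"
  )
}

#' @export
print.deg_collection <- function(x, ...) {
  cat("DEG collection (FDR <= ", format(x$fdr_threshold), ")\n", sep = "")
  if (nrow(x$records) == 0L) {
    cat("  no DEGs\n")
  } else {
    tab <- table(x$records$tissue, x$records$stress)
    cat("  DEGs per tissue x stress:\n")
    print(tab)
  }
  cat("  universes: ", length(x$universes), " group(s), sizes ",
      paste(range(vapply(x$universes, length, integer(1))), collapse = "-"),
      "\n", sep = "")
  invisible(x)
}

#' Number of DEGs in a collection
#'
#' @param x A [deg_collection].
#' @param tissue Optional tissue to restrict to.
#' @param stress Optional stress to restrict to.
#' @return Integer count of DEG records.
#' @export
n_degs <- function(x, tissue = NULL, stress = NULL) {
  stopifnot(inherits(x, "deg_collection"))
  r <- x$records
  if (!is.null(tissue)) r <- r[r$tissue == tissue, , drop = FALSE]
  if (!is.null(stress)) r <- r[r$stress == stress, , drop = FALSE]
  nrow(r)
}

#' Read a DEG result table
#'
#' Reads a tab-separated DE table with header columns `gene_id`, `tissue`,
#' `stress`, `log2fc`, `fdr` (any extra columns are ignored). All rows are
#' retained as universe members for their (tissue, stress) group; rows at or
#' below the FDR threshold become DEG records. An optional companion universe
#' file (`gene_id`, `tissue`, `stress`) overrides the universes, for the case
#' where the main table contains significant genes only.
#'
#' @param path Path to the DEG TSV.
#' @param fdr_threshold FDR cutoff for calling DEGs (default 0.05).
#' @param universe_path Optional path to a universe TSV.
#' @return A [deg_collection].
#' @export
read_deg_table <- function(path, fdr_threshold = 0.05, universe_path = NULL) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = NA, stringsAsFactors = FALSE)
  req <- c("gene_id", "tissue", "stress", "log2fc", "fdr")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0L) {
    stop("DEG table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  universes <- NULL
  if (!is.null(universe_path)) {
    uni <- utils::read.delim(universe_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    ureq <- c("gene_id", "tissue", "stress")
    umiss <- setdiff(ureq, names(uni))
    if (length(umiss) > 0L) {
      stop("universe table ", universe_path, " is missing column(s): ",
           paste(umiss, collapse = ", "), call. = FALSE)
    }
    universes <- lapply(
      split(as.character(uni$gene_id), universe_id(uni$tissue, uni$stress)),
      unique
    )
  }
  deg_collection(tab, universes = universes, fdr_threshold = fdr_threshold)
}

#' Write a DEG collection to disk
#'
#' Writes the DEG records as a TSV and the per-group universes as a companion
#' TSV (`gene_id`, `tissue`, `stress`), in the formats read back by
#' [read_deg_table()].
#'
#' @param x A [deg_collection].
#' @param path Output path for the DEG TSV.
#' @param universe_path Output path for the universe TSV (default:
#'   `path` with a `_universe.tsv` suffix).
#' @return Invisibly, the paths written.
#' @export
write_deg_table <- function(x, path, universe_path = NULL) {
  stopifnot(inherits(x, "deg_collection"))
  if (is.null(universe_path)) {
    universe_path <- paste0(sub("\\.tsv$", "", path), "_universe.tsv")
  }
  utils::write.table(x$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  grp <- strsplit(names(x$universes), ".", fixed = TRUE)
  uni <- data.frame(
    gene_id = unlist(x$universes, use.names = FALSE),
    tissue = rep(vapply(grp, `[`, "", 1L),
                 vapply(x$universes, length, integer(1))),
    stress = rep(vapply(grp, `[`, "", 2L),
                 vapply(x$universes, length, integer(1)))
  )
  utils::write.table(uni, universe_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, universe_path))
}

# DEG gene ids for one (tissue, stress); internal.
deg_genes <- function(x, tissue, stress) {
  r <- x$records
  unique(r$gene_id[r$tissue == tissue & r$stress == stress])
}

# Stresses with at least one DEG in a tissue, canonical order; internal.
stresses_present <- function(x, tissue) {
  s <- unique(x$records$stress[x$records$tissue == tissue])
  names(.stress_codes)[names(.stress_codes) %in% s]
}
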
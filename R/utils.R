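# Internal helpers shared across modules.

# Canonical stress codes, in the fixed reporting order D, S, P, N.
.stress_codes <- c(dry_down = "D", salt = "S", peg = "P", nutrient = "N")
.tissue_levels <- c("leaf", "root")

#' Canonical stress levels
#'
#' The four stress treatments recognised by the package, in their canonical
#' reporting order (dry-down, salt, PEG, low-nutrient).
#'
#' @return Named character vector mapping stress names to one-letter codes.
#' @export
#' @examples
#' stress_codes()
stress_codes <- function() .stress_codes

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero to `digits` decimals (table formatting
# convention; base round() rounds half to even).
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Render a subset of stresses as a canonical key string, e.g. c("salt",
# "dry_down") -> "DS".
stress_key <- function(stresses) {
  stresses <- unique(stresses)
  bad <- setdiff(stresses, names(.stress_codes))
  if (length(bad) > 0L) {
    stop("unknown stress label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ord <- names(.stress_codes)[names(.stress_codes) %in% stresses]
  paste(.stress_codes[ord], collapse = "")
}

# Inverse of stress_key(): "DS" -> c("dry_down", "salt").
key_stresses <- function(key) {
  codes <- strsplit(key, "", fixed = TRUE)[[1]]
  bad <- setdiff(codes, .stress_codes)
  if (length(bad) > 0L) {
    stop("unknown stress code(s) in key '", key, "'", call. = FALSE)
  }
  names(.stress_codes)[match(codes, .stress_codes)]
}

# All non-empty subsets of `stresses`, as canonical key strings, ordered by
# decreasing subset size then canonical order (the Table 3 layout).
all_keys <- function(stresses) {
  stresses <- names(.stress_codes)[names(.stress_codes) %in% stresses]
  k <- length(stresses)
  if (k == 0L) return(character(0))
  subsets <- lapply(seq_len(2^k - 1L), function(m) {
    stresses[bitwAnd(m, 2^(seq_len(k) - 1L)) > 0L]
  })
  keys <- vapply(subsets, stress_key, character(1))
  sizes <- nchar(keys)
  # decreasing subset size; within a size, canonical (D < S < P < N) order
  canon <- unlist(lapply(seq(k, 1L), function(s) {
    kk <- keys[sizes == s]
    kk[order(vapply(kk, function(x) {
      sum(match(strsplit(x, "")[[1]], .stress_codes) * 10^(4 - seq_len(s)))
    }, numeric(1)))]
  }))
  canon
}

check_tissue <- function(tissue) {
  if (!is.character(tissue) || length(tissue) != 1L ||
      !tissue %in% .tissue_levels) {
    stop("`tissue` must be one of: ", paste(.tissue_levels, collapse = ", "),
         call. = FALSE)
  }
  tissue
}

universe_id <- function(tissue, stress) paste(tissue, stress, sep = ".")
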
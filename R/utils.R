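#' @keywords internal
"_PACKAGE"

# Shared argument checks and small helpers used across modules.

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    stop_invalid("`%s` must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < lo || x > hi) {
    stop_invalid("`%s` must be a single number in [%g, %g]", name, lo, hi)
  }
  as.numeric(x)
}

#' Derive a stage-specific seed from a master seed
#'
#' Stage seeds are a stable hash of the stage name folded into the master
#' seed, so adding or reordering pipeline stages never perturbs the random
#' stream of the others. The result is always a valid 32-bit integer seed.
#'
#' @param master_seed single integer master seed.
#' @param stage character stage name.
#' @return a single integer seed.
#' @export
derive_seed <- function(master_seed, stage) {
  master_seed <- check_count(master_seed, "master_seed", min = 0L)
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 2147483647
  as.integer((master_seed + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  seed <- check_count(seed, "seed", min = 0L)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# TSV conventions: tab-separated, header row, no quoting, NA as empty string.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "", check.names = FALSE, ...)
}

format_num <- function(x) signif(x, 6)
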
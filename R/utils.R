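#' @keywords internal
"_PACKAGE"

# Internal assertion helper: stop with the caller's message if cond is FALSE.
stopifnot_msg <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Derive a reproducible per-subject seed from a master seed
#'
#' Stable FNV-1a-style hash of `paste(master_seed, subject_id)` reduced
#' modulo 2^31 - 1, so that every generated artifact is reproducible from
#' `(master_seed, subject_id)` alone and seeds stay within R's integer range.
#'
#' @param master_seed Integer master seed.
#' @param subject_id Character subject identifier (or anything coercible).
#' @return A positive integer seed.
#' @export
#' @examples
#' subject_seed(1L, "sub-001")
subject_seed <- function(master_seed, subject_id) {
  stopifnot_msg(length(master_seed) == 1 && is.finite(master_seed),
                "master_seed must be a single finite number")
  key <- paste0(format(as.integer(master_seed)), "|", as.character(subject_id))
  bytes <- utf8ToInt(key)
  h <- 2166136261
  m <- 2147483647  # 2^31 - 1, keeps arithmetic exact in doubles
  for (b in bytes) {
    h <- (h %% m) * 31 + b            # < 2^31 * 31 + 255 < 2^53: exact
    h <- h %% m
  }
  as.integer(h %% (m - 1L)) + 1L
}

# Evaluate an expression under a local RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
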
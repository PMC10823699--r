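# Internal helpers shared across the package.

# Evaluate `code` under a private, reproducible RNG stream without
# disturbing the caller's .Random.seed.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive independent child seeds from a master seed (for cohort draws vs
# per-participant session streams). Kept below 2^31 - 1.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Fingerprint of a task or cohort configuration
#'
#' MD5 digest of the canonical JSON serialization of a configuration
#' object, used to stamp every output artifact so that session logs,
#' score tables, and reports can be matched to the exact design that
#' produced them.
#'
#' @param config A [task_config()] or [cohort_spec()] object (any
#'   JSON-serializable list).
#' @return A 32-character hexadecimal string.
#' @export
#' @examples
#' config_fingerprint(task_config())
config_fingerprint <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                              force = TRUE),
             tmp)
  unname(tools::md5sum(tmp))
}

stop_domain <- function(...) stop(..., call. = FALSE)
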
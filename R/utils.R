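`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global RNG state, so seeded helpers do not disturb
#' the caller's random stream. `seed = NULL` leaves the RNG untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic 31-bit sub-seed: splits one user seed into independent
# per-subject / per-fold streams without consuming the global RNG.
derive_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 2147483647)
  x <- (s * 48271 + as.numeric(index) * 1013904223) %% 2147483647
  as.integer(x %% 2147483629 + 1)
}

# md5 of the canonical JSON serialization of a list (config provenance)
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# Deterministic numeric TSV writer (15 significant digits round-trips
# doubles closely enough for re-scoring; format is stable across runs).
write_numeric_tsv <- function(m, path) {
  df <- as.data.frame(m, check.names = FALSE)
  out <- lapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.15g", col) else as.character(col)
  })
  names(out) <- names(df)
  write.table(as.data.frame(out, check.names = FALSE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
}
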
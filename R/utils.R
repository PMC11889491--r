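# Internal helpers shared across modules.

# Signal a classed error so callers can branch on condition class.
sexome_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "sexome_error"), call = call))
}

# Round half away from zero to `digits` decimals (printed-table convention;
# base round() is round-half-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5) / p
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so simulation calls do not perturb the global stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a data.frame as plain TSV (UTF-8, no quoting) — the package's
# on-disk dialect for every tabular artifact.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}
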
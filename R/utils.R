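# Internal helpers: classed conditions, integer gcd, seeded RNG scope.

stop_pn <- function(class, message, call. = FALSE, ...) {
  cond <- structure(
    class = c(class, "pn_error", "error", "condition"),
    list(message = message, call = if (call.) sys.call(-1) else NULL, ...)
  )
  stop(cond)
}

#' @noRd
gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) {
    tmp <- b
    b <- a %% b
    a <- tmp
  }
  a
}

# gcd of the positive part of an integer vector; 0 for the zero vector
gcd_vec <- function(v) {
  v <- abs(v[v != 0])
  if (length(v) == 0L) return(0)
  Reduce(gcd2, v)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Canonical row-lexicographic order of an integer matrix.
lex_order <- function(mat) {
  if (nrow(mat) <= 1L) return(seq_len(nrow(mat)))
  do.call(order, lapply(seq_len(ncol(mat)), function(j) mat[, j]))
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop_pn("pn_value_error",
            sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}
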
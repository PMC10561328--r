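# Minimal semi-positive invariant enumeration by exact integer Farkas /
# Martinez-Silva elimination, plus an independent brute-force oracle.

new_invariant <- function(kind, vector, ids) {
  vector <- stats::setNames(as.integer(vector), ids)
  structure(
    list(kind = kind, vector = vector,
         support = ids[vector > 0L],
         normalized = gcd_vec(vector) == 1L),
    class = "pn_invariant"
  )
}

#' @export
print.pn_invariant <- function(x, ...) {
  cat(sprintf("<pn_invariant %s> (%s)  support {%s}\n", x$kind,
              paste(x$vector, collapse = ","),
              paste(x$support, collapse = ", ")))
  invisible(x)
}

# Farkas-style elimination.  `C` is a k x d integer matrix of equations over
# d nonnegative variables; returns the complete set of minimal-support,
# gcd-normalized semi-positive integer solutions of C y = 0, as rows of a
# matrix (0 rows when none exist), in canonical lexicographic order.
farkas_solve <- function(C, max_rows = 100000L) {
  d <- ncol(C)
  k <- nrow(C)
  # tableau rows start as unit vectors e_j with their equation values C e_j
  B <- cbind(t(C), diag(1, d, d))
  for (col in seq_len(k)) {
    vals <- B[, col]
    keep <- B[vals == 0, , drop = FALSE]
    pos <- which(vals > 0)
    neg <- which(vals < 0)
    if (length(pos) && length(neg)) {
      combs <- matrix(0, length(pos) * length(neg), ncol(B))
      r <- 0L
      for (i in pos) {
        for (j in neg) {
          r <- r + 1L
          row <- abs(vals[j]) * B[i, ] + vals[i] * B[j, ]
          g <- gcd_vec(row)
          if (g > 1) row <- row / g
          combs[r, ] <- row
        }
      }
      keep <- rbind(keep, combs)
    }
    keep <- unique(keep)
    if (nrow(keep) > max_rows) {
      stop_pn("pn_size_error",
              "invariant elimination exceeded the intermediate-row limit")
    }
    B <- keep
  }
  sol <- B[, k + seq_len(d), drop = FALSE]
  sol <- sol[rowSums(sol) > 0, , drop = FALSE]
  if (nrow(sol) > 0L) {
    sol <- normalize_rows(sol)
    sol <- unique(sol)
    sol <- minimal_support_filter(sol)
    sol <- sol[lex_order(sol), , drop = FALSE]
  }
  storage.mode(sol) <- "integer"
  sol
}

# Divide each row by the gcd of its entries (dimension-preserving).
normalize_rows <- function(sol) {
  g <- pmax(1, apply(sol, 1L, gcd_vec))
  sol / g  # column-major recycling divides row i by g[i]
}

# Keep only rows whose support contains no other row's support strictly.
minimal_support_filter <- function(sol) {
  if (nrow(sol) <= 1L) return(sol)
  supports <- lapply(seq_len(nrow(sol)), function(i) which(sol[i, ] > 0L))
  keep <- vapply(seq_along(supports), function(i) {
    !any(vapply(seq_along(supports), function(j) {
      j != i && length(supports[[j]]) < length(supports[[i]]) &&
        all(supports[[j]] %in% supports[[i]])
    }, logical(1)))
  }, logical(1))
  sol[keep, , drop = FALSE]
}

#' Minimal semi-positive S- and T-invariants
#'
#' An S-invariant (P-invariant) is a semi-positive integer place-weight
#' vector `Y` with `A Y = 0`: the `Y`-weighted token sum is conserved by
#' every firing.  A T-invariant is a semi-positive transition-count vector
#' `X` with `A' X = 0`: a firing-count vector that, if realizable, returns a
#' marking to itself.  "Semi-positive" means nonnegative and nonzero; the
#' functions return the complete set of *minimal-support*, gcd-normalized
#' invariants, computed by exact Farkas-style integer elimination and sorted
#' lexicographically by vector.
#'
#' @inheritParams input_matrix
#' @return A list of `pn_invariant` objects (possibly empty), each with
#'   fields `kind` (`"S"` or `"T"`), `vector` (named nonnegative integers),
#'   `support`, and `normalized`.
#' @examples
#' dana <- build_dana()
#' minimal_s_invariants(dana$net)  # two conserved place sets
#' minimal_t_invariants(dana$net)  # none: no firing sequence is cyclic
#' @export
minimal_s_invariants <- function(net) {
  a <- net$post - net$pre
  sol <- farkas_solve(a)   # equations: one per transition, vars = places
  lapply(seq_len(nrow(sol)), function(i) new_invariant("S", sol[i, ], net$places))
}

#' @rdname minimal_s_invariants
#' @export
minimal_t_invariants <- function(net) {
  a <- net$post - net$pre
  sol <- farkas_solve(t(a))
  lapply(seq_len(nrow(sol)), function(i) new_invariant("T", sol[i, ], net$transitions))
}

#' Verify an invariant exactly
#'
#' Checks the defining homogeneous system (`A Y = 0` for S-kind,
#' `A' X = 0` for T-kind) in exact integer arithmetic.
#'
#' @inheritParams input_matrix
#' @param inv a `pn_invariant`, or a plain numeric vector together with
#'   `kind`.
#' @param kind `"S"` or `"T"`; ignored when `inv` is a `pn_invariant`.
#' @return Logical scalar.
#' @export
verify_invariant <- function(net, inv, kind = NULL) {
  if (inherits(inv, "pn_invariant")) {
    kind <- inv$kind
    vec <- inv$vector
  } else {
    if (is.null(kind)) stop_pn("pn_kind_error", "`kind` required for a bare vector")
    vec <- inv
  }
  kind <- match.arg(toupper(kind), c("S", "T"))
  a <- net$post - net$pre
  expected <- if (kind == "S") length(net$places) else length(net$transitions)
  if (length(vec) != expected) {
    stop_pn("pn_dimension_error", sprintf(
      "%s-invariant must have length %d, got %d", kind, expected, length(vec)))
  }
  if (any(vec < 0) || all(vec == 0)) return(FALSE)
  if (kind == "S") all(a %*% vec == 0) else all(t(a) %*% vec == 0)
}

#' Invariant coverage of a net
#'
#' Reports which places (kind `"S"`) or transitions (kind `"T"`) appear in
#' no minimal invariant's support.  A place outside every S-invariant
#' support carries tokens whose weighted count is not conserved.
#'
#' @inheritParams input_matrix
#' @param kind `"S"` or `"T"`.
#' @return A list with `covered` (logical: no uncovered elements) and
#'   `uncovered` (character vector of identifiers).
#' @export
coverage <- function(net, kind = c("S", "T")) {
  kind <- match.arg(toupper(kind[1L]), c("S", "T"))
  invs <- if (kind == "S") minimal_s_invariants(net) else minimal_t_invariants(net)
  all_ids <- if (kind == "S") net$places else net$transitions
  in_support <- unique(unlist(lapply(invs, `[[`, "support")))
  uncovered <- setdiff(all_ids, in_support)
  list(covered = length(uncovered) == 0L, uncovered = uncovered)
}

#' Brute-force invariant enumeration (testing oracle)
#'
#' Enumerates every nonnegative integer vector with entries up to
#' `max_entry`, keeps exact solutions of the homogeneous system, and filters
#' to minimal support with gcd 1.  Exponential in the number of places (or
#' transitions); guarded for small nets only.  Serves as an independent
#' oracle for [minimal_s_invariants()] / [minimal_t_invariants()].
#'
#' @inheritParams coverage
#' @param max_entry largest entry enumerated per coordinate.
#' @return As [minimal_s_invariants()].
#' @export
brute_force_invariants <- function(net, kind = c("S", "T"), max_entry = 3L) {
  kind <- match.arg(toupper(kind[1L]), c("S", "T"))
  assert_count(max_entry, "max_entry", min = 1L)
  a <- net$post - net$pre
  if (kind == "T") a <- t(a)
  d <- ncol(a)
  ids <- if (kind == "S") net$places else net$transitions
  if (d == 0L) return(list())
  if ((max_entry + 1)^d > 2^20) {
    stop_pn("pn_size_error", sprintf(
      "brute force would enumerate (%d)^%d vectors; net too large",
      max_entry + 1L, d))
  }
  grid <- as.matrix(expand.grid(rep(list(0:max_entry), d)))
  dimnames(grid) <- NULL
  ok <- rowSums(grid) > 0
  if (nrow(a) > 0L) ok <- ok & rowSums(abs(grid %*% t(a))) == 0
  sol <- grid[ok, , drop = FALSE]
  if (nrow(sol) > 0L) {
    sol <- normalize_rows(sol)
    sol <- unique(sol)
    sol <- minimal_support_filter(sol)
    sol <- sol[lex_order(sol), , drop = FALSE]
  }
  lapply(seq_len(nrow(sol)), function(i) new_invariant(kind, sol[i, ], ids))
}
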
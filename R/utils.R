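# Classed condition helper: every user-facing failure in the package raises a
# condition of class "ielec_<class>_error" so callers (and tests) can
# discriminate I/O vs dimension vs frame errors etc.
ielec_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("ielec_", class, "_error"),
                                "ielec_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row-wise Euclidean norms of an n x 3 matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

as_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3, byrow = TRUE)
  storage.mode(p) <- "double"
  if (ncol(p) != 3L)
    ielec_stop("dim", "points must be a 3-vector or an n x 3 matrix, got %d columns", ncol(p))
  p
}

# Evaluate expr with a private, seeded RNG stream, restoring the caller's
# RNG state afterwards. Keeps phantom generation fully deterministic without
# clobbering the session RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
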
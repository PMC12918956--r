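#' @keywords internal
"_PACKAGE"

# All randomness in the package flows through this helper: run `code` under a
# caller-supplied integer seed with fixed RNG kinds, restoring the global RNG
# state afterwards so no generator leaks state into the session.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

# Canonical undirected edge key "a|b" with a < b; cell ids are integers.
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

edge_key_split <- function(keys) {
  if (length(keys) == 0L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("a", "b"))))
  }
  parts <- strsplit(keys, "|", fixed = TRUE)
  m <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
  colnames(m) <- c("a", "b")
  m
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Minimal-image difference on a periodic interval of length L.
wrap_diff <- function(d, L) {
  d - L * round(d / L)
}

# Wrap coordinates into [0, L).
wrap_coord <- function(x, L) {
  x - L * floor(x / L)
}

stop_epijam <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "epijam_error")))
}
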
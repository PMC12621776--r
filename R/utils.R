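# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards. Keeps library functions from
# clobbering user-level set.seed() state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1L)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  code
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x)
}

# Coerce a StateAnnotation (or bare vector) to an integer state vector.
state_vector <- function(x) {
  if (inherits(x, "StateAnnotation")) {
    x$states
  } else {
    as.integer(x)
  }
}

# Number of states implied by an annotation-like object.
n_states_of <- function(x, n_states = NULL) {
  if (!is.null(n_states)) return(as.integer(n_states))
  if (inherits(x, "StateAnnotation")) return(length(x$alphabet))
  if (inherits(x, "SoftAnnotation")) return(ncol(x$probs))
  max(state_vector(x), na.rm = TRUE)
}
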
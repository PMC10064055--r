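# Internal helpers shared across modules.

# Deterministic per-stage seed derived from a master seed and a stage name.
# Polynomial rolling hash of the name, folded into [0, 2^31 - 2] so the result
# is always a valid 32-bit integer seed. Keyed by name (not position) so
# inserting a stage never perturbs the seeds of other stages.
stage_seed <- function(master_seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% m
  }
  as.integer((as.numeric(master_seed) %% m + h) %% m)
}

check_scalar_int <- function(x, name, min = NULL) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x)) {
    abort(sprintf("`%s` must be a single integer", name))
  }
  if (!is.null(min) && x < min) {
    abort(sprintf("`%s` must be >= %s", name, min))
  }
  invisible(as.integer(x))
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1]", name))
  }
  invisible(as.numeric(x))
}

# Coerce a trait given as a named vector or a two-column data frame
# (tip id, value) to a named numeric vector.
as_trait_vector <- function(trait) {
  if (is.data.frame(trait)) {
    if (ncol(trait) < 2L) abort("trait data frame needs two columns: tip id, value")
    out <- as.numeric(trait[[2L]])
    names(out) <- as.character(trait[[1L]])
    return(out)
  }
  if (!is.numeric(trait) || is.null(names(trait))) {
    abort("trait must be a named numeric vector or a two-column data frame")
  }
  trait
}

# Shannon entropy of a nonnegative weight vector, in the given log base.
# Zero weights contribute nothing; an all-zero vector has entropy 0.
shannon_entropy <- function(w, base = exp(1)) {
  w <- w[w > 0]
  if (length(w) == 0L) return(0)
  p <- w / sum(w)
  -sum(p * log(p, base = base))
}

lower_tri_vec <- function(m) m[lower.tri(m)]
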
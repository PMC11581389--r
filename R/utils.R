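# Internal helpers: scoped RNG and the master-seed -> stage-seed derivation.

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic stage seeds derived from one master seed.  Documented
# derivation: seed_k = (master + 1009 * k) mod (2^31 - 1), with stage indices
# fixed below; every stage of an experiment is independently re-runnable.
.stageIndex <- c(simulate = 1L, split = 2L, weights = 3L, cv = 4L,
                 permutation = 5L)

#' Derive a stage seed from a master seed
#'
#' `seed_stage = (master + 1009 * index) mod (2^31 - 1)`, with a fixed
#' per-stage index (simulate = 1, split = 2, weights = 3, cv = 4,
#' permutation = 5).
#'
#' @param master integer master seed.
#' @param stage stage name.
#' @return an integer seed in \[1, 2^31 - 2\].
#' @export
stageSeed <- function(master, stage = names(.stageIndex)) {
  stage <- match.arg(stage)
  s <- (as.numeric(master) + 1009 * .stageIndex[[stage]]) %% 2147483647
  as.integer(max(1, s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cheap content fingerprint for weight arrays (no digest dependency).
weightFingerprint <- function(source, seed, ...) {
  parts <- vapply(list(...), function(w)
    sprintf("%.8e", sum(w) + sum(abs(w)) * 1e-3), "")
  paste0(source, ":", ifelse(is.na(seed), "file", seed), ":",
         paste(parts, collapse = "/"))
}
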
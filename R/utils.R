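# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
half_min_positive <- function(x) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) == 0L) return(0)
  min(x) / 2
}

# Shannon entropy (nats) of a non-negative vector; zeros dropped.
shannon <- function(x) {
  x <- x[x > 0]
  if (length(x) == 0L) return(NA_real_)
  p <- x / sum(x)
  -sum(p * log(p))
}

inv_simpson <- function(x) {
  x <- x[x > 0]
  if (length(x) == 0L) return(NA_real_)
  p <- x / sum(x)
  1 / sum(p^2)
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

# Structured log line to stderr; every dropped sample / missing-coded entry is
# reported through here so pipelines leave an audit trail.
log_msg <- function(...) message("[micoexpress] ", sprintf(...))

assert_matrix_aligned <- function(a, b, what = "matrices") {
  if (!identical(rownames(a), rownames(b)) || !identical(colnames(a), colnames(b)))
    stop_fmt("%s are not aligned on identical feature and sample indices", what)
  invisible(TRUE)
}

# Deterministic sub-seed derivation: one global seed fans out to per-stage
# streams so toggling a stage does not perturb another stage's randomness.
stage_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, quantify = 211L, taxa = 307L, network = 401L,
            topology = 503L, hubs = 601L, diversity = 701L,
            differential = 809L, enrichment = 907L, crossfeeding = 1009L)
  if (!stage %in% names(offs)) stop_fmt("unknown stage '%s'", stage)
  (as.integer(seed) %% 1000000L) * 1000L + offs[[stage]]
}
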
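# Internal helpers shared across modules.

# Typed validation failure naming the offending field (and row where known).
nq_abort <- function(message, field = NULL, row = NULL, class = "nq_validation_error") {
  if (!is.null(field)) message <- sprintf("%s [field: %s]", message, field)
  if (!is.null(row)) message <- sprintf("%s [row: %s]", message, paste(row, collapse = ", "))
  abort(message, class = c(class, "nq_error"))
}

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    nq_abort(sprintf("`%s` must be a single number", name), field = name)
  }
  if (finite && !is.finite(x)) nq_abort(sprintf("`%s` must be finite", name), field = name)
  if (positive && x <= 0) nq_abort(sprintf("`%s` must be > 0, got %g", name, x), field = name)
  invisible(x)
}

# Significance stars at the four caption levels.
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

# Deterministic child seeds below 2^31 derived from one user seed.
derive_seed <- function(seed, index) {
  (as.integer(seed) * 7919L + as.integer(index) * 104729L) %% 2147483399L
}
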
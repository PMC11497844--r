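# Internal helpers shared across modules.

# Half-up rounding; base round() is banker's and would send 0.5 down.
round_half_up <- function(x) floor(x + 0.5)

# Deterministic per-task sub-seed derived from a master seed.  Keeps every
# derived seed a valid 32-bit integer so set.seed() never overflows.
sub_seed <- function(seed, index) {
  s <- abs(as.double(seed)) %% 2147483647
  as.integer((s * 48271 + as.double(index) * 69621 + 1) %% 2147483587)
}

stop_if_not_df <- function(x, arg) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame, not %s.", arg, class(x)[1]))
  }
}

# Subject tables (dosage and prediction matrices) carry FID/IID as the first
# two columns; everything after is the numeric payload.
check_subject_table <- function(x, arg) {
  stop_if_not_df(x, arg)
  if (ncol(x) < 3 || !identical(names(x)[1:2], c("FID", "IID"))) {
    abort(sprintf("`%s` must start with columns FID, IID followed by at least one value column.", arg))
  }
  invisible(x)
}

subject_values <- function(x) {
  as.matrix(x[, -(1:2), drop = FALSE])
}

# Named count input: accepts a named numeric vector or a two-column data
# frame (gene, count) and returns a named vector.
as_gene_counts <- function(x, arg) {
  if (is.data.frame(x)) {
    if (ncol(x) != 2) {
      abort(sprintf("`%s` must have exactly two columns (gene, count).", arg))
    }
    out <- setNames(as.numeric(x[[2]]), as.character(x[[1]]))
  } else if (is.numeric(x) && !is.null(names(x))) {
    out <- x
  } else {
    abort(sprintf("`%s` must be a named numeric vector or a (gene, count) data frame.", arg))
  }
  if (anyNA(out) || any(out < 0)) {
    abort(sprintf("`%s` contains missing or negative counts.", arg))
  }
  out
}

maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), force(code))
  }
}
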
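# Internal helpers shared across modules.

# logit with clamping; differential analysis of methylation fractions runs on
# this scale (fractions clamped to [eps, 1 - eps] before transform).
.logit <- function(p, eps = 1e-4) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

.invlogit <- function(x) 1 / (1 + exp(-x))

.assertNumeric <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(name, " must be finite numeric", call. = FALSE)
  invisible(x)
}

# seed derived from a master seed and a stage label, kept below 2^31
.deriveSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) + 1009L * (h %% 1000003L)) %% 2147483647L
}

.asMatrixInput <- function(x) {
  if (is(x, "OmicsMatrix")) featureValues(x) else as.matrix(x)
}
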
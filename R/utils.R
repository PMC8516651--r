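#' Logit and inverse-logit
#'
#' Standard logit link helpers used throughout the package. `logit()` nudges
#' exact 0/1 inputs away from the boundary by `eps` (with a message) because
#' prevalence draws and observed proportions occasionally hit the boundary.
#'
#' @param p probabilities in \[0, 1\].
#' @param eps boundary nudge applied to exact 0/1 values.
#' @return numeric vector on the logit scale.
#' @export
logit <- function(p, eps = 1e-6) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  bad <- which(p <= 0 | p >= 1)
  if (length(bad)) {
    message(sprintf("logit(): %d boundary value(s) nudged by %g", length(bad), eps))
    p[p <= 0] <- eps
    p[p >= 1] <- 1 - eps
  }
  stats::qlogis(p)
}

#' @rdname logit
#' @param x values on the logit scale.
#' @export
invlogit <- function(x) stats::plogis(x)

#' Weighted median
#'
#' Lower weighted median: the smallest value `x` such that the cumulative
#' weight of observations `<= x` reaches half the total weight. This is the
#' split rule of the bi-tree partitioner; ties at the median go to the lower
#' partition by construction.
#'
#' @param x numeric values.
#' @param w non-negative weights, same length as `x`.
#' @return scalar weighted median.
#' @export
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  x[which(cw >= sum(w) / 2)[1]]
}

#' Stable hash of an R object (for workspace manifests)
#'
#' Serializes the object to a temporary file and returns its md5 digest.
#' Version-2 serialization keeps the hash stable across R sessions.
#'
#' @param x any R object.
#' @return md5 hex string.
#' @keywords internal
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Derive a child seed from a base seed and a label
#'
#' Gives each pipeline stage / replicate an independent, reproducible stream
#' while staying inside the 32-bit integer range.
#'
#' @param seed base integer seed.
#' @param label character tag of the consumer.
#' @return integer seed.
#' @keywords internal
child_seed <- function(seed, label) {
  h <- utf8ToInt(paste0(label, ":", seed))
  s <- as.numeric(seed) %% 2147483647
  for (v in h) s <- (s * 31 + v) %% 2147483647  # double arithmetic: exact
  as.integer(s)
}
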
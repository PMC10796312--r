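#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' Every source of randomness in the pipeline draws its seed from the single
#' experiment seed through this function, so that stages are independently
#' re-runnable yet jointly reproducible. The derivation is a small
#' multiplicative congruential mix over the tag characters, kept strictly
#' below 2^31 - 1 so the result is always a valid R seed.
#'
#' @param seed Integer master seed.
#' @param tag Character scalar naming the consumer (e.g. a subject id or a
#'   stage name).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
sub_seed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(tag),
            length(tag) == 1L)
  m <- 2147483647
  s <- abs(as.numeric(seed)) %% m
  # 69069 * (m - 1) < 2^53, so double arithmetic below is exact
  for (ch in utf8ToInt(tag)) s <- (s * 69069 + ch) %% m
  as.integer(s)
}

#' Evaluate an expression under a locally-set RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded helpers do not
#' disturb an enclosing simulation.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Internal: canonical benign/malignant factor from flexible label input.
as_nodule_label <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) labels <- ifelse(labels, "malignant", "benign")
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    labels <- ifelse(labels == 1, "malignant", "benign")
  }
  stopifnot(all(labels %in% c("benign", "malignant")))
  factor(labels, levels = c("benign", "malignant"))
}

# Internal: 0/1 vector with malignant = 1.
as_binary_labels <- function(labels) {
  as.integer(as_nodule_label(labels) == "malignant")
}
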
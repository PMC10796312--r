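# Shared fixtures: tiny architectures and miniature labelled tensor
# cohorts, all built in code at test time.

# Minimal conv -> pool -> flatten -> dense network for fast tests.
tiny_spec <- function(side = 8L, l2 = 0, filters = 4L, hidden = 8L) {
  layers <- list(
    petnodcnn:::node_conv("c1", "input", filters),
    petnodcnn:::node_pool("p1", "c1"),
    petnodcnn:::node_simple("flat", "flatten", "p1"),
    petnodcnn:::node_dense("d1", "flat", hidden),
    petnodcnn:::node_dense("out", "d1", 1, activation = "linear"))
  petnodcnn:::new_arch_spec("tiny", layers, l2,
                            input_shape = c(side, side, side, 1L))
}

# A tiny branching network covering every layer kind (concat, gap, same
# padding, 1^3 convolutions) for gradient and shape checks.
tiny_branchy_spec <- function(side = 8L) {
  nc <- petnodcnn:::node_conv; np <- petnodcnn:::node_pool
  nd <- petnodcnn:::node_dense; ns <- petnodcnn:::node_simple
  layers <- list(
    nc("c1", "input", 3),
    np("p1", "c1", k = 3L, stride = 2L, pad = "same"),
    nc("b1", "p1", 2, k = 1L),
    nc("b2", "p1", 2, pad = "same"),
    np("bp", "p1", k = 3L, stride = 1L, pad = "same"),
    nc("b3", "bp", 2, k = 1L),
    ns("cat", "concat", c("b1", "b2", "b3")),
    ns("g", "gap", "cat"),
    nd("d1", "g", 4),
    nd("out", "d1", 1, activation = "linear"))
  petnodcnn:::new_arch_spec("branchy", layers, 0,
                            input_shape = c(side, side, side, 1L))
}

# Labelled toy cohort: centred Gaussian blobs whose peak differs by class
# (bright = malignant), with additive noise. Learnable but overlapping.
toy_cohort <- function(n, side = 8L, peak_mal = 4, peak_ben = 1.5,
                       noise = 0.2, seed = 1) {
  petnodcnn:::with_seed(seed, {
    labels <- rep(c("malignant", "benign"), length.out = n)
    centre <- (side - 1) / 2
    g <- seq_len(side) - 1
    blob <- exp(-(outer(outer((g - centre)^2, (g - centre)^2, "+"),
                        (g - centre)^2, "+")) / (2 * 2^2))
    tensors <- lapply(seq_len(n), function(i) {
      peak <- if (labels[i] == "malignant") peak_mal else peak_ben
      peak <- peak * exp(rnorm(1, 0, 0.15))
      array(peak * blob + rnorm(side^3, 0, noise), dim = rep(side, 3))
    })
    names(tensors) <- sprintf("S%03d", seq_len(n))
    names(labels) <- names(tensors)
    list(tensors = tensors, labels = labels)
  })
}

# Brute-force AUC by Mann-Whitney pair counting (ties count one half).
mw_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# Exhaustive threshold search oracles (independent of the package path).
oracle_youden <- function(scores, y) {
  cand <- sort(unique(scores))
  best <- NULL
  for (t in cand) {
    sens <- mean(scores[y == 1] >= t)
    spec <- mean(scores[y == 0] < t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12) best <- list(threshold = t,
                                                          j = j)
  }
  best
}

oracle_constrained <- function(scores, y, min_sens = 0.95) {
  cand <- sort(unique(scores))
  best <- NULL
  for (t in cand) {
    sens <- mean(scores[y == 1] >= t)
    spec <- mean(scores[y == 0] < t)
    if (sens >= min_sens &&
        (is.null(best) || spec > best$spec + 1e-12))
      best <- list(threshold = t, spec = spec)
  }
  best
}
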
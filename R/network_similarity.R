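#' Build a binary network mask over an abstract parcel grid
#'
#' @param n_parcels Grid length (default 1000).
#' @param frac_in Fraction of parcels inside the network (default 0.2).
#' @param name Mask label.
#' @return Object of class `network_mask`: list with `indicator` (0/1
#'   vector) and `name`.
#' @export
make_network_mask <- function(n_parcels = 1000, frac_in = 0.2,
                              name = "frontoparietal") {
  k <- round(n_parcels * frac_in)
  if (k < 1 || k >= n_parcels) {
    stop("mask must contain at least one in-network and one out-of-network parcel",
         call. = FALSE)
  }
  structure(list(indicator = c(rep(1, k), rep(0, n_parcels - k)), name = name),
            class = "network_mask")
}

mask_indicator <- function(mask) {
  ind <- if (inherits(mask, "network_mask")) mask$indicator else mask
  if (!all(ind %in% c(0, 1)) || sum(ind) == 0 || sum(ind) == length(ind)) {
    stop("mask must be binary with at least one 1 and one 0", call. = FALSE)
  }
  ind
}

#' Similarity of a contrast vector to a binary network mask
#'
#' Pearson correlation between a subject's contrast amplitudes and the
#' 0/1 mask indicator, Fisher-z transformed. Up to a monotone transform
#' this equals the standardized in-mask versus out-of-mask mean difference
#' (point-biserial identity). A map perfectly collinear with the mask has
#' an infinite z and is a domain error.
#'
#' @param values Contrast amplitudes over the grid.
#' @param mask A `network_mask` or binary vector of the same length.
#' @return Fisher-z similarity (scalar).
#' @export
mask_similarity <- function(values, mask) {
  ind <- mask_indicator(mask)
  if (length(values) != length(ind)) {
    stop("contrast vector and mask lengths differ", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("contrast values must be finite", call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("degenerate input: constant contrast map", call. = FALSE)
  }
  r <- stats::cor(values, ind)
  if (abs(r) >= 1) {
    stop("map is perfectly collinear with the mask: Fisher z is infinite",
         call. = FALSE)
  }
  fisher_z(r)
}

#' Simulate per-subject contrast maps over a parcel grid
#'
#' Each subject's map is independent unit-variance Gaussian parcel noise
#' plus that subject's signal amplitude on the in-mask parcels.
#'
#' @param in_mask_signal Per-subject in-mask signal amplitudes.
#' @param mask A `network_mask` or binary indicator.
#' @param noise_sd Parcel noise SD (default 1).
#' @param seed Optional seed.
#' @return Matrix, subjects x parcels.
#' @export
simulate_contrast_maps <- function(in_mask_signal, mask, noise_sd = 1,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ind <- mask_indicator(mask)
  n <- length(in_mask_signal)
  noise <- matrix(stats::rnorm(n * length(ind), 0, noise_sd), n, length(ind))
  noise + outer(in_mask_signal, ind)
}

#' Fisher-z mask similarities for a stack of contrast maps
#'
#' @param maps Subjects x parcels matrix.
#' @param mask A `network_mask` or binary indicator.
#' @return Numeric vector of per-subject Fisher-z similarities.
#' @export
map_similarities <- function(maps, mask) {
  apply(as.matrix(maps), 1, mask_similarity, mask = mask)
}

#' Group comparison and behavioral correlations of network similarity
#'
#' Welch t-test of the Fisher-z similarities between the two groups
#' (first factor level minus second), plus Spearman correlations of the
#' similarity with the per-subject learning bias and with the
#' positive-learning beta, when supplied.
#'
#' @param z Per-subject Fisher-z similarities.
#' @param group Two-level factor (or character) of group labels.
#' @param learning_bias Optional per-subject `beta_pos - beta_neg`.
#' @param beta_pos Optional per-subject positive-learning beta.
#' @return Object of class `network_group_result`: `group_test`
#'   (`t_test_result`), `comparison` label, `cor_bias`, `cor_beta_pos`
#'   (`correlation_result` or NULL).
#' @export
group_network_test <- function(z, group, learning_bias = NULL,
                               beta_pos = NULL) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels", call. = FALSE)
  if (length(z) != length(group)) stop("z and group lengths differ", call. = FALSE)
  if (min(table(group)) < 2) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  g1 <- levels(group)[1]
  g2 <- levels(group)[2]
  res <- structure(
    list(
      group_test = welch_t(z[group == g1], z[group == g2]),
      comparison = paste(g1, "-", g2),
      cor_bias = if (!is.null(learning_bias))
        correlation_test(z, learning_bias, method = "spearman") else NULL,
      cor_beta_pos = if (!is.null(beta_pos))
        correlation_test(z, beta_pos, method = "spearman") else NULL
    ),
    class = "network_group_result"
  )
  res
}

#' @export
print.network_group_result <- function(x, ...) {
  cat(sprintf("Network similarity group test (%s):\n", x$comparison))
  print(x$group_test)
  if (!is.null(x$cor_bias)) {
    cat("  similarity ~ learning bias: ")
    print(x$cor_bias)
  }
  if (!is.null(x$cor_beta_pos)) {
    cat("  similarity ~ positive learning: ")
    print(x$cor_beta_pos)
  }
  invisible(x)
}
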
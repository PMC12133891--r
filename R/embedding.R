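#' Principal component analysis of a feature matrix
#'
#' Column-centers (and, by default, unit-scales) the matrix, decomposes it
#' by singular value decomposition, and returns sample scores with a
#' deterministic sign convention: each component is flipped so that its
#' largest-magnitude loading is positive. Constant columns are dropped
#' with a warning before scaling.
#'
#' @param x A numeric matrix or a data frame whose first character column
#'   is taken as sample names (e.g. the output of [nutrient_matrix()] or
#'   [flux_matrix()]).
#' @param k Number of components.
#' @param standardize Scale columns to unit variance (recommended when
#'   features are on different scales, as macro fractions vs mmol/day
#'   amounts are).
#' @return A `wbm_embedding` with `coordinates` (tibble: `sample`,
#'   `PC1..PCk`), `variance_explained`, `loadings`, `feature_names`,
#'   `sample_names` and `method = "pca"`.
#' @export
pca_embed <- function(x, k = 2, standardize = TRUE) {
  m <- as_feature_matrix(x)
  mat <- m$mat
  n <- nrow(mat)
  if (n < 2) {
    abort("PCA requires at least two samples.", class = "dietwbm_value_error")
  }
  if (k < 1 || k > min(n - 1, ncol(mat))) {
    abort(sprintf("k must lie in [1, %d].", min(n - 1, ncol(mat))),
          class = "dietwbm_value_error")
  }
  const <- apply(mat, 2, function(col) max(col) - min(col) < 1e-12)
  if (all(const)) {
    abort("All feature columns are constant; PCA is degenerate.",
          class = "dietwbm_degenerate_input")
  }
  if (any(const)) {
    warn(sprintf("Dropping %d constant feature column(s).", sum(const)),
         class = "dietwbm_constant_features")
    mat <- mat[, !const, drop = FALSE]
  }
  centered <- scale(mat, center = TRUE, scale = standardize)
  if (max(abs(centered)) < 1e-12) {
    warn("Samples are identical after centering; scores are all zero.",
         class = "dietwbm_degenerate_input")
  }
  sv <- svd(centered)
  k_eff <- min(k, length(sv$d))
  # deterministic sign: largest-magnitude loading of each component positive
  loadings <- sv$v[, seq_len(k_eff), drop = FALSE]
  flip <- vapply(seq_len(k_eff), function(j) {
    l <- loadings[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  loadings <- sweep(loadings, 2, flip, `*`)
  scores <- sweep(sv$u[, seq_len(k_eff), drop = FALSE] %*%
                    diag(sv$d[seq_len(k_eff)], k_eff), 2, flip, `*`)
  var_tot <- sum(sv$d^2)
  var_exp <- if (var_tot > 0) sv$d[seq_len(k_eff)]^2 / var_tot else rep(NA_real_, k_eff)
  coords <- as_tibble(setNames(as.data.frame(scores), paste0("PC", seq_len(k_eff))))
  coords <- bind_cols(tibble(sample = m$samples), coords)
  rownames(loadings) <- colnames(mat)
  structure(
    list(coordinates = coords, method = "pca",
         variance_explained = var_exp,
         loadings = loadings,
         feature_names = colnames(mat), sample_names = m$samples,
         seed = NA_integer_),
    class = "wbm_embedding"
  )
}

#' t-SNE embedding of a feature matrix
#'
#' Two-dimensional t-distributed stochastic neighbor embedding computed
#' with an exact (dense) implementation: input similarities from a
#' per-sample perplexity calibration, Kullback-Leibler gradient descent
#' with momentum and early exaggeration, seeded Gaussian initialization.
#' Deterministic for a fixed seed. Coordinates carry no semantic contract
#' beyond shape, finiteness and same-seed reproducibility; cluster reading
#' is left to visual inspection.
#'
#' @inheritParams pca_embed
#' @param seed Mandatory integer seed.
#' @param perplexity Target perplexity; default 30 capped at
#'   `(samples - 1) / 3`.
#' @param max_iter Gradient-descent iterations.
#' @return A `wbm_embedding` with 2-D `coordinates` and `method = "tsne"`.
#' @export
tsne_embed <- function(x, seed, perplexity = NULL, max_iter = 500) {
  m <- as_feature_matrix(x)
  mat <- m$mat
  n <- nrow(mat)
  if (n < 4) {
    abort("t-SNE requires at least four samples.", class = "dietwbm_value_error")
  }
  if (missing(seed) || is.null(seed)) {
    abort("A seed is mandatory for t-SNE.", class = "dietwbm_value_error")
  }
  perplexity <- perplexity %||% min(30, (n - 1) / 3)
  if (perplexity <= 0 || 3 * perplexity > n - 1) {
    abort(sprintf("Perplexity %.2f infeasible for %d samples.", perplexity, n),
          class = "dietwbm_value_error")
  }
  coords <- tsne_exact(mat, seed = seed, perplexity = perplexity,
                       max_iter = max_iter)
  structure(
    list(coordinates = bind_cols(tibble(sample = m$samples),
                                 as_tibble(setNames(as.data.frame(coords),
                                                    c("dim1", "dim2")))),
         method = "tsne", variance_explained = NULL, loadings = NULL,
         feature_names = colnames(mat), sample_names = m$samples,
         seed = as.integer(seed)),
    class = "wbm_embedding"
  )
}

#' @export
print.wbm_embedding <- function(x, ...) {
  cat(sprintf("<wbm_embedding> %s: %d samples x %d dims\n", x$method,
              nrow(x$coordinates), ncol(x$coordinates) - 1))
  if (x$method == "pca") {
    cat("  variance explained:",
        paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "), "\n")
  }
  invisible(x)
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    first_chr <- which(!vapply(x, is.numeric, logical(1)))
    if (length(first_chr)) {
      samples <- as.character(x[[first_chr[1]]])
      mat <- as.matrix(x[, -first_chr, drop = FALSE])
    } else {
      samples <- rownames(x) %||% paste0("sample", seq_len(nrow(x)))
      mat <- as.matrix(x)
    }
  } else {
    mat <- as.matrix(x)
    samples <- rownames(mat) %||% paste0("sample", seq_len(nrow(mat)))
  }
  storage.mode(mat) <- "double"
  if (any(!is.finite(mat))) {
    abort("Feature matrix contains non-finite values.",
          class = "dietwbm_value_error")
  }
  list(mat = mat, samples = samples)
}

# Exact t-SNE (dense pairwise affinities), suitable for the dozens of
# samples this package embeds. RNG state is restored on exit.
tsne_exact <- function(mat, seed, perplexity, max_iter = 500,
                       eta = 100, momentum0 = 0.5, momentum1 = 0.8,
                       exaggeration = 4, exaggeration_iter = 100) {
  n <- nrow(mat)
  D2 <- as.matrix(dist(mat))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:64) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp <= 0) { H <- 0; p[] <- 0 } else {
        p <- p / sp
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - logU) < 1e-7) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)

  inc <- matrix(0, n, 2)
  Pe <- P * exaggeration
  for (it in seq_len(max_iter)) {
    Puse <- if (it <= exaggeration_iter) Pe else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Puse - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it < 250) momentum0 else momentum1
    inc <- mom * inc - eta * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Flux feature matrix over solved diets
#'
#' Assembles the diets-by-reactions matrix used for flux-space embeddings,
#' either over all reactions or restricted to the resolved biomarker panel
#' reactions (glucose/TAG/LDL-C/HDL-C exchange plus fatty acid oxidation).
#'
#' @param solutions Named list (diet name -> `flux_solution`); all
#'   solutions must come from the same model.
#' @param scope `"all_reactions"` or `"panel_reactions"`.
#' @param panel A [resolve_panel()] result; required for panel scope.
#' @param drop_zero Drop reactions whose flux is zero across all diets
#'   (reported via an attribute).
#' @return A tibble with a `diet` column followed by one column per
#'   reaction.
#' @export
flux_matrix <- function(solutions, scope = c("all_reactions", "panel_reactions"),
                        panel = NULL, drop_zero = FALSE) {
  scope <- match.arg(scope)
  stopifnot(length(solutions) >= 1)
  models <- unique(map_chr(solutions, function(s) paste(s$model_id, s$sex)))
  if (length(models) > 1) {
    abort("All solutions must come from the same model.",
          class = "dietwbm_consistency_error")
  }
  ids <- solutions[[1]]$fluxes$reaction_id
  if (scope == "panel_reactions") {
    if (is.null(panel)) {
      abort("panel_reactions scope requires a resolved biomarker panel.",
            class = "dietwbm_value_error")
    }
    ids <- intersect(ids, unlist(panel[panel_metrics], use.names = FALSE))
  }
  rows <- map(solutions, function(s) {
    setNames(s$fluxes$flux[match(ids, s$fluxes$reaction_id)], ids)
  })
  mat <- do.call(rbind, rows)
  dropped <- character()
  if (drop_zero) {
    zero <- apply(mat, 2, function(col) all(abs(col) < 1e-12))
    dropped <- colnames(mat)[zero]
    mat <- mat[, !zero, drop = FALSE]
  }
  out <- bind_cols(tibble(diet = names(solutions)),
                   as_tibble(as.data.frame(mat)))
  attr(out, "dropped_zero_columns") <- dropped
  out
}
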
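# Focused-mask constrained-PCA classification of compositional
# heterogeneity (e.g. OST present/absent, TRAP present/absent).
#
# The pairwise kernel is the constrained cross-correlation of pose-aligned
# particles under a real-space focus mask, restricted to the intersection
# of their (rotated) wedge supports.  The matrix is double-centered and
# eigen-decomposed; particles are embedded in the leading coordinates and
# grouped by k-means.

#' Pairwise constrained-correlation matrix
#'
#' Entry (i, j) is the constrained cross-correlation of particles i and j
#' after rotating each into the common reference frame by its pose, masked
#' by `focus` in real space and restricted to the intersection of the two
#' rotated wedge supports.  Computed with dense matrix algebra: the masked
#' spectra and binary supports are assembled once, so the full n x n
#' matrix costs three matrix products.
#'
#' @param subtomos list of [subtomo()].
#' @param poses list of [rigid_transform()] mapping each particle to the
#'   common frame (defaults to the particles' stored poses).
#' @param focus a [volume_mask()]; an all-zero mask is an error.
#' @param stack optional pre-computed [align_stack()] result (internal
#'   reuse by [classify_pipeline()]).
#'
#' @details Correlations are computed over Fourier coefficients inside the
#'   Nyquist ball (|k| <= N/2); the anisotropically sampled cube corners
#'   beyond Nyquist carry no isotropic resolution information and are
#'   excluded.
#' @return symmetric n x n correlation matrix with unit diagonal.
#' @export
cc_matrix <- function(subtomos, poses = NULL, focus = NULL, stack = NULL) {
  n <- if (!is.null(stack)) nrow(stack$real) else length(subtomos)
  if (n < 2) stop("need at least 2 particles")
  stk <- stack %||% align_stack(subtomos,
                                poses %||% lapply(subtomos, `[[`, "pose"))
  d <- stk$dim
  nv <- prod(d)
  mv <- if (is.null(focus)) rep(1, nv) else as.vector(map_values(focus))
  if (!is.null(focus) && !identical(dim(map_values(focus)), d))
    stop("focus mask shape does not match particles")
  if (all(mv == 0)) stop("empty focus mask")
  cols <- which(as.vector(fft_radius(d)) <= min(d) / 2)
  cols <- cols[cols != 1L]                  # drop DC
  X <- matrix(0 + 0i, n, length(cols))
  S <- matrix(0, n, length(cols))
  for (i in seq_len(n)) {
    v <- stk$real[i, ] * mv
    v <- v - mean(v)
    Fv <- stats::fft(array(v, d))
    X[i, ] <- Fv[cols] * stk$supp[i, cols]
    S[i, ] <- stk$supp[i, cols]
  }
  num <- Re(X %*% Conj(t(X)))
  # P[i, j] = power of particle i inside support of particle j
  P <- (Mod(X)^2) %*% t(S)
  den <- sqrt(P * t(P))
  if (any(den == 0))
    stop("zero power inside a constrained support (flat particle or ",
         "disjoint wedges)")
  C <- num / den
  C <- (C + t(C)) / 2
  diag(C) <- 1
  pmax(pmin(C, 1), -1)
}

#' Classify particles from a constrained-correlation matrix
#'
#' Kernel-PCA style embedding: the matrix is double-centered and
#' eigen-decomposed, particles are embedded in the top `n_components`
#' coordinates (scaled by sqrt of the eigenvalues), and grouped by k-means
#' with 10 restarts under a fixed seed.
#'
#' @param C symmetric correlation matrix.
#' @param n_components embedding dimensions (default 4).
#' @param k number of classes.
#' @param seed RNG seed for the k-means restarts.
#' @return a `classification_result`: list with `labels`, `fractions`,
#'   `eigenvalues`, `degenerate` (logical: no usable spectrum).
#' @export
cpca_classify <- function(C, n_components = 4, k = 2, seed = 1) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  n <- nrow(C)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("more classes than particles")
  if (n_components < 1) stop("n_components must be >= 1")
  res <- if (k == 1) {
    list(labels = rep(1L, n), degenerate = FALSE,
         eigenvalues = numeric(0))
  } else {
    J <- scale(C, center = TRUE, scale = FALSE)
    J <- t(scale(t(J), center = TRUE, scale = FALSE))
    eg <- eigen((J + t(J)) / 2, symmetric = TRUE)
    pos <- pmax(eg$values, 0)
    degenerate <- sum(pos > 1e-12 * max(1, pos[1])) == 0
    p <- min(n_components, n)
    emb <- eg$vectors[, seq_len(p), drop = FALSE] %*%
      diag(sqrt(pos[seq_len(p)]), p)
    labels <- if (degenerate) rep(1L, n)
    else if (k == n) seq_len(n)       # every particle its own class
    else {
      km <- with_seed(seed,
                      stats::kmeans(emb, centers = k, nstart = 10,
                                    iter.max = 100))
      as.integer(km$cluster)
    }
    list(labels = labels, degenerate = degenerate, eigenvalues = eg$values)
  }
  fr <- as.vector(table(factor(res$labels, levels = seq_len(k)))) / n
  structure(list(labels = res$labels, fractions = fr,
                 eigenvalues = res$eigenvalues,
                 degenerate = res$degenerate),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result>\n")
  cat("  fractions:",
      paste(sprintf("%.1f%%", 100 * x$fractions), collapse = " / "), "\n")
  if (isTRUE(x$degenerate)) cat("  degenerate spectrum: no separation\n")
  invisible(x)
}

#' Successive-round focused classification
#'
#' Mirrors the successive sorting used in subtomogram analysis: each round
#' classifies only the class retained from the previous round, under its
#' own focus mask.  Within a round the retained class is the one whose
#' members have the higher mean density inside the focus mask (presence
#' of the focused component), unless the round requests `keep = "absent"`.
#' A split is accepted only when the leading eigenvalue of the centered
#' correlation matrix separates from the bulk (eigengap heuristic,
#' lambda1/lambda2 >= `eigengap_min`); with a flat spectrum the round is
#' declared homogeneous and every particle is retained.
#'
#' @param subtomos list of [subtomo()].
#' @param poses list of [rigid_transform()] to the common frame.
#' @param rounds list of rounds; each a list with `focus` (a
#'   [volume_mask()]), optional `k` (default 2), optional `keep`
#'   (`"present"` or `"absent"`, default `"present"`), optional
#'   `n_components` (default 4), optional `eigengap_min` (default 2).
#' @param seed RNG seed (k-means restarts).
#' @return a `classification_rounds` object: per round, the
#'   `classification_result`, the particle indices classified, the indices
#'   retained, and the focused-presence fraction; plus final retained
#'   indices.
#' @export
classify_pipeline <- function(subtomos, poses, rounds, seed = 1) {
  if (length(rounds) == 0) stop("`rounds` must be non-empty")
  stk <- align_stack(subtomos, poses)
  active <- seq_along(subtomos)
  out <- vector("list", length(rounds))
  degenerate_stop <- FALSE
  for (r in seq_along(rounds)) {
    rd <- rounds[[r]]
    if (length(active) == 0)
      stop("round ", r, ": retained class from previous round is empty")
    if (length(active) < 2) {
      # a singleton cannot be classified further; flag and stop sorting
      out[[r]] <- list(result = NULL, classified = active, retained = active,
                       present_class = NA_integer_,
                       retained_class = NA_integer_,
                       present_fraction = NA_real_, degenerate = TRUE)
      degenerate_stop <- TRUE
      break
    }
    k <- rd$k %||% 2
    keep <- match.arg(rd$keep %||% "present", c("present", "absent"))
    sub_stack <- list(real = stk$real[active, , drop = FALSE],
                      supp = stk$supp[active, , drop = FALSE],
                      dim = stk$dim)
    C <- cc_matrix(stack = sub_stack, focus = rd$focus)
    cls <- cpca_classify(C, n_components = rd$n_components %||% 4,
                         k = k, seed = derive_seed(seed, r))
    mv <- as.vector(map_values(rd$focus))
    in_focus <- mv > 0.5
    # per-particle mean density inside the focus mask, and its class means
    f_i <- rowMeans(sub_stack$real[, in_focus, drop = FALSE])
    cls_mean <- sapply(seq_len(k), function(ci) {
      rows <- which(cls$labels == ci)
      if (!length(rows)) return(NA_real_)
      mean(f_i[rows])
    })
    present_class <- which.max(cls_mean)
    retained_class <- if (keep == "present") present_class else
      which.min(cls_mean)
    # eigengap heuristic: a split is compositional only when the leading
    # eigenvalue separates from the bulk; a flat spectrum means k-means
    # carved noise, and the round keeps everyone together
    ev <- pmax(cls$eigenvalues, 0)
    eigengap <- if (length(ev) >= 2 && ev[2] > 0) ev[1] / ev[2] else Inf
    homogeneous <- isTRUE(cls$degenerate) ||
      eigengap < (rd$eigengap_min %||% 2)
    retained <- if (k == 1 || homogeneous) active else
      active[cls$labels == retained_class]
    out[[r]] <- list(
      result = cls,
      classified = active,
      retained = retained,
      present_class = present_class,
      retained_class = retained_class,
      homogeneous = homogeneous,
      eigengap = eigengap,
      present_fraction = length(retained) / length(active),
      focus_means = cls_mean
    )
    active <- retained
  }
  structure(list(rounds = out[!sapply(out, is.null)], final = active,
                 degenerate = degenerate_stop),
            class = "classification_rounds")
}

#' @export
print.classification_rounds <- function(x, ...) {
  cat("<classification_rounds>", length(x$rounds), "round(s)\n")
  for (r in seq_along(x$rounds)) {
    rd <- x$rounds[[r]]
    if (is.null(rd$result)) {
      cat(sprintf("  round %d: n=%d, degenerate (too few particles)\n",
                  r, length(rd$classified)))
      next
    }
    cat(sprintf(
      "  round %d: n=%d, fractions %s, present class %d (%.1f%%), kept %d\n",
      r, length(rd$classified),
      paste(sprintf("%.2f", rd$result$fractions), collapse = "/"),
      rd$present_class, 100 * rd$present_fraction, length(rd$retained)))
  }
  cat("  final retained:", length(x$final), "particles\n")
  invisible(x)
}

#' Write classification labels and fractions as TSV
#'
#' @param cr a `classification_rounds` object.
#' @param n_particles total particle count.
#' @param path output TSV path.
#' @export
write_classification <- function(cr, n_particles, path) {
  lab <- matrix(NA_integer_, n_particles, length(cr$rounds))
  for (r in seq_along(cr$rounds))
    if (!is.null(cr$rounds[[r]]$result))
      lab[cr$rounds[[r]]$classified, r] <- cr$rounds[[r]]$result$labels
  df <- data.frame(particle = seq_len(n_particles), lab)
  names(df) <- c("particle", paste0("round", seq_along(cr$rounds)))
  df$final_retained <- df$particle %in% cr$final
  write_tsv_exact(df, path)
}
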
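# Multivariate tissue segmentation: probabilistic latent semantic analysis
# (the aspect model P(pixel, peak) = sum_z P(z) P(pixel|z) P(peak|z), fitted
# by EM on the non-negative data cube treated as pseudo-counts) and PCA.

#' Fit a pLSA aspect model to a data cube
#'
#' EM on the aspect model with the cube's non-negative intensities as
#' pseudo-counts. One component is expected to absorb the off-tissue
#' background signature (see [identify_background()]). Initialization is
#' seeded uniform Dirichlet; the run is deterministic given the seed.
#'
#' @param cube An `msi_datacube` (or plain non-negative matrix, pixels in
#'   rows).
#' @param n_components Number of aspects (tissue compartments + 1
#'   background; >= 2).
#' @param seed RNG seed for the Dirichlet initialization.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param nstart Number of seeded EM restarts (seeds `seed`, `seed + 1`,
#'   ...); the run with the best final log-likelihood is returned. EM on
#'   the aspect model is a local optimizer, and restarts are the standard
#'   guard against poor local optima.
#' @return Object of class `plsa_model`: `prior` P(z), `p_pixel`
#'   (pixels x k, columns P(pixel|z)), `p_peak` (peaks x k, columns
#'   P(peak|z)), `loglik_trace`, `background` (set later), bookkeeping.
#' @export
fit_plsa <- function(cube, n_components, seed = 1L, max_iter = 500L,
                     tol = 1e-6, nstart = 1L) {
  if (nstart > 1L) {
    fits <- lapply(seq_len(nstart) - 1L, function(k) {
      fit_plsa(cube, n_components, seed = seed + k, max_iter = max_iter,
               tol = tol, nstart = 1L)
    })
    lls <- vapply(fits, function(f) f$loglik_trace[f$iterations],
                  numeric(1))
    return(fits[[which.max(lls)]])
  }
  V <- if (inherits(cube, "msi_datacube")) cube$intensity else as.matrix(cube)
  if (any(V < 0)) stop("data cube must be non-negative")
  total <- sum(V)
  if (total == 0) stop("all-zero data cube")
  if (n_components < 2L) stop("n_components must be >= 2")
  nd <- nrow(V)
  nw <- ncol(V)
  k <- as.integer(n_components)
  eps <- 1e-12

  set.seed(seed)
  rdir <- function(n) {
    g <- matrix(stats::rgamma(n * k, shape = 1), n, k)
    sweep(g, 2, colSums(g), "/")
  }
  Wd <- rdir(nd)                       # P(d|z), columns sum to 1
  Hw <- rdir(nw)                       # P(w|z), columns sum to 1
  pz <- rep(1 / k, k)

  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    pred <- Wd %*% (t(Hw) * pz)        # sum_z pz P(d|z) P(w|z)
    ll <- sum(V * log(pmax(pred, eps)))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) <= tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    R <- V / pmax(pred, eps)
    # expected counts n(d,z) and n(z,w)
    n_dz <- Wd * sweep(R %*% Hw, 2, pz, "*")
    n_zw <- Hw * sweep(t(R) %*% Wd, 2, pz, "*")
    nz <- colSums(n_dz)
    nz[nz == 0] <- eps
    Wd <- sweep(n_dz, 2, nz, "/")
    Hw <- sweep(n_zw, 2, colSums(n_zw) + (colSums(n_zw) == 0) * eps, "/")
    pz <- nz / sum(nz)
  }

  structure(list(
    n_components = k,
    prior = pz,
    p_pixel = Wd,
    p_peak = Hw,
    loglik_trace = ll_trace,
    background = NA_integer_,
    converged = converged,
    iterations = it,
    seed = seed,
    coords = if (inherits(cube, "msi_datacube")) cube$coords else NULL,
    peak_mz = if (inherits(cube, "msi_datacube")) cube$peak_mz else NULL
  ), class = "plsa_model")
}

#' @export
print.plsa_model <- function(x, ...) {
  cat(sprintf("<plsa_model> %d components, %d pixels x %d peaks, %s after %d iterations\n",
              x$n_components, nrow(x$p_pixel), nrow(x$p_peak),
              if (x$converged) "converged" else "not converged",
              x$iterations))
  invisible(x)
}

#' Identify the background component of a fitted pLSA model
#'
#' The component whose pixel-probability mass is most concentrated on
#' off-tissue pixels (the mask's background label). Ties resolve to the
#' lowest component index.
#'
#' @param model A `plsa_model` fitted on a cube with coordinates.
#' @param mask [roi_mask()] declaring the background pixels.
#' @return The model with `background` set (NA with a message when the mask
#'   has no background pixels).
#' @export
identify_background <- function(model, mask) {
  stopifnot(inherits(model, "plsa_model"))
  if (is.null(model$coords)) stop("model carries no pixel coordinates")
  lab <- mask_labels(mask, model$coords)
  bg <- lab == mask$vocabulary[1]
  if (!any(bg)) {
    message("mask has no background pixels; background component unset")
    model$background <- NA_integer_
    return(model)
  }
  conc <- colSums(model$p_pixel[bg, , drop = FALSE])
  model$background <- which(conc == max(conc))[1]
  model
}

#' Assign every peak to its dominant non-background component
#'
#' Peaks are assigned by the component posterior P(z|peak) proportional to
#' P(z) P(peak|z), normalized per peak over the retained components. Exact
#' ties resolve to the lowest component index (reported via a message).
#'
#' @param model A `plsa_model`.
#' @param exclude_background Drop the background component before taking the
#'   argmax (requires [identify_background()] to have run if TRUE and a
#'   background exists).
#' @return Data frame with `peak`, `peak_mz` (if known), `component`,
#'   `posterior`; attribute `"counts"` holds peaks per component.
#' @export
assign_peaks <- function(model, exclude_background = TRUE) {
  stopifnot(inherits(model, "plsa_model"))
  comps <- seq_len(model$n_components)
  if (exclude_background && !is.na(model$background)) {
    comps <- setdiff(comps, model$background)
  }
  w <- sweep(model$p_peak[, comps, drop = FALSE], 2, model$prior[comps], "*")
  norm <- rowSums(w)
  norm[norm == 0] <- 1
  post <- w / norm
  idx <- apply(post, 1, function(r) which(r == max(r))[1])
  nties <- sum(apply(post, 1, function(r) sum(r == max(r)) > 1))
  if (nties > 0) {
    message(nties, " peak(s) tied between components; lowest index kept")
  }
  out <- data.frame(peak = seq_len(nrow(post)),
                    component = comps[idx],
                    posterior = post[cbind(seq_len(nrow(post)), idx)])
  if (!is.null(model$peak_mz)) out$peak_mz <- model$peak_mz
  counts <- table(factor(out$component, levels = seq_len(model$n_components)))
  attr(out, "counts") <- counts
  out
}

#' Segment pixels by their dominant component
#'
#' Per-pixel argmax of P(z|pixel) proportional to P(z) P(pixel|z); the
#' background component is allowed. Ties resolve to the lowest index.
#'
#' @param model A `plsa_model` with coordinates.
#' @return List with `component` (vector aligned to the cube's pixels) and
#'   `image` (integer matrix on the pixel grid, NA off-grid).
#' @export
segment_pixels <- function(model) {
  stopifnot(inherits(model, "plsa_model"))
  w <- sweep(model$p_pixel, 2, model$prior, "*")
  comp <- apply(w, 1, function(r) which(r == max(r))[1])
  img <- NULL
  if (!is.null(model$coords)) {
    img <- matrix(NA_integer_,
                  max(model$coords$y) + 1L, max(model$coords$x) + 1L)
    img[cbind(model$coords$y + 1L, model$coords$x + 1L)] <- comp
  }
  list(component = comp, image = img)
}

#' Reconstruction of the joint pixel-peak probability table
#'
#' @param model A `plsa_model`.
#' @return Matrix sum_z P(z) P(pixel|z) P(peak|z).
#' @export
plsa_reconstruction <- function(model) {
  model$p_pixel %*% (t(model$p_peak) * model$prior)
}

#' PCA of a data cube
#'
#' Column-mean-centered singular value decomposition with a deterministic
#' sign convention: each loading vector's largest-magnitude entry is made
#' positive.
#'
#' @param cube An `msi_datacube` or matrix (pixels in rows).
#' @param n_components Number of components (<= matrix rank).
#' @return List with `scores` (pixels x k), `loadings` (peaks x k),
#'   `explained_variance` (proportions, length k).
#' @export
fit_pca <- function(cube, n_components) {
  V <- if (inherits(cube, "msi_datacube")) cube$intensity else as.matrix(cube)
  if (nrow(V) < 2L) stop("PCA needs at least 2 pixels")
  rank_max <- min(nrow(V) - 1L, ncol(V))
  if (n_components > rank_max) {
    stop("n_components exceeds the matrix rank (max ", rank_max, ")")
  }
  pc <- stats::prcomp(V, center = TRUE, scale. = FALSE, rank. = n_components)
  flip <- vapply(seq_len(n_components), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, seq_len(n_components), drop = FALSE], 2, flip, "*")
  loadings <- sweep(pc$rotation[, seq_len(n_components), drop = FALSE], 2,
                    flip, "*")
  ev <- pc$sdev^2
  list(scores = scores, loadings = loadings,
       explained_variance = (ev / sum(ev))[seq_len(n_components)])
}

# All permutations of 1..n (n small).
.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in .permutations(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[p])
    }
  }
  out
}

#' Best label-permutation accuracy of a segmentation
#'
#' Component indices are arbitrary, so predicted components are matched to
#' ground-truth labels by exhaustive search over injective label-to-component
#' assignments (practical for the handful of compartments used here) and the
#' best achievable accuracy is returned.
#'
#' @param predicted Integer vector of predicted components.
#' @param truth Vector (factor/character/integer) of true labels.
#' @param n_components Number of components available (default:
#'   `max(predicted)`).
#' @return List with `accuracy` and the winning `assignment` (named vector
#'   label -> component).
#' @export
best_label_accuracy <- function(predicted, truth,
                                n_components = max(predicted)) {
  truth <- as.factor(truth)
  labels <- levels(droplevels(truth))
  L <- length(labels)
  K <- n_components
  if (L > K) stop("more true labels than components")
  best <- -1
  best_asn <- NULL
  for (p in .permutations(K)) {
    asn <- p[seq_len(L)]               # label i -> component asn[i]
    acc <- mean(asn[as.integer(droplevels(truth))] == predicted)
    if (acc > best) {
      best <- acc
      best_asn <- stats::setNames(asn, labels)
    }
  }
  list(accuracy = best, assignment = best_asn)
}
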
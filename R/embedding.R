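#' Embed per-epoch power spectra into two dimensions
#'
#' Projects the PSD rows, restricted to `[fmin, fmax]` (default 0.2-30 Hz),
#' into a 2-D plane with UMAP (via uwot). The embedding is consumed purely
#' as coordinates by the staging cascade; two dimensions is the default
#' because staging performance is optimal there. Runs single-threaded with
#' a fixed seed, so identical inputs give identical coordinates.
#'
#' @param psd a `psd_matrix`.
#' @param fmin,fmax frequency range of the columns fed to the embedder, Hz.
#' @param n_components embedding dimension (2).
#' @param seed integer RNG seed.
#' @param cfg configuration; `umap$n_neighbors`, `umap$min_dist`,
#'   `umap$standardize` (z-score each frequency bin first, default off).
#' @return an `embedding2d`: list with `coords` (n_epochs x 2) and `seed`.
#' @export
embed_psd <- function(psd, fmin = NULL, fmax = NULL, n_components = 2,
                      seed = NULL, cfg = ais_config()) {
  stopifnot(inherits(psd, "psd_matrix"))
  if (is.null(fmin)) fmin <- cfg$umap$fmin
  if (is.null(fmax)) fmax <- cfg$umap$fmax
  if (is.null(seed)) seed <- cfg$umap$seed
  sel <- psd$freqs >= fmin & psd$freqs <= fmax
  if (!any(sel)) stop("frequency range outside the PSD grid")
  X <- psd$values[, sel, drop = FALSE]
  n <- nrow(X)
  if (n < 20L) stop("need at least 20 epochs for a usable embedding")
  if (n <= cfg$umap$n_neighbors) {
    stop("fewer epochs (", n, ") than the neighborhood size (",
         cfg$umap$n_neighbors, "); reduce umap$n_neighbors")
  }
  if (isTRUE(cfg$umap$standardize)) {
    X <- scale(X)
    X[, !is.finite(colSums(X))] <- 0
  }
  coords <- withr::with_seed(as.integer(seed), {
    uwot::umap(X, n_neighbors = cfg$umap$n_neighbors,
               n_components = n_components, min_dist = cfg$umap$min_dist,
               n_threads = 1, n_sgd_threads = 0, verbose = FALSE)
  })
  structure(list(coords = unname(coords), seed = as.integer(seed)),
            class = "embedding2d")
}

#' @export
print.embedding2d <- function(x, ...) {
  cat(sprintf("<embedding2d> %d epochs, seed %d\n", nrow(x$coords), x$seed))
  invisible(x)
}
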
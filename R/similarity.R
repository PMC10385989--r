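# System-comparison analytics over fitted solvation-parameter
# coefficients: agglomerative clustering of the D' matrix, principal
# component analysis of the (e, s, a, b, v) vectors, and scoring of
# PAMPA membranes against biological reference processes.

#' Hierarchical clustering of a D' distance matrix
#'
#' Agglomerative clustering of systems by their coefficient distances.
#' UPGMA (average linkage) is the default; single and complete linkage
#' are available.  The merge order is deterministic (ties broken by
#' lowest index, as in [stats::hclust()]).
#'
#' @param m symmetric distance matrix with system ids as dimnames,
#'   e.g. from [dprime_matrix()].
#' @param linkage `"upgma"`, `"single"` or `"complete"`.
#' @return An [stats::hclust] tree.
#' @examples
#' h <- hierarchical_cluster(dprime_matrix(pampa_systems()[1:9, ]))
#' @export
hierarchical_cluster <- function(m, linkage = c("upgma", "single",
                                                "complete")) {
  linkage <- match.arg(linkage)
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 systems", call. = FALSE)
  if (!isSymmetric(unname(m), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  method <- c(upgma = "average", single = "single",
              complete = "complete")[[linkage]]
  stats::hclust(stats::as.dist(m), method = method)
}

#' Newick export of a cluster tree
#'
#' @param h an [stats::hclust] tree.
#' @return A Newick string with branch lengths.
#' @export
dendrogram_newick <- function(h) {
  stopifnot(inherits(h, "hclust"))
  ape::write.tree(ape::as.phylo(h))
}

#' Principal component analysis of system coefficient vectors
#'
#' Eigendecomposition of the covariance matrix of the centered,
#' unscaled `(e, s, a, b, v)` rows.  Loadings are unit vectors; each
#' component's sign is fixed so that its largest-magnitude loading is
#' positive (PCA signs are otherwise arbitrary).
#'
#' @param systems data frame of systems (>= 3 rows) with
#'   `e, s, a, b, v` columns.
#' @param k number of components to retain (<= 5 and <= number of
#'   systems).
#' @return A list of class `lfer_pca`: `loadings` (5 x k matrix over
#'   e,s,a,b,v), `explained_variance_fraction` (length k, non-increasing),
#'   `scores` (systems x k), and `eigenvalues` (all 5).
#' @export
pca_coefficients <- function(systems, k = 2L) {
  validate_systems(systems)
  n <- nrow(systems)
  if (n < 3L) stop("need at least 3 systems for PCA", call. = FALSE)
  if (k < 1L || k > 5L || k > n) {
    stop("k must lie in [1, min(5, number of systems)]", call. = FALSE)
  }
  X <- as.matrix(systems[, c("e", "s", "a", "b", "v")])
  rownames(X) <- as.character(systems$system_id)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  eg <- eigen(stats::cov(Xc), symmetric = TRUE)
  load <- eg$vectors
  # deterministic sign convention: largest-|loading| entry positive
  for (j in seq_len(ncol(load))) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(c("e", "s", "a", "b", "v"),
                         paste0("PC", seq_len(ncol(load))))
  ev <- pmax(eg$values, 0)
  frac <- ev / sum(ev)
  scores <- Xc %*% load
  structure(list(loadings = load[, seq_len(k), drop = FALSE],
                 explained_variance_fraction = frac[seq_len(k)],
                 scores = scores[, seq_len(k), drop = FALSE],
                 eigenvalues = ev),
            class = "lfer_pca")
}

#' @export
print.lfer_pca <- function(x, ...) {
  cat("PCA of system coefficients (e, s, a, b, v)\n")
  print(round(x$loadings, 3))
  cat("explained variance fraction:",
      paste(sprintf("%.3f", x$explained_variance_fraction), collapse = ", "),
      "\n")
  invisible(x)
}

#' Score PAMPA systems against biological reference processes
#'
#' Computes the D' distance between every (biological, PAMPA) pair from
#' a single distance-matrix computation and flags pairs at or below the
#' emulation threshold (default D' <= 1).  Within each biological
#' process, PAMPA systems are ranked by increasing distance.
#'
#' @param pampa data frame of PAMPA systems.
#' @param biological data frame of biological systems.
#' @param threshold emulation cutoff on D'.
#' @return A data frame with columns `biological`, `pampa`, `dprime`,
#'   `emulates`, ordered by biological system then distance.
#' @examples
#' sys <- pampa_systems()
#' compare_to_biological(sys[sys$category == "pampa" & sys$system_id != "9", ],
#'                       sys[sys$category == "biological", ])
#' @export
compare_to_biological <- function(pampa, biological, threshold = 1.0) {
  if (nrow(pampa) < 1L || nrow(biological) < 1L) {
    stop("both system lists must be non-empty", call. = FALSE)
  }
  keep <- c("system_id", "e", "s", "a", "b", "v")
  all_sys <- rbind(pampa[, keep], biological[, keep])
  m <- dprime_matrix(all_sys)
  bio_ids <- as.character(biological$system_id)
  pam_ids <- as.character(pampa$system_id)
  out <- expand.grid(pampa = pam_ids, biological = bio_ids,
                     stringsAsFactors = FALSE)
  out$dprime <- m[cbind(out$biological, out$pampa)]
  out$emulates <- out$dprime <= threshold
  out <- out[order(match(out$biological, bio_ids), out$dprime), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("biological", "pampa", "dprime", "emulates")]
}

#' Coefficient polygons for a radial plot
#'
#' Returns each system's `(e, s, a, b, v)` values on a fixed axis
#' order, ready for radial plotting by any graphics front end.
#'
#' @param systems data frame of systems.
#' @return A data frame with columns `system_id`, `axis` (factor with
#'   levels e, s, a, b, v in fixed order) and `value`.
#' @export
radial_plot_data <- function(systems) {
  validate_systems(systems)
  axes <- c("e", "s", "a", "b", "v")
  out <- data.frame(
    system_id = rep(as.character(systems$system_id), each = length(axes)),
    axis = factor(rep(axes, times = nrow(systems)), levels = axes),
    value = as.vector(t(as.matrix(systems[, axes]))),
    stringsAsFactors = FALSE)
  out
}
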